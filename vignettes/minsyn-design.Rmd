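---
title: "Designing and scoring minimal synthetic plant promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring minimal synthetic plant promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minsynr)
```

## The problem

Plant synthetic biology needs suites of short promoters of graded, predictable
strength. Natural constitutive promoters (CaMV35S, MMV, *AtuNOS* and the like)
are kilobases long and their functional content is only partly charted.
`minsynr` implements a design pipeline for *minimal synthetic promoters*
(MinSyns): short sequences built from a catalogue of candidate cis-regulatory
elements (CREs) excised from natural constitutive promoters, assembled under a
fixed architecture, scored for expected strength, and audited for binding
sites created by accident at segment junctions.

The pipeline has five computational stages, each usable on its own:

1. **Scan** promoters for candidate transcription-factor binding sites
   (TFBSs) with position weight matrices at an exact p-value threshold.
2. **Dissect** promoters in silico: candidate-CRE maps, presence/absence
   matrices across a promoter panel, and deletion / relocation variants.
3. **Generate** MinSyn libraries by stochastic assembly from a CRE pool.
4. **Score** each design with a per-base strength model and calibrate the
   score against measured expression.
5. **Audit** assembled sequences for unintended TFBSs.

## Motif scanning with exact p-values

A motif is a position probability matrix (PPM) over A,C,G,T. Scores are
log-odds in bits against a zero-order background (uniform by default, the
conventional choice when no genome-derived composition is available; a
sequence-derived composition can be supplied and will shift marginal calls
in a presence/absence map). A pseudocount (default `1e-3`) is folded into
every PPM cell before renormalization so no score is `-Inf`.

The scan threshold for a target p-value (default `1e-4`, the conventional
single-motif threshold) is computed *exactly*: each log-odds entry is rounded
onto a fixed grid (1/1000 bit; the grid is part of the contract, so a
brute-force enumeration over all 4^W words reproduces the threshold bit for
bit, which is how the test suite checks it), and the null score distribution
is obtained by dynamic-programming convolution of the per-position score
distributions. The threshold is the smallest attained grid score whose
survival probability is at most p.

Numerical corner cases are part of the contract:

* If p is below the p-value of the best possible word (for example any
  width-6 motif under a uniform background at p = 1e-4, since 4^-6 > 1e-4),
  the threshold is set one grid step above the maximum score, a message is
  logged, and the scan returns no hits.
* Windows containing N are skipped rather than scored with ambiguity codes.
* Both strands are scanned; minus-strand hits are reported in forward
  0-based half-open coordinates. All overlapping hits are reported — no
  greedy masking, matching a candidate-mapping (rather than peak-calling)
  use of the scanner.

```{r scan}
m <- new_motif("demo", matrix(c(
  0.94, 0.02, 0.02, 0.02,
  0.02, 0.02, 0.02, 0.94,
  0.02, 0.02, 0.94, 0.02,
  0.94, 0.02, 0.02, 0.02,
  0.02, 0.94, 0.02, 0.02,
  0.02, 0.02, 0.94, 0.02,
  0.02, 0.02, 0.02, 0.94), nrow = 4))
threshold_for_pvalue(m, background_model(), p = 1e-3)
scan_sequence(paste0("CCCCC", motif_consensus(m), "CCCCC"), m, p = 1e-3)
```

## Promoter dissection

`annotate_promoter()` maps hits back onto a promoter and merges overlapping
same-family hits into candidate CRE regions (the merge policy for overlapping
candidates is not dictated by the data; merging per family is this package's
choice and is configurable through the `families` argument).
`presence_matrix()` tabulates which motif families occur in which promoters
of a panel. `deletion_variant()` excises a region cleanly;
`relocation_variant()` moves it so its 3' edge sits a slot-defined distance
upstream of the TATA box:

* `proximal` — a fixed gap, default 10 bp;
* `mid` — half of the maximum attainable gap after excision;
* `distal` — the region moves to the 5' end of the promoter.

The exact distal/mid/proximal coordinates used for the published CaMV35S,
MMV and *AtuNOS* variants are not on record; these defaults are declared,
configurable conventions. Relocation conserves sequence length and base
composition; deletion shortens by exactly the region length. The package
predicts nothing about the expression consequence of a dissection variant —
that is an experimental readout; the strength model below applies to MinSyn
designs only.

## The MinSyn architecture and the generator

Every MinSyn is

```
prefix(19) . (spacer . CRE)^N . TATATAA . core(43)
```

with N drawn uniformly from 3..10, each spacer an independent random
sequence of uniform length 5..30 bases, and the N CREs drawn from the pool
uniformly *without replacement*, inserted forward-strand in the drawn order.
A default library holds 1000 designs and is reproducible byte-for-byte from
(pool, seed).

Decisions the architecture description leaves open, fixed here as package
conventions:

* **One spacer per CRE iteration** (rather than a single random block for
  the whole variable region): gives variable regions of variable length and
  keeps each CRE's local context random.
* **Spacer precedes its CRE**, so the last CRE abuts the TATA box — the
  position where CRE proximity matters most.
* The 19 bp prefix is re-randomized per design (configurable by fixing the
  seed and assembling manually if a shared prefix is wanted).
* Random segments are i.i.d. bases at a configurable GC fraction
  (default 0.5).
* The literal 43 bp core downstream of the TATA box is construct-specific;
  the package ships a fixed synthetic default
  (`generator_config()$core_seq`) and any 43 bp sequence can be supplied.

`build_orthogonal_minsyn()` builds the companion architecture in which the
variable region is k copies of one synthetic-TF binding site separated by a
fixed short spacer, for promoter series whose output tracks binding-site
count.

```{r generate}
fx <- generate_fixtures()     # synthetic motifs, promoters, pool, measurements
fx$pool
lib <- generate_library(fx$pool, generator_config(rng_seed = 20))
length(lib$designs)
```

## The strength model

Each base of an assembled design receives a score; the design's raw score is
the per-base sum divided by the total length.

* Bases in GENERIC CREs score `s_generic` (default 1).
* Bases in C-CREs — the element common to the constitutive pathogen
  promoters, in two flavours: predicted to bind TGA bZIP factors directly,
  or not — score `s_ccre` (default 2) times a proximity weight.
* The proximity weight is 1 out to a class plateau — **60 bp** from the TATA
  box for TGA-binding C-CREs, **130 bp** for non-TGA C-CREs — then falls
  linearly to 0 over `decay_span` (default 70) bases.
* If a design carries two or more C-CREs, bases strictly between the two
  outermost C-CREs add `s_between` (default 0.5) times the proximity weight
  of the between-region midpoint (on the TGA plateau schedule) — a
  cooperativity term for CRE combinations.
* If the most TATA-proximal CRE sits more than **50 bp** from the TATA box,
  the summed score is multiplied by a penalty falling linearly from 1 to 0
  over `decay_span` bases.

The three distances (60, 130, 50 bp) are empirically grounded breakpoints
and are the model's load-bearing constants. The per-base score values and
the linear decay shape are *not* published; the defaults above are declared
stand-ins, all configurable, chosen so that C-CREs dominate generic CREs
(2:1) and the cooperative term is secondary (0.5). Conclusions that depend
on the exact score values should be drawn with calibrated data.

Raw scores are mapped to predicted expression by a single scalar fitted by
least squares through the origin, `k = sum(x*y)/sum(x^2)` — one "numerator",
not slope plus intercept, so a design with raw score 0 (e.g. the zero-CRE
control) always predicts 0:

```{r calibrate}
cal <- calibrate(strength_model(),
                 data.frame(raw_score = fx$measured$raw_score,
                            measured = fx$measured$measured))
cal$diagnostics$calibration_k
cal$diagnostics$r_squared
man <- score_library(lib, cal$model)
head(man[, c("design_id", "n_cre", "raw_score", "predicted_strength")], 3)
```

With a pool of mostly generic CREs and few C-CREs (the fixture pool mirrors
that composition: 2 TGA C-CREs, 1 non-TGA, 12 generic), the library's
predicted-strength distribution is right-skewed — most designs are predicted
weak:

```{r skew}
c(median = median(man$predicted_strength),
  mean = mean(man$predicted_strength))
```

## The junction audit

Concatenating spacers and CREs can create binding sites that were never in
the pool. `audit_design()` rescans the assembled sequence and classifies
every hit: **intended** if it lies wholly inside a CRE segment *and* matches
a motif that CRE is annotated to bind; everything else is **unintended**,
with the subset crossing a segment boundary reported as **junction** hits.
A hit of a *different* motif inside a CRE still counts as unintended — a
deliberately strict rule, since the audit's purpose is to explain designs
whose measured strength deviates from prediction. No multiple-testing
correction is applied across the audit scan (it mirrors the single-threshold
scan that built the pool). The audit verdict is `flagged` iff at least one
unintended hit exists.

```{r audit}
rep1 <- audit_design(lib$designs[[1]], fx$motifs)
rep1
```

## What the synthetic fixtures do and do not show

`generate_fixtures()` builds sharp PWMs (consensus probability 0.94),
promoters with planted motif instances at recorded coordinates, a pool with
the study-like class composition, and a measured-strength table simulated as
`k * raw_score + Gaussian noise` (k = 3, sd = 0.05, 24 designs — the size of
a typical tested panel). Motif widths default to 7–10 because a consensus
word can only attain p = 1e-4 under a uniform background when 4^-W <= 1e-4,
i.e. W >= 7.

Passing tests on these fixtures demonstrate that the machinery is correct:
thresholds match exhaustive enumeration, planted sites are recovered,
calibration recovers a known scalar, generated libraries obey the
architecture and its sampling distributions. They do **not** validate the
strength model against biology: real promoters have correlated motif
content, chromatin context and TF expression patterns that i.i.d. random
sequence does not emulate, and the measured-strength fixture is generated
*by the model itself* plus noise, so calibration tests are
parameter-recovery checks, not accuracy claims. Predictive accuracy on real
designs can only be established with measured expression data for the actual
pool.

## Problem sizes and numerics

The test suite and examples use the scales at which every check is exact or
statistically stable: exhaustive scanner oracles at motif widths <= 6
(4^6 = 4096 words), 200 bp random sequences for hit-set equality, libraries
of 1000 designs for architecture and skew checks, 4000 designs for
goodness-of-fit on the N and spacer-length distributions, and 200 replicates
of 50 noisy points for calibration recovery. The score grid is 1/1000 bit —
fine enough that discretization never reorders realistic word scores, coarse
enough that the DP table stays small (about 10^4 grid cells per position-row
at default pseudocount). Ties at the p-value boundary are compared with a
1e-12 relative slack so that summation order cannot flip a threshold.

## Known limitations

* CREs are inserted forward-strand only; reverse-orientation insertion is
  not modelled.
* The strength model's per-base constants are stand-ins (above); only the
  60/130/50 bp breakpoints are empirically grounded.
* The audit reports unintended sites but does not judge whether the bound
  TF would activate or repress — too few plant TF–DNA interactions are
  functionally characterized to automate that call.
* No q-value/FDR correction across scan hits; the scanner is a candidate
  mapper, not a discovery tool.
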