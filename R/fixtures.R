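# Synthetic fixture generator. Emulates the structure of the real inputs —
# a PWM library, promoter sequences carrying planted motif instances at known
# coordinates, a CRE pool with the study's class composition (two TGA-binding
# C-CREs, one non-TGA C-CRE, a dozen generic CREs), and a measured-strength
# table generated from the strength model plus Gaussian noise — so that every
# pipeline stage can be tested against planted ground truth.

#' Fixture specification
#'
#' @param n_motifs number of generic planted motifs.
#' @param width_min,width_max motif width range (>= 4; defaults 7..10 so a
#'   consensus word can pass p = 1e-4 under a uniform background, which
#'   requires 4^-W <= 1e-4, i.e. W >= 7).
#' @param n_promoters,promoter_length promoter panel dimensions.
#' @param planted_per_promoter motif instances planted per promoter.
#' @param n_generic,n_tga,n_nontga CRE pool class composition (defaults 12,
#'   2, 1 — the study's pool structure).
#' @param n_measured rows in the measured-strength table (default 24, the
#'   size of a tested MinSyn panel).
#' @param true_k ground-truth calibration scalar for the measured table.
#' @param noise_sd Gaussian noise on measured strengths.
#' @param rng_seed seed; fixtures are byte-identical under a fixed seed.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_motifs = 5L, width_min = 7L, width_max = 10L,
                         n_promoters = 3L, promoter_length = 300L,
                         planted_per_promoter = 2L,
                         n_generic = 12L, n_tga = 2L, n_nontga = 1L,
                         n_measured = 24L, true_k = 3.0, noise_sd = 0.05,
                         rng_seed = 42L) {
  if (width_min < 4L) stop("motif widths must be >= 4")
  if (width_max > promoter_length)
    stop("motifs longer than the promoters cannot be planted")
  structure(as.list(environment()), class = "fixture_spec")
}

#' @keywords internal
.sharp_motif <- function(id, consensus, sharpness = 0.94) {
  W <- nchar(consensus)
  ppm <- matrix((1 - sharpness) / 3, nrow = 4, ncol = W,
                dimnames = list(DNA_BASES, NULL))
  idx <- match(strsplit(consensus, "")[[1]], DNA_BASES)
  ppm[cbind(idx, seq_len(W))] <- sharpness
  new_motif(id, ppm, source = "synthetic")
}

#' Generate synthetic fixtures
#'
#' @param spec a \code{fixture_spec}.
#' @return list with elements \code{motifs} (generic planted motifs plus one
#'   dedicated motif per C-CRE), \code{promoters} (named character),
#'   \code{planted} (data.frame sequence_id, motif_id, start, end),
#'   \code{pool} (a \code{cre_pool}; CRE sequences are motif consensus words
#'   and motif_ids point at the matching motif), \code{measured} (data.frame
#'   design_id, raw_score, measured), \code{true_k}.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)

  widths <- vapply(seq_len(spec$n_motifs), function(i)
    .sample_int(spec$width_min, spec$width_max), integer(1))
  motifs <- lapply(seq_len(spec$n_motifs), function(i)
    .sharp_motif(sprintf("motif%02d", i), random_dna(widths[i])))

  # dedicated motifs for the C-CREs: TGA C-CREs carry the TGACG bZIP core
  n_cc <- spec$n_tga + spec$n_nontga
  cc_motifs <- lapply(seq_len(n_cc), function(i) {
    w <- .sample_int(max(spec$width_min, 9L), max(spec$width_max, 9L))
    cons <- if (i <= spec$n_tga)
      paste0(random_dna(2), "TGACG", random_dna(w - 7))
    else random_dna(w)
    .sharp_motif(sprintf("ccre_motif%02d", i), cons)
  })
  motifs <- c(motifs, cc_motifs)

  promoters <- character(spec$n_promoters)
  names(promoters) <- sprintf("prom%02d", seq_len(spec$n_promoters))
  planted <- list()
  for (j in seq_len(spec$n_promoters)) {
    seq <- random_dna(spec$promoter_length)
    used <- integer(0)
    for (k in seq_len(spec$planted_per_promoter)) {
      m <- motifs[[.sample_int(1L, spec$n_motifs)]]
      W <- motif_width(m)
      repeat {
        s <- .sample_int(0L, spec$promoter_length - W)
        if (!any(abs(s - used) < spec$width_max + 1L)) break
      }
      used <- c(used, s)
      substr(seq, s + 1, s + W) <- motif_consensus(m)
      planted[[length(planted) + 1L]] <- data.frame(
        sequence_id = names(promoters)[j], motif_id = m$id,
        start = s, end = s + W, stringsAsFactors = FALSE)
    }
    promoters[j] <- seq
  }
  planted <- do.call(rbind, planted)

  gen_idx <- rep(seq_len(spec$n_motifs), length.out = spec$n_generic)
  classes <- c(rep("C_CRE_TGA", spec$n_tga),
               rep("C_CRE_NON_TGA", spec$n_nontga),
               rep("GENERIC", spec$n_generic))
  which_motif <- c(seq_len(n_cc) + spec$n_motifs, gen_idx)
  records <- data.frame(
    cre_id = sprintf("cre%02d", seq_along(classes)),
    cre_class = classes,
    sequence = vapply(which_motif, function(i)
      motif_consensus(motifs[[i]]), character(1)),
    source_promoter = "synthetic",
    flank5 = vapply(seq_along(classes), function(i) random_dna(10),
                    character(1)),
    flank3 = vapply(seq_along(classes), function(i) random_dna(10),
                    character(1)),
    motif_ids = vapply(which_motif, function(i) motifs[[i]]$id, character(1)),
    stringsAsFactors = FALSE)
  pool <- cre_pool(records, provenance = "synthetic fixture pool",
                   version = paste0("fixture-", spec$rng_seed))

  cfg <- generator_config(library_size = spec$n_measured,
                          rng_seed = spec$rng_seed)
  lib <- generate_library(pool, cfg)
  model <- strength_model()
  x <- vapply(lib$designs, raw_score, numeric(1), model = model)
  measured <- data.frame(
    design_id = vapply(lib$designs, `[[`, "", "design_id"),
    raw_score = x,
    measured = pmax(0, spec$true_k * x + rnorm(length(x), 0, spec$noise_sd)),
    stringsAsFactors = FALSE)

  list(motifs = motifs, promoters = promoters, planted = planted,
       pool = pool, measured = measured, true_k = spec$true_k)
}

#' Write fixtures to disk
#'
#' Emits the motif library (MEME minimal format), promoter FASTA, planted
#' coordinates TSV, pool TSV and measured-strength TSV into a directory.
#'
#' @param fixtures result of \code{\link{generate_fixtures}}.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of the paths written.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    motifs = file.path(dir, "motifs.meme"),
    promoters = file.path(dir, "promoters.fasta"),
    planted = file.path(dir, "planted.tsv"),
    pool = file.path(dir, "pool.tsv"),
    measured = file.path(dir, "measured.tsv"))
  write_meme_motifs(fixtures$motifs, paths["motifs"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixtures$promoters), paths["promoters"])
  write.table(fixtures$planted, paths["planted"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  save_pool(fixtures$pool, paths["pool"])
  write.table(fixtures$measured[, c("design_id", "measured")],
              paths["measured"], sep = "\t", quote = FALSE,
              row.names = FALSE,
              col.names = c("design_id", "normalized_expression"))
  invisible(paths)
}
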