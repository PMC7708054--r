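# PWM scanning with exact score-distribution p-values.
#
# Log-odds entries are rounded onto a fixed grid (default 1/1000 bit) and the
# null distribution of the window score under the background model is
# computed exactly on that grid by positionwise convolution. Thresholds and
# per-hit p-values are exact with respect to the discretized matrix.

#' @keywords internal
.discretized_log_odds <- function(motif, bg, granularity) {
  round(log_odds(motif, bg) / granularity)
}

# Exact null distribution of the discretized window score.
# Returns list(base = minimum attainable integer score,
#              probs = P(score = base + i - 1) for i = 1..span)
#' @keywords internal
.score_distribution <- function(ilo, bg) {
  bgv <- as.numeric(bg)
  mins <- apply(ilo, 2, min)
  maxs <- apply(ilo, 2, max)
  d <- 1
  base <- 0
  for (j in seq_len(ncol(ilo))) {
    nd <- numeric(length(d) + (maxs[j] - mins[j]))
    for (b in 1:4) {
      sh <- ilo[b, j] - mins[j]
      idx <- seq_along(d) + sh
      nd[idx] <- nd[idx] + d * bgv[b]
    }
    d <- nd
    base <- base + mins[j]
  }
  list(base = base, probs = d)
}

# Threshold + survival lookup for one motif. Threshold is the smallest
# *attained* grid score whose exact p-value is <= p (with a 1e-12 relative
# slack against accumulation-order noise); if no word attains p, threshold is
# one grid step above the maximum score, so a scan yields no hits.
#' @keywords internal
.scan_table <- function(motif, bg, p, granularity) {
  ilo <- .discretized_log_odds(motif, bg, granularity)
  dist <- .score_distribution(ilo, bg)
  surv <- rev(cumsum(rev(dist$probs)))
  ok <- which(surv <= p * (1 + 1e-12) & dist$probs > 0)
  if (length(ok)) {
    t_int <- dist$base + ok[1] - 1
    attainable <- TRUE
  } else {
    t_int <- dist$base + length(dist$probs)  # max score + one grid step
    attainable <- FALSE
  }
  list(ilo = ilo, base = dist$base, surv = surv, t_int = t_int,
       attainable = attainable, granularity = granularity)
}

#' @keywords internal
.pvalue_lookup <- function(tab, s_int) {
  i <- s_int - tab$base + 1L
  i <- pmin(pmax(i, 1L), length(tab$surv))
  tab$surv[i]
}

#' Exact score threshold for a target p-value
#'
#' Computes the smallest attainable window score \code{t} (on the declared
#' discretization grid, in bits) such that the probability of a random
#' background word scoring at least \code{t} is no greater than \code{p}.
#' The null distribution is computed exactly by dynamic-programming
#' convolution of the per-position discretized log-odds scores.
#'
#' If \code{p} is smaller than the p-value of the best possible word, no
#' score qualifies; the returned threshold is the maximum score plus one grid
#' step (so a scan at this threshold yields no hits) and a message is logged.
#'
#' @param motif a \code{minsyn_motif}.
#' @param bg a \code{background_model}.
#' @param p target p-value, in (0, 1).
#' @param granularity score grid in bits (default 0.001).
#' @return threshold score in bits (a grid multiple).
#' @export
threshold_for_pvalue <- function(motif, bg = background_model(), p,
                                 granularity = 0.001) {
  if (!(p > 0 && p < 1) && p != 1) stop("p must be in (0, 1]")
  tab <- .scan_table(motif, bg, p, granularity)
  if (!tab$attainable)
    message("motif '", motif$id, "': no word attains p <= ", p,
            "; threshold set above the maximum score")
  tab$t_int * granularity
}

#' @keywords internal
.empty_hits <- function() {
  data.frame(motif_id = character(), sequence_id = character(),
             start = integer(), end = integer(), strand = character(),
             score = numeric(), p_value = numeric(),
             stringsAsFactors = FALSE)
}

#' @keywords internal
.seq_to_index <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

# Integer window scores for one strand; NA where the window contains N.
#' @keywords internal
.window_scores <- function(idx, ilo) {
  W <- ncol(ilo)
  n <- length(idx) - W + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(W))
    s <- s + ilo[cbind(idx[j:(j + n - 1L)], j)]
  s
}

#' Scan a DNA sequence for motif hits
#'
#' Scores every window of each motif's width on both strands against the
#' discretized log-odds matrix and reports windows whose exact p-value under
#' the background model is at most \code{p}. Windows containing N are
#' skipped. Minus-strand hits are reported in forward coordinates (0-based,
#' half-open). All overlapping hits are reported; no masking is applied.
#'
#' @param seq DNA character string over A, C, G, T, N.
#' @param motifs a \code{minsyn_motif} or list of them.
#' @param bg a \code{background_model}.
#' @param p p-value threshold (default 1e-4, the conventional single-motif
#'   scan threshold).
#' @param granularity score grid in bits.
#' @param sequence_id identifier recorded on the hits.
#' @return data.frame with columns motif_id, sequence_id, start, end, strand,
#'   score (bits), p_value; sorted by (sequence_id, start, motif_id, strand).
#' @export
scan_sequence <- function(seq, motifs, bg = background_model(), p = 1e-4,
                          granularity = 0.001, sequence_id = "seq") {
  if (inherits(motifs, "minsyn_motif")) motifs <- list(motifs)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
  L <- nchar(seq)
  idx_f <- .seq_to_index(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  idx_r <- .seq_to_index(rc)
  out <- list()
  for (m in motifs) {
    W <- ncol(m$ppm)
    if (W > L) next
    tab <- .scan_table(m, bg, p, granularity)
    for (strand in c("+", "-")) {
      idx <- if (strand == "+") idx_f else idx_r
      s <- .window_scores(idx, tab$ilo)
      pass <- which(!is.na(s) & s >= tab$t_int)
      if (!length(pass)) next
      st <- pass - 1L                       # 0-based start on scanned strand
      if (strand == "-") st <- L - (st + W) # map back to forward coordinates
      out[[length(out) + 1L]] <- data.frame(
        motif_id = m$id, sequence_id = sequence_id,
        start = st, end = st + W, strand = strand,
        score = s[pass] * granularity,
        p_value = .pvalue_lookup(tab, s[pass]),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else .empty_hits()
  hits <- hits[order(hits$sequence_id, hits$start, hits$motif_id,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a set of sequences
#'
#' @param seqs named character vector, \code{Biostrings::DNAStringSet}, or
#'   path to a FASTA file (multi-record, wrapped lines supported).
#' @inheritParams scan_sequence
#' @return combined hit data.frame across all records.
#' @export
scan_set <- function(seqs, motifs, bg = background_model(), p = 1e-4,
                     granularity = 0.001) {
  seqs <- .as_named_seqs(seqs)
  hits <- lapply(names(seqs), function(id)
    scan_sequence(seqs[[id]], motifs, bg = bg, p = p,
                  granularity = granularity, sequence_id = id))
  hits <- do.call(rbind, c(hits, list(.empty_hits())))
  hits <- hits[order(hits$sequence_id, hits$start, hits$motif_id,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @keywords internal
.as_named_seqs <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- Biostrings::readDNAStringSet(seqs)
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(seqs))
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  as.list(seqs)
}
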