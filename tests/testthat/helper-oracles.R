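# Brute-force oracles, independent of the package's DP/scanner code paths:
# enumerate every W-mer (or window) and score it directly against the
# discretized log-odds matrix.

# integer (grid-unit) scores and background probabilities of all 4^W words
bf_word_table <- function(motif, bg, granularity = 0.001) {
  ilo <- round(log_odds(motif, bg) / granularity)
  W <- ncol(ilo)
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  score <- unname(rowSums(vapply(seq_len(W), function(j) ilo[words[, j], j],
                                 numeric(nrow(words)))))
  prob <- apply(matrix(as.numeric(bg)[words], nrow(words), W), 1, prod)
  list(score = score, prob = prob, ilo = ilo, W = W)
}

# smallest attained integer score t with P(score >= t) <= p; max+1 if none
bf_threshold_int <- function(motif, bg, p, granularity = 0.001) {
  wt <- bf_word_table(motif, bg, granularity)
  o <- order(wt$score, decreasing = TRUE)
  s <- wt$score[o]
  cp <- cumsum(wt$prob[o])
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each distinct score
  cand <- s[last]                           # distinct scores, decreasing
  surv <- cp[last]                          # survival at each distinct score
  ok <- which(surv <= p * (1 + 1e-12))
  if (length(ok)) cand[max(ok)] else max(s) + 1L
}

bf_threshold <- function(motif, bg, p, granularity = 0.001) {
  bf_threshold_int(motif, bg, p, granularity) * granularity
}

# enumerate every window on both strands; windows with N are skipped
bf_scan <- function(seq, motifs, bg, p, granularity = 0.001,
                    sequence_id = "seq") {
  if (inherits(motifs, "minsyn_motif")) motifs <- list(motifs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (m in motifs) {
    ilo <- round(log_odds(m, bg) / granularity)
    W <- ncol(ilo)
    L <- nchar(seq)
    if (W > L) next
    t_int <- bf_threshold_int(m, bg, p, granularity)
    wt <- bf_word_table(m, bg, granularity)
    surv_of <- function(s) sum(wt$prob[wt$score >= s])
    chars <- strsplit(toupper(seq), "")[[1]]
    for (s0 in 0:(L - W)) {
      win <- chars[(s0 + 1):(s0 + W)]
      if (any(!win %in% names(comp))) next
      for (strand in c("+", "-")) {
        w <- if (strand == "+") win else rev(unname(comp[win]))
        sc <- sum(ilo[cbind(match(w, c("A", "C", "G", "T")), seq_len(W))])
        if (sc >= t_int)
          out[[length(out) + 1L]] <- data.frame(
            motif_id = m$id, sequence_id = sequence_id,
            start = s0, end = s0 + W, strand = strand,
            score = sc * granularity, p_value = surv_of(sc),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(motif_id = character(), sequence_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$sequence_id, hits$start, hits$motif_id,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
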