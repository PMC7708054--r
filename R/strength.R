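# Per-base promoter-strength model. Bases inside CREs score; bases inside
# C-CREs score higher, down-weighted by distance from the TATA box with a
# class-specific plateau (TGA-binding C-CREs act at full weight within 60 bp
# of the TATA box, non-TGA C-CREs within 130 bp). When a design carries two
# or more C-CREs, the bases between the two outermost C-CREs pick up an
# extra cooperative term weighted by the distance of the region midpoint to
# the TATA box. A design-level penalty applies when the most TATA-proximal
# CRE sits more than 50 bp from the TATA box. The mean per-base score is
# mapped to predicted expression by a single calibration scalar fitted on
# measured promoter strengths.

C_CRE_CLASSES <- c("C_CRE_TGA", "C_CRE_NON_TGA")

#' Promoter strength model
#'
#' @param s_generic per-base score inside GENERIC CREs (default 1.0).
#' @param s_ccre per-base score inside C-CREs before proximity weighting
#'   (default 2.0; C-CREs carry the strongest effect).
#' @param s_between per-base score added between the two outermost C-CREs
#'   (default 0.5).
#' @param plateau_tga distance (bp) up to which a TGA-binding C-CRE keeps
#'   full weight (default 60).
#' @param plateau_nontga same for non-TGA C-CREs (default 130).
#' @param generic_gap_limit largest penalty-free gap (bp) between the most
#'   TATA-proximal CRE and the TATA box (default 50).
#' @param decay_span distance (bp) over which a weight or penalty falls
#'   linearly from 1 to 0 past its plateau (default 70).
#' @param calibration_k scalar mapping mean per-base score to predicted
#'   strength; NULL until fitted by \code{\link{calibrate}}.
#' @return object of class \code{strength_model}.
#' @export
strength_model <- function(s_generic = 1.0, s_ccre = 2.0, s_between = 0.5,
                           plateau_tga = 60, plateau_nontga = 130,
                           generic_gap_limit = 50, decay_span = 70,
                           calibration_k = NULL) {
  if (any(c(s_generic, s_ccre, s_between) < 0)) stop("scores must be >= 0")
  if (any(c(plateau_tga, plateau_nontga, generic_gap_limit) < 0))
    stop("plateaus must be >= 0")
  if (decay_span <= 0) stop("decay_span must be > 0")
  if (!is.null(calibration_k) && calibration_k <= 0)
    stop("calibration_k must be > 0")
  structure(list(s_generic = s_generic, s_ccre = s_ccre,
                 s_between = s_between, plateau_tga = plateau_tga,
                 plateau_nontga = plateau_nontga,
                 generic_gap_limit = generic_gap_limit,
                 decay_span = decay_span, calibration_k = calibration_k),
            class = "strength_model")
}

#' TATA-proximity weight for a C-CRE
#'
#' Piecewise-linear weight: 1 up to the class plateau (60 bp for TGA-binding
#' C-CREs, 130 bp for non-TGA), falling linearly to 0 over the next
#' \code{decay_span} bases, 0 beyond.
#'
#' @param distance distance in bases from the CRE's TATA-proximal (3') edge
#'   to the first base of the TATA box; 0 = abutting. Vectorized.
#' @param cre_class "C_CRE_TGA" or "C_CRE_NON_TGA"; GENERIC CREs are not
#'   proximity-weighted (the gap rule applies at design level) and raise an
#'   error.
#' @param model a \code{strength_model}.
#' @return weight(s) in [0, 1].
#' @export
proximity_weight <- function(distance, cre_class, model = strength_model()) {
  if (any(distance < 0)) stop("distance must be >= 0")
  if (length(cre_class) != 1L || !cre_class %in% C_CRE_CLASSES)
    stop("proximity weighting applies only to C-CRE classes, got '",
         paste(cre_class, collapse = ","), "'")
  plateau <- if (cre_class == "C_CRE_TGA") model$plateau_tga
             else model$plateau_nontga
  pmin(1, pmax(0, 1 - (distance - plateau) / model$decay_span))
}

#' Raw (uncalibrated) design score
#'
#' Assigns every base a score — 0 by default, \code{s_generic} inside GENERIC
#' CREs, \code{s_ccre} times the class proximity weight inside C-CREs, plus
#' \code{s_between} times a midpoint proximity weight (TGA schedule) for
#' bases strictly between the two outermost C-CREs — applies the
#' first-CRE-to-TATA gap penalty to the summed score, and divides by the
#' total number of bases.
#'
#' @param design a \code{minsyn_design}.
#' @param model a \code{strength_model}.
#' @return mean per-base score (>= 0).
#' @export
raw_score <- function(design, model = strength_model()) {
  asm <- assemble_sequence(design)
  feats <- asm$features
  L <- nchar(asm$sequence)
  tata <- feats[feats$kind == "tata", , drop = FALSE]
  if (nrow(tata) != 1L) stop("design must contain exactly one TATA segment")
  tata_start <- tata$start[1]
  cre <- feats[feats$kind == "cre", , drop = FALSE]
  scores <- numeric(L)
  for (i in seq_len(nrow(cre))) {
    span <- (cre$start[i] + 1L):cre$end[i]
    d <- tata_start - cre$end[i]
    if (d < 0) stop("CRE '", cre$cre_id[i], "' downstream of the TATA box")
    cls <- cre$cre_class[i]
    scores[span] <- scores[span] +
      if (cls %in% C_CRE_CLASSES)
        model$s_ccre * proximity_weight(d, cls, model)
      else model$s_generic
  }
  cc <- cre[cre$cre_class %in% C_CRE_CLASSES, , drop = FALSE]
  if (nrow(cc) >= 2L) {
    first <- cc[which.min(cc$start), ]   # outermost 5'
    last <- cc[which.max(cc$start), ]    # outermost 3' (TATA-proximal)
    if (last$start > first$end) {
      span <- (first$end + 1L):last$start
      mid <- (first$end + last$start) %/% 2
      d_mid <- tata_start - mid
      scores[span] <- scores[span] +
        model$s_between * proximity_weight(d_mid, "C_CRE_TGA", model)
    }
  }
  total <- sum(scores)
  if (nrow(cre)) {
    gap <- tata_start - max(cre$end)
    if (gap > model$generic_gap_limit)
      total <- total *
        max(0, 1 - (gap - model$generic_gap_limit) / model$decay_span)
  }
  total / L
}

#' Fit the calibration scalar against measured strengths
#'
#' Least squares through the origin: k = sum(x*y) / sum(x^2), the single
#' scalar that maps mean per-base score to normalized expression.
#'
#' @param model a \code{strength_model}.
#' @param pairs data.frame with columns \code{raw_score} and
#'   \code{measured} (normalized expression), >= 2 rows, raw scores not all
#'   zero.
#' @return list with \code{model} (calibration_k set) and \code{diagnostics}
#'   (n_points, calibration_k, r_squared of k*x against y, residuals
#'   data.frame).
#' @export
calibrate <- function(model, pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("raw_score", "measured") %in% names(pairs)))
    stop("pairs must have columns raw_score, measured")
  x <- pairs$raw_score; y <- pairs$measured
  if (length(x) < 2L) stop("need at least 2 calibration points")
  if (all(x == 0)) stop("cannot calibrate: all raw scores are zero")
  k <- sum(x * y) / sum(x^2)
  fitted <- k * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  model$calibration_k <- k
  list(model = model,
       diagnostics = list(
         n_points = length(x), calibration_k = k, r_squared = r2,
         residuals = data.frame(raw_score = x, measured = y,
                                fitted = fitted, residual = y - fitted)))
}

#' Predicted strength of a design
#'
#' @param design a \code{minsyn_design}.
#' @param model a calibrated \code{strength_model}.
#' @return predicted normalized expression, \code{calibration_k * raw_score}.
#' @export
predict_strength <- function(design, model) {
  if (is.null(model$calibration_k))
    stop("model is not calibrated; run calibrate() first")
  model$calibration_k * raw_score(design, model)
}

#' Score every design in a library
#'
#' @param library a \code{minsyn_library}.
#' @param model a \code{strength_model}; predictions are added only when it
#'   is calibrated.
#' @return manifest data.frame: design_id, n_cre, cre_ids (comma-separated,
#'   in insertion order), spacer_lengths, total_length, seed, raw_score, and
#'   predicted_strength when calibrated.
#' @export
score_library <- function(library, model = strength_model()) {
  rows <- lapply(library$designs, function(d) {
    asm <- assemble_sequence(d)
    segs <- d$segments
    data.frame(
      design_id = d$design_id, n_cre = d$n_cre,
      cre_ids = paste(segs$cre_id[segs$kind == "cre"], collapse = ","),
      spacer_lengths = paste(nchar(segs$text[segs$kind == "spacer"]),
                             collapse = ","),
      total_length = nchar(asm$sequence),
      seed = library$config$rng_seed,
      raw_score = raw_score(d, model),
      stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(model$calibration_k))
    manifest$predicted_strength <- model$calibration_k * manifest$raw_score
  manifest
}
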