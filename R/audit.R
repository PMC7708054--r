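# Junction-TFBS audit. Assembled designs can create binding sites that were
# never in the CRE pool — most often straddling the junction between a spacer
# and a CRE. The audit rescans the full assembled sequence and classifies
# every hit as intended (wholly inside a CRE segment and matching a motif
# that CRE is annotated to bind) or unintended; unintended hits crossing a
# segment boundary are reported separately as junction hits.

#' Audit a design for unintended binding sites
#'
#' @param design a \code{minsyn_design}.
#' @param motifs motif library to audit against.
#' @param bg a \code{background_model}.
#' @param p scan p-value threshold (default 1e-4).
#' @param granularity score grid in bits.
#' @return object of class \code{audit_report}: design_id, hits (all),
#'   intended, unintended, junction (subset of unintended overlapping a
#'   segment boundary), verdict ("clean" or "flagged").
#' @export
audit_design <- function(design, motifs, bg = background_model(), p = 1e-4,
                         granularity = 0.001) {
  asm <- assemble_sequence(design)
  segs <- design$segments
  feats <- asm$features
  hits <- scan_sequence(asm$sequence, motifs, bg = bg, p = p,
                        granularity = granularity,
                        sequence_id = design$design_id)
  cre <- which(feats$kind == "cre")
  intended <- logical(nrow(hits))
  for (i in cre) {
    expected <- .split_motif_ids(segs$motif_ids[i])
    inside <- hits$start >= feats$start[i] & hits$end <= feats$end[i]
    intended <- intended | (inside & hits$motif_id %in% expected)
  }
  boundaries <- feats$start[-1]     # internal junction positions
  crosses <- vapply(seq_len(nrow(hits)), function(j)
    any(boundaries > hits$start[j] & boundaries < hits$end[j]), logical(1))
  unintended <- hits[!intended, , drop = FALSE]
  structure(list(
    design_id = design$design_id,
    hits = hits,
    intended = hits[intended, , drop = FALSE],
    unintended = unintended,
    junction = hits[!intended & crosses, , drop = FALSE],
    verdict = if (nrow(unintended)) "flagged" else "clean"),
    class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("audit_report '", x$design_id, "': ", nrow(x$hits), " hits, ",
      nrow(x$intended), " intended, ", nrow(x$unintended), " unintended (",
      nrow(x$junction), " at junctions) -> ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Audit every design in a library
#' @param library a \code{minsyn_library}.
#' @inheritParams audit_design
#' @return list of \code{audit_report}, one per design.
#' @export
audit_library <- function(library, motifs, bg = background_model(), p = 1e-4,
                          granularity = 0.001) {
  lapply(library$designs, audit_design, motifs = motifs, bg = bg, p = p,
         granularity = granularity)
}
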