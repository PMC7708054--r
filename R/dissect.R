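# In-silico promoter dissection: candidate-CRE annotation of natural
# promoters, presence/absence matrices across a promoter panel, and the
# deletion / relocation variants used to test whether a CRE's contribution
# depends on its distance from the TATA box.

#' Annotate a promoter with candidate CREs
#'
#' Scans the promoter with the motif library and calls candidate CRE regions
#' by merging overlapping hits of the same motif family.
#'
#' @param sequence_id promoter identifier.
#' @param sequence promoter DNA string.
#' @param motifs list of \code{minsyn_motif}.
#' @param bg a \code{background_model}.
#' @param p scan p-value threshold.
#' @param tata_start 0-based index of the first base of the TATA box, or NA
#'   when not annotated (relocation variants then refuse).
#' @param families optional named character vector mapping motif_id to a
#'   family label; defaults to each motif being its own family.
#' @param granularity score grid in bits.
#' @return object of class \code{promoter_annotation} with elements
#'   sequence_id, sequence, tata_start, hits (data.frame), families,
#'   cre_regions (data.frame cre_id, family, start, end).
#' @export
annotate_promoter <- function(sequence_id, sequence, motifs,
                              bg = background_model(), p = 1e-4,
                              tata_start = NA, families = NULL,
                              granularity = 0.001) {
  if (!is.na(tata_start) && tata_start >= nchar(sequence))
    stop("tata_start outside the promoter")
  hits <- scan_sequence(sequence, motifs, bg = bg, p = p,
                        granularity = granularity,
                        sequence_id = sequence_id)
  ids <- vapply(motifs, `[[`, "", "id")
  if (is.null(families)) families <- stats::setNames(ids, ids)
  fam <- unname(families[hits$motif_id])
  regions <- .merge_family_regions(hits$start, hits$end, fam)
  structure(list(sequence_id = sequence_id, sequence = sequence,
                 tata_start = tata_start, hits = hits, families = families,
                 cre_regions = regions),
            class = "promoter_annotation")
}

# Merge overlapping same-family intervals; abutting intervals stay separate.
#' @keywords internal
.merge_family_regions <- function(start, end, family) {
  out <- data.frame(cre_id = character(), family = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (f in unique(family)) {
    i <- which(family == f)
    o <- order(start[i], end[i])
    s <- start[i][o]; e <- end[i][o]
    ms <- s[1]; me <- e[1]; sl <- integer(0); el <- integer(0)
    for (k in seq_along(s)[-1]) {
      if (s[k] < me) me <- max(me, e[k])
      else { sl <- c(sl, ms); el <- c(el, me); ms <- s[k]; me <- e[k] }
    }
    sl <- c(sl, ms); el <- c(el, me)
    out <- rbind(out, data.frame(
      cre_id = paste0(f, "_", seq_along(sl)), family = f,
      start = sl, end = el, stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat("promoter_annotation '", x$sequence_id, "' (", nchar(x$sequence),
      " bp): ", nrow(x$hits), " hits, ", nrow(x$cre_regions),
      " candidate CRE regions\n", sep = "")
  invisible(x)
}

#' Motif-family presence/absence matrix
#'
#' @param annotations list of \code{promoter_annotation}.
#' @param families optional character vector fixing column order; defaults to
#'   the union of family labels over the annotations' motif libraries.
#' @return logical matrix, rows = promoters (input order), columns = motif
#'   families; a cell is TRUE iff at least one hit of that family passed the
#'   scan threshold in that promoter.
#' @export
presence_matrix <- function(annotations, families = NULL) {
  if (!length(annotations)) stop("need at least one annotation")
  if (is.null(families))
    families <- unique(unlist(lapply(annotations, function(a)
      unname(a$families))))
  m <- t(vapply(annotations, function(a) {
    present <- unique(unname(a$families[a$hits$motif_id]))
    families %in% present
  }, logical(length(families))))
  if (length(families) == 1L) m <- matrix(m, ncol = 1L)
  rownames(m) <- vapply(annotations, `[[`, "", "sequence_id")
  colnames(m) <- families
  m
}

#' @keywords internal
.region_of <- function(ann, cre_id) {
  r <- ann$cre_regions[ann$cre_regions$cre_id == cre_id, , drop = FALSE]
  if (!nrow(r)) stop("unknown cre_id '", cre_id, "'")
  r[1, ]
}

#' Deletion variant of an annotated promoter
#'
#' Returns the promoter with the named CRE region excised cleanly (flanks
#' abutted, no scar).
#'
#' @param ann a \code{promoter_annotation}.
#' @param cre_id region identifier from \code{ann$cre_regions}.
#' @return variant DNA string, shorter than the input by the region length.
#' @export
deletion_variant <- function(ann, cre_id) {
  r <- .region_of(ann, cre_id)
  paste0(substr(ann$sequence, 1, r$start),
         substr(ann$sequence, r$end + 1, nchar(ann$sequence)))
}

#' Relocation variant of an annotated promoter
#'
#' Excises the named CRE region and re-inserts it so that its 3' edge sits a
#' slot-defined number of bases upstream of the TATA box. Total length is
#' conserved. Slots: \code{proximal} uses \code{proximal_gap}; \code{mid}
#' uses half of the maximum attainable gap; \code{distal} places the region
#' at the 5' end of the promoter (the maximum gap).
#'
#' @param ann a \code{promoter_annotation} with \code{tata_start} set; the
#'   region must lie entirely upstream of the TATA box.
#' @param cre_id region identifier.
#' @param slot one of "distal", "mid", "proximal".
#' @param proximal_gap gap (bases) used by the proximal slot (default 10).
#' @return variant DNA string of the same length as the input.
#' @export
relocation_variant <- function(ann, cre_id,
                               slot = c("distal", "mid", "proximal"),
                               proximal_gap = 10) {
  slot <- match.arg(slot)
  if (is.na(ann$tata_start)) stop("tata_start is not annotated")
  r <- .region_of(ann, cre_id)
  if (r$end > ann$tata_start)
    stop("region '", cre_id, "' is not upstream of the TATA box")
  len <- r$end - r$start
  deleted <- paste0(substr(ann$sequence, 1, r$start),
                    substr(ann$sequence, r$end + 1, nchar(ann$sequence)))
  t_d <- ann$tata_start - len     # TATA position after excision = max gap
  gap <- switch(slot,
                proximal = proximal_gap,
                mid = t_d %/% 2,
                distal = t_d)
  if (gap > t_d)
    stop("slot gap ", gap, " exceeds available upstream span ", t_d)
  region <- substr(ann$sequence, r$start + 1, r$end)
  i <- t_d - gap                  # insertion point (0-based) in 'deleted'
  paste0(substr(deleted, 1, i), region,
         substr(deleted, i + 1, nchar(deleted)))
}
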