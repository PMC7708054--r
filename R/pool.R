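# CRE pool: the sampling catalogue from which MinSyn variable regions are
# assembled. Three classes are distinguished: GENERIC candidate CREs, and two
# kinds of "common CRE" (C-CRE) — those predicted to bind TGA bZIP factors
# directly and those that are not.

CRE_CLASSES <- c("GENERIC", "C_CRE_TGA", "C_CRE_NON_TGA")

#' Construct a CRE pool
#'
#' @param records data.frame with columns cre_id, cre_class, sequence and
#'   optionally source_promoter, flank5, flank3, motif_ids (comma-separated
#'   motif identifiers expected to bind within the CRE).
#' @param provenance free-text description of where the pool came from.
#' @param version version tag.
#' @return object of class \code{cre_pool}.
#' @export
cre_pool <- function(records, provenance = "", version = "1") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("source_promoter", "flank5", "flank3", "motif_ids"))
    if (is.null(records[[col]])) records[[col]] <- character(nrow(records))
  records <- records[, c("cre_id", "cre_class", "sequence",
                         "source_promoter", "flank5", "flank3", "motif_ids")]
  records[] <- lapply(records, function(x) {
    x <- as.character(x); x[is.na(x)] <- ""; x
  })
  dup <- records$cre_id[duplicated(records$cre_id)]
  if (length(dup)) stop("duplicate cre_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(!records$cre_class %in% CRE_CLASSES)
  if (length(bad))
    stop("row ", bad[1], ": illegal class label '",
         records$cre_class[bad[1]], "' (expected ",
         paste(CRE_CLASSES, collapse = ", "), ")")
  for (col in c("sequence", "flank5", "flank3")) {
    bad <- which(grepl("[^ACGT]", records[[col]]) & nzchar(records[[col]]))
    if (length(bad))
      stop("row ", bad[1], ": non-DNA characters in ", col)
  }
  n <- nchar(records$sequence)
  if (any(n < 4 | n > 40))
    stop("CRE sequences must be 4-40 bp; offending id: ",
         records$cre_id[which(n < 4 | n > 40)[1]])
  structure(list(records = records, provenance = provenance,
                 version = version),
            class = "cre_pool")
}

#' @export
print.cre_pool <- function(x, ...) {
  cat("cre_pool of", nrow(x$records), "records (",
      paste(names(table(x$records$cre_class)),
            table(x$records$cre_class), collapse = ", "),
      ") version", x$version, "\n")
  invisible(x)
}

#' Number of records in a pool
#' @param pool a \code{cre_pool}.
#' @return integer count.
#' @export
pool_size <- function(pool) nrow(pool$records)

#' Build a CRE pool from scanner hits
#'
#' Excises each assigned hit region from its source promoter, capturing
#' native flanking sequence on both sides, and labels it with a CRE class.
#'
#' @param hits hit data.frame from \code{\link{scan_set}}.
#' @param assignments data.frame with columns cre_id, cre_class, sequence_id,
#'   start, end (0-based half-open, matching a hit region in that promoter)
#'   and optionally motif_ids; when motif_ids is absent it is filled with the
#'   ids of the hits matching the region.
#' @param promoter_seqs named character vector / DNAStringSet / FASTA path.
#' @param flank number of native flanking bases captured each side
#'   (default 10; truncated at promoter bounds).
#' @param provenance,version stored on the pool.
#' @return a \code{cre_pool}.
#' @export
build_pool <- function(hits, assignments, promoter_seqs, flank = 10,
                       provenance = "built from hits", version = "1") {
  seqs <- .as_named_seqs(promoter_seqs)
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (!nrow(assignments))
    return(cre_pool(data.frame(cre_id = character(), cre_class = character(),
                               sequence = character()),
                    provenance = provenance, version = version))
  recs <- lapply(seq_len(nrow(assignments)), function(i) {
    a <- assignments[i, ]
    seq <- seqs[[a$sequence_id]]
    if (is.null(seq))
      stop("record '", a$cre_id, "': unknown promoter '", a$sequence_id, "'")
    L <- nchar(seq)
    if (a$start < 0 || a$end > L || a$start >= a$end)
      stop("record '", a$cre_id, "': region [", a$start, ", ", a$end,
           ") outside promoter '", a$sequence_id, "' (length ", L, ")")
    m <- hits$sequence_id == a$sequence_id &
      hits$start == a$start & hits$end == a$end
    if (!any(m))
      stop("record '", a$cre_id,
           "': no scanner hit matches the assigned region")
    motif_ids <- if (!is.null(a$motif_ids) && nzchar(a$motif_ids))
      a$motif_ids else paste(sort(unique(hits$motif_id[m])), collapse = ",")
    data.frame(
      cre_id = a$cre_id, cre_class = a$cre_class,
      sequence = substr(seq, a$start + 1, a$end),
      source_promoter = a$sequence_id,
      flank5 = substr(seq, max(1, a$start - flank + 1), a$start),
      flank3 = substr(seq, a$end + 1, min(L, a$end + flank)),
      motif_ids = motif_ids, stringsAsFactors = FALSE)
  })
  cre_pool(do.call(rbind, recs), provenance = provenance, version = version)
}

#' Write a CRE pool as TSV
#'
#' Columns: cre_id, class, sequence, source_promoter, flank5, flank3,
#' motif_ids (comma-separated). \code{load_pool(save_pool(pool))} is the
#' identity.
#'
#' @param pool a \code{cre_pool}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
save_pool <- function(pool, path) {
  df <- pool$records
  names(df)[names(df) == "cre_class"] <- "class"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# cre_pool version=", pool$version,
                    " provenance=", pool$provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CRE pool from TSV
#' @param path TSV written by \code{\link{save_pool}} or conforming to the
#'   same schema. Windows (CRLF) line endings are accepted.
#' @return a \code{cre_pool}.
#' @export
load_pool <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  meta <- grep("^#", lines, value = TRUE)
  version <- "1"; provenance <- ""
  if (length(meta)) {
    v <- regmatches(meta[1], regexpr("version=\\S+", meta[1]))
    if (length(v)) version <- sub("version=", "", v)
    pr <- regmatches(meta[1], regexpr("provenance=.*$", meta[1]))
    if (length(pr)) provenance <- sub("provenance=", "", pr)
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   colClasses = "character")
  if (!all(c("cre_id", "class", "sequence") %in% names(df)))
    stop("pool TSV must have columns cre_id, class, sequence")
  names(df)[names(df) == "class"] <- "cre_class"
  tryCatch(cre_pool(df, provenance = provenance, version = version),
           error = function(e) stop("loading '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' @keywords internal
.split_motif_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ",", fixed = TRUE)[[1]]
}
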