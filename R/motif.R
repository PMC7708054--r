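#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table head
#' @importFrom methods is
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a binding-site motif
#'
#' A motif is a position probability matrix (PPM) over the DNA alphabet
#' together with the pseudocount that was folded into it. Columns are motif
#' positions, rows are bases A, C, G, T. The raw probabilities are
#' regularized by adding \code{pseudocount} to every cell and renormalizing
#' each column, so that log-odds scores are always finite.
#'
#' @param id motif identifier (unique within a library).
#' @param ppm numeric matrix, either 4 x W (rows A,C,G,T) or W x 4; each
#'   position must sum to 1 within 0.01 before regularization.
#' @param pseudocount probability mass added to each cell before
#'   renormalization (default 1e-3).
#' @param source free-text provenance tag (e.g. "cistrome", "user").
#' @return an object of class \code{minsyn_motif} with elements \code{id},
#'   \code{ppm} (4 x W, columns summing to 1), \code{pseudocount},
#'   \code{source}.
#' @export
new_motif <- function(id, ppm, pseudocount = 1e-3, source = "user") {
  ppm <- as.matrix(ppm)
  if (ncol(ppm) == 4 && nrow(ppm) != 4) ppm <- t(ppm)
  if (nrow(ppm) != 4)
    stop("motif '", id, "': ppm must have 4 rows (A,C,G,T) or 4 columns")
  W <- ncol(ppm)
  if (W < 1 || W > 30)
    stop("motif '", id, "': width must be in [1, 30], got ", W)
  if (any(ppm < 0))
    stop("motif '", id, "': negative probabilities")
  sums <- colSums(ppm)
  bad <- which(abs(sums - 1) > 0.01)
  if (length(bad))
    stop("motif '", id, "': position ", bad[1], " sums to ",
         format(sums[bad[1]]), ", not ~1")
  ppm <- sweep(ppm + pseudocount, 2, sums + 4 * pseudocount, "/")
  rownames(ppm) <- DNA_BASES
  structure(
    list(id = as.character(id), ppm = ppm, pseudocount = pseudocount,
         source = source),
    class = "minsyn_motif")
}

#' @export
print.minsyn_motif <- function(x, ...) {
  cat("minsyn_motif '", x$id, "' width ", ncol(x$ppm),
      " consensus ", motif_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Motif width
#' @param motif a \code{minsyn_motif}.
#' @return integer motif width.
#' @export
motif_width <- function(motif) ncol(motif$ppm)

#' Consensus sequence of a motif
#' @param motif a \code{minsyn_motif}.
#' @return character string of the per-position most probable bases (ties
#'   broken in A,C,G,T order).
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$ppm, 2, which.max)], collapse = "")
}

#' Background base composition
#'
#' Zero-order background model used for log-odds scoring and for the exact
#' score distribution. Defaults to uniform, the conventional choice when no
#' genome-derived composition is supplied.
#'
#' @param p named numeric vector with entries A, C, G, T, strictly positive,
#'   summing to 1 within 1e-9.
#' @return normalized named vector of class \code{minsyn_background}.
#' @export
background_model <- function(p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (is.null(names(p))) names(p) <- DNA_BASES
  p <- p[DNA_BASES]
  if (anyNA(p)) stop("background must name all of A, C, G, T")
  if (any(p <= 0)) stop("background probabilities must be strictly positive")
  if (abs(sum(p) - 1) > 1e-9) stop("background must sum to 1")
  structure(p, class = "minsyn_background")
}

#' Log-odds score matrix
#'
#' @param motif a \code{minsyn_motif}.
#' @param bg a \code{background_model}.
#' @return 4 x W numeric matrix of \code{log2(ppm / bg)} in bits.
#' @export
log_odds <- function(motif, bg = background_model()) {
  log2(motif$ppm / as.numeric(bg))
}

#' Parse motifs from MEME minimal format text
#'
#' Reads the MEME suite "minimal motif" text format: a version line, an
#' ALPHABET= ACGT declaration, and one or more MOTIF blocks each carrying a
#' \code{letter-probability matrix:} header followed by W rows of four
#' probabilities (columns A, C, G, T). Background frequency lines are
#' tolerated and ignored; scanning takes its background separately.
#'
#' @param text character scalar (whole document) or character vector of lines.
#' @param pseudocount passed to \code{\link{new_motif}}.
#' @param source provenance tag stored on each motif.
#' @return list of \code{minsyn_motif}, in document order; empty list for a
#'   document with no MOTIF blocks.
#' @export
parse_meme_motifs <- function(text, pseudocount = 1e-3, source = "meme") {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  lines <- sub("\r$", "", lines)
  stripped <- trimws(lines)
  motif_at <- grep("^MOTIF\\b", stripped)
  if (!length(motif_at)) {
    if (any(nzchar(stripped)) && !any(grepl("^MEME version", stripped)))
      stop("not a MEME minimal motif document: no version line, no MOTIF block")
    return(list())
  }
  alpha <- grep("^ALPHABET=", stripped, value = TRUE)
  if (length(alpha)) {
    a <- gsub("\\s", "", sub("^ALPHABET=", "", alpha[1]))
    if (toupper(a) != "ACGT")
      stop("unsupported alphabet '", a, "': only ACGT is handled")
  }
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    toks <- strsplit(stripped[i], "\\s+")[[1]]
    if (length(toks) < 2) stop("line ", i, ": MOTIF line without an id")
    id <- toks[2]
    j <- i + 1
    while (j <= length(stripped) &&
           !grepl("^letter-probability matrix", stripped[j])) {
      if (grepl("^MOTIF\\b", stripped[j]))
        stop("motif '", id, "' (line ", i, "): no letter-probability matrix")
      j <- j + 1
    }
    if (j > length(stripped))
      stop("motif '", id, "' (line ", i, "): no letter-probability matrix")
    hdr <- stripped[j]
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr)))
    rows <- list(); j <- j + 1
    while (j <= length(stripped) && nzchar(stripped[j]) &&
           !grepl("^(MOTIF|URL|letter-probability)", stripped[j])) {
      vals <- suppressWarnings(as.numeric(strsplit(stripped[j], "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4)
        stop("motif '", id, "', line ", j, ": expected 4 probabilities")
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1
    }
    if (!is.na(w) && length(rows) != w)
      stop("motif '", id, "': header declares w=", w, " but found ",
           length(rows), " matrix rows")
    if (!length(rows)) stop("motif '", id, "': empty probability matrix")
    ppm <- t(do.call(rbind, rows))  # 4 x W, rows A,C,G,T
    motifs[[k]] <- new_motif(id, ppm, pseudocount = pseudocount,
                             source = source)
  }
  motifs
}

#' Read a MEME minimal motif file
#' @param path file path.
#' @inheritParams parse_meme_motifs
#' @return list of \code{minsyn_motif}.
#' @export
read_meme_motifs <- function(path, pseudocount = 1e-3, source = "meme") {
  parse_meme_motifs(readLines(path, warn = FALSE), pseudocount = pseudocount,
                    source = source)
}

#' Write motifs in MEME minimal format
#' @param motifs list of \code{minsyn_motif}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (m in motifs) {
    writeLines(paste("MOTIF", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m$ppm)), con)
    apply(m$ppm, 2, function(col)
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}
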