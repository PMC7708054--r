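# MinSyn assembly. Architecture is fixed library-wide:
#   prefix(19) . (spacer . CRE)^N . TATATAA . core(43)
# with N drawn uniformly from [3, 10], spacer lengths uniformly from
# [5, 30] bases, and CREs sampled from the pool without replacement, each in
# forward orientation. A spacer precedes its CRE, so the last CRE abuts the
# TATA-box region.

# Fixed synthetic default for the 43 bp minimal core + TSS. The core used
# experimentally is construct-specific; any 43 bp sequence can be supplied
# via generator_config(core_seq = ...).
MINSYN_DEFAULT_CORE <- "AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGA"

#' Generator configuration
#'
#' Architectural constants and sampling ranges for MinSyn assembly.
#'
#' @param n_cre_min,n_cre_max range of the number of CREs per design
#'   (default 3..10).
#' @param spacer_min,spacer_max random spacer length range in bases
#'   (default 5..30).
#' @param prefix_len length of the random 5' prefix (default 19).
#' @param tata_seq TATA box sequence (default "TATATAA").
#' @param core_len minimal core length (default 43).
#' @param core_seq literal core sequence; defaults to a fixed synthetic 43 bp
#'   constant shipped with the package.
#' @param library_size number of designs per library (default 1000).
#' @param rng_seed integer seed that fully determines a library.
#' @param gc_fraction GC content of random prefix/spacer segments
#'   (default 0.5).
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_cre_min = 3L, n_cre_max = 10L,
                             spacer_min = 5L, spacer_max = 30L,
                             prefix_len = 19L, tata_seq = "TATATAA",
                             core_len = 43L, core_seq = NULL,
                             library_size = 1000L, rng_seed = 1L,
                             gc_fraction = 0.5) {
  if (is.null(core_seq)) core_seq <- MINSYN_DEFAULT_CORE
  if (nchar(core_seq) != core_len)
    stop("core_seq length ", nchar(core_seq), " != core_len ", core_len)
  if (grepl("[^ACGT]", core_seq) || grepl("[^ACGT]", tata_seq))
    stop("tata_seq and core_seq must be plain ACGT")
  if (!(n_cre_min >= 0 && n_cre_min <= n_cre_max))
    stop("need 0 <= n_cre_min <= n_cre_max")
  if (!(spacer_min >= 0 && spacer_min <= spacer_max))
    stop("need 0 <= spacer_min <= spacer_max")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  structure(list(n_cre_min = as.integer(n_cre_min),
                 n_cre_max = as.integer(n_cre_max),
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 prefix_len = as.integer(prefix_len),
                 tata_seq = tata_seq, core_len = as.integer(core_len),
                 core_seq = core_seq,
                 library_size = as.integer(library_size),
                 rng_seed = as.integer(rng_seed),
                 gc_fraction = gc_fraction),
            class = "generator_config")
}

#' Random DNA segment
#' @param n length in bases.
#' @param gc_fraction target GC content.
#' @return character string; draws from the current RNG stream.
#' @export
random_dna <- function(n, gc_fraction = 0.5) {
  if (n == 0L) return("")
  at <- (1 - gc_fraction) / 2
  gc <- gc_fraction / 2
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c(at, gc, gc, at)), collapse = "")
}

# sample() treats a length-1 numeric as 1:x; guard against that.
#' @keywords internal
.sample_int <- function(lo, hi) {
  if (lo == hi) as.integer(lo) else sample(seq.int(lo, hi), 1L)
}

#' @keywords internal
.new_segment <- function(kind, text, cre_id = NA_character_,
                         cre_class = NA_character_,
                         motif_ids = NA_character_) {
  data.frame(kind = kind, text = text, cre_id = cre_id,
             cre_class = cre_class, motif_ids = motif_ids,
             stringsAsFactors = FALSE)
}

#' Sample one MinSyn design from a CRE pool
#'
#' Draws N uniformly from [n_cre_min, n_cre_max]; then, N times, appends a
#' fresh random spacer of uniform length in [spacer_min, spacer_max] followed
#' by a CRE drawn uniformly without replacement; prepends the random prefix
#' and appends the TATA box and core. Deterministic given the RNG state.
#'
#' @param pool a \code{cre_pool} with at least \code{n_cre_max} records.
#' @param cfg a \code{generator_config}.
#' @param design_id identifier stored on the design.
#' @return object of class \code{minsyn_design} with elements design_id,
#'   n_cre, segments (data.frame kind, text, cre_id, cre_class, motif_ids).
#' @export
sample_design <- function(pool, cfg = generator_config(),
                          design_id = "MinSyn0001") {
  if (pool_size(pool) < cfg$n_cre_max)
    stop("pool of ", pool_size(pool), " CREs cannot support up to ",
         cfg$n_cre_max, " draws without replacement")
  n <- .sample_int(cfg$n_cre_min, cfg$n_cre_max)
  segs <- list(.new_segment("prefix", random_dna(cfg$prefix_len,
                                                 cfg$gc_fraction)))
  picks <- if (n > 0) sample(pool_size(pool), n) else integer(0)
  for (i in picks) {
    rec <- pool$records[i, ]
    segs[[length(segs) + 1L]] <- .new_segment(
      "spacer", random_dna(.sample_int(cfg$spacer_min, cfg$spacer_max),
                           cfg$gc_fraction))
    segs[[length(segs) + 1L]] <- .new_segment(
      "cre", rec$sequence, rec$cre_id, rec$cre_class, rec$motif_ids)
  }
  segs[[length(segs) + 1L]] <- .new_segment("tata", cfg$tata_seq)
  segs[[length(segs) + 1L]] <- .new_segment("core", cfg$core_seq)
  structure(list(design_id = design_id, n_cre = n,
                 segments = do.call(rbind, segs)),
            class = "minsyn_design")
}

#' @export
print.minsyn_design <- function(x, ...) {
  cat("minsyn_design '", x$design_id, "': N=", x$n_cre, ", ",
      nchar(assemble_sequence(x)$sequence), " bp\n", sep = "")
  invisible(x)
}

#' Assemble a design into sequence and feature table
#'
#' @param design a \code{minsyn_design}.
#' @return list with \code{sequence} (character) and \code{features}
#'   (data.frame kind, start, end, cre_id, cre_class; 0-based half-open,
#'   concatenation of segment texts re-slices exactly).
#' @export
assemble_sequence <- function(design) {
  segs <- design$segments
  if (!all(segs$kind %in% c("prefix", "spacer", "cre", "tata", "core")))
    stop("unknown segment kind: ",
         segs$kind[!segs$kind %in%
                     c("prefix", "spacer", "cre", "tata", "core")][1])
  len <- nchar(segs$text)
  end <- cumsum(len)
  features <- data.frame(kind = segs$kind, start = end - len, end = end,
                         cre_id = segs$cre_id, cre_class = segs$cre_class,
                         stringsAsFactors = FALSE)
  list(sequence = paste(segs$text, collapse = ""), features = features)
}

#' Generate a MinSyn library
#'
#' Produces \code{cfg$library_size} designs from a single RNG stream seeded
#' with \code{cfg$rng_seed}; byte-for-byte reproducible from (pool, cfg).
#'
#' @param pool a \code{cre_pool}.
#' @param cfg a \code{generator_config}.
#' @return object of class \code{minsyn_library}: list with designs, config,
#'   pool_version.
#' @export
generate_library <- function(pool, cfg = generator_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$rng_seed)
  ids <- sprintf("MinSyn%0*d", max(4L, nchar(cfg$library_size)),
                 seq_len(cfg$library_size))
  designs <- lapply(ids, function(id) sample_design(pool, cfg, id))
  structure(list(designs = designs, config = cfg,
                 pool_version = pool$version),
            class = "minsyn_library")
}

#' @export
print.minsyn_library <- function(x, ...) {
  cat("minsyn_library of", length(x$designs), "designs (seed",
      x$config$rng_seed, ", pool version", x$pool_version, ")\n")
  invisible(x)
}

#' Build an orthogonal binding-site-array MinSyn
#'
#' The variable region is k copies of one synthetic-TF binding site separated
#' by a fixed random spacer; prefix, TATA box and core as in the constitutive
#' architecture. Used to build promoter series whose strength tracks the
#' number of binding sites.
#'
#' @param binding_site DNA string of the orthogonal TF binding site.
#' @param copies number of copies k (>= 0; k = 0 gives prefix + TATA + core).
#' @param cfg a \code{generator_config}.
#' @param spacer_len length of the fixed inter-site spacer (default 5).
#' @param design_id identifier.
#' @return a \code{minsyn_design}; sites carry cre_ids site1..siteK with
#'   class GENERIC.
#' @export
build_orthogonal_minsyn <- function(binding_site, copies, cfg = generator_config(),
                                    spacer_len = 5L,
                                    design_id = "MinSynOrth") {
  if (copies < 0) stop("copies must be >= 0")
  if (copies > 0 && (!nzchar(binding_site) || grepl("[^ACGT]", binding_site)))
    stop("binding_site must be non-empty ACGT")
  segs <- list(.new_segment("prefix", random_dna(cfg$prefix_len,
                                                 cfg$gc_fraction)))
  spacer <- random_dna(spacer_len, cfg$gc_fraction)
  for (i in seq_len(copies)) {
    if (i > 1)
      segs[[length(segs) + 1L]] <- .new_segment("spacer", spacer)
    segs[[length(segs) + 1L]] <- .new_segment(
      "cre", binding_site, paste0("site", i), "GENERIC")
  }
  segs[[length(segs) + 1L]] <- .new_segment("tata", cfg$tata_seq)
  segs[[length(segs) + 1L]] <- .new_segment("core", cfg$core_seq)
  structure(list(design_id = design_id, n_cre = as.integer(copies),
                 segments = do.call(rbind, segs)),
            class = "minsyn_design")
}
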