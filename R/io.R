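# Writers. Internal coordinates are 0-based half-open throughout the
# package; GFF3 output converts to the standard's 1-based inclusive
# coordinates (start + 1, end), a bijection on all features.

#' Write library sequences as FASTA
#'
#' @param library a \code{minsyn_library}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_library_fasta <- function(library, path) {
  seqs <- vapply(library$designs, function(d)
    assemble_sequence(d)$sequence, character(1))
  names(seqs) <- vapply(library$designs, `[[`, "", "design_id")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @keywords internal
.gff3_attr_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write per-design feature tables as GFF3
#'
#' One record per segment (prefix, spacer, cre, tata, core), seqid = the
#' design id, coordinates 1-based inclusive. CRE segments carry cre_id and
#' cre_class attributes.
#'
#' @param library a \code{minsyn_library}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_features_gff3 <- function(library, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (d in library$designs) {
    feats <- assemble_sequence(d)$features
    for (i in seq_len(nrow(feats))) {
      attrs <- paste0("ID=", .gff3_attr_escape(
        paste0(d$design_id, ".", i, ".", feats$kind[i])))
      if (feats$kind[i] == "cre" && !is.na(feats$cre_id[i]))
        attrs <- paste0(attrs, ";cre_id=", .gff3_attr_escape(feats$cre_id[i]),
                        ";cre_class=", feats$cre_class[i])
      writeLines(paste(d$design_id, "minsynr", feats$kind[i],
                       feats$start[i] + 1L, feats$end[i], ".", "+", ".",
                       attrs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write scanner hits as GFF3
#'
#' Records of type TF_binding_site with the log-odds score (bits) in the
#' score column and motif_id / p_value attributes.
#'
#' @param hits hit data.frame from \code{\link{scan_sequence}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_hits_gff3 <- function(hits, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(hits)))
    writeLines(paste(
      hits$sequence_id[i], "minsynr", "TF_binding_site",
      hits$start[i] + 1L, hits$end[i],
      format(hits$score[i], digits = 6), hits$strand[i], ".",
      paste0("motif_id=", .gff3_attr_escape(hits$motif_id[i]),
             ";p_value=", format(hits$p_value[i], digits = 6)),
      sep = "\t"), con)
  invisible(path)
}

#' Write scanner hits as TSV
#' @inheritParams write_hits_gff3
#' @return invisibly, the path.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a library manifest as TSV
#'
#' Header comment lines record the seed, pool version and a hash of the
#' generator configuration so that a run is reproducible from the manifest
#' alone. Columns: design_id, n_cre, cre_ids, spacer_lengths, total_length,
#' seed, raw_score and (when the model is calibrated) predicted_strength.
#'
#' @param library a \code{minsyn_library}.
#' @param path output path.
#' @param model a \code{strength_model} used to score the designs.
#' @return invisibly, the path.
#' @export
write_manifest_tsv <- function(library, path, model = strength_model()) {
  manifest <- score_library(library, model)
  cfg <- library$config
  cfg_string <- paste(names(cfg), vapply(cfg, paste, character(1),
                                         collapse = ","),
                      sep = "=", collapse = ";")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# minsynr manifest",
               paste0("# seed: ", cfg$rng_seed),
               paste0("# pool_version: ", library$pool_version),
               paste0("# config: ", cfg_string)), con)
  write.table(manifest, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a manifest TSV (comment header tolerated)
#' @param path manifest path.
#' @return data.frame of the manifest body.
#' @export
read_manifest_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
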