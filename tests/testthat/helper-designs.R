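# Construct designs with explicit segment layouts (raw_score and the audit
# accept any order of known segment kinds, so tests can place spacers between
# a CRE and the TATA box to probe the distance rules).

make_design <- function(..., design_id = "test_design") {
  segs <- do.call(rbind, list(...))
  structure(list(design_id = design_id,
                 n_cre = sum(segs$kind == "cre"),
                 segments = segs),
            class = "minsyn_design")
}

seg <- function(kind, text, cre_id = NA_character_,
                cre_class = NA_character_, motif_ids = NA_character_) {
  data.frame(kind = kind, text = text, cre_id = cre_id,
             cre_class = cre_class, motif_ids = motif_ids,
             stringsAsFactors = FALSE)
}

# a few sharp test motifs with hand-chosen consensi
sharp_motif <- function(id, consensus, sharpness = 0.94) {
  W <- nchar(consensus)
  ppm <- matrix((1 - sharpness) / 3, nrow = 4, ncol = W)
  rownames(ppm) <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "")[[1]], rownames(ppm))
  ppm[cbind(idx, seq_len(W))] <- sharpness
  new_motif(id, ppm)
}

# small pool used across generator/strength tests: 2 TGA C-CREs, 1 non-TGA,
# 12 generics (the study's pool composition)
test_pool <- function() {
  set.seed(7)
  n <- 15
  cre_pool(data.frame(
    cre_id = sprintf("cre%02d", 1:n),
    cre_class = c("C_CRE_TGA", "C_CRE_TGA", "C_CRE_NON_TGA",
                  rep("GENERIC", 12)),
    sequence = vapply(1:n, function(i) random_dna(10), character(1)),
    stringsAsFactors = FALSE))
}
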