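architecture_ok <- function(design, cfg) {
  segs <- design$segments
  kinds <- segs$kind
  n <- design$n_cre
  # prefix, then (spacer, cre) x N, then tata, core
  expect_identical(kinds,
                   c("prefix", rep(c("spacer", "cre"), n), "tata", "core"))
  expect_equal(nchar(segs$text[1]), cfg$prefix_len)
  expect_identical(segs$text[kinds == "tata"], cfg$tata_seq)
  expect_equal(nchar(segs$text[kinds == "core"]), cfg$core_len)
  sp <- nchar(segs$text[kinds == "spacer"])
  expect_true(all(sp >= cfg$spacer_min & sp <= cfg$spacer_max))
  ids <- segs$cre_id[kinds == "cre"]
  expect_false(any(duplicated(ids)))
  expect_true(n >= cfg$n_cre_min && n <= cfg$n_cre_max)
  asm <- assemble_sequence(design)
  expect_equal(nchar(asm$sequence),
               cfg$prefix_len + sum(sp) +
                 sum(nchar(segs$text[kinds == "cre"])) +
                 nchar(cfg$tata_seq) + cfg$core_len)
  expect_match(asm$sequence,
               paste0("^[ACGT]{", cfg$prefix_len, "}[ACGT]*",
                      cfg$tata_seq, cfg$core_seq, "$"))
}

test_that("a pool of exactly N CREs yields a design containing all of them", {
  pool <- test_pool()
  pool$records <- pool$records[1:3, ]
  cfg <- generator_config(n_cre_min = 3, n_cre_max = 3)
  set.seed(1)
  d <- sample_design(pool, cfg)
  expect_setequal(d$segments$cre_id[d$segments$kind == "cre"],
                  pool$records$cre_id)
  architecture_ok(d, cfg)
})

test_that("sampling is deterministic under a fixed seed", {
  pool <- test_pool()
  cfg <- generator_config(library_size = 5, rng_seed = 99)
  lib1 <- generate_library(pool, cfg)
  lib2 <- generate_library(pool, cfg)
  expect_identical(lib1, lib2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_library_fasta(lib1, f1)
  write_library_fasta(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(lib1$designs), 5)
  expect_false(any(duplicated(vapply(lib1$designs, `[[`, "", "design_id"))))
})

test_that("every design in a library obeys the architecture", {
  pool <- test_pool()
  cfg <- generator_config(library_size = 50, rng_seed = 3)
  lib <- generate_library(pool, cfg)
  for (d in lib$designs) architecture_ok(d, cfg)
})

test_that("feature coordinates re-slice the assembled sequence", {
  pool <- test_pool()
  set.seed(5)
  d <- sample_design(pool, generator_config())
  asm <- assemble_sequence(d)
  for (i in seq_len(nrow(asm$features))) {
    f <- asm$features[i, ]
    expect_identical(substr(asm$sequence, f$start + 1, f$end),
                     d$segments$text[i])
  }
  # hand-checked length for a 2-CRE design
  d2 <- make_design(seg("prefix", strrep("A", 19)),
                    seg("spacer", strrep("C", 6)),
                    seg("cre", "TTGACGTCAG", "c1", "GENERIC"),
                    seg("spacer", strrep("C", 8)),
                    seg("cre", "GGATTACCGG", "c2", "GENERIC"),
                    seg("tata", "TATATAA"),
                    seg("core", strrep("G", 43)))
  expect_equal(nchar(assemble_sequence(d2)$sequence),
               19 + 6 + 10 + 8 + 10 + 7 + 43)
  expect_error(assemble_sequence(make_design(seg("oops", "AAAA"))),
               "unknown segment kind")
})

test_that("zero-CRE control design assembles to prefix + tata + core", {
  cfg <- generator_config()
  set.seed(8)
  d0 <- build_orthogonal_minsyn("TTGACGTCAG", copies = 0, cfg)
  asm <- assemble_sequence(d0)
  expect_equal(nchar(asm$sequence), 19 + 7 + 43)
  expect_identical(asm$features$kind, c("prefix", "tata", "core"))
})

test_that("orthogonal arrays grow by one site plus one spacer per copy", {
  cfg <- generator_config()
  site <- strrep("ACGTG", 4)  # early TALE-style 20-mer stand-in
  lens <- vapply(0:4, function(k) {
    set.seed(13)
    nchar(assemble_sequence(
      build_orthogonal_minsyn(site, k, cfg, spacer_len = 5))$sequence)
  }, numeric(1))
  expect_equal(lens[1], 19 + 7 + 43)
  expect_equal(lens[4] - lens[1], 3 * 20 + 2 * 5)
  expect_equal(diff(lens)[-1], rep(20 + 5, 3))
  expect_equal(diff(lens)[1], 20)  # first copy brings no spacer
})

test_that("N and spacer lengths are uniform on their stated ranges", {
  pool <- test_pool()
  cfg <- generator_config(library_size = 4000, rng_seed = 17)
  lib <- generate_library(pool, cfg)
  n <- vapply(lib$designs, `[[`, integer(1), "n_cre")
  expect_true(all(n >= 3 & n <= 10))
  chi_n <- stats::chisq.test(table(factor(n, levels = 3:10)))
  expect_gt(chi_n$p.value, 1e-4)
  sp <- unlist(lapply(lib$designs, function(d)
    nchar(d$segments$text[d$segments$kind == "spacer"])))
  expect_true(all(sp >= 5 & sp <= 30))
  chi_sp <- stats::chisq.test(table(factor(sp, levels = 5:30)))
  expect_gt(chi_sp$p.value, 1e-4)
  # without replacement: no repeated CRE within any design
  expect_false(any(vapply(lib$designs, function(d)
    anyDuplicated(d$segments$cre_id[d$segments$kind == "cre"]) > 0,
    logical(1))))
})

test_that("infeasible configurations are refused before output", {
  pool <- test_pool()
  pool$records <- pool$records[1:4, ]
  expect_error(sample_design(pool, generator_config()),
               "without replacement")
  expect_error(generator_config(n_cre_min = 5, n_cre_max = 3), "n_cre_min")
  expect_error(generator_config(core_seq = "ACGT"), "core_seq length")
})
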