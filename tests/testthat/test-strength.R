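test_that("proximity weight follows the class plateaus and linear decay", {
  m <- strength_model()
  expect_equal(proximity_weight(0, "C_CRE_TGA", m), 1)
  expect_equal(proximity_weight(60, "C_CRE_TGA", m), 1)
  expect_equal(proximity_weight(130, "C_CRE_TGA", m), 0)   # 60 + 70
  expect_equal(proximity_weight(95, "C_CRE_TGA", m), 0.5)  # halfway down
  expect_equal(proximity_weight(100, "C_CRE_NON_TGA", m), 1)
  expect_equal(proximity_weight(130, "C_CRE_NON_TGA", m), 1)
  expect_equal(proximity_weight(200, "C_CRE_NON_TGA", m), 0)  # 130 + 70
  expect_error(proximity_weight(10, "GENERIC", m), "C-CRE")
  expect_error(proximity_weight(-1, "C_CRE_TGA", m), ">= 0")
})

zero_cre_design <- function() {
  make_design(seg("prefix", strrep("A", 19)),
              seg("spacer", strrep("C", 24)),
              seg("tata", "TATATAA"),
              seg("core", strrep("G", 43)))
}

# one generic CRE, its 3' edge `gap` bases before the TATA box
one_cre_design <- function(gap = 0, cre_len = 10,
                           cre_class = "GENERIC", pad = 21) {
  segs <- list(seg("prefix", strrep("A", 19)),
               seg("spacer", strrep("C", pad)),
               seg("cre", strrep("T", cre_len), "c1", cre_class))
  if (gap > 0) segs <- c(segs, list(seg("spacer", strrep("C", gap))))
  segs <- c(segs, list(seg("tata", "TATATAA"),
                       seg("core", strrep("G", 43))))
  do.call(make_design, segs)
}

test_that("raw score is the per-base sum divided by total length", {
  model <- strength_model()
  expect_equal(raw_score(zero_cre_design(), model), 0)

  # 100 bp design, one 10 bp generic CRE abutting the TATA box:
  # 19 + 21 + 10 + 7 + 43 = 100, score = 10 * 1 / 100
  d <- one_cre_design(gap = 0, cre_len = 10, pad = 21)
  expect_equal(nchar(assemble_sequence(d)$sequence), 100)
  expect_equal(raw_score(d, model), 0.1)

  # a TGA C-CRE abutting the TATA scores s_ccre per base
  dt <- one_cre_design(cre_class = "C_CRE_TGA")
  expect_equal(raw_score(dt, model), 10 * 2 / 100)
})

test_that("moving a TGA C-CRE past its plateau strictly lowers the score", {
  model <- strength_model()
  d30 <- one_cre_design(gap = 30, cre_class = "C_CRE_TGA")
  d90 <- one_cre_design(gap = 90, cre_class = "C_CRE_TGA")
  expect_gt(raw_score(d30, model), raw_score(d90, model))
  # within the plateau only the length denominator changes
  d10 <- one_cre_design(gap = 10, cre_class = "C_CRE_TGA")
  L10 <- nchar(assemble_sequence(d10)$sequence)
  expect_equal(raw_score(d10, model) * L10, 10 * 2)
  # monotone non-increasing in distance overall
  gaps <- seq(0, 200, by = 10)
  vals <- vapply(gaps, function(g)
    raw_score(one_cre_design(gap = g, cre_class = "C_CRE_TGA"), model),
    numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("bases between two C-CREs earn the cooperative mid-point term", {
  model <- strength_model()
  # two TGA C-CREs 20 bp apart, the downstream one abutting the TATA box
  d <- make_design(seg("prefix", strrep("A", 19)),
                   seg("spacer", strrep("C", 5)),
                   seg("cre", strrep("T", 10), "c1", "C_CRE_TGA"),
                   seg("spacer", strrep("C", 20)),
                   seg("cre", strrep("T", 10), "c2", "C_CRE_TGA"),
                   seg("tata", "TATATAA"),
                   seg("core", strrep("G", 43)))
  L <- nchar(assemble_sequence(d)$sequence)
  # upstream C-CRE 3' edge is 30 bp from the TATA (inside the 60 plateau),
  # the between-region midpoint is 20 bp from the TATA: both weights 1
  expected <- (10 * 2 + 10 * 2 + 20 * 0.5) / L
  expect_equal(raw_score(d, model), expected)

  # with a generic CRE in place of one C-CRE, no cooperative term applies
  d2 <- d
  d2$segments$cre_class[d2$segments$cre_id %in% "c1"] <- "GENERIC"
  expect_equal(raw_score(d2, model), (10 * 1 + 10 * 2) / L)
})

test_that("the first-CRE gap penalty starts past 50 bp", {
  model <- strength_model()
  base <- raw_score(one_cre_design(gap = 0), model) * 100  # summed score
  sums <- vapply(0:130, function(g) {
    d <- one_cre_design(gap = g)
    raw_score(d, model) * nchar(assemble_sequence(d)$sequence)
  }, numeric(1))
  expect_equal(sums[1], base)
  expect_equal(max(which(abs(sums - base) < 1e-12)) - 1, 50)
  expect_equal(sums[50 + 1], base)            # gap = 50: no penalty
  expect_lt(sums[51 + 1], base)               # gap = 51: penalized
  expect_equal(sums[120 + 1], 0)              # gap = 120 = 50 + 70: zero
})

test_that("adding a CRE moves the mean per-base score toward its own rate", {
  model <- strength_model()
  d <- one_cre_design(gap = 0, cre_class = "C_CRE_TGA")  # mean 0.2
  r0 <- raw_score(d, model)
  # append an extra generic CRE (rate 1 > 0.2) right before the TATA box
  add <- function(d, cls) {
    segs <- d$segments
    k <- which(segs$kind == "tata")
    make_design(seg("prefix", segs$text[1]),
                seg("spacer", segs$text[2]),
                seg("cre", segs$text[3], "c1", segs$cre_class[3]),
                seg("spacer", strrep("C", 5)),
                seg("cre", strrep("T", 10), "c9", cls),
                seg("tata", "TATATAA"),
                seg("core", strrep("G", 43)))
  }
  expect_gt(raw_score(add(d, "GENERIC"), model), r0)
})

test_that("calibration through the origin matches the closed form", {
  model <- strength_model()
  exact <- calibrate(model, data.frame(raw_score = c(1, 2, 3),
                                       measured = c(3, 6, 9)))
  expect_equal(exact$model$calibration_k, 3)
  expect_equal(exact$diagnostics$r_squared, 1)

  fit <- calibrate(model, data.frame(raw_score = c(1, 2, 3),
                                     measured = c(2, 4, 7)))
  expect_equal(fit$model$calibration_k, 31 / 14)
  expect_lt(fit$diagnostics$r_squared, 1)
  expect_equal(fit$diagnostics$n_points, 3)

  expect_error(calibrate(model, data.frame(raw_score = 1, measured = 2)),
               "at least 2")
  expect_error(calibrate(model, data.frame(raw_score = c(0, 0),
                                           measured = c(1, 2))),
               "all raw scores are zero")
})

test_that("calibration recovers a known scalar from noisy synthetic pairs", {
  set.seed(19)
  k_true <- 3
  model <- strength_model()
  fits <- replicate(50, {
    x <- runif(50, 0.05, 0.6)
    y <- k_true * x + rnorm(50, 0, 0.1)
    calibrate(model, data.frame(raw_score = x, measured = y))$model$calibration_k
  })
  se <- sd(fits) / sqrt(length(fits))
  expect_lt(abs(mean(fits) - k_true), 2 * se + 1e-3)
})

test_that("prediction is the calibrated linear map of the raw score", {
  model <- strength_model()
  d <- one_cre_design()
  expect_error(predict_strength(d, model), "not calibrated")
  cal <- calibrate(model, data.frame(raw_score = c(1, 2), measured = c(2, 4)))
  expect_equal(predict_strength(d, cal$model),
               cal$model$calibration_k * raw_score(d, cal$model))
  expect_equal(predict_strength(zero_cre_design(), cal$model), 0)
  m2 <- cal$model; m2$calibration_k <- 2 * cal$model$calibration_k
  expect_equal(predict_strength(d, m2), 2 * predict_strength(d, cal$model))
  # library-wide ordering is preserved by the monotone map
  lib <- generate_library(test_pool(), generator_config(library_size = 30,
                                                        rng_seed = 2))
  man <- score_library(lib, cal$model)
  expect_identical(order(man$raw_score), order(man$predicted_strength))
})
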