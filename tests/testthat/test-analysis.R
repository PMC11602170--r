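test_that("geometric mean is exact on constants and scale-equivariant", {
  expect_equal(geomean(c(7, 7, 7)), 7)
  set.seed(3)
  x <- runif(20, 1, 100)
  expect_equal(geomean(3.5 * x), 3.5 * geomean(x))
  expect_error(geomean(c(1, 0)), "positive")
  expect_error(geomean(c(1, -2)), "positive")
})

test_that("fold_change uses geometric means and quadrature errors", {
  on <- measurement_sample("c1", "ON", c(100, 100, 100))
  off <- measurement_sample("c1", "OFF", c(10, 10, 10))
  fc <- fold_change(on, off)
  expect_equal(fc$fold, 10)
  expect_equal(fc$relative_error, 0)
  # closed-form quadrature: rel 0.10 and 0.10 combine to sqrt(0.02)
  mk <- function(state, gm, rel) {
    s <- structure(list(construct_id = "x", state = state, values = gm,
                        geometric_mean = gm, relative_error = rel),
                   class = "measurement_sample")
    s
  }
  fc2 <- fold_change(mk("ON", 50, 0.10), mk("OFF", 5, 0.10))
  expect_equal(fc2$relative_error, sqrt(0.02))
  expect_equal(fc2$relative_error, 0.1414, tolerance = 1e-3)
  # ratio symmetry
  on2 <- measurement_sample("c2", "ON", c(90, 110, 105))
  off2 <- measurement_sample("c2", "OFF", c(9, 12, 10))
  f12 <- fold_change(on2, off2)$fold
  f21 <- fold_change(off2, on2)$fold
  expect_equal(f12 * f21, 1)
  # quadrature error is symmetric and >= each component
  e <- fold_change(on2, off2)$relative_error
  expect_equal(e, fold_change(off2, on2)$relative_error)
  expect_gte(e, max(on2$relative_error, off2$relative_error))
  expect_error(measurement_sample("c", "ON", c(10, 0)), "positive")
})

test_that("fit_linear matches the normal equations and handles edge cases", {
  x <- 1:10
  expect_equal(fit_linear(x, 2 * x + 1),
               structure(list(slope = 2, intercept = 1, r_squared = 1,
                              n_points = 10L), class = "regression_fit"),
               tolerance = 1e-12)
  const <- fit_linear(x, rep(4, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)
  # independent normal-equations oracle on seeded noisy data
  set.seed(77)
  xn <- runif(10, 0, 5)
  yn <- 3 * xn - 2 + rnorm(10, sd = 0.3)
  fit <- fit_linear(xn, yn)
  sxx <- sum((xn - mean(xn))^2)
  slope_ne <- sum((xn - mean(xn)) * (yn - mean(yn))) / sxx
  intercept_ne <- mean(yn) - slope_ne * mean(xn)
  expect_equal(fit$slope, slope_ne)
  expect_equal(fit$intercept, intercept_ne)
  pred <- intercept_ne + slope_ne * xn
  expect_equal(fit$r_squared,
               1 - sum((yn - pred)^2) / sum((yn - mean(yn))^2))
  # recovery within 3 standard errors at small noise
  se <- sqrt(sum((yn - pred)^2) / 8) / sqrt(sxx)
  expect_lt(abs(fit$slope - 3), 3 * se)
  expect_error(fit_linear(1:2, 1:2), "3 points")
  expect_error(fit_linear(1:4, 1:3), "equal length")
  expect_error(fit_linear(rep(2, 5), 1:5), "degenerate")
})

test_that("cfu_per_ml implements the plating formula", {
  expect_equal(cfu_per_ml(50, 1e4), 1e8)
  expect_equal(cfu_per_ml(0, 100), 0)
  expect_equal(cfu_per_ml(1, 1), 200)
  expect_error(cfu_per_ml(-1, 1), "non-negative")
  expect_error(cfu_per_ml(5, 0.5), ">= 1")
})

test_that("feature_table rows are complete and round-trip through TSV", {
  cands <- design_syntce(syntce_spec(n_candidates = 3, seed = 2),
                         MODEL, CONFIG)
  tab <- feature_table(cands, MODEL, CONFIG)
  expect_equal(nrow(tab), 3)
  need <- c("stem_dG", "rbs_total", "dG_rRNA_mRNA", "dG_spacing",
            "intergenic_distance", "loop_len", "local_struct_dG",
            "internal_rbs_count")
  expect_true(all(need %in% names(tab)))
  expect_true(all(stats::complete.cases(tab)))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back, tab, tolerance = 1e-12)
  # operon designs produce one row per junction
  reg <- fixture_registry()
  op <- assemble_operon(list(reg$gfp, fixture_syntce(), reg$mcherry))
  expect_equal(nrow(feature_table(op, MODEL, CONFIG)), 1)
  expect_error(feature_table(assemble_syntce(syntce_spec(), "GCAGCC")),
               "unscored")
})

test_that("an end-to-end synthetic regression recovers a planted linear law", {
  cands <- design_syntce(syntce_spec(n_candidates = 12, seed = 31),
                         MODEL, CONFIG)
  tab <- feature_table(cands, MODEL, CONFIG)
  y <- -1.8 * tab$stem_dG + 4
  fit <- fit_linear(tab$stem_dG, y)
  expect_equal(fit$slope, -1.8)
  expect_equal(fit$intercept, 4)
  expect_equal(fit$r_squared, 1)
})

test_that("measurement CSVs read into grouped samples", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("construct_id,state,replicate,value",
               "c1,ON,1,100", "c1,ON,2,110", "c1,ON,3,95",
               "c1,OFF,1,9", "c1,OFF,2,11", "c1,OFF,3,10"), f)
  samples <- read_measurements(f)
  expect_length(samples, 2)
  fc <- fold_change(samples[["c1.ON"]], samples[["c1.OFF"]])
  expect_equal(fc$fold,
               geomean(c(100, 110, 95)) / geomean(c(9, 11, 10)))
})
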