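# shared fixture: one optimized reference on a reduced grid
sens_fixture <- function() {
  ss <- simulate_samples(30, "cucumber-like", noise = "low",
                         grid = seq(450, 950, 5), seed = 19)
  grid <- grid_config(step = 5, bandwidths = c(1, 10),
                      formulas = c("NDVI", "SR"))
  list(ss = ss, grid = grid, opt = optimize_bands(ss, "chl", grid))
}
fx <- sens_fixture()

test_that("zero-offset entry reproduces the reference metrics exactly", {
  sp <- shift_profile(fx$ss, fx$opt$overall, max_shift = 10, step = 5)
  z <- sp[sp$offset1 == 0 & sp$offset2 == 0, ]
  expect_equal(z$r2, fx$opt$overall$r2, tolerance = 1e-12)
  expect_equal(z$rmse, fx$opt$overall$rmse, tolerance = 1e-12)
  expect_equal(z$re_percent, fx$opt$overall$re_percent, tolerance = 1e-12)
})

test_that("no probed joint shift beats the exhaustive-search reference", {
  sp <- shift_profile(fx$ss, fx$opt$overall, max_shift = 20, step = 5)
  r2_ref <- sp$r2[sp$offset1 == 0]
  expect_true(all(sp$r2 <= r2_ref + 1e-12))
})

test_that("deviation maxima grow with the probed shift range", {
  sp20 <- shift_profile(fx$ss, fx$opt$overall, max_shift = 20, step = 5)
  sp5 <- shift_profile(fx$ss, fx$opt$overall, max_shift = 5, step = 5)
  expect_gte(max(sp20$max_dev_percent), max(sp5$max_dev_percent))
  expect_gte(max(sp20$mean_dev_percent), max(sp5$mean_dev_percent))
})

test_that("per-channel mode probes the 2-D offset grid and drops clipped offsets", {
  sp <- shift_profile(fx$ss, fx$opt$overall, max_shift = 10, step = 10,
                      mode = "per_channel")
  expect_lte(nrow(sp), 9)
  expect_true(any(sp$offset1 == 0 & sp$offset2 == 0))
  expect_true(any(sp$offset1 != sp$offset2))
  ref_far <- fx$opt$overall
  ref_far$lambda1 <- 455
  sp2 <- shift_profile(fx$ss, ref_far, max_shift = 20, step = 5)
  expect_gt(attr(sp2, "n_dropped"), 0)
  expect_true(all(ref_far$lambda1 + sp2$offset1 >= 450))
})

test_that("frozen-model drift differs from re-fitted profiles", {
  sp_refit <- shift_profile(fx$ss, fx$opt$overall, max_shift = 10, step = 5)
  sp_frozen <- shift_profile(fx$ss, fx$opt$overall, max_shift = 10,
                             step = 5, frozen = TRUE)
  off <- sp_refit$offset1 != 0
  # a frozen calibration cannot beat the re-fitted one on RMSE
  expect_true(all(sp_frozen$rmse[off] >= sp_refit$rmse[off] - 1e-9))
})

test_that("sensitivity outputs are pure functions of their inputs", {
  a <- shift_profile(fx$ss, fx$opt$overall, max_shift = 10, step = 5)
  b <- shift_profile(fx$ss, fx$opt$overall, max_shift = 10, step = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ba <- bandwidth_profile(fx$ss, fx$opt$overall)
  bb <- bandwidth_profile(fx$ss, fx$opt$overall)
  expect_identical(as.data.frame(ba), as.data.frame(bb))
})

test_that("bandwidth profile embeds the reference bandwidth exactly", {
  bw <- bandwidth_profile(fx$ss, fx$opt$overall,
                          bandwidths = c(1, 5, 10, 30, 50))
  ref_bw <- fx$opt$overall$dl1  # reference pair has equal widths here
  if (fx$opt$overall$dl1 == fx$opt$overall$dl2 && ref_bw %in% bw$dl1) {
    row <- bw[bw$dl1 == ref_bw, ]
    expect_equal(row$r2, fx$opt$overall$r2, tolerance = 1e-12)
  }
  expect_equal(nrow(bw), 5)
  expect_true(all(is.finite(bw$stability)))
})

test_that("single-channel bandwidth sweep holds the other channel fixed", {
  bw <- bandwidth_profile(fx$ss, fx$opt$overall, bandwidths = c(1, 10, 50),
                          mode = "channel1")
  expect_equal(unique(bw$dl2), fx$opt$overall$dl2)
  expect_equal(bw$dl1, c(1, 10, 50))
})

test_that("degenerate constant-spectrum samples are masked at every width", {
  ss0 <- fx$ss
  ss0$spectra$values[] <- 0.4  # no spectral contrast -> constant index
  bw <- bandwidth_profile(ss0, fx$opt$overall)
  expect_true(all(is.na(bw$r2)))
  expect_true(all(is.na(bw$rmse)))
})

test_that("formula comparison evaluates all formulas at identical bands", {
  o <- fx$opt$overall
  fc <- formula_comparison(fx$ss, o$lambda1, o$dl1, o$lambda2, o$dl2, "chl")
  expect_setequal(fc$metrics$formula, vi_formulas()$name)
  # the formula that defined the fixed channels reproduces its reference
  own <- fc$metrics[fc$metrics$formula == o$formula, ]
  expect_equal(own$r2, o$r2, tolerance = 1e-12)
  expect_equal(own$rmse, o$rmse, tolerance = 1e-12)
  # mean per-sample deviation equals the aggregate RE for every formula
  for (f in fc$metrics$formula) {
    expect_equal(mean(fc$per_sample[, f]),
                 fc$metrics$re_percent[fc$metrics$formula == f],
                 tolerance = 1e-12)
  }
  expect_equal(fc$metrics$rank, rank(-fc$metrics$r2, ties.method = "min"))
})

test_that("formula choice spreads R2 widely at the optimal channel pair", {
  ss <- simulate_samples(50, "cucumber-like", noise = "low", seed = 11,
                         grid = seq(450, 950, 5))
  opt <- optimize_bands(ss, "chl",
                        grid_config(step = 5, bandwidths = c(1, 10, 50)))
  o <- opt$overall
  fc <- formula_comparison(ss, o$lambda1, o$dl1, o$lambda2, o$dl2, "chl")
  expect_gte(max(fc$metrics$r2) - min(fc$metrics$r2), 0.2)
})
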