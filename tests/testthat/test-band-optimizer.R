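test_that("configuration enumeration counts follow the combinatorics", {
  expect_equal(nrow(enumerate_configs(grid_config())), 501 * 500)
  expect_equal(nrow(enumerate_configs(grid_config(step = 5))), 101 * 100)
  tiny <- enumerate_configs(grid_config(start = 450, stop = 470, step = 10))
  expect_equal(nrow(tiny), 6)  # 3 wavelengths -> 6 ordered pairs
  # deterministic row-major order, diagonal excluded
  expect_equal(tiny$lambda1[1:4], c(450, 450, 460, 460))
  expect_equal(tiny$lambda2[1:4], c(460, 470, 450, 470))
  expect_true(all(tiny$lambda1 != tiny$lambda2))
})

test_that("bandwidth pairing supports full product and equal-pair modes", {
  g1 <- grid_config(bandwidths = c(1, 10, 50))
  expect_equal(nrow(viband:::bandwidth_pairs(g1)), 9)
  g2 <- grid_config(bandwidths = c(1, 10, 50), pairing = "equal")
  p2 <- viband:::bandwidth_pairs(g2)
  expect_equal(nrow(p2), 3)
  expect_true(all(p2[, 1] == p2[, 2]))
})

test_that("vectorized maps equal the scalar per-cell engine", {
  ss <- toy_sample_set(n = 10, seed = 42)  # 9 centers
  grid <- grid_config(step = 60)
  for (f in c("NDVI", "SR", "DI", "TVI")) {
    mv <- evaluate_map(ss, "chl", f, dl1 = 10, dl2 = 10, grid = grid)
    msc <- evaluate_map(ss, "chl", f, dl1 = 10, dl2 = 10, grid = grid,
                        engine = "scalar")
    expect_equal(mv$valid, msc$valid, info = f)
    for (comp in c("r2", "rmse", "re")) {
      d <- abs(mv[[comp]] - msc[[comp]])
      expect_lt(max(d[mv$valid]), 1e-10)
    }
    # model parameters can be huge at ill-conditioned cells: compare
    # relatively there
    for (comp in c("a", "b")) {
      d <- abs(mv[[comp]] - msc[[comp]]) / pmax(1, abs(msc[[comp]]))
      expect_lt(max(d[mv$valid]), 1e-10)
    }
  }
})

test_that("identical pigment values mask every cell", {
  ss <- toy_sample_set(n = 6, seed = 1)
  ss$pigments$chl <- rep(5, 6)
  m <- evaluate_map(ss, "chl", "NDVI", 10, 10, grid_config(step = 100))
  expect_false(any(m$valid))
  expect_error(select_optimal(m), "masked")
})

test_that("DI map is symmetric in fit quality under band swap", {
  # swapping bands flips the sign of the DI predictor; the log-linear fit
  # flips b and leaves R2 unchanged
  ss <- toy_sample_set(n = 10, seed = 5)
  m <- evaluate_map(ss, "chl", "DI", 10, 10, grid_config(step = 50))
  expect_equal(m$r2, t(m$r2), tolerance = 1e-10)
  expect_equal(m$b, -t(m$b), tolerance = 1e-10)
})

test_that("selection maximizes R2 with RMSE and lexicographic tie-breaks", {
  ss <- toy_sample_set(n = 10, seed = 6)
  m <- evaluate_map(ss, "chl", "NDVI", 10, 10, grid_config(step = 50))
  best <- select_optimal(m)
  expect_equal(best$r2[1], max(m$r2[m$valid]))
  # single unmasked cell -> that cell is returned
  m1 <- m
  keep <- which(m1$valid, arr.ind = TRUE)[5, ]
  m1$valid[] <- FALSE
  m1$valid[keep[1], keep[2]] <- TRUE
  single <- select_optimal(m1)
  expect_equal(single$lambda1, m1$lambda1[keep[1]])
  expect_equal(single$lambda2, m1$lambda2[keep[2]])
  # constructed tie on R2: lower RMSE wins
  m2 <- m1
  m2$valid[] <- FALSE
  m2$valid[2, 3] <- TRUE; m2$valid[4, 5] <- TRUE
  m2$r2[2, 3] <- 0.9; m2$r2[4, 5] <- 0.9
  m2$rmse[2, 3] <- 0.5; m2$rmse[4, 5] <- 0.2
  tie <- select_optimal(m2)
  expect_equal(c(tie$lambda1, tie$lambda2),
               c(m2$lambda1[4], m2$lambda2[5]))
})

test_that("R2-max and RMSE-min criteria are compared per map", {
  ss <- toy_sample_set(n = 12, seed = 7)
  maps <- list(
    evaluate_map(ss, "chl", "NDVI", 10, 10, grid_config(step = 25)),
    evaluate_map(ss, "chl", "SR", 10, 10, grid_config(step = 25)))
  cmp <- compare_criteria(maps)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$shift1_nm >= 0))
  # the RMSE-criterion optimum can never beat the R2-criterion optimum on R2
  r2_best <- select_optimal(maps, criterion = "r2")
  rmse_best <- select_optimal(maps, criterion = "rmse")
  expect_gte(r2_best$r2[1], rmse_best$r2[1] - 1e-12)
  expect_lte(rmse_best$rmse[1], r2_best$rmse[1] + 1e-12)
})

test_that("full optimization run returns ranked results and config count", {
  ss <- toy_sample_set(n = 15, seed = 8)
  grid <- grid_config(step = 25, bandwidths = c(1, 10),
                      formulas = c("NDVI", "SR", "DI"))
  opt <- optimize_bands(ss, "chl", grid)
  nc <- length(seq(450, 950, 25))
  expect_equal(opt$n_configs, 3 * 4 * nc * (nc - 1))
  expect_equal(nrow(opt$results), 12)  # 3 formulas x 4 bandwidth pairs
  expect_true(all(diff(opt$results$r2) <= 1e-12))  # sorted by R2
  expect_equal(opt$overall$r2, opt$results$r2[1])
  # maps retained on demand
  opt2 <- optimize_bands(ss, "chl",
                         grid_config(step = 50, bandwidths = 10,
                                     formulas = "NDVI"), keep_maps = TRUE)
  expect_length(opt2$maps, 1)
  expect_s3_class(opt2$maps[[1]], "metric_map")
})

test_that("maps are deterministic given the samples", {
  ss <- toy_sample_set(n = 8, seed = 9)
  m1 <- evaluate_map(ss, "car", "SAVI", 10, 30, grid_config(step = 50))
  m2 <- evaluate_map(ss, "car", "SAVI", 10, 30, grid_config(step = 50))
  expect_identical(m1$r2, m2$r2)
  expect_identical(m1$rmse, m2$rmse)
})

test_that("map export round-trips as a long table and serializes to JSON", {
  ss <- toy_sample_set(n = 8, seed = 10)
  m <- evaluate_map(ss, "chl", "NDVI", 10, 10, grid_config(step = 100))
  df <- as.data.frame(m)
  nc <- length(m$lambda1)
  expect_equal(nrow(df), nc^2)
  cell <- df[df$lambda1_nm == m$lambda1[2] & df$lambda2_nm == m$lambda2[3], ]
  expect_equal(cell$r2, m$r2[2, 3])
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(select_optimal(m), path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$r2, select_optimal(m)$r2)
})

test_that("auxiliary-band formulas work across the searched grid", {
  ss <- toy_sample_set(n = 10, seed = 11)
  # mSR uses a 445 nm auxiliary band, clamped onto the 450 nm grid edge
  m <- evaluate_map(ss, "chl", "mSR", dl1 = 1, dl2 = 1,
                    grid = grid_config(step = 50))
  expect_true(any(m$valid))
  # overriding the auxiliary center moves the result
  m2 <- evaluate_map(ss, "chl", "mSR", dl1 = 1, dl2 = 1,
                     grid = grid_config(step = 50),
                     aux_centers = list(mSR = 500))
  expect_false(isTRUE(all.equal(m$r2, m2$r2)))
})
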