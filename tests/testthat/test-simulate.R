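test_that("instrument profiles carry the documented channel counts", {
  expect_equal(instrument_profile("micronir")$p, 125L)
  expect_equal(instrument_profile("mems")$p, 3108L)
  expect_equal(instrument_profile("raman")$p, 3122L)
  expect_equal(range(instrument_profile("raman")$axis), c(175, 3200))
})

test_that("mixture fractions live on the simplex within the design ranges", {
  cfg <- simulation_config(seed = 2)
  f <- sample_fractions(cfg)
  expect_equal(dim(f), c(59L, 4L))
  expect_equal(rowSums(f), rep(1, 59), tolerance = 1e-12)
  # the default clip limits are the mixing-design bounds
  expect_equal(cfg$fraction_ranges[, 2], c(0.8546, 0.6934, 0.8835, 0.8546))
  for (j in 1:4)
    expect_true(all(f[, j] >= cfg$fraction_ranges[j, 1] &
                    f[, j] <= cfg$fraction_ranges[j, 2]))
  expect_identical(sample_fractions(cfg), f)  # seeded
  expect_error(
    simulation_config(fraction_ranges = cbind(rep(0.5, 4), rep(0.6, 4))),
    "infeasible")
})

test_that("a pure component with zero noise gives its spectrum plus baseline", {
  cfg <- simulation_config(noise_sd_spectral = 0, noise_sd_response = 0,
                           seed = 3)
  frac <- matrix(0, 2, 4); frac[, 2] <- 1  # pure olive, twice
  g <- generate_dataset(cfg, fractions = frac)
  expect_equal(g$dataset$X[1, ], g$dataset$X[2, ], tolerance = 1e-12)
  expect_equal(g$dataset$y, rep(cfg$components[[2]]$iodine_value, 2))
  # hand-summed Gaussian bands + baseline reproduce the row exactly
  bands <- cfg$components[[2]]$bands
  axis <- cfg$profile$axis
  pure <- rowSums(sapply(seq_len(nrow(bands)), function(b)
    bands$amplitude[b] *
      exp(-0.5 * ((axis - bands$center[b]) / bands$width[b])^2)))
  expect_equal(g$dataset$X[1, ], pure + g$baseline, tolerance = 1e-12)
})

test_that("zero noise makes the response an exact bilinear PLS model", {
  cfg <- simulation_config(noise_sd_spectral = 0, noise_sd_response = 0,
                           seed = 4)
  g <- generate_dataset(cfg)
  ivs <- vapply(cfg$components, `[[`, numeric(1), "iodine_value")
  expect_equal(g$dataset$y, as.numeric(g$fractions %*% ivs),
               tolerance = 1e-12)
  # PLS with 3 LVs (4 simplex fractions = 3 free dimensions) is exact
  Xc <- scale(g$dataset$X, scale = FALSE)
  yc <- g$dataset$y - mean(g$dataset$y)
  m <- fit_pls(Xc, yc, 3)
  expect_lt(rmse(yc, as.numeric(Xc %*% m$coef_b)), 1e-6)
})

test_that("realised iodine values span the expected blend range", {
  yr <- range(sapply(1:5, function(s)
    range(generate_dataset(simulation_config(seed = s))$dataset$y)))
  expect_lte(yr[1], 91)   # low end near 86
  expect_gte(yr[2], 121)  # high end near 126
  expect_gte(yr[1], 81)
  expect_lte(yr[2], 131)
})

test_that("planting an uninformative region removes it from the truth mask", {
  g <- generate_dataset(simulation_config(seed = 6))
  pl <- plant_uninformative_region(g$dataset, g$truth, c(1150, 1250),
                                   noise_sd = 0.01, seed = 6)
  idx <- which(g$dataset$axis >= 1150 & g$dataset$axis <= 1250)
  expect_length(intersect(pl$truth, idx), 0)
  expect_s3_class(pl$dataset, "spectral_dataset")
  # planted channels decorrelate from the response: their |r| is
  # consistent with the null band for n = 59
  r <- abs(cor(pl$dataset$X[, idx], pl$dataset$y))
  expect_lt(max(r), 0.45)
  expect_error(
    plant_uninformative_region(g$dataset, g$truth, c(900, 1700)),
    "every informative channel")
})

test_that("spectral noise degrades full-spectrum cross-validation", {
  rmsecvs <- sapply(c(0.001, 0.05, 0.5), function(ns) {
    g <- generate_dataset(simulation_config(noise_sd_spectral = ns,
                                            seed = 7))
    min(kfold_cv(g$dataset$X, g$dataset$y, seed = 7)$rmsecv_by_nlv)
  })
  expect_true(all(diff(rmsecvs) > 0))
})

test_that("the planted fixture has its stated geometry and truth mask", {
  pd <- planted_dataset(seed = 5)
  expect_equal(dim(pd$dataset$X), c(59L, 125L))
  expect_length(pd$truth, 5)
  expect_true(all(pd$truth %in% seq_len(125)))
  # planted channels correlate with the response well beyond the bulk
  # of the noise channels
  r <- abs(cor(pd$dataset$X, pd$dataset$y))
  expect_gt(mean(r[pd$truth]), quantile(r[-pd$truth], 0.95))
  expect_identical(planted_dataset(seed = 5)$dataset$X, pd$dataset$X)
})
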