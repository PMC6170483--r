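test_that("construction validates shape, axis and missing values", {
  X <- matrix(1:6, 2, 3)
  expect_s3_class(spectral_dataset(X, c(1, 2, 3), c(5, 6)),
                  "spectral_dataset")
  expect_error(spectral_dataset(X, c(1, 2), c(5, 6)), "axis")
  expect_error(spectral_dataset(X, c(1, 3, 2), c(5, 6)), "monotone|increasing")
  expect_error(spectral_dataset(X, c(1, 2, 3), c(5, 6, 7)), "length of y")
  Xna <- X; Xna[1, 2] <- NA
  expect_error(spectral_dataset(Xna, c(1, 2, 3), c(5, 6)), "missing")
  expect_error(spectral_dataset(X, c(1, 2, 3), c(5, 6),
                                sample_ids = c("a", "a")), "duplicate")
  # decreasing axis (wavenumber convention) is allowed
  expect_s3_class(spectral_dataset(X, c(3, 2, 1), c(5, 6)),
                  "spectral_dataset")
})

test_that("CSV I/O round-trips and rejects bad cells with locations", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,900,950,1000,1050,IV",
               "S1,0.1,0.2,0.3,0.4,95.5",
               "S2,0.5,0.6,0.7,0.8,102",
               "S3,0.9,1,1.1,1.2,110.25"), f)
  ds <- read_dataset(f)
  expect_equal(dim(ds$X), c(3L, 4L))
  expect_equal(ds$axis, c(900, 950, 1000, 1050))
  expect_equal(ds$y, c(95.5, 102, 110.25))
  expect_equal(ds$sample_ids, c("S1", "S2", "S3"))

  # write(read(f)) reproduces the file content
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f2)
  expect_identical(readLines(f2), readLines(f))

  # round trip through write/read preserves values exactly
  ds2 <- read_dataset(f2)
  expect_identical(ds2$X, ds$X)
  expect_identical(ds2$axis, ds$axis)
  expect_identical(ds2$y, ds$y)

  # an empty cell is rejected with its location
  writeLines(c("sample_id,900,950,1000,1050,IV",
               "S1,0.1,,0.3,0.4,95.5",
               "S2,0.5,0.6,0.7,0.8,102"), f)
  expect_error(read_dataset(f), "row 1, column '950'")
  writeLines(c("sample_id,900,950,1000,1050,IV",
               "S1,0.1,0.2,0.3,0.4,95.5",
               "S2,0.5,abc,0.7,0.8,102"), f)
  expect_error(read_dataset(f), "row 2.*'950'")
})

test_that("mean_center centers on calibration statistics only", {
  # calibration rows (1, 0) and (3, 0); test row (2, 5): the test block
  # is centered with the calibration means (2, 0), not its own
  ds <- spectral_dataset(rbind(c(1, 0), c(3, 0), c(2, 5)),
                         axis = c(1, 2), y = c(10, 20, 15))
  split <- structure(list(cal_indices = c(1L, 2L), test_indices = 3L),
                     class = "split_result")
  mc <- mean_center(ds, split)
  expect_equal(colMeans(mc$X_cal), c(0, 0), tolerance = 1e-10)
  expect_equal(as.numeric(mc$X_test), c(0, 5))
  expect_equal(mc$y_cal, c(-5, 5))
  expect_equal(mc$y_test, 0)
  # un-centering recovers the originals
  expect_equal(sweep(mc$X_cal, 2, mc$centering$x_means, "+"),
               ds$X[1:2, ], tolerance = 1e-12)
  expect_equal(mc$y_test + mc$centering$y_mean, ds$y[3], tolerance = 1e-12)
})

test_that("Kennard-Stone seeds with the extreme pair and is greedy", {
  # n = 2: both samples are calibration
  ds2 <- spectral_dataset(rbind(c(0, 0), c(1, 1)), c(1, 2), c(0, 1))
  expect_setequal(kennard_stone_split(ds2, 2)$cal_indices, 1:2)

  # 1-D geometry {0, 1, 10}: the max-distance pair is {0, 10}
  ds3 <- spectral_dataset(cbind(c(0, 1, 10), 0), c(1, 2), c(0, 1, 10))
  expect_setequal(kennard_stone_split(ds3, 2)$cal_indices, c(1L, 3L))
  # the third pick is the max-min-distance point
  expect_equal(sort(kennard_stone_split(ds3, 3)$cal_indices), 1:3)

  expect_error(kennard_stone_split(ds3, 1), "n_cal")
})

test_that("Kennard-Stone matches the brute-force greedy oracle", {
  set.seed(11)
  for (trial in 1:40) {
    n <- sample(3:8, 1); p <- sample(2:5, 1)
    X <- matrix(round(rnorm(n * p), 3), n, p)
    ds <- spectral_dataset(X, seq_len(p), rnorm(n))
    n_cal <- sample(2:n, 1)
    sp <- kennard_stone_split(ds, n_cal)
    expect_identical(sp$cal_indices, as.integer(ks_reference(X, n_cal)))
    # partition property
    expect_setequal(c(sp$cal_indices, sp$test_indices), seq_len(n))
  }
})

test_that("Kennard-Stone is permutation-covariant and handles ties", {
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  ds <- spectral_dataset(X, c(1, 2), rnorm(6))
  sp <- kennard_stone_split(ds, 4)
  perm <- sample(6)
  dsp <- spectral_dataset(X[perm, ], c(1, 2), ds$y[perm])
  spp <- kennard_stone_split(dsp, 4)
  expect_setequal(perm[spp$cal_indices], sp$cal_indices)

  # degenerate all-identical rows: forced ties resolve by index order
  dsi <- spectral_dataset(matrix(1, 5, 3), 1:3, rnorm(5))
  expect_identical(kennard_stone_split(dsi, 3)$cal_indices, c(1L, 2L, 3L))
})

test_that("subset_channels keeps a valid dataset", {
  ds <- toy_dataset()
  sub <- subset_channels(ds, c(7, 2, 5))
  expect_equal(sub$axis, c(2, 5, 7))
  expect_equal(sub$X, ds$X[, c(2, 5, 7)])
  expect_error(subset_channels(ds, c(2, 2, 5)), "invalid")
})
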