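test_that("taper_fft bins sit at integer Hz for 1-s epochs and zero in gives zero out", {
  ep <- make_epoch_set(array(0, c(500, 2, 3)), fs = 500)
  sp <- taper_fft(ep)
  expect_equal(sp$freq, 0:250)
  expect_true(all(Mod(sp$coefficients) == 0))
  expect_equal(dim(sp$coefficients), c(251L, 2L, 3L))
})

test_that("Hanning main lobe of a pure 8 Hz sine covers bins 7-9 with the 8 Hz bin dominant", {
  fs <- 500
  x <- sin(2 * pi * 8 * (0:(fs - 1)) / fs)
  sp <- taper_fft(make_epoch_set(array(x, c(fs, 1, 1)), fs = fs))
  pw <- Mod(sp$coefficients[, 1, 1])^2
  nondc <- sum(pw[-1])
  expect_equal(which.max(pw[-1]), 8L)                    # argmax at 8 Hz
  expect_equal(pw[9] / nondc, 2 / 3, tolerance = 0.01)   # Hann 0.25/0.5/0.25
  expect_gt(sum(pw[8:10]) / nondc, 0.99)                 # main lobe 7-9 Hz
})

test_that("power spectrum scales quadratically and reduces to the periodogram", {
  set.seed(1)
  arr <- array(rnorm(100 * 2 * 5), c(100, 2, 5))
  ep1 <- make_epoch_set(arr, fs = 100)
  ep2 <- make_epoch_set(2 * arr, fs = 100)
  expect_equal(power_spectrum(taper_fft(ep2)),
               4 * power_spectrum(taper_fft(ep1)))
  single <- make_epoch_set(arr[, , 1, drop = FALSE], fs = 100)
  sp <- taper_fft(single)
  expect_equal(power_spectrum(sp)[1, ],
               setNames(Mod(sp$coefficients[, 1, 1])^2 / 100,
                        as.character(sp$freq)))
  expect_true(all(power_spectrum(taper_fft(
    make_epoch_set(array(0, c(100, 1, 2)), fs = 100))) == 0))
})

test_that("dbwpli matches its closed-form on two-epoch degenerate cases", {
  # place Im X = F_a * Conj(F_b) by hand: F_a = i*c, F_b = 1 => Im X = c
  two_epoch_spec <- function(imx) {
    coef <- array(complex(real = 0), dim = c(9, 2, length(imx)))
    coef[8, 1, ] <- complex(imaginary = imx)
    coef[8, 2, ] <- 1
    make_spectral_tensor(coef)
  }
  expect_equal(dbwpli(two_epoch_spec(c(1, 1)), band = c(7, 7))[1, 2], 1)
  expect_equal(dbwpli(two_epoch_spec(c(1, -1)), band = c(7, 7))[1, 2], -1)
  expect_true(is.na(dbwpli(two_epoch_spec(c(1, 0)), band = c(7, 7))[1, 2]))
  expect_error(dbwpli(two_epoch_spec(c(1, 1)), band = c(100, 200)), "no frequency bin")
  expect_error(dbwpli(make_spectral_tensor(random_tensor(9, 2, 1)),
                      band = c(7, 8)), "at least 2 epochs")
})

test_that("vectorised dbwpli equals the pairwise-product oracle on random tensors", {
  set.seed(99)
  worst <- 0
  for (k in 1:100) {
    nch <- sample(2:5, 1L)
    nep <- sample(3:10, 1L)
    coef <- random_tensor(9, nch, nep)
    sp <- make_spectral_tensor(coef)
    got <- dbwpli(sp, band = c(6, 8))
    want <- dbwpli_matrix_oracle(coef, bins = 7:9)
    expect_equal(unclass(got), want, tolerance = 1e-10,
                 ignore_attr = TRUE)
    worst <- max(worst, max(abs(got - want), na.rm = TRUE))
  }
  expect_lt(worst, 1e-10)
})

test_that("dbwpli is symmetric, bounded by 1 and near zero for independent noise", {
  set.seed(5)
  sp <- make_spectral_tensor(random_tensor(9, 8, 200))
  m <- dbwpli(sp, band = c(7, 8))
  expect_identical(unclass(m), unclass(t(m)))
  expect_true(all(is.na(diag(m))))
  expect_true(all(m[lower.tri(m)] <= 1, na.rm = TRUE))
  expect_lt(abs(mean(m[lower.tri(m)], na.rm = TRUE)), 0.05)
})

test_that("dbwpli on a planted pair grows toward 1 with epoch count", {
  vals <- vapply(c(20, 80, 320), function(nep) {
    mean(vapply(1:3, function(seed) {
      set.seed(seed)
      # strength < 1 so the estimate is genuinely below 1 at small n
      coef <- random_tensor(9, 2, nep)
      phase <- pi / 2 + rnorm(nep, sd = 1.2)
      coef[8, 1, ] <- complex(modulus = 1, argument = phase)
      coef[8, 2, ] <- 1
      dbwpli(make_spectral_tensor(coef), band = c(7, 7))[1, 2]
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(vals) > 0))
})

test_that("global and masked means average defined lower-triangle entries", {
  m <- matrix(NA_real_, 3, 3)
  m[2, 1] <- m[1, 2] <- 0.1
  m[3, 1] <- m[1, 3] <- 0.2
  m[3, 2] <- m[2, 3] <- 0.3
  expect_equal(global_dbwpli(m), 0.2)
  expect_equal(global_dbwpli(matrix(0.7, 4, 4)), 0.7)
  m[3, 1] <- m[1, 3] <- NA
  expect_equal(global_dbwpli(m), 0.2)   # missing-aware
  m[] <- NA
  expect_true(is.na(global_dbwpli(m)))

  m2 <- matrix(NA_real_, 3, 3)
  m2[2, 1] <- m2[1, 2] <- 0.1
  m2[3, 2] <- m2[2, 3] <- 0.3
  m2[3, 1] <- m2[1, 3] <- 0.8
  mask <- edge_mask(cbind(c(1, 2), c(2, 3)), channels = 3)
  expect_equal(masked_mean(m2, mask), 0.2)
  full <- edge_mask(t(utils::combn(3, 2)), channels = 3)
  expect_equal(masked_mean(m2, full), global_dbwpli(m2))
  empty <- edge_mask(matrix(numeric(0), 0, 2), channels = 3)
  expect_error(masked_mean(m2, empty), "no connection")
})

test_that("connectivity matrices and edge masks round-trip through CSV", {
  set.seed(3)
  sp <- make_spectral_tensor(random_tensor(9, 4, 10))
  m <- dbwpli(sp, band = c(7, 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity(m, path)
  m2 <- read_connectivity(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12,
               ignore_attr = "bins")
  expect_equal(attr(m2, "band"), c(7, 8))

  mask <- edge_mask(cbind(c(1, 3), c(2, 4)), channels = rownames(m))
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_edge_mask(mask, mpath)
  expect_equal(unclass(read_edge_mask(mpath, rownames(m))), unclass(mask))
})
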