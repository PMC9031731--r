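test_that("GFP matches closed forms", {
  expect_equal(gfp_at_freq(rep(2 + 0i, 21) * exp(1i)), 2)
  expect_equal(gfp_at_freq(c(1, 2, 3, 4) * exp(1i * c(0, 1, 2, 3))),
               sqrt(7.5))
  expect_equal(gfp_at_freq(rep(0i, 5)), 0)
  expect_error(gfp_at_freq(1 + 0i), "channels")
})

test_that("GFP is absolutely homogeneous: gfp(a x) = |a| gfp(x)", {
  set.seed(8)
  for (i in 1:20) {
    z <- complex(real = rnorm(21), imaginary = rnorm(21))
    a <- rnorm(1)
    expect_equal(gfp_at_freq(a * z), abs(a) * gfp_at_freq(z),
                 tolerance = 1e-12)
  }
})

test_that("GFS identities: collinear cloud is 1, isotropic cloud is 0", {
  # all channels share one phase (real multiples of one complex number)
  z0 <- exp(1i * 0.7)
  expect_equal(gfs_at_freq(c(1, -2, 0.5, 3) * z0), 1)
  # two channels, equal amplitude, phases 0 and pi/2 -> exactly 0
  a <- 2.3
  expect_identical(gfs_at_freq(c(a + 0i, a * 1i)), 0)
  expect_error(gfs_at_freq(rep(0i, 4)), "silent frequency")
})

test_that("GFS is invariant to any nonzero complex global scaling", {
  set.seed(9)
  for (i in 1:50) {
    z <- complex(real = rnorm(21), imaginary = rnorm(21))
    c0 <- complex(real = rnorm(1), imaginary = rnorm(1))
    expect_equal(gfs_at_freq(c0 * z), gfs_at_freq(z), tolerance = 1e-12)
  }
})

test_that("GFS stays in [0, 1] on random complex inputs", {
  set.seed(10)
  for (i in 1:500) {
    k <- sample(2:30, 1)
    z <- complex(real = rnorm(k, sd = 10^runif(1, -3, 3)),
                 imaginary = rnorm(k, sd = 10^runif(1, -3, 3)))
    g <- gfs_at_freq(z)
    expect_gte(g, 0)
    expect_lte(g, 1)
  }
})

test_that("closed-form 2x2 eigenvalues agree with the generic eigensolver", {
  set.seed(11)
  max_diff <- 0
  for (i in 1:10000) {
    z <- complex(real = rnorm(21), imaginary = rnorm(21))
    M <- cbind(Re(z), Im(z))
    ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
    oracle <- (ev[1] - ev[2]) / (ev[1] + ev[2])
    max_diff <- max(max_diff, abs(gfs_at_freq(z) - oracle))
  }
  expect_lt(max_diff, 1e-12)
})

test_that("mean GFS of random-phase unit-amplitude draws matches the oracle", {
  oracle <- gfs_chance(21, n_draws = 10000, amplitude = "unit", seed = 12)
  # same draws recomputed through the generic eigensolver
  set.seed(12)
  generic <- vapply(seq_len(10000), function(i) {
    z <- exp(2i * pi * runif(21))
    M <- cbind(Re(z), Im(z))
    ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
    (ev[1] - ev[2]) / (ev[1] + ev[2])
  }, numeric(1))
  expect_equal(oracle$mean, mean(generic), tolerance = 1e-12)
})

test_that("subject features: full synchronization, epoch idempotence", {
  rec <- simulate_eeg(eeg_sim_spec(duration = 10, noise_amp = 0, bg_amp = 0,
                                   seed = 13))
  ft <- quick_features(rec)
  expect_true(all(ft$gfs_band > 0.99))
  expect_true(all(ft$gfp_band >= 0))
  expect_equal(ft$n_epochs_used, 5)

  # duplicating the epochs leaves per-epoch-averaged features unchanged
  rec2 <- rec
  rec2$data <- cbind(rec$data, rec$data)
  ft2 <- quick_features(rec2)
  expect_equal(ft2$gfs_band, ft$gfs_band, tolerance = 1e-12)
  expect_equal(ft2$gfp_band, ft$gfp_band, tolerance = 1e-12)
})

test_that("band values equal the unweighted mean of in-band bins", {
  rec <- quick_sim(1, duration = 10, seed = 14, bg_amp = 1)
  ft <- quick_features(rec)
  for (b in ft$bands) {
    sel <- ft$freqs >= b$f_lo & ft$freqs <= b$f_hi
    expect_equal(unname(ft$gfp_band[b$name]), mean(ft$gfp_by_freq[sel]))
    expect_equal(unname(ft$gfs_band[b$name]), mean(ft$gfs_by_freq[sel]))
  }
})

test_that("raising alpha common amplitude raises alpha GFP and leaves other-band GFS stable", {
  base <- c(delta = 1.5, theta = 1, alpha = 3, beta = 0.5)
  ft_of <- function(c_alpha, seed) {
    amp <- base
    amp["alpha"] <- c_alpha
    rec <- simulate_eeg(eeg_sim_spec(duration = 30, common_amp = amp,
                                     noise_amp = base, bg_amp = 1,
                                     seed = seed))
    quick_features(rec)
  }
  lo <- ft_of(1, seed = 15)
  hi <- ft_of(4, seed = 15)
  expect_gt(hi$gfp_band["alpha"], lo$gfp_band["alpha"])
  expect_gt(hi$gfs_band["alpha"], lo$gfs_band["alpha"])
  for (b in c("delta", "theta", "beta"))
    expect_lt(abs(hi$gfs_band[b] - lo$gfs_band[b]), 0.1)
})

test_that("pooled GFS mode matches per-epoch mode for a fully common source", {
  rec <- simulate_eeg(eeg_sim_spec(duration = 10, noise_amp = 0, bg_amp = 0,
                                   seed = 16))
  rec <- apply_average_reference(rec)
  sp <- spectra(epoch_and_screen(rec, Inf))
  per <- features_for_subject(sp, gfs_mode = "per_epoch")
  pooled <- features_for_subject(sp, gfs_mode = "pooled")
  expect_true(all(pooled$gfs_band > 0.99))
  expect_equal(per$gfp_band, pooled$gfp_band)
})
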