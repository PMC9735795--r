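test_that("two-proton absorbance model reproduces limits and direct values", {
  f <- list(pk1 = 7.5, pk2 = 8.6, a0 = 0.1, a1 = 0.3, a2 = 0.5)
  # fully protonated / deprotonated limits
  expect_equal(predict_titration_absorbance(f, f$pk1 - 6), f$a0,
               tolerance = 1e-4)
  expect_equal(predict_titration_absorbance(f, f$pk2 + 6), f$a2,
               tolerance = 1e-4)
  # all exponent terms equal to one
  f2 <- list(pk1 = 8, pk2 = 8, a0 = 0, a1 = 0.5, a2 = 1)
  expect_equal(predict_titration_absorbance(f2, 8), (0 + 0.5 + 2) / 4)
  expect_error(predict_titration_absorbance(
    list(pk1 = NA, pk2 = 8, a0 = 0, a1 = 0, a2 = 1), 7),
    class = "zf_invalid_parameter")
})

test_that("absorbance model is monotone and bounded for ordered plateaus", {
  ph <- seq(2, 13, by = 0.05)
  for (pks in list(c(6, 9), c(7.2, 7.9), c(8, 8))) {
    f <- list(pk1 = pks[1], pk2 = pks[2], a0 = 0.05, a1 = 0.3, a2 = 0.61)
    a <- predict_titration_absorbance(f, ph)
    expect_true(all(diff(a) >= -1e-12))
    expect_true(all(a >= f$a0 - 1e-12 & a <= f$a2 + 1e-12))
  }
})

test_that("average protonation matches the partition-function oracle on a grid", {
  pks <- seq(5, 10, length.out = 10)
  phs <- seq(4, 11, length.out = 10)
  for (pk1 in pks) for (pk2 in pks) for (ph in phs) {
    expect_equal(average_protonation(pk1, pk2, ph),
                 oracle_protonation(pk1, pk2, ph), tolerance = 1e-10)
  }
})

test_that("average protonation limits and monotonicity hold", {
  expect_equal(average_protonation(8, 8, 8), 1)
  expect_equal(average_protonation(8, 8, 0), 2, tolerance = 1e-6)
  expect_equal(average_protonation(8, 8, 16), 0, tolerance = 1e-6)
  n <- average_protonation(7.2, 8.5, seq(3, 12, 0.1))
  expect_true(all(diff(n) <= 1e-12))
  expect_true(all(n >= 0 & n <= 2))
})

test_that("pKa fit recovers generator truth", {
  # noiseless: self-consistency to machine-ish precision
  f0 <- fit_pka(gen_ph_titration(pk1 = 7.6, pk2 = 8.8, noise_sd = 0))
  expect_equal(f0$pk1, 7.6, tolerance = 1e-6)
  expect_equal(f0$pk2, 8.8, tolerance = 1e-6)
  expect_equal(f0$a1, 0.30, tolerance = 1e-6)
  # instrument-scale noise
  f1 <- fit_pka(gen_ph_titration(pk1 = 7.6, pk2 = 8.8, noise_sd = 0.002,
                                 seed = 1))
  expect_lt(abs(f1$pk1 - 7.6), 0.05)
  expect_lt(abs(f1$pk2 - 8.8), 0.05)
  expect_true(f1$pk1 <= f1$pk2)
})

test_that("pKa recovery is unbiased over repeated noise realisations", {
  errs <- vapply(1:50, function(s) {
    f <- fit_pka(gen_ph_titration(pk1 = 7.6, pk2 = 8.8, noise_sd = 0.002,
                                  seed = s))
    c(f$pk1 - 7.6, f$pk2 - 8.8)
  }, numeric(2))
  for (i in 1:2) {
    expect_lt(abs(mean(errs[i, ])), 2 * sd(errs[i, ]) / sqrt(50))
  }
})

test_that("degenerate titration input is rejected", {
  expect_error(fit_pka(data.frame(ph = 1:4, absorbance = 1:4)),
               class = "zf_insufficient_data")
  flat <- data.frame(ph = seq(3, 8, 0.5), absorbance = 0.2)
  expect_error(fit_pka(flat), class = "zf_fit_failure")
  expect_error(ph_titration_curve(c(3, 2, 4, 5, 6, 7, 8, 9), rep(0.1, 8)),
               class = "zf_invalid_input")
})

test_that("Hill model evaluates limits and direct values", {
  f <- list(theta_min = -10000, theta_max = -4000, hill_n = 1,
            zn_half = 1e-13)
  expect_equal(predict_hill(f, 9e-13), -10000 * 0.9 + -4000 * 0.1)
  expect_equal(predict_hill(f, 0), f$theta_max)
  expect_equal(predict_hill(f, f$zn_half),
               (f$theta_min + f$theta_max) / 2)
  expect_error(predict_hill(f, -1e-13), class = "zf_invalid_input")
})

test_that("Hill fit recovers generator truth", {
  h0 <- fit_hill(gen_competition_series(kd = 5e-13, noise_frac = 0))
  expect_equal(h0$zn_half, 5e-13, tolerance = 1e-6)
  expect_equal(h0$hill_n, 1, tolerance = 1e-6)
  h1 <- fit_hill(gen_competition_series(kd = 5e-13, hill_n = 1,
                                        noise_frac = 0.01, seed = 7))
  expect_lt(abs(h1$zn_half / 5e-13 - 1), 0.10)
})

test_that("Hill fit is unbiased over repeated noise realisations", {
  err <- vapply(1:50, function(s) {
    fit_hill(gen_competition_series(kd = 5e-13, seed = s))$zn_half / 5e-13 - 1
  }, numeric(1))
  expect_lt(abs(mean(err)), 2 * sd(err) / sqrt(50))
})

test_that("Hill fit rejects insufficient or non-spanning series", {
  expect_error(fit_hill(data.frame(pzn = c(12, 13, 14),
                                   ellipticity = c(-9, -7, -5) * 1e3)),
               class = "zf_insufficient_data")
  # plateau-only sampling: far above the transition
  s <- gen_competition_series(kd = 5e-13, pzn_grid = seq(15.5, 18, 0.25),
                              noise_frac = 0.001, seed = 2)
  expect_error(fit_hill(s), class = "zf_error")
})

test_that("replicate ellipticity readings are averaged before fitting", {
  s <- gen_competition_series(kd = 5e-13, noise_frac = 0)
  d <- s$data
  dup <- rbind(d, transform(d, ellipticity = ellipticity + 100),
               transform(d, ellipticity = ellipticity - 100))
  h <- fit_hill(dup)
  expect_equal(h$zn_half, 5e-13, tolerance = 1e-6)
})

test_that("Kd follows from the half-saturation free Zn", {
  mk <- function(zh) structure(list(theta_min = -1, theta_max = 0,
                                    hill_n = 1, zn_half = zh),
                               class = "hill_fit")
  expect_equal(kd_from_hill(mk(5.01e-13))$neg_log_kd, 12.30, tolerance = 5e-4)
  expect_equal(kd_from_hill(mk(1e-14))$neg_log_kd, 14)
  expect_equal(signif(kd_from_hill(mk(3.24e-15))$kd * 1e15, 2), 3.2)
  expect_error(kd_from_hill(mk(-1)), class = "zf_invalid_fit")
})

test_that("competition round-trip recovers -logKd across the affinity range", {
  for (nlk in c(12.3, 13.5, 14.5)) {
    s <- gen_competition_series(kd = 10^(-nlk), seed = 7)
    got <- kd_from_hill(fit_hill(s))$neg_log_kd
    expect_lt(abs(got - nlk), 0.1)
  }
})

test_that("titration and competition CSV round-trips preserve data", {
  tmp <- tempfile(fileext = ".csv")
  cur <- gen_ph_titration(seed = 4)
  write_titration_csv(cur, tmp)
  cur2 <- read_titration_csv(tmp)
  expect_equal(cur2$data$absorbance, cur$data$absorbance, tolerance = 1e-12)
  s <- gen_competition_series(seed = 4)
  write_competition_csv(s, tmp)
  s2 <- read_competition_csv(tmp)
  expect_equal(s2$data$ellipticity, s$data$ellipticity, tolerance = 1e-12)
  unlink(tmp)
})
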