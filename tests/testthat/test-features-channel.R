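test_that("time-domain features match closed forms", {
  const <- time_domain_features(rep(2, 1000))
  expect_equal(unname(const[c("TF_02", "TF_03", "TF_04", "TF_05", "TF_06",
                              "TF_07")]),
               c(2, 2, 0, 0, 0, 0))   # AEMG, RMS, var, WL, ZC, SSC
  expect_equal(unname(const[["TF_09"]]), 2)  # log detector of a constant

  two <- time_domain_features(c(3, -4))
  expect_equal(unname(two[["TF_01"]]), 7)        # IEMG
  expect_equal(unname(two[["TF_02"]]), 3.5)      # AEMG
  expect_equal(unname(two[["TF_03"]]), sqrt(12.5))

  n <- 400
  alt <- rep(c(1, -1), n / 2)
  expect_equal(unname(time_domain_features(alt)[["TF_06"]]), n - 1)

  expect_error(time_domain_features(c(1)), "at least 2")
  expect_length(time_domain_features(rnorm(500)), 11)
})

test_that("spectral features agree with periodogram oracles on tones", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  ff <- frequency_domain_features(sin(2 * pi * 100 * t), fs = fs)
  res <- fs / 512   # Welch bin width
  expect_lt(abs(ff[["FF_01"]] - 100), 2 * res)  # MF
  expect_lt(abs(ff[["FF_02"]] - 100), 2 * res)  # MPF
  expect_lt(abs(ff[["FF_03"]] - 100), res)      # peak

  # independent periodogram oracle for the peak
  x <- sin(2 * pi * 100 * t)
  pg <- Mod(fft(x))^2
  f_or <- (seq_along(pg) - 1) * fs / length(pg)
  expect_equal(f_or[which.max(pg[f_or <= fs / 2])], 100, tolerance = 1)

  # equal-power two-tone mixture: power-weighted mean sits midway
  ff2 <- frequency_domain_features(sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t),
                                   fs = fs)
  expect_lt(abs(ff2[["FF_02"]] - 100), 2)

  # flat spectrum: MPF near fs/4
  set.seed(1)
  ffw <- frequency_domain_features(rnorm(2^15), fs = fs)
  expect_lt(abs(ffw[["FF_02"]] - 250) / 250, 0.05)

  expect_error(frequency_domain_features(rep(0, 1000), fs = fs),
               "degenerate spectrum")
  expect_length(ff, 14)
})

test_that("wavelet energies conserve signal energy and normalize", {
  set.seed(2)
  x <- rnorm(4096)
  wf <- wavelet_features(x)
  expect_length(wf, 23)
  # Parseval over D1..D4 + A4
  expect_lt(abs(sum(wf[1:5]) - sum(x^2)) / sum(x^2), 1e-6)
  expect_equal(unname(wf[["WL_06"]]), sum(wf[1:5]), tolerance = 1e-9)
  # packet relative energies sum to one; absolute packets conserve energy
  expect_equal(sum(wf[16:23]), 1, tolerance = 1e-9)
  expect_lt(abs(sum(wf[8:15]) - sum(x^2)) / sum(x^2), 1e-6)

  # a 10 Hz tone at fs = 1000 lives in the deepest approximation band
  xs <- sin(2 * pi * 10 * seq(0, 4, by = 1e-3))
  wfs <- wavelet_features(xs)
  expect_equal(which.max(wfs[1:5]), 5L, ignore_attr = TRUE)  # A4

  expect_error(wavelet_features(rnorm(64)), ">= 128")
})

test_that("Burg autoregressive coefficients recover a known AR(1)", {
  set.seed(3)
  n <- 10000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  a <- ar_features(x)
  expect_length(a, 14)
  expect_lt(abs(a[["AR_01"]] - 0.9), 0.05)
  expect_true(all(abs(a[3:14]) <= 0.05))
  # independent Yule-Walker oracle agrees on the dominant coefficient
  yw <- stats::ar(x, aic = FALSE, order.max = 14, method = "yule-walker")
  expect_lt(abs(a[["AR_01"]] - yw$ar[1]), 0.02)

  set.seed(4)
  aw <- ar_features(rnorm(10000))
  expect_true(all(abs(aw) <= 0.05))
  expect_error(ar_features(rep(1, 1000)), "zero-variance")
})

test_that("sample entropy separates order from shuffle and is symmetric", {
  expect_equal(unname(sample_entropy(rep(5, 500))), 0)
  set.seed(5)
  x <- rnorm(400)
  expect_equal(unname(sample_entropy(x)), unname(sample_entropy(rev(x))))
  wins <- vapply(1:20, function(i) {
    set.seed(i)
    s <- sin(2 * pi * 5 * seq(0, 1, length.out = 600))
    sample_entropy(s) < sample_entropy(sample(s))
  }, logical(1))
  expect_true(all(wins))
  expect_error(sample_entropy(rnorm(50)), ">= 100")
})

test_that("amplitude scaling acts as the closed forms demand", {
  set.seed(6)
  x <- rnorm(2048)
  td1 <- time_domain_features(x); td3 <- time_domain_features(3 * x)
  expect_equal(unname(td3[["TF_01"]]), 3 * unname(td1[["TF_01"]]))
  expect_equal(unname(td3[["TF_02"]]), 3 * unname(td1[["TF_02"]]))
  expect_equal(unname(td3[["TF_03"]]), 3 * unname(td1[["TF_03"]]))
  expect_equal(unname(td3[["TF_06"]]), unname(td1[["TF_06"]]))  # ZC invariant
  ff1 <- frequency_domain_features(x, fs = 1000)
  ff3 <- frequency_domain_features(3 * x, fs = 1000)
  expect_equal(ff3[["FF_01"]], ff1[["FF_01"]], tolerance = 1e-9)
  expect_equal(ff3[["FF_02"]], ff1[["FF_02"]], tolerance = 1e-9)
  expect_equal(unname(sample_entropy(3 * x)), unname(sample_entropy(x)),
               tolerance = 1e-9)
  a1 <- ar_features(x); a3 <- ar_features(3 * x)
  expect_equal(a1, a3, tolerance = 1e-9)
})
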