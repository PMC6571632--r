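test_that("autocorrelation delay finds the 1/e lag and scales with period", {
  set.seed(1)
  expect_equal(delay_from_autocorrelation(rnorm(500)), 1L)

  # sampled sine of period 40: acf ~ cos(2 pi tau / 40) crosses 1/e
  # between lags 7 and 8
  s40 <- sin(2 * pi * (1:400) / 40)
  tau40 <- delay_from_autocorrelation(s40)
  expect_true(tau40 %in% 7:8)

  s80 <- sin(2 * pi * (1:800) / 80)
  tau80 <- delay_from_autocorrelation(s80)
  expect_true(abs(tau80 - 2 * tau40) <= 1)  # linear scaling with period

  expect_error(delay_from_autocorrelation(rep(2, 100)), "constant")
  expect_error(delay_from_autocorrelation(1:5), "short")
})

test_that("false nearest neighbors separate attractors from noise", {
  s <- sin(2 * pi * (1:600) / 40)
  m_sine <- fnn_embedding_dimension(s, tau = 8, m_max = 6)
  expect_lte(as.integer(m_sine), 2)
  expect_true(attr(m_sine, "plateau"))

  # fully developed logistic map: a low-dimensional chaotic attractor
  x <- numeric(600); x[1] <- 0.2
  for (i in 2:600) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  m_log <- fnn_embedding_dimension(x, tau = 1, m_max = 6)
  expect_lte(as.integer(m_log), 3)

  set.seed(2)
  m_noise <- fnn_embedding_dimension(rnorm(600), tau = 1, m_max = 4)
  expect_equal(as.integer(m_noise), 4)
  expect_false(attr(m_noise, "plateau"))

  expect_error(fnn_embedding_dimension(rnorm(30), tau = 5, m_max = 10),
               "short")
})

test_that("correlation dimension recovers closed-form attractor dimensions", {
  # noise-free sine, incommensurately sampled so the orbit fills the
  # closed curve: dimension 1
  s <- sin(2 * pi * (1:400) / 40.7)
  d2_sine <- correlation_dimension(s, m = 3, tau = 8)
  expect_equal(as.numeric(d2_sine), 1, tolerance = 0.15)

  # iid uniform noise embedded in the plane fills it: dimension 2
  set.seed(3)
  d2_noise <- correlation_dimension(runif(600), m = 2, tau = 1)
  expect_equal(as.numeric(d2_noise), 2, tolerance = 0.15)

  # a single repeated state is a point: dimension 0
  expect_equal(as.numeric(correlation_dimension(rep(1, 200), m = 2, tau = 1)),
               0)

  expect_error(correlation_dimension(s[1:50], m = 3, tau = 8), "100")
})

test_that("Shannon entropy respects its closed-form anchors and bounds", {
  expect_equal(shannon_entropy(rep(3.7, 50)), 0)

  # one value per bin: exactly uniform over 16 bins -> 4 bits
  expect_equal(shannon_entropy(rep(1:16, each = 8), n_bins = 16), 4)

  set.seed(4)
  x <- rnorm(1000)
  h16 <- shannon_entropy(x, 16)
  expect_gte(h16, 0)
  expect_lte(h16, 4)
  # coarsening the histogram never increases the entropy
  expect_lte(shannon_entropy(x, 8), h16)
  expect_error(shannon_entropy(numeric(0)), "empty")
})

test_that("recurrence matrices are symmetric distances with period banding", {
  expect_true(all(recurrence_matrix(rep(1, 20), tau = 2) == 0))

  s <- sin(2 * pi * (1:200) / 40)
  R <- recurrence_matrix(s, tau = 8)
  expect_equal(R, t(R))
  expect_true(all(diag(R) == 0))
  expect_true(all(R >= 0))
  # points one full period apart recur: the 40-lag diagonal is ~ zero
  lag_band <- R[cbind(1:100, 41:140)]
  expect_lt(max(lag_band), 1e-10)

  # two-point embedding: the single off-diagonal distance by hand
  x <- c(1, 2, 3, 5)
  R2 <- recurrence_matrix(x, tau = 1, m = 3)
  expect_equal(dim(R2), c(2, 2))
  expect_equal(R2[1, 2], sqrt((2 - 1)^2 + (3 - 2)^2 + (5 - 3)^2))

  expect_error(recurrence_matrix(c(1, 2), tau = 5), "short")
})

test_that("the full pipeline runs on an ISI-like series", {
  set.seed(5)
  isi <- abs(20 + 10 * sin(2 * pi * (1:300) / 15) + rnorm(300, 0, 2))
  out <- nonlinear_analysis(isi)
  expect_s3_class(out, "hs_nla")
  expect_gte(out$tau, 1)
  expect_gte(out$entropy_bits, 0)
  expect_lte(out$entropy_bits, 4)
  expect_true(is.matrix(out$recurrence))
})
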