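test_that("sham mean follows the exponential decay law", {
  p <- kinetics_params(0.24, 0.26, 0.3, 0.27, 0.01,
                       tibble::tibble(quality = "q", n_Q = 0.5, p_Q = 0.1))
  expect_equal(sham_mean(0.5, p), 0.24 + 0.26)
  expect_equal(sham_mean(24, p), 0.24 + 0.26 * exp(-0.3 * 23.5))
  p0 <- kinetics_params(0.24, 0.26, 0, 0.27, 0.01,
                        tibble::tibble(quality = "q", n_Q = 0.5, p_Q = 0.1))
  expect_equal(sham_mean(c(0.5, 8, 24), p0), rep(0.5, 3))
  expect_error(sham_mean(0.2, p), class = "foci_domain_error")
})

test_that("cluster focus probability honours its limits", {
  p <- make_test_params("qa")
  expect_equal(cluster_focus_prob(0.5, 2, p, "qa"),
               1 - exp(-2 * p$qualities$n_Q[1]))
  p0 <- kinetics_params(0.1, 0.1, 0.3, 0.27, 0.01,
                        tibble::tibble(quality = "qa", n_Q = 0, p_Q = 0.5))
  expect_equal(cluster_focus_prob(c(0.5, 4, 24), 3, p0, "qa"), rep(0, 3))
  # beta2 = 0: large-t limit is the persistent void probability
  pp <- kinetics_params(0.1, 0.1, 0.3, 0.5, 0,
                        tibble::tibble(quality = "qa", n_Q = 0.8, p_Q = 0.2))
  expect_equal(cluster_focus_prob(1e6, 2, pp, "qa"),
               1 - exp(-2 * 0.8 * 0.2), tolerance = 1e-12)
  expect_error(cluster_focus_prob(0.5, 0, p, "qa"), class = "foci_param_error")
})

test_that("fraction and mean parameterizations agree to machine precision", {
  set.seed(31)
  for (i in 1:200) {
    n_Q <- runif(1, 0, 3); p_Q <- runif(1)
    prm <- kinetics_params(runif(1), runif(1), runif(1, 0, 2),
                           runif(1, 0.1, 2), runif(1, 0, 0.1),
                           tibble::tibble(quality = "q", n_Q = n_Q, p_Q = p_Q))
    t <- runif(5, 0.5, 24)
    n_i <- sample(1:6, 1)
    expect_equal(cluster_focus_prob(t, n_i, prm, "q", "fraction"),
                 cluster_focus_prob(t, n_i, prm, "q", "mean"),
                 tolerance = 1e-13)
  }
})

test_that("cluster probability equals the enumerated Poisson-thinning limit", {
  prm <- make_test_params("qa")
  q <- prm$qualities
  for (t in c(0.5, 3, 11)) {
    for (n_i in c(1, 3)) {
      dt <- t - prm$t_M
      s <- (1 - q$p_Q[1]) * exp(-prm$beta1 * dt) + q$p_Q[1] * exp(-prm$beta2 * dt)
      lam <- n_i * q$n_Q[1]
      k <- 0:200
      p_enum <- sum(exp(-lam) * lam^k / factorial(k) * (1 - (1 - s)^k))
      expect_equal(cluster_focus_prob(t, n_i, prm, "qa"), p_enum,
                   tolerance = 1e-12)
    }
  }
})

test_that("probabilities stay in [0,1) and decrease in time when beta1 >= beta2", {
  set.seed(8)
  for (i in 1:50) {
    b2 <- runif(1, 0, 0.3)
    prm <- kinetics_params(0.1, 0.1, 0.3, b2 + runif(1, 0, 2), b2,
                           tibble::tibble(quality = "q", n_Q = runif(1, 0, 3),
                                          p_Q = runif(1)))
    t <- sort(runif(8, 0.5, 30))
    pr <- cluster_focus_prob(t, sample(1:5, 1), prm, "q")
    expect_true(all(pr >= 0 & pr < 1))
    expect_true(all(diff(pr) <= 1e-12))
  }
})

test_that("radiation and total means follow the spectrum-weighted sum", {
  prm <- make_test_params("qa")
  sp <- make_test_spectra("qa")
  t <- c(0.5, 2, 4, 8, 24)
  got <- total_mean(t, sp, prm)
  want <- vapply(t, ref_total_mean, numeric(1),
                 n_vec = sp$n, k_vec = sp$k_bar,
                 n_b = prm$n_b, n_s = prm$n_s, beta0 = prm$beta0,
                 beta1 = prm$beta1, beta2 = prm$beta2,
                 n_Q = prm$qualities$n_Q[1], p_Q = prm$qualities$p_Q[1])
  expect_equal(got, want, tolerance = 1e-12)
  # all-zero spectrum -> sham only
  sp0 <- tibble::tibble(quality = "qa", n = 1:3, k_bar = 0)
  expect_equal(total_mean(t, sp0, prm), sham_mean(t, prm))
  # value at t_M has the closed form n_b + n_s + sum k (1 - e^{-n n_Q})
  expect_equal(total_mean(0.5, sp, prm),
               prm$n_b + prm$n_s +
                 sum(sp$k_bar * (1 - exp(-sp$n * prm$qualities$n_Q[1]))))
  # monotone non-increasing
  expect_true(all(diff(total_mean(seq(0.5, 24, length.out = 50), sp, prm)) <= 0))
})

test_that("total mean approaches the persistent plateau when beta2 = 0", {
  prm <- kinetics_params(0.24, 0.26, 0.3, 0.4, 0,
                         tibble::tibble(quality = "qa", n_Q = 0.9, p_Q = 0.15))
  sp <- make_test_spectra("qa")
  plateau <- prm$n_b + sum(sp$k_bar * (1 - exp(-sp$n * 0.9 * 0.15)))
  expect_equal(total_mean(1e6, sp, prm), plateau, tolerance = 1e-10)
})

test_that("reparameterization reproduces the published derived values", {
  expect_equal(round(reparameterize(tibble::tibble(n_Q = 0.37, p_Q = 0.17),
                                    "to_mean")$pbar_Q, 2), 0.06)
  expect_equal(round(reparameterize(tibble::tibble(n_Q = 1.09, pbar_Q = 0.23),
                                    "to_fraction")$p_Q, 2), 0.21)
  # round trip and edge cases
  x <- tibble::tibble(n_Q = c(0.5, 1.2), p_Q = c(0, 0.3))
  rt <- reparameterize(reparameterize(x, "to_mean"), "to_fraction")
  expect_equal(rt$p_Q, x$p_Q)
  expect_equal(reparameterize(tibble::tibble(n_Q = 1, p_Q = 0), "to_mean")$pbar_Q, 0)
  expect_error(reparameterize(tibble::tibble(n_Q = 0, pbar_Q = 0.1), "to_fraction"),
               class = "foci_param_error")
  expect_error(reparameterize(tibble::tibble(n_Q = 0.2, pbar_Q = 0.5), "to_fraction"),
               class = "foci_param_error")
})

test_that("parameter validation rejects inconsistent persistence values", {
  expect_error(
    kinetics_params(0.1, 0.1, 0.3, 0.3, 0.01,
                    tibble::tibble(quality = "q", n_Q = 0.3, pbar_Q = 0.5)),
    class = "foci_param_error"
  )
  expect_warning(
    kinetics_params(0.1, 0.1, 0.3, 0.01, 0.3,
                    tibble::tibble(quality = "q", n_Q = 0.3, p_Q = 0.1)),
    "beta2"
  )
})
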