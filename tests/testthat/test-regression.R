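test_that("weighted residuals match an independently coded loop", {
  prm <- make_test_params()
  sp <- make_test_spectra()
  dat <- make_noise_free_data(prm, sp)
  set.seed(17)
  dat$mean <- dat$mean + rnorm(nrow(dat), 0, 0.1)
  dat$sd <- runif(nrow(dat), 0.02, 0.2)
  res <- foci_residuals(prm, dat, sp)
  chisq <- sum(res$residual^2)
  ref <- 0
  for (i in seq_len(nrow(dat))) {
    mu <- if (dat$quality[i] == "sham") {
      ref_sham_mean(dat$t_h[i], prm$n_b, prm$n_s, prm$beta0)
    } else {
      spq <- sp[sp$quality == dat$quality[i], ]
      j <- match(dat$quality[i], prm$qualities$quality)
      ref_total_mean(dat$t_h[i], spq$n, spq$k_bar, prm$n_b, prm$n_s,
                     prm$beta0, prm$beta1, prm$beta2,
                     prm$qualities$n_Q[j], prm$qualities$p_Q[j])
    }
    ref <- ref + ((dat$mean[i] - mu) / dat$sd[i])^2
  }
  expect_equal(chisq, ref, tolerance = 1e-12)
  # perfect model -> zero residuals
  res0 <- foci_residuals(prm, make_noise_free_data(prm, sp), sp)
  expect_equal(res0$residual, rep(0, nrow(res0)), tolerance = 1e-12)
  # a single point off by 2 sd contributes 4
  one <- tibble::tibble(quality = "sham", t_h = 2,
                        mean = ref_sham_mean(2, prm$n_b, prm$n_s, prm$beta0) + 0.2,
                        sd = 0.1)
  expect_equal(foci_residuals(prm, one, sp)$residual^2, 4)
  # zero uncertainties are refused with guidance
  bad <- make_noise_free_data(prm, sp); bad$sd[3] <- 0
  expect_error(foci_residuals(prm, bad, sp), class = "foci_config_error")
})

test_that("noise-free synthetic data are recovered to 1e-4 relative error", {
  prm <- make_test_params()
  sp <- make_test_spectra()
  dat <- make_noise_free_data(prm, sp)
  fit <- simultaneous_fit(dat, sp, fit_options(beta0 = "free"),
                          n_starts = 8, seed = 3)
  truth <- c(n_b = prm$n_b, n_s = prm$n_s, beta0 = prm$beta0,
             beta1 = prm$beta1, beta2 = prm$beta2,
             n_qa = prm$qualities$n_Q[1], n_qb = prm$qualities$n_Q[2],
             p_qa = prm$qualities$p_Q[1], p_qb = prm$qualities$p_Q[2])
  expect_lt(fit$chisq, 1e-10)
  for (nm in names(truth)) {
    expect_lt(abs(fit$estimates[[nm]] - truth[[nm]]) / truth[[nm]], 1e-4)
  }
})

test_that("degrees of freedom follow the free-parameter accounting", {
  prm <- make_test_params(c("q1", "q2", "q3", "q4"))
  sp <- make_test_spectra(c("q1", "q2", "q3", "q4"))
  dat <- make_noise_free_data(prm, sp)
  fit <- simultaneous_fit(dat, sp, n_starts = 2, seed = 1)
  # 25 points, 13 free parameters
  expect_equal(length(fit$estimates), 13L)
  expect_equal(fit$df, 12L)
  fit_b0 <- simultaneous_fit(dat, sp, fit_options(beta0 = "eq_beta1"),
                             n_starts = 2, seed = 1)
  expect_equal(fit_b0$df, 13L)
  fit_b2 <- simultaneous_fit(dat, sp, fit_options(beta2 = "zero"),
                             n_starts = 2, seed = 1)
  expect_equal(fit_b2$df, 13L)
})

test_that("independent difference fits have f = 1, or f = 2 with beta2 fixed", {
  prm <- make_test_params("qa")
  sp <- make_test_spectra("qa")
  dat <- make_noise_free_data(prm, sp)
  dd <- difference_dataset(dat, "qa")
  expect_equal(dd$sd, rep(sqrt(0.05^2 + 0.05^2), nrow(dd)))
  f1 <- independent_fit(dd, sp, n_starts = 6, seed = 2)
  expect_equal(length(f1$estimates), 4L)
  expect_equal(f1$df, 1L)
  f2 <- independent_fit(dd, sp, fit_options(beta2 = "zero"),
                        n_starts = 6, seed = 2)
  expect_equal(f2$df, 2L)
  # noise-free difference data recover (n_Q, p_Q, beta1, beta2)
  expect_lt(abs(f1$estimates[["n_qa"]] - prm$qualities$n_Q[1]) /
              prm$qualities$n_Q[1], 1e-4)
  expect_lt(abs(f1$estimates[["p_qa"]] - prm$qualities$p_Q[1]) /
              prm$qualities$p_Q[1], 1e-3)
})

test_that("standard errors match the closed form for a weighted linear model", {
  # y = a + b x with weights 1/sd^2: cov = (X^T W X)^{-1}
  set.seed(4)
  x <- seq(0, 10, length.out = 12)
  sdv <- runif(12, 0.1, 0.5)
  y <- 1.5 + 0.7 * x + rnorm(12, 0, sdv)
  fn <- function(theta) (y - theta[1] - theta[2] * x) / sdv
  X <- cbind(1, x)
  W <- diag(1 / sdv^2)
  cov_ref <- solve(t(X) %*% W %*% X)
  cv <- focikinetics:::.lsq_covariance(fn, c(1.5, 0.7), c(-Inf, -Inf), c(Inf, Inf))
  expect_false(cv$rank_deficient)
  expect_equal(cv$cov, cov_ref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("rank deficiency and boundary estimates are flagged, not hidden", {
  # duplicate parameter: residual depends only on theta1 + theta2
  y <- c(1, 2, 3); x <- c(0, 1, 2)
  fn <- function(theta) y - (theta[1] + theta[2]) * x
  cv <- focikinetics:::.lsq_covariance(fn, c(0.5, 0.5), c(-Inf, -Inf), c(Inf, Inf))
  expect_true(cv$rank_deficient)
  # beta2 driven to its bound is reported as at_boundary
  prm <- kinetics_params(0.2, 0.2, 0.3, 0.4, 0,
                         tibble::tibble(quality = "qa", n_Q = 0.8, p_Q = 0.2))
  sp <- make_test_spectra("qa")
  dat <- make_noise_free_data(prm, sp)
  fit <- simultaneous_fit(dat, sp, n_starts = 6, seed = 5)
  expect_true(fit$at_boundary[["beta2"]] ||
                fit$estimates[["beta2"]] < 1e-6)
  se <- standard_errors(fit)
  expect_setequal(names(se),
                  c("term", "estimate", "se_scaled", "se_unscaled",
                    "at_boundary", "rank_deficient"))
})

test_that("the optimum is a fixed point and invariant to data ordering", {
  prm <- make_test_params()
  sp <- make_test_spectra()
  dat <- make_noise_free_data(prm, sp)
  set.seed(8)
  dat$mean <- dat$mean + rnorm(nrow(dat), 0, 0.05)
  fit <- simultaneous_fit(dat, sp, n_starts = 6, seed = 6)
  refit <- simultaneous_fit(dat, sp, starts = list(fit$estimates))
  expect_equal(refit$estimates, fit$estimates, tolerance = 1e-8)
  expect_equal(refit$chisq, fit$chisq, tolerance = 1e-10)
  shuffled <- dat[sample(nrow(dat)), ]
  fit2 <- simultaneous_fit(shuffled, sp, starts = list(fit$estimates))
  expect_equal(fit2$chisq, fit$chisq, tolerance = 1e-10)
})

test_that("the two parameterizations reach the same objective", {
  prm <- make_test_params()
  sp <- make_test_spectra()
  dat <- make_noise_free_data(prm, sp)
  set.seed(9)
  dat$mean <- dat$mean + rnorm(nrow(dat), 0, 0.05)
  f_frac <- simultaneous_fit(dat, sp, fit_options("fraction"),
                             n_starts = 8, seed = 10)
  start_mean <- f_frac$estimates
  nm <- names(start_mean)
  for (q in c("qa", "qb")) {
    start_mean[[paste0("p_", q)]] <-
      start_mean[[paste0("n_", q)]] * start_mean[[paste0("p_", q)]]
  }
  names(start_mean)[match(paste0("p_", c("qa", "qb")), nm)] <-
    paste0("pbar_", c("qa", "qb"))
  f_mean <- simultaneous_fit(dat, sp, fit_options("mean"),
                             starts = list(start_mean))
  expect_equal(f_mean$chisq, f_frac$chisq, tolerance = 1e-6)
})

test_that("fit accessors expose a coherent broom-style surface", {
  prm <- make_test_params("qa")
  sp <- make_test_spectra("qa")
  dat <- make_noise_free_data(prm, sp)
  fit <- simultaneous_fit(dat, sp, n_starts = 4, seed = 11)
  td <- tidy(fit)
  expect_setequal(names(td), c("term", "estimate", "std.error", "at_boundary"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 10L)
  expect_equal(gl$n_par, 7L)
  curves <- fitted_curves(fit, c(0.5, 2, 24))
  expect_setequal(unique(curves$quality), c("qa", "sham"))
  prm2 <- as_kinetics_params(fit)
  expect_s3_class(prm2, "kinetics_params")
  expect_equal(prm2$qualities$n_Q, prm$qualities$n_Q[1], tolerance = 1e-3)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("a missing sham dataset or spectrum is refused", {
  prm <- make_test_params("qa")
  sp <- make_test_spectra("qa")
  dat <- make_noise_free_data(prm, sp)
  expect_error(simultaneous_fit(dat[dat$quality != "sham", ], sp),
               class = "foci_config_error")
  expect_error(simultaneous_fit(dat, sp[0, ]), class = "foci_config_error")
})
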