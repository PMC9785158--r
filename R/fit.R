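# Weighted simultaneous nonlinear least squares across radiation qualities.
#
# All irradiated datasets are modelled by the full kinetics model (sham +
# radiation terms) and the sham dataset by the sham term alone; beta1,
# beta2, n_b and n_s are shared across datasets by default.  The minimised
# quantity is the sum of squared residual-to-uncertainty ratios, under the
# constraint that every parameter is >= 0 (and p_Q <= 1).  Optimisation is
# bound-constrained Levenberg-Marquardt (minpack.lm) from multiple starts;
# standard errors come from the Jacobian of the weighted residuals at the
# optimum.

#' Fit options
#'
#' Records the constraint variant and parameterization under which a fit is
#' (or was) performed.
#'
#' @param parameterization `"fraction"` fits per-quality `(n_Q, p_Q)`;
#'   `"mean"` fits `(n_Q, pbar_Q)`.  The two are algebraically equivalent
#'   models but differ in constraint geometry (`p_Q <= 1` is intrinsic;
#'   `pbar_Q` is only bounded below).
#' @param beta0 `"free"` or `"eq_beta1"` (sham foci repaired with the same
#'   kinetics as normal radiation-induced foci).
#' @param beta2 `"free"` or `"zero"` (persistent foci never repaired).
#' @param per_quality_beta1 If `TRUE`, the normal repair rate may differ
#'   between radiation qualities.  Cannot be combined with
#'   `beta0 = "eq_beta1"`.
#' @param t_M Reference time (h).
#' @param sampling_upper Upper bounds used only for drawing multi-start
#'   points (the optimizer itself bounds parameters below by 0 and `p_Q`
#'   above by 1): list with elements `n_b`, `n_s`, `beta`, `n_Q`.
#' @return A `fit_options` object.
#' @export
fit_options <- function(parameterization = c("fraction", "mean"),
                        beta0 = c("free", "eq_beta1"),
                        beta2 = c("free", "zero"),
                        per_quality_beta1 = FALSE,
                        t_M = 0.5,
                        sampling_upper = list(n_b = 5, n_s = 5, beta = 10, n_Q = 5)) {
  parameterization <- match.arg(parameterization)
  beta0 <- match.arg(beta0)
  beta2 <- match.arg(beta2)
  if (per_quality_beta1 && beta0 == "eq_beta1") {
    abort("`beta0 = \"eq_beta1\"` cannot be combined with `per_quality_beta1 = TRUE`.",
          class = "foci_config_error")
  }
  su <- modifyList(list(n_b = 5, n_s = 5, beta = 10, n_Q = 5), sampling_upper)
  structure(
    list(parameterization = parameterization, beta0 = beta0, beta2 = beta2,
         per_quality_beta1 = per_quality_beta1, t_M = t_M,
         sampling_upper = su),
    class = "fit_options"
  )
}

# Parameter vector layout ----------------------------------------------------

.par_layout <- function(qualities, options, mode = c("simultaneous", "difference")) {
  mode <- match.arg(mode)
  pcol <- if (options$parameterization == "fraction") "p_" else "pbar_"
  nm <- c(
    if (mode == "simultaneous") c("n_b", "n_s"),
    if (mode == "simultaneous" && options$beta0 == "free") "beta0",
    if (options$per_quality_beta1) paste0("beta1_", qualities) else "beta1",
    if (options$beta2 == "free") "beta2",
    paste0("n_", qualities),
    paste0(pcol, qualities)
  )
  is_frac <- startsWith(nm, "p_") & !startsWith(nm, "pbar_")
  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(rep(Inf, length(nm)), nm)
  upper[is_frac] <- 1
  su <- options$sampling_upper
  samp <- upper
  if ("n_b" %in% nm) samp["n_b"] <- su$n_b
  if ("n_s" %in% nm) samp["n_s"] <- su$n_s
  samp[startsWith(nm, "beta")] <- su$beta
  samp[startsWith(nm, "n_") & !(nm %in% c("n_b", "n_s"))] <- su$n_Q
  samp[startsWith(nm, "pbar_")] <- su$n_Q
  samp[is_frac] <- 1
  list(names = nm, lower = lower, upper = upper, sampling_upper = samp,
       qualities = qualities, mode = mode)
}

.unpack_theta <- function(theta, layout, options) {
  qs <- layout$qualities
  g <- function(x) unname(theta[x])
  beta1 <- if (options$per_quality_beta1) {
    setNames(g(paste0("beta1_", qs)), qs)
  } else {
    setNames(rep(g("beta1"), length(qs)), qs)
  }
  beta2 <- if (options$beta2 == "free") g("beta2") else 0
  list(
    n_b = if (layout$mode == "simultaneous") g("n_b") else NA_real_,
    n_s = if (layout$mode == "simultaneous") g("n_s") else NA_real_,
    beta0 = if (layout$mode == "simultaneous") {
      if (options$beta0 == "free") g("beta0") else g("beta1")
    } else NA_real_,
    beta1 = beta1,
    beta2 = beta2,
    n_Q = setNames(g(paste0("n_", qs)), qs),
    pq = if (options$parameterization == "fraction") {
      setNames(g(paste0("p_", qs)), qs)
    } else {
      setNames(g(paste0("pbar_", qs)), qs)
    }
  )
}

# Data preparation: fixed structures the residual closure indexes into.
.prepare_fit_data <- function(data, spectra, qualities, options, mode) {
  blocks <- list()
  for (q in qualities) {
    d <- data[data$quality == q, , drop = FALSE]
    d <- d[order(d$t_h), , drop = FALSE]
    sp <- spectra[spectra$quality == q, , drop = FALSE]
    if (nrow(sp) == 0L) {
      abort(sprintf("no cluster spectrum for quality '%s'.", q),
            class = "foci_config_error")
    }
    blocks[[q]] <- list(quality = q, t = d$t_h, y = d$mean, sd = d$sd,
                        n = sp$n, k = sp$k_bar)
  }
  if (mode == "simultaneous") {
    d <- data[data$quality == "sham", , drop = FALSE]
    d <- d[order(d$t_h), , drop = FALSE]
    blocks[["sham"]] <- list(quality = "sham", t = d$t_h, y = d$mean,
                             sd = d$sd, n = NULL, k = NULL)
  }
  blocks
}

# Model means for one block given unpacked parameters (lean: used inside
# the optimizer's residual function).
.block_mean <- function(block, u, options, mode) {
  dt <- block$t - options$t_M
  if (is.null(block$n)) {  # sham block
    return(u$n_b + u$n_s * exp(-u$beta0 * dt))
  }
  q <- block$quality
  e1 <- exp(-u$beta1[[q]] * dt)
  e2 <- exp(-u$beta2 * dt)
  cvec <- if (options$parameterization == "fraction") {
    u$n_Q[[q]] * ((1 - u$pq[[q]]) * e1 + u$pq[[q]] * e2)
  } else {
    (u$n_Q[[q]] - u$pq[[q]]) * e1 + u$pq[[q]] * e2
  }
  rad <- drop((1 - exp(-outer(cvec, block$n))) %*% block$k)
  if (mode == "simultaneous") {
    u$n_b + u$n_s * exp(-u$beta0 * dt) + rad
  } else {
    rad
  }
}

# The closure is the optimizer's hot path: all name lookups are resolved
# to integer indices up front.
.make_resid_fn <- function(blocks, layout, options) {
  qs <- layout$qualities
  nm <- layout$names
  mode <- layout$mode
  frac <- options$parameterization == "fraction"
  b0_free <- options$beta0 == "free"
  b2_free <- options$beta2 == "free"
  i_nb <- match("n_b", nm)
  i_ns <- match("n_s", nm)
  i_b0 <- match("beta0", nm)
  i_b1 <- if (options$per_quality_beta1) {
    setNames(match(paste0("beta1_", qs), nm), qs)
  } else {
    setNames(rep(match("beta1", nm), length(qs)), qs)
  }
  i_b2 <- match("beta2", nm)
  i_nQ <- setNames(match(paste0("n_", qs), nm), qs)
  i_p <- setNames(match(paste0(if (frac) "p_" else "pbar_", qs), nm), qs)
  for (j in seq_along(blocks)) blocks[[j]]$dt <- blocks[[j]]$t - options$t_M
  function(theta) {
    b2 <- if (b2_free) theta[[i_b2]] else 0
    out <- vector("list", length(blocks))
    for (j in seq_along(blocks)) {
      b <- blocks[[j]]
      if (is.null(b$n)) {
        b0 <- if (b0_free) theta[[i_b0]] else theta[[i_b1[[1]]]]
        mu <- theta[[i_nb]] + theta[[i_ns]] * exp(-b0 * b$dt)
      } else {
        q <- b$quality
        e1 <- exp(-theta[[i_b1[[q]]]] * b$dt)
        e2 <- exp(-b2 * b$dt)
        cvec <- if (frac) {
          theta[[i_nQ[[q]]]] *
            ((1 - theta[[i_p[[q]]]]) * e1 + theta[[i_p[[q]]]] * e2)
        } else {
          (theta[[i_nQ[[q]]]] - theta[[i_p[[q]]]]) * e1 + theta[[i_p[[q]]]] * e2
        }
        mu <- drop((1 - exp(-outer(cvec, b$n))) %*% b$k)
        if (mode == "simultaneous") {
          b0 <- if (b0_free) theta[[i_b0]] else theta[[i_b1[[1]]]]
          mu <- mu + theta[[i_nb]] + theta[[i_ns]] * exp(-b0 * b$dt)
        }
      }
      out[[j]] <- (b$y - mu) / b$sd
    }
    unlist(out, use.names = FALSE)
  }
}

# Analytic Jacobian of the weighted residual vector, matching
# .make_resid_fn row for row.  With mu = n_b + n_s e^{-b0 dt} +
# sum_n k_n (1 - e^{-n c(t)}) the chain rule gives d mu / d x =
# [sum_n k_n n e^{-n c}] dc/dx for every parameter x entering c.
.make_jac_fn <- function(blocks, layout, options) {
  qs <- layout$qualities
  nm <- layout$names
  mode <- layout$mode
  frac <- options$parameterization == "fraction"
  b0_free <- options$beta0 == "free"
  b2_free <- options$beta2 == "free"
  npar <- length(nm)
  i_nb <- match("n_b", nm)
  i_ns <- match("n_s", nm)
  i_b0 <- match("beta0", nm)
  i_b1 <- if (options$per_quality_beta1) {
    setNames(match(paste0("beta1_", qs), nm), qs)
  } else {
    setNames(rep(match("beta1", nm), length(qs)), qs)
  }
  i_b2 <- match("beta2", nm)
  i_nQ <- setNames(match(paste0("n_", qs), nm), qs)
  i_p <- setNames(match(paste0(if (frac) "p_" else "pbar_", qs), nm), qs)
  for (j in seq_along(blocks)) blocks[[j]]$dt <- blocks[[j]]$t - options$t_M
  function(theta) {
    b2 <- if (b2_free) theta[[i_b2]] else 0
    rows <- vector("list", length(blocks))
    for (j in seq_along(blocks)) {
      b <- blocks[[j]]
      dt <- b$dt
      J <- matrix(0, length(dt), npar)
      if (is.null(b$n)) {
        b0 <- if (b0_free) theta[[i_b0]] else theta[[i_b1[[1]]]]
        eb0 <- exp(-b0 * dt)
        J[, i_nb] <- 1
        J[, i_ns] <- eb0
        d_b0 <- -theta[[i_ns]] * dt * eb0
        if (b0_free) J[, i_b0] <- d_b0 else J[, i_b1[[1]]] <- d_b0
      } else {
        q <- b$quality
        b1 <- theta[[i_b1[[q]]]]
        e1 <- exp(-b1 * dt)
        e2 <- exp(-b2 * dt)
        nQ <- theta[[i_nQ[[q]]]]
        pq <- theta[[i_p[[q]]]]
        if (frac) {
          cvec <- nQ * ((1 - pq) * e1 + pq * e2)
          dc_dn <- (1 - pq) * e1 + pq * e2
          dc_dp <- nQ * (e2 - e1)
          dc_db1 <- -nQ * (1 - pq) * dt * e1
          dc_db2 <- -nQ * pq * dt * e2
        } else {
          cvec <- (nQ - pq) * e1 + pq * e2
          dc_dn <- e1
          dc_dp <- e2 - e1
          dc_db1 <- -(nQ - pq) * dt * e1
          dc_db2 <- -pq * dt * e2
        }
        # S(t) = sum_n k_n n e^{-n c(t)}
        S <- drop(exp(-outer(cvec, b$n)) %*% (b$k * b$n))
        J[, i_nQ[[q]]] <- S * dc_dn
        J[, i_p[[q]]] <- S * dc_dp
        J[, i_b1[[q]]] <- J[, i_b1[[q]]] + S * dc_db1
        if (b2_free) J[, i_b2] <- S * dc_db2
        if (mode == "simultaneous") {
          b0 <- if (b0_free) theta[[i_b0]] else theta[[i_b1[[1]]]]
          eb0 <- exp(-b0 * dt)
          J[, i_nb] <- 1
          J[, i_ns] <- eb0
          d_b0 <- -theta[[i_ns]] * dt * eb0
          if (b0_free) J[, i_b0] <- d_b0
          else J[, i_b1[[1]]] <- J[, i_b1[[1]]] + d_b0
        }
      }
      rows[[j]] <- -J / b$sd  # residual = (y - mu)/sd
    }
    do.call(rbind, rows)
  }
}

.validate_fit_data <- function(data, need_sham) {
  req <- c("quality", "t_h", "mean", "sd")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort("`data` must have columns quality, t_h, mean, sd.",
          class = "foci_config_error")
  }
  if (any(!is.finite(data$sd)) || any(data$sd <= 0)) {
    abort(paste0("all `sd` must be finite and > 0 for weighted fitting; ",
                 "replace zero uncertainties by a weight floor or exclude those points."),
          class = "foci_config_error")
  }
  if (need_sham && !("sham" %in% data$quality)) {
    abort("the simultaneous fit requires a 'sham' dataset.",
          class = "foci_config_error")
  }
  data[data$quality != "control", , drop = FALSE]
}

#' Weighted residuals of the kinetics model
#'
#' Residual-to-uncertainty ratios `(observed - model) / sd` for every data
#' point; the fit minimises the sum of their squares.  Irradiated datasets
#' are modelled by the full model (sham + radiation terms), the sham
#' dataset by the sham term alone; `control` rows are ignored.
#'
#' @param params A [kinetics_params()] object.
#' @param data Long tibble with columns `quality` (including `"sham"`),
#'   `t_h`, `mean`, `sd`.
#' @param spectra Cluster spectra for the irradiated qualities (columns
#'   `quality`, `n`, `k_bar`).
#' @param options A [fit_options()] record (its `parameterization` selects
#'   the form of the cluster-probability term; results are identical when
#'   `pbar_Q = n_Q * p_Q`).
#' @return A tibble with columns `quality`, `t_h`, `observed`, `fitted`,
#'   `sd`, `residual` (weighted).
#' @export
foci_residuals <- function(params, data, spectra, options = fit_options()) {
  data <- .validate_fit_data(data, need_sham = FALSE)
  out <- lapply(split(data, data$quality), function(d) {
    d <- d[order(d$t_h), , drop = FALSE]
    mu <- if (unique(d$quality) == "sham") {
      sham_mean(d$t_h, params)
    } else {
      sp <- spectra[spectra$quality == unique(d$quality), , drop = FALSE]
      if (nrow(sp) == 0L) {
        abort(sprintf("no cluster spectrum for quality '%s'.", unique(d$quality)),
              class = "foci_config_error")
      }
      total_mean(d$t_h, sp, params, options$parameterization)
    }
    tibble::tibble(quality = d$quality, t_h = d$t_h, observed = d$mean,
                   fitted = mu, sd = d$sd,
                   residual = (d$mean - mu) / d$sd)
  })
  dplyr::bind_rows(out)
}

# Multi-start machinery -------------------------------------------------------

.default_starts <- function(layout, n_starts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samp <- layout$sampling_upper
  starts <- list(
    extreme_low = layout$lower,
    extreme_high = samp
  )
  if (n_starts > 0) {
    u <- lhs::randomLHS(n_starts, length(samp))
    for (i in seq_len(n_starts)) {
      starts[[paste0("lhs_", i)]] <-
        setNames(layout$lower + u[i, ] * (samp - layout$lower), layout$names)
    }
  }
  starts
}

.run_starts <- function(resid_fn, starts, layout, control = NULL,
                        jac_fn = NULL) {
  control <- control %||% minpack.lm::nls.lm.control(
    maxiter = 1000, ftol = 1e-12, ptol = 1e-12, maxfev = 100000
  )
  lapply(starts, function(s) {
    s <- setNames(as.numeric(s[layout$names]), layout$names)
    tryCatch({
      # Levenberg-Marquardt steps can collapse prematurely when a
      # parameter is clamped at a bound; alternate LM with a projected
      # quasi-Newton polish on the sum of squares until the objective is
      # stationary under both.
      obj <- function(th) sum(resid_fn(th)^2)
      grad <- if (!is.null(jac_fn)) {
        function(th) drop(2 * crossprod(jac_fn(th), resid_fn(th)))
      } else NULL
      par <- s
      dev <- Inf
      prev <- Inf
      r <- NULL
      for (cycle in seq_len(10L)) {
        # divergent starts legitimately exhaust maxiter; that is recorded
        # in the per-start info codes, not surfaced as a warning
        r <- withCallingHandlers(
          minpack.lm::nls.lm(par = par, lower = unname(layout$lower),
                             upper = unname(layout$upper), fn = resid_fn,
                             jac = jac_fn, control = control),
          warning = function(w) invokeRestart("muffleWarning")
        )
        par <- setNames(coef(r), layout$names)
        dev <- r$deviance
        o <- tryCatch(
          stats::optim(par, obj, gr = grad, method = "L-BFGS-B",
                       lower = unname(layout$lower),
                       upper = unname(layout$upper),
                       control = list(maxit = 500, factr = 10)),
          error = function(e) NULL
        )
        if (!is.null(o) && is.finite(o$value) && o$value < dev) {
          par <- setNames(o$par, layout$names)
          dev <- o$value
        }
        if (prev - dev < 1e-12 * max(1, dev)) break
        prev <- dev
      }
      list(ok = r$info %in% c(1, 2, 3, 4, 6, 7), info = r$info,
           message = r$message, par = par,
           deviance = dev, niter = r$niter, start = s)
    }, error = function(e) {
      list(ok = FALSE, info = NA_integer_, message = conditionMessage(e),
           par = s * NA_real_, deviance = NA_real_, niter = NA_integer_,
           start = s)
    })
  })
}

# The two-class survival s(t) = (1-p) e^{-beta1 dt} + p e^{-beta2 dt} is
# invariant under swapping (beta1, p) <-> (beta2, 1-p); the persistent
# class is by definition the slower one, so report the representative with
# beta1 >= beta2.  Only applicable when the objective actually has that
# symmetry (shared free beta2 and beta1, beta0 not tied to beta1).
.canonicalize_persistence <- function(par, layout, options) {
  symmetric <- options$beta2 == "free" && !options$per_quality_beta1 &&
    (layout$mode == "difference" || options$beta0 == "free")
  if (!symmetric) return(par)
  if (par[["beta2"]] <= par[["beta1"]]) return(par)
  b1 <- par[["beta1"]]
  par[["beta1"]] <- par[["beta2"]]
  par[["beta2"]] <- b1
  for (q in layout$qualities) {
    if (options$parameterization == "fraction") {
      nm <- paste0("p_", q)
      par[[nm]] <- 1 - par[[nm]]
    } else {
      nm <- paste0("pbar_", q)
      par[[nm]] <- max(par[[paste0("n_", q)]] - par[[nm]], 0)
    }
  }
  par
}

# Jacobian of the residual vector by finite differences, respecting bounds.
.num_jacobian <- function(fn, theta, lower, upper) {
  r0 <- fn(theta)
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    up <- min(theta[j] + h, upper[j])
    dn <- max(theta[j] - h, lower[j])
    if (up == dn) next
    tu <- theta; tu[j] <- up
    td <- theta; td[j] <- dn
    J[, j] <- (fn(tu) - fn(td)) / (up - dn)
  }
  J
}

# Covariance of the estimates from the linearised problem.  Residuals are
# already weighted, so J^T J is the weighted information matrix.
.lsq_covariance <- function(resid_fn, theta, lower, upper) {
  J <- .num_jacobian(resid_fn, theta, lower, upper)
  JtJ <- crossprod(J)
  rk <- qr(JtJ)$rank
  deficient <- rk < length(theta)
  cov <- if (deficient) MASS::ginv(JtJ) else solve(JtJ)
  list(cov = cov, rank_deficient = deficient, jacobian = J)
}

.finalize_fit <- function(best, results, blocks, layout, options, data,
                          spectra, resid_fn) {
  theta <- best$par
  m <- sum(vapply(blocks, function(b) length(b$t), integer(1)))
  p <- length(theta)
  df <- m - p
  chisq <- best$deviance
  cv <- .lsq_covariance(resid_fn, theta, layout$lower, layout$upper)
  se_unscaled <- sqrt(pmax(diag(cv$cov), 0))
  se_scaled <- if (df > 0) se_unscaled * sqrt(chisq / df) else rep(NA_real_, p)
  at_boundary <- theta <= layout$lower + 1e-8 |
    (is.finite(layout$upper) & theta >= layout$upper - 1e-8)
  start_tbl <- tibble::tibble(
    start = names(results),
    converged = vapply(results, `[[`, logical(1), "ok"),
    info = vapply(results, `[[`, numeric(1), "info"),
    chisq = vapply(results, `[[`, numeric(1), "deviance"),
    niter = vapply(results, `[[`, numeric(1), "niter")
  )
  structure(
    list(
      estimates = setNames(theta, layout$names),
      se = setNames(se_scaled, layout$names),
      se_unscaled = setNames(se_unscaled, layout$names),
      covariance = cv$cov,
      chisq = chisq,
      df = df,
      chisq_per_df = if (df > 0) chisq / df else NA_real_,
      options = options,
      layout = layout,
      qualities = layout$qualities,
      mode = layout$mode,
      at_boundary = setNames(at_boundary, layout$names),
      rank_deficient = cv$rank_deficient,
      convergence = list(info = best$info, message = best$message,
                         niter = best$niter, start = best$start),
      starts = start_tbl,
      data = data,
      spectra = spectra,
      resid_fn = resid_fn
    ),
    class = "foci_fit"
  )
}

#' Simultaneous fit of all radiation-quality datasets and the sham dataset
#'
#' Estimates all kinetics parameters in one weighted nonlinear regression:
#' per-quality `(n_Q, p_Q)` (or `(n_Q, pbar_Q)`), shared `beta1`, `beta2`,
#' `n_b`, `n_s` and (unless constrained) `beta0`.  Bound-constrained
#' Levenberg-Marquardt is run from a set of start points (the two extremes
#' "all parameters zero" and "all at their sampling maximum" plus Latin
#' hypercube draws); the best converged objective wins.
#'
#' @param data Long tibble with columns `quality` (irradiated labels plus
#'   `"sham"`; `"control"` rows are dropped), `t_h` (h), `mean`, `sd`
#'   (between-replicate standard deviation, > 0), optionally `n_rep`.
#' @param spectra Cluster spectra for every irradiated quality (columns
#'   `quality`, `n`, `k_bar`).
#' @param options A [fit_options()] record.
#' @param starts Optional list of named start vectors (each covering all
#'   free parameters).  When supplied, only these starts are used.
#' @param n_starts Number of Latin-hypercube starts added to the two
#'   extreme starts when `starts` is `NULL`.
#' @param seed Seed for the Latin-hypercube draw.
#' @return A `foci_fit` object; see [tidy.foci_fit()], [glance.foci_fit()],
#'   [fitted_curves()], [standard_errors()].
#' @export
simultaneous_fit <- function(data, spectra, options = fit_options(),
                             starts = NULL, n_starts = 16, seed = NULL) {
  data <- .validate_fit_data(data, need_sham = TRUE)
  qualities <- setdiff(unique(data$quality), "sham")
  if (length(qualities) < 1L) {
    abort("need at least one irradiated dataset.", class = "foci_config_error")
  }
  layout <- .par_layout(qualities, options, "simultaneous")
  blocks <- .prepare_fit_data(data, spectra, qualities, options, "simultaneous")
  resid_fn <- .make_resid_fn(blocks, layout, options)
  jac_fn <- .make_jac_fn(blocks, layout, options)
  starts <- starts %||% .default_starts(layout, n_starts, seed)
  results <- .run_starts(resid_fn, starts, layout, jac_fn = jac_fn)
  ok <- vapply(results, `[[`, logical(1), "ok")
  if (!any(ok)) {
    info <- paste(sprintf("%s: info=%s (%s)", names(results),
                          vapply(results, `[[`, numeric(1), "info"),
                          vapply(results, `[[`, character(1), "message")),
                  collapse = "; ")
    abort(paste0("no start converged. Per-start diagnostics: ", info),
          class = "foci_fit_error")
  }
  best <- results[ok][[which.min(vapply(results[ok], `[[`, numeric(1), "deviance"))]]
  best$par <- .canonicalize_persistence(best$par, layout, options)
  best$deviance <- sum(resid_fn(best$par)^2)
  .finalize_fit(best, results, blocks, layout, options, data, spectra, resid_fn)
}

#' Build the irradiated-minus-sham difference series for one quality
#'
#' Means are subtracted at matching times; uncertainties are combined
#' root-sum-square.  (This introduces a correlation between the difference
#' points that the independent fit does not model.)
#'
#' @param data Long tibble as in [simultaneous_fit()], containing both the
#'   chosen quality and `"sham"`.
#' @param quality Irradiated quality label.
#' @return A tibble with columns `quality`, `t_h`, `mean`, `sd`.
#' @export
difference_dataset <- function(data, quality) {
  d <- data[data$quality == quality, , drop = FALSE]
  s <- data[data$quality == "sham", , drop = FALSE]
  if (nrow(d) == 0L || nrow(s) == 0L) {
    abort("`data` must contain the chosen quality and 'sham'.",
          class = "foci_config_error")
  }
  j <- dplyr::inner_join(
    dplyr::select(d, "t_h", mean_q = "mean", sd_q = "sd"),
    dplyr::select(s, "t_h", mean_s = "mean", sd_s = "sd"),
    by = "t_h"
  )
  tibble::tibble(
    quality = quality,
    t_h = j$t_h,
    mean = j$mean_q - j$mean_s,
    sd = sqrt(j$sd_q^2 + j$sd_s^2)
  )
}

#' Independent fit of a single quality's difference series
#'
#' Fits the radiation term alone to the irradiated-minus-sham difference
#' series of one radiation quality, with free `(n_Q, p_Q, beta1, beta2)`
#' (or `pbar_Q`, or `beta2` fixed to zero, per `options`).  With five time
#' points and four free parameters this leaves one degree of freedom; fixing
#' `beta2 = 0` raises it to two.
#'
#' @param data Difference series for one quality (columns `quality`, `t_h`,
#'   `mean`, `sd`), e.g. from [difference_dataset()].
#' @param spectrum Cluster spectrum of that quality.
#' @inheritParams simultaneous_fit
#' @return A `foci_fit` object with `mode = "difference"`.
#' @export
independent_fit <- function(data, spectrum, options = fit_options(),
                            starts = NULL, n_starts = 16, seed = NULL) {
  data <- .validate_fit_data(data, need_sham = FALSE)
  quality <- unique(data$quality)
  if (length(quality) != 1L || quality %in% c("sham", "control")) {
    abort("`data` must hold exactly one irradiated quality's difference series.",
          class = "foci_config_error")
  }
  layout <- .par_layout(quality, options, "difference")
  blocks <- .prepare_fit_data(data, spectrum, quality, options, "difference")
  resid_fn <- .make_resid_fn(blocks, layout, options)
  jac_fn <- .make_jac_fn(blocks, layout, options)
  starts <- starts %||% .default_starts(layout, n_starts, seed)
  results <- .run_starts(resid_fn, starts, layout, jac_fn = jac_fn)
  ok <- vapply(results, `[[`, logical(1), "ok")
  if (!any(ok)) {
    abort("no start converged for the independent fit.", class = "foci_fit_error")
  }
  best <- results[ok][[which.min(vapply(results[ok], `[[`, numeric(1), "deviance"))]]
  best$par <- .canonicalize_persistence(best$par, layout, options)
  best$deviance <- sum(resid_fn(best$par)^2)
  .finalize_fit(best, results, blocks, layout, options, data, spectrum, resid_fn)
}

#' Standard errors of a fitted model
#'
#' Recomputes per-parameter standard errors from the Jacobian of the
#' weighted residuals at the optimum: `SE_i = sqrt([(J^T J)^-1]_ii)`,
#' optionally scaled by `sqrt(chisq / f)` to absorb overdispersion.
#' Parameters sitting at a constraint boundary are flagged (the linearised
#' interval ignores the constraint there); a rank-deficient information
#' matrix is flagged and handled by pseudo-inverse.
#'
#' @param fit A `foci_fit` object.
#' @return A tibble with columns `term`, `estimate`, `se_scaled`,
#'   `se_unscaled`, `at_boundary`, `rank_deficient`.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "foci_fit"))
  cv <- .lsq_covariance(fit$resid_fn, fit$estimates, fit$layout$lower,
                        fit$layout$upper)
  if (cv$rank_deficient) {
    warn("information matrix is rank deficient; standard errors use a pseudo-inverse and are unreliable.")
  }
  se_u <- sqrt(pmax(diag(cv$cov), 0))
  tibble::tibble(
    term = names(fit$estimates),
    estimate = unname(fit$estimates),
    se_scaled = if (fit$df > 0) se_u * sqrt(fit$chisq / fit$df) else NA_real_,
    se_unscaled = se_u,
    at_boundary = unname(fit$at_boundary),
    rank_deficient = cv$rank_deficient
  )
}

# broom-style accessors -------------------------------------------------------

#' @export
coef.foci_fit <- function(object, ...) object$estimates

#' Tidy a foci kinetics fit
#'
#' @param x A `foci_fit` object.
#' @param scaled Use standard errors scaled by `sqrt(chisq / f)` (default)
#'   or the unscaled linearised errors.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `at_boundary`.
#' @method tidy foci_fit
#' @export
tidy.foci_fit <- function(x, scaled = TRUE, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(if (scaled) x$se else x$se_unscaled),
    at_boundary = unname(x$at_boundary)
  )
}

#' One-row fit summary
#'
#' @param x A `foci_fit` object.
#' @param ... Unused.
#' @return A tibble with the weighted residual sum of squares, degrees of
#'   freedom, their ratio, and convergence bookkeeping.
#' @method glance foci_fit
#' @export
glance.foci_fit <- function(x, ...) {
  tibble::tibble(
    chisq = x$chisq,
    df = x$df,
    chisq_per_df = x$chisq_per_df,
    n_obs = x$df + length(x$estimates),
    n_par = length(x$estimates),
    n_starts = nrow(x$starts),
    n_converged = sum(x$starts$converged),
    rank_deficient = x$rank_deficient
  )
}

#' @export
print.foci_fit <- function(x, ...) {
  cat(sprintf("<foci_fit> %s fit, %d parameters, chisq/f = %.3g (f = %d)\n",
              x$mode, length(x$estimates), x$chisq_per_df, x$df))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Model curves of a fitted object
#'
#' Evaluates the fitted model over a time grid, per dataset: full model for
#' each irradiated quality, sham term for the sham dataset (simultaneous
#' fits), or the radiation term only (difference fits).
#'
#' @param fit A `foci_fit` object.
#' @param t Time grid (h); defaults to 100 log-spaced points over the
#'   observed span.
#' @return A tibble with columns `quality`, `t_h`, `mean`.
#' @export
fitted_curves <- function(fit, t = NULL) {
  stopifnot(inherits(fit, "foci_fit"))
  t <- t %||% exp(seq(log(min(fit$data$t_h)), log(max(fit$data$t_h)),
                      length.out = 100))
  u <- .unpack_theta(fit$estimates, fit$layout, fit$options)
  qs <- fit$qualities
  blocks <- lapply(qs, function(q) {
    sp <- fit$spectra[fit$spectra$quality == q, , drop = FALSE]
    b <- list(quality = q, t = t, n = sp$n, k = sp$k_bar)
    tibble::tibble(quality = q, t_h = t,
                   mean = .block_mean(b, u, fit$options, fit$mode))
  })
  out <- dplyr::bind_rows(blocks)
  if (fit$mode == "simultaneous") {
    sham <- tibble::tibble(
      quality = "sham", t_h = t,
      mean = .block_mean(list(quality = "sham", t = t, n = NULL, k = NULL),
                         u, fit$options, "simultaneous")
    )
    out <- dplyr::bind_rows(out, sham)
  }
  out
}

#' Kinetics parameters implied by a fit
#'
#' Packs the estimates of a simultaneous fit back into a
#' [kinetics_params()] object (with both persistence parameterizations
#' derived).  For per-quality `beta1` fits the quality-specific rates
#' cannot be represented and an error is raised.
#'
#' @param fit A `foci_fit` from [simultaneous_fit()].
#' @return A `kinetics_params` object.
#' @export
as_kinetics_params <- function(fit) {
  stopifnot(inherits(fit, "foci_fit"), fit$mode == "simultaneous")
  if (fit$options$per_quality_beta1) {
    abort("per-quality beta1 fits cannot be packed into a single kinetics_params.",
          class = "foci_param_error")
  }
  u <- .unpack_theta(fit$estimates, fit$layout, fit$options)
  q <- tibble::tibble(quality = fit$qualities, n_Q = unname(u$n_Q))
  if (fit$options$parameterization == "fraction") {
    q$p_Q <- pmin(unname(u$pq), 1)
  } else {
    q$pbar_Q <- pmin(unname(u$pq), unname(u$n_Q))
  }
  kinetics_params(u$n_b, u$n_s, u$beta0, u$beta1[[1]], u$beta2, q,
                  t_M = fit$options$t_M)
}
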