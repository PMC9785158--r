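# Two-class first-order repair-kinetics model for the mean number of
# observed foci per nucleus.
#
# Observed foci decompose into background foci (constant mean n_b), foci
# induced by the sham treatment (staining + near-UV illumination; mean n_s
# at the reference time t_M, always repairable, rate beta0), and
# radiation-induced foci.  The number of foci formed along an ion track is
# Poisson with per-track mean n_Q at t_M; a fraction p_Q of them belongs to
# a persistent class repaired at rate beta2, the rest at rate beta1.  A
# cluster of n_i unresolvable tracks is scored as one focus as long as at
# least one of its foci survives; by Poisson thinning that probability is
# 1 - exp(-n_i * n_Q * s(t)) with survival s(t) = (1 - p_Q) e^{-beta1 dt}
# + p_Q e^{-beta2 dt}, dt = t - t_M.

.check_time <- function(t, t_M) {
  if (any(!is.finite(t)) || any(t < t_M)) {
    abort(sprintf("the model is defined for t >= t_M = %g h only.", t_M),
          class = "foci_domain_error")
  }
}

.check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("%s must be finite and >= 0.", what),
          class = "foci_param_error")
  }
}

#' Kinetics model parameters
#'
#' Bundles the shared parameters of the foci-disappearance model with the
#' per-quality parameters.  Per quality, either the persistent fraction
#' `p_Q` or the mean number of persistent foci per track `pbar_Q` may be
#' given; the other is derived through the identity `pbar_Q = n_Q * p_Q`.
#'
#' @param n_b Mean number of background foci per nucleus.
#' @param n_s Mean number of sham-induced foci per nucleus at `t_M`.
#' @param beta0 Repair rate of sham-induced foci (1/h).
#' @param beta1 Repair rate of normal radiation-induced foci (1/h).
#' @param beta2 Repair rate of persistent radiation-induced foci (1/h).
#' @param qualities Data frame with columns `quality`, `n_Q` (mean foci per
#'   track at `t_M`) and `p_Q` and/or `pbar_Q`.
#' @param t_M Reference time (h) of the maximal focus count post
#'   irradiation; fixed at 0.5 h in the experiment.
#' @return A `kinetics_params` object.
#' @export
#' @examples
#' kinetics_params(
#'   n_b = 0.24, n_s = 0.26, beta0 = 0.27, beta1 = 0.27, beta2 = 0.01,
#'   qualities = tibble::tibble(quality = "protons_3MeV", n_Q = 0.37, p_Q = 0.17)
#' )
kinetics_params <- function(n_b, n_s, beta0, beta1, beta2, qualities,
                            t_M = 0.5) {
  .check_nonneg(c(n_b, n_s, beta0, beta1, beta2), "rates and mean focus numbers")
  if (!is.numeric(t_M) || length(t_M) != 1L || t_M < 0) {
    abort("`t_M` must be a single non-negative time.", class = "foci_param_error")
  }
  if (!is.data.frame(qualities) || !all(c("quality", "n_Q") %in% names(qualities))) {
    abort("`qualities` must be a data frame with columns `quality` and `n_Q`.",
          class = "foci_param_error")
  }
  q <- tibble::as_tibble(qualities)
  .check_nonneg(q$n_Q, "`n_Q`")
  if (!("p_Q" %in% names(q)) && !("pbar_Q" %in% names(q))) {
    abort("`qualities` needs `p_Q` or `pbar_Q`.", class = "foci_param_error")
  }
  if (!("pbar_Q" %in% names(q))) q <- reparameterize(q, "to_mean")
  if (!("p_Q" %in% names(q))) q <- reparameterize(q, "to_fraction")
  if (any(q$p_Q < 0 | q$p_Q > 1)) {
    abort("`p_Q` must lie in [0, 1].", class = "foci_param_error")
  }
  if (any(q$pbar_Q > q$n_Q + 1e-12)) {
    abort("`pbar_Q` must not exceed `n_Q`.", class = "foci_param_error")
  }
  if (beta2 > beta1) {
    warn("beta2 > beta1: the 'persistent' class disappears faster than the normal class.")
  }
  structure(
    list(n_b = n_b, n_s = n_s, beta0 = beta0, beta1 = beta1, beta2 = beta2,
         qualities = q, t_M = t_M),
    class = "kinetics_params"
  )
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat(sprintf(
    "<kinetics_params>  n_b = %.4g, n_s = %.4g, beta0 = %.4g, beta1 = %.4g, beta2 = %.4g, t_M = %g h\n",
    x$n_b, x$n_s, x$beta0, x$beta1, x$beta2, x$t_M
  ))
  print(x$qualities)
  invisible(x)
}

#' @method tidy kinetics_params
#' @export
tidy.kinetics_params <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      term = c("n_b", "n_s", "beta0", "beta1", "beta2"),
      quality = NA_character_,
      value = c(x$n_b, x$n_s, x$beta0, x$beta1, x$beta2)
    ),
    x$qualities |>
      tidyr::pivot_longer(cols = c("n_Q", "p_Q", "pbar_Q"),
                          names_to = "term", values_to = "value") |>
      dplyr::select("term", "quality", "value")
  )
}

.q_row <- function(params, quality) {
  i <- match(quality, params$qualities$quality)
  if (is.na(i)) {
    abort(sprintf("no parameters for quality '%s'.", quality),
          class = "foci_param_error")
  }
  params$qualities[i, ]
}

#' Mean foci per nucleus in sham-irradiated cells
#'
#' Background plus an exponentially repaired sham-induced component:
#' `n_b + n_s * exp(-beta0 * (t - t_M))`.
#'
#' @param t Time post irradiation (h), `t >= t_M`.
#' @param params A [kinetics_params()] object.
#' @return Mean number of foci per nucleus (vectorised over `t`).
#' @export
sham_mean <- function(t, params) {
  .check_time(t, params$t_M)
  params$n_b + params$n_s * exp(-params$beta0 * (t - params$t_M))
}

#' Probability of observing a focus at a track cluster
#'
#' For a cluster of `n_i` unresolvable ion tracks, the number of initially
#' formed foci is Poisson with mean `n_i * n_Q`; each survives to time `t`
#' with probability `e^{-beta1 dt}` (normal) or `e^{-beta2 dt}`
#' (persistent).  The cluster is scored as one focus while at least one of
#' its foci survives.  Two algebraically equivalent parameterizations are
#' offered: the persistent-fraction form (using `p_Q`) and the
#' persistent-mean form (using `pbar_Q = n_Q * p_Q`).
#'
#' @param t Time post irradiation (h), `t >= t_M`; vectorised.
#' @param n_i Cluster multiplicity (number of tracks), integer `>= 1`.
#' @param params A [kinetics_params()] object.
#' @param quality Radiation-quality label (row of `params$qualities`).
#' @param parameterization `"fraction"` or `"mean"`.
#' @return Probability in [0, 1), non-increasing in `t` when
#'   `beta1 >= beta2`.
#' @export
cluster_focus_prob <- function(t, n_i, params, quality,
                               parameterization = c("fraction", "mean")) {
  parameterization <- match.arg(parameterization)
  .check_time(t, params$t_M)
  if (any(n_i < 1) || any(n_i != round(n_i))) {
    abort("`n_i` must be a positive integer cluster size.",
          class = "foci_param_error")
  }
  q <- .q_row(params, quality)
  dt <- t - params$t_M
  e1 <- exp(-params$beta1 * dt)
  e2 <- exp(-params$beta2 * dt)
  lam <- if (parameterization == "fraction") {
    n_i * q$n_Q * ((1 - q$p_Q) * e1 + q$p_Q * e2)
  } else {
    n_i * ((q$n_Q - q$pbar_Q) * e1 + q$pbar_Q * e2)
  }
  1 - exp(-lam)
}

#' Mean number of observed radiation-induced foci per nucleus
#'
#' Sum over cluster multiplicities of the focus-observation probability
#' weighted by the mean number of clusters of that multiplicity:
#' `sum_n k_bar(n) * P(t | n)`.
#'
#' @param t Time post irradiation (h); vectorised.
#' @param spectrum Cluster spectrum tibble (columns `quality`, `n`,
#'   `k_bar`), e.g. from [estimate_cluster_spectrum()].
#' @param params A [kinetics_params()] object.
#' @param parameterization `"fraction"` or `"mean"`.
#' @return Mean number of radiation-induced foci per nucleus.
#' @export
radiation_mean <- function(t, spectrum, params,
                           parameterization = c("fraction", "mean")) {
  parameterization <- match.arg(parameterization)
  quality <- unique(spectrum$quality)
  if (length(quality) != 1L) {
    abort("`spectrum` must contain exactly one quality.",
          class = "foci_param_error")
  }
  .check_time(t, params$t_M)
  q <- .q_row(params, quality)
  dt <- t - params$t_M
  e1 <- exp(-params$beta1 * dt)
  e2 <- exp(-params$beta2 * dt)
  cvec <- if (parameterization == "fraction") {
    q$n_Q * ((1 - q$p_Q) * e1 + q$p_Q * e2)
  } else {
    (q$n_Q - q$pbar_Q) * e1 + q$pbar_Q * e2
  }
  p_mat <- 1 - exp(-outer(cvec, spectrum$n))  # time x size
  drop(p_mat %*% spectrum$k_bar)
}

#' Total mean foci per nucleus in irradiated cells
#'
#' Sham-treated and radiation-induced foci occur independently, so their
#' means add: `m_Q(t) = m_s(t) + m_{r,Q}(t)`.
#'
#' @inheritParams radiation_mean
#' @return Mean number of observed foci per nucleus.
#' @export
total_mean <- function(t, spectrum, params,
                       parameterization = c("fraction", "mean")) {
  sham_mean(t, params) + radiation_mean(t, spectrum, params, parameterization)
}

#' Convert between the two persistence parameterizations
#'
#' The persistent class of radiation-induced foci can be described either
#' by its fraction `p_Q` of the per-track mean `n_Q` or by the mean number
#' of persistent foci per track `pbar_Q = n_Q * p_Q`.  This converts a
#' per-quality parameter table (or a full [kinetics_params()] object) in
#' either direction; round trips are exact.
#'
#' @param x Data frame with columns `n_Q` and `p_Q` (direction `"to_mean"`)
#'   or `n_Q` and `pbar_Q` (direction `"to_fraction"`), or a
#'   `kinetics_params` object.
#' @param direction `"to_mean"` computes `pbar_Q`; `"to_fraction"` computes
#'   `p_Q`.
#' @return The input with the derived column added/overwritten.
#' @export
#' @examples
#' reparameterize(tibble::tibble(n_Q = 0.37, p_Q = 0.17), "to_mean")
reparameterize <- function(x, direction = c("to_mean", "to_fraction")) {
  direction <- match.arg(direction)
  if (inherits(x, "kinetics_params")) {
    x$qualities <- reparameterize(x$qualities, direction)
    return(x)
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame or kinetics_params.", class = "foci_param_error")
  }
  if (direction == "to_mean") {
    if (!all(c("n_Q", "p_Q") %in% names(x))) {
      abort("need columns `n_Q` and `p_Q`.", class = "foci_param_error")
    }
    x$pbar_Q <- x$n_Q * x$p_Q
  } else {
    if (!all(c("n_Q", "pbar_Q") %in% names(x))) {
      abort("need columns `n_Q` and `pbar_Q`.", class = "foci_param_error")
    }
    if (any(x$n_Q == 0 & x$pbar_Q > 0)) {
      abort("cannot derive `p_Q`: `pbar_Q` > 0 while `n_Q` = 0.",
            class = "foci_param_error")
    }
    if (any(x$pbar_Q > x$n_Q + 1e-12)) {
      abort("`pbar_Q` exceeds `n_Q`: persistent mean larger than the per-track mean.",
            class = "foci_param_error")
    }
    x$p_Q <- ifelse(x$n_Q == 0, 0, x$pbar_Q / x$n_Q)
  }
  x
}
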