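# Robustness protocol: the fitted parameters must not depend on the start
# point, on the Monte Carlo sampling of the fixed cluster spectra, or
# unduly on the constraint variant.  Each sweep returns a report carrying
# the individual fits, per-parameter spreads, and (for the variant sweep)
# min/max envelopes of the fitted model curves over a time grid.

.tidy_fit_row <- function(fit, id) {
  dplyr::mutate(tidy(fit), id = id, chisq = fit$chisq, .before = 1)
}

#' Start-value sweep
#'
#' Runs the simultaneous fit once per start point and reports the spread of
#' the converged objectives and parameters.  Failed starts are counted, not
#' hidden.
#'
#' @inheritParams simultaneous_fit
#' @param starts List of named start vectors; defaults to the extreme
#'   starts (all zero; all at the sampling maximum) plus 16 Latin-hypercube
#'   draws.
#' @param seed Seed for the default start draw.
#' @return A `start_sweep` report: list with `fits` (per-start tidy
#'   estimates), `ranges` (per-term min/max/spread over converged starts),
#'   `objectives`, `n_failed`, and `best` (the best `foci_fit`).
#' @export
start_value_sweep <- function(data, spectra, options = fit_options(),
                              starts = NULL, seed = NULL) {
  data_v <- .validate_fit_data(data, need_sham = TRUE)
  qualities <- setdiff(unique(data_v$quality), "sham")
  layout <- .par_layout(qualities, options, "simultaneous")
  starts <- starts %||% .default_starts(layout, 16, seed)
  fits <- purrr::imap(starts, function(s, id) {
    tryCatch(
      simultaneous_fit(data, spectra, options, starts = list(s)),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    return(structure(list(fits = tibble::tibble(), ranges = tibble::tibble(),
                          objectives = tibble::tibble(),
                          n_failed = length(starts), best = NULL),
                     class = c("start_sweep", "robustness_report")))
  }
  est <- purrr::imap_dfr(fits[ok], .tidy_fit_row)
  objectives <- tibble::tibble(
    id = names(fits[ok]),
    chisq = vapply(fits[ok], `[[`, numeric(1), "chisq")
  )
  ranges <- est |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(min = min(.data$estimate), max = max(.data$estimate),
                     spread = max(.data$estimate) - min(.data$estimate),
                     .groups = "drop")
  best <- fits[ok][[which.min(objectives$chisq)]]
  structure(
    list(fits = est, ranges = ranges, objectives = objectives,
         n_failed = sum(!ok), best = best),
    class = c("start_sweep", "robustness_report")
  )
}

#' Spectrum-batch sweep
#'
#' Propagates the Monte Carlo sampling spread of the fixed cluster spectra
#' into the fitted parameters: one regression per spectrum batch, each
#' started from the reference optimum.  The per-parameter standard
#' deviation across batches is compared with the fit standard errors.
#'
#' @inheritParams simultaneous_fit
#' @param batches Long batch spectra (from [batch_spectra()], possibly
#'   row-bound over qualities) with a `batch` column.
#' @param reference Optional reference `foci_fit` on a default spectrum;
#'   when missing, the first batch is fitted with the full multi-start
#'   protocol and used as reference.
#' @return A `batch_sweep` report: list with `fits` (per-batch tidy
#'   estimates), `spread` (per-term SD across batches, the reference SE and
#'   their ratio), `n_failed`, `reference`.
#' @export
spectrum_batch_sweep <- function(data, batches, options = fit_options(),
                                 reference = NULL, seed = NULL) {
  if (!("batch" %in% names(batches))) {
    abort("`batches` must carry a `batch` column (see batch_spectra()).",
          class = "foci_config_error")
  }
  ids <- sort(unique(batches$batch))
  if (length(ids) < 2L) {
    abort("need at least two spectrum batches.", class = "foci_config_error")
  }
  spectra1 <- dplyr::select(batches[batches$batch == ids[1], ], -"batch")
  reference <- reference %||%
    simultaneous_fit(data, spectra1, options, n_starts = 16, seed = seed)
  ref_start <- list(reference = reference$estimates)
  fits <- purrr::map(ids, function(b) {
    sp <- dplyr::select(batches[batches$batch == b, ], -"batch")
    tryCatch(
      simultaneous_fit(data, sp, options, starts = ref_start),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  est <- purrr::imap_dfr(fits[ok], function(f, i) .tidy_fit_row(f, ids[ok][i]))
  spread <- est |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(sd_batches = sd(.data$estimate), .groups = "drop") |>
    dplyr::left_join(
      tibble::tibble(term = names(reference$estimates),
                     se_fit = unname(reference$se),
                     se_fit_unscaled = unname(reference$se_unscaled)),
      by = "term"
    ) |>
    dplyr::mutate(ratio = .data$sd_batches / .data$se_fit,
                  ratio_unscaled = .data$sd_batches / .data$se_fit_unscaled)
  structure(
    list(fits = est, spread = spread, n_failed = sum(!ok),
         reference = reference),
    class = c("batch_sweep", "robustness_report")
  )
}

.default_variants <- function() {
  grid <- expand.grid(
    parameterization = c("fraction", "mean"),
    beta0 = c("free", "eq_beta1"),
    beta2 = c("free", "zero"),
    stringsAsFactors = FALSE
  )
  variants <- purrr::pmap(grid, function(parameterization, beta0, beta2) {
    fit_options(parameterization, beta0, beta2)
  })
  names(variants) <- sprintf("%s_b0%s_b2%s", grid$parameterization,
                             grid$beta0, grid$beta2)
  variants$fraction_perQbeta1 <- fit_options("fraction", per_quality_beta1 = TRUE)
  variants
}

#' Constraint-variant sweep with fit-curve envelopes
#'
#' Refits under the enumerated option set (both parameterizations crossed
#' with `beta0` free / equal to `beta1` and `beta2` free / zero, plus a
#' per-quality-`beta1` variant), optionally adds independent
#' difference-series fits per quality, and reduces the fitted model curves
#' to a per-(quality, time) min/max envelope over a log-spaced time grid.
#' Independent-fit curves enter the envelope as radiation term plus the
#' default variant's sham term, so all curves live on the observed scale.
#'
#' @inheritParams simultaneous_fit
#' @param variants Named list of [fit_options()]; defaults to the grid
#'   above.  The first element is the default variant whose curve the
#'   envelope must bracket.
#' @param include_independent Also run per-quality independent difference
#'   fits (with `beta2` free and fixed to zero).
#' @param t_grid Time grid for the envelope; default 100 log-spaced points
#'   over 0.5-24 h.
#' @param n_starts,seed Multi-start settings passed to each fit.
#' @return A `variant_sweep` report: list with `fits` (named list of
#'   `foci_fit`s), `params` (canonical per-variant estimates, with both
#'   persistence parameterizations derived), `ranges`, `envelope` (tibble
#'   `quality`, `t_h`, `lo`, `hi`, `default`), `n_failed`.
#' @export
variant_sweep <- function(data, spectra, variants = NULL,
                          include_independent = TRUE,
                          t_grid = NULL, n_starts = 16, seed = NULL) {
  variants <- variants %||% .default_variants()
  t_grid <- t_grid %||% exp(seq(log(0.5), log(24), length.out = 100))
  fits <- purrr::imap(variants, function(opt, id) {
    tryCatch(
      simultaneous_fit(data, spectra, opt, n_starts = n_starts, seed = seed),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!ok[[1]]) {
    abort("the default variant failed to fit.", class = "foci_fit_error")
  }
  default_fit <- fits[[1]]
  curves <- purrr::imap_dfr(fits[ok], function(f, id) {
    dplyr::mutate(fitted_curves(f, t_grid), variant = id)
  })
  ind_fits <- list()
  if (include_independent) {
    qualities <- default_fit$qualities
    sham_curve <- fitted_curves(default_fit, t_grid)
    sham_curve <- sham_curve[sham_curve$quality == "sham", ]
    for (q in qualities) {
      dd <- difference_dataset(data, q)
      sp <- spectra[spectra$quality == q, , drop = FALSE]
      for (b2 in c("free", "zero")) {
        id <- sprintf("independent_%s_b2%s", q, b2)
        f <- tryCatch(
          independent_fit(dd, sp, fit_options(beta2 = b2),
                          n_starts = n_starts, seed = seed),
          error = function(e) NULL
        )
        if (is.null(f)) next
        ind_fits[[id]] <- f
        curves <- dplyr::bind_rows(
          curves,
          tibble::tibble(quality = q, t_h = t_grid,
                         mean = fitted_curves(f, t_grid)$mean + sham_curve$mean,
                         variant = id)
        )
      }
    }
  }
  envelope <- curves |>
    dplyr::filter(.data$quality != "sham") |>
    dplyr::group_by(.data$quality, .data$t_h) |>
    dplyr::summarise(lo = min(.data$mean), hi = max(.data$mean), .groups = "drop")
  default_curves <- fitted_curves(default_fit, t_grid) |>
    dplyr::filter(.data$quality != "sham") |>
    dplyr::rename(default = "mean")
  envelope <- dplyr::left_join(envelope, default_curves,
                               by = c("quality", "t_h"))
  params <- purrr::imap_dfr(fits[ok], .canonical_params)
  ranges <- params |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(min = min(.data$estimate), max = max(.data$estimate),
                     .groups = "drop")
  structure(
    list(fits = c(fits[ok], ind_fits), params = params, ranges = ranges,
         envelope = envelope, default = names(variants)[1],
         n_failed = sum(!ok)),
    class = c("variant_sweep", "robustness_report")
  )
}

# Canonical parameter table for cross-variant comparison: persistence is
# reported in both parameterizations regardless of which one was fitted.
.canonical_params <- function(fit, id) {
  td <- tidy(fit)
  qs <- fit$qualities
  frac <- fit$options$parameterization == "fraction"
  extra <- purrr::map_dfr(qs, function(q) {
    n_Q <- fit$estimates[[paste0("n_", q)]]
    if (frac) {
      p <- fit$estimates[[paste0("p_", q)]]
      tibble::tibble(term = paste0("pbar_", q), estimate = n_Q * p,
                     std.error = NA_real_, at_boundary = NA)
    } else {
      pb <- fit$estimates[[paste0("pbar_", q)]]
      tibble::tibble(term = paste0("p_", q),
                     estimate = if (n_Q > 0) pb / n_Q else 0,
                     std.error = NA_real_, at_boundary = NA)
    }
  })
  dplyr::bind_rows(td, extra) |>
    dplyr::mutate(variant = id, chisq_per_df = fit$chisq_per_df, .before = 1)
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<%s> %d fits, %d failed\n",
              class(x)[1],
              if (!is.null(x$fits) && is.data.frame(x$fits)) length(unique(x$fits$id))
              else length(x$fits),
              x$n_failed))
  if (!is.null(x$ranges) && nrow(x$ranges)) print(x$ranges, n = Inf)
  if (!is.null(x$spread)) print(x$spread, n = Inf)
  invisible(x)
}
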