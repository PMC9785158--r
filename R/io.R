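# File schemas, YAML configuration, and the end-to-end pipeline.
#
# All tables travel as CSV with header rows and explicit units in the
# column names (t_h for hours, rates are 1/h); written files re-read to
# the in-memory structures exactly.

.dataset_cols <- c("quality", "t_h", "mean", "sd", "n_rep")
.spectrum_cols <- c("quality", "n", "k_bar", "n_nuclei", "seed")

#' Read / write foci datasets and cluster spectra
#'
#' CSV round trip for the two table schemas used by the fitting module:
#' datasets (`quality`, `t_h`, `mean`, `sd`, `n_rep`) and cluster spectra
#' (`quality`, `n`, `k_bar`, `n_nuclei`, `seed`).
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Readers return a validated tibble; writers return `x`
#'   invisibly.
#' @name foci_io
NULL

#' @rdname foci_io
#' @export
write_foci_data <- function(x, path) {
  stopifnot(all(.dataset_cols[1:4] %in% names(x)))
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname foci_io
#' @export
read_foci_data <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(.dataset_cols[1:4] %in% names(x))) {
    abort(sprintf("dataset file '%s' must have columns %s.", path,
                  paste(.dataset_cols[1:4], collapse = ", ")),
          class = "foci_config_error")
  }
  x
}

#' @rdname foci_io
#' @export
write_cluster_spectra <- function(x, path) {
  stopifnot(all(c("quality", "n", "k_bar") %in% names(x)))
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname foci_io
#' @export
read_cluster_spectra <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("quality", "n", "k_bar") %in% names(x))) {
    abort(sprintf("spectrum file '%s' must have columns quality, n, k_bar.",
                  path),
          class = "foci_config_error")
  }
  x
}

# Configuration ---------------------------------------------------------------

.config_schema <- list(
  seed = NULL, output_dir = NULL,
  geometry = list(pattern_side = NULL, fwhm = NULL, p0 = NULL, p1 = NULL,
                  p2 = NULL, mean_long = NULL, mean_short = NULL,
                  sd_pc1 = NULL, sd_pc2 = NULL, pc_angle = NULL,
                  min_short = NULL, proximity_radius = NULL, n_nuclei = NULL),
  data = list(datasets_csv = NULL, spectra_csv = NULL, simulate = NULL,
              design = list(times = NULL, n_dishes = NULL, n_nuclei = NULL),
              params = list(n_b = NULL, n_s = NULL, beta0 = NULL,
                            beta1 = NULL, beta2 = NULL, t_M = NULL,
                            qualities = NULL)),
  fit = list(parameterization = NULL, beta0 = NULL, beta2 = NULL,
             per_quality_beta1 = NULL, n_starts = NULL),
  robustness = list(enabled = NULL, n_batches = NULL, batch_nuclei = NULL,
                    t_grid_n = NULL, include_independent = NULL)
)

.check_keys <- function(x, schema, where = "config") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown)) {
    abort(sprintf("unknown %s key(s): %s", where,
                  paste(unknown, collapse = ", ")),
          class = "foci_config_error")
  }
  for (k in names(x)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      if (!is.list(x[[k]])) {
        abort(sprintf("config block '%s' must be a mapping.", k),
              class = "foci_config_error")
      }
      if (k == "data" && "qualities" %in% names(x[[k]])) next
      .check_keys(x[[k]], schema[[k]], paste0(where, "$", k))
    }
  }
  invisible(TRUE)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with blocks `seed`, `output_dir`, `geometry`, `data`,
#' `fit`, `robustness`.  Unknown keys are rejected by name, and the `data`
#' block must either point at existing `datasets_csv`/`spectra_csv` files
#' or set `simulate: true` (in which case the `params` block supplies the
#' generator truth).
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, .config_schema)
  if (!is.null(cfg$data)) {
    .check_keys(cfg$data, .config_schema$data, "config$data")
    if (!is.null(cfg$data$design)) {
      .check_keys(cfg$data$design, .config_schema$data$design, "config$data$design")
    }
    if (!is.null(cfg$data$params)) {
      .check_keys(cfg$data$params, .config_schema$data$params, "config$data$params")
    }
  }
  simulate <- isTRUE(cfg$data$simulate)
  if (!simulate && is.null(cfg$data$datasets_csv)) {
    abort("config$data must set `simulate: true` or provide `datasets_csv`.",
          class = "foci_config_error")
  }
  if (!simulate && is.null(cfg$data$spectra_csv) && is.null(cfg$geometry)) {
    abort("config$data needs `spectra_csv` (or a `geometry` block to simulate spectra).",
          class = "foci_config_error")
  }
  cfg
}

.geometry_from_config <- function(g) {
  g <- g %||% list()
  list(
    pop = nucleus_population(
      mean_long = g$mean_long %||% 8, mean_short = g$mean_short %||% 5,
      sd_pc = c(g$sd_pc1 %||% 2, g$sd_pc2 %||% 1),
      pc_angle = g$pc_angle %||% (pi / 4),
      min_short = g$min_short %||% 0.5
    ),
    pattern = target_pattern(g$pattern_side %||% 4),
    beam = beam_profile(g$fwhm %||% 4),
    delivery = ion_delivery(g$p0 %||% 0.05, g$p1 %||% 0.90, g$p2 %||% 0.05),
    proximity_radius = g$proximity_radius %||% 2,
    n_nuclei = g$n_nuclei %||% 1000
  )
}

.params_from_config <- function(p) {
  if (is.null(p)) return(default_kinetics_params())
  q <- if (is.null(p$qualities)) {
    default_kinetics_params()$qualities
  } else {
    dplyr::bind_rows(lapply(p$qualities, tibble::as_tibble))
  }
  kinetics_params(
    n_b = p$n_b %||% 0.24, n_s = p$n_s %||% 0.26,
    beta0 = p$beta0 %||% 0.27, beta1 = p$beta1 %||% 0.27,
    beta2 = p$beta2 %||% 0.01, qualities = q, t_M = p$t_M %||% 0.5
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cluster-spectrum simulation (or loading), data
#' simulation (or loading), the simultaneous fit, the robustness sweeps
#' (optional), and report rendering.  Every output file is stamped with the
#' seed and a hash of the configuration; one log line is emitted per
#' stage.
#'
#' @param config A configuration list from [read_pipeline_config()] or a
#'   path to the YAML file.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with elements `spectra`, `data`, `fit`,
#'   `report`, `robustness` (possibly `NULL`), `config_hash`, `files`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed %||% 1L
  out_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  stamp <- sprintf("# seed: %d, config: %s", seed, cfg_hash)
  files <- character(0)

  params <- .params_from_config(config$data$params)
  qualities <- params$qualities$quality

  t0 <- Sys.time()
  if (!is.null(config$data$spectra_csv)) {
    spectra <- read_cluster_spectra(config$data$spectra_csv)
  } else {
    g <- .geometry_from_config(config$geometry)
    set.seed(seed)
    sub_seeds <- sample.int(.Machine$integer.max, length(qualities))
    spectra <- purrr::map2_dfr(qualities, sub_seeds, function(q, s) {
      estimate_cluster_spectrum(
        q, g$n_nuclei, pop = g$pop, pattern = g$pattern, beam = g$beam,
        delivery = g$delivery, proximity_radius = g$proximity_radius,
        seed = s
      )
    })
  }
  f <- file.path(out_dir, "spectra.csv")
  write_cluster_spectra(spectra, f)
  files <- c(files, f)
  inform(sprintf("[spectra] %d qualities, seed %d, %.1f s",
                 length(qualities), seed,
                 as.numeric(Sys.time() - t0, units = "secs")))

  t0 <- Sys.time()
  if (isTRUE(config$data$simulate)) {
    dsg <- config$data$design %||% list()
    design <- experiment_design(
      times = dsg$times %||% c(0.5, 2, 4, 8, 24),
      n_dishes = dsg$n_dishes %||% 3, n_nuclei = dsg$n_nuclei %||% 1000
    )
    data <- generate_foci_tables(design, params, spectra,
                                 seed = seed + 1L)
  } else {
    data <- read_foci_data(config$data$datasets_csv)
  }
  f <- file.path(out_dir, "datasets.csv")
  write_foci_data(data, f)
  files <- c(files, f)
  inform(sprintf("[data] %d rows, %.1f s", nrow(data),
                 as.numeric(Sys.time() - t0, units = "secs")))

  t0 <- Sys.time()
  fo <- config$fit %||% list()
  options <- fit_options(
    parameterization = fo$parameterization %||% "fraction",
    beta0 = fo$beta0 %||% "free",
    beta2 = fo$beta2 %||% "free",
    per_quality_beta1 = isTRUE(fo$per_quality_beta1)
  )
  fit <- simultaneous_fit(data, spectra, options,
                          n_starts = fo$n_starts %||% 16, seed = seed + 2L)
  report <- render_report(fit)
  f <- file.path(out_dir, "fit_report.csv")
  readr::write_csv(report, f)
  files <- c(files, f)
  f <- file.path(out_dir, "fit_report.json")
  jsonlite::write_json(
    list(stamp = stamp, glance = glance(fit), tidy = tidy(fit)),
    f, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, f)
  inform(sprintf("[fit] chisq/f = %.3g (f = %d), %.1f s",
                 fit$chisq_per_df, fit$df,
                 as.numeric(Sys.time() - t0, units = "secs")))

  robustness <- NULL
  rb <- config$robustness %||% list()
  if (isTRUE(rb$enabled)) {
    t0 <- Sys.time()
    sweep <- variant_sweep(
      data, spectra,
      include_independent = rb$include_independent %||% TRUE,
      t_grid = exp(seq(log(min(data$t_h)), log(max(data$t_h)),
                       length.out = rb$t_grid_n %||% 100)),
      n_starts = fo$n_starts %||% 16, seed = seed + 3L
    )
    g <- .geometry_from_config(config$geometry)
    set.seed(seed + 4L)
    bsub <- sample.int(.Machine$integer.max, length(qualities))
    batches <- purrr::map2_dfr(qualities, bsub, function(q, s) {
      batch_spectra(q, rb$n_batches %||% 100, rb$batch_nuclei %||% 1000,
                    pop = g$pop, pattern = g$pattern, beam = g$beam,
                    delivery = g$delivery,
                    proximity_radius = g$proximity_radius, seed = s)
    })
    bs <- spectrum_batch_sweep(data, batches, options, reference = fit)
    robustness <- list(variants = sweep, batches = bs)
    f <- file.path(out_dir, "envelope.csv")
    readr::write_csv(sweep$envelope, f)
    files <- c(files, f)
    f <- file.path(out_dir, "robustness.json")
    jsonlite::write_json(
      list(stamp = stamp, variant_params = sweep$params,
           variant_ranges = sweep$ranges, batch_spread = bs$spread),
      f, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, f)
    inform(sprintf("[robustness] %d variants, %d batches, %.1f s",
                   length(sweep$fits), length(unique(batches$batch)),
                   as.numeric(Sys.time() - t0, units = "secs")))
  }

  invisible(list(spectra = spectra, data = data, fit = fit, report = report,
                 robustness = robustness, config_hash = cfg_hash,
                 files = files))
}

#' Render a fit as a per-quality report table
#'
#' One row per radiation quality with LET metadata, the estimates and
#' standard errors of `n_Q`, `p_Q`, `pbar_Q`, the shared repair rates, and
#' the goodness of fit.  Whichever persistence parameter was not fitted is
#' computed through [reparameterize()] and marked in the `derived` column.
#'
#' @param fit A `foci_fit` from [simultaneous_fit()].
#' @param digits Rounding applied to the displayed values (`NULL` keeps
#'   full precision).
#' @return A tibble mirroring the published layout.
#' @export
render_report <- function(fit, digits = NULL) {
  stopifnot(inherits(fit, "foci_fit"))
  frac <- fit$options$parameterization == "fraction"
  derived_col <- if (frac) "pbar_Q" else "p_Q"
  qmeta <- radiation_qualities()
  rows <- purrr::map_dfr(fit$qualities, function(q) {
    n_Q <- fit$estimates[[paste0("n_", q)]]
    n_se <- fit$se[[paste0("n_", q)]]
    if (frac) {
      p_Q <- fit$estimates[[paste0("p_", q)]]
      p_se <- fit$se[[paste0("p_", q)]]
      pbar <- reparameterize(tibble::tibble(n_Q = n_Q, p_Q = p_Q), "to_mean")$pbar_Q
      pbar_se <- NA_real_
    } else {
      pbar <- fit$estimates[[paste0("pbar_", q)]]
      pbar_se <- fit$se[[paste0("pbar_", q)]]
      p_Q <- reparameterize(tibble::tibble(n_Q = n_Q, pbar_Q = min(pbar, n_Q)),
                            "to_fraction")$p_Q
      p_se <- NA_real_
    }
    beta1 <- if (fit$options$per_quality_beta1) {
      fit$estimates[[paste0("beta1_", q)]]
    } else {
      fit$estimates[["beta1"]]
    }
    beta1_se <- if (fit$options$per_quality_beta1) {
      fit$se[[paste0("beta1_", q)]]
    } else {
      fit$se[["beta1"]]
    }
    beta2 <- if (fit$options$beta2 == "free") fit$estimates[["beta2"]] else 0
    beta2_se <- if (fit$options$beta2 == "free") fit$se[["beta2"]] else NA_real_
    tibble::tibble(
      quality = q,
      let_keV_um = qmeta$let_keV_um[match(q, qmeta$quality)],
      n_Q = n_Q, n_Q_se = n_se,
      p_Q = p_Q, p_Q_se = p_se,
      pbar_Q = pbar, pbar_Q_se = pbar_se,
      beta1_per_h = beta1, beta1_se = beta1_se,
      beta2_per_h = beta2, beta2_se = beta2_se,
      chisq_per_df = fit$chisq_per_df, df = fit$df,
      derived = derived_col
    )
  })
  if (!is.null(digits)) {
    rows <- dplyr::mutate(rows, dplyr::across(dplyr::where(is.numeric),
                                              ~ round(.x, digits)))
  }
  rows
}
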