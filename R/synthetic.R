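# Per-nucleus generative model matching the kinetics model's assumptions.
#
# Each nucleus observation is built from independent components:
# background foci ~ Poisson(n_b); sham-induced foci ~ Poisson(n_s *
# exp(-beta0 dt)); and, per track cluster, foci formed at t_M ~
# Poisson(n_i * n_Q), each focus assigned at creation to the persistent
# class with probability p_Q, each surviving to t with probability
# exp(-beta2 dt) (persistent) or exp(-beta1 dt) (normal); the cluster is
# scored as one observed focus while at least one of its foci survives.
# The per-component decomposition is retained so conservation can be
# checked.  This generator is the package's brute-force oracle for the
# closed-form model and the testbed for parameter recovery.

#' Experiment design
#'
#' Replicate structure of the focus-counting experiment: fixation times,
#' replicate dishes per condition, and nuclei scored per dish.
#'
#' @param times Fixation times post irradiation (h); must include the
#'   reference time 0.5 h.
#' @param n_dishes Replicate dishes per condition.
#' @param n_nuclei Nuclei scored per dish.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(times = c(0.5, 2, 4, 8, 24), n_dishes = 3,
                              n_nuclei = 1000) {
  if (!is.numeric(times) || length(times) < 1 || any(times < 0)) {
    abort("`times` must be non-negative times in hours.",
          class = "foci_config_error")
  }
  if (n_dishes < 1 || n_nuclei < 1) {
    abort("`n_dishes` and `n_nuclei` must be positive counts.",
          class = "foci_config_error")
  }
  structure(
    list(times = sort(unique(times)), n_dishes = as.integer(n_dishes),
         n_nuclei = as.integer(n_nuclei)),
    class = "experiment_design"
  )
}

#' Reference kinetics parameters of the study conditions
#'
#' The parameter set used as generator truth throughout the package's
#' simulation studies: per-quality means and persistent fractions from the
#' simultaneous-regression estimates (fraction parameterization), shared
#' repair rates `beta1 = 0.27/h`, `beta2 = 0.01/h`, background mean
#' `n_b = 0.24`, sham-induced mean `n_s = 0.26` and `beta0 = 0.27/h`.
#'
#' @return A [kinetics_params()] object covering the four radiation
#'   qualities of [radiation_qualities()].
#' @export
default_kinetics_params <- function() {
  kinetics_params(
    n_b = 0.24, n_s = 0.26, beta0 = 0.27, beta1 = 0.27, beta2 = 0.01,
    qualities = tibble::tibble(
      quality = c("protons_3MeV", "alpha_20MeV", "alpha_10MeV", "alpha_8MeV"),
      n_Q = c(0.37, 0.63, 1.08, 1.66),
      p_Q = c(0.17, 0.10, 0.11, 0.11)
    )
  )
}

# Radiation component for n nuclei given per-nucleus cluster-size lists is
# shared between the spectrum route (Poisson cluster counts) and the
# geometry route (simulated irradiations).
.cluster_survivals <- function(sizes, nucleus_id, n_nuclei, n_Q, p_Q, s1, s2) {
  C <- length(sizes)
  if (C == 0L) return(integer(n_nuclei))
  f <- rpois(C, sizes * n_Q)
  pers <- rbinom(C, f, p_Q)
  surv <- rbinom(C, pers, s2) + rbinom(C, f - pers, s1)
  tabulate(nucleus_id[surv > 0L], nbins = n_nuclei)
}

#' Simulate per-nucleus focus counts for one condition
#'
#' Draws `n_nuclei` independent nucleus observations for one radiation
#' quality (or `"sham"` / `"control"`) at one fixation time, keeping the
#' background / sham / radiation decomposition of each count.
#'
#' Track clusters are realised either from a fixed cluster spectrum
#' (independent Poisson counts of clusters of each size, mean `k_bar[n]`
#' per nucleus) or, if `geometry` is supplied, by simulating the
#' irradiation of each nucleus with the Monte Carlo geometry model.
#'
#' @param quality Radiation-quality label, `"sham"` or `"control"`.
#' @param t Fixation time (h), `>= t_M`.
#' @param n_nuclei Number of nuclei.
#' @param params A [kinetics_params()] object.
#' @param spectrum Cluster spectrum for the quality (ignored for sham and
#'   control).
#' @param geometry Optional list with elements `pop`, `pattern`, `beam`,
#'   `delivery`, `proximity_radius`; when supplied, cluster sizes are drawn
#'   per nucleus from the irradiation simulation instead of the spectrum.
#' @param dish Dish index stamped into the output.
#' @return A tibble with columns `quality`, `dish`, `t_h`, `nucleus`,
#'   `background`, `sham`, `radiation`, `count` (= sum of the components).
#' @export
simulate_foci_counts <- function(quality, t, n_nuclei, params,
                                 spectrum = NULL, geometry = NULL,
                                 dish = 1L) {
  .check_time(t, params$t_M)
  stopifnot(length(t) == 1L, n_nuclei >= 1)
  n_nuclei <- as.integer(n_nuclei)
  dt <- t - params$t_M
  bg <- rpois(n_nuclei, params$n_b)
  sh <- if (identical(quality, "control")) {
    integer(n_nuclei)
  } else {
    rpois(n_nuclei, params$n_s * exp(-params$beta0 * dt))
  }
  rad <- integer(n_nuclei)
  if (!quality %in% c("sham", "control")) {
    q <- .q_row(params, quality)
    s1 <- exp(-params$beta1 * dt)
    s2 <- exp(-params$beta2 * dt)
    if (!is.null(geometry)) {
      g <- modifyList(
        list(pop = nucleus_population(), pattern = target_pattern(),
             beam = beam_profile(), delivery = ion_delivery(),
             proximity_radius = 2),
        geometry
      )
      nuc <- sample_nuclei(n_nuclei, g$pop)
      probs <- c(g$delivery$p0, g$delivery$p1, g$delivery$p2)
      sizes <- integer(0)
      ids <- integer(0)
      for (i in seq_len(n_nuclei)) {
        xy <- .sample_ion_xy(g$pattern$x, g$pattern$y, g$beam$sigma, probs)
        if (length(xy$x) == 0L) next
        keep <- points_in_ellipse(xy$x, xy$y, nuc$a[i], nuc$b[i], nuc$phi[i])
        if (!any(keep)) next
        sz <- cluster_tracks(list(x = xy$x[keep], y = xy$y[keep]),
                             g$proximity_radius)
        sizes <- c(sizes, sz)
        ids <- c(ids, rep.int(i, length(sz)))
      }
      rad <- .cluster_survivals(sizes, ids, n_nuclei, q$n_Q, q$p_Q, s1, s2)
    } else {
      if (is.null(spectrum)) {
        abort("supply `spectrum` or `geometry` for an irradiated quality.",
              class = "foci_config_error")
      }
      sp <- spectrum[spectrum$quality == quality, , drop = FALSE]
      if (nrow(sp) == 0L) {
        abort(sprintf("no spectrum rows for quality '%s'.", quality),
              class = "foci_config_error")
      }
      for (r in seq_len(nrow(sp))) {
        cnt <- rpois(n_nuclei, sp$k_bar[r])
        C <- sum(cnt)
        if (C == 0L) next
        ids <- rep.int(seq_len(n_nuclei), cnt)
        rad <- rad + .cluster_survivals(rep.int(sp$n[r], C), ids, n_nuclei,
                                        q$n_Q, q$p_Q, s1, s2)
      }
    }
  }
  tibble::tibble(
    quality = quality, dish = as.integer(dish), t_h = t,
    nucleus = seq_len(n_nuclei),
    background = bg, sham = sh, radiation = as.integer(rad),
    count = bg + sh + as.integer(rad)
  )
}

#' Generate aggregated foci tables for a full experiment
#'
#' Simulates every (quality, time, dish) cell of the design, aggregates to
#' dish means, and reduces to the mean of the dish means and the standard
#' deviation between them -- the exact input schema of the regression
#' module.  Sham (and optionally control) tables are generated alongside
#' the irradiated qualities; control samples are background-only.
#'
#' @param design An [experiment_design()].
#' @param params A [kinetics_params()] object; its `qualities` table
#'   defines the irradiated conditions.
#' @param spectra Cluster spectra covering every irradiated quality.
#' @param geometry Optional geometry configuration forwarded to
#'   [simulate_foci_counts()] (replaces `spectra` as the cluster source).
#' @param include_control Also generate the background-only control table.
#' @param keep_nuclei Attach the full per-nucleus table as attribute
#'   `"nuclei"`.
#' @param seed Optional seed; with a fixed seed the output is reproducible
#'   bit for bit.
#' @return A tibble with columns `quality`, `t_h`, `mean`, `sd`, `n_rep`
#'   (`sd` is `NA` for single-dish designs).
#' @export
generate_foci_tables <- function(design, params, spectra = NULL,
                                 geometry = NULL, include_control = TRUE,
                                 keep_nuclei = FALSE, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "kinetics_params"))
  if (any(design$times < params$t_M)) {
    abort("design times must all be >= t_M.", class = "foci_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  qualities <- c(params$qualities$quality, "sham",
                 if (include_control) "control")
  cells <- list()
  nuclei <- list()
  for (q in qualities) {
    for (t in design$times) {
      dish_means <- numeric(design$n_dishes)
      for (d in seq_len(design$n_dishes)) {
        obs <- simulate_foci_counts(q, t, design$n_nuclei, params,
                                    spectrum = spectra, geometry = geometry,
                                    dish = d)
        dish_means[d] <- mean(obs$count)
        if (keep_nuclei) nuclei[[length(nuclei) + 1L]] <- obs
      }
      cells[[length(cells) + 1L]] <- tibble::tibble(
        quality = q, t_h = t,
        mean = mean(dish_means),
        sd = if (design$n_dishes > 1) sd(dish_means) else NA_real_,
        n_rep = design$n_dishes
      )
    }
  }
  out <- dplyr::bind_rows(cells)
  if (keep_nuclei) attr(out, "nuclei") <- dplyr::bind_rows(nuclei)
  out
}
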