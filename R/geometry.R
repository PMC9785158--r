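# Monte Carlo model of the targeted microbeam irradiation geometry.
#
# Each recognised nucleus is targeted with five single ions in a fixed
# pattern.  The realised traversal points scatter about the targets with the
# beam's Gaussian profile, the single-ion counter can miscount (0 or 2 ions
# delivered per registered ion), and the nucleus cross-section is an ellipse
# with randomly sampled half-axes and orientation.  Traversals falling close
# together produce foci that cannot be resolved as separate; the simulation
# estimates, per radiation quality, the mean number of track clusters of
# each multiplicity per nucleus.

#' Ion targeting pattern
#'
#' Target positions of the five ions delivered to each nucleus: the four
#' corners and the centre of a square of side `side` micrometres.  The
#' pattern is fixed in the lab frame and is not rotated with the nucleus.
#'
#' @param side Side length of the square (micrometres).
#' @return A tibble with columns `x`, `y` (micrometres), centred on the origin.
#' @export
#' @examples
#' target_pattern()
target_pattern <- function(side = 4) {
  if (!is.numeric(side) || length(side) != 1L || !is.finite(side) || side <= 0) {
    abort("`side` must be a single positive length in micrometres.",
          class = "foci_config_error")
  }
  h <- side / 2
  tibble::tibble(
    x = c(-h, h, h, -h, 0),
    y = c(-h, -h, h, h, 0)
  )
}

#' Beam spatial profile
#'
#' Isotropic 2-D Gaussian scatter of the actual ion traversal about each
#' target point, parameterised by the full width at half maximum.
#'
#' @param fwhm Full width at half maximum of the beam spot (micrometres).
#' @return A `beam_profile` object with elements `fwhm` and the implied
#'   Gaussian `sigma` = fwhm / (2 sqrt(2 log 2)).
#' @export
beam_profile <- function(fwhm = 4) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0) {
    abort("`fwhm` must be a single positive length in micrometres.",
          class = "foci_config_error")
  }
  structure(
    list(fwhm = fwhm, sigma = fwhm / (2 * sqrt(2 * log(2)))),
    class = "beam_profile"
  )
}

#' Ion delivery (miscounting) model
#'
#' When the detection system registers the passage of one ion, the number of
#' ions actually delivered can be 0, 1 or 2.  `p0`, `p1`, `p2` are the
#' probabilities of these three multiplicities; they must sum to one.
#'
#' @param p0,p1,p2 Probabilities that a registered ion corresponds to 0, 1
#'   or 2 actual ions.
#' @return An `ion_delivery` object.
#' @export
ion_delivery <- function(p0 = 0.05, p1 = 0.90, p2 = 0.05) {
  p <- c(p0, p1, p2)
  if (!is.numeric(p) || length(p) != 3L || anyNA(p) || any(p < 0)) {
    abort("`p0`, `p1`, `p2` must be non-negative probabilities.",
          class = "foci_config_error")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort("`p0 + p1 + p2` must equal 1.", class = "foci_config_error")
  }
  structure(list(p0 = p0, p1 = p1, p2 = p2), class = "ion_delivery")
}

#' Population model for nucleus cross-section geometry
#'
#' Cell-nucleus cross-sections are modelled as ellipses whose long and short
#' half-axes (a, b) follow a bivariate normal distribution specified in its
#' principal-component frame: independent normal deviations with standard
#' deviations `sd_pc` along axes rotated by `pc_angle` from the (a, b) axes,
#' added to the means.  Samples are truncated to a >= b > `min_short` (and
#' a <= `max_long` if finite).  The ellipse orientation is uniform on
#' [0, pi), independent of size.
#'
#' @param mean_long,mean_short Mean long and short half-axes (micrometres).
#' @param sd_pc Length-2 vector of principal-component standard deviations
#'   (micrometres).
#' @param pc_angle Rotation of the principal axes relative to the (a, b)
#'   coordinate axes (radians).  A positive angle induces positive
#'   correlation between the two half-axes.
#' @param min_short Lower truncation bound for the short half-axis
#'   (micrometres).
#' @param max_long Upper truncation bound for the long half-axis.
#' @return A `nucleus_population` object.
#' @export
nucleus_population <- function(mean_long = 8, mean_short = 5,
                               sd_pc = c(2, 1), pc_angle = pi / 4,
                               min_short = 0.5, max_long = Inf) {
  if (!is.numeric(sd_pc) || length(sd_pc) != 2L || any(sd_pc < 0)) {
    abort("`sd_pc` must be two non-negative standard deviations.",
          class = "foci_config_error")
  }
  if (!is.numeric(mean_long) || !is.numeric(mean_short) ||
      mean_long <= 0 || mean_short <= 0) {
    abort("half-axis means must be positive.", class = "foci_config_error")
  }
  if (mean_long < mean_short) {
    abort("`mean_long` must be >= `mean_short`.", class = "foci_config_error")
  }
  if (mean_short <= min_short || mean_long > max_long) {
    abort("truncation bounds exclude the configured half-axis means.",
          class = "foci_config_error")
  }
  structure(
    list(mean_long = mean_long, mean_short = mean_short, sd_pc = sd_pc,
         pc_angle = pc_angle, min_short = min_short, max_long = max_long),
    class = "nucleus_population"
  )
}

#' Sample nucleus cross-section geometries
#'
#' Draws `n` elliptical nucleus cross-sections from a population model by
#' rejection sampling of the truncated bivariate normal.  The targeting
#' pattern centroid is taken to coincide with the nucleus centre (the beam
#' targets recognised nuclei), so positions are not sampled; only half-axes
#' and orientation are.
#'
#' @param n Number of nuclei.
#' @param pop A [nucleus_population()] model.
#' @return A tibble with columns `a` (long half-axis), `b` (short half-axis),
#'   `phi` (orientation, radians in [0, pi)).
#' @export
sample_nuclei <- function(n, pop = nucleus_population()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a positive count.", class = "foci_config_error")
  }
  n <- as.integer(n)
  ca <- cos(pop$pc_angle)
  sa <- sin(pop$pc_angle)
  a_out <- numeric(0)
  b_out <- numeric(0)
  for (round in seq_len(100L)) {
    m <- max(2L * (n - length(a_out)), 16L)
    z1 <- rnorm(m, 0, pop$sd_pc[1])
    z2 <- rnorm(m, 0, pop$sd_pc[2])
    a <- pop$mean_long + ca * z1 - sa * z2
    b <- pop$mean_short + sa * z1 + ca * z2
    keep <- a >= b & b > pop$min_short & a <= pop$max_long
    a_out <- c(a_out, a[keep])
    b_out <- c(b_out, b[keep])
    if (length(a_out) >= n) break
  }
  if (length(a_out) < n) {
    abort("rejection sampling failed: the truncation region has negligible mass under the configured model.",
          class = "foci_config_error")
  }
  tibble::tibble(
    a = a_out[seq_len(n)],
    b = b_out[seq_len(n)],
    phi = runif(n, 0, pi)
  )
}

# Fast internal sampler used in tight loops: returns list(x, y) without
# tibble overhead.
.sample_ion_xy <- function(px, py, sigma, probs) {
  m <- sample.int(3L, length(px), replace = TRUE, prob = probs) - 1L
  k <- sum(m)
  if (k == 0L) {
    return(list(x = numeric(0), y = numeric(0)))
  }
  list(
    x = rep.int(px, m) + rnorm(k, 0, sigma),
    y = rep.int(py, m) + rnorm(k, 0, sigma)
  )
}

#' Sample realised ion traversal positions for one nucleus
#'
#' For each target point, the number of delivered ions (0, 1 or 2) is drawn
#' from the delivery model; each delivered ion lands at the target plus
#' independent isotropic Gaussian scatter with the beam's sigma.
#'
#' @param pattern A [target_pattern()] tibble.
#' @param beam A [beam_profile()].
#' @param delivery An [ion_delivery()] model.
#' @return A tibble of traversal points with columns `x`, `y` (micrometres);
#'   0 to 2 rows per target point.
#' @export
sample_ion_positions <- function(pattern = target_pattern(),
                                 beam = beam_profile(),
                                 delivery = ion_delivery()) {
  stopifnot(inherits(beam, "beam_profile"), inherits(delivery, "ion_delivery"))
  xy <- .sample_ion_xy(pattern$x, pattern$y, beam$sigma,
                       c(delivery$p0, delivery$p1, delivery$p2))
  tibble::tibble(x = xy$x, y = xy$y)
}

#' Test points against an elliptical nucleus cross-section
#'
#' @param x,y Point coordinates (micrometres), nucleus centre at the origin.
#' @param a,b Long and short half-axes.
#' @param phi Orientation of the long axis (radians).
#' @return Logical vector: point inside (or on) the ellipse.
#' @export
points_in_ellipse <- function(x, y, a, b, phi) {
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Cluster ion tracks by proximity
#'
#' Two traversals whose planar distance is at most `proximity_radius` are
#' considered to produce unresolvable foci.  Clusters are the connected
#' components of this proximity graph, computed by single-linkage
#' agglomeration; the returned sizes partition the input points.
#'
#' @param points A data frame of traversal points with columns `x`, `y`.
#' @param proximity_radius Linkage distance (micrometres).  The default
#'   2 is of the order of a focus diameter, i.e. of optical resolvability
#'   at the magnification used for focus scoring.
#' @return Integer vector of cluster sizes (empty for empty input).
#' @export
cluster_tracks <- function(points, proximity_radius = 2) {
  if (!is.numeric(proximity_radius) || length(proximity_radius) != 1L ||
      is.na(proximity_radius) || proximity_radius <= 0) {
    abort("`proximity_radius` must be a single positive distance.",
          class = "foci_config_error")
  }
  n <- length(points$x)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  d <- dist(cbind(points$x, points$y))
  if (all(d > proximity_radius)) return(rep.int(1L, n))
  grp <- cutree(hclust(d, method = "single"), h = proximity_radius)
  tabulate(grp)
}

#' Estimate the track-cluster spectrum for one radiation quality
#'
#' Simulates `n_nuclei` irradiations: sample a nucleus geometry, sample the
#' realised traversal points, keep those inside the ellipse, cluster them by
#' proximity, and tally cluster sizes.  `k_bar[n]` is the mean number of
#' clusters of `n` tracks per nucleus; these are the fixed weights of the
#' kinetics model.
#'
#' @param quality Radiation-quality label carried into the output.
#' @param n_nuclei Number of simulated nuclei.
#' @param pop,pattern,beam,delivery Geometry configuration; see
#'   [nucleus_population()], [target_pattern()], [beam_profile()],
#'   [ion_delivery()].
#' @param proximity_radius Linkage distance for [cluster_tracks()].
#' @param seed Optional integer seed; recorded in the output.
#' @return A tibble with columns `quality`, `n`, `k_bar`, `n_nuclei`,
#'   `seed`, covering n = 1 up to the largest observed cluster.  The mean
#'   number of in-nucleus tracks, tallied independently of the clustering,
#'   is attached as attribute `"mean_tracks"`.
#' @export
estimate_cluster_spectrum <- function(quality, n_nuclei = 1000,
                                      pop = nucleus_population(),
                                      pattern = target_pattern(),
                                      beam = beam_profile(),
                                      delivery = ion_delivery(),
                                      proximity_radius = 2,
                                      seed = NULL) {
  if (!is.numeric(n_nuclei) || n_nuclei < 1) {
    abort("`n_nuclei` must be >= 1.", class = "foci_config_error")
  }
  n_nuclei <- as.integer(n_nuclei)
  if (!is.null(seed)) set.seed(seed)
  nuc <- sample_nuclei(n_nuclei, pop)
  probs <- c(delivery$p0, delivery$p1, delivery$p2)
  counts <- numeric(2L * nrow(pattern))  # at most 2 ions per target
  total_tracks <- 0L
  for (i in seq_len(n_nuclei)) {
    xy <- .sample_ion_xy(pattern$x, pattern$y, beam$sigma, probs)
    if (length(xy$x) == 0L) next
    keep <- points_in_ellipse(xy$x, xy$y, nuc$a[i], nuc$b[i], nuc$phi[i])
    m <- sum(keep)
    if (m == 0L) next
    total_tracks <- total_tracks + m
    sz <- cluster_tracks(list(x = xy$x[keep], y = xy$y[keep]),
                         proximity_radius)
    counts <- counts + tabulate(sz, nbins = length(counts))
  }
  n_max <- max(1L, which(counts > 0), na.rm = TRUE)
  out <- tibble::tibble(
    quality = quality,
    n = seq_len(n_max),
    k_bar = counts[seq_len(n_max)] / n_nuclei,
    n_nuclei = n_nuclei,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  attr(out, "mean_tracks") <- total_tracks / n_nuclei
  out
}

#' Independent spectrum batches for robustness propagation
#'
#' Repeats [estimate_cluster_spectrum()] `n_batches` times with independent
#' sub-seeds so that the sampling spread of the cluster spectrum can be
#' propagated into the fitted kinetics parameters.
#'
#' @inheritParams estimate_cluster_spectrum
#' @param n_batches Number of independent batches.
#' @param n_nuclei Nuclei simulated per batch.
#' @param seed Seed for the batch sub-seed stream.
#' @return A tibble like [estimate_cluster_spectrum()]'s output with a
#'   leading `batch` column.
#' @seealso [spectrum_cv()] for the per-size coefficient of variation.
#' @export
batch_spectra <- function(quality, n_batches, n_nuclei = 1000,
                          pop = nucleus_population(),
                          pattern = target_pattern(),
                          beam = beam_profile(),
                          delivery = ion_delivery(),
                          proximity_radius = 2,
                          seed = NULL) {
  if (!is.numeric(n_batches) || n_batches < 1) {
    abort("`n_batches` must be >= 1.", class = "foci_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  batch_seeds <- sample.int(.Machine$integer.max, n_batches)
  purrr::map_dfr(seq_len(as.integer(n_batches)), function(b) {
    sp <- estimate_cluster_spectrum(
      quality, n_nuclei,
      pop = pop, pattern = pattern, beam = beam, delivery = delivery,
      proximity_radius = proximity_radius, seed = batch_seeds[b]
    )
    dplyr::mutate(sp, batch = b, .before = 1)
  })
}

#' Per-size spread of the cluster spectrum across batches
#'
#' @param batches Output of [batch_spectra()].
#' @return A tibble with columns `quality`, `n`, `mean_k`, `sd_k`, `cv`
#'   (sd/mean; `NA` where the mean is zero).  Batches in which a given size
#'   was not observed contribute k_bar = 0.
#' @export
spectrum_cv <- function(batches) {
  batches |>
    dplyr::select("batch", "quality", "n", "k_bar") |>
    dplyr::group_by(.data$quality) |>
    tidyr::complete(batch = unique(.data$batch), n = seq_len(max(.data$n)),
                    fill = list(k_bar = 0)) |>
    dplyr::group_by(.data$quality, .data$n) |>
    dplyr::summarise(
      mean_k = mean(.data$k_bar),
      sd_k = sd(.data$k_bar),
      cv = ifelse(mean(.data$k_bar) > 0, sd(.data$k_bar) / mean(.data$k_bar), NA_real_),
      .groups = "drop"
    )
}
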