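test_that("targeting pattern has five points with the stated square geometry", {
  p <- target_pattern(4)
  expect_equal(nrow(p), 5L)
  corners <- p[1:4, ]
  d <- as.matrix(dist(cbind(corners$x, corners$y)))
  expect_equal(sort(unique(round(d[upper.tri(d)], 10))),
               c(4, 4 * sqrt(2)))
  expect_equal(c(mean(p$x[1:4]), mean(p$y[1:4])), c(p$x[5], p$y[5]))
  expect_error(target_pattern(-1), class = "foci_config_error")
})

test_that("beam sigma follows the FWHM relation and invalid configs error", {
  b <- beam_profile(4)
  expect_equal(b$sigma, 4 / (2 * sqrt(2 * log(2))))
  expect_error(beam_profile(0), class = "foci_config_error")
  expect_error(ion_delivery(0.5, 0.4, 0.2), class = "foci_config_error")
  expect_error(ion_delivery(-0.1, 1.0, 0.1), class = "foci_config_error")
})

test_that("degenerate population model yields circles; bad truncation errors", {
  pop <- nucleus_population(mean_long = 6, mean_short = 6, sd_pc = c(0, 0))
  nuc <- sample_nuclei(50, pop)
  expect_true(all(nuc$a == 6) && all(nuc$b == 6))
  expect_true(all(nuc$phi >= 0 & nuc$phi < pi))
  expect_error(nucleus_population(mean_short = 0.4, min_short = 0.5),
               class = "foci_config_error")
  expect_error(nucleus_population(mean_long = 4, mean_short = 5),
               class = "foci_config_error")
})

test_that("sampled half-axis means match the configured means (LLN)", {
  # narrow spread so truncation to a >= b > min_short has negligible mass
  pop <- nucleus_population(mean_long = 8, mean_short = 5, sd_pc = c(0.5, 0.3))
  set.seed(41)
  nuc <- sample_nuclei(1e5, pop)
  # PC rotation by pi/4 mixes the two PC sds into each half-axis
  sd_a <- sqrt((0.5^2 + 0.3^2) / 2)
  expect_lt(abs(mean(nuc$a) - 8), 3 * sd_a / sqrt(1e5))
  expect_lt(abs(mean(nuc$b) - 5), 3 * sd_a / sqrt(1e5))
  expect_true(all(nuc$a >= nuc$b), all(nuc$b > 0.5))
})

test_that("ion positions reduce to the targets for a pencil beam and certain delivery", {
  set.seed(1)
  pts <- sample_ion_positions(target_pattern(), beam_profile(1e-12),
                              ion_delivery(0, 1, 0))
  expect_equal(nrow(pts), 5L)
  expect_equal(pts$x, target_pattern()$x, tolerance = 1e-9)
  expect_equal(pts$y, target_pattern()$y, tolerance = 1e-9)
})

test_that("delivered ion count matches the exact trinomial moments", {
  # exact enumeration over multiplicities {0, 1, 2} per target
  p <- c(0.05, 0.90, 0.05)
  mean_per_target <- sum(c(0, 1, 2) * p)
  var_per_target <- sum(c(0, 1, 4) * p) - mean_per_target^2
  expect_equal(mean_per_target, 1.0)
  expect_equal(var_per_target, 0.1)
  set.seed(7)
  counts <- replicate(2e4, nrow(sample_ion_positions(
    delivery = ion_delivery(0.05, 0.90, 0.05))))
  expect_lt(abs(mean(counts) - 5 * mean_per_target),
            3 * sqrt(5 * var_per_target / 2e4))
  expect_lt(abs(var(counts) - 5 * var_per_target), 0.05)
})

test_that("single-linkage clustering matches chain and limit cases", {
  pts <- tibble::tibble(x = c(0, 1, 2), y = c(0, 0, 0))
  expect_equal(cluster_tracks(pts, proximity_radius = 1), 3L)
  expect_equal(sort(cluster_tracks(pts, proximity_radius = 1e-9)),
               c(1L, 1L, 1L))
  expect_equal(cluster_tracks(pts[0, ], 1), integer(0))
  expect_error(cluster_tracks(pts, 0), class = "foci_config_error")
})

test_that("single-linkage clustering equals the brute-force graph oracle", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    x <- runif(n, 0, 8); y <- runif(n, 0, 8)
    r <- runif(1, 0.5, 4)
    got <- sort(cluster_tracks(tibble::tibble(x = x, y = y), r))
    want <- sort(brute_force_cluster_sizes(x, y, r))
    expect_identical(got, as.integer(want))
  }
})

test_that("cluster count is monotone non-increasing in the proximity radius", {
  set.seed(99)
  for (i in 1:20) {
    pts <- tibble::tibble(x = runif(8, 0, 10), y = runif(8, 0, 10))
    radii <- sort(runif(5, 0.2, 6))
    n_clusters <- vapply(radii, function(r) length(cluster_tracks(pts, r)),
                         integer(1))
    expect_true(all(diff(n_clusters) <= 0))
    # total tracks conserved whatever the radius
    expect_true(all(vapply(radii, function(r) sum(cluster_tracks(pts, r)),
                           integer(1)) == 8L))
  }
})

test_that("spectrum limits: all-covering nucleus gives k(1)=5 or k(5)=1", {
  huge <- nucleus_population(mean_long = 1e4, mean_short = 1e4, sd_pc = c(0, 0))
  certain <- ion_delivery(0, 1, 0)
  sp1 <- estimate_cluster_spectrum("q", 200, pop = huge, delivery = certain,
                                   proximity_radius = 1e-9, seed = 5)
  expect_equal(sp1$k_bar[sp1$n == 1], 5)
  expect_equal(sum(sp1$n * sp1$k_bar), 5)
  sp5 <- estimate_cluster_spectrum("q", 200, pop = huge, delivery = certain,
                                   proximity_radius = 1e6, seed = 5)
  expect_equal(sp5$k_bar[sp5$n == 5], 1)
  expect_equal(sum(sp5$k_bar[sp5$n != 5]), 0)
})

test_that("spectrum conserves tracks against the independent tally", {
  sp <- estimate_cluster_spectrum("q", 500, seed = 21)
  expect_equal(sum(sp$n * sp$k_bar), attr(sp, "mean_tracks"))
  expect_true(all(sp$k_bar >= 0))
  # fixed seed -> bitwise reproducible
  sp2 <- estimate_cluster_spectrum("q", 500, seed = 21)
  expect_identical(sp$k_bar, sp2$k_bar)
})

test_that("track mean is invariant to the proximity radius at fixed seed", {
  m <- vapply(c(0.5, 2, 5), function(r) {
    sp <- estimate_cluster_spectrum("q", 300, proximity_radius = r, seed = 77)
    sum(sp$n * sp$k_bar)
  }, numeric(1))
  expect_equal(m[1], m[2])
  expect_equal(m[2], m[3])
})

test_that("batch spectra are reproducible and reduce to single estimates", {
  b <- batch_spectra("q", n_batches = 3, n_nuclei = 100, seed = 9)
  b2 <- batch_spectra("q", n_batches = 3, n_nuclei = 100, seed = 9)
  expect_identical(b, b2)
  expect_equal(sort(unique(b$batch)), 1:3)
  cv <- spectrum_cv(b)
  expect_true(all(cv$mean_k >= 0))
  # n_batches = 1 is just one spectrum
  b1 <- batch_spectra("q", n_batches = 1, n_nuclei = 100, seed = 3)
  expect_equal(unique(b1$batch), 1L)
})
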