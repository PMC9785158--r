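# Independent oracles and small fixtures, built in code.

# Brute-force connected components of the proximity graph: breadth-first
# search over the full O(n^2) distance matrix.  Independent of the
# single-linkage implementation under test.
brute_force_cluster_sizes <- function(x, y, r) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  dmat <- as.matrix(stats::dist(cbind(x, y)))
  adj <- dmat <= r
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  as.integer(table(comp))
}

# Scalar re-implementation of the model equations, written independently of
# the vectorised package code (plain loops, no shared helpers).
ref_sham_mean <- function(t, n_b, n_s, beta0, t_M = 0.5) {
  n_b + n_s * exp(-beta0 * (t - t_M))
}

ref_total_mean <- function(t, n_vec, k_vec, n_b, n_s, beta0, beta1, beta2,
                           n_Q, p_Q, t_M = 0.5) {
  acc <- ref_sham_mean(t, n_b, n_s, beta0, t_M)
  for (i in seq_along(n_vec)) {
    s <- (1 - p_Q) * exp(-beta1 * (t - t_M)) + p_Q * exp(-beta2 * (t - t_M))
    acc <- acc + k_vec[i] * (1 - exp(-n_vec[i] * n_Q * s))
  }
  acc
}

# Small fixed cluster spectra (plausible shape for the 5-ion pattern).
make_test_spectra <- function(qualities = c("qa", "qb")) {
  dplyr::bind_rows(lapply(qualities, function(q) {
    tibble::tibble(quality = q, n = 1:3, k_bar = c(4.0, 0.4, 0.05),
                   n_nuclei = NA_integer_, seed = NA_integer_)
  }))
}

make_test_params <- function(qualities = c("qa", "qb")) {
  kinetics_params(
    n_b = 0.24, n_s = 0.26, beta0 = 0.3, beta1 = 0.27, beta2 = 0.01,
    qualities = tibble::tibble(
      quality = qualities,
      n_Q = seq(0.4, 1.2, length.out = length(qualities)),
      p_Q = seq(0.15, 0.10, length.out = length(qualities))
    )
  )
}

# Noise-free tables evaluated from the closed-form model (exact generative
# inverse for recovery tests); sd is an arbitrary positive weight.
make_noise_free_data <- function(params, spectra,
                                 times = c(0.5, 2, 4, 8, 24), sd = 0.05) {
  qs <- params$qualities$quality
  irr <- dplyr::bind_rows(lapply(qs, function(q) {
    sp <- spectra[spectra$quality == q, ]
    tibble::tibble(quality = q, t_h = times,
                   mean = total_mean(times, sp, params), sd = sd, n_rep = 3L)
  }))
  sham <- tibble::tibble(quality = "sham", t_h = times,
                         mean = sham_mean(times, params), sd = sd, n_rep = 3L)
  dplyr::bind_rows(irr, sham)
}
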