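# Shared fixtures: random states and closed-form reference values.

# Random Hermitian unit-trace PSD matrix (complex unless real = TRUE).
random_density <- function(seed, rank = 64, real = FALSE) {
  set.seed(seed)
  A <- matrix(rnorm(64 * rank), 64, rank)
  if (!real) A <- A + 1i * matrix(rnorm(64 * rank), 64, rank)
  rho <- A %*% Conj(t(A))
  rho / Re(sum(diag(rho)))
}

# Random pure state density matrix.
random_pure_density <- function(seed, real = FALSE) {
  set.seed(seed)
  psi <- rnorm(64)
  if (!real) psi <- psi + 1i * rnorm(64)
  psi <- psi / sqrt(sum(Mod(psi)^2))
  rho <- psi %o% Conj(psi)
  if (real) Re(rho) else rho
}

# Closed-form Holevo information at p = 0 for amino-acid granularity:
# log2(61) minus the degeneracy-weighted subspace entropies.
chi_amino_p0 <- function() {
  n <- degeneracy_table()$degeneracy
  log2(61) - sum(n * log2(n)) / 61
}

# Independent brute-force mutual information: explicit double loop over all
# input/output pairs (the package implementation is vectorised).
mi_brute_force <- function(conditional, prior) {
  prior <- unname(prior)
  ny <- ncol(conditional)
  py <- numeric(ny)
  for (i in seq_along(prior)) {
    for (j in seq_len(ny)) {
      py[j] <- py[j] + prior[i] * conditional[i, j]
    }
  }
  h_y <- 0
  for (j in seq_len(ny)) {
    if (py[j] > 0) h_y <- h_y - py[j] * log2(py[j])
  }
  h_yx <- 0
  for (i in seq_along(prior)) {
    for (j in seq_len(ny)) {
      v <- conditional[i, j]
      if (prior[i] > 0 && v > 0) h_yx <- h_yx - prior[i] * v * log2(v)
    }
  }
  h_y - h_yx
}

# Explicit operator-sum application, summing E rho E^dagger over the
# materialised Kraus operators (dense), independent of the fast paths.
apply_channel_explicit <- function(ks, rho) {
  ops <- kraus_matrices(ks)
  out <- matrix(0 + 0i, 64, 64)
  for (E in ops) {
    E <- as.matrix(E)
    out <- out + E %*% rho %*% Conj(t(E))
  }
  out
}

kernel_grid <- function() {
  list(
    list(mode = "uniform", kappa = NULL),
    list(mode = "transition_only", kappa = NULL),
    list(mode = "kimura", kappa = 0.8)
  )
}
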