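# Operator-sum (Kraus) realisations of the codon channel, input ensembles,
# von Neumann entropy, entropy exchange and Holevo information.
#
# The state space is the 64-dimensional Hilbert space spanned by one basis
# vector per codon. Two Kraus constructions realise the same codon transition
# matrix P:
#
#   * dephasing: one rank-one operator E_{m,n} = sqrt(p_{m,n}) |n><m| per
#     codon pair, 64^2 = 4096 operators in all. Its output is always diagonal
#     in the codon basis, so any coherence between codons is destroyed and
#     the channel is classically equivalent to P.
#   * coherent (random-unitary): one permutation operator per triple of
#     base-permutations from the kernel decomposition, weighted by the
#     product of the per-position weights. It induces the same transition
#     probabilities between basis states but preserves superpositions with
#     probability mass (1-p)^3 on the identity, which is what separates the
#     mixed-state and superposition input scenarios.

#' Dephasing Kraus construction
#'
#' One operator `E[m,n] = sqrt(P[m,n]) |n><m|` per ordered codon pair; with
#' 64 codons this is 4096 operators. Operators are held implicitly through
#' `P` (each has a single nonzero entry); use [kraus_matrices()] to
#' materialise them.
#'
#' @param P 64x64 row-stochastic codon transition matrix.
#' @return Object of class `kraus_set`.
#' @export
build_kraus_dephasing <- function(P) {
  P <- validate_transition_matrix(P)
  structure(list(construction = "dephasing", P = P,
                 n_ops = nrow(P) * ncol(P)),
            class = "kraus_set")
}

#' Coherent (random-unitary) Kraus construction
#'
#' Builds one operator per triple of base permutations, the triple
#' `(Pi_a, Pi_b, Pi_c)` acting on codon positions 1..3 with weight
#' `sqrt(w_a w_b w_c)`. The induced basis-state transition probabilities
#' reproduce the product-form codon matrix exactly, while superpositions are
#' transported coherently.
#'
#' @param dec1,dec2,dec3 Per-position [decompose_kernel()] results; by
#'   default the same decomposition is used at every codon position.
#' @return Object of class `kraus_set` with fields `weights` (summing to 1),
#'   `perms` (1-based permutations of the 64 codon indices) and the induced
#'   transition matrix `P`.
#' @export
build_kraus_coherent <- function(dec1, dec2 = dec1, dec3 = dec1) {
  for (d in list(dec1, dec2, dec3)) {
    stopifnot(inherits(d, "perm_decomposition"))
    if (abs(sum(d$weights) - 1) > 1e-12) {
      stop("decomposition weights must sum to 1", call. = FALSE)
    }
  }
  i <- 0:63
  b1 <- i %/% 16L + 1L
  b2 <- (i %/% 4L) %% 4L + 1L
  b3 <- i %% 4L + 1L
  weights <- numeric(0)
  perms <- list()
  for (a in seq_along(dec1$weights)) {
    for (b in seq_along(dec2$weights)) {
      for (cc in seq_along(dec3$weights)) {
        w <- dec1$weights[a] * dec2$weights[b] * dec3$weights[cc]
        if (w <= 0) next
        pi1 <- dec1$perms[[a]]; pi2 <- dec2$perms[[b]]; pi3 <- dec3$perms[[cc]]
        # image of codon index m under per-position base permutations
        perm <- 16L * (pi1[b1] - 1L) + 4L * (pi2[b2] - 1L) + (pi3[b3] - 1L) + 1L
        weights <- c(weights, w)
        perms <- c(perms, list(perm))
      }
    }
  }
  P <- matrix(0, 64, 64, dimnames = list(codons(), codons()))
  for (k in seq_along(weights)) {
    P[cbind(1:64, perms[[k]])] <- P[cbind(1:64, perms[[k]])] + weights[k]
  }
  structure(list(construction = "coherent", P = P, weights = weights,
                 perms = perms, n_ops = length(weights)),
            class = "kraus_set")
}

#' @export
print.kraus_set <- function(x, ...) {
  cat(sprintf("<kraus_set> construction=%s operators=%d\n",
              x$construction, x$n_ops))
  invisible(x)
}

validate_transition_matrix <- function(P, tol = 1e-10) {
  P <- as.matrix(P)
  if (nrow(P) != 64L || ncol(P) != 64L) {
    stop("expected a 64x64 codon transition matrix", call. = FALSE)
  }
  if (any(P < -tol) || max(abs(rowSums(P) - 1)) > tol) {
    stop("transition matrix must be row-stochastic", call. = FALSE)
  }
  if (is.null(dimnames(P))) dimnames(P) <- list(codons(), codons())
  P
}

#' Materialise the Kraus operators of a channel
#'
#' @param ks A `kraus_set`.
#' @return List of 64x64 operators: sparse `Matrix` objects for the
#'   dephasing construction (each has one nonzero entry), dense matrices for
#'   the coherent construction.
#' @export
kraus_matrices <- function(ks) {
  stopifnot(inherits(ks, "kraus_set"))
  if (ks$construction == "dephasing") {
    P <- unclass(ks$P)
    ops <- vector("list", 64L * 64L)
    k <- 0L
    for (m in 1:64) {
      for (n in 1:64) {
        k <- k + 1L
        ops[[k]] <- Matrix::sparseMatrix(i = n, j = m, x = sqrt(P[m, n]),
                                         dims = c(64L, 64L))
      }
    }
    ops
  } else {
    lapply(seq_along(ks$weights), function(k) {
      E <- matrix(0, 64, 64)
      E[cbind(ks$perms[[k]], 1:64)] <- sqrt(ks$weights[k])
      E
    })
  }
}

#' Completeness sum of a Kraus set
#'
#' Computes `sum_i E_i^dagger E_i` by direct summation over the materialised
#' operators; a trace-preserving channel returns the identity.
#'
#' @param ks A `kraus_set`.
#' @return 64x64 matrix.
#' @export
kraus_completeness <- function(ks) {
  ops <- kraus_matrices(ks)
  acc <- matrix(0, 64, 64)
  for (E in ops) acc <- acc + as.matrix(Matrix::crossprod(E))
  acc
}

validate_density_matrix <- function(rho, tol = 1e-8) {
  if (!is.matrix(rho) || nrow(rho) != 64L || ncol(rho) != 64L) {
    stop("density matrix must be 64x64", call. = FALSE)
  }
  if (max(abs(rho - Conj(t(rho)))) > tol) {
    stop("density matrix must be Hermitian", call. = FALSE)
  }
  if (abs(sum(diag(rho)) - 1) > 1e-8) {
    stop("density matrix must have unit trace", call. = FALSE)
  }
  invisible(rho)
}

#' Apply a quantum channel to a density matrix
#'
#' `rho' = sum_i E_i rho E_i^dagger`, evaluated through the structure of the
#' construction: the dephasing output is the diagonal matrix with entries
#' `t(P) %*% diag(rho)`, and the coherent output is the weighted sum of
#' permutation-conjugated copies of `rho`.
#'
#' @param ks A `kraus_set`.
#' @param rho 64x64 Hermitian, unit-trace (possibly complex) matrix.
#' @return 64x64 density matrix.
#' @export
apply_channel <- function(ks, rho) {
  stopifnot(inherits(ks, "kraus_set"))
  validate_density_matrix(rho)
  if (ks$construction == "dephasing") {
    d <- as.vector(crossprod(unclass(ks$P), diag(rho)))
    out <- diag(Re(d))
    dimnames(out) <- dimnames(rho)
    out
  } else {
    out <- matrix(0 + 0i, 64, 64)
    for (k in seq_along(ks$weights)) {
      pi_k <- ks$perms[[k]]
      tmp <- matrix(0 + 0i, 64, 64)
      tmp[pi_k, pi_k] <- rho
      out <- out + ks$weights[k] * tmp
    }
    if (all(Im(out) == 0)) out <- Re(out)
    dimnames(out) <- dimnames(rho)
    out
  }
}

#' von Neumann entropy in bits
#'
#' `S(rho) = -sum lambda log2 lambda` over the eigenvalues of `rho`.
#' Eigenvalues below `zero_tol` (tiny negatives arise numerically for PSD
#' matrices) are treated as exact zeros with `0 log 0 = 0`.
#'
#' @param rho Hermitian PSD matrix with unit trace (any dimension).
#' @param zero_tol Eigenvalue floor, default `1e-12`.
#' @return Entropy in bits, in `[0, log2(dim)]`.
#' @export
#' @examples
#' von_neumann_entropy(diag(rep(1/64, 64)))  # 6 bits
von_neumann_entropy <- function(rho, zero_tol = 1e-12) {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) {
    stop("expected a square matrix", call. = FALSE)
  }
  if (max(abs(rho - Conj(t(rho)))) > 1e-8) {
    stop("entropy requires a Hermitian matrix", call. = FALSE)
  }
  off <- rho; diag(off) <- 0
  if (max(abs(off)) < 1e-14) {
    lam <- Re(diag(rho))  # already diagonal: spectrum is the diagonal
  } else {
    lam <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  }
  lam[lam < zero_tol] <- 0
  lam <- lam[lam > 0]
  -sum(lam * log2(lam))
}

#' Entropy-exchange matrix of a channel at a state
#'
#' Builds `W[i, j] = tr(E_i rho E_j^dagger)`, the Hermitian, PSD, unit-trace
#' matrix whose entropy is the entropy acquired by an initially pure
#' environment during the interaction. For the dephasing construction W is
#' 4096x4096 but block-diagonal over the output codon `n` (entries with
#' different output codons vanish), so it is stored and diagonalised
#' blockwise.
#'
#' @param ks A `kraus_set`.
#' @param rho 64x64 density matrix.
#' @return Object of class `exchange_matrix` with `eigenvalues`, the trace,
#'   and the dense `W` when the operator count is at most 64 (`NULL`
#'   otherwise, with the 64 blocks retained in `blocks`).
#' @export
exchange_matrix <- function(ks, rho) {
  stopifnot(inherits(ks, "kraus_set"))
  validate_density_matrix(rho)
  if (ks$construction == "dephasing") {
    P <- unclass(ks$P)
    blocks <- lapply(1:64, function(n) {
      d <- sqrt(P[, n])
      (d %o% d) * rho  # D_n rho D_n with D_n = diag(sqrt(P[, n]))
    })
    vals <- unlist(lapply(blocks, function(B) {
      eigen(B, symmetric = TRUE, only.values = TRUE)$values
    }))
    structure(list(construction = "dephasing", K = ks$n_ops, W = NULL,
                   blocks = blocks, eigenvalues = Re(vals),
                   trace = Re(sum(vapply(blocks, function(B) sum(diag(B)),
                                         complex(1))))),
              class = "exchange_matrix")
  } else {
    K <- length(ks$weights)
    inv <- lapply(ks$perms, order)  # inverse permutations
    W <- matrix(0 + 0i, K, K)
    for (i in 1:K) {
      for (j in 1:K) {
        # tr(E_i rho E_j^dagger) = sqrt(w_i w_j) sum_m rho[inv_i(m), inv_j(m)]
        W[i, j] <- sqrt(ks$weights[i] * ks$weights[j]) *
          sum(rho[cbind(inv[[i]], inv[[j]])])
      }
    }
    vals <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    structure(list(construction = "coherent", K = K, W = W, blocks = NULL,
                   eigenvalues = Re(vals), trace = Re(sum(diag(W)))),
              class = "exchange_matrix")
  }
}

#' Entropy exchange in bits
#'
#' Entropy of the [exchange_matrix()] spectrum; with an initially pure
#' environment this is the environment's entropy after the interaction, and
#' for a pure input state it coincides with the output entropy.
#'
#' @param x An `exchange_matrix` (or a `kraus_set`, with `rho` supplied).
#' @param rho Density matrix, when `x` is a `kraus_set`.
#' @return Bits.
#' @export
entropy_exchange <- function(x, rho = NULL) {
  if (inherits(x, "kraus_set")) x <- exchange_matrix(x, rho)
  stopifnot(inherits(x, "exchange_matrix"))
  lam <- x$eigenvalues
  lam[lam < 1e-12] <- 0
  lam <- lam[lam > 0]
  -sum(lam * log2(lam))
}

#' Input ensembles for the three transmission scenarios
#'
#' Builds the weighted state ensemble fed to the channel. At `amino_acid`
#' granularity there is one member per amino acid, weighted by its
#' degeneracy over 61 (so the underlying codon prior is the uniform 1/61
#' sense-codon prior); at `codon` granularity the ensemble is the 61 sense
#' basis states with weight 1/61 each and the scenario is irrelevant.
#'
#' Scenarios at amino-acid granularity:
#' \describe{
#'   \item{mixed}{the completely mixed state on the synonym subspace,
#'     `rho = (1/n) sum |m><m|`.}
#'   \item{superposition}{the equal-amplitude pure state
#'     `(1/sqrt(n)) sum |m>`; amplitudes are taken equal and real in the
#'     absence of measured values.}
#'   \item{random_eigenket}{one pure state drawn uniformly (seeded) from the
#'     discrete-Fourier orthonormal basis of the synonym subspace,
#'     `v_k[j] = exp(2 pi i j k / n) / sqrt(n)`; for two-fold degeneracy this
#'     basis is exactly `(|m1> + |m2>)/sqrt(2)`, `(|m1> - |m2>)/sqrt(2)`.}
#' }
#'
#' @param scenario `"mixed"`, `"superposition"` or `"random_eigenket"`.
#' @param granularity `"amino_acid"` (default) or `"codon"`.
#' @param seed Integer seed, required for `random_eigenket`.
#' @return Object of class `input_ensemble`: list with `weights`, `states`
#'   (64x64 density matrices), `labels`, and the call parameters.
#' @export
make_ensemble <- function(scenario = c("mixed", "superposition", "random_eigenket"),
                          granularity = c("amino_acid", "codon"),
                          seed = NULL) {
  scenario <- match.arg(scenario)
  granularity <- match.arg(granularity)
  if (granularity == "codon") {
    idx <- codon_index(sense_codons()) + 1L
    states <- lapply(idx, function(i) {
      rho <- matrix(0, 64, 64)
      rho[i, i] <- 1
      rho
    })
    return(structure(list(weights = rep(1 / 61, 61), states = states,
                          labels = sense_codons(), scenario = scenario,
                          granularity = granularity, seed = seed),
                     class = "input_ensemble"))
  }
  if (scenario == "random_eigenket" && is.null(seed)) {
    stop("random_eigenket scenario requires a seed", call. = FALSE)
  }
  aas <- amino_acids()
  draws <- NULL
  if (scenario == "random_eigenket") {
    rng <- local_rng(seed)
    draws <- setNames(vapply(aas, function(a) {
      n <- length(synonym_class(a))
      sample.int(n, 1L)
    }, integer(1)), aas)
    restore_rng(rng)
  }
  states <- vector("list", length(aas))
  weights <- numeric(length(aas))
  for (k in seq_along(aas)) {
    syn <- synonym_class(aas[k])
    idx <- codon_index(syn) + 1L
    n <- length(idx)
    weights[k] <- n / 61
    if (scenario == "mixed") {
      rho <- matrix(0, 64, 64)
      rho[cbind(idx, idx)] <- 1 / n
    } else {
      if (scenario == "superposition") {
        amp <- rep(1 / sqrt(n), n)
      } else {
        j <- 0:(n - 1)
        kk <- draws[[aas[k]]] - 1L
        amp <- exp(2i * pi * j * kk / n) / sqrt(n)
      }
      psi <- rep(0 + 0i, 64)
      psi[idx] <- amp
      rho <- psi %o% Conj(psi)
      if (all(Im(rho) == 0)) rho <- Re(rho)
    }
    states[[k]] <- rho
  }
  structure(list(weights = weights, states = states, labels = aas,
                 scenario = scenario, granularity = granularity, seed = seed),
            class = "input_ensemble")
}

#' @export
print.input_ensemble <- function(x, ...) {
  cat(sprintf("<input_ensemble> scenario=%s granularity=%s members=%d\n",
              x$scenario, x$granularity, length(x$weights)))
  invisible(x)
}

#' Ensemble-average input state
#'
#' @param ensemble An `input_ensemble`.
#' @return 64x64 density matrix `sum_j p_j rho_j`.
#' @export
ensemble_average_state <- function(ensemble) {
  stopifnot(inherits(ensemble, "input_ensemble"))
  Reduce(`+`, Map(function(w, s) w * s, ensemble$weights, ensemble$states))
}

#' Holevo information of an ensemble through a channel
#'
#' `chi = S(sum_j p_j U(rho_j)) - sum_j p_j S(U(rho_j))`, in bits per codon.
#' At the fixed uniform sense-codon prior this is the HSW classical capacity
#' of the channel for the given signal ensemble (no maximisation over
#' ensembles is performed).
#'
#' @param ensemble An `input_ensemble`.
#' @param ks A `kraus_set`.
#' @return Bits per codon, in `[0, 6]`.
#' @export
holevo_information <- function(ensemble, ks) {
  stopifnot(inherits(ensemble, "input_ensemble"), inherits(ks, "kraus_set"))
  outs <- lapply(ensemble$states, function(rho) apply_channel(ks, rho))
  avg <- Reduce(`+`, Map(function(w, s) w * s, ensemble$weights, outs))
  s_avg <- von_neumann_entropy(avg)
  s_members <- vapply(outs, von_neumann_entropy, numeric(1))
  s_avg - sum(ensemble$weights * s_members)
}

#' Holevo capacity curve over a grid of base error probabilities
#'
#' For each p, builds the kernel, the requested Kraus construction and the
#' scenario ensemble, and records the Holevo information. The
#' `random_eigenket` scenario is replicated with independent seeded draws and
#' every draw is reported (one row per replicate).
#'
#' @param p_grid Numeric vector of single-base error probabilities.
#' @param construction `"coherent"` (default) or `"dephasing"`.
#' @param scenario Ensemble scenario, see [make_ensemble()].
#' @param granularity `"amino_acid"` or `"codon"`.
#' @param kernel_mode Kernel mode, see [build_base_kernel()].
#' @param kappa Kimura transition weight (kimura mode only).
#' @param seed Master seed for `random_eigenket` draws.
#' @param replicates Number of seeded draws for `random_eigenket`, default 32.
#' @return Data frame with columns `p`, `kernel_mode`, `construction`,
#'   `scenario`, `granularity`, `replicate`, `capacity_bits`, ordered by
#'   ascending `p` then replicate.
#' @export
quantum_capacity_curve <- function(p_grid,
                                   construction = c("coherent", "dephasing"),
                                   scenario = c("mixed", "superposition",
                                                "random_eigenket"),
                                   granularity = c("amino_acid", "codon"),
                                   kernel_mode = "uniform", kappa = NULL,
                                   seed = NULL, replicates = 32L) {
  construction <- match.arg(construction)
  scenario <- match.arg(scenario)
  granularity <- match.arg(granularity)
  if (length(p_grid) == 0L) stop("empty p grid", call. = FALSE)
  if (any(p_grid < 0 | p_grid > 1)) stop("p values must be in [0, 1]",
                                         call. = FALSE)
  p_grid <- sort(p_grid)
  random <- scenario == "random_eigenket" && granularity == "amino_acid"
  if (random && is.null(seed)) {
    stop("random_eigenket scenario requires a seed", call. = FALSE)
  }
  reps <- if (random) as.integer(replicates) else 1L
  member_seeds <- if (random) derive_seeds(seed, reps) else NA_integer_
  rows <- vector("list", length(p_grid) * reps)
  r <- 0L
  for (p in p_grid) {
    kern <- build_base_kernel(p, kernel_mode, kappa = kappa)
    ks <- if (construction == "dephasing") {
      build_kraus_dephasing(build_codon_matrix(kern))
    } else {
      build_kraus_coherent(decompose_kernel(kern))
    }
    for (rep_i in seq_len(reps)) {
      ens <- make_ensemble(scenario, granularity,
                           seed = if (random) member_seeds[rep_i] else NULL)
      r <- r + 1L
      rows[[r]] <- data.frame(
        p = p, kernel_mode = kernel_mode, construction = construction,
        scenario = scenario, granularity = granularity, replicate = rep_i,
        capacity_bits = holevo_information(ens, ks),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
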