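test_that("both Kraus constructions are complete and induce the transition matrix", {
  for (p in c(0, 1e-3, 0.1)) {
    for (kern_spec in kernel_grid()) {
      k <- build_base_kernel(p, kern_spec$mode, kappa = kern_spec$kappa)
      P <- build_codon_matrix(k)
      kd <- build_kraus_dephasing(P)
      kc <- build_kraus_coherent(decompose_kernel(k))
      expect_identical(kd$n_ops, 4096L)
      expect_lte(kc$n_ops, 64L)
      expect_lt(max(abs(kraus_completeness(kd) - diag(64))), 1e-12)
      expect_lt(max(abs(kraus_completeness(kc) - diag(64))), 1e-12)
      # both constructions act identically on basis states
      expect_lt(max(abs(kc$P - unclass(P))), 1e-12)
      for (m in c(1L, 15L, 64L)) {
        rho <- matrix(0, 64, 64); rho[m, m] <- 1
        expect_equal(Re(diag(apply_channel(kd, rho))), unname(P[m, ]),
                     tolerance = 1e-12)
        expect_equal(Re(diag(apply_channel(kc, rho))), unname(P[m, ]),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(build_kraus_dephasing(matrix(1, 64, 64)), "stochastic")
})

test_that("coherent operator counts reflect the kernel decomposition", {
  k <- build_base_kernel(0.01, "uniform")
  expect_identical(build_kraus_coherent(decompose_kernel(k))$n_ops, 64L)
  kt <- build_base_kernel(0.01, "transition_only")
  expect_identical(build_kraus_coherent(decompose_kernel(kt))$n_ops, 8L)
  k0 <- build_base_kernel(0, "uniform")
  kc0 <- build_kraus_coherent(decompose_kernel(k0))
  expect_identical(kc0$n_ops, 1L)
  rho <- random_density(11)
  expect_equal(apply_channel(kc0, rho), rho, ignore_attr = TRUE,
               tolerance = 1e-14)
})

test_that("fast channel application equals the explicit operator sum", {
  k <- build_base_kernel(0.05, "uniform")
  P <- build_codon_matrix(k)
  kc <- build_kraus_coherent(decompose_kernel(k))
  rho <- random_density(21)
  expect_lt(max(abs(apply_channel(kc, rho) - apply_channel_explicit(kc, rho))),
            1e-12)
  # dephasing: explicit sum over all 4096 operators, real symmetric state
  kd <- build_kraus_dephasing(P)
  rho_r <- random_density(22, real = TRUE)
  expect_lt(max(abs(apply_channel(kd, rho_r) -
                      apply_channel_explicit(kd, rho_r))), 1e-12)
})

test_that("channels preserve trace, Hermiticity and positivity", {
  k <- build_base_kernel(0.08, "kimura", kappa = 0.7)
  kc <- build_kraus_coherent(decompose_kernel(k))
  kd <- build_kraus_dephasing(build_codon_matrix(k))
  for (seed in 31:33) {
    rho <- random_density(seed)
    for (ks in list(kc, kd)) {
      out <- apply_channel(ks, rho)
      expect_equal(Re(sum(diag(out))), 1, tolerance = 1e-12)
      expect_lt(max(abs(out - Conj(t(out)))), 1e-12)
      ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
  # dephasing output is diagonal with entries t(P) %*% diag(rho)
  rho <- random_density(34)
  out <- apply_channel(kd, rho)
  off <- out; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-14)
  expect_equal(Re(diag(out)),
               as.vector(crossprod(unclass(kd$P), Re(diag(rho)))),
               tolerance = 1e-12)
  # the maximally mixed state is a fixed point (P is doubly stochastic)
  mix <- diag(rep(1 / 64, 64))
  expect_lt(max(abs(apply_channel(kc, mix) - mix)), 1e-14)
  expect_lt(max(abs(apply_channel(kd, mix) - mix)), 1e-14)
})

test_that("von Neumann entropy matches its closed forms", {
  pure <- matrix(0, 64, 64); pure[5, 5] <- 1
  expect_equal(von_neumann_entropy(pure), 0)
  expect_equal(von_neumann_entropy(diag(rep(1 / 64, 64))), 6,
               tolerance = 1e-12)
  ile <- matrix(0, 64, 64)
  idx <- codon_index(synonym_class("Ile")) + 1L
  ile[cbind(idx, idx)] <- 1 / 3
  expect_equal(von_neumann_entropy(ile), log2(3), tolerance = 1e-12)
  # basis-independent: entropy of a rotated pure state is still 0
  expect_equal(von_neumann_entropy(random_pure_density(41)), 0,
               tolerance = 1e-9)
  expect_error(von_neumann_entropy(matrix(1:16, 4, 4) * 1.0), "Hermitian")
})

test_that("entropy exchange is a unit-trace PSD spectrum matching purification", {
  k <- build_base_kernel(0.03, "uniform")
  kc <- build_kraus_coherent(decompose_kernel(k))
  kd <- build_kraus_dephasing(build_codon_matrix(k))
  # identity channel: W = [[1]], zero exchange
  kc0 <- build_kraus_coherent(decompose_kernel(build_base_kernel(0, "uniform")))
  W0 <- exchange_matrix(kc0, random_density(51))
  expect_equal(dim(W0$W), c(1L, 1L))
  expect_equal(Re(W0$W[1, 1]), 1, tolerance = 1e-12)
  expect_equal(entropy_exchange(W0), 0, tolerance = 1e-12)
  for (seed in 52:54) {
    rho <- random_pure_density(seed)
    for (ks in list(kc, kd)) {
      W <- exchange_matrix(ks, rho)
      expect_equal(W$trace, 1, tolerance = 1e-10)
      expect_gt(min(W$eigenvalues), -1e-9)
      # purification identity: pure input => S_exchange = S(output)
      expect_equal(entropy_exchange(W),
                   von_neumann_entropy(apply_channel(ks, rho)),
                   tolerance = 1e-9)
    }
    W <- exchange_matrix(kc, rho)
    expect_lt(max(abs(W$W - Conj(t(W$W)))), 1e-12)
  }
})

test_that("ensembles encode the three scenarios at both granularities", {
  ens_cod <- make_ensemble("mixed", "codon")
  expect_length(ens_cod$weights, 61L)
  expect_equal(sum(ens_cod$weights), 1, tolerance = 1e-12)
  for (sc in c("mixed", "superposition")) {
    ens <- make_ensemble(sc, "amino_acid")
    expect_length(ens$weights, 20L)
    expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
    expect_equal(ens$weights[ens$labels == "Ile"], 3 / 61)
    expect_equal(ens$weights[ens$labels == "Met"], 1 / 61)
    for (rho in ens$states) {
      expect_equal(Re(sum(diag(rho))), 1, tolerance = 1e-12)
      expect_lt(max(abs(rho - Conj(t(rho)))), 1e-12)
    }
    # distinct amino-acid members live on orthogonal subspaces
    for (i in 1:5) {
      for (j in (i + 1):6) {
        expect_lt(Mod(sum(ens$states[[i]] * t(ens$states[[j]]))), 1e-14)
      }
    }
  }
  # scenario (i): Ile is diag(1/3) on its synonym subspace
  ens_m <- make_ensemble("mixed", "amino_acid")
  rho_ile <- ens_m$states[[which(ens_m$labels == "Ile")]]
  idx <- codon_index(synonym_class("Ile")) + 1L
  expect_equal(unname(diag(rho_ile)[idx]), rep(1 / 3, 3))
  expect_equal(sum(abs(rho_ile)), 1, tolerance = 1e-12)  # no coherences
  # scenario (ii): Phe is the symmetric superposition (|UUU> + |UUC>)/sqrt(2)
  ens_s <- make_ensemble("superposition", "amino_acid")
  rho_phe <- ens_s$states[[which(ens_s$labels == "Phe")]]
  idx <- codon_index(c("UUC", "UUU")) + 1L
  expect_equal(Re(rho_phe[idx, idx]), matrix(1 / 2, 2, 2), tolerance = 1e-12)
  expect_equal(Re(sum(diag(rho_phe %*% rho_phe))), 1, tolerance = 1e-12)
})

test_that("random eigenkets are seeded draws from an orthonormal Fourier basis", {
  expect_error(make_ensemble("random_eigenket", "amino_acid"), "seed")
  e1 <- make_ensemble("random_eigenket", "amino_acid", seed = 9)
  e2 <- make_ensemble("random_eigenket", "amino_acid", seed = 9)
  e3 <- make_ensemble("random_eigenket", "amino_acid", seed = 10)
  for (i in seq_along(e1$states)) {
    expect_identical(e1$states[[i]], e2$states[[i]])
  }
  expect_false(all(vapply(seq_along(e1$states), function(i) {
    isTRUE(all.equal(e1$states[[i]], e3$states[[i]]))
  }, logical(1))))
  # every member is pure and supported on its own synonym subspace
  for (i in seq_along(e1$states)) {
    rho <- e1$states[[i]]
    expect_equal(Re(sum(diag(rho %*% Conj(t(rho))))), 1, tolerance = 1e-12)
    idx <- codon_index(synonym_class(e1$labels[i])) + 1L
    expect_equal(Re(sum(diag(rho)[idx])), 1, tolerance = 1e-12)
  }
  # two-fold degeneracy: the Fourier basis is (|m1> +/- |m2>)/sqrt(2)
  phe <- e1$states[[which(e1$labels == "Phe")]]
  idx <- codon_index(synonym_class("Phe")) + 1L
  expect_equal(abs(Re(phe[idx[1], idx[2]])), 1 / 2, tolerance = 1e-12)
})

test_that("Holevo information hits its noiseless closed forms", {
  k0 <- build_base_kernel(0, "uniform")
  kc0 <- build_kraus_coherent(decompose_kernel(k0))
  kd0 <- build_kraus_dephasing(build_codon_matrix(k0))
  expect_equal(holevo_information(make_ensemble("mixed", "codon"), kc0),
               log2(61), tolerance = 1e-12)
  for (sc in c("mixed", "superposition")) {
    expect_equal(holevo_information(make_ensemble(sc, "amino_acid"), kc0),
                 chi_amino_p0(), tolerance = 1e-12)
  }
  expect_equal(holevo_information(
    make_ensemble("random_eigenket", "amino_acid", seed = 3), kc0),
    chi_amino_p0(), tolerance = 1e-9)
  # dephasing construction cannot distinguish scenarios (i) and (ii)
  k <- build_base_kernel(0.02, "uniform")
  kd <- build_kraus_dephasing(build_codon_matrix(k))
  expect_equal(holevo_information(make_ensemble("mixed", "amino_acid"), kd),
               holevo_information(make_ensemble("superposition", "amino_acid"),
                                  kd),
               tolerance = 1e-12)
  # Holevo bound on its own ensemble: 0 <= chi <= S(average input)
  kc <- build_kraus_coherent(decompose_kernel(k))
  for (sc in c("mixed", "superposition")) {
    ens <- make_ensemble(sc, "amino_acid")
    chi <- holevo_information(ens, kc)
    expect_gte(chi, 0)
    expect_lte(chi, von_neumann_entropy(ensemble_average_state(ens)) + 1e-9)
  }
})

test_that("quantum capacity curves are bounded and degrade with noise", {
  grid <- c(0, 1e-3, 0.1)
  cur <- quantum_capacity_curve(grid, "coherent", "superposition")
  expect_identical(cur$p, grid)
  expect_true(all(cur$capacity_bits >= 0 & cur$capacity_bits <= 6))
  expect_equal(cur$capacity_bits[cur$p == 0], chi_amino_p0(),
               tolerance = 1e-9)
  expect_lt(cur$capacity_bits[cur$p == 0.1],
            cur$capacity_bits[cur$p == 1e-3])
  # random-eigenket replicates: one row per seeded draw, deterministic
  cur_r <- quantum_capacity_curve(c(1e-3), "coherent", "random_eigenket",
                                  seed = 5, replicates = 4L)
  expect_identical(nrow(cur_r), 4L)
  expect_identical(cur_r$replicate, 1:4)
  cur_r2 <- quantum_capacity_curve(c(1e-3), "coherent", "random_eigenket",
                                   seed = 5, replicates = 4L)
  expect_identical(cur_r$capacity_bits, cur_r2$capacity_bits)
  expect_error(quantum_capacity_curve(numeric(0), "coherent", "mixed"),
               "empty")
  expect_error(quantum_capacity_curve(c(0.1), "coherent", "random_eigenket"),
               "seed")
})
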