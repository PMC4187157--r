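# Single-base substitution kernels and their composition into the 64x64
# codon transition matrix.
#
# Three kernels are supported. "uniform" spreads the single-base error
# probability p evenly over the three alternative bases. "transition_only"
# puts all of p on the transition partner (A<->G, C<->U), the pattern forced
# by tautomeric mispairing: a rare proton-shifted base pairs with the wrong
# partner (A*.C, C*.A, G*.U, U*.G), and one replication round resolves each
# mispair into a purine<->purine or pyrimidine<->pyrimidine change. "kimura"
# interpolates, weighting the transition by kappa and each transversion by
# (1-kappa)/2. Codons are assumed to mutate with independent errors per base,
# so the codon matrix is the per-position product of kernel entries.

TRANSITION_PARTNER <- c(A = "G", C = "U", G = "A", U = "C")

#' Build a single-base substitution kernel
#'
#' @param p Single-base error probability in `[0, 1]`.
#' @param mode `"uniform"`, `"transition_only"` or `"kimura"`.
#' @param kappa Transition weight in `(0, 1]`, kimura mode only: the
#'   transition receives `kappa * p`, each transversion `(1 - kappa) * p / 2`.
#' @return Object of class `base_kernel` with fields `mode`, `p`, `kappa` and
#'   `Q`, a 4x4 row-stochastic matrix over base order A, C, G, U with diagonal
#'   `1 - p`.
#' @export
#' @examples
#' build_base_kernel(0.01, "uniform")$Q
#' build_base_kernel(1e-3, "transition_only")$Q["A", "G"]  # 1e-3
build_base_kernel <- function(p, mode = c("uniform", "transition_only", "kimura"),
                              kappa = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  }
  if (mode != "kimura" && !is.null(kappa)) {
    stop("kappa is only meaningful in kimura mode", call. = FALSE)
  }
  if (mode == "kimura") {
    if (is.null(kappa) || !is.numeric(kappa) || kappa <= 0 || kappa > 1) {
      stop("kimura mode requires kappa in (0, 1]", call. = FALSE)
    }
  }
  Q <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (b in RNA_BASES) {
    ts <- TRANSITION_PARTNER[[b]]
    tv <- setdiff(RNA_BASES, c(b, ts))
    Q[b, b] <- 1 - p
    if (mode == "uniform") {
      Q[b, c(ts, tv)] <- p / 3
    } else if (mode == "transition_only") {
      Q[b, ts] <- p
    } else {
      Q[b, ts] <- kappa * p
      Q[b, tv] <- (1 - kappa) * p / 2
    }
  }
  structure(list(mode = mode, p = p, kappa = kappa, Q = Q),
            class = "base_kernel")
}

#' @export
print.base_kernel <- function(x, ...) {
  cat(sprintf("<base_kernel> mode=%s p=%g%s\n", x$mode, x$p,
              if (is.null(x$kappa)) "" else sprintf(" kappa=%g", x$kappa)))
  print(x$Q)
  invisible(x)
}

#' Decompose a base kernel into weighted base permutations
#'
#' Writes the 4x4 kernel as a convex combination of permutation matrices:
#' the identity with weight `1 - p`, plus fixed-point-free permutations
#' carrying the error mass. The uniform kernel uses the three cyclic shifts
#' on the A,C,G,U index ring (their sum is exactly all-ones minus identity);
#' transition_only uses the transition swap A<->G, C<->U; kimura adds the two
#' transversion double-swaps. Zero-weight terms are dropped. This is the raw
#' material of the coherent (random-unitary) Kraus construction.
#'
#' @param kernel A `base_kernel`.
#' @return Object of class `perm_decomposition`: list with `weights` (numeric,
#'   summing to 1) and `perms` (list of permutations of `1:4`, each `perm[i]`
#'   the image of base `i`).
#' @export
decompose_kernel <- function(kernel) {
  stopifnot(inherits(kernel, "base_kernel"))
  p <- kernel$p
  id <- 1:4
  shift <- function(k) ((id - 1L + k) %% 4L) + 1L
  swap_ts <- c(3L, 4L, 1L, 2L)  # A<->G, C<->U
  swap_tv1 <- c(2L, 1L, 4L, 3L) # A<->C, G<->U
  swap_tv2 <- c(4L, 3L, 2L, 1L) # A<->U, C<->G
  if (kernel$mode == "uniform") {
    weights <- c(1 - p, rep(p / 3, 3))
    perms <- list(id, shift(1L), shift(2L), shift(3L))
  } else if (kernel$mode == "transition_only") {
    weights <- c(1 - p, p)
    perms <- list(id, swap_ts)
  } else {
    weights <- c(1 - p, kernel$kappa * p,
                 (1 - kernel$kappa) * p / 2, (1 - kernel$kappa) * p / 2)
    perms <- list(id, swap_ts, swap_tv1, swap_tv2)
  }
  keep <- weights > 0
  weights <- weights[keep]
  perms <- perms[keep]
  # sanity: the weighted permutation sum must reproduce Q entrywise
  Qrec <- matrix(0, 4, 4)
  for (k in seq_along(weights)) {
    Qrec[cbind(1:4, perms[[k]])] <- Qrec[cbind(1:4, perms[[k]])] + weights[k]
  }
  if (max(abs(Qrec - unname(kernel$Q))) > 1e-12) {
    stop("internal error: permutation decomposition does not reproduce Q",
         call. = FALSE)
  }
  structure(list(weights = weights, perms = perms, kernel = kernel),
            class = "perm_decomposition")
}

#' Compose a base kernel into the 64x64 codon transition matrix
#'
#' Under per-base independence the codon transition probability is the
#' product over the three positions of the base-kernel entries:
#' `P[m, n] = Q(n1|m1) Q(n2|m2) Q(n3|m3)`. The diagonal is `(1 - p)^3` and
#' every row sums to 1.
#'
#' @param kernel A `base_kernel`.
#' @return 64x64 row-stochastic matrix of class `codon_matrix`, dimnames set
#'   to codon strings in index order; the generating kernel is attached as
#'   attribute `kernel`.
#' @export
#' @examples
#' P <- build_codon_matrix(build_base_kernel(0.01, "uniform"))
#' P["AUU", "AUC"]  # (1 - p)^2 * p/3
build_codon_matrix <- function(kernel) {
  stopifnot(inherits(kernel, "base_kernel"))
  Q <- unname(kernel$Q)
  i <- 0:63
  b1 <- i %/% 16L + 1L
  b2 <- (i %/% 4L) %% 4L + 1L
  b3 <- i %% 4L + 1L
  P <- Q[b1, b1] * Q[b2, b2] * Q[b3, b3]
  dimnames(P) <- list(codons(), codons())
  structure(P, class = c("codon_matrix", "matrix"), kernel = kernel)
}

#' Single-base-error neighbours of a codon
#'
#' @param codon A single codon.
#' @return The 9 codons at Hamming distance 1 (3 positions x 3 alternative
#'   bases), in position-major order.
#' @export
#' @examples
#' single_error_neighbors("AUU")
single_error_neighbors <- function(codon) {
  x <- normalize_codon(codon)
  if (length(x) != 1L) stop("one codon at a time", call. = FALSE)
  out <- character(0)
  for (k in 1:3) {
    for (b in setdiff(RNA_BASES, substr(x, k, k))) {
      y <- x
      substr(y, k, k) <- b
      out <- c(out, y)
    }
  }
  out
}

#' Write a labelled codon matrix as TSV
#'
#' @param P A `codon_matrix` (or any 64x64 matrix with codon dimnames).
#' @param path Output file.
#' @export
write_codon_matrix_tsv <- function(P, path) {
  df <- data.frame(codon = rownames(P), as.data.frame(unclass(P)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codon matrix written by [write_codon_matrix_tsv()]
#'
#' @param path TSV file with a `codon` label column and 64 codon columns.
#' @return 64x64 matrix with codon dimnames.
#' @export
read_codon_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$codon
  m[codons(), codons()]
}
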