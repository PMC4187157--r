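# Classical discrete codon channel: mutual information at the uniform
# sense-codon prior, amino-acid output aggregation, and a Blahut-Arimoto
# capacity solver used as an independent check on the fixed-prior value.

#' Mutual information of a discrete channel in bits
#'
#' `I(X; Y) = H(Y) - H(Y|X)` with `H(Y) = -sum_j p(Y_j) log2 p(Y_j)` and
#' `H(Y|X) = -sum_i p(X_i) sum_j p(Y_j|X_i) log2 p(Y_j|X_i)`; terms with zero
#' probability contribute 0.
#'
#' @param conditional Row-stochastic matrix `p(Y_j | X_i)`, inputs in rows.
#' @param prior Input distribution over the rows; defaults to the uniform
#'   1/61 sense-codon prior when the channel has 64 codon rows.
#' @return Bits per channel use (non-negative).
#' @export
#' @examples
#' P <- build_codon_matrix(build_base_kernel(0, "uniform"))
#' mutual_information(P)  # log2(61)
mutual_information <- function(conditional, prior = NULL) {
  W <- as.matrix(conditional)
  if (any(W < -1e-12) || max(abs(rowSums(W) - 1)) > 1e-10) {
    stop("conditional matrix must be row-stochastic", call. = FALSE)
  }
  if (is.null(prior)) {
    if (nrow(W) != 64L) {
      stop("prior must be supplied unless the channel has 64 codon inputs",
           call. = FALSE)
    }
    prior <- sense_codon_prior()
  }
  prior <- as.numeric(prior)
  if (length(prior) != nrow(W) || abs(sum(prior) - 1) > 1e-10 ||
      any(prior < 0)) {
    stop("prior must be a distribution over the channel inputs",
         call. = FALSE)
  }
  py <- as.vector(crossprod(W, prior))
  h_y <- shannon_entropy(py)
  h_y_given_x <- sum(vapply(seq_len(nrow(W)), function(i) {
    if (prior[i] == 0) return(0)
    prior[i] * shannon_entropy(W[i, ])
  }, numeric(1)))
  max(h_y - h_y_given_x, 0)
}

#' Aggregate a codon channel to amino-acid outputs
#'
#' Collapses the 64 output codons to 21 output symbols (20 amino acids plus
#' Stop, since mutation can turn a sense codon into a stop) and restricts the
#' inputs to the 61 sense codons. This is the codon-level equivalent of
#' Yockey's amino-acid channel view of protein synthesis.
#'
#' @param P 64x64 codon transition matrix.
#' @return List with `conditional` (61x21 row-stochastic matrix, rows named
#'   by sense codons, columns by residues with `"Stop"` last) and `prior`
#'   (uniform 1/61 over the sense rows).
#' @export
aggregate_to_amino_acids <- function(P) {
  P <- validate_transition_matrix(P)
  residues <- c(amino_acids(), "Stop")
  out_res <- translate_codon(colnames(P))
  sense <- sense_codons()
  cond <- matrix(0, length(sense), length(residues),
                 dimnames = list(sense, residues))
  for (r in residues) {
    cols <- which(out_res == r)
    cond[, r] <- rowSums(P[sense, cols, drop = FALSE])
  }
  list(conditional = cond,
       prior = setNames(rep(1 / 61, length(sense)), sense))
}

#' Blahut-Arimoto capacity of a discrete memoryless channel
#'
#' Alternating maximisation over the input distribution. Iterations stop when
#' the standard capacity bracket (lower bound: current mutual information;
#' upper bound: max over inputs of the Kullback-Leibler divergence to the
#' current output) narrows below `tol`.
#'
#' @param conditional Row-stochastic matrix `p(Y|X)`.
#' @param prior_init Starting input distribution (default uniform over rows).
#' @param tol Bracket width tolerance in bits, default `1e-10`.
#' @param max_iter Iteration cap, default `10000`.
#' @return List with `capacity_bits`, the maximising `prior`, `iterations`,
#'   `converged`, and the final `bracket` (lower, upper bounds in bits).
#' @export
#' @examples
#' bsc <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
#' blahut_arimoto(bsc)$capacity_bits  # 1 - H2(0.1)
blahut_arimoto <- function(conditional, prior_init = NULL, tol = 1e-10,
                           max_iter = 10000L) {
  W <- as.matrix(conditional)
  if (any(W < -1e-12) || max(abs(rowSums(W) - 1)) > 1e-10) {
    stop("conditional matrix must be row-stochastic", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  nx <- nrow(W)
  r <- if (is.null(prior_init)) rep(1 / nx, nx) else as.numeric(prior_init)
  stopifnot(length(r) == nx, abs(sum(r) - 1) < 1e-10)
  logW <- ifelse(W > 0, log2(W), 0)
  bracket <- c(-Inf, Inf)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    q <- as.vector(crossprod(W, r))          # output distribution
    logq <- ifelse(q > 0, log2(q), 0)
    # per-input divergence D(W[i, ] || q), in bits
    d <- vapply(seq_len(nx), function(i) {
      j <- W[i, ] > 0
      sum(W[i, j] * (logW[i, j] - logq[j]))
    }, numeric(1))
    i_lower <- sum(r * d)
    i_upper <- max(d)
    bracket <- c(i_lower, i_upper)
    if (i_upper - i_lower < tol) {
      converged <- TRUE
      break
    }
    r <- r * 2^d
    r <- r / sum(r)
  }
  list(capacity_bits = bracket[1], prior = r, iterations = it,
       converged = converged, bracket = bracket)
}

#' Classical capacity curve over a grid of base error probabilities
#'
#' Mutual information at the uniform 1/61 sense-codon prior for each p,
#' either at codon output resolution or after amino-acid aggregation.
#'
#' @param p_grid Numeric vector of single-base error probabilities.
#' @param kernel_mode Kernel mode, see [build_base_kernel()].
#' @param kappa Kimura transition weight (kimura mode only).
#' @param level `"codon"` (default) or `"amino_acid"` output alphabet.
#' @return Data frame with columns `p`, `kernel_mode`, `construction`
#'   (`"classical"`), `scenario` (`NA`), `granularity` (the output level),
#'   `replicate` and `capacity_bits`, ordered by ascending `p`.
#' @export
classical_capacity_curve <- function(p_grid, kernel_mode = "uniform",
                                     kappa = NULL,
                                     level = c("codon", "amino_acid")) {
  level <- match.arg(level)
  if (length(p_grid) == 0L) stop("empty p grid", call. = FALSE)
  if (any(p_grid < 0 | p_grid > 1)) stop("p values must be in [0, 1]",
                                         call. = FALSE)
  p_grid <- sort(p_grid)
  cap <- vapply(p_grid, function(p) {
    P <- build_codon_matrix(build_base_kernel(p, kernel_mode, kappa = kappa))
    if (level == "codon") {
      mutual_information(P)
    } else {
      ch <- aggregate_to_amino_acids(P)
      mutual_information(ch$conditional, ch$prior)
    }
  }, numeric(1))
  data.frame(p = p_grid, kernel_mode = kernel_mode,
             construction = "classical", scenario = NA_character_,
             granularity = level, replicate = 1L, capacity_bits = cap,
             stringsAsFactors = FALSE)
}
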