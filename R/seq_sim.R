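# Monte Carlo sequence-level validation: generate coding sequences, mutate
# them base-by-base under a kernel, and compare the empirical codon
# transition counts with the analytic matrix.

new_seq_record <- function(id, seq, alphabet = "rna") {
  structure(list(id = id, seq = seq, alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt, %s)\n", x$id, nchar(x$seq),
              x$alphabet))
  invisible(x)
}

#' Generate a random coding sequence
#'
#' Synthetic CDS: starts with AUG, ends with one stop codon (drawn uniformly
#' from UAA/UAG/UGA), and has interior codons drawn i.i.d. uniformly from
#' the sense codons other than AUG — so the body carries no internal stops
#' and the start codon stays unique as a frame marker.
#'
#' @param n_codons Total codon count including start and stop; at least 3.
#' @param seed Integer seed for reproducibility.
#' @return A `seq_record` (RNA alphabet).
#' @export
#' @examples
#' rec <- generate_random_cds(10, seed = 1)
#' substr(rec$seq, 1, 3)  # "AUG"
generate_random_cds <- function(n_codons, seed = NULL) {
  n_codons <- as.integer(n_codons)
  if (is.na(n_codons) || n_codons < 3L) {
    stop("n_codons must be at least 3 (start + body + stop)", call. = FALSE)
  }
  pool <- setdiff(sense_codons(), "AUG")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  body <- sample(pool, n_codons - 2L, replace = TRUE)
  stop_c <- sample(stop_codons(), 1L)
  new_seq_record(
    id = sprintf("synthetic_cds_%dcodons%s", n_codons,
                 if (is.null(seed)) "" else paste0("_seed", seed)),
    seq = paste(c("AUG", body, stop_c), collapse = ""))
}

#' Mutate a sequence under a single-base substitution kernel
#'
#' Each base is resampled independently from its kernel row (one storage or
#' replication generation); repeated application compounds generations.
#' Length and alphabet are preserved.
#'
#' @param rec A `seq_record`.
#' @param kernel A [build_base_kernel()] result.
#' @param seed Integer seed for reproducibility.
#' @return A mutated `seq_record`.
#' @export
mutate_sequence <- function(rec, kernel, seed = NULL) {
  stopifnot(inherits(rec, "seq_record"), inherits(kernel, "base_kernel"))
  bases <- strsplit(chartr("T", "U", toupper(rec$seq)), "")[[1]]
  bi <- match(bases, RNA_BASES)
  if (anyNA(bi)) stop("sequence contains non-ACGU/T characters",
                      call. = FALSE)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  out <- integer(length(bi))
  for (b in 1:4) {
    at <- which(bi == b)
    if (length(at)) {
      out[at] <- sample.int(4L, length(at), replace = TRUE,
                            prob = kernel$Q[b, ])
    }
  }
  seq_out <- paste(RNA_BASES[out], collapse = "")
  if (rec$alphabet == "dna") seq_out <- chartr("U", "T", seq_out)
  new_seq_record(paste0(rec$id, "_mut"), seq_out, rec$alphabet)
}

#' Empirical codon transition counts between two aligned sequences
#'
#' Tallies (original codon, mutated codon) pairs read in the given frame;
#' row-normalising the counts estimates the codon transition matrix.
#'
#' @param original,mutated `seq_record`s of equal length.
#' @param frame 0-based frame offset in `{0, 1, 2}`.
#' @return Object of class `codon_counts`: 64x64 integer matrix `counts`
#'   (codon dimnames) plus the `total` codon count.
#' @export
empirical_codon_matrix <- function(original, mutated, frame = 0L) {
  stopifnot(inherits(original, "seq_record"), inherits(mutated, "seq_record"))
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  s1 <- chartr("T", "U", toupper(original$seq))
  s2 <- chartr("T", "U", toupper(mutated$seq))
  if (nchar(s1) != nchar(s2)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  n_cod <- (nchar(s1) - frame) %/% 3L
  counts <- matrix(0L, 64, 64, dimnames = list(codons(), codons()))
  if (n_cod > 0L) {
    starts <- frame + 3L * (seq_len(n_cod) - 1L) + 1L
    from <- codon_index(substring(s1, starts, starts + 2L)) + 1L
    to <- codon_index(substring(s2, starts, starts + 2L)) + 1L
    tab <- table(factor(from, levels = 1:64), factor(to, levels = 1:64))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, total = n_cod), class = "codon_counts")
}

#' Agreement between empirical counts and an analytic transition matrix
#'
#' Per-source-codon comparison of the empirical row distribution with the
#' analytic row: total-variation distance per row, the worst row, and a
#' pooled chi-square goodness-of-fit test over cells with adequate expected
#' counts.
#'
#' @param counts A `codon_counts` object.
#' @param P 64x64 analytic transition matrix.
#' @param min_expected Minimum expected cell count admitted to the
#'   chi-square pool, default 5.
#' @return List with `row_tv` (named per-row TV distances), `max_tv`,
#'   `chisq_stat`, `df`, `p_value`, and `n_codons`.
#' @export
transition_agreement <- function(counts, P, min_expected = 5) {
  stopifnot(inherits(counts, "codon_counts"))
  P <- validate_transition_matrix(P)
  N <- counts$counts
  row_n <- rowSums(N)
  use <- which(row_n > 0)
  row_tv <- vapply(use, function(m) {
    0.5 * sum(abs(N[m, ] / row_n[m] - P[m, ]))
  }, numeric(1))
  names(row_tv) <- rownames(N)[use]
  chisq <- 0
  df <- 0L
  for (m in use) {
    expd <- row_n[m] * P[m, ]
    keep <- expd >= min_expected
    if (sum(keep) < 1L) next
    # fold cells below the threshold into one pooled cell
    obs <- c(N[m, keep], sum(N[m, !keep]))
    expv <- c(expd[keep], sum(expd[!keep]))
    ok <- expv > 0
    if (sum(ok) < 2L) next
    chisq <- chisq + sum((obs[ok] - expv[ok])^2 / expv[ok])
    df <- df + sum(ok) - 1L
  }
  p_value <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  list(row_tv = row_tv, max_tv = if (length(row_tv)) max(row_tv) else 0,
       chisq_stat = chisq, df = df, p_value = p_value,
       n_codons = counts$total)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings. On read, sequences are kept as records
#' with the original alphabet noted (`"dna"` if the file uses T); writing
#' uses the record's alphabet, wrapped at 60 columns.
#'
#' @param path FASTA file path.
#' @param records A `seq_record` or list of them.
#' @return `read_fasta()`: list of `seq_record`s.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    s <- toupper(as.character(set[[i]]))
    alphabet <- if (grepl("T", s) && !grepl("U", s)) "dna" else "rna"
    if (grepl("[^ACGUT]", s)) {
      stop("record '", names(set)[i], "' contains non-ACGU/T characters",
           call. = FALSE)
    }
    new_seq_record(names(set)[i], chartr("T", "U", s), alphabet)
  })
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) {
    if (r$alphabet == "dna") chartr("U", "T", r$seq) else r$seq
  }, character(1))
  set <- Biostrings::BStringSet(setNames(seqs,
                                         vapply(records, `[[`, character(1),
                                                "id")))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Export empirical codon counts as labelled TSV
#'
#' @param counts A `codon_counts` object.
#' @param path Output file.
#' @export
write_codon_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "codon_counts"))
  write_codon_matrix_tsv(counts$counts, path)
}
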