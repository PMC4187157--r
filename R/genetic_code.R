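# Standard genetic code, codon indexing and the sense-codon prior.
#
# Codons are mRNA triplets over {A, C, G, U}; DNA input (T) is normalised to
# U on read. All 64x64 matrices in the package are indexed by the fixed
# lexicographic convention A=0, C=1, G=2, U=3, codon index
# 16*i(b1) + 4*i(b2) + i(b3), so "AAA" is 0 and "UUU" is 63.

#' All 64 codons in index order
#'
#' @return Character vector of length 64; element `i` is the codon with
#'   zero-based index `i - 1` under the A,C,G,U convention.
#' @export
#' @examples
#' codons()[1]   # "AAA"
#' codons()[64]  # "UUU"
codons <- function() {
  if (is.null(.cc_env$codons)) {
    g <- expand.grid(b3 = RNA_BASES, b2 = RNA_BASES, b1 = RNA_BASES,
                     stringsAsFactors = FALSE)
    .cc_env$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .cc_env$codons
}

normalize_codon <- function(codon) {
  x <- chartr("tu", "TU", toupper(codon))
  x <- chartr("T", "U", x)
  bad <- nchar(x) != 3L | grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (expected 3 characters over A, C, G, U/T)", call. = FALSE)
  }
  x
}

#' Codon to index and back
#'
#' `codon_index()` maps codon strings to their zero-based index
#' (16*i(b1) + 4*i(b2) + i(b3), base order A=0, C=1, G=2, U=3);
#' `index_to_codon()` is its inverse. DNA spelling (T) is accepted and
#' normalised to U.
#'
#' @param codon Character vector of codons (3 letters over A,C,G,U/T).
#' @param index Integer vector in `[0, 63]`.
#' @return Integer vector in `[0, 63]`, or a character vector of codons.
#' @export
#' @examples
#' codon_index("AUG")      # 14
#' index_to_codon(14)      # "AUG"
#' codon_index("ATG")      # DNA spelling, also 14
codon_index <- function(codon) {
  x <- normalize_codon(codon)
  b <- vapply(seq_len(3L), function(k) {
    match(substr(x, k, k), RNA_BASES) - 1L
  }, integer(length(x)))
  b <- matrix(b, ncol = 3L)
  as.integer(16L * b[, 1L] + 4L * b[, 2L] + b[, 3L])
}

#' @rdname codon_index
#' @export
index_to_codon <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 0L) || any(index > 63L)) {
    stop("codon index must be in [0, 63]", call. = FALSE)
  }
  codons()[index + 1L]
}

genetic_code_map <- function() {
  if (is.null(.cc_env$code)) {
    path <- system.file("extdata", "standard_genetic_code.tsv",
                        package = "codonchannel", mustWork = TRUE)
    tab <- read.delim(path, header = FALSE, col.names = c("codon", "residue"),
                      stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 64L, identical(tab$codon, codons()))
    .cc_env$code <- setNames(tab$residue, tab$codon)
  }
  .cc_env$code
}

#' The standard genetic code table
#'
#' Returns the standard (NCBI translation table 1) genetic code as a
#' data frame in codon-index order, read from the plain-text resource
#' shipped with the package.
#'
#' @return Data frame with columns `codon`, `index` (0-based) and `residue`
#'   (three-letter amino-acid code or `"Stop"`).
#' @export
genetic_code_table <- function() {
  code <- genetic_code_map()
  data.frame(codon = names(code), index = 0:63, residue = unname(code),
             stringsAsFactors = FALSE)
}

#' Translate codons to residues
#'
#' @param codon Character vector of codons (RNA or DNA spelling).
#' @return Character vector of three-letter residue codes, `"Stop"` for the
#'   three stop codons UAA, UAG, UGA.
#' @export
#' @examples
#' translate_codon("AUU")  # "Ile"
#' translate_codon("UAA")  # "Stop"
translate_codon <- function(codon) {
  unname(genetic_code_map()[normalize_codon(codon)])
}

#' Stop and sense codons
#'
#' @return Character vector of codons.
#' @export
stop_codons <- function() {
  code <- genetic_code_map()
  names(code)[code == "Stop"]
}

#' @rdname stop_codons
#' @export
sense_codons <- function() {
  code <- genetic_code_map()
  names(code)[code != "Stop"]
}

#' Amino acids and their degeneracy
#'
#' `amino_acids()` lists the 20 amino acids in a fixed (alphabetical) order;
#' `synonym_class()` returns the synonymous codons of one amino acid;
#' `degeneracy_table()` tabulates class sizes. The classes partition the 61
#' sense codons.
#'
#' @param residue Three-letter amino-acid code (e.g. `"Ile"`). Requesting
#'   `"Stop"` is an error: stop codons are not an amino-acid class.
#' @return `synonym_class()`: character vector of codons.
#' @export
#' @examples
#' synonym_class("Ile")  # AUA, AUC, AUU
#' synonym_class("Met")  # AUG
amino_acids <- function() {
  code <- genetic_code_map()
  sort(unique(unname(code[code != "Stop"])))
}

#' @rdname amino_acids
#' @export
synonym_class <- function(residue) {
  if (identical(residue, "Stop")) {
    stop("'Stop' is not an amino acid; use stop_codons()", call. = FALSE)
  }
  code <- genetic_code_map()
  hits <- names(code)[code == residue]
  if (length(hits) == 0L) {
    stop("unknown residue: ", residue, call. = FALSE)
  }
  hits
}

#' @rdname amino_acids
#' @export
degeneracy_table <- function() {
  aas <- amino_acids()
  n <- vapply(aas, function(a) length(synonym_class(a)), integer(1))
  data.frame(residue = aas, degeneracy = unname(n), stringsAsFactors = FALSE)
}

#' Uniform prior over sense codons
#'
#' The default input distribution of the channel model: probability 1/61 on
#' each of the 61 sense codons and 0 on the three stop codons, reflecting
#' that stop codons are never transmitted as amino-acid information.
#'
#' @return Named numeric vector of length 64 (names are codons, index order)
#'   summing to 1.
#' @export
#' @examples
#' p <- sense_codon_prior()
#' p["AUG"]  # 1/61
#' p["UAA"]  # 0
sense_codon_prior <- function() {
  code <- genetic_code_map()
  p <- ifelse(code == "Stop", 0, 1 / 61)
  setNames(as.numeric(p), names(code))
}
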