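#!/usr/bin/env Rscript
# Command-line front end for the codonchannel package.
#
#   Rscript scripts/codon_channel.R sweep      [options]   capacity curves CSV
#   Rscript scripts/codon_channel.R simulate   [options]   Monte Carlo mutation run
#   Rscript scripts/codon_channel.R codon-table            dump genetic code + degeneracies
#
# A YAML config (--config) mirrors the sweep flags; explicit flags override it.

suppressMessages({
  library(codonchannel)
  library(optparse)
})

usage <- function() {
  cat("usage: Rscript scripts/codon_channel.R <sweep|simulate|codon-table> [options]\n")
  quit(status = 2)
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) usage()
cmd <- args[[1]]
rest <- args[-1]

if (cmd == "sweep") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML sweep config"),
    make_option("--mode", type = "character", default = NULL,
                help = "kernel mode: uniform | transition_only | kimura"),
    make_option("--kappa", type = "double", default = NULL,
                help = "transition weight (kimura mode)"),
    make_option("--seed", type = "integer", default = NULL),
    make_option("--replicates", type = "integer", default = NULL,
                help = "random-eigenket draws per p [32]"),
    make_option("--out", type = "character", default = "capacity_curves.csv")
  )), args = rest)
  cfg <- if (!is.null(opts$config)) read_sweep_config(opts$config) else
    default_sweep_config()
  if (!is.null(opts$mode)) cfg$kernel_mode <- opts$mode
  if (!is.null(opts$kappa)) cfg$kappa <- opts$kappa
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  if (!is.null(opts$replicates)) cfg$replicates <- opts$replicates
  run_sweep(cfg, out_csv = opts$out)
} else if (cmd == "simulate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--p", type = "double", default = 0.01,
                help = "single-base error probability [0.01]"),
    make_option("--mode", type = "character", default = "uniform"),
    make_option("--kappa", type = "double", default = NULL),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--frame", type = "integer", default = 0L),
    make_option("--n-codons", type = "integer", default = NULL,
                dest = "n_codons", help = "synthetic CDS length in codons"),
    make_option("--fasta", type = "character", default = NULL,
                help = "input FASTA (overrides --n-codons)"),
    make_option("--out-fasta", type = "character", default = "mutated.fasta",
                dest = "out_fasta"),
    make_option("--out-counts", type = "character", default = "codon_counts.tsv",
                dest = "out_counts")
  )), args = rest)
  sim <- run_simulate(p = opts$p, mode = opts$mode, kappa = opts$kappa,
                      seed = opts$seed, n_codons = opts$n_codons,
                      fasta_in = opts$fasta, frame = opts$frame,
                      out_fasta = opts$out_fasta, out_counts = opts$out_counts)
  rep <- sim$report
  cat(sprintf("codons: %d\nmax row TV distance: %.6f\nchi-square: %.2f (df=%d, p=%.4g)\n",
              rep$n_codons, rep$max_tv, rep$chisq_stat, rep$df, rep$p_value))
} else if (cmd == "codon-table") {
  tab <- genetic_code_table()
  deg <- degeneracy_table()
  tab$degeneracy <- deg$degeneracy[match(tab$residue, deg$residue)]
  tab$degeneracy[is.na(tab$degeneracy)] <- 3L  # the three stop codons
  write.table(tab, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
} else {
  usage()
}
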