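# Capacity sweep front end: assembles the classical curve and the quantum
# curves for every requested construction/scenario over a p grid, writes the
# CSV of record plus a run manifest, and drives the sequence simulator.
# The thin command-line wrapper in scripts/ calls straight into these
# functions.

#' Default capacity sweep configuration
#'
#' The default grid is 30 log-spaced points from 1e-5 to 0.5 plus p = 0
#' (the noiseless reference); both Kraus constructions and all three
#' scenarios are swept at amino-acid granularity with the uniform kernel.
#'
#' @param seed Master seed for the random-eigenket draws.
#' @param replicates Random-eigenket replicates per p, default 32.
#' @return Named list understood by [run_sweep()].
#' @export
default_sweep_config <- function(seed = 1L, replicates = 32L) {
  list(
    p_grid = c(0, 10^seq(log10(1e-5), log10(0.5), length.out = 30)),
    kernel_mode = "uniform",
    kappa = NULL,
    constructions = c("dephasing", "coherent"),
    scenarios = c("mixed", "superposition", "random_eigenket"),
    granularity = "amino_acid",
    classical_levels = c("codon", "amino_acid"),
    seed = as.integer(seed),
    replicates = as.integer(replicates)
  )
}

validate_sweep_config <- function(config) {
  known <- names(default_sweep_config())
  extra <- setdiff(names(config), c(known, "out_csv"))
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  config <- utils::modifyList(default_sweep_config(), config)
  if (length(config$p_grid) == 0L) stop("empty p grid", call. = FALSE)
  if (any(config$p_grid < 0 | config$p_grid > 1)) {
    stop("p values must be in [0, 1]", call. = FALSE)
  }
  config$p_grid <- sort(unique(config$p_grid))
  config
}

#' Read and write sweep configurations as YAML
#'
#' A config written by the tool re-parses to an equivalent sweep.
#'
#' @param config Sweep configuration list.
#' @param path YAML file path.
#' @return `read_sweep_config()`: validated configuration list.
#' @export
write_sweep_config <- function(config, path) {
  yaml::write_yaml(validate_sweep_config(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_sweep_config
#' @export
read_sweep_config <- function(path) {
  validate_sweep_config(yaml::read_yaml(path))
}

#' Run the full capacity sweep
#'
#' One classical curve per output level and one quantum curve per
#' (construction, scenario) pair, all on the same p grid, assembled into a
#' single deterministic table (p ascending, classical rows first, then
#' constructions and scenarios in config order). When `out_csv` is set the
#' table is written there together with a YAML run manifest
#' (`<out>.manifest.yml` holding the config and package version), making a
#' rerun with the same seed byte-identical.
#'
#' @param config Configuration list, see [default_sweep_config()]; missing
#'   entries take their defaults.
#' @param out_csv Optional CSV output path (overrides `config$out_csv`).
#' @return The curve data frame, invisibly when written to file.
#' @export
run_sweep <- function(config = default_sweep_config(), out_csv = NULL) {
  t0 <- Sys.time()
  config <- validate_sweep_config(config)
  if (!is.null(out_csv)) config$out_csv <- out_csv
  msg <- function(...) message(sprintf("[%s] %s",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))
  msg("sweep: %d p values, kernel=%s, seed=%d", length(config$p_grid),
      config$kernel_mode, config$seed)
  parts <- list()
  for (level in config$classical_levels) {
    parts[[length(parts) + 1L]] <-
      classical_capacity_curve(config$p_grid, config$kernel_mode,
                               kappa = config$kappa, level = level)
    msg("classical curve (%s) done", level)
  }
  for (con in config$constructions) {
    for (sc in config$scenarios) {
      parts[[length(parts) + 1L]] <-
        quantum_capacity_curve(config$p_grid, construction = con,
                               scenario = sc,
                               granularity = config$granularity,
                               kernel_mode = config$kernel_mode,
                               kappa = config$kappa, seed = config$seed,
                               replicates = config$replicates)
      msg("quantum curve %s/%s done", con, sc)
    }
  }
  curve <- do.call(rbind, parts)
  rownames(curve) <- NULL
  if (!is.null(config$out_csv)) {
    write.csv(curve, config$out_csv, row.names = FALSE, quote = FALSE)
    manifest <- list(
      config = config[setdiff(names(config), "out_csv")],
      package = "codonchannel",
      version = as.character(utils::packageVersion("codonchannel")),
      rows = nrow(curve))
    yaml::write_yaml(manifest, paste0(config$out_csv, ".manifest.yml"))
    msg("wrote %d rows to %s (%.1f s)", nrow(curve), config$out_csv,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    return(invisible(curve))
  }
  curve
}

#' Run the sequence-level Monte Carlo validation
#'
#' Generates (or loads) a coding sequence, mutates it under the configured
#' kernel, tallies the empirical codon transition counts and reports their
#' agreement with the analytic matrix.
#'
#' @param p Single-base error probability.
#' @param mode Kernel mode.
#' @param kappa Kimura transition weight (kimura mode only).
#' @param seed Integer seed.
#' @param n_codons Length of the synthetic CDS; ignored when `fasta_in` is
#'   given. One of the two must be supplied.
#' @param fasta_in Optional input FASTA (first record is used).
#' @param frame 0-based reading frame offset.
#' @param out_fasta Optional path for the mutated FASTA.
#' @param out_counts Optional path for the counts TSV.
#' @return List with the `original` and `mutated` records, the
#'   `codon_counts`, and the [transition_agreement()] `report`.
#' @export
run_simulate <- function(p, mode = "uniform", kappa = NULL, seed = 1L,
                         n_codons = NULL, fasta_in = NULL, frame = 0L,
                         out_fasta = NULL, out_counts = NULL) {
  if (is.null(fasta_in) && is.null(n_codons)) {
    stop("supply either fasta_in or n_codons", call. = FALSE)
  }
  kernel <- build_base_kernel(p, mode, kappa = kappa)
  seeds <- derive_seeds(seed, 2L)
  original <- if (!is.null(fasta_in)) {
    read_fasta(fasta_in)[[1L]]
  } else {
    generate_random_cds(n_codons, seed = seeds[1L])
  }
  mutated <- mutate_sequence(original, kernel, seed = seeds[2L])
  counts <- empirical_codon_matrix(original, mutated, frame = frame)
  P <- build_codon_matrix(kernel)
  report <- transition_agreement(counts, P)
  if (!is.null(out_fasta)) write_fasta(list(original, mutated), out_fasta)
  if (!is.null(out_counts)) write_codon_counts_tsv(counts, out_counts)
  list(original = original, mutated = mutated, counts = counts,
       report = report)
}
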