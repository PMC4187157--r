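# codonchannel

Information transfer from DNA to protein, treated as a noisy communication
channel — classically and quantum mechanically.

Protein synthesis reads a message written in codons through an imperfect
pipeline: DNA storage, replication, transcription and translation all
introduce "genetic noise", dominated by single-base substitutions (for
example from rare tautomeric base forms, which mispair and fix as
transition mutations). `codonchannel` is for researchers in molecular
information theory and quantum biology who want to quantify how much
information survives that pipeline, and whether treating codon states
quantum mechanically changes the answer.

## The model

Each of the 64 codons is a basis vector of a 64-dimensional Hilbert space.
A single-base error probability *p* and a 4×4 base kernel *Q* (uniform,
transition-only, or Kimura two-parameter) compose, under per-base
independence, into the codon transition matrix

> p(m→n) = Q(n₁|m₁) · Q(n₂|m₂) · Q(n₃|m₃)

which is realised as a quantum operation ρ′ = Σᵢ Eᵢ ρ Eᵢ† in two ways: a
**dephasing** construction with 4096 rank-one operators
E(m,n) = √p(m→n) |n⟩⟨m| (classically equivalent to the transition matrix),
and a **coherent** random-unitary construction of weighted permutation
operators that induces the same transition probabilities while preserving
superpositions. Channels are scored at the uniform sense-codon prior
(1/61 per sense codon, 0 on the stops) by

* **Holevo information** χ = S(Σ pⱼ U(ρⱼ)) − Σ pⱼ S(U(ρⱼ)), the HSW
  capacity at the fixed prior, for three amino-acid input scenarios
  (completely mixed, equal superposition, random subspace eigenket);
* **classical mutual information** I(X;Y) = H(Y) − H(Y|X) of the matching
  discrete codon channel, at codon or amino-acid output resolution, with a
  Blahut–Arimoto solver as an independent capacity check;
* a **Monte Carlo simulator** that mutates (synthetic or FASTA) coding
  sequences base-by-base and verifies the empirical codon transition
  matrix against the analytic one.

## Worked example

```r
library(codonchannel)

kern <- build_base_kernel(0.01, "uniform")     # p = 0.01 per base
P <- build_codon_matrix(kern)
round(P["AUU", single_error_neighbors("AUU")], 6)
#>      CUU      GUU      UUU      AAU      ACU      AGU      AUA      AUC      AUG
#> 0.003267 0.003267 0.003267 0.003267 0.003267 0.003267 0.003267 0.003267 0.003267

cls <- mutual_information(P)                   # classical codon channel
kc  <- build_kraus_coherent(decompose_kernel(kern))
chi <- sapply(c("mixed", "superposition"), function(sc)
  holevo_information(make_ensemble(sc, "amino_acid"), kc))
rand <- quantum_capacity_curve(0.01, "coherent", "random_eigenket",
                               seed = 1, replicates = 32)
round(c(classical = cls, chi, random_eigenket = mean(rand$capacity_bits)), 4)
#>       classical           mixed   superposition random_eigenket
#>          5.6492          3.9333          3.9742          4.0491

sim <- run_simulate(p = 0.01, n_codons = 100000, seed = 1)
sprintf("max row TV: %.4f  chi-square p: %.3f",
        sim$report$max_tv, sim$report$p_value)
#> "max row TV: 0.0297  chi-square p: 0.452"
```

Reading the numbers: at p = 0.01 each of the nine single-error neighbours
of AUU receives (1−p)²·p/3 ≈ 0.00327 of the probability mass. The
classical codon channel still carries 5.649 of its noiseless log₂ 61 ≈
5.931 bits per codon. At amino-acid granularity the capacity is lower
(synonymous codons are indistinguishable as signals — at p = 0 the limit
is ≈ 4.139 bits), and the three quantum scenarios through the coherent
channel order as mixed < superposition < random eigenket, the mixed case
coinciding with the classical value — so coherent quantum encodings sit at
or above the classical one. The simulator confirms the analytic transition
matrix: every row of the 10⁵-codon empirical matrix is within a 0.03
total-variation distance and the goodness-of-fit test is comfortable.

A command-line front end wraps the same functions:

```sh
Rscript scripts/codon_channel.R sweep --seed 1 --out capacity_curves.csv
Rscript scripts/codon_channel.R simulate --p 0.01 --n-codons 100000 --seed 1
Rscript scripts/codon_channel.R codon-table
```

`sweep` writes the full capacity-versus-p table (31 grid points from 0 to
0.5; classical curves at both output levels plus all three scenarios
through both constructions) with a YAML run manifest; reruns with the same
seed are byte-identical.

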