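---
title: "Modelling DNA-to-protein information transfer as a quantum channel"
author: "codonchannel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA-to-protein information transfer as a quantum channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonchannel)
```

## The model

Protein synthesis can be read as a communication problem: the genome encodes
a message in codons, and replication, transcription and translation act as a
noisy channel between the DNA "source" and the protein "sink". `codonchannel`
implements this picture quantum mechanically. Each of the 64 codons is a
basis vector of a 64-dimensional Hilbert space, so an amino acid with
degeneracy $n$ occupies an $n$-dimensional synonym subspace (Ile, for
instance, spans $\{|AUA\rangle, |AUC\rangle, |AUU\rangle\}$). Genetic noise
is modelled as a quantum operation in operator-sum form,

$$\rho' = \sum_i E_i\,\rho\,E_i^\dagger, \qquad \sum_i E_i^\dagger E_i = I,$$

whose statistics are fixed by a $64\times 64$ codon transition matrix
$p_{m,n}$, the probability that codon $m$ is read as codon $n$.

### Mutation kernels

All noise is reduced to a single-base error probability $p$, applied
independently at the three codon positions (single-base errors dominate;
double and triple errors enter automatically through the product structure
at order $p^2$ and $p^3$). Three $4\times4$ base kernels are provided, all
with diagonal $1-p$:

* **uniform** — $p/3$ to each alternative base; the maximally agnostic
  choice and the sweep default.
* **transition_only** — all of $p$ to the transition partner
  (A$\leftrightarrow$G, C$\leftrightarrow$U). This is the pattern forced by
  tautomeric mispairing: a proton-shifted base pairs with the wrong partner
  (A\*$\cdot$C, C\*$\cdot$A, G\*$\cdot$U, U\*$\cdot$G), and one round of
  replication resolves each mispair into a purine$\leftrightarrow$purine or
  pyrimidine$\leftrightarrow$pyrimidine substitution. Tautomer occupancies
  of order $10^{-5}$–$10^{-3}$ motivate the recommended $p$ range for this
  mode; no separate occupancy-to-fixation model is attempted.
* **kimura** — two-parameter interpolation: $\kappa p$ on the transition and
  $(1-\kappa)p/2$ on each transversion, with $\kappa \in (0, 1]$
  (dimensionless; `uniform` is $\kappa = 1/3$).

The codon matrix is the per-position product
$p_{m,n} = \prod_{k=1}^{3} Q(n_k \mid m_k)$, verified in the tests against a
threefold Kronecker composition; its diagonal is $(1-p)^3$ and it is doubly
stochastic for every mode, so the maximally mixed state is a fixed point of
every channel built from it.

### Two Kraus constructions

The transition matrix does not determine the channel: many operator-sum
representations share the same basis-state statistics but differ on
superpositions. Two constructions bracket the possibilities.

The **dephasing** construction uses one rank-one operator per ordered codon
pair, $E_{m,n} = \sqrt{p_{m,n}}\,|n\rangle\langle m|$ — $64^2 = 4096$
operators. Its output is always diagonal in the codon basis, so codon
coherences are destroyed and the channel is exactly the classical channel
$p_{m,n}$ wearing quantum clothes. A provable consequence, asserted in the
test suite, is that input ensembles with identical diagonals are
indistinguishable: the completely-mixed and superposition scenarios below
give the same Holevo information through this construction.

The **coherent** (random-unitary) construction first writes the base kernel
as a convex mixture of permutations — identity with weight $1-p$, plus
fixed-point-free permutations carrying the error mass (the three cyclic
shifts on the A,C,G,U ring for the uniform kernel, chosen because they sum
exactly to all-ones minus identity; the transition swap for
transition_only; transition swap plus the two transversion double-swaps for
kimura) — and then takes one operator
$\sqrt{w_a w_b w_c}\,(\Pi_a \otimes \Pi_b \otimes \Pi_c)$ per permutation
triple (at most 64 operators). It induces the same $p_{m,n}$ between basis
states but transports superpositions coherently. It is the minimal channel
consistent with both the stated transition probabilities and preservation of
within-subspace coherence, and it is the default for the quantum sweep
because only a coherence-preserving channel can separate the three input
scenarios.

### Input scenarios and the prior

Codons are transmitted with the uniform sense prior: $1/61$ per sense codon,
$0$ for the stops UAA, UAG, UGA. At amino-acid granularity this becomes a
20-member ensemble weighted by degeneracy $n_{aa}/61$, with three readings
of "the state of an amino acid":

1. **mixed** — the completely mixed state on the synonym subspace,
   $\rho_{aa} = \tfrac1n \sum_m |m\rangle\langle m|$;
2. **superposition** — the equal-amplitude pure state
   $\tfrac1{\sqrt n}\sum_m |m\rangle$ (amplitudes are taken equal and real
   for want of measured values);
3. **random_eigenket** — one pure state drawn uniformly (seeded) from the
   discrete-Fourier orthonormal basis of the subspace,
   $v_k[j] = e^{2\pi i jk/n}/\sqrt n$, which for two-fold degeneracy is
   exactly $(|m_1\rangle \pm |m_2\rangle)/\sqrt 2$.

A 61-member pure-codon ensemble (`granularity = "codon"`) is also provided;
it is the natural reading of the per-codon $1/61$ prior, while the
amino-acid granularity matches the per-amino-acid phrasing of the scenarios.
Both are exposed; the sweep defaults to amino-acid granularity.

### Capacities

The quantum figure of merit is the Holevo information at the fixed prior,

$$\chi = S\!\Big(\sum_j p_j\, U(\rho_j)\Big) - \sum_j p_j\, S(U(\rho_j)),$$

with $S(\rho) = -\mathrm{tr}(\rho \log_2 \rho)$ the von Neumann entropy in
bits. Because the prior is held at the uniform sense-codon distribution
(taken as capacity-achieving for this symmetric channel), no maximisation
over ensembles is performed — $\chi$ is the HSW capacity of the channel for
the given signal ensemble. The classical benchmark is the mutual information
$I(X;Y) = H(Y) - H(Y\mid X)$ of the discrete channel $p_{m,n}$ at the same
prior, optionally after collapsing outputs to 21 symbols (20 amino acids
plus Stop, since noise can create stops). A Blahut–Arimoto solver is
included purely as a check on the uniform-prior claim: for the uniform
kernel at $p = 0.01$ the maximised capacity exceeds the fixed-prior value by
under $10^{-4}$ bits, so the claim is a very good approximation but not
exact, and any gap is reported rather than hidden.

The entropy-exchange matrix $W_{ij} = \mathrm{tr}(E_i \rho E_j^\dagger)$ is
also exposed; with an initially pure environment $S(W)$ is the entropy the
environment acquires, and for pure inputs it equals the output entropy (the
purification identity, tested numerically).

## Capacity curves

```{r curves, eval = FALSE}
cfg <- default_sweep_config(seed = 1)
curve <- run_sweep(cfg, out_csv = "capacity_curves.csv")
```

The default grid is 30 log-spaced points on $[10^{-5}, 0.5]$ plus $p = 0$.
At $p = 0$ the closed forms are recovered exactly: $\log_2 61 \approx 5.931$
bits at codon granularity, and at amino-acid granularity

$$\log_2 61 - \tfrac1{61}\big(18\log_2 6 + 20\log_2 4 + 3\log_2 3
  + 18\log_2 2\big) \approx 4.139 \text{ bits},$$

the degeneracy-weighted loss from not being able to distinguish synonymous
codons. As $p$ grows the curves decrease monotonically, slowly below
$p \approx 10^{-2}$ and then dramatically towards $p \approx 0.1$ — the
regime where codon identity, and with it the capacity to specify a protein,
is effectively lost. Through the coherent construction the three scenarios
separate in a fixed order — mixed $<$ superposition $<$ random eigenket —
with the mixed scenario numerically indistinguishable from the classical
curve at amino-acid resolution, so the quantum readings of the channel sit
at or above the classical one. The dephasing construction collapses all
scenarios onto the classical curve, which is why the scenario separation is
evidence specifically of coherence preservation.

Which construction and which granularity generated the published
capacity-versus-$p$ figure this analysis mirrors is not stated in the
source; both constructions and both granularities are therefore shipped and
swept, and no attempt is made to tune toward figure-read values. Likewise
the base-level kernel behind that figure is unstated: the sweep defaults to
the uniform kernel, with transition_only and kimura available.

## Monte Carlo validation

The sequence simulator provides an independent, sampling-based check of the
analytic transition matrix. `generate_random_cds(n, seed)` builds a
synthetic coding sequence — AUG, then i.i.d. uniform sense codons (AUG
excluded from the interior so the start stays a unique frame marker, stops
excluded by construction), then one uniform stop codon. `mutate_sequence()`
resamples every base independently from its kernel row (one
storage/replication generation; apply it repeatedly to compound
generations), and `empirical_codon_matrix()` tallies aligned codon pairs in
a chosen frame. At $10^5$ codons and $p = 0.01$ the empirical rows sit
within 4-sigma multinomial bounds of the analytic rows, the pooled
chi-square goodness-of-fit p-value is far above 0.001, and the mean row
total-variation distance scales as $n^{-1/2}$ across $10^3$–$10^5$ codons.

What the generator does *not* emulate about real coding sequences: codon
usage bias, neighbour-dependent (context) mutation, strand asymmetry,
indels and selection. Passing tests therefore validate the package's own
probability model, not any claim about a particular genome; real sequences
can be substituted through the FASTA interface (`read_fasta()`, DNA
normalised to RNA on read).

## Numerical choices

* Eigenvalues below $10^{-12}$ are treated as exact zeros in every entropy
  ($0\log 0 = 0$); PSD matrices routinely acquire tiny negative eigenvalues
  numerically.
* Stochasticity is validated to $10^{-10}$ on row sums; kernel and
  decomposition reconstructions must agree to $10^{-12}$ entrywise.
* Degenerate inputs behave by construction: $p = 0$ gives the identity
  channel (a single Kraus operator in the coherent construction), $p = 3/4$
  under the uniform kernel gives a fully depolarising base and zero
  capacity, and $p = 1$ under transition_only is the deterministic
  transition swap.
* The dephasing entropy-exchange matrix is $4096\times4096$ but
  block-diagonal over the output codon; it is stored and diagonalised as 64
  blocks of $64\times64$, which changes nothing observable.
* Blahut–Arimoto stops when the standard capacity bracket (current mutual
  information vs. the maximal input divergence) narrows below `tol`
  (default $10^{-10}$ bits); non-convergence is flagged with the bracket.
* All randomness (random-eigenket draws, sequence generation, mutation) is
  seeded, applied locally without disturbing the caller's RNG stream, and
  replicate seeds are derived deterministically from the master seed. The
  random-eigenket scenario defaults to 32 replicates with every draw
  reported, since a single draw is an arbitrary representative.
* Test and validation problem sizes — $10^5$-codon sequences, 4–8 replicate
  draws on coarse grids, the full 31-point sweep only through the
  command-line tool — were chosen to exercise every contract at high
  statistical power while keeping the default suite fast.

## Limitations

* The prior is fixed; true HSW maximisation over ensembles, coherent
  information and entanglement-assisted capacities are out of scope.
* No indel/frameshift model: the mechanism exists biologically but has no
  quantitative rate model here, so only substitutions are simulated.
* Tautomer occupancy is taken as a range for $p$, not derived from a
  double-well tunnelling computation.
* The amino-acid aggregation reproduces the codon-level equivalent of
  Yockey's classical channel view, not his original published capacity
  values, whose transition-probability derivation is separate.
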