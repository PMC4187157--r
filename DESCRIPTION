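Package: codonchannel
Title: Quantum and Classical Channel Capacity of the Genetic Code
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the transfer of genetic information from DNA to protein as
    a noisy communication channel over the 64 codon basis states. Single-base
    substitution kernels (uniform, tautomer-motivated transition-only, and
    Kimura two-parameter) are composed into 64x64 codon transition matrices,
    realised as quantum channels in operator-sum (Kraus) form via either a
    fully dephasing or a coherent random-permutation construction, and scored
    by Holevo information at the uniform sense-codon prior alongside the
    classical mutual information of the matching discrete codon channel. A
    Blahut-Arimoto capacity solver, a Monte Carlo coding-sequence mutation
    simulator with empirical transition-matrix estimation, and a capacity
    sweep front end reproduce the full capacity-versus-error-probability
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
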