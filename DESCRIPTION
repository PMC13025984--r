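Package: algoreg
Title: Contrastive Compressibility Diagnostics for Algorithmic Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying regulation as compression. Simulates
    deterministic coupled world-regulator systems built from finite causal
    transducers with self-delimiting binary codes, estimates codelengths with
    practical proxies for Kolmogorov complexity (Lempel-Ziv 76 parsing, the
    Block Decomposition Method over exactly enumerated program tables, and
    general-purpose codecs), and measures the contrastive compressibility gap
    between regulated (ON) and unregulated (OFF) readouts together with paired
    permutation inference and compression-based mutual-information estimates.
    An exactly enumerated micro program universe provides exact universal-prior
    semimeasures, prefix complexities and Coding-Theorem constants, inside
    which the posterior-tilt bounds relating the gap to mutual algorithmic
    information are verified with exact arithmetic. Includes a thermostat
    test bed and a membrane-scanning agency diagnostic for Conway's Game of
    Life histories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
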