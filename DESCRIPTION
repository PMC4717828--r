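Package: triadPC
Title: Principal-Component Tests for Association and Maternal Effects in
    Case-Parent Trios
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Family-based tests for genetic association and maternally
    mediated genetic effects from case-parent trio genotypes at multiple
    linked SNPs. Implements the max_PC statistic, which applies principal
    component analysis to the per-trio difference vectors X = 2C - F - M
    (affected child versus the non-transmitted "complement") and
    Y = M - F (mother versus father), together with the max_Z^2
    comparator, a sign-flip permutation engine for multiplicity-corrected
    p-values across correlated loci, a forward haplotype simulator
    (first-order Markov linkage disequilibrium, ancestral disease
    haplotype decay, population admixture), and drivers for replicated
    type-I-error and power studies. Reads standard linkage PED/MAP files
    and tolerates missing genotypes via per-locus complete-case analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
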