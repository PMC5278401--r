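Package: pseudokin
Title: Relatedness Estimation from Forced-Homozygote Pseudo-Haploid Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates pairwise genetic relatedness between individuals typed
    at very low sequencing coverage by reducing every locus to a single
    randomly drawn allele ("forced homozygote" or pseudo-haploid calls) and
    computing the Queller-Goodnight symmetric Rxy estimator against external
    reference allele frequencies. Includes readers and writers for text PLINK
    (.ped/.map) genotypes, .frq allele-frequency tables and per-site pileup
    call tables; a Mendelian gene-dropping simulator that builds empirical
    Rxy distributions for unrelated, first-order and second-order dyads; and
    a maximum-likelihood framework that scores the eleven canonical
    three-individual relationship hypotheses and reports posterior
    probabilities and odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
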