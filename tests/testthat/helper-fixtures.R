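# Shared in-code fixtures for the suite.

# A hand-built panel where every field is known exactly.
tiny_frq <- function() {
  tibble::tibble(
    chrom = "1",
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    a1 = c("A", "C", "G", "T", "A"),
    a2 = c("G", "T", "A", "C", "C"),
    maf = c(0.2, 0.5, 0.1, 0.35, 0.45)
  )
}

# A single-individual pseudo-haploid tibble from snp/allele vectors.
haploid <- function(snp, allele, id = "x") {
  tibble::tibble(sample = id, snp = snp, allele = allele)
}

# A single-individual diploid tibble.
diploid <- function(snp, allele1, allele2, id = "x") {
  tibble::tibble(sample = id, snp = snp, allele1 = allele1, allele2 = allele2)
}

# Duplicate pseudo-haploid calls into the homozygous-diploid encoding.
duplicate_alleles <- function(g) {
  tibble::tibble(sample = g$sample, snp = g$snp,
                 allele1 = g$allele, allele2 = g$allele)
}

# Independent per-locus oracle for the forced estimator: plain loop over
# loci accumulating (2*I(a==c) - p_a - p_c) and (2 - p_a - p_c).
oracle_rxy_forced <- function(allele_x, allele_y, a1, maf) {
  num <- 0
  den <- 0
  for (l in seq_along(allele_x)) {
    p_a <- if (allele_x[l] == a1[l]) maf[l] else 1 - maf[l]
    p_c <- if (allele_y[l] == a1[l]) maf[l] else 1 - maf[l]
    num <- num + 2 * (allele_x[l] == allele_y[l]) - p_a - p_c
    den <- den + 2 - p_a - p_c
  }
  num / den
}
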