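# Forced-homozygote (pseudo-haploid) reduction and dyad intersection.
#
# The central data reduction: every locus is collapsed to ONE allele — a
# random qualifying read for pileup input, a random member of the diploid
# pair for genotype input — and is treated downstream as a homozygous call.
# This halves the expected Queller-Goodnight relatedness (first order
# 0.5 -> 0.25, second order 0.25 -> 0.125) but removes the bias that
# spurious homozygosity at 1X coverage would otherwise introduce.

#' Force one pileup site to a single allele
#'
#' Picks one base uniformly at random among the calls with phred quality at
#' or above `min_qual`; returns `NA` when no call qualifies. With exactly
#' one qualifying call the choice is deterministic and the random stream is
#' left untouched.
#'
#' @param bases Character vector of base calls at the site.
#' @param quals Integer phred qualities, same length as `bases`.
#' @param min_qual Minimum phred quality for a call to be eligible
#'   (inclusive; default 30, i.e. error probability 0.1%).
#' @return A single allele character, or `NA_character_`.
#' @examples
#' force_site(c("A", "G"), c(35, 12))  # only "A" qualifies
#' @export
force_site <- function(bases, quals, min_qual = 30) {
  if (length(bases) != length(quals)) {
    abort("`bases` and `quals` must have the same length.")
  }
  keep <- which(quals >= min_qual)
  if (length(keep) == 0) return(NA_character_)
  if (length(keep) == 1) return(bases[keep])
  bases[keep[sample.int(length(keep), 1L)]]
}

#' Force all sites of a pileup to pseudo-haploid calls
#'
#' Applies [force_site()] to every site of a pileup call table, in site
#' order, so a run is reproducible site-by-site from the same seed. Sites
#' with no qualifying call are retained with `allele = NA`, which keeps the
#' accounting identity `called + dropped = total sites`.
#'
#' @param calls Long pileup tibble (`snp`, `base`, `qual`), as from
#'   [read_pileup()]; the `"sites"` attribute, when present, supplies the
#'   site order and any zero-depth sites.
#' @param min_qual Minimum phred quality (inclusive), default 30.
#' @param sample_id Sample identifier attached to the output.
#' @return A tibble with columns `sample`, `snp`, `allele` (one row per
#'   site, `NA` allele where no call qualified), with attribute `"n_dropped"`
#'   giving the number of uncalled sites.
#' @export
force_pileup <- function(calls, min_qual = 30, sample_id = "sample") {
  if (!all(c("snp", "base", "qual") %in% names(calls))) {
    abort("`calls` must have columns `snp`, `base`, `qual`.")
  }
  sites <- attr(calls, "sites")
  if (is.null(sites)) sites <- unique(calls$snp)
  if (anyDuplicated(sites) > 0) {
    abort("Duplicate locus id in pileup sites.")
  }
  grouped <- split(seq_len(nrow(calls)), factor(calls$snp, levels = sites))
  allele <- vapply(sites, function(s) {
    idx <- grouped[[s]]
    force_site(calls$base[idx], calls$qual[idx], min_qual = min_qual)
  }, character(1))
  out <- tibble(sample = sample_id, snp = sites, allele = unname(allele))
  attr(out, "n_dropped") <- sum(is.na(out$allele))
  out
}

#' Force diploid genotypes to pseudo-haploid calls
#'
#' For every called locus one of the two alleles is kept, chosen uniformly
#' at random, and treated as a homozygous call; a homozygous input returns
#' its allele with certainty, so forcing is idempotent. Loci with a missing
#' diploid call stay missing — missingness is never imputed.
#'
#' @param geno Long diploid genotype tibble with columns `sample`, `snp`,
#'   `allele1`, `allele2` (other columns are carried through).
#' @return A tibble `sample`, `snp`, `allele` (plus carried columns), with
#'   attribute `"n_dropped"` counting missing calls.
#' @export
force_diploid <- function(geno) {
  if (!all(c("sample", "snp", "allele1", "allele2") %in% names(geno))) {
    abort("`geno` must have columns `sample`, `snp`, `allele1`, `allele2`.")
  }
  n <- nrow(geno)
  keep_first <- runif(n) < 0.5
  allele <- ifelse(keep_first, geno$allele1, geno$allele2)
  allele[is.na(geno$allele1) | is.na(geno$allele2)] <- NA_character_
  out <- geno
  out$allele1 <- NULL
  out$allele2 <- NULL
  out$allele <- allele
  attr(out, "n_dropped") <- sum(is.na(allele))
  out
}

#' Intersect two pseudo-haploid individuals on usable shared loci
#'
#' Builds the estimator's input for one dyad: the loci called in *both*
#' individuals, present in the frequency panel with a frequency strictly
#' inside (0, 1), and whose observed alleles both belong to the panel's
#' allele pair. Loci failing any condition are excluded and counted, never
#' silently recoded.
#'
#' @param gx,gy Pseudo-haploid tibbles (`snp`, `allele`, optionally
#'   `sample`), e.g. from [force_pileup()] or [force_diploid()]. Each must
#'   describe a single individual.
#' @param frq Allele-frequency tibble (`chrom`, `snp`, `a1`, `a2`, `maf`).
#' @return A dyad tibble with columns `snp`, `a1`, `a2`, `maf`, `allele_x`,
#'   `allele_y`, in panel order, with attributes `id_x`, `id_y` and
#'   `exclusions` (named integer vector: `missing_in_one`, `not_in_panel`,
#'   `monomorphic`, `allele_mismatch`).
#' @export
intersect_dyad <- function(gx, gy, frq) {
  check_frq(frq)
  for (g in list(gx, gy)) {
    if (!all(c("snp", "allele") %in% names(g))) {
      abort("`gx`/`gy` must have columns `snp` and `allele`.")
    }
  }
  one_id <- function(g, default) {
    if ("sample" %in% names(g)) {
      ids <- unique(g$sample)
      if (length(ids) > 1) abort("Each of `gx`, `gy` must hold one individual.")
      if (length(ids) == 1) return(ids)
    }
    default
  }
  id_x <- one_id(gx, "x")
  id_y <- one_id(gy, "y")

  cx <- gx[!is.na(gx$allele), c("snp", "allele")]
  cy <- gy[!is.na(gy$allele), c("snp", "allele")]
  if (nrow(cx) == 0 || nrow(cy) == 0) {
    abort("no shared loci: an individual has no called locus.")
  }
  names(cx)[2] <- "allele_x"
  names(cy)[2] <- "allele_y"

  shared <- inner_join(cx, cy, by = "snp")
  n_union_called <- length(union(cx$snp, cy$snp))
  n_missing_in_one <- n_union_called - nrow(shared)

  d <- inner_join(frq, shared, by = "snp")
  n_not_in_panel <- nrow(shared) - nrow(d)

  poly <- d$maf > 0 & d$maf < 1
  n_monomorphic <- sum(!poly)
  d <- d[poly, ]

  ok <- (d$allele_x == d$a1 | d$allele_x == d$a2) &
    (d$allele_y == d$a1 | d$allele_y == d$a2)
  n_mismatch <- sum(!ok)
  d <- d[ok, c("snp", "a1", "a2", "maf", "allele_x", "allele_y")]

  if (nrow(d) == 0) {
    abort(paste0("no shared loci between '", id_x, "' and '", id_y,
                 "' after exclusions."))
  }
  d <- as_tibble(d)
  attr(d, "id_x") <- id_x
  attr(d, "id_y") <- id_y
  attr(d, "exclusions") <- c(
    missing_in_one = n_missing_in_one,
    not_in_panel = n_not_in_panel,
    monomorphic = n_monomorphic,
    allele_mismatch = as.integer(n_mismatch)
  )
  d
}
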