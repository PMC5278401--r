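# Queller & Goodnight (1989) symmetric relatedness estimator against
# external reference allele frequencies, as a ratio of sums across loci.
#
# General diploid form, per locus, focal individual x = (a, b) versus
# y = (c, d) with carried-allele frequencies p_a, p_b:
#   num_x = 0.5 * (I(a=c) + I(a=d) + I(b=c) + I(b=d)) - p_a - p_b
#   den_x = 1 + I(a=b) - p_a - p_b
# and symmetrically for focal y; Rxy = (sum num_x + sum num_y) /
# (sum den_x + sum den_y).  Under forced homozygosity (a = b, c = d) both
# focal terms coincide and the estimator reduces per locus to
#   num = 2 I(a=c) - p_a - p_c,   den = 2 - p_a - p_c.
# The value is a ratio of summed terms, never a mean of per-locus ratios,
# and is deliberately not clamped to [0, 1].

# Core on integer allele codes (1 = a1, 2 = a2); p1 = freq of a1.
#' @noRd
rxy_codes_forced <- function(x, y, p1) {
  px <- carried_freq(x, p1)
  py <- carried_freq(y, p1)
  num <- 2 * (x == y) - px - py
  den <- 2 - px - py
  list(num_sum = sum(num), den_sum = sum(den), n_loci = length(x),
       n_uninformative = 0L)
}

#' @noRd
rxy_codes_general <- function(xa, xb, ya, yb, p1) {
  pxa <- carried_freq(xa, p1); pxb <- carried_freq(xb, p1)
  pya <- carried_freq(ya, p1); pyb <- carried_freq(yb, p1)
  share <- (xa == ya) + (xa == yb) + (xb == ya) + (xb == yb)
  num_x <- 0.5 * share - pxa - pxb
  den_x <- 1 + (xa == xb) - pxa - pxb
  num_y <- 0.5 * share - pya - pyb
  den_y <- 1 + (ya == yb) - pya - pyb
  informative <- (den_x + den_y) != 0
  list(
    num_sum = sum(num_x[informative]) + sum(num_y[informative]),
    den_sum = sum(den_x[informative]) + sum(den_y[informative]),
    n_loci = sum(informative),
    n_uninformative = sum(!informative)
  )
}

#' @noRd
rxy_result <- function(id_x, id_y, acc) {
  if (acc$den_sum <= 0) {
    abort(paste0(
      "Rxy denominator is not positive for dyad ", id_x, ":", id_y,
      "; no informative polymorphic locus."
    ))
  }
  tibble(
    id_x = id_x, id_y = id_y,
    n_loci = as.integer(acc$n_loci),
    n_uninformative = as.integer(acc$n_uninformative),
    num_sum = acc$num_sum, den_sum = acc$den_sum,
    rxy = acc$num_sum / acc$den_sum
  )
}

#' Rxy for a forced-homozygote dyad
#'
#' Evaluates the symmetric Queller-Goodnight estimator on a dyad of
#' pseudo-haploid individuals, using the homozygous reduction of the
#' estimator. Because only one allele per locus is interrogated, expected
#' values are half the diploid ones: 0.25 for first-order and 0.125 for
#' second-order relatives, 0 for unrelated pairs.
#'
#' @param dyad Dyad tibble from [intersect_dyad()] (columns `snp`, `a1`,
#'   `a2`, `maf`, `allele_x`, `allele_y`).
#' @return A one-row tibble: `id_x`, `id_y`, `n_loci`, `n_uninformative`,
#'   `num_sum`, `den_sum`, `rxy`. `rxy = num_sum / den_sum` exactly, and may
#'   legitimately be negative.
#' @examples
#' frq <- simulate_frq_panel(200)
#' d <- simulate_dyad(frq, "first_order")
#' gx <- d[d$sample == "x", ]; gy <- d[d$sample == "y", ]
#' rxy_forced(intersect_dyad(gx, gy, frq))
#' @export
rxy_forced <- function(dyad) {
  need <- c("snp", "a1", "a2", "maf", "allele_x", "allele_y")
  if (!all(need %in% names(dyad))) {
    abort("`dyad` must come from `intersect_dyad()`.")
  }
  x <- allele_to_code(dyad$allele_x, dyad$a1, dyad$a2)
  y <- allele_to_code(dyad$allele_y, dyad$a1, dyad$a2)
  if (anyNA(x) || anyNA(y)) {
    abort("`dyad` contains alleles outside the panel's allele pair.")
  }
  id_x <- attr(dyad, "id_x") %||% "x"
  id_y <- attr(dyad, "id_y") %||% "y"
  rxy_result(id_x, id_y, rxy_codes_forced(x, y, dyad$maf))
}

#' Rxy for a diploid dyad (general estimator)
#'
#' Evaluates the full diploid symmetric Queller-Goodnight estimator for two
#' individuals with (possibly heterozygous) diploid genotypes, against an
#' external frequency panel. Shared loci are those called in both
#' individuals, polymorphic in the panel, with all observed alleles in the
#' panel's allele pair. At a biallelic locus a heterozygous focal individual
#' contributes zero to both sums; loci where both focal denominators vanish
#' are skipped and counted in `n_uninformative`.
#'
#' On duplicated-allele (forced) input this reduces exactly to
#' [rxy_forced()].
#'
#' @param gx,gy Single-individual diploid tibbles (`snp`, `allele1`,
#'   `allele2`, optionally `sample`).
#' @param frq Allele-frequency tibble.
#' @return A one-row tibble as in [rxy_forced()].
#' @export
rxy_general <- function(gx, gy, frq) {
  check_frq(frq)
  for (g in list(gx, gy)) {
    if (!all(c("snp", "allele1", "allele2") %in% names(g))) {
      abort("`gx`/`gy` must have columns `snp`, `allele1`, `allele2`.")
    }
  }
  one_id <- function(g, default) {
    if ("sample" %in% names(g) && length(unique(g$sample)) == 1)
      unique(g$sample) else default
  }
  id_x <- one_id(gx, "x")
  id_y <- one_id(gy, "y")

  cx <- gx[!is.na(gx$allele1) & !is.na(gx$allele2),
           c("snp", "allele1", "allele2")]
  cy <- gy[!is.na(gy$allele1) & !is.na(gy$allele2),
           c("snp", "allele1", "allele2")]
  names(cx)[2:3] <- c("xa", "xb")
  names(cy)[2:3] <- c("ya", "yb")
  d <- inner_join(usable_frq(frq), inner_join(cx, cy, by = "snp"),
                  by = "snp")
  code <- function(al) allele_to_code(al, d$a1, d$a2)
  xa <- code(d$xa); xb <- code(d$xb); ya <- code(d$ya); yb <- code(d$yb)
  ok <- !(is.na(xa) | is.na(xb) | is.na(ya) | is.na(yb))
  if (!any(ok)) {
    abort(paste0("no shared usable loci between '", id_x, "' and '", id_y, "'."))
  }
  acc <- rxy_codes_general(xa[ok], xb[ok], ya[ok], yb[ok], d$maf[ok])
  rxy_result(id_x, id_y, acc)
}
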