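# Internal helpers shared across modules.
#
# Allele codes: at every biallelic locus the two panel alleles are mapped to
# the integers 1 (allele `a1`, the frequency-bearing allele of the .frq
# table) and 2 (allele `a2`); NA codes a missing call.  All simulation and
# estimation cores work on code vectors; character alleles only exist at the
# file-format boundary.

VALID_BASES <- c("A", "C", "G", "T")

FRQ_COLS <- c("chrom", "snp", "a1", "a2", "maf")

#' @noRd
check_frq <- function(frq, arg = "frq") {
  if (!is.data.frame(frq) || !all(FRQ_COLS %in% names(frq))) {
    abort(paste0(
      "`", arg, "` must be an allele-frequency table with columns ",
      paste0("`", FRQ_COLS, "`", collapse = ", "),
      " (see `read_frq()` / `simulate_frq_panel()`)."
    ))
  }
  if (anyDuplicated(frq$snp) > 0) {
    abort(paste0("`", arg, "` contains duplicated SNP ids."))
  }
  invisible(frq)
}

# Loci usable by the estimator: frequency strictly inside (0, 1).
#' @noRd
usable_frq <- function(frq) {
  dplyr::filter(frq, .data$maf > 0, .data$maf < 1)
}

#' @noRd
allele_to_code <- function(allele, a1, a2) {
  out <- rep(NA_integer_, length(allele))
  out[!is.na(allele) & allele == a1] <- 1L
  out[!is.na(allele) & allele == a2] <- 2L
  out
}

#' @noRd
code_to_allele <- function(code, a1, a2) {
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & code == 1L] <- a1[!is.na(code) & code == 1L]
  out[!is.na(code) & code == 2L] <- a2[!is.na(code) & code == 2L]
  out
}

# Frequency of the allele actually carried, from the a1 frequency.
#' @noRd
carried_freq <- function(code, p1) {
  ifelse(code == 1L, p1, 1 - p1)
}

#' @noRd
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
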