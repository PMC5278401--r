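# Synthetic fixture generators: frequency panels emulating an ascertained
# common-SNP array, and trio pileup data emulating very low-coverage
# shotgun sequencing (per-locus Bernoulli coverage, mostly 1X depth).

#' Generate a synthetic allele-frequency panel
#'
#' Builds a biallelic SNP panel `rs1..rsN` with random distinct allele
#' pairs and minor-allele frequencies drawn uniformly from
#' `(maf_low, maf_high)` — a simple stand-in for an ascertained common-SNP
#' genotyping panel with external reference frequencies. `a1` is the minor
#' allele and `maf` its frequency.
#'
#' @param n_loci Number of loci (>= 1).
#' @param maf_low,maf_high MAF spectrum bounds; `0 < maf_low < maf_high
#'   <= 0.5` (defaults 0.05 and 0.5).
#' @param chrom Chromosome label written for every locus.
#' @return An allele-frequency tibble (`chrom`, `snp`, `a1`, `a2`, `maf`)
#'   usable everywhere a `.frq`-derived table is.
#' @examples
#' set.seed(1)
#' simulate_frq_panel(5)
#' @export
simulate_frq_panel <- function(n_loci, maf_low = 0.05, maf_high = 0.5,
                               chrom = "1") {
  if (!is_scalar_number(n_loci) || n_loci < 1) {
    abort("`n_loci` must be a single number >= 1.")
  }
  if (!(maf_low > 0 && maf_low < maf_high && maf_high <= 0.5)) {
    abort("Need 0 < maf_low < maf_high <= 0.5.")
  }
  n_loci <- as.integer(n_loci)
  first <- sample(VALID_BASES, n_loci, replace = TRUE)
  shift <- sample.int(3L, n_loci, replace = TRUE)
  second <- VALID_BASES[((match(first, VALID_BASES) - 1L + shift) %% 4L) + 1L]
  tibble(
    chrom = chrom,
    snp = paste0("rs", seq_len(n_loci)),
    a1 = first,
    a2 = second,
    maf = runif(n_loci, maf_low, maf_high)
  )
}

# Pedigrees realizable for the supported trio structures, as functions of
# founder draws; returns diploid code lists for A, B, C.
#' @noRd
sim_trio_codes <- function(p1, structure) {
  L <- length(p1)
  if (structure == "avuncular") {
    # A is the full sibling of B and C's parent: A-B and A-C second order,
    # B-C first order (the (2nd, 2nd, 1st) structure).
    g1 <- draw_founder(p1); g2 <- draw_founder(p1)
    a <- draw_child(g1, g2, L)
    par <- draw_child(g1, g2, L)
    spouse <- draw_founder(p1)
    b <- draw_child(par, spouse, L)
    c <- draw_child(par, spouse, L)
  } else if (structure == "siblings") {
    p <- draw_founder(p1); q <- draw_founder(p1)
    a <- draw_child(p, q, L); b <- draw_child(p, q, L)
    c <- draw_child(p, q, L)
  } else if (structure == "unrelated") {
    a <- draw_founder(p1); b <- draw_founder(p1); c <- draw_founder(p1)
  } else {
    abort(paste0("Unknown trio structure '", structure, "'."))
  }
  list(a = a, b = b, c = c)
}

#' True dyad classes implied by a trio structure
#'
#' @param structure One of `"avuncular"`, `"siblings"`, `"unrelated"`.
#' @return Named character vector of relatedness classes for dyads `ab`,
#'   `ac`, `bc`.
#' @export
trio_structure_classes <- function(structure = c("avuncular", "siblings",
                                                 "unrelated")) {
  structure <- arg_match(structure)
  switch(structure,
    avuncular = c(ab = "second_order", ac = "second_order",
                  bc = "first_order"),
    siblings = c(ab = "first_order", ac = "first_order", bc = "first_order"),
    unrelated = c(ab = "unrelated", ac = "unrelated", bc = "unrelated")
  )
}

#' Generate a low-coverage trio pileup fixture
#'
#' Simulates a pedigree realizing a trio structure on a frequency panel,
#' thins each individual's loci with an independent per-locus Bernoulli
#' coverage model (the faithful reduction of sparse shotgun coverage, where
#' almost every covered site has depth 1), emits per-site read calls with
#' phred qualities, and records the ground truth. Read bases are always
#' true alleles of the carrier (sequencing-error injection is out of
#' scope); a small fraction of sites receives a second read so that the
#' random-selection path of [force_site()] is exercised.
#'
#' @param frq Allele-frequency panel; its size times the product of two hit
#'   probabilities sets the expected shared-locus count of a dyad.
#' @param structure Trio structure (see [trio_structure_classes()]).
#' @param hit_prob Length-3 numeric: per-locus coverage probability for A,
#'   B, C. The defaults mimic genome coverages of a degraded sample versus
#'   two modern ones.
#' @param p_extra_read Probability that a covered locus carries a second
#'   read.
#' @param p_lowqual Probability that a read's quality falls below 30 (it is
#'   then drawn from 2..29, else from 30..45).
#' @param ids Sample identifiers.
#' @param dir Optional directory; when given, one pileup TSV per individual
#'   (`<id>.pileup.tsv`) and a `truth.json` are written there.
#' @return A list of class `trio_fixture`: `pileups` (named list of call
#'   tibbles), `truth` (list: `structure`, `classes`, `genotypes` — the
#'   true diploid tibbles — `covered` — per-individual covered SNP ids —
#'   `callable` — per-individual SNP ids with at least one read of quality
#'   >= 30 — and `shared_callable` — per-dyad counts of loci callable in
#'   both members), and `paths` when `dir` was given.
#' @export
simulate_trio_pileups <- function(frq, structure = c("avuncular", "siblings",
                                                     "unrelated"),
                                  hit_prob = c(0.049, 0.097, 0.119),
                                  p_extra_read = 0.02, p_lowqual = 0.05,
                                  ids = c("A", "B", "C"), dir = NULL) {
  check_frq(frq)
  structure <- arg_match(structure)
  stopifnot(length(hit_prob) == 3, all(hit_prob > 0 & hit_prob <= 1),
            length(ids) == 3)
  frq <- usable_frq(frq)
  p1 <- frq$maf
  L <- length(p1)
  trio <- sim_trio_codes(p1, structure)

  one_individual <- function(ind, hp, id) {
    covered <- which(runif(L) < hp)
    depth <- 1L + rbinom(length(covered), 1L, p_extra_read)
    snp <- rep(frq$snp[covered], depth)
    loc <- rep(covered, depth)
    pick <- runif(length(loc)) < 0.5
    codes <- ifelse(pick, ind$a[loc], ind$b[loc])
    base <- code_to_allele(codes, frq$a1[loc], frq$a2[loc])
    low <- runif(length(loc)) < p_lowqual
    qual <- ifelse(low,
                   sample(2:29, length(loc), replace = TRUE),
                   sample(30:45, length(loc), replace = TRUE))
    calls <- tibble(snp = snp, base = base, qual = as.integer(qual))
    attr(calls, "sites") <- frq$snp[covered]
    ok <- unique(calls$snp[calls$qual >= 30])
    geno <- tibble(
      sample = id, snp = frq$snp,
      allele1 = code_to_allele(ind$a, frq$a1, frq$a2),
      allele2 = code_to_allele(ind$b, frq$a1, frq$a2)
    )
    list(calls = calls, covered = frq$snp[covered], callable = ok,
         geno = geno)
  }

  made <- purrr::pmap(list(trio, hit_prob, ids), one_individual)
  names(made) <- ids
  callable <- purrr::map(made, "callable")
  shared_callable <- c(
    ab = length(intersect(callable[[1]], callable[[2]])),
    ac = length(intersect(callable[[1]], callable[[3]])),
    bc = length(intersect(callable[[2]], callable[[3]]))
  )
  out <- structure(
    list(
      pileups = purrr::map(made, "calls"),
      truth = list(
        structure = structure,
        classes = trio_structure_classes(structure),
        genotypes = purrr::map(made, "geno"),
        covered = purrr::map(made, "covered"),
        callable = callable,
        shared_callable = shared_callable
      )
    ),
    class = "trio_fixture"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- setNames(file.path(dir, paste0(ids, ".pileup.tsv")), ids)
    purrr::walk2(out$pileups, paths, write_pileup)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(structure = structure,
           classes = as.list(out$truth$classes),
           covered = purrr::map(out$truth$covered, identity),
           callable = purrr::map(out$truth$callable, identity),
           shared_callable = as.list(shared_callable)),
      truth_path, auto_unbox = TRUE, digits = NA
    )
    out$paths <- c(as.list(paths), truth = truth_path)
  }
  out
}
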