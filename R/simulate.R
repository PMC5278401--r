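# Gene-dropping simulator for calibrating the forced-homozygote estimator.
#
# Dyads of a stated relatedness class are simulated from a frequency panel:
# founders are drawn in Hardy-Weinberg proportions, relatives are produced
# by Mendelian segregation (one allele from each parent, independently
# across loci; loci are unlinked), the final dyad members are forced
# pseudo-haploid, and Rxy is evaluated against the generating frequencies.
# Repeating this for many dyads gives the empirical Rxy distribution for a
# class, against which an observed coefficient is scored.

RELATEDNESS_CLASSES <- c("unrelated", "first_order", "second_order")

#' The three calibrated relatedness classes
#'
#' @return A tibble with one row per class: `class`, `expected_forced_rxy`
#'   (0, 0.25, 0.125) and `expected_diploid_rxy` (0, 0.5, 0.25). Forcing a
#'   single allele per locus interrogates half the genome, so every forced
#'   expectation is half its diploid counterpart.
#' @export
relatedness_classes <- function() {
  tibble(
    class = RELATEDNESS_CLASSES,
    expected_forced_rxy = c(0, 0.25, 0.125),
    expected_diploid_rxy = c(0, 0.5, 0.25)
  )
}

# ---- internal code-space cores ------------------------------------------

# A founder gamete: allele code 1 with probability p1, per locus.
#' @noRd
draw_gamete <- function(p1) {
  ifelse(runif(length(p1)) < p1, 1L, 2L)
}

#' @noRd
draw_founder <- function(p1) {
  list(a = draw_gamete(p1), b = draw_gamete(p1))
}

# Mendelian segregation: one uniformly chosen allele from each parent.
#' @noRd
draw_child <- function(par1, par2, L) {
  g1 <- ifelse(runif(L) < 0.5, par1$a, par1$b)
  g2 <- ifelse(runif(L) < 0.5, par2$a, par2$b)
  list(a = g1, b = g2)
}

#' @noRd
force_codes <- function(ind, L) {
  ifelse(runif(L) < 0.5, ind$a, ind$b)
}

#' @noRd
sim_dyad_codes <- function(p1, class, first_order = "full_sibling") {
  L <- length(p1)
  if (class == "unrelated") {
    x <- draw_founder(p1)
    y <- draw_founder(p1)
  } else if (class == "first_order") {
    p1_ <- draw_founder(p1)
    p2_ <- draw_founder(p1)
    if (first_order == "full_sibling") {
      x <- draw_child(p1_, p2_, L)
      y <- draw_child(p1_, p2_, L)
    } else { # parent_offspring
      x <- p1_
      y <- draw_child(p1_, p2_, L)
    }
  } else if (class == "second_order") {
    shared <- draw_founder(p1)
    x <- draw_child(shared, draw_founder(p1), L)
    y <- draw_child(shared, draw_founder(p1), L)
  } else {
    abort(paste0("Unknown relatedness class '", class, "'."))
  }
  list(x = x, y = y)
}

# ---- exported tibble-facing surface -------------------------------------

#' Simulate unrelated individuals in Hardy-Weinberg proportions
#'
#' At each panel locus two alleles are drawn independently, allele `a1`
#' with probability `maf`, so genotype frequencies follow p^2 / 2pq / q^2.
#'
#' @param frq Allele-frequency tibble; all loci must have `maf` strictly in
#'   (0, 1).
#' @param n Number of individuals.
#' @param ids Sample identifiers (default `sim_1`, ..., `sim_n`).
#' @return A long diploid genotype tibble: `sample`, `snp`, `allele1`,
#'   `allele2`.
#' @export
simulate_unrelated <- function(frq, n = 1, ids = paste0("sim_", seq_len(n))) {
  check_frq(frq)
  if (any(frq$maf <= 0 | frq$maf >= 1)) {
    abort("All panel frequencies must lie strictly inside (0, 1).")
  }
  stopifnot(length(ids) == n)
  p1 <- frq$maf
  out <- purrr::map(seq_len(n), function(i) {
    ind <- draw_founder(p1)
    tibble(
      sample = ids[i], snp = frq$snp,
      allele1 = code_to_allele(ind$a, frq$a1, frq$a2),
      allele2 = code_to_allele(ind$b, frq$a1, frq$a2)
    )
  })
  bind_rows(out)
}

#' Produce one offspring by Mendelian segregation
#'
#' At every locus one allele is chosen uniformly from each parent,
#' independently across loci (no linkage).
#'
#' @param p1,p2 Single-individual diploid tibbles (`snp`, `allele1`,
#'   `allele2`) on identical locus panels (same SNPs, same order).
#' @param id Sample id of the offspring.
#' @return A diploid genotype tibble for the offspring; `allele1` is the
#'   maternal (`p1`) allele, `allele2` the paternal (`p2`) allele.
#' @export
mendelian_offspring <- function(p1, p2, id = "offspring") {
  for (g in list(p1, p2)) {
    if (!all(c("snp", "allele1", "allele2") %in% names(g))) {
      abort("Parents must have columns `snp`, `allele1`, `allele2`.")
    }
  }
  if (nrow(p1) != nrow(p2) || !identical(p1$snp, p2$snp)) {
    abort("Parental locus panels do not match.")
  }
  L <- nrow(p1)
  from1 <- ifelse(runif(L) < 0.5, p1$allele1, p1$allele2)
  from2 <- ifelse(runif(L) < 0.5, p2$allele1, p2$allele2)
  tibble(sample = id, snp = p1$snp, allele1 = from1, allele2 = from2)
}

#' Simulate one dyad of a given relatedness class
#'
#' Unrelated: two independent Hardy-Weinberg founders. First order: two
#' offspring of the same two founders (full siblings; set
#' `first_order = "parent_offspring"` for the other first-order structure,
#' which has the same expectation but lower variance). Second order: half
#' siblings — offspring of one shared founder paired with two different
#' unrelated founders. With `forced = TRUE` (the default) both members are
#' reduced to pseudo-haploid calls.
#'
#' @param frq Allele-frequency tibble with all `maf` strictly in (0, 1).
#' @param class One of `"unrelated"`, `"first_order"`, `"second_order"`.
#' @param forced Reduce both members to one random allele per locus?
#' @param first_order `"full_sibling"` (default) or `"parent_offspring"`.
#' @return A tibble with `sample` in `c("x", "y")`: columns `sample`,
#'   `snp`, `allele` when forced, or `sample`, `snp`, `allele1`, `allele2`
#'   when diploid.
#' @export
simulate_dyad <- function(frq, class = RELATEDNESS_CLASSES, forced = TRUE,
                          first_order = c("full_sibling", "parent_offspring")) {
  check_frq(frq)
  class <- arg_match(class, RELATEDNESS_CLASSES)
  first_order <- arg_match(first_order)
  if (any(frq$maf <= 0 | frq$maf >= 1)) {
    abort("All panel frequencies must lie strictly inside (0, 1).")
  }
  p1 <- frq$maf
  L <- length(p1)
  dy <- sim_dyad_codes(p1, class, first_order)
  if (forced) {
    fx <- force_codes(dy$x, L)
    fy <- force_codes(dy$y, L)
    bind_rows(
      tibble(sample = "x", snp = frq$snp,
             allele = code_to_allele(fx, frq$a1, frq$a2)),
      tibble(sample = "y", snp = frq$snp,
             allele = code_to_allele(fy, frq$a1, frq$a2))
    )
  } else {
    bind_rows(
      tibble(sample = "x", snp = frq$snp,
             allele1 = code_to_allele(dy$x$a, frq$a1, frq$a2),
             allele2 = code_to_allele(dy$x$b, frq$a1, frq$a2)),
      tibble(sample = "y", snp = frq$snp,
             allele1 = code_to_allele(dy$y$a, frq$a1, frq$a2),
             allele2 = code_to_allele(dy$y$b, frq$a1, frq$a2))
    )
  }
}

#' Build the empirical Rxy distribution for a relatedness class
#'
#' Simulates `n_dyads` independent dyads of the class on the supplied
#' frequency panel, evaluates Rxy for each (forced pseudo-haploid by
#' default, full diploid with `forced = FALSE`) and fits a normal
#' distribution by maximum likelihood. The resulting distribution is the
#' calibration against which an observed coefficient for the same locus
#' panel is scored.
#'
#' @inheritParams simulate_dyad
#' @param n_dyads Number of simulated dyads (default 2000).
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first and recorded in the result.
#' @param sigma_floor Lower bound applied to the fitted standard deviation.
#' @return An object of class `rxy_distribution`: a list with `class`
#'   (relatedness class label), `samples` (numeric Rxy values), `n_dyads`,
#'   `n_loci`, `forced`, `first_order`, `mu`, `sigma`, `seed`. Methods:
#'   [tidy()], [glance()], [autoplot()], `print()`.
#' @examples
#' frq <- simulate_frq_panel(300)
#' d <- simulate_rxy_distribution(frq, "first_order", n_dyads = 50, seed = 1)
#' glance(d)
#' @export
simulate_rxy_distribution <- function(frq, class = RELATEDNESS_CLASSES,
                                      n_dyads = 2000, forced = TRUE,
                                      first_order = c("full_sibling",
                                                      "parent_offspring"),
                                      seed = NULL, sigma_floor = 1e-6) {
  check_frq(frq)
  class <- arg_match(class, RELATEDNESS_CLASSES)
  first_order <- arg_match(first_order)
  if (!is_scalar_number(n_dyads) || n_dyads < 2) {
    abort("`n_dyads` must be a single number >= 2.")
  }
  if (!is.null(seed)) set.seed(seed)
  frq <- usable_frq(frq)
  if (nrow(frq) == 0) abort("No polymorphic locus in `frq`.")
  p1 <- frq$maf
  L <- length(p1)

  samples <- vapply(seq_len(n_dyads), function(i) {
    dy <- sim_dyad_codes(p1, class, first_order)
    acc <- if (forced) {
      rxy_codes_forced(force_codes(dy$x, L), force_codes(dy$y, L), p1)
    } else {
      rxy_codes_general(dy$x$a, dy$x$b, dy$y$a, dy$y$b, p1)
    }
    acc$num_sum / acc$den_sum
  }, numeric(1))

  fit <- fit_normal(samples, sigma_floor = sigma_floor)
  structure(
    list(
      class = class, samples = samples, n_dyads = as.integer(n_dyads),
      n_loci = L, forced = forced, first_order = first_order,
      mu = fit$mu, sigma = fit$sigma,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "rxy_distribution"
  )
}

#' @export
print.rxy_distribution <- function(x, ...) {
  cat(sprintf(
    "<rxy_distribution> class=%s %s | %d dyads x %d loci | mu=%.4f sigma=%.4f\n",
    x$class, if (x$forced) "(forced pseudo-haploid)" else "(diploid)",
    x$n_dyads, x$n_loci, x$mu, x$sigma
  ))
  invisible(x)
}

#' @describeIn simulate_rxy_distribution One row per simulated dyad
#'   (`class`, `rxy`).
#' @param x An `rxy_distribution`.
#' @param ... Unused.
#' @export
tidy.rxy_distribution <- function(x, ...) {
  tibble(class = x$class, rxy = x$samples)
}

#' @describeIn simulate_rxy_distribution One-row summary (`class`,
#'   `n_dyads`, `n_loci`, `forced`, `mu`, `sigma`, `seed`).
#' @export
glance.rxy_distribution <- function(x, ...) {
  tibble(
    class = x$class, n_dyads = x$n_dyads, n_loci = x$n_loci,
    forced = x$forced, mu = x$mu, sigma = x$sigma, seed = x$seed
  )
}

#' Serialize an empirical Rxy distribution to JSON
#'
#' @param dist An `rxy_distribution`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distribution_json <- function(dist, path) {
  stopifnot(inherits(dist, "rxy_distribution"))
  jsonlite::write_json(
    list(
      class = dist$class, n_dyads = dist$n_dyads, n_loci = dist$n_loci,
      forced = dist$forced, seed = dist$seed, mu = dist$mu,
      sigma = dist$sigma, samples = dist$samples
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
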