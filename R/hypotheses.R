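# Likelihood framework for three-individual relationship hypotheses.
#
# Each dyad of a trio gets its own empirical Rxy distributions (its shared
# locus panel differs, so its calibration differs) summarised by a fitted
# normal (mu, sigma).  A hypothesis assigns a named relationship to each
# dyad; its log-likelihood is the sum over dyads of the log normal density
# of the observed Rxy under the class the relationship maps to.  Posterior
# probabilities follow from a (default flat) prior via log-sum-exp.

DYADS <- c("ab", "ac", "bc")

RELATIONSHIP_CLASS <- c(
  "Unrelated" = "unrelated",
  "Parent" = "first_order",
  "Full Sibling" = "first_order",
  "Uncle" = "second_order",
  "Half Sibling" = "second_order"
)

#' Map a named relationship to its relatedness class
#'
#' `Parent` and `Full Sibling` are first order; `Uncle` (avuncular) and
#' `Half Sibling` are second order; `Unrelated` is unrelated. Relationships
#' sharing a class are likelihood-equivalent for a single dyad but are kept
#' distinct in the hypothesis set.
#'
#' @param rel Character vector of relationship names.
#' @return Character vector of class labels.
#' @export
relationship_class <- function(rel) {
  bad <- setdiff(unique(rel), names(RELATIONSHIP_CLASS))
  if (length(bad) > 0) {
    abort(paste0("Unknown relationship name(s): ",
                 paste0("'", bad, "'", collapse = ", "), "."))
  }
  unname(RELATIONSHIP_CLASS[rel])
}

#' The default set of eleven trio relationship hypotheses
#'
#' All combinations of full-sibling/parental and half-sibling/avuncular
#' relationships consistent with a trio in which individual A is tested
#' against a pair (B, C) of putative relatives. Dyads are labelled
#' `ab` (A-B), `ac` (A-C) and `bc` (B-C).
#'
#' @return An 11-row tibble: `hypothesis` (1-11), `rel_ab`, `rel_ac`,
#'   `rel_bc` (relationship names), `class_ab`, `class_ac`, `class_bc`
#'   (relatedness classes).
#' @export
default_hypotheses <- function() {
  h <- tibble(
    hypothesis = 1:11,
    rel_ab = c("Unrelated", "Unrelated", "Unrelated", "Uncle", "Parent",
               "Parent", "Uncle", "Parent", "Uncle", "Unrelated",
               "Unrelated"),
    rel_ac = c("Unrelated", "Unrelated", "Unrelated", "Uncle", "Parent",
               "Uncle", "Parent", "Unrelated", "Unrelated", "Parent",
               "Uncle"),
    rel_bc = c("Unrelated", "Full Sibling", "Half Sibling", "Full Sibling",
               "Full Sibling", "Half Sibling", "Half Sibling", "Unrelated",
               "Unrelated", "Unrelated", "Unrelated")
  )
  mutate(
    h,
    class_ab = relationship_class(.data$rel_ab),
    class_ac = relationship_class(.data$rel_ac),
    class_bc = relationship_class(.data$rel_bc)
  )
}

#' Fit a normal distribution by maximum likelihood
#'
#' `mu` is the sample mean and `sigma` the maximum-likelihood standard
#' deviation (divisor n, not n - 1), floored at `sigma_floor` so that a
#' degenerate sample still yields a proper density.
#'
#' @param x Numeric vector of at least two values, or an
#'   `rxy_distribution`.
#' @param sigma_floor Lower bound on `sigma` (default 1e-6).
#' @return A one-row tibble: `mu`, `sigma`, `n`.
#' @examples
#' fit_normal(c(0.1, 0.3)) # mu 0.2, sigma 0.1
#' @export
fit_normal <- function(x, sigma_floor = 1e-6) {
  if (inherits(x, "rxy_distribution")) x <- x$samples
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric vector with at least 2 values.")
  }
  mu <- mean(x)
  sigma <- max(sqrt(mean((x - mu)^2)), sigma_floor)
  tibble(mu = mu, sigma = sigma, n = length(x))
}

#' Fit dyad-specific class distributions for a trio
#'
#' Builds, for each dyad of a trio, the empirical Rxy distribution of every
#' relatedness class on that dyad's own locus panel, and fits a normal to
#' each — nine simulated data sets in total for the default three classes.
#'
#' @param frq_panels Named list of allele-frequency tibbles, names `ab`,
#'   `ac`, `bc`: each dyad's shared-locus panel.
#' @param n_dyads Simulated dyads per class per dyad (default 2000).
#' @param classes Relatedness classes to calibrate.
#' @param ... Passed to [simulate_rxy_distribution()] (e.g. `first_order`,
#'   `sigma_floor`).
#' @return A tibble with one row per dyad x class: `dyad`, `class`, `mu`,
#'   `sigma`, `n_loci`, `n_dyads`, and a list-column `dist` holding each
#'   `rxy_distribution`.
#' @export
trio_fit_distributions <- function(frq_panels, n_dyads = 2000,
                                   classes = RELATEDNESS_CLASSES, ...) {
  if (!is.list(frq_panels) || !all(DYADS %in% names(frq_panels))) {
    abort("`frq_panels` must be a named list with elements `ab`, `ac`, `bc`.")
  }
  grid <- tidyr::expand_grid(dyad = DYADS, class = classes)
  dists <- purrr::map2(grid$dyad, grid$class, function(d, cl) {
    simulate_rxy_distribution(frq_panels[[d]], class = cl,
                              n_dyads = n_dyads, forced = TRUE, ...)
  })
  mutate(
    grid,
    mu = purrr::map_dbl(dists, "mu"),
    sigma = purrr::map_dbl(dists, "sigma"),
    n_loci = purrr::map_int(dists, "n_loci"),
    n_dyads = purrr::map_int(dists, "n_dyads"),
    dist = dists
  )
}

#' @noRd
check_fits <- function(fits) {
  if (!is.data.frame(fits) ||
      !all(c("dyad", "class", "mu", "sigma") %in% names(fits))) {
    abort("`fits` must have columns `dyad`, `class`, `mu`, `sigma`.")
  }
  invisible(fits)
}

#' @noRd
check_observed <- function(observed) {
  if (!is.numeric(observed) || !all(DYADS %in% names(observed))) {
    abort("`observed` must be a numeric vector with names `ab`, `ac`, `bc`.")
  }
  observed[DYADS]
}

#' Log-likelihood of trio hypotheses
#'
#' For each hypothesis, sums over the three dyads the natural-log normal
#' density of the observed Rxy under the fitted distribution of the class
#' that hypothesis assigns to the dyad. Densities can exceed 1, so the
#' log-likelihood may be positive.
#'
#' @param hypotheses Hypothesis tibble, e.g. [default_hypotheses()].
#' @param observed Named numeric vector of observed Rxy values (`ab`, `ac`,
#'   `bc`).
#' @param fits Fitted distributions per dyad and class, e.g. from
#'   [trio_fit_distributions()].
#' @return `hypotheses` with an added `lnl` column.
#' @export
trio_lnl <- function(hypotheses, observed, fits) {
  observed <- check_observed(observed)
  check_fits(fits)
  look <- function(d, cl) {
    row <- fits[fits$dyad == d & fits$class == cl, ]
    if (nrow(row) != 1) {
      abort(paste0("No fitted distribution for dyad '", d, "', class '",
                   cl, "'."))
    }
    dnorm(observed[[d]], mean = row$mu, sd = row$sigma, log = TRUE)
  }
  lnl <- vapply(seq_len(nrow(hypotheses)), function(i) {
    look("ab", hypotheses$class_ab[i]) +
      look("ac", hypotheses$class_ac[i]) +
      look("bc", hypotheses$class_bc[i])
  }, numeric(1))
  mutate(hypotheses, lnl = lnl)
}

#' Posterior probabilities from log-likelihoods
#'
#' Normalizes `prior * exp(lnl)` over hypotheses through a log-sum-exp
#' scheme, so the result is invariant to adding any constant to all
#' log-likelihoods and never overflows.
#'
#' @param lnl Numeric vector of finite log-likelihoods.
#' @param prior Optional non-negative prior weights (default flat); need
#'   not be normalized.
#' @return Numeric vector of posterior probabilities summing to 1.
#' @export
posteriors <- function(lnl, prior = NULL) {
  if (length(lnl) < 1 || !all(is.finite(lnl))) {
    abort("`lnl` must be a non-empty vector of finite values.")
  }
  if (is.null(prior)) prior <- rep(1, length(lnl))
  if (length(prior) != length(lnl) || any(prior < 0) || sum(prior) == 0) {
    abort("`prior` must be non-negative weights with a positive sum.")
  }
  lp <- lnl + log(prior)
  lp[prior == 0] <- -Inf
  m <- max(lp)
  w <- exp(lp - m)
  w / sum(w)
}

#' Odds ratio between two sets of hypotheses
#'
#' Ratio of summed posterior probabilities of two disjoint hypothesis
#' subsets.
#'
#' @param scored Tibble with columns `hypothesis` and `posterior` (e.g.
#'   `tidy()` of a trio report).
#' @param a,b Disjoint, non-empty vectors of hypothesis ids.
#' @return A one-row tibble: `odds`, `posterior_a`, `posterior_b`,
#'   `divergent` (`TRUE` when the denominator is zero and `odds` is
#'   `Inf`).
#' @export
odds_ratio <- function(scored, a, b) {
  if (!all(c("hypothesis", "posterior") %in% names(scored))) {
    abort("`scored` must have columns `hypothesis` and `posterior`.")
  }
  if (length(a) == 0 || length(b) == 0) abort("`a` and `b` must be non-empty.")
  if (length(intersect(a, b)) > 0) abort("`a` and `b` must be disjoint.")
  missing <- setdiff(c(a, b), scored$hypothesis)
  if (length(missing) > 0) {
    abort(paste0("Unknown hypothesis id(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  pa <- sum(scored$posterior[scored$hypothesis %in% a])
  pb <- sum(scored$posterior[scored$hypothesis %in% b])
  tibble(
    odds = if (pb == 0) Inf else pa / pb,
    posterior_a = pa, posterior_b = pb,
    divergent = pb == 0
  )
}

#' Score trio relationship hypotheses
#'
#' Combines observed per-dyad Rxy coefficients with dyad-specific fitted
#' class distributions into per-hypothesis log-likelihoods and posterior
#' probabilities.
#'
#' @param observed Named numeric vector (`ab`, `ac`, `bc`) of observed Rxy.
#' @param fits Fitted distributions (see [trio_fit_distributions()]).
#' @param hypotheses Hypothesis set (default [default_hypotheses()]).
#' @param prior Optional prior weights over hypotheses (default flat).
#' @return An object of class `trio_report`: list with `observed`, `fits`,
#'   `table` (hypotheses + `lnl` + `posterior`), `top` (the top-ranked
#'   hypothesis row) and `prior`. Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#' @export
trio_test <- function(observed, fits, hypotheses = default_hypotheses(),
                      prior = NULL) {
  observed <- check_observed(observed)
  scored <- trio_lnl(hypotheses, observed, fits)
  scored <- mutate(scored, posterior = posteriors(.data$lnl, prior))
  top <- scored[which.max(scored$posterior), ]
  structure(
    list(
      observed = observed,
      fits = select(fits, !dplyr::any_of("dist")),
      table = scored, top = top, prior = prior
    ),
    class = "trio_report"
  )
}

#' @export
print.trio_report <- function(x, ...) {
  cat("<trio_report>\n")
  cat(sprintf("  observed Rxy: ab=%.4f ac=%.4f bc=%.4f\n",
              x$observed[["ab"]], x$observed[["ac"]], x$observed[["bc"]]))
  cat(sprintf(
    "  top hypothesis %d (%s / %s / %s), posterior %.6g\n",
    x$top$hypothesis, x$top$rel_ab, x$top$rel_ac, x$top$rel_bc,
    x$top$posterior
  ))
  print(select(x$table, "hypothesis", "rel_ab", "rel_ac", "rel_bc",
               "lnl", "posterior"))
  invisible(x)
}

#' @describeIn trio_test The full scored hypothesis table.
#' @param x A `trio_report`.
#' @param ... Unused.
#' @export
tidy.trio_report <- function(x, ...) {
  as_tibble(x$table)
}

#' @describeIn trio_test One-row summary: top hypothesis, its relationships,
#'   `lnl`, `posterior`, and `p_other` = 1 - posterior.
#' @export
glance.trio_report <- function(x, ...) {
  tibble(
    top_hypothesis = x$top$hypothesis,
    rel_ab = x$top$rel_ab, rel_ac = x$top$rel_ac, rel_bc = x$top$rel_bc,
    lnl = x$top$lnl, posterior = x$top$posterior,
    p_other = 1 - x$top$posterior
  )
}

#' Serialize a trio report to JSON
#'
#' @param report A `trio_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trio_json <- function(report, path) {
  stopifnot(inherits(report, "trio_report"))
  jsonlite::write_json(
    list(
      observed = as.list(report$observed),
      fits = report$fits,
      hypotheses = report$table,
      top_hypothesis = report$top$hypothesis,
      top_posterior = report$top$posterior
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Full trio analysis from pseudo-haploid genotypes
#'
#' Runs the complete inference for three individuals: intersects each dyad
#' on its shared usable loci, computes the forced-homozygote Rxy, simulates
#' the three class distributions on each dyad's own shared panel, and
#' scores the hypothesis set.
#'
#' @param ga,gb,gc Pseudo-haploid genotype tibbles (`snp`, `allele`,
#'   optionally `sample`) for individuals A, B, C.
#' @param frq Reference allele-frequency tibble.
#' @param n_dyads Simulated dyads per class per dyad (default 2000).
#' @param hypotheses Hypothesis set (default [default_hypotheses()]).
#' @param prior Optional prior weights.
#' @param ... Passed to [simulate_rxy_distribution()].
#' @return A `trio_report` whose `observed` carries an `"n_loci"` attribute
#'   with the per-dyad shared-locus counts.
#' @export
trio_analysis <- function(ga, gb, gc, frq, n_dyads = 2000,
                          hypotheses = default_hypotheses(), prior = NULL,
                          ...) {
  check_frq(frq)
  pairs <- list(ab = list(ga, gb), ac = list(ga, gc), bc = list(gb, gc))
  dyads <- purrr::map(pairs, function(p) intersect_dyad(p[[1]], p[[2]], frq))
  est <- purrr::map(dyads, rxy_forced)
  observed <- vapply(est, function(e) e$rxy, numeric(1))
  names(observed) <- names(dyads)
  panels <- purrr::map(dyads, function(d) semi_join(frq, d, by = "snp"))
  fits <- trio_fit_distributions(panels, n_dyads = n_dyads, ...)
  report <- trio_test(observed, fits, hypotheses = hypotheses, prior = prior)
  attr(report$observed, "n_loci") <-
    vapply(est, function(e) e$n_loci, integer(1))
  report
}
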