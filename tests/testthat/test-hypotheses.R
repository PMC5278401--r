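test_that("fit_normal uses the maximum-likelihood divisor and a floor", {
  f <- fit_normal(c(0.1, 0.3))
  expect_equal(f$mu, 0.2)
  expect_equal(f$sigma, 0.1)  # ML divisor n = 2

  f0 <- fit_normal(c(0, 0, 0))
  expect_equal(f0$mu, 0)
  expect_equal(f0$sigma, 1e-6)

  expect_error(fit_normal(0.5), "at least 2")

  set.seed(10)
  x <- rnorm(2000, 0.25, 0.03)
  f2 <- fit_normal(x)
  expect_lt(abs(f2$mu - 0.25), 4 * 0.03 / sqrt(2000))
  expect_lt(abs(f2$sigma - 0.03), 4 * 0.03 / sqrt(2 * 2000))
})

test_that("the default hypothesis set has the canonical eleven rows", {
  h <- default_hypotheses()
  expect_equal(nrow(h), 11L)
  expect_equal(h$hypothesis, 1:11)
  expect_equal(unname(unlist(h[1, c("rel_ab", "rel_ac", "rel_bc")])),
               rep("Unrelated", 3))
  expect_equal(unname(unlist(h[4, c("rel_ab", "rel_ac", "rel_bc")])),
               c("Uncle", "Uncle", "Full Sibling"))
  expect_equal(unname(unlist(h[4, c("class_ab", "class_ac", "class_bc")])),
               c("second_order", "second_order", "first_order"))
  expect_equal(unname(unlist(h[5, c("rel_ab", "rel_ac", "rel_bc")])),
               c("Parent", "Parent", "Full Sibling"))
})

test_that("relationship names map to their relatedness classes", {
  expect_equal(relationship_class(c("Parent", "Full Sibling")),
               c("first_order", "first_order"))
  expect_equal(relationship_class(c("Uncle", "Half Sibling")),
               c("second_order", "second_order"))
  expect_equal(relationship_class("Unrelated"), "unrelated")
  expect_error(relationship_class("Cousin"), "Unknown relationship")
})

test_that("trio_lnl matches closed-form normal densities", {
  h <- default_hypotheses()[4, ]
  obs <- c(ab = 0.12, ac = 0.13, bc = 0.27)
  # observed exactly at each mu with sd (2*pi)^(-1/2): unit density x3
  fits <- tidyr::expand_grid(dyad = c("ab", "ac", "bc"),
                             class = c("unrelated", "first_order",
                                       "second_order"))
  fits$mu <- ifelse(fits$dyad == "ab", 0.12,
                    ifelse(fits$dyad == "ac", 0.13, 0.27))
  fits$sigma <- (2 * pi)^(-1 / 2)
  expect_equal(trio_lnl(h, obs, fits)$lnl, 0)

  fits$sigma <- 0.03
  expect_equal(trio_lnl(h, obs, fits)$lnl,
               3 * log(1 / (0.03 * sqrt(2 * pi))))

  expect_error(trio_lnl(h, obs, fits[fits$class != "first_order", ]),
               "No fitted distribution")
})

test_that("posteriors normalize, are shift-invariant, honour priors", {
  p <- posteriors(rep(-3.2, 11))
  expect_equal(p, rep(1 / 11, 11))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  set.seed(14)
  lnl <- rnorm(11, sd = 20)
  expect_equal(posteriors(lnl), posteriors(lnl + 123.456), tolerance = 1e-12)
  # extreme magnitudes do not overflow
  expect_equal(sum(posteriors(lnl + 5000)), 1)

  pr <- c(2, rep(0, 10))
  expect_equal(posteriors(lnl, pr), c(1, rep(0, 10)))
  expect_error(posteriors(lnl, rep(0, 11)), "positive sum")
  expect_error(posteriors(c(1, NA, 2)), "finite")
})

test_that("odds_ratio sums disjoint subsets and flags divergence", {
  scored <- tibble::tibble(hypothesis = 1:4,
                           posterior = c(0.25, 0.25, 0.5, 0))
  o <- odds_ratio(scored, a = 1, b = 2)
  expect_equal(o$odds, 1)
  expect_false(o$divergent)
  o2 <- odds_ratio(scored, a = c(1, 3), b = 2)
  expect_equal(o2$odds, 3)
  o3 <- odds_ratio(scored, a = 1, b = 4)
  expect_true(is.infinite(o3$odds))
  expect_true(o3$divergent)
  expect_error(odds_ratio(scored, a = 1, b = 1), "disjoint")
  expect_error(odds_ratio(scored, a = integer(0), b = 1), "non-empty")
})

test_that("trio_test ranks the generating hypothesis first", {
  set.seed(15)
  panels <- list(ab = simulate_frq_panel(400), ac = simulate_frq_panel(500),
                 bc = simulate_frq_panel(600))
  fits <- trio_fit_distributions(panels, n_dyads = 200)
  expect_equal(nrow(fits), 9L)
  report <- trio_test(c(ab = 0.125, ac = 0.125, bc = 0.25), fits)
  expect_s3_class(report, "trio_report")
  expect_equal(report$top$hypothesis, 4L)
  expect_equal(sum(tidy(report)$posterior), 1, tolerance = 1e-12)
  expect_equal(glance(report)$posterior, report$top$posterior)

  path <- withr::local_tempfile(fileext = ".json")
  write_trio_json(report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$top_hypothesis, 4L)
})

test_that("the full pipeline recovers an avuncular trio from pileups", {
  set.seed(16)
  frq <- simulate_frq_panel(15000)
  hits <- 0L
  n_rep <- 4
  for (r in seq_len(n_rep)) {
    fx <- simulate_trio_pileups(frq, "avuncular",
                                hit_prob = c(0.30, 0.32, 0.36))
    ga <- force_pileup(fx$pileups$A, sample_id = "A")
    gb <- force_pileup(fx$pileups$B, sample_id = "B")
    gc_ <- force_pileup(fx$pileups$C, sample_id = "C")
    report <- trio_analysis(ga, gb, gc_, frq, n_dyads = 200)
    expect_true(all(attr(report$observed, "n_loci") > 1000))
    if (report$top$hypothesis == 4L) hits <- hits + 1L
  }
  expect_equal(hits, n_rep)
})
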