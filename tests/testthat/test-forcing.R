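test_that("force_site keeps only qualifying calls", {
  expect_equal(force_site("A", 35), "A")
  expect_equal(force_site(c("A", "G"), c(35, 12)), "A")
  expect_true(is.na(force_site(c("A", "G"), c(20, 25))))
  expect_true(is.na(force_site(character(0), integer(0))))
  # threshold is inclusive
  expect_equal(force_site("A", 30), "A")
  expect_true(is.na(force_site("A", 29)))
})

test_that("force_site picks uniformly among qualifying calls", {
  set.seed(123)
  draws <- replicate(10000, force_site(c("A", "G"), c(40, 40)))
  frac_a <- mean(draws == "A")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("force_pileup accounts for every site and replays force_site", {
  set.seed(11)
  frq <- simulate_frq_panel(500)
  fx <- simulate_trio_pileups(frq, "unrelated", hit_prob = c(0.6, 0.5, 0.5),
                              p_extra_read = 0.3, p_lowqual = 0.3)
  calls <- fx$pileups$A
  sites <- attr(calls, "sites")

  set.seed(42)
  forced <- force_pileup(calls, min_qual = 30, sample_id = "A")
  expect_equal(forced$snp, sites)
  expect_equal(nrow(forced), length(sites))
  expect_equal(sum(is.na(forced$allele)) , attr(forced, "n_dropped"))
  # called + dropped = total sites
  expect_equal(sum(!is.na(forced$allele)) + attr(forced, "n_dropped"),
               length(sites))

  # site-by-site replay with the same seed reproduces every call
  set.seed(42)
  replay <- vapply(sites, function(s) {
    idx <- calls$snp == s
    force_site(calls$base[idx], calls$qual[idx], min_qual = 30)
  }, character(1))
  expect_equal(forced$allele, unname(replay))
})

test_that("force_pileup drops everything below the threshold", {
  calls <- tibble::tibble(snp = c("rs1", "rs2"), base = c("A", "G"),
                          qual = c(10L, 20L))
  forced <- force_pileup(calls, min_qual = 30)
  expect_true(all(is.na(forced$allele)))
  expect_equal(attr(forced, "n_dropped"), 2L)
  # all qualifying at depth 1: everything called, nothing dropped
  forced2 <- force_pileup(tibble::tibble(snp = c("rs1", "rs2"),
                                         base = c("A", "G"),
                                         qual = c(35L, 40L)))
  expect_equal(forced2$allele, c("A", "G"))
  expect_equal(attr(forced2, "n_dropped"), 0L)
})

test_that("force_diploid keeps homozygotes, drops missing, is idempotent", {
  g <- diploid(c("rs1", "rs2", "rs3"), c("A", "A", NA), c("A", "G", NA))
  set.seed(1)
  f <- force_diploid(g)
  expect_equal(f$allele[1], "A")
  expect_true(f$allele[2] %in% c("A", "G"))
  expect_true(is.na(f$allele[3]))
  expect_equal(attr(f, "n_dropped"), 1L)

  # forcing an already-duplicated genotype returns it unchanged
  dup <- duplicate_alleles(f)
  f2 <- force_diploid(dup)
  expect_equal(f2$allele, f$allele)
})

test_that("force_diploid picks each allele with probability one half", {
  set.seed(5)
  g <- diploid(paste0("rs", 1:10000), rep("A", 10000), rep("G", 10000))
  f <- force_diploid(g)
  expect_lt(abs(mean(f$allele == "A") - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("intersect_dyad keeps exactly the usable shared loci", {
  frq <- tiny_frq()
  gx <- haploid(c("rs1", "rs2"), c("A", "C"), id = "s1")
  gy <- haploid(c("rs2", "rs3"), c("T", "G"), id = "s2")
  d <- intersect_dyad(gx, gy, frq)
  expect_equal(d$snp, "rs2")
  expect_equal(d$allele_x, "C")
  expect_equal(d$allele_y, "T")
  expect_equal(attr(d, "id_x"), "s1")
  ex <- attr(d, "exclusions")
  expect_equal(unname(ex["missing_in_one"]), 2L)
})

test_that("monomorphic and off-panel loci are excluded with counts", {
  frq <- tiny_frq()
  frq$maf[2] <- 1.0  # rs2 monomorphic
  gx <- haploid(c("rs1", "rs2", "rs4", "rs99"), c("A", "C", "T", "A"))
  gy <- haploid(c("rs1", "rs2", "rs4", "rs99"), c("G", "C", "G", "A"),
                id = "y")
  d <- intersect_dyad(gx, gy, frq)
  # rs1 kept; rs2 monomorphic; rs4 has off-panel allele G in y; rs99 not in
  # the panel
  expect_equal(d$snp, "rs1")
  ex <- attr(d, "exclusions")
  expect_equal(unname(ex["monomorphic"]), 1L)
  expect_equal(unname(ex["allele_mismatch"]), 1L)
  expect_equal(unname(ex["not_in_panel"]), 1L)
})

test_that("intersect_dyad is symmetric up to label swap and errors when empty", {
  frq <- tiny_frq()
  gx <- haploid(c("rs1", "rs3"), c("A", "G"))
  gy <- haploid(c("rs1", "rs3"), c("G", "A"), id = "y")
  d_xy <- intersect_dyad(gx, gy, frq)
  d_yx <- intersect_dyad(gy, gx, frq)
  expect_equal(d_xy$allele_x, d_yx$allele_y)
  expect_equal(d_xy$allele_y, d_yx$allele_x)
  expect_equal(d_xy$snp, d_yx$snp)

  gz <- haploid("rs5", "A", id = "z")
  expect_error(intersect_dyad(gx, gz, frq), "no shared loci")
})

test_that("planted shared loci are recovered exactly", {
  set.seed(9)
  frq <- simulate_frq_panel(200)
  k <- 57
  shared <- sample(frq$snp, k)
  only_x <- setdiff(frq$snp, shared)[1:40]
  gx <- haploid(c(shared, only_x),
                frq$a1[match(c(shared, only_x), frq$snp)])
  gy <- haploid(shared, frq$a2[match(shared, frq$snp)], id = "y")
  d <- intersect_dyad(gx, gy, frq)
  expect_equal(nrow(d), k)
  expect_setequal(d$snp, shared)
})
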