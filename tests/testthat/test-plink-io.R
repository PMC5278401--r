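test_that("ped/map round-trip is the identity on generated datasets", {
  dir <- withr::local_tempdir()
  set.seed(1)
  frq <- simulate_frq_panel(5)
  geno <- simulate_unrelated(frq, n = 3)
  # plant a missing diploid call
  geno$allele1[4] <- NA
  geno$allele2[4] <- NA
  ped <- file.path(dir, "d.ped")
  map <- file.path(dir, "d.map")
  write_ped_map(geno, ped, map)
  back <- read_ped_map(ped, map)

  expect_equal(back$sample, geno$sample)
  expect_equal(back$snp, geno$snp)
  expect_equal(back$allele1, geno$allele1)
  expect_equal(back$allele2, geno$allele2)
  # loci keep .map order, samples keep .ped order
  expect_equal(unique(back$snp), frq$snp)
  expect_equal(attr(back, "fam")$sample, unique(geno$sample))

  # second round trip is byte-stable
  ped2 <- file.path(dir, "d2.ped")
  map2 <- file.path(dir, "d2.map")
  write_ped_map(back, ped2, map2)
  expect_identical(readLines(ped), readLines(ped2))
  expect_identical(readLines(map), readLines(map2))
})

test_that("read_ped_map parses calls matching the generator's record", {
  dir <- withr::local_tempdir()
  set.seed(1)
  frq <- simulate_frq_panel(5)
  truth <- simulate_unrelated(frq, n = 3)
  write_ped_map(truth, file.path(dir, "t.ped"), file.path(dir, "t.map"))
  got <- read_ped_map(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_equal(got$allele1, truth$allele1)
  expect_equal(got$allele2, truth$allele2)
})

test_that("malformed or duplicated .ped input is rejected with the row", {
  dir <- withr::local_tempdir()
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), file.path(dir, "m.map"))
  # 2*2+5 = 9 fields: one allele short
  writeLines("fam1 s1 0 0 1 -9 A A G", file.path(dir, "bad.ped"))
  expect_error(
    read_ped_map(file.path(dir, "bad.ped"), file.path(dir, "m.map")),
    "row 1"
  )
  writeLines(c("f s1 0 0 1 -9 A A G G", "f s1 0 0 1 -9 A A G G"),
             file.path(dir, "dup.ped"))
  expect_error(
    read_ped_map(file.path(dir, "dup.ped"), file.path(dir, "m.map")),
    "Duplicate sample"
  )
})

test_that("pseudo-haploid genotypes are written with the allele duplicated", {
  dir <- withr::local_tempdir()
  g <- haploid(c("rs1", "rs2"), c("A", NA), id = "s1")
  write_ped_map(g, file.path(dir, "h.ped"), file.path(dir, "h.map"))
  line <- readLines(file.path(dir, "h.ped"))
  expect_match(line, "A A 0 0$")
})

test_that("an empty dataset writes empty files and reads back empty", {
  dir <- withr::local_tempdir()
  g <- tibble::tibble(sample = character(), snp = character(),
                      allele1 = character(), allele2 = character())
  write_ped_map(g, file.path(dir, "e.ped"), file.path(dir, "e.map"))
  expect_identical(readLines(file.path(dir, "e.ped")), character(0))
  expect_identical(readLines(file.path(dir, "e.map")), character(0))
  back <- read_ped_map(file.path(dir, "e.ped"), file.path(dir, "e.map"))
  expect_equal(nrow(back), 0L)
})

test_that("read_frq maps fields directly and validates MAF", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "a.frq")
  writeLines(c("CHR SNP A1 A2 MAF", "1 rs1 A G 0.25"), f)
  frq <- read_frq(f)
  expect_equal(frq$snp, "rs1")
  expect_equal(frq$a1, "A")
  expect_equal(frq$a2, "G")
  expect_equal(frq$maf, 0.25)

  writeLines(c("CHR SNP A1 A2 MAF", "1 rs1 A G 1.2"), f)
  expect_error(read_frq(f), "outside")
  writeLines(c("CHR SNP A1 A2 MAF", "1 rs1 A G x"), f)
  expect_error(read_frq(f), "Non-numeric")
  writeLines("1 rs1 A G 0.25", f)
  expect_error(read_frq(f), "header")
})

test_that("a generated .frq file re-reads to the generator's table", {
  dir <- withr::local_tempdir()
  set.seed(7)
  frq <- simulate_frq_panel(1000)
  f <- file.path(dir, "p.frq")
  write_frq(frq, f)
  back <- read_frq(f)
  expect_equal(nrow(back), 1000L)
  expect_equal(back$maf, frq$maf, tolerance = 1e-9)
  expect_equal(mean(back$maf), mean(frq$maf), tolerance = 1e-9)
  expect_equal(back$a1, frq$a1)
})

test_that("pileup tables parse, validate and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "p.tsv")
  writeLines(c("rs1\tA,G\t35,12", "rs2\tC\t40"), f)
  calls <- read_pileup(f)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$qual, c(35L, 12L, 40L))
  expect_equal(attr(calls, "sites"), c("rs1", "rs2"))

  writeLines("rs1\tA\t35,12", f)
  expect_error(read_pileup(f), "rs1")
  writeLines(c("rs1\tA\t35", "rs1\tG\t20"), f)
  expect_error(read_pileup(f), "Duplicate locus")

  # round trip preserves site order and zero-depth sites
  writeLines(c("rs1\tA,G\t35,12", "rs2\t\t", "rs3\tC\t40"), f)
  calls <- read_pileup(f)
  f2 <- file.path(dir, "p2.tsv")
  write_pileup(calls, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("generated pileup depth histogram matches the generator record", {
  set.seed(3)
  dir <- withr::local_tempdir()
  frq <- simulate_frq_panel(2000)
  fx <- simulate_trio_pileups(frq, "unrelated", hit_prob = c(0.5, 0.5, 0.5),
                              dir = dir)
  back <- read_pileup(file.path(dir, "A.pileup.tsv"))
  hist_file <- table(table(back$snp))
  hist_mem <- table(table(fx$pileups$A$snp))
  expect_equal(hist_file, hist_mem)
  expect_setequal(attr(back, "sites"), fx$truth$covered$A)
})
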