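# Text PLINK (.ped/.map) and .frq readers and writers.
#
# Dialects: .map has four whitespace-separated columns (chromosome, SNP id,
# genetic distance, physical position); .ped has six leading columns
# (family, individual, father, mother, sex, phenotype) followed by two
# allele columns per .map locus, with "0" as the missing-allele code.
# .frq is PLINK's CHR SNP A1 A2 MAF [NCHROBS]; MAF is read as the frequency
# of allele A1.  Coordinates are 1-based; no strand flipping is ever
# performed (alleles that do not match the panel are excluded downstream,
# never complemented).

#' Read a text PLINK genotype dataset
#'
#' Reads a `.ped`/`.map` pair into a long tibble of diploid calls, one row
#' per sample x locus, preserving file order for both. The six leading
#' `.ped` columns (family, individual, father, mother, sex, phenotype) are
#' kept verbatim as the `"fam"` attribute; the full `.map` table (including
#' the genetic-distance column) is kept as the `"map"` attribute so that
#' [write_ped_map()] can round-trip the files field-for-field.
#'
#' @param ped_path Path to the `.ped` file.
#' @param map_path Path to the `.map` file.
#' @return A tibble with columns `sample`, `snp`, `chrom`, `pos`, `allele1`,
#'   `allele2`. The PLINK missing code `"0"` is parsed to `NA`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' frq <- simulate_frq_panel(5)
#' geno <- simulate_unrelated(frq, n = 2)
#' write_ped_map(geno, file.path(dir, "x.ped"), file.path(dir, "x.map"))
#' read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map"))
#' @seealso [write_ped_map()], [read_frq()]
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readr::read_lines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(vapply(map_fields, length, integer(1)) != 4L)
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed .map row ", bad[1], " in '", map_path,
      "': expected 4 whitespace-separated columns."
    ))
  }
  map <- tibble(
    chrom = vapply(map_fields, `[[`, character(1), 1L),
    snp   = vapply(map_fields, `[[`, character(1), 2L),
    cm    = vapply(map_fields, `[[`, character(1), 3L),
    pos   = as.integer(vapply(map_fields, `[[`, character(1), 4L))
  )
  if (anyDuplicated(map$snp) > 0) {
    abort(paste0("Duplicate SNP id in '", map_path, "'."))
  }
  n_loci <- nrow(map)

  ped_lines <- readr::read_lines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  want <- 6L + 2L * n_loci

  fam_raw <- vector("list", n_samp)
  a1m <- matrix(NA_character_, nrow = n_samp, ncol = n_loci)
  a2m <- matrix(NA_character_, nrow = n_samp, ncol = n_loci)
  for (i in seq_len(n_samp)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != want) {
      abort(paste0(
        "Malformed .ped row ", i, " in '", ped_path, "': expected ", want,
        " fields for ", n_loci, " map loci, found ", length(f), "."
      ))
    }
    fam_raw[[i]] <- f[1:6]
    if (n_loci > 0) {
      al <- f[-(1:6)]
      a1m[i, ] <- al[seq(1L, 2L * n_loci, by = 2L)]
      a2m[i, ] <- al[seq(2L, 2L * n_loci, by = 2L)]
    }
  }
  fam_col <- function(k) vapply(fam_raw, `[[`, character(1), k)
  fam <- tibble(
    fam = fam_col(1L), sample = fam_col(2L), father = fam_col(3L),
    mother = fam_col(4L), sex = fam_col(5L), phenotype = fam_col(6L)
  )
  if (n_samp == 0) {
    fam <- tibble(
      fam = character(), sample = character(), father = character(),
      mother = character(), sex = character(), phenotype = character()
    )
  }
  if (anyDuplicated(fam$sample) > 0) {
    abort(paste0("Duplicate sample id in '", ped_path, "'."))
  }
  a1m[a1m == "0"] <- NA_character_
  a2m[a2m == "0"] <- NA_character_

  geno <- tibble(
    sample  = rep(fam$sample, each = n_loci),
    snp     = rep(map$snp, times = n_samp),
    chrom   = rep(map$chrom, times = n_samp),
    pos     = rep(map$pos, times = n_samp),
    allele1 = as.vector(t(a1m)),
    allele2 = as.vector(t(a2m))
  )
  attr(geno, "fam") <- fam
  attr(geno, "map") <- map
  geno
}

#' Write a genotype dataset as text PLINK
#'
#' Inverse of [read_ped_map()]. Accepts either diploid calls (`allele1`,
#' `allele2` columns) or pseudo-haploid calls (a single `allele` column, as
#' produced by the forcing functions), in which case the one allele is
#' written duplicated in both `.ped` columns — the forced-homozygote
#' encoding. Missing calls are written as `0 0`.
#'
#' @param geno Long genotype tibble (`sample`, `snp`, and either
#'   `allele1`/`allele2` or `allele`). `"fam"`/`"map"` attributes from
#'   [read_ped_map()] are honoured when present; otherwise default family
#'   metadata (`fam = sample`, parents/sex `0`, phenotype `-9`) and map rows
#'   (`chrom` and `pos` columns if present, else chromosome 1 and ordinal
#'   positions) are synthesised.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `geno`.
#' @export
write_ped_map <- function(geno, ped_path, map_path) {
  if (!is.data.frame(geno) || !all(c("sample", "snp") %in% names(geno))) {
    abort("`geno` must be a genotype tibble with `sample` and `snp` columns.")
  }
  if ("allele" %in% names(geno) && !"allele1" %in% names(geno)) {
    geno$allele1 <- geno$allele
    geno$allele2 <- geno$allele
  }
  if (!all(c("allele1", "allele2") %in% names(geno))) {
    abort("`geno` must have `allele1`/`allele2` (or a single `allele`) column.")
  }

  map <- attr(geno, "map")
  if (is.null(map)) {
    loci <- distinct(geno, .data$snp, .keep_all = TRUE)
    map <- tibble(
      chrom = if ("chrom" %in% names(loci)) as.character(loci$chrom) else
        rep("1", nrow(loci)),
      snp = loci$snp,
      cm = rep("0", nrow(loci)),
      pos = if ("pos" %in% names(loci)) as.integer(loci$pos) else
        seq_len(nrow(loci))
    )
  }
  fam <- attr(geno, "fam")
  if (is.null(fam)) {
    ids <- unique(geno$sample)
    fam <- tibble(
      fam = ids, sample = ids, father = "0", mother = "0",
      sex = "0", phenotype = "-9"
    )
  }

  n_loci <- nrow(map)
  a1m <- matrix(NA_character_, nrow = nrow(fam), ncol = n_loci,
                dimnames = list(fam$sample, map$snp))
  a2m <- a1m
  if (nrow(geno) > 0) {
    a1m[cbind(geno$sample, geno$snp)] <- geno$allele1
    a2m[cbind(geno$sample, geno$snp)] <- geno$allele2
  }
  a1m[is.na(a1m)] <- "0"
  a2m[is.na(a2m)] <- "0"

  map_lines <- if (n_loci > 0) {
    paste(map$chrom, map$snp, map$cm, map$pos)
  } else character(0)
  readr::write_lines(map_lines, map_path)

  ped_lines <- vapply(seq_len(nrow(fam)), function(i) {
    lead <- paste(fam$fam[i], fam$sample[i], fam$father[i], fam$mother[i],
                  fam$sex[i], fam$phenotype[i])
    if (n_loci == 0) return(lead)
    al <- character(2L * n_loci)
    al[seq(1L, 2L * n_loci, by = 2L)] <- a1m[i, ]
    al[seq(2L, 2L * n_loci, by = 2L)] <- a2m[i, ]
    paste(lead, paste(al, collapse = " "))
  }, character(1))
  readr::write_lines(ped_lines, ped_path)
  invisible(geno)
}

#' Read a PLINK allele-frequency table
#'
#' Parses a `.frq` file (header `CHR SNP A1 A2 MAF`, optionally `NCHROBS`)
#' into the package's allele-frequency tibble. `MAF` is interpreted as the
#' frequency of allele `A1` in the reference population — the `p` terms of
#' the Rxy estimator.
#'
#' @param frq_path Path to the `.frq` file.
#' @return A tibble with columns `chrom`, `snp`, `a1`, `a2`, `maf`, in file
#'   order.
#' @export
read_frq <- function(frq_path) {
  lines <- readr::read_lines(frq_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("'", frq_path, "' is empty: missing .frq header."))
  }
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) < 5 || !all(toupper(hdr[1:5]) == c("CHR", "SNP", "A1", "A2", "MAF"))) {
    abort(paste0(
      "'", frq_path, "' does not start with a CHR SNP A1 A2 MAF header."
    ))
  }
  body <- lines[-1]
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- vapply(fields, length, integer(1))
  bad <- which(nf < 5L)
  if (length(bad) > 0) {
    abort(paste0("Malformed .frq row ", bad[1] + 1L, " in '", frq_path, "'."))
  }
  maf <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  if (anyNA(maf)) {
    abort(paste0(
      "Non-numeric MAF at .frq row ",
      which(is.na(maf))[1] + 1L, " in '", frq_path, "'."
    ))
  }
  if (any(maf < 0 | maf > 1)) {
    abort(paste0(
      "MAF outside [0, 1] at .frq row ",
      which(maf < 0 | maf > 1)[1] + 1L, " in '", frq_path, "'."
    ))
  }
  frq <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1L),
    snp   = vapply(fields, `[[`, character(1), 2L),
    a1    = vapply(fields, `[[`, character(1), 3L),
    a2    = vapply(fields, `[[`, character(1), 4L),
    maf   = maf
  )
  if (length(body) == 0) {
    frq <- tibble(
      chrom = character(), snp = character(), a1 = character(),
      a2 = character(), maf = numeric()
    )
  }
  if (anyDuplicated(frq$snp) > 0) {
    abort(paste0("Duplicate SNP id in '", frq_path, "'."))
  }
  if (any(frq$a1 == frq$a2)) {
    abort(paste0("Identical A1/A2 alleles in '", frq_path, "'."))
  }
  frq
}

#' Write an allele-frequency table as a .frq file
#'
#' @param frq Allele-frequency tibble (`chrom`, `snp`, `a1`, `a2`, `maf`).
#' @param frq_path Output path.
#' @return Invisibly, `frq`.
#' @export
write_frq <- function(frq, frq_path) {
  check_frq(frq)
  lines <- c(
    "CHR SNP A1 A2 MAF",
    paste(frq$chrom, frq$snp, frq$a1, frq$a2, format(frq$maf, digits = 10,
                                                     trim = TRUE))
  )
  readr::write_lines(lines, frq_path)
  invisible(frq)
}

#' Read a per-site pileup call table
#'
#' Reads the three-column tab-separated bridge format for per-site base
#' calls produced by external pileup tools: `locus_id`, comma-joined base
#' calls and comma-joined phred qualities (`rs1<TAB>A,G<TAB>35,12`). A site
#' with no calls may leave fields 2 and 3 empty.
#'
#' @param path Path to the pileup TSV.
#' @return A long tibble with one row per read call: columns `snp`, `base`,
#'   `qual`. All site ids present in the file (including zero-depth sites)
#'   are recorded in the `"sites"` attribute, in file order.
#' @export
read_pileup <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sites <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(sites) > 0) {
    abort(paste0(
      "Duplicate locus id '", sites[duplicated(sites)][1], "' in '", path, "'."
    ))
  }
  parse_csv <- function(x) if (is.na(x) || !nzchar(x)) character(0) else
    strsplit(x, ",", fixed = TRUE)[[1]]
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    bases <- parse_csv(if (length(f) >= 2) f[2] else "")
    quals <- parse_csv(if (length(f) >= 3) f[3] else "")
    if (length(bases) != length(quals)) {
      abort(paste0(
        "Base/quality length mismatch at locus '", sites[i], "' in '", path,
        "': ", length(bases), " bases vs ", length(quals), " qualities."
      ))
    }
    q <- suppressWarnings(as.integer(quals))
    if (anyNA(q) && length(q) > 0) {
      abort(paste0("Non-integer quality at locus '", sites[i], "'."))
    }
    if (any(q < 0 | q > 93)) {
      abort(paste0("Phred quality outside [0, 93] at locus '", sites[i], "'."))
    }
    out[[i]] <- tibble(snp = rep(sites[i], length(bases)), base = bases,
                       qual = q)
  }
  calls <- bind_rows(out)
  if (nrow(calls) == 0) {
    calls <- tibble(snp = character(), base = character(), qual = integer())
  }
  attr(calls, "sites") <- sites
  calls
}

#' Write a per-site pileup call table
#'
#' @param calls Long call tibble (`snp`, `base`, `qual`), as returned by
#'   [read_pileup()]; a `"sites"` attribute, when present, fixes the site
#'   order and preserves zero-depth sites.
#' @param path Output path.
#' @return Invisibly, `calls`.
#' @export
write_pileup <- function(calls, path) {
  sites <- attr(calls, "sites")
  if (is.null(sites)) sites <- unique(calls$snp)
  grouped <- split(calls[c("base", "qual")], factor(calls$snp, levels = sites))
  lines <- vapply(sites, function(s) {
    g <- grouped[[s]]
    paste(s, paste(g$base, collapse = ","), paste(g$qual, collapse = ","),
          sep = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(calls)
}
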