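test_that("PED/MAP parsing assigns alleles deterministically and counts allele2", {
  f <- tiny_ped_map(c("F1 S1 0 0 1 2 A A G T"))
  d <- read_genotypes(f, "ped_map")
  expect_equal(dim(d), c(1L, 2L))
  expect_equal(d$samples$fid, "F1")
  expect_equal(d$samples$sex, "male")
  expect_equal(d$samples$phenotype, 2)
  # M1 is monomorphic A: allele1 is the absent "0", allele2 = A, call = 2
  expect_equal(d$markers$allele1, c("0", "G"))
  expect_equal(d$markers$allele2, c("A", "T"))
  expect_equal(unname(d$calls[1, ]), c(2L, 1L))
})

test_that("PED allele code 0 loads as a missing call", {
  f <- tiny_ped_map(c("F1 S1 0 0 1 2 0 0 G T",
                      "F2 S2 0 0 2 1 A A G G"))
  d <- read_genotypes(f, "ped_map")
  expect_true(is.na(d$calls["F1:S1", "M1"]))
  # M1 is monomorphic A among observed calls: counted allele is A, so A A = 2
  expect_equal(unname(d$calls["F2:S2", "M1"]), 2L)
})

test_that("malformed PED and duplicate keys are rejected", {
  f <- tiny_ped_map(c("F1 S1 0 0 1 2 A A"))
  expect_error(read_genotypes(f, "ped_map"), "fields")
  f2 <- tiny_ped_map(c("F1 S1 0 0 1 2 A A G T",
                       "F1 S1 0 0 1 2 A A G T"))
  expect_error(read_genotypes(f2, "ped_map"), "duplicate sample")
})

test_that("BED magic bytes are checked", {
  bed <- tempfile(fileext = ".bed")
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), bed)
  bim <- write_lines_tmp("1\tM1\t0\t1000\tA\tG", ".bim")
  fam <- write_lines_tmp("F1\tS1\t0\t0\t1\t2", ".fam")
  expect_error(read_genotypes(list(bed = bed, bim = bim, fam = fam),
                              "bed_bim_fam"), "magic")
})

test_that("multi-allelic VCF sites are skipped with a warning", {
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tC\tA,T\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./."), ".vcf")
  expect_warning(d <- read_genotypes(vcf, "vcf"), "multi-allelic")
  expect_equal(d$markers$id, "rs2")
  expect_equal(unname(d$calls[, "rs2"]), c(1L, NA))
})

test_that("genotype round-trips preserve calls, marker order and sample keys", {
  d <- simulate_genotypes(25, 10, maf = c(0.1, 0.25, 0.4), seed = 7,
                          missing_rate = 0.08)
  for (dialect in c("ped_map", "bed_bim_fam", "vcf")) {
    pfx <- tempfile()
    paths <- if (dialect == "vcf") paste0(pfx, ".vcf") else pfx
    write_genotypes(d, paths, dialect)
    r <- read_genotypes(paths, dialect)
    expect_equal(unname(r$calls), unname(d$calls), label = dialect)
    expect_equal(r$markers$id, d$markers$id)
    expect_equal(paste(r$samples$fid, r$samples$iid),
                 paste(d$samples$fid, d$samples$iid))
  }
})

test_that("PED/MAP and VCF encodings of one fixture give identical call matrices", {
  d <- simulate_genotypes(40, 6, maf = 0.3, seed = 9, missing_rate = 0.05)
  pfx <- tempfile()
  write_genotypes(d, pfx, "ped_map")
  write_genotypes(d, paste0(pfx, ".vcf"), "vcf")
  a <- read_genotypes(pfx, "ped_map")
  b <- read_genotypes(paste0(pfx, ".vcf"), "vcf")
  expect_equal(unname(a$calls), unname(b$calls))
})

test_that("trait tables infer types and honour dialect flags", {
  tf <- tiny_trait_file()
  tr <- read_trait_table(tf)
  expect_s3_class(tr, "trait_table")
  expect_equal(trait_types(tr), c(T2D = "binary", BMI = "continuous"))

  nofid <- write_lines_tmp(c("IID pheno", "S1 0.5", "S2 1.3"), ".txt")
  tr2 <- read_trait_table(nofid, has_fid = FALSE)
  expect_equal(tr2$fid, tr2$iid)

  miss <- write_lines_tmp(c("FID IID Y", "F1 S1 -9", "F2 S2 3.1",
                            "F3 S3 2.0"), ".txt")
  tr3 <- read_trait_table(miss, missing_code = "-9")
  expect_true(is.na(tr3$Y[1]))

  cats <- write_lines_tmp(c("FID IID SMOKE", "F1 S1 never", "F2 S2 past",
                            "F3 S3 current"), ".txt")
  expect_equal(unname(trait_types(read_trait_table(cats))["SMOKE"]),
               "categorical")
})

test_that("trait tables reject duplicates and empty variable sets", {
  dup <- write_lines_tmp(c("FID IID Y", "F1 S1 1", "F1 S1 0"), ".txt")
  expect_error(read_trait_table(dup), "duplicate sample")
  empt <- write_lines_tmp(c("FID IID", "F1 S1"), ".txt")
  expect_error(read_trait_table(empt), "variable")
})

test_that("CNV call tables derive state from copy number and reject cn = 2", {
  f <- write_lines_tmp(c("sample chrom start stop copy_number n_snps",
                         "S1 1 1001 2000 1 12",
                         "S2 1 5000 9000 3 20"), ".txt")
  cc <- read_cnv_calls(f)
  expect_equal(cc$state, c("deletion", "duplication"))
  expect_equal(cc$start[1], 1001L)
  expect_equal(cc$stop[1], 2000L)

  bad <- write_lines_tmp(c("sample chrom start stop copy_number n_snps",
                           "S1 1 1001 2000 2 12"), ".txt")
  expect_error(read_cnv_calls(bad), "not a CNV")
  rev <- write_lines_tmp(c("sample chrom start stop copy_number n_snps",
                           "S1 1 2000 1000 1 12"), ".txt")
  expect_error(read_cnv_calls(rev), "start > stop")
})

test_that("concordance counts discordant calls per sample and per marker", {
  f <- tiny_ped_map(c("F1 S1 0 0 1 2 A G G T",
                      "F2 S2 0 0 2 1 A A T T"))
  a <- read_genotypes(f, "ped_map")
  expect_equal(nrow(check_concordance(a, a)$detail), 0L)

  # flip S1's call at M1 (het -> hom) in the second dataset
  f2 <- tiny_ped_map(c("F1 S1 0 0 1 2 G G G T",
                       "F2 S2 0 0 2 1 A A T T"))
  b <- read_genotypes(f2, "ped_map")
  rep <- check_concordance(a, b)
  ps <- rep$per_sample
  expect_equal(ps$discordant[ps$sample == "F1:S1"], 1)
  expect_equal(ps$compared[ps$sample == "F1:S1"], 2)
  pm <- rep$per_marker
  expect_equal(pm$discordant[pm$marker == "M1"], 1)
  expect_equal(pm$compared[pm$marker == "M1"], 2)
  expect_equal(nrow(rep$detail), 1L)
  # counts balance: sample-wise and marker-wise totals equal the detail rows
  expect_equal(sum(ps$discordant), nrow(rep$detail))
  expect_equal(sum(pm$discordant), nrow(rep$detail))
  # symmetry
  rep2 <- check_concordance(b, a)
  expect_equal(rep2$per_sample$discordant, ps$discordant)
  expect_equal(rep2$per_marker$discordant, pm$discordant)
})

test_that("concordance excludes missing pairs and errors on no overlap", {
  f <- tiny_ped_map(c("F1 S1 0 0 1 2 0 0 G T"))
  a <- read_genotypes(f, "ped_map")
  f2 <- tiny_ped_map(c("F1 S1 0 0 1 2 A A G T"))
  b <- read_genotypes(f2, "ped_map")
  rep <- suppressWarnings(check_concordance(a, b))
  # M1 missing in a -> not compared anywhere at M1
  expect_equal(rep$per_marker$compared[rep$per_marker$marker == "M1"], 0)

  d1 <- simulate_genotypes(5, 3, seed = 1)
  d2 <- simulate_genotypes(5, 3, seed = 1)
  d2$markers$id <- paste0("other", 1:3)
  colnames(d2$calls) <- d2$markers$id
  expect_error(check_concordance(d1, d2), "no overlap")
})

test_that("result files are tab-delimited with constant field counts and NA markers", {
  rows <- data.frame(model_id = c("m1", "m2"), outcome = "T2D",
                     beta = c(0.5, NA), p = c(1.234567e-8, NA),
                     converged = c(TRUE, FALSE))
  f <- tempfile()
  write_results(rows, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  expect_length(unique(lengths(strsplit(lines, "\t"))), 1L)
  expect_match(lines[2], "1\\.23457e-08")
  expect_match(lines[3], "\tNA\t")
})
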