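# Small fixture builders shared across test files.  Everything is generated
# in code at test time; no binary fixtures exist on disk.

write_lines_tmp <- function(lines, ext = "") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# 2-sample x 2-marker PED/MAP pair used by the parsing and concordance tests
tiny_ped_map <- function(ped_lines = c("F1 S1 0 0 1 2 A A G T",
                                       "F2 S2 0 0 2 1 A A T T")) {
  map <- write_lines_tmp(c("1\tM1\t0\t1000", "1\tM2\t0\t2000"), ".map")
  ped <- write_lines_tmp(ped_lines, ".ped")
  list(ped = ped, map = map)
}

tiny_trait_file <- function(lines = c("FID IID T2D BMI",
                                      "F1 S1 1 24.5",
                                      "F2 S2 0 31.2",
                                      "F3 S3 0 27.0")) {
  write_lines_tmp(lines, ".txt")
}

# genotype+trait fixture with one causal marker, used by the scan tests
causal_fixture <- function(n = 800, n_markers = 5, beta = 1, seed = 11) {
  geno <- simulate_genotypes(n, n_markers, maf = 0.3, seed = seed)
  y <- simulate_phenotype(geno, betas = c(snp00003 = beta),
                          intercept = -0.5, family = "logistic",
                          seed = seed + 1)
  age <- with_seed(seed + 2, round(rnorm(n, 50, 8), 1))
  traits <- make_trait_table(data.frame(
    fid = geno$samples$fid, iid = geno$samples$iid,
    T2D = y, AGE = age, stringsAsFactors = FALSE))
  list(geno = geno, traits = traits)
}
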