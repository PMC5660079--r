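test_that("model enumeration counts: pairs, listed models, phewas grid", {
  for (m in c(2, 5, 16)) {
    ml <- enumerate_models("gxg_pairwise",
                           markers = sprintf("rs%03d", 1:m), outcome = "Y")
    expect_equal(nrow(ml), m * (m - 1) / 2)
    expect_false(any(ml$term1 == ml$term2))
    expect_false(anyDuplicated(ml$model_id) > 0)
    expect_true(all(ml$term1 < ml$term2))
  }
  # a main-effect filter keeping 256 markers implies 32,640 pairwise models
  ml256 <- enumerate_models("gxg_pairwise",
                            markers = sprintf("rs%04d", 1:256), outcome = "Y")
  expect_equal(nrow(ml256), 32640L)

  ph <- enumerate_models("phewas", markers = c("a", "b", "c"),
                         phenotypes = c("p1", "p2"))
  expect_equal(nrow(ph), 6L)
  expect_equal(unique(ph$interaction), FALSE)
})

test_that("model-list files are validated with line numbers", {
  f <- write_lines_tmp(c("# comment", "rs1 rs2", "", "rs3 rs_unknown"))
  expect_error(
    enumerate_models("gxg_list", markers = c("rs1", "rs2", "rs3"),
                     outcome = "Y", model_list_file = f),
    "line 4.*rs_unknown")
  f2 <- write_lines_tmp(c("rs2 rs1", "rs1 rs3"))
  ml <- enumerate_models("gxg_list", markers = c("rs1", "rs2", "rs3"),
                         outcome = "Y", model_list_file = f2)
  expect_equal(nrow(ml), 2L)
  expect_equal(ml$term1, c("rs1", "rs1"))  # pairs ordered lexicographically
})

test_that("Bonferroni correction and threshold reproduce printed arithmetic", {
  expect_equal(bonferroni(4.72e-7, 33622), 0.0158696, tolerance = 1e-5)
  expect_equal(bonferroni(3.54e-5, 404), 0.0143016, tolerance = 1e-5)
  expect_equal(bonferroni(0.1, 100), 1)
  expect_equal(bonferroni_threshold(0.05, 33683), 1.48443e-6,
               tolerance = 1e-5)
  expect_equal(bonferroni_threshold(0.05, 404), 1.237624e-4,
               tolerance = 1e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 33683) * 33683, 0.05)
})

test_that("BH-FDR follows the step-up rule and dominates the raw p", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_bh(0.5), 0.5)
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_bh(numeric(0)), numeric(0))
  p <- with_seed(6, runif(50))
  expect_true(all(fdr_bh(p) >= p))
  expect_equal(max(fdr_bh(p)), max(p))
})

test_that("main-effect scan ranks the causal marker first", {
  d <- causal_fixture(n = 800, n_markers = 5, beta = 1, seed = 11)
  ml <- enumerate_models("main_effect", markers = d$geno$markers$id,
                         outcome = "T2D")
  res <- run_scan(ml, d$geno, d$traits, covariates = "AGE",
                  family = "logistic")
  expect_equal(nrow(res), 5L)
  expect_true(all(res$converged))
  expect_equal(res$model_id[which.min(res$p)], "snp00003")
  expect_true(all(res$bonferroni_p >= res$p, na.rm = TRUE))
  expect_true(all(res$bonferroni_p <= 1, na.rm = TRUE))
  expect_equal(attr(res, "m_tests"), 5L)
  expect_equal(res$n_cases + res$n_controls, res$n_used)
})

test_that("scan results are invariant to marker input order", {
  d <- causal_fixture(n = 300, n_markers = 4, seed = 13)
  ml1 <- enumerate_models("main_effect", markers = d$geno$markers$id,
                          outcome = "T2D")
  ml2 <- enumerate_models("main_effect", markers = rev(d$geno$markers$id),
                          outcome = "T2D")
  r1 <- run_scan(ml1, d$geno, d$traits, family = "logistic")
  r2 <- run_scan(ml2, d$geno, d$traits, family = "logistic")
  r2s <- r2[match(r1$model_id, r2$model_id), ]
  expect_equal(r1$p, r2s$p)
  expect_equal(r1$term1_beta, r2s$term1_beta)
})

test_that("phewas mixes logistic and linear fits within one scan", {
  n <- 400
  geno <- simulate_genotypes(n, 2, maf = 0.3, seed = 17)
  bin <- simulate_phenotype(geno, betas = c(snp00001 = 0.6),
                            family = "logistic", seed = 18)
  cont <- simulate_phenotype(geno, betas = c(snp00002 = 0.5),
                             family = "linear", seed = 19)
  traits <- make_trait_table(data.frame(
    fid = geno$samples$fid, iid = geno$samples$iid,
    GLAUCOMA = bin, HDL = cont))
  ml <- enumerate_models("phewas", markers = geno$markers$id,
                         phenotypes = c("GLAUCOMA", "HDL"))
  res <- run_scan(ml, geno, traits, family = "auto")
  expect_equal(sort(unique(res$family)), c("linear", "logistic"))
  expect_equal(res$family[res$outcome == "GLAUCOMA"], rep("logistic", 2))
  expect_equal(res$family[res$outcome == "HDL"], rep("linear", 2))
})

test_that("a degenerate model is recorded without aborting the scan", {
  n <- 200
  geno <- simulate_genotypes(n, 2, maf = 0.3, seed = 23)
  y <- simulate_phenotype(geno, betas = c(snp00001 = 0.4),
                          family = "logistic", seed = 24)
  e <- rep(NA_real_, n)        # exposure entirely missing
  e[y == 0] <- with_seed(25, rnorm(sum(y == 0)))
  traits <- make_trait_table(data.frame(
    fid = geno$samples$fid, iid = geno$samples$iid, T2D = y, EXPO = e))
  ml <- enumerate_models("gxe", markers = geno$markers$id, outcome = "T2D",
                         exposures = "EXPO")
  res <- run_scan(ml, geno, traits, family = "logistic")
  expect_equal(nrow(res), 2L)
  expect_true(all(!res$converged))
})

test_that("interaction scans populate LRT and per-term Wald columns", {
  n <- 600
  geno <- simulate_genotypes(n, 3, maf = 0.3, seed = 27)
  e <- with_seed(28, rnorm(n))
  y <- simulate_phenotype(geno, betas = c(snp00001 = 0.3), exposure = e,
                          beta_exposure = 0.2,
                          interaction_marker = "snp00001",
                          beta_interaction = 0.9, intercept = -0.8,
                          family = "logistic", seed = 29)
  traits <- make_trait_table(data.frame(
    fid = geno$samples$fid, iid = geno$samples$iid, T2D = y, EXPO = e))
  ml <- enumerate_models("gxe", markers = geno$markers$id, outcome = "T2D",
                         exposures = "EXPO")
  res <- run_scan(ml, geno, traits, family = "logistic")
  expect_true(all(is.finite(res$lrt_stat)))
  expect_true(all(res$lrt_df == 1L))
  expect_true(all(is.finite(res$interaction_beta)))
  expect_equal(res$p, res$lrt_p)
  expect_equal(res$model_id[which.min(res$lrt_p)], "snp00001×EXPO")
})
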