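# The printed shell command shapes the pipeline interface must accept,
# and a fixture cohort rich enough to drive every one of them.

shell_commands <- c(
  main_effect = "load-data recode-alleles --auto load-trait logistic ---covariates --correction",
  rare_variant = "load-trait --no-fid logistic ---covariates --correction",
  gxe = "load-data recode-alleles --auto load-trait logistic --interaction --use-traits ---covariates --correction",
  cnv_burden = "load-trait --dummy-samples logistic --models --exclude-markers --covariates --correction",
  cnv_gxe = "load-trait --dummy-samples logistic --models --exclude-markers --interactions --covariates --correction",
  gxg_pairwise = "load-data recode-alleles --auto load-trait logistic --interaction --pairwise ---covariates --correction",
  gxg_list = "load-data recode-alleles --auto load-trait logistic --interaction --model --covariates --correction",
  phewas = "load-data recode-alleles --auto load-trait regress-auto --phewas --covariates --correction")

pipeline_fixture <- function(seed = 101, n = 250, n_markers = 4) {
  geno <- simulate_genotypes(n, n_markers, maf = 0.3, seed = seed)
  e <- with_seed(seed + 1, rnorm(n))
  y <- simulate_phenotype(geno, betas = c(snp00002 = 0.7), exposure = e,
                          beta_exposure = 0.2,
                          interaction_marker = "snp00002",
                          beta_interaction = 0.5, intercept = -0.5,
                          family = "logistic", seed = seed + 2)
  bmi <- with_seed(seed + 3, round(rnorm(n, 27, 4), 1))
  hdl <- with_seed(seed + 4, round(rnorm(n, 50, 12), 1))
  traits <- make_trait_table(data.frame(
    fid = geno$samples$fid, iid = geno$samples$iid,
    T2D = y, EXPO = e, BMI = bmi, HDL = hdl, stringsAsFactors = FALSE))
  cnv <- simulate_cnv_calls(geno$samples$iid, phenotype = y,
                            mean_calls = 2, seed = seed + 5)
  burden <- compute_cnv_burden(filter_cnv_calls(cnv), geno$samples$iid)
  burden_tr <- burden
  burden_tr$T2D <- y
  burden_tr$EXPO <- e
  burden_tr <- make_trait_table(as.data.frame(burden_tr)[
    , c("fid", "iid", "deletion_bp", "duplication_bp", "total_bp",
        "T2D", "EXPO")])
  pfx <- tempfile()
  write_genotypes(geno, pfx, "ped_map")
  model_file <- write_lines_tmp(c("snp00001 snp00002", "snp00003 snp00004"))
  list(geno = geno, traits = traits, burden = burden_tr, prefix = pfx,
       models = model_file)
}
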