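# Build a small collection and a deterministic phenotype from a formula so
# that exact model behaviour can be checked.
noiseless_pheno <- function(rc, f) {
  data.frame(strain_id = rc$strains$strain_id,
             mitotype = rc$strains$mitotype,
             response = f(rc),
             stringsAsFactors = FALSE)
}

test_that("an exactly additive SNP + mitotype phenotype has zero interaction", {
  fx <- scan_fixture()
  rc <- fx$rc
  snp <- fx$tab$variants$id[5]
  ph <- noiseless_pheno(rc, function(rc)
    2 * rc$geno[, snp] + 3 * (rc$strains$mitotype == "RC2") +
      5 * (rc$strains$mitotype == "RC3") + 10)
  sc <- scan_mitonuclear(ph, fx$tab, spec = model_spec(n_pcs = 0))
  i <- match(snp, sc$snp_id)
  expect_equal(sc$stat_int[i], 0)
  expect_equal(sc$p_int[i], 1)
  expect_lt(sc$p_main[i], 1e-10)
  expect_equal(sc$beta_main[i], 2, tolerance = 1e-8)
})

test_that("a pure interaction phenotype is detected with a tiny p-value", {
  fx <- scan_fixture()
  rc <- fx$rc
  snp <- fx$tab$variants$id[10]
  ph <- noiseless_pheno(rc, function(rc)
    1.5 * rc$geno[, snp] * (rc$strains$mitotype == "RC3") + 4)
  sc <- scan_mitonuclear(ph, fx$tab, spec = model_spec(n_pcs = 0))
  i <- match(snp, sc$snp_id)
  expect_lt(sc$p_int[i], 1e-10)
  expect_lt(sc$p_main[i], 0.05)
})

test_that("monomorphic and collinear SNPs are flagged, not fitted", {
  fx <- scan_fixture()
  rc <- fx$rc
  tab <- fx$tab
  # make the first variant monomorphic
  tab$calls[1, ] <- 0L
  snp <- tab$variants$id[7]
  ph <- noiseless_pheno(rc, function(rc)
    rc$geno[, snp] + as.numeric(rc$strains$mitotype == "RC2"))
  sc <- scan_mitonuclear(
    ph, tab, spec = model_spec(n_pcs = 0, condition_snps = snp))
  expect_equal(sc$status[1], "monomorphic")
  expect_true(is.na(sc$p_main[1]))
  i <- match(snp, sc$snp_id)
  expect_equal(sc$status[i], "collinear")  # conditioned on itself
})

test_that("an allele absent from one mitotype reduces the interaction df", {
  fx <- scan_fixture()
  rc <- fx$rc
  snp <- fx$tab$variants$id[12]
  ph <- noiseless_pheno(rc, function(rc) rc$geno[, snp])
  set.seed(1)
  ph$response <- ph$response + stats::rnorm(nrow(ph), 0, 0.1)
  # drop every RC3 row of alternate-allele carriers
  drop <- ph$mitotype == "RC3" & rc$geno[, snp] == 1
  sc <- scan_mitonuclear(ph[!drop, ], fx$tab, spec = model_spec(n_pcs = 0))
  i <- match(snp, sc$snp_id)
  expect_equal(sc$status[i], "reduced_df")
  expect_lt(sc$df_int[i], 2)
})

test_that("the binomial family detects a planted interaction on counts", {
  fx <- scan_fixture()
  rc <- fx$rc
  snp <- fx$tab$variants$id[10]
  arch <- pheno_architecture(
    interaction_effects = data.frame(marker = snp, mitotype = "RC3",
                                     delta = 1.5))
  cnt <- simulate_petite_counts(rc, arch, assay_design(500), seed = 23)
  agg <- stats::aggregate(cbind(petite_count, total_count) ~
                            strain_id + mitotype, cnt, sum)
  ph <- merge(strain_petite_means(cnt, "logit"), agg,
              by = c("strain_id", "mitotype"))
  sc <- scan_mitonuclear(ph, fx$tab, covariates = fx$covars,
                         spec = model_spec("binomial",
                                           covariates = "mating_type",
                                           n_pcs = 4))
  i <- match(snp, sc$snp_id)
  expect_lt(sc$p_int[i], 1e-20)
  expect_equal(sc$df_int[i], 2L)
  expect_true(all(sc$stat_int >= 0, na.rm = TRUE))
  expect_true(all(sc$q_int >= 0 & sc$q_int <= 1, na.rm = TRUE))
})

test_that("the scan requires two mitotype levels and a response", {
  fx <- scan_fixture()
  ph <- data.frame(strain_id = fx$rc$strains$strain_id,
                   mitotype = "RC1",
                   response = 1)
  expect_error(scan_mitonuclear(ph, fx$tab), "2 mitotype levels")
  ph2 <- data.frame(strain_id = fx$rc$strains$strain_id,
                    mitotype = fx$rc$strains$mitotype)
  expect_error(scan_mitonuclear(ph2, fx$tab, spec = model_spec(n_pcs = 0)),
               "response")
})

test_that("a factorial nuclear background reproduces two-way mitonuclear ANOVA", {
  set.seed(47)
  nuclear <- factor(rep(sprintf("N%d", 1:4), each = 12))
  mito <- factor(rep(rep(sprintf("mt%d", 1:4), each = 3), 4))
  # additive truth: no interaction
  y_add <- 2 * as.integer(nuclear) + 3 * as.integer(mito)
  res_add <- mitonuclear_anova(y_add, nuclear, mito)
  expect_equal(res_add$p_int, 1)
  # one coadapted combination departs from additivity
  y_int <- y_add + 6 * (nuclear == "N2" & mito == "mt3") +
    stats::rnorm(48, 0, 0.5)
  res_int <- mitonuclear_anova(y_int, nuclear, mito)
  expect_lt(res_int$p_int, 1e-6)
  expect_equal(res_int$df_int, 9L)
  # matches stats::anova on the equivalent linear model
  ref <- stats::anova(stats::lm(y_int ~ mito + nuclear + nuclear:mito))
  expect_equal(res_int$p_int, ref["mito:nuclear", "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(res_int$p_main, ref["nuclear", "Pr(>F)"], tolerance = 1e-8)
})
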