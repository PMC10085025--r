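test_that("PCA scores are mutually orthogonal", {
  set.seed(55)
  geno <- matrix(stats::rbinom(40 * 200, 1, 0.4), 40, 200)
  pca <- genotype_pca(geno, k = 5)
  g <- crossprod(pca$scores)
  off <- g[upper.tri(g)]
  expect_true(all(abs(off) < 1e-6 * max(diag(g))))
})

test_that("PC1 separates two differentiated founder populations", {
  map <- yeast_map(800)
  panel <- simulate_founders(40, 2, map, Fst = 0.3, seed = 56)
  pca <- genotype_pca(panel$haplotypes, k = 2)
  lab <- as.integer(factor(panel$founders$population))
  expect_gt(abs(stats::cor(pca$scores[, 1], lab)), 0.9)
})

test_that("a constant genotype matrix yields a rank warning and no scores", {
  geno <- matrix(1, 10, 20)
  expect_warning(pca <- genotype_pca(geno, k = 3), "rank")
  expect_equal(ncol(pca$scores), 0)
  # k above rank truncates
  set.seed(57)
  lowrank <- matrix(stats::rbinom(30, 1, 0.5), 30, 1)[, rep(1, 10)]
  expect_warning(p2 <- genotype_pca(lowrank, k = 5), "truncating")
  expect_equal(p2$k_used, 1)
})

test_that("the effect size delta follows the weighted-frequency formula", {
  g <- c(rep(0, 6), rep(1, 4))
  y <- c(rep(10, 6), rep(5, 4))
  expect_equal(effect_size_delta(g, y), 4.0)  # |0.6*10 - 0.4*5|
  # balanced products cancel
  expect_equal(effect_size_delta(c(0, 1), c(5, 5)), 0)
  # monomorphic undefined
  expect_true(is.na(effect_size_delta(rep(1, 5), 1:5)))
})

test_that("delta equals a brute-force recomputation from replicate counts", {
  set.seed(58)
  for (rep_i in 1:5) {
    n <- 40
    g <- stats::rbinom(n, 1, 0.4)
    g[sample(n, 3)] <- NA
    counts <- lapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      tot <- sample(c(100, 200, 500), k, replace = TRUE)
      list(petite = stats::rbinom(k, tot, 0.05 + 0.05 * isTRUE(g[i] == 1)),
           total = tot)
    })
    means <- vapply(counts, function(cc)
      mean(100 * cc$petite / cc$total), numeric(1))
    expect_equal(effect_size_delta(g, means), delta_brute(g, counts))
  }
})

test_that("pairwise epistasis: additive pairs are null, XOR pairs explode", {
  g1 <- rep(c(0L, 1L), each = 20)
  g2 <- rep(c(0L, 1L), 20)
  vc <- variant_calls(
    data.frame(chrom = "chr01", pos = c(50000L, 70000L), ref = "A",
               alt = "G"),
    matrix(c(g1, g2), nrow = 2, byrow = TRUE,
           dimnames = list(NULL, sprintf("S%02d", 1:40))),
    c(chr01 = 230218))
  tab <- build_snp_table(vc, telomere_mask_bp = 0, maf_threshold = 0)$table
  ids <- tab$variants$id

  ph_add <- data.frame(strain_id = sprintf("S%02d", 1:40),
                       response = 2 * g1 + 3 * g2)
  add <- pairwise_epistasis_scan(ph_add, tab, focal_snps = ids[2])
  expect_equal(add$p[add$snp_id == ids[1]], 1)

  ph_xor <- data.frame(strain_id = sprintf("S%02d", 1:40),
                       response = as.numeric(xor(g1, g2)))
  x <- pairwise_epistasis_scan(ph_xor, tab, focal_snps = ids[2])
  expect_lt(x$p[x$snp_id == ids[1]], 1e-10)
  expect_equal(x$status[x$snp_id == ids[2]], "self")
})

test_that("pairwise epistasis excludes perfectly linked pairs and is calibrated", {
  set.seed(59)
  n <- 80
  g1 <- stats::rbinom(n, 1, 0.5)
  calls <- rbind(g1, g1, stats::rbinom(n, 1, 0.5))
  colnames(calls) <- sprintf("S%02d", 1:n)
  vc <- variant_calls(
    data.frame(chrom = "chr01", pos = c(30000L, 60000L, 90000L),
               ref = "A", alt = "G"),
    calls, c(chr01 = 230218))
  tab <- build_snp_table(vc, telomere_mask_bp = 0, maf_threshold = 0)$table
  ph <- data.frame(strain_id = sprintf("S%02d", 1:n),
                   response = stats::rnorm(n))
  pe <- pairwise_epistasis_scan(ph, tab, focal_snps = tab$variants$id[1])
  expect_equal(pe$status[pe$snp_id == tab$variants$id[2]], "excluded_ld")
  expect_true(is.na(pe$q[pe$snp_id == tab$variants$id[2]]))

  # null calibration: type-I error at 0.05 within the binomial CI
  fx <- scan_fixture()
  sg <- strain_genotypes(fx$rc)
  set.seed(60)
  ps <- unlist(lapply(1:40, function(k) {
    phk <- data.frame(strain_id = sg$strains$strain_id,
                      response = stats::rnorm(nrow(sg$strains)))
    pek <- pairwise_epistasis_scan(
      phk, fx$tab, focal_snps = fx$tab$variants$id[c(20, 90)])
    pek$p[pek$status == "ok"]
  }))
  rate <- mean(ps < 0.05)
  half <- 3 * sqrt(0.05 * 0.95 / length(ps))
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})
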