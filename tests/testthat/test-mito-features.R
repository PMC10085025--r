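test_that("GC percent follows the definition and its symmetries", {
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("AAAA"), 0)
  expect_error(gc_percent(""), "empty")
  set.seed(71)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_percent(s), gc_percent(rc))
  }
  # ambiguity codes drop out of numerator and denominator
  expect_equal(gc_percent("ATGCNNNN"), 50)
})

test_that("planted cluster classes are recovered exactly (round trip)", {
  lib <- gc_cluster_library()
  g <- simulate_mtgenome(20000, 0.05, c(M4 = 3, M1 = 2), lib, seed = 72)
  det <- detect_gc_clusters(g, lib)
  expect_equal(det$counts[["M4"]], 3L)
  expect_equal(det$counts[["M1"]], 2L)
  expect_equal(sum(det$counts), 5L)
  expect_true(all(det$matches$start >= 1 &
                    det$matches$end <= length(g)))
})

test_that("a motif-free genome has zero counts and backbone GC content", {
  lib <- gc_cluster_library()
  g <- simulate_mtgenome(20000, 0.05, seed = 73)
  det <- detect_gc_clusters(g, lib)
  expect_true(all(det$counts == 0))
  expect_lt(abs(gc_percent(g) - 5), 0.6)  # ~4 sd of the backbone draw
})

test_that("a motif planted on the reverse strand is counted once", {
  mot <- "GGGCGCATCGCGCAATGGCC"  # deliberately non-palindromic
  lib <- motif_library("V1", mot, max_mismatch = 1)
  backbone <- paste(rep("AT", 500), collapse = "")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(mot)))
  seqs <- paste0(substr(backbone, 1, 400), rc,
                 substr(backbone, 421, 1000))
  det <- detect_gc_clusters(seqs, lib)
  expect_equal(det$counts[["V1"]], 1L)
  expect_equal(det$matches$strand, "-")
})

test_that("palindromic motifs never double-count their own complement", {
  lib <- gc_cluster_library()
  g <- simulate_mtgenome(8000, 0.04, c(M5 = 1), lib, seed = 74)
  expect_equal(sum(detect_gc_clusters(g, lib)$counts), 1L)
})

test_that("cluster counts add over disjoint segments", {
  lib <- gc_cluster_library()
  g1 <- simulate_mtgenome(10000, 0.05, c(M2 = 2), lib, seed = 75)
  g2 <- simulate_mtgenome(10000, 0.05, c(M7 = 3), lib, seed = 76)
  joint <- paste0(as.character(g1), as.character(g2))
  dj <- detect_gc_clusters(joint, lib)
  expect_equal(dj$counts[["M2"]], 2L)
  expect_equal(dj$counts[["M7"]], 3L)
})

test_that("the genome simulator validates its motif inputs", {
  lib <- gc_cluster_library()
  expect_error(simulate_mtgenome(1000, 0.05, c(M1 = 1), NULL),
               "empty motif library")
  expect_error(simulate_mtgenome(1000, 0.05, c(ZZ = 1), lib), "ZZ")
  expect_error(simulate_mtgenome(10, 0.05, c(M1 = 1), lib), "longer")
  expect_error(motif_library("M1", "GCWGC"), "uppercase")
})

test_that("feature correlations reproduce the t-transform and a permutation null", {
  # construct a feature with Pearson r exactly 0.59 at n = 18
  n <- 18
  r <- 0.59
  x <- scale(seq_len(n))[, 1]
  set.seed(77)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- e / sqrt(sum(e^2) / (n - 1))
  y <- r * x + sqrt(1 - r^2) * e
  ft <- data.frame(gc_pct = x)
  res <- correlate_features(ft, y)
  expect_equal(res$r, 0.59, tolerance = 1e-10)
  expect_equal(res$r_squared, 0.59^2, tolerance = 1e-10)
  expect_lt(abs(res$p - 0.01), 0.001)

  # small-n p agrees with a permutation oracle
  set.seed(78)
  xs <- stats::rnorm(12)
  ys <- 0.8 * xs + stats::rnorm(12, 0, 0.8)
  pr <- correlate_features(data.frame(f = xs), ys)$p
  robs <- abs(stats::cor(xs, ys))
  perm <- replicate(10000, abs(stats::cor(xs, sample(ys))))
  p_perm <- (sum(perm >= robs) + 1) / (10000 + 1)
  expect_lt(abs(pr - p_perm), 0.02)

  # degenerate features are flagged, not errors
  res2 <- correlate_features(data.frame(flat = rep(1, 5)), 1:5)
  expect_equal(res2$status, "zero_variance")
  # perfectly linear feature
  res3 <- correlate_features(data.frame(lin = 1:10), 2 * (1:10) + 3)
  expect_equal(res3$r, 1)
  expect_equal(res3$r_squared, 1)
})

test_that("feature tables carry length, GC and per-class counts", {
  lib <- gc_cluster_library()
  g1 <- simulate_mtgenome(6000, 0.05, c(M1 = 1), lib, seed = 79)
  g2 <- simulate_mtgenome(9000, 0.05, c(M4 = 2, M9 = 1), lib, seed = 80)
  ss <- Biostrings::DNAStringSet(c(a = as.character(g1),
                                   b = as.character(g2)))
  ft <- mtdna_features(ss, lib, intron_lengths = c(a = 100, b = 0))
  expect_equal(ft$length_bp, c(6000, 9000))
  expect_equal(ft$total_clusters, c(1, 3))
  expect_equal(ft$M4, c(0, 2))
  expect_equal(ft$intron_bp, c(100, 0), ignore_attr = TRUE)
})
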