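# Hand-checkable toy input: 6 strains, one 200 kb chromosome, variants at
# 10000 (masked), 50000/50001 (adjacent, merged), 120000 (triallelic,
# dropped) and 180000 (MAF 1/6).
toy_calls <- function() {
  strains <- sprintf("S%d", 1:6)
  variants <- data.frame(
    chrom = "chr1",
    pos = c(10000L, 50000L, 50001L, 120000L, 180000L),
    ref = c("A", "A", "C", "A", "T"),
    alt = c("G", "G", "T", "G,T", "C"))
  calls <- rbind(
    c(1, 1, 1, 0, 0, 0),
    c(1, 1, 1, 0, 0, 0),
    c(1, 1, 1, 0, 0, 0),
    c(0, 1, 0, 1, 0, 0),
    c(1, 0, 0, 0, 0, 0))
  colnames(calls) <- strains
  variant_calls(variants, calls, c(chr1 = 200000))
}

test_that("the filtering pipeline applies merge, mask, biallelic and MAF in order", {
  res <- build_snp_table(toy_calls(), telomere_mask_bp = 20000,
                         maf_threshold = 0.05, merge_adjacent = TRUE)
  tab <- res$table
  rep <- res$report

  expect_equal(tab$variants$pos, c(50000L, 180000L))
  expect_equal(tab$variants$ref[1], "AC")
  expect_equal(tab$variants$alt[1], "GT")
  expect_equal(unname(tab$calls[1, ]), c(1, 1, 1, 0, 0, 0))

  expect_equal(rep$filter,
               c("merge_adjacent", "telomere_mask", "biallelic", "maf"))
  expect_equal(rep$variants_in[1], 5)
  expect_equal(rep$variants_out, c(4, 3, 2, 2))
  # counts telescope
  expect_equal(rep$variants_in[-1], rep$variants_out[-nrow(rep)])
})

test_that("monomorphic input is emptied by the MAF filter", {
  strains <- sprintf("S%d", 1:4)
  calls <- matrix(0, 3, 4, dimnames = list(NULL, strains))
  vc <- variant_calls(
    data.frame(chrom = "chr1", pos = c(30000L, 60000L, 90000L),
               ref = "A", alt = "G"),
    calls, c(chr1 = 200000))
  res <- build_snp_table(vc, telomere_mask_bp = 0, maf_threshold = 0.05)
  expect_equal(nrow(res$table$variants), 0)
  maf_row <- res$report[res$report$filter == "maf", ]
  expect_equal(maf_row$variants_in, 3)
  expect_equal(maf_row$variants_out, 0)
})

test_that("disabling the optional filters returns the biallelic subset", {
  res <- build_snp_table(toy_calls(), telomere_mask_bp = 0,
                         maf_threshold = 0, merge_adjacent = FALSE)
  expect_equal(res$table$variants$pos,
               c(10000L, 50000L, 50001L, 180000L))
})

test_that("merged calls that disagree within a strain become missing", {
  strains <- sprintf("S%d", 1:3)
  calls <- matrix(c(0, 1, NA,
                    1, 1, 1), 2, 3, byrow = TRUE,
                  dimnames = list(NULL, strains))
  vc <- variant_calls(
    data.frame(chrom = "chr1", pos = c(50000L, 50001L), ref = "A",
               alt = "G"),
    calls, c(chr1 = 200000))
  res <- build_snp_table(vc, telomere_mask_bp = 0, maf_threshold = 0)
  expect_equal(nrow(res$table$variants), 1)
  expect_equal(unname(res$table$calls[1, ]), c(NA, 1, 1))
})

test_that("a MAF exactly at the threshold is kept", {
  strains <- sprintf("S%d", 1:10)
  calls <- matrix(c(rep(1, 2), rep(0, 8)), 1, 10,
                  dimnames = list(NULL, strains))
  vc <- variant_calls(
    data.frame(chrom = "chr1", pos = 50000L, ref = "A", alt = "G"),
    calls, c(chr1 = 200000))
  res <- build_snp_table(vc, telomere_mask_bp = 0, maf_threshold = 0.2)
  expect_equal(nrow(res$table$variants), 1)
})

test_that("unknown chromosomes are a reference error", {
  expect_error(
    variant_calls(data.frame(chrom = "chrX", pos = 1L, ref = "A",
                             alt = "G"),
                  matrix(0, 1, 2, dimnames = list(NULL, c("a", "b"))),
                  c(chr1 = 1000)),
    "unknown chromosome")
})

test_that("allele statistics follow the hand count and MAF is bounded", {
  strains <- sprintf("S%d", 1:6)
  calls <- rbind(c(0, 0, 1, 1, 1, NA),
                 c(NA, NA, NA, NA, NA, NA))
  colnames(calls) <- strains
  vc <- variant_calls(
    data.frame(chrom = "chr1", pos = c(1000L, 2000L), ref = "A",
               alt = "G"),
    calls, c(chr1 = 10000))
  st <- allele_stats(vc)
  expect_equal(st$alt_freq[1], 0.6)
  expect_equal(st$maf[1], 0.4)
  expect_equal(st$missing_frac[1], 1 / 6)
  expect_equal(st$status[2], "all_missing")
  expect_true(is.na(st$maf[2]))

  set.seed(9)
  calls <- matrix(stats::rbinom(300, 1, 0.7), 30, 10,
                  dimnames = list(NULL, sprintf("T%d", 1:10)))
  vc2 <- variant_calls(
    data.frame(chrom = "chr1", pos = seq(100L, by = 10L,
                                         length.out = 30),
               ref = "A", alt = "G"),
    calls, c(chr1 = 10000))
  expect_true(all(allele_stats(vc2)$maf <= 0.5))
})

test_that("mitotype allele-frequency differences follow the hand example", {
  # 20 strains per group; alt frequencies 0.50 / 0.30 / 0.45
  strains <- sprintf("S%02d", 1:60)
  calls <- matrix(c(rep(1, 10), rep(0, 10),
                    rep(1, 6), rep(0, 14),
                    rep(1, 9), rep(0, 11)), 1, 60,
                  dimnames = list(NULL, strains))
  vc <- variant_calls(
    data.frame(chrom = "chr1", pos = 5000L, ref = "A", alt = "G"),
    calls, c(chr1 = 10000))
  membership <- data.frame(strain_id = strains,
                           mitotype = rep(c("A", "B", "C"), each = 20))
  md <- mitotype_freq_diff(vc, membership)
  expect_equal(md$max_diff, 0.20)

  # isonuclear replication: identical strain sets => all zero
  fx <- scan_fixture()
  mem <- fx$rc$strains[, c("strain_id", "mitotype")]
  md2 <- mitotype_freq_diff(fx$tab, mem)
  expect_true(all(md2$max_diff == 0))

  # an empty mitotype group is an error naming the group
  expect_error(
    mitotype_freq_diff(vc, data.frame(
      strain_id = strains,
      mitotype = factor(rep(c("A", "B"), 30), levels = c("A", "B", "C")))),
    "'C' is empty")
  # unknown strains are reported
  expect_error(
    mitotype_freq_diff(vc, data.frame(
      strain_id = c(strains[-1], "nope"),
      mitotype = rep(c("A", "B"), 30))), "nope")
})
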