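test_that("rounds = 0 returns unrecombined founder haplotypes", {
  map <- yeast_map(120)
  panel <- simulate_founders(10, 2, map, Fst = 0.2, seed = 31)
  rc <- advanced_intercross(panel, rounds = 0, sample_size = 15, seed = 32)
  for (i in seq_len(nrow(rc$geno))) {
    matches <- apply(panel$haplotypes, 1,
                     function(h) all(h == rc$geno[i, ]))
    expect_true(any(matches))
    expect_equal(length(unique(rc$ancestry[i, ])), 1L)
  }
})

test_that("genotypes stay binary, ancestry partitions the genome, mating types segregate", {
  map <- yeast_map(200)
  panel <- simulate_founders(12, 3, map, Fst = 0.2, seed = 41)
  rc <- advanced_intercross(panel, rounds = 3, progeny_per_round = 300,
                            sample_size = 80, seed = 42)
  expect_true(all(rc$geno %in% c(0L, 1L)))
  expect_true(all(rc$ancestry %in% seq_len(12)))
  expect_setequal(unique(rc$strains$mating_type), c("MATa", "MATalpha"))
  expect_true(all(rc$strains$aux_arg8 %in% c(0L, 1L)))
  expect_equal(sum(founder_shares(rc)), 1)
})

test_that("allele frequencies are preserved in expectation through the intercross", {
  map <- yeast_map(300)
  panel <- simulate_founders(20, 4, map, Fst = 0.2, seed = 51)
  rc <- advanced_intercross(panel, rounds = 7, progeny_per_round = 800,
                            sample_size = 181, seed = 52)
  f0 <- colMeans(panel$haplotypes)
  f7 <- colMeans(strain_genotypes(rc)$geno)
  expect_gt(stats::cor(f0, f7), 0.9)
  expect_lt(mean(abs(f7 - f0)), 0.08)
})

test_that("an all-MATa panel cannot be intercrossed", {
  map <- yeast_map(60)
  panel <- simulate_founders(6, 2, map, Fst = 0.2, seed = 61)
  panel$founders$mating_type <- "MATa"
  expect_error(
    advanced_intercross(panel, rounds = 1, progeny_per_round = 50,
                        sample_size = 10, seed = 62),
    "no compatible")
})

test_that("mitotype replication produces identical nuclear rows within strain", {
  rc <- small_collection()
  expect_equal(nrow(rc$strains), 181 * 3)
  for (s in sample(unique(rc$strains$strain_id), 5)) {
    rows <- which(rc$strains$strain_id == s)
    expect_equal(length(rows), 3L)
    expect_equal(rc$geno[rows[1], ], rc$geno[rows[2], ])
    expect_equal(rc$geno[rows[1], ], rc$geno[rows[3], ])
    expect_setequal(rc$strains$mitotype[rows], c("RC1", "RC2", "RC3"))
  }
})

test_that("mitotype replication validates labels and input uniqueness", {
  map <- yeast_map(40)
  panel <- simulate_founders(4, 2, map, Fst = 0.1, seed = 71)
  rc1 <- advanced_intercross(panel, rounds = 1, progeny_per_round = 30,
                             sample_size = 10, seed = 72)
  one <- replicate_with_mitotypes(rc1, "RC1")
  expect_equal(one$geno, rc1$geno, ignore_attr = TRUE)
  expect_equal(one$strains$mitotype, rep("RC1", 10))

  expect_error(replicate_with_mitotypes(rc1, c("RC1", "RC1")), "duplicate")
  rc3 <- replicate_with_mitotypes(rc1)
  expect_error(replicate_with_mitotypes(rc3), "integrity")
})

test_that("the intercross is reproducible from its seed", {
  map <- yeast_map(80)
  panel <- simulate_founders(8, 2, map, Fst = 0.2, seed = 81)
  a <- advanced_intercross(panel, rounds = 2, progeny_per_round = 100,
                           sample_size = 20, seed = 82)
  b <- advanced_intercross(panel, rounds = 2, progeny_per_round = 100,
                           sample_size = 20, seed = 82)
  expect_identical(a$geno, b$geno)
  expect_identical(a$strains, b$strains)
})
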