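# Shared fixtures built in code.  Heavier simulated objects are cached per
# test run so multiple test blocks can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

two_marker_map <- function(d_cm, same_cm = FALSE) {
  genetic_map(
    data.frame(chrom = "c1", length_bp = 1e6),
    data.frame(chrom = "c1", pos_bp = c(1e5, 5e5),
               pos_cm = if (same_cm) c(10, 10) else c(0, d_cm)))
}

# Small recombinant collection (181 strains x 3 mitotypes) for phenotype
# sampling tests; few markers keep it fast.
small_collection <- function() {
  cached("small_collection", function() {
    map <- yeast_map(100)
    panel <- simulate_founders(25, 5, map, Fst = 0.2, seed = 301)
    rc1 <- advanced_intercross(panel, rounds = 2, progeny_per_round = 400,
                               sample_size = 181, seed = 302)
    replicate_with_mitotypes(rc1)
  })
}

# Mid-sized collection + filtered table for scan tests.
scan_fixture <- function() {
  cached("scan_fixture", function() {
    map <- yeast_map(160)
    panel <- simulate_founders(8, 2, map, Fst = 0.2, seed = 401)
    rc1 <- advanced_intercross(panel, rounds = 3, progeny_per_round = 300,
                               sample_size = 60, seed = 402)
    rc <- replicate_with_mitotypes(rc1)
    tab <- build_snp_table(calls_from_collection(rc),
                           telomere_mask_bp = 0)$table
    list(rc = rc, tab = tab,
         covars = strain_genotypes(rc)$strains)
  })
}

# The full default simulated collection (the study-design conditions);
# built once and reused by the acceptance suite.
default_collection <- function() {
  cached("default_collection", function() {
    cfg <- default_config()$sim
    map <- yeast_map(cfg$n_markers)
    panel <- simulate_founders(cfg$n_founders, cfg$n_populations, map,
                               Fst = cfg$fst, seed = 501)
    rc1 <- advanced_intercross(panel, rounds = cfg$rounds,
                               progeny_per_round = cfg$progeny_per_round,
                               sample_size = cfg$sample_size, seed = 502)
    rc <- replicate_with_mitotypes(rc1, cfg$mitotypes)
    tab <- build_snp_table(calls_from_collection(rc))$table
    list(rc = rc, tab = tab, covars = strain_genotypes(rc)$strains)
  })
}

# Golden-run configuration: one large main-effect locus and three
# interaction loci, scanned on the empirical-logit scale.
golden_config <- function(seed) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$sim$progeny_per_round <- 2000
  cfg
}

# Conditioning-experiment configuration: a large-effect nuclear locus
# masking several small interaction loci.
masking_config <- function(seed) {
  cfg <- golden_config(seed)
  cfg$sim$architecture$main$beta <- 2.5
  cfg$sim$architecture$interaction$n <- 5
  cfg$sim$architecture$interaction$delta <- 0.8
  cfg
}

# Brute-force oracle for the sliding-window Vmax: fit lm() in every window.
vmax_brute <- function(curve, window = 5) {
  n <- nrow(curve)
  max(vapply(seq_len(n - window + 1), function(i) {
    idx <- i:(i + window - 1)
    unname(stats::coef(stats::lm(od600 ~ time_h, curve[idx, ]))[2])
  }, numeric(1)))
}

# Brute-force oracle for the allele-frequency-weighted effect size,
# recomputed from raw replicate counts.
delta_brute <- function(g, counts_by_strain) {
  means <- vapply(counts_by_strain,
                  function(cc) mean(100 * cc$petite / cc$total), numeric(1))
  ok <- !is.na(g)
  g <- g[ok]
  means <- means[ok]
  f0 <- sum(g == 0) / length(g)
  f1 <- sum(g == 1) / length(g)
  abs(f0 * mean(means[g == 0]) - f1 * mean(means[g == 1]))
}
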