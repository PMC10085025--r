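#' Default workflow configuration
#'
#' Returns the full nested parameter list for [run_end_to_end()], with the
#' study-design defaults: 25 founders from 5 ancestral populations at
#' Fst 0.2, 7 rounds of random mating with 10000 progeny per round, 181
#' sampled strains replicated across 3 mitotypes, 500 colonies per petite
#' assay, one planted large main-effect locus (beta = 1 logit) and three
#' planted interaction loci (delta = 1.5 logit, mitotype RC3, MAF near
#' 0.3).
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    sim = list(
      n_founders = 25, n_populations = 5, fst = 0.2,
      n_markers = 1200, cm_per_kb = 0.35,
      rounds = 7, progeny_per_round = 10000, sample_size = 181,
      mitotypes = c("RC1", "RC2", "RC3"),
      missing_rate = 0,
      colonies = 500, replicates = 1,
      architecture = list(
        baseline_p = 0.05,
        main = list(n = 1, beta = 1.0, maf = 0.3),
        interaction = list(n = 3, delta = 1.5, maf = 0.3,
                           mitotype = "RC3"),
        mito_effects = c(RC1 = 0, RC2 = 0, RC3 = 0),
        overdispersion = 1)),
    filter = list(telomere_mask_bp = 20000, maf_threshold = 0.05,
                  merge_adjacent = TRUE),
    scan = list(family = "gaussian", response_scale = "logit",
                n_pcs = 10, covariates = c("mating_type", "aux_arg8"),
                condition_snps = character(0),
                main_fdr = 0.001, interaction_fdr = 0.05),
    annotate = list(gff = NULL, upstream_window = 250,
                    merge_window_bp = 25000),
    mitofeat = list(fasta = NULL, motif_library = NULL),
    inputs = list(genotypes = NULL, phenotypes = NULL),
    out = NULL), class = "run_config")
}

# Recursively check that a user config only uses known keys.
.validate_config <- function(cfg, ref = default_config(), path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop("invalid config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
        is.list(cfg[[nm]]))
      .validate_config(cfg[[nm]], ref[[nm]], paste0(path, ".", nm))
  }
  invisible(TRUE)
}

# Merge a partial config over the defaults.
.merge_config <- function(user, ref = default_config()) {
  for (nm in names(user)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
        is.list(user[[nm]]))
      ref[[nm]] <- .merge_config(user[[nm]], ref[[nm]])
    else ref[[nm]] <- user[[nm]]
  }
  ref
}

#' Load / save a workflow configuration
#'
#' Configs are YAML; unknown keys are rejected with the offending key
#' named, and missing keys fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  .validate_config(user)
  cfg <- .merge_config(user)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_config
#' @param config A `run_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Choose planted loci: markers whose realized MAF is closest to the
# target, spread over distinct chromosomes where possible, away from
# already chosen loci, and statistically independent of them (low realized
# genotype correlation), so every planted effect is attributable to its own
# locus.  Markers inside the telomere mask are excluded so every planted
# locus survives the SNP filters.  Deterministic given the collection.
.pick_loci <- function(rc, n, maf_target, avoid = character(),
                       min_gap_bp = 2e5, telomere_mask_bp = 0,
                       max_abs_cor = 0.1) {
  sg <- strain_genotypes(rc)
  f <- colMeans(sg$geno)
  maf <- pmin(f, 1 - f)
  mk <- rc$map$markers
  len <- stats::setNames(rc$map$chromosomes$length_bp,
                         rc$map$chromosomes$chrom)
  inside <- mk$pos_bp > telomere_mask_bp &
    mk$pos_bp <= len[mk$chrom] - telomere_mask_bp
  cand <- order(abs(maf - maf_target))
  cand <- cand[inside[cand]]
  picked <- character(0)
  for (i in cand) {
    id <- mk$id[i]
    if (id %in% avoid) next
    ok <- TRUE
    for (p in c(picked, avoid)) {
      j <- match(p, mk$id)
      if (is.na(j)) next
      if (mk$chrom[j] == mk$chrom[i] &&
          abs(mk$pos_bp[j] - mk$pos_bp[i]) < min_gap_bp) {
        ok <- FALSE
        break
      }
      if (stats::var(sg$geno[, j]) > 0 &&
          abs(stats::cor(sg$geno[, i], sg$geno[, j])) > max_abs_cor) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    picked <- c(picked, id)
    if (length(picked) == n) break
  }
  if (length(picked) < n)
    stop("could not place ", n, " loci at MAF ~", maf_target)
  picked
}

.log_line <- function(log, ...) c(log, paste0(...))

#' Run the full simulate-filter-scan-annotate workflow
#'
#' Deterministic given the master seed: every stage draws from its own
#' child stream derived with [stage_seed()].  Outputs (when `config$out`
#' is set) are written as TSV/VCF/YAML with fixed formatting, so repeated
#' runs are byte-identical.
#'
#' @param config A `run_config` (see [default_config()], [read_config()]).
#' @return list with the collection, truth (planted loci), snp table and
#'   filter report, phenotypes, scan results, significant hit tables, QTLs,
#'   optional annotation and mtDNA feature tables, and the run log.
#' @export
run_end_to_end <- function(config = default_config()) {
  .validate_config(config)
  cfg <- .merge_config(config)
  log <- character(0)
  seed <- cfg$seed
  log <- .log_line(log, "config: master seed ", seed)

  # --- genotypes: simulate or load ------------------------------------
  truth <- NULL
  covars <- NULL
  pheno_counts <- NULL
  if (!is.null(cfg$inputs$genotypes)) {
    path <- cfg$inputs$genotypes
    if (!file.exists(path)) stop("file not found: ", path)
    calls <- if (grepl("\\.vcf(\\.gz)?$", path)) read_snp_vcf(path)
             else read_snp_tsv(path)
    log <- .log_line(log, "genotypes: loaded ", nrow(calls$variants),
                     " variants from ", path)
    rc <- NULL
  } else {
    s <- cfg$sim
    map <- yeast_map(n_markers = s$n_markers, cm_per_kb = s$cm_per_kb)
    panel <- simulate_founders(s$n_founders, s$n_populations, map,
                               Fst = s$fst,
                               seed = stage_seed(seed, "founders"))
    rc1 <- advanced_intercross(panel, rounds = s$rounds,
                               progeny_per_round = s$progeny_per_round,
                               sample_size = s$sample_size,
                               seed = stage_seed(seed, "intercross"))
    rc <- replicate_with_mitotypes(rc1, s$mitotypes)
    log <- .log_line(log, "simulate: ", s$n_founders, " founders, ",
                     s$rounds, " rounds, ", s$sample_size, " strains x ",
                     length(s$mitotypes), " mitotypes, ",
                     ncol(rc$geno), " markers")

    a <- s$architecture
    main_loci <- .pick_loci(rc, a$main$n, a$main$maf,
                            telomere_mask_bp = cfg$filter$telomere_mask_bp)
    int_loci <- .pick_loci(rc, a$interaction$n, a$interaction$maf,
                           avoid = main_loci,
                           telomere_mask_bp = cfg$filter$telomere_mask_bp)
    arch <- pheno_architecture(
      baseline = stats::qlogis(a$baseline_p),
      main_effects = stats::setNames(rep(a$main$beta, length(main_loci)),
                                     main_loci),
      mito_effects = unlist(a$mito_effects),
      interaction_effects = data.frame(
        marker = int_loci,
        mitotype = a$interaction$mitotype,
        delta = a$interaction$delta,
        stringsAsFactors = FALSE),
      overdispersion = a$overdispersion)
    truth <- list(main_loci = main_loci, interaction_loci = int_loci,
                  architecture = arch)
    pheno_counts <- simulate_petite_counts(
      rc, arch, assay_design(s$colonies, s$replicates),
      seed = stage_seed(seed, "phenotype"))
    log <- .log_line(log, "phenotype: planted main ",
                     paste(main_loci, collapse = ","), "; interaction ",
                     paste(int_loci, collapse = ","))
    calls <- calls_from_collection(rc, missing_rate = s$missing_rate,
                                   seed = stage_seed(seed, "missingness"))
    covars <- strain_genotypes(rc)$strains
  }
  if (!is.null(cfg$inputs$phenotypes)) {
    path <- cfg$inputs$phenotypes
    if (!file.exists(path)) stop("file not found: ", path)
    pheno_counts <- utils::read.delim(path, stringsAsFactors = FALSE)
    log <- .log_line(log, "phenotype: loaded ", nrow(pheno_counts),
                     " assay rows from ", path)
  }
  if (is.null(pheno_counts))
    stop("no phenotype source: supply inputs$phenotypes or simulate")

  # --- SNP table -------------------------------------------------------
  fl <- cfg$filter
  built <- build_snp_table(calls, telomere_mask_bp = fl$telomere_mask_bp,
                           maf_threshold = fl$maf_threshold,
                           merge_adjacent = fl$merge_adjacent)
  tab <- built$table
  log <- .log_line(log, "filter: ", built$report$variants_in[1], " -> ",
                   utils::tail(built$report$variants_out, 1),
                   " variants (mask=", fl$telomere_mask_bp,
                   ", maf>=", fl$maf_threshold, ")")

  # --- scan ------------------------------------------------------------
  sc <- cfg$scan
  spec <- model_spec(family = sc$family, covariates = sc$covariates,
                     n_pcs = sc$n_pcs,
                     condition_snps = as.character(sc$condition_snps),
                     main_fdr = sc$main_fdr,
                     interaction_fdr = sc$interaction_fdr)
  pheno <- strain_petite_means(pheno_counts, scale = sc$response_scale)
  if (sc$family == "binomial") {
    agg <- stats::aggregate(
      cbind(petite_count, total_count) ~ strain_id + mitotype,
      data = pheno_counts, FUN = sum)
    pheno <- merge(pheno, agg, by = c("strain_id", "mitotype"),
                   sort = TRUE)
  }
  pheno <- pheno[order(pheno$strain_id, pheno$mitotype), , drop = FALSE]
  scan <- scan_mitonuclear(pheno, tab, covariates = covars, spec = spec)
  scan$delta <- unname(effect_sizes(tab, pheno)[scan$snp_id])
  log <- .log_line(log, "scan: family=", sc$family, " response=",
                   sc$response_scale, " pcs=", sc$n_pcs,
                   if (length(spec$condition_snps))
                     paste0(" conditioned_on=",
                            paste(spec$condition_snps, collapse = ","))
                   else "")

  sig_main <- scan[!is.na(scan$q_main) & scan$q_main < sc$main_fdr, ,
                   drop = FALSE]
  sig_int <- scan[!is.na(scan$q_int) & scan$q_int < sc$interaction_fdr, ,
                  drop = FALSE]
  log <- .log_line(log, "hits: ", nrow(sig_main), " main (q<",
                   sc$main_fdr, "), ", nrow(sig_int), " interaction (q<",
                   sc$interaction_fdr, ")")
  qtl_int <- collapse_qtls(
    data.frame(snp_id = sig_int$snp_id, chrom = sig_int$chrom,
               pos = sig_int$pos, p = sig_int$p_int,
               stringsAsFactors = FALSE),
    merge_window_bp = cfg$annotate$merge_window_bp)

  # --- optional annotation / mito features -----------------------------
  annotation <- NULL
  if (!is.null(cfg$annotate$gff)) {
    gm <- read_gene_models(cfg$annotate$gff)
    annotation <- assign_snp_to_genes(
      data.frame(snp_id = sig_int$snp_id, chrom = sig_int$chrom,
                 pos = sig_int$pos, stringsAsFactors = FALSE),
      gm, upstream_window = cfg$annotate$upstream_window)
    log <- .log_line(log, "annotate: ", nrow(annotation),
                     " SNP-gene assignments")
  }
  mitofeat <- NULL
  if (!is.null(cfg$mitofeat$fasta)) {
    if (!file.exists(cfg$mitofeat$fasta))
      stop("file not found: ", cfg$mitofeat$fasta)
    lib <- if (is.null(cfg$mitofeat$motif_library)) gc_cluster_library()
           else read_motif_library(cfg$mitofeat$motif_library)
    seqs <- Biostrings::readDNAStringSet(cfg$mitofeat$fasta)
    mitofeat <- mtdna_features(seqs, lib)
    log <- .log_line(log, "mitofeat: ", nrow(mitofeat), " genomes")
  }

  result <- list(config = cfg, collection = rc, truth = truth,
                 snp_table = tab, filter_report = built$report,
                 phenotypes = pheno_counts, pheno_means = pheno,
                 scan = scan, significant_main = sig_main,
                 significant_interaction = sig_int,
                 qtls_interaction = qtl_int, annotation = annotation,
                 mito_features = mitofeat, log = log)

  # --- persist ---------------------------------------------------------
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) utils::write.table(
      df, file.path(cfg$out, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_snp_tsv(tab, file.path(cfg$out, "snp_table.tsv"))
    write_snp_vcf(tab, file.path(cfg$out, "genotypes.vcf"))
    wt(built$report, "filter_report.tsv")
    wt(pheno_counts, "phenotypes.tsv")
    wt(as.data.frame(scan), "scan_results.tsv")
    wt(as.data.frame(sig_main), "significant_main.tsv")
    wt(as.data.frame(sig_int), "significant_interaction.tsv")
    wt(qtl_int$qtls, "qtls_interaction.tsv")
    if (!is.null(annotation)) wt(annotation, "annotation.tsv")
    if (!is.null(mitofeat)) wt(mitofeat, "mito_features.tsv")
    if (!is.null(truth))
      wt(data.frame(locus = c(truth$main_loci, truth$interaction_loci),
                    role = c(rep("main", length(truth$main_loci)),
                             rep("interaction",
                                 length(truth$interaction_loci)))),
         "truth.tsv")
    write_config(cfg, file.path(cfg$out, "config_used.yaml"))
    writeLines(log, file.path(cfg$out, "log.txt"))
  }
  invisible(result)
}

#' Manhattan plot of scan results
#'
#' @param scan An `mnrc_scan` result.
#' @param which `"main"` or `"interaction"` p-values.
#' @param threshold Optional horizontal reference p-value line(s).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the cumulative positions used.
#' @export
plot_manhattan <- function(scan, which = c("main", "interaction"),
                           threshold = NULL, ...) {
  which <- match.arg(which)
  p <- if (which == "main") scan$p_main else scan$p_int
  chrs <- unique(scan$chrom)
  offs <- c(0, cumsum(vapply(chrs, function(ch)
    max(scan$pos[scan$chrom == ch]), numeric(1))))
  x <- scan$pos + offs[match(scan$chrom, chrs)]
  col <- (match(scan$chrom, chrs) %% 2) + 1
  graphics::plot(x, -log10(p), pch = 16, cex = 0.5,
                 col = c("grey30", "steelblue")[col],
                 xlab = "genome position (bp)",
                 ylab = expression(-log[10](italic(p))), ...)
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), lty = 2, col = "red")
  invisible(x)
}
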