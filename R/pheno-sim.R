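#' Phenotype architecture on the logit scale
#'
#' Declares the generative model for petite-colony counts: a baseline
#' log-odds of mtDNA loss, additive nuclear SNP effects, mitotype effects,
#' SNP-by-mitotype interaction effects, covariate effects and an optional
#' variance inflation.  All effects are in logit units; the per-strain
#' petite probability is the inverse logit of the linear predictor.
#'
#' @param baseline Baseline log-odds (default `qlogis(0.05)`, i.e. 5 percent
#'   petites in a reference strain).
#' @param main_effects Named numeric vector, marker id -> beta (logit).
#' @param mito_effects Named numeric vector, mitotype label -> beta_m.
#' @param interaction_effects data.frame with columns `marker`, `mitotype`,
#'   `delta`: the extra log-odds for carriers of the alternate allele in
#'   that mitotype only.
#' @param covariate_effects Named numeric vector, covariate column -> gamma.
#' @param overdispersion Variance inflation factor >= 1 (1 = pure binomial
#'   sampling; > 1 mixes the success probability through a Beta draw).
#' @return An object of class `pheno_architecture`.
#' @export
pheno_architecture <- function(baseline = stats::qlogis(0.05),
                               main_effects = numeric(),
                               mito_effects = numeric(),
                               interaction_effects =
                                 data.frame(marker = character(),
                                            mitotype = character(),
                                            delta = numeric()),
                               covariate_effects = numeric(),
                               overdispersion = 1) {
  if (overdispersion < 1) stop("overdispersion must be >= 1")
  stopifnot(is.data.frame(interaction_effects),
            all(c("marker", "mitotype", "delta") %in%
                  names(interaction_effects)))
  structure(list(baseline = baseline,
                 main_effects = main_effects,
                 mito_effects = mito_effects,
                 interaction_effects = interaction_effects,
                 covariate_effects = covariate_effects,
                 overdispersion = overdispersion),
            class = "pheno_architecture")
}

#' Petite assay design
#'
#' @param colonies Total colonies plated per assay (>= 1; default 500).
#' @param replicates Replicate assays per strain (>= 1; default 1).
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(colonies = 500, replicates = 1) {
  if (colonies < 1) stop("design error: colonies per assay must be >= 1")
  if (replicates < 1) stop("design error: replicates must be >= 1")
  structure(list(colonies = as.integer(colonies),
                 replicates = as.integer(replicates)),
            class = "assay_design")
}

# Linear predictor of the architecture for every collection row.
.petite_eta <- function(rc, arch) {
  eta <- rep(arch$baseline, nrow(rc$strains))
  mk <- colnames(rc$geno)
  if (length(arch$main_effects)) {
    miss <- setdiff(names(arch$main_effects), mk)
    if (length(miss))
      stop("architecture references unknown SNP(s): ",
           paste(miss, collapse = ", "))
    for (s in names(arch$main_effects))
      eta <- eta + arch$main_effects[[s]] * rc$geno[, s]
  }
  if (length(arch$mito_effects)) {
    b <- arch$mito_effects[rc$strains$mitotype]
    b[is.na(b)] <- 0
    eta <- eta + b
  }
  ie <- arch$interaction_effects
  if (nrow(ie)) {
    miss <- setdiff(ie$marker, mk)
    if (length(miss))
      stop("architecture references unknown SNP(s): ",
           paste(miss, collapse = ", "))
    for (i in seq_len(nrow(ie)))
      eta <- eta + ie$delta[i] * rc$geno[, ie$marker[i]] *
        (rc$strains$mitotype == ie$mitotype[i])
  }
  if (length(arch$covariate_effects)) {
    miss <- setdiff(names(arch$covariate_effects), names(rc$strains))
    if (length(miss))
      stop("architecture references unknown covariate(s): ",
           paste(miss, collapse = ", "))
    for (cv in names(arch$covariate_effects))
      eta <- eta + arch$covariate_effects[[cv]] *
        as.numeric(rc$strains[[cv]])
  }
  unname(eta)
}

#' Simulate petite colony counts
#'
#' For every collection row (strain x mitotype) and replicate, draws
#' `petite_count ~ Binomial(colonies, expit(eta))` where `eta` is the
#' architecture's linear predictor.  With `overdispersion > 1` the success
#' probability is first perturbed by a Beta draw calibrated so that the
#' count variance is inflated by that factor.
#'
#' @param rc An `mnrc` collection.
#' @param arch A [pheno_architecture()].
#' @param design An [assay_design()].
#' @param seed Optional integer seed.
#' @return data.frame(strain_id, mitotype, replicate, petite_count,
#'   total_count).
#' @export
simulate_petite_counts <- function(rc, arch, design = assay_design(),
                                   seed = NULL) {
  stopifnot(inherits(rc, "mnrc"), inherits(arch, "pheno_architecture"),
            inherits(design, "assay_design"))
  if (!is.null(seed)) set.seed(seed)
  eta <- .petite_eta(rc, arch)
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  n <- design$colonies
  reps <- design$replicates
  rows <- rep(seq_along(p), each = reps)
  pp <- p[rows]
  if (arch$overdispersion > 1 && n > 1) {
    rho <- (arch$overdispersion - 1) / (n - 1)
    s <- (1 - rho) / rho
    pp <- stats::rbeta(length(pp), pp * s, (1 - pp) * s)
  }
  data.frame(strain_id = rc$strains$strain_id[rows],
             mitotype = rc$strains$mitotype[rows],
             replicate = rep(seq_len(reps), times = length(p)),
             petite_count = stats::rbinom(length(pp), n, pp),
             total_count = n,
             stringsAsFactors = FALSE)
}

#' Simulate a logistic growth curve
#'
#' OD600 readings follow `K / (1 + exp(-r (t - t0)))` plus Gaussian noise,
#' sampled on the given time schedule (hours).
#'
#' @param K Carrying capacity (OD units, > 0).
#' @param r Intrinsic rate per hour (>= 0).
#' @param t0 Inflection time (hours).
#' @param schedule Sampling times in hours (nonempty; default 15-minute
#'   intervals over 24 h).
#' @param noise_sd Gaussian noise SD (OD units).
#' @param seed Optional integer seed.
#' @return data.frame(time_h, od600).
#' @export
simulate_growth_curve <- function(K = 1, r = 0.4, t0 = 8,
                                  schedule = seq(0, 24, by = 0.25),
                                  noise_sd = 0, seed = NULL) {
  if (K <= 0) stop("K must be > 0")
  if (r < 0) stop("r must be >= 0")
  if (!length(schedule)) stop("schedule must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  od <- K / (1 + exp(-r * (schedule - t0)))
  if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
  data.frame(time_h = schedule, od600 = od)
}

#' Simulate qPCR Ct records
#'
#' Cycle thresholds follow `Ct = intercept - log(template) / log(efficiency)`
#' plus Gaussian noise, for a candidate and a control gene measured on the
#' same samples.
#'
#' @param true_expression Candidate-gene template amounts (> 0), one per
#'   sample.
#' @param control_expression Control-gene template amounts (> 0), same
#'   length.
#' @param efficiency Amplification efficiency in (1, 2] (2 = perfect
#'   doubling).
#' @param noise_sd Gaussian Ct noise SD.
#' @param seed Optional integer seed.
#' @param intercept Ct of one template unit (default 35).
#' @return data.frame(sample, ct_candidate, ct_control).
#' @export
simulate_ct_records <- function(true_expression, control_expression,
                                efficiency = 2, noise_sd = 0, seed = NULL,
                                intercept = 35) {
  if (length(true_expression) != length(control_expression))
    stop("expression vectors must have equal length")
  if (any(true_expression <= 0) || any(control_expression <= 0))
    stop("expression values must be > 0")
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must be in (1, 2]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_expression)
  ct_c <- intercept - log(true_expression) / log(efficiency)
  ct_u <- intercept - log(control_expression) / log(efficiency)
  if (noise_sd > 0) {
    ct_c <- ct_c + stats::rnorm(n, 0, noise_sd)
    ct_u <- ct_u + stats::rnorm(n, 0, noise_sd)
  }
  data.frame(sample = sprintf("S%02d", seq_len(n)),
             ct_candidate = ct_c, ct_control = ct_u,
             stringsAsFactors = FALSE)
}
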