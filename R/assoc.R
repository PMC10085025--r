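#' Model specification for the mitonuclear scan
#'
#' @param family `"gaussian"` fits strain-level phenotype means by least
#'   squares and tests nested models with F statistics; `"binomial"` fits
#'   (petite, grande) counts with a logit-link GLM and tests with
#'   likelihood-ratio chi-squared statistics.
#' @param covariates Names of covariate columns (e.g. mating type,
#'   auxotrophy flags) supplied to [scan_mitonuclear()].
#' @param n_pcs Number of genotype principal components included as
#'   covariates (default 10).
#' @param condition_snps Marker ids whose genotypes are added to the
#'   covariate set (conditioning, e.g. on a known large-effect locus).
#' @param main_fdr,interaction_fdr Default significance levels used when
#'   reporting hits (FDR 0.1 percent for main effects, 5 percent for
#'   interactions).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("gaussian", "binomial"),
                       covariates = character(), n_pcs = 10,
                       condition_snps = character(),
                       main_fdr = 0.001, interaction_fdr = 0.05) {
  family <- match.arg(family)
  stopifnot(n_pcs >= 0)
  structure(list(family = family, covariates = covariates, n_pcs = n_pcs,
                 condition_snps = condition_snps, main_fdr = main_fdr,
                 interaction_fdr = interaction_fdr),
            class = "model_spec")
}

#' Principal components of a genotype matrix
#'
#' Missing entries are mean-imputed per variant, variants are centered
#' (optionally standardized by the binomial SD of their allele frequency),
#' and the top `k` left singular directions give per-strain scores.  `k`
#' greater than the matrix rank is truncated with a warning.
#'
#' @param geno Strains x variants matrix of 0/1/NA genotypes (one row per
#'   unique nuclear genotype, not per mitotype replicate).
#' @param k Number of components requested.
#' @param standardize Divide each variant by `sqrt(p(1-p))` (default
#'   FALSE).
#' @return list(scores = strains x k_used matrix, sdev, k_used), class
#'   `genotype_pca`.
#' @export
genotype_pca <- function(geno, k = 10, standardize = FALSE) {
  stopifnot(is.matrix(geno), nrow(geno) >= 2, k >= 0)
  X <- geno
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- mu[na[, 2]]
  X <- sweep(X, 2, mu)
  if (standardize) {
    s <- sqrt(pmax(mu * (1 - mu), 1e-12))
    X <- sweep(X, 2, s, "/")
  }
  sv <- svd(X)
  rank <- sum(sv$d > max(sv$d[1], 0) * 1e-8)
  k_used <- min(k, rank)
  if (k_used < k)
    warning("requested ", k, " components but matrix rank is ", rank,
            "; truncating")
  scores <- if (k_used > 0)
    sv$u[, seq_len(k_used), drop = FALSE] %*% diag(sv$d[seq_len(k_used)],
                                                   k_used)
  else matrix(0, nrow(X), 0)
  rownames(scores) <- rownames(geno)
  if (k_used > 0) colnames(scores) <- paste0("PC", seq_len(k_used))
  structure(list(scores = scores, sdev = sv$d / sqrt(max(1, nrow(X) - 1)),
                 k_used = k_used),
            class = "genotype_pca")
}

# Nested F comparison.  A numerically-zero drop in residual sum of squares
# (exactly additive, noiseless data) is reported as statistic 0, p = 1.
.ftest <- function(rss_r, rank_r, rss_f, rank_f, n) {
  df1 <- rank_f - rank_r
  df2 <- n - rank_f
  if (df1 <= 0 || df2 <= 0)
    return(list(stat = NA_real_, df = df1, p = NA_real_))
  num <- rss_r - rss_f
  if (num <= 1e-10 * max(rss_r, 1e-8))
    return(list(stat = 0, df = df1, p = 1))
  stat <- (num / df1) / (rss_f / df2)
  list(stat = stat, df = df1,
       p = stats::pf(stat, df1, df2, lower.tail = FALSE))
}

.lrt <- function(dev_r, rank_r, dev_f, rank_f) {
  df <- rank_f - rank_r
  if (df <= 0) return(list(stat = NA_real_, df = df, p = NA_real_))
  stat <- max(dev_r - dev_f, 0)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

.fit_binom <- function(X, y, w) {
  f <- suppressWarnings(stats::glm.fit(X, y, weights = w,
                                       family = stats::binomial()))
  list(dev = f$deviance, rank = f$rank, coef = f$coefficients)
}

# Core nested comparison M0 (X0) vs M1 (+ nuclear term) vs M2
# (+ nuclear x mitotype interaction).  Xn: nuclear design columns (a SNP
# genotype, or dummies of any categorical nuclear-background factor);
# D: mitotype dummy columns (levels - 1).
.mitonuclear_fit <- function(X0, Xn, D, family, y, w = NULL) {
  n <- length(y)
  X1 <- cbind(X0, Xn)
  XI <- do.call(cbind, lapply(seq_len(ncol(D)),
                              function(j) Xn * D[, j]))
  X2 <- cbind(X1, XI)
  if (family == "gaussian") {
    f0 <- stats::lm.fit(X0, y)
    f1 <- stats::lm.fit(X1, y)
    f2 <- stats::lm.fit(X2, y)
    main <- .ftest(sum(f0$residuals^2), f0$rank,
                   sum(f1$residuals^2), f1$rank, n)
    intx <- .ftest(sum(f1$residuals^2), f1$rank,
                   sum(f2$residuals^2), f2$rank, n)
    beta <- f1$coefficients[ncol(X0) + 1]
  } else {
    f0 <- .fit_binom(X0, y, w)
    f1 <- .fit_binom(X1, y, w)
    f2 <- .fit_binom(X2, y, w)
    main <- .lrt(f0$dev, f0$rank, f1$dev, f1$rank)
    intx <- .lrt(f1$dev, f1$rank, f2$dev, f2$rank)
    beta <- f1$coef[ncol(X0) + 1]
  }
  list(main = main, int = intx, beta = unname(beta),
       df_int_expected = ncol(D) * ncol(Xn))
}

# Assemble the covariate design shared by all SNPs: intercept, mitotype
# dummies, user covariates, genotype PCs and conditioning genotypes.
.scan_design <- function(phenotype, snp_table, covariates, spec) {
  strains <- colnames(snp_table$calls)
  if (!all(phenotype$strain_id %in% strains))
    stop("phenotype strains missing from the SNP table: ",
         paste(setdiff(phenotype$strain_id, strains), collapse = ", "))
  mito <- factor(phenotype$mitotype,
                 levels = sort(unique(phenotype$mitotype)))
  d0 <- data.frame(mito = mito)
  if (!is.null(covariates) && length(spec$covariates)) {
    miss <- setdiff(spec$covariates, names(covariates))
    if (length(miss))
      stop("covariate column(s) not supplied: ", paste(miss, collapse = ", "))
    ridx <- match(phenotype$strain_id, covariates$strain_id)
    for (cv in spec$covariates) {
      val <- covariates[[cv]][ridx]
      d0[[cv]] <- if (is.character(val)) factor(val) else val
    }
  }
  if (spec$n_pcs > 0) {
    pca <- genotype_pca(t(snp_table$calls), spec$n_pcs)
    if (pca$k_used > 0) {
      sc <- pca$scores[match(phenotype$strain_id, strains), , drop = FALSE]
      for (j in seq_len(ncol(sc))) d0[[colnames(sc)[j]]] <- sc[, j]
    }
  }
  if (length(spec$condition_snps)) {
    miss <- setdiff(spec$condition_snps, rownames(snp_table$calls))
    if (length(miss))
      stop("conditioning SNP(s) not in table: ", paste(miss, collapse = ", "))
    for (s in spec$condition_snps)
      d0[[paste0("cond_", s)]] <-
        snp_table$calls[s, match(phenotype$strain_id, strains)]
  }
  keep <- stats::complete.cases(d0)
  X0 <- stats::model.matrix(~ ., d0[keep, , drop = FALSE])
  D <- stats::model.matrix(~ mito, d0[keep, , drop = FALSE])[, -1,
                                                             drop = FALSE]
  list(X0 = X0, D = D, keep = keep, mito = mito,
       n_levels = nlevels(mito))
}

#' Genome-wide mitonuclear association scan
#'
#' For every SNP fits three nested models: M0 = covariates + mitotype;
#' M1 = M0 + SNP; M2 = M1 + SNP x mitotype.  The main-effect p-value
#' compares M0 vs M1 and the interaction p-value M1 vs M2 with
#' (mitotype levels - 1) numerator degrees of freedom.  The Gaussian family
#' uses F tests on strain-level means; the binomial family uses
#' likelihood-ratio chi-squared tests on (petite, grande) counts.  Strains
#' with a missing call are dropped for that SNP only.  Storey q-values are
#' attached for both test families.
#'
#' @param phenotype data.frame with columns `strain_id`, `mitotype` and a
#'   response: `response` (Gaussian; see [strain_petite_means()]) or
#'   `petite_count` + `total_count` (binomial).
#' @param snp_table An `snp_table` from [build_snp_table()].
#' @param covariates Optional data.frame with `strain_id` plus the columns
#'   named in `spec$covariates`.
#' @param spec A [model_spec()].
#' @return data.frame of class `mnrc_scan`: per SNP id/position, analyzed
#'   sample size, minor allele frequency, main-effect and interaction
#'   statistics, p-values, q-values and a status flag (`ok`, `monomorphic`,
#'   `collinear`, `reduced_df`).
#' @export
scan_mitonuclear <- function(phenotype, snp_table, covariates = NULL,
                             spec = model_spec()) {
  stopifnot(inherits(snp_table, "snp_table"), inherits(spec, "model_spec"))
  if (length(unique(phenotype$mitotype)) < 2)
    stop("need at least 2 mitotype levels for interaction testing")
  des <- .scan_design(phenotype, snp_table, covariates, spec)
  keep <- des$keep
  fam <- spec$family
  if (fam == "gaussian") {
    if (!"response" %in% names(phenotype))
      stop("gaussian family needs a 'response' column")
    y <- phenotype$response[keep]
    w <- NULL
  } else {
    if (!all(c("petite_count", "total_count") %in% names(phenotype)))
      stop("binomial family needs 'petite_count' and 'total_count' columns")
    y <- (phenotype$petite_count / phenotype$total_count)[keep]
    w <- phenotype$total_count[keep]
  }
  strains <- colnames(snp_table$calls)
  ridx <- match(phenotype$strain_id, strains)[keep]
  v <- snp_table$variants
  m <- nrow(v)
  out <- data.frame(
    snp_id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    n = NA_integer_, maf = NA_real_, beta_main = NA_real_,
    stat_main = NA_real_, df_main = NA_integer_, p_main = NA_real_,
    stat_int = NA_real_, df_int = NA_integer_, p_int = NA_real_,
    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    g <- snp_table$calls[i, ridx]
    ok <- !is.na(g)
    gs <- g[ok]
    out$n[i] <- sum(ok)
    if (!length(gs) || stats::var(gs) == 0) {
      out$status[i] <- "monomorphic"
      next
    }
    f <- mean(gs)
    out$maf[i] <- min(f, 1 - f)
    fit <- .mitonuclear_fit(des$X0[ok, , drop = FALSE],
                            matrix(as.numeric(gs), ncol = 1),
                            des$D[ok, , drop = FALSE], fam,
                            y[ok], if (is.null(w)) NULL else w[ok])
    if (is.na(fit$main$p) || fit$main$df == 0) {
      out$status[i] <- "collinear"
      next
    }
    out$beta_main[i] <- fit$beta
    out$stat_main[i] <- fit$main$stat
    out$df_main[i] <- fit$main$df
    out$p_main[i] <- fit$main$p
    out$stat_int[i] <- fit$int$stat
    out$df_int[i] <- fit$int$df
    out$p_int[i] <- fit$int$p
    if (!is.na(fit$int$df) && fit$int$df < des$n_levels - 1)
      out$status[i] <- "reduced_df"
  }
  ok_main <- !is.na(out$p_main)
  if (any(ok_main)) {
    out$q_main <- NA_real_
    out$q_main[ok_main] <- adjust_pvalues(out$p_main[ok_main],
                                          "storey")$adjusted
  }
  ok_int <- !is.na(out$p_int)
  if (any(ok_int)) {
    out$q_int <- NA_real_
    out$q_int[ok_int] <- adjust_pvalues(out$p_int[ok_int],
                                        "storey")$adjusted
  }
  class(out) <- c("mnrc_scan", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Factorial mitonuclear ANOVA
#'
#' Runs the same nested comparison as the genome scan with an arbitrary
#' categorical nuclear-background factor in place of a SNP, reproducing a
#' factorial nuclear x mitotype analysis (e.g. a 4 x 4 cybrid panel) within
#' the association machinery.
#'
#' @param response Numeric phenotype vector (Gaussian family) or a
#'   two-column matrix `cbind(petite, grande)` of counts (binomial).
#' @param nuclear Factor of nuclear backgrounds.
#' @param mitotype Factor of mitotypes.
#' @param covariates Optional numeric design matrix of extra covariates.
#' @param family `"gaussian"` or `"binomial"`.
#' @return list with main-effect and interaction statistics, degrees of
#'   freedom and p-values.
#' @export
mitonuclear_anova <- function(response, nuclear, mitotype,
                              covariates = NULL,
                              family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  nuclear <- factor(nuclear)
  mitotype <- factor(mitotype)
  n <- length(nuclear)
  X0 <- cbind(`(Intercept)` = rep(1, n),
              stats::model.matrix(~ mitotype)[, -1, drop = FALSE])
  if (!is.null(covariates)) X0 <- cbind(X0, covariates)
  Xn <- stats::model.matrix(~ nuclear)[, -1, drop = FALSE]
  D <- stats::model.matrix(~ mitotype)[, -1, drop = FALSE]
  if (family == "gaussian") {
    fit <- .mitonuclear_fit(X0, Xn, D, "gaussian", response)
  } else {
    stopifnot(is.matrix(response), ncol(response) == 2)
    tot <- rowSums(response)
    fit <- .mitonuclear_fit(X0, Xn, D, "binomial",
                            response[, 1] / tot, tot)
  }
  list(stat_main = fit$main$stat, df_main = fit$main$df,
       p_main = fit$main$p, stat_int = fit$int$stat,
       df_int = fit$int$df, p_int = fit$int$p)
}

#' Multiple-testing adjustment
#'
#' `bonferroni` reports the per-test threshold `alpha/m` and adjusted
#' p-values `min(1, p * m)`; `bh` the Benjamini-Hochberg step-up adjusted
#' values; `storey` q-values with the proportion of true nulls estimated by
#' the natural cubic smoother over `lambda = 0.05, 0.10, ..., 0.90`
#' evaluated at 0.90 and clipped to (0, 1].
#'
#' @param p Numeric vector of p-values in [0, 1] (nonempty, no NA).
#' @param method `"bonferroni"`, `"bh"` or `"storey"`.
#' @param alpha Significance level for the Bonferroni threshold.
#' @param pi0 Optional fixed true-null proportion for `storey` (with
#'   `pi0 = 1` q-values equal BH-adjusted values exactly).
#' @return list of class `mt_result` with `method`, `m`, `alpha`,
#'   `threshold` (Bonferroni only), `adjusted` and `pi0` (Storey only).
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "storey"),
                           alpha = 0.05, pi0 = NULL) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no NA")
  m <- length(p)
  threshold <- NULL
  pi0_used <- NULL
  adjusted <- switch(method,
    bonferroni = {
      threshold <- alpha / m
      pmin(1, p * m)
    },
    bh = stats::p.adjust(p, method = "BH"),
    storey = {
      pi0_used <- if (is.null(pi0)) storey_pi0(p) else pi0
      o <- order(p, decreasing = TRUE)
      q <- pmin(1, cummin(pi0_used * m * p[o] / (m:1)))
      res <- numeric(m)
      res[o] <- q
      res
    })
  structure(list(method = method, m = m, alpha = alpha,
                 threshold = threshold, adjusted = adjusted,
                 pi0 = pi0_used),
            class = "mt_result")
}

#' Storey estimate of the true-null proportion
#'
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` is evaluated on the
#' grid `lambda = 0.05 ... 0.90`, smoothed with a cubic smoothing spline
#' (3 df), and read off at `lambda = 0.90`, clipped to (0, 1].
#'
#' @param p P-values.
#' @param lambda Tuning grid.
#' @return Estimated pi0.
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.90, by = 0.05)) {
  m <- length(p)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Allele-frequency-weighted effect size
#'
#' The effect size of a biallelic SNP on petite frequency is
#' `delta = |f0 * pbar0 - f1 * pbar1|`, the absolute difference of the
#' allele frequencies multiplied by the mean strain petite frequency
#' (percent) of each allele class.  Monomorphic input gives NA.
#'
#' @param snp_calls 0/1/NA genotype vector over strains.
#' @param strain_petite_means Mean petite frequency (percent) per strain,
#'   aligned with `snp_calls`.
#' @return Delta in percent units (NA if monomorphic).
#' @export
effect_size_delta <- function(snp_calls, strain_petite_means) {
  if (length(snp_calls) != length(strain_petite_means))
    stop("inputs must have equal length")
  ok <- !is.na(snp_calls) & !is.na(strain_petite_means)
  g <- snp_calls[ok]
  y <- strain_petite_means[ok]
  if (length(unique(g)) < 2) return(NA_real_)
  f0 <- mean(g == 0)
  f1 <- mean(g == 1)
  abs(f0 * mean(y[g == 0]) - f1 * mean(y[g == 1]))
}

#' Effect sizes for every SNP in a table
#'
#' @param snp_table An `snp_table`.
#' @param phenotype data.frame with `strain_id` and `petite_pct` (rows may
#'   repeat per mitotype; strain means are taken first).
#' @return Named numeric vector of deltas (percent).
#' @export
effect_sizes <- function(snp_table, phenotype) {
  stopifnot(all(c("strain_id", "petite_pct") %in% names(phenotype)))
  means <- tapply(phenotype$petite_pct, phenotype$strain_id, mean)
  strains <- colnames(snp_table$calls)
  y <- as.numeric(means[strains])
  vapply(seq_len(nrow(snp_table$variants)), function(i) {
    effect_size_delta(snp_table$calls[i, ], y)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(snp_table$variants$id)
}

#' Pairwise nuclear epistasis scan
#'
#' For each (SNP i, focal SNP j) pair compares an additive model
#' (covariates + SNPi + SNPj) against the model with the SNPi x SNPj
#' product term, within a single mitotype population.  Pairs with i = j or
#' in (near-)perfect linkage disequilibrium are flagged and excluded from
#' the FDR, which is computed with Storey q-values over the tested pairs.
#'
#' @param phenotype data.frame(strain_id, response) for one population.
#' @param snp_table An `snp_table`.
#' @param focal_snps Marker ids of the focal SNPs (e.g. candidate
#'   mitonuclear hits).
#' @param covariates Optional covariate data.frame (see
#'   [scan_mitonuclear()]).
#' @param spec A [model_spec()]; mitotype terms are not used here.
#' @return data.frame(snp_id, focal_snp, stat, df, p, q, status).
#' @export
pairwise_epistasis_scan <- function(phenotype, snp_table, focal_snps,
                                    covariates = NULL,
                                    spec = model_spec(n_pcs = 0)) {
  stopifnot(inherits(snp_table, "snp_table"))
  miss <- setdiff(focal_snps, snp_table$variants$id)
  if (length(miss))
    stop("focal SNP(s) not in table: ", paste(miss, collapse = ", "))
  strains <- colnames(snp_table$calls)
  ridx <- match(phenotype$strain_id, strains)
  if (anyNA(ridx)) stop("phenotype strains missing from the SNP table")
  y <- phenotype$response
  n <- length(y)
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates) && length(spec$covariates)) {
    cv <- covariates[match(phenotype$strain_id, covariates$strain_id),
                     spec$covariates, drop = FALSE]
    cv[] <- lapply(cv, function(x) if (is.character(x)) factor(x) else x)
    X0 <- cbind(X0, stats::model.matrix(~ . - 1, cv))
  }
  if (spec$n_pcs > 0) {
    pca <- genotype_pca(t(snp_table$calls), spec$n_pcs)
    if (pca$k_used > 0)
      X0 <- cbind(X0, pca$scores[ridx, , drop = FALSE])
  }
  res <- list()
  for (fs in focal_snps) {
    gf <- snp_table$calls[fs, ridx]
    for (i in seq_len(nrow(snp_table$variants))) {
      id <- snp_table$variants$id[i]
      if (id == fs) {
        res[[length(res) + 1]] <- data.frame(
          snp_id = id, focal_snp = fs, stat = NA_real_, df = NA_integer_,
          p = NA_real_, status = "self", stringsAsFactors = FALSE)
        next
      }
      gi <- snp_table$calls[i, ridx]
      ok <- !is.na(gi) & !is.na(gf)
      status <- "ok"
      stat <- df <- p <- NA_real_
      if (sum(ok) < 4 || stats::var(gi[ok]) == 0 ||
          stats::var(gf[ok]) == 0) {
        status <- "monomorphic"
      } else if (abs(stats::cor(gi[ok], gf[ok])) > 1 - 1e-10) {
        status <- "excluded_ld"
      } else {
        Xa <- cbind(X0[ok, , drop = FALSE], gi[ok], gf[ok])
        Xi <- cbind(Xa, gi[ok] * gf[ok])
        fa <- stats::lm.fit(Xa, y[ok])
        fi <- stats::lm.fit(Xi, y[ok])
        ft <- .ftest(sum(fa$residuals^2), fa$rank,
                     sum(fi$residuals^2), fi$rank, sum(ok))
        stat <- ft$stat
        df <- ft$df
        p <- ft$p
        if (is.na(p)) status <- "collinear"
      }
      res[[length(res) + 1]] <- data.frame(
        snp_id = id, focal_snp = fs, stat = stat, df = df, p = p,
        status = status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- adjust_pvalues(out$p[ok], "storey")$adjusted
  out
}
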