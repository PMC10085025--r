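#' Petite frequency in percent
#'
#' @param petite_count Number of petite colonies (0 <= petite <= total).
#' @param total_count Total colonies counted (>= 1).
#' @return `100 * petite_count / total_count`, in `[0, 100]`.
#' @export
#' @examples
#' petite_frequency(5, 100)
petite_frequency <- function(petite_count, total_count) {
  if (any(total_count < 1)) stop("total_count must be >= 1")
  if (any(petite_count < 0) || any(petite_count > total_count))
    stop("petite_count must be in [0, total_count]")
  100 * petite_count / total_count
}

#' Strain-level petite phenotype from replicate counts
#'
#' Averages replicate assays per strain x mitotype.  The `percent` scale is
#' the mean petite frequency (used for reporting and effect sizes); the
#' `logit` scale is the empirical logit of pooled counts,
#' `log((x + 0.5) / (n - x + 0.5))`, the scale on which nuclear and
#' mitotype effects act additively in the generative model.
#'
#' @param counts data.frame(strain_id, mitotype, petite_count, total_count)
#'   as returned by [simulate_petite_counts()].
#' @param scale `"percent"` or `"logit"`.
#' @return data.frame(strain_id, mitotype, response) with a `scale`
#'   attribute; `petite_pct` is always included.
#' @export
strain_petite_means <- function(counts, scale = c("percent", "logit")) {
  scale <- match.arg(scale)
  stopifnot(all(c("strain_id", "mitotype", "petite_count", "total_count")
                %in% names(counts)))
  key <- interaction(counts$strain_id, counts$mitotype, drop = TRUE)
  agg <- data.frame(
    strain_id = tapply(counts$strain_id, key, `[`, 1),
    mitotype = tapply(counts$mitotype, key, `[`, 1),
    petite_pct = tapply(100 * counts$petite_count / counts$total_count,
                        key, mean),
    x = tapply(counts$petite_count, key, sum),
    n = tapply(counts$total_count, key, sum),
    stringsAsFactors = FALSE)
  agg$response <- if (scale == "percent") agg$petite_pct else
    log((agg$x + 0.5) / (agg$n - agg$x + 0.5))
  rownames(agg) <- NULL
  out <- agg[, c("strain_id", "mitotype", "response", "petite_pct")]
  attr(out, "scale") <- scale
  out
}

#' Maximal growth rate from sliding-window regression
#'
#' Fits an ordinary least-squares line in every contiguous window of
#' `window` data points along the growth curve and returns the maximum
#' slope (OD per hour).  Slopes use the actual time values, so irregular
#' sampling is handled; windows are over consecutive samples regardless of
#' wall-clock gaps.
#'
#' @param curve data.frame(time_h, od600) with strictly increasing times.
#' @param window Window size in points (default 5).
#' @return Maximum OLS slope.
#' @export
vmax_sliding <- function(curve, window = 5) {
  stopifnot(is.data.frame(curve),
            all(c("time_h", "od600") %in% names(curve)))
  t <- curve$time_h
  y <- curve$od600
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  n <- length(t)
  if (n < window) stop("need at least ", window, " points")
  slopes <- vapply(seq_len(n - window + 1), function(i) {
    idx <- i:(i + window - 1)
    tt <- t[idx] - mean(t[idx])
    sum(tt * y[idx]) / sum(tt^2)
  }, numeric(1))
  max(slopes)
}

#' Colony-size growth proxy
#'
#' The difference between the maximum and minimum colony size across
#' replicates (arbitrary units), used as a proxy for mitotic growth on
#' solid media.
#'
#' @param colony_sizes Numeric vector of replicate colony sizes (>= 1
#'   value).
#' @return max - min.
#' @export
colony_growth_proxy <- function(colony_sizes) {
  if (!length(colony_sizes)) stop("need at least one colony size")
  max(colony_sizes) - min(colony_sizes)
}

#' Relative expression from qPCR Ct values
#'
#' Regresses `1/Ct` of the candidate gene on `1/Ct` of the control gene
#' across samples (ordinary least squares) and returns the residuals as
#' relative expression: higher residual = higher starting mRNA.  This
#' controls for extraction and cDNA synthesis efficiency differences
#' between samples.
#'
#' @param ct_candidate,ct_control Positive Ct vectors over the same >= 3
#'   samples.
#' @return Numeric vector of residuals (sums to 0).
#' @export
qpcr_relative_expression <- function(ct_candidate, ct_control) {
  if (length(ct_candidate) != length(ct_control))
    stop("Ct vectors must have equal length")
  if (length(ct_candidate) < 3) stop("need at least 3 samples")
  if (any(ct_candidate <= 0) || any(ct_control <= 0))
    stop("Ct values must be > 0")
  x <- 1 / ct_control
  y <- 1 / ct_candidate
  if (stats::var(x) == 0)
    stop("control 1/Ct is constant; regression undefined")
  stats::residuals(stats::lm(y ~ x))
}
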