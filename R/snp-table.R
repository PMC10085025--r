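#' Raw variant calls
#'
#' Container for per-strain haploid calls prior to filtering: a variant
#' table (chromosome, 1-based position, ref/alt allele labels) and a
#' variants x strains call matrix with entries 0 (ref), 1 (alt) or NA
#' (missing).  Multiallelic records carry comma-separated alt labels.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param calls Matrix (variants x strains) of 0/1/NA calls with strain ids
#'   as column names.
#' @param chr_lengths Named numeric vector of chromosome lengths in bp.
#' @return An object of class `variant_calls`.
#' @export
variant_calls <- function(variants, calls, chr_lengths) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            is.matrix(calls), nrow(calls) == nrow(variants),
            !is.null(colnames(calls)))
  bad <- setdiff(unique(variants$chrom), names(chr_lengths))
  if (length(bad))
    stop("reference error: unknown chromosome(s) in calls: ",
         paste(bad, collapse = ", "))
  variants$pos <- as.integer(variants$pos)
  ord <- order(match(variants$chrom, names(chr_lengths)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  if (is.null(variants$id))
    variants$id <- sprintf("%s_%d", variants$chrom, variants$pos)
  rownames(variants) <- NULL
  rownames(calls) <- variants$id
  structure(list(variants = variants[, c("id", "chrom", "pos", "ref", "alt")],
                 calls = calls, chr_lengths = chr_lengths),
            class = "variant_calls")
}

#' Extract raw calls from a simulated collection
#'
#' @param rc An `mnrc` collection.
#' @param missing_rate Fraction of calls set to missing at random.
#' @param seed Optional integer seed for the missingness mask.
#' @return A [variant_calls()] object over the unique strains.
#' @export
calls_from_collection <- function(rc, missing_rate = 0, seed = NULL) {
  stopifnot(inherits(rc, "mnrc"))
  sg <- strain_genotypes(rc)
  calls <- t(sg$geno)
  if (missing_rate > 0) {
    if (!is.null(seed)) set.seed(seed)
    calls[stats::runif(length(calls)) < missing_rate] <- NA
  }
  mk <- rc$map$markers
  variants <- data.frame(chrom = mk$chrom, pos = mk$pos_bp,
                         ref = mk$ref, alt = mk$alt, id = mk$id,
                         stringsAsFactors = FALSE)
  chr_len <- stats::setNames(rc$map$chromosomes$length_bp,
                             rc$map$chromosomes$chrom)
  variant_calls(variants, calls, chr_len)
}

#' Build and filter the biallelic SNP table
#'
#' Applies, in order: (1) merging of runs of adjacent variants (consecutive
#' base positions) into one record keyed by the leftmost position with
#' concatenated allele labels; (2) removal of variants within
#' `telomere_mask_bp` of either chromosome end; (3) restriction to
#' biallelic records; (4) removal of variants with minor allele frequency
#' strictly below `maf_threshold` (missing calls are excluded from the
#' frequency denominator; a variant with all calls missing is removed).
#' Every stage's in/out variant counts are recorded in the filter report.
#'
#' When merging, a strain's merged call is the shared value of its calls in
#' the run if they agree (ignoring missing), and missing otherwise.
#'
#' @param x A [variant_calls()] (or an already filtered `snp_table`).
#' @param telomere_mask_bp Mask width from each chromosome end (default
#'   20000 bp).
#' @param maf_threshold Minimum minor allele frequency (default 0.05;
#'   values exactly at the threshold are kept).
#' @param merge_adjacent Merge runs of adjacent variants (default TRUE).
#' @return list(table = `snp_table`, report = `data.frame` with columns
#'   filter, params, variants_in, variants_out).  The report carries a
#'   `note` attribute flagging the MAF threshold convention.
#' @export
build_snp_table <- function(x, telomere_mask_bp = 20000,
                            maf_threshold = 0.05, merge_adjacent = TRUE) {
  stopifnot(inherits(x, c("variant_calls", "snp_table")))
  v <- x$variants
  calls <- x$calls
  report <- data.frame(filter = character(), params = character(),
                       variants_in = integer(), variants_out = integer(),
                       stringsAsFactors = FALSE)
  n_in <- nrow(v)

  # 1. merge adjacent runs (gap 0 in bp)
  if (merge_adjacent && nrow(v) > 1) {
    new_run <- c(TRUE, !(v$chrom[-1] == v$chrom[-nrow(v)] &
                           diff(v$pos) == 1))
    grp <- cumsum(new_run)
    ng <- max(grp)
    if (ng < nrow(v)) {
      firsts <- match(seq_len(ng), grp)
      v2 <- v[firsts, , drop = FALSE]
      calls2 <- calls[firsts, , drop = FALSE]
      for (g in which(tabulate(grp) > 1)) {
        rows <- which(grp == g)
        v2$ref[g] <- paste(v$ref[rows], collapse = "")
        v2$alt[g] <- paste(v$alt[rows], collapse = "")
        sub <- calls[rows, , drop = FALSE]
        calls2[g, ] <- apply(sub, 2, function(cc) {
          u <- unique(cc[!is.na(cc)])
          if (length(u) == 1) u else NA
        })
      }
      v <- v2
      calls <- calls2
    }
  }
  report <- rbind(report, data.frame(
    filter = "merge_adjacent",
    params = if (merge_adjacent) "gap=0,keep=leftmost" else "disabled",
    variants_in = n_in, variants_out = nrow(v)))

  # 2. telomere mask
  n_in <- nrow(v)
  len <- x$chr_lengths[v$chrom]
  keep <- v$pos > telomere_mask_bp & v$pos <= len - telomere_mask_bp
  v <- v[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  report <- rbind(report, data.frame(
    filter = "telomere_mask",
    params = sprintf("mask_bp=%d", as.integer(telomere_mask_bp)),
    variants_in = n_in, variants_out = nrow(v)))

  # 3. biallelic only
  n_in <- nrow(v)
  keep <- !grepl(",", v$alt, fixed = TRUE) & !grepl(",", v$ref, fixed = TRUE)
  v <- v[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  report <- rbind(report, data.frame(
    filter = "biallelic", params = "",
    variants_in = n_in, variants_out = nrow(v)))

  # 4. MAF filter (strictly below threshold removed; all-missing removed)
  n_in <- nrow(v)
  if (nrow(v)) {
    f <- rowMeans(calls == 1, na.rm = TRUE)
    maf <- pmin(f, 1 - f)
    keep <- !is.nan(maf) & maf >= maf_threshold
    v <- v[keep, , drop = FALSE]
    calls <- calls[keep, , drop = FALSE]
  }
  report <- rbind(report, data.frame(
    filter = "maf",
    params = sprintf("maf>=%g", maf_threshold),
    variants_in = n_in, variants_out = nrow(v)))
  attr(report, "note") <- paste(
    "MAF threshold is a required configuration value (default 0.05,",
    "boundary kept); missing calls excluded from the denominator.")

  rownames(v) <- NULL
  rownames(calls) <- v$id
  tab <- structure(list(variants = v, calls = calls,
                        chr_lengths = x$chr_lengths, report = report),
                   class = "snp_table")
  list(table = tab, report = report)
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", nrow(x$variants), "variants x", ncol(x$calls),
      "strains\n")
  invisible(x)
}

#' Per-variant allele statistics
#'
#' Frequencies are computed over non-missing haploid calls.  A variant with
#' every call missing is flagged `all_missing` with undefined frequencies.
#'
#' @param table An `snp_table` (or `variant_calls`).
#' @return data.frame(snp_id, alt_freq, maf, missing_frac, status).
#' @export
allele_stats <- function(table) {
  stopifnot(inherits(table, c("snp_table", "variant_calls")))
  if (!nrow(table$variants)) stop("empty table")
  calls <- table$calls
  f <- rowMeans(calls == 1, na.rm = TRUE)
  f[is.nan(f)] <- NA
  data.frame(snp_id = table$variants$id,
             alt_freq = f,
             maf = pmin(f, 1 - f),
             missing_frac = rowMeans(is.na(calls)),
             status = ifelse(is.na(f), "all_missing", "ok"),
             stringsAsFactors = FALSE)
}

#' Maximum allele-frequency difference between mitotype populations
#'
#' For each variant, computes the alternate allele frequency within each
#' mitotype's strain set and returns the largest absolute pairwise
#' difference.  In a perfectly isonuclear collection this is 0 everywhere;
#' values above 0 arise when the mitotype populations contain different
#' strains or different missingness.
#'
#' @param table An `snp_table`.
#' @param membership data.frame(strain_id, mitotype) listing the strains
#'   present in each mitotype population.
#' @return data.frame with per-mitotype frequencies and `max_diff`.
#' @export
mitotype_freq_diff <- function(table, membership) {
  stopifnot(inherits(table, c("snp_table", "variant_calls")),
            is.data.frame(membership),
            all(c("strain_id", "mitotype") %in% names(membership)))
  groups <- if (is.factor(membership$mitotype))
    levels(membership$mitotype) else sort(unique(membership$mitotype))
  freqs <- sapply(groups, function(g) {
    ss <- membership$strain_id[membership$mitotype == g]
    if (!length(ss)) stop("mitotype group '", g, "' is empty")
    miss <- setdiff(ss, colnames(table$calls))
    if (length(miss))
      stop("strains not in table for mitotype '", g, "': ",
           paste(miss, collapse = ", "))
    rowMeans(table$calls[, ss, drop = FALSE] == 1, na.rm = TRUE)
  })
  freqs <- matrix(freqs, ncol = length(groups),
                  dimnames = list(table$variants$id, groups))
  cmb <- utils::combn(length(groups), 2)
  md <- apply(freqs, 1, function(fr)
    max(abs(fr[cmb[1, ]] - fr[cmb[2, ]])))
  out <- data.frame(snp_id = table$variants$id, stringsAsFactors = FALSE)
  for (g in groups) out[[paste0("freq_", g)]] <- freqs[, g]
  out$max_diff <- unname(md)
  out
}
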