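# Batched meiosis engine.  All parent pairs share one crossover realization
# per gamete, applied to every tracked layer (alleles, ancestry) and to
# "hidden" loci (mating type, auxotrophy marker) that are not in the marker
# set but recombine at their own cM positions.
#
# pairs: named list of list(A = P x M matrix, B = P x M matrix)
# hidden_loci: data.frame(chrom, pos_cm) or NULL
# Returns list(values = named list of P x M gamete matrices,
#              hidden_origin = P x H matrix of parental origins 0/1).
.meiosis_batch <- function(map, pairs, hidden_loci = NULL) {
  P <- nrow(pairs[[1]]$A)
  out <- lapply(pairs, function(pr) pr$A)
  H <- if (is.null(hidden_loci)) 0L else nrow(hidden_loci)
  hid <- if (H) matrix(0L, P, H) else NULL
  for (ci in seq_along(map$chrom_index)) {
    ch <- names(map$chrom_index)[ci]
    idx <- map$chrom_index[[ci]]
    hcol <- if (H) which(hidden_loci$chrom == ch) else integer(0)
    m <- length(idx)
    k <- m + length(hcol)
    if (k == 0) next
    pos <- c(map$markers$pos_cm[idx],
             if (length(hcol)) hidden_loci$pos_cm[hcol])
    ord <- order(pos)
    z1 <- as.integer(stats::runif(P) < 0.5)
    if (k > 1) {
      r <- recomb_fraction(diff(pos[ord]))
      S <- matrix(as.integer(matrix(stats::runif(P * (k - 1)), P) <
                               matrix(r, P, k - 1, byrow = TRUE)), P)
      if (k > 2) for (j in 2:(k - 1)) S[, j] <- S[, j] + S[, j - 1]
      Z <- (z1 + cbind(0L, S)) %% 2L
      Zo <- matrix(0L, P, k)
      Zo[, ord] <- Z
    } else {
      Zo <- matrix(z1, P, 1)
    }
    if (m) {
      sel <- Zo[, seq_len(m), drop = FALSE] == 1L
      for (nm in names(out)) {
        blk <- out[[nm]][, idx, drop = FALSE]
        bb <- pairs[[nm]]$B[, idx, drop = FALSE]
        blk[sel] <- bb[sel]
        out[[nm]][, idx] <- blk
      }
    }
    if (length(hcol)) hid[, hcol] <- Zo[, m + seq_along(hcol), drop = FALSE]
  }
  list(values = out, hidden_origin = hid)
}

# Interpolate a physical position to cM using the chromosome's markers.
.bp_to_cm <- function(map, chrom, pos_bp) {
  idx <- map$chrom_index[[chrom]]
  if (is.null(idx) || length(idx) < 2) {
    rate <- stats::median(map$markers$pos_cm / (map$markers$pos_bp / 1000))
    return(pos_bp / 1000 * rate)
  }
  stats::approx(map$markers$pos_bp[idx], map$markers$pos_cm[idx],
                xout = pos_bp, rule = 2)$y
}

#' Simulate one meiosis between two haploid parents
#'
#' Produces a haploid gamete whose alleles follow a Markov chain along each
#' chromosome: the parental origin switches between adjacent markers with
#' probability given by the Haldane recombination fraction of their cM
#' distance; chromosomes assort independently.
#'
#' @param parent_hap_a,parent_hap_b Haplotype vectors (one allele code per
#'   marker of `map`, in map order).
#' @param map A [genetic_map()].
#' @param seed Optional integer seed.
#' @return Integer gamete vector named by marker id.
#' @export
meiosis <- function(parent_hap_a, parent_hap_b, map, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  m <- nrow(map$markers)
  if (length(parent_hap_a) != m || length(parent_hap_b) != m)
    stop("shape error: parent haplotypes must match the marker set")
  if (!is.null(seed)) set.seed(seed)
  res <- .meiosis_batch(map, list(g = list(A = matrix(parent_hap_a, 1),
                                           B = matrix(parent_hap_b, 1))))
  stats::setNames(drop(res$values$g), map$markers$id)
}

#' Advanced intercross of a founder panel
#'
#' Runs `rounds` rounds of random mating restricted to MATa x MATalpha
#' pairs.  Each round samples mating pairs from the previous generation,
#' performs one meiosis per progeny, and assigns progeny mating types (and
#' the arg8::URA3 auxotrophy marker) by segregation of hidden loci at fixed
#' chromosome positions.  Founder ancestry is tracked per marker.  With
#' `rounds = 0` the sample consists of unrecombined founder haplotypes.
#'
#' @param panel A [simulate_founders()] panel.
#' @param rounds Number of meiosis rounds (>= 0; default 7).
#' @param progeny_per_round Haploid progeny kept per round (default 10000).
#' @param sample_size Number of strains sampled after the last round
#'   (default 181).
#' @param seed Optional integer seed.
#' @param mitotype_label Mitotype assigned to the sampled strains.
#' @param mat_locus,aux_locus Hidden locus positions (`list(chrom, pos_bp)`)
#'   for the mating-type and auxotrophy markers.
#' @return An object of class `mnrc`: list with `strains` (data.frame:
#'   strain_id, mitotype, mating_type, aux_arg8), `geno` (strains x markers
#'   0/1 matrix), `ancestry` (founder index per strain x marker), `map`,
#'   `founder_info`.
#' @export
advanced_intercross <- function(panel, rounds = 7, progeny_per_round = 10000,
                                sample_size = 181, seed = NULL,
                                mitotype_label = "RC1",
                                mat_locus = list(chrom = "chr03",
                                                 pos_bp = 200000),
                                aux_locus = list(chrom = "chr15",
                                                 pos_bp = 566000)) {
  stopifnot(inherits(panel, "founder_panel"))
  if (rounds < 0) stop("rounds must be >= 0")
  if (rounds > 0 && sample_size > progeny_per_round)
    stop("sample_size must not exceed progeny_per_round")
  if (!is.null(seed)) set.seed(seed)
  map <- panel$map

  hap <- panel$haplotypes
  anc <- matrix(rep(seq_len(nrow(hap)), ncol(hap)), nrow(hap))
  mat <- panel$founders$mating_type
  aux <- panel$founders$aux_arg8
  hidden <- data.frame(
    chrom = c(mat_locus$chrom, aux_locus$chrom),
    pos_cm = c(.bp_to_cm(map, mat_locus$chrom, mat_locus$pos_bp),
               .bp_to_cm(map, aux_locus$chrom, aux_locus$pos_bp)))

  if (rounds > 0) {
    for (t in seq_len(rounds)) {
      ia <- which(mat == "MATa")
      ib <- which(mat == "MATalpha")
      if (!length(ia) || !length(ib))
        stop("design error: no compatible MATa x MATalpha mating pairs ",
             "in round ", t)
      pa <- sample(ia, progeny_per_round, replace = TRUE)
      pb <- sample(ib, progeny_per_round, replace = TRUE)
      res <- .meiosis_batch(
        map,
        list(hap = list(A = hap[pa, , drop = FALSE],
                        B = hap[pb, , drop = FALSE]),
             anc = list(A = anc[pa, , drop = FALSE],
                        B = anc[pb, , drop = FALSE])),
        hidden_loci = hidden)
      hap <- res$values$hap
      anc <- res$values$anc
      om <- res$hidden_origin[, 1]
      oa <- res$hidden_origin[, 2]
      mat <- ifelse(om == 0L, mat[pa], mat[pb])
      aux <- ifelse(oa == 0L, aux[pa], aux[pb])
    }
    sel <- sample(nrow(hap), sample_size)
  } else {
    sel <- sample(nrow(hap), sample_size, replace = sample_size > nrow(hap))
  }

  ids <- sprintf("RC%03d", seq_len(sample_size))
  geno <- hap[sel, , drop = FALSE]
  dimnames(geno) <- list(ids, map$markers$id)
  ancestry <- anc[sel, , drop = FALSE]
  dimnames(ancestry) <- list(ids, map$markers$id)
  strains <- data.frame(strain_id = ids,
                        mitotype = mitotype_label,
                        mating_type = mat[sel],
                        aux_arg8 = aux[sel],
                        stringsAsFactors = FALSE)
  structure(list(strains = strains, geno = geno, ancestry = ancestry,
                 map = map, founder_info = panel$founders),
            class = "mnrc")
}

#' @export
print.mnrc <- function(x, ...) {
  cat("mnrc collection:", length(unique(x$strains$strain_id)), "strains x",
      length(unique(x$strains$mitotype)), "mitotype(s),",
      ncol(x$geno), "markers\n")
  invisible(x)
}

#' Replicate a collection across mitotypes
#'
#' Expands a one-row-per-strain collection so that every strain appears once
#' per mitotype label, with identical nuclear genotypes and covariates
#' within a strain (isonuclear replication).
#'
#' @param rc An `mnrc` collection with one row per strain.
#' @param mitotypes Character vector of distinct mitotype labels.
#' @return An `mnrc` with `length(mitotypes)` rows per strain.
#' @export
replicate_with_mitotypes <- function(rc, mitotypes = c("RC1", "RC2", "RC3")) {
  stopifnot(inherits(rc, "mnrc"))
  if (anyDuplicated(mitotypes)) stop("duplicate mitotype labels")
  if (anyDuplicated(rc$strains$strain_id))
    stop("integrity error: duplicated strain_id in input collection")
  n <- nrow(rc$strains)
  k <- length(mitotypes)
  rep_idx <- rep(seq_len(n), each = k)
  strains <- rc$strains[rep_idx, , drop = FALSE]
  strains$mitotype <- rep(mitotypes, times = n)
  rownames(strains) <- NULL
  out <- rc
  out$strains <- strains
  out$geno <- rc$geno[rep_idx, , drop = FALSE]
  rownames(out$geno) <- NULL
  if (!is.null(rc$ancestry)) {
    out$ancestry <- rc$ancestry[rep_idx, , drop = FALSE]
    rownames(out$ancestry) <- NULL
  }
  out
}

#' Unique nuclear genotypes of a collection
#'
#' Collapses mitotype replicates to one row per strain (the nuclear
#' genotype matrix used for PCA and SNP-table construction).
#'
#' @param rc An `mnrc`.
#' @return list(strains = data.frame without mitotype column, geno = matrix).
#' @export
strain_genotypes <- function(rc) {
  stopifnot(inherits(rc, "mnrc"))
  keep <- !duplicated(rc$strains$strain_id)
  st <- rc$strains[keep, setdiff(names(rc$strains), "mitotype"),
                   drop = FALSE]
  rownames(st) <- NULL
  geno <- rc$geno[keep, , drop = FALSE]
  rownames(geno) <- st$strain_id
  list(strains = st, geno = geno)
}

#' Genome-wide founder ancestry fractions
#'
#' @param rc An `mnrc` with ancestry tracks.
#' @return Named numeric vector of per-founder genome fractions (sums to 1).
#' @export
founder_shares <- function(rc) {
  stopifnot(inherits(rc, "mnrc"), !is.null(rc$ancestry))
  nf <- nrow(rc$founder_info)
  counts <- tabulate(rc$ancestry, nbins = nf)
  stats::setNames(counts / sum(counts), rc$founder_info$founder_id)
}

#' Mean pairwise LD (r-squared) between distant markers
#'
#' Computes the squared Pearson correlation between genotype columns for
#' marker pairs on the same chromosome separated by at least `min_cm`
#' centimorgans, over unique strains.  Monomorphic markers are skipped.
#'
#' @param rc An `mnrc`.
#' @param min_cm Minimum cM separation (default 25).
#' @param max_pairs Cap on the number of pairs (taken deterministically,
#'   evenly spaced through the pair list).
#' @return Mean r-squared (NA if no eligible pairs).
#' @export
ld_mean_r2 <- function(rc, min_cm = 25, max_pairs = 2000) {
  sg <- strain_genotypes(rc)
  g <- sg$geno
  mk <- rc$map$markers
  poly <- which(apply(g, 2, stats::var) > 0)
  pairs <- list()
  for (ch in unique(mk$chrom)) {
    idx <- intersect(which(mk$chrom == ch), poly)
    if (length(idx) < 2) next
    cm <- mk$pos_cm[idx]
    dd <- abs(outer(cm, cm, "-")) >= min_cm
    w <- which(dd & upper.tri(dd), arr.ind = TRUE)
    if (nrow(w)) pairs[[ch]] <- cbind(idx[w[, 1]], idx[w[, 2]])
  }
  if (!length(pairs)) return(NA_real_)
  pw <- do.call(rbind, pairs)
  if (nrow(pw) > max_pairs)
    pw <- pw[round(seq(1, nrow(pw), length.out = max_pairs)), , drop = FALSE]
  r2 <- vapply(seq_len(nrow(pw)), function(i) {
    stats::cor(g[, pw[i, 1]], g[, pw[i, 2]])^2
  }, numeric(1))
  mean(r2)
}
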