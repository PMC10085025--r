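#' Haldane recombination fraction
#'
#' Converts a genetic map distance into a recombination fraction under the
#' Haldane mapping function (Poisson crossovers, no interference):
#' \eqn{r = (1 - e^{-2d/100})/2} for a distance \eqn{d} in centimorgans.
#'
#' @param d_cm Numeric vector of map distances in centimorgans (>= 0).
#' @return Recombination fractions in `[0, 0.5)`.
#' @export
#' @examples
#' recomb_fraction(c(0, 1, 50, 1e6))
recomb_fraction <- function(d_cm) {
  if (any(d_cm < 0)) stop("map distances must be non-negative")
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Construct a genetic map
#'
#' A genetic map carries chromosome lengths and marker positions in physical
#' (bp, 1-based) and genetic (cM) coordinates.  Within a chromosome the cM
#' positions must be nondecreasing in bp order, and every marker must lie on
#' exactly one declared chromosome.
#'
#' @param chromosomes data.frame with columns `chrom` and `length_bp`.
#' @param markers data.frame with columns `chrom`, `pos_bp`, `pos_cm`, and
#'   optionally `id`, `ref`, `alt`.  Missing ids default to `<chrom>_<pos>`;
#'   missing ref/alt allele labels default to `"A"`/`"G"`.
#' @return An object of class `genetic_map`.
#' @seealso [yeast_map()] for a ready-made 16-chromosome map.
#' @export
genetic_map <- function(chromosomes, markers) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(markers))
  if (!all(c("chrom", "length_bp") %in% names(chromosomes)))
    stop("chromosomes needs columns 'chrom' and 'length_bp'")
  if (!all(c("chrom", "pos_bp", "pos_cm") %in% names(markers)))
    stop("markers needs columns 'chrom', 'pos_bp' and 'pos_cm'")
  if (any(chromosomes$length_bp <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  bad <- setdiff(unique(markers$chrom), chromosomes$chrom)
  if (length(bad))
    stop("markers on unknown chromosome(s): ", paste(bad, collapse = ", "))

  chromosomes$chrom <- as.character(chromosomes$chrom)
  markers$chrom <- as.character(markers$chrom)
  ord <- order(match(markers$chrom, chromosomes$chrom), markers$pos_bp)
  markers <- markers[ord, , drop = FALSE]
  if (is.null(markers$id))
    markers$id <- sprintf("%s_%d", markers$chrom, markers$pos_bp)
  if (is.null(markers$ref)) markers$ref <- "A"
  if (is.null(markers$alt)) markers$alt <- "G"
  if (anyDuplicated(markers$id)) stop("duplicated marker ids")

  len <- stats::setNames(chromosomes$length_bp, chromosomes$chrom)
  for (ch in unique(markers$chrom)) {
    m <- markers[markers$chrom == ch, ]
    if (any(m$pos_bp < 1) || any(m$pos_bp > len[[ch]]))
      stop("marker position outside chromosome ", ch)
    if (anyDuplicated(m$pos_bp)) stop("duplicated marker positions on ", ch)
    if (is.unsorted(m$pos_cm)) stop("cM positions must be nondecreasing on ", ch)
  }
  rownames(markers) <- NULL
  obj <- list(chromosomes = chromosomes,
              markers = markers[, c("id", "chrom", "pos_bp", "pos_cm",
                                    "ref", "alt")])
  obj$chrom_index <- split(seq_len(nrow(markers)),
                           factor(markers$chrom, levels = chromosomes$chrom))
  class(obj) <- "genetic_map"
  obj
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers\n")
  invisible(x)
}

# Approximate S. cerevisiae (R64) chromosome lengths in bp.
.yeast_chrom_lengths <- c(
  230218, 813184, 316620, 1531933, 576874, 270161, 1090940, 562643,
  439888, 745751, 666816, 1078177, 924431, 784333, 1091291, 948066)

#' Yeast-like 16-chromosome genetic map
#'
#' Builds a map with the 16 S. cerevisiae chromosome lengths and `n_markers`
#' biallelic markers spaced evenly in bp, allocated to chromosomes in
#' proportion to their physical length.  Genetic positions use a constant
#' cM/kb rate (default 0.35 cM/kb, the genome-wide yeast average).
#'
#' @param n_markers Total number of markers (default 1200).
#' @param cm_per_kb Map expansion rate in cM per kb.
#' @param end_gap_bp Distance of the outermost markers from each chromosome
#'   end (default 10 kb, so a default telomere mask removes the ends).
#' @return A `genetic_map`.
#' @export
yeast_map <- function(n_markers = 1200, cm_per_kb = 0.35, end_gap_bp = 10000) {
  stopifnot(n_markers >= 16, cm_per_kb > 0)
  len <- .yeast_chrom_lengths
  chrom <- sprintf("chr%02d", seq_along(len))
  n_chr <- pmax(3L, round(n_markers * len / sum(len)))
  markers <- do.call(rbind, lapply(seq_along(len), function(i) {
    pos <- round(seq(end_gap_bp, len[i] - end_gap_bp, length.out = n_chr[i]))
    data.frame(chrom = chrom[i], pos_bp = pos,
               pos_cm = pos / 1000 * cm_per_kb)
  }))
  # deterministic ref/alt labels cycling over transversion pairs
  pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                  byrow = TRUE)
  k <- (seq_len(nrow(markers)) - 1L) %% 4L + 1L
  markers$ref <- pairs[k, 1]
  markers$alt <- pairs[k, 2]
  genetic_map(data.frame(chrom = chrom, length_bp = len), markers)
}

# Derive an independent per-stage RNG seed from a master seed.  The
# derivation is a fixed affine hash of the stage name, so any stage can be
# re-run in isolation and still reproduce the full-pipeline stream.
#' @rdname run_end_to_end
#' @param master Integer master seed.
#' @param stage Stage name (character scalar).
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 104729
  as.integer((abs(as.numeric(master)) * 48271 + h * 9973) %% 2147483647)
}
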