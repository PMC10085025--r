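# Mitochondrial genome features: GC content and GC-cluster detection.
# Yeast mtDNA is a long AT-rich sequence interrupted by short (~30-40 bp)
# mobile GC-rich elements ("GC-clusters") that fall into homology classes;
# cluster load varies between mitotypes and is a candidate driver of mtDNA
# instability.

.as_dna <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  if (methods::is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1)
    return(x[[1]])
  }
  Biostrings::DNAString(toupper(as.character(x)))
}

#' GC percentage of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity codes are excluded from
#' both numerator and denominator.  The value is invariant under reverse
#' complement.
#'
#' @param sequence Character string, `DNAString`, or length-1
#'   `DNAStringSet`.
#' @return GC percent in [0, 100].
#' @export
gc_percent <- function(sequence) {
  s <- .as_dna(sequence)
  if (length(s) == 0) stop("empty sequence")
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) {
    warning("sequence has no unambiguous A/C/G/T bases")
    return(NA_real_)
  }
  unname(100 * (f[["C"]] + f[["G"]]) / denom)
}

#' GC-cluster motif library
#'
#' One or more motif sequences per homology class, with a shared maximum
#' mismatch tolerance used during scanning.
#'
#' @param class Character vector of class labels (e.g. M1...M9).
#' @param motif Uppercase nucleotide motifs, same length as `class`.
#' @param max_mismatch Mismatch tolerance (default 2).
#' @return data.frame of class `motif_library`.
#' @export
motif_library <- function(class, motif, max_mismatch = 2) {
  if (!length(class)) stop("empty motif library")
  motif <- toupper(motif)
  if (any(!nzchar(motif)) || any(grepl("[^ACGT]", motif)))
    stop("motifs must be nonempty uppercase A/C/G/T sequences")
  df <- data.frame(class = as.character(class), motif = motif,
                   stringsAsFactors = FALSE)
  attr(df, "max_mismatch") <- max_mismatch
  class(df) <- c("motif_library", "data.frame")
  df
}

#' Read a motif library from TSV or FASTA
#'
#' TSV: two columns `class`, `motif` (header optional).  FASTA: the record
#' name up to the first `_` or space is the class label.
#'
#' @param path File path.
#' @param max_mismatch Mismatch tolerance attached to the library.
#' @return A [motif_library()].
#' @export
read_motif_library <- function(path, max_mismatch = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    cls <- sub("[_ ].*$", "", names(ss))
    return(motif_library(cls, as.character(ss), max_mismatch))
  }
  df <- utils::read.table(path, header = grepl("class", first),
                          sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("class", "motif"))
  motif_library(df$class, df$motif, max_mismatch)
}

#' Bundled synthetic GC-cluster motif library
#'
#' Nine synthetic palindromic GC-rich motif classes (M1-M9) shipped with
#' the package for testing and examples.  The classes are mutually distant
#' in Hamming distance so that detection is unambiguous at the default
#' mismatch tolerance.  They are synthetic stand-ins, not the published
#' cluster consensus sequences.
#'
#' @param max_mismatch Mismatch tolerance (default 2).
#' @return A [motif_library()].
#' @export
gc_cluster_library <- function(max_mismatch = 2) {
  read_motif_library(system.file("extdata", "gc_cluster_motifs.tsv",
                                 package = "mitoscan", mustWork = TRUE),
                     max_mismatch)
}

#' Detect GC-cluster motifs in a sequence
#'
#' Scans both strands for motif matches within the library's mismatch
#' tolerance, then assigns matches greedily left to right without overlap
#' (deterministic: ties broken by position, class label, then forward
#' strand first).  A match and its reverse complement at the same locus
#' therefore count once, as appropriate for palindromic motifs.
#'
#' @param sequence Character, `DNAString` or length-1 `DNAStringSet`.
#' @param library A [motif_library()].
#' @param max_mismatch Override of the library tolerance.
#' @return list(counts = named integer vector per class, matches =
#'   data.frame(class, start, end, strand) with 1-based coordinates).
#' @export
detect_gc_clusters <- function(sequence, library,
                               max_mismatch = attr(library, "max_mismatch")) {
  if (!inherits(library, "motif_library") || !nrow(library))
    stop("empty motif library")
  s <- .as_dna(sequence)
  found <- list()
  for (i in seq_len(nrow(library))) {
    pat <- Biostrings::DNAString(library$motif[i])
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      mm <- Biostrings::matchPattern(qq, s, max.mismatch = max_mismatch)
      if (length(mm))
        found[[length(found) + 1]] <- data.frame(
          class = library$class[i],
          start = Biostrings::start(mm), end = Biostrings::end(mm),
          strand = strand, stringsAsFactors = FALSE)
    }
  }
  classes <- unique(library$class)
  counts <- stats::setNames(integer(length(classes)), classes)
  if (!length(found))
    return(list(counts = counts,
                matches = data.frame(class = character(), start = integer(),
                                     end = integer(), strand = character())))
  all_m <- do.call(rbind, found)
  all_m <- all_m[order(all_m$start, all_m$end, all_m$class,
                       all_m$strand != "+"), , drop = FALSE]
  keep <- logical(nrow(all_m))
  last_end <- 0L
  for (i in seq_len(nrow(all_m))) {
    if (all_m$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- all_m$end[i]
    }
  }
  sel <- all_m[keep, , drop = FALSE]
  tab <- table(factor(sel$class, levels = classes))
  counts[] <- as.integer(tab)
  rownames(sel) <- NULL
  list(counts = counts, matches = sel)
}

#' Simulate a mitochondrial genome with planted GC-clusters
#'
#' Generates an AT-rich random backbone and inserts the requested number of
#' motif instances per class at non-overlapping random positions
#' (replacing backbone bases, so total length is `backbone_length`).
#'
#' @param backbone_length Genome length in bp.
#' @param backbone_gc Backbone GC fraction (default 0.05, AT-rich
#'   intergenic yeast mtDNA).
#' @param class_counts Named integer vector, class -> number of instances.
#' @param library A [motif_library()] providing the class motifs.
#' @param seed Optional integer seed.
#' @return A `DNAString`.
#' @export
simulate_mtgenome <- function(backbone_length = 20000, backbone_gc = 0.05,
                              class_counts = integer(), library = NULL,
                              seed = NULL) {
  if (length(class_counts) && sum(class_counts) > 0) {
    if (is.null(library) || !nrow(library)) stop("empty motif library")
    miss <- setdiff(names(class_counts), library$class)
    if (length(miss))
      stop("no motif for class(es): ", paste(miss, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  prob <- c((1 - backbone_gc) / 2, backbone_gc / 2, backbone_gc / 2,
            (1 - backbone_gc) / 2)
  seq <- sample(c("A", "C", "G", "T"), backbone_length, replace = TRUE,
                prob = prob)
  if (length(class_counts) && sum(class_counts) > 0) {
    inserts <- unlist(lapply(names(class_counts), function(cl) {
      mots <- library$motif[library$class == cl]
      rep(mots[((seq_len(class_counts[[cl]]) - 1L) %% length(mots)) + 1L],
          length.out = class_counts[[cl]])
    }))
    if (any(nchar(inserts) > backbone_length))
      stop("construction error: motif longer than the genome")
    if (sum(nchar(inserts)) > backbone_length)
      stop("construction error: total motif length exceeds the genome")
    taken <- matrix(numeric(0), ncol = 2)
    for (mot in inserts) {
      w <- nchar(mot)
      placed <- FALSE
      for (try in seq_len(10000)) {
        st <- sample.int(backbone_length - w + 1L, 1)
        en <- st + w - 1L
        if (!nrow(taken) ||
            all(en < taken[, 1] - 1 | st > taken[, 2] + 1)) {
          seq[st:en] <- strsplit(mot, "")[[1]]
          taken <- rbind(taken, c(st, en))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("construction error: could not place all motifs without overlap")
    }
  }
  Biostrings::DNAString(paste(seq, collapse = ""))
}

#' Feature table for a set of mitochondrial genomes
#'
#' @param seqs A `DNAStringSet` (or named list / character vector of
#'   sequences).
#' @param library A [motif_library()].
#' @param intron_lengths Optional named numeric vector of total intron
#'   length (bp) per genome.
#' @return data.frame: genome id, length_bp, gc_pct, one count column per
#'   cluster class, total_clusters, intron_bp (if given).
#' @export
mtdna_features <- function(seqs, library, intron_lengths = NULL) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(vapply(seqs, as.character,
                                            character(1)))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("mt%02d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    det <- detect_gc_clusters(seqs[[i]], library)
    out <- data.frame(id = ids[i], length_bp = length(seqs[[i]]),
                      gc_pct = gc_percent(seqs[[i]]),
                      stringsAsFactors = FALSE)
    for (cl in names(det$counts)) out[[cl]] <- det$counts[[cl]]
    out$total_clusters <- sum(det$counts)
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(intron_lengths)) out$intron_bp <- intron_lengths[out$id]
  out
}

#' Correlate mtDNA features with petite frequency
#'
#' Pearson correlation per feature, with the two-sided p-value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom and
#' `R^2 = r^2`.  Zero-variance features are flagged, not errors.
#'
#' @param feature_table data.frame of numeric feature columns (non-numeric
#'   columns are ignored).
#' @param petite_means Numeric vector aligned with the rows.
#' @return data.frame(feature, n, r, r_squared, p, status).
#' @export
correlate_features <- function(feature_table, petite_means) {
  stopifnot(nrow(feature_table) == length(petite_means))
  num <- names(feature_table)[vapply(feature_table, is.numeric,
                                     logical(1))]
  rows <- lapply(num, function(f) {
    x <- feature_table[[f]]
    ok <- !is.na(x) & !is.na(petite_means)
    n <- sum(ok)
    if (n < 3)
      return(data.frame(feature = f, n = n, r = NA_real_,
                        r_squared = NA_real_, p = NA_real_,
                        status = "too_few", stringsAsFactors = FALSE))
    if (stats::sd(x[ok]) == 0 || stats::sd(petite_means[ok]) == 0)
      return(data.frame(feature = f, n = n, r = NA_real_,
                        r_squared = NA_real_, p = NA_real_,
                        status = "zero_variance", stringsAsFactors = FALSE))
    r <- stats::cor(x[ok], petite_means[ok])
    tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    data.frame(feature = f, n = n, r = r, r_squared = r^2, p = p,
               status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
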