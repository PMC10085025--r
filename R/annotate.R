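#' Gene models from coding-sequence intervals
#'
#' @param df data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `strand` (`"+"`/`"-"`), one row per CDS
#'   interval.
#' @return An object of class `gene_models` (a validated data.frame).
#' @export
gene_models <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene", "chrom", "start", "end", "strand") %in% names(df)))
  if (any(df$start > df$end)) stop("CDS start must be <= end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from a GFF3 file
#'
#' Imports CDS features and groups them by gene (the `Parent`, `gene`,
#' `Name` or `ID` attribute, whichever is present first).
#'
#' @param path GFF3 file path.
#' @return A [gene_models()] data.frame.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (!length(gr)) stop("no CDS features in ", path)
  mc <- S4Vectors::mcols(gr)
  pick <- function(field) {
    if (!field %in% names(mc)) return(NULL)
    v <- mc[[field]]
    if (methods::is(v, "List") || is.list(v))
      v <- vapply(v, function(x) if (length(x)) as.character(x[1])
                  else NA_character_, character(1))
    as.character(v)
  }
  gene <- pick("Parent")
  for (f in c("gene", "Name", "ID")) {
    alt <- pick(f)
    if (is.null(gene)) gene <- alt
    else if (!is.null(alt)) gene[is.na(gene)] <- alt[is.na(gene)]
  }
  if (is.null(gene)) stop("no gene attribute found in ", path)
  gene_models(data.frame(
    gene = gene,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE))
}

#' Write gene models to GFF3
#'
#' @param gm A [gene_models()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(gm$start, gm$end),
    strand = gm$strand,
    type = "CDS",
    phase = 0L,
    ID = paste0(gm$gene, "_CDS", stats::ave(seq_len(nrow(gm)), gm$gene,
                                            FUN = seq_along)),
    Parent = gm$gene)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Map SNPs to genes (CDS or upstream window)
#'
#' A SNP maps to a gene if it lies inside any of the gene's CDS intervals
#' (`relation = "cds"`, distance 0), or within `upstream_window` bp 5' of
#' the CDS start on the gene's strand (`relation = "upstream"`, distance in
#' `[1, upstream_window]`).  The CDS start is the translation start: the
#' smallest `start` on `+` genes and the largest `end` on `-` genes.  A SNP
#' may map to several genes.
#'
#' @param snps data.frame(snp_id, chrom, pos).
#' @param models A [gene_models()] data.frame.
#' @param upstream_window Upstream window in bp (default 250,
#'   end-inclusive).
#' @return data.frame(snp_id, gene, relation, distance).
#' @export
assign_snp_to_genes <- function(snps, models, upstream_window = 250) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            inherits(models, "gene_models"))
  bad <- setdiff(unique(snps$chrom), unique(models$chrom))
  if (length(bad))
    stop("reference error: SNP chromosome(s) absent from gene models: ",
         paste(bad, collapse = ", "))
  hits <- list()
  for (g in unique(models$gene)) {
    cds <- models[models$gene == g, , drop = FALSE]
    ch <- cds$chrom[1]
    strand <- cds$strand[1]
    on_chr <- which(snps$chrom == ch)
    if (!length(on_chr)) next
    pos <- snps$pos[on_chr]
    in_cds <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(cds)))
      in_cds <- in_cds | (pos >= cds$start[r] & pos <= cds$end[r])
    if (strand == "+") {
      cds_start <- min(cds$start)
      updist <- cds_start - pos
    } else {
      cds_start <- max(cds$end)
      updist <- pos - cds_start
    }
    upstream <- !in_cds & updist >= 1 & updist <= upstream_window
    sel <- which(in_cds | upstream)
    if (!length(sel)) next
    hits[[g]] <- data.frame(
      snp_id = snps$snp_id[on_chr][sel],
      gene = g,
      relation = ifelse(in_cds[sel], "cds", "upstream"),
      distance = ifelse(in_cds[sel], 0L, updist[sel]),
      stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(snp_id = character(), gene = character(),
                      relation = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(match(out$snp_id, snps$snp_id), out$gene), , drop = FALSE]
}

#' Group significant SNPs into QTL intervals
#'
#' Single-linkage merging: significant SNPs on the same chromosome whose
#' positions are within `merge_window_bp` of the previous member join the
#' same QTL.  Each SNP belongs to exactly one QTL; intervals on a
#' chromosome are disjoint.
#'
#' @param hits data.frame(snp_id, chrom, pos) plus optionally `p` (used to
#'   pick the peak SNP; first member otherwise).
#' @param merge_window_bp Merge window in bp (default 25000; 0 gives one
#'   QTL per SNP).
#' @return list(qtls = data.frame(qtl_id, chrom, start, end, n_snps,
#'   peak_snp, peak_p), members = data.frame(qtl_id, snp_id)).
#' @export
collapse_qtls <- function(hits, merge_window_bp = 25000) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(hits)))
  if (!nrow(hits))
    return(list(qtls = data.frame(qtl_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  n_snps = integer(), peak_snp = character(),
                                  peak_p = numeric()),
                members = data.frame(qtl_id = character(),
                                     snp_id = character())))
  hits <- hits[order(hits$chrom, hits$pos), , drop = FALSE]
  newg <- c(TRUE, !(hits$chrom[-1] == hits$chrom[-nrow(hits)] &
                      diff(hits$pos) <= merge_window_bp))
  grp <- cumsum(newg)
  qtls <- do.call(rbind, lapply(unique(grp), function(g) {
    sub <- hits[grp == g, , drop = FALSE]
    peak <- if ("p" %in% names(sub)) which.min(sub$p) else 1L
    data.frame(qtl_id = sprintf("QTL_%s_%d", sub$chrom[1], min(sub$pos)),
               chrom = sub$chrom[1], start = min(sub$pos),
               end = max(sub$pos), n_snps = nrow(sub),
               peak_snp = sub$snp_id[peak],
               peak_p = if ("p" %in% names(sub)) sub$p[peak] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  members <- data.frame(qtl_id = qtls$qtl_id[grp], snp_id = hits$snp_id,
                        stringsAsFactors = FALSE)
  rownames(qtls) <- rownames(members) <- NULL
  list(qtls = qtls, members = members)
}
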