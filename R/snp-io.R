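# Genotype table input/output: VCF v4.2 with haploid GT calls, and a plain
# TSV matrix.  Both formats round-trip losslessly, including missing calls
# and chromosome lengths (carried as contig records / header comments).

#' Write genotypes as VCF v4.2
#'
#' Haploid calls are written as single-allele GT fields (`0`, `1` or `.`).
#' Chromosome lengths are recorded as contig meta lines.
#'
#' @param table An `snp_table` or [variant_calls()] object.
#' @param path Output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(table, path) {
  stopifnot(inherits(table, c("snp_table", "variant_calls")))
  v <- table$variants
  gt <- table$calls
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mitoscan",
    sprintf("##contig=<ID=%s,length=%d>", names(table$chr_lengths),
            as.integer(table$chr_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"))
  gtc <- gt
  gtc[] <- as.character(gt)
  gtc[is.na(gt)] <- "."
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gtc, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a haploid VCF
#'
#' @param path VCF file path (`.vcf` or `.vcf.gz`).
#' @return A [variant_calls()] object.
#' @export
read_snp_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vv <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vv@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vv, element = "GT")
  calls <- suppressWarnings(matrix(as.integer(gt), nrow(gt),
                                   dimnames = dimnames(gt)))
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         id = fix$ID, stringsAsFactors = FALSE)
  meta <- vv@meta
  contig <- meta[grepl("^##contig=", meta)]
  ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
  lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", contig))
  chr_lengths <- stats::setNames(lens, ids)
  if (!length(chr_lengths))
    chr_lengths <- tapply(variants$pos, variants$chrom, max)
  variant_calls(variants, calls, chr_lengths)
}

#' Write genotypes as a TSV matrix
#'
#' Columns: chrom, pos, id, ref, alt, then one 0/1/`.` column per strain.
#' Chromosome lengths are preserved in `##contig` comment lines.
#'
#' @param table An `snp_table` or [variant_calls()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_tsv <- function(table, path) {
  stopifnot(inherits(table, c("snp_table", "variant_calls")))
  v <- table$variants
  gtc <- table$calls
  gtc[] <- as.character(table$calls)
  gtc[is.na(table$calls)] <- "."
  df <- cbind(v[, c("chrom", "pos", "id", "ref", "alt")],
              as.data.frame(gtc, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##contig=<ID=%s,length=%d>", names(table$chr_lengths),
                     as.integer(table$chr_lengths)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a TSV matrix
#'
#' @param path TSV file written by [write_snp_tsv()].
#' @return A [variant_calls()] object.
#' @export
read_snp_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  contig <- lines[grepl("^##contig=", lines)]
  ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
  lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", contig))
  body <- lines[!grepl("^##", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  variants <- data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                         ref = df$ref, alt = df$alt, id = df$id,
                         stringsAsFactors = FALSE)
  strains <- setdiff(names(df), c("chrom", "pos", "id", "ref", "alt"))
  calls <- as.matrix(df[, strains, drop = FALSE])
  calls[calls == "."] <- NA
  calls <- matrix(as.integer(calls), nrow(calls),
                  dimnames = list(variants$id, strains))
  variant_calls(variants, calls, stats::setNames(lens, ids))
}
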