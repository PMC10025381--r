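# Plain-text readers and writers for the pipeline's stage formats.
# All tables are tab-separated with a header; genotypes are additionally
# exported as VCF (homozygous GT calls, suitable for inbred/DH lines).

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a dosage matrix as TSV
#'
#' @param geno Lines x markers dosage matrix (NA = missing).
#' @param path Output file.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a dosage matrix from TSV
#'
#' @param path File written by [write_dosage_tsv()] (first column `line`).
#' @return Lines x markers numeric matrix.
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write inbred-line genotypes as VCF
#'
#' Emits a minimal VCF 4.2 with GT fields: dosage 0 becomes `0/0`, dosage 1
#' becomes `1/1` (lines are fully homozygous), missing becomes `./.`.
#' Map positions in cM are scaled to integer base-pair-like coordinates
#' (1 cM = 10,000 units) and made strictly increasing within chromosomes.
#'
#' @param geno Lines x markers dosage matrix with values in {0, 1, NA}.
#' @param map Marker map (`marker`, `chrom`, `pos_cM`).
#' @param path Output file.
#' @export
write_vcf <- function(geno, map, path) {
  stopifnot(all(map$marker %in% colnames(geno)))
  vals <- geno[, map$marker, drop = FALSE]
  if (!all(vals %in% c(0, 1) | is.na(vals)))
    stop_invalid("write_vcf: dosages must be 0, 1 or NA (inbred lines)")
  pos <- as.integer(round(map$pos_cM * 1e4)) + 1L
  for (c in unique(map$chrom)) {      # force strictly increasing positions
    i <- which(map$chrom == c)
    pos[i] <- pos[i] + cumsum(c(0L, diff(pos[i]) <= 0L))
  }
  gt <- matrix("./.", nrow(map), nrow(geno))
  gt[t(vals) == 0] <- "0/0"
  gt[t(vals) == 1] <- "1/1"
  body <- cbind(map$chrom, pos, map$marker, "A", "G", ".", "PASS", ".",
                "GT", gt)
  header <- c("##fileformat=VCFv4.2",
              "##source=hybridcv",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read homozygous genotypes from a VCF into a dosage matrix
#'
#' Uses the vcfR package; genotypes `0/0` (or `0|0`) map to dosage 0,
#' `1/1` to 1, anything else (including heterozygous or missing calls)
#' to NA.
#'
#' @param path VCF file.
#' @return Lines x markers dosage matrix.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_invalid("read_genotypes_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt %in% c("0/0", "0|0")] <- 0
  d[gt %in% c("1/1", "1|1")] <- 1
  t(d)
}

#' Write a synthetic dataset to a directory
#'
#' Writes parental genotypes (VCF and dosage TSV), the marker map, line
#' metadata, trial layout, phenotypes and the generative truth (per-hybrid
#' genetic values by trait) as plain-text files.
#'
#' @param dataset A `tc_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(dataset$geno, dataset$map, file.path(dir, "genotypes.vcf"))
  write_dosage_tsv(dataset$geno, file.path(dir, "genotypes.tsv"))
  write_tsv(dataset$map, file.path(dir, "map.tsv"))
  write_tsv(dataset$line_info, file.path(dir, "lines.tsv"))
  write_tsv(dataset$layout, file.path(dir, "layout.tsv"))
  write_tsv(dataset$plots, file.path(dir, "phenotypes.tsv"))
  truth <- do.call(rbind, lapply(dataset$truth, function(ef)
    data.frame(trait = ef$trait, ef$genetic, stringsAsFactors = FALSE)))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
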