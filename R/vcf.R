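#' Read a biallelic dosage matrix from a VCF file
#'
#' Extracts GT calls into alternate-allele dosages 0/1/2 with `./.` (and
#' half-missing calls) as `NA`. Multiallelic records are retained with
#' `is_biallelic = FALSE` (their dosage is the count of non-reference
#' alleles) so that [marker_qc()] can exclude and tally them; indels are
#' flagged from the REF/ALT lengths.
#'
#' @param path VCF file (plain or bgzipped).
#' @return list with `dosage` (markers x individuals), `info` data frame
#'   (`chrom`, `pos`, `id`, `ref`, `alt`, `is_biallelic`, `is_indel`).
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(g) {
    g <- sub("\\|", "/", g)
    parts <- strsplit(g, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".") || any(is.na(p)))
        return(NA_real_)
      sum(as.numeric(p) > 0)
    }, numeric(1))
  }
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  for (cc in seq_len(ncol(gt))) dosage[, cc] <- alleles(gt[, cc])
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = ncol(vcfR::getFIX(v)),
               dimnames = dimnames(vcfR::getFIX(v)))
  ref <- fx[, "REF"]
  alt <- fx[, "ALT"]
  alt[is.na(alt)] <- ""
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  is_biallelic <- n_alt == 1
  alt_lens <- vapply(strsplit(alt, ",", fixed = TRUE), function(a)
    if (length(a)) max(nchar(a)) else 0L, integer(1))
  info <- data.frame(chrom = fx[, "CHROM"],
                     pos = as.integer(fx[, "POS"]),
                     id = fx[, "ID"],
                     ref = ref, alt = alt,
                     is_biallelic = is_biallelic,
                     is_indel = nchar(ref) > 1 | alt_lens > 1,
                     row.names = NULL)
  list(dosage = dosage, info = info)
}

#' Write a dosage matrix as a minimal VCF
#'
#' Inverse of [read_vcf_dosage()] for simulated populations: dosages 0/1/2
#' become `0/0`, `0/1`, `1/1`, and `NA` becomes `./.`.
#'
#' @param geno markers x individuals dosage matrix.
#' @param path output file.
#' @param info optional data frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @return `path`, invisibly.
#' @export
write_vcf_dosage <- function(geno, path, info = NULL) {
  m <- nrow(geno)
  if (is.null(info))
    info <- data.frame(chrom = rep("1", m), pos = seq_len(m) * 100L,
                       id = rownames(geno) %||% sprintf("m%d", seq_len(m)),
                       ref = rep("A", m), alt = rep("T", m))
  gtxt <- matrix("./.", m, ncol(geno))
  gtxt[!is.na(geno) & geno == 0] <- "0/0"
  gtxt[!is.na(geno) & geno == 1] <- "0/1"
  gtxt[!is.na(geno) & geno == 2] <- "1/1"
  samples <- colnames(geno) %||% sprintf("s%d", seq_len(ncol(geno)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  rows <- cbind(info$chrom, info$pos, info$id, info$ref, info$alt,
                ".", "PASS", ".", "GT", gtxt)
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(path)
}
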