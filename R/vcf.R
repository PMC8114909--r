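## Plain-text VCF export/import and pedigree listing.  Writers emit
## minimal VCF 4.2 (biallelic SNVs, GT with '|' for phased and '/' for
## unphased data, optional DS dosage); the reader uses vcfR when
## available.

.vcf_header <- function(chrom, ids, dosage = FALSE) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (dosage)
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
}

.vcf_body <- function(chrom, pos, fields) {
  paste(chrom, sprintf("%.0f", pos), ".", "A", "T", ".", "PASS", ".",
        fields, sep = "\t")
}

#' Write a haplotype panel as a phased VCF
#'
#' Consecutive haplotype pairs form diploid samples with `|`-separated
#' genotypes; the panel must have an even number of haplotypes.
#'
#' @param panel a [HaplotypePanel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHaplotypeVcf <- function(panel, path) {
  stopifnot(is(panel, "HaplotypePanel"))
  H <- haplotypes(panel)
  if (nrow(H) %% 2 != 0)
    stop("panel must have an even number of haplotypes to form samples")
  n <- nrow(H) / 2
  ids <- paste0("H", seq_len(n))
  a <- H[seq(1, 2 * n, 2), , drop = FALSE]
  b <- H[seq(2, 2 * n, 2), , drop = FALSE]
  gt <- matrix(paste0(a, "|", b), nrow = n)
  fields <- apply(gt, 2, paste, collapse = "\t")
  writeLines(c(.vcf_header(chromName(panel), ids),
               .vcf_body(chromName(panel), positions(panel),
                         paste("GT", fields, sep = "\t"))), path)
  invisible(path)
}

#' Write a genotype matrix as an unphased VCF
#'
#' @param gm a [GenotypeMatrix-class]; missing genotypes become `./.`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  G <- genotypes(gm)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(G), ncol(G))
  ok <- !is.na(G)
  gt[ok] <- code[as.character(G[ok])]
  fields <- apply(gt, 2, paste, collapse = "\t")
  writeLines(c(.vcf_header(chromName(gm), sampleIds(gm)),
               .vcf_body(chromName(gm), positions(gm),
                         paste("GT", fields, sep = "\t"))), path)
  invisible(path)
}

#' Write a phased cohort as a VCF with `|`-separated genotypes
#'
#' @param phased a [PhasedCohort-class]; sites with unphased (NA)
#'   haplotypes become `./.`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhasedVcf <- function(phased, path) {
  stopifnot(is(phased, "PhasedCohort"))
  gt <- matrix("./.", nrow(phased@hap1), ncol(phased@hap1))
  ok <- !is.na(phased@hap1) & !is.na(phased@hap2)
  gt[ok] <- paste0(phased@hap1[ok], "|", phased@hap2[ok])
  fields <- apply(gt, 2, paste, collapse = "\t")
  writeLines(c(.vcf_header(phased@chrom, phased@sampleIds),
               .vcf_body(phased@chrom, phased@positions,
                         paste("GT", fields, sep = "\t"))), path)
  invisible(path)
}

#' Write imputed genotypes as a VCF with GT and DS fields
#'
#' @param imputed an [ImputedGenotypes-class].
#' @param chrom chromosome label.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeImputedVcf <- function(imputed, path, chrom = "chr1") {
  stopifnot(is(imputed, "ImputedGenotypes"))
  G <- imputed@hardCalls
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(G), ncol(G))
  ok <- !is.na(G)
  gt[ok] <- code[as.character(G[ok])]
  ds <- matrix(".", nrow(G), ncol(G))
  okd <- !is.na(imputed@dosage)
  ds[okd] <- sprintf("%.4f", imputed@dosage[okd])
  cell <- matrix(paste0(gt, ":", ds), nrow(G))
  fields <- apply(cell, 2, paste, collapse = "\t")
  writeLines(c(.vcf_header(chrom, imputed@sampleIds, dosage = TRUE),
               .vcf_body(chrom, imputed@positions,
                         paste("GT:DS", fields, sep = "\t"))), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires the vcfR package; every genotype must be phased (`|`).
#'
#' @param path VCF file.
#' @return A [HaplotypePanel-class] with two haplotypes per sample.
#' @export
readHaplotypeVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readHaplotypeVcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes in ", path)
  S <- nrow(gt); n <- ncol(gt)
  a <- matrix(as.integer(substr(t(gt), 1, 1)), nrow = n)
  b <- matrix(as.integer(substr(t(gt), 3, 3)), nrow = n)
  H <- matrix(0L, 2 * n, S)
  H[seq(1, 2 * n, 2), ] <- a
  H[seq(2, 2 * n, 2), ] <- b
  HaplotypePanel(H, as.numeric(v@fix[, "POS"]),
                 chrom = unique(v@fix[, "CHROM"])[1])
}

#' Read an (un)phased VCF into a genotype matrix
#'
#' Requires the vcfR package.
#'
#' @param path VCF file.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readGenotypeVcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a <- suppressWarnings(as.integer(substr(t(gt), 1, 1)))
  b <- suppressWarnings(as.integer(substr(t(gt), 3, 3)))
  G <- matrix(a + b, nrow = ncol(gt))
  GenotypeMatrix(G, as.numeric(v@fix[, "POS"]),
                 sampleIds = colnames(gt),
                 chrom = unique(v@fix[, "CHROM"])[1])
}

#' Write a trio pedigree listing
#'
#' Three whitespace-separated columns: child, father, mother.
#'
#' @param cohort a [TrioCohort-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(cohort, path) {
  stopifnot(is(cohort, "TrioCohort"))
  tr <- cohort@trios
  writeLines(c("child father mother",
               paste(tr$child, tr$father, tr$mother)), path)
  invisible(path)
}
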