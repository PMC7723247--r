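# VCF input/output for genotype matrices. Reading goes through vcfR;
# writing is a plain deterministic text formatter so files are stable
# byte-for-byte for a given matrix.

#' Read a VCF into a genotype matrix
#'
#' Parses VCF 4.x via `vcfR`, decomposes multi-allelic records into one
#' biallelic row per alternate allele, and maps genotype calls to alt-allele
#' dosage. Missing (`./.`) and half calls become missing dosages; site
#' ordering is normalized to (chromosome, position).
#'
#' @param path path to a `.vcf` (optionally gzipped) file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(genotype_matrix(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      samples = colnames(v@gt)[-1] %||% character(0),
      dosage = matrix(NA_integer_, 0, max(0L, ncol(v@gt) - 1L))))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  sites <- NULL
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    calls <- strsplit(gt[i, ], "[/|]")
    for (ai in seq_along(alts)) {
      dos <- vapply(calls, function(a) {
        if (length(a) != 2L || any(a == ".") || anyNA(a)) {
          return(NA_integer_)
        }
        sum(a == as.character(ai))
      }, integer(1))
      sites <- rbind(sites, data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[ai], stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- dos
    }
  }
  genotype_matrix(sites, samples, do.call(rbind, rows))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Dosages map to unphased genotypes (`0/0`, `0/1`, `1/1`, `./.`). If a
#' matching `haplotype_set` is supplied the known phase is written instead
#' (`hapP|hapM` with phase bars). Output is deterministic for fixed input.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param hapset optional `haplotype_set` covering the same sites/samples.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, hapset = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=colonymap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  for (chrom in unique(gm$sites$chrom)) {
    writeLines(sprintf("##contig=<ID=%s>", chrom), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (nrow(gm$sites) == 0L) return(invisible(path))
  phased <- NULL
  if (!is.null(hapset)) {
    key_gm <- paste(gm$sites$chrom, gm$sites$pos)
    key_hs <- paste(hapset$sites$chrom, hapset$sites$pos)
    si <- match(key_gm, key_hs)
    pi <- match(gm$samples, hapset$samples)
    if (!anyNA(si) && !anyNA(pi)) {
      phased <- matrix(paste(t(hapset$hapP[pi, si, drop = FALSE]),
                             t(hapset$hapM[pi, si, drop = FALSE]),
                             sep = "|"),
                       nrow = length(si))
    }
  }
  gt_code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  for (i in seq_len(nrow(gm$sites))) {
    gts <- if (!is.null(phased)) phased[i, ] else gt_code(gm$dosage[i, ])
    if (!is.null(phased)) {
      miss <- is.na(gm$dosage[i, ])
      gts[miss] <- "./."
    }
    writeLines(paste(c(gm$sites$chrom[i], gm$sites$pos[i], ".",
                       gm$sites$ref[i], gm$sites$alt[i], ".", "PASS", ".",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
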