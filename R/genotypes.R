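#' Construct a genotype matrix
#'
#' Sites-by-samples alt-allele dosages. `sites` is a data frame with columns
#' `chrom`, `pos` (1-based), `ref`, `alt`; rows are sorted by (chrom, pos) and
#' must be unique. Dosages are 0, 1, 2 or `NA` (missing call).
#'
#' @param sites data frame of site definitions.
#' @param samples character vector of sample ids (column order of `dosage`).
#' @param dosage numeric matrix, `nrow(sites)` x `length(samples)`.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(sites, samples, dosage) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(sites) || ncol(dosage) != length(samples)) {
    stop("dosage must be nrow(sites) x length(samples)")
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  ord <- order(as.character(sites$chrom), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[ord, , drop = FALSE]
  key <- paste(sites$chrom, sites$pos, sites$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, alt) site entries")
  rownames(sites) <- NULL
  dimnames(dosage) <- list(paste(sites$chrom, sites$pos, sep = ":"), samples)
  structure(list(sites = sites, samples = as.character(samples),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%.1f%% missing)\n",
              nrow(x$sites), length(x$samples),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param sites integer/logical index over site rows (optional).
#' @param samples character ids or index over samples (optional).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, sites = NULL, samples = NULL) {
  s <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  if (is.null(samples)) {
    j <- seq_along(x$samples)
  } else if (is.character(samples)) {
    j <- match(samples, x$samples)
    if (anyNA(j)) stop("unknown sample ids: ",
                       paste(samples[is.na(j)], collapse = ", "))
  } else j <- samples
  genotype_matrix(x$sites[s, , drop = FALSE], x$samples[j],
                  x$dosage[s, j, drop = FALSE])
}
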