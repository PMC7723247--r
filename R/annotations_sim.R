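#' Simulate an annotation table for colony variants
#'
#' Companion generator for [simulate_colony()]: joins each simulated site to
#' population allele frequency (a fraction of variants are private, i.e.
#' absent), CADD and GERP scores, tissue expression (CPM) of the host gene,
#' and a consequence class. The planted causal variant is annotated as a
#' private frameshift in a highly brain-expressed gene with the highest
#' CADD score among simulated variants, mirroring the evidence structure of
#' a strong loss-of-function candidate; background variants are mostly
#' noncoding with sub-maximal scores.
#'
#' @param sites site table (`chrom`, `pos`, `ref`, `alt`).
#' @param causal row index of the causal variant.
#' @param p_private probability a background variant is absent from the
#'   population database (default 0.15).
#' @param causal_cadd,causal_cpm annotation of the causal variant (defaults
#'   29.7 and 1075.2).
#' @param seed integer seed.
#' @return annotation data frame suitable for [filter_and_rank()].
#' @export
simulate_annotations <- function(sites, causal, p_private = 0.15,
                                 causal_cadd = 29.7, causal_cpm = 1075.2,
                                 seed = 1) {
  n <- nrow(sites)
  with_seed(seed, {
    af <- stats::rbeta(n, 0.4, 4)
    af[stats::runif(n) < p_private] <- NA
    cons <- sample(c("noncoding", "synonymous", "missense"), n,
                   replace = TRUE, prob = c(0.9, 0.06, 0.04))
    cadd <- pmin(stats::rexp(n, 1 / 4), causal_cadd - 1)
    gerp <- stats::rnorm(n, 0, 2)
    cpm <- stats::rlnorm(n, log(5), 1.5)
    lift <- stats::runif(n) > 0.05
    cadd[!lift] <- NA
    an <- data.frame(
      gene = sprintf("GENE_%s_%d", sites$chrom, sites$pos),
      chrom = sites$chrom, pos = sites$pos, alt = sites$alt,
      consequence = cons, af = af, cadd = cadd, gerp = gerp, cpm = cpm,
      liftover_ok = lift,
      consequence_liftover = cons,
      stringsAsFactors = FALSE
    )
    an$gene[causal] <- "TARGET"
    an$consequence[causal] <- "frameshift"
    an$consequence_liftover[causal] <- "frameshift"
    an$af[causal] <- NA
    an$cadd[causal] <- causal_cadd
    an$cpm[causal] <- causal_cpm
    an$liftover_ok[causal] <- TRUE
    an
  })
}
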