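#' Zygosity filter for a fully penetrant recessive trait
#'
#' A variant is compatible with recessive inheritance if every called
#' affected individual is homozygous for the alt allele (dosage 2) and every
#' called obligate carrier is heterozygous (dosage 1). Sites violating
#' either condition in any called labeled individual fail regardless of how
#' many calls are missing; sites with fewer than `min_called` labeled calls
#' are discarded as under-covered.
#'
#' @param gm a [genotype_matrix()].
#' @param affected character ids of affected individuals (non-empty).
#' @param carriers character ids of obligate carriers (disjoint from
#'   `affected`).
#' @param min_called minimum number of called labeled individuals
#'   (absolute count; default 11, matching a "11 of 14" call-rate rule).
#' @return a `zygosity_result`: list with `sites` (site table with
#'   per-site call counts and `pass`), `pass_idx` (row indices of passing
#'   sites), `affected`, `carriers`, `min_called`.
#' @export
zygosity_filter <- function(gm, affected, carriers, min_called = 11L) {
  affected <- as.character(affected)
  carriers <- as.character(carriers)
  if (length(affected) == 0L) stop("empty affected set")
  if (length(intersect(affected, carriers))) {
    stop("affected and carrier sets overlap: ",
         paste(intersect(affected, carriers), collapse = ", "))
  }
  unknown <- setdiff(c(affected, carriers), gm$samples)
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  min_called <- check_count(min_called, "min_called")
  n_lab <- length(affected) + length(carriers)
  if (min_called > n_lab) {
    stop("min_called (", min_called, ") exceeds number of labeled individuals (",
         n_lab, ")")
  }
  A <- gm$dosage[, affected, drop = FALSE]
  C <- gm$dosage[, carriers, drop = FALSE]
  called_a <- rowSums(!is.na(A))
  called_c <- rowSums(!is.na(C))
  ok_a <- rowSums(A != 2L, na.rm = TRUE) == 0L
  ok_c <- if (length(carriers)) rowSums(C != 1L, na.rm = TRUE) == 0L else TRUE
  # a site with no called affected carries no evidence of homozygosity
  pass <- ok_a & ok_c & (called_a + called_c >= min_called) & called_a > 0L
  sites <- gm$sites
  sites$n_called_affected <- called_a
  sites$n_called_carrier <- called_c
  sites$pass <- pass
  structure(list(sites = sites, pass_idx = which(pass),
                 affected = affected, carriers = carriers,
                 min_called = min_called),
            class = "zygosity_result")
}

#' @export
print.zygosity_result <- function(x, ...) {
  cat(sprintf("zygosity filter: %d / %d sites pass (%d affected, %d carriers, min_called %d)\n",
              length(x$pass_idx), nrow(x$sites), length(x$affected),
              length(x$carriers), x$min_called))
  invisible(x)
}

# Fixed genome windows; a trailing window shorter than half `window_size`
# is merged into the previous one to avoid small-expectation cells.
genome_windows <- function(genome, window_size) {
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    starts <- seq(1, len, by = window_size)
    ends <- pmin(starts + window_size - 1, len)
    if (length(starts) > 1L &&
        (ends[length(ends)] - starts[length(starts)] + 1) < window_size / 2) {
      ends[length(ends) - 1L] <- ends[length(ends)]
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
    data.frame(chrom = genome$chrom[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chi-square test of genomic clustering of passing variants
#'
#' Partitions the genome into fixed windows and tests the observed window
#' counts of zygosity-passing variants against a random genome-wide
#' distribution: uniform expected counts per window (default), or expected
#' counts proportional to the number of tested variants per window (for real
#' data where callable density varies). Chromosomes with no tested variants
#' are excluded from windowing.
#'
#' @param passing data frame with columns `chrom`, `pos` of passing sites
#'   (e.g. `zy$sites[zy$pass_idx, ]`).
#' @param genome data frame `chrom`/`length_bp` defining the windowed genome.
#' @param window_size window width in bp (default 5,000,000).
#' @param tested optional data frame `chrom`/`pos` of all tested sites; used
#'   to exclude untested chromosomes and for the proportional null.
#' @param null `"uniform"` or `"tested_density"`.
#' @return a `cluster_test`: list with `windows` (observed, expected,
#'   standardized residuals), `statistic`, `df`, `p_value`, `peak` (row
#'   index of the maximum-residual window), `n_passing`.
#' @export
cluster_enrichment <- function(passing, genome, window_size = 5e6,
                               tested = NULL,
                               null = c("uniform", "tested_density")) {
  null <- match.arg(null)
  if (is.null(passing) || nrow(passing) == 0L) {
    stop("no passing variants: cluster enrichment is undefined")
  }
  if (null == "tested_density" && is.null(tested)) {
    stop("tested site table required for the tested_density null")
  }
  if (!is.null(tested)) {
    genome <- genome[genome$chrom %in% unique(tested$chrom), , drop = FALSE]
  }
  if (!all(passing$chrom %in% genome$chrom)) {
    stop("passing sites on chromosomes absent from the windowed genome")
  }
  win <- genome_windows(genome, window_size)
  locate <- function(df) {
    hit <- rep(NA_integer_, nrow(df))
    for (i in seq_len(nrow(win))) {
      sel <- df$chrom == win$chrom[i] & df$pos >= win$start[i] &
        df$pos < win$end[i] + 1
      hit[sel] <- i
    }
    hit
  }
  wp <- locate(passing)
  if (anyNA(wp)) stop("passing site outside windowed genome")
  K <- nrow(passing)
  obs <- tabulate(wp, nbins = nrow(win))
  expd <- if (null == "uniform") {
    rep(K / nrow(win), nrow(win))
  } else {
    wt <- tabulate(locate(tested), nbins = nrow(win))
    if (any(wt == 0L)) {
      keep <- wt > 0L
      win <- win[keep, , drop = FALSE]
      obs <- obs[keep]
      wt <- wt[keep]
    }
    K * wt / sum(wt)
  }
  stat <- sum((obs - expd)^2 / expd)
  df <- nrow(win) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  win$observed <- obs
  win$expected <- expd
  win$residual <- (obs - expd) / sqrt(expd)
  structure(list(windows = win, statistic = stat, df = df, p_value = p,
                 peak = which.max(win$residual), n_passing = K,
                 window_size = window_size, null = null),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  pk <- x$windows[x$peak, ]
  cat(sprintf("cluster enrichment: X2 = %.2f, df = %d, p = %.3g (%d passing variants, %d windows)\n",
              x$statistic, x$df, x$p_value, x$n_passing, nrow(x$windows)))
  cat(sprintf("peak window: %s:%d-%d (observed %d, expected %.2f)\n",
              pk$chrom, pk$start, pk$end, pk$observed, pk$expected))
  invisible(x)
}

#' Expected double-homozygous-reference count at two independent loci
#'
#' Bookkeeping for co-segregating colony variants: given the number of
#' individuals carrying at least one non-reference allele at each of two
#' loci, and the number carrying non-reference alleles at both, the count of
#' individuals homozygous reference at both loci follows by
#' inclusion-exclusion.
#'
#' @param n_total number of individuals examined.
#' @param n_nonref_a,n_nonref_b individuals carrying >= 1 non-reference
#'   allele at locus A / locus B (heterozygous or homozygous).
#' @param n_nonref_both individuals carrying non-reference alleles at both
#'   loci (default 0).
#' @return integer count homozygous reference at both loci.
#' @examples
#' # 25 affected cats: 9 carry one storage-disease allele, 4 the other,
#' # none both
#' double_homref_count(25, 9, 4)  # 12
#' @export
double_homref_count <- function(n_total, n_nonref_a, n_nonref_b,
                                n_nonref_both = 0L) {
  n_total <- check_count(n_total, "n_total")
  n_nonref_a <- check_count(n_nonref_a, "n_nonref_a")
  n_nonref_b <- check_count(n_nonref_b, "n_nonref_b")
  n_nonref_both <- check_count(n_nonref_both, "n_nonref_both")
  if (n_nonref_both > min(n_nonref_a, n_nonref_b)) {
    stop("overlap exceeds a marginal count")
  }
  out <- n_total - n_nonref_a - n_nonref_b + n_nonref_both
  if (out < 0L) stop("inconsistent counts: negative double-reference count")
  out
}
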