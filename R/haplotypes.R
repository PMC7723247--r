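# Rule-based diplotype reconstruction over an ordered marker panel, and
# delineation of the recessive critical interval from the reconstructed (or
# simulated) diplotypes.

#' Reconstruct diplotypes through a pedigree
#'
#' Assigns parental phase at each panel marker by Mendelian transmission
#' where it is unambiguous: a homozygous individual is trivially phased, a
#' heterozygous child is phased wherever a parent's genotype forces the
#' transmitted allele (parent homozygous, or the trio constraint leaves a
#' single possibility), and rules are iterated to a fixed point.
#' Ungenotyped individuals with a genotyped mate and progeny are imputed:
#' the transmitted haplotype is the child haplotype not attributable to the
#' other parent; anything unresolvable stays `NA` (uncertain), never
#' guessed. Markers with a Mendelian inconsistency in a family are excluded
#' for that family's trio rules and reported.
#'
#' @param ped a [pedigree()].
#' @param panel a [genotype_matrix()] of ordered markers on one chromosome.
#' @return a `diplotype_set`: list with `sites`, `samples`, `hap1`/`hap2`
#'   (individual x marker allele matrices; `hap1` = paternal for
#'   non-founders, while a founder's `hap1` is anchored per marker to the
#'   allele it transmitted to its first phase-resolved child; `NA` =
#'   uncertain), `imputed` (logical per individual), and `mendel_errors`
#'   (data frame of excluded (child, parent, marker) combinations).
#' @export
reconstruct_diplotypes <- function(ped, panel) {
  validate_pedigree(ped)
  if (length(unique(panel$sites$chrom)) > 1L) {
    stop("panel markers must lie on a single chromosome")
  }
  n <- nrow(ped)
  M <- nrow(panel$sites)
  idx <- match(ped$id, panel$samples)
  dos <- matrix(NA_integer_, n, M, dimnames = list(ped$id, NULL))
  typed <- !is.na(idx)
  dos[typed, ] <- t(panel$dosage[, idx[typed], drop = FALSE])

  hap1 <- matrix(NA_integer_, n, M, dimnames = list(ped$id, NULL))
  hap2 <- hap1
  # rule 1: homozygotes are phased trivially
  hap1[dos == 0L] <- 0L; hap2[dos == 0L] <- 0L
  hap1[dos == 2L] <- 1L; hap2[dos == 2L] <- 1L

  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)

  # Mendelian screen: child/parent genotype incompatibility at a marker
  mendel <- NULL
  excluded <- matrix(FALSE, n, M)
  for (i in which(!is.na(sire_i))) {
    for (p in c(sire_i[i], dam_i[i])) {
      bad <- (dos[i, ] == 2L & dos[p, ] == 0L) |
        (dos[i, ] == 0L & dos[p, ] == 2L)
      bad[is.na(bad)] <- FALSE
      if (any(bad)) {
        mendel <- rbind(mendel, data.frame(
          child = ped$id[i], parent = ped$id[p], marker = which(bad)))
        excluded[i, bad] <- TRUE
      }
    }
  }
  if (!is.null(mendel)) {
    warning("Mendelian inconsistencies at ", nrow(mendel),
            " (child, parent, marker) combinations; those markers are ",
            "excluded from trio phasing for those children")
    hap1[excluded] <- NA_integer_
    hap2[excluded] <- NA_integer_
  }

  # rule 2/3: iterate transmission constraints to a fixed point
  repeat {
    changed <- FALSE
    for (i in which(!is.na(sire_i))) {
      het <- which(dos[i, ] == 1L & !excluded[i, ])
      if (!length(het)) next
      si <- sire_i[i]; di <- dam_i[i]
      for (m in het) {
        if (!is.na(hap1[i, m]) && !is.na(hap2[i, m])) next
        pat <- NA_integer_
        # sire cannot transmit allele a -> paternal allele is 1 - a
        if (!is.na(dos[si, m]) && dos[si, m] %in% c(0L, 2L)) {
          pat <- dos[si, m] / 2L
        } else if (!is.na(dos[di, m]) && dos[di, m] %in% c(0L, 2L)) {
          pat <- 1L - dos[di, m] / 2L
        }
        if (!is.na(pat)) {
          if (is.na(hap1[i, m])) { hap1[i, m] <- pat; changed <- TRUE }
          if (is.na(hap2[i, m])) { hap2[i, m] <- 1L - pat; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }

  # founder phase anchoring: a founder's two haplotypes have no inherent
  # paternal/maternal order, so where a child's allele received from the
  # founder is known, hap1 is anchored to the allele transmitted to the
  # first such child (hap2 = complement)
  for (p in which(is.na(sire_i))) {
    kids <- which(sire_i == p | dam_i == p)
    if (!length(kids)) next
    unres <- which(dos[p, ] == 1L & is.na(hap1[p, ]))
    for (m in unres) {
      for (i in kids) {
        recv <- if (!is.na(dos[i, m]) && dos[i, m] %in% c(0L, 2L)) {
          dos[i, m] / 2L
        } else if (identical(sire_i[i], p)) hap1[i, m] else hap2[i, m]
        if (!is.na(recv)) {
          hap1[p, m] <- recv
          hap2[p, m] <- 1L - recv
          break
        }
      }
    }
  }

  # progeny imputation for fully ungenotyped individuals
  imputed <- stats::setNames(rep(FALSE, n), ped$id)
  genotyped <- rowSums(!is.na(dos)) > 0L
  for (p in which(!genotyped)) {
    kids <- which(sire_i == p | dam_i == p)
    if (!length(kids)) next
    trans <- matrix(NA_integer_, length(kids), M)
    for (kk in seq_along(kids)) {
      i <- kids[kk]
      other <- if (identical(sire_i[i], p)) dam_i[i] else sire_i[i]
      # child allele not attributable to the other (genotyped) parent
      ch <- dos[i, ]
      oth <- dos[other, ]
      tr <- rep(NA_integer_, M)
      tr[ch == 0L] <- 0L
      tr[ch == 2L] <- 1L
      amb <- which(ch == 1L & !is.na(oth) & oth %in% c(0L, 2L))
      # if the other parent is homozygous a, it transmitted a; this parent
      # transmitted 1 - a
      tr[amb] <- 1L - oth[amb] / 2L
      trans[kk, ] <- tr
    }
    cons <- apply(trans, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) && length(unique(v)) == 1L) v[1] else NA_integer_
    })
    if (any(!is.na(cons))) {
      hap1[p, ] <- cons
      imputed[p] <- TRUE
    }
  }

  structure(list(sites = panel$sites, samples = ped$id,
                 hap1 = hap1, hap2 = hap2, dosage = dos,
                 imputed = imputed,
                 mendel_errors = mendel %||% data.frame()),
            class = "diplotype_set")
}

#' Delineate the recessive critical interval
#'
#' The critical interval is the maximal run of contiguous panel markers at
#' which every affected individual is homozygous for the shared disease
#' haplotype. With founder-origin labels available (simulated haplotype
#' sets) homozygosity means both haplotypes descend from the labeled carrier
#' haplotype; from genotypes alone it means all called affected individuals
#' are homozygous for one common allele. Reports conservative inner bounds
#' (first/last markers of the run) and recombinant-bounded outer bounds (the
#' nearest flanking markers violating the condition, or the panel/chromosome
#' ends).
#'
#' @param x a `haplotype_set` (from [gene_drop()]), `diplotype_set` (from
#'   [reconstruct_diplotypes()]) or [genotype_matrix()] restricted to one
#'   chromosome's panel.
#' @param affected character ids of affected individuals.
#' @param disease_hap founder haplotype label of the disease haplotype (only
#'   used for `haplotype_set` input; default the carrier haplotype).
#' @param anchor optional base-pair position(s) implicating the locus,
#'   typically the zygosity-passing variant positions. When given, the run
#'   whose recombinant-bounded outer span contains the most anchor
#'   positions is delineated (ties broken by run length, then by distance
#'   to the anchor median); in a heavily inbred colony other autozygous
#'   runs can by chance be longer, so anchoring at the mapping signal is
#'   how the disease-haplotype run is identified in practice. Without an
#'   anchor the longest run is returned.
#' @return a `critical_interval`: list with `status`
#'   (`"ok"`/`"no critical interval"`), `chrom`, `inner_start`, `inner_end`,
#'   `outer_start`, `outer_end`, `span_bp` (inner), `markers` (indices of
#'   the run).
#' @export
delineate_critical_interval <- function(x, affected, disease_hap = NULL,
                                        anchor = NULL) {
  if (inherits(x, "haplotype_set")) {
    lab <- disease_hap %||% x$carrier_hap
    ai <- match(affected, x$samples)
    if (anyNA(ai)) stop("affected ids missing from haplotype set")
    hom <- colSums(x$originP[ai, , drop = FALSE] == lab &
                     x$originM[ai, , drop = FALSE] == lab) == length(ai)
    sites <- x$sites
  } else {
    if (inherits(x, "diplotype_set")) {
      dos <- x$dosage[match(affected, x$samples), , drop = FALSE]
    } else if (inherits(x, "genotype_matrix")) {
      ai <- match(affected, x$samples)
      if (anyNA(ai)) stop("affected ids missing from genotype matrix")
      dos <- t(x$dosage[, ai, drop = FALSE])
    } else stop("unsupported input")
    if (length(unique(x$sites$chrom)) > 1L) {
      stop("critical-interval input must cover a single chromosome")
    }
    # all called affected homozygous for one common allele
    hom <- apply(dos, 2, function(g) {
      g <- g[!is.na(g)]
      length(g) > 0L && (all(g == 0L) || all(g == 2L))
    })
    sites <- x$sites
  }
  if (!any(hom)) {
    return(structure(list(status = "no critical interval",
                          chrom = sites$chrom[1],
                          inner_start = NA, inner_end = NA,
                          outer_start = NA, outer_end = NA,
                          span_bp = NA, markers = integer(0)),
                     class = "critical_interval"))
  }
  r <- rle(hom)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (is.null(anchor)) {
    best <- runs[which.max(r$lengths[runs])]
  } else {
    m <- nrow(sites)
    outer_lo <- sites$pos[pmax(starts[runs] - 1L, 1L)]
    outer_hi <- sites$pos[pmin(ends[runs] + 1L, m)]
    n_anch <- vapply(seq_along(runs), function(k) {
      sum(anchor >= outer_lo[k] & anchor <= outer_hi[k])
    }, 0L)
    med <- stats::median(anchor)
    center <- (sites$pos[starts[runs]] + sites$pos[ends[runs]]) / 2
    ord <- order(-n_anch, -r$lengths[runs], abs(center - med))
    best <- runs[ord[1]]
  }
  i0 <- starts[best]; i1 <- ends[best]
  structure(list(
    status = "ok",
    chrom = sites$chrom[1],
    inner_start = sites$pos[i0], inner_end = sites$pos[i1],
    outer_start = if (i0 > 1L) sites$pos[i0 - 1L] else sites$pos[1],
    outer_end = if (i1 < nrow(sites)) sites$pos[i1 + 1L]
                else sites$pos[nrow(sites)],
    span_bp = sites$pos[i1] - sites$pos[i0] + 1L,
    markers = i0:i1), class = "critical_interval")
}

#' @export
print.critical_interval <- function(x, ...) {
  if (x$status != "ok") {
    cat("critical interval: none (no shared homozygous run)\n")
  } else {
    cat(sprintf("critical interval: %s:%d-%d (inner, %.2f Mb; outer %d-%d), %d markers\n",
                x$chrom, x$inner_start, x$inner_end, x$span_bp / 1e6,
                x$outer_start, x$outer_end, length(x$markers)))
  }
  invisible(x)
}
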