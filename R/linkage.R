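# Exact parametric two-point linkage.
#
# The likelihood of a pedigree at recombination fraction theta is the sum
# over all phased two-locus genotype assignments of
#   prod(founder HWE priors) * prod(transmissions) * prod(penetrances)
#   * indicator(observed marker genotypes),
# where each individual's state is an ordered (paternal, maternal) pair of
# two-locus haplotypes (disease allele x marker allele). The sum is computed
# exactly by variable elimination on the pedigree's factor graph, which
# handles the looped pedigrees of closed colonies without loop-breaking
# approximations, under an explicit state-space budget.

#' Parametric disease model for linkage
#'
#' @param q disease allele frequency in (0, 1); default 0.001 (rare
#'   recessive model).
#' @param penetrance probability of being affected given 0, 1, 2 copies of
#'   the disease allele; default `c(0, 0, 1)` (fully penetrant recessive, no
#'   phenocopies).
#' @return a `disease_model`.
#' @export
disease_model <- function(q = 0.001, penetrance = c(0, 0, 1)) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must be in (0, 1)")
  }
  if (length(penetrance) != 3L || any(penetrance < 0) || any(penetrance > 1)) {
    stop("penetrance must be 3 probabilities")
  }
  structure(list(q = q, penetrance = as.numeric(penetrance)),
            class = "disease_model")
}

# --- state space -----------------------------------------------------------
# haplotype h in 1..(2k): disease allele d(h) in {1 = wild, 2 = disease},
# marker allele m(h) in 1..k;  h = (d - 1) * k + m.
# individual state s in 1..S, S = (2k)^2: ordered (paternal hap, maternal
# hap); s = (hp - 1) * 2k + hm.

hap_d <- function(h, k) (h - 1L) %/% k + 1L
hap_m <- function(h, k) (h - 1L) %% k + 1L

# P(parent in state s transmits gamete haplotype g) at recombination theta.
# 2k x S matrix.
gamete_matrix <- function(k, theta) {
  H <- 2L * k
  S <- H * H
  G <- matrix(0, H, S)
  for (hp in seq_len(H)) for (hm in seq_len(H)) {
    s <- (hp - 1L) * H + hm
    for (orig in 1:2) {
      ho <- if (orig == 1L) hp else hm
      hx <- if (orig == 1L) hm else hp
      d <- hap_d(ho, k)
      # marker allele follows the same parental haplotype w.p. 1 - theta
      g_same <- (d - 1L) * k + hap_m(ho, k)
      g_rec <- (d - 1L) * k + hap_m(hx, k)
      G[g_same, s] <- G[g_same, s] + 0.5 * (1 - theta)
      G[g_rec, s] <- G[g_rec, s] + 0.5 * theta
    }
  }
  G
}

# Evidence vector over states for one individual: penetrance times marker
# observation indicator. geno is NULL (untyped) or an unordered pair of
# marker allele indices.
evidence_vector <- function(k, phenotype, geno, model) {
  H <- 2L * k
  hp <- rep(seq_len(H), each = H)
  hm <- rep(seq_len(H), times = H)
  ndis <- (hap_d(hp, k) == 2L) + (hap_d(hm, k) == 2L)
  f <- model$penetrance[ndis + 1L]
  pen <- switch(phenotype,
                affected = f,
                unaffected = 1 - f,
                unknown = rep(1, length(f)))
  if (!is.null(geno) && !anyNA(geno)) {
    mp <- hap_m(hp, k); mm <- hap_m(hm, k)
    ok <- (mp == geno[1] & mm == geno[2]) | (mp == geno[2] & mm == geno[1])
    pen <- pen * ok
  }
  pen
}

# Founder prior over states under HWE and linkage equilibrium.
founder_prior <- function(k, model, marker_freqs) {
  H <- 2L * k
  pd <- c(1 - model$q, model$q)
  ph <- pd[hap_d(seq_len(H), k)] * marker_freqs[hap_m(seq_len(H), k)]
  as.vector(outer(ph, ph))  # s = (hp-1)*H + hm ordering: hp slow, hm fast
}

# --- factor elimination ----------------------------------------------------
# A factor is list(vars = integer ids, tab = numeric array with one dim of
# size S per var).

align_factor <- function(f, uvars, S) {
  miss <- setdiff(uvars, f$vars)
  tab <- f$tab
  vars <- f$vars
  if (length(miss)) {
    tab <- array(rep(tab, S^length(miss)),
                 dim = c(rep(S, length(vars)), rep(S, length(miss))))
    vars <- c(vars, miss)
  }
  aperm(array(tab, dim = rep(S, length(vars))), match(uvars, vars))
}

multiply_factors <- function(fs, S, budget) {
  uvars <- Reduce(union, lapply(fs, `[[`, "vars"))
  if (S^length(uvars) > budget) {
    stop("pedigree too large for exact likelihood (intermediate table of ",
         S^length(uvars), " states exceeds budget ", budget,
         "); split the pedigree, e.g. into nuclear families ",
         "(see lod_by_families)")
  }
  tab <- align_factor(fs[[1]], uvars, S)
  for (f in fs[-1]) tab <- tab * align_factor(f, uvars, S)
  list(vars = uvars, tab = tab)
}

sum_out <- function(f, var, S) {
  d <- length(f$vars)
  if (d == 1L) return(list(vars = integer(0), tab = sum(f$tab)))
  perm <- c(setdiff(seq_len(d), match(var, f$vars)), match(var, f$vars))
  tab <- aperm(array(f$tab, dim = rep(S, d)), perm)
  dim(tab) <- c(S^(d - 1L), S)
  tab <- rowSums(tab)
  dim(tab) <- rep(S, d - 1L)
  list(vars = f$vars[perm[seq_len(d - 1L)]], tab = tab)
}

# Exact sum-product over all variables; returns the scalar likelihood.
eliminate_all <- function(factors, n_vars, S, budget) {
  remaining <- seq_len(n_vars)
  while (length(remaining)) {
    # greedy: eliminate the variable with the smallest induced cluster
    costs <- vapply(remaining, function(v) {
      inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
      length(Reduce(union, lapply(factors[inv], `[[`, "vars")))
    }, 0L)
    v <- remaining[which.min(costs)]
    inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- multiply_factors(factors[inv], S, budget)
    marg <- sum_out(prod_f, v, S)
    factors <- c(factors[!inv], list(marg))
    remaining <- setdiff(remaining, v)
  }
  out <- 1
  for (f in factors) out <- out * f$tab
  out
}

# Pedigree likelihood at one theta for one marker.
pedigree_likelihood <- function(ped, geno, model, theta, marker_freqs, k,
                                budget) {
  S <- (2L * k)^2
  n <- nrow(ped)
  G <- gamete_matrix(k, theta)
  prior <- founder_prior(k, model, marker_freqs)
  H <- 2L * k
  factors <- list()
  for (i in seq_len(n)) {
    ev <- evidence_vector(k, ped$phenotype[i], geno[[i]], model)
    if (is.na(ped$sire[i])) {
      factors[[length(factors) + 1L]] <-
        list(vars = i, tab = prior * ev)
    } else {
      si <- match(ped$sire[i], ped$id)
      di <- match(ped$dam[i], ped$id)
      # T[c, s, d] = G[hp(c), s] * G[hm(c), d], folded with child evidence
      hp <- rep(seq_len(H), each = H)
      hm <- rep(seq_len(H), times = H)
      Tp <- G[hp, , drop = FALSE]  # S x S: child state x sire state
      Tm <- G[hm, , drop = FALSE]
      tab <- array(0, dim = c(S, S, S))
      evTp <- Tp * ev
      for (dstate in seq_len(S)) {
        tab[, , dstate] <- evTp * Tm[, dstate]
      }
      factors[[length(factors) + 1L]] <- list(vars = c(i, si, di), tab = tab)
    }
  }
  eliminate_all(factors, n, S, budget)
}

# Normalize one marker's genotypes into the list-of-pairs form and allele
# count k. `geno` may be a length-n vector of dosages (biallelic), an n x 2
# matrix of allele indices, or a list of pairs/NULL.
normalize_marker <- function(geno, n) {
  if (is.list(geno)) {
    stopifnot(length(geno) == n)
    return(geno)
  }
  if (is.matrix(geno)) {
    stopifnot(nrow(geno) == n, ncol(geno) == 2L)
    return(lapply(seq_len(n), function(i) {
      g <- geno[i, ]
      if (anyNA(g)) NULL else as.integer(g)
    }))
  }
  stopifnot(length(geno) == n)
  lapply(as.integer(geno), function(d) {
    if (is.na(d)) NULL else switch(d + 1L, c(1L, 1L), c(1L, 2L), c(2L, 2L))
  })
}

#' Exact two-point LOD score under a parametric recessive model
#'
#' Computes `LOD = log10 L(theta = 0) - log10 L(theta = 0.5)` for each
#' marker by exact summation over phased founder genotypes and
#' transmissions (variable elimination), with Hardy-Weinberg founder priors
#' (`q` for the disease locus, equal or supplied frequencies for the marker)
#' and the model's penetrances. Genotype configurations that are impossible
#' under complete cosegregation give `L(0) = 0` and a `-Inf` LOD, reported
#' explicitly.
#'
#' @param ped a [pedigree()] with phenotypes.
#' @param markers marker genotypes: a [genotype_matrix()], a single dosage
#'   vector over `ped$id`, an n x 2 allele-index matrix, or a list of
#'   allele-index pairs (NULL/NA = untyped).
#' @param model a [disease_model()].
#' @param marker_freqs optional marker allele frequencies (default equal).
#' @param budget maximum intermediate table size in states (default `16^6`);
#'   exceeding it is an error, never a silent approximation.
#' @return data frame with one row per marker: `marker`, `lod`,
#'   `informative`.
#' @export
two_point_lod <- function(ped, markers, model = disease_model(),
                          marker_freqs = NULL, budget = 16^6) {
  validate_pedigree(ped)
  n <- nrow(ped)
  if (inherits(markers, "genotype_matrix")) {
    idx <- match(ped$id, markers$samples)
    if (anyNA(idx)) stop("pedigree ids missing from genotype matrix: ",
                         paste(ped$id[is.na(idx)], collapse = ", "))
    glist <- lapply(seq_len(nrow(markers$sites)), function(j) {
      markers$dosage[j, idx]
    })
    names(glist) <- paste(markers$sites$chrom, markers$sites$pos, sep = ":")
  } else {
    glist <- list(marker = markers)
  }
  out <- lapply(names(glist), function(nm) {
    geno <- normalize_marker(glist[[nm]], n)
    k <- max(2L, unlist(geno), na.rm = TRUE)
    freqs <- marker_freqs %||% rep(1 / k, k)
    if (length(freqs) != k) stop("marker_freqs must have one entry per allele")
    L0 <- pedigree_likelihood(ped, geno, model, 0, freqs, k, budget)
    L5 <- pedigree_likelihood(ped, geno, model, 0.5, freqs, k, budget)
    if (L5 <= 0) stop("likelihood zero at theta = 0.5: genotypes are ",
                      "Mendelian-inconsistent at marker ", nm)
    lod <- if (L0 <= 0) -Inf else log10(L0) - log10(L5)
    data.frame(marker = nm, lod = lod,
               informative = is.finite(lod) && abs(lod) > 1e-12,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summed nuclear-family two-point LOD
#'
#' Exact LOD of each nuclear family (parents treated as population founders,
#' phase unknown) summed over families: the standard decomposition for
#' pedigrees whose loops put the joint likelihood beyond the exact
#' enumeration budget.
#'
#' @inheritParams two_point_lod
#' @return data frame per marker: `marker`, `lod` (sum), `n_families`.
#' @export
lod_by_families <- function(ped, markers, model = disease_model(),
                            marker_freqs = NULL, budget = 16^6) {
  validate_pedigree(ped)
  fams <- nuclear_families(ped)
  if (length(fams) == 0L) stop("pedigree has no nuclear families")
  tot <- NULL
  for (fam in fams) {
    ids <- c(fam$sire, fam$dam, fam$children)
    sub <- ped[match(ids, ped$id), , drop = FALSE]
    sub$sire[1:2] <- NA; sub$dam[1:2] <- NA
    sub <- pedigree(sub$id, sub$sire, sub$dam, sub$sex, sub$phenotype)
    mk <- if (inherits(markers, "genotype_matrix")) {
      subset_genotypes(markers, samples = ids)
    } else markers
    r <- two_point_lod(sub, mk, model, marker_freqs, budget)
    r$lod[!is.finite(r$lod)] <- NA  # inconsistent family excluded per marker
    if (is.null(tot)) {
      tot <- data.frame(marker = r$marker, lod = 0, n_families = 0L)
    }
    ok <- !is.na(r$lod)
    tot$lod[ok] <- tot$lod[ok] + r$lod[ok]
    tot$n_families[ok] <- tot$n_families[ok] + 1L
  }
  tot
}
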