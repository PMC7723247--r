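# Brute-force verification oracle for two-point linkage.
#
# Enumerates founder phased two-locus diplotypes and every per-meiosis
# transmission outcome explicitly, accumulating an expanding table of joint
# assignments (zero-probability rows pruned as observations are applied).
# Deliberately naive and separate from the elimination engine so the two can
# check each other; limited to small pedigrees.

# transmission probability that a parent with ordered haplotype pair
# (hp, hm) produces gamete g, written as explicit sums (independent of
# gamete_matrix()).
oracle_gamete_prob <- function(g, hp, hm, k, theta) {
  p <- 0
  for (orig in 1:2) {
    ho <- if (orig == 1) hp else hm
    hx <- if (orig == 1) hm else hp
    d_o <- (ho - 1) %/% k + 1
    m_o <- (ho - 1) %% k + 1
    m_x <- (hx - 1) %% k + 1
    dg <- (g - 1) %/% k + 1
    mg <- (g - 1) %% k + 1
    if (dg == d_o) {
      if (mg == m_o) p <- p + 0.5 * (1 - theta)
      if (mg == m_x) p <- p + 0.5 * theta
    }
  }
  p
}

oracle_state_weight <- function(s, phenotype, geno, model, k) {
  H <- 2 * k
  hp <- (s - 1) %/% H + 1
  hm <- (s - 1) %% H + 1
  ndis <- ((hp - 1) %/% k + 1 == 2) + ((hm - 1) %/% k + 1 == 2)
  f <- model$penetrance[ndis + 1]
  w <- switch(phenotype, affected = f, unaffected = 1 - f, unknown = 1)
  if (!is.null(geno) && !anyNA(geno)) {
    mp <- (hp - 1) %% k + 1
    mm <- (hm - 1) %% k + 1
    if (!((mp == geno[1] && mm == geno[2]) ||
          (mp == geno[2] && mm == geno[1]))) {
      w <- 0
    }
  }
  w
}

oracle_likelihood <- function(ped, geno, model, theta, marker_freqs, k,
                              max_rows = 5e6) {
  H <- 2 * k
  S <- H * H
  n <- nrow(ped)
  pd <- c(1 - model$q, model$q)
  hapfreq <- function(h) pd[(h - 1) %/% k + 1] * marker_freqs[(h - 1) %% k + 1]
  ord <- pedigree_order(ped)

  # expanding joint table: states (rows x individuals placed so far), weights
  tab <- matrix(integer(0), nrow = 1, ncol = 0)
  w <- 1
  placed <- integer(0)
  for (id in ord) {
    i <- match(id, ped$id)
    cand <- seq_len(S)
    if (is.na(ped$sire[i])) {
      cw <- vapply(cand, function(s) {
        hp <- (s - 1) %/% H + 1
        hm <- (s - 1) %% H + 1
        hapfreq(hp) * hapfreq(hm) *
          oracle_state_weight(s, ped$phenotype[i], geno[[i]], model, k)
      }, 0)
      keep <- cw > 0
      nr <- nrow(tab)
      tab <- cbind(tab[rep(seq_len(nr), each = sum(keep)), , drop = FALSE],
                   rep(cand[keep], times = nr))
      w <- rep(w, each = sum(keep)) * rep(cw[keep], times = nr)
    } else {
      si <- match(match(ped$sire[i], ped$id), placed)
      di <- match(match(ped$dam[i], ped$id), placed)
      ev <- vapply(cand, function(s) {
        oracle_state_weight(s, ped$phenotype[i], geno[[i]], model, k)
      }, 0)
      cand2 <- cand[ev > 0]
      ev <- ev[ev > 0]
      nr <- nrow(tab)
      newtab <- cbind(tab[rep(seq_len(nr), each = length(cand2)), ,
                          drop = FALSE],
                      rep(cand2, times = nr))
      neww <- rep(w, each = length(cand2)) * rep(ev, times = nr)
      # transmission probability per row
      cs <- newtab[, ncol(newtab)]
      ss <- newtab[, si]
      ds <- newtab[, di]
      tp <- vapply(seq_along(neww), function(r) {
        hpc <- (cs[r] - 1) %/% H + 1
        hmc <- (cs[r] - 1) %% H + 1
        oracle_gamete_prob(hpc, (ss[r] - 1) %/% H + 1, (ss[r] - 1) %% H + 1,
                           k, theta) *
          oracle_gamete_prob(hmc, (ds[r] - 1) %/% H + 1, (ds[r] - 1) %% H + 1,
                             k, theta)
      }, 0)
      neww <- neww * tp
      keep <- neww > 0
      tab <- newtab[keep, , drop = FALSE]
      w <- neww[keep]
    }
    placed <- c(placed, i)
    if (nrow(tab) > max_rows) {
      stop("oracle enumeration table exceeded ", max_rows, " rows")
    }
    if (nrow(tab) == 0L) return(0)
  }
  sum(w)
}

#' Brute-force two-point LOD oracle
#'
#' Exhaustive enumeration over founder phased diplotypes and all
#' transmission outcomes; must agree with [two_point_lod()] to within 1e-9
#' log10 units. Refuses pedigrees with more than `max_meioses` meioses.
#'
#' @inheritParams two_point_lod
#' @param max_meioses enumeration size limit (default 10 meioses).
#' @param max_rows row cap on the expanding joint table.
#' @return data frame as in [two_point_lod()].
#' @export
lod_enumeration_oracle <- function(ped, markers, model = disease_model(),
                                   marker_freqs = NULL, max_meioses = 10L,
                                   max_rows = 5e6) {
  validate_pedigree(ped)
  n_meioses <- 2L * sum(!is.na(ped$sire))
  if (n_meioses > max_meioses) {
    stop("pedigree has ", n_meioses, " meioses; oracle limit is ", max_meioses)
  }
  n <- nrow(ped)
  geno <- normalize_marker(markers, n)
  k <- max(2L, unlist(geno), na.rm = TRUE)
  freqs <- marker_freqs %||% rep(1 / k, k)
  L0 <- oracle_likelihood(ped, geno, model, 0, freqs, k, max_rows)
  L5 <- oracle_likelihood(ped, geno, model, 0.5, freqs, k, max_rows)
  if (L5 <= 0) stop("likelihood zero at theta = 0.5")
  lod <- if (L0 <= 0) -Inf else log10(L0) - log10(L5)
  data.frame(marker = "marker", lod = lod,
             informative = is.finite(lod) && abs(lod) > 1e-12,
             stringsAsFactors = FALSE)
}
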