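# Shared fixtures and independent oracles for the test suite. The oracles
# here are deliberately naive re-derivations (series expansions, exhaustive
# enumeration, brute-force sorts) kept separate from the package's own code
# paths.

# nuclear family: two founder parents and n children
make_family <- function(n_kids, kid_phen = "affected",
                        parent_phen = "unaffected") {
  pedigree(
    id = c("S", "D", paste0("K", seq_len(n_kids))),
    sire = c(NA, NA, rep("S", n_kids)),
    dam = c(NA, NA, rep("D", n_kids)),
    sex = c("M", "F", rep(c("M", "F"), length.out = n_kids)),
    phenotype = c(parent_phen, parent_phen,
                  rep_len(kid_phen, n_kids))
  )
}

# small colony config for module-level tests (quicker than the defaults)
small_colony_config <- function(seed, ...) {
  colony_config(
    seed = seed,
    target_colony_size = 60,
    min_affected = 5,
    genome = data.frame(chrom = c("A1", "F1"),
                        length_bp = c(120e6, 71.5e6),
                        map_cm = c(120, 71.5)),
    ...
  )
}

# random genotype matrix for round-trip properties
random_genotype_matrix <- function(seed, n_sites = 6, n_samples = 4,
                                   p_missing = 0.1) {
  set.seed(seed)
  sites <- data.frame(
    chrom = sample(c("A1", "B1"), n_sites, replace = TRUE),
    pos = sample.int(1e6, n_sites),
    ref = sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
    stringsAsFactors = FALSE
  )
  sites$alt <- ifelse(sites$alt == sites$ref, "T", sites$alt)
  sites$alt[sites$ref == "T" & sites$alt == "T"] <- "G"
  dos <- matrix(sample(c(0:2, NA), n_sites * n_samples, replace = TRUE,
                       prob = c((1 - p_missing) / 3, (1 - p_missing) / 3,
                                (1 - p_missing) / 3, p_missing)),
                n_sites, n_samples)
  genotype_matrix(sites, paste0("smp", seq_len(n_samples)), dos)
}

# --- independent oracles ---------------------------------------------------

# upper-tail chi-square probability via the regularized incomplete gamma
# function, computed from the textbook series / continued-fraction forms
# (no calls to R's distribution functions).
oracle_chisq_sf <- function(x, df) {
  a <- df / 2
  x <- x / 2
  if (x <= 0) return(1)
  gln <- lgamma(a)
  if (x < a + 1) {
    # lower series
    ap <- a
    s <- 1 / a
    del <- s
    for (i in 1:1000) {
      ap <- ap + 1
      del <- del * x / ap
      s <- s + del
      if (abs(del) < abs(s) * 1e-15) break
    }
    1 - s * exp(-x + a * log(x) - gln)
  } else {
    # upper continued fraction (Lentz)
    tiny <- 1e-300
    b <- x + 1 - a
    c <- 1 / tiny
    d <- 1 / b
    h <- d
    for (i in 1:1000) {
      an <- -i * (i - a)
      b <- b + 2
      d <- an * d + b
      if (abs(d) < tiny) d <- tiny
      c <- b + an / c
      if (abs(c) < tiny) c <- tiny
      d <- 1 / d
      del <- d * c
      h <- h * del
      if (abs(del - 1) < 1e-15) break
    }
    h * exp(-x + a * log(x) - gln)
  }
}

# Benjamini-Hochberg by direct definition: q_(i) = min_{j >= i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# brute-force comparator sort matching the declared prioritization key
oracle_rank <- function(an, af_max = 0.05, cpm_min = 1.0) {
  an <- an[is.na(an$af) | an$af < af_max, , drop = FALSE]
  if (nrow(an) == 0L) return(an)
  lift <- if ("liftover_ok" %in% names(an)) an$liftover_ok else !is.na(an$cadd)
  csl <- if ("consequence_liftover" %in% names(an)) {
    an$consequence_liftover
  } else an$consequence
  mism <- !is.na(an$cadd) & an$consequence == "synonymous" &
    csl %in% c("missense", "frameshift", "other_lof")
  tier <- ifelse(an$consequence %in% c("frameshift", "other_lof"), 1,
                 ifelse(an$consequence == "missense", 2, 3))
  usable <- ifelse(is.na(an$cadd) | mism | !lift, -Inf, an$cadd)
  notexp <- !is.na(an$cpm) & an$cpm < cpm_min
  better <- function(i, j) {
    if (tier[i] != tier[j]) return(tier[i] < tier[j])
    if (usable[i] != usable[j]) return(usable[i] > usable[j])
    if (notexp[i] != notexp[j]) return(!notexp[i])
    if (an$chrom[i] != an$chrom[j]) return(an$chrom[i] < an$chrom[j])
    if (an$pos[i] != an$pos[j]) return(an$pos[i] < an$pos[j])
    an$alt[i] <= an$alt[j]
  }
  ord <- seq_len(nrow(an))
  # insertion sort with the pairwise comparator
  for (i in seq_along(ord)[-1]) {
    k <- ord[i]
    j <- i - 1
    while (j >= 1 && !better(ord[j], k)) {
      ord[j + 1] <- ord[j]
      j <- j - 1
    }
    ord[j + 1] <- k
  }
  an[ord, , drop = FALSE]
}

# simulated nuclear family with a marker transmitted consistently with
# Mendelian inheritance (for LOD equivalence sweeps): returns pedigree and
# genotype list; disease status from a linked disease locus at the given
# recombination fraction between disease and marker.
random_linked_family <- function(seed, theta_truth = 0, k = 2,
                                 n_generations = 1) {
  set.seed(seed)
  nk <- sample(3:6, 1)
  par_mark <- replicate(2, sample.int(k, 2, replace = TRUE),
                        simplify = FALSE)
  par_dis <- replicate(2, c(2L, 1L), simplify = FALSE)  # both carriers
  kid_geno <- vector("list", nk)
  kid_phen <- character(nk)
  for (i in seq_len(nk)) {
    hap <- integer(2)
    dis <- integer(2)
    for (p in 1:2) {
      o <- sample(1:2, 1)
      dis[p] <- par_dis[[p]][o]
      mo <- if (runif(1) < theta_truth) 3 - o else o
      hap[p] <- par_mark[[p]][mo]
    }
    kid_geno[[i]] <- sort(hap)
    kid_phen[i] <- if (all(dis == 2L)) "affected" else "unaffected"
  }
  ped <- make_family(nk, kid_phen = "unaffected")
  ped$phenotype <- c("unaffected", "unaffected", kid_phen)
  list(ped = ped,
       geno = c(lapply(par_mark, sort), kid_geno))
}
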