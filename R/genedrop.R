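# Gene-drop simulation: founder haplotypes transmitted down the pedigree with
# Haldane (no-interference) recombination, with full founder-origin
# bookkeeping so identity-by-descent can be asserted exactly in tests.

# Simulated site map for a config: Poisson-ish uniform site placement per
# chromosome at `variant_density` per Mb, with the causal site inserted at
# its exact position.
simulate_sites_impl <- function(config) {
  bases <- c("A", "C", "G", "T")
  has_causal <- config$causal_chromosome %in% config$genome$chrom
  out <- lapply(seq_len(nrow(config$genome)), function(i) {
    chrom <- config$genome$chrom[i]
    len <- config$genome$length_bp[i]
    n <- max(0L, round(config$variant_density * len / 1e6))
    pos <- sort(sample.int(len, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- bases[(match(ref, bases) + sample.int(3L, n, replace = TRUE) - 1L) %% 4L + 1L]
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, out)
  if (has_causal) {
    causal <- sites$chrom == config$causal_chromosome &
      sites$pos == config$causal_position
    if (!any(causal)) {
      sites <- rbind(sites, data.frame(
        chrom = config$causal_chromosome, pos = config$causal_position,
        ref = "GT", alt = "G", stringsAsFactors = FALSE))
    } else {
      sites$ref[causal] <- "GT"
      sites$alt[causal] <- "G"
    }
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# Founder haplotype alleles (2F x S 0/1 matrix). Row 1 is the carrier
# haplotype: alt at the causal site and at every site inside the IBD
# segment, making the segment haplotype effectively unique.
simulate_founder_haplotypes_impl <- function(config, sites) {
  nf <- config$n_founders
  s <- nrow(sites)
  freq <- stats::runif(s, 0.1, 0.5)
  seg <- in_ibd_segment(config, sites)
  freq[seg] <- config$segment_alt_freq
  H <- matrix(stats::rbinom(2L * nf * s, 1L, rep(freq, each = 2L * nf)),
              nrow = 2L * nf, ncol = s)
  if (config$causal_chromosome %in% sites$chrom) {
    H[1L, seg] <- 1L
    causal <- causal_site_index(config, sites)
    H[, causal] <- 0L
    H[1L, causal] <- 1L
  }
  H
}

in_ibd_segment <- function(config, sites) {
  half <- config$ibd_segment_length / 2
  sites$chrom == config$causal_chromosome &
    abs(sites$pos - config$causal_position) <= half
}

causal_site_index <- function(config, sites) {
  i <- which(sites$chrom == config$causal_chromosome &
               sites$pos == config$causal_position)
  if (length(i) != 1L) stop("causal site not present in site table")
  i
}

# One meiosis over one chromosome under the Haldane model: crossover count is
# Poisson(map length in Morgans), crossover positions uniform in bp (linear
# map), starting haplotype fair. Returns the transmitted rows as a 2-column
# index matrix is avoided; we return the chosen source (1/2) per site.
meiosis_source <- function(pos, length_bp, map_cm) {
  k <- stats::rpois(1L, map_cm / 100)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(rep.int(start, length(pos)))
  cuts <- sort(stats::runif(k, 0, length_bp))
  seg <- findInterval(pos, cuts)
  src <- ifelse(seg %% 2L == 0L, start, 3L - start)
  as.integer(src)
}

#' Drop founder haplotypes through a pedigree
#'
#' Simulates two haplotypes per individual over the config's simulated site
#' map. Founder haplotypes are drawn from per-site allele frequencies, except
#' that exactly one founder haplotype (the "carrier" haplotype) carries the
#' causal allele embedded in a unique alt-allele signature spanning
#' `ibd_segment_length`. Each transmitted haplotype is a recombinant mosaic
#' of one parent's two haplotypes with breakpoints from Haldane's model, and
#' every allele carries a founder-haplotype origin label.
#'
#' @param ped a [pedigree()].
#' @param config a [colony_config()].
#' @param chromosomes optional character vector restricting the simulated
#'   site map to a subset of chromosomes (the causal chromosome must be
#'   included).
#' @param seed optional seed override; defaults to `config$seed + 1`.
#' @return a `haplotype_set`: list with `sites`, `samples`, allele matrices
#'   `hapP`/`hapM` (individual x site, paternal/maternal), origin-label
#'   matrices `originP`/`originM` (founder haplotype ids 1..2F), and
#'   `carrier_hap = 1L`.
#' @export
gene_drop <- function(ped, config, chromosomes = NULL, seed = NULL) {
  validate_pedigree(ped)
  if (!is.null(chromosomes) && !config$causal_chromosome %in% chromosomes) {
    stop("configuration error: causal chromosome absent from genome subset")
  }
  with_seed(seed %||% (config$seed + 1L),
            gene_drop_impl(ped, config, chromosomes))
}

gene_drop_impl <- function(ped, config, chromosomes = NULL) {
  genome <- config$genome
  if (!is.null(chromosomes)) {
    genome <- genome[genome$chrom %in% chromosomes, , drop = FALSE]
    if (nrow(genome) == 0L) stop("no chromosomes selected")
  }
  cfg <- config
  cfg$genome <- genome
  sites <- simulate_sites_impl(cfg)
  H <- simulate_founder_haplotypes_impl(cfg, sites)

  n <- nrow(ped)
  s <- nrow(sites)
  ids <- ped$id
  hapP <- matrix(NA_integer_, n, s, dimnames = list(ids, NULL))
  hapM <- hapP; originP <- hapP; originM <- hapP

  fids <- founders(ped)
  for (k in seq_along(fids)) {
    i <- match(fids[k], ids)
    hapP[i, ] <- H[2L * k - 1L, ]
    hapM[i, ] <- H[2L * k, ]
    originP[i, ] <- 2L * k - 1L
    originM[i, ] <- 2L * k
  }

  chrom_idx <- split(seq_len(s), sites$chrom)
  ord <- pedigree_order(ped)
  for (id in setdiff(ord, fids)) {
    i <- match(id, ids)
    si <- match(ped$sire[i], ids)
    di <- match(ped$dam[i], ids)
    for (ci in seq_len(nrow(genome))) {
      j <- chrom_idx[[genome$chrom[ci]]]
      if (is.null(j) || length(j) == 0L) next
      src <- meiosis_source(sites$pos[j], genome$length_bp[ci],
                            genome$map_cm[ci])
      two <- src == 2L
      a <- hapP[si, j]; o <- originP[si, j]
      a[two] <- hapM[si, j][two]; o[two] <- originM[si, j][two]
      hapP[i, j] <- a; originP[i, j] <- o
      src <- meiosis_source(sites$pos[j], genome$length_bp[ci],
                            genome$map_cm[ci])
      two <- src == 2L
      a <- hapP[di, j]; o <- originP[di, j]
      a[two] <- hapM[di, j][two]; o[two] <- originM[di, j][two]
      hapM[i, j] <- a; originM[i, j] <- o
    }
  }
  structure(list(sites = sites, samples = ids, hapP = hapP, hapM = hapM,
                 originP = originP, originM = originM, carrier_hap = 1L,
                 config = cfg),
            class = "haplotype_set")
}

#' Genotype matrix of a haplotype set
#'
#' Sums the two haplotype alleles per individual per site, optionally
#' injecting per-call dropout (missing calls) at the config's
#' `dropout_prob`.
#'
#' @param hapset a `haplotype_set` from [gene_drop()].
#' @param dropout_prob per-call missingness probability (default taken from
#'   the generating config).
#' @param seed seed for the dropout draw.
#' @return a [genotype_matrix()].
#' @export
hap_genotypes <- function(hapset, dropout_prob = NULL, seed = 1) {
  p <- dropout_prob %||% hapset$config$dropout_prob
  dos <- t(hapset$hapP + hapset$hapM)
  if (p > 0) {
    dos <- with_seed(seed, {
      drop <- matrix(stats::runif(length(dos)) < p, nrow(dos))
      dos[drop] <- NA_integer_
      dos
    })
  }
  genotype_matrix(hapset$sites, hapset$samples, dos)
}

#' Assign phenotypes from the causal genotype
#'
#' Fully penetrant recessive model with no phenocopies: an individual is
#' affected if and only if it carries two copies of the causal allele.
#'
#' @param ped a [pedigree()].
#' @param hapset the `haplotype_set` carrying the causal site.
#' @return the pedigree with `phenotype` filled in.
#' @export
assign_phenotypes <- function(ped, hapset) {
  ci <- causal_site_index(hapset$config, hapset$sites)
  dos <- hapset$hapP[, ci] + hapset$hapM[, ci]
  ped$phenotype <- ifelse(dos[match(ped$id, hapset$samples)] == 2L,
                          "affected", "unaffected")
  ped
}

# Concatenate two haplotype sets over disjoint chromosomes for the same
# individuals, restoring (chrom, pos) ordering.
merge_hapsets <- function(a, b, config) {
  stopifnot(identical(a$samples, b$samples))
  sites <- rbind(a$sites, b$sites)
  ord <- order(sites$chrom, sites$pos)
  glue <- function(field) cbind(a[[field]], b[[field]])[, ord, drop = FALSE]
  structure(list(sites = sites[ord, , drop = FALSE], samples = a$samples,
                 hapP = glue("hapP"), hapM = glue("hapM"),
                 originP = glue("originP"), originM = glue("originM"),
                 carrier_hap = 1L, config = config),
            class = "haplotype_set")
}

#' Simulate a complete mapped colony
#'
#' Convenience wrapper tying the generator together: simulates pedigrees and
#' causal-chromosome gene drops until the causal allele segregates with at
#' least `min_affected` homozygotes (ascertainment conditioning: a colony is
#' only a mapping substrate because affected animals were observed in it),
#' then drops the remaining chromosomes and assigns phenotypes.
#'
#' @param config a [colony_config()].
#' @return list with `pedigree`, `hapset`, `genotypes` (a
#'   [genotype_matrix()]), `causal` (site row index), and `n_tries`.
#' @export
simulate_colony <- function(config) {
  with_seed(config$seed, {
    rest <- setdiff(config$genome$chrom, config$causal_chromosome)
    for (try in seq_len(config$max_tries)) {
      ped <- simulate_pedigree_impl(config)
      hs_causal <- gene_drop_impl(ped, config, config$causal_chromosome)
      ped <- assign_phenotypes(ped, hs_causal)
      if (sum(ped$phenotype == "affected") < config$min_affected) next
      hapset <- if (length(rest)) {
        merge_hapsets(hs_causal, gene_drop_impl(ped, config, rest), config)
      } else hs_causal
      gm <- hap_genotypes(hapset, seed = config$seed + 2L)
      return(list(pedigree = ped, hapset = hapset, genotypes = gm,
                  causal = causal_site_index(config, gm$sites),
                  n_tries = try))
    }
    stop("colony ascertainment failed after ", config$max_tries,
         " attempts; increase max_tries or relax min_affected")
  })
}

#' Extract an amplicon-style marker panel
#'
#' Selects polymorphic sites in three strata mirroring an amplicon
#' genotyping panel: `interval` markers evenly spaced within a stated region
#' on the causal chromosome, `chromosome` markers spanning the remainder of
#' that chromosome, and `genomewide` markers spread over the other
#' chromosomes proportionally to their lengths.
#'
#' @param gm a [genotype_matrix()] (typically the full colony matrix).
#' @param spec named counts `c(interval=, chromosome=, genomewide=)`.
#' @param interval list/vector with `chrom`, `start`, `end` defining the
#'   fine-mapping region.
#' @return a [genotype_matrix()] of the selected markers, sorted by
#'   (chromosome, position).
#' @export
extract_marker_panel <- function(gm, spec, interval) {
  spec <- c(interval = unname(spec["interval"]),
            chromosome = unname(spec["chromosome"]),
            genomewide = unname(spec["genomewide"]))
  if (anyNA(spec)) stop("spec must name counts interval/chromosome/genomewide")
  chrom <- as.character(interval$chrom %||% interval[["chrom"]])
  start <- as.numeric(interval$start); end <- as.numeric(interval$end)
  poly <- apply(gm$dosage, 1, function(d) {
    d <- d[!is.na(d)]
    length(d) > 0L && any(d > 0L) && any(d < 2L)
  })
  in_int <- gm$sites$chrom == chrom & gm$sites$pos >= start &
    gm$sites$pos <= end
  on_chr <- gm$sites$chrom == chrom & !in_int
  off_chr <- gm$sites$chrom != chrom

  pick_even <- function(idx, n, stratum) {
    idx <- idx[poly[idx]]
    if (length(idx) < n) {
      stop(sprintf(
        "insufficient polymorphic sites in stratum '%s': need %d, have %d",
        stratum, n, length(idx)))
    }
    if (n == 0L) return(integer(0))
    pos <- gm$sites$pos[idx]
    targets <- seq(min(pos), max(pos), length.out = n)
    sel <- integer(0)
    for (t in targets) {
      free <- setdiff(idx, sel)
      sel <- c(sel, free[which.min(abs(gm$sites$pos[free] - t))])
    }
    sel
  }

  sel <- pick_even(which(in_int), spec["interval"], "interval")
  sel <- c(sel, pick_even(which(on_chr), spec["chromosome"], "chromosome"))
  if (spec["genomewide"] > 0L) {
    chroms <- unique(gm$sites$chrom[off_chr])
    if (length(chroms) == 0L) {
      stop("insufficient polymorphic sites in stratum 'genomewide': ",
           "no other chromosomes")
    }
    lens <- vapply(chroms, function(cc) {
      max(gm$sites$pos[gm$sites$chrom == cc])
    }, 0)
    alloc <- diff(round(cumsum(c(0, lens / sum(lens) * spec["genomewide"]))))
    # ensure exact total despite rounding
    while (sum(alloc) < spec["genomewide"]) alloc[which.max(lens)] <- alloc[which.max(lens)] + 1L
    while (sum(alloc) > spec["genomewide"]) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
    for (k in seq_along(chroms)) {
      if (alloc[k] == 0) next
      idx <- which(gm$sites$chrom == chroms[k])
      sel <- c(sel, pick_even(idx, alloc[k], "genomewide"))
    }
  }
  subset_genotypes(gm, sites = sort(unique(sel)))
}
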