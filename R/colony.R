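#' Default simulated genome
#'
#' A reduced six-autosome genome used by the colony simulator: chromosome
#' lengths follow representative cat autosomes (including the ~71.5 Mb
#' chromosome carrying the causal locus) and the genetic map is linear at
#' 1 cM/Mb. A reduced genome keeps whole-colony simulations desk-scale while
#' preserving the geometry the mapping statistics depend on (many windows,
#' one causal chromosome).
#'
#' @return data frame with columns `chrom`, `length_bp`, `map_cm`.
#' @export
default_genome <- function() {
  data.frame(
    chrom = c("A1", "B1", "C1", "D1", "E1", "F1"),
    length_bp = c(240e6, 205e6, 220e6, 115e6, 62e6, 71.5e6),
    map_cm = c(240, 205, 220, 115, 62, 71.5),
    stringsAsFactors = FALSE
  )
}

#' Colony simulation configuration
#'
#' Parameters of the synthetic closed-colony generator. Defaults emulate the
#' mapped study colony: ~123 individuals of which ~25 are affected, a fully
#' penetrant recessive causal allele carried on a single founder haplotype
#' embedded in a unique 1.3 Mb identical-by-descent marker haplotype near the
#' end of chromosome F1, and a 26 + 4 + 20 amplicon marker panel.
#'
#' @param n_founders number of unrelated founders (default 4; a small founder
#'   pool plus single-stud overlapping-generation matings reproduces the high
#'   inbreeding of a colony closed for decades).
#' @param n_generations maximum number of breeding rounds (default 8).
#' @param mating_scheme `"random_within_colony"` (default; each round one
#'   stud male from the whole colony sires all litters, so sibling and
#'   parent-offspring matings occur as in a closed colony) or
#'   `"sibling_avoidance"` (a female full-sib to the stud is mated to a
#'   random non-sib male instead).
#' @param offspring_mean mean litter size (Poisson, default 4).
#' @param target_colony_size growth stops when this size is reached
#'   mid-generation (default 123).
#' @param causal_chromosome,causal_position location of the planted causal
#'   variant (defaults `"F1"`, 66,768,323 bp).
#' @param ibd_segment_length length in bp of the unique founder haplotype
#'   around the causal allele (default 1,300,000).
#' @param genome data frame of chromosome lengths and map lengths
#'   (default [default_genome()]).
#' @param variant_density simulated biallelic variants per Mb (default 10;
#'   a sparse genome-wide site set sufficient for window statistics and for
#'   a 26-marker fine-mapping panel inside a 5 Mb window).
#' @param marker_panel_spec named counts
#'   `c(interval = 26, chromosome = 4, genomewide = 20)`.
#' @param segment_alt_freq Bernoulli alt frequency of non-carrier founder
#'   haplotypes at sites inside the IBD segment (default 0.1, keeping the
#'   carrier haplotype essentially unique over the segment).
#' @param dropout_prob per-call missingness probability (default 0).
#' @param min_affected ascertainment threshold: colonies are resimulated
#'   until at least this many affected individuals segregate (default 8,
#'   the number of affected animals the zygosity filter is labeled with).
#' @param max_tries maximum resimulation attempts before erroring.
#' @param seed integer seed; identical configs and seeds give identical
#'   colonies.
#' @return a `colony_config` list.
#' @export
colony_config <- function(n_founders = 4,
                          n_generations = 8,
                          mating_scheme = c("random_within_colony",
                                            "sibling_avoidance"),
                          offspring_mean = 4,
                          target_colony_size = 123,
                          causal_chromosome = "F1",
                          causal_position = 66768323,
                          ibd_segment_length = 1300000,
                          genome = default_genome(),
                          variant_density = 10,
                          marker_panel_spec = c(interval = 26, chromosome = 4,
                                                genomewide = 20),
                          segment_alt_freq = 0.1,
                          dropout_prob = 0,
                          min_affected = 8,
                          max_tries = 200,
                          seed = 1) {
  mating_scheme <- match.arg(mating_scheme)
  cfg <- list(
    n_founders = check_count(n_founders, "n_founders", min = 1L),
    n_generations = check_count(n_generations, "n_generations"),
    mating_scheme = mating_scheme,
    offspring_mean = offspring_mean,
    target_colony_size = check_count(target_colony_size, "target_colony_size",
                                     min = 1L),
    causal_chromosome = as.character(causal_chromosome),
    causal_position = check_count(causal_position, "causal_position", min = 1L),
    ibd_segment_length = check_count(ibd_segment_length, "ibd_segment_length",
                                     min = 1L),
    genome = genome,
    variant_density = variant_density,
    marker_panel_spec = marker_panel_spec,
    segment_alt_freq = check_fraction(segment_alt_freq, "segment_alt_freq"),
    dropout_prob = check_fraction(dropout_prob, "dropout_prob"),
    min_affected = check_count(min_affected, "min_affected"),
    max_tries = check_count(max_tries, "max_tries", min = 1L),
    seed = check_count(seed, "seed")
  )
  stopifnot(is.data.frame(genome),
            all(c("chrom", "length_bp", "map_cm") %in% names(genome)))
  if (any(genome$length_bp <= 0) || any(genome$map_cm < 0)) {
    stop("chromosome lengths must be > 0 and map lengths >= 0")
  }
  if (anyDuplicated(genome$chrom)) stop("duplicate chromosome labels in genome")
  if (!cfg$causal_chromosome %in% genome$chrom) {
    stop("causal chromosome '", cfg$causal_chromosome,
         "' absent from genome")
  }
  clen <- genome$length_bp[genome$chrom == cfg$causal_chromosome]
  if (cfg$causal_position > clen) {
    stop("causal_position lies outside its chromosome (length ", clen, ")")
  }
  if (offspring_mean <= 0) stop("offspring_mean must be > 0")
  if (any(marker_panel_spec < 0)) stop("marker panel counts must be >= 0")
  class(cfg) <- "colony_config"
  cfg
}

#' Simulate a closed-colony pedigree
#'
#' Starts from `n_founders` unrelated founders (alternating sex) and breeds
#' for up to `n_generations` rounds with overlapping generations. Each round
#' one stud male drawn from the whole colony sires all litters (the
#' single-stud structure typical of small research colonies, and the main
#' driver of the inbreeding a recessive allele needs to reach homozygosity);
#' every female is mated with probability 0.6, litter sizes are Poisson, and
#' growth stops as soon as `target_colony_size` is reached mid-generation.
#' Phenotypes are `"unknown"`; see [assign_phenotypes()].
#'
#' @param config a [colony_config()].
#' @return a [pedigree()].
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  with_seed(config$seed, simulate_pedigree_impl(config))
}

# RNG-consuming implementation; callers manage the seed.
simulate_pedigree_impl <- function(config) {
  nf <- config$n_founders
  if (nf < 2L && config$n_generations > 0L) {
    stop("configuration error: cannot breed a colony from ", nf, " founder")
  }
  id <- sprintf("I%03d", seq_len(nf))
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  sibkey <- rep(NA_character_, nf)   # full-sib group = "sire|dam"
  nxt <- nf + 1L
  target <- config$target_colony_size
  avoid <- config$mating_scheme == "sibling_avoidance"

  for (g in seq_len(config$n_generations)) {
    if (length(id) >= target) break
    females <- which(sex == "F")
    males <- which(sex == "M")
    if (length(females) == 0L || length(males) == 0L) break
    stud <- males[sample.int(length(males), 1L)]
    mated <- females[stats::runif(length(females)) < 0.6]
    if (length(mated) == 0L) mated <- females[sample.int(length(females), 1L)]
    for (f in mated) {
      m <- stud
      if (avoid && !is.na(sibkey[f]) && !is.na(sibkey[m]) &&
          sibkey[f] == sibkey[m]) {
        cand <- males[is.na(sibkey[males]) | sibkey[males] != sibkey[f]]
        if (length(cand) == 0L) next
        m <- cand[sample.int(length(cand), 1L)]
      }
      litter <- stats::rpois(1L, config$offspring_mean)
      litter <- min(litter, target - length(id))
      if (litter <= 0L) next
      for (k in seq_len(litter)) {
        id <- c(id, sprintf("I%03d", nxt))
        sire <- c(sire, id[m])
        dam <- c(dam, id[f])
        sex <- c(sex, if (stats::runif(1) < 0.5) "M" else "F")
        sibkey <- c(sibkey, paste(id[m], id[f], sep = "|"))
        nxt <- nxt + 1L
      }
      if (length(id) >= target) break
    }
  }
  pedigree(id = id, sire = sire, dam = dam, sex = sex, phenotype = "unknown")
}
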