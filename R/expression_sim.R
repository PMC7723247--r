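# RNA-seq style count simulation with a nonsense-mediated-decay target gene,
# allele-specific read counts, and cell-type marker structure.

#' Expression simulation configuration
#'
#' The central parameter is the NMD retention fraction `lambda`: the
#' transcript output of the mutant allele relative to the wild-type allele.
#' It fixes two observable quantities: the homozygote total-expression
#' reduction `r = 1 - lambda` and the heterozygote mutant-read fraction
#' `pi = lambda / (1 + lambda)`. The default `lambda = 0.41` corresponds to
#' the 59% homozygote reduction seen for a decayed frameshift transcript
#' (and `pi ~= 0.29`).
#'
#' @param n_genes background genes simulated (default 2000).
#' @param baseline_mean_log mean of the log-normal per-gene baseline
#'   (default `log(100)`).
#' @param baseline_sd_log sd of the log-normal per-gene baseline (default 1).
#' @param dispersion negative-binomial dispersion shared across genes
#'   (`size = 1/dispersion`; default 0.05).
#' @param nmd_retention mutant-allele relative output `lambda` in `[0, 1]`
#'   (default 0.41).
#' @param target_gene name of the NMD target gene (default `"PEA15"`).
#' @param target_baseline baseline mean count of the target gene
#'   (default 4000).
#' @param reads_per_het_site range of allele-informative read depths per
#'   heterozygous animal per gene (default `c(24, 3000)`).
#' @param n_control_genes genes used as allele-bias controls (default 3).
#' @param cell_types data frame `name`, `n_markers`, `shift` (multiplier
#'   applied to marker genes in homozygous mutant animals). Defaults model
#'   a dysgenic cortex: more astrocytes, endothelium and oligodendrocyte
#'   precursors, fewer mature oligodendrocytes, unchanged neurons and
#'   microglia.
#' @param n_reference_reps replicates per cell type in the simulated
#'   reference expression table (default 3).
#' @param marker_enrichment fold enrichment of a marker gene in its own
#'   cell type within the reference (default 8).
#' @param n_de_genes background genes planted as differentially expressed
#'   in homozygous mutants (default 0).
#' @param de_lfc log2 fold change of planted DE genes (default 3, the
#'   magnitude of strongly dysregulated structural genes).
#' @param replicates samples per genotype group,
#'   named `c(hom_mutant, het, hom_ref)` (default `c(4, 3, 3)`, the group
#'   sizes of the motivating cortex RNA-seq design).
#' @param seed integer seed.
#' @return an `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  baseline_mean_log = log(100),
                                  baseline_sd_log = 1,
                                  dispersion = 0.05,
                                  nmd_retention = 0.41,
                                  target_gene = "PEA15",
                                  target_baseline = 4000,
                                  reads_per_het_site = c(24, 3000),
                                  n_control_genes = 3,
                                  cell_types = data.frame(
                                    name = c("astrocyte", "neuron",
                                             "oligodendrocyte", "opc",
                                             "microglia", "endothelial"),
                                    n_markers = 25,
                                    shift = c(1.4, 1.0, 0.6, 1.6, 1.0, 1.3),
                                    stringsAsFactors = FALSE),
                                  n_reference_reps = 3,
                                  marker_enrichment = 8,
                                  n_de_genes = 0,
                                  de_lfc = 3,
                                  replicates = c(hom_mutant = 4, het = 3,
                                                 hom_ref = 3),
                                  seed = 1) {
  lam <- nmd_retention
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 ||
      lam > 1) {
    stop("configuration error: nmd_retention (lambda) must lie in [0, 1]")
  }
  stopifnot(dispersion > 0, target_baseline > 0,
            length(reads_per_het_site) == 2L,
            all(replicates >= 0))
  cfg <- list(n_genes = check_count(n_genes, "n_genes"),
              baseline_mean_log = baseline_mean_log,
              baseline_sd_log = baseline_sd_log,
              dispersion = dispersion,
              nmd_retention = lam,
              target_gene = target_gene,
              target_baseline = target_baseline,
              reads_per_het_site = reads_per_het_site,
              n_control_genes = check_count(n_control_genes,
                                            "n_control_genes"),
              cell_types = cell_types,
              n_reference_reps = check_count(n_reference_reps,
                                             "n_reference_reps", min = 2L),
              marker_enrichment = marker_enrichment,
              n_de_genes = check_count(n_de_genes, "n_de_genes"),
              de_lfc = de_lfc,
              replicates = replicates,
              seed = check_count(seed, "seed"))
  class(cfg) <- "expression_sim_config"
  cfg
}

#' Implied observables of an NMD retention fraction
#'
#' @param lambda mutant-allele relative transcript output in `[0, 1]`.
#' @return list with `reduction` (`1 - lambda`, homozygote total-expression
#'   reduction) and `het_mutant_fraction` (`lambda / (1 + lambda)`).
#' @export
nmd_observables <- function(lambda) {
  lambda <- check_fraction(lambda, "lambda")
  list(reduction = 1 - lambda,
       het_mutant_fraction = lambda / (1 + lambda))
}

#' Simulate an expression bundle
#'
#' Draws negative-binomial counts for background genes, cell-type marker
#' genes (scaled in homozygous mutants by the configured shift multipliers)
#' and the NMD target gene, whose group means follow the retention
#' fraction: homozygote mean `lambda * baseline`, heterozygote mean
#' `(1 + lambda) / 2 * baseline`. Allele-specific read counts at the target
#' are binomial with mutant-read probability `pi = lambda / (1 + lambda)`
#' in heterozygotes; control genes have no allele bias (p = 0.5). A
#' replicate cell-type reference expression table is included.
#'
#' @param config an [expression_sim_config()].
#' @param groups optional named character vector mapping sample id to group
#'   (`hom_mutant`/`het`/`hom_ref`); by default samples are generated per
#'   `config$replicates`. When simulating from a mapped colony, pass the
#'   genotype groups of the chosen animals.
#' @return an `expression_bundle`: list with `counts` (gene x sample),
#'   `lib_sizes`, `groups` (factor per sample), `target_gene`,
#'   `control_genes`, `marker_sets` (list per cell type),
#'   `allele_counts` (data frame: sample, gene, ref_reads, alt_reads),
#'   `reference` (long data frame: gene, cell_type, replicate, abundance),
#'   `truth` (planted DE genes and parameters).
#' @export
simulate_expression <- function(config, groups = NULL) {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(config$seed, simulate_expression_impl(config, groups))
}

simulate_expression_impl <- function(config, groups = NULL) {
  lam <- config$nmd_retention
  if (is.null(groups)) {
    reps <- config$replicates
    groups <- rep(names(reps), times = reps)
    names(groups) <- sprintf("S%02d", seq_along(groups))
  }
  groups <- factor(groups, levels = c("hom_mutant", "het", "hom_ref"))
  samples <- names(groups)
  ns <- length(samples)

  ct <- config$cell_types
  marker_sets <- list()
  marker_names <- character(0)
  for (i in seq_len(nrow(ct))) {
    nm <- sprintf("%s_marker_%02d", ct$name[i], seq_len(ct$n_markers[i]))
    marker_sets[[ct$name[i]]] <- nm
    marker_names <- c(marker_names, nm)
  }
  bg_names <- sprintf("gene_%04d", seq_len(config$n_genes))
  control_genes <- sprintf("control_%d", seq_len(config$n_control_genes))
  genes <- c(config$target_gene, control_genes, bg_names, marker_names)

  base <- stats::rlnorm(length(genes), config$baseline_mean_log,
                        config$baseline_sd_log)
  names(base) <- genes
  base[config$target_gene] <- config$target_baseline
  base[control_genes] <- stats::runif(length(control_genes), 500, 2000)

  # per-gene x sample mean matrix
  mu <- matrix(rep(base, ns), nrow = length(genes), ncol = ns,
               dimnames = list(genes, samples))
  dose_scale <- c(hom_mutant = lam, het = (1 + lam) / 2, hom_ref = 1)
  mu[config$target_gene, ] <- mu[config$target_gene, ] *
    dose_scale[as.character(groups)]
  hom <- groups == "hom_mutant"
  for (i in seq_len(nrow(ct))) {
    mu[marker_sets[[ct$name[i]]], hom] <-
      mu[marker_sets[[ct$name[i]]], hom] * ct$shift[i]
  }
  de_genes <- character(0)
  if (config$n_de_genes > 0) {
    # planted DE genes are drawn from well-expressed background genes,
    # emulating the robustly detected structural genes of a dysgenic cortex
    pool <- bg_names[base[bg_names] >= 100]
    if (length(pool) < config$n_de_genes) pool <- bg_names
    de_genes <- sample(pool, config$n_de_genes)
    mu[de_genes, hom] <- mu[de_genes, hom] * 2^config$de_lfc
  }

  size <- 1 / config$dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  # allele-specific reads in heterozygotes at target + controls
  pi_mut <- if (lam == 0) 0 else lam / (1 + lam)
  het_samples <- samples[groups == "het"]
  ac <- NULL
  for (g in c(config$target_gene, control_genes)) {
    p <- if (g == config$target_gene) pi_mut else 0.5
    depth <- round(stats::runif(length(het_samples),
                                config$reads_per_het_site[1],
                                config$reads_per_het_site[2]))
    alt <- stats::rbinom(length(het_samples), depth, p)
    ac <- rbind(ac, data.frame(sample = het_samples, gene = g,
                               ref_reads = depth - alt, alt_reads = alt,
                               stringsAsFactors = FALSE))
  }

  # cell-type reference: marker genes enriched in their own type
  ref <- NULL
  for (i in seq_len(nrow(ct))) {
    for (j in seq_len(nrow(ct))) {
      m <- marker_sets[[ct$name[j]]]
      lvl <- ifelse(rep(i == j, length(m)), config$marker_enrichment, 1) * 10
      for (r in seq_len(config$n_reference_reps)) {
        ref <- rbind(ref, data.frame(
          gene = m, cell_type = ct$name[i], replicate = r,
          abundance = stats::rgamma(length(m), shape = 20, rate = 20 / lvl),
          stringsAsFactors = FALSE))
      }
    }
  }

  structure(list(counts = counts, lib_sizes = colSums(counts),
                 groups = groups, target_gene = config$target_gene,
                 control_genes = control_genes, marker_sets = marker_sets,
                 allele_counts = ac, reference = ref,
                 truth = list(lambda = lam, pi = pi_mut,
                              de_genes = de_genes,
                              cell_type_shift = ct)),
            class = "expression_bundle")
}
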