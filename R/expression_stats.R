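# Validation statistics: CPM normalization, NMD reduction and allele-bias
# tests, dual-contrast FDR-intersection differential expression, cell-type
# marker selection and genotype-effect tests, and the brain-weight contrast.

#' Counts-per-million normalization
#'
#' @param counts gene x sample count matrix.
#' @param lib_sizes per-sample library sizes (default column sums).
#' @return list with `cpm` and `log2cpm` (`log2(CPM + 1)`) matrices.
#' @export
cpm_normalize <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(lib_sizes) != ncol(counts)) {
    stop("lib_sizes must have one entry per sample")
  }
  if (any(lib_sizes <= 0)) stop("zero or negative library size")
  cpm <- sweep(counts, 2, lib_sizes, "/") * 1e6
  list(cpm = cpm, log2cpm = log2(cpm + 1))
}

#' Genotype-group expression reduction test for a target gene
#'
#' Computes per-group mean expression of the target gene, the percent
#' reduction in homozygous mutants relative to homozygous reference
#' animals, a one-way ANOVA across genotype groups, and Tukey HSD
#' post-hoc contrasts.
#'
#' @param cpm CPM matrix (gene x sample).
#' @param groups factor per sample with levels among
#'   `hom_mutant`/`het`/`hom_ref`.
#' @param gene target gene id (row of `cpm`).
#' @return list with `group_means`, `percent_reduction`, `anova_p`,
#'   `posthoc` (Tukey table).
#' @export
expression_reduction_test <- function(cpm, groups, gene) {
  if (!gene %in% rownames(cpm)) stop("gene not in matrix: ", gene)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 genotype groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  y <- as.numeric(cpm[gene, ])
  gm <- tapply(y, groups, mean)
  if (!all(c("hom_mutant", "hom_ref") %in% names(gm))) {
    stop("groups must include hom_mutant and hom_ref")
  }
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = groups))
  pv <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(group_means = gm,
       percent_reduction = (1 - gm[["hom_mutant"]] / gm[["hom_ref"]]) * 100,
       anova_p = pv,
       posthoc = stats::TukeyHSD(fit)$g)
}

#' Allele-specific read bias test
#'
#' Per animal and gene, the mutant-read fraction is
#' `alt_reads / (ref_reads + alt_reads)`; the per-animal fractions are the
#' units of comparison. Tests the target gene against control genes by
#' one-way ANOVA over genes with Tukey post-hoc contrasts of the target vs
#' each control. Genes with zero coverage in all animals are dropped with a
#' warning.
#'
#' @param allele_counts data frame `sample`, `gene`, `ref_reads`,
#'   `alt_reads`.
#' @param target target gene id.
#' @param controls character vector of control gene ids.
#' @return list with `fractions` (per sample x gene data frame),
#'   `gene_means`, `anova_p`, `posthoc` (target vs each control).
#' @export
allele_bias_test <- function(allele_counts, target, controls) {
  ac <- allele_counts[allele_counts$gene %in% c(target, controls), ,
                      drop = FALSE]
  ac$depth <- ac$ref_reads + ac$alt_reads
  dead <- tapply(ac$depth, ac$gene, function(d) all(d == 0))
  if (any(dead)) {
    warning("dropping zero-coverage gene(s): ",
            paste(names(dead)[dead], collapse = ", "))
    ac <- ac[!ac$gene %in% names(dead)[dead], , drop = FALSE]
  }
  if (!target %in% ac$gene) stop("target gene has no coverage")
  ac <- ac[ac$depth > 0, , drop = FALSE]
  ac$fraction <- ac$alt_reads / ac$depth
  ac$gene <- factor(ac$gene, levels = c(target, intersect(controls, ac$gene)))
  if (stats::var(ac$fraction) < 1e-20) {
    # identical fractions everywhere: no evidence of bias either way
    return(list(fractions = ac[, c("sample", "gene", "fraction", "depth")],
                gene_means = tapply(ac$fraction, ac$gene, mean),
                anova_p = NA_real_, posthoc = NULL))
  }
  fit <- stats::aov(fraction ~ gene, data = ac)
  pv <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$gene
  vs_target <- tk[grepl(paste0("-", target, "$"), rownames(tk)) |
                    grepl(paste0("^", target, "-"), rownames(tk)), ,
                  drop = FALSE]
  list(fractions = ac[, c("sample", "gene", "fraction", "depth")],
       gene_means = tapply(ac$fraction, ac$gene, mean),
       anova_p = pv,
       posthoc = vs_target)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, as in
#' `p.adjust(method = "BH")`; input outside `[0, 1]` is an error.
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1] with no NAs")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene two-group differential expression contrast
#'
#' The per-gene test behind the contrast design. The default engine
#' (`"nb_lrt"`) fits per-group negative-binomial means with library-size
#' offsets and a common genome-wide dispersion (Pearson-pooled unless
#' supplied) and compares nested fits by likelihood ratio against
#' chi-square(1); the alternative `"welch"` engine is a plain Welch t on
#' `log2(CPM + 1)` values. The scientific content of this module is which
#' groups are contrasted and how the contrasts are intersected; the
#' per-gene test is a standard component.
#'
#' @param x for `engine = "nb_lrt"` the raw count matrix (gene x sample);
#'   for `engine = "welch"` a `log2(CPM + 1)` matrix.
#' @param groups factor per sample.
#' @param group_a,group_b character vectors of group levels: the contrast is
#'   `a` vs `b` (positive effect = higher in `a`).
#' @param engine `"nb_lrt"` (default) or `"welch"`.
#' @param lib_sizes effective library sizes for the NB engine (default
#'   [effective_lib_sizes()] of `x`).
#' @param dispersion common NB dispersion; estimated from the data when
#'   `NULL`.
#' @return data frame per gene: `gene`, `lfc` (log2), `p`, `q`
#'   (Benjamini-Hochberg).
#' @export
de_contrast <- function(x, groups, group_a, group_b,
                        engine = c("nb_lrt", "welch"),
                        lib_sizes = NULL, dispersion = NULL) {
  engine <- match.arg(engine)
  ia <- which(groups %in% group_a)
  ib <- which(groups %in% group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each side of the contrast needs >= 2 samples")
  }
  if (engine == "welch") {
    A <- x[, ia, drop = FALSE]
    B <- x[, ib, drop = FALSE]
    na <- ncol(A); nb <- ncol(B)
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- rowSums((A - ma)^2) / (na - 1)
    vb <- rowSums((B - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    p[se2 == 0] <- 1  # constant genes carry no evidence
    return(data.frame(gene = rownames(x), lfc = ma - mb, p = p,
                      q = bh_adjust(p), row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  counts <- as.matrix(x)
  ls <- lib_sizes %||% effective_lib_sizes(counts)
  sel <- c(ia, ib)
  g2 <- factor(sel %in% ia)
  phi <- dispersion %||%
    estimate_common_dispersion(counts[, sel, drop = FALSE], ls[sel], g2)
  fa <- nb_group_fit(counts[, ia, drop = FALSE], ls[ia], phi)
  fb <- nb_group_fit(counts[, ib, drop = FALSE], ls[ib], phi)
  f0 <- nb_group_fit(counts[, sel, drop = FALSE], ls[sel], phi)
  lrt <- 2 * (nb_row_loglik(counts[, ia, drop = FALSE], ls[ia], fa$beta, phi) +
                nb_row_loglik(counts[, ib, drop = FALSE], ls[ib], fb$beta, phi) -
                nb_row_loglik(counts[, sel, drop = FALSE], ls[sel], f0$beta, phi))
  p <- stats::pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE)
  p[rowSums(counts[, sel, drop = FALSE]) == 0] <- 1
  data.frame(gene = rownames(counts), lfc = (fa$beta - fb$beta) / log(2),
             p = p, q = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Effective library sizes for differential expression
#'
#' Library sizes scaled by trimmed-mean-of-M-values (TMM) normalization
#' factors, correcting the compositional bias that strongly shifted genes
#' induce in raw library sizes.
#'
#' @param counts gene x sample count matrix.
#' @param lib_sizes raw library sizes (default column sums).
#' @return numeric vector of effective library sizes.
#' @export
effective_lib_sizes <- function(counts, lib_sizes = colSums(counts)) {
  lib_sizes * edgeR::calcNormFactors(as.matrix(counts),
                                     lib.size = lib_sizes)
}

# Common (genome-wide) NB dispersion: the value at which the summed Pearson
# chi-square of the per-group NB fits equals its residual degrees of
# freedom (a pooled quasi-likelihood estimator, approximately unbiased at
# small group sizes where per-gene moment estimators are not).
estimate_common_dispersion <- function(counts, lib_sizes, groups) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  expressed <- rowSums(counts) > 0
  df <- (ncol(counts) - nlevels(groups)) * sum(expressed)
  pearson_excess <- function(phi) {
    tot <- 0
    for (g in levels(groups)) {
      X <- counts[expressed, groups == g, drop = FALSE]
      lg <- lib_sizes[groups == g]
      f <- nb_group_fit(X, lg, phi)
      mu <- exp(f$beta) %o% lg
      tot <- tot + sum((X - mu)^2 / (mu * (1 + phi * mu)))
    }
    tot - df
  }
  if (pearson_excess(1e-4) < 0) return(1e-4)  # essentially Poisson
  stats::uniroot(pearson_excess, c(1e-4, 5), tol = 1e-4,
                 extendInt = "downX")$root
}

# row-wise NB log-likelihood at fitted per-group means
nb_row_loglik <- function(counts, lib_sizes, beta, phi) {
  mu <- exp(beta) %o% lib_sizes
  rowSums(stats::dnbinom(as.matrix(counts), size = 1 / phi, mu = mu,
                         log = TRUE))
}

# Vectorized per-group NB mean fit (log link with library-size offsets) by
# Newton iteration, returning the estimate and its Wald variance.
nb_group_fit <- function(counts, lib_sizes, phi) {
  # beta = log mean rate per unit library size
  y <- as.matrix(counts)
  ls <- matrix(lib_sizes, nrow(y), ncol(y), byrow = TRUE)
  beta <- log((rowSums(y) + 0.5) / sum(lib_sizes))
  for (it in 1:25) {
    mu <- exp(beta) * ls
    w <- mu / (1 + phi * mu)
    score <- rowSums((y - mu) / (1 + phi * mu))
    info <- rowSums(w)
    step <- score / info
    step <- pmax(pmin(step, 2), -2)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(beta) * ls
  list(beta = beta, var = 1 / rowSums(mu / (1 + phi * mu)))
}

#' Intersection of two differential-expression contrasts
#'
#' Genes significant (q below threshold) in both contrasts with concordant
#' effect sign; discordant-sign double-significant genes are reported
#' separately, never silently merged.
#'
#' @param res_a,res_b results from [de_contrast()] over the same gene
#'   universe.
#' @param q_threshold FDR threshold (default 0.05).
#' @return list with `intersection` (character), `discordant` (character),
#'   `n_a`, `n_b` (per-contrast significant counts).
#' @export
de_intersection <- function(res_a, res_b, q_threshold = 0.05) {
  if (!setequal(res_a$gene, res_b$gene)) {
    d <- c(setdiff(res_a$gene, res_b$gene), setdiff(res_b$gene, res_a$gene))
    stop("mismatched gene universes; differing genes: ",
         paste(utils::head(d, 10), collapse = ", "))
  }
  res_b <- res_b[match(res_a$gene, res_b$gene), , drop = FALSE]
  sig <- res_a$q < q_threshold & res_b$q < q_threshold
  conc <- sign(res_a$lfc) == sign(res_b$lfc)
  list(intersection = res_a$gene[sig & conc],
       discordant = res_a$gene[sig & !conc],
       n_a = sum(res_a$q < q_threshold),
       n_b = sum(res_b$q < q_threshold))
}

#' Select cell-type marker genes from a reference expression table
#'
#' A gene is a marker of a cell type if its mean abundance in that type is
#' at least `fold` times the mean in every other type (boundary included)
#' and a Welch two-sample test of the type against the runner-up type gives
#' a raw p below `p_max`. Cell types with fewer than two replicates are
#' excluded with a warning.
#'
#' @param reference long data frame `gene`, `cell_type`, `replicate`,
#'   `abundance`.
#' @param fold fold-enrichment threshold (default 2; `>=`).
#' @param p_max raw p-value threshold (default 0.2; `<`, strict).
#' @return named list of marker gene vectors per cell type.
#' @export
select_celltype_markers <- function(reference, fold = 2, p_max = 0.2) {
  reps <- tapply(reference$replicate, reference$cell_type,
                 function(r) length(unique(r)))
  drop <- names(reps)[reps < 2]
  if (length(drop)) {
    warning("excluding cell type(s) with < 2 replicates: ",
            paste(drop, collapse = ", "))
    reference <- reference[!reference$cell_type %in% drop, , drop = FALSE]
  }
  types <- unique(reference$cell_type)
  if (length(types) < 2L) stop("need >= 2 cell types with replicates")
  genes <- unique(reference$gene)
  out <- stats::setNames(vector("list", length(types)), types)
  mean_tab <- tapply(reference$abundance,
                     list(reference$gene, reference$cell_type), mean)
  for (g in genes) {
    mu <- mean_tab[g, types]
    best <- names(which.max(mu))
    runner <- names(which.max(mu[setdiff(types, best)]))
    if (mu[best] < fold * mu[runner]) next
    a <- reference$abundance[reference$gene == g &
                               reference$cell_type == best]
    b <- reference$abundance[reference$gene == g &
                               reference$cell_type == runner]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      pv <- if (mean(a) != mean(b)) 0 else 1
    } else {
      pv <- stats::t.test(a, b)$p.value
    }
    if (pv < p_max) out[[best]] <- c(out[[best]], g)
  }
  out
}

#' Cell-type composition shift test
#'
#' For each cell type with at least two marker genes, fits a two-way ANOVA
#' of `log2(CPM + 1)` with genotype group and gene as factors over the
#' marker genes, and reports the genotype main-effect p-value and the
#' direction of the homozygous-mutant shift.
#'
#' @param log2cpm `log2(CPM + 1)` matrix.
#' @param markers named list of marker gene vectors per cell type.
#' @param groups factor per sample.
#' @return data frame per cell type: `cell_type`, `n_markers`,
#'   `genotype_p`, `direction` (`"increased"`/`"decreased"` in
#'   hom_mutant vs hom_ref), `delta_log2`.
#' @export
celltype_shift_test <- function(log2cpm, markers, groups) {
  groups <- factor(groups)
  out <- NULL
  for (ctype in names(markers)) {
    m <- intersect(markers[[ctype]], rownames(log2cpm))
    if (length(m) < 2L) {
      warning("cell type '", ctype, "' has < 2 marker genes; skipped")
      next
    }
    sub <- log2cpm[m, , drop = FALSE]
    dat <- data.frame(
      y = as.vector(sub),
      gene = factor(rep(m, times = ncol(sub))),
      g = factor(rep(as.character(groups), each = length(m)),
                 levels = levels(groups))
    )
    fit <- stats::aov(y ~ g + gene, data = dat)
    tab <- summary(fit)[[1]]
    pv <- tab[["Pr(>F)"]][trimws(rownames(tab)) == "g"][1]
    mm <- tapply(dat$y, dat$g, mean)
    delta <- mm[["hom_mutant"]] - mm[["hom_ref"]]
    out <- rbind(out, data.frame(
      cell_type = ctype, n_markers = length(m), genotype_p = pv,
      direction = if (delta >= 0) "increased" else "decreased",
      delta_log2 = delta, stringsAsFactors = FALSE))
  }
  out
}

#' Normalized brain-weight contrast
#'
#' Brain weight per kilogram of body weight, compared between affected
#' animals and (unaffected + carrier) controls:
#' `percent decrease = (1 - mean_affected / mean_control) * 100`, rounded
#' to the nearest integer percent for reporting.
#'
#' @param brain_g per-animal brain weight in grams (> 0).
#' @param body_kg per-animal body weight in kilograms (> 0).
#' @param group per-animal label; `"affected"` vs anything else (controls).
#' @return list with `mean_affected`, `mean_control` (g/kg),
#'   `percent_decrease` (exact), `percent_decrease_rounded`.
#' @export
brain_weight_contrast <- function(brain_g, body_kg, group) {
  if (any(brain_g <= 0) || any(body_kg <= 0)) {
    stop("weights must be positive")
  }
  gkg <- brain_g / body_kg
  aff <- group == "affected"
  if (!any(aff) || all(aff)) stop("need both affected and control animals")
  ma <- mean(gkg[aff])
  mc <- mean(gkg[!aff])
  pd <- (1 - ma / mc) * 100
  list(mean_affected = ma, mean_control = mc,
       percent_decrease = pd, percent_decrease_rounded = round(pd))
}
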