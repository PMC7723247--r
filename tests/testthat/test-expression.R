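test_that("CPM normalization preserves totals and handles edge cases", {
  counts <- rbind(a = c(10, 20), b = c(0, 0), c = c(990, 980))
  nz <- cpm_normalize(counts, lib_sizes = c(1e6, 1e6))
  expect_equal(unname(nz$cpm["a", 1]), 10)
  expect_true(all(nz$cpm["b", ] == 0))
  nz2 <- cpm_normalize(counts)
  expect_equal(unname(colSums(nz2$cpm)), c(1e6, 1e6))
  expect_error(cpm_normalize(counts, c(0, 1)), "library size")
})

test_that("expression reduction test: null, scale invariance and recovery", {
  groups <- factor(rep(c("hom_mutant", "het", "hom_ref"), each = 3))
  flat <- matrix(rep(c(9, 10, 11), 3), nrow = 1,
                 dimnames = list("g", NULL))
  r0 <- expression_reduction_test(flat, groups, "g")
  expect_equal(r0$percent_reduction, 0)
  expect_equal(r0$anova_p, 1, tolerance = 1e-9)

  red <- matrix(c(4, 4.2, 3.8, 7, 7.2, 6.8, 10, 10.2, 9.8), nrow = 1,
                dimnames = list("g", NULL))
  r1 <- expression_reduction_test(red, groups, "g")
  expect_equal(r1$percent_reduction, 60)
  expect_lt(r1$anova_p, 1e-4)
  r2 <- expression_reduction_test(2 * red, groups, "g")
  expect_equal(r2$percent_reduction, r1$percent_reduction)
  expect_equal(nrow(r1$posthoc), 3)

  expect_error(expression_reduction_test(red, factor(rep("hom_mutant", 9)),
                                         "g"), "groups")
  expect_error(expression_reduction_test(red, groups, "nope"), "not in matrix")
})

test_that("allele-bias test: balanced null, symmetry, zero coverage", {
  ac <- expand.grid(sample = paste0("s", 1:3),
                    gene = c("t", "c1", "c2"), stringsAsFactors = FALSE)
  ac$ref_reads <- 50L
  ac$alt_reads <- 50L
  r <- allele_bias_test(ac, "t", c("c1", "c2"))
  expect_true(all(r$fractions$fraction == 0.5))
  # identical fractions carry no evidence of bias
  expect_true(is.na(r$anova_p) || r$anova_p > 0.9)
  expect_true(all(abs(r$gene_means - 0.5) < 1e-12))

  set.seed(12)
  ac2 <- ac
  ac2$ref_reads <- rbinom(9, 200, 0.5)
  ac2$alt_reads <- 200L - ac2$ref_reads
  r2 <- allele_bias_test(ac2, "t", c("c1", "c2"))
  swapped <- ac2
  names(swapped)[3:4] <- c("alt_reads", "ref_reads")
  r3 <- allele_bias_test(swapped, "t", c("c1", "c2"))
  expect_equal(unname(r3$gene_means), unname(1 - r2$gene_means))

  ac3 <- ac
  ac3$ref_reads[ac3$gene == "c2"] <- 0L
  ac3$alt_reads[ac3$gene == "c2"] <- 0L
  expect_warning(r4 <- allele_bias_test(ac3, "t", c("c1", "c2")),
                 "zero-coverage")
  expect_false("c2" %in% r4$fractions$gene)
})

test_that("BH adjustment matches hand computation and the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
  expect_error(bh_adjust(c(0.5, NA)), "p-values")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # order invariance
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("contrast intersection applies set logic and sign concordance", {
  mk <- function(genes, q, lfc) data.frame(gene = genes, lfc = lfc, p = q,
                                           q = q, stringsAsFactors = FALSE)
  genes <- paste0("g", 1:5)
  a <- mk(genes, c(0.01, 0.01, 0.01, 0.5, 0.5), c(1, 1, -1, 1, 1))
  b <- mk(genes, c(0.5, 0.01, 0.01, 0.01, 0.5), c(1, 1, 1, 1, 1))
  ix <- de_intersection(a, b)
  expect_equal(ix$intersection, "g2")
  expect_equal(ix$discordant, "g3")
  expect_equal(ix$n_a, 3)

  disj <- de_intersection(mk(genes, c(0.01, rep(0.5, 4)), 1),
                          mk(genes, c(0.5, 0.01, rep(0.5, 3)), 1))
  expect_equal(length(disj$intersection), 0)

  expect_error(de_intersection(a, b[1:4, ]), "mismatched gene universes")
})

test_that("planted differentially expressed genes are recovered by the dual contrast", {
  hits <- 0; planted <- 0; fp <- 0
  for (s in 1:5) {
    b <- simulate_expression(expression_sim_config(seed = 300 + s,
                                                   n_genes = 1000,
                                                   n_de_genes = 20))
    ls <- effective_lib_sizes(b$counts, b$lib_sizes)
    A <- de_contrast(b$counts, b$groups, c("het", "hom_ref"), "hom_mutant",
                     lib_sizes = ls)
    B <- de_contrast(b$counts, b$groups, "hom_ref", "hom_mutant",
                     lib_sizes = ls)
    ix <- de_intersection(A, B)
    inter <- setdiff(ix$intersection, c(b$target_gene, unlist(b$marker_sets)))
    hits <- hits + sum(b$truth$de_genes %in% inter)
    fp <- fp + sum(!inter %in% b$truth$de_genes)
    planted <- planted + length(b$truth$de_genes)
  }
  expect_gte(hits / planted, 0.8)
  expect_lte(fp / max(1, hits + fp), 0.15)
})

test_that("cell-type marker rule enforces fold boundary and p threshold", {
  mkref <- function(means_by_type, sd = 0.2, reps = 3) {
    set.seed(99)
    out <- NULL
    for (t in names(means_by_type)) {
      out <- rbind(out, data.frame(
        gene = names(means_by_type[[t]]),
        cell_type = t, replicate = rep(seq_len(reps),
                                       each = length(means_by_type[[t]])),
        abundance = rep(means_by_type[[t]], reps) +
          rnorm(length(means_by_type[[t]]) * reps, 0, sd)))
    }
    out
  }
  genes <- c(flat = 10, strong = 30, boundary = 20)
  ref <- mkref(list(
    astro = c(flat = 10, strong = 30, boundary = 20),
    neuron = c(flat = 10, strong = 10, boundary = 10),
    oligo = c(flat = 10, strong = 5, boundary = 8)))
  mk <- select_celltype_markers(ref)
  expect_false("flat" %in% unlist(mk))
  expect_true("strong" %in% mk$astro)
  expect_true("boundary" %in% mk$astro)  # 2.0-fold boundary included

  # exact 2.0-fold with zero variance: fold passes, p = 0 (means differ)
  ref0 <- rbind(
    data.frame(gene = "g", cell_type = "a", replicate = 1:3, abundance = 20),
    data.frame(gene = "g", cell_type = "b", replicate = 1:3, abundance = 10))
  mk0 <- select_celltype_markers(ref0)
  expect_true("g" %in% mk0$a)

  # brute-force reimplementation of the rule on a random reference
  set.seed(41)
  rr <- data.frame(
    gene = rep(paste0("g", 1:30), each = 9),
    cell_type = rep(rep(c("a", "b", "c"), each = 3), 30),
    replicate = rep(1:3, 90),
    abundance = rlnorm(270, 2, 0.8))
  got <- select_celltype_markers(rr)
  for (g in paste0("g", 1:30)) {
    sub <- rr[rr$gene == g, ]
    mu <- tapply(sub$abundance, sub$cell_type, mean)
    top <- names(which.max(mu))
    run <- names(sort(mu, decreasing = TRUE))[2]
    is_marker <- mu[top] >= 2 * mu[run] &&
      t.test(sub$abundance[sub$cell_type == top],
             sub$abundance[sub$cell_type == run])$p.value < 0.2
    expect_equal(g %in% got[[top]], is_marker)
  }

  oneRep <- rbind(ref0, data.frame(gene = "g", cell_type = "solo",
                                   replicate = 1, abundance = 100))
  expect_warning(select_celltype_markers(oneRep), "excluding")
})

test_that("cell-type shift test finds planted shifts and respects exchangeability", {
  b <- simulate_expression(expression_sim_config(seed = 71, n_genes = 200))
  nz <- cpm_normalize(b$counts, b$lib_sizes)
  st <- celltype_shift_test(nz$log2cpm, b$marker_sets, b$groups)
  truth <- b$truth$cell_type_shift
  up <- truth$name[truth$shift > 1]
  down <- truth$name[truth$shift < 1]
  for (t in up) {
    expect_lt(st$genotype_p[st$cell_type == t], 0.01)
    expect_equal(st$direction[st$cell_type == t], "increased")
  }
  for (t in down) {
    expect_equal(st$direction[st$cell_type == t], "decreased")
  }
  # exchangeability: permuting genotype labels loses the precursor-cell
  # signal relative to the true labeling
  true_p <- st$genotype_p[st$cell_type == "opc"]
  set.seed(5)
  perm_p <- replicate(20, {
    g2 <- sample(as.character(b$groups))
    celltype_shift_test(nz$log2cpm, b$marker_sets["opc"],
                        factor(g2, levels = levels(b$groups)))$genotype_p
  })
  expect_gt(mean(perm_p > true_p), 0.9)

  expect_warning(
    celltype_shift_test(nz$log2cpm, list(tiny = b$marker_sets[[1]][1]),
                        b$groups),
    "< 2 marker genes")
})

test_that("brain-weight contrast reproduces the ratio arithmetic", {
  brain <- c(4.0, 4.3, 4.6, 7.5, 7.8, 8.1)
  body <- rep(1, 6)
  grp <- c(rep("affected", 3), rep("control", 3))
  bw <- brain_weight_contrast(brain, body, grp)
  expect_equal(bw$mean_affected, 4.3)
  expect_equal(bw$mean_control, 7.8)
  expect_equal(bw$percent_decrease, (1 - 4.3 / 7.8) * 100)
  expect_equal(bw$percent_decrease_rounded, 45)

  same <- brain_weight_contrast(c(5, 5), c(1, 1), c("affected", "control"))
  expect_equal(same$percent_decrease, 0)

  # scaling all body weights rescales g/kg but not the percent decrease
  bw2 <- brain_weight_contrast(brain, 2 * body, grp)
  expect_equal(bw2$mean_affected, bw$mean_affected / 2)
  expect_equal(bw2$percent_decrease, bw$percent_decrease)

  expect_error(brain_weight_contrast(c(-1, 5), c(1, 1),
                                     c("affected", "control")), "positive")
  expect_error(brain_weight_contrast(c(5, 5), c(1, 1),
                                     c("affected", "affected")), "both")
})

test_that("test statistics are invariant to gene and sample ordering", {
  b <- simulate_expression(expression_sim_config(seed = 23, n_genes = 100))
  nz <- cpm_normalize(b$counts, b$lib_sizes)
  set.seed(2)
  gs <- sample(nrow(nz$log2cpm))
  ss <- sample(ncol(nz$log2cpm))
  shuffled <- nz$log2cpm[gs, ss]
  a1 <- de_contrast(nz$log2cpm, b$groups, "hom_ref", "hom_mutant",
                    engine = "welch")
  a2 <- de_contrast(shuffled, b$groups[ss], "hom_ref", "hom_mutant",
                    engine = "welch")
  a2 <- a2[match(a1$gene, a2$gene), ]
  expect_equal(a1$q, a2$q)
  ls <- effective_lib_sizes(b$counts, b$lib_sizes)
  n1 <- de_contrast(b$counts, b$groups, "hom_ref", "hom_mutant",
                    lib_sizes = ls)
  n2 <- de_contrast(b$counts[gs, ss], b$groups[ss], "hom_ref", "hom_mutant",
                    lib_sizes = ls[ss])
  n2 <- n2[match(n1$gene, n2$gene), ]
  expect_equal(n1$q, n2$q)
  r1 <- expression_reduction_test(nz$cpm, b$groups, b$target_gene)
  r2 <- expression_reduction_test(nz$cpm[, ss], b$groups[ss], b$target_gene)
  expect_equal(r1$percent_reduction, r2$percent_reduction)
  expect_equal(r1$anova_p, r2$anova_p)
})
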