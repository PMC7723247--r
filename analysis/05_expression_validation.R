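#!/usr/bin/env Rscript
# Stage 5 — expression-level and phenotype-level validation.
#
# Simulates a cortex RNA-seq bundle for the candidate gene (4 homozygous
# mutant, 3 heterozygous, 3 homozygous reference animals, the analyzed
# group sizes of the motivating design) and runs the validation statistics:
# the nonsense-mediated-decay transcript reduction with one-way ANOVA and
# Tukey post-hoc, allele-specific read bias in heterozygotes against
# nearby control genes, the dual-contrast FDR-intersection differential
# expression list, cell-type marker selection and genotype-effect tests,
# and the normalized brain-weight contrast.

suppressPackageStartupMessages(library(colonymap))

cfgx <- expression_sim_config(seed = 7, n_de_genes = 20)
b <- simulate_expression(cfgx)
nz <- cpm_normalize(b$counts, b$lib_sizes)

## NMD transcript reduction
red <- expression_reduction_test(nz$cpm, b$groups, b$target_gene)
cat(sprintf("Target transcript reduction in homozygotes: %.1f%% (one-way ANOVA p = %.2g)\n",
            red$percent_reduction, red$anova_p))
write.table(data.frame(group = names(red$group_means),
                       mean_cpm = as.numeric(red$group_means)),
            "results/target_group_means.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## allele-specific read bias in heterozygotes
ab <- allele_bias_test(b$allele_counts, b$target_gene, b$control_genes)
cat(sprintf("Heterozygote mutant-read fraction at the target: %.3f (controls ~0.5; ANOVA p = %.2g)\n",
            ab$gene_means[[b$target_gene]], ab$anova_p))
write.table(ab$fractions, "results/allele_fractions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## dual-contrast differential expression with FDR intersection
ls <- effective_lib_sizes(b$counts, b$lib_sizes)
A <- de_contrast(b$counts, b$groups, c("het", "hom_ref"), "hom_mutant",
                 lib_sizes = ls)
B <- de_contrast(b$counts, b$groups, "hom_ref", "hom_mutant",
                 lib_sizes = ls)
ix <- de_intersection(A, B)
cat(sprintf("Significant genes (q < 0.05): %d in all-unaffected-vs-mutant, %d in non-mutant-vs-mutant; intersection %d (discordant signs: %d)\n",
            ix$n_a, ix$n_b, length(ix$intersection), length(ix$discordant)))
planted <- sum(b$truth$de_genes %in% ix$intersection)
cat(sprintf("Of %d planted genes, %d recovered in the intersection.\n",
            length(b$truth$de_genes), planted))
write.table(data.frame(gene = ix$intersection),
            "results/de_intersection.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
merged <- merge(A, B, by = "gene", suffixes = c("_allunaff", "_nonmut"))
write.table(merged[order(merged$q_nonmut), ][1:50, ],
            "results/de_contrasts_top50.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## cell-type markers and genotype-effect tests
mk <- select_celltype_markers(b$reference)
st <- celltype_shift_test(nz$log2cpm, mk, b$groups)
write.table(st, "results/celltype_shift_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nCell-type genotype effects:\n")
print(st, row.names = FALSE)

## brain-weight contrast at the published group means
bw <- brain_weight_contrast(
  brain_g = c(4.0, 4.3, 4.6, 7.5, 7.8, 8.1),
  body_kg = rep(1, 6),
  group = c(rep("affected", 3), rep("control", 3)))
cat(sprintf("\nBrain weight: affected %.1f vs control %.1f g/kg -> %d%% decrease\n",
            bw$mean_affected, bw$mean_control, bw$percent_decrease_rounded))
write.table(data.frame(mean_affected_gkg = bw$mean_affected,
                       mean_control_gkg = bw$mean_control,
                       percent_decrease = bw$percent_decrease,
                       rounded = bw$percent_decrease_rounded),
            "results/brain_weight_contrast.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
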