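test_that("pedigree simulation respects generations, target size and seeds", {
  cfg0 <- colony_config(n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), cfg0$n_founders)
  expect_true(all(is.na(ped0$sire)) && all(is.na(ped0$dam)))

  cfg <- colony_config(seed = 5)
  a <- simulate_pedigree(cfg)
  b <- simulate_pedigree(cfg)
  expect_identical(a, b)
  c2 <- simulate_pedigree(colony_config(seed = 6))
  expect_false(identical(a, c2))

  expect_error(simulate_pedigree(colony_config(n_founders = 1, seed = 1)),
               "configuration error")
})

test_that("mean colony size over seeds is close to the 123-cat target", {
  sizes <- vapply(1:200, function(s) {
    nrow(simulate_pedigree(colony_config(seed = s)))
  }, 0L)
  expect_lt(abs(mean(sizes) - 123) / 123, 0.10)
})

test_that("colony config validates its geometry", {
  expect_error(colony_config(causal_position = 80e6), "outside")
  expect_error(colony_config(causal_chromosome = "Z9"), "absent")
  expect_error(colony_config(offspring_mean = 0), "offspring_mean")
  expect_error(gene_drop(simulate_pedigree(colony_config(seed = 1)),
                         colony_config(seed = 1), chromosomes = "A1"),
               "causal chromosome absent")
})

test_that("gene drop is Mendelian-consistent at every site and conserves founder alleles", {
  cfg <- small_colony_config(seed = 3)
  ped <- simulate_pedigree(cfg)
  hs <- gene_drop(ped, cfg)
  ids <- ped$id
  for (i in which(!is.na(ped$sire))) {
    si <- match(ped$sire[i], ids)
    di <- match(ped$dam[i], ids)
    expect_true(all(hs$hapP[i, ] == hs$hapP[si, ] |
                      hs$hapP[i, ] == hs$hapM[si, ]))
    expect_true(all(hs$hapM[i, ] == hs$hapP[di, ] |
                      hs$hapM[i, ] == hs$hapM[di, ]))
  }
  # allele conservation: every allele traces to the founder haplotype its
  # origin label names
  fidx <- match(founders(ped), ids)
  fh <- rbind(hs$hapP[fidx, ], hs$hapM[fidx, ])
  flab <- c(hs$originP[fidx, 1], hs$originM[fidx, 1])
  ok <- TRUE
  for (i in seq_along(ids)) {
    src <- match(hs$originP[i, ], flab)
    ok <- ok && all(hs$hapP[i, ] == fh[cbind(src, seq_len(ncol(fh)))])
    src <- match(hs$originM[i, ], flab)
    ok <- ok && all(hs$hapM[i, ] == fh[cbind(src, seq_len(ncol(fh)))])
  }
  expect_true(ok)
})

test_that("a zero-length genetic map transmits whole chromosomes intact", {
  cfg <- colony_config(
    seed = 2, target_colony_size = 30, min_affected = 0,
    genome = data.frame(chrom = c("A1", "F1"),
                        length_bp = c(50e6, 71.5e6),
                        map_cm = c(0, 71.5)))
  ped <- simulate_pedigree(cfg)
  hs <- gene_drop(ped, cfg)
  j <- which(hs$sites$chrom == "A1")
  for (i in which(!is.na(ped$sire))) {
    si <- match(ped$sire[i], ped$id)
    from_p <- all(hs$hapP[i, j] == hs$hapP[si, j]) &&
      all(hs$originP[i, j] == hs$originP[si, j])
    from_m <- all(hs$hapP[i, j] == hs$hapM[si, j]) &&
      all(hs$originP[i, j] == hs$originM[si, j])
    expect_true(from_p || from_m)
  }
})

test_that("crossover counts follow the Haldane expectation", {
  pos <- seq(1, 100e6, length.out = 400)
  n <- 10000
  set.seed(9)
  brk <- vapply(seq_len(n), function(i) {
    src <- colonymap:::meiosis_source(pos, 100e6, 85)
    sum(diff(src) != 0L)
  }, 0L)
  expected <- 0.85  # Morgans
  se <- sqrt(expected / n)  # Poisson
  expect_lt(abs(mean(brk) - expected), 3 * se)
})

test_that("phenotypes follow the fully penetrant recessive causal genotype", {
  cfg <- small_colony_config(seed = 8)
  col <- simulate_colony(cfg)
  ci <- col$causal
  dos <- col$genotypes$dosage[ci, match(col$pedigree$id,
                                        col$genotypes$samples)]
  expect_identical(col$pedigree$phenotype == "affected", unname(dos == 2L))
  expect_true(all(dos[col$pedigree$phenotype == "unaffected"] < 2L))
})

test_that("affected individuals are homozygous IBD for the carrier founder haplotype", {
  for (s in 1:10) {
    col <- simulate_colony(small_colony_config(seed = 100 + s))
    hs <- col$hapset
    ci <- which(hs$sites$chrom == hs$config$causal_chromosome &
                  hs$sites$pos == hs$config$causal_position)
    aff <- match(col$pedigree$id[col$pedigree$phenotype == "affected"],
                 hs$samples)
    expect_true(all(hs$originP[aff, ci] == hs$carrier_hap))
    expect_true(all(hs$originM[aff, ci] == hs$carrier_hap))
    # the causal site lies inside the shared IBD segment by construction
    seg <- colonymap:::in_ibd_segment(hs$config, hs$sites)
    expect_true(seg[ci])
  }
})

test_that("marker panel extraction honors counts, strata and spacing", {
  col <- simulate_colony(small_colony_config(seed = 21))
  gm <- col$genotypes
  interval <- list(chrom = "F1", start = 60e6, end = 71.5e6)
  panel <- extract_marker_panel(gm, c(interval = 26, chromosome = 4,
                                      genomewide = 20), interval)
  expect_equal(nrow(panel$sites), 50)
  expect_identical(order(panel$sites$chrom, panel$sites$pos),
                   seq_len(50))
  in_int <- panel$sites$chrom == "F1" & panel$sites$pos >= 60e6 &
    panel$sites$pos <= 71.5e6
  expect_gte(sum(in_int), 26)
  # spacing within the interval stays near-uniform: no gap deviates from
  # the mean gap by more than 2x the mean gap
  gaps <- diff(sort(panel$sites$pos[in_int]))
  expect_true(all(abs(gaps - mean(gaps)) < 2 * mean(gaps)))

  empty <- extract_marker_panel(gm, c(interval = 0, chromosome = 0,
                                      genomewide = 0), interval)
  expect_equal(nrow(empty$sites), 0)

  expect_error(
    extract_marker_panel(gm, c(interval = 10000, chromosome = 0,
                               genomewide = 0), interval),
    "stratum 'interval'")
})

test_that("expression simulator reproduces the NMD identities", {
  obs <- nmd_observables(0.41)
  expect_equal(obs$reduction, 0.59)
  expect_equal(obs$het_mutant_fraction, 0.41 / 1.41)
  expect_equal(round(obs$het_mutant_fraction, 4), 0.2908)

  expect_error(expression_sim_config(nmd_retention = 1.2),
               "configuration error")

  # lambda = 1: no reduction and balanced alleles
  b1 <- simulate_expression(expression_sim_config(
    nmd_retention = 1, seed = 4, n_genes = 50,
    replicates = c(hom_mutant = 20, het = 20, hom_ref = 20)))
  mu <- tapply(b1$counts[b1$target_gene, ], b1$groups, mean)
  expect_lt(abs(mu[["hom_mutant"]] / mu[["hom_ref"]] - 1), 0.2)
  ac <- b1$allele_counts[b1$allele_counts$gene == b1$target_gene, ]
  frac <- sum(ac$alt_reads) / sum(ac$alt_reads + ac$ref_reads)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(ac$alt_reads + ac$ref_reads)))

  # lambda = 0: complete decay
  b0 <- simulate_expression(expression_sim_config(
    nmd_retention = 0, seed = 4, n_genes = 20))
  expect_true(all(b0$counts[b0$target_gene, b0$groups == "hom_mutant"] == 0))
  ac0 <- b0$allele_counts[b0$allele_counts$gene == b0$target_gene, ]
  expect_true(all(ac0$alt_reads == 0))
})

test_that("het mutant-read fraction converges to lambda/(1+lambda)", {
  lam <- 0.41
  pi_true <- lam / (1 + lam)
  b <- simulate_expression(expression_sim_config(
    nmd_retention = lam, seed = 17, n_genes = 20,
    replicates = c(hom_mutant = 2, het = 40, hom_ref = 2)))
  ac <- b$allele_counts[b$allele_counts$gene == b$target_gene, ]
  tot <- sum(ac$alt_reads + ac$ref_reads)
  frac <- sum(ac$alt_reads) / tot
  expect_lt(abs(frac - pi_true), 3 * sqrt(pi_true * (1 - pi_true) / tot))
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- small_colony_config(seed = 12)
  expect_identical(simulate_colony(cfg)$genotypes$dosage,
                   simulate_colony(cfg)$genotypes$dosage)
  xc <- expression_sim_config(seed = 12, n_genes = 30)
  expect_identical(simulate_expression(xc)$counts,
                   simulate_expression(xc)$counts)
})
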