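# helper to build a genotype matrix from a dosage matrix
gm_from <- function(dos, samples) {
  genotype_matrix(
    data.frame(chrom = "F1", pos = seq_len(nrow(dos)) * 1000L,
               ref = "A", alt = "G"),
    samples, dos)
}

test_that("zygosity filter implements the recessive compatibility predicate", {
  aff <- paste0("a", 1:8)
  car <- paste0("c", 1:6)
  # site 1: all affected hom alt, all carriers het -> pass
  # site 2: one affected het -> fail
  # site 3: one carrier hom alt -> fail
  # site 4: pattern ok but only 10 of 14 called -> fail
  # site 5: pattern ok with 3 missing (11 called) -> pass
  d <- rbind(
    c(rep(2, 8), rep(1, 6)),
    c(1, rep(2, 7), rep(1, 6)),
    c(rep(2, 8), 2, rep(1, 5)),
    c(rep(2, 6), NA, NA, rep(1, 4), NA, NA),
    c(rep(2, 7), NA, rep(1, 5), NA)
  )
  d[4, 9] <- NA  # 10 called at site 4
  gm <- gm_from(d, c(aff, car))
  zy <- zygosity_filter(gm, aff, car, min_called = 11)
  expect_equal(unname(zy$pass_idx), c(1L, 5L))
  expect_equal(zy$sites$n_called_affected[4], 6)

  expect_error(zygosity_filter(gm, character(0), car), "empty affected")
  expect_error(zygosity_filter(gm, c(aff, "ghost"), car), "unknown sample")
  expect_error(zygosity_filter(gm, aff, c(car, aff[1])), "overlap")
  expect_error(zygosity_filter(gm, aff, car, min_called = 15), "exceeds")
})

test_that("with 2 affected + 1 carrier exactly one of the 27 dosage vectors passes", {
  combos <- expand.grid(a1 = 0:2, a2 = 0:2, c1 = 0:2)
  passed <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    gm <- gm_from(matrix(as.numeric(combos[i, ]), 1), c("a1", "a2", "c1"))
    zy <- zygosity_filter(gm, c("a1", "a2"), "c1", min_called = 3)
    passed[i] <- length(zy$pass_idx) == 1L
  }
  expect_equal(sum(passed), 1L)
  expect_equal(as.numeric(combos[passed, ]), c(2, 2, 1))
})

test_that("adding a labeled individual can only shrink the passing set", {
  set.seed(31)
  for (rep in 1:20) {
    n_aff <- 4; n_car <- 3
    d <- matrix(sample(c(0:2, NA), 50 * (n_aff + n_car + 2), replace = TRUE,
                       prob = c(.2, .3, .4, .1)), nrow = 50)
    ids <- c(paste0("a", 1:(n_aff + 1)), paste0("c", 1:(n_car + 1)))
    gm <- gm_from(d, ids)
    base <- zygosity_filter(gm, paste0("a", 1:n_aff), paste0("c", 1:n_car),
                            min_called = 4)
    plus_a <- zygosity_filter(gm, paste0("a", 1:(n_aff + 1)),
                              paste0("c", 1:n_car), min_called = 4)
    plus_c <- zygosity_filter(gm, paste0("a", 1:n_aff),
                              paste0("c", 1:(n_car + 1)), min_called = 4)
    expect_true(all(plus_a$pass_idx %in% base$pass_idx))
    expect_true(all(plus_c$pass_idx %in% base$pass_idx))
  }
})

test_that("cluster enrichment matches hand arithmetic and the gamma-tail oracle", {
  genome <- data.frame(chrom = "F1", length_bp = 50e6, map_cm = 50)
  # 20 variants spread 2 per 5 Mb window -> X2 = 0, p = 1
  uniform <- data.frame(chrom = "F1",
                        pos = rep(seq(2e6, 47e6, by = 5e6), each = 2))
  ct0 <- cluster_enrichment(uniform, genome)
  expect_equal(ct0$statistic, 0)
  expect_equal(ct0$p_value, 1)
  expect_equal(sum(ct0$windows$observed), 20)
  expect_equal(sum(ct0$windows$expected), 20)

  # all 20 in one window -> X2 = 18^2/2 + 9 * 2 = 180, df = 9
  clustered <- data.frame(chrom = "F1", pos = rep(2.5e6, 20))
  ct1 <- cluster_enrichment(clustered, genome)
  expect_equal(ct1$statistic, 180)
  expect_equal(ct1$df, 9)
  expect_lt(ct1$p_value, 1e-30)
  expect_equal(ct1$p_value, oracle_chisq_sf(180, 9), tolerance = 1e-10)
  expect_equal(ct1$peak, 1L)

  expect_error(cluster_enrichment(uniform[0, ], genome), "no passing")
})

test_that("chi-square tail probabilities agree with the series oracle across regimes", {
  for (x in c(0.5, 3, 11, 40, 180)) {
    for (df in c(1, 4, 9, 30)) {
      expect_equal(stats::pchisq(x, df, lower.tail = FALSE),
                   oracle_chisq_sf(x, df), tolerance = 1e-12)
    }
  }
})

test_that("trailing short windows merge and untested chromosomes are excluded", {
  genome <- data.frame(chrom = c("A1", "B1"), length_bp = c(12e6, 30e6),
                       map_cm = c(12, 30))
  win <- colonymap:::genome_windows(genome[1, , drop = FALSE], 5e6)
  # 12 Mb at 5 Mb windows: trailing 2 Mb (< 2.5 Mb) merges into the second
  expect_equal(nrow(win), 2)
  expect_equal(win$end[2], 12e6)

  passing <- data.frame(chrom = "B1", pos = c(1e6, 2e6, 11e6))
  tested <- data.frame(chrom = "B1", pos = seq(1e6, 29e6, by = 1e6))
  ct <- cluster_enrichment(passing, genome, tested = tested)
  expect_true(all(ct$windows$chrom == "B1"))
})

test_that("phenotype-label permutation destroys the zygosity cluster signal", {
  col <- simulate_colony(small_colony_config(seed = 41))
  ped <- col$pedigree
  gm <- col$genotypes
  aff <- head(ped$id[ped$phenotype == "affected"], 5)
  car <- head(obligate_carriers(ped), 4)
  cfg <- col$hapset$config
  true_stat <- cluster_enrichment(
    zygosity_filter(gm, aff, car, min_called = 8)$sites[
      zygosity_filter(gm, aff, car, min_called = 8)$pass_idx, ],
    cfg$genome, tested = gm$sites)$statistic
  set.seed(77)
  perm_stats <- replicate(200, {
    ids <- sample(ped$id, length(aff) + length(car))
    zy <- zygosity_filter(gm, ids[seq_along(aff)], ids[-seq_along(aff)],
                          min_called = 8)
    if (length(zy$pass_idx) == 0L) return(0)
    cluster_enrichment(zy$sites[zy$pass_idx, ], cfg$genome,
                       tested = gm$sites)$statistic
  })
  expect_gte(mean(true_stat > perm_stats), 0.95)
})

test_that("two-locus bookkeeping follows inclusion-exclusion", {
  expect_equal(double_homref_count(25, 9, 4), 12)
  expect_equal(double_homref_count(10, 0, 0), 10)
  expect_equal(double_homref_count(10, 6, 6, 4), 2)
  expect_error(double_homref_count(10, 9, 9), "negative")
  expect_error(double_homref_count(10, 2, 3, 3), "overlap")
})
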