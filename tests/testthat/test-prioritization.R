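# toy transcript: 60-codon CDS split over two exons on the forward strand
toy_transcript <- function(strand = "+") {
  set.seed(606)
  # construct a CDS with a defined start codon and no internal stops
  codons <- c("ATG", sample(setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste0, collapse = ""),
    c("TAA", "TAG", "TGA")), 58, replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  exons <- data.frame(start = c(1001L, 1301L), end = c(1100L, 1380L))
  if (strand == "-") {
    # genomic sequence is the reverse complement; exon coordinates unchanged
    tx <- transcript_model("toy-", "F1", "-", exons, cds)
  } else {
    tx <- transcript_model("toy+", "F1", "+", exons, cds)
  }
  tx
}

# genomic base of the toy transcript at a position (forward strand)
toy_genomic_base <- function(tx, pos) {
  cp <- colonymap:::genomic_to_cds(tx, pos)
  b <- substr(tx$cds_seq, cp, cp)
  if (tx$strand == "-") chartr("ACGT", "TGCA", b) else b
}

test_that("codon arithmetic matches the triplet-enumeration oracle", {
  expect_equal(hgvs_codon_index(176), 59)
  expect_equal(hgvs_codon_index(c(1, 3, 4)), c(1, 1, 2))
  # oracle: build codons triplet by triplet and look the position up
  codon_of <- rep(seq_len(100), each = 3)
  expect_equal(hgvs_codon_index(1:300), codon_of)
  expect_error(hgvs_codon_index(0), "positive")
})

test_that("coding-effect annotation agrees with a translation oracle", {
  for (strand in c("+", "-")) {
    tx <- toy_transcript(strand)
    positions <- c(1001:1100, 1301:1380)
    set.seed(9 + (strand == "-"))
    test_pos <- sample(positions, 40)
    for (pos in test_pos) {
      refb <- toy_genomic_base(tx, pos)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      got <- annotate_coding_effect(pos, refb, altb, tx)
      # oracle: full codon-by-codon translation of both sequences
      cp <- colonymap:::genomic_to_cds(tx, pos)
      alt_tx <- if (strand == "-") chartr("ACGT", "TGCA", altb) else altb
      mut <- tx$cds_seq
      substr(mut, cp, cp) <- alt_tx
      n <- nchar(mut) / 3
      aa <- function(s) vapply(seq_len(n), function(i) {
        unname(Biostrings::GENETIC_CODE[substr(s, 3 * i - 2, 3 * i)])
      }, "")
      p0 <- aa(tx$cds_seq); p1 <- aa(mut)
      want <- if (identical(p0, p1)) "synonymous"
      else if (any(p1 == "*" & p0 != "*") || any(p0 == "*" & p1 != "*")) "other_lof"
      else "missense"
      expect_equal(got, want)
    }
  }
})

test_that("indel consequences follow the mod-3 rule", {
  tx <- toy_transcript("+")
  expect_equal(annotate_coding_effect(1050, "AA", "A", tx), "frameshift")
  expect_equal(annotate_coding_effect(1050, "AAAA", "A", tx), "other_lof")
  expect_equal(annotate_coding_effect(1050, "A", "AG", tx), "frameshift")
  expect_equal(annotate_coding_effect(500, "AA", "A", tx), "noncoding")
  expect_equal(annotate_coding_effect(500, "A", "G", tx), "noncoding")
  refb <- toy_genomic_base(tx, 1001)
  wrong <- setdiff(c("A", "C", "G", "T"), refb)[1]
  expect_error(annotate_coding_effect(1001, wrong, refb, tx),
               "annotation error")
})

test_that("the packaged candidate table ranks the frameshift first", {
  path <- system.file("extdata/table1_candidates.tsv", package = "colonymap")
  an <- read_annotation_table(path)
  expect_equal(nrow(an), 10)
  rk <- filter_and_rank(an)
  expect_equal(rk$gene[1], "PEA15")
  expect_equal(rk$consequence[1], "frameshift")
  expect_equal(rk$cadd[1], 29.7)
  expect_equal(rk$af_label[1], "Absent")
  # the two human-liftover synonymous variants are flagged and their CADD
  # scores excluded from ordering
  flagged <- rk$gene[rk$cadd_consequence_mismatch]
  expect_setequal(flagged, c("SLAMF1", "ATP1A2"))
  # flagged scores (22.4, 18.0) would otherwise outrank CADD 21.1 and 6.6
  expect_gt(match("ATP1A2-IGSF8", rk$gene), 1)
  expect_lt(match("ATP1A2-IGSF8", rk$gene), match("SLAMF1", rk$gene))
  # no-liftover rows carry the flag and missing scores stay NA, not zero
  expect_true(all(rk$no_liftover[rk$gene == "ATP1A4"]))
  expect_true(is.na(rk$cadd[rk$gene == "ATP1A4"]))
})

test_that("ranking equals a brute-force comparator sort on random tables", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(5:25, 1)
    an <- data.frame(
      gene = paste0("g", seq_len(n)),
      chrom = sample(c("A1", "F1"), n, TRUE),
      pos = sample.int(1e6, n),
      alt = sample(c("A", "C", "G", "T"), n, TRUE),
      consequence = sample(c("frameshift", "other_lof", "missense",
                             "synonymous", "noncoding"), n, TRUE),
      af = ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.2)),
      cadd = ifelse(runif(n) < 0.2, NA, round(runif(n, 0, 30), 3)),
      gerp = rnorm(n),
      cpm = ifelse(runif(n) < 0.2, 0, rlnorm(n, 2, 1)),
      liftover_ok = runif(n) > 0.1,
      stringsAsFactors = FALSE)
    an$consequence_liftover <- ifelse(
      runif(n) < 0.2 & an$consequence == "synonymous", "missense",
      an$consequence)
    got <- filter_and_rank(an)
    want <- oracle_rank(an)
    expect_equal(got$gene, want$gene)
  }
})

test_that("ranking is stable under row permutation and top-candidate deletion", {
  path <- system.file("extdata/table1_candidates.tsv", package = "colonymap")
  an <- read_annotation_table(path)
  rk <- filter_and_rank(an)
  set.seed(3)
  for (i in 1:5) {
    perm <- filter_and_rank(an[sample(nrow(an)), ])
    expect_equal(perm$gene, rk$gene)
    expect_equal(perm$hgvs_dna, rk$hgvs_dna)
  }
  dropped <- filter_and_rank(an[!(an$gene == "PEA15"), ])
  expect_equal(dropped$gene[1], rk$gene[2])
  expect_equal(dropped$rank[1], 1L)
})

test_that("allele-frequency filtering and empty inputs behave as declared", {
  an <- data.frame(gene = c("a", "b"), consequence = c("missense", "missense"),
                   af = c(0.051, 0.049), cadd = c(10, 1), cpm = c(5, 5),
                   stringsAsFactors = FALSE)
  rk <- filter_and_rank(an)
  expect_equal(rk$gene, "b")
  empty <- filter_and_rank(an[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("Hardy-Weinberg extrapolation follows p^2 scaling", {
  expect_equal(hwe_extrapolate(0, 1000, 1e9), 0)
  got <- hwe_extrapolate(11, 198527, 7.7e9)
  p <- 11 / (2 * 198527)
  expect_equal(got, 7.7e9 * p^2)
  expect_lt(abs(got - 5.91), 0.01)
  expect_equal(hwe_extrapolate(11, 198527, 2 * 7.7e9), 2 * got)
  expect_error(hwe_extrapolate(5, 0, 1e9), "positive")
})
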