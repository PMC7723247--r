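# Candidate-variant annotation and ranking inside the critical interval.

#' Transcript model for coding-effect annotation
#'
#' @param id transcript id.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame `start`/`end` of CDS exons, 1-based inclusive,
#'   non-overlapping, ordered by genomic position.
#' @param cds_seq coding sequence (5'->3' on the coding strand) as a single
#'   string; its length must equal the summed exon widths. A length not
#'   divisible by 3 warns (truncated annotation) but is not an error.
#' @return a `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand = "+", exons, cds_seq) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (nrow(exons) > 1L &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exon spans overlap")
  }
  cds_seq <- toupper(cds_seq)
  width <- sum(exons$end - exons$start + 1)
  if (nchar(cds_seq) != width) {
    stop("cds_seq length (", nchar(cds_seq), ") != summed exon width (",
         width, ")")
  }
  if (width %% 3 != 0) warning("CDS length not divisible by 3")
  structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                 cds_seq = cds_seq, cds_len = width),
            class = "transcript_model")
}

# genomic position -> 1-based CDS coordinate (NA if not in an exon)
genomic_to_cds <- function(tx, pos) {
  w <- tx$exons$end - tx$exons$start + 1
  offs <- cumsum(c(0, w))[seq_len(nrow(tx$exons))]
  hit <- which(pos >= tx$exons$start & pos <= tx$exons$end)
  if (!length(hit)) return(NA_integer_)
  plus <- offs[hit] + (pos - tx$exons$start[hit]) + 1L
  if (tx$strand == "+") plus else tx$cds_len - plus + 1L
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

translate_cds <- function(seq) {
  n <- nchar(seq) %/% 3
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Classify the coding consequence of a variant
#'
#' Classifies a variant against a [transcript_model()] as `synonymous`,
#' `missense`, `frameshift` (indel of length not divisible by 3 inside the
#' CDS), `other_lof` (stop gain, stop loss, or in-frame indel) or
#' `noncoding`, using the transcript strand and the standard codon table.
#' The variant's reference allele must agree with the transcript sequence.
#'
#' @param pos genomic position (1-based) of the variant's first reference
#'   base.
#' @param ref,alt reference and alternate alleles on the forward genomic
#'   strand (VCF style; indels share the anchor base).
#' @param tx a [transcript_model()].
#' @return one of `"synonymous"`, `"missense"`, `"frameshift"`,
#'   `"other_lof"`, `"noncoding"`.
#' @export
annotate_coding_effect <- function(pos, ref, alt, tx) {
  ref <- toupper(ref); alt <- toupper(alt)
  cds_pos <- genomic_to_cds(tx, pos)
  if (nchar(ref) != nchar(alt)) {
    # indel: classify by the length change of bases inside the CDS
    shared <- min(nchar(ref), nchar(alt))
    changed <- seq(pos + shared, pos + max(nchar(ref), nchar(alt)) - 1L)
    inside <- vapply(changed, function(p) !is.na(genomic_to_cds(tx, p)), TRUE)
    if (!any(inside)) return("noncoding")
    delta <- sum(inside)
    return(if (delta %% 3L == 0L) "other_lof" else "frameshift")
  }
  if (is.na(cds_pos)) return("noncoding")
  base_tx <- if (tx$strand == "+") ref else revcomp(ref)
  alt_tx <- if (tx$strand == "+") alt else revcomp(alt)
  have <- substr(tx$cds_seq, cds_pos, cds_pos)
  if (have != base_tx) {
    stop("annotation error: reference allele ", ref, " at ", tx$chrom, ":",
         pos, " disagrees with transcript base ", have)
  }
  mutated <- tx$cds_seq
  substr(mutated, cds_pos, cds_pos) <- alt_tx
  ci <- hgvs_codon_index(cds_pos)
  aa_ref <- translate_cds(substr(tx$cds_seq, 3 * ci - 2, 3 * ci))
  aa_alt <- translate_cds(substr(mutated, 3 * ci - 2, 3 * ci))
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*" || aa_ref == "*") return("other_lof")
  "missense"
}

#' Codon index of a coding nucleotide position
#'
#' Maps a 1-based coding (CDS) nucleotide position to the 1-based index of
#' the codon containing it: `floor((cds_position - 1) / 3) + 1`. This is the
#' arithmetic behind HGVS protein annotations of coding variants, e.g. a
#' deletion at c.176 falls in codon 59.
#'
#' @param cds_position 1-based coding nucleotide position (vectorized).
#' @return integer codon index.
#' @examples
#' hgvs_codon_index(176)  # 59
#' @export
hgvs_codon_index <- function(cds_position) {
  if (any(cds_position < 1) || any(cds_position != round(cds_position))) {
    stop("cds_position must be a positive integer")
  }
  (as.integer(cds_position) - 1L) %/% 3L + 1L
}

consequence_tier <- function(consequence) {
  unname(c(frameshift = 1, other_lof = 1, missense = 2,
           synonymous = 3, noncoding = 3)[consequence])
}

#' Filter and rank candidate variants in the critical interval
#'
#' Applies the evidence rules used to call the causal candidate: drop
#' variants with population allele frequency >= `af_max` (absent = private,
#' treated as 0 and reported "Absent"); rank the rest by (1) consequence
#' tier (frameshift/other LoF > missense > synonymous/noncoding), (2)
#' usable CADD score descending, with missing CADD below any present score
#' within a tier, and (3) expression in the affected tissue
#' (CPM >= `expressed_cpm_min`) as a tie-break. A CADD score is unusable —
#' flagged `cadd_consequence_mismatch` and excluded from ordering — when the
#' target-species consequence is synonymous but the score derives from a
#' non-synonymous annotation in the lifted-over species, which inflates it.
#'
#' @param annotations data frame with one row per variant: columns `gene`,
#'   `chrom`, `pos`, `alt` (optional but used for deterministic
#'   tie-breaking), `consequence`, `af` (NA = absent from the population
#'   database), `cadd`, `gerp`, `cpm`, `liftover_ok` (logical), and
#'   optionally `consequence_liftover` (consequence in the score's source
#'   species).
#' @param af_max allele-frequency cutoff (default 0.05).
#' @param expressed_cpm_min tissue-expression threshold used for the
#'   `not_expressed` flag and tie-break (default 1.0).
#' @return the filtered table ordered by rank, with columns `rank`,
#'   `af_label`, and logical flags `cadd_consequence_mismatch`,
#'   `no_liftover`, `not_expressed`.
#' @export
filter_and_rank <- function(annotations, af_max = 0.05,
                            expressed_cpm_min = 1.0) {
  an <- as.data.frame(annotations)
  if (nrow(an) == 0L) {
    an$rank <- integer(0)
    return(an)
  }
  req <- c("gene", "consequence", "af", "cadd", "cpm")
  miss <- setdiff(req, names(an))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  keep <- is.na(an$af) | an$af < af_max
  an <- an[keep, , drop = FALSE]
  if (nrow(an) == 0L) {
    an$rank <- integer(0)
    return(an)
  }
  an$af_label <- ifelse(is.na(an$af), "Absent",
                        sprintf("%.1f%%", 100 * an$af))
  lift <- if ("liftover_ok" %in% names(an)) an$liftover_ok else !is.na(an$cadd)
  an$no_liftover <- !lift
  csl <- if ("consequence_liftover" %in% names(an)) {
    an$consequence_liftover
  } else an$consequence
  an$cadd_consequence_mismatch <- !is.na(an$cadd) &
    an$consequence == "synonymous" & !is.na(csl) & csl %in%
    c("missense", "frameshift", "other_lof")
  an$not_expressed <- !is.na(an$cpm) & an$cpm < expressed_cpm_min
  usable_cadd <- ifelse(is.na(an$cadd) | an$cadd_consequence_mismatch |
                          an$no_liftover, -Inf, an$cadd)
  tier <- consequence_tier(an$consequence)
  blank <- rep("", nrow(an))
  pos <- if ("pos" %in% names(an)) an$pos else rep(0, nrow(an))
  chrom <- if ("chrom" %in% names(an)) as.character(an$chrom) else blank
  alt <- if ("alt" %in% names(an)) as.character(an$alt) else blank
  hgvs <- if ("hgvs_dna" %in% names(an)) as.character(an$hgvs_dna) else blank
  ord <- order(tier, -usable_cadd, an$not_expressed, chrom, pos, alt,
               an$gene, hgvs)
  an <- an[ord, , drop = FALSE]
  an$rank <- seq_len(nrow(an))
  rownames(an) <- NULL
  an
}

#' Hardy-Weinberg extrapolation of homozygote carriers
#'
#' From the count of heterozygous loss-of-function carriers in a reference
#' cohort (with no homozygotes observed), estimates the allele frequency
#' `p = n_het / (2 n_individuals)` and the expected number of individuals
#' homozygous (or compound heterozygous) for such alleles in a population:
#' `population_size * p^2`.
#'
#' @param n_het_carriers heterozygous carriers observed.
#' @param n_individuals cohort size.
#' @param population_size population to extrapolate to.
#' @return expected count (numeric).
#' @examples
#' hwe_extrapolate(11, 198527, 7.7e9)  # ~5.9 people
#' @export
hwe_extrapolate <- function(n_het_carriers, n_individuals, population_size) {
  if (n_individuals <= 0) stop("n_individuals must be positive")
  if (n_het_carriers < 0 || population_size < 0) stop("counts must be >= 0")
  p <- n_het_carriers / (2 * n_individuals)
  population_size * p^2
}

#' Read a delimited candidate-annotation table
#'
#' Parses a tab-delimited table with the column layout of a published
#' candidate-variant table: `Gene`, `Transcript`, `HGVS_DNA`,
#' `HGVS_Protein`, `Protein_Change`, `AF` (`Absent` or a percentage),
#' `CADD` (a score, `NA`, or `No Liftover`), `GERP`, `CPM`, and optionally
#' `Consequence_Liftover`. Missing annotation fields become explicit `NA`s,
#' never zeros.
#'
#' @param path path to the delimited file.
#' @return data frame with normalized columns `gene`, `consequence`, `af`,
#'   `cadd`, `gerp`, `cpm`, `liftover_ok`, `consequence_liftover`.
#' @export
read_annotation_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  norm_cons <- function(x) {
    x <- tolower(x)
    x[x %in% c("stop gained", "stop_gained", "nonsense")] <- "other_lof"
    x[!x %in% c("synonymous", "missense", "frameshift", "other_lof",
                "noncoding")] <- "noncoding"
    x
  }
  af <- rep(NA_real_, nrow(raw))
  pct <- grepl("%$", raw$AF)
  af[pct] <- as.numeric(sub("%$", "", raw$AF[pct])) / 100
  num <- suppressWarnings(as.numeric(raw$AF))
  af[!pct & !is.na(num)] <- num[!pct & !is.na(num)]
  no_lift <- !is.na(raw$CADD) & raw$CADD == "No Liftover"
  cadd <- suppressWarnings(as.numeric(raw$CADD))
  data.frame(
    gene = raw$Gene,
    transcript = raw$Transcript,
    hgvs_dna = raw$HGVS_DNA,
    consequence = norm_cons(raw$Protein_Change),
    af = af,
    cadd = cadd,
    gerp = suppressWarnings(as.numeric(raw$GERP)),
    cpm = suppressWarnings(as.numeric(raw$CPM)),
    liftover_ok = !no_lift,
    consequence_liftover = if ("Consequence_Liftover" %in% names(raw)) {
      norm_cons(raw$Consequence_Liftover)
    } else norm_cons(raw$Protein_Change),
    stringsAsFactors = FALSE
  )
}
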