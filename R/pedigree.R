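#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns `id`,
#' `sire`, `dam`, `sex` (`"M"`/`"F"`) and `phenotype` (`"affected"`,
#' `"unaffected"`, `"unknown"`). Founders have both parents `NA`; all other
#' individuals must name two existing parents of opposite sex, and the
#' parent-child graph must be acyclic.
#'
#' @param id character vector of unique individual ids.
#' @param sire,dam character vectors of parent ids (`NA` for founders).
#' @param sex character vector, `"M"` or `"F"`.
#' @param phenotype character vector in
#'   `c("affected", "unaffected", "unknown")`.
#' @return a `pedigree` object (a validated data frame).
#' @examples
#' ped <- pedigree(
#'   id  = c("f1", "f2", "k1"),
#'   sire = c(NA, NA, "f1"), dam = c(NA, NA, "f2"),
#'   sex = c("M", "F", "M"),
#'   phenotype = c("unaffected", "unaffected", "affected")
#' )
#' @export
pedigree <- function(id, sire = NA_character_, dam = NA_character_,
                     sex, phenotype = "unknown") {
  ped <- data.frame(
    id = as.character(id),
    sire = as.character(sire),
    dam = as.character(dam),
    sex = as.character(sex),
    phenotype = rep_len(as.character(phenotype), length(id)),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, parent existence, both-or-neither parents, opposite
#' parental sexes, legal phenotype labels, and acyclicity. Called by all
#' pedigree consumers; errors list the offending ids.
#'
#' @param ped a pedigree data frame.
#' @return `ped`, invisibly, if valid.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "sire", "dam", "sex", "phenotype")
  if (!all(req %in% names(ped))) {
    stop("pedigree must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(ped$id)) {
    stop("duplicate ids: ", paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (!all(ped$phenotype %in% c("affected", "unaffected", "unknown"))) {
    stop("phenotype must be affected/unaffected/unknown")
  }
  half <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(half)) {
    stop("individuals with exactly one parent recorded: ",
         paste(ped$id[half], collapse = ", "))
  }
  nonf <- !is.na(ped$sire)
  miss <- nonf & (!(ped$sire %in% ped$id) | !(ped$dam %in% ped$id))
  if (any(miss)) {
    stop("missing parent id for: ", paste(ped$id[miss], collapse = ", "))
  }
  sx <- ped$sex[match(ped$sire, ped$id)]
  dx <- ped$sex[match(ped$dam, ped$id)]
  bad <- nonf & (sx != "M" | dx != "F")
  if (any(bad, na.rm = TRUE)) {
    stop("sire must be male and dam female for: ",
         paste(ped$id[which(bad)], collapse = ", "))
  }
  if (is.null(pedigree_order(ped, quiet = TRUE))) {
    stop("pedigree contains a cycle in the ancestry graph")
  }
  invisible(ped)
}

# Topological order (founders first); NULL if cyclic.
pedigree_order <- function(ped, quiet = FALSE) {
  n <- nrow(ped)
  placed <- is.na(ped$sire)
  ord <- ped$id[placed]
  while (length(ord) < n) {
    ready <- !placed & ped$sire %in% ord & ped$dam %in% ord
    if (!any(ready)) {
      if (!quiet) warning("cycle detected in pedigree")
      return(NULL)
    }
    ord <- c(ord, ped$id[ready])
    placed <- placed | ready
  }
  ord
}

#' Founder ids of a pedigree
#' @param ped a pedigree.
#' @return character vector of ids with no recorded parents.
#' @export
founders <- function(ped) ped$id[is.na(ped$sire)]

#' Obligate carriers of a recessive trait
#'
#' Under a fully penetrant autosomal recessive model, every unaffected parent
#' of an affected individual must carry exactly one copy of the disease
#' allele.
#'
#' @param ped a pedigree with phenotypes.
#' @return character vector of obligate-carrier ids.
#' @export
obligate_carriers <- function(ped) {
  aff <- ped[ped$phenotype == "affected", , drop = FALSE]
  parents <- unique(c(aff$sire, aff$dam))
  parents <- parents[!is.na(parents)]
  parents[ped$phenotype[match(parents, ped$id)] != "affected"]
}

#' Split a pedigree into nuclear families
#'
#' @param ped a pedigree.
#' @return list of `list(sire, dam, children)` with one entry per mating pair.
#' @export
nuclear_families <- function(ped) {
  nonf <- ped[!is.na(ped$sire), , drop = FALSE]
  if (nrow(nonf) == 0L) return(list())
  key <- paste(nonf$sire, nonf$dam, sep = "\r")
  lapply(split(nonf$id, key), function(kids) {
    i <- match(kids[1], ped$id)
    list(sire = ped$sire[i], dam = ped$dam[i], children = kids)
  })
}

#' Read a 6-column LINKAGE/PED pedigree file
#'
#' Columns: family id, individual id, sire id, dam id, sex (1 = male,
#' 2 = female), phenotype (2 = affected, 1 = unaffected, 0 or -9 = unknown).
#' Parent ids of `0` denote founders. Parsing is order independent: children
#' may be listed before their parents.
#'
#' @param path path to a whitespace-delimited PED file.
#' @return a `pedigree`; the family column is kept as attribute `family`.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6L) stop("PED file must have 6 columns: ", path)
  names(tab)[1:6] <- c("fam", "id", "sire", "dam", "sex", "phen")
  sex <- c("1" = "M", "2" = "F")[tab$sex]
  if (anyNA(sex)) stop("invalid sex code in PED file (must be 1/2)")
  phen <- rep("unknown", nrow(tab))
  phen[tab$phen == "2"] <- "affected"
  phen[tab$phen == "1"] <- "unaffected"
  if (!all(tab$phen %in% c("0", "1", "2", "-9"))) {
    stop("invalid phenotype code in PED file (must be 0/1/2/-9)")
  }
  ped <- pedigree(
    id = tab$id,
    sire = ifelse(tab$sire == "0", NA_character_, tab$sire),
    dam = ifelse(tab$dam == "0", NA_character_, tab$dam),
    sex = unname(sex),
    phenotype = phen
  )
  attr(ped, "family") <- tab$fam
  ped
}

#' Write a pedigree as a 6-column LINKAGE/PED file
#'
#' @param ped a pedigree.
#' @param path output path.
#' @param family family id used for all rows (default `"FAM1"`).
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  validate_pedigree(ped)
  phen <- c(affected = "2", unaffected = "1", unknown = "0")[ped$phenotype]
  out <- data.frame(
    fam = attr(ped, "family") %||% rep(family, nrow(ped)),
    id = ped$id,
    sire = ifelse(is.na(ped$sire), "0", ped$sire),
    dam = ifelse(is.na(ped$dam), "0", ped$dam),
    sex = c(M = "1", F = "2")[ped$sex],
    phen = unname(phen)
  )
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
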