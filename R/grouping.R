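# Chemical grouping of ligands into density-indistinguishable classes.
#
# Several ligands cannot be told apart by density alone (e.g. enantiomers of
# unresolved stereocenters, or isoelectronic pairs); the classifier therefore
# predicts ligand *groups*. Two ligands share a group iff they agree on heavy
# atom count, ring count, heavy-atom graph connectivity, chirality and
# element composition. Parsing and canonicalization are delegated to
# OpenBabel via ChemmineR/ChemmineOB.

ELEMENT_Z <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L,
  O = 8L, F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Sc = 21L, Ti = 22L,
  V = 23L, Cr = 24L, Mn = 25L, Fe = 26L, Co = 27L, Ni = 28L, Cu = 29L,
  Zn = 30L, Ga = 31L, Ge = 32L, As = 33L, Se = 34L, Br = 35L, Kr = 36L,
  Rb = 37L, Sr = 38L, Y = 39L, Zr = 40L, Nb = 41L, Mo = 42L, Ru = 44L,
  Rh = 45L, Pd = 46L, Ag = 47L, Cd = 48L, In = 49L, Sn = 50L, Sb = 51L,
  Te = 52L, I = 53L, Xe = 54L, Cs = 55L, Ba = 56L, W = 74L, Re = 75L,
  Os = 76L, Ir = 77L, Pt = 78L, Au = 79L, Hg = 80L, Tl = 81L, Pb = 82L,
  Bi = 83L, U = 92L)

obCanonicalSmiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) lbChemError(sprintf("unparseable SMILES: '%s'", smiles))
  out
}

stripStereo <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("[/\\\\]", "-", s)
  # collapse explicit-H brackets left over from stereocenters, e.g. [CH] -> C
  gsub("\\[(C|N|O|S|P)H\\]", "\\1", s)
}

stereoTokens <- function(smiles) {
  toks <- regmatches(smiles, gregexpr("@{1,2}|[/\\\\]", smiles))[[1]]
  paste(toks, collapse = "")
}

#' Compute the grouping descriptor of a ligand
#'
#' Parses a SMILES string and derives the five features that decide density
#' indistinguishability: heavy-atom count, ring count (cyclomatic number of
#' the heavy-atom graph), canonical connectivity, chirality descriptor, and
#' the sorted heavy-atom atomic numbers. Hydrogens are excluded throughout.
#'
#' @param smiles SMILES string.
#' @param ccdCode Chemical Component Dictionary code (optional label).
#' @return A \linkS4class{LigandChemistry}. Unparseable SMILES raise a
#'   chemistry-parse error (condition class \code{ligandblob_chem_error});
#'   callers building a label space route such ligands to the rare class.
#' @examples
#' \dontrun{
#' ligandDescriptorKey("[O-]P(=O)([O-])[O-]", "PO4")  # 5 heavy atoms
#' }
#' @export
ligandDescriptorKey <- function(smiles, ccdCode = NA_character_) {
  canon <- obCanonicalSmiles(smiles)
  connectivity <- obCanonicalSmiles(stripStereo(canon))
  chirality <- stereoTokens(canon)

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(sdf) || !methods::is(sdf, "SDFset") || length(sdf) < 1L)
    lbChemError(sprintf("unparseable SMILES: '%s'", smiles))
  mol <- sdf[[1]]
  atoms <- ChemmineR::atomblock(mol)
  elements <- sub("_.*$", "", rownames(atoms))
  heavy <- elements[toupper(elements) != "H"]
  z <- ELEMENT_Z[heavy]
  if (anyNA(z))
    lbChemError(sprintf("unknown element(s) %s in '%s'",
                        paste(unique(heavy[is.na(z)]), collapse = ","), smiles))
  bonds <- ChemmineR::bondblock(mol)
  nBondsHeavy <- if (is.null(dim(bonds)) || nrow(bonds) == 0L) 0L else {
    isH <- toupper(elements) == "H"
    sum(!isH[bonds[, 1]] & !isH[bonds[, 2]])
  }
  nComp <- countGraphComponents(length(heavy),
                                bonds, toupper(elements) == "H")
  ringCount <- as.integer(nBondsHeavy - length(heavy) + nComp)

  new("LigandChemistry", ccdCode = as.character(ccdCode), smiles = smiles,
      heavyAtomCount = length(heavy), ringCount = max(0L, ringCount),
      connectivityKey = connectivity, chiralityKey = chirality,
      atomicNumbers = as.integer(sort(unname(z))))
}

# number of connected components of the heavy-atom graph
countGraphComponents <- function(nHeavy, bonds, isH) {
  heavyIdx <- which(!isH)
  if (length(heavyIdx) == 0L) return(0L)
  parent <- seq_along(isH)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(dim(bonds)) && nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      i <- as.integer(bonds[b, 1]); j <- as.integer(bonds[b, 2])
      if (isH[i] || isH[j]) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- as.integer(rj)
    }
  }
  length(unique(vapply(heavyIdx, function(i) as.integer(find(i)), integer(1))))
}

chemistryKeyString <- function(chem) {
  paste(chem@heavyAtomCount, chem@ringCount, chem@connectivityKey,
        chem@chiralityKey, paste(chem@atomicNumbers, collapse = ","),
        sep = "|")
}

#' Cluster ligand chemistries into classification groups
#'
#' Ligands with identical descriptor keys are merged; a group's instance
#' count is the sum of its members' blob counts. Groups below
#' \code{minInstances} are collapsed into a single catch-all "rare" class.
#' Group ids are stable under input permutation (groups are ordered by their
#' key; rare is always last).
#'
#' @param chemistries list of \linkS4class{LigandChemistry} objects, or
#'   \code{NA} entries for unparseable ligands (routed to rare). The list
#'   names (or ccdCode slots) identify the ligands.
#' @param blobCounts named integer vector, CCD code -> blob instance count.
#'   Codes absent from the vector count 0.
#' @param minInstances minimum blob instances for a standalone group
#'   (default 100).
#' @return A list of \linkS4class{LigandGroup} objects.
#' @export
clusterIntoGroups <- function(chemistries, blobCounts = integer(),
                              minInstances = 100) {
  codes <- vapply(seq_along(chemistries), function(i) {
    ch <- chemistries[[i]]
    if (methods::is(ch, "LigandChemistry") && !is.na(ch@ccdCode))
      ch@ccdCode
    else if (!is.null(names(chemistries)) && nzchar(names(chemistries)[i]))
      names(chemistries)[i]
    else sprintf("LIG%03d", i)
  }, character(1))
  if (anyDuplicated(codes))
    lbValidationError("duplicate ligand codes in input")
  countOf <- function(code) {
    i <- match(code, names(blobCounts))
    if (is.na(i)) 0L else as.integer(blobCounts[i])
  }

  keys <- vapply(chemistries, function(ch) {
    if (methods::is(ch, "LigandChemistry")) chemistryKeyString(ch)
    else NA_character_   # unparseable -> rare
  }, character(1))

  parseable <- which(!is.na(keys))
  byKey <- split(parseable, keys[parseable])
  byKey <- byKey[order(names(byKey))]

  groups <- list()
  rareCodes <- codes[is.na(keys)]
  rareCount <- sum(vapply(rareCodes, countOf, integer(1)), 0L)
  gid <- 0L
  for (k in seq_along(byKey)) {
    members <- sort(codes[byKey[[k]]])
    n <- sum(vapply(members, countOf, integer(1)))
    if (n >= minInstances) {
      gid <- gid + 1L
      groups[[gid]] <- new("LigandGroup", groupId = gid,
                           memberCodes = members, label = members[1],
                           instanceCount = as.integer(n))
    } else {
      rareCodes <- c(rareCodes, members)
      rareCount <- rareCount + n
    }
  }
  groups[[gid + 1L]] <- new("LigandGroup", groupId = gid + 1L,
                            memberCodes = sort(unname(rareCodes)),
                            label = "rare",
                            instanceCount = as.integer(rareCount))
  groups
}

#' Tabulate a list of ligand groups
#'
#' @param groups list of \linkS4class{LigandGroup}.
#' @return data.frame with group_id, label, n_members, instance_count.
#' @export
groupTable <- function(groups) {
  data.frame(
    group_id = vapply(groups, function(g) g@groupId, integer(1)),
    label = vapply(groups, function(g) g@label, character(1)),
    n_members = vapply(groups, function(g) length(g@memberCodes), integer(1)),
    instance_count = vapply(groups, function(g) g@instanceCount, integer(1)))
}
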