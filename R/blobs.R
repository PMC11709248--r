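# Blob extraction: connected components of thresholded grids, volumes, and
# the standard ligand quality filters.

#' Extract connected positive-density components as blobs
#'
#' Labels the nonzero voxels of a thresholded grid under the chosen
#' connectivity and returns one \linkS4class{Blob} per component, each
#' cropped to its bounding box, ordered by descending voxel count.
#'
#' @param grid a \linkS4class{VoxelGrid} (all values >= 0).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (default; faces,
#'   edges and corners - the most permissive choice, which avoids splitting
#'   ligands connected through thin density bridges at 0.2 A sampling).
#' @param minVoxels components with fewer nonzero voxels are dropped.
#' @return A list of \linkS4class{Blob} objects (empty for an all-zero grid).
#' @export
connectedComponents <- function(grid, connectivity = 26, minVoxels = 1) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!connectivity %in% c(6, 18, 26))
    lbValidationError("connectivity must be 6, 18 or 26")
  d <- dim(grid@values)
  labels <- .label_components(as.numeric(grid@values), as.integer(d),
                              as.integer(connectivity))
  if (all(labels == 0L)) return(list())
  counts <- tabulate(labels)
  keep <- which(counts >= minVoxels)
  keep <- keep[order(counts[keep], decreasing = TRUE)]
  lapply(keep, function(lab) {
    lin <- which(labels == lab)
    idx0 <- arrayIndices3d(lin, d)
    lo <- apply(idx0, 2, min)
    hi <- apply(idx0, 2, max)
    sub <- array(0, dim = hi - lo + 1L)
    sub[idx0 - matrix(lo, nrow(idx0), 3, byrow = TRUE) + 1L] <-
      grid@values[lin]
    centers <- voxelCenters(idx0, grid@spacing, grid@origin)
    new("Blob",
        grid = VoxelGrid(sub, spacing = grid@spacing,
                         origin = grid@origin + lo * grid@spacing),
        depositId = NA_character_, chain = NA_character_,
        residueNumber = NA_integer_, ligandCode = NA_character_,
        centroid = colMeans(centers))
  })
}

#' Blob volume in cubic Angstrom
#'
#' Volume is the nonzero voxel count times the voxel volume; at the canonical
#' 0.2 A spacing each voxel contributes 0.008 A^3.
#'
#' @param blob a \linkS4class{Blob} or \linkS4class{VoxelGrid}.
#' @return Volume in A^3.
#' @export
blobVolume <- function(blob) {
  grid <- if (is(blob, "Blob")) blob@grid else blob
  stopifnot(is(grid, "VoxelGrid"))
  sum(grid@values > 0) * grid@spacing^3
}

# X-ray rejection criteria, in the order they are reported; each is the
# printed inequality that *rejects* a ligand.
XRAY_CRITERIA <- list(
  resolution = function(r) r$resolution > 4.0,
  rscc       = function(r) r$rscc < 0.6,
  rszo       = function(r) r$rszo < 1.0,
  rszd       = function(r) r$rszd >= 6.0,
  r_factor   = function(r) r$r_factor > 0.3,
  occupancy  = function(r) r$occupancy < 0.3)

checkFields <- function(records, fields) {
  for (f in fields) {
    if (!f %in% names(records))
      lbValidationError(sprintf("missing quality field '%s'", f))
    if (anyNA(records[[f]]))
      lbValidationError(sprintf("missing values in quality field '%s'", f))
  }
}

#' Filter X-ray ligands on the standard quality criteria
#'
#' A ligand is rejected iff any criterion fires: resolution > 4.0 A,
#' RSCC < 0.6, RSZO < 1.0, RSZD >= 6.0, R factor > 0.3, or occupancy < 0.3.
#' Boundary semantics follow the printed inequalities exactly. Each rejected
#' record is labeled with the first firing criterion in that order.
#'
#' @param records data.frame with columns resolution, rscc, rszo, rszd,
#'   r_factor, occupancy (one row per ligand).
#' @return A list with \code{kept} and \code{rejected} data.frames; the
#'   latter gains a \code{reason} column.
#' @export
filterXrayLigands <- function(records) {
  records <- as.data.frame(records)
  checkFields(records, names(XRAY_CRITERIA))
  reason <- rep(NA_character_, nrow(records))
  for (crit in rev(names(XRAY_CRITERIA))) {
    fires <- XRAY_CRITERIA[[crit]](records)
    reason[fires] <- crit
  }
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = kept, rejected = rejected)
}

#' Filter cryoEM ligands on Q-score and volume
#'
#' Kept iff Q-score >= 0.6 ("0.6 or better", inclusive) and volume
#' strictly greater than 2.14 A^3.
#'
#' @param records data.frame with columns q_score and volume.
#' @return A list with \code{kept} and \code{rejected} data.frames; the
#'   latter gains a \code{reason} column (first failing criterion).
#' @export
filterCryoemLigands <- function(records) {
  records <- as.data.frame(records)
  checkFields(records, c("q_score", "volume"))
  reason <- rep(NA_character_, nrow(records))
  reason[records$volume <= 2.14] <- "volume"
  reason[records$q_score < 0.6] <- "q_score"
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = kept, rejected = rejected)
}

#' Does a blob belong to a ligand's atoms?
#'
#' True iff any non-hydrogen atom lies within \code{maxDist} of the center
#' of a nonzero voxel. Used to transfer residue-identifier labels from a
#' deposited model onto extracted blobs.
#'
#' @param blob a \linkS4class{Blob}.
#' @param ligandAtoms data.frame with columns element, x, y, z (Angstrom).
#' @param maxDist assignment radius in Angstrom; the 2.0 default is roughly a
#'   covalent bond length plus half a voxel diagonal.
#' @return TRUE or FALSE.
#' @export
assignBlobToLigand <- function(blob, ligandAtoms, maxDist = 2.0) {
  stopifnot(is(blob, "Blob"))
  atoms <- as.data.frame(ligandAtoms)
  atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  if (nrow(atoms) == 0L)
    lbValidationError("at least one non-hydrogen atom is required")
  g <- blob@grid
  lin <- which(g@values > 0)
  centers <- voxelCenters(arrayIndices3d(lin, dim(g@values)), g@spacing,
                          g@origin)
  for (a in seq_len(nrow(atoms))) {
    d2 <- (centers[, 1] - atoms$x[a])^2 + (centers[, 2] - atoms$y[a])^2 +
          (centers[, 3] - atoms$z[a])^2
    if (min(d2) <= maxDist^2) return(TRUE)
  }
  FALSE
}
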