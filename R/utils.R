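# Structured error helpers; error classes let callers route failures without
# parsing messages.

lbStop <- function(msg, class) {
  stop(structure(class = c(class, "ligandblob_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

lbFormatError     <- function(msg) lbStop(msg, "ligandblob_format_error")
lbValidationError <- function(msg) lbStop(msg, "ligandblob_validation_error")
lbDegenerateError <- function(msg) lbStop(msg, "ligandblob_degenerate_error")
lbChemError       <- function(msg) lbStop(msg, "ligandblob_chem_error")

# Run expr with a fixed RNG stream, restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Population standard deviation (divides by n, not n - 1); the crystallographic
# sigma convention.
populationSd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

# Linear (zero-based triple) indexing helpers for 3D arrays.
arrayIndices3d <- function(linear, dims) {
  linear <- linear - 1L
  i <- linear %% dims[1]
  j <- (linear %/% dims[1]) %% dims[2]
  k <- linear %/% (dims[1] * dims[2])
  cbind(i, j, k)  # zero-based
}

# Voxel centers (Angstrom) for zero-based index triples of a VoxelGrid.
voxelCenters <- function(idx0, spacing, origin) {
  sweep((idx0 + 0.5) * spacing, 2, origin, "+")
}
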