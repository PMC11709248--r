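# Shared fixtures, all generated in code.

# A zero-inflated map whose blob peaks are scaled to a target
# signal-to-noise ratio (peak density over background SD). Boxes of at
# least 11 A a side hold two separated ligands; smaller boxes get a single
# centered one (pseudo-ligand support is ~4 A around the atoms).
recoveryFixture <- function(seed = 5, snr = 8, box = c(64L, 64L, 64L)) {
  scaleTo <- function(atoms, res) {
    peak <- max(gridValues(renderPseudoLigand(atoms, res)))
    atoms$weight <- atoms$weight * snr / peak
    atoms
  }
  if (all(box * 0.2 >= 11)) {
    atoms1 <- data.frame(weight = c(8, 8, 6),
                         x = c(2.8, 4.0, 3.4), y = c(3.2, 3.2, 4.2),
                         z = c(6.4, 6.4, 6.4))
    atoms2 <- data.frame(weight = c(8, 7),
                         x = c(9.2, 10.2), y = c(9.6, 9.6), z = c(6.4, 6.4))
    blobs <- list(list(atoms = scaleTo(atoms1, 2.0), resolution = 2.0),
                  list(atoms = scaleTo(atoms2, 2.0), resolution = 2.0))
  } else {
    ctr <- box[1] * 0.2 / 2
    atoms <- data.frame(weight = c(8, 6), x = ctr + c(-0.5, 0.5),
                        y = ctr, z = ctr)
    blobs <- list(list(atoms = scaleTo(atoms, 2.0), resolution = 2.0))
  }
  z <- makeZeroInflatedMap(box = box, maskFraction = 0.6,
                           background = c(0, 1), blobs = blobs, seed = seed)
  z$blobs <- blobs
  z
}

# tiny model configs that keep gradient checks and invariance loops fast
tinyRiconvConfig <- function(nClasses = 3)
  modelConfig("riconvpp", nClasses = nClasses,
              riconvChannels = c(8L, 8L, 8L, 8L, 8L), fcHidden = 16L,
              neighborhoodK = 8L)

tinyMinklocConfig <- function(nClasses = 3)
  modelConfig("minkloc", nClasses = nClasses, quantizationSize = 0.5,
              channels = c(8L, 12L, 16L), fusedChannels = 12L,
              netvladClusters = 4L)

# give a model a non-degenerate random head so score differences are visible
randomizeHead <- function(model, seed = 1) {
  nm <- if (model@config$architecture == "riconvpp") "Wfc2" else "Wout"
  old <- get(nm, model@params)
  set.seed(seed)
  assign(nm, matrix(stats::rnorm(length(old), sd = 0.1), nrow(old)),
         envir = model@params)
  model
}

pythonBin <- function() Sys.which("python")
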