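# Evaluation protocol: deposit-grouped stratified splitting and the five
# classification metrics.

#' Deposit-grouped stratified holdout split
#'
#' Assigns whole deposits (PDB entries) to train or test - never splitting a
#' deposit - while keeping each ligand group's train fraction close to
#' \code{trainFrac}. A quarter of the training examples (per group, again at
#' deposit granularity) is then carved out as an independent validation set.
#' Deposits are processed largest-first in a seeded random order; each is
#' greedily assigned to the side that keeps the per-group fractions closest
#' to target.
#'
#' @param examples data.frame with columns id, deposit, group.
#' @param trainFrac target train fraction (default 0.7).
#' @param valFracOfTrain fraction of the training set carved out for
#'   validation (default 0.25).
#' @param seed RNG seed; identical seeds give identical plans.
#' @return A \linkS4class{SplitPlan} with assignments train/val/test.
#' @export
depositStratifiedSplit <- function(examples, trainFrac = 0.7,
                                   valFracOfTrain = 0.25, seed = 1) {
  examples <- as.data.frame(examples)
  checkSplitInput(examples)
  withSeed(seed, {
    singles <- tapply(examples$deposit, examples$group,
                      function(d) length(unique(d)) == 1L)
    for (g in names(singles)[singles])
      warning(sprintf("group '%s' occurs in a single deposit; it cannot be split", g))
    part <- greedyGroupedAssign(examples, targetFrac = trainFrac,
                                sides = c("train", "test"))
    trainIds <- names(part)[part == "train"]
    trainEx <- examples[examples$id %in% trainIds, , drop = FALSE]
    if (nrow(trainEx) > 0 && length(unique(trainEx$deposit)) > 1L) {
      val <- greedyGroupedAssign(trainEx, targetFrac = valFracOfTrain,
                                 sides = c("val", "train"))
      part[names(val)[val == "val"]] <- "val"
    }
  })
  newSplitPlan(examples, part)
}

checkSplitInput <- function(examples) {
  for (f in c("id", "deposit", "group")) {
    if (!f %in% names(examples))
      lbValidationError(sprintf("examples must have a '%s' column", f))
  }
  if (anyDuplicated(examples$id))
    lbValidationError("example ids must be unique")
}

newSplitPlan <- function(examples, assignment) {
  ids <- as.character(examples$id)
  new("SplitPlan", assignment = assignment[ids],
      groupKey = stats::setNames(as.character(examples$deposit), ids),
      strata = stats::setNames(as.character(examples$group), ids))
}

# Greedy deposit assignment: deposits visited largest-first (random order
# within ties); each goes to sides[1] if that keeps the per-group fraction
# of sides[1] no further from target than the alternative.
greedyGroupedAssign <- function(examples, targetFrac, sides) {
  ids <- as.character(examples$id)
  deposits <- split(seq_len(nrow(examples)), examples$deposit)
  deposits <- deposits[sample(length(deposits))]
  deposits <- deposits[order(-lengths(deposits))]
  groups <- sort(unique(as.character(examples$group)))
  totals <- table(factor(examples$group, levels = groups))
  inSide <- stats::setNames(numeric(length(groups)), groups)
  assigned <- stats::setNames(numeric(length(groups)), groups)
  out <- stats::setNames(character(nrow(examples)), ids)
  for (dep in deposits) {
    depGroups <- table(factor(examples$group[dep], levels = groups))
    withDep <- sum(abs((inSide + depGroups) / totals - targetFrac) *
                     totals / sum(totals))
    without <- sum(abs(inSide / totals - targetFrac) *
                     totals / sum(totals))
    if (withDep <= without) {
      out[ids[dep]] <- sides[1]
      inSide <- inSide + depGroups
    } else {
      out[ids[dep]] <- sides[2]
    }
  }
  out
}

#' Deposit-grouped stratified k-fold plan
#'
#' Whole deposits are distributed over k folds so that, per ligand group,
#' fold sizes differ by at most one wherever deposit granularity permits.
#'
#' @param examples data.frame with columns id, deposit, group.
#' @param k number of folds (default 3).
#' @param seed RNG seed.
#' @return A \linkS4class{SplitPlan} with assignments "fold1".."foldk".
#' @export
stratifiedKfold <- function(examples, k = 3, seed = 1) {
  examples <- as.data.frame(examples)
  checkSplitInput(examples)
  if (k < 2) lbValidationError("k must be >= 2")
  nDep <- length(unique(examples$deposit))
  if (k > nDep)
    lbValidationError(sprintf("k = %d exceeds the number of deposits (%d)", k, nDep))
  groups <- sort(unique(as.character(examples$group)))
  foldCounts <- matrix(0, k, length(groups), dimnames = list(NULL, groups))
  out <- stats::setNames(character(nrow(examples)), as.character(examples$id))
  withSeed(seed, {
    deposits <- split(seq_len(nrow(examples)), examples$deposit)
    deposits <- deposits[sample(length(deposits))]
    deposits <- deposits[order(-lengths(deposits))]
    for (dep in deposits) {
      depGroups <- table(factor(examples$group[dep], levels = groups))
      # fold that minimizes the resulting per-group imbalance, ties to the
      # emptiest fold then lowest index
      costs <- vapply(seq_len(k), function(f) {
        trial <- foldCounts
        trial[f, ] <- trial[f, ] + depGroups
        sum(apply(trial, 2, function(col) max(col) - min(col)))
      }, numeric(1))
      f <- order(costs, rowSums(foldCounts), seq_len(k))[1]
      foldCounts[f, ] <- foldCounts[f, ] + depGroups
      out[as.character(examples$id[dep])] <- sprintf("fold%d", f)
    }
  })
  newSplitPlan(examples, out)
}

#' Rank of the correct class in a score vector
#'
#' Rank 1 is best. Ties are broken by class index: the rank counts classes
#' with strictly greater score plus tied classes with a smaller index.
#'
#' @param scores probability (or score) vector.
#' @param trueClass index of the correct class (1-based), or its name.
#' @return Integer rank in 1..length(scores).
#' @export
rankOfCorrect <- function(scores, trueClass) {
  if (is.character(trueClass)) {
    trueClass <- match(trueClass, names(scores))
  }
  if (is.na(trueClass) || trueClass < 1 || trueClass > length(scores))
    lbValidationError("trueClass out of range")
  st <- scores[trueClass]
  as.integer(1L + sum(scores > st) +
               sum(scores == st & seq_along(scores) < trueClass))
}

#' Compute the five evaluation metrics
#'
#' Accuracy, top-10 accuracy, mean correct prediction rank, Brier score
#' (squared probability error for the correct class, mean((1 - p_true)^2)),
#' and macro-averaged recall (unweighted mean of per-class recall over
#' classes present in the truth labels). Argmax ties are broken towards the
#' smallest class index throughout.
#'
#' @param predictions either a numeric score matrix (one row per example,
#'   one column per class) or a list of \linkS4class{PredictionResult}.
#' @param truths integer class indices (or label names matching the score
#'   columns), one per example.
#' @param multiclassBrier if TRUE, use the sum-over-classes Brier variant
#'   mean(sum_k (p_k - y_k)^2) instead of the correct-class form.
#' @return A \linkS4class{MetricsReport}.
#' @export
computeMetrics <- function(predictions, truths, multiclassBrier = FALSE) {
  if (is.list(predictions) && !is.data.frame(predictions)) {
    scores <- do.call(rbind, lapply(predictions, classScores))
  } else {
    scores <- as.matrix(predictions)
  }
  n <- nrow(scores)
  if (length(truths) != n)
    lbValidationError("predictions and truths differ in length")
  if (is.character(truths)) {
    truths <- match(truths, colnames(scores))
    if (anyNA(truths)) lbValidationError("truth label not among score columns")
  }
  if (any(truths < 1 | truths > ncol(scores)))
    lbValidationError("trueClass out of range")

  ranks <- vapply(seq_len(n), function(i) rankOfCorrect(scores[i, ], truths[i]),
                  integer(1))
  pTrue <- scores[cbind(seq_len(n), truths)]
  brier <- if (multiclassBrier) {
    onehot <- matrix(0, n, ncol(scores))
    onehot[cbind(seq_len(n), truths)] <- 1
    mean(rowSums((scores - onehot)^2))
  } else mean((1 - pTrue)^2)

  predicted <- vapply(seq_len(n), function(i) which.max2(scores[i, ]),
                      integer(1))
  present <- sort(unique(truths))
  recalls <- vapply(present, function(cl)
    mean(predicted[truths == cl] == cl), numeric(1))

  new("MetricsReport",
      accuracy = mean(ranks == 1L),
      top10Accuracy = mean(ranks <= 10L),
      meanCorrectRank = mean(ranks),
      brierScore = brier,
      macroRecall = mean(recalls))
}
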