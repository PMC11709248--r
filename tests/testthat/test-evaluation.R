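# Splitting protocols and the five evaluation metrics.

test_that("deposit-grouped holdout hits target fractions on divisible data", {
  ex <- data.frame(id = sprintf("e%03d", 1:100),
                   deposit = sprintf("d%03d", 1:100),
                   group = rep(c("A", "B"), each = 50))
  plan <- depositStratifiedSplit(ex, seed = 4)
  tab <- table(plan@strata, splitAssignment(plan))
  trainish <- tab[, "train"] + tab[, "val"]
  expect_equal(unname(trainish), c(35, 35))              # exact 70%
  expect_equal(unname(tab[, "test"]), c(15, 15))
  # validation is ~25% of the training set per group
  expect_true(all(abs(tab[, "val"] / trainish - 0.25) <= 0.05))
})

test_that("a single shared deposit cannot be split and warns", {
  ex <- data.frame(id = 1:10, deposit = "only", group = rep(c("A", "B"), 5))
  w <- capture_warnings(plan <- depositStratifiedSplit(ex, seed = 1))
  expect_gte(length(w), 1L)                # one warning per confined group
  expect_true(all(grepl("single deposit", w)))
  expect_identical(length(unique(splitAssignment(plan))), 1L)
})

test_that("no deposit ever spans partitions (leakage check, 1000 configs)", {
  set.seed(55)
  for (rep in 1:1000) {
    nDep <- sample(3:25, 1)
    nEx <- sample(nDep:(3 * nDep), 1)
    ex <- data.frame(id = seq_len(nEx),
                     deposit = sprintf("d%d", sample(nDep, nEx,
                                                     replace = TRUE)),
                     group = sample(c("A", "B", "C"), nEx, replace = TRUE))
    plan <- suppressWarnings(depositStratifiedSplit(ex, seed = rep))
    crossings <- tapply(splitAssignment(plan), plan@groupKey,
                        function(a) length(unique(a)))
    expect_true(all(crossings == 1L))
  }
})

test_that("stratified k-fold balances strata and respects deposits", {
  ex <- data.frame(id = 1:9, deposit = sprintf("d%d", 1:9),
                   group = rep(c("A", "B", "C"), 3))
  plan <- stratifiedKfold(ex, k = 3, seed = 2)
  tab <- table(plan@strata, splitAssignment(plan))
  expect_true(all(tab == 1L))                            # one of each per fold
  expect_setequal(names(splitAssignment(plan)), as.character(ex$id))

  set.seed(56)
  for (rep in 1:20) {
    nDep <- sample(6:30, 1)
    ex <- data.frame(id = seq_len(nDep), deposit = sprintf("d%d", seq_len(nDep)),
                     group = sample(c("A", "B"), nDep, replace = TRUE))
    plan <- stratifiedKfold(ex, k = 3, seed = rep)
    # folds disjoint and exhaustive by construction of the assignment map
    expect_identical(sort(names(splitAssignment(plan))),
                     sort(as.character(ex$id)))
    # per-fold class counts within 1 of each other (single-example deposits)
    tab <- table(plan@strata, splitAssignment(plan))
    expect_true(all(apply(tab, 1, function(r) max(r) - min(r)) <= 1))
  }

  expect_error(stratifiedKfold(ex, k = 99, seed = 1),
               class = "ligandblob_validation_error")
})

test_that("split plans are seed-deterministic and seed-sensitive", {
  ex <- data.frame(id = 1:60, deposit = sprintf("d%d", rep(1:30, 2)),
                   group = rep(c("A", "B"), 30))
  p1 <- depositStratifiedSplit(ex, seed = 7)
  p2 <- depositStratifiedSplit(ex, seed = 7)
  expect_identical(splitAssignment(p1), splitAssignment(p2))
  different <- any(vapply(8:17, function(s)
    !identical(splitAssignment(depositStratifiedSplit(ex, seed = s)),
               splitAssignment(p1)), logical(1)))
  expect_true(different)
})

test_that("rank of the correct class follows the tie-breaking rule", {
  expect_identical(rankOfCorrect(c(0, 1, 0), 2), 1L)     # one-hot
  expect_identical(rankOfCorrect(rep(0.25, 4), 1), 1L)   # uniform, id 1 wins
  expect_identical(rankOfCorrect(rep(0.25, 4), 3), 3L)
  expect_error(rankOfCorrect(c(0.5, 0.5), 3),
               class = "ligandblob_validation_error")

  set.seed(57)
  for (rep in 1:50) {
    k <- sample(3:12, 1)
    s <- runif(k); s <- s / sum(s)
    t0 <- sample(k, 1)
    # sort-based oracle with the same tie rule
    ord <- order(-s, seq_len(k))
    expect_identical(rankOfCorrect(s, t0), which(ord == t0))
  }
})

test_that("metrics match closed forms and a pencil-and-paper case", {
  onehot <- diag(4)[c(1, 3, 2), ]
  perfect <- computeMetrics(onehot, c(1, 3, 2))
  expect_identical(unname(metricsVector(perfect)),
                   c(1, 1, 1, 0, 1))

  uniform <- computeMetrics(matrix(1 / 20, 5, 20), c(1, 3, 5, 7, 20))
  expect_equal(metricsVector(uniform)[["brier_score"]], (1 - 1 / 20)^2)

  # hand-computed: 3 predictions over 4 classes
  s <- rbind(c(0.4, 0.3, 0.2, 0.1),    # truth 1: rank 1, p = 0.4
             c(0.1, 0.2, 0.3, 0.4),    # truth 2: rank 3, p = 0.2
             c(0.25, 0.25, 0.25, 0.25))  # truth 4: rank 4 (ties), p = 0.25
  r <- computeMetrics(s, c(1, 2, 4))
  expect_equal(metricsVector(r)[["accuracy"]], 1 / 3)
  expect_equal(metricsVector(r)[["top10_accuracy"]], 1)
  expect_equal(metricsVector(r)[["mean_correct_rank"]], (1 + 3 + 4) / 3)
  expect_equal(metricsVector(r)[["brier_score"]],
               ((1 - 0.4)^2 + (1 - 0.2)^2 + (1 - 0.25)^2) / 3)
  expect_equal(metricsVector(r)[["macro_recall"]], (1 + 0 + 0) / 3)

  expect_error(computeMetrics(s, c(1, 2)),
               class = "ligandblob_validation_error")
})

test_that("metric invariants hold on random predictions", {
  set.seed(58)
  for (rep in 1:20) {
    n <- sample(5:40, 1); k <- sample(3:15, 1)
    s <- matrix(rexp(n * k), n)
    s <- s / rowSums(s)
    truths <- sample(k, n, replace = TRUE)
    m <- metricsVector(computeMetrics(s, truths))
    expect_lte(m[["accuracy"]], m[["top10_accuracy"]])
    expect_lte(m[["top10_accuracy"]], 1)
    expect_gte(m[["mean_correct_rank"]], 1)
    expect_lte(m[["mean_correct_rank"]], k)
    expect_gte(m[["brier_score"]], 0)
    expect_lte(m[["brier_score"]], 1)
    expect_gte(m[["macro_recall"]], 0)
    expect_lte(m[["macro_recall"]], 1)
  }

  # macro recall ignores class frequency: duplicating one class's examples
  # leaves it unchanged
  s <- rbind(c(0.8, 0.2), c(0.3, 0.7), c(0.6, 0.4))
  t0 <- c(1, 2, 2)
  base <- metricsVector(computeMetrics(s, t0))[["macro_recall"]]
  dup <- metricsVector(computeMetrics(rbind(s, s[1, , drop = FALSE]),
                                      c(t0, 1)))[["macro_recall"]]
  expect_equal(dup, base)

  # Brier is 0 iff every prediction is a correct one-hot
  expect_identical(metricsVector(computeMetrics(diag(3), 1:3))[["brier_score"]],
                   0)
})

test_that("metrics accept PredictionResult lists", {
  p1 <- new("PredictionResult",
            classScores = c(a = 0.7, b = 0.2, c = 0.1),
            rankedLabels = c("a", "b", "c"))
  p2 <- new("PredictionResult",
            classScores = c(a = 0.1, b = 0.6, c = 0.3),
            rankedLabels = c("b", "c", "a"))
  r <- computeMetrics(list(p1, p2), c("a", "c"))
  expect_equal(metricsVector(r)[["accuracy"]], 0.5)
  expect_equal(metricsVector(r)[["brier_score"]],
               ((1 - 0.7)^2 + (1 - 0.3)^2) / 2)
})
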