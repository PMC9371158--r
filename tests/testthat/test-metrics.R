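test_that("confusion matrices tally true-by-predicted counts", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unclass(cm)[1, ], c(A = 1L, B = 1L))
  expect_equal(unclass(cm)[2, ], c(A = 0L, B = 1L))

  perfect <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"),
                              c("A", "B", "C"))
  expect_true(all(unclass(perfect)[upper.tri(perfect) | lower.tri(perfect)] == 0))

  empty <- confusion_matrix(character(), character(), c("A", "B"))
  expect_true(all(unclass(empty) == 0))

  expect_error(confusion_matrix("A", "Z", c("A", "B")), "outside")
  expect_error(confusion_matrix(c("A", "B"), "A", c("A", "B")), "equal length")
})

test_that("per-class one-vs-all metrics evaluate the standard formulas", {
  # binary case: TP=50, FP=10, FN=10, TN=30
  y_true <- c(rep("pos", 60), rep("neg", 40))
  y_pred <- c(rep("pos", 50), rep("neg", 10), rep("pos", 10), rep("neg", 30))
  cm <- confusion_matrix(y_true, y_pred, c("pos", "neg"))
  pc <- per_class_metrics(cm)
  pos <- pc[pc$class == "pos", ]
  expect_equal(pos$TP, 50L); expect_equal(pos$FP, 10L)
  expect_equal(pos$FN, 10L); expect_equal(pos$TN, 30L)
  expect_equal(pos$precision, 5 / 6)
  expect_equal(pos$recall, 5 / 6)
  expect_equal(pos$f1, 5 / 6)
  expect_equal(pos$TP + pos$TN + pos$FP + pos$FN, 100L)
  rep <- aggregate_metrics(pc)
  expect_equal(rep$accuracy, 0.8)

  diagc <- per_class_metrics(confusion_matrix(c("A", "B"), c("A", "B"),
                                              c("A", "B")))
  expect_true(all(diagc$precision == 1) && all(diagc$recall == 1))
})

test_that("zero-denominator metrics return 0 with the undefined flag", {
  cm <- confusion_matrix(c("A", "A"), c("A", "A"), c("A", "B"))
  pc <- per_class_metrics(cm)
  b <- pc[pc$class == "B", ]
  expect_equal(b$recall, 0)
  expect_equal(b$precision, 0)
  expect_true(b$undefined)
  expect_false(pc$undefined[pc$class == "A"])
})

test_that("macro and weighted aggregation weight classes as documented", {
  # recalls (1.0, 0.5) with supports (30, 10)
  y_true <- c(rep("A", 30), rep("B", 10))
  y_pred <- c(rep("A", 30), rep("B", 5), rep("A", 5))
  rep <- aggregate_metrics(per_class_metrics(
    confusion_matrix(y_true, y_pred, c("A", "B"))))
  expect_equal(rep$macro$recall, 0.75)
  expect_equal(rep$weighted$recall, 0.875)
  expect_equal(rep$accuracy, 0.875)

  # equal supports make macro and weighted coincide
  y_true2 <- c(rep("A", 10), rep("B", 10))
  y_pred2 <- c(rep("A", 10), rep("B", 5), rep("A", 5))
  rep2 <- aggregate_metrics(per_class_metrics(
    confusion_matrix(y_true2, y_pred2, c("A", "B"))))
  expect_equal(rep2$macro$recall, rep2$weighted$recall)
  expect_equal(rep2$macro$recall, 0.75)
})

test_that("weighted recall equals accuracy on random confusion matrices", {
  set.seed(99)
  for (k in 1:25) {
    n_cls <- sample(2:6, 1)
    labels <- LETTERS[seq_len(n_cls)]
    y_true <- sample(labels, 200, replace = TRUE, prob = runif(n_cls))
    y_pred <- sample(labels, 200, replace = TRUE)
    rep <- aggregate_metrics(per_class_metrics(
      confusion_matrix(y_true, y_pred, labels)))
    expect_equal(rep$weighted$recall, rep$accuracy, tolerance = 1e-12)
  }
})

test_that("class order permutations leave the aggregates unchanged", {
  set.seed(7)
  labels <- c("A", "B", "C")
  y_true <- sample(labels, 120, replace = TRUE)
  y_pred <- sample(labels, 120, replace = TRUE)
  r1 <- aggregate_metrics(per_class_metrics(
    confusion_matrix(y_true, y_pred, labels)))
  r2 <- aggregate_metrics(per_class_metrics(
    confusion_matrix(y_true, y_pred, rev(labels))))
  expect_equal(r1$macro, r2$macro)
  expect_equal(r1$weighted, r2$weighted)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_true(all(unlist(r1$macro) >= 0 & unlist(r1$macro) <= 1))
})

test_that("metrics agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(41)
  labels <- c("A", "B", "C", "D")
  y_true <- factor(sample(labels, 300, replace = TRUE), labels)
  y_pred <- factor(sample(labels, 300, replace = TRUE), labels)
  ours <- aggregate_metrics(per_class_metrics(
    confusion_matrix(as.character(y_true), as.character(y_pred), labels)))
  ref <- caret::confusionMatrix(y_pred, y_true)
  expect_equal(ours$accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(ours$per_class$recall,
               unname(ref$byClass[, "Sensitivity"]))
  prec <- ifelse(is.na(ref$byClass[, "Precision"]), 0,
                 ref$byClass[, "Precision"])
  expect_equal(ours$per_class$precision, unname(prec))
})

test_that("evaluate_model reports on the validation windows only", {
  m <- toy_model()
  ds <- toy_dataset()
  plan <- split_subject_dependent(ds, 0.3, seed = 42)
  rep <- evaluate_model(m, ds, plan)
  cm <- attr(rep, "confusion")
  expect_equal(sum(cm), length(plan$val_indices))
  expect_gte(rep$macro$f1, 0.95)

  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, f)
  js <- jsonlite::fromJSON(f)
  expect_equal(js$accuracy, rep$accuracy)
})
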