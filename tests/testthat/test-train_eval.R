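test_that("metric formulas reproduce the worked confusion-count cases", {
  m <- metrics_from_counts(9, 8, 1, 2)
  expect_equal(m$accuracy, 17 / 20)
  # precision 0.75, recall 0.6 -> F1 = 2*0.45/1.35
  m2 <- metrics_from_counts(tp = 3, tn = 0, fp = 1, fn = 2)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.6)
  expect_equal(m2$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(m2$f1, 4), 0.6667)
  # degenerate denominators report 0, not NaN
  z <- metrics_from_counts(0, 10, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
})

test_that("evaluation reports confusion-consistent accuracy and perfect scores", {
  truth <- rep(c("a", "b", "c"), each = 4)
  perfect <- eval_report(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$f1, rep(1, 3))
  set.seed(1)
  pred <- sample(c("a", "b", "c"), 12, replace = TRUE)
  rep <- eval_report(truth, pred)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_equal(unname(rowSums(rep$confusion)), unname(table(truth)),
               ignore_attr = TRUE)
  # one-vs-rest counts tile the test set for every class
  expect_equal(rep$per_class$tp + rep$per_class$tn + rep$per_class$fp +
                 rep$per_class$fn, rep(12, 3))
})

test_that("macro F1 is invariant to class label permutation", {
  set.seed(2)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  r1 <- eval_report(truth, pred)
  relab <- c(a = "c", b = "a", c = "b")
  r2 <- eval_report(unname(relab[truth]), unname(relab[pred]))
  expect_equal(r2$macro_f1, r1$macro_f1)
  expect_equal(r2$accuracy, r1$accuracy)
})

test_that("ROC/AUC behaves on separable, random and negated scores", {
  set.seed(3)
  labels <- rep(c("pos", "neg"), each = 50)
  sep <- cbind(pos = c(stats::runif(50, 0.6, 1), stats::runif(50, 0, 0.4)))
  r <- roc_auc(sep, labels, classes = "pos")
  expect_equal(r$pos$auc, 1)
  n <- 4000
  labels2 <- sample(c("pos", "neg"), n, replace = TRUE)
  rnd <- cbind(pos = stats::runif(n))
  expect_lt(abs(roc_auc(rnd, labels2, "pos")$pos$auc - 0.5), 0.05)
  # symmetry: AUC(s) + AUC(-s) = 1
  a1 <- roc_auc(rnd, labels2, "pos")$pos$auc
  a2 <- roc_auc(-rnd, labels2, "pos")$pos$auc
  expect_equal(a1 + a2, 1)
  expect_error(roc_auc(cbind(pos = runif(5)), rep("pos", 5), "pos"),
               "single class")
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  labels <- sample(c("x", "y"), 200, replace = TRUE)
  scores <- cbind(x = stats::rnorm(200) + (labels == "x"),
                  y = stats::rnorm(200))
  ours <- roc_auc(scores, labels)
  for (cls in c("x", "y")) {
    ref <- suppressMessages(
      pROC::auc(pROC::roc(labels == cls, scores[, cls], quiet = TRUE,
                          levels = c(FALSE, TRUE), direction = "<")))
    expect_equal(ours[[cls]]$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("training is seeded, validates class counts, and lr=0 freezes weights", {
  spec <- toy_spec(classes = 3L, widths = c(4L, 4L, 4L, 4L), stem = 4L,
                   blocks = c(1L, 1L, 1L, 1L))
  imgs <- random_images(12, seed = 21)
  set <- leaf_image_set(imgs, rep(c("a", "b", "c"), 4), c("a", "b", "c"))
  hp <- hyperparams(epochs = 2L, batch_size = 4L, learning_rate = 0.01,
                    seed = 31L)
  n1 <- build_model(spec, seed = 1)
  f1 <- train(n1, set, hp)
  n2 <- build_model(spec, seed = 1)
  f2 <- train(n2, set, hp)
  expect_equal(f1$history, f2$history)
  expect_equal(n1$head$W, n2$head$W)
  # zero learning rate: only BN running statistics change
  n3 <- build_model(spec, seed = 1)
  w_before <- n3$stages[[2]][[1]]$conv1$W
  rm_before <- n3$stem$bn$running_mean
  train(n3, set, hyperparams(epochs = 1L, learning_rate = 0,
                             weight_decay = 0, seed = 31L))
  expect_identical(n3$stages[[2]][[1]]$conv1$W, w_before)
  expect_false(identical(n3$stem$bn$running_mean, rm_before))
  bad <- leaf_image_set(imgs, rep(c("a", "b"), 6), c("a", "b"))
  expect_error(train(n1, bad, hp), "classes")
  expect_error(evaluate(n1, leaf_image_set(list(), character(0), "a")),
               "empty")
})

test_that("a short run learns a separable toy problem", {
  # two visually trivial classes: bright vs dark images
  set.seed(5)
  imgs <- c(lapply(1:10, function(i) array(stats::rnorm(32 * 32 * 3, 1, 0.1),
                                           c(32, 32, 3))),
            lapply(1:10, function(i) array(stats::rnorm(32 * 32 * 3, -1, 0.1),
                                           c(32, 32, 3))))
  set <- leaf_image_set(imgs, rep(c("hi", "lo"), each = 10))
  spec <- toy_spec(classes = 2L, widths = c(4L, 6L, 8L, 8L), stem = 4L)
  net <- build_model(spec, seed = 2)
  # enough epochs for the BN running statistics to reach the batch statistics
  fit <- train(net, set, hyperparams(epochs = 12L, batch_size = 4L,
                                     learning_rate = 0.02, seed = 7L))
  expect_gte(fit$history$accuracy[12], 0.95)
  ev <- evaluate(net, set)
  expect_gte(ev$accuracy, 0.95)
  expect_equal(dim(ev$confusion), c(2L, 2L))
})
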