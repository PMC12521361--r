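test_that("majority vote takes the modal label with the stated tie rule", {
  tab <- data.frame(bone_id = "b1", slice_index = c(1, 1, 1, 2, 2),
                    rater_id = c("r1", "r2", "r3", "r1", "r2"),
                    repeat_id = 1L, label = c(1L, 1L, 2L, 0L, 1L))
  expect_warning(mv <- majority_vote(tab), "tie")
  expect_equal(mv$label[mv$slice_index == 1], 1L)
  expect_equal(mv$label[mv$slice_index == 2], 0L)  # tie -> lower code
  expect_true(mv$tie[mv$slice_index == 2])
})

test_that("majority vote equals a per-slice histogram argmax oracle", {
  set.seed(21)
  tab <- expand.grid(bone_id = c("a", "b"), slice_index = 1:40,
                     rater_id = c("r1", "r2", "r3"))
  tab$repeat_id <- 1L
  tab$label <- sample(0:3, nrow(tab), replace = TRUE)
  mv <- suppressWarnings(majority_vote(tab))
  for (i in seq_len(nrow(mv))) {
    votes <- tab$label[tab$bone_id == mv$bone_id[i] &
                         tab$slice_index == mv$slice_index[i]]
    counts <- tabulate(votes + 1L, 4L)
    expect_equal(mv$label[i], which(counts == max(counts))[1] - 1L)
  }
})

test_that("softmax probabilities are normalized and ordered", {
  p <- tibiamorph:::softmax_rows(matrix(c(0, 0, 0, 0), 1))
  expect_equal(as.numeric(p), rep(0.25, 4))
  p2 <- tibiamorph:::softmax_rows(matrix(c(10, 0, 0, 0), 1))
  expect_gt(p2[1], 0.999)
  set.seed(3)
  L <- matrix(rnorm(40, sd = 5), 10, 4)
  expect_equal(rowSums(tibiamorph:::softmax_rows(L)), rep(1, 10),
               tolerance = 1e-9)
})

test_that("training succeeds on separable features and is deterministic", {
  set.seed(12)
  n <- 80
  lab <- rep(0:3, each = n / 4)
  feats <- matrix(rnorm(n * 5, sd = 0.02), n, 5)
  feats[, 1] <- feats[, 1] + lab          # linearly separable direction
  colnames(feats) <- paste0("f", 1:5)
  # a larger step size reaches the separating solution quickly; the default
  # 1e-3 recipe converges to the same solution, just more slowly
  cfg <- train_config(learning_rate = 0.05, epochs = 2000L, seed = 9L)
  clf <- train_classifier(feats, lab, cfg)
  P <- tibiamorph:::softmax_rows(tibiamorph:::classifier_logits(clf, feats))
  expect_equal(max.col(P) - 1L, lab)      # training accuracy 1.0
  clf2 <- train_classifier(feats, lab, cfg)
  expect_identical(clf$weights, clf2$weights)
  expect_error(train_classifier(feats[lab != 2, ], lab[lab != 2], cfg),
               "missing")
})

test_that("bone-level k-fold split partitions bones evenly", {
  bones <- paste0("bone", 1:40)
  folds <- kfold_split(bones, k = 5, seed = 2)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 8))
  expect_setequal(unlist(folds), bones)
  expect_equal(sum(duplicated(unlist(folds))), 0)
  folds7 <- kfold_split(paste0("b", 1:7), k = 5, seed = 1)
  expect_setequal(sort(lengths(folds7)), c(1, 1, 1, 2, 2))
  expect_error(kfold_split(paste0("b", 1:3), k = 5), "exceeds")
})

test_that("classification report reproduces printed-table F1 arithmetic", {
  # growth-plate worked example: precision 0.974, recall 0.943
  expect_equal(round(f1_score(0.974, 0.943), 3), 0.958)
  scores <- read.csv(system.file("extdata", "classification_scores.csv",
                                 package = "tibiamorph"))
  recomputed <- f1_score(scores$precision, scores$recall)
  expect_lte(max(abs(recomputed - scores$f1)), 0.001)
})

test_that("classification report counts match hand-computed confusion", {
  true <- c(rep(0, 10), rep(1, 10))
  pred <- c(rep(0, 8), 1, 1, 0, rep(1, 9))
  rep_ <- classification_report(true, pred)
  expect_equal(unname(rep_$confusion[1:2, 1:2]),
               matrix(c(8, 1, 2, 9), 2))
  pc <- rep_$per_class
  expect_equal(pc$precision[1], 8 / 9)
  expect_equal(pc$recall[1], 0.8)
  expect_true(is.na(pc$recall[3]))  # zero-support class reported absent
  perfect <- classification_report(0:3, 0:3)
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(sum(rep_$confusion), length(true))
})

test_that("F1 lies between precision and recall when both are positive", {
  set.seed(8)
  p <- runif(50, 0.01, 1); r <- runif(50, 0.01, 1)
  f <- f1_score(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("misclassifications concentrate at compartment boundaries", {
  mk <- function(i) phantom_preset(
    "test", seed = 700 + i,
    compartment_heights_mm = c(epiphysis = 0.4 + 0.02 * i,
                               growth_plate = 0.1,
                               primary = 0.2 + 0.02 * i,
                               secondary = 0.85, shaft = 0))
  feats <- NULL; labels <- integer(0)
  for (i in 1:3) {
    sdd <- phantom_slice_data(generate_phantom(mk(i)))
    feats <- rbind(feats, sdd$features)
    labels <- c(labels, sdd$labels)
  }
  clf <- train_classifier(feats, labels, train_config(seed = 5))
  td <- phantom_slice_data(generate_phantom(mk(4)))
  prof <- predict_probabilities(clf, td$features, 0.020)
  pred <- max.col(tibiamorph:::profile_matrix(prof)) - 1L
  tl <- td$truth$true_landmarks
  z <- td$slices_kept * 0.020
  near <- pmin(abs(z - tl$Z_eg), abs(z - tl$Z_gp), abs(z - tl$Z_ps)) <= 0.05
  acc_near <- mean(pred[near] == td$labels[near])
  acc_far <- mean(pred[!near] == td$labels[!near])
  expect_gt(acc_far, acc_near)
  expect_gt(acc_far, 0.9)
})
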