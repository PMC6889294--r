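test_that("stratified splitting preserves class balance and is seed-stable", {
  ts <- simulate_training_set(seed = 3)
  sp <- stratified_split(ts, 62, seed = 5)
  expect_equal(nrow(sp$train), 62)
  expect_equal(nrow(sp$validation), 86)
  expect_equal(sort(c(sp$train$sample_id, sp$validation$sample_id)),
               sort(ts$sample_id))
  full_frac <- mean(ts$label == "CNH")
  expect_lte(abs(sum(sp$train$label == "CNH") - 62 * full_frac), 1)
  expect_lte(abs(sum(sp$validation$label == "CNH") - 86 * full_frac), 1)
  again <- stratified_split(ts, 62, seed = 5)
  expect_identical(sp$train$sample_id, again$train$sample_id)

  tiny <- separable_training_set(4)
  sp4 <- stratified_split(tiny, 2, seed = 1)
  expect_equal(sort(sp4$train$label), c("CNH", "CNL"))
  expect_error(stratified_split(tiny, 1, seed = 1), "class")
})

test_that("mtry tuning maximizes CV accuracy with ties broken downward", {
  ts <- separable_training_set(40)
  one <- tune_mtry(ts, grid = 7, seed = 2, n_trees = 101)
  expect_equal(one$best_mtry, 7)
  # a perfectly separating feature makes every mtry tie at accuracy 1,
  # so the smaller candidate must win
  tied <- tune_mtry(ts, grid = c(3, 9), seed = 2, n_trees = 101)
  expect_equal(tied$trace$cv_accuracy, c(1, 1))
  expect_equal(tied$best_mtry, 3)
})

test_that("a forest on a perfectly separating feature is its oracle", {
  ts <- separable_training_set(40)
  fit <- train_rf(ts, mtry = 12, n_trees = 101, seed = 9)
  expect_equal(fit$oob_accuracy, 1)
  pred <- predict(fit, ts)
  expect_equal(pred$label, ts$label)
  expect_true(all(pred$vote_fraction > 0.9))
  single <- train_rf(ts, mtry = 12, n_trees = 1, seed = 9)
  expect_equal(predict(single, ts)$label, ts$label)
  expect_error(train_rf(dplyr::mutate(ts, label = "CNL"), mtry = 2),
               "Both labels")
})

test_that("training and prediction are reproducible for a fixed seed", {
  ts <- simulate_training_set(n = 80, seed = 4)
  a <- train_rf(ts, mtry = 3, n_trees = 301, seed = 7)
  b <- train_rf(ts, mtry = 3, n_trees = 301, seed = 7)
  expect_identical(predict(a, ts), predict(b, ts))
  expect_identical(gini_importance(a), gini_importance(b))
})

test_that("the Table-3-style metric suite reproduces a known confusion matrix", {
  truth <- rep(c("CNH", "CNH", "CNL", "CNL"), c(31, 1, 1, 48))
  pred <- rep(c("CNH", "CNL", "CNH", "CNL"), c(31, 1, 1, 48))
  m <- performance_metrics(truth, pred)
  expect_equal(m$accuracy, 79 / 81)
  expect_equal(round(m$kappa, 4), 0.9483)
  expect_equal(round(m$sensitivity, 4), 0.9688)
  expect_equal(round(m$specificity, 4), 0.9796)
  expect_equal(round(m$no_information_rate, 4), 0.6049)
  expect_equal(round(m$balanced_accuracy, 4), 0.9742)
  expect_equal(m$mcnemar_p, 1)
  # metric identities
  expect_gte(m$detection_prevalence, m$detection_rate)
  expect_true(m$accuracy >= m$ci_lower && m$accuracy <= m$ci_upper)
  expect_lte(m$kappa, m$accuracy)
})

test_that("the metric suite agrees with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(31)
  truth <- sample(c("CNL", "CNH"), 120, replace = TRUE, prob = c(0.6, 0.4))
  pred <- ifelse(runif(120) < 0.85, truth,
                 ifelse(truth == "CNL", "CNH", "CNL"))
  m <- performance_metrics(truth, pred)
  ref <- caret::confusionMatrix(
    factor(pred, c("CNH", "CNL")), factor(truth, c("CNH", "CNL")),
    positive = "CNH")
  expect_equal(m$accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(m$ci_lower, unname(ref$overall["AccuracyLower"]))
  expect_equal(m$ci_upper, unname(ref$overall["AccuracyUpper"]))
  expect_equal(m$kappa, unname(ref$overall["Kappa"]))
  # the McNemar field is not compared: this suite uses the exact binomial
  # form (needed to reproduce a balanced-discordance p of exactly 1), while
  # the reference implementation uses the corrected asymptotic test
  expect_equal(m$sensitivity, unname(ref$byClass["Sensitivity"]))
  expect_equal(m$specificity, unname(ref$byClass["Specificity"]))
  expect_equal(m$balanced_accuracy, unname(ref$byClass["Balanced Accuracy"]))
})

test_that("degenerate agreement patterns hit the closed-form corners", {
  perfect <- performance_metrics(rep(c("CNH", "CNL"), c(10, 15)),
                                 rep(c("CNH", "CNL"), c(10, 15)))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$mcnemar_p, 1)
  constant <- performance_metrics(rep(c("CNH", "CNL"), c(10, 15)),
                                  rep("CNL", 25))
  expect_equal(constant$accuracy, constant$no_information_rate)
  expect_equal(constant$kappa, 0)
})

test_that("Gini importance scores unused features 0 and ranks the dominant gene first", {
  ts <- separable_training_set(60)  # every non-TP53 feature is constant 0
  fit <- train_rf(ts, mtry = 4, n_trees = 201, seed = 3)
  gi <- gini_importance(fit)
  expect_equal(gi$gene[1], "TP53")
  expect_true(all(gi$gini[gi$gene != "TP53"] == 0))
  expect_equal(nrow(gi), 12)
  expect_true(all(gi$gini >= 0))
  expect_error(gini_importance(list()), "ec_rf")
})

test_that("adding a duplicated pure-noise feature leaves the top gene unchanged", {
  ts <- simulate_training_set(n = 100, seed = 6)
  feats <- gene_panel()$rf_genes
  base <- train_rf(ts, mtry = 3, n_trees = 301, seed = 6)
  top <- gini_importance(base)$gene[1]
  with_noise <- ts
  set.seed(99)
  with_noise$NOISE1 <- rbinom(100, 1, 0.5)
  with_noise$NOISE2 <- with_noise$NOISE1
  refit <- train_rf(with_noise, mtry = 3, n_trees = 301, seed = 6,
                    features = c(feats, "NOISE1", "NOISE2"))
  expect_equal(gini_importance(refit)$gene[1], top)
})

test_that("the published protocol reaches high validation accuracy on one synthetic cohort", {
  ts <- simulate_training_set(seed = 1)
  sp <- stratified_split(ts, 62, seed = 1)
  tuned <- tune_mtry(sp$train, seed = 1)
  fit <- train_rf(sp$train, tuned$best_mtry, seed = 1)
  acc <- mean(predict(fit, sp$validation)$label == sp$validation$label)
  expect_gte(acc, 0.85)
  expect_equal(nrow(tuned$trace), 12)
})
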