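cohort_54 <- function() {
  data.frame(patient_id = sprintf("P%02d", 1:54),
             class_label = rep(c("cancer", "control"), c(22, 32)))
}

test_that("split plan is stratified, exact-sized and reproducible", {
  plan <- make_split_plan(cohort_54(), eval_config(master_seed = 9))
  expect_length(plan$iterations, 10L)
  for (it in plan$iterations) {
    expect_length(it$train, 38L)
    expect_length(it$test, 16L)
    expect_length(intersect(it$train, it$test), 0L)
    expect_setequal(c(it$train, it$test), cohort_54()$patient_id)
    # both classes on both sides
    cl <- cohort_54()
    expect_setequal(unique(cl$class_label[cl$patient_id %in% it$train]),
                    c("cancer", "control"))
    expect_setequal(unique(cl$class_label[cl$patient_id %in% it$test]),
                    c("cancer", "control"))
  }
  expect_identical(make_split_plan(cohort_54(), eval_config(master_seed = 9)),
                   plan)
  expect_false(identical(plan$iterations[[1]]$train,
                         plan$iterations[[2]]$train))

  tiny <- data.frame(patient_id = c("A", "B", "C"),
                     class_label = c("cancer", "control", "control"))
  expect_error(make_split_plan(tiny, eval_config()), "at least 2")
})

test_that("PCA retains the minimal component count for the target", {
  set.seed(4)
  # exactly rank-1 data
  X1 <- outer(rnorm(20), rnorm(30))
  p1 <- fit_pca(X1, 0.95)
  expect_equal(p1$n_components, 1L)
  expect_equal(p1$explained[1], 1.0)

  X <- matrix(rnorm(40 * 15), 40) %*% diag(seq(3, 0.2, length.out = 15))
  p <- fit_pca(X, 0.95)
  expect_gte(sum(p$explained[seq_len(p$n_components)]), 0.95)
  if (p$n_components > 1)
    expect_lt(sum(p$explained[seq_len(p$n_components - 1L)]), 0.95)

  # reconstruction error of retained components <= 5% of total variance
  S <- predict(p, X)
  recon <- S %*% t(p$rotation) + matrix(p$mean, nrow(X), ncol(X),
                                        byrow = TRUE)
  tot <- sum(scale(X, scale = FALSE)^2)
  expect_lte(sum((X - recon)^2) / tot, 0.05 + 1e-12)

  expect_error(fit_pca(matrix(1, 5, 4)), "degenerate")
})

test_that("classifiers separate separable data and are seeded", {
  blobs <- separable_blobs()
  for (kind in c("svm", "knn")) {
    m <- train_classifier(kind, blobs$X, blobs$y, seed = 1)
    pred <- predict(m, blobs$X)
    expect_equal(as.character(pred$class), blobs$y,
                 label = paste(kind, "training accuracy"))
  }
  # kNN with k = 1 memorises any consistent training set
  set.seed(9)
  Xr <- matrix(rnorm(60), 30)
  yr <- rep(c("cancer", "control"), 15)
  m1 <- train_classifier("knn", Xr, yr, hyperparams = list(k = 1))
  expect_equal(as.character(predict(m1, Xr)$class), yr)

  # RF with a fixed seed reproduces its predictions exactly
  ma <- train_classifier("rf", blobs$X, blobs$y, seed = 11)
  mb <- train_classifier("rf", blobs$X, blobs$y, seed = 11)
  expect_identical(predict(ma, blobs$X)$score, predict(mb, blobs$X)$score)

  expect_error(train_classifier("mystery", blobs$X, blobs$y), "unknown")
  expect_error(train_classifier("svm", blobs$X, rep("cancer", 20)),
               "both classes")
})

test_that("cross-validation partitions rows into near-equal stratified folds", {
  set.seed(3)
  X <- matrix(rnorm(200), 100)
  y <- rep(c("cancer", "control"), each = 50)
  fold_id <- local({set.seed(1); plasmavib:::stratified_folds(factor(y), 10)})
  expect_equal(as.numeric(table(fold_id)), rep(10, 10))
  expect_setequal(unique(fold_id), 1:10)

  res <- cross_validate("knn", X, y, folds = 10, seed = 1)
  expect_equal(nrow(res), 10L)
  expect_true(all(res$tp + res$fp + res$tn + res$fn == 10))
  expect_error(cross_validate("knn", X[1:5, ], y[1:5], folds = 10), "folds")
})

test_that("evaluation metrics follow the cancer-positive convention", {
  blobs <- separable_blobs()
  m <- train_classifier("svm", blobs$X, blobs$y, seed = 1)
  perfect <- evaluate_model(m, blobs$X, blobs$y)
  expect_equal(perfect[, c("sensitivity", "specificity", "accuracy", "auc")],
               data.frame(sensitivity = 1, specificity = 1, accuracy = 1,
                          auc = 1))

  # all-control predictions on a balanced test set
  mknn <- train_classifier("knn", matrix(c(0, 0.1, -0.1, 0.05), 4, 2),
                           c("control", "control", "control", "cancer"),
                           hyperparams = list(k = 3))
  far <- matrix(c(0, 0, 0.1, 0.1, -0.1, 0, 0.05, -0.05), 4, 2)
  y_far <- c("cancer", "cancer", "control", "control")
  res <- evaluate_model(mknn, far, y_far)
  expect_equal(res$sensitivity, 0)
  expect_equal(res$specificity, 1)
  expect_equal(res$accuracy, 0.5)

  expect_error(evaluate_model(m, blobs$X, rep("cancer", 20)), "both classes")
})

test_that("rank AUC equals the pairwise oracle and the ROC trapezoid", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(score, pos), auc_pairwise_oracle(score, pos))
    roc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = pos, predictor = score, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(auc_rank(score, pos), roc_auc)
  }
  expect_error(auc_rank(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("metric aggregation produces t-based intervals and CV", {
  v <- c(0.8, 0.85, 0.9, 0.75, 0.8)
  s <- summarize_metric(v, 0.95)
  expect_equal(s$mean, mean(v))
  expect_equal(s$sd, sd(v))
  half <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(c(s$ci_lo, s$ci_hi), mean(v) + c(-half, half))
  expect_equal(s$cv, sd(v) / mean(v))

  degenerate <- summarize_metric(rep(0.8, 6))
  expect_equal(degenerate$sd, 0)
  expect_equal(degenerate$cv, 0)
  expect_equal(degenerate$ci_lo, 0.8)
})

test_that("the supervised study never leaks test patients and is deterministic", {
  st <- synth_study(synth_config(seed = 2), datasets = "raman_wet")
  rw <- preprocess_modality(st$raman_wet, preprocess_params(), "single")
  cfg <- eval_config(n_iterations = 3, compute_cv = TRUE, cv_folds = 5,
                     classifiers = c("svm", "lr"), master_seed = 4)
  study <- run_supervised_study(list(raman = rw), cfg)

  for (it in seq_along(study$plan$iterations)) {
    split <- study$plan$iterations[[it]]
    aud <- study$audit[[it]][["raman"]]
    expect_length(intersect(split$train, split$test), 0L)
    expect_length(intersect(aud$pca_and_train_patients, split$test), 0L)
    expect_setequal(aud$pca_and_train_patients, split$train)
    expect_setequal(aud$test_patients, split$test)
  }
  expect_gte(min(study$metrics$n_components), 1)
  # aggregate mean equals the mean of per-iteration accuracies exactly
  acc <- study$metrics[study$metrics$classifier == "svm", "accuracy"]
  expect_identical(
    study$summary[study$summary$classifier == "svm" &
                    study$summary$metric == "accuracy", "mean"],
    mean(acc))

  study2 <- run_supervised_study(list(raman = rw), cfg)
  expect_identical(study$metrics, study2$metrics)
  expect_identical(study$cv_metrics, study2$cv_metrics)

  # degenerate single-iteration plan: SD and CV collapse to 0
  cfg1 <- eval_config(n_iterations = 1, compute_cv = FALSE,
                      classifiers = "svm", master_seed = 4)
  s1 <- run_supervised_study(list(raman = rw), cfg1)
  expect_equal(unique(s1$summary$sd), 0)
})

test_that("unsupervised PCA scatter: rank-1 data and ellipse coverage", {
  set.seed(6)
  # rank-1 dataset: PC2 scores vanish
  base <- outer(runif(30, 0.5, 1.5), c(1, 2, 3, 2, 1))
  ds <- spectral_dataset(c(1000, 1010, 1020, 1030, 1040), base, data.frame(
    patient_id = sprintf("P%d", 1:30),
    group = rep(c("cancer", "healthy", "pcos"), 10),
    modality = "ftir", hydration = "wet", replicate = 1L))
  sc <- unsupervised_pca_scatter(ds, "3-class")
  expect_lt(max(abs(sc$scores$PC2)), 1e-10)

  # 95% ellipse covers about 95% of a large Gaussian group
  set.seed(8)
  n <- 2000
  X <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 1), rnorm(n, 0, 0.1))
  dsg <- spectral_dataset(c(1, 2, 3), X, data.frame(
    patient_id = sprintf("P%d", 1:n), group = "healthy",
    modality = "ftir", hydration = "wet", replicate = 1L))
  scg <- unsupervised_pca_scatter(dsg, "3-class")
  el <- scg$ellipses$healthy
  R <- matrix(c(cos(el$angle), sin(el$angle),
                -sin(el$angle), cos(el$angle)), 2)
  z <- t(t(R) %*% (t(as.matrix(scg$scores[, 1:2])) - el$center)) %*%
    diag(1 / el$radii)
  coverage <- mean(rowSums(z^2) <= 1)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})
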