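# Supervised evaluation engine: repeated patient-level 70/30 splits, PCA
# retaining 95% variance fitted on training rows only, four classifiers
# with optional stratified 10-fold cross-validation, held-out test metrics,
# and the unsupervised PCA scatter analysis.

#' Evaluation configuration
#'
#' @param train_frac Fraction of patients allocated to training (0.7).
#' @param n_iterations Number of independent random splits (10).
#' @param cv_folds Folds for the training-set cross-validation (10).
#' @param variance_target Cumulative explained-variance fraction the PCA
#'   must retain (0.95).
#' @param classifiers Character subset of `c("svm", "rf", "knn", "lr")`.
#' @param compute_cv Whether to run the training-set cross-validation in
#'   [run_supervised_study()] (the headline metrics always come from the
#'   held-out test patients).
#' @param master_seed Integer seed from which all split and classifier
#'   randomness derives.
#' @param ci_level Confidence level for the t-based summary intervals.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(train_frac = 0.7, n_iterations = 10L, cv_folds = 10L,
                        variance_target = 0.95,
                        classifiers = c("svm", "rf", "knn", "lr"),
                        compute_cv = TRUE, master_seed = 1L,
                        ci_level = 0.95) {
  stopifnot(train_frac > 0, train_frac < 1, n_iterations >= 1, cv_folds >= 2,
            variance_target > 0, variance_target <= 1,
            all(classifiers %in% c("svm", "rf", "knn", "lr")))
  structure(as.list(environment()), class = "eval_config")
}

#' Build a seeded patient-level split plan
#'
#' Each iteration is a class-stratified random partition of the patients
#' with `|train| = round(train_frac * n)` enforced exactly (per-class
#' allocations by largest remainder). The same plan is applied to every
#' dataset in a study so the modalities see identical patient partitions.
#'
#' @param patients Data frame with `patient_id` and `class_label` (one row
#'   per patient).
#' @param cfg An [eval_config()].
#' @return An object of class `split_plan`: list of
#'   `list(train = ids, test = ids)` per iteration.
#' @export
make_split_plan <- function(patients, cfg = eval_config()) {
  patients <- unique(patients[, c("patient_id", "class_label")])
  if (anyDuplicated(patients$patient_id))
    stop("a patient_id appears with conflicting class labels")
  counts <- table(patients$class_label)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need at least 2 patients in each class for stratified splitting")

  n <- nrow(patients)
  n_train <- round(cfg$train_frac * n)
  # largest-remainder apportionment of n_train across classes
  quota <- cfg$train_frac * as.numeric(counts)
  alloc <- floor(quota)
  rem <- n_train - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - alloc, as.numeric(counts), decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  names(alloc) <- names(counts)
  if (any(alloc < 1) || any(alloc >= as.numeric(counts)))
    stop("split leaves a class absent from train or test")

  set.seed(cfg$master_seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_iterations)
  iterations <- lapply(seq_len(cfg$n_iterations), function(i) {
    set.seed(iter_seeds[i])
    train <- unlist(lapply(names(counts), function(cl) {
      ids <- patients$patient_id[patients$class_label == cl]
      sample(ids, alloc[[cl]])
    }))
    list(train = sort(train),
         test = sort(setdiff(patients$patient_id, train)),
         seed = iter_seeds[i])
  })
  structure(list(iterations = iterations, patients = patients,
                 n_train = n_train),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d iterations, %d train / %d test patients\n",
              length(x$iterations), x$n_train,
              nrow(x$patients) - x$n_train))
  invisible(x)
}

#' Fit a PCA retaining a variance target
#'
#' Mean-centred principal component analysis fitted on training rows only;
#' the number of retained components is the smallest k whose cumulative
#' explained-variance fraction reaches `variance_target`.
#'
#' @param X Numeric training matrix (rows = samples).
#' @param variance_target Cumulative explained-variance fraction in (0, 1].
#' @return An object of class `pca_model` with `mean`, `rotation`
#'   (features x k), `explained` (per-component fractions, all components)
#'   and `n_components`.
#' @export
fit_pca <- function(X, variance_target = 0.95) {
  stopifnot(nrow(X) >= 2L, all(is.finite(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total <= 0) stop("zero-variance matrix: PCA is degenerate")
  explained <- pc$sdev^2 / total
  k <- which(cumsum(explained) >= variance_target - 1e-12)[1L]
  structure(list(mean = pc$center, rotation = pc$rotation[, seq_len(k),
                                                          drop = FALSE],
                 explained = explained, n_components = k,
                 variance_target = variance_target),
            class = "pca_model")
}

#' Project rows onto a fitted PCA
#' @param object A `pca_model`.
#' @param newdata Matrix with the same feature count the model was fitted on.
#' @param ... Unused.
#' @return Score matrix, rows x `n_components`.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$mean) %*% object$rotation
}

#' Train one classifier on PCA scores
#'
#' Wraps the four classifier families behind one interface. Defaults:
#' SVM = RBF kernel, cost 1, gamma `1/(n_features * var(X))`;
#' RF = 100 trees, `floor(sqrt(p))` features per split; kNN = k = 5,
#' Euclidean; LR = ridge-penalised logistic regression with penalty
#' `lambda = 1/n`.
#'
#' @param kind One of `"svm"`, `"rf"`, `"knn"`, `"lr"`.
#' @param X Numeric score matrix.
#' @param y Class labels (`"cancer"` / `"control"`).
#' @param hyperparams Optional named list overriding defaults
#'   (`cost`, `gamma`, `ntree`, `mtry`, `k`, `lambda`).
#' @param seed Integer seed for the stochastic learners.
#' @return An object of class `vib_classifier` exposing [predict()] with
#'   hard labels and a continuous cancer score.
#' @export
train_classifier <- function(kind, X, y, hyperparams = list(), seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("control", "cancer"))
  if (length(unique(y)) < 2L || anyNA(y))
    stop("training labels must contain both classes")
  stopifnot(nrow(X) == length(y))
  hp <- function(name, default)
    if (!is.null(hyperparams[[name]])) hyperparams[[name]] else default

  set.seed(seed)
  fit <- switch(kind,
    svm = {
      gamma <- hp("gamma", 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12)))
      e1071::svm(X, y, kernel = "radial", cost = hp("cost", 1),
                 gamma = gamma, scale = FALSE)
    },
    rf = randomForest::randomForest(
      X, y, ntree = hp("ntree", 100L),
      mtry = hp("mtry", max(1L, floor(sqrt(ncol(X)))))),
    knn = list(X = X, y = y, k = hp("k", 5L)),
    lr = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = hp("lambda", 1 / nrow(X))),
    stop("unknown classifier kind: ", kind))
  structure(list(kind = kind, fit = fit, levels = levels(y)),
            class = "vib_classifier")
}

#' Predict classes and cancer scores
#' @param object A `vib_classifier`.
#' @param newdata Score matrix.
#' @param ... Unused.
#' @return List with `class` (factor) and `score` (numeric; larger =
#'   more cancer-like).
#' @export
predict.vib_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(object$kind,
    svm = {
      pred <- stats::predict(object$fit, newdata, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # orient the decision value so larger means cancer
      if (grepl("^cancer", colnames(attr(pred, "decision.values"))[1]))
        score <- dv else score <- -dv
      list(class = pred, score = score)
    },
    rf = {
      prob <- stats::predict(object$fit, newdata, type = "prob")[, "cancer"]
      cls <- factor(ifelse(prob > 0.5, "cancer", "control"),
                    levels = object$levels)
      list(class = cls, score = prob)
    },
    knn = {
      pred <- class::knn(object$fit$X, newdata, object$fit$y,
                         k = object$fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      score <- ifelse(pred == "cancer", win, 1 - win)
      list(class = pred, score = score)
    },
    lr = {
      prob <- drop(stats::predict(object$fit, newdata, type = "response"))
      cls <- factor(ifelse(prob > 0.5, "cancer", "control"),
                    levels = object$levels)
      list(class = cls, score = prob)
    })
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counting one half.
#'
#' @param score Numeric scores (larger = more positive).
#' @param positive Logical, `TRUE` for the positive class.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need both classes present")
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix performance metrics
#'
#' Cancer is the positive class throughout: sensitivity = TP/(TP+FN) among
#' cancers, specificity = TN/(TN+FP) among controls.
#'
#' @param model A `vib_classifier`.
#' @param X_test Score matrix of held-out rows.
#' @param y_test Their class labels (both classes must appear).
#' @return One-row data frame: confusion counts, sensitivity, specificity,
#'   accuracy, AUC.
#' @export
evaluate_model <- function(model, X_test, y_test) {
  y_test <- factor(y_test, levels = c("control", "cancer"))
  if (length(unique(y_test)) < 2L)
    stop("test labels must contain both classes (AUC undefined otherwise)")
  pred <- predict(model, X_test)
  is_pos <- y_test == "cancer"
  called_pos <- pred$class == "cancer"
  tp <- sum(called_pos & is_pos); fn <- sum(!called_pos & is_pos)
  tn <- sum(!called_pos & !is_pos); fp <- sum(called_pos & !is_pos)
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             accuracy = (tp + tn) / length(y_test),
             auc = auc_rank(pred$score, is_pos))
}

# Stratified fold assignment: within each class, rows are shuffled and
# dealt round-robin so fold sizes differ by at most one.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validation of one classifier
#'
#' @param kind Classifier kind (see [train_classifier()]).
#' @param X Score matrix of training rows.
#' @param y Class labels.
#' @param folds Number of folds.
#' @param seed Integer seed (fold assignment and learner randomness).
#' @param hyperparams Passed to [train_classifier()].
#' @return Data frame of per-fold metrics (one row per fold).
#' @export
cross_validate <- function(kind, X, y, folds = 10L, seed = 1L,
                           hyperparams = list()) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("control", "cancer"))
  if (folds > nrow(X)) stop("more folds than rows")
  set.seed(seed)
  fold_id <- stratified_folds(y, folds)
  out <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    m <- train_classifier(kind, X[tr, , drop = FALSE], y[tr], hyperparams,
                          seed = seed + f)
    cbind(fold = f, evaluate_model(m, X[!tr, , drop = FALSE], y[!tr]))
  })
  do.call(rbind, out)
}

#' Aggregate per-iteration metrics
#'
#' Mean, SD, t-based confidence interval
#' (mean +/- t_{1-(1-level)/2, n-1} * SD / sqrt(n)) and coefficient of
#' variation (SD/mean) per metric.
#'
#' @param values Numeric vector of per-iteration metric values.
#' @param ci_level Confidence level.
#' @return One-row data frame with `mean`, `sd`, `ci_lo`, `ci_hi`, `cv`.
#' @export
summarize_metric <- function(values, ci_level = 0.95) {
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  half <- if (n > 1) stats::qt(1 - (1 - ci_level) / 2, n - 1) * s / sqrt(n)
          else 0
  data.frame(mean = m, sd = if (n > 1) s else 0,
             ci_lo = m - half, ci_hi = m + half,
             cv = if (m != 0) (if (n > 1) s else 0) / m else NA_real_)
}

#' Run the repeated patient-level supervised study
#'
#' For each iteration of the split plan and each dataset: select training
#' rows by patient, fit PCA on training rows only, project, train each
#' classifier, evaluate on the held-out test patients' rows, and (optionally)
#' run a stratified cross-validation inside the training set. Test-patient
#' rows never touch the PCA fit, the CV, or classifier training.
#'
#' @param datasets Named list of `spectral_dataset` / `fused_dataset`
#'   objects; all must cover the same patients.
#' @param cfg An [eval_config()].
#' @param plan Optional pre-built [make_split_plan()] (shared across
#'   studies); derived from the common patient list otherwise.
#' @return An object of class `supervised_study` with `$metrics`
#'   (per dataset x classifier x iteration test metrics), `$cv_metrics`
#'   (per-fold training CV metrics, if computed), `$summary` and `$plan`.
#' @export
run_supervised_study <- function(datasets, cfg = eval_config(), plan = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            !is.null(names(datasets)))
  pat_tabs <- lapply(datasets, function(d)
    unique(dataset_samples(d)[, c("patient_id", "class_label")]))
  common <- Reduce(function(a, b) merge(a, b), pat_tabs)
  if (any(vapply(pat_tabs, nrow, 1L) != nrow(common)))
    stop("datasets do not share a common patient list")
  if (is.null(plan)) plan <- make_split_plan(common, cfg)

  metrics <- list(); cv_metrics <- list(); audit <- list()
  for (it in seq_along(plan$iterations)) {
    split <- plan$iterations[[it]]
    audit[[it]] <- list()
    for (dn in names(datasets)) {
      ds <- datasets[[dn]]
      X <- dataset_matrix(ds)
      samples <- dataset_samples(ds)
      tr <- samples$patient_id %in% split$train
      te <- samples$patient_id %in% split$test
      pca <- fit_pca(X[tr, , drop = FALSE], cfg$variance_target)
      Str <- predict(pca, X[tr, , drop = FALSE])
      Ste <- predict(pca, X[te, , drop = FALSE])
      ytr <- samples$class_label[tr]
      yte <- samples$class_label[te]
      # provenance record: exactly which patients' rows entered the PCA fit
      # and classifier training vs the held-out evaluation
      audit[[it]][[dn]] <- list(
        pca_and_train_patients = sort(unique(samples$patient_id[tr])),
        test_patients = sort(unique(samples$patient_id[te])))
      for (kind in cfg$classifiers) {
        seed_k <- (split$seed + match(kind, c("svm", "rf", "knn", "lr"))) %%
          .Machine$integer.max
        model <- train_classifier(kind, Str, ytr, seed = seed_k)
        res <- evaluate_model(model, Ste, yte)
        metrics[[length(metrics) + 1L]] <-
          cbind(dataset = dn, classifier = kind, iteration = it,
                n_components = pca$n_components, res)
        if (cfg$compute_cv) {
          cvres <- cross_validate(kind, Str, ytr,
                                  folds = min(cfg$cv_folds, nrow(Str)),
                                  seed = seed_k)
          cv_metrics[[length(cv_metrics) + 1L]] <-
            cbind(dataset = dn, classifier = kind, iteration = it, cvres)
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  cv_metrics <- if (length(cv_metrics)) do.call(rbind, cv_metrics)

  summ <- do.call(rbind, lapply(split(metrics,
                                      metrics[c("dataset", "classifier")],
                                      drop = TRUE), function(g) {
    do.call(rbind, lapply(c("sensitivity", "specificity", "accuracy", "auc"),
                          function(metric)
      cbind(dataset = g$dataset[1], classifier = g$classifier[1],
            metric = metric, summarize_metric(g[[metric]], cfg$ci_level))))
  }))
  rownames(summ) <- NULL

  structure(list(metrics = metrics, cv_metrics = cv_metrics,
                 summary = summ, plan = plan, config = cfg, audit = audit),
            class = "supervised_study")
}

#' @export
print.supervised_study <- function(x, ...) {
  cat(sprintf("supervised_study: %d datasets x %d classifiers x %d iterations\n",
              length(unique(x$metrics$dataset)),
              length(unique(x$metrics$classifier)),
              max(x$metrics$iteration)))
  acc <- x$summary[x$summary$metric == "accuracy", ]
  acc <- acc[order(acc$dataset, -acc$mean), ]
  for (dn in unique(acc$dataset)) {
    g <- acc[acc$dataset == dn, ]
    cat(sprintf("  %-10s best: %s accuracy %.1f%% (SD %.1f)\n", dn,
                g$classifier[1], 100 * g$mean[1], 100 * g$sd[1]))
  }
  invisible(x)
}

#' @export
summary.supervised_study <- function(object, ...) object$summary

#' Unsupervised PCA scatter with group confidence ellipses
#'
#' PCA is fitted on all rows without labels; PC1/PC2 scores are returned
#' with one 95% normal confidence ellipse per group (mean plus the
#' eigen-decomposition of the group's 2x2 score covariance scaled by the
#' chi-squared(2) quantile).
#'
#' @param ds A pre-processed `spectral_dataset` or `fused_dataset`.
#' @param groups `"2-class"` (cancer vs control) or `"3-class"`
#'   (cancer / healthy / PCOS).
#' @param level Ellipse confidence level.
#' @return An object of class `pca_scatter` with `$scores` (data frame:
#'   PC1, PC2, group) and `$ellipses` (per-group center, axes, angle);
#'   groups with fewer than 3 rows get no ellipse.
#' @export
unsupervised_pca_scatter <- function(ds, groups = c("3-class", "2-class"),
                                     level = 0.95) {
  groups <- match.arg(groups)
  X <- dataset_matrix(ds)
  samples <- dataset_samples(ds)
  lab <- if (groups == "2-class") samples$class_label else samples$group
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(PC1 = sc[, 1], PC2 = sc[, 2], group = lab)

  q <- stats::qchisq(level, df = 2)
  ellipses <- lapply(split(scores[, 1:2], scores$group), function(g) {
    if (nrow(g) < 3L) return(NULL)
    S <- stats::cov(g)
    e <- eigen(S, symmetric = TRUE)
    list(center = colMeans(g),
         radii = sqrt(pmax(e$values, 0) * q),
         angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
  })
  structure(list(scores = scores, ellipses = ellipses,
                 explained = explained[1:2], level = level),
            class = "pca_scatter")
}

#' @export
print.pca_scatter <- function(x, ...) {
  cat(sprintf("pca_scatter: %d points, PC1 %.1f%% / PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * x$explained[1], 100 * x$explained[2]))
  cent <- vapply(split(x$scores[, 1:2], x$scores$group), colMeans, numeric(2))
  for (g in colnames(cent))
    cat(sprintf("  %-8s centroid (%.3g, %.3g)\n", g, cent[1, g], cent[2, g]))
  invisible(x)
}

#' @export
plot.pca_scatter <- function(x, ...) {
  cols <- stats::setNames(
    grDevices::hcl.colors(length(unique(x$scores$group)), "Dark 3"),
    sort(unique(x$scores$group)))
  plot(x$scores$PC1, x$scores$PC2, col = cols[x$scores$group], pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  th <- seq(0, 2 * pi, length.out = 181)
  for (g in names(x$ellipses)) {
    el <- x$ellipses[[g]]
    if (is.null(el)) next
    R <- matrix(c(cos(el$angle), sin(el$angle),
                  -sin(el$angle), cos(el$angle)), 2)
    pts <- t(R %*% rbind(el$radii[1] * cos(th), el$radii[2] * sin(th)) +
               el$center)
    graphics::lines(pts, col = cols[g], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
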