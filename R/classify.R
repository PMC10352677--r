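#' Assemble a classification dataset from window-filtered spectra
#'
#' One feature row per retained window-mean spectrum, labeled by the tray's
#' treatment. Feature columns are the reduced-band wavelengths.
#'
#' @param wf_list List of `window_filter_result`, one per tray.
#' @param labels Character/factor treatment per tray (e.g. "control",
#'   "drought"); recycled if scalar per element is not intended.
#' @param day Optional day index stored with the dataset.
#' @return A `classification_dataset`: `x` (matrix), `y` (factor),
#'   `provenance` (tray and window grid position), `day`, `wavelengths`.
#' @export
build_dataset <- function(wf_list, labels, day = NA_integer_) {
  if (length(labels) != length(wf_list))
    stop("one label per window_filter_result required")
  xs <- list(); ys <- character(0); prov <- list()
  for (i in seq_along(wf_list)) {
    wf <- wf_list[[i]]
    n <- nrow(wf$spectra)
    if (n == 0L) next
    xs[[length(xs) + 1L]] <- wf$spectra
    ys <- c(ys, rep(as.character(labels[i]), n))
    kept <- wf$window_info[wf$window_info$status == "kept", , drop = FALSE]
    prov[[length(prov) + 1L]] <-
      data.frame(tray = i, gy = kept$gy, gx = kept$gx)
  }
  x <- do.call(rbind, xs)
  y <- factor(ys)
  if (nlevels(y) < 2L) stop("single-class dataset: need both classes present")
  if (anyNA(x)) stop("dataset contains missing values")
  structure(
    list(x = x, y = y, day = day,
         provenance = do.call(rbind, prov),
         wavelengths = wf_list[[1L]]$wavelengths),
    class = "classification_dataset")
}

#' @export
print.classification_dataset <- function(x, ...) {
  cat(sprintf("<classification_dataset> %d spectra x %d bands (day %s)\n",
              nrow(x$x), ncol(x$x), x$day))
  print(table(x$y))
  invisible(x)
}

# ---- classifier families ----------------------------------------------------
# Each family exposes: grid (list of hyperparameter settings) and
# fit(x, y, par) -> model with predict_cls(model, x) -> factor and
# predict_score(model, x) -> numeric score for the second class level.

.family_defs <- function(p) {
  list(
    naive_bayes = list(
      grid = list(list()),
      fit = function(x, y, par) e1071::naiveBayes(x, y),
      predict_cls = function(m, x) stats::predict(m, x),
      predict_score = function(m, x)
        stats::predict(m, x, type = "raw")[, 2L]),
    tree = list(
      grid = lapply(c(0.001, 0.01, 0.05), function(cp) list(cp = cp)),
      fit = function(x, y, par) {
        df <- data.frame(y = y, x)
        rpart::rpart(y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = par$cp))
      },
      predict_cls = function(m, x)
        stats::predict(m, data.frame(x), type = "class"),
      predict_score = function(m, x)
        stats::predict(m, data.frame(x), type = "prob")[, 2L]),
    ensemble = list(
      grid = lapply(unique(c(max(1L, floor(sqrt(p))), max(1L, p %/% 3))),
                    function(mt) list(mtry = mt)),
      fit = function(x, y, par)
        randomForest::randomForest(x, y, ntree = 200L, mtry = par$mtry),
      predict_cls = function(m, x) stats::predict(m, x),
      predict_score = function(m, x)
        stats::predict(m, x, type = "prob")[, 2L]),
    knn = list(
      grid = lapply(c(1L, 3L, 5L, 9L, 15L, 25L), function(k) list(k = k)),
      fit = function(x, y, par) list(x = x, y = y, k = par$k),
      predict_cls = function(m, x)
        class::knn(m$x, x, m$y, k = min(m$k, nrow(m$x))),
      predict_score = function(m, x) {
        pr <- class::knn(m$x, x, m$y, k = min(m$k, nrow(m$x)), prob = TRUE)
        p2 <- attr(pr, "prob")
        ifelse(pr == levels(m$y)[2L], p2, 1 - p2)
      }),
    svm = list(
      grid = {
        g <- expand.grid(cost = c(0.1, 1, 10), gamma = c(0.1, 1, 10) / p)
        lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
      },
      fit = function(x, y, par)
        e1071::svm(x, y, cost = par$cost, gamma = par$gamma,
                   kernel = "radial", probability = TRUE),
      predict_cls = function(m, x) stats::predict(m, x),
      predict_score = function(m, x) {
        pr <- stats::predict(m, x, probability = TRUE)
        attr(pr, "probabilities")[, m$levels[2L]]
      }),
    neural_net = list(
      grid = {
        g <- expand.grid(size = c(3L, 8L), decay = c(0.01, 0.1))
        lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
      },
      fit = function(x, y, par) {
        ctr <- colMeans(x); scl <- apply(x, 2L, stats::sd); scl[scl == 0] <- 1
        xs <- scale(x, ctr, scl)
        net <- nnet::nnet(xs, stats::model.matrix(~ y - 1)[, 2L, drop = FALSE],
                          size = par$size, decay = par$decay, maxit = 150L,
                          trace = FALSE, entropy = TRUE,
                          MaxNWts = 50000L)
        list(net = net, ctr = ctr, scl = scl, levels = levels(y))
      },
      predict_cls = function(m, x) {
        s <- stats::predict(m$net, scale(x, m$ctr, m$scl))
        factor(m$levels[1L + (s[, 1L] > 0.5)], levels = m$levels)
      },
      predict_score = function(m, x)
        stats::predict(m$net, scale(x, m$ctr, m$scl))[, 1L]),
    discriminant = list(
      grid = {
        g <- expand.grid(gamma = seq(0, 1, by = 0.1),
                         type = c("linear", "quadratic"),
                         stringsAsFactors = FALSE)
        lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
      },
      fit = function(x, y, par) rda_fit(x, y, gamma = par$gamma,
                                        type = par$type),
      predict_cls = function(m, x) rda_predict(m, x)$class,
      predict_score = function(m, x) rda_predict(m, x)$score))
}

#' List the available classifier families
#' @return Character vector of family names.
#' @export
classifier_families <- function() {
  c("naive_bayes", "tree", "ensemble", "knn", "svm", "neural_net",
    "discriminant")
}

# ---- regularized discriminant analysis --------------------------------------
# Shrinkage toward a scaled identity makes the covariance invertible when the
# band count approaches or exceeds the per-class sample count:
#   Sigma(gamma) = (1 - gamma) * Sigma_hat + gamma * mean(diag(Sigma_hat)) * I
# "linear" pools one covariance across classes; "quadratic" shrinks each
# class's own covariance.

#' Fit a regularized (shrinkage) discriminant classifier
#'
#' @param x Feature matrix; `y` factor with >= 2 levels.
#' @param y Class factor.
#' @param gamma Shrinkage weight in [0, 1] toward the scaled identity.
#' @param type `"linear"` (pooled covariance) or `"quadratic"` (per-class).
#' @return An `rda_model`.
#' @export
rda_fit <- function(x, y, gamma = 0.5, type = c("linear", "quadratic")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  lev <- levels(y)
  means <- lapply(lev, function(l) colMeans(x[y == l, , drop = FALSE]))
  priors <- as.numeric(table(y)[lev]) / length(y)
  shrink <- function(S) {
    (1 - gamma) * S + gamma * mean(diag(S)) * diag(nrow(S))
  }
  if (type == "linear") {
    n <- nrow(x); k <- length(lev)
    Sp <- 0
    for (i in seq_along(lev)) {
      xi <- x[y == lev[i], , drop = FALSE]
      Sp <- Sp + crossprod(sweep(xi, 2L, means[[i]]))
    }
    Sp <- Sp / (n - k)
    Sg <- shrink(Sp)
    ch <- tryCatch(chol(Sg), error = function(e)
      stop("singular covariance at gamma = ", gamma))
    covs <- list(ch)
  } else {
    covs <- lapply(seq_along(lev), function(i) {
      xi <- x[y == lev[i], , drop = FALSE]
      if (nrow(xi) < 2L) stop("quadratic discriminant needs >= 2 per class")
      Sg <- shrink(stats::cov(xi))
      tryCatch(chol(Sg), error = function(e)
        stop("singular class covariance at gamma = ", gamma))
    })
  }
  structure(list(means = means, chols = covs, priors = priors,
                 levels = lev, type = type, gamma = gamma),
            class = "rda_model")
}

#' Predict from a regularized discriminant model
#'
#' @param model An `rda_model`.
#' @param x Feature matrix.
#' @return List: `class` (factor), `score` (log-posterior difference for the
#'   second class level), `posterior` (matrix).
#' @export
rda_predict <- function(model, x) {
  x <- as.matrix(x)
  k <- length(model$levels)
  disc <- matrix(NA_real_, nrow(x), k)
  for (i in seq_len(k)) {
    ch <- if (model$type == "linear") model$chols[[1L]] else model$chols[[i]]
    dx <- sweep(x, 2L, model$means[[i]])
    z <- backsolve(ch, t(dx), transpose = TRUE)   # ch' z = dx'
    maha <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    disc[, i] <- -0.5 * maha - 0.5 * logdet + log(model$priors[i])
  }
  cls <- factor(model$levels[max.col(disc)], levels = model$levels)
  # softmax posteriors, numerically stabilized
  m <- apply(disc, 1L, max)
  ex <- exp(disc - m)
  post <- ex / rowSums(ex)
  colnames(post) <- model$levels
  list(class = cls, score = disc[, 2L] - disc[, 1L], posterior = post)
}

# ---- cross-validation protocol ----------------------------------------------

# Stratified fold assignment: within each class, shuffle and deal into folds.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    if (length(idx) < folds)
      stop("class '", l, "' has fewer members (", length(idx),
           ") than folds (", folds, ")")
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

# Inner hyperparameter selection: k-fold CV over the family's grid on the
# training portion; ties go to the earlier grid entry. Settings that fail to
# fit (e.g. singular covariance at gamma = 0) are skipped.
select_hyperparameters <- function(def, x, y, inner_folds = 5L) {
  if (length(def$grid) == 1L) return(def$grid[[1L]])
  folds <- min(inner_folds, min(table(y)))
  if (folds < 2L) return(def$grid[[1L]])
  assign <- stratified_folds(y, folds)
  errs <- vapply(def$grid, function(par) {
    wrong <- 0L; total <- 0L
    for (f in seq_len(folds)) {
      tr <- assign != f; te <- !tr
      fitted <- tryCatch(def$fit(x[tr, , drop = FALSE], droplevels(y[tr]), par),
                         error = function(e) NULL)
      if (is.null(fitted)) return(Inf)
      pred <- def$predict_cls(fitted, x[te, , drop = FALSE])
      wrong <- wrong + sum(as.character(pred) != as.character(y[te]))
      total <- total + sum(te)
    }
    wrong / total
  }, numeric(1))
  def$grid[[which.min(errs)]]
}

#' Repeated cross-validated evaluation of one classifier family
#'
#' Stratified k-fold cross-validation, re-randomized `repeats` times from the
#' seed. Within each training fold, hyperparameters are selected by an inner
#' k-fold search minimizing classification error with equal misclassification
#' cost. The overall accuracy is the mean of the per-repeat cross-validation
#' accuracies; the confusion matrix and ROC pool the out-of-fold predictions
#' and scores across all repeats.
#'
#' @param ds A `classification_dataset`.
#' @param family One of [classifier_families()].
#' @param folds Number of outer folds (default 5).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed controlling all fold randomization and stochastic
#'   fits.
#' @param optimize Run the inner hyperparameter search (default `TRUE`;
#'   `FALSE` uses the first grid entry).
#' @param fold_assignments Optional list of precomputed fold assignment
#'   vectors (one per repeat), as produced internally; used by
#'   [compare_families()] to share splits across families.
#' @return A `cv_report`.
#' @export
run_cv <- function(ds, family, folds = 5L, repeats = 10L, seed = 1L,
                   optimize = TRUE, fold_assignments = NULL) {
  stopifnot(inherits(ds, "classification_dataset"))
  family <- match.arg(family, classifier_families())
  x <- ds$x; y <- ds$y
  def <- .family_defs(ncol(x))[[family]]
  set.seed(seed)
  if (is.null(fold_assignments))
    fold_assignments <- replicate(repeats, stratified_folds(y, folds),
                                  simplify = FALSE)
  acc_fold <- matrix(NA_real_, repeats, folds)
  repeat_acc <- numeric(repeats)
  pooled_truth <- character(0); pooled_pred <- character(0)
  pooled_score <- numeric(0)
  chosen <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    assign <- fold_assignments[[rep_i]]
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- assign != f; te <- !tr
      xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
      par <- if (optimize) select_hyperparameters(def, xtr, ytr) else
        def$grid[[1L]]
      model <- def$fit(xtr, ytr, par)
      pred <- def$predict_cls(model, x[te, , drop = FALSE])
      score <- def$predict_score(model, x[te, , drop = FALSE])
      hit <- as.character(pred) == as.character(y[te])
      correct <- correct + sum(hit)
      acc_fold[rep_i, f] <- mean(hit)
      pooled_truth <- c(pooled_truth, as.character(y[te]))
      pooled_pred <- c(pooled_pred, as.character(pred))
      pooled_score <- c(pooled_score, score)
      if (f == 1L) chosen[[rep_i]] <- par
    }
    repeat_acc[rep_i] <- correct / length(y)
  }
  lev <- levels(y)
  confusion <- table(truth = factor(pooled_truth, lev),
                     predicted = factor(pooled_pred, lev))
  roc_obj <- pROC::roc(response = factor(pooled_truth, lev),
                       predictor = pooled_score, levels = lev,
                       direction = "<", quiet = TRUE)
  structure(
    list(family = family, folds = folds, repeats = repeats, seed = seed,
         fold_accuracies = acc_fold, repeat_accuracies = repeat_acc,
         overall_accuracy = 100 * mean(repeat_acc),
         confusion = confusion,
         roc = data.frame(fpr = 1 - roc_obj$specificities,
                          tpr = roc_obj$sensitivities),
         auc = as.numeric(pROC::auc(roc_obj)),
         hyperparameters = chosen, n = length(y)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: %.1f%% accuracy (%d-fold x %d repeats, n = %d)\n",
              x$family, x$overall_accuracy, x$folds, x$repeats, x$n))
  cat(sprintf("  AUC %.3f; repeat accuracies %.1f-%.1f%%\n", x$auc,
              100 * min(x$repeat_accuracies), 100 * max(x$repeat_accuracies)))
  print(x$confusion)
  invisible(x)
}

#' Compare classifier families under a common protocol
#'
#' Runs [run_cv()] for each family with identical fold assignments (same
#' seed, same splits) for a paired comparison, and ranks the families by
#' overall accuracy.
#'
#' @param ds A `classification_dataset`.
#' @param families Character vector of families (default all seven).
#' @inheritParams run_cv
#' @return List: `reports` (named list of `cv_report`), `summary` (data
#'   frame ranked by accuracy).
#' @export
compare_families <- function(ds, families = classifier_families(),
                             folds = 5L, repeats = 10L, seed = 1L,
                             optimize = TRUE) {
  set.seed(seed)
  shared <- replicate(repeats, stratified_folds(ds$y, folds),
                      simplify = FALSE)
  reports <- lapply(families, function(fam)
    run_cv(ds, fam, folds = folds, repeats = repeats, seed = seed,
           optimize = optimize, fold_assignments = shared))
  names(reports) <- families
  summary <- data.frame(
    family = families,
    accuracy = vapply(reports, function(r) r$overall_accuracy, numeric(1)),
    auc = vapply(reports, function(r) r$auc, numeric(1)))
  summary <- summary[order(-summary$accuracy), ]
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}
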