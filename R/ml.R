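# The evaluation protocol: label construction, leakage-safe preprocessing
# (min-max fitted on training folds only), SVM-SMOTE oversampling, greedy
# forward feature selection with inner CV, grid search over XGB/RF
# hyperparameters, repeated stratified 5-fold CV with top-5 ensembling,
# cross-dataset testing, the four metrics, calibration and the DeLong test.

# ---- label construction ----------------------------------------------------

#' Binarize overall-survival times at the per-dataset median
#'
#' Label 1 (long-term survivor) iff time >= median of the known times in the
#' subject's dataset; subjects exactly at the median are long-term (fixed,
#' balance-preserving tie rule). Unknown times give NA and are counted in a
#' message.
#'
#' @param times Numeric survival durations (any consistent unit); NA = unknown.
#' @param dataset Optional grouping vector; the median is taken per dataset.
#' @return Integer vector of 0/1 labels with NA for unknown times.
#' @export
binarize_os <- function(times, dataset = NULL) {
  if (is.null(dataset)) dataset <- rep("all", length(times))
  known <- !is.na(times)
  if (sum(known) < 2) stop("need at least 2 known survival times")
  out <- rep(NA_integer_, length(times))
  for (d in unique(dataset)) {
    sel <- dataset == d & known
    if (!any(sel)) next
    out[sel] <- as.integer(times[sel] >= median(times[sel]))
  }
  if (any(!known))
    message(sum(!known), " subject(s) with unknown survival time excluded")
  out
}

#' Binarize IDH mutation status: wildtype against the rest
#'
#' Wildtype maps to 1; mutated, NOS/NEC and negative are grouped into the
#' "rest" class 0; unknown is excluded (NA) with a message.
#'
#' @param statuses Character vector drawn from wildtype / mutated / NOS/NEC /
#'   negative / unknown (case-insensitive).
#' @return Integer 0/1 labels with NA for unknown.
#' @export
binarize_idh <- function(statuses) {
  s <- tolower(trimws(statuses))
  vocab <- c("wildtype", "mutated", "nos/nec", "negative", "unknown")
  bad <- setdiff(unique(s), vocab)
  if (length(bad))
    stop("unrecognized IDH status value(s): ", paste(bad, collapse = ", "))
  out <- ifelse(s == "wildtype", 1L, ifelse(s == "unknown", NA_integer_, 0L))
  if (anyNA(out))
    message(sum(is.na(out)), " subject(s) with unknown IDH status excluded")
  out
}

# ---- preprocessing ---------------------------------------------------------

#' Fit min-max normalization on training features
#'
#' @param X Numeric matrix or data.frame of training features (>= 2 rows).
#' @return A `preprocess_state` storing per-feature min and max. Constant
#'   training columns are flagged and map to 0 everywhere.
#' @export
minmax_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("min-max fit requires at least 2 rows")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs <= mins,
                 features = colnames(X)),
            class = "preprocess_state")
}

#' Apply a fitted min-max normalization
#'
#' Training columns map to `[0, 1]`; applied data may exceed that range and
#' is deliberately not clipped (the stored transform is used unchanged).
#'
#' @param state A [minmax_fit()] result.
#' @param X Features with the same columns the state was fitted on.
#' @return Scaled matrix.
#' @export
minmax_apply <- function(state, X) {
  X <- as.matrix(X)[, state$features, drop = FALSE]
  out <- sweep(sweep(X, 2, state$min), 2,
               ifelse(state$constant, 1, state$max - state$min), `/`)
  out[, state$constant] <- 0
  out
}

#' Invert a min-max normalization (for non-constant columns)
#' @inheritParams minmax_apply
#' @return Matrix on the original scale.
#' @export
minmax_invert <- function(state, X) {
  X <- as.matrix(X)[, state$features, drop = FALSE]
  sweep(sweep(X, 2, ifelse(state$constant, 1, state$max - state$min), `*`),
        2, state$min, `+`)
}

#' SVM-SMOTE minority oversampling
#'
#' Oversamples the minority class to parity by interpolating between
#' borderline minority samples, identified as the minority-class support
#' vectors of an SVM decision boundary, and their nearest minority
#' neighbours. Every synthetic row is a convex combination of two real
#' minority rows. Already-balanced input is returned unchanged.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels (both classes present, minority count >= 2).
#' @param seed Integer seed.
#' @param k Number of nearest minority neighbours considered.
#' @return List with oversampled `X` and `y`.
#' @export
svm_smote <- function(X, y, seed = 1, k = 5) {
  X <- as.matrix(X)
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  minority <- as.integer(names(which.min(tab)))
  need <- abs(diff(as.integer(tab)))
  min_idx <- which(y == minority)
  if (length(min_idx) < 2)
    stop("minority class has fewer than 2 samples; cannot oversample")
  sv_min <- tryCatch({
    fit <- e1071::svm(x = X, y = factor(y), kernel = "radial", cost = 1,
                      scale = FALSE)
    intersect(fit$index, min_idx)
  }, error = function(e) integer(0))
  if (!length(sv_min)) sv_min <- min_idx
  synth <- with_stream(seed, "svm_smote", {
    rows <- matrix(NA_real_, need, ncol(X))
    for (i in seq_len(need)) {
      a <- sv_min[((i - 1) %% length(sv_min)) + 1]
      others <- setdiff(min_idx, a)
      d <- colSums((t(X[others, , drop = FALSE]) - X[a, ])^2)
      nb <- others[order(d)[seq_len(min(k, length(others)))]]
      b <- nb[sample.int(length(nb), 1)]
      g <- runif(1)
      rows[i, ] <- X[a, ] + g * (X[b, ] - X[a, ])
    }
    rows
  })
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth), y = c(y, rep(minority, need)))
}

# ---- models ----------------------------------------------------------------

#' Define a classifier configuration
#'
#' @param family "xgb" (gradient-boosted trees) or "rf" (random forest).
#' @param ... Hyperparameters: for xgb `nrounds`, `max_depth`, `eta`; for rf
#'   `num.trees`, `min.node.size`, `mtry`.
#' @return A `model_config` list.
#' @export
model_config <- function(family = c("xgb", "rf"), ...) {
  family <- match.arg(family)
  structure(list(family = family, params = list(...)),
            class = "model_config")
}

.fit_model <- function(config, X, y, seed = 1) {
  X <- as.matrix(X)
  p <- config$params
  if (config$family == "xgb") {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    max_depth = p$max_depth %||% 3, eta = p$eta %||% 0.3,
                    seed = seed),
      data = dtrain, nrounds = p$nrounds %||% 50, verbose = 0)
  } else {
    fit <- ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.threads = 1, seed = seed,
      num.trees = p$num.trees %||% 100,
      min.node.size = p$min.node.size %||% 5,
      mtry = p$mtry)
  }
  list(config = config, fit = fit, features = colnames(X))
}

.predict_model <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  if (model$config$family == "xgb")
    as.numeric(predict(model$fit, xgboost::xgb.DMatrix(X)))
  else
    as.numeric(predict(model$fit, as.data.frame(X),
                       num.threads = 1)$predictions[, "1"])
}

.make_folds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  folds <- integer(n)
  with_stream(seed, "folds", {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else folds[sample.int(n)] <- rep_len(seq_len(k), n)
    folds
  })
}

.inner_cv_auroc <- function(config, X, y, k = 3, seed = 1) {
  folds <- .make_folds(y, k, seed)
  scores <- numeric(0); labs <- integer(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    m <- .fit_model(config, X[tr, , drop = FALSE], y[tr], seed = seed + f)
    scores <- c(scores, .predict_model(m, X[!tr, , drop = FALSE]))
    labs <- c(labs, y[!tr])
  }
  if (length(unique(labs)) < 2) return(NA_real_)
  .auroc(scores, labs)
}

# Mann-Whitney AUROC with ties counted 1/2 (midrank formulation)
.auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- selection and tuning --------------------------------------------------

#' Greedy forward feature selection scored by inner-CV AUROC
#'
#' At each step the feature whose addition maximizes inner cross-validated
#' AUROC of `config` is added; selection stops at `cap` features or as soon
#' as no addition strictly improves the score. Ties break toward the lower
#' column index.
#'
#' @param X Feature matrix (training fold only).
#' @param y 0/1 labels.
#' @param config A [model_config()].
#' @param cap Maximum number of features selected (>= 1).
#' @param inner_folds Inner CV fold count.
#' @param seed Integer seed.
#' @return Character vector of selected feature names, in selection order.
#' @export
forward_select <- function(X, y, config, cap, inner_folds = 3, seed = 1) {
  if (cap < 1) stop("cap must be >= 1")
  X <- as.matrix(X)
  selected <- character(0)
  best <- -Inf
  remaining <- colnames(X)
  while (length(selected) < cap && length(remaining)) {
    cand_scores <- vapply(remaining, function(f) {
      s <- .inner_cv_auroc(config, X[, c(selected, f), drop = FALSE], y,
                           k = inner_folds, seed = seed)
      if (is.na(s)) -Inf else s
    }, numeric(1))
    j <- which.max(cand_scores)  # first max: lower column index wins ties
    if (cand_scores[j] <= best + 1e-9) break
    best <- cand_scores[j]
    selected <- c(selected, remaining[j])
    remaining <- remaining[-j]
  }
  selected
}

#' Default hyperparameter grid over both model families
#' @return List of [model_config()] objects.
#' @export
default_model_grid <- function() {
  c(lapply(seq_len(4), function(i) {
    g <- expand.grid(nrounds = c(50, 100), max_depth = c(2, 4))
    model_config("xgb", nrounds = g$nrounds[i], max_depth = g$max_depth[i],
                 eta = 0.3)
  }),
  lapply(seq_len(4), function(i) {
    g <- expand.grid(num.trees = c(100, 300), min.node.size = c(1, 5))
    model_config("rf", num.trees = g$num.trees[i],
                 min.node.size = g$min.node.size[i])
  }))
}

#' Grid search: rank configurations by inner-CV AUROC
#'
#' @param grid List of [model_config()] objects (non-empty).
#' @param table Feature table (data.frame with a `label` column).
#' @param inner_folds CV folds used for scoring.
#' @param seed Integer seed (ranking is deterministic given it).
#' @return The grid reordered by descending score, with the scores attached
#'   as attribute `scores`; take the first five entries for the ensemble.
#' @export
grid_search <- function(grid, table, inner_folds = 3, seed = 1) {
  if (!length(grid)) stop("empty hyperparameter grid")
  xy <- .split_table(table)
  scores <- vapply(seq_along(grid), function(i)
    .inner_cv_auroc(grid[[i]], xy$X, xy$y, k = inner_folds,
                    seed = seed + i), numeric(1))
  ord <- order(scores, decreasing = TRUE)
  out <- grid[ord]
  attr(out, "scores") <- scores[ord]
  out
}

.split_table <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  drop <- intersect(c("subject_id", "label", "dataset"), names(table))
  X <- as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
  if (anyNA(X) || anyNA(table$label)) stop("feature table contains NA")
  list(X = X, y = as.integer(table$label))
}

# ---- the CV harness --------------------------------------------------------

#' Define a repeated cross-validation plan
#'
#' @param n_repeats Number of CV repetitions (default 10).
#' @param k Folds per repetition (default 5).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @param stratified Preserve the label ratio within each fold (+/- 1).
#' @return A `cv_plan` object.
#' @export
cv_plan <- function(n_repeats = 10, k = 5, seed = 1, stratified = TRUE) {
  structure(list(n_repeats = n_repeats, k = k, seed = seed,
                 repeat_seeds = vapply(seq_len(n_repeats), function(r)
                   stream_seed(seed, paste0("repeat_", r)), integer(1)),
                 stratified = stratified),
            class = "cv_plan")
}

#' Repeated stratified k-fold cross-validation of a model ensemble
#'
#' For every repeat x fold x model: min-max scaling, SVM-SMOTE and forward
#' feature selection are fitted on the training folds only, the model is
#' trained, and the held-out fold is scored. With the default plan and five
#' configurations this yields 10 x 5 x 5 = 250 observations, reported
#' per-observation and as mean +/- sd.
#'
#' @param table Feature table: data.frame with feature columns and a 0/1
#'   `label` column (optionally `subject_id`, `dataset`).
#' @param plan A [cv_plan()].
#' @param configs List of [model_config()] objects (the ensemble members).
#' @param ffs_cap Forward-selection cap; `Inf` disables selection.
#' @param smote Apply SVM-SMOTE inside each training fold.
#' @param inner_folds Inner CV folds for forward selection.
#' @param threshold Classification threshold for accuracy / sensitivity /
#'   specificity.
#' @return A `metrics_report`: list with `observations` (one row per
#'   repeat/fold/model), `summary` (mean and sd of the four metrics) and
#'   `count`.
#' @export
repeated_cv <- function(table, plan, configs, ffs_cap = 10, smote = TRUE,
                        inner_folds = 3, threshold = 0.5) {
  stopifnot(inherits(plan, "cv_plan"))
  xy <- .split_table(table)
  obs <- list()
  for (r in seq_len(plan$n_repeats)) {
    folds <- .make_folds(xy$y, plan$k, plan$repeat_seeds[r], plan$stratified)
    for (f in seq_len(plan$k)) {
      tr <- folds != f
      if (length(unique(xy$y[!tr])) < 2 || length(unique(xy$y[tr])) < 2)
        stop(sprintf("repeat %d fold %d is missing a class; %s", r, f,
                     "stratification failed for this cohort"))
      seed_rf <- stream_seed(plan$seed, sprintf("r%df%d", r, f))
      prep <- .fit_fold(xy$X[tr, , drop = FALSE], xy$y[tr], configs,
                        ffs_cap, smote, inner_folds, seed_rf)
      for (m in seq_along(configs)) {
        sc <- .predict_member(prep$members[[m]], xy$X[!tr, , drop = FALSE])
        met <- evaluate_scores(sc, xy$y[!tr], threshold)
        obs[[length(obs) + 1]] <- data.frame(
          rep = r, fold = f, model = m, t(met))
      }
    }
  }
  observations <- do.call(rbind, obs)
  .metrics_report(observations)
}

# Fit preprocessing + all ensemble members on one training set.
.fit_fold <- function(Xtr, ytr, configs, ffs_cap, smote, inner_folds, seed) {
  state <- minmax_fit(Xtr)
  Xs <- minmax_apply(state, Xtr)
  ys <- ytr
  if (smote && length(unique(ytr)) == 2 &&
      min(table(ytr)) >= 2 && diff(range(table(ytr))) > 0) {
    res <- svm_smote(Xs, ytr, seed = seed)
    Xs <- res$X; ys <- res$y
  }
  members <- lapply(seq_along(configs), function(m) {
    sel <- if (is.finite(ffs_cap))
      forward_select(Xs, ys, configs[[m]], cap = ffs_cap,
                     inner_folds = inner_folds, seed = seed + m)
    else colnames(Xs)
    if (!length(sel)) sel <- colnames(Xs)[1]
    fit <- .fit_model(configs[[m]], Xs[, sel, drop = FALSE], ys,
                      seed = seed + m)
    list(state = state, selected = sel, model = fit)
  })
  list(members = members, state = state)
}

.predict_member <- function(member, X) {
  Xs <- minmax_apply(member$state, X)
  .predict_model(member$model, Xs[, member$selected, drop = FALSE])
}

.metrics_report <- function(observations) {
  met <- c("auroc", "accuracy", "sensitivity", "specificity")
  summary <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(observations[[m]]), numeric(1)),
    sd = vapply(met, function(m) stats::sd(observations[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(observations = observations, summary = summary,
                 count = nrow(observations)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report over", x$count, "observation(s):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %.3f ± %.3f\n", x$summary$metric[i],
                x$summary$mean[i],
                if (is.na(x$summary$sd[i])) 0 else x$summary$sd[i]))
  invisible(x)
}

# ---- ensembling and external testing ---------------------------------------

#' Train the final frozen ensemble on a full cohort
#'
#' Fits min-max scaling, SVM-SMOTE and per-member forward selection on the
#' whole training cohort, then the five member models. The returned object
#' carries every transformation parameter needed to score external data
#' without refitting.
#'
#' @inheritParams repeated_cv
#' @param seed Integer seed.
#' @return A `trained_ensemble`.
#' @export
train_ensemble <- function(table, configs, ffs_cap = 10, smote = TRUE,
                           inner_folds = 3, seed = 1) {
  xy <- .split_table(table)
  prep <- .fit_fold(xy$X, xy$y, configs, ffs_cap, smote, inner_folds,
                    stream_seed(seed, "ensemble"))
  structure(list(members = prep$members, features = colnames(xy$X),
                 n_models = length(configs)),
            class = "trained_ensemble")
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat("trained_ensemble of", x$n_models, "model(s) over",
      length(x$features), "features\n")
  for (m in seq_along(x$members))
    cat(sprintf("  model %d (%s): %d feature(s) selected\n", m,
                x$members[[m]]$model$config$family,
                length(x$members[[m]]$selected)))
  invisible(x)
}

#' Ensemble prediction: unweighted mean of member probabilities
#'
#' @param ensemble A [train_ensemble()] result.
#' @param X Feature matrix or data.frame covering the training features.
#' @return Per-subject probability of class 1.
#' @export
ensemble_predict <- function(ensemble, X) {
  missing <- setdiff(ensemble$features, colnames(X))
  if (length(missing))
    stop("feature manifest mismatch; missing column(s): ",
         paste(missing, collapse = ", "))
  X <- as.matrix(X)[, ensemble$features, drop = FALSE]
  probs <- vapply(ensemble$members, function(m) .predict_member(m, X),
                  numeric(nrow(X)))
  rowMeans(as.matrix(probs))
}

#' @export
predict.trained_ensemble <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    drop <- intersect(c("subject_id", "label", "dataset"), names(newdata))
    newdata <- newdata[, setdiff(names(newdata), drop), drop = FALSE]
  }
  ensemble_predict(object, newdata)
}

#' Evaluate a frozen ensemble on an external cohort
#'
#' Applies the stored preprocessing and models to cohort B without any
#' refitting; no ensemble parameter changes during evaluation.
#'
#' @param ensemble A [train_ensemble()] result (from cohort A).
#' @param table External feature table with the same feature manifest.
#' @param threshold Classification threshold.
#' @return A `metrics_report` for the ensemble prediction, with per-member
#'   metrics attached as attribute `member_observations`.
#' @export
cross_dataset_eval <- function(ensemble, table, threshold = 0.5) {
  xy <- .split_table(table)
  missing <- setdiff(ensemble$features, colnames(xy$X))
  if (length(missing))
    stop("feature manifest mismatch; missing column(s): ",
         paste(missing, collapse = ", "))
  scores <- ensemble_predict(ensemble, xy$X)
  member_obs <- do.call(rbind, lapply(seq_along(ensemble$members),
    function(m) {
      sc <- .predict_member(ensemble$members[[m]], xy$X)
      data.frame(model = m, t(evaluate_scores(sc, xy$y, threshold)))
    }))
  rep <- .metrics_report(data.frame(rep = 1, fold = 1, model = 0,
                                    t(evaluate_scores(scores, xy$y,
                                                      threshold))))
  attr(rep, "member_observations") <- member_obs
  rep
}

# ---- metrics ---------------------------------------------------------------

#' AUROC, accuracy, sensitivity and specificity
#'
#' AUROC is the Mann-Whitney probability with ties counted one half;
#' accuracy, sensitivity (class-1 recall) and specificity are computed at
#' the stated threshold (predicted positive iff score >= threshold).
#'
#' @param scores Predicted probabilities or scores.
#' @param labels 0/1 labels (both classes required).
#' @param threshold Classification threshold (default 0.5).
#' @return Named numeric vector of the four metrics.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  auc <- .auroc(scores, labels)
  pred <- as.integer(scores >= threshold)
  pos <- labels == 1
  c(auroc = auc,
    accuracy = mean(pred == labels),
    sensitivity = if (any(pos)) mean(pred[pos] == 1) else NA_real_,
    specificity = if (any(!pos)) mean(pred[!pos] == 0) else NA_real_)
}

#' Calibration curve: observed event frequency per predicted-probability bin
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param n_bins Number of equal-width bins on `[0, 1]` (>= 2).
#' @return Data.frame with one row per non-empty bin: `bin`, `mean_score`,
#'   `observed`, `count`; counts sum to `length(scores)`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(pmin(pmax(scores, 0), 1), breaks, include.lowest = TRUE,
             labels = FALSE)
  keep <- sort(unique(bin))
  data.frame(bin = keep,
             mean_score = vapply(keep, function(b) mean(scores[bin == b]),
                                 numeric(1)),
             observed = vapply(keep, function(b) mean(labels[bin == b]),
                               numeric(1)),
             count = vapply(keep, function(b) sum(bin == b), numeric(1)))
}

#' DeLong test for two correlated AUROCs
#'
#' Placement-value (structural component) estimate of the covariance of the
#' two paired AUROC estimators; z = difference / sqrt(var), two-sided normal
#' p-value. Identical scores give variance 0 and p = 1 by convention.
#'
#' @param scores_a,scores_b Paired scores of the two classifiers on the same
#'   subjects.
#' @param labels 0/1 labels (both classes present, >= 2 subjects each).
#' @return A `delong_result`: `auc1`, `auc2`, `difference`, `variance`, `z`,
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  if (m < 2 || n < 2)
    stop("DeLong test requires at least 2 subjects in each class")
  placements <- function(s) {
    psi <- outer(s[pos], s[neg],
                 function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(1 - pa$v01, 1 - pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc1 = pa$auc, auc2 = pb$auc, difference = d,
                 variance = v, z = z, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(paste0("DeLong paired AUROC test: %.4f vs %.4f ",
                     "(diff %+.4f), z = %.3f, p = %.4g\n"),
              x$auc1, x$auc2, x$difference, x$z, x$p_value))
  invisible(x)
}
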