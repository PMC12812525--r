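# Label construction, leakage-safe preprocessing, SMOTE, selection, the CV
# harness, ensembling, metrics, calibration and the DeLong test.

test_that("survival binarization uses a median split with ties long-term", {
  expect_identical(binarize_os(c(10, 20, 30, 40)), c(0L, 0L, 1L, 1L))
  expect_identical(binarize_os(c(1, 2, 3)), c(0L, 1L, 1L))
  expect_message(out <- binarize_os(c(5, NA, 10, 20)), "excluded")
  expect_identical(out, c(0L, NA, 1L, 1L))
  # per-dataset medians
  two <- binarize_os(c(1, 2, 100, 200), dataset = c("a", "a", "b", "b"))
  expect_identical(two, c(0L, 1L, 0L, 1L))
  expect_error(binarize_os(c(NA, NA)), "at least 2")
  # near-balance across seeds when times are distinct
  for (s in 1:5) {
    set.seed(s)
    lab <- binarize_os(sample(1000, 101))
    expect_lte(abs(sum(lab == 1) - sum(lab == 0)), 1)
  }
})

test_that("IDH binarization groups wildtype against the rest", {
  expect_identical(binarize_idh(c("wildtype", "mutated")), c(1L, 0L))
  expect_identical(binarize_idh(c("NOS/NEC", "negative")), c(0L, 0L))
  expect_message(out <- binarize_idh(c("wildtype", "unknown")), "excluded")
  expect_identical(out, c(1L, NA))
  expect_error(binarize_idh("sometimes"), "unrecognized")
})

test_that("min-max scaling: train mapping, unclipped transfer, round trip", {
  X <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  st <- minmax_fit(X)
  expect_equal(unname(minmax_apply(st, X)[, "a"]), c(0, 0.5, 1))
  expect_true(all(minmax_apply(st, X)[, "b"] == 0))  # constant column
  expect_equal(unname(minmax_apply(st, cbind(a = 8, b = 1))[, "a"]), 1.5)
  set.seed(3)
  Xr <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  str <- minmax_fit(Xr)
  expect_equal(minmax_invert(str, minmax_apply(str, Xr)), Xr,
               tolerance = 1e-12)
  expect_error(minmax_fit(Xr[1, , drop = FALSE]), "at least 2")
})

test_that("svm-smote reaches parity with convex-combination synthetics", {
  tab <- make_ml_cohort(90, 8, 0, 2, 1.5, class_balance = 1 / 3, seed = 5)
  X <- as.matrix(tab[, grep("spatial", names(tab))])
  y <- tab$label
  res <- svm_smote(X, y, seed = 2)
  expect_identical(sum(res$y == 0), sum(res$y == 1))
  expect_identical(res$X[seq_len(nrow(X)), ], X)  # originals untouched
  synth <- res$X[-seq_len(nrow(X)), , drop = FALSE]
  minX <- X[y == 1, ]
  for (i in seq_len(nrow(synth))) {
    on_segment <- FALSE
    for (a in seq_len(nrow(minX))) {
      d2 <- synth[i, ] - minX[a, ]
      for (b in seq_len(nrow(minX))[-a]) {
        d1 <- minX[b, ] - minX[a, ]
        g <- sum(d1 * d2) / sum(d1^2)
        if (g >= -1e-9 && g <= 1 + 1e-9 &&
            max(abs(d2 - g * d1)) < 1e-8) { on_segment <- TRUE; break }
      }
      if (on_segment) break
    }
    expect_true(on_segment)
  }
  # balanced input is a no-op; tiny minorities are rejected
  bal <- svm_smote(X[1:20, ], rep(0:1, 10), seed = 1)
  expect_identical(bal$X, X[1:20, ])
  expect_error(svm_smote(X, c(1, rep(0, nrow(X) - 1)), seed = 1),
               "fewer than 2")
  # determinism
  res2 <- svm_smote(X, y, seed = 2)
  expect_identical(res$X, res2$X)
})

test_that("forward selection finds planted signal and respects its cap", {
  tab <- make_ml_cohort(150, 8, 4, 1, 3, seed = 9)
  planted <- attr(tab, "informative")
  X <- as.matrix(tab[, setdiff(names(tab), c("subject_id", "label"))])
  y <- tab$label
  cfg <- model_config("xgb", nrounds = 20, max_depth = 2)
  sel <- forward_select(X, y, cfg, cap = 5, seed = 2)
  expect_identical(sel[1], planted)
  expect_lte(length(sel), 5)

  # cap 1 equals the brute-force best single feature
  sel1 <- forward_select(X, y, cfg, cap = 1, seed = 7)
  brute <- vapply(colnames(X), function(f)
    gliomap:::.inner_cv_auroc(cfg, X[, f, drop = FALSE], y, k = 3, seed = 7),
    numeric(1))
  expect_identical(sel1, names(brute)[which.max(brute)])
  expect_error(forward_select(X, y, cfg, cap = 0), "cap")
})

test_that("forward selection usually stops early on pure noise", {
  cfg <- model_config("xgb", nrounds = 15, max_depth = 2)
  short <- 0
  for (s in 1:5) {
    tab <- make_ml_cohort(80, 6, 0, 1, 0, seed = 100 + s)
    X <- as.matrix(tab[, grep("spatial", names(tab))])
    sel <- forward_select(X, tab$label, cfg, cap = 6, seed = s)
    if (length(sel) < 6) short <- short + 1
  }
  expect_gte(short, 3)  # majority of seeds stop before the cap
})

test_that("grid search ranks configurations sensibly and deterministically", {
  tab <- make_ml_cohort(120, 8, 0, 3, 3, seed = 12)
  single <- grid_search(list(model_config("rf", num.trees = 50)), tab,
                        seed = 1)
  expect_length(single, 1)

  grid <- list(model_config("xgb", nrounds = 1, max_depth = 1, eta = 0.01),
               model_config("rf", num.trees = 100),
               model_config("xgb", nrounds = 40, max_depth = 3))
  ranked <- grid_search(grid, tab, seed = 4)
  # the one-stump near-zero-eta config never ranks first on separable data
  expect_false(identical(ranked[[1]]$params$nrounds, 1))
  ranked2 <- grid_search(grid, tab, seed = 4)
  expect_identical(attr(ranked, "scores"), attr(ranked2, "scores"))
  expect_error(grid_search(list(), tab), "empty")
})

test_that("repeated CV emits n_repeats x k x n_models observations", {
  tab <- make_ml_cohort(60, 6, 0, 2, 2, seed = 31)
  configs <- list(model_config("xgb", nrounds = 10, max_depth = 2),
                  model_config("rf", num.trees = 30))
  plan <- cv_plan(n_repeats = 2, k = 3, seed = 5)
  rep1 <- repeated_cv(tab, plan, configs, ffs_cap = 2)
  expect_identical(rep1$count, 2L * 3L * 2L)
  expect_true(all(rep1$observations$auroc >= 0 &
                    rep1$observations$auroc <= 1))
  # aggregate mean is recomputable from the per-observation rows
  expect_equal(rep1$summary$mean[rep1$summary$metric == "auroc"],
               mean(rep1$observations$auroc))
  rep2 <- repeated_cv(tab, plan, configs, ffs_cap = 2)
  expect_identical(rep1$observations, rep2$observations)  # determinism
})

test_that("stratified folds preserve the label ratio within one subject", {
  y <- rep(c(0L, 1L), c(70, 30))
  folds <- gliomap:::.make_folds(y, 5, seed = 3)
  for (f in 1:5) {
    expect_lte(abs(sum(y[folds == f] == 1) - 6), 1)
    expect_lte(abs(sum(y[folds == f] == 0) - 14), 1)
  }
})

test_that("label-copy feature gives AUROC 1; validation-only copy gives 0.5", {
  set.seed(41)
  n <- 120
  y <- rep(0:1, each = n / 2)[sample(n)]
  noise <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
  plan <- cv_plan(n_repeats = 1, k = 5, seed = 13)
  cfg <- list(model_config("xgb", nrounds = 20, max_depth = 2))

  leak_all <- cbind(noise, sentinel = as.numeric(y))
  tab1 <- data.frame(leak_all, label = y)
  rep1 <- repeated_cv(tab1, plan, cfg, ffs_cap = 2)
  expect_gte(rep1$summary$mean[rep1$summary$metric == "auroc"], 0.99)

  # sentinel equals the label only on one fold's rows: when that fold is
  # held out, a leak-free pipeline never saw the informative values while
  # fitting, so its AUROC there stays near chance
  folds <- gliomap:::.make_folds(y, 5, plan$repeat_seeds[1], TRUE)
  sentinel <- rnorm(n)
  sentinel[folds == 1] <- y[folds == 1]
  tab2 <- data.frame(noise, sentinel = sentinel, label = y)
  rep2 <- repeated_cv(tab2, plan, cfg, ffs_cap = 2)
  auc_f1 <- rep2$observations$auroc[rep2$observations$fold == 1]
  expect_lt(abs(auc_f1 - 0.5), 0.25)
  auc <- rep2$summary$mean[rep2$summary$metric == "auroc"]
  expect_lt(abs(auc - 0.5), 0.15)
})

test_that("ensemble prediction is the unweighted probability mean", {
  tab <- make_ml_cohort(80, 6, 0, 2, 2, seed = 17)
  cfgs <- list(model_config("xgb", nrounds = 20, max_depth = 2),
               model_config("xgb", nrounds = 20, max_depth = 2))
  ens <- train_ensemble(tab, cfgs, ffs_cap = 2, seed = 3)
  X <- as.matrix(tab[, grep("spatial", names(tab))])
  p <- ensemble_predict(ens, X)
  p1 <- gliomap:::.predict_member(ens$members[[1]], X)
  p2 <- gliomap:::.predict_member(ens$members[[2]], X)
  expect_equal(p, (p1 + p2) / 2, tolerance = 1e-12)
  # identical member configurations fit identically: ensemble = single model
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("cross-dataset evaluation freezes the ensemble", {
  tabA <- make_ml_cohort(100, 8, 0, 3, 2.5, seed = 19)
  cfgs <- list(model_config("xgb", nrounds = 25, max_depth = 2),
               model_config("rf", num.trees = 60))
  ens <- train_ensemble(tabA, cfgs, ffs_cap = 3, seed = 4)
  before <- serialize(ens$members[[2]]$state, NULL)
  repA <- cross_dataset_eval(ens, tabA)
  expect_identical(serialize(ens$members[[2]]$state, NULL), before)
  # in-sample consistency: external eval on A equals direct scoring on A
  sc <- ensemble_predict(ens, as.matrix(tabA[, grep("spatial|radiomic",
                                                    names(tabA))]))
  expect_equal(repA$observations$auroc,
               unname(evaluate_scores(sc, tabA$label)["auroc"]))
  # planted scale shift degrades external performance vs the no-shift control
  tabB <- make_ml_cohort(100, 8, 0, 3, 2.5, seed = 19)
  shift <- tabB
  fcols <- grep("spatial", names(shift))
  shift[fcols] <- shift[fcols] * 2
  auc_ctrl <- cross_dataset_eval(ens, tabB)$observations$auroc
  auc_shift <- cross_dataset_eval(ens, shift)$observations$auroc
  expect_lte(auc_shift, auc_ctrl + 0.02)
  missing <- tabA[, -grep("spatial_01", names(tabA))]
  expect_error(cross_dataset_eval(ens, missing), "spatial_01")
})

test_that("AUROC equals the brute-force pairwise count", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.5)
  y <- c(1, 1, 0, 1, 0, 0)
  met <- evaluate_scores(s, y)
  pairs <- 0; wins <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    pairs <- pairs + 1
    wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(unname(met["auroc"]), wins / pairs, tolerance = 1e-12)
  expect_equal(unname(evaluate_scores(c(1, 1, 0, 0), c(1, 1, 0, 0))["auroc"]),
               1.0)
  expect_equal(unname(evaluate_scores(rep(0.4, 6),
                                      rep(0:1, 3))["auroc"]), 0.5)
  expect_error(evaluate_scores(1:4, rep(1, 4)), "single-class")
})

test_that("calibration curve conserves counts and tracks true frequencies", {
  set.seed(51)
  p <- runif(4000)
  ylab <- rbinom(4000, 1, p)
  cc <- calibration_curve(p, ylab, n_bins = 10)
  expect_equal(sum(cc$count), 4000)
  expect_lt(max(abs(cc$observed - cc$mean_score)), 0.08)
  one <- calibration_curve(rep(0.55, 20), rbinom(20, 1, 0.5), n_bins = 5)
  expect_identical(nrow(one), 1L)
  expect_error(calibration_curve(p, ylab, n_bins = 1), "n_bins")
})

test_that("DeLong test matches a placement-value oracle and pROC", {
  set.seed(61)
  y <- rep(c(1, 0), each = 4)
  a <- c(0.9, 0.8, 0.6, 0.55, 0.7, 0.5, 0.4, 0.3)
  b <- c(0.85, 0.6, 0.65, 0.5, 0.75, 0.45, 0.55, 0.35)
  res <- delong_test(a, b, y)

  # independent oracle: explicit psi loops
  oracle <- function(s) {
    pos <- which(y == 1); neg <- which(y == 0)
    v10 <- numeric(length(pos)); v01 <- numeric(length(neg))
    for (i in seq_along(pos)) {
      acc <- 0
      for (j in seq_along(neg))
        acc <- acc + (s[pos[i]] > s[neg[j]]) + 0.5 * (s[pos[i]] == s[neg[j]])
      v10[i] <- acc / length(neg)
    }
    for (j in seq_along(neg)) {
      acc <- 0
      for (i in seq_along(pos))
        acc <- acc + (s[pos[i]] > s[neg[j]]) + 0.5 * (s[pos[i]] == s[neg[j]])
      v01[j] <- acc / length(pos)
    }
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  oa <- oracle(a); ob <- oracle(b)
  var_or <- (var(oa$v10) + var(ob$v10) - 2 * cov(oa$v10, ob$v10)) / 4 +
    (var(oa$v01) + var(ob$v01) - 2 * cov(oa$v01, ob$v01)) / 4
  expect_equal(res$auc1, oa$auc, tolerance = 1e-12)
  expect_equal(res$variance, var_or, tolerance = 1e-12)

  # antisymmetry and the identical-classifier convention
  swap <- delong_test(b, a, y)
  expect_equal(swap$difference, -res$difference, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-12)
  same <- delong_test(a, a, y)
  expect_identical(same$p_value, 1)
  expect_identical(same$difference, 0)

  skip_if_not_installed("pROC")
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                       pROC::roc(y, b, quiet = TRUE), method = "delong",
                       paired = TRUE)
  expect_equal(res$p_value, as.numeric(pr$p.value), tolerance = 1e-9)
})

test_that("DeLong AUROC agrees with the Mann-Whitney AUROC to 1e-12", {
  set.seed(71)
  y <- rep(0:1, each = 30)
  s1 <- y + rnorm(60)
  s2 <- y + rnorm(60, sd = 2)
  res <- delong_test(s1, s2, y)
  expect_equal(res$auc1, unname(evaluate_scores(s1, y)["auroc"]),
               tolerance = 1e-12)
  expect_equal(res$auc2, unname(evaluate_scores(s2, y)["auroc"]),
               tolerance = 1e-12)
})
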