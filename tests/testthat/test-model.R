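# Separable two-group feature matrix with nuisance noise columns.
toy_data <- function(n_per = 30, shift = 10, p_noise = 8, seed = 1,
                     windows_per_subject = 1) {
  set.seed(seed)
  n <- 2 * n_per * windows_per_subject
  subj <- rep(seq_len(2 * n_per), each = windows_per_subject)
  y <- factor(rep(c("control", "task"), each = n_per * windows_per_subject),
              levels = c("control", "task"))
  x <- cbind(sig = stats::rnorm(n) + ifelse(y == "task", shift, 0),
             matrix(stats::rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(x = x, y = y, subjects = subj)
}

test_that("ANOVA selection keeps separated features, drops identical ones", {
  d <- toy_data(n_per = 45, shift = 10)
  x <- cbind(d$x, same = rep(1, nrow(d$x)))
  sel <- anova_select(x, d$y)
  expect_true("sig" %in% sel$keep)
  expect_false("same" %in% sel$keep)
  expect_equal(unname(sel$f["same"]), 0)
  # closed-form F for a 10-sigma shift is astronomically significant
  expect_gt(unname(sel$f["sig"]), stats::qf(1 - 1e-12, 1, 88))

  expect_error(anova_select(x[1:3, ], droplevels(d$y[1:3])), "at least 2")
  xs <- matrix(stats::rnorm(20), 10, dimnames = list(NULL, c("a", "b")))
  yy <- factor(rep(c("control", "task"), 5))
  expect_error(anova_select(xs, yy, alpha = 1e-12), "alpha")
})

test_that("selection on exchangeable groups stays near the nominal level", {
  set.seed(10)
  rates <- replicate(30, {
    x <- matrix(stats::rnorm(60 * 40), 60,
                dimnames = list(NULL, paste0("f", 1:40)))
    y <- factor(rep(c("control", "task"), each = 30))
    sel <- anova_select(x, y, on_empty = "silent")
    length(sel$keep) / ncol(x)
  })
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.09)
})

test_that("grid enumeration preserves declared order and all combinations", {
  g <- list(a = c(1, 2), b = list(NULL, "x"))
  combos <- physiowork:::expand_grid_spec(g)
  expect_equal(length(combos), 4)
  expect_equal(combos[[1]], list(a = 1, b = NULL))
  expect_equal(combos[[2]], list(a = 2, b = NULL))
  expect_equal(vapply(grid_stage1(), function(s)
    length(physiowork:::expand_grid_spec(s)), numeric(1)),
    c(RF = 4 * 6, SVC = 2 * 6 * 5, MLP = 2 * 2 * 5 * 5 * 2))
})

test_that("cross-validation separates an obvious signal with any classifier", {
  d <- toy_data(n_per = 30, shift = 10)
  for (cl in c("RF", "SVC", "MLP")) {
    ev <- cross_validate(d$x, d$y, d$subjects, cl, grid_reduced(), k = 10)
    expect_equal(ev$mean_accuracy, 1.0, info = cl)
    expect_equal(length(ev$fold_accuracy), 10)
    expect_true(all(ev$fold_accuracy >= 0 & ev$fold_accuracy <= 1))
    expect_equal(ev$mean_accuracy, mean(ev$fold_accuracy))
    expect_equal(ev$sd_accuracy, stats::sd(ev$fold_accuracy))
  }
  expect_error(cross_validate(d$x[1:6, ], d$y[1:6], d$subjects[1:6],
                              "RF", grid_reduced(), k = 10),
               "fewer")
})

test_that("cross-validation is deterministic under a fixed seed", {
  d <- toy_data(n_per = 20, shift = 1)
  a <- cross_validate(d$x, d$y, d$subjects, "RF", grid_reduced(), seed = 7)
  b <- cross_validate(d$x, d$y, d$subjects, "RF", grid_reduced(), seed = 7)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_identical(a$best_params, b$best_params)
})

test_that("folds partition rows exactly once and respect subject grouping", {
  d <- toy_data(n_per = 15, windows_per_subject = 3)
  fold <- physiowork:::make_folds(d$y, d$subjects, k = 10,
                                  grouping = "subject", seed = 2)
  expect_equal(length(fold), length(d$y))
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(sum(table(fold)), length(d$y))
  # all windows of one subject share a fold
  expect_true(all(tapply(fold, d$subjects, function(f)
    length(unique(f))) == 1))
  # row-level folds are class-stratified
  fr <- physiowork:::make_folds(d$y, d$subjects, k = 5, grouping = "row",
                                seed = 2)
  per_fold <- table(fr, d$y)
  expect_true(all(abs(per_fold[, 1] - per_fold[, 2]) <= 1))
})

test_that("permuted labels score at chance level", {
  set.seed(77)
  accs <- vapply(1:5, function(i) {
    d <- toy_data(n_per = 30, shift = 0, seed = 100 + i)
    cross_validate(d$x, d$y, d$subjects, "SVC", grid_reduced(),
                   seed = i)$mean_accuracy
  }, numeric(1))
  # 95% binomial interval around 0.5 for 60 samples, averaged over runs
  expect_lt(abs(mean(accs) - 0.5), 2 * sqrt(0.25 / 60) / sqrt(5) * 3)
})

test_that("coarse screening returns a subset grid containing the best", {
  d <- toy_data(n_per = 30, shift = 10)
  g1 <- list(SVC = list(kernel = "linear", C = c(2e-3, 2e-1, 2e1)))
  red <- coarse_grid_search(d$x, d$y, d$subjects, g1, classifiers = "SVC",
                            seed = 3)
  expect_true(all(unlist(red$SVC$C) %in% g1$SVC$C))
  expect_gte(length(red$SVC$C), 1)
  scr <- attr(red, "screening")
  expect_equal(nrow(scr), 3)
  # separable data: every retained candidate is within the margin of best
  expect_true(all(scr$accuracy[scr$accuracy >= max(scr$accuracy) - 0.02] >=
                  max(scr$accuracy) - 0.02))
  # a one-point grid comes back unchanged
  red1 <- coarse_grid_search(d$x, d$y, d$subjects,
                             list(RF = grid_reduced()$RF),
                             classifiers = "RF", seed = 3)
  expect_equal(red1$RF$n_estimators, list(300))
})

test_that("design evaluation produces one row per cell", {
  tabs <- local({
    set.seed(42)
    cat <- indicator_catalog()
    n_subj <- 12
    rows <- list(); base <- list()
    for (id in seq_len(n_subj)) {
      cond <- ifelse(id %% 2 == 1, "task", "control")
      v <- stats::rnorm(61) + (cond == "task") * 1.5
      rows[[id]] <- data.frame(subject_id = id, condition = cond, level = 1,
                               window = 1,
                               as.list(stats::setNames(v, cat$name)),
                               check.names = FALSE)
      base[[id]] <- data.frame(subject_id = id,
                               as.list(stats::setNames(stats::rnorm(61),
                                                       cat$name)),
                               check.names = FALSE)
    }
    list(windows = do.call(rbind, rows), baseline = do.call(rbind, base))
  })
  res <- evaluate_design(tabs, levels = 1, classifiers = c("RF", "SVC"),
                         grid = grid_reduced(), k = 4)
  expect_equal(nrow(res), 7 * 1 * 2)
  expect_true(all(res$mean_accuracy >= 0 & res$mean_accuracy <= 1))
  expect_equal(length(attr(res, "folds")), 14)
  expect_true(all(vapply(attr(res, "folds"), length, numeric(1)) == 4))
})

test_that("results reporting formats mean (SD) tables", {
  res <- data.frame(selection = c("EDA", "EDA", "ECG"), level = c(1, 1, 1),
                    classifier = c("RF", "SVC", "RF"),
                    mean_accuracy = c(0.9481, 0.91, 0.88),
                    sd_accuracy = c(0.0491, 0.02, 0.05))
  rep <- report_results(res)
  expect_equal(rep$by_selection$best_accuracy[rep$by_selection$selection == "EDA"],
               "0.95 (0.05)")
  expect_equal(nrow(rep$by_level), 1)
  expect_message(empty <- report_results(data.frame()), "no results")
  expect_equal(nrow(empty$by_selection), 0)
})

test_that("pooled-mode validation uses global selection and row folds", {
  d <- toy_data(n_per = 20, shift = 3, windows_per_subject = 2)
  a <- cross_validate(d$x, d$y, d$subjects, "SVC", grid_reduced(),
                      k = 5, pooled_mode = TRUE, seed = 4)
  b <- cross_validate(d$x, d$y, d$subjects, "SVC", grid_reduced(),
                      k = 5, pooled_mode = TRUE, seed = 4)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_gt(a$mean_accuracy, 0.8)
})

test_that("pipeline reruns with the same seed write identical results", {
  tabs <- local({
    set.seed(14)
    cat61 <- indicator_catalog()
    rows <- list(); base <- list()
    for (id in 1:10) {
      cond <- ifelse(id %% 2 == 1, "task", "control")
      rows[[id]] <- data.frame(subject_id = id, condition = cond, level = 1,
                               window = 1,
                               as.list(stats::setNames(
                                 stats::rnorm(61) + (cond == "task"),
                                 cat61$name)), check.names = FALSE)
      base[[id]] <- data.frame(subject_id = id,
                               as.list(stats::setNames(stats::rnorm(61),
                                                       cat61$name)),
                               check.names = FALSE)
    }
    list(windows = do.call(rbind, rows), baseline = do.call(rbind, base))
  })
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(dataset = tabs, levels = 1, selections = all_selections()["EDA"],
               classifiers = "RF", grid = grid_reduced(), out_dir = d1,
               k = 5, seed = 3)
  run_pipeline(dataset = tabs, levels = 1, selections = all_selections()["EDA"],
               classifiers = "RF", grid = grid_reduced(), out_dir = d2,
               k = 5, seed = 3)
  f1 <- file.path(d1, "evaluation.csv"); f2 <- file.path(d2, "evaluation.csv")
  expect_identical(readLines(f1), readLines(f2))
})
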