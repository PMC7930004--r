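#' Hyperparameter grids
#'
#' `grid_stage1()` is the wide first-pass grid (random forests: tree count
#' and depth; support-vector classifier: linear and RBF kernels over decade
#' steps of C and gamma; multi-layer perceptron: solver, iteration cap, L2
#' penalty, hidden width, init seed). `grid_stage2()` is the refined grid
#' used inside the final cross-validated evaluation. `grid_reduced()` is a
#' minimal one-point-per-classifier grid for quick evaluations and
#' large-cohort runs.
#'
#' A grid is a named list (RF/SVC/MLP) of named candidate-value lists; all
#' combinations are enumerated in declared order and ties in mean accuracy
#' are broken by enumeration order. The MLP is fitted by quasi-Newton
#' (BFGS) optimisation whatever the `solver` label requests.
#'
#' @return Named list of per-classifier hyperparameter candidate lists.
#' @export
grid_stage1 <- function() {
  list(
    RF = list(n_estimators = c(10, 507, 1005, 2000),
              max_depth = list(NULL, 10, 57, 105, 152, 200),
              max_features = "sqrt"),
    SVC = list(kernel = c("linear", "RBF"),
               C = c(2e-3, 2e-1, 2e1, 2e7, 2e9, 2e11),
               gamma = c(2e-13, 2e-12, 2e-11, 2e-10, 2e-9)),
    MLP = list(solver = c("lbfgs", "adam"),
               max_iter = c(500, 1500),
               alpha = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
               hidden = c(32, 64, 128, 256, 512),
               random_state = c(0, 42)))
}

#' @rdname grid_stage1
#' @export
grid_stage2 <- function() {
  list(
    RF = list(n_estimators = c(10, 257, 505, 752, 1000),
              max_depth = list(NULL, 10, 40, 70, 100),
              max_features = "sqrt"),
    SVC = list(kernel = "linear",
               C = c(2e-3, 2e-2, 2e-1, 2e0, 2e1, 2e2, 2e3, 2e4, 2e5, 2e6, 2e7)),
    MLP = list(solver = "lbfgs",
               max_iter = 2000,
               alpha = c(1e-3, 1e-2, 1e-1, 1),
               hidden = c(32, 64, 128, 256),
               random_state = 42))
}

#' @rdname grid_stage1
#' @export
grid_reduced <- function() {
  list(
    RF = list(n_estimators = 300, max_depth = list(NULL),
              max_features = "sqrt"),
    SVC = list(kernel = "linear", C = 1),
    MLP = list(solver = "lbfgs", max_iter = 500, alpha = 1e-2, hidden = 32,
               random_state = 42))
}

# Enumerate all combinations of one classifier's candidate lists, preserving
# declared order (first parameter varies slowest).
expand_grid_spec <- function(spec) {
  spec <- lapply(spec, function(v) if (is.list(v)) v else as.list(v))
  lens <- vapply(spec, length, integer(1))
  idx <- matrix(1L, nrow = 1)
  for (k in seq_along(spec)) {
    prev <- idx
    idx <- do.call(rbind, lapply(seq_len(lens[k]), function(j)
      cbind(prev, j)))
  }
  idx <- idx[, -1, drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) {
    stats::setNames(lapply(seq_along(spec), function(k)
      spec[[k]][[idx[r, k]]]), names(spec))
  })
}

#' Per-feature one-way ANOVA selection
#'
#' Runs an independent one-way ANOVA of each feature across the two
#' condition groups and keeps features with p below `alpha`. Features with
#' missing values use listwise deletion; zero-variance features get F = 0
#' and are never selected.
#'
#' @param x Feature matrix.
#' @param y Two-level factor.
#' @param alpha Significance level (default 0.05).
#' @param on_empty What to do when no feature is selected: `"error"`
#'   (default, advising a larger alpha) or `"silent"` (return an empty
#'   selection, used inside cross-validation folds where the caller falls
#'   back to majority-class prediction).
#' @return List with `keep` (selected column names), `f`, `p` (named
#'   vectors). Errors when fewer than 2 samples per group.
#' @export
anova_select <- function(x, y, alpha = 0.05,
                         on_empty = c("error", "silent")) {
  on_empty <- match.arg(on_empty)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2 || min(table(y)) < 2)
    stop("need two groups with at least 2 samples each", call. = FALSE)
  x <- as.matrix(x)
  # vectorised two-group one-way ANOVA with per-feature listwise deletion
  g2 <- y == levels(y)[2]
  ok <- is.finite(x)
  x0 <- x; x0[!ok] <- 0
  n1 <- colSums(ok & !g2); n2 <- colSums(ok & g2)
  s1 <- colSums(x0 * !g2); s2 <- colSums(x0 * g2)
  n <- n1 + n2
  m <- (s1 + s2) / n
  # centre each column on its overall finite mean before forming sums of
  # squares (guards against catastrophic cancellation)
  xc <- sweep(x0, 2, m, "-"); xc[!ok] <- 0
  s1c <- colSums(xc * !g2); s2c <- colSums(xc * g2)
  q1 <- colSums(xc^2 * !g2); q2 <- colSums(xc^2 * g2)
  m1 <- s1c / n1; m2 <- s2c / n2
  ssb <- n1 * m1^2 + n2 * m2^2
  ssw <- pmax((q1 - n1 * m1^2) + (q2 - n2 * m2^2), 0)
  fv <- ifelse(ssw > 0, ssb / (ssw / (n - 2)),
               ifelse(ssb > 0, Inf, 0))
  pv <- ifelse(ssw > 0, stats::pf(fv, 1, n - 2, lower.tail = FALSE),
               ifelse(ssb > 0, 0, 1))
  # features with fewer than 2 finite values in either group are excluded
  bad <- n1 < 2 | n2 < 2
  fv[bad] <- 0; pv[bad] <- 1
  names(fv) <- names(pv) <- colnames(x)
  keep <- names(pv)[pv < alpha]
  if (length(keep) == 0 && on_empty == "error")
    stop("no feature reached p < ", alpha, "; consider increasing alpha",
         call. = FALSE)
  list(keep = keep, f = fv, p = pv)
}

# Median imputation learned on training rows; all-NA columns fall back to 0.
impute_median <- function(x, fit_rows) {
  med <- apply(x[fit_rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  n_imp <- 0
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) { x[bad, j] <- med[j]; n_imp <- n_imp + sum(bad) }
  }
  attr(x, "n_imputed") <- n_imp
  x
}

# Fit one classifier; x is a numeric matrix, y a two-level factor.
fit_classifier <- function(x, y, classifier, params) {
  switch(classifier,
    RF = {
      depth <- params$max_depth
      ranger::ranger(
        x = x, y = y,
        num.trees = params$n_estimators,
        mtry = max(floor(sqrt(ncol(x))), 1),
        max.depth = if (is.null(depth)) 0 else depth,
        min.node.size = 2,
        seed = 42, num.threads = 1)
    },
    SVC = e1071::svm(
      x = x, y = y, type = "C-classification",
      kernel = if (identical(params$kernel, "RBF")) "radial" else "linear",
      cost = params$C,
      gamma = if (!is.null(params$gamma)) params$gamma else 1 / ncol(x),
      scale = FALSE),
    MLP = {
      set.seed(params$random_state)
      nnet::nnet(x = x, y = stats::model.matrix(~ y - 1),
                 size = params$hidden, decay = params$alpha,
                 maxit = params$max_iter, softmax = TRUE,
                 MaxNWts = 100000, trace = FALSE)
    },
    stop("unknown classifier: ", classifier, call. = FALSE))
}

predict_classifier <- function(fit, classifier, x, levels_y) {
  switch(classifier,
    RF = stats::predict(fit, data = x, num.threads = 1)$predictions,
    SVC = stats::predict(fit, x),
    MLP = factor(levels_y[max.col(stats::predict(fit, x))],
                 levels = levels_y))
}

# Stratified fold assignment. grouping = "subject": all rows of a subject
# share a fold, subjects stratified by class; "row": plain row-level
# stratification.
make_folds <- function(y, subjects, k, grouping = c("subject", "row"),
                       seed = 1) {
  grouping <- match.arg(grouping)
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (grouping == "subject") {
    us <- unique(subjects)
    if (length(us) < k)
      stop("fewer subjects than folds", call. = FALSE)
    scls <- vapply(us, function(s) as.character(y[match(s, subjects)]),
                   character(1))
    f_of_subj <- stats::setNames(integer(length(us)), us)
    nxt <- 0
    for (cl in unique(scls)) {
      ss <- sample(us[scls == cl])
      f_of_subj[as.character(ss)] <- (seq_along(ss) + nxt - 1) %% k + 1
      nxt <- nxt + length(ss)
    }
    fold <- f_of_subj[as.character(subjects)]
  } else {
    if (n < k) stop("fewer samples than folds", call. = FALSE)
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      fold[rows] <- (seq_along(rows) - 1) %% k + 1
    }
  }
  unname(fold)
}

#' Cross-validated, ANOVA-selected classification
#'
#' For every hyperparameter set of `grid[[classifier]]`, one full k-fold
#' pass is performed over the same folds, and the set with the best mean
#' accuracy is reported (ties break in enumeration order). By default folds
#' are stratified by class with all windows of a subject kept in a single
#' fold, feature selection is re-fit on each training fold, missing
#' indicator values are imputed by the training-fold median, and min-max
#' scaling (fitted on the training fold) is applied for the scale-sensitive
#' classifiers (SVC, MLP). `pooled_mode = TRUE` instead selects features once
#' on the full dataset, fits the scaling on all rows and uses row-level
#' folds.
#'
#' When a training fold selects no feature, the fold falls back to
#' predicting its majority class.
#'
#' @param x Feature matrix.
#' @param y Two-level factor (control/task).
#' @param subjects Subject identifier per row (for grouped folding).
#' @param classifier `"RF"`, `"SVC"` or `"MLP"`.
#' @param grid Hyperparameter grid (named list, see [grid_stage2()]).
#' @param k Number of folds.
#' @param grouping `"subject"` or `"row"`.
#' @param alpha ANOVA selection level.
#' @param pooled_mode Use global selection/scaling and row-level folds.
#' @param seed Fold-assignment seed.
#' @return List of class `pw_eval`: `classifier`, `best_params`,
#'   `fold_accuracy` (k values), `mean_accuracy`, `sd_accuracy`,
#'   `selected` (features selected on the full data, for reporting),
#'   `n_selected_mean` (mean per-fold selection size).
#' @export
cross_validate <- function(x, y, subjects = seq_len(nrow(x)),
                           classifier = "RF", grid = grid_reduced(), k = 10,
                           grouping = c("subject", "row"), alpha = 0.05,
                           pooled_mode = FALSE, seed = 1) {
  grouping <- match.arg(grouping)
  if (pooled_mode) grouping <- "row"
  y <- droplevels(factor(y))
  if (nrow(x) < k) stop("fewer samples than folds", call. = FALSE)
  fold <- make_folds(y, subjects, k, grouping, seed)
  if (any(vapply(seq_len(k), function(f)
    nlevels(droplevels(y[fold != f])) < 2, logical(1))))
    stop("a training fold lost one class; use fewer folds", call. = FALSE)

  params_list <- expand_grid_spec(grid[[classifier]])
  scale_sensitive <- classifier %in% c("SVC", "MLP")

  global_keep <- NULL
  x_global <- x
  if (pooled_mode) {
    xg <- impute_median(x, seq_len(nrow(x)))
    sel <- anova_select(xg, y, alpha, on_empty = "silent")
    global_keep <- sel$keep
    x_global <- if (scale_sensitive)
      suppressWarnings(minmax_normalize(xg)) else xg
  }

  eval_params <- function(params) {
    acc <- numeric(k)
    nsel <- numeric(k)
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (pooled_mode) {
        keep <- global_keep
        xtr <- x_global[tr, keep, drop = FALSE]
        xte <- x_global[te, keep, drop = FALSE]
      } else {
        xi <- impute_median(x, tr)
        sel <- anova_select(xi[tr, , drop = FALSE], y[tr], alpha,
                            on_empty = "silent")
        keep <- sel$keep
        if (length(keep)) {
          xs <- xi[, keep, drop = FALSE]
          if (scale_sensitive) {
            xs <- suppressWarnings(minmax_normalize(xs, fit_rows = tr))
          }
          xtr <- xs[tr, , drop = FALSE]
          xte <- xs[te, , drop = FALSE]
        }
      }
      nsel[f] <- length(keep)
      if (length(keep) == 0) {
        maj <- names(which.max(table(y[tr])))
        acc[f] <- mean(y[te] == maj)
        next
      }
      fit <- fit_classifier(xtr, y[tr], classifier, params)
      pred <- predict_classifier(fit, classifier, xte, levels(y))
      acc[f] <- mean(pred == y[te])
    }
    list(acc = acc, nsel = nsel)
  }

  best <- NULL
  for (params in params_list) {
    r <- eval_params(params)
    if (is.null(best) || mean(r$acc) > best$mean + 1e-12)
      best <- list(params = params, acc = r$acc, nsel = r$nsel,
                   mean = mean(r$acc))
  }

  xg <- impute_median(x, seq_len(nrow(x)))
  sel_all <- anova_select(xg, y, alpha, on_empty = "silent")
  structure(list(classifier = classifier,
                 best_params = best$params,
                 fold_accuracy = best$acc,
                 mean_accuracy = mean(best$acc),
                 sd_accuracy = stats::sd(best$acc),
                 selected = sel_all$keep,
                 n_selected_mean = mean(best$nsel)),
            class = "pw_eval")
}

#' Coarse 75/25 grid screening
#'
#' Evaluates every hyperparameter combination of each classifier on one
#' stratified 75%/25% train/validation split (with training-set feature
#' selection, imputation and scaling as in [cross_validate()]) and retains,
#' per parameter, the candidate values that appear in at least one
#' combination whose validation accuracy is within `margin` of that
#' classifier's best. The result is a reduced grid contained in the input
#' grid.
#'
#' @param x,y,subjects,alpha As in [cross_validate()].
#' @param grid Stage-1 grid (see [grid_stage1()]).
#' @param classifiers Which classifiers to screen.
#' @param margin Retention margin on validation accuracy (default 0.02).
#' @param seed Split seed.
#' @return Named list: reduced grid per classifier, with attribute
#'   `screening` (data frame of all evaluated combinations).
#' @export
coarse_grid_search <- function(x, y, subjects = seq_len(nrow(x)),
                               grid = grid_stage1(),
                               classifiers = names(grid), margin = 0.02,
                               alpha = 0.05, seed = 1) {
  y <- droplevels(factor(y))
  set.seed(seed)
  # stratified 75/25 split at subject level
  us <- unique(subjects)
  scls <- vapply(us, function(s) as.character(y[match(s, subjects)]),
                 character(1))
  val_subj <- unlist(lapply(unique(scls), function(cl) {
    ss <- sample(us[scls == cl])
    ss[seq_len(max(round(length(ss) * 0.25), 1))]
  }))
  te <- which(subjects %in% val_subj)
  tr <- setdiff(seq_len(nrow(x)), te)

  xi <- impute_median(x, tr)
  sel <- anova_select(xi[tr, , drop = FALSE], y[tr], alpha,
                      on_empty = "silent")
  keep <- sel$keep
  screening <- list()
  out <- list()
  for (cl in classifiers) {
    params_list <- expand_grid_spec(grid[[cl]])
    xs <- xi[, keep, drop = FALSE]
    if (cl %in% c("SVC", "MLP") && length(keep))
      xs <- suppressWarnings(minmax_normalize(xs, fit_rows = tr))
    accs <- vapply(params_list, function(params) {
      if (length(keep) == 0) return(mean(y[te] == names(which.max(table(y[tr])))))
      fit <- fit_classifier(xs[tr, , drop = FALSE], y[tr], cl, params)
      mean(predict_classifier(fit, cl, xs[te, , drop = FALSE], levels(y)) == y[te])
    }, numeric(1))
    good <- accs >= max(accs) - margin
    red <- list()
    for (pn in names(grid[[cl]])) {
      vals <- lapply(params_list[good], `[[`, pn)
      uniq <- vals[!duplicated(vapply(vals, function(v)
        paste(deparse(v), collapse = ""), character(1)))]
      # preserve declared candidate order
      declared <- grid[[cl]][[pn]]
      if (!is.list(declared)) declared <- as.list(declared)
      red[[pn]] <- declared[vapply(declared, function(d)
        any(vapply(uniq, identical, logical(1), d)), logical(1))]
    }
    out[[cl]] <- red
    screening[[cl]] <- data.frame(
      classifier = cl,
      params = vapply(params_list, function(p)
        paste(names(p), vapply(p, function(v) paste(deparse(v), collapse = ""),
                               character(1)), sep = "=", collapse = ";"),
      character(1)),
      accuracy = accs)
  }
  attr(out, "screening") <- do.call(rbind, screening)
  out
}

#' All non-empty sensor selections
#'
#' @return Named list of the 7 non-empty subsets of EDA, ECG, RESP.
#' @export
all_selections <- function() {
  sels <- list(c("EDA"), c("ECG"), c("RESP"),
               c("EDA", "ECG"), c("EDA", "RESP"), c("ECG", "RESP"),
               c("EDA", "ECG", "RESP"))
  stats::setNames(sels, vapply(sels, paste, character(1), collapse = "+"))
}

#' Evaluate the sensor-fusion x segmentation design grid
#'
#' Builds the feature matrix for every (selection, level) combination and
#' cross-validates every classifier on it, producing one row per design
#' cell.
#'
#' @param dataset A [cohort_dataset()] result.
#' @param selections List of signal subsets (see [all_selections()]).
#' @param levels Segmentation levels present in `dataset`.
#' @param classifiers Character vector of classifiers.
#' @param grid Hyperparameter grid.
#' @param k,grouping,alpha,pooled_mode,seed As in [cross_validate()].
#' @return Data frame: `selection`, `level`, `classifier`, `mean_accuracy`,
#'   `sd_accuracy`, `n_features`, `n_selected`, `best_params` (JSON string),
#'   with attribute `folds` holding per-cell fold accuracies.
#' @export
evaluate_design <- function(dataset, selections = all_selections(),
                            levels = c(1, 2, 5, 10, 20, 40),
                            classifiers = c("RF", "SVC", "MLP"),
                            grid = grid_stage2(), k = 10,
                            grouping = "subject", alpha = 0.05,
                            pooled_mode = FALSE, seed = 1) {
  if (is.character(selections)) selections <- list(selections)
  if (is.null(names(selections)))
    names(selections) <- vapply(selections, paste, character(1),
                                collapse = "+")
  rows <- list(); folds <- list()
  for (L in levels) {
    wi <- dataset$windows[dataset$windows$level == L, , drop = FALSE]
    for (sn in names(selections)) {
      fm <- engineer_features(wi, dataset$baseline, selections[[sn]])
      for (cl in classifiers) {
        ev <- cross_validate(fm$x, fm$y, fm$meta$subject_id, cl, grid, k,
                             grouping = grouping, alpha = alpha,
                             pooled_mode = pooled_mode, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          selection = sn, level = L, classifier = cl,
          mean_accuracy = ev$mean_accuracy, sd_accuracy = ev$sd_accuracy,
          n_features = ncol(fm$x), n_selected = ev$n_selected_mean,
          best_params = as.character(jsonlite::toJSON(ev$best_params,
                                                      auto_unbox = TRUE,
                                                      null = "null")))
        folds[[paste(sn, L, cl, sep = "|")]] <- ev$fold_accuracy
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "folds") <- folds
  out
}

#' Summarise an evaluation table
#'
#' Formats "mean (SD)" accuracy summaries: the best cell for each sensor
#' selection and for each segmentation level.
#'
#' @param results Data frame from [evaluate_design()].
#' @return List of two data frames, `by_selection` and `by_level`, printed
#'   with accuracies formatted to two decimals. Empty input yields a list
#'   of empty tables and a message.
#' @export
report_results <- function(results) {
  fmt <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  if (is.null(results) || nrow(results) == 0) {
    message("no results")
    empty <- data.frame()
    return(list(by_selection = empty, by_level = empty))
  }
  pick_best <- function(df) df[which.max(df$mean_accuracy), , drop = FALSE]
  by_sel <- do.call(rbind, lapply(split(results, results$selection), pick_best))
  by_lvl <- do.call(rbind, lapply(split(results, results$level), pick_best))
  list(
    by_selection = data.frame(
      selection = by_sel$selection, best_classifier = by_sel$classifier,
      best_accuracy = fmt(by_sel$mean_accuracy, by_sel$sd_accuracy),
      row.names = NULL),
    by_level = data.frame(
      level = by_lvl$level, best_selection = by_lvl$selection,
      best_classifier = by_lvl$classifier,
      best_accuracy = fmt(by_lvl$mean_accuracy, by_lvl$sd_accuracy),
      row.names = NULL))
}
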