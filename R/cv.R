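# Bag-level repeated k-fold cross-validation and (C, L) grid search. Folds
# always partition BAGS, never instances, so no instance of a held-out bag
# is ever seen in training; feature scaling and win-instance selection
# happen inside each training fold.

#' Cross-validation plan
#'
#' @param k number of folds (default 10).
#' @param repeats number of repetitions with fresh random partitions
#'   (default 10).
#' @param stratified balance positive bags across folds (classification
#'   only; ignored for regression).
#' @param seed integer seed controlling the partitions and the per-fold fit
#'   seeds.
#' @return An object of class `"cv_plan"`.
#' @export
cv_plan <- function(k = 10L, repeats = 10L, stratified = TRUE, seed = 1L) {
  structure(list(k = check_positive_int(k, "k"),
                 repeats = check_positive_int(repeats, "repeats"),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Bag-level fold assignments
#'
#' Partitions the bags of a dataset into `k` folds, once per repeat. With
#' stratification the positive bags are spread across folds within one bag
#' of each other; fold sizes always differ by at most one. Deterministic
#' given the plan seed.
#'
#' @param dataset a [mil_dataset()].
#' @param plan a [cv_plan()].
#' @return A list with one integer vector per repeat; entry `i` is the fold
#'   (1..k) holding bag `i` out as test data.
#' @export
make_folds <- function(dataset, plan = cv_plan()) {
  stopifnot(inherits(dataset, "mil_dataset"), inherits(plan, "cv_plan"))
  M <- n_bags(dataset)
  if (M < plan$k) {
    stop(sprintf("cannot make %d folds from %d bags", plan$k, M),
         call. = FALSE)
  }
  labels <- bag_labels(dataset)
  strat <- plan$stratified && dataset$task == "classification"
  with_seed(plan$seed, {
    lapply(seq_len(plan$repeats), function(r) {
      fold <- integer(M)
      if (strat) {
        # deal each class round-robin, carrying the fold pointer across
        # classes so overall fold sizes stay within one bag of each other
        ptr <- 0L
        for (cls in sort(unique(labels))) {
          idx <- sample(which(labels == cls))
          fold[idx] <- ((ptr + seq_along(idx) - 1L) %% plan$k) + 1L
          ptr <- (ptr + length(idx)) %% plan$k
        }
      } else {
        idx <- sample.int(M)
        fold[idx] <- ((seq_len(M) - 1L) %% plan$k) + 1L
      }
      fold
    })
  })
}

#' Cross-validate an ELM-MIL configuration
#'
#' For every repeat and fold, fits [elm_mil()] on the training bags only
#' (feature scaling and win-instance selection are refit inside the fold)
#' and evaluates on the held-out bags: bag-level accuracy for
#' classification, mean squared bag loss for regression.
#'
#' @param dataset a [mil_dataset()].
#' @param L hidden-layer width.
#' @param C ridge regulator.
#' @param plan a [cv_plan()].
#' @param activation `"sigmoid"` or `"gaussian"`.
#' @param audit when `TRUE`, verify after each fold that the fitted scaling
#'   parameters equal the per-feature min/max of the training bags alone
#'   (a test-bag leakage check); results are attached as attribute
#'   `"leakage_audit"`.
#' @param ... further arguments passed to [elm_mil()].
#' @return A `data.frame` with columns `rep`, `fold`, `metric`, one row per
#'   fold evaluation, with attributes `metric_name` and (optionally)
#'   `leakage_audit`.
#' @export
cross_validate <- function(dataset, L, C, plan = cv_plan(),
                           activation = "sigmoid", audit = FALSE, ...) {
  folds <- make_folds(dataset, plan)
  metric_name <- if (dataset$task == "classification") "accuracy"
                 else "squared_loss"
  rows <- list()
  audit_ok <- logical(0)
  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    for (f in seq_len(plan$k)) {
      train <- subset_bags(dataset, fold != f)
      test <- subset_bags(dataset, fold == f)
      fit_seed <- derive_seed(plan$seed, r, f)
      model <- tryCatch(
        elm_mil(train, L = L, C = C, activation = activation,
                seed = fit_seed, ...),
        error = function(e) {
          stop(sprintf("fit failed in repeat %d, fold %d: %s", r, f,
                       conditionMessage(e)), call. = FALSE)
        })
      if (audit && !is.null(model$scaling)) {
        Xtr <- all_instances(train)
        audit_ok <- c(audit_ok,
                      isTRUE(all.equal(model$scaling$min,
                                       apply(Xtr, 2L, min))) &&
                      isTRUE(all.equal(model$scaling$max,
                                       apply(Xtr, 2L, max))))
      }
      m <- if (dataset$task == "classification") {
        mil_accuracy(model, test)
      } else {
        squared_loss(model, test)
      }
      rows[[length(rows) + 1L]] <- data.frame(rep = r, fold = f, metric = m)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metric_name") <- metric_name
  if (audit) attr(out, "leakage_audit") <- audit_ok
  out
}

#' Hyper-parameter grid
#'
#' Defaults are the canonical search ranges for this learner: the regulator
#' `C` over \eqn{2^{-3}, \dots, 2^{7}} (11 values) and the hidden-layer
#' width over 10 and 50-600 in steps of 50 (13 values), 143 cells in all.
#'
#' @param C_values positive reals.
#' @param L_values positive integers.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(C_values = 2^seq(-3, 7),
                      L_values = c(10L, seq(50L, 600L, by = 50L))) {
  if (length(C_values) == 0L || length(L_values) == 0L) {
    stop("grids must be nonempty", call. = FALSE)
  }
  if (any(C_values <= 0) || any(L_values < 1)) {
    stop("C values must be positive and L values >= 1", call. = FALSE)
  }
  structure(list(C_values = as.numeric(C_values),
                 L_values = as.integer(L_values)),
            class = "grid_spec")
}

#' Grid search over (C, L) under repeated bag-level cross-validation
#'
#' Runs [cross_validate()] for every grid cell and summarizes each cell by
#' the mean and standard deviation of its fold metrics (and, at coarser
#' granularity, of its per-repeat means). The best cell maximizes mean
#' accuracy (classification) or minimizes mean squared loss (regression);
#' ties are broken by smaller `L`, then smaller `C`. The same fold
#' partitions (plan seed) are reused across cells so cells are comparable.
#'
#' @param dataset a [mil_dataset()].
#' @param grid a [grid_spec()].
#' @param plan a [cv_plan()].
#' @param activation `"sigmoid"` or `"gaussian"`.
#' @param ... passed to [elm_mil()].
#' @return An object of class `"cv_report"`: `cells` (a `data.frame` with
#'   `C`, `L`, `mean`, `sd`, `sd_repeat`), `metrics` (the per-fold values
#'   per cell), `best` (list with `C`, `L`, `mean`), `metric_name`, `plan`.
#' @export
grid_search <- function(dataset, grid = grid_spec(), plan = cv_plan(),
                        activation = "sigmoid", ...) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- expand.grid(C = grid$C_values, L = grid$L_values,
                       KEEP.OUT.ATTRS = FALSE)
  metrics <- vector("list", nrow(cells))
  means <- sds <- sd_rep <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    res <- cross_validate(dataset, L = cells$L[i], C = cells$C[i],
                          plan = plan, activation = activation, ...)
    metrics[[i]] <- res
    means[i] <- mean(res$metric)
    sds[i] <- stats::sd(res$metric)
    rep_means <- tapply(res$metric, res$rep, mean)
    sd_rep[i] <- if (length(rep_means) > 1L) stats::sd(rep_means) else NA_real_
  }
  cells$mean <- means
  cells$sd <- sds
  cells$sd_repeat <- sd_rep
  maximize <- dataset$task == "classification"
  ord <- order(if (maximize) -cells$mean else cells$mean, cells$L, cells$C)
  best_i <- ord[1L]
  structure(list(cells = cells, metrics = metrics,
                 best = list(C = cells$C[best_i], L = cells$L[best_i],
                             mean = cells$mean[best_i]),
                 metric_name = if (maximize) "accuracy" else "squared_loss",
                 plan = plan),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Grid-search CV report: %d cell(s), metric = %s\n",
              nrow(x$cells), x$metric_name))
  cat(sprintf("  plan: %d-fold x %d repeat(s), seed %d\n", x$plan$k,
              x$plan$repeats, x$plan$seed))
  cat(sprintf("  best cell: C = %g, L = %d, mean %s = %.4f\n", x$best$C,
              x$best$L, x$metric_name, x$best$mean))
  cat("  (a best-cell CV score chosen over a grid is optimistically",
      "biased;\n   treat it as model selection, not an unbiased estimate)\n")
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  cells <- object$cells[order(object$cells$L, object$cells$C), ]
  rownames(cells) <- NULL
  cells
}

#' @export
plot.cv_report <- function(x, ...) {
  curve <- metric_vs_L(x)
  graphics::plot(curve$L, curve$mean, type = "b", pch = 16,
                 xlab = "hidden nodes (L)",
                 ylab = paste("mean", x$metric_name), ...)
  invisible(curve)
}

#' Accuracy (or loss) versus hidden-layer width
#'
#' Collapses a [grid_search()] report over `C` at fixed quantiles or a fixed
#' `C`, giving the metric-vs-L curve used to check that performance
#' plateaus once the hidden layer is wide enough.
#'
#' @param report a [cv_report][grid_search()].
#' @param C fix this regulator value; `NULL` takes, for each `L`, the best
#'   cell over `C`.
#' @return A `data.frame` with columns `L` and `mean`.
#' @export
metric_vs_L <- function(report, C = NULL) {
  cells <- report$cells
  if (!is.null(C)) cells <- cells[cells$C == C, ]
  maximize <- report$metric_name == "accuracy"
  agg <- tapply(cells$mean, cells$L, if (maximize) max else min)
  data.frame(L = as.integer(names(agg)), mean = as.numeric(agg),
             row.names = NULL)
}
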