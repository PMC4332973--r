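# The ELM-MIL learner: a two-step fit. Step 1 freezes a random hidden layer
# and a random initial output weight vector beta0. Step 2 scores every
# instance with (layer, beta0) and keeps the argmax instance of each bag --
# the "win-instance" (the most positive instance of a positive bag, the
# least negative of a negative one). Steps 3-4 build the hidden matrix on
# the M win-instances and solve the output weights by ridge least squares.
# The hidden layer is never retrained; only beta changes.

#' Fit an ELM-MIL model
#'
#' Trains the two-step extreme-learning-machine multiple-instance learner on
#' a bag dataset. The supervision is at bag level: a bag is positive iff at
#' least one instance is positive (the standard MIL assumption), so the bag
#' error is charged to the instance with the maximum network output and the
#' fit regresses one selected instance per bag onto the bag label.
#'
#' @param dataset a [mil_dataset()].
#' @param L number of hidden nodes.
#' @param C positive ridge regulator; `1/C` is added to the diagonal of the
#'   normal-equation matrix.
#' @param activation `"sigmoid"` (default) or `"gaussian"`.
#' @param seed integer seed; reproduces the whole fit (layer, initial
#'   weights, selection) exactly.
#' @param threshold classification decision threshold on the bag score; the
#'   boundary value is classified positive. Default 0.5.
#' @param scale fit per-feature min-max scaling to \eqn{[-1, 1]} on the
#'   training instances and apply it at prediction time. Default `TRUE`.
#' @param n_reselect optional number of extra selection rounds: after
#'   solving, re-select win-instances with the solved weights and re-solve.
#'   The canonical algorithm is a single pass (`0`, the default).
#' @param weight_range,bias_range sampling ranges for the random layer, see
#'   [init_hidden_layer()].
#'
#' @return An object of class `"elm_mil"`: the frozen `layer`, solved
#'   `weights`, `win_indices` (1-based index of the selected instance in
#'   each bag), the `scaling` parameters, `threshold`, `task` and the call.
#'   Supports [predict()][predict.elm_mil()], `print()`, `summary()`,
#'   `coef()`.
#' @export
#' @examples
#' gen <- generate_classification_bags(synth_spec(n_bags = 20, seed = 3))
#' fit <- elm_mil(gen$dataset, L = 50, C = 8, seed = 1)
#' predict(fit, gen$dataset, type = "label")
elm_mil <- function(dataset, L = 100, C = 8, activation = c("sigmoid",
                    "gaussian"), seed = 1L, threshold = 0.5, scale = TRUE,
                    n_reselect = 0L, weight_range = c(-1, 1),
                    bias_range = c(0, 1)) {
  activation <- match.arg(activation)
  if (!inherits(dataset, "mil_dataset")) {
    stop("`dataset` must be a `mil_dataset`", call. = FALSE)
  }
  if (n_bags(dataset) < 2L) {
    stop("need at least two bags to fit", call. = FALSE)
  }
  L <- check_positive_int(L, "L")
  C <- check_positive_real(C, "C")
  Y <- bag_labels(dataset)
  if (dataset$task == "classification" && !all(Y %in% c(0, 1))) {
    stop("classification labels must be 0 or 1", call. = FALSE)
  }
  p <- feature_dim(dataset)

  scaling <- if (isTRUE(scale)) fit_minmax_scaling(all_instances(dataset))
             else NULL
  ds <- scale_dataset(dataset, scaling)

  # Step 1: one seeded stream draws the layer, then beta0, so a single
  # integer seed reproduces the whole fit.
  init <- with_seed(seed, {
    layer <- draw_hidden_layer(L, p, activation, weight_range, bias_range)
    beta0 <- stats::runif(L, -1, 1)
    list(layer = layer, beta0 = beta0)
  })
  layer <- init$layer
  layer$seed <- as.integer(seed)

  # Step 2: win-instance selection with the random initial weights.
  win <- select_win_instances(ds, layer, init$beta0)

  # Steps 3-4: hidden matrix on the M win-instances, ridge solve.
  solve_round <- function(win_idx) {
    Xwin <- t(vapply(seq_along(ds$bags), function(i) {
      ds$bags[[i]]$instances[win_idx[i], ]
    }, numeric(p)))
    if (p == 1L) Xwin <- matrix(Xwin, ncol = 1L)
    solve_output_weights(hidden_matrix(layer, Xwin), Y, C)
  }
  weights <- solve_round(win)

  # optional iterated selection (off by default; the canonical algorithm is
  # a single pass)
  n_reselect <- as.integer(n_reselect)
  for (k in seq_len(max(0L, n_reselect))) {
    win_new <- select_win_instances(ds, layer, weights$beta)
    weights <- solve_round(win_new)
    if (identical(win_new, win)) break
    win <- win_new
  }

  structure(list(layer = layer, weights = weights, beta0 = init$beta0,
                 threshold = threshold, scaling = scaling,
                 win_indices = win, task = dataset$task, L = L, C = C,
                 activation = activation, seed = as.integer(seed),
                 labels = Y, call = match.call()),
            class = "elm_mil")
}

#' Select one win-instance per bag
#'
#' Scores every instance with the given network and returns, per bag, the
#' (1-based) index of the instance with the maximum output; ties are broken
#' by the lowest index. The same argmax rule applies to positive and
#' negative bags: the most positive, respectively least negative, instance
#' represents its bag.
#'
#' @param dataset a [mil_dataset()] (instances already on the scale the
#'   layer expects).
#' @param layer a [init_hidden_layer()] object.
#' @param beta numeric output-weight vector of length `L` (typically the
#'   random initial weights).
#' @return Integer vector of length `n_bags(dataset)`.
#' @export
select_win_instances <- function(dataset, layer, beta) {
  if (inherits(beta, "elm_weights")) beta <- beta$beta
  if (length(beta) != nrow(layer$input_weights)) {
    stop("length of `beta` must equal the number of hidden nodes",
         call. = FALSE)
  }
  vapply(dataset$bags, function(b) {
    which.max(predict_instances(layer, beta, b$instances))
  }, integer(1))
}

#' Bag-level squared error
#'
#' The error a bag contributes to the global objective:
#' \eqn{E_i = (max_j o_{ij} - Y_i)^2 / 2}, i.e. half the squared deviation
#' of the win-instance output from the bag label. The global error is the
#' sum of `bag_error` over bags.
#'
#' @param scores numeric vector of per-instance network outputs for one bag.
#' @param label the bag label.
#' @return A nonnegative scalar.
#' @export
bag_error <- function(scores, label) {
  if (length(scores) < 1L) {
    stop("`scores` must contain at least one instance output", call. = FALSE)
  }
  0.5 * (max(scores) - label)^2
}

#' Predict bag scores or labels
#'
#' The score of a bag is the maximum per-instance network output under the
#' fitted weights (after applying the stored feature scaling), mirroring the
#' win-instance rule used in training. For classification, `type = "label"`
#' thresholds the score; the boundary value counts as positive.
#'
#' @param object a fitted [elm_mil()] model.
#' @param newdata a [mil_dataset()] or a single [mil_bag()].
#' @param type `"score"` (default) for raw bag scores (unbounded reals, the
#'   output layer is linear) or `"label"` for 0/1 labels (classification
#'   models only).
#' @param ... unused.
#' @return Numeric vector with one entry per bag.
#' @export
predict.elm_mil <- function(object, newdata, type = c("score", "label"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "mil_bag")) {
    newdata <- structure(list(bags = list(newdata), task = object$task),
                         class = "mil_dataset")
  }
  if (!inherits(newdata, "mil_dataset")) {
    stop("`newdata` must be a `mil_dataset` or `mil_bag`", call. = FALSE)
  }
  if (feature_dim(newdata) != ncol(object$layer$input_weights)) {
    stop("feature dimension of `newdata` does not match the model",
         call. = FALSE)
  }
  scores <- vapply(newdata$bags, function(b) {
    X <- apply_minmax_scaling(b$instances, object$scaling)
    max(predict_instances(object$layer, object$weights$beta, X))
  }, numeric(1))
  if (type == "score") return(scores)
  if (object$task != "classification") {
    stop("`type = \"label\"` requires a classification model", call. = FALSE)
  }
  as.integer(scores >= object$threshold)
}

#' Mean squared bag loss of a model on a dataset
#'
#' The regression evaluation metric: the mean over bags of the squared
#' difference between the predicted bag score and the bag label.
#'
#' @param model a fitted [elm_mil()] model.
#' @param dataset a [mil_dataset()].
#' @return A nonnegative scalar.
#' @export
squared_loss <- function(model, dataset) {
  if (!inherits(dataset, "mil_dataset") || n_bags(dataset) < 1L) {
    stop("`dataset` must be a non-empty `mil_dataset`", call. = FALSE)
  }
  mean((predict(model, dataset, type = "score") - bag_labels(dataset))^2)
}

#' Bag-level classification accuracy of a model on a dataset
#'
#' @param model a fitted classification [elm_mil()] model.
#' @param dataset a [mil_dataset()] with 0/1 labels.
#' @return Fraction of bags whose predicted label matches the true label.
#' @export
mil_accuracy <- function(model, dataset) {
  mean(predict(model, dataset, type = "label") == bag_labels(dataset))
}

#' @export
coef.elm_mil <- function(object, ...) object$weights$beta

#' @export
print.elm_mil <- function(x, ...) {
  cat("ELM-MIL model\n")
  cat(sprintf("  task: %s | hidden nodes: %d (%s) | C: %g | seed: %d\n",
              x$task, x$L, x$activation, x$C, x$seed))
  cat(sprintf("  bags trained on: %d | feature scaling: %s\n",
              length(x$win_indices),
              if (is.null(x$scaling)) "off" else "min-max to [-1, 1]"))
  if (x$task == "classification") {
    cat(sprintf("  decision threshold: %g (boundary positive)\n",
                x$threshold))
  }
  invisible(x)
}

#' @export
summary.elm_mil <- function(object, ...) {
  out <- list(model = object)
  out$n_train <- length(object$win_indices)
  out$beta_norm <- sqrt(sum(object$weights$beta^2))
  class(out) <- "summary.elm_mil"
  out
}

#' @export
print.summary.elm_mil <- function(x, ...) {
  print(x$model)
  cat(sprintf("  ||beta||: %.4g | win-instance indices recorded for %d bags\n",
              x$beta_norm, x$n_train))
  invisible(x)
}
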