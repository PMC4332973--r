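# Bag-structured data containers. A bag is a labeled set of instances
# (feature vectors); instance labels are unobserved. In drug-activity data a
# bag is a molecule and its instances are low-energy conformations.

#' Construct a single bag
#'
#' @param instances numeric matrix, one instance (feature vector) per row; a
#'   plain vector is treated as one instance.
#' @param label bag label: 0/1 for classification, any real for regression.
#' @param bag_id character identifier.
#' @return An object of class `"mil_bag"`.
#' @export
#' @examples
#' mil_bag(matrix(rnorm(6), 2, 3), label = 1, bag_id = "mol1")
mil_bag <- function(instances, label, bag_id = "bag") {
  if (is.null(dim(instances))) instances <- matrix(instances, nrow = 1L)
  instances <- as.matrix(instances)
  storage.mode(instances) <- "double"
  if (nrow(instances) < 1L) {
    stop("a bag must contain at least one instance", call. = FALSE)
  }
  if (!all(is.finite(instances))) {
    stop(sprintf("bag '%s' contains non-finite feature values", bag_id),
         call. = FALSE)
  }
  if (!is.numeric(label) || length(label) != 1L || !is.finite(label)) {
    stop(sprintf("bag '%s' must have a single finite numeric label", bag_id),
         call. = FALSE)
  }
  structure(list(bag_id = as.character(bag_id), instances = instances,
                 label = as.numeric(label)),
            class = "mil_bag")
}

#' Construct a multiple-instance dataset
#'
#' An ordered collection of bags sharing one feature dimension. For
#' classification all labels must be 0 or 1; a dataset needs at least two
#' bags.
#'
#' @param bags list of [mil_bag()] objects.
#' @param task `"classification"` or `"regression"`.
#' @return An object of class `"mil_dataset"`.
#' @export
mil_dataset <- function(bags, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (!is.list(bags) || length(bags) < 2L) {
    stop("`bags` must be a list of at least two bags", call. = FALSE)
  }
  if (!all(vapply(bags, inherits, logical(1), "mil_bag"))) {
    stop("every element of `bags` must be a `mil_bag`", call. = FALSE)
  }
  p <- ncol(bags[[1L]]$instances)
  dims <- vapply(bags, function(b) ncol(b$instances), integer(1))
  if (any(dims != p)) {
    stop("all bags must share one feature dimension", call. = FALSE)
  }
  labels <- vapply(bags, function(b) b$label, numeric(1))
  if (task == "classification" && !all(labels %in% c(0, 1))) {
    stop("classification labels must be 0 or 1", call. = FALSE)
  }
  structure(list(bags = bags, task = task), class = "mil_dataset")
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("Bag '%s': %d instance(s) x %d feature(s), label %g\n",
              x$bag_id, nrow(x$instances), ncol(x$instances), x$label))
  invisible(x)
}

#' @export
print.mil_dataset <- function(x, ...) {
  lab <- bag_labels(x)
  cat(sprintf("MIL dataset (%s): %d bags, %d features, %d instances\n",
              x$task, n_bags(x), feature_dim(x), sum(bag_sizes(x))))
  if (x$task == "classification") {
    cat(sprintf("  positive bags: %d, negative bags: %d\n",
                sum(lab == 1), sum(lab == 0)))
  } else {
    cat(sprintf("  label range: [%.4g, %.4g]\n", min(lab), max(lab)))
  }
  invisible(x)
}

#' Number of bags in a dataset
#' @param dataset a [mil_dataset()].
#' @return Integer count of bags.
#' @export
n_bags <- function(dataset) length(dataset$bags)

#' Bag labels as a numeric vector
#' @param dataset a [mil_dataset()].
#' @return Numeric vector of length `n_bags(dataset)`.
#' @export
bag_labels <- function(dataset) {
  vapply(dataset$bags, function(b) b$label, numeric(1))
}

#' Instance counts per bag
#' @param dataset a [mil_dataset()].
#' @return Integer vector of per-bag instance counts.
#' @export
bag_sizes <- function(dataset) {
  vapply(dataset$bags, function(b) nrow(b$instances), integer(1))
}

#' Feature dimension of a dataset
#' @param dataset a [mil_dataset()].
#' @return Integer, the shared number of features `p`.
#' @export
feature_dim <- function(dataset) ncol(dataset$bags[[1L]]$instances)

#' Subset a dataset by bag index
#' @param dataset a [mil_dataset()].
#' @param idx integer or logical index over bags.
#' @return A `mil_dataset` with the selected bags (order preserved).
#' @export
subset_bags <- function(dataset, idx) {
  bags <- dataset$bags[idx]
  if (length(bags) < 2L) {
    # keep the container honest even for one-bag test folds
    out <- dataset
    out$bags <- bags
    return(out)
  }
  mil_dataset(bags, task = dataset$task)
}

# Stack all instances into one matrix (rows follow bag order).
all_instances <- function(dataset) {
  do.call(rbind, lapply(dataset$bags, function(b) b$instances))
}

#' Flatten a dataset to an instance table
#'
#' @param x a [mil_dataset()].
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return A `data.frame` with `bag_id`, `instance`, feature columns
#'   `x1..xp`, and the bag `label` repeated across its instances.
#' @export
as.data.frame.mil_dataset <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  rows <- lapply(x$bags, function(b) {
    data.frame(bag_id = b$bag_id, instance = seq_len(nrow(b$instances)),
               b$instances, label = b$label,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("bag_id", "instance",
                  paste0("x", seq_len(feature_dim(x))), "label")
  rownames(out) <- NULL
  out
}
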