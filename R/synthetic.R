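# Synthetic bag generators with known ground truth, so every pipeline stage
# (selection, fitting, cross-validation) is testable without external
# downloads. Two regimes: MUSK-style classification bags under the standard
# MIL assumption, and LJ-style regression bags where the bag label is the
# best instance's response under a hidden target function.

#' Specification for a synthetic MIL dataset
#'
#' Defaults describe a desk-scale MUSK1-like benchmark: 92 bags of 2-10
#' instances each, 20 features of which 5 are relevant, half the bags
#' positive, witness instances separated from the background by 3 standard
#' deviations along each relevant axis, and 30% of a positive bag's
#' instances being witnesses. `p = 166, n_relevant = 80` emulates the
#' LJ-80.166 regression family.
#'
#' @param n_bags number of bags.
#' @param instances_per_bag integer range `c(min, max)` for per-bag instance
#'   counts, drawn uniformly.
#' @param p number of features.
#' @param n_relevant number of relevant features (`<= p`); the hidden
#'   structure lives on the first `n_relevant` axes.
#' @param witness_rate fraction in (0, 1] of a positive bag's instances that
#'   are true witnesses (`ceiling(witness_rate * N_i)`, so at least one).
#' @param class_separation shift, in background standard deviations, applied
#'   to each relevant coordinate of a witness instance.
#' @param noise_sd standard deviation of the Gaussian noise added to
#'   regression bag labels.
#' @param positive_fraction fraction of bags labeled positive
#'   (classification only).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_bags = 92, instances_per_bag = c(2, 10), p = 20,
                       n_relevant = 5, witness_rate = 0.3,
                       class_separation = 3, noise_sd = 0.05,
                       positive_fraction = 0.5, seed = 1L) {
  n_bags <- check_positive_int(n_bags, "n_bags")
  p <- check_positive_int(p, "p")
  n_relevant <- check_positive_int(n_relevant, "n_relevant")
  if (n_relevant > p) stop("`n_relevant` must be <= `p`", call. = FALSE)
  if (length(instances_per_bag) != 2L || any(instances_per_bag < 1) ||
      instances_per_bag[1] > instances_per_bag[2]) {
    stop("`instances_per_bag` must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (!is.numeric(witness_rate) || witness_rate <= 0 || witness_rate > 1) {
    stop("`witness_rate` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(class_separation) || class_separation < 0) {
    stop("`class_separation` must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(positive_fraction) || positive_fraction <= 0 ||
      positive_fraction >= 1) {
    stop("`positive_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_bags = n_bags,
                 instances_per_bag = as.integer(instances_per_bag),
                 p = p, n_relevant = n_relevant,
                 witness_rate = as.numeric(witness_rate),
                 class_separation = as.numeric(class_separation),
                 noise_sd = as.numeric(noise_sd),
                 positive_fraction = as.numeric(positive_fraction),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic MIL spec: %d bags x [%d,%d] instances, ",
                     "p = %d (%d relevant), seed = %d\n"),
              x$n_bags, x$instances_per_bag[1], x$instances_per_bag[2],
              x$p, x$n_relevant, x$seed))
  invisible(x)
}

#' Generate MUSK-style classification bags
#'
#' Background instances are drawn from a standard spherical Gaussian.
#' Witness instances are background draws shifted by `class_separation`
#' along each of the first `n_relevant` axes. A positive bag receives
#' `ceiling(witness_rate * N_i)` witnesses; negative bags receive none. The
#' MIL assumption holds exactly by construction: a bag's label is 1 iff it
#' contains at least one witness.
#'
#' @param spec a [synth_spec()].
#' @return A list with `dataset` (a [mil_dataset()]) and `truth`, which
#'   carries `witness_mask` (per-bag logical vectors) and
#'   `target_function_params` (the relevant-axis shift vector).
#' @export
#' @examples
#' gen <- generate_classification_bags(synth_spec(n_bags = 10, seed = 7))
#' table(bag_labels(gen$dataset))
generate_classification_bags <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n_pos <- round(spec$positive_fraction * spec$n_bags)
    labels <- sample(c(rep(1, n_pos), rep(0, spec$n_bags - n_pos)))
    sizes <- sample(seq(spec$instances_per_bag[1], spec$instances_per_bag[2]),
                    spec$n_bags, replace = TRUE)
    shift <- c(rep(spec$class_separation, spec$n_relevant),
               rep(0, spec$p - spec$n_relevant))
    bags <- vector("list", spec$n_bags)
    masks <- vector("list", spec$n_bags)
    for (i in seq_len(spec$n_bags)) {
      n_i <- sizes[i]
      X <- matrix(stats::rnorm(n_i * spec$p), nrow = n_i, ncol = spec$p)
      mask <- rep(FALSE, n_i)
      if (labels[i] == 1) {
        n_w <- ceiling(spec$witness_rate * n_i)
        w_idx <- sample(n_i, n_w)
        X[w_idx, ] <- sweep(X[w_idx, , drop = FALSE], 2L, shift, "+")
        mask[w_idx] <- TRUE
      }
      bags[[i]] <- mil_bag(X, labels[i],
                           bag_id = sprintf("bag_%03d", i))
      masks[[i]] <- mask
    }
    list(dataset = mil_dataset(bags, task = "classification"),
         truth = structure(list(witness_mask = masks,
                                target_function_params = shift),
                           class = "mil_ground_truth"))
  })
}

#' Generate LJ-style regression bags
#'
#' A hidden linear-logistic target on the first `n_relevant` features maps
#' each instance to a response in (0, 1); the noiseless bag label is the
#' maximum instance response, to which Gaussian noise (`noise_sd`) is added
#' before clipping to [0, 1]. With `filter_near_half = TRUE` bags whose
#' noiseless label lies within `delta` of 1/2 are discarded and regenerated,
#' emulating benchmark variants that keep only labels away from 1/2.
#'
#' @param spec a [synth_spec()].
#' @param filter_near_half drop bags with noiseless label in
#'   `(0.5 - delta, 0.5 + delta)`.
#' @param delta half-width of the exclusion band around 1/2.
#' @return A list with `dataset` (a regression [mil_dataset()]) and `truth`
#'   carrying `witness_mask` (the argmax-response instance per bag) and
#'   `target_function_params` (the hidden weight vector over all `p`
#'   features; zeros on irrelevant axes).
#' @export
generate_regression_bags <- function(spec, filter_near_half = FALSE,
                                     delta = 0.1) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    w_rel <- stats::rnorm(spec$n_relevant)
    # normalize so the latent score w . x has unit variance, then rescale so
    # instance responses spread over most of (0, 1)
    w_rel <- 2 * w_rel / sqrt(sum(w_rel^2))
    w <- c(w_rel, rep(0, spec$p - spec$n_relevant))
    bags <- vector("list", spec$n_bags)
    masks <- vector("list", spec$n_bags)
    made <- 0L
    attempts <- 0L
    max_attempts <- 1000L * spec$n_bags
    while (made < spec$n_bags) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not generate enough bags outside the exclusion band",
             call. = FALSE)
      }
      n_i <- sample(seq(spec$instances_per_bag[1],
                        spec$instances_per_bag[2]), 1L)
      X <- matrix(stats::rnorm(n_i * spec$p), nrow = n_i, ncol = spec$p)
      resp <- stats::plogis(drop(X %*% w))
      y0 <- max(resp)
      if (filter_near_half && abs(y0 - 0.5) < delta) next
      y <- min(1, max(0, y0 + stats::rnorm(1L, 0, spec$noise_sd)))
      made <- made + 1L
      bags[[made]] <- mil_bag(X, y, bag_id = sprintf("bag_%03d", made))
      masks[[made]] <- seq_len(n_i) == which.max(resp)
    }
    list(dataset = mil_dataset(bags, task = "regression"),
         truth = structure(list(witness_mask = masks,
                                target_function_params = w),
                           class = "mil_ground_truth"))
  })
}
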