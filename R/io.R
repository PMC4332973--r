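# Readers and writers for bag-structured tables (MUSK/C4.5-style CSV: bag
# name, optional instance name, p feature columns, class column), ground
# truth sidecars, flat run configs, and model serialization.

#' Describe the column layout of a bag CSV file
#'
#' The default matches the MUSK "clean" layout: column 1 is the bag
#' (molecule) name, column 2 the instance (conformation) name, the last
#' column the class, and everything in between the features. Columns may be
#' given by index (numeric) or, with `header = TRUE`, by name.
#'
#' @param bag_id_column bag identifier column.
#' @param instance_id_column optional instance identifier column; `NULL` if
#'   the file has none.
#' @param label_column class/label column.
#' @param feature_columns feature columns, in order; `NULL` means all
#'   remaining columns.
#' @param header whether the file has a header row.
#' @param delimiter field separator.
#' @param label_map optional named vector mapping raw label strings to 0/1,
#'   e.g. `c("NON-MUSK" = 0, "MUSK" = 1)`. Numeric `{0,1}` and `{-1,1}`
#'   labels are normalized automatically.
#' @return An object of class `"bag_dialect"`.
#' @export
bag_dialect <- function(bag_id_column = 1L, instance_id_column = 2L,
                        label_column = -1L, feature_columns = NULL,
                        header = FALSE, delimiter = ",", label_map = NULL) {
  structure(list(bag_id_column = bag_id_column,
                 instance_id_column = instance_id_column,
                 label_column = label_column,
                 feature_columns = feature_columns,
                 header = isTRUE(header), delimiter = delimiter,
                 label_map = label_map),
            class = "bag_dialect")
}

resolve_column <- function(spec, columns, what) {
  if (is.null(spec)) return(NULL)
  if (is.character(spec)) {
    idx <- match(spec, columns)
    if (is.na(idx)) {
      stop(sprintf("%s column '%s' not found", what, spec), call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(spec)
  if (idx < 0) idx <- length(columns) + 1L + idx  # -1 = last column
  if (idx < 1L || idx > length(columns)) {
    stop(sprintf("%s column index %s out of range", what, spec),
         call. = FALSE)
  }
  idx
}

normalize_labels <- function(raw, map, task, path) {
  if (!is.null(map)) {
    out <- unname(map[as.character(raw)])
    if (anyNA(out)) {
      bad <- unique(as.character(raw)[is.na(out)])
      stop(sprintf("labels in '%s' not covered by label_map: %s", path,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    return(as.numeric(out))
  }
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    stop(sprintf("non-numeric label in '%s'; supply a label_map", path),
         call. = FALSE)
  }
  if (task == "classification") {
    u <- sort(unique(num))
    if (identical(u, c(-1, 1))) num <- (num + 1) / 2  # {-1,1} -> {0,1}
    if (!all(num %in% c(0, 1))) {
      stop(sprintf("classification labels in '%s' must be {0,1} or {-1,1}",
                   path), call. = FALSE)
    }
  }
  num
}

#' Read a bag CSV file into a MIL dataset
#'
#' Rows sharing a bag identifier are grouped into one bag, preserving row
#' order; grouping is by identifier value, not row adjacency, so shuffled
#' exports are read correctly. Every row of a bag must carry the same label.
#'
#' @param path file path.
#' @param dialect a [bag_dialect()] describing the column layout.
#' @param task `"classification"` or `"regression"`.
#' @return A [mil_dataset()].
#' @export
read_bags <- function(path, dialect = bag_dialect(),
                      task = c("classification", "regression")) {
  task <- match.arg(task)
  stopifnot(inherits(dialect, "bag_dialect"))
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.table(path, header = dialect$header, sep = dialect$delimiter,
                      colClasses = "character", fill = FALSE,
                      strip.white = TRUE, check.names = FALSE,
                      comment.char = ""),
    error = function(e) {
      stop(sprintf("malformed table in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  cols <- names(df)
  bag_i <- resolve_column(dialect$bag_id_column, cols, "bag id")
  inst_i <- resolve_column(dialect$instance_id_column, cols, "instance id")
  lab_i <- resolve_column(dialect$label_column, cols, "label")
  feat_i <- if (is.null(dialect$feature_columns)) {
    setdiff(seq_along(cols), c(bag_i, inst_i, lab_i))
  } else {
    vapply(dialect$feature_columns, resolve_column, integer(1),
           columns = cols, what = "feature")
  }
  if (length(feat_i) == 0L) {
    stop(sprintf("no feature columns in '%s'", path), call. = FALSE)
  }
  feats <- vapply(df[feat_i], function(col) {
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(df)))
  feats <- matrix(feats, nrow = nrow(df))
  if (anyNA(feats)) {
    bad_row <- which(rowSums(is.na(feats)) > 0)[1L]
    stop(sprintf("non-numeric feature value in '%s' at data row %d", path,
                 bad_row), call. = FALSE)
  }
  labels <- normalize_labels(df[[lab_i]], dialect$label_map, task, path)
  ids <- as.character(df[[bag_i]])
  groups <- split(seq_len(nrow(df)), factor(ids, levels = unique(ids)))
  bags <- lapply(names(groups), function(id) {
    rows <- groups[[id]]
    lab <- unique(labels[rows])
    if (length(lab) != 1L) {
      stop(sprintf("bag '%s' in '%s' carries inconsistent labels (%s)", id,
                   path, paste(lab, collapse = ", ")), call. = FALSE)
    }
    mil_bag(feats[rows, , drop = FALSE], lab, bag_id = id)
  })
  mil_dataset(bags, task = task)
}

#' Write a MIL dataset as a bag CSV file
#'
#' One row per instance; floating point is written with 17 significant
#' digits so that a read/write round trip is lossless.
#'
#' @param dataset a [mil_dataset()].
#' @param path output file path.
#' @param dialect a [bag_dialect()]; only `instance_id_column` (presence),
#'   `header` and `delimiter` influence the output layout, which is always
#'   bag id, optional instance id, features, label.
#' @return Invisibly, `path`.
#' @export
write_bags <- function(dataset, path, dialect = bag_dialect()) {
  stopifnot(inherits(dataset, "mil_dataset"), inherits(dialect, "bag_dialect"))
  p <- feature_dim(dataset)
  if (p < 1L) stop("dataset has no features", call. = FALSE)
  with_inst <- !is.null(dialect$instance_id_column)
  rows <- lapply(dataset$bags, function(b) {
    n <- nrow(b$instances)
    feat_chr <- matrix(sprintf("%.17g", b$instances), nrow = n)
    lead <- if (with_inst) {
      cbind(rep(b$bag_id, n), paste0(b$bag_id, "_", seq_len(n)))
    } else {
      cbind(rep(b$bag_id, n))
    }
    cbind(lead, feat_chr, sprintf("%.17g", rep(b$label, n)))
  })
  tab <- do.call(rbind, rows)
  if (dialect$header) {
    hdr <- c("bag_id", if (with_inst) "instance_id",
             paste0("x", seq_len(p)), "label")
    tab <- rbind(hdr, tab)
  }
  ok <- tryCatch({
    utils::write.table(tab, path, sep = dialect$delimiter, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) {
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Write the witness ground truth of a synthetic dataset
#'
#' Sidecar CSV with columns `bag_id`, `instance_index` (1-based) and
#' `is_witness` (0/1), one row per instance.
#'
#' @param truth the `truth` component returned by the generators.
#' @param dataset the matching [mil_dataset()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, dataset, path) {
  stopifnot(inherits(truth, "mil_ground_truth"),
            inherits(dataset, "mil_dataset"))
  rows <- do.call(rbind, lapply(seq_along(dataset$bags), function(i) {
    mask <- truth$witness_mask[[i]]
    data.frame(bag_id = dataset$bags[[i]]$bag_id,
               instance_index = seq_along(mask),
               is_witness = as.integer(mask))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' A YAML file of flat keys (`L`, `C`, `activation`, `seed`, `threshold`,
#' `scaling`, `task`, `k`, `repeats`, and grid lists `C_values`,
#' `L_values`). Unknown keys are rejected to catch typos.
#'
#' @param path config file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config not found: '%s'", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  allowed <- c("L", "C", "activation", "seed", "threshold", "scaling",
               "task", "k", "repeats", "stratified", "C_values", "L_values")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("unknown config key(s) in '%s': %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  # YAML sequences of mixed int/double parse as lists; flatten grid lists
  for (key in c("C_values", "L_values")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- as.numeric(unlist(cfg[[key]]))
  }
  cfg
}

#' Serialize a fitted model to a self-describing JSON file
#'
#' Stores the hidden-layer weights and biases, solved output weights, the
#' regulator, activation, feature-scaling parameters, threshold, task and
#' seed, so the model can be reloaded and used for prediction elsewhere.
#'
#' @param model a fitted [elm_mil()] model.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "elm_mil"))
  payload <- list(
    format = "elmmil-model",
    package_version = as.character(utils::packageVersion("elmmil")),
    task = model$task,
    activation = model$activation,
    L = model$L, C = model$C, seed = model$seed,
    threshold = model$threshold,
    input_weights = model$layer$input_weights,
    biases = model$layer$biases,
    beta = model$weights$beta,
    scaling = model$scaling,
    win_indices = model$win_indices
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a serialized model
#'
#' @param path a file written by [write_model()].
#' @return An [elm_mil()] model usable with [predict.elm_mil()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: '%s'", path), call. = FALSE)
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "elmmil-model")) {
    stop(sprintf("'%s' is not an elmmil model file", path), call. = FALSE)
  }
  W <- as.matrix(payload$input_weights)
  layer <- structure(list(input_weights = W,
                          biases = as.numeric(payload$biases),
                          activation = payload$activation,
                          seed = as.integer(payload$seed)),
                     class = "hidden_layer")
  scaling <- if (is.null(payload$scaling)) NULL else {
    list(min = as.numeric(payload$scaling$min),
         max = as.numeric(payload$scaling$max))
  }
  structure(list(layer = layer,
                 weights = structure(list(beta = as.numeric(payload$beta),
                                          C = payload$C),
                                     class = "elm_weights"),
                 threshold = payload$threshold, scaling = scaling,
                 win_indices = as.integer(payload$win_indices),
                 task = payload$task, L = as.integer(payload$L),
                 C = payload$C, activation = payload$activation,
                 seed = as.integer(payload$seed),
                 call = quote(read_model(path))),
            class = "elm_mil")
}
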