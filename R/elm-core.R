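# Single-hidden-layer feedforward network (SLFN) machinery: random hidden
# layers, activations, the hidden-layer output matrix H, and the regularized
# least-squares output-weight solvers used by the extreme learning machine.

#' Random hidden layer for an extreme learning machine
#'
#' Draws the input weights and biases of a single-hidden-layer feedforward
#' network. In an ELM these parameters are random and stay frozen; only the
#' output weights are ever solved for. Input weights are i.i.d. uniform on
#' `weight_range` (default \eqn{[-1, 1]}); biases are uniform on `bias_range`
#' (default \eqn{[0, 1]}). For Gaussian nodes the bias acts as the impact
#' factor \eqn{b > 0} and is drawn from \eqn{(0, 1]}.
#'
#' @param L number of hidden nodes (positive integer).
#' @param p input dimension (positive integer).
#' @param activation `"sigmoid"` or `"gaussian"`.
#' @param seed integer seed; the same seed reproduces the layer bit for bit.
#' @param weight_range length-2 numeric, sampling range for input weights.
#' @param bias_range length-2 numeric, sampling range for biases (sigmoid
#'   nodes only; Gaussian impact factors are always drawn from (0, 1]).
#'
#' @return An object of class `"hidden_layer"`: a list with `input_weights`
#'   (an `L x p` matrix whose row `j` holds the weights of node `j`),
#'   `biases` (length `L`), `activation` and `seed`.
#' @seealso [hidden_matrix()], [solve_output_weights()], [elm_mil()]
#' @export
#' @examples
#' layer <- init_hidden_layer(5, 2, "sigmoid", seed = 1)
#' dim(layer$input_weights)
init_hidden_layer <- function(L, p, activation = c("sigmoid", "gaussian"),
                              seed = 1L, weight_range = c(-1, 1),
                              bias_range = c(0, 1)) {
  activation <- match.arg(activation)
  with_seed(seed, {
    layer <- draw_hidden_layer(L, p, activation, weight_range, bias_range)
  })
  layer$seed <- as.integer(seed)
  layer
}

# Draw a layer from the *current* RNG stream. elm_mil() uses this so that
# the layer and the initial output weights come from one seeded stream.
draw_hidden_layer <- function(L, p, activation, weight_range = c(-1, 1),
                              bias_range = c(0, 1)) {
  L <- check_positive_int(L, "L")
  p <- check_positive_int(p, "p")
  stopifnot(length(weight_range) == 2L, length(bias_range) == 2L)
  W <- matrix(stats::runif(L * p, weight_range[1], weight_range[2]),
              nrow = L, ncol = p)
  b <- if (activation == "gaussian") {
    # impact factor must be strictly positive: uniform on (0, 1]
    1 - stats::runif(L)
  } else {
    stats::runif(L, bias_range[1], bias_range[2])
  }
  structure(list(input_weights = W, biases = b, activation = activation,
                 seed = NA_integer_),
            class = "hidden_layer")
}

#' @export
print.hidden_layer <- function(x, ...) {
  cat(sprintf("Random hidden layer: %d %s node(s), input dimension %d\n",
              nrow(x$input_weights), x$activation, ncol(x$input_weights)))
  invisible(x)
}

#' Sigmoid (additive) hidden-node activation
#'
#' Computes \eqn{G(a, b, x) = 1 / (1 + \exp(-(a \cdot x + b)))}, the
#' additive-node map of an SLFN. The value is strictly inside \eqn{(0, 1)}.
#'
#' @param a weight vector of length `p`.
#' @param b scalar bias.
#' @param x input vector of length `p`.
#' @return A scalar in (0, 1).
#' @export
activate_sigmoid <- function(a, b, x) {
  if (length(a) != length(x)) {
    stop("`a` and `x` must have the same length", call. = FALSE)
  }
  stats::plogis(sum(a * x) + b)
}

#' Gaussian (RBF) hidden-node activation
#'
#' Computes \eqn{G(a, b, x) = \exp(-b \, \|x - a\|^2)} where `a` is the node
#' center and `b > 0` its impact factor. The value lies in \eqn{(0, 1]} and
#' equals 1 exactly at the center.
#'
#' @param a center vector of length `p`.
#' @param b positive impact factor.
#' @param x input vector of length `p`.
#' @return A scalar in (0, 1].
#' @export
activate_gaussian <- function(a, b, x) {
  if (length(a) != length(x)) {
    stop("`a` and `x` must have the same length", call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("Gaussian impact factor `b` must be positive", call. = FALSE)
  }
  exp(-b * sum((x - a)^2))
}

#' Hidden-layer output matrix
#'
#' Evaluates every hidden node on every input row, giving the `N x L` matrix
#' `H` with `H[i, j] = G(a_j, b_j, x_i)`. This matrix is the design matrix of
#' the linear output layer of an ELM.
#'
#' @param layer a [init_hidden_layer()] object.
#' @param X numeric matrix with one input per row; its column count must
#'   equal the layer's input dimension. `N = 0` rows are allowed.
#' @return An `N x L` numeric matrix.
#' @export
hidden_matrix <- function(layer, X) {
  stopifnot(inherits(layer, "hidden_layer"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  W <- layer$input_weights
  if (ncol(X) != ncol(W)) {
    stop(sprintf("input has %d feature(s) but the layer expects %d",
                 ncol(X), ncol(W)), call. = FALSE)
  }
  if (nrow(X) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = nrow(W)))
  }
  if (layer$activation == "sigmoid") {
    Z <- sweep(X %*% t(W), 2L, layer$biases, "+")
    stats::plogis(Z)
  } else {
    # squared distances ||x_i - a_j||^2 via the expansion trick
    d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * (X %*% t(W))
    d2[d2 < 0] <- 0
    exp(-sweep(d2, 2L, layer$biases, "*"))
  }
}

#' Solve ELM output weights by ridge-regularized least squares
#'
#' Returns the output-weight vector \eqn{\beta} minimizing
#' \eqn{\|H\beta - Y\|^2 + \|\beta\|^2 / C}. Two algebraically equivalent
#' closed forms are used depending on shape: when `N < L` the dual form
#' \eqn{\beta = H^T (I/C + H H^T)^{-1} Y}, otherwise the primal form
#' \eqn{\beta = (I/C + H^T H)^{-1} H^T Y}. As \eqn{C \to \infty} both
#' converge to the minimal-norm least-squares solution \eqn{H^\dagger Y}.
#'
#' @param H hidden-layer output matrix, `N x L`.
#' @param Y numeric response vector of length `N`.
#' @param C positive ridge regulator; `1/C` is added to the diagonal of the
#'   normal-equation matrix.
#' @param form `"auto"` picks the branch by shape; `"primal"` or `"dual"`
#'   forces one (useful for cross-checking).
#' @return An object of class `"elm_weights"`: list with `beta` (length `L`)
#'   and `C`.
#' @export
solve_output_weights <- function(H, Y, C, form = c("auto", "primal", "dual")) {
  form <- match.arg(form)
  H <- as.matrix(H)
  Y <- as.numeric(Y)
  C <- check_positive_real(C, "C")
  if (nrow(H) != length(Y)) {
    stop("row count of `H` must equal length of `Y`", call. = FALSE)
  }
  if (!all(is.finite(H)) || !all(is.finite(Y))) {
    stop("`H` and `Y` must be finite", call. = FALSE)
  }
  N <- nrow(H)
  L <- ncol(H)
  if (form == "auto") form <- if (N < L) "dual" else "primal"
  beta <- if (form == "dual") {
    drop(crossprod(H, ridge_chol_solve(tcrossprod(H), Y, C)))
  } else {
    drop(ridge_chol_solve(crossprod(H), crossprod(H, Y), C))
  }
  structure(list(beta = as.numeric(beta), C = C), class = "elm_weights")
}

#' @export
print.elm_weights <- function(x, ...) {
  cat(sprintf("ELM output weights: L = %d, C = %g, ||beta|| = %.4g\n",
              length(x$beta), x$C, sqrt(sum(x$beta^2))))
  invisible(x)
}

#' Per-instance network outputs
#'
#' Evaluates the full SLFN \eqn{o(x) = \sum_j \beta_j G(a_j, b_j, x)} on each
#' row of `X`. The output layer is linear, so scores are unbounded reals.
#'
#' @param layer a [init_hidden_layer()] object.
#' @param beta output weights: an [solve_output_weights()] object or a
#'   numeric vector of length `L`.
#' @param X numeric matrix of inputs, one per row.
#' @return Numeric vector with one score per row of `X`.
#' @export
predict_instances <- function(layer, beta, X) {
  if (inherits(beta, "elm_weights")) beta <- beta$beta
  beta <- as.numeric(beta)
  if (length(beta) != nrow(layer$input_weights)) {
    stop("length of `beta` must equal the number of hidden nodes",
         call. = FALSE)
  }
  drop(hidden_matrix(layer, X) %*% beta)
}
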