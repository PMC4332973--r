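# fixtures built in code

# tiny handmade classification dataset: 2 bags x 3 instances, p = 2
toy_dataset <- function() {
  b1 <- mil_bag(rbind(c(0, 0), c(1, 1), c(2, 0)), label = 1, bag_id = "a")
  b2 <- mil_bag(rbind(c(-1, 0), c(0, -1), c(-2, -2)), label = 0, bag_id = "b")
  mil_dataset(list(b1, b2))
}

# a degenerate model whose bag score is exactly 0.5 for any input:
# one sigmoid node with zero weights and bias (activation 0.5), beta = 1
constant_half_model <- function(p = 2) {
  layer <- structure(list(input_weights = matrix(0, 1, p), biases = 0,
                          activation = "sigmoid", seed = 0L),
                     class = "hidden_layer")
  structure(list(layer = layer,
                 weights = structure(list(beta = 1, C = 1),
                                     class = "elm_weights"),
                 threshold = 0.5, scaling = NULL, win_indices = integer(0),
                 task = "classification", L = 1L, C = 1, seed = 0L,
                 activation = "sigmoid", call = NULL),
            class = "elm_mil")
}

# independent reference implementation of the two-step fit: plain loops,
# no shared code path with elm_mil() beyond the RNG draw order contract
reference_fit <- function(dataset, L, C, seed, scale = TRUE) {
  X <- do.call(rbind, lapply(dataset$bags, function(b) b$instances))
  p <- ncol(X)
  if (scale) {
    mn <- apply(X, 2, min); mx <- apply(X, 2, max)
    rng <- mx - mn; rng[rng == 0] <- 1
    sc <- function(M) sweep(sweep(M, 2, (mn + mx) / 2, "-"), 2, rng / 2, "/")
  } else {
    sc <- identity
  }
  set.seed(seed)
  W <- matrix(runif(L * p, -1, 1), L, p)
  b <- runif(L)
  beta0 <- runif(L, -1, 1)
  node <- function(x) 1 / (1 + exp(-(W %*% x + b)))
  win <- vapply(dataset$bags, function(bag) {
    S <- sc(bag$instances)
    o <- apply(S, 1, function(x) sum(beta0 * node(x)))
    which.max(o)
  }, integer(1))
  Xw <- t(vapply(seq_along(dataset$bags), function(i) {
    sc(dataset$bags[[i]]$instances)[win[i], ]
  }, numeric(p)))
  H <- t(apply(Xw, 1, node))
  Y <- vapply(dataset$bags, function(bag) bag$label, numeric(1))
  M <- nrow(H)
  beta <- if (M < L) {
    t(H) %*% solve(diag(M) / C + H %*% t(H), Y)
  } else {
    solve(diag(L) / C + t(H) %*% H, t(H) %*% Y)
  }
  list(win = win, beta = as.numeric(beta))
}
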