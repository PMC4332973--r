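test_that("hidden layers are reproducible, shaped and range-bounded", {
  l1 <- init_hidden_layer(3, 2, "sigmoid", seed = 42)
  l2 <- init_hidden_layer(3, 2, "sigmoid", seed = 42)
  expect_identical(l1, l2)

  l <- init_hidden_layer(1, 1, "sigmoid", seed = 1)
  expect_equal(dim(l$input_weights), c(1L, 1L))
  expect_length(l$biases, 1L)

  big <- init_hidden_layer(500, 166, "sigmoid", seed = 7)
  expect_true(all(big$input_weights >= -1 & big$input_weights <= 1))
  expect_true(all(big$biases >= 0 & big$biases <= 1))

  g <- init_hidden_layer(200, 5, "gaussian", seed = 3)
  expect_true(all(g$biases > 0 & g$biases <= 1))

  expect_error(init_hidden_layer(0, 3), "positive integer")
  expect_error(init_hidden_layer(3, -1), "positive integer")
})

test_that("activations match their closed forms", {
  # symmetry point, saturation, and a hand-computed zero of a.x + b
  expect_equal(activate_sigmoid(c(1, -1), 0, c(2, 2)), 0.5)
  expect_gt(activate_sigmoid(c(1, 1), 0, c(10, 10)), 0.999999)
  expect_equal(activate_sigmoid(c(0.3, -0.2), 0.1, c(1, 2)), 0.5)
  expect_error(activate_sigmoid(c(1, 2), 0, c(1, 2, 3)), "same length")

  expect_equal(activate_gaussian(c(1, 2), 5, c(1, 2)), 1)
  expect_equal(activate_gaussian(0, 1, 1), exp(-1))
  expect_equal(activate_gaussian(c(0, 0), 0.5, c(1, 1)), exp(-1))
  expect_error(activate_gaussian(c(0, 0), 0, c(1, 1)), "positive")
  expect_error(activate_gaussian(c(0, 0), -2, c(1, 1)), "positive")
})

test_that("hidden_matrix equals the per-element activation loop", {
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3)
  for (act in c("sigmoid", "gaussian")) {
    layer <- init_hidden_layer(4, 3, act, seed = 2)
    H <- hidden_matrix(layer, X)
    expect_equal(dim(H), c(5L, 4L))
    fun <- if (act == "sigmoid") activate_sigmoid else activate_gaussian
    ref <- matrix(0, 5, 4)
    for (i in 1:5) for (j in 1:4) {
      ref[i, j] <- fun(layer$input_weights[j, ], layer$biases[j], X[i, ])
    }
    expect_equal(H, ref, tolerance = 1e-12)
  }
  # vacuous input keeps the column contract
  layer <- init_hidden_layer(4, 3, seed = 2)
  expect_equal(dim(hidden_matrix(layer, matrix(0, 0, 3))), c(0L, 4L))
  expect_error(hidden_matrix(layer, matrix(0, 2, 5)), "expects")
})

test_that("hidden matrix entries obey the activation ranges", {
  set.seed(4)
  X <- matrix(rnorm(100 * 10, sd = 3), 100, 10)
  Hs <- hidden_matrix(init_hidden_layer(100, 10, "sigmoid", seed = 1), X)
  expect_true(all(Hs > 0 & Hs < 1))
  Hg <- hidden_matrix(init_hidden_layer(100, 10, "gaussian", seed = 1), X)
  expect_true(all(Hg > 0 & Hg <= 1))
})

test_that("output-weight solver matches hand-computable cases", {
  w <- solve_output_weights(diag(2), c(1, 0), C = 1)
  expect_equal(w$beta, c(0.5, 0))
  w <- solve_output_weights(diag(2), c(1, 0), C = 1e8)
  expect_equal(w$beta, c(1, 0), tolerance = 1e-6)
  expect_error(solve_output_weights(diag(2), c(1, 0), C = -1), "positive")
  expect_error(solve_output_weights(matrix(c(1, NA), 1), 1, C = 1), "finite")
  expect_error(solve_output_weights(diag(3), c(1, 0), C = 1), "row count")
})

test_that("primal and dual ridge forms agree on random problems", {
  set.seed(21)
  for (rep in 1:20) {
    N <- sample(3:12, 1)
    L <- sample(3:12, 1)
    H <- matrix(rnorm(N * L), N, L)
    Y <- rnorm(N)
    C <- 2^runif(1, -3, 7)
    b1 <- solve_output_weights(H, Y, C, form = "primal")$beta
    b2 <- solve_output_weights(H, Y, C, form = "dual")$beta
    expect_equal(b1, b2, tolerance = 1e-8)
  }
  # the spec-level wide example
  set.seed(5)
  H <- matrix(rnorm(54), 6, 9)
  Y <- rnorm(6)
  expect_equal(solve_output_weights(H, Y, 4, form = "dual")$beta,
               solve_output_weights(H, Y, 4, form = "primal")$beta,
               tolerance = 1e-8)
})

test_that("large C recovers the minimal-norm least-squares solution", {
  skip_if_not_installed("MASS")
  set.seed(31)
  for (dims in list(c(6, 9), c(9, 6), c(8, 8))) {
    H <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    Y <- rnorm(dims[1])
    b <- solve_output_weights(H, Y, C = 1e10)$beta
    expect_equal(b, as.numeric(MASS::ginv(H) %*% Y), tolerance = 1e-4)
  }
})

test_that("training residual is non-increasing in C and interpolates", {
  set.seed(41)
  H <- matrix(rnorm(40), 5, 8)
  Y <- rnorm(5)
  rss <- vapply(2^seq(-3, 10), function(C) {
    b <- solve_output_weights(H, Y, C)$beta
    sum((H %*% b - Y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
  # full-row-rank underdetermined system interpolates at huge C
  b <- solve_output_weights(H, Y, C = 1e10)$beta
  expect_lt(max(abs(H %*% b - Y)), 1e-4)
})

test_that("predict_instances equals the scalar network sum", {
  layer <- init_hidden_layer(6, 4, "sigmoid", seed = 8)
  beta <- runif(6, -1, 1)
  X <- matrix(rnorm(40), 10, 4)
  o <- predict_instances(layer, beta, X)
  ref <- apply(X, 1, function(x) {
    sum(beta * vapply(1:6, function(j) {
      activate_sigmoid(layer$input_weights[j, ], layer$biases[j], x)
    }, numeric(1)))
  })
  expect_equal(o, ref, tolerance = 1e-12)
  expect_equal(predict_instances(layer, rep(0, 6), X), rep(0, 10))
  expect_error(predict_instances(layer, rep(0, 5), X), "hidden nodes")
})
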