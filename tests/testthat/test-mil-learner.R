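test_that("bag_error is half the squared win-instance deviation", {
  expect_equal(bag_error(c(0.2, 0.9), 1), 0.005)
  expect_equal(bag_error(c(0.7, 0.7, 0.7), 0.7), 0)
  expect_equal(bag_error(c(0.3, 0.7), 0), 0.245)
  expect_error(bag_error(numeric(0), 1), "at least one")
})

test_that("win-instance selection is the first-max argmax per bag", {
  ds <- toy_dataset()
  layer <- init_hidden_layer(4, 2, seed = 3)
  # all-equal outputs tie-break to the first instance
  expect_equal(select_win_instances(ds, layer, rep(0, 4)), c(1L, 1L))
  # single-instance bags select their only instance
  one <- mil_dataset(list(mil_bag(c(1, 2), 1, "u"), mil_bag(c(3, 4), 0, "v")))
  beta <- runif(4, -1, 1)
  expect_equal(select_win_instances(one, layer, beta), c(1L, 1L))
  # brute-force argmax agreement, including a manufactured tie
  set.seed(9)
  bag <- mil_bag(matrix(rnorm(8), 4, 2), 1, "t")
  bag$instances[3, ] <- bag$instances[2, ]  # tie: instances 2 and 3 equal
  ds2 <- mil_dataset(list(bag, ds$bags[[2]]))
  o <- predict_instances(layer, beta, bag$instances)
  expect_equal(select_win_instances(ds2, layer, beta)[1],
               which(o == max(o))[1])
  expect_error(select_win_instances(ds, layer, rep(0, 3)), "hidden nodes")
})

test_that("the fit replays an independent reference loop exactly", {
  gen <- generate_classification_bags(synth_spec(n_bags = 50, seed = 4))
  for (seed in c(1, 9)) {
    fit <- elm_mil(gen$dataset, L = 30, C = 4, seed = seed)
    ref <- reference_fit(gen$dataset, L = 30, C = 4, seed = seed)
    expect_identical(fit$win_indices, ref$win)
    expect_equal(coef(fit), ref$beta, tolerance = 1e-10)
  }
})

test_that("the fit is deterministic given a seed", {
  gen <- generate_classification_bags(synth_spec(n_bags = 20, seed = 2))
  f1 <- elm_mil(gen$dataset, L = 25, C = 2, seed = 5)
  f2 <- elm_mil(gen$dataset, L = 25, C = 2, seed = 5)
  expect_identical(f1$win_indices, f2$win_indices)
  expect_identical(coef(f1), coef(f2))
})

test_that("single-instance bags reduce to plain ridge ELM", {
  set.seed(13)
  bags <- lapply(1:12, function(i) {
    mil_bag(rnorm(3), label = as.numeric(i %% 2), bag_id = paste0("b", i))
  })
  ds <- mil_dataset(bags)
  fit <- elm_mil(ds, L = 8, C = 4, seed = 6)
  # plain supervised ELM on the flattened instance table, same layer/scaling
  X <- do.call(rbind, lapply(bags, function(b) b$instances))
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  Xs <- sweep(sweep(X, 2, (mn + mx) / 2, "-"), 2, (mx - mn) / 2, "/")
  layer <- init_hidden_layer(8, 3, seed = 6)
  plain <- solve_output_weights(hidden_matrix(layer, Xs), bag_labels(ds), 4)
  expect_equal(coef(fit), plain$beta, tolerance = 1e-10)
})

test_that("beta is invariant to permuting distinct instances within bags", {
  gen <- generate_classification_bags(synth_spec(n_bags = 15, seed = 8))
  perm <- gen$dataset
  set.seed(1)
  perm$bags <- lapply(perm$bags, function(b) {
    b$instances <- b$instances[sample(nrow(b$instances)), , drop = FALSE]
    b
  })
  f1 <- elm_mil(gen$dataset, L = 20, C = 2, seed = 3)
  f2 <- elm_mil(perm, L = 20, C = 2, seed = 3)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("interpolation: with huge C training win-instances hit the labels", {
  gen <- generate_classification_bags(
    synth_spec(n_bags = 4, instances_per_bag = c(2, 4), p = 3,
               n_relevant = 2, seed = 12))
  fit <- elm_mil(gen$dataset, L = 10, C = 1e8, seed = 2)
  # positive training bags must score at least their label at the win
  # instance; verify via the stored win-instance rows
  ds <- elmmil:::scale_dataset(gen$dataset, fit$scaling)
  Xw <- t(sapply(seq_along(ds$bags), function(i) {
    ds$bags[[i]]$instances[fit$win_indices[i], ]
  }))
  o <- predict_instances(fit$layer, coef(fit), Xw)
  expect_equal(o, bag_labels(gen$dataset), tolerance = 1e-4)
})

test_that("bag scores are the max instance output and duplication-invariant", {
  gen <- generate_classification_bags(synth_spec(n_bags = 10, seed = 3))
  fit <- elm_mil(gen$dataset, L = 15, C = 2, seed = 4)
  bag <- gen$dataset$bags[[1]]
  s <- predict(fit, bag)
  Xs <- elmmil:::apply_minmax_scaling(bag$instances, fit$scaling)
  per_inst <- predict_instances(fit$layer, coef(fit), Xs)
  expect_equal(s, max(per_inst))
  # duplicating the argmax instance leaves the score unchanged
  top <- which.max(per_inst)
  bag2 <- mil_bag(rbind(bag$instances, bag$instances[top, ]), bag$label, "d")
  expect_equal(predict(fit, bag2), s)
})

test_that("classification threshold is closed at 0.5 and never clips", {
  m <- constant_half_model()
  bag <- mil_bag(c(0.3, -0.2), 1, "z")
  expect_equal(predict(m, bag), 0.5)
  expect_equal(predict(m, bag, type = "label"), 1L)
  # score just below the boundary is negative; above 1 stays positive
  m_low <- m; m_low$weights$beta <- 0.9998  # score 0.4999
  expect_equal(predict(m_low, bag, type = "label"), 0L)
  m_hi <- m; m_hi$weights$beta <- 2.6       # score 1.3
  expect_equal(predict(m_hi, bag, type = "label"), 1L)
})

test_that("squared_loss matches the scalar loop and label errors are caught", {
  gen <- generate_regression_bags(synth_spec(n_bags = 12, seed = 5))
  fit <- elm_mil(gen$dataset, L = 20, C = 2, seed = 1)
  loop <- mean(vapply(gen$dataset$bags, function(b) {
    (predict(fit, b) - b$label)^2
  }, numeric(1)))
  expect_equal(squared_loss(fit, gen$dataset), loop, tolerance = 1e-12)
  expect_error(predict(fit, gen$dataset, type = "label"), "classification")
})

test_that("fit rejects invalid inputs", {
  gen <- generate_classification_bags(synth_spec(n_bags = 6, seed = 1))
  expect_error(elm_mil(gen$dataset, L = 0), "positive integer")
  expect_error(elm_mil(gen$dataset, C = -1), "positive real")
  bad <- gen$dataset
  bad$bags[[1]]$label <- 0.3
  expect_error(elm_mil(bad), "0 or 1")
  expect_error(elm_mil(subset_bags(gen$dataset, 1)), "two bags")
})

test_that("single-pass recovery holds when every positive instance is a witness", {
  accs <- vapply(1:3, function(s) {
    gen <- generate_classification_bags(
      synth_spec(witness_rate = 1, seed = 20 + s))
    mean(cross_validate(gen$dataset, L = 100, C = 8,
                        plan = cv_plan(k = 10, repeats = 1, seed = s))$metric)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("iterated selection recovers sparse witnesses", {
  accs <- vapply(1:3, function(s) {
    gen <- generate_classification_bags(synth_spec(seed = 20 + s))
    mean(cross_validate(gen$dataset, L = 100, C = 8,
                        plan = cv_plan(k = 10, repeats = 1, seed = s),
                        n_reselect = 2)$metric)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})
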