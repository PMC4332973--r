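# Per-feature min-max scaling to [-1, 1], fitted on training instances only.
# MUSK-style features are large-magnitude integers; sigmoid nodes saturate
# without rescaling. Constant features map to 0.

fit_minmax_scaling <- function(X) {
  X <- as.matrix(X)
  list(min = apply(X, 2L, min), max = apply(X, 2L, max))
}

apply_minmax_scaling <- function(X, scaling) {
  if (is.null(scaling)) return(as.matrix(X))
  X <- as.matrix(X)
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1  # constant feature: centred to 0 below
  ctr <- (scaling$min + scaling$max) / 2
  sweep(sweep(X, 2L, ctr, "-"), 2L, rng / 2, "/")
}

scale_dataset <- function(dataset, scaling) {
  if (is.null(scaling)) return(dataset)
  out <- dataset
  out$bags <- lapply(dataset$bags, function(b) {
    b$instances <- apply_minmax_scaling(b$instances, scaling)
    b
  })
  out
}
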