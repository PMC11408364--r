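# Independent oracles and small random-instance generators. Every oracle is
# a literal transliteration of the defining rule (explicit loops and set
# arithmetic), deliberately separate from the vectorised implementation.

# clip/subtract preprocessing applied voxel by voxel
oracle_preprocess <- function(v, lower, upper) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    x <- v[i]
    if (x > upper) x <- 0 else {
      x <- x - lower
      if (x < 0) x <- 0
    }
    out[i] <- x
  }
  out
}

# Pearson coefficient as the literal covariance quotient
oracle_pcc <- function(a, b, ta, tb) {
  x <- oracle_preprocess(as.vector(a), ta[1], ta[2])
  y <- oracle_preprocess(as.vector(b), tb[1], tb[2])
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  if (dx == 0 || dy == 0) return(NA_real_)
  num / sqrt(dx * dy)
}

# binarisation rule applied voxel by voxel
oracle_mask <- function(v, lower, upper) {
  w <- numeric(length(v))
  for (i in seq_along(v))
    w[i] <- if (v[i] > lower && v[i] <= upper) 1 else 0
  w
}

# intersection coefficients by explicit voxel index sets
oracle_intersection <- function(mask_vectors) {
  sets <- lapply(mask_vectors, function(w) which(w == 1))
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  I <- if (length(uni) == 0) NA_real_ else length(inter) / length(uni)
  iks <- vapply(sets, function(s)
    if (length(s) == 0) NA_real_ else length(inter) / length(s), numeric(1))
  c(list(I = I), as.list(iks))
}

# random integer-valued stack channels on a small grid
random_channels <- function(k, dims = c(4, 6, 6), maxv = 20) {
  lapply(seq_len(k), function(i)
    array(sample(0:maxv, prod(dims), replace = TRUE), dims))
}

# random threshold pair inside [0, maxv]
random_threshold <- function(maxv = 20) {
  b <- sort(sample(0:maxv, 2, replace = TRUE))
  threshold_range(b[1], b[2])
}

# the engineered two-box geometry: |A| = 4000, |B| = 3000, |A&B| = 2000
engineered_two_box_spec <- function(noise_sd = 0, seed = 7L) {
  fixture_spec(
    dims = c(10, 20, 40), bit_depth = 8,
    shapes = list(
      list(list(type = "box", min = c(0, 0, 0),  max = c(10, 20, 20))),
      list(list(type = "box", min = c(0, 0, 10), max = c(10, 20, 25)))),
    plateau = 200, background_level = 0, noise_sd = noise_sd, seed = seed,
    name = "engineered")
}
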