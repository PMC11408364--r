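test_that("weight mask obeys the boundary rule: strict at lower, inclusive at upper", {
  t <- threshold_range(2, 5)
  v <- array(c(1, 2, 3, 5, 6, 0), c(1, 2, 3))
  w <- weight_mask(v, t)$weights
  # value at lower -> 0, at upper -> 1, above upper -> 0
  expect_identical(as.vector(w), c(0, 0, 1, 1, 0, 0))
  expect_identical(as.vector(weight_mask(array(c(1, 3, 6), c(1, 1, 3)),
                                         t)$weights),
                   c(0, 1, 0))
})

test_that("weight mask matches the voxel-by-voxel rule on random channels", {
  set.seed(21)
  for (rep in 1:20) {
    v <- random_channels(1, c(3, 4, 4))[[1]]
    t <- random_threshold()
    expect_identical(as.vector(weight_mask(v, t)$weights),
                     oracle_mask(as.vector(v), t$lower, t$upper))
  }
})

test_that("all voxels below lower give an all-zero mask; lower == upper empties it", {
  v <- array(0:7, c(2, 2, 2))
  expect_true(all(weight_mask(v, threshold_range(10, 20))$weights == 0))
  expect_true(all(weight_mask(v, threshold_range(4, 4))$weights == 0))
})

test_that("widening the threshold range never shrinks the mask", {
  set.seed(22)
  v <- random_channels(1)[[1]]
  for (rep in 1:25) {
    t1 <- random_threshold()
    widen_lo <- max(t1$lower - sample(0:3, 1), 0)
    widen_hi <- t1$upper + sample(0:3, 1)
    t2 <- threshold_range(widen_lo, widen_hi)
    expect_gte(sum(weight_mask(v, t2)$weights),
               sum(weight_mask(v, t1)$weights))
  }
})

test_that("mask binarisation is idempotent on a rescaled binary volume", {
  set.seed(23)
  v <- random_channels(1)[[1]]
  w1 <- weight_mask(v, threshold_range(5, 15))$weights
  w2 <- weight_mask(w1, threshold_range(0, 1))$weights
  expect_identical(w1, w2)
})

test_that("clip-and-subtract preprocessing follows the stated rule", {
  t <- threshold_range(2, 5)
  expect_identical(as.vector(preprocess_for_pcc(array(c(1, 3, 6),
                                                      c(1, 1, 3)), t)),
                   c(0, 1, 0))
  # all voxels equal to upper become upper - lower
  v <- array(5, c(2, 2, 2))
  expect_true(all(preprocess_for_pcc(v, t) == 3))
  # full-range thresholds with lower 0: identity transform
  v2 <- array(0:7, c(2, 2, 2))
  expect_identical(preprocess_for_pcc(v2, threshold_range(0, 7)), v2 * 1.0)
})

test_that("preprocessing matches the voxel-by-voxel oracle on random channels", {
  set.seed(24)
  for (rep in 1:20) {
    v <- random_channels(1, c(3, 4, 4))[[1]]
    t <- random_threshold()
    expect_equal(as.vector(preprocess_for_pcc(v, t)),
                 oracle_preprocess(as.vector(v), t$lower, t$upper))
  }
})

test_that("mask = 1 implies preprocessed value = v - lower > 0", {
  set.seed(25)
  for (rep in 1:20) {
    v <- random_channels(1)[[1]]
    t <- random_threshold()
    w <- weight_mask(v, t)$weights
    p <- preprocess_for_pcc(v, t)
    on_mask <- w == 1
    expect_true(all(p[on_mask] == v[on_mask] - t$lower))
    expect_true(all(p[on_mask] > 0))
  }
})

test_that("auto threshold excludes the top/bottom 0.1% by nearest rank", {
  # constant channel: both bounds collapse to the constant
  t0 <- auto_threshold(array(7, c(2, 2, 2)))
  expect_identical(c(t0$lower, t0$upper), c(7, 7))

  # sorted-index oracle on a seeded uniform sample
  set.seed(26)
  v <- array(sample(0:65535, 100000, replace = TRUE), c(100, 100, 10))
  t <- auto_threshold(v)
  s <- sort(as.vector(v))
  expect_identical(t$lower, as.numeric(s[ceiling(0.001 * length(s))]))
  expect_identical(t$upper, as.numeric(s[ceiling(0.999 * length(s))]))
  expect_true(t$lower < 200 && t$upper > 65300)

  # each value once: ranks 1 and 999 of 1..1000
  v2 <- array(sample(1:1000), c(10, 10, 10))
  t2 <- auto_threshold(v2)
  expect_identical(c(t2$lower, t2$upper), c(1, 999))
})

test_that("threshold construction validates its bounds", {
  expect_error(threshold_range(5, 2), "exceeds")
  expect_s3_class(full_range(array(3:9, c(1, 1, 7))), "threshold_range")
  expect_identical(full_range(array(3:9, c(1, 1, 7)))$lower, 3)
})
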