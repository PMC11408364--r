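test_that("identical, affine and complemented channels hit the PCC extremes", {
  a <- array(c(0, 1, 2, 3, 10, 20, 30, 40), c(2, 2, 2))
  expect_equal(pearson_coloc(a, a), 1)
  expect_equal(pearson_coloc(a, 3 * a + 7), 1)      # perfect linear
  expect_equal(pearson_coloc(a, max(a) - a), -1)    # perfectly inverse
})

test_that("zero-variance preprocessed channels yield an undefined marker", {
  a <- array(c(0, 1, 2, 3, 4, 5, 6, 7), c(2, 2, 2))
  flat <- array(5, c(2, 2, 2))
  expect_true(is.na(pearson_coloc(a, flat)))
  # a threshold band that silences every voxel also kills the variance
  expect_true(is.na(pearson_coloc(a, a, t_b = threshold_range(7, 7))))
  expect_identical(format_coeff(NA_real_), "n/a")
})

test_that("pearson matches the literal covariance-quotient oracle", {
  # fixed small example with thresholds (2, 5) on both channels
  a <- array(c(1, 3, 6, 2, 4, 5, 0, 3), c(2, 2, 2))
  b <- array(c(2, 5, 1, 3, 6, 4, 2, 0), c(2, 2, 2))
  t <- threshold_range(2, 5)
  expect_equal(pearson_coloc(a, b, t, t), oracle_pcc(a, b, c(2, 5), c(2, 5)),
               tolerance = 1e-12)

  set.seed(41)
  n_def <- 0
  for (rep in 1:60) {
    ch <- random_channels(2)
    ta <- random_threshold(); tb <- random_threshold()
    got <- pearson_coloc(ch[[1]], ch[[2]], ta, tb)
    want <- oracle_pcc(ch[[1]], ch[[2]], c(ta$lower, ta$upper),
                       c(tb$lower, tb$upper))
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      n_def <- n_def + 1
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(got >= -1 && got <= 1)
      # symmetry and positive-affine invariance on the same instance
      expect_equal(pearson_coloc(ch[[2]], ch[[1]], tb, ta), got,
                   tolerance = 1e-12)
      scaled <- preprocess_for_pcc(ch[[1]], ta) * 2.5 + 1
      expect_equal(pearson_coloc(scaled, ch[[2]],
                                 threshold_range(0, max(scaled)), tb),
                   got, tolerance = 1e-10)
    }
  }
  expect_gt(n_def, 30)  # the sweep must actually exercise defined cases
})

test_that("two-channel intersection coefficients match hand counts", {
  # 8-voxel fixture: |A| = 4, |B| = 3, |A&B| = 2
  a <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  b <- array(c(1, 1, 0, 0, 1, 0, 0, 0), c(2, 2, 2))
  r <- intersection_2ch(a, b)
  expect_equal(r$I, 0.4)
  expect_equal(r$i1, 0.5)
  expect_equal(r$i2, 2 / 3)
  # identical non-empty masks
  r1 <- intersection_2ch(a, a)
  expect_equal(unlist(r1), c(I = 1, i1 = 1, i2 = 1))
  # disjoint non-empty masks
  d <- array(c(0, 0, 0, 0, 1, 1, 0, 0), c(2, 2, 2))
  r0 <- intersection_2ch(a, d)
  expect_equal(unlist(r0), c(I = 0, i1 = 0, i2 = 0))
})

test_that("three-channel coefficients follow inclusion-exclusion", {
  m <- function(idx) {
    w <- numeric(5); w[idx] <- 1; array(w, c(1, 1, 5))
  }
  r <- intersection_3ch(m(1:3), m(2:4), m(3:5))
  expect_equal(r$I, 0.2)          # triple = {3}, union = 5 voxels
  expect_equal(r$i1, 1 / 3)
  expect_equal(r$i2, 1 / 3)
  expect_equal(r$i3, 1 / 3)
  r1 <- intersection_3ch(m(1:3), m(1:3), m(1:3))
  expect_equal(unlist(r1), c(I = 1, i1 = 1, i2 = 1, i3 = 1))
})

test_that("intersection coefficients equal the set-arithmetic oracle", {
  set.seed(42)
  for (rep in 1:60) {
    k <- sample(2:3, 1)
    ch <- random_channels(k)
    ts <- replicate(k, random_threshold(), simplify = FALSE)
    masks <- lapply(seq_len(k), function(j) weight_mask(ch[[j]], ts[[j]]))
    got <- if (k == 2) intersection_2ch(masks[[1]], masks[[2]])
           else intersection_3ch(masks[[1]], masks[[2]], masks[[3]])
    want <- oracle_intersection(lapply(masks,
                                       function(m) as.vector(m$weights)))
    expect_equal(unname(unlist(got)), unname(unlist(want)))
    # union denominator equals the logical-OR voxel count
    if (!is.na(got$I) && got$I > 0) {
      or_count <- sum(Reduce(`|`, lapply(masks, function(m) m$weights == 1)))
      inter_count <- sum(Reduce(`*`, lapply(masks, function(m) m$weights)))
      expect_equal(got$I, inter_count / or_count)
    }
    # I <= i_k for every defined per-channel coefficient
    for (ik in unlist(got[-1]))
      if (!is.na(ik) && !is.na(got$I)) expect_lte(got$I, ik + 1e-15)
  }
})

test_that("degenerate masks produce undefined markers exactly as specified", {
  e <- array(0, c(1, 2, 2))
  a <- array(c(1, 1, 0, 0), c(1, 2, 2))
  both_empty <- intersection_2ch(e, e)
  expect_true(all(is.na(unlist(both_empty))))
  one_empty <- intersection_2ch(e, a)
  expect_true(is.na(one_empty$i1))
  expect_equal(one_empty$I, 0)
  expect_equal(one_empty$i2, 0)
  tri <- intersection_3ch(e, e, e)
  expect_true(all(is.na(unlist(tri))))
  tri1 <- intersection_3ch(a, a, e)
  expect_true(is.na(tri1$i3))
  expect_equal(tri1$I, 0)
})

test_that("two-channel form agrees with the three-channel form on a duplicated mask", {
  set.seed(43)
  for (rep in 1:25) {
    ch <- random_channels(2)
    ta <- random_threshold(); tb <- random_threshold()
    ma <- weight_mask(ch[[1]], ta); mb <- weight_mask(ch[[2]], tb)
    r2 <- intersection_2ch(ma, mb)
    r3 <- intersection_3ch(ma, mb, mb)
    expect_equal(r3$I, r2$I)
    expect_equal(r3$i1, r2$i1)
    expect_equal(r3$i2, r2$i2)
    expect_equal(r3$i3, r2$i2)
  }
})

test_that("intersection coefficients depend only on the masks", {
  set.seed(44)
  ch <- random_channels(2)
  ta <- random_threshold(); tb <- random_threshold()
  ma <- weight_mask(ch[[1]], ta)
  # any intensity change preserving the mask preserves the coefficients
  bumped <- ch[[1]]
  inside <- ma$weights == 1 & ch[[1]] < ta$upper
  bumped[inside] <- pmin(bumped[inside] + 1, ta$upper)
  ma2 <- weight_mask(bumped, ta)
  expect_identical(ma$weights, ma2$weights)
  mb <- weight_mask(ch[[2]], tb)
  expect_identical(unlist(intersection_2ch(ma, mb)),
                   unlist(intersection_2ch(ma2, mb)))
})

test_that("analyze_coloc validates its channel selection", {
  s <- zstack(random_channels(4, c(2, 3, 3), 255), bit_depth = 8)
  expect_error(analyze_coloc(s, 1:4), "2 or 3")
  expect_error(analyze_coloc(s, 1), "2 or 3")
  expect_error(analyze_coloc(s, c(1, 1)), "distinct")
  expect_error(analyze_coloc(s, c(1, 9)), "out of range")
})

test_that("full-extent ROI and omitted ROI give identical results", {
  set.seed(45)
  s <- zstack(random_channels(2, c(4, 6, 6), 20), bit_depth = 8)
  ts <- list(c(5, 15), c(3, 18))
  r1 <- analyze_coloc(s, c(1, 2), ts)
  r2 <- analyze_coloc(s, c(1, 2), ts, box = roi_box(c(0, 0, 0), s$dims))
  expect_equal(r1$pcc, r2$pcc)
  expect_equal(r1$global_intersection, r2$global_intersection)
  expect_equal(r1$venn_fractions, r2$venn_fractions)
  expect_identical(r1$n_voxels, prod(s$dims))
})

test_that("metrics commute with ROI cropping", {
  set.seed(46)
  for (rep in 1:10) {
    s <- zstack(random_channels(2, c(4, 6, 6), 20), bit_depth = 8)
    box <- roi_box(c(1, 0, 2), c(4, 5, 6))
    ts <- replicate(2, random_threshold(), simplify = FALSE)
    r_boxed <- analyze_coloc(s, c(1, 2), ts, box)
    r_pre <- analyze_coloc(crop_stack(s, box), c(1, 2), ts)
    expect_equal(r_boxed$pcc, r_pre$pcc)
    expect_equal(r_boxed$global_intersection, r_pre$global_intersection)
    expect_equal(r_boxed$per_channel_intersection,
                 r_pre$per_channel_intersection)
  }
})

test_that("analyze_coloc resolves keyword and named threshold specs", {
  set.seed(47)
  s <- zstack(random_channels(2, c(3, 4, 4), 255), bit_depth = 8)
  r_auto <- analyze_coloc(s, c(1, 2), "auto")
  expect_s3_class(r_auto$thresholds[["1"]], "threshold_range")
  r_named <- analyze_coloc(s, c(2, 1),
                           list("1" = c(0, 100), "2" = c(50, 255)))
  expect_equal(r_named$thresholds[["1"]]$upper, 100)
  expect_equal(r_named$thresholds[["2"]]$lower, 50)
  expect_error(analyze_coloc(s, c(1, 2), list("bogus", "full")),
               "unrecognised threshold")
})
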