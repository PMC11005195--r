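test_that("sum projection matches a brute-force per-pixel loop", {
  set.seed(3)
  v <- array(runif(3 * 5 * 4), c(3, 5, 4))
  got <- sum_projection(v)
  oracle <- matrix(0, 5, 4)
  for (y in 1:5) for (x in 1:4) for (z in 1:3) {
    oracle[y, x] <- oracle[y, x] + v[z, y, x]
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  one <- array(runif(20), c(1, 5, 4))
  expect_equal(sum_projection(one), matrix(one[1, , ], 5, 4))
  plane <- matrix(runif(20), 5, 4)
  two <- array(0, c(2, 5, 4)); two[1, , ] <- plane; two[2, , ] <- plane
  expect_equal(sum_projection(two), 2 * plane)
  expect_error(sum_projection(array(0, c(0, 4, 4))), "empty|non-empty")
})

test_that("ratio image guards the division and masks low donors", {
  don <- matrix(c(0, 1, 10, 20), 2, 2)
  acc <- 2 * don
  ri <- ratio_image(acc, don, donor_floor = 5)
  expect_true(is.na(ri$ratio[1, 1]))      # donor 0: masked, not infinite
  expect_true(is.na(ri$ratio[2, 1]))      # below floor
  expect_equal(ri$ratio[don >= 5], c(2, 2))
  expect_identical(ri$valid, don >= 5)
  expect_error(ratio_image(acc, don[1, , drop = FALSE], 5), "shape")
  expect_error(ratio_image(acc, don, 0), "> 0")
})

test_that("FRET index is the raw integrated density of the ratio in the ROI", {
  don <- matrix(10, 20, 20)
  acc <- matrix(20, 20, 20)
  cp <- structure(list(donor = array(don, c(1, 20, 20)),
                       acceptor = array(acc, c(1, 20, 20)),
                       method = "band_window"), class = "channel_pair")
  roi <- rect_roi(0, 10, 0, 10, c(20, 20))   # 100 px, ratio 2 everywhere
  m <- fret_index(cp, roi, donor_floor = 1)
  expect_equal(m$index, 200)
  # additivity over disjoint ROIs
  roi2 <- rect_roi(10, 20, 0, 10, c(20, 20))
  m2 <- fret_index(cp, roi2, donor_floor = 1)
  mu <- fret_index(cp, roi | roi2, donor_floor = 1)
  expect_equal(mu$index, m$index + m2$index, tolerance = 1e-12)
  # ROI entirely below the floor -> flagged, index undefined
  low <- fret_index(cp, roi, donor_floor = 100)
  expect_true(is.na(low$index))
  expect_identical(low$flag, "all_below_floor")
})

test_that("FRET index is invariant to a common intensity scale", {
  ph <- uniform_phantom(0.5, c(32, 32), seed = 2, texture = 0.1)
  st <- render_lambda_stack(ph, noise = noise_free())
  cp <- band_window_separation(st)
  roi <- roi_from_domain(ph, "margin")
  m1 <- fret_index(cp, roi, donor_floor = 0.5)
  cp_scaled <- cp
  cp_scaled$donor <- cp$donor * 3
  cp_scaled$acceptor <- cp$acceptor * 3
  m2 <- fret_index(cp_scaled, roi, donor_floor = 0.5 * 3)
  expect_equal(m2$index, m1$index, tolerance = 1e-12)
})

test_that("FRET index increases strictly with ground-truth activity", {
  acts <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  idx <- vapply(acts, function(a) {
    ph <- uniform_phantom(a, c(32, 32), texture = 0)
    cp <- band_window_separation(render_lambda_stack(ph, noise = noise_free()))
    fret_index(cp, ph$mask)$index
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("margin ROI outranks bulk ROI when margin activity is higher", {
  ph <- make_embryo_phantom("gastrula_5hpf", c(48, 48),
                            c(margin = 0.6, bulk = 0.2), seed = 5,
                            density_texture_sd = 0)
  cp <- band_window_separation(render_lambda_stack(ph, noise = noise_free()))
  don <- sum_projection(cp$donor); acc <- sum_projection(cp$acceptor)
  ri <- ratio_image(acc, don, 0.01 * max(don))
  m_margin <- mean(ri$ratio[roi_from_domain(ph, "margin")], na.rm = TRUE)
  m_bulk <- mean(ri$ratio[roi_from_domain(ph, "bulk")], na.rm = TRUE)
  expect_gt(m_margin, m_bulk)
})

test_that("projection order changes the index by less than 5% on noise-free data", {
  ph <- uniform_phantom(0.5, c(32, 32), seed = 4, texture = 0.15)
  st <- render_lambda_stack(ph, acquisition = spectral_acquisition(n_z = 3),
                            noise = noise_free())
  cp <- band_window_separation(st)
  roi <- roi_from_domain(ph, "margin")
  a <- fret_index(cp, roi, order = "ratio_of_projections")$index
  b <- fret_index(cp, roi, order = "projection_of_ratios")$index
  expect_lt(abs(a - b) / a, 0.05)
})

test_that("fold change behaves as declared", {
  ctrl <- c(10, 12, 8, 10)
  fc1 <- fold_change(list(t = ctrl, c = ctrl), "t", "c")
  expect_equal(fc1$fc, 1)
  fc2 <- fold_change(list(t = rep(2 * mean(ctrl), 5), c = ctrl), "t", "c")
  expect_equal(fc2$fc, 2)
  # paired mode: per-embryo post/pre
  fcp <- fold_change(list(post = c(2, 4, 6), pre = c(1, 2, 3)), "post", "pre",
                     paired = TRUE)
  expect_equal(fcp$per_embryo_fc, c(2, 2, 2))
  expect_error(fold_change(list(t = 1, c = numeric(0)), "t", "c"), "empty")
  expect_error(fold_change(list(t = 1, c = c(-2, 2)), "t", "c"), "> 0")
})
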