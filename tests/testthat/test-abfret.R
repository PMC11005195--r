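test_that("efficiency formula reproduces the de-quenching arithmetic", {
  pre <- matrix(100, 8, 8)
  post <- matrix(125, 8, 8)
  roi <- matrix(TRUE, 8, 8)
  est <- ab_efficiency(pre, post, roi)
  expect_equal(est$E, 0.20)
  expect_equal(est$DA, 100); expect_equal(est$DOmega, 125)
  # DA = DOmega -> E = 0
  expect_equal(ab_efficiency(pre, pre, roi)$E, 0)
  # negative E retained and flagged, never clamped
  neg <- ab_efficiency(matrix(110, 8, 8), matrix(100, 8, 8), roi)
  expect_lt(neg$E, 0)
  expect_true(neg$negative)
  expect_error(ab_efficiency(pre, matrix(0, 8, 8), roi), "undefined")
  # the two pre scans are averaged before DA
  est2 <- ab_efficiency(list(matrix(90, 8, 8), matrix(110, 8, 8)), post, roi)
  expect_equal(est2$DA, 100)
})

test_that("noise-free complete-bleach series recovers the generator truth", {
  ph <- uniform_phantom(0.5, c(48, 48), texture = 0.1)   # E_eff = 0.20
  roi <- roi_from_domain(ph, "margin")
  bs <- render_bleach_series(ph, roi, iterations = 50,
                             per_iteration_survival = 0,
                             noise = noise_free())
  est <- ab_efficiency(bs$pre_donor, bs$post_donor, roi)
  expect_equal(est$E, mean(ph$efficiency[roi]), tolerance = 1e-6)
})

test_that("incomplete bleach follows the exact closed form E(1-s)/(1-Es)", {
  ph <- uniform_phantom(5 / 6, c(48, 48), texture = 0)   # E_eff = 0.30
  roi <- roi_from_domain(ph, "margin")
  E <- ph$efficiency[roi][1]
  for (surv in c(0.9, 0.95)) {
    bs <- render_bleach_series(ph, roi, iterations = 50,
                               per_iteration_survival = surv,
                               noise = noise_free())
    s <- surv^50
    est <- ab_efficiency(bs$pre_donor, bs$post_donor, roi)
    expect_equal(est$E, E * (1 - s) / (1 - E * s), tolerance = 1e-9)
    # the first-order reading (1 - s) * E holds within its analytic bound
    expect_lt(abs(est$E - (1 - s) * E), E^2 * s / (1 - E * s) + 1e-12)
  }
})

test_that("estimated efficiency increases with ground-truth efficiency", {
  ests <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(a) {
    ph <- uniform_phantom(a, c(32, 32), texture = 0)
    roi <- roi_from_domain(ph, "margin")
    bs <- render_bleach_series(ph, roi, per_iteration_survival = 0,
                               noise = noise_free())
    ab_efficiency(bs$pre_donor, bs$post_donor, roi)$E
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("distance inversion matches the printed formula and its limits", {
  expect_equal(distance_from_efficiency(0.5), 4.7, tolerance = 1e-12)
  # (1/E - 1) = 64 -> 64^(1/6) = 2 -> 9.4 nm
  expect_equal(distance_from_efficiency(1 / 65), 9.4, tolerance = 1e-12)
  expect_true(is.na(distance_from_efficiency(0)))
  expect_true(is.na(distance_from_efficiency(-0.1)))
  expect_warning(r1 <- distance_from_efficiency(1), "limit")
  expect_equal(unname(r1), 0)
  # E -> 1- drives R_DA -> 0
  expect_lt(distance_from_efficiency(1 - 1e-9), 0.15)
  expect_error(forster_config(-1), "positive")
})

test_that("efficiency-distance round trip is exact", {
  E <- seq(0.01, 0.99, by = 0.01)
  R <- distance_from_efficiency(E)
  expect_equal(efficiency_from_distance(R), E, tolerance = 1e-12)
  # monotone: R_DA strictly decreasing in E
  expect_true(all(diff(R) < 0))
})

test_that("pre-bleach metrics report donor de-quenching of suppressed sensors", {
  roi <- matrix(TRUE, 8, 8)
  same <- matrix(50, 8, 8)
  pm <- pre_ab_metrics(same, same, roi)
  expect_equal(pm$pre_ratio, 1)
  # suppressed efficiency (MEKi) -> lower acceptor/donor ratio, brighter donor
  hi <- uniform_phantom(0.8, c(48, 48), texture = 0)
  lo <- uniform_phantom(0.2, c(48, 48), texture = 0)
  roi2 <- roi_from_domain(hi, "margin")
  bhi <- render_bleach_series(hi, roi2, noise = noise_free())
  blo <- render_bleach_series(lo, roi2, noise = noise_free())
  mhi <- pre_ab_metrics(bhi$pre_donor, bhi$pre_acceptor, roi2)
  mlo <- pre_ab_metrics(blo$pre_donor, blo$pre_acceptor, roi2)
  expect_lt(mlo$pre_ratio, mhi$pre_ratio)
  expect_gt(mlo$pre_donor, mhi$pre_donor)
  expect_error(pre_ab_metrics(same, same, matrix(FALSE, 8, 8)), "non-empty")
})

test_that("run_abfret applies the exclusion rules per ROI", {
  ph <- uniform_phantom(0.5, c(48, 48), texture = 0)
  margin <- roi_from_domain(ph, "margin")
  bs <- render_bleach_series(ph, margin, per_iteration_survival = 0,
                             noise = noise_free())
  outside <- roi_from_domain(ph, "bulk")
  res <- run_abfret(bs, list(margin = margin, bulk = outside))
  expect_identical(res$excluded_reason, c("none", "not_bleached"))
  expect_true(is.na(res$E[2]) && is.na(res$R_DA_nm[2]))
  expect_false(is.na(res$pre_ratio[2]))   # pre-bleach metrics still reported
  expect_equal(res$E[1], 0.20, tolerance = 1e-9)
  # survival 1 -> E ~ 0
  bs1 <- render_bleach_series(ph, margin, per_iteration_survival = 1,
                              noise = noise_free())
  res1 <- run_abfret(bs1, list(margin = margin))
  expect_lt(abs(res1$E[1]), 1e-12)
  expect_identical(res1$excluded_reason[1], "E_zero_or_negative")
  expect_true(is.na(res1$R_DA_nm[1]))
})

test_that("threshold classification counts strictly-greater as high, ties as low", {
  cl <- classify_by_threshold(c(5, 8, 9), threshold = 7.53)
  expect_equal(cl$prop_high, 2 / 3)
  expect_equal(classify_by_threshold(c(1, 2, 3), 7.53)$n_high, 0L)
  expect_equal(classify_by_threshold(c(7.53, 8), 7.53)$n_high, 1L)  # tie -> low
  two <- classify_by_threshold(list(a = c(10, 10), b = c(1, 10)), 7.53)
  expect_equal(two$prop_high, c(1, 0.5))
  expect_error(classify_by_threshold(numeric(0)), "empty")
  expect_error(classify_by_threshold(c(1, 2), threshold = -1), "> 0")
})
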