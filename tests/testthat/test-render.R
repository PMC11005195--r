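test_that("noise-free total intensity matches the conservation identity", {
  # with unit-area spectra and an acquisition covering the support, the sum
  # over bands is density * photon_budget * ((1 - E) * Q_D + E * Q_A)
  ph <- uniform_phantom(0.5, c(48, 48), texture = 0)
  acq <- spectral_acquisition(400, 700, 5)
  st <- render_lambda_stack(ph, acquisition = acq, noise = noise_free(100))
  tot <- apply(st$data[1, , , ], c(1, 2), sum)
  inside <- ph$mask
  E <- ph$efficiency[inside][1]
  expect_equal(tot[inside], rep(100 * ((1 - E) + E), sum(inside)),
               tolerance = 1e-6)
  expect_true(all(tot[!inside] == 0))
})

test_that("rendered stacks are deterministic in the seed", {
  ph <- uniform_phantom(0.3)
  a <- render_lambda_stack(ph, seed = 5)
  b <- render_lambda_stack(ph, seed = 5)
  c <- render_lambda_stack(ph, seed = 6)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("acceptor-window/donor-window ratio increases strictly with efficiency", {
  # expected-value model across E = 0.1 ... 0.9, noise off
  ratios <- vapply(seq(0.1, 0.9, by = 0.1), function(E) {
    s <- expected_window_signal(E)
    s[["acceptor"]] / s[["donor"]]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  # and the rendered stacks agree: donor signal strictly decreasing in E
  acts <- seq(0.1, 0.9, by = 0.2)
  donor_sig <- vapply(acts, function(a) {
    ph <- uniform_phantom(a, c(32, 32), texture = 0)
    cp <- band_window_separation(render_lambda_stack(ph, noise = noise_free()))
    mean(cp$donor[1, , ][ph$mask])
  }, numeric(1))
  expect_true(all(diff(donor_sig) < 0))
})

test_that("pure-donor stack puts only bleed-through in the acceptor window", {
  # activity chosen so E_eff = 0 exactly (degenerate two-state sensor)
  ph <- make_embryo_phantom("gastrula_5hpf", c(32, 32),
                            c(margin = 0, bulk = 0), seed = 1,
                            e_inactive = 0, e_active = 0.5,
                            density_texture_sd = 0)
  st <- render_lambda_stack(ph, noise = noise_free(100))
  cp <- band_window_separation(st)
  # the selected bands tile 467-502 nm (donor) and 527-572 nm (acceptor):
  # integrate the oracle over the actual band coverage
  oracle <- expected_window_signal(0, donor_window = c(467, 502),
                                   acceptor_window = c(527, 572))
  px <- which(ph$mask)[1]
  # the acceptor window sees only the donor's far tail, where linear
  # interpolation of the sampled spectrum costs a few parts in a thousand
  expect_equal(cp$acceptor[1, , ][px], oracle[["acceptor"]], tolerance = 5e-3)
  expect_equal(cp$donor[1, , ][px], oracle[["donor"]], tolerance = 1e-3)
})

test_that("bleach series obeys the forward-model algebra", {
  ph <- uniform_phantom(0.5, c(48, 48), texture = 0)  # E_eff = 0.20
  roi <- roi_from_domain(ph, "margin")
  E <- ph$efficiency[roi][1]
  # complete bleach: donor rises by 1/(1-E) inside the ROI
  bs <- render_bleach_series(ph, roi, iterations = 1,
                             per_iteration_survival = 0,
                             noise = noise_free(100))
  expect_equal(mean(bs$post_donor[roi]) / mean(bs$pre_donor[[1]][roi]),
               1 / (1 - E), tolerance = 1e-9)
  # donor untouched outside the bleach ROI
  outside <- ph$mask & !roi
  expect_equal(bs$post_donor[outside], bs$pre_donor[[1]][outside],
               tolerance = 1e-12)
  # survival 1: pre and post expected frames identical
  bs1 <- render_bleach_series(ph, roi, iterations = 50,
                              per_iteration_survival = 1,
                              noise = noise_free(100))
  expect_equal(bs1$post_donor, bs1$pre_donor[[1]], tolerance = 1e-12)
  # acceptor never gains from bleaching
  expect_true(all(bs$post_acceptor[roi] <= bs$pre_acceptor[[1]][roi] + 1e-12))
})

test_that("bleach series validates its inputs", {
  ph <- uniform_phantom(0.3, c(32, 32))
  roi <- roi_from_domain(ph, "margin")
  expect_error(render_bleach_series(ph, roi[1:10, 1:10]), "matching")
  expect_error(render_bleach_series(ph, roi, iterations = 0), ">= 1")
  expect_error(render_bleach_series(ph, roi, per_iteration_survival = 1.5),
               "\\[0, 1\\]")
  expect_error(render_bleach_series(ph, matrix(FALSE, 32, 32)), "empty")
})

test_that("cohort generation writes the group effects into the truth maps", {
  cfg <- cohort_config(
    groups = list(list(name = "WT", n_embryos = 4, multipliers = list(margin = 1)),
                  list(name = "D61G", n_embryos = 4, multipliers = list(margin = 1.3))),
    shape = c(48L, 48L), embryo_sdlog = 0.02, seed = 9)
  coh <- make_cohort(cfg, render = character(0))
  tr <- coh$truth
  ratio <- mean(tr$margin_activity[tr$group == "D61G"]) /
    mean(tr$margin_activity[tr$group == "WT"])
  expect_equal(ratio, 1.3, tolerance = 0.05)  # sampling error at sdlog 0.02
  # same seed => bit-identical cohort
  coh2 <- make_cohort(cfg, render = character(0))
  expect_identical(coh$truth, coh2$truth)
  expect_error(cohort_config(groups = list()), "non-empty")
})

test_that("dose suppression is written into the truth exactly", {
  cfg <- cohort_config(
    groups = list(list(name = "D61G", n_embryos = 3, multipliers = list(margin = 4)),
                  list(name = "D61G_hi", n_embryos = 3,
                       multipliers = list(margin = 4 * 0.4))),
    shape = c(48L, 48L), embryo_sdlog = 0, seed = 4)
  tr <- make_cohort(cfg, render = character(0))$truth
  expect_equal(mean(tr$margin_activity[tr$group == "D61G_hi"]),
               0.4 * mean(tr$margin_activity[tr$group == "D61G"]),
               tolerance = 1e-9)
})
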