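test_that("EM recovers a single Gaussian component", {
  set.seed(1)
  x <- rnorm(5000, 633, 22)
  fit <- fit_mixture(x, k = 1)
  expect_equal(fit$components$mean, 633, tolerance = 2 / 633)
  expect_equal(fit$components$sd, 22, tolerance = 2 / 22)
  expect_equal(fit$components$weight, 1)
})

test_that("EM log-likelihood is monotone and weights stay normalized", {
  masses <- mech_native_masses(seed = 7, n = 3000)
  fit <- fit_mixture(masses, k = 3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-7))
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-12)
  expect_true(all(fit$components$sd > 0))
  expect_true(all(diff(fit$components$mean) > 0))
})

test_that("BIC auto mode selects three native components", {
  ev <- gen_cdms_events("SERUM-CDMS-NATIVE", 5000, seed = 42)
  masses <- cdms_event_to_mass(ev)$mass
  fit <- fit_mixture(masses, k = "auto")
  expect_equal(fit$k, 3)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  masses <- cdms_event_to_mass(
    gen_cdms_events("SERUM-CDMS-NATIVE", 4000, seed = 13))$mass
  fit <- fit_mixture(masses, k = 3)
  mc <- mclust::Mclust(masses, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$components$mean, sort(as.numeric(mc$parameters$mean)),
               tolerance = 1 / 500)
})

test_that("fitted means recover generating means at 3-sigma separation", {
  for (seed in 1:20) {
    set.seed(seed)
    truth <- c(400, 480, 560)  # separations 80 kDa, pooled SD ~25
    x <- c(rnorm(700, truth[1], 25), rnorm(700, truth[2], 25),
           rnorm(600, truth[3], 25))
    fit <- fit_mixture(x, k = 3)
    expect_true(all(abs(fit$components$mean - truth) < 5),
                info = paste("seed", seed))
  }
})

test_that("fit_mixture rejects degenerate inputs", {
  expect_error(fit_mixture(rep(500, 50), k = 2), "degenerate")
  expect_error(fit_mixture(rnorm(15, 500, 10), k = 2), "too few events")
})

test_that("overlap algebra resolves the middle population", {
  est <- resolve_overlap(0.374, 0.482, 0.144, f7 = 0.55)
  expect_equal(est$x, 0.176)
  expect_equal(est$pros_bound, 0.68)
  expect_true(est$feasible)
  # f7 = a1: middle peak holds no unbound a7b1
  est0 <- resolve_overlap(0.374, 0.482, 0.144, f7 = 0.374)
  expect_equal(est0$x, 0)
  expect_equal(est0$pros_bound, 0.374 + 0.482)
  # f7 < a1 is compositionally impossible
  bad <- resolve_overlap(0.374, 0.482, 0.144, f7 = 0.2)
  expect_false(bad$feasible)
  expect_equal(bad$x, 0)
  expect_error(resolve_overlap(0.5, 0.3, 0.3, 0.5), "sum to 1")
})

test_that("overlap algebra equals the grid-search oracle", {
  set.seed(23)
  for (i in 1:30) {
    w <- runif(3)
    w <- w / sum(w)
    f7 <- runif(1)
    est <- resolve_overlap(w[1], w[2], w[3], f7)
    # grid step 1e-4: the best grid point is within one step of x
    # (the clamp boundary a2 need not be a grid point)
    expect_lt(abs(est$x - oracle_overlap_grid(w[1], w[2], f7)), 1.01e-4)
  }
})

test_that("component weights are reported by counting and by mixture", {
  masses <- cdms_event_to_mass(
    gen_cdms_events("SERUM-CDMS-NATIVE", 5000, seed = 42))$mass
  fit <- fit_mixture(masses, k = 3)
  w_cnt <- component_weights(fit, method = "counts")
  w_mix <- component_weights(fit, method = "mixture")
  expect_equal(sum(w_cnt), 1, tolerance = 1e-12)
  truth <- c(0.144, 0.482, 0.374)
  expect_true(all(abs(w_cnt - truth) < 0.04))
  expect_true(all(abs(w_mix - truth) < 0.04))
})

test_that("occupancy inference recovers q across the plausible range", {
  for (q in c(0.3, 0.5, 0.68, 0.9)) {
    preset <- serum_preset("mechanistic", q = q)
    nat <- cdms_event_to_mass(gen_cdms_events(preset, 4000, seed = 31))
    aci <- cdms_event_to_mass(gen_acidified(preset, 4000, seed = 32))
    est <- estimate_occupancy(nat, aci)
    expect_lt(abs(est$pros_bound - q), 0.05)
  }
})

test_that("occupancy inference handles the q = 1 and q = 0 extremes", {
  p1 <- serum_preset("mechanistic", q = 1)
  nat <- cdms_event_to_mass(gen_cdms_events(p1, 3000, seed = 41))
  aci <- cdms_event_to_mass(gen_acidified(p1, 3000, seed = 42))
  expect_gt(estimate_occupancy(nat, aci)$pros_bound, 0.95)
  p0 <- serum_preset("mechanistic", q = 0)
  nat0 <- cdms_event_to_mass(gen_cdms_events(p0, 3000, seed = 43))
  aci0 <- cdms_event_to_mass(gen_acidified(p0, 3000, seed = 44))
  est0 <- estimate_occupancy(nat0, aci0)
  expect_lt(est0$pros_bound, 0.05)
})

test_that("isoform quantification propagates assignment ambiguity", {
  masses <- cdms_event_to_mass(
    gen_cdms_events("SERUM-CDMS-ACID", 5000, seed = 42))$mass
  fit <- fit_mixture(masses[masses > 200], k = 2)
  iq <- quantify_isoforms(fit)
  expect_equal(iq$abundance, c(0.45, 0.55), tolerance = 0.05 / 0.45)
  nat <- fit_mixture(cdms_event_to_mass(
    gen_cdms_events("SERUM-CDMS-NATIVE", 5000, seed = 42))$mass, k = 3)
  iqn <- quantify_isoforms(nat)
  # middle native component is ambiguous between a7b1 and a6b1+ProS
  mid <- iqn[which.min(abs(iqn$mean - 553)), ]
  expect_true(mid$ambiguous)
  expect_match(mid$labels, "a7b1")
  expect_match(mid$labels, "a6b1\\+ProS")
  one <- fit_mixture(rnorm(500, 630, 20), k = 1)
  expect_equal(quantify_isoforms(one)$abundance, 1)
})

test_that("shift detection pairs native and acidified components", {
  nat <- structure(list(components = data.frame(
    mean = c(481, 553, 633), sd = c(20, 20, 22),
    weight = c(0.144, 0.482, 0.374)), k = 3), class = "mass_mixture")
  aci <- structure(list(components = data.frame(
    mean = c(478, 551), sd = c(23, 22), weight = c(0.45, 0.55)), k = 2),
    class = "mass_mixture")
  rep <- detect_shift(nat, aci, m_pros = 79.8, tol = 15)
  expect_equal(nrow(rep$pairs), 2)
  expect_equal(rep$pairs$native_mean, c(633, 553))
  expect_equal(rep$pairs$acid_mean, c(551, 478))
  expect_equal(rep$pairs$delta, c(82, 75))
  expect_true(all(rep$pairs$flagged_dissociation))
  same <- detect_shift(nat, nat, m_pros = 79.8)
  expect_true(all(same$pairs$delta == 0))
  expect_false(any(same$pairs$flagged_dissociation))
  far <- detect_shift(nat, structure(list(components = data.frame(
    mean = c(381, 453, 533), sd = 20, weight = 1 / 3), k = 3),
    class = "mass_mixture"), m_pros = 79.8, tol = 15)
  expect_false(any(far$pairs$flagged_dissociation))
})
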