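test_that("presets validate their invariants", {
  for (nm in c("SERUM-CDMS-NATIVE", "SERUM-CDMS-ACID", "SERUM-MP-NATIVE"))
    expect_equal(sum(named_preset(nm)$components$weight), 1)
  mech <- named_preset("MECHANISTIC")
  cm <- mech$chain_masses
  comps <- mech$components
  m <- function(lab) comps$mean[comps$species == lab]
  # exact chain-mass identities of the mechanistic population
  expect_equal(m("a7b1") - m("a6b1"), cm[["alpha"]], ignore_attr = TRUE)
  expect_equal(m("a7b1+ProS") - m("a7b1"), cm[["pros"]], ignore_attr = TRUE)
  expect_equal(m("a6b1+ProS") - m("a6b1"), cm[["pros"]], ignore_attr = TRUE)
  expect_error(serum_preset("observed",
                            data.frame(species = "x", mean = 1, sd = 1,
                                       weight = 0.5)),
               "sum to 1")
  expect_error(gen_cdms_events(named_preset("MECHANISTIC"), n_events = 0),
               "n_events")
})

test_that("noise-free CDMS generation round-trips through mass inversion", {
  ev <- gen_cdms_events("SERUM-CDMS-NATIVE", n_events = 1, seed = 99,
                        charge = charge_model(sd_z = 0, sd_I = 0))
  me <- cdms_event_to_mass(ev)
  expect_lt(abs(me$mass - ev$true_mass) / ev$true_mass, 1e-9)
  # and for a larger noise-free batch
  ev2 <- gen_cdms_events("MECHANISTIC", n_events = 200, seed = 5,
                         charge = charge_model(sd_z = 0, sd_I = 0))
  me2 <- cdms_event_to_mass(ev2)
  expect_true(all(abs(me2$mass - ev2$true_mass) / ev2$true_mass < 1e-9))
})

test_that("generators are bit-reproducible given the seed", {
  a <- gen_cdms_events("SERUM-CDMS-NATIVE", 500, seed = 3)
  b <- gen_cdms_events("SERUM-CDMS-NATIVE", 500, seed = 3)
  expect_identical(a, b)
  expect_false(identical(
    a, gen_cdms_events("SERUM-CDMS-NATIVE", 500, seed = 4)))
  p1 <- gen_plasma_cohort(seed = 8)
  p2 <- gen_plasma_cohort(seed = 8)
  expect_identical(p1$lfq, p2$lfq)
})

test_that("heaviest third of native CDMS events tracks the 633 kDa peak", {
  ev <- gen_cdms_events("SERUM-CDMS-NATIVE", 5000, seed = 42)
  me <- cdms_event_to_mass(ev)
  # Monte-Carlo oracle on the population (2e6 direct mixture draws):
  # selecting the top third by mass shifts its mean to 637.7 kDa, since
  # the 633-component holds 37.4% of events and truncation biases upward.
  top <- sort(me$mass, decreasing = TRUE)[1:(5000 %/% 3)]
  expect_equal(mean(top), 637.7, tolerance = 3 / 637.7)
  # events drawn from the heaviest species themselves center on 633
  heavy <- me$mass[me$true_species == "a7b1+ProS"]
  expect_equal(mean(heavy), 633, tolerance = 3 / 633)
})

test_that("mechanistic ProS-bound fraction matches q at n = 5000", {
  ev <- gen_cdms_events("MECHANISTIC", 5000, seed = 42)
  expect_equal(mean(ev$true_has_pros), 0.68, tolerance = 0.02 / 0.68)
})

test_that("empirical species weights converge at the root-n rate", {
  preset <- named_preset("SERUM-CDMS-NATIVE")
  w <- preset$components$weight
  for (n in c(500, 5000)) {
    ev <- gen_cdms_events(preset, n, seed = 21)
    emp <- as.numeric(table(factor(ev$true_species,
                                   levels = preset$components$species))) / n
    se <- sqrt(w * (1 - w) / n)
    expect_true(all(abs(emp - w) < 4 * se),
                info = paste("n =", n))
  }
})

test_that("acid dissociation splits bound particles and preserves ratios", {
  # pure a7b1+ProS population -> complexes at 551, free ProS at 79.8
  pure <- serum_preset("mechanistic", f7 = 1, q = 1)
  ev <- gen_acidified(pure, 2000, seed = 2)
  me <- cdms_event_to_mass(ev)
  expect_equal(nrow(ev), 4000)  # every particle splits
  expect_equal(mean(me$mass[me$mass > 200]), 551.0, tolerance = 2 / 551)
  expect_equal(mean(me$mass[me$mass < 200]), 79.8, tolerance = 1 / 79.8)
  # q = 0: nothing dissociates, output identical to the native draw
  q0 <- serum_preset("mechanistic", q = 0)
  expect_identical(gen_acidified(q0, 1000, seed = 6),
                   gen_cdms_events(q0, 1000, seed = 6))
  # default: complex species ratio a7b1:a6b1 near f7:f6
  ev3 <- gen_acidified(named_preset("MECHANISTIC"), 5000, seed = 9)
  cx <- ev3$true_species[ev3$true_species != "ProS"]
  expect_equal(mean(cx == "a7b1"), 0.55, tolerance = 0.03 / 0.55)
  expect_error(gen_acidified(named_preset("SERUM-CDMS-NATIVE")),
               "mechanistic")
})

test_that("MP generation is linear in mass with an exact calibrant block", {
  mp <- gen_mp_events("SERUM-MP-NATIVE", 100, seed = 1, slope = 2e-5,
                      intercept = 1e-4, noise_kda = 0)
  c73 <- mp$calibrants$contrast[mp$calibrants$calibrant_mass == 73]
  expect_true(all(abs(c73 - 1.56e-3) < 1e-12))
  expect_equal(mp$events$contrast,
               2e-5 * mp$events$true_mass + 1e-4)
  none <- gen_mp_events("SERUM-MP-NATIVE", 10, seed = 1,
                        include_calibrants = FALSE)
  expect_equal(nrow(none$calibrants), 0)
  expect_error(gen_mp_events("SERUM-MP-NATIVE", 10, slope = -1), "slope")
})

test_that("MP native preset yields the four expected populations", {
  mp <- gen_mp_events("SERUM-MP-NATIVE", 5000, seed = 42)
  cal <- fit_mp_calibration(mp$calibrants)
  me <- mp_contrast_to_mass(mp$events, cal)
  fit <- fit_mixture(me$mass, k = 4)
  expect_true(all(abs(fit$components$mean - c(68, 487, 553, 630)) <
                    c(5, 10, 10, 10)))
})

test_that("glyco PSM generator covers the eleven sites", {
  expect_equal(nrow(gen_glyco_psms(n_psm_per_site = 0)), 0)
  psm <- gen_glyco_psms(seed = 1)
  expect_equal(nrow(unique(psm[, c("protein", "site")])), 11)
  # forcing a site fully unoccupied propagates downstream
  st <- default_glyco_sites()
  st$p_unoccupied[st$protein == "C4BPa" & st$site == 506] <- 1
  psm2 <- gen_glyco_psms(st, 50, seed = 2)
  prof <- site_profiles(filter_psms(psm2))
  row <- prof[prof$protein == "C4BPa" & prof$site == 506, ]
  expect_true(is.na(row$dominant))
  expect_equal(row$unoccupied_fraction, 1)
})

test_that("plasma cohort truth table encodes the stoichiometry arithmetic", {
  h <- gen_plasma_cohort(scenario = "healthy", sigma = 0, seed = 1)
  expect_true(all(h$truth$ratio_true == 6.5))
  a <- gen_plasma_cohort(scenario = "acute", sigma = 0, seed = 1,
                         frac_7a = 0.5)
  expect_equal(unique(a$truth$ratio_true[a$truth$acute]), 13.5)
  expect_equal(unique(a$truth$ratio_true[!a$truth$acute]), 6.5)
  # CRP stays below the acute level outside acute timepoints
  expect_true(all(a$truth$crp_gL[!a$truth$acute] < 0.15))
})

test_that("cross-link fixture replicates span the design", {
  fx <- gen_xl_fixture(seed = 1)
  reps <- tapply(fx$links$replicate, fx$links$link_id,
                 function(r) length(unique(r)))
  expect_true(any(reps == 3))
  expect_true(all(fx$links$replicate %in% 1:3))
})
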