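test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 5, start = "2014-06-01", end = "2014-06-20")
  t1 <- simulate_track(cfg, "A", "female")
  t2 <- simulate_track(cfg, "A", "female")
  expect_identical(t1$fixes, t2$fixes)
  t3 <- simulate_track(cfg, "A", "female", seed = 6)
  expect_false(identical(t1$fixes, t3$fixes))
})

test_that("zero patches degenerate to out-and-back travel without forage labels", {
  cfg <- sim_config(seed = 5, start = "2014-06-01", end = "2014-06-20")
  cfg$patches <- default_patches(cfg$colony, dist_km = numeric(0))[0, ]
  trk <- simulate_track(cfg, "A", "female")
  expect_false("forage" %in% trk$fixes$mode)
  expect_true("travel" %in% trk$fixes$mode)
})

test_that("forage fixes stay within their patch radius and labels cover fixes", {
  cfg <- sim_config(seed = 9, start = "2014-06-01", end = "2014-07-01")
  cfg$patches <- default_patches(cfg$colony, dist_km = c(40, 70),
                                 radius_km = 8)
  trk <- simulate_track(cfg, "A", "female")
  f <- trk$fixes
  expect_true(all(f$mode %in% c("travel", "forage", "haulout")))
  fo <- f[f$mode == "forage", ]
  expect_gt(nrow(fo), 0)
  expect_true(all(!is.na(fo$patch)))
  xy <- project_track(data.frame(lon = fo$lon, lat = fo$lat), cfg$colony)
  pxy <- project_track(data.frame(lon = cfg$patches$lon,
                                  lat = cfg$patches$lat), cfg$colony)
  d_km <- sqrt((xy$x - pxy$x[fo$patch])^2 +
                 (xy$y - pxy$y[fo$patch])^2) / 1000
  expect_true(all(d_km <= cfg$patches$radius_km[fo$patch] + 1e-6))
})

test_that("the configured at-sea forage/travel split is realised on a long track", {
  cfg <- sim_config(seed = 11) # full June-December window
  cfg$patches <- default_patches(cfg$colony, dist_km = c(40, 70, 100),
                                 radius_km = 8)
  trk <- simulate_track(cfg, "A", "female")
  f <- trk$fixes
  at_sea <- f$mode != "haulout"
  expect_equal(mean(f$mode[at_sea] == "forage"), 0.6, tolerance = 0.05)
})

test_that("defect injection flags disjoint defects that the filter removes", {
  cfg <- sim_config(seed = 13, start = "2014-06-01", end = "2014-09-15")
  cfg$patches <- default_patches(cfg$colony, dist_km = c(40, 70),
                                 radius_km = 8)
  trk <- simulate_track(cfg, "A", "female")
  ## all-zero rates leave the track unchanged
  cfg0 <- cfg
  cfg0$low_sat_frac <- cfg0$high_residual_frac <- cfg0$teleport_frac <- 0
  expect_identical(inject_defects(trk, cfg0)$fixes, trk$fixes)
  ## defaults: one defect type per fix, rates near nominal
  bad <- inject_defects(trk, cfg)
  f <- bad$fixes
  n <- nrow(f)
  expect_equal(sum(f$defect == "teleport") / n, cfg$teleport_frac,
               tolerance = 0.01)
  expect_true(all(f$defect %in% c("none", "low_sat", "high_residual",
                                  "teleport")))
  expect_true(all(f$n_sats[f$defect == "low_sat"] < 5))
  expect_true(all(f$residual[f$defect == "high_residual"] > 30))
  ## filter fidelity against truth flags
  flt <- filter_fixes(project_track(bad, cfg$colony))
  removed <- flt$removal_report$removed_idx
  truth_bad <- which(f$defect != "none")
  recall <- mean(truth_bad %in% removed)
  false_rate <- sum(!(removed %in% truth_bad)) / sum(f$defect == "none")
  expect_gte(recall, 0.95)
  expect_lte(false_rate, 0.01)
})

test_that("ground-truth ARS fraction agrees with the HMM decoding", {
  sim <- sim_small_track(seed = 17, days = 40)
  trk <- sim$filtered
  st <- compute_speeds(trk)
  fit <- fit_hmm2(st, seed = 1)
  vit <- viterbi_states(fit)
  truth <- trk$fixes$mode[st$fix] == "forage"
  decoded_slow <- vit == 1
  expect_lt(abs(mean(decoded_slow) - mean(truth)), 0.10)
})

test_that("population generation is reproducible with sex-specific structure", {
  cfg <- sim_config(seed = 19, start = "2014-06-01", end = "2014-06-25")
  pop1 <- simulate_population(cfg, n_males = 1, n_females = 2)
  pop2 <- simulate_population(cfg, n_males = 1, n_females = 2)
  expect_identical(pop1$metadata, pop2$metadata)
  expect_identical(lapply(pop1$tracks, `[[`, "fixes"),
                   lapply(pop2$tracks, `[[`, "fixes"))
  expect_equal(pop1$metadata$sex, c("male", "female", "female"))
  expect_true(all(pop1$metadata$deploy_mass_kg > 0))
  ## single-animal population
  solo <- simulate_population(cfg, n_males = 1, n_females = 0)
  expect_length(solo$tracks, 1)
})

test_that("synthetic bathymetry puts banks at patch depths", {
  cfg <- sim_config(seed = 3)
  cfg$patches <- default_patches(cfg$colony, dist_km = c(40, 90),
                                 radius_km = 8)
  g <- simulate_bathymetry(cfg, cellsize = 0.05, margin_deg = 1.6)
  expect_true(all(g$depth > 0))
  d_at_patches <- lookup_depth(g, cfg$patches$lon, cfg$patches$lat)
  expect_true(all(d_at_patches >= 45 & d_at_patches <= 80))
  ## depth grows away from the colony off-bank
  d_near <- lookup_depth(g, cfg$colony[1] + 0.1, cfg$colony[2])
  d_far <- lookup_depth(g, cfg$colony[1] + 1.5, cfg$colony[2] + 1)
  expect_gt(d_far, d_near)
})

test_that("write_sim emits the CSV dialects that track_io reads back", {
  cfg <- sim_config(seed = 23, start = "2014-06-01", end = "2014-06-20")
  pop <- simulate_population(cfg, n_males = 0, n_females = 2)
  dir <- withr::local_tempdir()
  paths <- write_sim(pop, dir, bathy = simulate_bathymetry(cfg))
  trks <- read_fixes(paths[["fixes"]], metadata = paths[["metadata"]])
  expect_length(trks, 2)
  ids <- vapply(pop$tracks, `[[`, "", "animal_id")
  expect_setequal(names(trks), ids)
  expect_equal(nrow(trks[[ids[1]]]$fixes),
               nrow(pop$tracks[[ids[1]]]$fixes))
  expect_equal(trks[[ids[1]]]$sex, pop$tracks[[ids[1]]]$sex)
  truth <- read.csv(paths[["truth"]])
  expect_equal(nrow(truth), sum(vapply(pop$tracks,
                                       function(t) nrow(t$fixes), 0L)))
  g <- read_ascii_grid(paths[["bathy"]])
  expect_s3_class(g, "bathymetry_grid")
})
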