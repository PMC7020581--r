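test_that("time-scaled distance has the stated limits and metric properties", {
  ## direct evaluation
  expect_equal(tsd(0, 0, 0, 3000, 4000, 2, s = 0.05, v_max = 6000),
               sqrt(5000^2 + 600^2), tolerance = 1e-9)
  set.seed(4)
  x1 <- runif(1e4, -5e4, 5e4); y1 <- runif(1e4, -5e4, 5e4)
  x2 <- runif(1e4, -5e4, 5e4); y2 <- runif(1e4, -5e4, 5e4)
  t1 <- runif(1e4, 0, 100); t2 <- runif(1e4, 0, 100)
  eu <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  ## s = 0 reproduces Euclidean exactly; TSD always dominates Euclidean
  expect_identical(tsd(x1, y1, t1, x2, y2, t2, s = 0, v_max = 8000), eu)
  d <- tsd(x1, y1, t1, x2, y2, t2, s = 0.05, v_max = 8000)
  expect_true(all(d >= eu))
  ## symmetry and dt = 0 limit
  expect_equal(d, tsd(x2, y2, t2, x1, y1, t1, s = 0.05, v_max = 8000))
  expect_equal(tsd(x1, y1, 5, x2, y2, 5, s = 0.05, v_max = 8000), eu)
})

test_that("k- and a-method neighbour selection match the brute-force oracle", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(50:300, 1)
    trk <- random_track(n, seed = 100 + rep)
    v_max <- 8000
    s <- runif(1, 0, 0.2)
    parents <- sample(n, 5)
    for (p in parents) {
      expect_identical(select_neighbors_k(trk, p, 15, s, v_max),
                       oracle_neighbors_k(trk, p, 15, s, v_max))
      a <- runif(1, 0, 5e4)
      expect_identical(select_neighbors_a(trk, p, a, s, v_max),
                       oracle_neighbors_a(trk, p, a, s, v_max))
    }
  }
})

test_that("neighbour selection honours limits and degenerate cases", {
  trk <- random_track(60, seed = 3)
  expect_identical(select_neighbors_k(trk, 7, 1, s = 0.1, v_max = 8000), 7L)
  expect_error(select_neighbors_k(trk, 1, 61, 0.1, 8000), "exceeds")
  ## a = 0 keeps the parent (and any zero-distance co-located fixes)
  expect_identical(select_neighbors_a(trk, 5, 0, 0.1, 8000), 5L)
  ## a >= total distance selects everything
  big <- sum(oracle_tsd_matrix(trk, 0.1, 8000)[9, ])
  expect_identical(select_neighbors_a(trk, 9, big, 0.1, 8000), 1:60)
  ## huge s makes neighbours temporally adjacent regardless of position
  set.seed(5)
  trk2 <- make_track(x = rep(c(0, 50000), 30), y = runif(60, 0, 100))
  nb <- select_neighbors_k(trk2, 30, 5, s = 1000, v_max = 8000)
  expect_identical(nb, 28:32)
})

test_that("hull construction matches analytic polygons and flags degeneracy", {
  sq <- build_hull(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  expect_false(sq$degenerate)
  expect_equal(sq$area_km2, 1)
  col <- build_hull(c(0, 500, 1000), c(0, 500, 1000))
  expect_true(col$degenerate)
  expect_equal(col$area_km2, 0)
  ## random points agree with chull directly on area and vertex set
  set.seed(8)
  x <- rnorm(100) * 1000; y <- rnorm(100) * 1000
  h <- build_hull(x, y)
  idx <- grDevices::chull(x, y)
  expect_equal(h$area_km2 * 1e6,
               abs(hullrange:::polygon_area(x[idx], y[idx])),
               tolerance = 1e-9)
  expect_setequal(round(h$x, 6), round(x[idx], 6))
})

test_that("time-selected fraction is zero at s = 0 and grows along an s sweep", {
  sim <- sim_small_track(seed = 13, days = 20)
  trk <- sim$filtered
  trk$fixes <- trk$fixes[seq(1, nrow(trk$fixes), by = 8), ] # thin for speed
  rownames(trk$fixes) <- NULL
  diag <- time_selected_fraction(trk, c(0, 0.01, 0.05, 0.2, 1),
                                 tlocoh_config(method = "k", k = 10))
  expect_equal(diag$frac_time_selected[1], 0)
  expect_gte(diag$frac_time_selected[5], diag$frac_time_selected[1])
  expect_true(all(diag$frac_time_selected >= 0 &
                    diag$frac_time_selected <= 1))
  rec <- attr(diag, "recommended_s")
  if (!is.na(rec)) {
    expect_gte(diag$frac_time_selected[diag$s == rec], 0.40)
    expect_lte(diag$frac_time_selected[diag$s == rec], 0.80)
  }
})

test_that("isopleths respect requested coverage and nest across levels", {
  sim <- sim_small_track(seed = 17, days = 30)
  hs <- build_hullset(sim$filtered, tlocoh_config(s = 0.05))
  iso <- build_isopleths(hs, "point_density", levels = c(0.3, 0.6, 0.95, 1))
  expect_true(all(iso$info$achieved >= iso$info$level))
  expect_true(all(diff(iso$info$area_km2) >= -1e-9))
  expect_equal(iso$info$achieved[4], 1, tolerance = 1e-6)
  ## areas invariant to rotation + translation of coordinates
  th <- 0.7
  f <- hs$fixes
  hs2 <- hs
  hs2$fixes$x <- cos(th) * f$x - sin(th) * f$y + 5e4
  hs2$fixes$y <- sin(th) * f$x + cos(th) * f$y - 2e4
  rot <- build_hullset(structure(list(animal_id = "r", sex = "female",
                                      fixes = hs2$fixes, meta = list(),
                                      n_duplicates_dropped = 0L),
                                 class = "forager_track"),
                       hs$config)
  iso_rot <- build_isopleths(rot, "point_density", levels = 0.95)
  expect_equal(iso_rot$info$area_km2,
               build_isopleths(hs, "point_density", 0.95)$info$area_km2,
               tolerance = 1e-6)
})

test_that("a 10-hull toy set reproduces the hand-computed union areas", {
  ## ten 1x1 km squares stepping right by 500 m: hull i spans
  ## x in [500 i, 500 i + 1000]. Ten fixes sit in each column
  ## x = 500 j + 250, so hull i encloses columns i and i+1 (20 fixes,
  ## 10 for the last hull). Densities 20, ..., 20, 10; ties resolve by
  ## parent timestamp, giving merge order h0, h1, ..., h8, h9.
  fx <- unlist(lapply(0:9, function(i) rep(i * 500 + 250, 10)))
  fy <- rep(seq(100, 900, length.out = 10), 10)
  trk <- make_track(fx, fy)
  polys <- lapply(0:9, function(i) {
    list(x = c(0, 1000, 1000, 0) + i * 500, y = c(0, 0, 1000, 1000))
  })
  enclosed <- lapply(polys, function(p) {
    which(hullrange:::points_in_polygon(trk$fixes$x, trk$fixes$y, p))
  })
  info <- data.frame(parent = 1:10,
                     parent_time = trk$fixes$timestamp[1:10],
                     n_members = 4L, area_km2 = 1, degenerate = FALSE,
                     n_enclosed = vapply(enclosed, length, integer(1)),
                     nsv = 1L, mnlv = 1)
  info$density <- info$n_enclosed / info$area_km2
  hs <- structure(list(fixes = trk$fixes, config = tlocoh_config(),
                       polys = polys, members = enclosed,
                       enclosed = enclosed, info = info,
                       animal_id = "toy", sex = "female"),
                  class = "locoh_hullset")
  expect_equal(info$n_enclosed, c(rep(20L, 9), 10L))
  iso <- build_isopleths(hs, "point_density", levels = c(0.5, 1))
  ## 0.5 level: h0..h3 cover columns 0-4 = 50 fixes exactly; the union
  ## of k squares offset by 500 m is 1 + (k - 1)/2 km2
  expect_equal(iso$info$n_hulls[1], 4)
  expect_equal(iso$info$achieved[1], 0.5)
  expect_equal(iso$info$area_km2[1], 2.5, tolerance = 1e-6)
  ## 1.0 level: h0..h8 already cover all 100 fixes; h9 is never needed
  expect_equal(iso$info$n_hulls[2], 9)
  expect_equal(iso$info$area_km2[2], 5.0, tolerance = 1e-6)
  expect_equal(iso$info$achieved[2], 1)
})

test_that("isopleth diagnostics stabilise and expose per-hull area growth in k", {
  sim <- sim_small_track(seed = 19, days = 15)
  trk <- sim$filtered
  trk$fixes <- trk$fixes[seq(1, nrow(trk$fixes), by = 4), ]
  rownames(trk$fixes) <- NULL
  cfg <- tlocoh_config(s = 0.05)
  diag <- isopleth_diagnostics(trk, c(6, 10, 15, 20), type = "k",
                               config = cfg, level = 0.95)
  expect_equal(nrow(diag), 4)
  expect_true(all(is.finite(diag$area_km2)))
  ## per-hull monotonicity: a larger k can only grow each hull
  v_max <- vmax_from_track(trk)
  for (p in c(5, 25, 60)) {
    nb1 <- select_neighbors_k(trk, p, 6, 0.05, v_max)
    nb2 <- select_neighbors_k(trk, p, 15, 0.05, v_max)
    expect_true(all(nb1 %in% nb2))
    h1 <- build_hull(trk$fixes$x[nb1], trk$fixes$y[nb1])
    h2 <- build_hull(trk$fixes$x[nb2], trk$fixes$y[nb2])
    expect_gte(h2$area_km2, h1$area_km2 - 1e-12)
  }
  ## single candidate -> no recommendation
  d1 <- isopleth_diagnostics(trk, 10, type = "k", config = cfg)
  expect_true(is.na(attr(d1, "recommended")))
})

test_that("a_k15 anchors an adaptive-a candidate range", {
  sim <- sim_small_track(seed = 23, days = 15)
  trk <- sim$filtered
  trk$fixes <- trk$fixes[seq(1, nrow(trk$fixes), by = 4), ]
  rownames(trk$fixes) <- NULL
  v_max <- vmax_from_track(trk)
  ak <- a_for_k(trk, k = 15, s = 0.05, v_max = v_max)
  expect_gt(ak, 0)
  cands <- ak * c(0.5, 0.75, 1, 1.5, 2)
  diag <- isopleth_diagnostics(trk, cands, type = "a",
                               config = tlocoh_config(s = 0.05),
                               level = 0.95)
  expect_equal(diag$candidate, sort(cands))
  expect_true(all(diff(diag$area_km2) >= -1e-9)) # larger a, larger hulls
})

test_that("seasonal home range and core flag insufficient data", {
  ## summer-only track: fall must be flagged insufficient
  sim <- sim_small_track(seed = 29, days = 40)
  hr <- home_range_95(sim$filtered, tlocoh_config(s = 0.05))
  expect_false(isTRUE(hr$summer$insufficient))
  expect_true(isTRUE(hr$fall$insufficient))
  expect_equal(hr$summer$info$level, 0.95)
  expect_gte(hr$summer$info$achieved, 0.95)
  core <- core_area_30(sim$filtered, tlocoh_config(s = 0.05))
  expect_equal(core$summer$info$level, 0.30)
  expect_equal(core$summer$sort_metric, "visit_frequency")
  ## the conservative core is smaller than the home range here
  expect_lt(core$summer$info$area_km2, hr$summer$info$area_km2)
})

test_that("isopleth GeoJSON export round-trips through lon/lat", {
  sim <- sim_small_track(seed = 31, days = 15)
  trk <- sim$filtered
  trk$fixes <- trk$fixes[seq(1, nrow(trk$fixes), by = 4), ]
  rownames(trk$fixes) <- NULL
  hs <- build_hullset(trk, tlocoh_config(s = 0.05))
  iso <- build_isopleths(hs, "point_density", levels = 0.95)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_isopleths_geojson(iso, COLONY, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(gj$features[[1]]$properties$level, 0.95)
  ring <- gj$features[[1]]$geometry$coordinates[[1]][[1]]
  expect_equal(ring[[1]], ring[[length(ring)]]) # closed ring
})
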