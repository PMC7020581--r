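test_that("enclosed points use a boundary-inclusive membership test", {
  sq <- list(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  set.seed(6)
  px <- runif(1000, -500, 1500)
  py <- runif(1000, -500, 1500)
  fixes <- data.frame(x = px, y = py)
  got <- enclosed_points(sq, fixes)
  want <- which(px >= 0 & px <= 1000 & py >= 0 & py <= 1000)
  expect_identical(got, want)
  ## a point exactly on an edge is included
  fixes2 <- data.frame(x = c(500, 0, 1500), y = c(0, 0, 500))
  expect_identical(enclosed_points(sq, fixes2), c(1L, 2L))
})

test_that("visit counting follows the strict 12-hour rule exactly", {
  t0 <- as.POSIXct("2014-06-01", tz = "UTC")
  ## continuous occupancy
  expect_equal(count_visits(t0 + (0:10) * 3600), 1)
  ## a gap of exactly 12 h does not start a new visit; > 12 h does
  expect_equal(count_visits(t0 + c(0, 12) * 3600), 1)
  expect_equal(count_visits(t0 + c(0, 12.01) * 3600), 2)
  ## constructed gaps {13 h, 20 h} -> 3 visits
  expect_equal(count_visits(t0 + c(0, 1, 14, 15, 35) * 3600), 3)
  expect_equal(count_visits(as.POSIXct(character(0))), 0)
})

test_that("nsv equals 1 + count of gaps exceeding the ivg on random patterns", {
  t0 <- as.POSIXct("2014-06-01", tz = "UTC")
  set.seed(12)
  for (i in 1:200) {
    gaps_h <- rexp(sample(1:30, 1), rate = 1 / 8)
    ts <- t0 + cumsum(c(0, gaps_h)) * 3600
    expect_equal(count_visits(ts, ivg_h = 12),
                 1 + sum(gaps_h > 12))
  }
})

test_that("mnlv is enclosed fixes per visit and respects the identity", {
  t0 <- as.POSIXct("2014-06-01", tz = "UTC")
  one <- t0 + (0:9) * 3600
  expect_equal(mean_locations_per_visit(one), 10)
  two <- t0 + c(0:3, 40 + 0:5) * 3600 # visits of 4 and 6 fixes
  expect_equal(mean_locations_per_visit(two), 5)
  expect_equal(mean_locations_per_visit(two) * count_visits(two), 10)
  expect_true(is.na(mean_locations_per_visit(two[0])))
})

test_that("area normalisation flags degenerate hulls", {
  expect_equal(normalize_by_area(4, 2), 2)
  expect_equal(normalize_by_area(7, 1), 7)
  expect_true(is.na(normalize_by_area(4, 0)))
  expect_true(is.na(normalize_by_area(4, NA)))
})

test_that("eccentricity matches enclosing-ellipse geometry and is invariant", {
  ## regular hexagon -> circle-like
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  hex <- list(x = cos(ang) * 1000, y = sin(ang) * 1000)
  expect_lt(hull_eccentricity(hex), 1e-6)
  ## 4 x 2 rectangle: b/a = 1/2 -> e = sqrt(3)/2
  rect <- list(x = c(-2, 2, 2, -2) * 1000, y = c(-1, -1, 1, 1) * 1000)
  expect_equal(hull_eccentricity(rect), sqrt(3) / 2, tolerance = 1e-3)
  ## rotation, translation, uniform scaling leave e unchanged
  th <- 0.53
  rot <- list(x = (cos(th) * rect$x - sin(th) * rect$y) * 3.7 + 1e5,
              y = (sin(th) * rect$x + cos(th) * rect$y) * 3.7 - 4e4)
  expect_equal(hull_eccentricity(rot), hull_eccentricity(rect),
               tolerance = 1e-4)
  ## near-collinear -> e close to 1 (degenerate convention is exactly 1)
  thin <- list(x = c(0, 5000, 10000), y = c(0, 1, 0))
  expect_gt(hull_eccentricity(thin), 0.99)
})

test_that("mean p(ARS) over enclosed fixes is a bounded arithmetic mean", {
  p <- c(0.2, 0.4, 0.9, NA, 1)
  expect_equal(hull_mean_pars(1:3, p), 0.5)
  expect_equal(hull_mean_pars(c(3, 5), p), 0.95)
  expect_equal(hull_mean_pars(4, p), NA_real_)
  expect_gte(hull_mean_pars(1:5, p), min(p, na.rm = TRUE))
  expect_lte(hull_mean_pars(1:5, p), max(p, na.rm = TRUE))
})

test_that("near-colony exclusion respects the 15-km boundary", {
  m <- data.frame(hull = 1:3, dist_colony_km = c(14.9, 15.1, NA))
  kept <- exclude_near_colony(m)
  expect_setequal(kept$hull, c(2, 3))
  expect_equal(nrow(exclude_near_colony(m, radius_km = 0)), 3)
})

test_that("six-category classification partitions hulls by the quartile scheme", {
  set.seed(21)
  n <- 400
  m <- data.frame(hull = 1:n, animal_id = rep(c("A", "B"), n / 2),
                  season = factor(rep("summer", n),
                                  levels = c("summer", "fall",
                                             "excluded")),
                  nsv_km2 = rlnorm(n, 0, 1),
                  mnlv_km2 = rlnorm(n, 0.5, 0.8))
  cls <- classify_categories(m)
  h <- cls$hulls
  expect_equal(nrow(h), n)
  expect_true(all(h$category %in% 1:6))
  ## band boundaries reconstruct the quartiles
  q <- quantile(m$nsv_km2, c(0.25, 0.75), names = FALSE)
  expect_equal(cls$q1, q[1])
  expect_equal(cls$q3, q[2])
  expect_true(all(h$nsv_km2[h$category <= 2] < cls$q1))
  expect_true(all(h$nsv_km2[h$category >= 5] > cls$q3))
  ## ~25/50/25 split up to ties
  expect_equal(mean(h$category <= 2), 0.25, tolerance = 0.02)
  expect_equal(mean(h$category %in% 3:4), 0.50, tolerance = 0.02)
  ## within-band median split, ties to the lower category
  for (b in 1:3) {
    in_band <- h[h$category %in% c(2 * b - 1, 2 * b), ]
    med <- cls$duration_medians[b]
    expect_true(all(in_band$mnlv_km2[in_band$category %% 2 == 1] <= med))
    expect_true(all(in_band$mnlv_km2[in_band$category %% 2 == 0] > med))
  }
  ## order invariance
  cls2 <- classify_categories(m[sample(n), ])
  expect_equal(cls2$q1, cls$q1)
  expect_equal(sort(cls2$hulls$hull), sort(cls$hulls$hull))
  expect_equal(cls2$hulls$category[order(cls2$hulls$hull)],
               cls$hulls$category[order(cls$hulls$hull)])
  ## degenerate thresholds error
  bad <- m
  bad$nsv_km2 <- 1
  expect_error(classify_categories(bad), "degenerate")
})

test_that("time budgets are per-animal proportions that sum to one", {
  m <- data.frame(hull = 1:120,
                  animal_id = rep(c("A", "B", "C"), each = 40),
                  season = factor(rep(c("summer", "fall"), 60),
                                  levels = c("summer", "fall",
                                             "excluded")),
                  nsv_km2 = rlnorm(120), mnlv_km2 = rlnorm(120))
  cls <- classify_categories(m)
  tb <- time_budget(cls)
  sums <- aggregate(proportion ~ animal_id + season, tb$by_animal, sum)
  expect_true(all(abs(sums$proportion - 1) < 1e-9))
  expect_equal(sort(unique(tb$summary$category)), 1:6)
  expect_true(all(tb$summary$median >= 0 & tb$summary$median <= 1))
  ## an animal whose hulls are all one category gets a unit vector
  solo <- cls
  solo$hulls <- cls$hulls[cls$hulls$animal_id == "A", ]
  solo$hulls$category <- 3L
  tb2 <- time_budget(solo)
  v <- tb2$by_animal$proportion[tb2$by_animal$season == "summer"]
  expect_equal(v, c(0, 0, 1, 0, 0, 0))
})
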