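test_that("read_fixes round-trips a well-formed file and collapses duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(animal_id = "A",
                   timestamp_iso8601_utc = c("2014-06-01T00:00:00",
                                             "2014-06-01T00:15:00",
                                             "2014-06-01T00:15:00",
                                             "2014-06-01T00:30:00"),
                   lon = c(-59.9, -59.89, -59.89, -59.88),
                   lat = c(43.95, 43.96, 43.96, 43.97),
                   n_sats = 9, residual = 1)
  write.csv(df, path, row.names = FALSE)
  trks <- read_fixes(path)
  expect_length(trks, 1)
  expect_equal(nrow(trks$A$fixes), 3) # duplicate timestamp dropped
  expect_equal(trks$A$n_duplicates_dropped, 1)
  expect_true(!is.unsorted(trks$A$fixes$timestamp, strictly = TRUE))
})

test_that("read_fixes errors name the missing column and bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(animal_id = "A",
                       timestamp_iso8601_utc = "2014-06-01T00:00:00",
                       lon = -59.9, n_sats = 9, residual = 1),
            path, row.names = FALSE)
  expect_error(read_fixes(path), "lat")
  write.csv(data.frame(animal_id = "A",
                       timestamp_iso8601_utc = "not-a-time",
                       lon = -59.9, lat = 43.9, n_sats = 9, residual = 1),
            path, row.names = FALSE)
  expect_error(read_fixes(path), "timestamp")
})

test_that("quality filter applies the satellite, residual and speed rules", {
  ## 10 good fixes, one low-satellite fix, one high-residual fix
  trk <- make_track(x = seq(0, 1100, by = 100), y = rep(0, 12))
  trk$fixes$n_sats[3] <- 4
  trk$fixes$residual[5] <- 31
  out <- filter_fixes(trk)
  rep <- out$removal_report
  expect_equal(rep$removed_satellites, 1)
  expect_equal(rep$removed_residual, 1)
  expect_equal(nrow(out$fixes), 10)
  ## boundary: exactly 5 satellites and residual exactly 30 are kept
  trk2 <- make_track(x = c(0, 100), y = c(0, 0), n_sats = 5, residual = 30)
  expect_equal(filter_fixes(trk2)$removal_report$n_removed, 0)
})

test_that("speed rule removes injected teleports against the last retained fix", {
  set.seed(42)
  n <- 200
  x <- cumsum(rnorm(n, 0, 300)) # ~1.2 km/h at 15-min sampling
  y <- cumsum(rnorm(n, 0, 300))
  bad <- sort(sample(5:(n - 5), 10))
  x[bad] <- x[bad] + 12000 # implies ~50 km/h over 15 min
  trk <- make_track(x, y)
  out <- filter_fixes(trk)
  expect_setequal(out$removal_report$removed_idx, bad)
  ## idempotence: refiltering removes nothing
  again <- filter_fixes(out)
  expect_equal(again$removal_report$n_removed, 0)
})

test_that("removal report partitions removals by first rule fired", {
  trk <- make_track(x = seq(0, 900, by = 100), y = rep(0, 10))
  trk$fixes$n_sats[4] <- 3
  trk$fixes$residual[4] <- 99 # satellite rule fires first
  out <- filter_fixes(trk)
  rep <- out$removal_report
  expect_equal(rep$removed_satellites, 1)
  expect_equal(rep$removed_residual, 0)
  expect_equal(rep$removed_satellites + rep$removed_residual +
                 rep$removed_speed, rep$n_removed)
  ## empty track is fine
  empty <- trk
  empty$fixes <- trk$fixes[0, ]
  expect_equal(filter_fixes(empty)$removal_report$n_input, 0)
})

test_that("projection centre maps to origin and 1 degree north spans ~111.2 km", {
  trk <- make_track(x = 0, y = 0)
  f <- project_track(trk, COLONY)$fixes
  expect_lt(abs(f$x[1]), 1e-6)
  expect_lt(abs(f$y[1]), 1e-6)
  north <- data.frame(lon = COLONY[1], lat = COLONY[2] + 1)
  xy <- project_track(north, COLONY)
  expect_lt(abs(xy$x), 1) # metres
  expect_equal(xy$y / 1000, 111.195, tolerance = 1e-3)
})

test_that("projection is invertible and preserves pairwise distances", {
  set.seed(9)
  lon <- COLONY[1] + runif(100, -4, 4)
  lat <- COLONY[2] + runif(100, -3, 3)
  xy <- project_track(data.frame(lon = lon, lat = lat), COLONY)
  ll <- unproject(xy$x, xy$y, COLONY)
  expect_lt(max(abs(ll$lon - lon)), 1e-7)
  expect_lt(max(abs(ll$lat - lat)), 1e-7)
  ## great-circle oracle on the same sphere radius as the projection
  hav <- function(i, j) {
    r <- 6371008.8
    dphi <- (lat[j] - lat[i]) * pi / 180
    dlam <- (lon[j] - lon[i]) * pi / 180
    a <- sin(dphi / 2)^2 +
      cos(lat[i] * pi / 180) * cos(lat[j] * pi / 180) * sin(dlam / 2)^2
    2 * r * asin(sqrt(a))
  }
  set.seed(10)
  pairs <- cbind(sample(100, 60, TRUE), sample(100, 60, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  planar <- sqrt((xy$x[pairs[, 1]] - xy$x[pairs[, 2]])^2 +
                   (xy$y[pairs[, 1]] - xy$y[pairs[, 2]])^2)
  gc <- mapply(hav, pairs[, 1], pairs[, 2])
  expect_lt(max(abs(planar - gc) / gc), 0.005)
})

test_that("season assignment follows the summer/fall windows inclusively", {
  ts <- as.POSIXct(c("2014-06-01", "2014-09-30", "2014-10-01",
                     "2014-12-04", "2014-12-05", "2014-05-31",
                     "2015-07-15"), tz = "UTC")
  expect_equal(as.character(assign_season(ts)),
               c("summer", "summer", "fall", "fall", "excluded",
                 "excluded", "summer"))
})

test_that("colony distance is a symmetric non-negative metric", {
  expect_equal(distance_to_colony(COLONY[1], COLONY[2], COLONY), 0)
  ## 1 degree of longitude on the equator
  d <- distance_to_colony(1, 0, c(0, 0))
  expect_equal(d, 111.3, tolerance = 0.01)
  expect_equal(distance_to_colony(0, 0, c(1, 0)), d)
  ## triangle inequality on three arbitrary points
  p <- list(c(-59, 43), c(-58, 44.5), c(-60.5, 44))
  d12 <- distance_to_colony(p[[1]][1], p[[1]][2], p[[2]])
  d13 <- distance_to_colony(p[[1]][1], p[[1]][2], p[[3]])
  d23 <- distance_to_colony(p[[2]][1], p[[2]][2], p[[3]])
  expect_lte(d12, d13 + d23)
})

test_that("bathymetry lookup is bilinear with node and out-of-bounds handling", {
  g <- bathymetry_grid(lon0 = -60, lat0 = 43, cellsize = 0.5,
                       depth = matrix(c(40, 60, 40, 60), 2, 2))
  expect_equal(lookup_depth(g, -60, 43), 40)
  expect_equal(lookup_depth(g, -59.5, 43.5), 60)
  expect_equal(lookup_depth(g, -59.75, 43.25), 50) # cell centre
  expect_error(lookup_depth(g, -61, 43), "outside")
})

test_that("ASCII grid writer and reader round-trip", {
  g <- bathymetry_grid(-61, 43, 0.25,
                       matrix(seq(30, 200, length.out = 48), 6, 8))
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_equal(g2$cellsize, g$cellsize)
  expect_equal(g2$lon0, g$lon0, tolerance = 1e-9)
  expect_equal(g2$depth, g$depth, tolerance = 1e-6, ignore_attr = TRUE)
})
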