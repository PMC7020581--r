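## Shared fixture builders. Everything is generated in code; no files.

COLONY <- c(-59.9158, 43.95)

## A minimal projected track from explicit planar coordinates (metres)
## at regular intervals.
make_track <- function(x, y, start = "2014-06-01 00:00:00",
                       interval_min = 15, n_sats = 9, residual = 0,
                       animal_id = "T1", sex = "female",
                       center = COLONY) {
  n <- length(x)
  ts <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * interval_min * 60
  ll <- unproject(x, y, center)
  fixes <- data.frame(timestamp = ts, lon = ll$lon, lat = ll$lat,
                      n_sats = rep_len(n_sats, n),
                      residual = rep_len(residual, n))
  trk <- track(fixes, animal_id = animal_id, sex = sex)
  project_track(trk, center)
}

## Random-walk track in a box, for neighbour-selection oracles.
random_track <- function(n, seed = 1, scale = 5000) {
  set.seed(seed)
  make_track(cumsum(stats::rnorm(n, 0, scale / 10)),
             cumsum(stats::rnorm(n, 0, scale / 10)))
}

## Brute-force TSD neighbour oracles (independent of the package's
## selection code paths: full pairwise TSD matrix + explicit sort).
oracle_tsd_matrix <- function(trk, s, v_max) {
  f <- trk$fixes
  th <- as.numeric(f$timestamp) / 3600
  n <- nrow(f)
  outer(seq_len(n), seq_len(n), function(i, j) {
    sqrt((f$x[i] - f$x[j])^2 + (f$y[i] - f$y[j])^2 +
           (s * v_max * (th[i] - th[j]))^2)
  })
}

oracle_neighbors_k <- function(trk, parent, k, s, v_max) {
  d <- oracle_tsd_matrix(trk, s, v_max)[parent, ]
  sort(order(d, seq_along(d))[seq_len(k)])
}

oracle_neighbors_a <- function(trk, parent, a, s, v_max) {
  d <- oracle_tsd_matrix(trk, s, v_max)[parent, ]
  o <- order(d, seq_along(d))
  keep <- cumsum(d[o]) <= a
  keep[1] <- TRUE
  sort(o[keep])
}

## Small simulated animal used by several suites (summer-only window
## keeps runtime modest).
sim_small_track <- function(seed = 7, days = 45, two_patches = TRUE) {
  cfg <- sim_config(seed = seed, start = "2014-06-01",
                    end = format(as.Date("2014-06-01") + days))
  if (two_patches) {
    cfg$patches <- default_patches(cfg$colony, dist_km = c(40, 70),
                                   radius_km = 8)
  }
  trk <- simulate_track(cfg, "S1", "female")
  list(cfg = cfg, raw = trk,
       filtered = filter_fixes(project_track(trk, cfg$colony)))
}
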