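## Ground-truth validation of the analysis chain against the simulator:
## do visitation-sorted core areas recover the banks the animal actually
## exploited, and are bank hulls enriched in the high-fidelity behaviour
## categories?

#' Which hulls contain a given point
#'
#' Bounding-box prefiltered point-in-hull test across a hullset.
#'
#' @param hs A `locoh_hullset`.
#' @param px,py Point in projected metres.
#' @return Integer indices of non-degenerate hulls containing the point.
#' @keywords internal
hulls_containing <- function(hs, px, py) {
  ok <- which(!vapply(hs$polys, function(p) isTRUE(p$degenerate),
                      logical(1)))
  cand <- ok[vapply(hs$polys[ok], function(p) {
    px >= min(p$x) && px <= max(p$x) && py >= min(p$y) && py <= max(p$y)
  }, logical(1))]
  cand[vapply(hs$polys[cand], function(p) {
    points_in_polygon(px, py, p)
  }, logical(1))]
}

#' Validate core areas and behaviour categories against simulation truth
#'
#' For each simulated animal: filters and projects the track, builds the
#' hullset, and checks (a) whether the centres of the banks the animal
#' actually visited fall inside its visitation-sorted 30\% core
#' isopleth (computed over the whole track), and (b) pooling all
#' animals, whether hulls containing a visited bank centre are enriched
#' in behaviour categories 5-6 relative to other classified hulls
#' (odds ratio), after the near-colony exclusion.
#'
#' @param pop Output of [simulate_population()].
#' @param colony `c(lon, lat)` used for projection and exclusion.
#' @param config A [tlocoh_config()] for the hullsets.
#' @param core_level Core isopleth level (default 0.30).
#' @param exclusion_radius_km Near-colony exclusion for the
#'   classification arm (default 15).
#' @return List: `containment` (fraction of visited bank centres inside
#'   the core), `n_patches`, `per_patch` (data frame), `odds_ratio`
#'   (categories 5-6 enrichment of bank hulls), `category_table`.
#' @export
validate_against_truth <- function(pop, colony,
                                   config = tlocoh_config(s = 0.05),
                                   core_level = 0.30,
                                   exclusion_radius_km = 15) {
  per_patch <- list()
  metric_tabs <- list()
  patch_flag <- list()
  for (trk in pop$tracks) {
    pat <- trk$patches
    trk <- project_track(trk, colony)
    trk <- filter_fixes(trk)
    f <- trk$fixes
    visited <- sort(unique(f$patch[!is.na(f$patch)]))
    hs <- build_hullset(trk, config)
    core <- build_isopleths(hs, "visit_frequency", levels = core_level)
    core_polys <- hs$polys[core$hull_idx[[1]]]
    pxy <- aeqd_forward(pat$lon[visited], pat$lat[visited], colony)
    in_core <- points_in_any(pxy$x, pxy$y, core_polys)
    rl <- rle(ifelse(is.na(f$patch), 0, f$patch))
    truth_visits <- table(factor(rl$values[rl$values > 0],
                                 levels = visited))
    per_patch[[trk$animal_id]] <- data.frame(
      animal_id = trk$animal_id, patch = visited,
      truth_visits = as.integer(truth_visits), in_core = in_core)
    ## classification arm
    m <- hull_metrics(hs, colony = colony, eccentricity = FALSE)
    is_patch_hull <- rep(FALSE, nrow(m))
    for (j in seq_along(visited)) {
      idx <- hulls_containing(hs, pxy$x[j], pxy$y[j])
      is_patch_hull[idx] <- TRUE
    }
    metric_tabs[[trk$animal_id]] <- m
    patch_flag[[trk$animal_id]] <- is_patch_hull
  }
  pp <- do.call(rbind, per_patch)
  pooled <- do.call(rbind, metric_tabs)
  pooled$patch_hull <- unlist(patch_flag, use.names = FALSE)
  retained <- exclude_near_colony(pooled,
                                  radius_km = exclusion_radius_km)
  or <- NA_real_
  tab <- NULL
  cls <- tryCatch(classify_categories(retained), error = function(e) NULL)
  if (!is.null(cls)) {
    h <- cls$hulls
    tab <- table(patch_hull = h$patch_hull, cat56 = h$category %in% 5:6)
    if (all(dim(tab) == c(2, 2)) && all(tab > 0)) {
      or <- (tab[2, 2] / tab[2, 1]) / (tab[1, 2] / tab[1, 1])
    }
  }
  list(containment = mean(pp$in_core), n_patches = nrow(pp),
       per_patch = pp, odds_ratio = or, category_table = tab)
}
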