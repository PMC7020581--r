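## Configuration-driven orchestration of the full analysis, with a
## manifest that makes stages seeded, auditable and idempotent.

#' Pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param n_males,n_females Simulated population size (simulate stage).
#' @param start,end Study window dates.
#' @param colony `c(lon, lat)`.
#' @param sim A [sim_config()] (built from the above when `NULL`).
#' @param filter List of filter thresholds (`min_sats`, `max_residual`,
#'   `max_speed`).
#' @param hmm List of HMM settings (`gap_threshold_h`, `tol`,
#'   `max_iter`).
#' @param tlocoh A [tlocoh_config()].
#' @param exclusion_radius_km Near-colony exclusion for classification
#'   (default 15).
#' @param defects Inject quality defects in the simulate stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, n_males = 1, n_females = 2,
                            start = "2014-06-01", end = "2014-12-04",
                            colony = c(-59.9158, 43.95), sim = NULL,
                            filter = list(min_sats = 5, max_residual = 30,
                                          max_speed = 10),
                            hmm = list(gap_threshold_h = 2, tol = 1e-6,
                                       max_iter = 500),
                            tlocoh = tlocoh_config(),
                            exclusion_radius_km = 15, defects = TRUE) {
  if (is.null(sim)) {
    sim <- sim_config(seed = seed, colony = colony, start = start,
                      end = end)
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_males = n_males, n_females = n_females,
                 start = start, end = end, colony = colony, sim = sim,
                 filter = filter, hmm = hmm, tlocoh = tlocoh,
                 exclusion_radius_km = exclusion_radius_km,
                 defects = defects),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' unknown keys are ignored.
#'
#' @param path YAML file.
#' @param outdir Override for the output directory.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("outdir", "seed", "n_males", "n_females", "start", "end",
              "colony", "exclusion_radius_km", "defects")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$colony)) args$colony <- as.numeric(unlist(y$colony))
  if (!is.null(y$filter)) args$filter <- utils::modifyList(
    list(min_sats = 5, max_residual = 30, max_speed = 10), y$filter)
  if (!is.null(y$hmm)) args$hmm <- utils::modifyList(
    list(gap_threshold_h = 2, tol = 1e-6, max_iter = 500), y$hmm)
  if (!is.null(y$tlocoh)) args$tlocoh <- do.call(tlocoh_config, y$tlocoh)
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(pipeline_config, args)
}

pipeline_stages <- function() {
  c("simulate", "filter", "hmm", "hulls", "isopleths", "classify",
    "budgets", "stats")
}

stage_deps <- list(simulate = character(0), filter = "simulate",
                   hmm = "filter", hulls = c("filter", "hmm"),
                   isopleths = "hulls", classify = c("hulls", "hmm"),
                   budgets = "classify", stats = c("isopleths", "simulate"))

stage_outputs <- list(
  simulate = c("fixes.csv", "metadata.csv", "truth.csv", "bathy.asc"),
  filter = c("filtered_fixes.csv", "filter_report.csv"),
  hmm = c("pars.csv", "hmm_params.json"),
  hulls = c("hull_table.csv", "cache/hullsets.rds"),
  isopleths = c("isopleth_areas.csv"),
  classify = c("classified_hulls.csv", "classification_thresholds.csv"),
  budgets = c("time_budget.csv", "time_budget_bands.csv"),
  stats = c("selection_home_range.csv", "selection_core.csv",
            "mass_gain.csv"))

params_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

file_hashes <- function(paths) {
  ex <- paths[file.exists(paths)]
  h <- tools::md5sum(ex)
  names(h) <- basename(ex)
  as.list(h)
}

read_manifest <- function(outdir) {
  p <- file.path(outdir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

write_manifest <- function(outdir, manifest) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_params <- function(stage, config) {
  switch(stage,
         simulate = config[c("seed", "n_males", "n_females", "start",
                             "end", "colony", "defects")],
         filter = config$filter,
         hmm = config$hmm,
         hulls = unclass(config$tlocoh),
         isopleths = unclass(config$tlocoh),
         classify = list(radius = config$exclusion_radius_km,
                         ivg = config$tlocoh$ivg_h),
         budgets = list(),
         stats = list(seed = config$seed))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `filter`, `hmm`, `hulls`, `isopleths`,
#' `classify`, `budgets`, `stats`. Each writes its outputs under the
#' configured `outdir` and records a manifest entry (parameter hash,
#' input-file hashes, seed, timestamp, outputs). Re-running a stage
#' whose inputs and parameters are unchanged and whose outputs exist is
#' a no-op. A stage whose upstream outputs are missing fails with an
#' error naming the stage to run first.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the stage's output paths.
#' @export
run_stage <- function(stage, config, quiet = FALSE) {
  stage <- match.arg(stage, pipeline_stages())
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ## dependency check
  for (dep in stage_deps[[stage]]) {
    need <- file.path(outdir, stage_outputs[[dep]])
    if (!all(file.exists(need))) {
      stop("stage '", stage, "' requires outputs of stage '", dep,
           "'; run it first", call. = FALSE)
    }
  }
  outs <- file.path(outdir, stage_outputs[[stage]])
  inputs <- file.path(outdir,
                      unlist(stage_outputs[stage_deps[[stage]]],
                             use.names = FALSE))
  manifest <- read_manifest(outdir)
  ph <- params_hash(stage_params(stage, config))
  ih <- file_hashes(inputs)
  prev <- manifest[[stage]]
  if (!is.null(prev) && identical(prev$params_hash, unname(ph)) &&
        identical(prev$input_hashes, ih) && all(file.exists(outs))) {
    if (!quiet) message("stage '", stage, "': up to date, skipping")
    return(invisible(outs))
  }
  if (!quiet) message("stage '", stage, "': running")
  do.call(paste0("stage_", stage), list(config = config))
  manifest[[stage]] <- list(params_hash = unname(ph), input_hashes = ih,
                            seed = config$seed,
                            timestamp = format(Sys.time(), tz = "UTC"),
                            outputs = stage_outputs[[stage]])
  write_manifest(outdir, manifest)
  invisible(outs)
}

#' Run the full pipeline (or a suffix of it)
#'
#' @param config A [pipeline_config()].
#' @param stages Stage names (default all, in order).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, stages = pipeline_stages(),
                         quiet = FALSE) {
  for (s in stages) run_stage(s, config, quiet = quiet)
  invisible(config$outdir)
}

## ---- stage implementations ------------------------------------------------

stage_simulate <- function(config) {
  pop <- simulate_population(config$sim, n_males = config$n_males,
                             n_females = config$n_females,
                             defects = config$defects)
  ## one shared bathymetry across both sexes' patch sets
  allpat <- rbind(default_patches(config$colony,
                                  dist_km = c(60, 95, 130, 150),
                                  n_fall = 2),
                  default_patches(config$colony, dist_km = c(30, 55, 80),
                                  n_fall = 2,
                                  bearings_deg = c(60, 100, 140)))
  cfgb <- config$sim
  cfgb$patches <- allpat
  bathy <- simulate_bathymetry(cfgb, cellsize = 0.05)
  write_sim(pop, config$outdir, bathy = bathy)
}

stage_filter <- function(config) {
  outdir <- config$outdir
  tracks <- read_fixes(file.path(outdir, "fixes.csv"),
                       metadata = file.path(outdir, "metadata.csv"))
  bathy <- read_ascii_grid(file.path(outdir, "bathy.asc"))
  rows <- list()
  reps <- list()
  for (trk in tracks) {
    trk <- project_track(trk, config$colony)
    trk <- do.call(filter_fixes, c(list(trk), config$filter))
    trk <- annotate_track(trk, config$colony, bathy = bathy)
    f <- trk$fixes
    rows[[trk$animal_id]] <- data.frame(
      animal_id = trk$animal_id, sex = trk$sex,
      timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%S"),
      lon = f$lon, lat = f$lat, x = f$x, y = f$y,
      dist_colony_km = f$dist_colony_km, depth_m = f$depth_m)
    r <- trk$removal_report
    reps[[trk$animal_id]] <- data.frame(
      animal_id = trk$animal_id, n_input = r$n_input,
      removed_satellites = r$removed_satellites,
      removed_residual = r$removed_residual,
      removed_speed = r$removed_speed, n_removed = r$n_removed,
      fraction_removed = r$fraction_removed)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(outdir, "filtered_fixes.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, reps),
                   file.path(outdir, "filter_report.csv"),
                   row.names = FALSE)
}

read_filtered <- function(config) {
  f <- utils::read.csv(file.path(config$outdir, "filtered_fixes.csv"),
                       stringsAsFactors = FALSE)
  f$timestamp <- as.POSIXct(f$timestamp, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%S")
  split(f, f$animal_id)
}

stage_hmm <- function(config) {
  outdir <- config$outdir
  per <- read_filtered(config)
  pars_rows <- list()
  params <- list()
  for (id in names(per)) {
    f <- per[[id]]
    f$n_sats <- 9; f$residual <- 0 # already filtered
    trk <- track(f, animal_id = id, sex = f$sex[1])
    st <- compute_speeds(trk, gap_threshold_h = config$hmm$gap_threshold_h)
    fit <- fit_hmm2(st, tol = config$hmm$tol,
                    max_iter = config$hmm$max_iter, seed = config$seed)
    pp <- posterior_pars(fit, accept_unconverged = TRUE)
    trk <- attach_pars(trk, pp)
    pars_rows[[id]] <- data.frame(
      animal_id = id,
      timestamp = format(trk$fixes$timestamp, "%Y-%m-%dT%H:%M:%S"),
      p_ars = trk$fixes$p_ars)
    params[[id]] <- list(shape = fit$shape, rate = fit$rate,
                         means_kmh = fit$shape / fit$rate,
                         tpm = list(slow = fit$tpm[1, ],
                                    fast = fit$tpm[2, ]),
                         logLik = fit$logLik, converged = fit$converged)
  }
  utils::write.csv(do.call(rbind, pars_rows),
                   file.path(outdir, "pars.csv"), row.names = FALSE)
  jsonlite::write_json(params, file.path(outdir, "hmm_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_hulls <- function(config) {
  outdir <- config$outdir
  per <- read_filtered(config)
  pars <- utils::read.csv(file.path(outdir, "pars.csv"),
                          stringsAsFactors = FALSE)
  hullsets <- list()
  tabs <- list()
  for (id in names(per)) {
    f <- per[[id]]
    f$n_sats <- 9; f$residual <- 0
    pa <- pars[pars$animal_id == id, ]
    f$p_ars <- pa$p_ars[match(format(f$timestamp, "%Y-%m-%dT%H:%M:%S"),
                              pa$timestamp)]
    trk <- track(f, animal_id = id, sex = f$sex[1])
    hs <- build_hullset(trk, config$tlocoh)
    hullsets[[id]] <- hs
    m <- hull_metrics(hs, colony = config$colony)
    tabs[[id]] <- m
  }
  dir.create(file.path(outdir, "cache"), showWarnings = FALSE)
  saveRDS(hullsets, file.path(outdir, "cache", "hullsets.rds"))
  utils::write.csv(do.call(rbind, tabs),
                   file.path(outdir, "hull_table.csv"), row.names = FALSE)
}

stage_isopleths <- function(config) {
  outdir <- config$outdir
  hullsets <- readRDS(file.path(outdir, "cache", "hullsets.rds"))
  rows <- list()
  for (id in names(hullsets)) {
    hs <- hullsets[[id]]
    trk <- track(transform(hs$fixes, n_sats = 9, residual = 0),
                 animal_id = id, sex = hs$sex)
    for (kind in c("home_range", "core")) {
      iso <- if (kind == "home_range") home_range_95(trk, config$tlocoh)
      else core_area_30(trk, config$tlocoh)
      for (sn in names(iso)) {
        e <- iso[[sn]]
        if (isTRUE(e$insufficient)) {
          rows[[length(rows) + 1]] <- data.frame(
            animal_id = id, sex = hs$sex, season = sn, kind = kind,
            area_km2 = NA_real_, achieved = NA_real_,
            n_fixes = e$n_fixes, insufficient = TRUE)
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            animal_id = id, sex = hs$sex, season = sn, kind = kind,
            area_km2 = e$info$area_km2[1], achieved = e$info$achieved[1],
            n_fixes = NA_integer_, insufficient = FALSE)
          write_isopleths_geojson(e, config$colony,
                                  file.path(outdir,
                                            sprintf("iso_%s_%s_%s.geojson",
                                                    id, kind, sn)))
        }
      }
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(outdir, "isopleth_areas.csv"),
                   row.names = FALSE)
}

stage_classify <- function(config) {
  outdir <- config$outdir
  hullsets <- readRDS(file.path(outdir, "cache", "hullsets.rds"))
  pars <- utils::read.csv(file.path(outdir, "pars.csv"),
                          stringsAsFactors = FALSE)
  tabs <- lapply(names(hullsets), function(id) {
    hs <- hullsets[[id]]
    pa <- pars[pars$animal_id == id, ]
    p_ars <- pa$p_ars[match(format(hs$fixes$timestamp,
                                   "%Y-%m-%dT%H:%M:%S"), pa$timestamp)]
    hull_metrics(hs, colony = config$colony, p_ars = p_ars)
  })
  pooled <- do.call(rbind, tabs)
  retained <- exclude_near_colony(pooled,
                                  radius_km = config$exclusion_radius_km)
  cls <- classify_categories(retained)
  utils::write.csv(cls$hulls, file.path(outdir, "classified_hulls.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(q1_nsv_km2 = cls$q1, q3_nsv_km2 = cls$q3,
                              median_mnlv_km2_infrequent =
                                cls$duration_medians[1],
                              median_mnlv_km2_frequent =
                                cls$duration_medians[2],
                              median_mnlv_km2_very_frequent =
                                cls$duration_medians[3]),
                   file.path(outdir, "classification_thresholds.csv"),
                   row.names = FALSE)
}

stage_budgets <- function(config) {
  outdir <- config$outdir
  h <- utils::read.csv(file.path(outdir, "classified_hulls.csv"),
                       stringsAsFactors = FALSE)
  th <- utils::read.csv(file.path(outdir,
                                  "classification_thresholds.csv"))
  cls <- structure(list(hulls = transform(h, season = factor(season)),
                        q1 = th$q1_nsv_km2, q3 = th$q3_nsv_km2,
                        duration_medians = as.numeric(th[1, 3:5])),
                   class = "hull_classification")
  tb <- time_budget(cls)
  utils::write.csv(tb$summary, file.path(outdir, "time_budget.csv"),
                   row.names = FALSE)
  utils::write.csv(tb$band_summary,
                   file.path(outdir, "time_budget_bands.csv"),
                   row.names = FALSE)
}

stage_stats <- function(config) {
  outdir <- config$outdir
  iso <- utils::read.csv(file.path(outdir, "isopleth_areas.csv"),
                         stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(outdir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  meta$days <- as.numeric(as.Date(meta$recapture_date) -
                            as.Date(meta$deploy_date))
  final_mass <- ifelse(!is.na(meta$postpartum_day) & meta$pregnant,
                       parturition_mass(meta$recapture_mass_kg,
                                        meta$postpartum_day),
                       meta$recapture_mass_kg)
  meta$gain_pct_day <- mass_gain_rate(meta$deploy_mass_kg, final_mass,
                                      meta$days)
  utils::write.csv(meta[, c("animal_id", "sex", "deploy_mass_kg",
                            "recapture_mass_kg", "gain_pct_day")],
                   file.path(outdir, "mass_gain.csv"), row.names = FALSE)
  for (kind in c("home_range", "core")) {
    d <- iso[iso$kind == kind & !iso$insufficient & !is.na(iso$area_km2), ]
    out_path <- file.path(outdir, paste0(
      "selection_", ifelse(kind == "core", "core", "home_range"), ".csv"))
    d <- merge(d, meta[, c("animal_id", "deploy_mass_kg")],
               by = "animal_id")
    d$log_area <- log(pmax(d$area_km2, 1e-6))
    d$Bm <- d$deploy_mass_kg
    d$Sn <- factor(d$season)
    d$Sx <- factor(d$sex)
    enough <- nrow(d) >= 10 && length(unique(d$Sn)) > 1 &&
      length(unique(d$Sx)) > 1
    if (!enough) {
      utils::write.csv(data.frame(), out_path, row.names = FALSE)
      next
    }
    fits <- fit_candidates(d, candidate_models_hr("log_area"),
                           random = "animal_id")
    st <- selection_table(fits)
    write_selection_table(st, out_path)
  }
}
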