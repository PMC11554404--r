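## End-to-end orchestration: detections -> events -> retention -> models,
## with per-stage row accounting. The study's own exclusions (tuxedo,
## unknown coats, short cat-free deployments) are the main silent-failure
## risk, so every stage that drops rows records the count and reason in the
## run manifest.

survey_tables <- function(survey) {
  det <- survey$detections
  if (is.null(det$category)) det <- read_detections(det)
  list(detections = det, deployments = survey$deployments,
       weather = survey$weather, sites = survey$sites)
}

manifest_entry <- function(stage, rows_in, rows_out, note = "") {
  data.frame(stage = stage, rows_in = rows_in, rows_out = rows_out,
             dropped = rows_in - rows_out, note = note,
             stringsAsFactors = FALSE)
}

#' Shared event-level preprocessing
#'
#' Validates detections, groups them into events, applies the retention
#' rule, and tallies images with conservation checks.
#'
#' @param survey A `survey` list (simulated or read from disk).
#' @param gap_seconds Event-definition gap (default 60 s).
#' @param retention_days Minimum cat-free operation time (default 83 days).
#' @return List: `detections`, `events`, `daily`, `retained_sites`,
#'   `deployments` (retained only), `tally`, `manifest`.
#' @export
prepare_events <- function(survey, gap_seconds = 60, retention_days = 83) {
  tb <- survey_tables(survey)
  det <- tb$detections
  if (nrow(det) == 0L) stop("empty detection table", call. = FALSE)
  manifest <- manifest_entry("ingest", nrow(det), nrow(det))
  tally <- image_tally(det)
  if (sum(tally) != nrow(det)) {
    stop("image tally does not conserve detections", call. = FALSE)
  }
  events <- group_events(det, gap_seconds)
  manifest <- rbind(manifest,
                    manifest_entry("events", nrow(det), nrow(events),
                                   "images grouped into events"))
  retained <- filter_sites(tb$deployments, events, retention_days)
  dep <- tb$deployments[tb$deployments$site_id %in% retained, , drop = FALSE]
  manifest <- rbind(manifest,
                    manifest_entry("retention", nrow(tb$deployments),
                                   nrow(dep),
                                   sprintf("short cat-free deployments (< %d days)",
                                           retention_days)))
  events <- events[events$site_id %in% retained, , drop = FALSE]
  model_events <- events[events$category %in% model_categories(), ,
                         drop = FALSE]
  manifest <- rbind(manifest,
                    manifest_entry("category_filter", nrow(events),
                                   nrow(model_events),
                                   "excluded-category events (tuxedo/unknown)"))
  daily <- daily_records(model_events)
  list(detections = det, events = events, model_events = model_events,
       daily = daily, retained_sites = retained, deployments = dep,
       tally = tally, manifest = manifest)
}

#' Black-cat estimate from a prepared survey
#'
#' Identifiable images are all images that are neither solid black nor
#' unknown-coat; individuals are counted over marked categories.
#'
#' @param prep Output of [prepare_events()].
#' @return A `black_estimate`.
#' @export
survey_black_estimate <- function(prep) {
  det <- prep$detections
  unknown_imgs <- sum(det$pattern == "unknown" | det$colour == "unknown")
  black_imgs <- sum(det$category == "solid_black")
  identifiable <- nrow(det) - black_imgs - unknown_imgs
  marked <- prep$model_events
  marked <- marked[!(is.na(marked$individual_id) |
                       marked$individual_id == ""), , drop = FALSE]
  individuals <- length(unique(marked$individual_id))
  estimate_black(identifiable, individuals, black_imgs)
}

#' Run the spatial analysis
#'
#' Detections to events to retained sites to modal coat types, then the
#' multinomial model of modal coat type against site covariates with Wald
#' odds-ratio intervals.
#'
#' @param survey A `survey` list.
#' @param config A [spatial_config()].
#' @param gap_seconds,retention_days See [prepare_events()].
#' @param level Confidence level for [wald_intervals()].
#' @param ridge Optional ridge passed to [fit_multinomial()].
#' @param out_dir Optional directory: tidy CSV outputs and a JSON manifest
#'   are written there.
#' @return List of class `spatial_run`: `summaries`, `black`, `fit`,
#'   `odds_ratios`, `manifest`, `retained_sites`.
#' @export
run_spatial <- function(survey, config = spatial_config(),
                        gap_seconds = 60, retention_days = 83,
                        level = 0.975, ridge = 0, out_dir = NULL) {
  tb <- survey_tables(survey)
  prep <- prepare_events(survey, gap_seconds, retention_days)
  black <- survey_black_estimate(prep)
  summaries <- site_summaries(prep$model_events, black$images_per_cat)
  built <- build_spatial_model(summaries, tb$sites, config)
  fit <- fit_multinomial(built$X, built$y, reference = config$reference,
                         ridge = ridge)
  ors <- wald_intervals(fit, level)
  manifest <- rbind(prep$manifest,
                    manifest_entry("spatial_model", nrow(summaries),
                                   length(built$y),
                                   "sites with excluded modal category"))
  out <- structure(list(summaries = summaries, black = black, fit = fit,
                        odds_ratios = ors, scaling = built$scaling,
                        manifest = manifest,
                        retained_sites = prep$retained_sites),
                   class = "spatial_run")
  if (!is.null(out_dir)) write_run(out, out_dir, "spatial")
  out
}

#' Run the temporal analysis
#'
#' Restricts camera-nights to full/new moon classes, fits the multinomial
#' model of nightly coat-type capture (absence reference) against weather,
#' moon luminosity and the moon x solar interaction, and computes PDE
#' activity indices with bootstrap standard errors per stratum.
#'
#' @param survey A `survey` list.
#' @param config A [temporal_config()].
#' @param lunar A [lunar_config()].
#' @param gap_seconds,retention_days See [prepare_events()].
#' @param level Confidence level for [wald_intervals()].
#' @param ridge Optional ridge passed to [fit_multinomial()].
#' @param bootstrap_reps,seed Bootstrap settings for the PDE.
#' @param out_dir Optional output directory.
#' @return List of class `temporal_run`: `nights`, `fit`, `odds_ratios`,
#'   `pde` (list full/new/all of `pde_result`), `manifest`.
#' @export
run_temporal <- function(survey, config = temporal_config(),
                         lunar = lunar_config(),
                         gap_seconds = 60, retention_days = 83,
                         level = 0.975, ridge = 0,
                         bootstrap_reps = 1000, seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory (PDE bootstrap)", call. = FALSE)
  tb <- survey_tables(survey)
  prep <- prepare_events(survey, gap_seconds, retention_days)
  dep <- prep$deployments
  nights <- data.frame(
    site_id = rep(dep$site_id, as.integer(dep$end_date - dep$start_date) + 1L),
    date = as.Date(unlist(Map(function(s, e) seq(s, e, by = "day"),
                              dep$start_date, dep$end_date)),
                   origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  nights$moon_class <- classify_night(nights$date, lunar)
  modelled <- nights[nights$moon_class != "excluded", , drop = FALSE]
  if (!nrow(modelled)) stop("no modelling nights", call. = FALSE)
  manifest <- rbind(prep$manifest,
                    manifest_entry("moon_subset", nrow(nights), nrow(modelled),
                                   "intermediate-luminosity nights"))
  built <- build_temporal_model(prep$daily, modelled, tb$weather, config)
  fit <- fit_multinomial(built$X, built$y, reference = config$reference,
                         ridge = ridge)
  ors <- wald_intervals(fit, level)
  pde_res <- list()
  for (st in c("full", "new", "all")) {
    tab <- site_night_summary(prep$daily, modelled, st)
    pde_res[[st]] <- bootstrap_pde(tab, st, B = bootstrap_reps, seed = seed)
  }
  out <- structure(list(nights = modelled, fit = fit, odds_ratios = ors,
                        pde = pde_res, scaling = built$scaling,
                        manifest = manifest),
                   class = "temporal_run")
  if (!is.null(out_dir)) write_run(out, out_dir, "temporal")
  out
}

#' Write tidy run outputs
#'
#' Writes the odds-ratio table, stage manifest and any summaries/PDE tables
#' as CSV/JSON under `dir`, and records output checksums in the manifest.
#'
#' @param run A `spatial_run` or `temporal_run`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named md5 checksums of the written files, invisibly.
#' @export
write_run <- function(run, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, paste0(prefix, "_odds_ratios.csv"))
  utils::write.csv(as.data.frame(run$odds_ratios), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(run$manifest, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(run$summaries)) {
    p <- file.path(dir, paste0(prefix, "_site_summaries.csv"))
    utils::write.csv(run$summaries, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(run$pde)) {
    pdes <- do.call(rbind, lapply(run$pde, function(x) {
      data.frame(stratum = x$stratum, pde_percent = x$pde_percent,
                 se = x$se, pde_mean_site = x$pde_mean_site,
                 se_mean_site = x$se_mean_site, n_sites = x$n_sites,
                 B = x$bootstrap_reps, seed = x$seed)
    }))
    p <- file.path(dir, paste0(prefix, "_pde.csv"))
    utils::write.csv(pdes, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sums <- tools::md5sum(paths)
  jsonlite::write_json(as.list(sums),
                       file.path(dir, paste0(prefix, "_checksums.json")),
                       auto_unbox = TRUE)
  invisible(sums)
}
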