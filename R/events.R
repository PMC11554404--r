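## Detection -> event -> daily-record machinery, site retention, modal coat
## types and the black-cat abundance ratio estimator.

#' Group detections into independent events
#'
#' An event is a run of images of the same cat at one camera separated by at
#' most `gap_seconds` between consecutive images; a gap strictly greater than
#' `gap_seconds` starts a new event. Images of different known individuals
#' never merge into one event. Images without an individual identity are
#' grouped purely by time within their (site, category) stream, so every
#' event carries a single coat category.
#'
#' @param detections data.frame with columns `site_id`, `timestamp`
#'   (POSIXct), `category` (a modelling category or `"excluded"`), and
#'   optionally `individual_id` (`NA` = unknown individual).
#' @param gap_seconds Maximum within-event spacing in seconds (default 60).
#' @return data.frame of events: `site_id`, `category`, `individual_id`,
#'   `start_time`, `end_time`, `n_images`.
#' @export
group_events <- function(detections, gap_seconds = 60) {
  stopifnot(is.numeric(gap_seconds), gap_seconds > 0)
  need <- c("site_id", "timestamp", "category")
  missing_cols <- setdiff(need, names(detections))
  if (length(missing_cols)) {
    stop("detections lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(detections) == 0L) {
    return(data.frame(site_id = character(), category = character(),
                      individual_id = character(),
                      start_time = as.POSIXct(character(), tz = "UTC"),
                      end_time = as.POSIXct(character(), tz = "UTC"),
                      n_images = integer()))
  }
  d <- detections
  if (is.null(d$individual_id)) d$individual_id <- NA_character_
  stream <- ifelse(is.na(d$individual_id) | d$individual_id == "",
                   paste0("unk::", d$category), paste0("id::", d$individual_id))
  ord <- order(d$site_id, stream, as.numeric(d$timestamp))
  d <- d[ord, , drop = FALSE]
  stream <- stream[ord]
  key <- paste(d$site_id, stream, sep = "\r")
  t <- as.numeric(d$timestamp)
  new_stream <- c(TRUE, key[-1L] != key[-length(key)])
  dt <- c(Inf, diff(t))
  dt[new_stream] <- Inf
  dup <- !new_stream & dt == 0
  if (any(dup)) {
    warning(sum(dup), " duplicate detection timestamp(s) dropped (first kept)",
            call. = FALSE)
    d <- d[!dup, , drop = FALSE]
    key <- key[!dup]; t <- t[!dup]
    new_stream <- c(TRUE, key[-1L] != key[-length(key)])
    dt <- c(Inf, diff(t)); dt[new_stream] <- Inf
  }
  event_id <- cumsum(new_stream | dt > gap_seconds)
  idx <- split(seq_along(event_id), event_id)
  first <- vapply(idx, `[`, integer(1), 1L)
  n_img <- lengths(idx)
  last <- first + n_img - 1L
  out <- data.frame(
    site_id = d$site_id[first],
    category = d$category[first],
    individual_id = d$individual_id[first],
    start_time = d$timestamp[first],
    end_time = d$timestamp[last],
    n_images = as.integer(n_img),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Collapse events to daily presence records
#'
#' One record per (site, calendar date, category) with at least one event.
#' The day is the local calendar date of the event start; a category's
#' "daily event" count is the number of such flagged camera-days.
#'
#' @param events Output of [group_events()].
#' @return data.frame `site_id`, `date`, `category`, one row per flag.
#' @export
daily_records <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(site_id = character(), date = as.Date(character()),
                      category = character()))
  }
  d <- unique(data.frame(
    site_id = events$site_id,
    date = as.Date(events$start_time, tz = "UTC"),
    category = events$category,
    stringsAsFactors = FALSE
  ))
  d <- d[order(d$site_id, d$date, d$category), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Days from deployment start to first cat detection
#'
#' @param deployments data.frame `site_id`, `start_date`, `end_date`
#'   (Date), optionally `operating_days`.
#' @param events Output of [group_events()].
#' @return data.frame `site_id`, `latency_days` (NA where the camera never
#'   recorded a cat). An event preceding its deployment start is an error.
#' @export
first_detection_latency <- function(deployments, events) {
  first_by_site <- if (nrow(events)) {
    tapply(as.Date(events$start_time, tz = "UTC"), events$site_id,
           min, simplify = TRUE)
  } else {
    NULL
  }
  lat <- rep(NA_integer_, nrow(deployments))
  if (!is.null(first_by_site)) {
    m <- match(deployments$site_id, names(first_by_site))
    hit <- !is.na(m)
    fd <- as.Date(as.vector(first_by_site[m[hit]]), origin = "1970-01-01")
    delta <- as.integer(fd - deployments$start_date[hit])
    if (any(delta < 0)) {
      stop("event precedes deployment start at site(s): ",
           paste(unique(deployments$site_id[hit][delta < 0]), collapse = ", "),
           call. = FALSE)
    }
    lat[hit] <- delta
  }
  data.frame(site_id = deployments$site_id, latency_days = lat,
             stringsAsFactors = FALSE)
}

#' Empirical percentile of detection latencies, in whole days
#'
#' The retention threshold is the time within which the given percentage of
#' cameras first recorded a cat: the linear-interpolation quantile of the
#' finite latencies (ECDF interpolation, `type = 4`), rounded up to whole
#' days. Rounding up is conservative - it retains fewer potentially false
#' absences.
#'
#' @param latencies Numeric vector of latencies in days; NAs dropped.
#' @param percentile Percentile in (0, 100], default 95.
#' @return Integer number of days.
#' @export
derive_retention_threshold <- function(latencies, percentile = 95) {
  latencies <- latencies[is.finite(latencies)]
  if (!length(latencies)) stop("no finite latencies supplied", call. = FALSE)
  stopifnot(percentile > 0, percentile <= 100)
  q <- stats::quantile(latencies, probs = percentile / 100, type = 4,
                       names = FALSE)
  as.integer(ceiling(q))
}

#' Retain sites with detections or long enough operation
#'
#' A camera that operated fewer than `threshold_days` and recorded no cat is
#' a potential false negative and is discarded; any site with at least one
#' cat event is always retained, as is any site operating at least the
#' threshold (a trusted true absence).
#'
#' @param deployments data.frame with `site_id` and either `operating_days`
#'   or `start_date`/`end_date` (inclusive day count used as fallback).
#' @param events Output of [group_events()].
#' @param threshold_days Minimum operation time in days (study value 83).
#' @return Character vector of retained site ids.
#' @export
filter_sites <- function(deployments, events, threshold_days = 83) {
  op <- deployments$operating_days
  if (is.null(op)) {
    op <- as.integer(deployments$end_date - deployments$start_date) + 1L
  }
  has_cat <- deployments$site_id %in% unique(events$site_id)
  deployments$site_id[has_cat | op >= threshold_days]
}

#' Estimate the number of unmarked black cats
#'
#' Solid black cats carry no individually identifying markings, so their
#' abundance is approximated by a ratio estimator: divide the number of
#' images of individually identifiable cats by the number of individuals
#' identified to get an images-per-cat rate, then divide the black image
#' count by that rate. The estimate is known to overestimate when other coat
#' types are image-poor; downstream modelling therefore uses modal coat
#' types, not raw individual counts.
#'
#' @param images_identifiable Images of cats that could in principle be
#'   identified to individual (all non-black, non-unknown-coat images).
#' @param individuals_identified Number of distinct individuals identified.
#' @param black_images Number of solid-black images.
#' @return List of class `black_estimate`: `images_per_cat`,
#'   `estimated_black` (unrounded), `estimated_black_rounded`, plus inputs.
#' @export
estimate_black <- function(images_identifiable, individuals_identified,
                           black_images) {
  stopifnot(length(images_identifiable) == 1L, length(black_images) == 1L)
  if (individuals_identified <= 0 || images_identifiable <= 0) {
    stop("images_identifiable and individuals_identified must be positive",
         call. = FALSE)
  }
  ipc <- images_identifiable / individuals_identified
  est <- black_images / ipc
  structure(list(
    images_identifiable = images_identifiable,
    individuals_identified = individuals_identified,
    black_images = black_images,
    images_per_cat = ipc,
    estimated_black = est,
    estimated_black_rounded = as.integer(round(est))
  ), class = "black_estimate")
}

#' @export
print.black_estimate <- function(x, ...) {
  cat(sprintf(
    "Black-cat ratio estimate\n  images per identifiable cat: %.2f (%d images / %d individuals)\n  estimated black individuals: %.2f (~%d) from %d black images\n",
    x$images_per_cat, x$images_identifiable, x$individuals_identified,
    x$estimated_black, x$estimated_black_rounded, x$black_images))
  invisible(x)
}

#' Modal coat type of a site
#'
#' The category with the most identified individuals; ties are broken by the
#' category with the most events; residual ties fall back on the fixed
#' category order of [model_categories()] (descending survey-wide
#' prevalence) and are flagged.
#'
#' @param individuals Named numeric vector of per-category individual counts
#'   (non-excluded categories only).
#' @param events Named numeric vector of per-category event counts.
#' @return List `category`, `tie_broken`.
#' @export
modal_coat <- function(individuals, events = NULL) {
  cats <- model_categories()
  ind <- setNames(numeric(length(cats)), cats)
  ind[intersect(names(individuals), cats)] <-
    individuals[intersect(names(individuals), cats)]
  ev <- setNames(numeric(length(cats)), cats)
  if (!is.null(events)) {
    ev[intersect(names(events), cats)] <- events[intersect(names(events), cats)]
  }
  if (all(ind == 0) && all(ev == 0)) {
    stop("site has no non-excluded coat records; it should have been filtered",
         call. = FALSE)
  }
  top <- cats[ind == max(ind)]
  tie_broken <- FALSE
  if (length(top) > 1L) {
    tie_broken <- TRUE
    top_ev <- ev[top]
    top <- top[top_ev == max(top_ev)]
    # residual tie: fixed prevalence order (vector is already ordered)
  }
  list(category = top[1L], tie_broken = tie_broken)
}

#' Per-site coat tallies and modal categories
#'
#' Tallies individuals and events per category at each site and derives the
#' modal coat type. Marked categories count distinct individual ids; solid
#' black cats are unmarked, so their site individual count is imputed from
#' the site's black image count and the survey-wide images-per-cat rate as
#' `max(1, round(images / images_per_cat))` wherever black images occur.
#'
#' @param events Output of [group_events()] (excluded categories are
#'   ignored).
#' @param images_per_cat Survey-wide images-per-identifiable-cat rate used
#'   for the black imputation; `NULL` falls back to counting each site's
#'   black presence as one individual.
#' @return data.frame with one row per site: individual and event counts per
#'   category (`ind_*`, `ev_*`), `modal_category`, `tie_broken`.
#' @export
site_summaries <- function(events, images_per_cat = NULL) {
  ev <- events[events$category %in% model_categories(), , drop = FALSE]
  if (!nrow(ev)) stop("no events in modelling categories", call. = FALSE)
  sites <- sort(unique(ev$site_id))
  cats <- model_categories()
  ev_count <- table(factor(ev$site_id, sites), factor(ev$category, cats))
  img_count <- tapply(ev$n_images,
                      list(factor(ev$site_id, sites), factor(ev$category, cats)),
                      sum, default = 0L)
  ind_count <- matrix(0, length(sites), length(cats),
                      dimnames = list(sites, cats))
  marked <- ev[!(is.na(ev$individual_id) | ev$individual_id == ""), , drop = FALSE]
  if (nrow(marked)) {
    for (k in setdiff(cats, "solid_black")) {
      sub <- marked[marked$category == k, , drop = FALSE]
      if (nrow(sub)) {
        n <- tapply(sub$individual_id, factor(sub$site_id, sites),
                    function(x) length(unique(x)), default = 0L)
        ind_count[, k] <- n
      }
    }
  }
  black_imgs <- img_count[, "solid_black"]
  if (is.null(images_per_cat)) {
    ind_count[, "solid_black"] <- as.integer(black_imgs > 0)
  } else {
    ind_count[, "solid_black"] <- ifelse(
      black_imgs > 0, pmax(1, round(black_imgs / images_per_cat)), 0)
  }
  modal <- lapply(seq_along(sites), function(i) {
    modal_coat(ind_count[i, ], ev_count[i, ])
  })
  out <- data.frame(site_id = sites, stringsAsFactors = FALSE)
  for (k in cats) out[[paste0("ind_", k)]] <- as.numeric(ind_count[, k])
  for (k in cats) out[[paste0("ev_", k)]] <- as.integer(ev_count[, k])
  out$modal_category <- vapply(modal, `[[`, character(1), "category")
  out$tie_broken <- vapply(modal, `[[`, logical(1), "tie_broken")
  rownames(out) <- NULL
  out
}

#' Per-category image tally with conservation of totals
#'
#' Counts ingested images per modelling category plus `excluded`; the counts
#' always sum to the number of detection rows, mirroring how survey summary
#' tables account for every image including unknowns.
#'
#' @param detections Detection data.frame with a `category` column.
#' @return Named integer vector over `c(model_categories(), "excluded")`.
#' @export
image_tally <- function(detections) {
  lv <- c(model_categories(), "excluded")
  tab <- table(factor(detections$category, lv))
  setNames(as.integer(tab), lv)
}
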