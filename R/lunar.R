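## Mean-synodic-month lunar phase model and night classification.
##
## The temporal analysis only needs a full/new dichotomy (> 80% / < 20%
## illuminated), for which a cosine phase-age model on the mean synodic month
## errs by at most a few hours near the thresholds. An ephemeris table
## (date -> fraction) can be supplied to override the model where exactness
## matters.

#' Lunar model configuration
#'
#' @param full_threshold Illuminated fraction above which a night is "full"
#'   (strict inequality; default 0.80).
#' @param new_threshold Fraction below which a night is "new" (strict;
#'   default 0.20).
#' @param epoch A reference new moon instant (default 2000-01-06 18:14 UTC).
#' @param synodic_days Mean synodic month length in days.
#' @param tz_offset_hours Hours ahead of UTC of the survey's local clock;
#'   nights are evaluated at local midnight of the capture date. Default +10
#'   (Tasmania, standard time).
#' @param ephemeris Optional data.frame `date`, `fraction` overriding the
#'   cosine model on the listed dates.
#' @return List of class `lunar_config`.
#' @export
lunar_config <- function(full_threshold = 0.80, new_threshold = 0.20,
                         epoch = as.POSIXct("2000-01-06 18:14:00", tz = "UTC"),
                         synodic_days = 29.530588,
                         tz_offset_hours = 10,
                         ephemeris = NULL) {
  stopifnot(new_threshold >= 0, new_threshold < full_threshold,
            full_threshold <= 1, synodic_days > 0)
  structure(list(full_threshold = full_threshold,
                 new_threshold = new_threshold,
                 epoch = epoch, synodic_days = synodic_days,
                 tz_offset_hours = tz_offset_hours,
                 ephemeris = ephemeris),
            class = "lunar_config")
}

#' Illuminated fraction of the moon
#'
#' Cosine phase-age model: `(1 - cos(2 * pi * age / period)) / 2` with `age`
#' the elapsed time since a reference new moon, modulo the mean synodic
#' month. Continuous and periodic; 0 at new moon, 1 at full moon.
#'
#' @param when POSIXct instant(s).
#' @param config A [lunar_config()].
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
illuminated_fraction <- function(when, config = lunar_config()) {
  age <- (as.numeric(when) - as.numeric(config$epoch)) / 86400
  age <- age %% config$synodic_days
  (1 - cos(2 * pi * age / config$synodic_days)) / 2
}

#' Classify nights by moon luminosity
#'
#' Evaluates the illuminated fraction at local midnight of each date and
#' applies the strict > full / < new thresholds; everything between is
#' excluded from the temporal model (too ambiguous under unmeasured cloud).
#'
#' @param dates Date vector (the calendar date of the night).
#' @param config A [lunar_config()].
#' @return Character vector over `c("full", "new", "excluded")`.
#' @export
classify_night <- function(dates, config = lunar_config()) {
  dates <- as.Date(dates)
  if (!is.null(config$ephemeris)) {
    m <- match(dates, as.Date(config$ephemeris$date))
    frac <- rep(NA_real_, length(dates))
    frac[!is.na(m)] <- config$ephemeris$fraction[m[!is.na(m)]]
    need <- is.na(frac)
  } else {
    frac <- rep(NA_real_, length(dates))
    need <- rep(TRUE, length(dates))
  }
  if (any(need)) {
    midnight <- as.POSIXct(as.numeric(dates[need]) * 86400 -
                             config$tz_offset_hours * 3600,
                           origin = "1970-01-01", tz = "UTC")
    frac[need] <- illuminated_fraction(midnight, config)
  }
  out <- rep("excluded", length(dates))
  out[frac > config$full_threshold] <- "full"
  out[frac < config$new_threshold] <- "new"
  out
}

#' Moon-class table for a date range
#'
#' @param from,to Dates (inclusive).
#' @param config A [lunar_config()].
#' @return data.frame `date`, `fraction`, `moon_class`.
#' @export
moon_calendar <- function(from, to, config = lunar_config()) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  midnight <- as.POSIXct(as.numeric(dates) * 86400 -
                           config$tz_offset_hours * 3600,
                         origin = "1970-01-01", tz = "UTC")
  data.frame(date = dates,
             fraction = illuminated_fraction(midnight, config),
             moon_class = classify_night(dates, config),
             stringsAsFactors = FALSE)
}
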