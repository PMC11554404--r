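## Builders for the two study model specifications: a spatial model of the
## per-site modal coat type against landscape covariates, and a temporal
## model of nightly coat-type captures against moon luminosity and weather.

#' Spatial model configuration
#'
#' @param continuous Continuous site covariates entering the design, in
#'   order.
#' @param vegetation_column Name of the categorical vegetation column.
#' @param vegetation_reference Vegetation class absorbed by the intercept.
#' @param standardize Z-score the continuous covariates (default TRUE; the
#'   recorded transform is attached to the design so odds ratios are per
#'   standard deviation).
#' @param reference Reference coat category (default solid black, the most
#'   common and distinct type).
#' @return List of class `spatial_config`.
#' @export
spatial_config <- function(continuous = c("elevation", "roughness",
                                          "isothermality", "fpar", "dtnt"),
                           vegetation_column = "vegetation",
                           vegetation_reference = "grassland",
                           standardize = TRUE,
                           reference = "solid_black") {
  structure(list(continuous = continuous,
                 vegetation_column = vegetation_column,
                 vegetation_reference = vegetation_reference,
                 standardize = standardize, reference = reference),
            class = "spatial_config")
}

standardize_columns <- function(M) {
  mu <- colMeans(M)
  sd_ <- apply(M, 2L, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)
  if (any(const)) {
    stop("constant covariate column(s): ",
         paste(colnames(M)[const], collapse = ", "), call. = FALSE)
  }
  list(X = sweep(sweep(M, 2L, mu), 2L, sd_, "/"),
       center = mu, scale = sd_)
}

#' Build the spatial design (modal coat type ~ site covariates)
#'
#' One row per retained site with a non-excluded modal category. Design:
#' intercept, the continuous covariates (standardized by default), and
#' dummy columns for vegetation class against the configured reference
#' class.
#'
#' @param summaries Output of [site_summaries()] (needs `site_id`,
#'   `modal_category`).
#' @param covariates data.frame keyed by `site_id` with the configured
#'   covariate columns.
#' @param config A [spatial_config()].
#' @return List `X` (design matrix), `y` (factor, reference level first),
#'   `dropped` (site count dropped for excluded modal type), `scaling`
#'   (center/scale per standardized column or NULL), `config`.
#' @export
build_spatial_model <- function(summaries, covariates,
                                config = spatial_config()) {
  keep <- summaries$modal_category %in% model_categories()
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " site(s) dropped: modal category excluded")
  }
  s <- summaries[keep, , drop = FALSE]
  m <- match(s$site_id, covariates$site_id)
  if (anyNA(m)) {
    stop("missing covariates for site(s): ",
         paste(s$site_id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  cov <- covariates[m, , drop = FALSE]
  missing_cols <- setdiff(c(config$continuous, config$vegetation_column),
                          names(cov))
  if (length(missing_cols)) {
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !stats::complete.cases(cov[, c(config$continuous,
                                        config$vegetation_column)])
  if (any(bad)) {
    stop("incomplete covariates for site(s): ",
         paste(cov$site_id[bad], collapse = ", "), call. = FALSE)
  }
  M <- as.matrix(cov[, config$continuous, drop = FALSE])
  scaling <- NULL
  if (config$standardize) {
    std <- standardize_columns(M)
    M <- std$X
    scaling <- std[c("center", "scale")]
  }
  veg <- factor(cov[[config$vegetation_column]])
  if (!config$vegetation_reference %in% levels(veg)) {
    stop("vegetation reference class '", config$vegetation_reference,
         "' absent from data", call. = FALSE)
  }
  veg <- stats::relevel(veg, ref = config$vegetation_reference)
  Vd <- NULL
  if (nlevels(veg) > 1L) {
    Vd <- stats::model.matrix(~veg)[, -1L, drop = FALSE]
    colnames(Vd) <- paste0("veg_", levels(veg)[-1L])
  }
  X <- cbind(intercept = 1, M, Vd)
  y <- factor(s$modal_category,
              levels = c(config$reference,
                         setdiff(model_categories(), config$reference)))
  y <- droplevels(y)
  list(X = X, y = y, dropped = dropped, scaling = scaling, config = config)
}

#' Temporal model configuration
#'
#' @param weather Continuous nightly weather covariates.
#' @param standardize Z-score the weather covariates (default TRUE).
#' @param reference Reference outcome; nights with no cat capture form an
#'   explicit "absence" level used as the reference (absence vastly
#'   outnumbers captures).
#' @return List of class `temporal_config`.
#' @export
temporal_config <- function(weather = c("rainfall", "solar", "min_temp"),
                            standardize = TRUE,
                            reference = "absence") {
  structure(list(weather = weather, standardize = standardize,
                 reference = reference),
            class = "temporal_config")
}

#' Build the temporal design (nightly coat-type capture ~ moon + weather)
#'
#' Input nights must already be restricted to full- or new-moon classes.
#' Each camera-night contributes one row per coat category captured that
#' night, or a single "absence" row when no cat was captured; a night with
#' several categories therefore contributes several capture rows and no
#' absence row. Design: intercept, weather covariates, a new-moon dummy
#' (new = 1, full = 0, so positive coefficients mean more activity on dark
#' nights) and the moon x solar-exposure interaction (solar exposure proxies
#' cloud cover).
#'
#' @param daily Output of [daily_records()] (site, date, category), already
#'   restricted to the modelling categories.
#' @param nights data.frame `site_id`, `date`, `moon_class` of camera
#'   operating nights; a class other than full/new is an error.
#' @param weather data.frame `site_id`, `date` plus the configured weather
#'   columns.
#' @param config A [temporal_config()].
#' @return List `X`, `y` (factor, absence reference), `nights_used`,
#'   `scaling`, `config`.
#' @export
build_temporal_model <- function(daily, nights, weather,
                                 config = temporal_config()) {
  if (!all(nights$moon_class %in% c("full", "new"))) {
    stop("nights table contains moon classes other than full/new; ",
         "subset before modelling", call. = FALSE)
  }
  if (!nrow(nights)) stop("no modelling nights", call. = FALSE)
  night_key <- paste(nights$site_id, nights$date, sep = "\r")
  if (anyDuplicated(night_key)) {
    stop("duplicated camera-nights in nights table", call. = FALSE)
  }
  daily <- daily[daily$category %in% model_categories(), , drop = FALSE]
  cap_key <- paste(daily$site_id, daily$date, sep = "\r")
  keep <- cap_key %in% night_key
  daily <- daily[keep, , drop = FALSE]
  cap_key <- cap_key[keep]

  ## capture rows + absence rows for capture-free nights
  absent <- !(night_key %in% cap_key)
  obs <- data.frame(
    site_id = c(daily$site_id, nights$site_id[absent]),
    date = c(daily$date, nights$date[absent]),
    outcome = c(daily$category, rep(config$reference, sum(absent))),
    stringsAsFactors = FALSE
  )
  m_night <- match(paste(obs$site_id, obs$date, sep = "\r"), night_key)
  obs$moon_class <- nights$moon_class[m_night]

  mw <- match(paste(obs$site_id, obs$date, sep = "\r"),
              paste(weather$site_id, weather$date, sep = "\r"))
  if (anyNA(mw)) {
    stop("missing weather for ", sum(is.na(mw)), " camera-night(s)",
         call. = FALSE)
  }
  W <- as.matrix(weather[mw, config$weather, drop = FALSE])
  if (anyNA(W)) stop("missing weather values", call. = FALSE)
  scaling <- NULL
  if (config$standardize) {
    std <- standardize_columns(W)
    W <- std$X
    scaling <- std[c("center", "scale")]
  }
  moon_new <- as.numeric(obs$moon_class == "new")
  solar_col <- match("solar", config$weather)
  if (is.na(solar_col)) {
    stop("temporal config must include a 'solar' weather column for the ",
         "moon x solar interaction", call. = FALSE)
  }
  X <- cbind(intercept = 1, W, moon_new = moon_new,
             moon_new_x_solar = moon_new * W[, solar_col])
  lv <- c(config$reference,
          intersect(model_categories(), unique(obs$outcome)))
  y <- factor(obs$outcome, levels = lv)
  list(X = X, y = y, nights_used = nrow(nights), scaling = scaling,
       config = config)
}
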