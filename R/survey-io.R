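## CSV ingest/egest for survey tables. All dates ISO-8601; timestamps in the
## survey's local clock.

#' Read a detection table
#'
#' Expects columns `site_id`, `timestamp` (ISO-8601), `pattern`, `colour`,
#' `white` (0/1 or logical), `individual_id` (empty = unknown). Grey cats
#' sit on a gradient to brown and are recoded `grey -> brown` at ingest
#' (logged); all records are then validated against the coat vocabulary and
#' annotated with their modelling category.
#'
#' @param path CSV file path, or a data.frame already in this layout.
#' @return Validated data.frame with an added `category` column.
#' @export
read_detections <- function(path) {
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "timestamp", "pattern", "colour", "white")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("detections lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(d$timestamp)) {
    # accept both ISO-8601 separators ("T" and space), even mixed
    d$timestamp <- as.POSIXct(sub("T", " ", d$timestamp, fixed = TRUE),
                              tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  }
  if (anyNA(d$timestamp)) stop("unparseable timestamps", call. = FALSE)
  n_grey <- sum(d$colour == "grey")
  if (n_grey > 0) {
    message(n_grey, " grey record(s) recoded to brown")
    d$colour[d$colour == "grey"] <- "brown"
  }
  d$white <- as.logical(d$white)
  if (is.null(d$individual_id)) d$individual_id <- NA_character_
  d$individual_id[d$individual_id == ""] <- NA_character_
  validate_coat(d$pattern, d$colour, d$white)
  d$category <- to_model_category(d$pattern, d$colour, d$white)
  d
}

#' Write a simulated survey to a directory
#'
#' Writes `detections.csv`, `deployments.csv`, `sites.csv`, `weather.csv`
#' and the generating ground truth as `truth.json`.
#'
#' @param survey Output of [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- survey$detections
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  det$white <- as.integer(det$white)
  det$individual_id[is.na(det$individual_id)] <- ""
  utils::write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(survey$deployments, file.path(dir, "deployments.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$weather, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  truth <- survey$truth
  truth$B_star <- list(values = as.vector(truth$B_star),
                       rows = rownames(truth$B_star),
                       cols = colnames(truth$B_star))
  truth$dominant <- as.list(truth$dominant[c("site_id", "dominant")])
  truth$moon_multipliers <- as.list(truth$moon_multipliers)  # keep names
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a survey directory written by [write_survey()]
#'
#' @param dir Directory path.
#' @return List with `sites`, `deployments`, `detections` (validated, with
#'   `category`), `weather`, and `truth` when present.
#' @export
read_survey <- function(dir) {
  detections <- read_detections(file.path(dir, "detections.csv"))
  deployments <- utils::read.csv(file.path(dir, "deployments.csv"),
                                 stringsAsFactors = FALSE)
  deployments$start_date <- as.Date(deployments$start_date)
  deployments$end_date <- as.Date(deployments$end_date)
  weather <- utils::read.csv(file.path(dir, "weather.csv"),
                             stringsAsFactors = FALSE)
  weather$date <- as.Date(weather$date)
  sites <- utils::read.csv(file.path(dir, "sites.csv"),
                           stringsAsFactors = FALSE)
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
    if (!is.null(truth$moon_multipliers)) {
      truth$moon_multipliers <- unlist(truth$moon_multipliers)
    }
    if (!is.null(truth$B_star)) {
      truth$B_star <- matrix(truth$B_star$values,
                             nrow = length(truth$B_star$rows),
                             dimnames = list(truth$B_star$rows,
                                             truth$B_star$cols))
    }
  }
  structure(list(sites = sites, deployments = deployments,
                 detections = detections, weather = weather, truth = truth),
            class = "survey")
}
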