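## Published summary counts from the state-wide Tasmanian feral cat
## camera-trap survey (2018 network; 651 retained sites). These printed
## tallies are inputs: they feed the black-cat ratio estimate and the
## bookkeeping identities checked by the test suite.

#' Published Tasmanian survey coat-type counts
#'
#' Per coat type: image count, daily events (camera-days with a capture),
#' percentage of images, identified individuals, images with white markings
#' and camera sites. Mackerel rows carry subcategory breakdowns (broken,
#' spotted, striped, ticked). The `total` row holds the printed grand
#' totals. Individuals are `NA` for unmarked solid black cats and for
#' unknown-coat images.
#'
#' @return data.frame, one row per coat type or subcategory.
#' @export
tasmanian_coat_counts <- function() {
  utils::read.csv(system.file("extdata", "tas_survey_coat_counts.csv",
                              package = "feralcoats"),
                  stringsAsFactors = FALSE)
}

#' Published Tasmanian survey night bookkeeping counts
#'
#' Moon-subset sizes (full and new nights, printed subset total), capture
#' nights within the subset, total operating days and retained sites.
#'
#' @return Named numeric vector.
#' @export
tasmanian_night_counts <- function() {
  d <- utils::read.csv(system.file("extdata", "tas_survey_night_counts.csv",
                                   package = "feralcoats"),
                       stringsAsFactors = FALSE)
  setNames(d$count, d$quantity)
}

#' Black-cat estimate from the published survey counts
#'
#' Applies the images-per-cat ratio estimator to the published tallies:
#' identifiable images are the grand total minus solid-black and
#' unknown-coat images; individuals are the printed grand total of
#' identified individuals; black images are the solid-black image count.
#'
#' @return A `black_estimate`.
#' @export
tasmanian_black_estimate <- function() {
  cc <- tasmanian_coat_counts()
  main <- cc[cc$subcategory == "" | is.na(cc$subcategory), , drop = FALSE]
  total <- main$image_count[main$coat_type == "total"]
  black <- main$image_count[main$coat_type == "solid_black"]
  unknown <- main$image_count[main$coat_type == "unknown"]
  individuals <- main$individuals[main$coat_type == "total"]
  estimate_black(total - black - unknown, individuals, black)
}
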