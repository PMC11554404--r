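## Controlled vocabularies for raw coat labels and the five modelling
## categories. Grey pelage is folded into brown upstream (see read_detections),
## so "grey" is deliberately absent from the colour vocabulary.

#' Coat vocabulary constants
#'
#' `coat_patterns()` and `coat_colours()` return the legal raw label sets;
#' `model_categories()` returns the five coat categories used in modelling,
#' in the fixed order also used for deterministic tie-breaking (descending
#' survey-wide prevalence).
#'
#' @return Character vector of legal values.
#' @export
coat_patterns <- function() {
  c("solid", "blotched", "broken", "spotted", "striped", "ticked",
    "tortoiseshell", "tuxedo", "unknown")
}

#' @rdname coat_patterns
#' @export
coat_colours <- function() {
  c("black", "brown", "orange", "mixed", "unknown")
}

#' @rdname coat_patterns
#' @export
model_categories <- function() {
  c("solid_black", "mackerel_brown", "blotched_brown", "orange",
    "tortoiseshell")
}

# tabby patterns can carry the brown or orange colour gene
tabby_patterns <- function() c("blotched", "broken", "spotted", "striped", "ticked")

# the four tabby patterns grouped as "mackerel" for modelling
mackerel_patterns <- function() c("broken", "spotted", "striped", "ticked")

#' Enumerate the legal raw coat types
#'
#' The raw vocabulary admits exactly 13 (pattern, colour) coat types: five
#' tabby patterns in brown or orange (10), solid black, tortoiseshell
#' (always a mixed orange/dark mosaic) and tuxedo (majority-white over
#' black). The white-markings flag is a separate locus and may accompany any
#' type; tuxedo is *defined* by white coverage and therefore requires
#' `white = TRUE`.
#'
#' @return A data.frame with columns `pattern`, `colour`.
#' @export
legal_coat_types <- function() {
  types <- rbind(
    expand.grid(pattern = tabby_patterns(), colour = c("brown", "orange"),
                stringsAsFactors = FALSE),
    data.frame(pattern = c("solid", "tortoiseshell", "tuxedo"),
               colour  = c("black", "mixed", "black"))
  )
  types[order(types$pattern, types$colour), , drop = FALSE]
}

#' Construct a single validated coat record
#'
#' @param pattern One of [coat_patterns()].
#' @param colour One of [coat_colours()].
#' @param white Logical: any white patch, star, sock or point colouration.
#'   Independent of pattern/colour except that tuxedo implies `white = TRUE`.
#' @return A list of class `coat_record`.
#' @export
coat_record <- function(pattern, colour, white = FALSE) {
  validate_coat(pattern, colour, white)
  structure(list(pattern = pattern, colour = colour, white = white),
            class = "coat_record")
}

#' Validate raw coat labels
#'
#' Vectorised consistency check of (pattern, colour, white) triples. Illegal
#' pairings (e.g. a solid pattern with orange colour) are rejected rather
#' than coerced, so labelling errors surface at ingest. `unknown` in either
#' field is a legal terminal state.
#'
#' @param pattern,colour,white Parallel vectors of raw labels.
#' @return Invisibly `TRUE`; otherwise an error naming the offending fields.
#' @export
validate_coat <- function(pattern, colour, white) {
  stopifnot(length(pattern) == length(colour),
            length(pattern) == length(white))
  if (!is.logical(white) || anyNA(white)) {
    stop("`white` must be logical with no missing values", call. = FALSE)
  }
  bad_p <- !pattern %in% coat_patterns()
  bad_c <- !colour %in% coat_colours()
  if (any(bad_p)) {
    stop("unknown pattern value(s): ",
         paste(unique(pattern[bad_p]), collapse = ", "), call. = FALSE)
  }
  if (any(bad_c)) {
    stop("unknown colour value(s): ",
         paste(unique(colour[bad_c]), collapse = ", "), call. = FALSE)
  }
  known <- pattern != "unknown" & colour != "unknown"
  ok <- !known |
    (pattern == "solid" & colour == "black") |
    (pattern == "tortoiseshell" & colour == "mixed") |
    (pattern == "tuxedo" & colour == "black" & white) |
    (pattern %in% tabby_patterns() & colour %in% c("brown", "orange"))
  if (any(!ok)) {
    i <- which(!ok)[1L]
    stop(sprintf(
      "inconsistent coat record: pattern = '%s' cannot pair with colour = '%s'%s",
      pattern[i], colour[i],
      if (pattern[i] == "tuxedo" && !white[i]) " (tuxedo requires white = TRUE)" else ""
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Map raw coat labels to modelling categories
#'
#' Deterministic, total mapping from validated (pattern, colour, white)
#' triples to the five analysis categories: the four non-blotched tabby
#' patterns in brown collapse to `mackerel_brown`; blotched brown stays its
#' own category; any tabby pattern in orange collapses to `orange`
#' (colouration assumed to dominate pattern at these sample sizes);
#' solid black and tortoiseshell map to themselves. Tuxedo (mostly-white)
#' cats and records with an unknown pattern or colour map to `excluded` and
#' never enter a model. The white flag never alters the category.
#'
#' @param pattern,colour,white Parallel label vectors, or a `coat_record` as
#'   the first argument.
#' @return Character vector over `c(model_categories(), "excluded")`.
#' @export
#' @examples
#' to_model_category("broken", "brown", FALSE)   # mackerel_brown
#' to_model_category("blotched", "orange", TRUE) # orange
to_model_category <- function(pattern, colour = NULL, white = FALSE) {
  if (inherits(pattern, "coat_record")) {
    rec <- pattern
    pattern <- rec$pattern; colour <- rec$colour; white <- rec$white
  }
  if (length(white) == 1L) white <- rep(white, length(pattern))
  validate_coat(pattern, colour, white)
  out <- rep("excluded", length(pattern))
  out[pattern %in% mackerel_patterns() & colour == "brown"] <- "mackerel_brown"
  out[pattern == "blotched" & colour == "brown"] <- "blotched_brown"
  out[pattern %in% tabby_patterns() & colour == "orange"] <- "orange"
  out[pattern == "solid" & colour == "black"] <- "solid_black"
  out[pattern == "tortoiseshell"] <- "tortoiseshell"
  out[pattern == "tuxedo" | pattern == "unknown" | colour == "unknown"] <- "excluded"
  out
}
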