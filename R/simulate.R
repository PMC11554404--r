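## Synthetic camera-trap surveys with known ground truth.
##
## The generator emulates the structure of a state-wide feral cat survey:
## site covariates with realistic Tasmanian ranges, coat-category assignment
## through a softmax-linear model with known coefficients, one dominant coat
## category per site with low-rate minority intruders, nightly detection
## processes whose rates differ between new- and full-moon nights,
## individually marked cats with an unknown-identity noise rate, and solid
## black cats that can never be individually identified.

#' Simulation configuration
#'
#' Defaults are calibrated to the marginal structure of a large Tasmanian
#' feral cat survey: coat prevalence roughly 43/33/16/5/3 percent across
#' solid black / mackerel brown / blotched brown / orange / tortoiseshell
#' among the five modelling categories, nightly per-category capture
#' probabilities giving an overall activity (PDE) of a few percent, and a
#' new-moon activity advantage for all coat types except orange.
#'
#' @param n_sites Number of camera sites.
#' @param start_date First deployment date.
#' @param n_nights Deployment length in nights (>= 60 for moon-cycle
#'   coverage).
#' @param B_star True coefficient matrix of the site-level coat model,
#'   (K-1) x P with rows `mackerel_brown`, `blotched_brown`, `orange`,
#'   `tortoiseshell` (reference `solid_black` fixed at zero) and columns
#'   `intercept`, standardized `elevation`, `roughness`, `isothermality`,
#'   `fpar`, `dtnt`, `veg_woodland`, `veg_forest`.
#' @param vegetation_probs Class probabilities for grassland/woodland/forest.
#' @param base_rate Nightly capture probability of a resident category on a
#'   full-moon night.
#' @param moon_multipliers Named per-category ratio of new-moon to full-moon
#'   capture rate; intermediate nights use the geometric mean of the two
#'   rates.
#' @param mean_extra_individuals Dominant-category residents are
#'   `1 + Poisson(mean_extra_individuals)`.
#' @param intruder_prob Probability each non-dominant category is resident
#'   (with one individual) at a site.
#' @param images_per_event_mean Mean images per capture event
#'   (`1 + Poisson(mean - 1)`).
#' @param unknown_id_prob Probability a marked cat's image cannot be
#'   attributed to an individual.
#' @param white_prob Probability of white markings on a non-tuxedo cat.
#' @param unknown_coat_rate Per camera-night rate of unclassifiable
#'   (unknown-coat) captures.
#' @param tuxedo_rate Per camera-night rate of tuxedo captures.
#' @param short_deploy_frac Fraction of cameras with a short (30-80 night)
#'   deployment, exercising the retention rule.
#' @param dominant_draw Draw the dominant category from the softmax
#'   probabilities (TRUE) or take the arg-max (FALSE).
#' @param lunar A [lunar_config()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_sites = 651,
                       start_date = as.Date("2019-01-01"),
                       n_nights = 365,
                       B_star = default_B_star(),
                       vegetation_probs = c(grassland = 0.25, woodland = 0.30,
                                            forest = 0.45),
                       base_rate = 0.022,
                       moon_multipliers = c(solid_black = 1.6,
                                            mackerel_brown = 1.5,
                                            blotched_brown = 1.5,
                                            orange = 1.0,
                                            tortoiseshell = 2.0),
                       mean_extra_individuals = 1.0,
                       intruder_prob = 0.15,
                       images_per_event_mean = 3,
                       unknown_id_prob = 0.25,
                       white_prob = 0.02,
                       unknown_coat_rate = 5e-4,
                       tuxedo_rate = 1e-4,
                       short_deploy_frac = 0.05,
                       dominant_draw = TRUE,
                       lunar = lunar_config()) {
  stopifnot(n_nights >= 60, base_rate > 0, base_rate < 1,
            all(moon_multipliers > 0),
            setequal(names(moon_multipliers), model_categories()),
            abs(sum(vegetation_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

#' Default true coefficients of the site-level coat model
#'
#' Intercepts reproduce the survey-scale category prevalence; the non-zero
#' slopes mirror effect sizes on the odds-ratio scale reported for Tasmanian
#' feral cats (orange and tortoiseshell more dominant at high elevation,
#' blotched brown less; mackerel brown favoured by dense, forested
#' vegetation; orange also tracking isothermality and FPAR).
#'
#' @return 4 x 8 numeric matrix (see [sim_config()]).
#' @export
default_B_star <- function() {
  preds <- c("intercept", "elevation", "roughness", "isothermality",
             "fpar", "dtnt", "veg_woodland", "veg_forest")
  cats <- setdiff(model_categories(), "solid_black")
  B <- matrix(0, length(cats), length(preds),
              dimnames = list(cats, preds))
  B["mackerel_brown", "intercept"] <- -0.26
  B["blotched_brown", "intercept"] <- -0.99
  B["orange", "intercept"] <- -2.21
  B["tortoiseshell", "intercept"] <- -2.63
  B["orange", "elevation"] <- log(2.5)
  B["tortoiseshell", "elevation"] <- log(4.0)
  B["blotched_brown", "elevation"] <- log(0.64)
  B["mackerel_brown", "fpar"] <- log(1.3)
  B["mackerel_brown", "veg_forest"] <- log(1.9)
  B["orange", "isothermality"] <- log(2.7)
  B["orange", "fpar"] <- log(1.5)
  B
}

# distinct RNG substream per generation stage: a site's covariate draw and
# its category draw must never share the underlying uniform
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 1299709) %% 2147483647)
}

#' Generate site covariates
#'
#' Elevation uniform on 0-1500 m, topographic roughness log-normal,
#' isothermality normal around 0.48, FPAR uniform on 0.2-0.95, distance to
#' nearest town exponential with 15 km mean, vegetation multinomial over
#' grassland/woodland/forest.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return data.frame keyed by `site_id`.
#' @export
gen_sites <- function(config, seed) {
  n <- config$n_sites
  with_preserved_rng({
    set.seed(derive_seed(seed, 1L))
    out <- data.frame(
      site_id = sprintf("S%04d", seq_len(n)),
      elevation = stats::runif(n, 0, 1500),
      roughness = stats::rlnorm(n, meanlog = 3, sdlog = 0.5),
      isothermality = stats::rnorm(n, 0.48, 0.04),
      fpar = stats::runif(n, 0.2, 0.95),
      dtnt = stats::rexp(n, rate = 1 / 15),
      vegetation = sample(names(config$vegetation_probs), n, replace = TRUE,
                          prob = config$vegetation_probs),
      stringsAsFactors = FALSE
    )
  })
  out
}

# standardized generation design matching build_spatial_model()'s encoding
sim_design <- function(sites, config) {
  M <- as.matrix(sites[, c("elevation", "roughness", "isothermality",
                           "fpar", "dtnt")])
  std <- standardize_columns(M)
  veg <- factor(sites$vegetation,
                levels = c("grassland", "woodland", "forest"))
  Vd <- cbind(veg_woodland = as.numeric(veg == "woodland"),
              veg_forest = as.numeric(veg == "forest"))
  list(X = cbind(intercept = 1, std$X, Vd), scaling = std[c("center", "scale")])
}

#' Assign coat-category fields to sites
#'
#' Site category probabilities are `softmax(B_star x)` with the reference
#' (solid black) row fixed at zero; the dominant category is drawn from
#' these probabilities (or arg-maxed). The probabilities and design scaling
#' are kept as ground truth for recovery tests.
#'
#' @param sites Output of [gen_sites()].
#' @param config A [sim_config()] (supplies `B_star` and `dominant_draw`).
#' @param seed Integer seed.
#' @return data.frame `site_id`, `dominant`; attributes `probs` (n x 5
#'   matrix) and `scaling`.
#' @export
gen_coat_field <- function(sites, config, seed) {
  des <- sim_design(sites, config)
  B <- config$B_star
  if (ncol(B) != ncol(des$X)) {
    stop("B_star has ", ncol(B), " columns; design has ", ncol(des$X),
         call. = FALSE)
  }
  eta <- cbind(0, des$X %*% t(B))
  colnames(eta) <- c("solid_black", rownames(B))
  m <- apply(eta, 1L, max)
  p <- exp(eta - m)
  p <- p / rowSums(p)
  with_preserved_rng({
    set.seed(derive_seed(seed, 2L))
    dominant <- if (config$dominant_draw) {
      apply(p, 1L, function(pr) sample(colnames(p), 1L, prob = pr))
    } else {
      colnames(p)[max.col(p, ties.method = "first")]
    }
  })
  out <- data.frame(site_id = sites$site_id, dominant = dominant,
                    stringsAsFactors = FALSE)
  attr(out, "probs") <- p
  attr(out, "scaling") <- des$scaling
  out
}

# draw concrete raw coat labels for a modelling category
raw_coat_for_category <- function(category, n) {
  pattern <- character(n); colour <- character(n)
  switch(category,
    solid_black = { pattern[] <- "solid"; colour[] <- "black" },
    blotched_brown = { pattern[] <- "blotched"; colour[] <- "brown" },
    mackerel_brown = {
      pattern <- sample(mackerel_patterns(), n, replace = TRUE,
                        prob = c(0.57, 0.39, 0.03, 0.01))
      colour[] <- "brown"
    },
    orange = {
      pattern <- sample(tabby_patterns(), n, replace = TRUE,
                        prob = c(0.28, 0.42, 0.27, 0.02, 0.01))
      colour[] <- "orange"
    },
    tortoiseshell = { pattern[] <- "tortoiseshell"; colour[] <- "mixed" },
    stop("unknown category ", category)
  )
  data.frame(pattern = pattern, colour = colour, stringsAsFactors = FALSE)
}

#' Generate detections and nightly weather for a simulated survey
#'
#' Residents per site: the dominant category holds
#' `1 + Poisson(mean_extra_individuals)` individuals; every other category
#' is resident with one individual with probability `intruder_prob`. On
#' each operating night each resident category is captured with probability
#' `base_rate` (full moon), `base_rate * multiplier` (new moon) or the
#' geometric mean (intermediate nights). Captures expand to image bursts
#' spaced under a minute apart; the pictured individual is drawn uniformly
#' from the site's residents of that category. Individual identities are
#' withheld with probability `unknown_id_prob`, and always for solid black
#' cats. Weather is drawn independently of moon phase.
#'
#' @param sites Output of [gen_sites()].
#' @param assignments Output of [gen_coat_field()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `detections`, `deployments`, `weather`, `residents`
#'   (site x category individual counts, ground truth).
#' @export
gen_detections <- function(sites, assignments, config, seed) {
  cats <- model_categories()
  n <- nrow(sites)
  start <- as.Date(config$start_date)
  with_preserved_rng({
    set.seed(derive_seed(seed, 3L))
    ## deployments, a few deliberately short
    len <- rep(config$n_nights, n)
    short <- stats::runif(n) < config$short_deploy_frac
    len[short] <- sample(30:80, sum(short), replace = TRUE)
    deployments <- data.frame(
      site_id = sites$site_id,
      start_date = start,
      end_date = start + len - 1L,
      operating_days = as.integer(len),
      stringsAsFactors = FALSE
    )

    ## residents
    dom <- assignments$dominant[match(sites$site_id, assignments$site_id)]
    res_list <- vector("list", length(cats))
    for (j in seq_along(cats)) {
      k <- cats[j]
      n_ind <- ifelse(dom == k,
                      1L + stats::rpois(n, config$mean_extra_individuals),
                      ifelse(stats::runif(n) < config$intruder_prob, 1L, 0L))
      res_list[[j]] <- data.frame(site_id = sites$site_id, category = k,
                                  n_ind = as.integer(n_ind),
                                  stringsAsFactors = FALSE)
    }
    residents <- do.call(rbind, res_list)
    residents <- residents[residents$n_ind > 0L, , drop = FALSE]

    ## operating nights with moon class
    cal <- moon_calendar(start, start + config$n_nights - 1L, config$lunar)
    night_idx <- sequence(deployments$operating_days)
    site_rep <- rep(deployments$site_id, deployments$operating_days)
    nights <- data.frame(
      site_id = site_rep,
      date = start + night_idx - 1L,
      stringsAsFactors = FALSE
    )
    mi <- match(nights$date, cal$date)
    nights$moon_class <- cal$moon_class[mi]
    nights$fraction <- cal$fraction[mi]

    ## nightly weather per camera-night
    nw <- nrow(nights)
    rain_wet <- stats::runif(nw) < 0.4
    weather <- data.frame(
      site_id = nights$site_id,
      date = nights$date,
      rainfall = ifelse(rain_wet, stats::rexp(nw, 1 / 4), 0),
      solar = pmax(stats::rnorm(nw, 18, 6), 0.5),
      min_temp = stats::rnorm(nw, 8, 4),
      stringsAsFactors = FALSE
    )

    ## capture process: residents x operating nights
    grid <- merge(residents, nights, by = "site_id")
    mult <- config$moon_multipliers[grid$category]
    rate <- config$base_rate *
      ifelse(grid$moon_class == "new", mult,
             ifelse(grid$moon_class == "full", 1, sqrt(mult)))
    captured <- grid[stats::runif(nrow(grid)) < rate, , drop = FALSE]

    detections <- NULL
    if (nrow(captured)) {
      ne <- nrow(captured)
      ind_idx <- ceiling(stats::runif(ne) * captured$n_ind)
      individual <- sprintf("%s_%s_%02d", captured$site_id,
                            captured$category, ind_idx)
      hide <- captured$category == "solid_black" |
        stats::runif(ne) < config$unknown_id_prob
      individual[hide] <- NA_character_
      n_img <- 1L + stats::rpois(ne, max(config$images_per_event_mean - 1, 0))
      t0 <- as.numeric(as.POSIXct(paste(captured$date, "00:00:00"),
                                  tz = "UTC")) +
        floor(stats::runif(ne, 0, 86400 - 600))
      rows <- rep(seq_len(ne), n_img)
      gaps <- stats::runif(length(rows), 5, 55)  # within-burst spacing < 60 s
      gaps[!duplicated(rows)] <- 0
      tt <- t0[rows] + stats::ave(gaps, rows, FUN = cumsum)
      coat <- do.call(rbind, lapply(split(seq_len(ne), captured$category),
        function(ii) {
          rc <- raw_coat_for_category(captured$category[ii[1L]], length(ii))
          rc$row <- ii
          rc
        }))
      coat <- coat[order(coat$row), , drop = FALSE]
      detections <- data.frame(
        site_id = captured$site_id[rows],
        timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
        pattern = coat$pattern[rows],
        colour = coat$colour[rows],
        white = stats::runif(length(rows)) < config$white_prob,
        individual_id = individual[rows],
        stringsAsFactors = FALSE
      )
    }

    ## occasional unclassifiable and tuxedo captures
    extra_mask <- stats::runif(nw) < config$unknown_coat_rate
    tux_mask <- stats::runif(nw) < config$tuxedo_rate
    extras <- NULL
    if (any(extra_mask) || any(tux_mask)) {
      mk <- function(mask, pattern, colour, white) {
        if (!any(mask)) return(NULL)
        data.frame(
          site_id = nights$site_id[mask],
          timestamp = as.POSIXct(
            as.numeric(as.POSIXct(paste(nights$date[mask], "00:00:00"),
                                  tz = "UTC")) +
              floor(stats::runif(sum(mask), 0, 86000)),
            origin = "1970-01-01", tz = "UTC"),
          pattern = pattern, colour = colour, white = white,
          individual_id = NA_character_,
          stringsAsFactors = FALSE
        )
      }
      extras <- rbind(mk(extra_mask, "unknown", "unknown", FALSE),
                      mk(tux_mask, "tuxedo", "black", TRUE))
    }
    detections <- rbind(detections, extras)
  })
  if (is.null(detections)) {
    detections <- data.frame(site_id = character(),
                             timestamp = as.POSIXct(character(), tz = "UTC"),
                             pattern = character(), colour = character(),
                             white = logical(),
                             individual_id = character(),
                             stringsAsFactors = FALSE)
  }
  detections <- detections[order(detections$site_id, detections$timestamp), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  list(detections = detections, deployments = deployments, weather = weather,
       residents = residents)
}

#' Simulate a complete survey with ground truth
#'
#' Runs [gen_sites()], [gen_coat_field()] and [gen_detections()] under one
#' seed and bundles the result with the generating truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory).
#' @return List of class `survey`: `sites`, `deployments`, `detections`,
#'   `weather`, `truth` (B_star, scaling, dominant assignments, residents,
#'   moon multipliers, base rate, seed), `config`.
#' @export
simulate_survey <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  sites <- gen_sites(config, seed)
  assignments <- gen_coat_field(sites, config, seed)
  gd <- gen_detections(sites, assignments, config, seed)
  truth <- list(
    B_star = config$B_star,
    scaling = attr(assignments, "scaling"),
    dominant = assignments,
    residents = gd$residents,
    n_black_individuals = sum(gd$residents$n_ind[
      gd$residents$category == "solid_black"]),
    moon_multipliers = config$moon_multipliers,
    base_rate = config$base_rate,
    seed = seed
  )
  structure(list(sites = sites, deployments = gd$deployments,
                 detections = gd$detections, weather = gd$weather,
                 truth = truth, config = config),
            class = "survey")
}
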