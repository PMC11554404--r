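toy_summaries <- function() {
  data.frame(
    site_id = paste0("S", 1:6),
    modal_category = c("solid_black", "mackerel_brown", "orange",
                       "blotched_brown", "tortoiseshell", "excluded"),
    stringsAsFactors = FALSE
  )
}

toy_covariates <- function() {
  set.seed(12)
  data.frame(
    site_id = paste0("S", 1:6),
    elevation = c(100, 900, 1200, 300, 1100, 500),
    roughness = runif(6, 5, 40),
    isothermality = runif(6, 0.4, 0.55),
    fpar = runif(6, 0.3, 0.9),
    dtnt = runif(6, 1, 40),
    vegetation = c("grassland", "forest", "woodland", "forest",
                   "grassland", "woodland"),
    stringsAsFactors = FALSE
  )
}

test_that("spatial design has intercept, scaled covariates and veg dummies", {
  suppressMessages(b <- build_spatial_model(toy_summaries(), toy_covariates()))
  expect_identical(nrow(b$X), 5L)        # excluded modal site dropped
  expect_identical(b$dropped, 1L)
  expect_identical(colnames(b$X)[1], "intercept")
  # 3 vegetation classes -> 2 dummies against the grassland reference
  expect_identical(sum(grepl("^veg_", colnames(b$X))), 2L)
  # standardized continuous columns have mean 0, sd 1
  expect_lt(max(abs(colMeans(b$X[, 2:6]))), 1e-10)
  expect_equal(unname(apply(b$X[, 2:6], 2, sd)), rep(1, 5))
  expect_identical(levels(b$y)[1], "solid_black")
})

test_that("spatial builder reports missing covariates and constant columns", {
  s <- toy_summaries()[1:5, ]
  cov <- toy_covariates()
  expect_error(build_spatial_model(s, cov[-2, ]), "S2")
  cov2 <- cov; cov2$elevation <- 500
  expect_error(build_spatial_model(s, cov2), "elevation")
  cov3 <- cov; cov3$fpar[3] <- NA
  expect_error(build_spatial_model(s, cov3), "S3")
})

toy_nights <- function() {
  data.frame(
    site_id = rep(c("S1", "S2"), each = 5),
    date = rep(as.Date("2019-07-01") + 0:4, 2),
    moon_class = rep(c("full", "new"), 5),
    stringsAsFactors = FALSE
  )
}

toy_weather <- function() {
  n <- toy_nights()
  set.seed(4)
  data.frame(site_id = n$site_id, date = n$date,
             rainfall = rexp(10), solar = runif(10, 5, 25),
             min_temp = rnorm(10, 8, 3), stringsAsFactors = FALSE)
}

test_that("temporal rows are one per captured category plus absence rows", {
  daily <- data.frame(
    site_id = c("S1", "S1", "S2"),
    date = as.Date(c("2019-07-01", "2019-07-01", "2019-07-03")),
    category = c("solid_black", "orange", "tortoiseshell"),
    stringsAsFactors = FALSE
  )
  b <- build_temporal_model(daily, toy_nights(), toy_weather())
  # 10 camera-nights: 2 with captures -> 3 capture rows + 8 absence rows
  expect_identical(length(b$y), 11L)
  expect_identical(sum(b$y == "absence"), 8L)
  expect_identical(levels(b$y)[1], "absence")
  # multi-category night contributes no absence row
  keyed <- paste(c("S1"), as.Date("2019-07-01"))
  expect_identical(sum(b$y[1:3] == "absence"), 0L)
})

test_that("temporal design carries the new-moon dummy and moon x solar column", {
  daily <- data.frame(site_id = "S1", date = as.Date("2019-07-02"),
                      category = "solid_black", stringsAsFactors = FALSE)
  cfg <- temporal_config(standardize = FALSE)
  b <- build_temporal_model(daily, toy_nights(), toy_weather(), cfg)
  moon <- b$X[, "moon_new"]
  expect_setequal(unique(moon), c(0, 1))
  expect_equal(b$X[, "moon_new_x_solar"], moon * b$X[, "solar"])
  # full-moon rows have a zeroed interaction regardless of solar
  expect_true(all(b$X[moon == 0, "moon_new_x_solar"] == 0))
})

test_that("temporal builder rejects excluded nights and empty night sets", {
  n <- toy_nights(); n$moon_class[3] <- "excluded"
  daily <- data.frame(site_id = character(), date = as.Date(character()),
                      category = character())
  expect_error(build_temporal_model(daily, n, toy_weather()), "full/new")
  expect_error(build_temporal_model(daily, toy_nights()[0, ], toy_weather()),
               "no modelling nights")
  w <- toy_weather()[-1, ]
  expect_error(build_temporal_model(daily, toy_nights(), w), "weather")
})
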