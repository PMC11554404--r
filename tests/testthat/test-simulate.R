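test_that("site generation is reproducible, bounded and sized", {
  cfg <- sim_config(n_sites = 40)
  s1 <- gen_sites(cfg, 7)
  s2 <- gen_sites(cfg, 7)
  expect_identical(s1, s2)
  s3 <- gen_sites(cfg, 8)
  expect_false(identical(s1$elevation, s3$elevation))
  expect_identical(nrow(s1), 40L)
  expect_true(all(s1$elevation >= 0 & s1$elevation <= 1500))
  expect_true(all(s1$fpar >= 0.2 & s1$fpar <= 0.95))
  expect_true(all(s1$vegetation %in% c("grassland", "woodland", "forest")))
  expect_identical(nrow(gen_sites(sim_config(n_sites = 0), 1)), 0L)
})

test_that("zero coefficients give uniform category probabilities", {
  cfg <- sim_config(n_sites = 30, B_star = default_B_star() * 0)
  sites <- gen_sites(cfg, 3)
  asg <- gen_coat_field(sites, cfg, 3)
  p <- attr(asg, "probs")
  expect_equal(unname(p), matrix(0.2, 30, 5), tolerance = 1e-12)
})

test_that("a positive elevation coefficient raises that category's probability", {
  B <- default_B_star() * 0
  B["orange", "elevation"] <- 2
  cfg <- sim_config(n_sites = 200, B_star = B)
  sites <- gen_sites(cfg, 5)
  asg <- gen_coat_field(sites, cfg, 5)
  p <- attr(asg, "probs")[, "orange"]
  ord <- order(sites$elevation)
  expect_true(all(diff(p[ord]) > 0))
})

test_that("coat-field draws follow the softmax probabilities", {
  cfg <- sim_config(n_sites = 4000)
  sites <- gen_sites(cfg, 19)
  asg <- gen_coat_field(sites, cfg, 19)
  p <- attr(asg, "probs")
  drawn <- prop.table(table(factor(asg$dominant, colnames(p))))
  expect_equal(as.numeric(drawn), unname(colMeans(p)), tolerance = 0.05)
  # conditional structure, not just margins: tortoiseshell rises with elevation
  hi <- sites$elevation > 1200
  expect_gt(mean(asg$dominant[hi] == "tortoiseshell"),
            mean(asg$dominant[!hi] == "tortoiseshell"))
})

test_that("B_star dimensions are checked", {
  cfg <- sim_config(n_sites = 10)
  cfg$B_star <- cfg$B_star[, 1:3]
  sites <- gen_sites(cfg, 1)
  expect_error(gen_coat_field(sites, cfg, 1), "columns")
})

test_that("moon multipliers shape the new:full capture ratio", {
  B <- default_B_star() * 0
  mult <- c(solid_black = 1, mackerel_brown = 1, blotched_brown = 1,
            orange = 1, tortoiseshell = 2)
  cfg <- sim_config(n_sites = 250, n_nights = 365, B_star = B,
                    moon_multipliers = mult, base_rate = 0.03,
                    unknown_coat_rate = 0, tuxedo_rate = 0,
                    short_deploy_frac = 0)
  sv <- simulate_survey(cfg, seed = 31)
  det <- read_detections(sv$detections)
  det$date <- as.Date(det$timestamp, tz = "UTC")
  det$moon <- classify_night(det$date, cfg$lunar)
  cal <- moon_calendar(cfg$start_date, cfg$start_date + cfg$n_nights - 1,
                       cfg$lunar)
  n_full <- sum(cal$moon_class == "full") * cfg$n_sites
  n_new <- sum(cal$moon_class == "new") * cfg$n_sites
  # distinct capture nights per stratum for the multiplier-2 category
  tort <- unique(det[det$category == "tortoiseshell" & det$moon != "excluded",
                     c("site_id", "date", "moon")])
  rate_new <- nrow(tort[tort$moon == "new", ]) / n_new
  rate_full <- nrow(tort[tort$moon == "full", ]) / n_full
  expect_gt(rate_new / rate_full, 1.5)
  expect_lt(rate_new / rate_full, 2.6)
  # multiplier-1 category: ratio compatible with no moon effect
  mb <- unique(det[det$category == "mackerel_brown" & det$moon != "excluded",
                   c("site_id", "date", "moon")])
  k_new <- nrow(mb[mb$moon == "new", ]); k_full <- nrow(mb[mb$moon == "full", ])
  pt <- prop.test(c(k_new, k_full), c(n_new, n_full))
  expect_gt(pt$p.value, 0.01)
})

test_that("zero base rate yields no resident captures", {
  cfg <- sim_config(n_sites = 30, n_nights = 90, base_rate = 1e-12,
                    unknown_coat_rate = 0, tuxedo_rate = 0)
  sv <- simulate_survey(cfg, seed = 2)
  expect_identical(nrow(sv$detections), 0L)
})

test_that("detections respect deployment windows and the coat vocabulary", {
  sv <- small_survey(17, n_sites = 60)
  det <- sv$detections
  expect_silent(validate_coat(det$pattern, det$colour, det$white))
  dep <- sv$deployments
  d <- as.Date(det$timestamp, tz = "UTC")
  m <- match(det$site_id, dep$site_id)
  expect_true(all(d >= dep$start_date[m] & d <= dep$end_date[m]))
  # black cats are never individually identified
  blk <- to_model_category(det$pattern, det$colour, det$white) == "solid_black"
  expect_true(all(is.na(det$individual_id[blk])))
})

test_that("survey round-trips through the CSV/JSON directory format", {
  sv <- small_survey(23, n_sites = 25, n_nights = 70)
  dir <- withr::local_tempdir()
  write_survey(sv, dir)
  expect_true(all(file.exists(file.path(dir,
    c("detections.csv", "deployments.csv", "sites.csv", "weather.csv",
      "truth.json")))))
  rt <- read_survey(dir)
  expect_identical(nrow(rt$detections), nrow(sv$detections))
  expect_equal(rt$truth$B_star, sv$truth$B_star)
  expect_identical(sort(rt$deployments$site_id), sort(sv$deployments$site_id))
  expect_equal(as.numeric(rt$detections$timestamp),
               as.numeric(sv$detections$timestamp))
})
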