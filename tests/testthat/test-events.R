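test_that("a gap strictly over 60 s starts a new event", {
  d <- make_detections(c(0, 30, 95))
  ev <- group_events(d)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$n_images, c(2L, 1L))

  # boundary: exactly 60 s stays in one event
  expect_identical(nrow(group_events(make_detections(c(0, 60)))), 1L)
  expect_identical(nrow(group_events(make_detections(c(0, 61)))), 2L)

  # single image is its own event
  ev1 <- group_events(make_detections(0))
  expect_identical(ev1$n_images, 1L)
  expect_identical(ev1$start_time, ev1$end_time)

  # long burst at 10 s spacing is one event (oracle: count gaps > 60)
  d <- make_detections(seq(0, by = 10, length.out = 100))
  expect_identical(nrow(group_events(d)), 1L)
  expect_identical(group_events(d)$n_images, 100L)
})

test_that("events never merge across known individuals, unknowns group by time", {
  d <- rbind(make_detections(c(0, 20), individual = "cat_A"),
             make_detections(c(10, 30), individual = "cat_B"))
  ev <- group_events(d)
  expect_identical(nrow(ev), 2L)
  expect_setequal(ev$individual_id, c("cat_A", "cat_B"))

  # same times, both unknown: one time-grouped stream
  d2 <- rbind(make_detections(c(0, 20)), make_detections(c(10, 30)))
  expect_identical(nrow(group_events(d2)), 1L)
})

test_that("event count is permutation-invariant and monotone in gap", {
  set.seed(71)
  for (rep in 1:5) {
    d <- make_detections(sort(sample.int(3000, 60)),
                         individual = sample(c(NA, "a", "b"), 60, TRUE))
    shuffled <- d[sample.int(nrow(d)), , drop = FALSE]
    expect_identical(nrow(group_events(shuffled)), nrow(group_events(d)))
    n_by_gap <- vapply(c(10, 30, 60, 120, 600),
                       function(g) nrow(group_events(d, g)), integer(1))
    expect_true(all(diff(n_by_gap) <= 0))
  }
})

test_that("duplicate timestamps warn and keep the first image", {
  d <- make_detections(c(0, 0, 30))
  expect_warning(ev <- group_events(d), "duplicate")
  expect_identical(ev$n_images, 2L)
})

test_that("daily records flag one row per site-date-category", {
  d <- rbind(make_detections(c(0, 3600, 7200)),            # 3 events, 1 day
             make_detections(0, category = "orange"),
             make_detections(86400 * 2, category = "orange"))
  ev <- group_events(d)
  dr <- daily_records(ev)
  expect_identical(nrow(dr), 3L)
  expect_identical(sum(dr$category == "mackerel_brown"), 1L)
  expect_identical(sum(dr$category == "orange"), 2L)
  expect_identical(nrow(daily_records(group_events(make_detections(numeric(0))))),
                   0L)
})

test_that("detection latency is whole days from deployment start", {
  dep <- make_deployments(c("S1", "S2", "S3"))
  ev <- group_events(rbind(
    make_detections(0, origin = ts_utc("2019-06-11 04:00:00")),   # day 10
    make_detections(0, site = "S2", origin = ts_utc("2019-06-01 12:00:00"))
  ))
  lat <- first_detection_latency(dep, ev)
  expect_identical(lat$latency_days, c(10L, 0L, NA_integer_))

  bad <- group_events(make_detections(0, origin = ts_utc("2019-05-20 10:00:00")))
  expect_error(first_detection_latency(dep, bad), "precedes")
})

test_that("retention threshold is the ceiling of the interpolated percentile", {
  expect_identical(derive_retention_threshold(1:20), 19L)
  expect_identical(derive_retention_threshold(rep(83, 40)), 83L)
  expect_identical(derive_retention_threshold(5), 5L)
  expect_identical(derive_retention_threshold(c(2.5, 7.5), percentile = 50), 3L)
  expect_error(derive_retention_threshold(numeric(0)), "latencies")
})

test_that("retention keeps every site with a detection and long true absences", {
  dep <- make_deployments(c("A", "B", "C"), days = 50)
  dep$operating_days[3] <- 90L
  ev <- group_events(make_detections(0, site = "B",
                                     origin = ts_utc("2019-06-05 01:00:00")))
  kept <- filter_sites(dep, ev, threshold_days = 83)
  expect_setequal(kept, c("B", "C"))
  # property: a detection always rescues a site, any threshold
  for (thr in c(0, 10, 1000)) {
    expect_true("B" %in% filter_sites(dep, ev, thr))
  }
})

test_that("black-cat ratio estimator reproduces hand arithmetic", {
  e <- estimate_black(100, 10, 40)
  expect_equal(e$images_per_cat, 10)
  expect_equal(e$estimated_black, 4)
  # algebraic identity: (k*r, k, m*r) -> m exactly
  e2 <- estimate_black(17 * 23, 17, 6 * 23)
  expect_equal(e2$estimated_black, 6)
  expect_error(estimate_black(0, 5, 10), "positive")
  expect_error(estimate_black(10, 0, 10), "positive")
})

test_that("modal coat type follows individuals, then events, then fixed order", {
  m <- modal_coat(c(solid_black = 3, mackerel_brown = 1))
  expect_identical(m$category, "solid_black")
  expect_false(m$tie_broken)

  m2 <- modal_coat(c(blotched_brown = 2, mackerel_brown = 2),
                   c(blotched_brown = 10, mackerel_brown = 7))
  expect_identical(m2$category, "blotched_brown")
  expect_true(m2$tie_broken)

  # individuals and events both tied: fixed prevalence order wins
  m3 <- modal_coat(c(tortoiseshell = 2, orange = 2),
                   c(tortoiseshell = 5, orange = 5))
  expect_identical(m3$category, "orange")
  expect_true(m3$tie_broken)

  expect_error(modal_coat(c(solid_black = 0)), "filtered")
})

test_that("image tally conserves every ingested detection", {
  sv <- small_survey(5)
  det <- read_detections(sv$detections)
  tal <- image_tally(det)
  expect_identical(sum(tal), nrow(det))
  expect_true(all(tal >= 0))
})

test_that("black estimator recovers simulated abundance under homogeneous imaging", {
  set.seed(909)
  n_black <- 150; n_marked <- 350
  imgs_marked <- rpois(n_marked, 20)
  imgs_black <- rpois(n_black, 20)
  est <- estimate_black(sum(imgs_marked), n_marked, sum(imgs_black))
  expect_lt(abs(est$estimated_black - n_black) / n_black, 0.10)
})
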