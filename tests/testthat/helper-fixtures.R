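# shared fixture builders; all randomness seeded at call sites

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# detection rows at one site with explicit timestamps (seconds offsets)
make_detections <- function(offsets, site = "S1", category = "mackerel_brown",
                            individual = NA_character_,
                            origin = ts_utc("2019-06-01 21:00:00")) {
  data.frame(
    site_id = rep_len(site, length(offsets)),
    timestamp = origin + offsets,
    category = rep_len(category, length(offsets)),
    individual_id = rep_len(individual, length(offsets)),
    stringsAsFactors = FALSE
  )
}

make_deployments <- function(site_ids, start = as.Date("2019-06-01"),
                             days = 100) {
  data.frame(site_id = site_ids, start_date = start,
             end_date = start + days - 1L,
             operating_days = as.integer(days),
             stringsAsFactors = FALSE)
}

small_survey <- function(seed, n_sites = 120, n_nights = 120, ...) {
  simulate_survey(sim_config(n_sites = n_sites, n_nights = n_nights, ...),
                  seed = seed)
}
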