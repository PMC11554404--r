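#!/usr/bin/env Rscript
# Stage 5 — PDE activity index by moon stratum.
#
# Proportion of dates with events (100 x capture nights / operating
# nights), pooled over sites, with site-level bootstrap standard errors
# (B = 1000). Cats in the simulated survey, like their real counterparts,
# are more active on dark nights.

suppressMessages(library(feralcoats))

seed <- 20240505
sv <- read_survey("results/survey")
prep <- prepare_events(sv)

dep <- prep$deployments
nights <- data.frame(
  site_id = rep(dep$site_id, dep$operating_days),
  date = dep$start_date[rep(seq_len(nrow(dep)), dep$operating_days)] +
    sequence(dep$operating_days) - 1L
)
nights$moon_class <- classify_night(nights$date)
nights <- nights[nights$moon_class != "excluded", ]

for (st in c("full", "new", "all")) {
  tab <- site_night_summary(prep$daily, nights, st)
  print(bootstrap_pde(tab, st, B = 1000, seed = seed))
}
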