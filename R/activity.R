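## PDE (proportion of dates with events) activity index with site-level
## bootstrap standard errors.

#' Proportion of dates with events
#'
#' `100 * nights_with_captures / operating_nights`, the standard
#' camera-trap activity index.
#'
#' @param nights_with_captures,operating_nights Counts.
#' @return Percent in `[0, 100]`.
#' @export
pde <- function(nights_with_captures, operating_nights) {
  if (any(operating_nights <= 0)) {
    stop("operating_nights must be positive", call. = FALSE)
  }
  if (any(nights_with_captures > operating_nights) ||
      any(nights_with_captures < 0)) {
    stop("nights_with_captures must lie in [0, operating_nights]",
         call. = FALSE)
  }
  100 * nights_with_captures / operating_nights
}

#' Per-site capture/operating night counts by moon stratum
#'
#' @param daily Output of [daily_records()]; any category counts as a
#'   capture night.
#' @param nights data.frame `site_id`, `date`, `moon_class` of operating
#'   nights.
#' @param stratum `"full"`, `"new"` or `"all"`.
#' @return data.frame `site_id`, `capture_nights`, `operating_nights`.
#' @export
site_night_summary <- function(daily, nights, stratum = "all") {
  stopifnot(stratum %in% c("full", "new", "all"))
  if (stratum != "all") {
    nights <- nights[nights$moon_class == stratum, , drop = FALSE]
  }
  sites <- sort(unique(nights$site_id))
  op <- table(factor(nights$site_id, sites))
  cap_nights <- unique(daily[, c("site_id", "date")])
  key_cap <- paste(cap_nights$site_id, cap_nights$date, sep = "\r")
  key_night <- paste(nights$site_id, nights$date, sep = "\r")
  hit <- nights[key_night %in% key_cap, , drop = FALSE]
  cp <- table(factor(hit$site_id, sites))
  data.frame(site_id = sites,
             capture_nights = as.integer(cp),
             operating_nights = as.integer(op),
             stringsAsFactors = FALSE)
}

#' Bootstrap the PDE over camera sites
#'
#' Nights within a site are dependent, so the resampling unit is the site:
#' sites are drawn with replacement `B` times and the pooled PDE (total
#' capture nights / total operating nights) recomputed per replicate; the
#' standard error is the standard deviation of the replicates. The
#' mean-of-site-PDEs variant is also reported; the pooled index is primary.
#'
#' @param site_table Output of [site_night_summary()] (already restricted
#'   to the stratum of interest).
#' @param stratum Label stored in the result.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return List of class `pde_result`: `stratum`, `pde_percent` (pooled),
#'   `pde_mean_site`, `se`, `se_mean_site`, `n_sites`, `bootstrap_reps`,
#'   `seed`.
#' @export
bootstrap_pde <- function(site_table, stratum = "all", B = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n <- nrow(site_table)
  if (n < 2L) stop("bootstrap needs at least 2 sites", call. = FALSE)
  keep <- site_table$operating_nights > 0
  site_table <- site_table[keep, , drop = FALSE]
  n <- nrow(site_table)
  cap <- site_table$capture_nights
  op <- site_table$operating_nights
  point <- pde(sum(cap), sum(op))
  site_pde <- pde(cap, op)
  reps_pooled <- numeric(B)
  reps_mean <- numeric(B)
  with_preserved_rng({
    set.seed(seed)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      reps_pooled[b] <- 100 * sum(cap[idx]) / sum(op[idx])
      reps_mean[b] <- mean(site_pde[idx])
    }
  })
  structure(list(stratum = stratum,
                 pde_percent = point,
                 pde_mean_site = mean(site_pde),
                 se = stats::sd(reps_pooled),
                 se_mean_site = stats::sd(reps_mean),
                 n_sites = n, bootstrap_reps = B, seed = seed),
            class = "pde_result")
}

#' @export
print.pde_result <- function(x, ...) {
  cat(sprintf(
    "PDE [%s]: %.2f%% (bootstrap SE %.3f, %d sites, B = %d, seed = %d)\n",
    x$stratum, x$pde_percent, x$se, x$n_sites, x$bootstrap_reps,
    as.integer(x$seed)))
  invisible(x)
}

# evaluate `expr` without disturbing the caller's RNG stream
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
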