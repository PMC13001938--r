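#' Configuration for the synthetic microcosm cohort generator
#'
#' Defaults emulate the structure of the study cohort this package is built
#' around: 172 incubation bottles spread over 4 Great-Lakes-like sites, about
#' 404 samples in total across incubation weeks 0-7, three oil conditions
#' (no oil / crude / diesel), and 503 sparse taxa count columns of which a
#' small planted subset blooms under oil amendment.
#'
#' @param n_bottles Number of independent microcosm bottles.
#' @param samples_per_bottle_mean Expected samples per bottle; samples per
#'   bottle are `1 + Poisson(mean - 1)`, capped at 8 distinct weeks.
#' @param n_taxa Number of taxa count columns.
#' @param n_sites Number of sampling sites (distinct lat/lon anchors).
#' @param n_responsive Number of planted oil-responsive taxa.
#' @param effect_log2fc `n_responsive x 2` matrix of log2 fold changes
#'   (columns: crude, diesel) applied at full ramp. Default alternates
#'   crude-responders (3, 0.5) and diesel-responders (0.5, 3) so the two oil
#'   types stay distinguishable.
#' @param sparsity Zero-inflation probability for structural zeros. The
#'   probability is abundance-damped, `sparsity * exp(-mu / zi_mean_scale)`:
#'   dropout hits rare taxa, not blooming populations.
#' @param dispersion Negative-binomial overdispersion phi
#'   (variance = mu + phi * mu^2).
#' @param zi_mean_scale Mean-abundance scale of the zero-inflation damping.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-taxon
#'   baseline mean abundances.
#' @param bottle_effect_sd SD (log2 scale) of per-bottle, per-taxon random
#'   effects; raise it to make bottles heterogeneous and hold-out hard.
#' @param ramp_week Incubation week by which the oil response saturates.
#' @param ramp_offset Head start of the response in weeks: the ramp is
#'   `min((week + ramp_offset) / ramp_week, 1)`, so with the defaults the
#'   bloom is already at 1/3 strength at the week-0 sampling (degraders
#'   respond within days of amendment) and saturates by week 3.
#' @param seed Integer seed; identical config implies identical cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_bottles = 172,
                          samples_per_bottle_mean = 404 / 172,
                          n_taxa = 503,
                          n_sites = 4,
                          n_responsive = 10,
                          effect_log2fc = NULL,
                          sparsity = 0.4,
                          dispersion = 0.1,
                          zi_mean_scale = 10,
                          baseline_meanlog = 1.0,
                          baseline_sdlog = 1.5,
                          bottle_effect_sd = 0.25,
                          ramp_week = 3,
                          ramp_offset = 1,
                          seed = 1) {
  if (is.null(effect_log2fc) && n_responsive > 0) {
    crude <- rep(c(3, 0.5), length.out = n_responsive)
    diesel <- rep(c(0.5, 3), length.out = n_responsive)
    effect_log2fc <- cbind(crude = crude, diesel = diesel)
  }
  cfg <- list(
    n_bottles = as.integer(n_bottles),
    samples_per_bottle_mean = samples_per_bottle_mean,
    n_taxa = as.integer(n_taxa),
    n_sites = as.integer(n_sites),
    n_responsive = as.integer(n_responsive),
    effect_log2fc = effect_log2fc,
    sparsity = sparsity,
    dispersion = dispersion,
    zi_mean_scale = zi_mean_scale,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    bottle_effect_sd = bottle_effect_sd,
    ramp_week = ramp_week,
    ramp_offset = ramp_offset,
    seed = as.integer(seed)
  )
  bad <- cfg$n_bottles < 1 || cfg$n_taxa < 0 || cfg$n_sites < 1 ||
    cfg$n_responsive < 0 || cfg$n_responsive > cfg$n_taxa ||
    cfg$sparsity < 0 || cfg$sparsity > 1 || cfg$dispersion <= 0 ||
    cfg$zi_mean_scale <= 0 ||
    cfg$samples_per_bottle_mean < 1 || cfg$bottle_effect_sd < 0 ||
    cfg$ramp_week <= 0 || cfg$ramp_offset < 0
  if (bad) {
    rlang::abort("invalid cohort configuration", class = "microstress_config_error")
  }
  if (cfg$n_responsive > 0 &&
    (!is.matrix(cfg$effect_log2fc) || nrow(cfg$effect_log2fc) != cfg$n_responsive ||
      ncol(cfg$effect_log2fc) != 2)) {
    rlang::abort("effect_log2fc must be an n_responsive x 2 matrix",
      class = "microstress_config_error"
    )
  }
  structure(cfg, class = "cohort_config")
}

# default site anchors: four Great-Lakes-like coordinates (any four distinct
# points are equally valid; nothing downstream depends on the values)
default_sites <- function(n_sites) {
  base <- data.frame(
    site = c("SUP", "MI", "GLRC", "STR"),
    latitude = c(47.62, 44.80, 47.12, 45.81),
    longitude = c(-87.50, -86.90, -88.55, -84.73)
  )
  if (n_sites <= 4) return(base[seq_len(n_sites), , drop = FALSE])
  extra <- data.frame(
    site = paste0("S", seq_len(n_sites - 4)),
    latitude = 44 + seq_len(n_sites - 4) * 0.7,
    longitude = -89 + seq_len(n_sites - 4) * 0.6
  )
  rbind(base, extra)
}

# canonical placeholder oil encoding used by the generator; the pipeline
# replaces it with trained-codec encodings
canonical_oil_enc <- function(labels) {
  unname(c(no_oil = 0, crude = 1, diesel = 2)[labels])
}

#' Generate a seeded synthetic microcosm cohort
#'
#' Draws a study-shaped cohort: bottles are assigned a site (with jittered
#' coordinates), a collection month, an incubation temperature and an oil
#' condition held constant over the bottle's time series; each sample gets a
#' distinct incubation week in 0-7. Taxa counts are zero-inflated negative
#' binomial around per-taxon log-normal baselines with per-bottle random
#' effects; planted responsive taxa have their means multiplied by
#' `2^(log2fc * ramp(week))` under the matching oil condition.
#'
#' @param config A [cohort_config()].
#' @return A list of class `microstress_cohort` with elements
#'   `samples` (the sample-table tibble), `metadata` (per-sample raw
#'   metadata: site, latitude, longitude, oil label, week, month) and
#'   `truth` (planted ground truth: responsive taxon indices, effect matrix,
#'   per-bottle oil labels, site coordinates).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    rlang::abort("config must be a cohort_config", class = "microstress_config_error")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    sites <- default_sites(cfg$n_sites)

    # bottle-level design: balanced sites and oil conditions, then shuffled.
    # Each site stands for one sampling campaign, so collection month and
    # lab incubation temperature are campaign constants, not per-bottle draws.
    bottle_site <- sample(rep_len(seq_len(cfg$n_sites), cfg$n_bottles))
    bottle_oil <- sample(rep_len(c("no_oil", "crude", "diesel"), cfg$n_bottles))
    site_month <- sample(5:10, cfg$n_sites, replace = cfg$n_sites > 6)
    site_temp <- round(pmin(pmax(stats::rnorm(cfg$n_sites, 18, 5), 4), 28))
    bottle_month <- site_month[bottle_site]
    bottle_temp <- site_temp[bottle_site]
    bottle_lat <- sites$latitude[bottle_site] + stats::rnorm(cfg$n_bottles, 0, 0.02)
    bottle_lon <- sites$longitude[bottle_site] + stats::rnorm(cfg$n_bottles, 0, 0.02)

    n_per <- pmin(1 + stats::rpois(cfg$n_bottles, max(cfg$samples_per_bottle_mean - 1, 0)), 8)
    bottle_idx <- rep(seq_len(cfg$n_bottles), n_per)
    week <- unlist(lapply(n_per, function(k) sort(sample(0:7, k))))
    n <- length(week)

    # per-taxon baselines and per-bottle random effects (log2 scale)
    lambda <- stats::rlnorm(cfg$n_taxa, cfg$baseline_meanlog, cfg$baseline_sdlog)
    bottle_eff <- matrix(stats::rnorm(cfg$n_bottles * cfg$n_taxa, 0, cfg$bottle_effect_sd),
      cfg$n_bottles, cfg$n_taxa
    )

    responsive <- if (cfg$n_responsive > 0) sort(sample.int(cfg$n_taxa, cfg$n_responsive)) else integer(0)

    log2mu <- matrix(log2(lambda), n, cfg$n_taxa, byrow = TRUE) + bottle_eff[bottle_idx, , drop = FALSE]
    if (cfg$n_responsive > 0) {
      ramp <- pmin((week + cfg$ramp_offset) / cfg$ramp_week, 1)
      oil_of_sample <- bottle_oil[bottle_idx]
      for (j in seq_along(responsive)) {
        tj <- responsive[j]
        lfc <- ifelse(oil_of_sample == "crude", cfg$effect_log2fc[j, "crude"],
          ifelse(oil_of_sample == "diesel", cfg$effect_log2fc[j, "diesel"], 0)
        )
        log2mu[, tj] <- log2mu[, tj] + lfc * ramp
      }
    }
    mu <- 2^log2mu

    counts <- draw_zinb_counts(mu, cfg$sparsity, cfg$dispersion, cfg$zi_mean_scale)

    samples <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      bottle_id = sprintf("B%03d", bottle_idx),
      location_enc = round(10 + 15 * (bottle_site[bottle_idx] - 1) +
        (bottle_lat[bottle_idx] - sites$latitude[bottle_site[bottle_idx]]) * 10, 3),
      time_enc = 10 * week,
      oil_enc = canonical_oil_enc(bottle_oil[bottle_idx]),
      temperature = bottle_temp[bottle_idx],
      month_enc = 10 * bottle_month[bottle_idx]
    )
    if (cfg$n_taxa > 0) {
      cnt <- tibble::as_tibble(as.data.frame(counts))
      names(cnt) <- paste0("Bac_", seq_len(cfg$n_taxa))
      samples <- dplyr::bind_cols(samples, cnt)
    }

    metadata <- tibble::tibble(
      sample_id = samples$sample_id,
      bottle_id = samples$bottle_id,
      site = sites$site[bottle_site[bottle_idx]],
      latitude = bottle_lat[bottle_idx],
      longitude = bottle_lon[bottle_idx],
      oil_label = bottle_oil[bottle_idx],
      week = week,
      month = bottle_month[bottle_idx]
    )

    truth <- list(
      responsive_taxa = responsive,
      effect_log2fc = cfg$effect_log2fc,
      bottle_oil = tibble::tibble(
        bottle_id = sprintf("B%03d", seq_len(cfg$n_bottles)),
        oil_label = bottle_oil
      ),
      sites = tibble::as_tibble(sites)
    )

    structure(
      list(samples = validate_sample_table(samples), metadata = metadata, truth = truth, config = cfg),
      class = "microstress_cohort"
    )
  })
}

# zero-inflated negative binomial draw for a matrix of means;
# variance = mu + phi * mu^2, structural zeros with abundance-damped
# probability sparsity * exp(-mu / zi_scale)
draw_zinb_counts <- function(mu, sparsity, dispersion, zi_scale = 10) {
  n <- length(mu)
  mu_v <- as.vector(mu)
  counts <- stats::rnbinom(n, mu = mu_v, size = 1 / dispersion)
  if (sparsity > 0) {
    counts[stats::runif(n) < sparsity * exp(-mu_v / zi_scale)] <- 0L
  }
  matrix(as.integer(counts), nrow(mu), ncol(mu))
}

#' @export
print.microstress_cohort <- function(x, ...) {
  cat(sprintf(
    "<microstress_cohort> %d samples, %d bottles, %d taxa (%d planted responsive), seed %d\n",
    nrow(x$samples), length(unique(x$samples$bottle_id)),
    length(taxa_cols(x$samples)), length(x$truth$responsive_taxa), x$config$seed
  ))
  invisible(x)
}

#' Write the planted ground truth of a synthetic cohort as JSON
#'
#' @param cohort A `microstress_cohort`.
#' @param path Output path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      responsive_taxa = truth$responsive_taxa,
      effect_log2fc = as.data.frame(truth$effect_log2fc),
      bottle_oil = truth$bottle_oil,
      sites = truth$sites
    ),
    path,
    dataframe = "columns", digits = NA
  )
  invisible(path)
}
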