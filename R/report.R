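#' Study configuration
#'
#' @param conditions named list: condition label -> character vector of
#'   device ids.
#' @param panel a prebuilt [network_panel()], or `NULL` when building from
#'   recordings.
#' @param recordings list of [spike_recording()] (used when `panel` is NULL).
#' @param divs declared DIV grid (defaults to those present; missing cells
#'   are allowed).
#' @param threshold,bin_width,min_spikes,burst_window,min_channels,global_window
#'   network-construction parameters (see the ephys functions).
#' @param k maximum communities for the joint fit.
#' @param mcmc an [mcmc_config()].
#' @param priors a [tsbm_priors()].
#' @param min_community_size nodes needed before a community counts as
#'   occupied in a device (default 1).
#' @param out_dir optional directory for CSV/JSON report tables.
#' @param seed master seed for the whole study.
#' @return a `study_config` list.
#' @export
study_config <- function(conditions, panel = NULL, recordings = NULL,
                         divs = NULL, threshold = 0.20, bin_width = 0.010,
                         min_spikes = 4, burst_window = 0.100,
                         min_channels = 4, global_window = 0.250,
                         k = 10, mcmc = mcmc_config(), priors = tsbm_priors(),
                         min_community_size = 1, out_dir = NULL, seed = 1) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  structure(list(conditions = conditions, panel = panel,
                 recordings = recordings, divs = divs, threshold = threshold,
                 bin_width = bin_width, min_spikes = min_spikes,
                 burst_window = burst_window, min_channels = min_channels,
                 global_window = global_window, k = k, mcmc = mcmc,
                 priors = priors, min_community_size = min_community_size,
                 out_dir = out_dir, seed = seed),
            class = "study_config")
}

#' Build a functional network from one spike recording
#'
#' Convenience chain: channel bursts -> global bursts -> burst-windowed
#' cross-correlation -> thresholding.
#'
#' @param rec a [spike_recording()].
#' @param threshold correlation cutoff (default 0.20).
#' @param bin_width correlation bin width in seconds.
#' @param min_spikes,burst_window channel-burst parameters.
#' @param min_channels,global_window global-burst parameters.
#' @return a [functional_network()].
#' @export
build_network <- function(rec, threshold = 0.20, bin_width = 0.010,
                          min_spikes = 4, burst_window = 0.100,
                          min_channels = 4, global_window = 0.250) {
  cb <- detect_channel_bursts(rec, min_spikes, burst_window)
  gb <- detect_global_bursts(cb, min_channels, global_window)
  C <- suppressWarnings(cross_correlation_matrix(rec, gb, bin_width))
  threshold_network(C, threshold)
}

#' Run a full study: networks, one joint fit, per-condition reports
#'
#' One model is fitted jointly over all devices and DIVs of the study (so
#' community labels are shared across conditions); conditions are then
#' distinguished at reporting time. All stages are seeded from the config.
#'
#' @param config a [study_config()].
#' @return a `study_report`: the `fit_summary`, shared `eta_curves` and
#'   per-community `trend_labels`, and per-condition tibbles
#'   `community_counts` (occupied communities per device) and
#'   `density_table` (device x community node counts).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  all_devices <- unique(unlist(config$conditions))
  panel <- config$panel
  if (is.null(panel)) {
    if (is.null(config$recordings)) {
      stop("study needs either a panel or recordings", call. = FALSE)
    }
    nets <- purrr::map(config$recordings, function(rec) {
      build_network(rec, config$threshold, config$bin_width,
                    config$min_spikes, config$burst_window,
                    config$min_channels, config$global_window)
    })
    panel <- network_panel(nets)
  }
  missing_dev <- setdiff(all_devices, panel$devices)
  if (length(missing_dev)) {
    stop("stage build-network: devices missing from inputs: ",
         paste(missing_dev, collapse = ", "), call. = FALSE)
  }
  fit <- fit_tsbm(panel, k = config$k, mcmc = config$mcmc,
                  priors = config$priors)
  summ <- relabel_by_size(fit)
  curves <- posterior_eta(fit)
  k <- fit$k
  trends <- purrr::map_dfr(seq_len(k), function(i) {
    cv <- summ$eta_mean[i, i, ]
    all_pairs_low <- all(summ$eta_mean[i, , ] < 0.05)
    lab <- if (all_pairs_low) "inactive" else classify_community_trend(cv)
    tibble::tibble(community = i, trend = lab)
  })
  cond_reports <- purrr::imap(config$conditions, function(devs, cond) {
    rows <- match(devs, rownames(summ$community_counts))
    counts <- summ$community_counts[rows, , drop = FALSE]
    occupied <- apply(counts, 1, function(x) sum(x >= config$min_community_size))
    list(
      condition = cond,
      community_counts = tibble::tibble(device = devs,
                                        n_communities = as.integer(occupied)),
      density_table = counts
    )
  })
  report <- structure(
    list(summary = summ, eta_curves = curves, trend_labels = trends,
         conditions = cond_reports, panel = panel, config = config),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cc <- purrr::map_dfr(report$conditions, function(cr) {
    dplyr::mutate(cr$community_counts, condition = cr$condition,
                  .before = 1)
  })
  utils::write.csv(cc, file.path(dir, "community_counts.csv"),
                   row.names = FALSE)
  dens <- purrr::map_dfr(report$conditions, function(cr) {
    tb <- tibble::as_tibble(cr$density_table, rownames = "device")
    dplyr::mutate(tb, condition = cr$condition, .before = 1)
  })
  utils::write.csv(dens, file.path(dir, "density_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$eta_curves, file.path(dir, "eta_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(report$trend_labels, file.path(dir, "trend_labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(occupied_k = report$summary$occupied_k,
         community_sizes = report$summary$community_sizes,
         diagnostics = report$summary$fit$diagnostics),
    file.path(dir, "diagnostics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Find the inactive community, if any
#'
#' The community (smallest label first) whose posterior-mean connection
#' probability with every community — including itself — stays below
#' `cutoff` at all DIVs: electrodes that never interact with the rest of
#' the device.
#'
#' @param x a `fit_summary` or `study_report`.
#' @param cutoff probability ceiling (default 0.05).
#' @return the community id, or `NA_integer_` when none qualifies.
#' @export
inactive_community <- function(x, cutoff = 0.05) {
  summ <- if (inherits(x, "study_report")) x$summary else x
  stopifnot(inherits(summ, "fit_summary"))
  em <- summ$eta_mean
  if (length(dim(em)) == 2) em <- array(em, c(dim(em), 1))
  k <- dim(em)[1]
  for (i in seq_len(k)) {
    if (all(em[i, , ] < cutoff)) return(i)
  }
  NA_integer_
}

#' Classify the temporal trend of a connection-probability curve
#'
#' Rule-based quantification of the qualitative vocabulary used for
#' community behaviour. Consecutive duplicate values are collapsed first, so
#' padding a curve with repeated DIV columns does not change its label.
#' Rules (checked in order): *inactive* — all points below
#' `rules$inactive`; *transient* — exactly one point above
#' `rules$transient_hi` and the rest below `rules$transient_lo`;
#' *increasing* — last point exceeds the first by `rules$increase` and the
#' non-decreasing isotonic fit captures at least 90 % of the curve's
#' variance; *persistent* — all points above `rules$persistent`; otherwise
#' *mixed*.
#'
#' @param eta_curve per-DIV posterior means, length >= 3.
#' @param rules named list of thresholds; see [trend_rules()].
#' @return one of `"inactive"`, `"transient"`, `"increasing"`,
#'   `"persistent"`, `"mixed"`.
#' @export
classify_community_trend <- function(eta_curve, rules = trend_rules()) {
  if (length(eta_curve) < 3) stop("curve must span at least 3 DIVs", call. = FALSE)
  v <- eta_curve[c(TRUE, diff(eta_curve) != 0)]  # collapse duplicate runs
  if (all(v < rules$inactive)) return("inactive")
  if (sum(v > rules$transient_hi) == 1 &&
      all(v[v <= rules$transient_hi] < rules$transient_lo)) {
    return("transient")
  }
  if (length(v) >= 2 && v[length(v)] > v[1] + rules$increase) {
    tot <- sum((v - mean(v))^2)
    iso <- isoreg(seq_along(v), v)
    res <- sum((v - iso$yf)^2)
    if (tot > 0 && res / tot <= 0.10) return("increasing")
  }
  if (all(v > rules$persistent)) return("persistent")
  "mixed"
}

#' Default trend-classification thresholds
#'
#' @param inactive,transient_hi,transient_lo,increase,persistent probability
#'   thresholds used by [classify_community_trend()].
#' @return a named list.
#' @export
trend_rules <- function(inactive = 0.05, transient_hi = 0.5,
                        transient_lo = 0.2, increase = 0.3,
                        persistent = 0.5) {
  list(inactive = inactive, transient_hi = transient_hi,
       transient_lo = transient_lo, increase = increase,
       persistent = persistent)
}

#' Mean firing rate versus node degree
#'
#' Pairs each electrode's mean firing rate with its degree in the matching
#' functional network and reports the Spearman rank correlation with an
#' approximate 95 % confidence interval (Fisher transform with the
#' Bonett-Wright standard error). When all degrees (or rates) are tied the
#' correlation is undefined and reported as `NA`.
#'
#' @param recs list of [spike_recording()].
#' @param panel a [network_panel()] with matching (device, div) cells.
#' @return a list with `data` (tibble: device, div, channel, rate_hz,
#'   degree), `rho`, `conf_low`, `conf_high`, `p_value`, `n`.
#' @export
firing_rate_vs_degree <- function(recs, panel) {
  if (inherits(recs, "spike_recording")) recs <- list(recs)
  tab <- purrr::map_dfr(recs, function(rec) {
    nw <- panel_get(panel, rec$device_id, rec$div)
    if (is.null(nw)) {
      stop("no network for device ", rec$device_id, " DIV ", rec$div,
           call. = FALSE)
    }
    if (!identical(nw$channels, rec$channels)) {
      stop("recording and network channel sets differ", call. = FALSE)
    }
    fr <- mean_firing_rate(rec)
    tibble::tibble(device = rec$device_id, div = rec$div,
                   channel = fr$channel, rate_hz = fr$rate_hz,
                   degree = as.numeric(colSums(nw$adjacency)))
  })
  n <- nrow(tab)
  if (sd(tab$degree) == 0 || sd(tab$rate_hz) == 0 || n < 4) {
    return(list(data = tab, rho = NA_real_, conf_low = NA_real_,
                conf_high = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(tab$rate_hz, tab$degree,
                                  method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  list(data = tab, rho = rho,
       conf_low = tanh(z - 1.96 * se), conf_high = tanh(z + 1.96 * se),
       p_value = ct$p.value, n = n)
}
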