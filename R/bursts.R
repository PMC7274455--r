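#' Detect channel bursts
#'
#' A channel burst is a run of at least `min_spikes` spikes on one electrode
#' in which some sliding window of `window` seconds contains `min_spikes` or
#' more spikes; overlapping qualifying windows are merged into one burst whose
#' extent runs from its first to its last member spike.
#'
#' @param rec a [spike_recording()].
#' @param min_spikes minimum spikes per qualifying window (default 4).
#' @param window window length in seconds (default 0.100).
#' @return a tibble with columns `channel`, `t_start`, `t_end`, `n_spikes`;
#'   bursts are disjoint and ordered within a channel.
#' @export
detect_channel_bursts <- function(rec, min_spikes = 4, window = 0.100) {
  stopifnot(inherits(rec, "spike_recording"))
  check_number(min_spikes, "min_spikes", lower = 2)
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  sp <- spike_list(rec)
  out <- purrr::imap(sp, function(ts, ch) {
    b <- burst_spans(ts, min_spikes, window)
    if (!nrow(b)) return(NULL)
    tibble::tibble(channel = ch,
                   t_start = ts[b$i], t_end = ts[b$j],
                   n_spikes = b$j - b$i + 1L)
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(channel = character(), t_start = numeric(),
                          t_end = numeric(), n_spikes = integer())
  }
  res
}

# Maximal merged spans of spike indices [i, j] such that some window of
# `window` seconds within the span holds >= min_spikes spikes. For each spike
# i the furthest spike j with ts[j] <= ts[i] + window is found; qualifying
# index intervals are merged when they overlap.
burst_spans <- function(ts, min_spikes, window) {
  n <- length(ts)
  if (n < min_spikes) return(data.frame(i = integer(), j = integer()))
  j <- findInterval(ts + window, ts)          # last index with ts[j] <= ts[i] + window
  qual <- which(j - seq_len(n) + 1L >= min_spikes)
  if (!length(qual)) return(data.frame(i = integer(), j = integer()))
  starts <- qual
  ends <- j[qual]
  # merge overlapping/adjacent index intervals
  mi <- starts[1]; mj <- ends[1]
  out_i <- integer(); out_j <- integer()
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= mj) {  # spans share at least one spike
      mj <- max(mj, ends[k])
    } else {
      out_i <- c(out_i, mi); out_j <- c(out_j, mj)
      mi <- starts[k]; mj <- ends[k]
    }
  }
  out_i <- c(out_i, mi); out_j <- c(out_j, mj)
  data.frame(i = out_i, j = out_j)
}

#' Detect global bursts
#'
#' A global burst is an epoch in which channel bursts start on at least
#' `min_channels` distinct electrodes within `window` seconds of the earliest
#' (anchor) start. Starts are scanned in ascending order; each maximal
#' qualifying group forms one global burst and each channel burst joins at
#' most one global burst.
#'
#' @param bursts a channel-burst tibble from [detect_channel_bursts()].
#' @param min_channels minimum distinct channels (default 4).
#' @param window anchor window in seconds (default 0.250).
#' @return a tibble with columns `t_start`, `t_end`, `n_channels`,
#'   `n_bursts`, and a list-column `members` of the member channel bursts.
#' @export
detect_global_bursts <- function(bursts, min_channels = 4, window = 0.250) {
  check_number(min_channels, "min_channels", lower = 2)
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          n_channels = integer(), n_bursts = integer(),
                          members = list())
  if (!nrow(bursts)) return(empty)
  b <- dplyr::arrange(bursts, .data$t_start, .data$channel)
  n <- nrow(b)
  assigned <- rep(FALSE, n)
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (assigned[i]) { i <- i + 1L; next }
    grp <- which(!assigned & b$t_start >= b$t_start[i] &
                   b$t_start <= b$t_start[i] + window)
    grp <- grp[grp >= i]
    if (length(unique(b$channel[grp])) >= min_channels) {
      assigned[grp] <- TRUE
      mem <- b[grp, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        t_start = min(mem$t_start), t_end = max(mem$t_end),
        n_channels = length(unique(mem$channel)),
        n_bursts = nrow(mem), members = list(mem)
      )
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}
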