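# Independent brute-force oracles for burst detection, used by the property
# suites. These re-derive the definitions with different mechanics (explicit
# window enumeration + transitive interval union) than the package code.

# all maximal merged spans of spikes where some `window`-second window holds
# >= min_spikes spikes; merging is the transitive union of overlapping
# qualifying index intervals
oracle_channel_bursts <- function(ts, min_spikes = 4, window = 0.100) {
  n <- length(ts)
  ivs <- list()
  for (i in seq_len(n)) {
    members <- which(ts >= ts[i] & ts <= ts[i] + window)
    if (length(members) >= min_spikes) {
      ivs[[length(ivs) + 1L]] <- c(min(members), max(members))
    }
  }
  if (!length(ivs)) {
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      n_spikes = integer()))
  }
  # transitive union of intervals sharing at least one index
  iv <- do.call(rbind, ivs)
  alive <- rep(TRUE, nrow(iv))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (a in seq_len(nrow(iv))) {
      if (!alive[a]) next
      for (b in seq_len(nrow(iv))) {
        if (a == b || !alive[b]) next
        if (iv[a, 1] <= iv[b, 2] && iv[b, 1] <= iv[a, 2]) {
          iv[a, ] <- c(min(iv[a, 1], iv[b, 1]), max(iv[a, 2], iv[b, 2]))
          alive[b] <- FALSE
          changed <- TRUE
        }
      }
    }
  }
  iv <- iv[alive, , drop = FALSE]
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  ivs <- lapply(seq_len(nrow(iv)), function(r) iv[r, ])
  data.frame(
    t_start = vapply(ivs, function(iv) ts[iv[1]], 1),
    t_end = vapply(ivs, function(iv) ts[iv[2]], 1),
    n_spikes = vapply(ivs, function(iv) iv[2] - iv[1] + 1L, 1L)
  )
}

# literal re-derivation of anchored global-burst grouping on a start table
oracle_global_bursts <- function(bursts, min_channels = 4, window = 0.250) {
  b <- bursts[order(bursts$t_start, bursts$channel), ]
  taken <- rep(FALSE, nrow(b))
  out <- data.frame(t_start = numeric(), t_end = numeric(),
                    n_channels = integer())
  repeat {
    anchor <- NA
    for (i in seq_len(nrow(b))) {
      if (!taken[i]) { anchor <- i; break }
    }
    if (is.na(anchor)) break
    grp <- integer()
    for (i in anchor:nrow(b)) {
      if (!taken[i] && b$t_start[i] <= b$t_start[anchor] + window) {
        grp <- c(grp, i)
      }
    }
    if (length(unique(b$channel[grp])) >= min_channels) {
      taken[grp] <- TRUE
      out <- rbind(out, data.frame(t_start = min(b$t_start[grp]),
                                   t_end = max(b$t_end[grp]),
                                   n_channels = length(unique(b$channel[grp]))))
    } else {
      # a failed anchor can never join a later group (later windows start
      # at or after it and scan forward only), so it is spent
      taken[anchor] <- TRUE
    }
  }
  out
}

# quick construction of a spike recording from a named list of spike vectors
make_recording <- function(spikes, duration = 10, device = "devA", div = 14L,
                           channels = names(spikes)) {
  tab <- purrr::imap_dfr(spikes, function(ts, ch) {
    tibble::tibble(channel = ch, time_s = ts)
  })
  if (nrow(tab) == 0) tab <- tibble::tibble(channel = character(), time_s = numeric())
  spike_recording(tab, device_id = device, div = div, duration = duration,
                  channels = channels)
}
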