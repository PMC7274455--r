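#' Construct a spike recording
#'
#' A spike recording holds per-channel spike timestamps for one MEA device at
#' one day in vitro (DIV). Channels with no spikes are kept so that silent
#' electrodes remain nodes of the functional network.
#'
#' @param spikes a data frame with columns `channel` and `time_s` (seconds).
#' @param device_id device label.
#' @param div integer day in vitro.
#' @param duration recording length in seconds, > 0.
#' @param channels ordered channel ids; defaults to the sorted unique channels
#'   present in `spikes`.
#' @return a `spike_recording` object.
#' @export
spike_recording <- function(spikes, device_id, div, duration, channels = NULL) {
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("channel", "time_s") %in% names(spikes)))
  spikes$channel <- as.character(spikes$channel)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  if (is.null(channels)) channels <- sort(unique(spikes$channel))
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("duplicate channel ids", call. = FALSE)

  bad <- which(spikes$time_s < 0 | spikes$time_s > duration)
  if (length(bad)) {
    stop(sprintf("timestamp out of [0, duration] at row %d (t = %g s)",
                 bad[1], spikes$time_s[bad[1]]), call. = FALSE)
  }
  unknown <- setdiff(unique(spikes$channel), channels)
  if (length(unknown)) {
    stop("spike rows reference channels not in the channel list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # strict within-channel ordering, checked in file/row order
  ord_bad <- spikes |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$channel) |>
    dplyr::filter(dplyr::row_number() > 1 & diff(c(-Inf, .data$time_s)) <= 0) |>
    dplyr::ungroup()
  if (nrow(ord_bad)) {
    stop(sprintf("timestamps not strictly increasing within channel %s at row %d",
                 ord_bad$channel[1], ord_bad$.row[1]), call. = FALSE)
  }

  structure(
    list(device_id = as.character(device_id), div = as.integer(div),
         duration = duration, channels = channels, spikes = spikes),
    class = "spike_recording"
  )
}

#' @export
print.spike_recording <- function(x, ...) {
  cat(sprintf("<spike_recording> device %s, DIV %d: %d channels, %d spikes over %g s\n",
              x$device_id, x$div, length(x$channels), nrow(x$spikes), x$duration))
  invisible(x)
}

#' Read a spike recording from delimited text
#'
#' Expects a TSV/CSV with columns `channel` and `time_s`, plus a JSON sidecar
#' (same path with extension `.json`) giving `device`, `div`, `duration_s` and
#' the full channel list, so silent channels are retained.
#'
#' @param path path to the delimited spike table.
#' @param header optional list overriding the sidecar
#'   (`device`, `div`, `duration_s`, `channels`).
#' @return a [spike_recording()].
#' @export
read_spikes <- function(path, header = NULL) {
  if (is.null(header)) {
    side <- paste0(tools::file_path_sans_ext(path), ".json")
    if (!file.exists(side)) {
      stop("no sidecar header found at ", side, call. = FALSE)
    }
    header <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("channel", "time_s") %in% names(tab))) {
    stop("spike table must have columns `channel` and `time_s`", call. = FALSE)
  }
  spike_recording(tab,
                  device_id = header$device, div = header$div,
                  duration = header$duration_s,
                  channels = header$channels)
}

#' Write a spike recording as delimited text plus JSON sidecar
#'
#' @param rec a [spike_recording()].
#' @param path output path for the spike table (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_spikes <- function(rec, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(rec$spikes[, c("channel", "time_s")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(device = rec$device_id, div = rec$div, duration_s = rec$duration,
         channels = rec$channels),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Mean firing rate per channel
#'
#' @param rec a [spike_recording()].
#' @return a tibble with columns `channel`, `n_spikes`, `rate_hz`
#'   (count / duration), one row per channel in recording order.
#' @export
mean_firing_rate <- function(rec) {
  stopifnot(inherits(rec, "spike_recording"))
  counts <- table(factor(rec$spikes$channel, levels = rec$channels))
  tibble::tibble(
    channel = rec$channels,
    n_spikes = as.integer(counts),
    rate_hz = as.numeric(counts) / rec$duration
  )
}

# per-channel list of sorted spike times, in channel order
spike_list <- function(rec) {
  sp <- split(rec$spikes$time_s, factor(rec$spikes$channel, levels = rec$channels))
  lapply(sp, as.numeric)
}
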