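#' Burst-windowed cross-correlation matrix
#'
#' Within each global burst, each channel's spikes are binned at `bin_width`
#' and the zero-lag Pearson correlation is computed for every channel pair
#' whose binned vectors both have nonzero variance. The matrix entry is the
#' mean over the global bursts where the pair was defined; pairs never
#' defined (e.g. involving electrodes silent during all bursts) are 0, so
#' downstream graphs are always well-formed.
#'
#' @param rec a [spike_recording()].
#' @param gbursts global bursts from [detect_global_bursts()].
#' @param bin_width bin size in seconds (default 0.010).
#' @return a `correlation_matrix` object: symmetric `values` in \[-1, 1\]
#'   (diagonal 1 for channels active within some burst, 0 otherwise) plus the
#'   channel ordering.
#' @export
cross_correlation_matrix <- function(rec, gbursts, bin_width = 0.010) {
  stopifnot(inherits(rec, "spike_recording"))
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  n <- length(rec$channels)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  active <- rep(FALSE, n)
  if (!nrow(gbursts)) {
    warning("no global bursts; returning an all-zero correlation matrix")
  } else {
    sp <- spike_list(rec)
    for (g in seq_len(nrow(gbursts))) {
      t0 <- gbursts$t_start[g]; t1 <- gbursts$t_end[g]
      nb <- max(1L, ceiling((t1 - t0) / bin_width))
      breaks <- t0 + bin_width * seq.int(0L, nb)
      counts <- vapply(sp, function(ts) {
        ts <- ts[ts >= t0 & ts <= t1]
        if (!length(ts)) return(integer(nb))
        idx <- pmin(nb, findInterval(ts, breaks, left.open = FALSE))
        tabulate(idx, nbins = nb)
      }, integer(nb))
      if (nb < 2L) next  # a single bin carries no variance
      ok <- apply(counts, 2L, function(x) stats::var(x) > 0)
      active <- active | ok
      if (sum(ok) < 2L) next
      r <- stats::cor(counts[, ok, drop = FALSE])
      acc[ok, ok] <- acc[ok, ok] + r
      cnt[ok, ok] <- cnt[ok, ok] + 1L
    }
  }
  vals <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), 0)
  diag(vals) <- as.numeric(active)
  dimnames(vals) <- list(rec$channels, rec$channels)
  structure(list(values = vals, channels = rec$channels,
                 device_id = rec$device_id, div = rec$div),
            class = "correlation_matrix")
}

#' Threshold a correlation matrix into a binary functional network
#'
#' An edge joins two electrodes when their cross-correlation is strictly
#' above the threshold; equality at the threshold yields no edge.
#'
#' @param C a `correlation_matrix`.
#' @param threshold correlation cutoff in \[-1, 1\] (default 0.20).
#' @return a `functional_network`: symmetric hollow binary `adjacency` plus
#'   channel ordering and device/DIV labels.
#' @export
threshold_network <- function(C, threshold = 0.20) {
  stopifnot(inherits(C, "correlation_matrix"))
  check_number(threshold, "threshold", lower = -1, upper = 1)
  adj <- (C$values > threshold) * 1L
  diag(adj) <- 0L
  adj <- pmax(adj, t(adj))  # values are symmetric; keep the contract explicit
  functional_network(adj, channels = C$channels,
                     device_id = C$device_id, div = C$div)
}

#' Construct a functional network
#'
#' @param adjacency symmetric hollow binary matrix.
#' @param channels node (channel) ids in matrix order.
#' @param device_id,div provenance labels.
#' @return a `functional_network` object.
#' @export
functional_network <- function(adjacency, channels = NULL,
                               device_id = NA_character_, div = NA_integer_) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square", call. = FALSE)
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal", call. = FALSE)
  if (is.null(channels)) channels <- as.character(seq_len(n))
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(channels, channels)
  structure(list(adjacency = adjacency, channels = as.character(channels),
                 device_id = as.character(device_id), div = as.integer(div)),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> device %s, DIV %s: %d nodes, %d edges\n",
              x$device_id, x$div, nrow(x$adjacency), sum(x$adjacency) / 2))
  invisible(x)
}

#' Average degree across a grid of correlation thresholds
#'
#' @param C a `correlation_matrix`.
#' @param thresholds ascending vector of thresholds.
#' @return a tibble with columns `threshold`, `avg_degree`, `n_edges`;
#'   `avg_degree` is non-increasing in `threshold`.
#' @export
threshold_sweep <- function(C, thresholds) {
  stopifnot(inherits(C, "correlation_matrix"))
  if (is.unsorted(thresholds)) stop("thresholds must be ascending", call. = FALSE)
  purrr::map_dfr(thresholds, function(th) {
    net <- threshold_network(C, th)
    deg <- colSums(net$adjacency)
    tibble::tibble(threshold = th, avg_degree = mean(deg),
                   n_edges = sum(net$adjacency) / 2L)
  })
}
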