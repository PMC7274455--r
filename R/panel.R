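#' Bundle functional networks into a device-by-DIV panel
#'
#' A panel holds the binary functional networks of several devices recorded
#' over a common DIV grid and a common node (channel) set. Cells may be
#' missing (a device not recorded at some DIV); model likelihoods simply
#' omit missing networks.
#'
#' @param networks list of [functional_network()] objects carrying their
#'   `device_id` and `div`.
#' @return a `network_panel` with elements `networks` (keyed
#'   `"device@div"`), `devices`, `divs` (strictly increasing), `channels`,
#'   `n`, and an index tibble `cells`.
#' @export
network_panel <- function(networks) {
  stopifnot(length(networks) > 0,
            all(vapply(networks, inherits, TRUE, "functional_network")))
  ch <- networks[[1]]$channels
  for (nw in networks) {
    if (!identical(nw$channels, ch)) {
      stop("all networks in a panel must share an identical channel ordering",
           call. = FALSE)
    }
  }
  cells <- purrr::map_dfr(networks, function(nw) {
    tibble::tibble(device = nw$device_id, div = nw$div)
  })
  if (anyDuplicated(cells)) stop("duplicate (device, div) cell", call. = FALSE)
  devices <- unique(cells$device)
  divs <- sort(unique(cells$div))
  names(networks) <- paste0(cells$device, "@", cells$div)
  structure(list(networks = networks, devices = devices, divs = divs,
                 channels = ch, n = length(ch), cells = cells),
            class = "network_panel")
}

#' @export
print.network_panel <- function(x, ...) {
  cat(sprintf("<network_panel> %d devices x %d DIVs (%d networks), %d nodes\n",
              length(x$devices), length(x$divs), length(x$networks), x$n))
  invisible(x)
}

panel_get <- function(panel, device, div) {
  panel$networks[[paste0(device, "@", div)]]
}

#' Edge densities of every network in a panel
#'
#' @param panel a [network_panel()].
#' @return a tibble with one row per (device, div): `n_edges`, `density`.
#' @export
panel_densities <- function(panel) {
  purrr::map_dfr(panel$networks, function(nw) {
    n <- nrow(nw$adjacency)
    tibble::tibble(device = nw$device_id, div = nw$div,
                   n_edges = sum(nw$adjacency) / 2L,
                   density = sum(nw$adjacency) / (n * (n - 1)))
  })
}

#' Write a panel as delimited adjacency matrices plus a JSON manifest
#'
#' Each network goes to `<device>_div<div>.tsv` (0/1 matrix with a channel-id
#' header row); `manifest.json` lists devices, DIVs, channels and file paths.
#'
#' @param panel a [network_panel()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::map_chr(panel$networks, function(nw) {
    f <- sprintf("%s_div%d.tsv", gsub("[^A-Za-z0-9_.-]", "_", nw$device_id), nw$div)
    utils::write.table(nw$adjacency, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    f
  })
  manifest <- list(
    devices = panel$devices, divs = panel$divs, channels = panel$channels,
    cells = purrr::pmap(list(panel$cells$device, panel$cells$div, unname(files)),
                        function(d, t, f) list(device = d, div = t, file = f))
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a panel written by [write_panel()]
#'
#' @param dir directory containing `manifest.json` and the adjacency files.
#' @return a [network_panel()].
#' @export
read_panel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  channels <- as.character(manifest$channels)
  nets <- purrr::pmap(manifest$cells, function(device, div, file) {
    m <- as.matrix(utils::read.delim(file.path(dir, file), check.names = FALSE))
    functional_network(m, channels = channels, device_id = device, div = div)
  })
  network_panel(nets)
}

# panel as an n x n x T x D array (NA where a cell is missing), plus masks
panel_array <- function(panel) {
  n <- panel$n; Tt <- length(panel$divs); D <- length(panel$devices)
  A <- array(NA_integer_, c(n, n, Tt, D),
             dimnames = list(NULL, NULL, panel$divs, panel$devices))
  for (nw in panel$networks) {
    ti <- match(nw$div, panel$divs); di <- match(nw$device_id, panel$devices)
    A[, , ti, di] <- nw$adjacency
  }
  A
}
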