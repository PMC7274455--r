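#' Full parameter set of the temporal stochastic block model
#'
#' Holds the maximum community count `k`, Dirichlet weights `alpha`, the
#' community proportions `pi`, per-device community assignments `z` (devices
#' in rows), the within- and between-community kernels, the symmetric offset
#' table `beta`, the latent values `X` on the DIV grid and the implied
#' connection probabilities `eta = plogis(beta + X)`.
#'
#' @param k maximum number of communities.
#' @param alpha positive Dirichlet weights, length `k`.
#' @param pi simplex vector of community proportions.
#' @param z integer matrix devices x nodes with entries in `1..k`.
#' @param kernel_in,kernel_out [kernel_params()] for within-/between-community
#'   latent processes.
#' @param beta symmetric `k x k` offset matrix (logit scale).
#' @param divs strictly increasing DIV grid.
#' @param X `k x k x T` latent values, symmetric in its first two dimensions.
#' @return a `tsbm_params` object.
#' @export
tsbm_params <- function(k, alpha, pi, z, kernel_in, kernel_out, beta, divs, X) {
  stopifnot(length(alpha) == k, all(alpha > 0),
            length(pi) == k, abs(sum(pi) - 1) < 1e-8,
            is.matrix(z), all(z >= 1), all(z <= k),
            is.matrix(beta), nrow(beta) == k, ncol(beta) == k,
            max(abs(beta - t(beta))) < 1e-12,
            length(dim(X)) == 3, dim(X)[1] == k, dim(X)[2] == k,
            dim(X)[3] == length(divs), !is.unsorted(divs, strictly = TRUE))
  eta <- X
  for (tt in seq_along(divs)) eta[, , tt] <- plogis(beta + X[, , tt])
  structure(list(k = k, alpha = alpha, pi = pi, z = z,
                 kernel_in = as_kernel_params(kernel_in),
                 kernel_out = as_kernel_params(kernel_out),
                 beta = beta, divs = divs, X = X, eta = eta),
            class = "tsbm_params")
}

#' Simulate a network panel from the temporal stochastic block model
#'
#' Draws community proportions from `Dirichlet(alpha)` and per-device
#' assignments from them (or accepts a fixed `z`), samples one latent
#' Gaussian-process path per community pair (within-community pairs use
#' `kernel_in`, between-community pairs `kernel_out`) via the Cholesky factor
#' of the kernel Gram matrix, applies the logistic link with the offsets
#' `beta`, and emits independent symmetric Bernoulli adjacencies per device
#' and DIV.
#'
#' @param n_nodes nodes (electrodes) per device.
#' @param n_devices number of devices.
#' @param divs DIV grid.
#' @param k maximum communities (default 2).
#' @param alpha Dirichlet weights (default flat).
#' @param kernel_in,kernel_out [kernel_params()].
#' @param beta optional fixed symmetric offset table; when `NULL` each upper
#'   triangle entry is drawn standard normal and mirrored.
#' @param z optional fixed assignment: a length-`n_nodes` vector (shared by
#'   all devices) or a devices x nodes matrix.
#' @param seed integer seed; the draw is fully reproducible from it.
#' @param device_ids,channels optional labels.
#' @return a `synthetic_truth` list with elements `params`
#'   ([tsbm_params()]), `panel` ([network_panel()]) and `seed`.
#' @examples
#' truth <- sample_tsbm(n_nodes = 12, n_devices = 2, divs = c(7, 10, 14),
#'                      kernel_in = kernel_params(0.25, 3, 0.01),
#'                      kernel_out = kernel_params(0.25, 3, 0.01),
#'                      seed = 1)
#' @export
sample_tsbm <- function(n_nodes, n_devices, divs, k = 2,
                        alpha = rep(1, k),
                        kernel_in = kernel_params(0.25, 3, 0.01),
                        kernel_out = kernel_params(0.25, 3, 0.01),
                        beta = NULL, z = NULL, seed = NULL,
                        device_ids = paste0("dev", seq_len(n_devices)),
                        channels = as.character(seq_len(n_nodes))) {
  if (!is.null(seed)) set.seed(seed)
  if (length(divs) < 1) stop("divs must be non-empty", call. = FALSE)
  Tt <- length(divs)
  if (is.null(z)) {
    pi <- rdirichlet1(alpha)
    z <- matrix(sample.int(k, n_devices * n_nodes, replace = TRUE, prob = pi),
                nrow = n_devices)
  } else {
    if (is.vector(z)) z <- matrix(rep(as.integer(z), each = 1),
                                  nrow = n_devices, ncol = n_nodes, byrow = TRUE)
    if (ncol(z) != n_nodes || nrow(z) != n_devices) {
      stop("z must be n_devices x n_nodes", call. = FALSE)
    }
    pi <- as.numeric(table(factor(z, levels = 1:k))) / length(z)
  }
  if (is.null(beta)) {
    beta <- matrix(0, k, k)
    beta[upper.tri(beta, diag = TRUE)] <- rnorm(k * (k + 1) / 2)
    beta <- symmetrize_upper(beta)
  } else {
    beta <- as.matrix(beta)
    if (max(abs(beta - t(beta))) > 1e-12) stop("beta must be symmetric", call. = FALSE)
  }
  L_in <- se_chol(divs, kernel_in)
  L_out <- se_chol(divs, kernel_out)
  X <- array(0, c(k, k, Tt))
  for (i in 1:k) for (j in i:k) {
    L <- if (i == j) L_in else L_out
    x <- as.numeric(L %*% rnorm(Tt))
    X[i, j, ] <- x
    X[j, i, ] <- x
  }
  params <- tsbm_params(k, alpha, pi, z, kernel_in, kernel_out, beta, divs, X)
  nets <- list()
  for (d in seq_len(n_devices)) for (tt in seq_len(Tt)) {
    P <- params$eta[z[d, ], z[d, ], tt]
    adj <- matrix(0L, n_nodes, n_nodes)
    up <- upper.tri(adj)
    adj[up] <- as.integer(runif(sum(up)) < P[up])
    adj <- adj + t(adj)
    nets[[length(nets) + 1L]] <- functional_network(
      adj, channels = channels, device_id = device_ids[d], div = divs[tt])
  }
  structure(list(params = params, panel = network_panel(nets), seed = seed),
            class = "synthetic_truth")
}

#' The synthetic validation scenario
#'
#' Four devices of 20 nodes with two fixed communities of 10 nodes each, on
#' the DIV grid 11, 14, 18, 21, 25, 28, 31; both kernels use sigma = 0.25,
#' ell = 3, eps = 0.01 and the offsets are beta_11 = 0.5, beta_12 = -2,
#' beta_22 = 0.7, giving modular networks with many within-community and few
#' between-community edges.
#'
#' @param seed integer seed.
#' @return a `synthetic_truth` (see [sample_tsbm()]).
#' @export
validation_scenario <- function(seed = 1) {
  kp <- kernel_params(sigma = 0.25, ell = 3, eps = 0.01)
  beta <- matrix(c(0.5, -2, -2, 0.7), 2, 2)
  sample_tsbm(n_nodes = 20, n_devices = 4,
              divs = c(11, 14, 18, 21, 25, 28, 31),
              k = 2, kernel_in = kp, kernel_out = kp,
              beta = beta, z = rep(1:2, each = 10), seed = seed)
}

#' Parameters of the static multi-device stochastic block model
#'
#' @param k,alpha,pi,z as in [tsbm_params()].
#' @param a,b Beta prior shapes for the edge probabilities.
#' @param eta symmetric `k x k` matrix of edge probabilities in (0, 1).
#' @return a `static_sbm_params` object.
#' @export
static_sbm_params <- function(k, alpha, pi, z, a, b, eta) {
  stopifnot(a > 0, b > 0, is.matrix(eta), nrow(eta) == k,
            max(abs(eta - t(eta))) < 1e-12, all(eta > 0), all(eta < 1))
  structure(list(k = k, alpha = alpha, pi = pi, z = z, a = a, b = b, eta = eta),
            class = "static_sbm_params")
}

#' Simulate networks from the static multi-device stochastic block model
#'
#' One edge-probability table `eta ~ Beta(a, b)` is shared across devices;
#' each node picks its community independently per device.
#'
#' @inheritParams sample_tsbm
#' @param a,b Beta shapes (default 1, 1).
#' @param eta optional fixed symmetric edge-probability table.
#' @return a list with `params` ([static_sbm_params()]) and `networks`
#'   (list of [functional_network()], one per device).
#' @export
sample_static_sbm <- function(n_nodes, n_devices, k = 2, alpha = rep(1, k),
                              a = 1, b = 1, eta = NULL, z = NULL, seed = NULL,
                              device_ids = paste0("dev", seq_len(n_devices)),
                              channels = as.character(seq_len(n_nodes))) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(a > 0, b > 0)
  if (is.null(z)) {
    pi <- rdirichlet1(alpha)
    z <- matrix(sample.int(k, n_devices * n_nodes, replace = TRUE, prob = pi),
                nrow = n_devices)
  } else {
    if (is.vector(z)) z <- matrix(as.integer(z), nrow = n_devices,
                                  ncol = n_nodes, byrow = TRUE)
    pi <- as.numeric(table(factor(z, levels = 1:k))) / length(z)
  }
  if (is.null(eta)) {
    eta <- matrix(0, k, k)
    eta[upper.tri(eta, diag = TRUE)] <- rbeta(k * (k + 1) / 2, a, b)
    eta <- symmetrize_upper(eta)
  }
  nets <- purrr::map(seq_len(n_devices), function(d) {
    P <- eta[z[d, ], z[d, ]]
    adj <- matrix(0L, n_nodes, n_nodes)
    up <- upper.tri(adj)
    adj[up] <- as.integer(runif(sum(up)) < P[up])
    functional_network(adj + t(adj), channels = channels,
                       device_id = device_ids[d], div = d)
  })
  eta_chk <- pmin(pmax(eta, 1e-12), 1 - 1e-12)
  list(params = static_sbm_params(k, alpha, pi, z, a, b, eta_chk),
       networks = nets)
}

#' Log-likelihood of a panel under fixed model parameters
#'
#' Sums, over devices, DIVs and unordered node pairs, the log Bernoulli mass
#' of each adjacency entry given `eta[z_u, z_v](t)`.
#'
#' @param panel a [network_panel()].
#' @param params a [tsbm_params()] whose `divs` cover the panel's.
#' @return a single finite number (for `eta` strictly inside (0, 1)).
#' @export
log_likelihood <- function(panel, params) {
  stopifnot(inherits(panel, "network_panel"), inherits(params, "tsbm_params"))
  if (!all(panel$divs %in% params$divs)) {
    stop("params do not cover the panel's DIV grid", call. = FALSE)
  }
  ll <- 0
  for (nw in panel$networks) {
    d <- match(nw$device_id, panel$devices)
    tt <- match(nw$div, params$divs)
    zd <- params$z[d, ]
    if (length(zd) != nrow(nw$adjacency)) stop("dimension mismatch", call. = FALSE)
    Q <- qlogis(params$eta[zd, zd, tt])
    up <- upper.tri(Q)
    ll <- ll + sum(log_bern_logit(Q[up], nw$adjacency[up]))
  }
  ll
}
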