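#' Fit the static multi-device stochastic block model by MCMC
#'
#' Time-free baseline: a single symmetric edge-probability table `eta` with
#' conjugate `Beta(a, b)` updates is shared across all networks, while each
#' device keeps its own community assignment (shared across its DIVs when a
#' panel is supplied). Community labels are updated by exact categorical
#' Gibbs sweeps and the proportions by a conjugate Dirichlet draw.
#'
#' @param networks a [network_panel()] or a list of [functional_network()]
#'   (one assignment row per network in the latter case).
#' @param k maximum number of communities (>= 2).
#' @param mcmc an [mcmc_config()].
#' @param a,b Beta prior shapes for the edge probabilities (default 1, 1).
#' @param alpha Dirichlet weight per community.
#' @return a `static_sbm_fit` object with draws of `z`, `eta`, `pi`.
#' @export
fit_static_sbm <- function(networks, k, mcmc = mcmc_config(), a = 1, b = 1,
                           alpha = 1) {
  stopifnot(k >= 1, a > 0, b > 0)
  if (inherits(networks, "functional_network")) networks <- list(networks)
  panel <- if (inherits(networks, "network_panel")) {
    networks
  } else {
    # give each network its own assignment row
    nets <- purrr::imap(networks, function(nw, i) {
      functional_network(nw$adjacency, nw$channels,
                         device_id = paste0(nw$device_id, "#", i),
                         div = nw$div %||% 1L)
    })
    network_panel(nets)
  }
  A <- panel_array(panel)
  n <- dim(A)[1]; Tt <- dim(A)[3]; D <- dim(A)[4]
  obs <- !apply(A, c(3, 4), function(x) anyNA(x))
  A[is.na(A)] <- 0L
  pairs <- pair_index(k); P <- nrow(pairs)

  keep_total <- mcmc$n_samples %/% mcmc$thin
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 1000L * (ch - 1L))
    Z <- informed_init_z(A, obs, k)
    log_pi <- rep(log(1 / k), k)
    eta <- matrix(0.5, k, k)
    draws <- list(
      z = array(NA_integer_, c(keep_total, D, n)),
      eta = array(NA_real_, c(keep_total, k, k)),
      pi = matrix(NA_real_, keep_total, k),
      loglik = numeric(keep_total)
    )
    kept <- 0L
    for (it in seq_len(mcmc$n_warmup + mcmc$n_samples)) {
      Q <- qlogis(eta)
      logeta <- array(plogis(Q, log.p = TRUE), c(k, k, Tt))
      lognot <- array(plogis(-Q, log.p = TRUE), c(k, k, Tt))
      for (tt in seq_len(Tt)[-1]) {
        logeta[, , tt] <- logeta[, , 1]; lognot[, , tt] <- lognot[, , 1]
      }
      Z <- gibbs_z_sweep(A, obs, Z, logeta, lognot, log_pi, k)
      st <- block_stats(A, obs, Z, k)
      m_pool <- apply(st$m, c(1, 2), sum); N_pool <- apply(st$N, c(1, 2), sum)
      for (p in seq_len(P)) {
        i <- pairs$i[p]; j <- pairs$j[p]
        e <- rbeta(1, a + m_pool[i, j], b + N_pool[i, j] - m_pool[i, j])
        e <- min(max(e, 1e-12), 1 - 1e-12)
        eta[i, j] <- e; eta[j, i] <- e
      }
      pi_cur <- rdirichlet1(alpha + tabulate(Z, nbins = k))
      log_pi <- log(pi_cur)
      if (it > mcmc$n_warmup && (it - mcmc$n_warmup) %% mcmc$thin == 0) {
        kept <- kept + 1L
        draws$z[kept, , ] <- Z
        draws$eta[kept, , ] <- eta
        draws$pi[kept, ] <- pi_cur
        Qc <- qlogis(eta)
        ll <- 0
        for (p in seq_len(P)) {
          ll <- ll + pair_loglik(rep(Qc[pairs$i[p], pairs$j[p]], Tt),
                                 st$m[pairs$i[p], pairs$j[p], ],
                                 st$N[pairs$i[p], pairs$j[p], ])
        }
        draws$loglik[kept] <- ll
      }
    }
    chains[[ch]] <- draws
  }
  combine_chains(chains, panel, k, mcmc,
                 tsbm_priors(alpha = alpha), model = "static_sbm")
}
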