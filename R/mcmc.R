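#' MCMC configuration
#'
#' @param n_chains number of chains (default 2).
#' @param n_samples post-warmup draws kept per chain.
#' @param n_warmup adaptation/burn-in draws discarded per chain; defaults to
#'   `n_samples` so the first half of each chain is dropped.
#' @param seed integer master seed; chain c uses `seed + 1000 * (c - 1)`.
#' @param thin keep every `thin`-th post-warmup draw.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2, n_samples = 1000, n_warmup = n_samples,
                        seed = 1, thin = 1) {
  check_number(n_chains, "n_chains", lower = 1)
  check_number(n_samples, "n_samples", lower = 1)
  check_number(n_warmup, "n_warmup", lower = 0)
  check_number(thin, "thin", lower = 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' Prior specification for the temporal model
#'
#' Deliberately weak defaults: flat Dirichlet on the community proportions,
#' half-normal on the kernel output scales, a gamma prior on the length
#' scales centred near a third of the DIV-grid span and truncated below at
#' the smallest DIV gap (so the latent process cannot wiggle between
#' neighbouring recordings), standard normal offsets, and a fixed nugget.
#'
#' The output-scale prior is kept at half-normal(0.5): the latent process
#' models temporal modulation around the pair-specific baseline `beta`, and
#' because a near-constant latent path is indistinguishable from a shift of
#' `beta`, a more generous output scale lets the process absorb the baseline
#' (a wider prior fits extreme logit levels better) and biases `beta`
#' toward zero.
#'
#' @param alpha Dirichlet weight per community (default 1).
#' @param sigma_scale half-normal scale for `sigma_in`, `sigma_out`.
#' @param ell_mean prior mean of the length scales; `NULL` = grid span / 3.
#' @param eps fixed nugget variance (default 0.01).
#' @param beta_sd prior standard deviation of the offsets (model value 1).
#' @return a `tsbm_priors` list.
#' @export
tsbm_priors <- function(alpha = 1, sigma_scale = 0.5, ell_mean = NULL,
                        eps = 0.01, beta_sd = 1) {
  structure(list(alpha = alpha, sigma_scale = sigma_scale,
                 ell_mean = ell_mean, eps = eps, beta_sd = beta_sd),
            class = "tsbm_priors")
}

# ---- internal helpers shared by both samplers -------------------------------

# upper-triangle (incl. diagonal) pair index table for k communities
pair_index <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

# sufficient statistics: edge counts m and dyad counts N per pair per DIV,
# pooled over devices. Z is a D x n assignment matrix.
block_stats <- function(A, obs, Z, k) {
  n <- dim(A)[1]; Tt <- dim(A)[3]; D <- dim(A)[4]
  m <- array(0, c(k, k, Tt)); N <- array(0, c(k, k, Tt))
  for (d in seq_len(D)) {
    Zd <- matrix(0, n, k); Zd[cbind(seq_len(n), Z[d, ])] <- 1
    cnt <- colSums(Zd)
    dy <- outer(cnt, cnt); diag(dy) <- cnt * (cnt - 1)
    for (tt in which(obs[, d])) {
      Mb <- crossprod(Zd, A[, , tt, d] %*% Zd)
      m[, , tt] <- m[, , tt] + Mb
      N[, , tt] <- N[, , tt] + dy
    }
  }
  # t(Z) A Z double-counts within-community edges; so does n_i (n_i - 1)
  for (tt in seq_len(Tt)) {
    mm <- matrix(m[, , tt], k, k); nn <- matrix(N[, , tt], k, k)
    diag(mm) <- diag(mm) / 2; diag(nn) <- diag(nn) / 2
    m[, , tt] <- mm; N[, , tt] <- nn
  }
  list(m = m, N = N)
}

# one categorical Gibbs sweep over all (device, node) assignments.
# logeta/lognot are k x k x Tt arrays; returns the updated Z.
gibbs_z_sweep <- function(A, obs, Z, logeta, lognot, log_pi, k) {
  n <- dim(A)[1]; D <- dim(A)[4]
  for (d in seq_len(D)) {
    ot <- which(obs[, d])
    To <- length(ot)
    if (To == 0L) {  # unobserved device: prior draw
      Z[d, ] <- sample.int(k, n, replace = TRUE, prob = exp(log_pi))
      next
    }
    LpM <- matrix(logeta[, , ot], k, k * To)
    LnM <- matrix(lognot[, , ot], k, k * To)
    Zd <- matrix(0, n, k); Zd[cbind(seq_len(n), Z[d, ])] <- 1
    cnt <- colSums(Zd)
    for (u in seq_len(n)) {
      cu <- Z[d, u]
      cnt_u <- cnt; cnt_u[cu] <- cnt_u[cu] - 1
      # E[c, t] = number of edges from u to community c at DIV t
      Au <- matrix(A[, u, ot, d], n, To)
      E <- crossprod(Zd, Au)             # k x To; A_uu = 0 so u contributes nothing
      Ncur <- matrix(cnt_u, k, To)
      ll <- LpM %*% as.vector(E) + LnM %*% as.vector(Ncur - E)
      lp <- log_pi + as.vector(ll)
      lp <- lp - max(lp)
      cnew <- sample.int(k, 1L, prob = exp(lp))
      if (cnew != cu) {
        Z[d, u] <- cnew
        Zd[u, cu] <- 0; Zd[u, cnew] <- 1
        cnt[cu] <- cnt[cu] - 1; cnt[cnew] <- cnt[cnew] + 1
      }
    }
  }
  Z
}

# Bernoulli log-likelihood of one community pair's curve on the logit scale
pair_loglik <- function(q, m_t, N_t) {
  sum(m_t * plogis(q, log.p = TRUE) + (N_t - m_t) * plogis(-q, log.p = TRUE))
}

# Exact Gibbs step along the likelihood-invariant direction of one pair's
# (offset, latent) vector. The map w -> q = beta_sd * w[1] + L w[-1] has a
# one-dimensional null space spanned by u ~ (1, -beta_sd * L^{-1} 1); moving
# along it leaves eta(t) untouched, so the conditional is the standard-normal
# prior restricted to the line: alpha ~ N(-w.u, 1) for unit u. This removes
# the slow random walk along the beta-vs-constant-GP-level ridge.
ridge_gibbs_update <- function(w, L, beta_sd) {
  u <- c(1, -beta_sd * forwardsolve(L, rep(1, nrow(L))))
  u <- u / sqrt(sum(u^2))
  alpha <- rnorm(1, -sum(w * u), 1)
  w + alpha * u
}

# elliptical slice sampling for w ~ N(0, I) a priori with log-lik f(w)
ess_update <- function(w, f) {
  nu <- rnorm(length(w))
  logy <- f(w) + log(runif(1))
  theta <- runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi; hi <- theta
  repeat {
    wp <- w * cos(theta) + nu * sin(theta)
    if (f(wp) > logy) return(wp)
    if (theta < 0) lo <- theta else hi <- theta
    theta <- runif(1, lo, hi)
    if (hi - lo < 1e-12) return(w)
  }
}

half_normal_lp <- function(x, scale) -x^2 / (2 * scale^2)

# k-means warm start on the rows of each device's time-averaged adjacency;
# falls back to a random assignment when clustering is degenerate. Cluster
# labels are arbitrary per device, so devices after the first are aligned to
# the first by node-assignment overlap — starting devices in conflicting
# label orientations creates a metastable averaged mode the samplers cannot
# leave.
informed_init_z <- function(A, obs, k) {
  n <- dim(A)[1]; D <- dim(A)[4]
  Z <- matrix(sample.int(k, D * n, replace = TRUE), nrow = D)
  for (d in seq_len(D)) {
    ot <- which(obs[, d])
    if (!length(ot)) next
    Abar <- apply(A[, , ot, d, drop = FALSE], c(1, 2), mean)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(Abar, centers = min(k, n - 1),
                                     nstart = 5)),
      error = function(e) NULL)
    if (!is.null(km)) Z[d, ] <- km$cluster
  }
  for (d in seq_len(D)[-1]) {
    perm <- match_labels(Z[d, ], Z[1, ], k)
    Z[d, ] <- perm[Z[d, ]]
  }
  Z
}

#' Fit the temporal stochastic block model by MCMC
#'
#' Compound sampler: exact categorical Gibbs sweeps for each node's
#' community assignment, elliptical slice sampling for the joint
#' (offset, latent path) vector of every community pair under its
#' non-centred Gaussian-process parameterisation, random-walk Metropolis on
#' the log kernel hyperparameters with warmup step-size adaptation, and a
#' conjugate Dirichlet update for the community proportions.
#'
#' @param panel a [network_panel()] of binary symmetric networks.
#' @param k maximum number of communities (>= 2).
#' @param mcmc an [mcmc_config()].
#' @param priors a [tsbm_priors()].
#' @param init_z starting assignments: `"informed"` (default, k-means on
#'   each device's time-averaged adjacency rows), `"random"`, or a devices x
#'   nodes matrix.
#' @return a `tsbm_fit` object holding the posterior draws of `z`, `beta`,
#'   `X`, the kernel parameters and `pi`, with chain indices, the data
#'   log-likelihood path, and split R-hat / effective-sample-size
#'   diagnostics for the continuous parameters.
#' @export
fit_tsbm <- function(panel, k, mcmc = mcmc_config(), priors = tsbm_priors(),
                     init_z = "informed") {
  stopifnot(inherits(panel, "network_panel"), k >= 2)
  A <- panel_array(panel)
  n <- dim(A)[1]; Tt <- dim(A)[3]; D <- dim(A)[4]
  obs <- !apply(A, c(3, 4), function(x) anyNA(x))
  A[is.na(A)] <- 0L
  divs <- panel$divs
  span <- max(divs) - min(divs)
  min_gap <- if (Tt > 1) min(diff(divs)) else 1
  ell_mean <- priors$ell_mean %||% max(span / 3, min_gap)
  ell_shape <- 2; ell_rate <- ell_shape / ell_mean
  eps <- priors$eps
  pairs <- pair_index(k); P <- nrow(pairs)
  diag_pairs <- which(pairs$i == pairs$j)
  off_pairs <- which(pairs$i != pairs$j)

  keep_total <- mcmc$n_samples %/% mcmc$thin
  chains <- vector("list", mcmc$n_chains)

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 1000L * (ch - 1L))
    Z <- if (is.matrix(init_z)) {
      stopifnot(dim(init_z) == c(D, n))
      init_z
    } else if (identical(init_z, "informed")) {
      informed_init_z(A, obs, k)
    } else {
      matrix(sample.int(k, D * n, replace = TRUE), nrow = D)
    }
    log_pi <- rep(log(1 / k), k)
    beta_p <- rep(0, P)
    V <- matrix(0, Tt, P)
    sig <- c(in_ = 0.5, out = 0.5)
    ell <- c(in_ = max(ell_mean, min_gap), out = max(ell_mean, min_gap))
    L_in <- se_chol(divs, kernel_params(sig[1], ell[1], eps))
    L_out <- se_chol(divs, kernel_params(sig[2], ell[2], eps))
    step <- c(in_ = 0.3, out = 0.3)
    acc <- c(in_ = 0, out = 0); try_n <- c(in_ = 0, out = 0)

    draws <- list(
      z = array(NA_integer_, c(keep_total, D, n)),
      beta = array(NA_real_, c(keep_total, k, k)),
      X = array(NA_real_, c(keep_total, k, k, Tt)),
      kernel = matrix(NA_real_, keep_total, 4,
                      dimnames = list(NULL, c("sigma_in", "ell_in",
                                              "sigma_out", "ell_out"))),
      pi = matrix(NA_real_, keep_total, k),
      loglik = numeric(keep_total)
    )
    kept <- 0L
    total_iter <- mcmc$n_warmup + mcmc$n_samples

    # latent paths for the current kernels
    Xmat <- matrix(0, Tt, P)
    Xmat[, diag_pairs] <- L_in %*% V[, diag_pairs, drop = FALSE]
    if (length(off_pairs)) {
      Xmat[, off_pairs] <- L_out %*% V[, off_pairs, drop = FALSE]
    }

    build_eta_logs <- function(beta_p, Xmat) {
      Q <- array(0, c(k, k, Tt))
      for (p in seq_len(P)) {
        q <- beta_p[p] + Xmat[, p]
        Q[pairs$i[p], pairs$j[p], ] <- q
        Q[pairs$j[p], pairs$i[p], ] <- q
      }
      list(logeta = plogis(Q, log.p = TRUE), lognot = plogis(-Q, log.p = TRUE),
           Q = Q)
    }

    st <- block_stats(A, obs, Z, k)

    # assignments are held at their initial value for the first few warmup
    # iterations: eta starts at one half everywhere, and a Gibbs sweep under
    # a non-informative eta would randomise the warm start before the
    # continuous parameters have adapted to it
    z_start <- min(25L, max(1L, mcmc$n_warmup %/% 4))

    for (it in seq_len(total_iter)) {
      el <- build_eta_logs(beta_p, Xmat)

      # -- z | rest ---------------------------------------------------------
      if (it >= z_start) {
        Z <- gibbs_z_sweep(A, obs, Z, el$logeta, el$lognot, log_pi, k)
      }
      # Per-device label permutations are an identifiability artifact of
      # the block-label symmetry: when diagonal offsets are similar, a
      # device scores almost equally under permuted labels, so the
      # posterior has near-degenerate orientation modes. The sampler works
      # in the canonical cross-device-consistent representative: devices
      # start label-aligned (informed init) and single-site sweeps cannot
      # flip a whole device, so that orientation is preserved, while
      # genuinely misassigned nodes still migrate individually.
      st <- block_stats(A, obs, Z, k)

      # -- pi | z -----------------------------------------------------------
      cnt_all <- tabulate(Z, nbins = k)
      pi_cur <- rdirichlet1(priors$alpha + cnt_all)
      log_pi <- log(pi_cur)

      # -- (beta, v) per pair via elliptical slice sampling -----------------
      for (p in seq_len(P)) {
        Lp <- if (pairs$i[p] == pairs$j[p]) L_in else L_out
        m_t <- st$m[pairs$i[p], pairs$j[p], ]
        N_t <- st$N[pairs$i[p], pairs$j[p], ]
        f <- function(w) {
          pair_loglik(priors$beta_sd * w[1] + as.vector(Lp %*% w[-1]), m_t, N_t)
        }
        w <- c(beta_p[p] / priors$beta_sd, V[, p])
        w <- ess_update(w, f)
        w <- ridge_gibbs_update(w, Lp, priors$beta_sd)
        beta_p[p] <- priors$beta_sd * w[1]
        V[, p] <- w[-1]
        Xmat[, p] <- as.vector(Lp %*% w[-1])
      }

      # -- kernel hyperparameters (random-walk on log scale) ----------------
      for (side in c("in_", "out")) {
        pset <- if (side == "in_") diag_pairs else off_pairs
        if (!length(pset)) next
        cur <- c(log(sig[side]), log(ell[side]))
        kern_ll <- function(lsig, lell) {
          s <- exp(lsig); l <- exp(lell)
          if (l < min_gap) return(-Inf)
          L <- se_chol(divs, kernel_params(s, l, eps))
          ll <- 0
          for (p in pset) {
            q <- beta_p[p] + as.vector(L %*% V[, p])
            ll <- ll + pair_loglik(q, st$m[pairs$i[p], pairs$j[p], ],
                                   st$N[pairs$i[p], pairs$j[p], ])
          }
          ll + half_normal_lp(s, priors$sigma_scale) + lsig +
            stats::dgamma(l, ell_shape, ell_rate, log = TRUE) + lell
        }
        prop <- cur + rnorm(2, 0, step[side])
        lp_cur <- kern_ll(cur[1], cur[2])
        lp_new <- kern_ll(prop[1], prop[2])
        try_n[side] <- try_n[side] + 1
        if (is.finite(lp_new) && log(runif(1)) < lp_new - lp_cur) {
          acc[side] <- acc[side] + 1
          sig[side] <- exp(prop[1]); ell[side] <- exp(prop[2])
          if (side == "in_") {
            L_in <- se_chol(divs, kernel_params(sig[1], ell[1], eps))
            Xmat[, diag_pairs] <- L_in %*% V[, diag_pairs, drop = FALSE]
          } else {
            L_out <- se_chol(divs, kernel_params(sig[2], ell[2], eps))
            Xmat[, off_pairs] <- L_out %*% V[, off_pairs, drop = FALSE]
          }
        }
        if (it <= mcmc$n_warmup && it %% 50 == 0 && try_n[side] > 0) {
          rate <- acc[side] / try_n[side]
          step[side] <- min(2, max(0.02, step[side] * exp(rate - 0.3)))
          acc[side] <- 0; try_n[side] <- 0
        }

        # centered/non-centred swap: rescale sigma while holding every
        # latent path x = L v fixed (v is re-whitened under the new factor),
        # so the move walks the sigma-vs-|v| ridge at constant likelihood.
        lsig_new <- log(sig[side]) + rnorm(1, 0, 0.4)
        s_new <- exp(lsig_new)
        L_old <- if (side == "in_") L_in else L_out
        L_new <- se_chol(divs, kernel_params(s_new, ell[side], eps))
        pset2 <- if (side == "in_") diag_pairs else off_pairs
        Vnew <- forwardsolve(L_new, Xmat[, pset2, drop = FALSE])
        lacc <- sum(V[, pset2, drop = FALSE]^2 - Vnew^2) / 2 +
          length(pset2) * (sum(log(diag(L_old))) - sum(log(diag(L_new)))) +
          half_normal_lp(s_new, priors$sigma_scale) - half_normal_lp(sig[side], priors$sigma_scale) +
          lsig_new - log(sig[side])
        if (is.finite(lacc) && log(runif(1)) < lacc) {
          sig[side] <- s_new
          V[, pset2] <- Vnew
          if (side == "in_") L_in <- L_new else L_out <- L_new
        }
      }

      # -- store ------------------------------------------------------------
      if (it > mcmc$n_warmup && (it - mcmc$n_warmup) %% mcmc$thin == 0) {
        kept <- kept + 1L
        draws$z[kept, , ] <- Z
        Bm <- matrix(0, k, k); Xarr <- array(0, c(k, k, Tt))
        for (p in seq_len(P)) {
          Bm[pairs$i[p], pairs$j[p]] <- beta_p[p]
          Bm[pairs$j[p], pairs$i[p]] <- beta_p[p]
          Xarr[pairs$i[p], pairs$j[p], ] <- Xmat[, p]
          Xarr[pairs$j[p], pairs$i[p], ] <- Xmat[, p]
        }
        draws$beta[kept, , ] <- Bm
        draws$X[kept, , , ] <- Xarr
        draws$kernel[kept, ] <- c(sig[1], ell[1], sig[2], ell[2])
        draws$pi[kept, ] <- pi_cur
        ll_data <- 0
        for (p in seq_len(P)) {
          q <- beta_p[p] + Xmat[, p]
          ll_data <- ll_data + pair_loglik(q, st$m[pairs$i[p], pairs$j[p], ],
                                           st$N[pairs$i[p], pairs$j[p], ])
        }
        draws$loglik[kept] <- ll_data
      }
    }
    chains[[ch]] <- draws
  }

  fit <- combine_chains(chains, panel, k, mcmc, priors, model = "tsbm")
  fit
}

# bind per-chain draw lists into one tsbm_fit with diagnostics
combine_chains <- function(chains, panel, k, mcmc, priors, model) {
  S1 <- dim(chains[[1]]$z)[1]
  nm <- names(chains[[1]])
  bound <- lapply(nm, function(field) {
    parts <- lapply(chains, `[[`, field)
    x <- parts[[1]]
    if (is.null(dim(x))) return(do.call(c, parts))
    do.call(abind1, parts)
  })
  names(bound) <- nm
  chain_id <- rep(seq_along(chains), each = S1)
  diag_tbl <- fit_diagnostics(bound, chain_id, model)
  structure(
    list(model = model, k = k, devices = panel$devices, divs = panel$divs,
         channels = panel$channels, n = panel$n,
         config = mcmc, priors = priors, draws = bound, chain = chain_id,
         diagnostics = diag_tbl),
    class = c(paste0(model, "_fit"), "sbm_fit")
  )
}

# rbind along the first (draw) dimension for arrays/matrices
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  tot <- sum(vapply(parts, function(x) dim(x)[1], 1))
  out <- array(NA, c(tot, d[-1]))
  at <- 0L
  for (x in parts) {
    s <- dim(x)[1]
    idx <- c(list(at + seq_len(s)), rep(list(quote(expr = )), length(d) - 1))
    out <- do.call(`[<-`, c(list(out), idx, list(x)))
    at <- at + s
  }
  dimnames(out) <- c(list(NULL), dimnames(parts[[1]])[-1])
  out
}

split_rhat <- function(x, chain_id) {
  # split each chain in half, compute potential scale reduction
  halves <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    h <- length(v) %/% 2
    if (h < 2) return(NA_real_)
    halves <- c(halves, list(v[1:h]), list(v[(h + 1):(2 * h)]))
  }
  m <- length(halves); nn <- length(halves[[1]])
  means <- vapply(halves, mean, 1); vars <- vapply(halves, var, 1)
  B <- nn * var(means); W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  a <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(a < 0.05)[1]
  if (is.na(pos)) pos <- length(a)
  tau <- 1 + 2 * sum(a[seq_len(max(pos - 1, 0))])
  max(1, n / max(tau, 1))
}

fit_diagnostics <- function(draws, chain_id, model) {
  pars <- list()
  k <- dim(draws$beta %||% draws$eta)[2]
  src <- if (model == "tsbm") draws$beta else draws$eta
  nmp <- if (model == "tsbm") "beta" else "eta"
  for (i in 1:k) for (j in i:k) {
    pars[[sprintf("%s[%d,%d]", nmp, i, j)]] <- src[, i, j]
  }
  if (!is.null(draws$kernel)) {
    for (cn in colnames(draws$kernel)) pars[[cn]] <- draws$kernel[, cn]
  }
  pars$loglik <- draws$loglik
  purrr::imap_dfr(pars, function(v, nm) {
    tibble::tibble(parameter = nm,
                   mean = mean(v), sd = sd(v),
                   rhat = split_rhat(v, chain_id),
                   ess = ess_basic(v))
  })
}

#' @export
print.sbm_fit <- function(x, ...) {
  S <- length(x$chain)
  cat(sprintf("<%s_fit> k = %d, %d devices, %d DIVs, %d nodes; %d draws in %d chains\n",
              x$model, x$k, length(x$devices), length(x$divs), x$n,
              S, length(unique(x$chain))))
  bad <- x$diagnostics$parameter[!is.na(x$diagnostics$rhat) &
                                   x$diagnostics$rhat > 1.05]
  if (length(bad)) {
    cat("  convergence flags (split R-hat > 1.05): ",
        paste(bad, collapse = ", "), "\n")
  }
  invisible(x)
}
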