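#' Adjusted mutual information between two partitions
#'
#' Chance-corrected mutual information under the hypergeometric permutation
#' model, with the arithmetic-mean normalisation
#' `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`. Identical partitions
#' score 1 regardless of labelling.
#'
#' @param x,y label vectors of equal length.
#' @return a number, ~0 for independent partitions, 1 for identical ones.
#' @export
ami <- function(x, y) {
  stopifnot(length(x) == length(y))
  N <- length(x)
  cx <- table(x); cy <- table(y)
  if ((length(cx) == 1 && length(cy) == 1) ||
      (length(cx) == N && length(cy) == N)) {
    return(1)
  }
  ct <- table(x, y)
  a <- rowSums(ct); b <- colSums(ct)
  # observed mutual information (nats)
  nz <- ct > 0
  mi <- sum((ct[nz] / N) * log(N * ct[nz] / (outer(a, b)[nz])))
  hx <- -sum((a / N) * log(a / N)); hy <- -sum((b / N) * log(b / N))
  # expected MI under the permutation model
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    ai <- a[i]; bj <- b[j]
    lo <- max(1, ai + bj - N); hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    term <- (nij / N) * log(N * nij / (ai * bj))
    lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) +
      lgamma(N - bj + 1) - lgamma(N + 1) - lgamma(nij + 1) -
      lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
      lgamma(N - ai - bj + nij + 1)
    emi <- emi + sum(term * exp(lp))
  }
  den <- mean(c(hx, hy)) - emi
  if (abs(den) < .Machine$double.eps) return(0)
  (mi - emi) / den
}

#' Average AMI between late posterior draws and a reference assignment
#'
#' Takes the last `last_n` kept draws (split evenly over the ends of the
#' chains), concatenates each draw's assignments across devices, and
#' averages the adjusted mutual information against the concatenated
#' reference. Label-permutation invariant.
#'
#' @param fit an `sbm_fit`.
#' @param truth_z devices x nodes reference assignment.
#' @param last_n number of draws to score (default 500).
#' @return the mean AMI.
#' @export
ami_recovery <- function(fit, truth_z, last_n = 500) {
  stopifnot(inherits(fit, "sbm_fit"))
  idx <- tail_draw_index(fit$chain, last_n)
  truth <- as.vector(t(truth_z))
  scores <- vapply(idx, function(s) {
    ami(as.vector(t(fit$draws$z[s, , ])), truth)
  }, 1)
  mean(scores)
}

# indices of the last `last_n` draws, taken from the end of each chain
tail_draw_index <- function(chain, last_n) {
  chains <- unique(chain)
  if (last_n > length(chain)) {
    stop("last_n exceeds the number of kept draws", call. = FALSE)
  }
  per <- rep(last_n %/% length(chains), length(chains))
  extra <- last_n - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  unlist(purrr::map2(chains, per, function(ch, p) {
    w <- which(chain == ch)
    w[(length(w) - p + 1):length(w)]
  }))
}

modal_assignment <- function(zdraws) {
  # zdraws: S x D x n -> D x n posterior mode
  D <- dim(zdraws)[2]; n <- dim(zdraws)[3]
  out <- matrix(0L, D, n)
  for (d in seq_len(D)) for (u in seq_len(n)) {
    tab <- tabulate(zdraws[, d, u])
    out[d, u] <- which.max(tab)
  }
  out
}

# greedy label matching: permutation p with p[old] = new maximizing overlap
match_labels <- function(est, ref, k) {
  conf <- matrix(0, k, k)  # rows: est labels, cols: ref labels
  for (i in seq_along(est)) conf[est[i], ref[i]] <- conf[est[i], ref[i]] + 1
  perm <- rep(NA_integer_, k)
  used <- rep(FALSE, k)
  for (step in seq_len(k)) {
    w <- which(conf == max(conf), arr.ind = TRUE)[1, , drop = TRUE]
    if (conf[w[1], w[2]] < 0) break
    perm[w[1]] <- w[2]; used[w[2]] <- TRUE
    conf[w[1], ] <- -1; conf[, w[2]] <- -1
  }
  perm[is.na(perm)] <- setdiff(seq_len(k), perm[!is.na(perm)])
  perm
}

apply_label_perm <- function(fit, perm, rows) {
  inv <- order(perm)  # new label l holds old label inv[l]
  dr <- fit$draws
  zz <- dr$z[rows, , , drop = FALSE]
  zz[] <- perm[zz]
  dr$z[rows, , ] <- zz
  if (!is.null(dr$beta)) {
    dr$beta[rows, , ] <- dr$beta[rows, inv, inv, drop = FALSE]
    dr$X[rows, , , ] <- dr$X[rows, inv, inv, , drop = FALSE]
  }
  if (!is.null(dr$eta) && length(dim(dr$eta)) == 3) {
    dr$eta[rows, , ] <- dr$eta[rows, inv, inv, drop = FALSE]
  }
  dr$pi[rows, ] <- dr$pi[rows, inv, drop = FALSE]
  fit$draws <- dr
  fit
}

#' Relabel a fitted model and summarise its posterior
#'
#' Handles label switching post hoc: each chain's draws are permuted to agree
#' with the first chain's modal assignment, then community labels are ordered
#' by decreasing total occupancy across devices (community 1 = most populated)
#' — or aligned to a `reference` partition when one is given, which resolves
#' ties such as equally sized communities.
#'
#' @param fit an `sbm_fit`.
#' @param reference optional devices x nodes assignment to orient labels
#'   against (e.g. a simulation ground truth).
#' @param rhat_limit convergence gate on split R-hat; exceedances are
#'   reported in the summary, never hidden.
#' @return a `fit_summary`: relabeled `fit`, `mode_z`, `occupied_k`,
#'   `community_counts` (devices x communities), `community_sizes`,
#'   posterior `eta_mean`/`eta_lower`/`eta_upper` (central 94 %),
#'   `beta_mean`/`beta_sd` (temporal model), kernel posterior means, and
#'   `convergence_flags`.
#' @export
relabel_by_size <- function(fit, reference = NULL, rhat_limit = 1.05) {
  stopifnot(inherits(fit, "sbm_fit"))
  k <- fit$k
  chains <- unique(fit$chain)
  ref_mode <- modal_assignment(fit$draws$z[fit$chain == chains[1], , ,
                                           drop = FALSE])
  for (ch in chains[-1]) {
    rows <- which(fit$chain == ch)
    mode_ch <- modal_assignment(fit$draws$z[rows, , , drop = FALSE])
    perm <- match_labels(as.vector(mode_ch), as.vector(ref_mode), k)
    if (!identical(perm, seq_len(k))) fit <- apply_label_perm(fit, perm, rows)
  }
  pooled_mode <- modal_assignment(fit$draws$z)
  sizes <- tabulate(pooled_mode, nbins = k)
  perm_final <- if (is.null(reference)) {
    order(order(-sizes, seq_len(k)))  # old label -> new rank
  } else {
    stopifnot(all(dim(reference) == dim(pooled_mode)))
    match_labels(as.vector(pooled_mode), as.vector(reference), k)
  }
  if (!identical(perm_final, seq_len(k))) {
    fit <- apply_label_perm(fit, perm_final, seq_along(fit$chain))
    pooled_mode <- matrix(perm_final[pooled_mode], nrow = nrow(pooled_mode))
  }
  sizes <- tabulate(pooled_mode, nbins = k)
  D <- nrow(pooled_mode)
  counts <- t(vapply(seq_len(D), function(d) {
    tabulate(pooled_mode[d, ], nbins = k)
  }, integer(k)))
  rownames(counts) <- fit$devices
  colnames(counts) <- paste0("community_", seq_len(k))

  ed <- eta_draws(fit)
  qs <- apply(ed, c(2, 3, 4), quantile, probs = c(0.03, 0.97))
  summ <- list(
    fit = fit,
    mode_z = pooled_mode,
    occupied_k = sum(sizes > 0),
    community_sizes = sizes,
    community_counts = counts,
    divs = if (fit$model == "tsbm") fit$divs else NA,
    eta_mean = apply(ed, c(2, 3, 4), mean),
    eta_lower = qs[1, , , , drop = TRUE],
    eta_upper = qs[2, , , , drop = TRUE],
    convergence_flags = dplyr::filter(fit$diagnostics,
                                      !is.na(.data$rhat),
                                      .data$rhat > rhat_limit)
  )
  if (fit$model == "tsbm") {
    summ$beta_mean <- apply(fit$draws$beta, c(2, 3), mean)
    summ$beta_sd <- apply(fit$draws$beta, c(2, 3), sd)
    summ$kernel_mean <- colMeans(fit$draws$kernel)
  }
  structure(summ, class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("<fit_summary> %d occupied of %d communities; sizes: %s\n",
              x$occupied_k, x$fit$k,
              paste(x$community_sizes, collapse = ", ")))
  if (nrow(x$convergence_flags)) {
    cat("  convergence flags:", paste(x$convergence_flags$parameter,
                                      collapse = ", "), "\n")
  }
  invisible(x)
}

# eta draws as S x k x k x T (static models get T = 1)
eta_draws <- function(fit) {
  if (fit$model == "tsbm") {
    S <- dim(fit$draws$beta)[1]; k <- fit$k; Tt <- length(fit$divs)
    out <- array(NA_real_, c(S, k, k, Tt))
    for (tt in seq_len(Tt)) {
      out[, , , tt] <- plogis(fit$draws$beta + fit$draws$X[, , , tt])
    }
    out
  } else {
    S <- dim(fit$draws$eta)[1]
    array(fit$draws$eta, c(S, fit$k, fit$k, 1))
  }
}

#' Posterior connection-probability curves
#'
#' Pointwise posterior mean and central credible interval of
#' `eta_ij(t) = plogis(beta_ij + x_ij(t))` for every community pair on the
#' training DIV grid. Symmetric in (i, j) by construction.
#'
#' @param fit an `sbm_fit`.
#' @param prob central interval mass (default 0.94).
#' @return a tibble with columns `i`, `j` (i <= j), `div`, `mean`, `lower`,
#'   `upper`.
#' @export
posterior_eta <- function(fit, prob = 0.94) {
  stopifnot(inherits(fit, "sbm_fit"))
  ed <- eta_draws(fit)
  divs <- if (fit$model == "tsbm") fit$divs else NA_real_
  k <- fit$k; Tt <- dim(ed)[4]
  a <- (1 - prob) / 2
  res <- list()
  for (i in 1:k) for (j in i:k) for (tt in seq_len(Tt)) {
    v <- ed[, i, j, tt]
    res[[length(res) + 1L]] <- tibble::tibble(
      i = i, j = j, div = divs[tt], mean = mean(v),
      lower = quantile(v, a, names = FALSE),
      upper = quantile(v, 1 - a, names = FALSE))
  }
  dplyr::bind_rows(res)
}

# ---- GP prediction ----------------------------------------------------------

# sampled eta at new DIVs, per posterior draw: S x k x k x M array
predict_eta_draws <- function(fit, t_new) {
  stopifnot(fit$model == "tsbm")
  divs <- fit$divs; k <- fit$k
  S <- dim(fit$draws$beta)[1]
  M <- length(t_new); Tt <- length(divs)
  eps <- fit$priors$eps
  pairs <- pair_index(k)
  out <- array(NA_real_, c(S, k, k, M))
  for (s in seq_len(S)) {
    kd <- fit$draws$kernel[s, ]
    for (side in c("in", "out")) {
      kp <- if (side == "in") {
        kernel_params(kd[["sigma_in"]], kd[["ell_in"]], eps)
      } else {
        kernel_params(kd[["sigma_out"]], kd[["ell_out"]], eps)
      }
      pset <- if (side == "in") which(pairs$i == pairs$j) else which(pairs$i != pairs$j)
      if (!length(pset)) next
      Ktr <- se_gram(divs, kp)
      kst <- kp$sigma^2 * exp(-outer(divs, t_new, "-")^2 / (2 * kp$ell^2))
      Kinv_kst <- solve(Ktr, kst)                      # T x M
      pred_var <- pmax(kp$sigma^2 - colSums(kst * Kinv_kst), 0)
      for (p in pset) {
        i <- pairs$i[p]; j <- pairs$j[p]
        x_tr <- fit$draws$X[s, i, j, ]
        mu <- as.vector(crossprod(Kinv_kst, x_tr))     # M
        x_new <- rnorm(M, mu, sqrt(pred_var))
        e <- plogis(fit$draws$beta[s, i, j] + x_new)
        out[s, i, j, ] <- e; out[s, j, i, ] <- e
      }
    }
  }
  out
}

#' Predict connection probabilities at unobserved DIVs
#'
#' For each posterior draw, the latent path at `t_new` is sampled from its
#' Gaussian-process conditional given that draw's latent values on the
#' training grid and kernel parameters, then pushed through the logistic
#' link; draws are aggregated pointwise. Points farther than three posterior
#' mean length scales outside the grid revert to the prior and are returned
#' with a warning.
#'
#' @param fit a `tsbm_fit`.
#' @param t_new DIVs at which to predict (may overlap the training grid).
#' @param prob central interval mass (default 0.94).
#' @return a tibble `i`, `j`, `div`, `mean`, `lower`, `upper`.
#' @export
predict_eta <- function(fit, t_new, prob = 0.94) {
  stopifnot(inherits(fit, "tsbm_fit"))
  ellbar <- max(mean(fit$draws$kernel[, "ell_in"]),
                mean(fit$draws$kernel[, "ell_out"]))
  far <- t_new[t_new > max(fit$divs) + 3 * ellbar |
                 t_new < min(fit$divs) - 3 * ellbar]
  if (length(far)) {
    warning("DIVs ", paste(far, collapse = ", "),
            " lie beyond 3 length scales of the grid; ",
            "predictions there revert to the prior (wide intervals)")
  }
  ed <- predict_eta_draws(fit, t_new)
  a <- (1 - prob) / 2
  k <- fit$k
  res <- list()
  for (i in 1:k) for (j in i:k) for (m in seq_along(t_new)) {
    v <- ed[, i, j, m]
    res[[length(res) + 1L]] <- tibble::tibble(
      i = i, j = j, div = t_new[m], mean = mean(v),
      lower = quantile(v, a, names = FALSE),
      upper = quantile(v, 1 - a, names = FALSE))
  }
  dplyr::bind_rows(res)
}

#' Held-out posterior-predictive log-likelihood
#'
#' Log of the posterior-predictive mass of held-out networks: for each
#' posterior draw, the Bernoulli likelihood of every held-out adjacency is
#' evaluated at the draw's predicted `eta` (GP conditional for the temporal
#' model, the time-free table for the static model) and the draw's community
#' assignment of the matching device, then combined by log-mean-exp.
#'
#' @param fit an `sbm_fit` trained on the same devices and node set.
#' @param heldout list of [functional_network()] at the held-out DIV.
#' @param t_star the held-out DIV; defaults to the common `div` of `heldout`.
#' @return a single number (log scale).
#' @export
predictive_loglik <- function(fit, heldout, t_star = NULL) {
  stopifnot(inherits(fit, "sbm_fit"))
  if (inherits(heldout, "functional_network")) heldout <- list(heldout)
  t_star <- t_star %||% unique(vapply(heldout, function(x) x$div, 1L))
  stopifnot(length(t_star) == 1)
  for (nw in heldout) {
    if (nrow(nw$adjacency) != fit$n) {
      stop("held-out networks must share the panel's node set", call. = FALSE)
    }
  }
  ed <- if (fit$model == "tsbm") {
    predict_eta_draws(fit, t_star)
  } else {
    array(eta_draws(fit), c(dim(fit$draws$eta)[1], fit$k, fit$k, 1))
  }
  S <- dim(ed)[1]
  lls <- vapply(seq_len(S), function(s) {
    Q <- matrix(qlogis(pmin(pmax(ed[s, , , 1], 1e-12), 1 - 1e-12)),
                fit$k, fit$k)
    tot <- 0
    for (nw in heldout) {
      d <- match(nw$device_id, fit$devices)
      if (is.na(d)) stop("unknown device ", nw$device_id, call. = FALSE)
      zd <- fit$draws$z[s, d, ]
      Qn <- Q[zd, zd, drop = FALSE]
      up <- upper.tri(Qn)
      tot <- tot + sum(log_bern_logit(Qn[up], nw$adjacency[up]))
    }
    tot
  }, 1)
  log_mean_exp(lls)
}

#' Model selection over the maximum community count
#'
#' Fits the model for each `k` in the grid and reports the number of
#' occupied communities and the mean data log-likelihood. The chosen `k` is
#' the smallest whose occupancy stays strictly below `k` (the cap is then
#' not binding); if every fit saturates, the largest `k` is returned with a
#' warning.
#'
#' @param panel a [network_panel()].
#' @param k_grid candidate maxima (default 6, 8, 10, 12).
#' @param mcmc an [mcmc_config()].
#' @param priors a [tsbm_priors()].
#' @param keep_fits return the individual fits as well?
#' @return a list with `chosen_k`, a per-k `report` tibble, and optionally
#'   `fits`.
#' @export
select_k <- function(panel, k_grid = c(6, 8, 10, 12), mcmc = mcmc_config(),
                     priors = tsbm_priors(), keep_fits = FALSE) {
  stopifnot(length(k_grid) >= 1)
  fits <- list()
  report <- purrr::map_dfr(k_grid, function(kk) {
    fit <- fit_tsbm(panel, k = kk, mcmc = mcmc, priors = priors)
    if (keep_fits) fits[[as.character(kk)]] <<- fit
    summ <- relabel_by_size(fit)
    tibble::tibble(k = kk, occupied_k = summ$occupied_k,
                   mean_loglik = mean(fit$draws$loglik))
  })
  free <- report$k[report$occupied_k < report$k]
  chosen <- if (length(free)) {
    min(free)
  } else {
    warning("every candidate k is saturated; returning the largest")
    max(report$k)
  }
  out <- list(chosen_k = chosen, report = report)
  if (keep_fits) out$fits <- fits
  out
}
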