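test_that("adjusted mutual information matches an independent implementation", {
  # expected values frozen from scikit-learn's
  # adjusted_mutual_info_score (arithmetic normalisation)
  expect_equal(ami(c(1, 1, 2, 2, 3, 3), c(1, 1, 2, 2, 3, 3)), 1)
  expect_equal(ami(c(1, 1, 1, 2, 2, 2), c(2, 2, 2, 1, 1, 1)), 1)
  expect_equal(ami(c(1, 1, 2, 2, 3, 3), c(1, 2, 1, 2, 1, 2)),
               -0.448188687256, tolerance = 1e-10)
  expect_equal(ami(c(1, 1, 1, 1, 2, 2, 2, 3, 3, 1),
                   c(1, 2, 1, 1, 2, 2, 3, 3, 3, 1)),
               0.466656778282, tolerance = 1e-10)
  expect_equal(ami(c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2),
                   c(1, 1, 1, 2, 2, 2, 3, 3, 3, 1, 2, 3)),
               -0.133383977062, tolerance = 1e-10)
  x <- c(3, 2, 2, 1, 1, 1, 1, 1, 1, 3, 2, 3, 2, 2, 3, 3, 2, 2, 2, 3,
         1, 3, 3, 1, 2, 3, 2, 1, 3, 3)
  y <- c(3, 1, 1, 3, 1, 2, 1, 1, 2, 2, 2, 1, 1, 1, 1, 3, 2, 2, 1, 2,
         3, 2, 2, 3, 3, 3, 2, 3, 3, 2)
  expect_equal(ami(x, y), 0.007692344070669, tolerance = 1e-10)
  expect_equal(ami(rep(1, 5), rep(2, 5)), 1)  # both trivial partitions
})

test_that("AMI of independent random partitions concentrates near zero", {
  set.seed(123)
  truth <- rep(1:2, each = 10)
  scores <- replicate(200, ami(sample(1:2, 20, replace = TRUE), truth))
  expect_lt(abs(mean(scores)), 0.15)
})

test_that("ami_recovery is invariant to global label permutation of the trace", {
  set.seed(2)
  S <- 20; D <- 2; n <- 10
  z <- array(sample(1:3, S * D * n, replace = TRUE), c(S, D, n))
  beta <- array(rnorm(S * 9), c(S, 3, 3))
  X <- array(rnorm(S * 9 * 2), c(S, 3, 3, 2))
  fit <- manual_tsbm_fit(z, beta, X, divs = c(7, 10),
                         devices = c("d1", "d2"))
  perm <- c(3L, 1L, 2L)
  zp <- z; zp[] <- perm[z]
  fitp <- manual_tsbm_fit(zp, beta, X, divs = c(7, 10),
                          devices = c("d1", "d2"))
  truth_z <- matrix(rep(1:2, each = 5), D, n, byrow = TRUE)
  expect_equal(ami_recovery(fit, truth_z, last_n = 20),
               ami_recovery(fitp, truth_z, last_n = 20))
})

test_that("relabeling orders communities by size and is permutation invariant", {
  set.seed(3)
  S <- 30; D <- 2; n <- 12
  # stable partition: community 2 largest, 3 middle, 1 smallest
  zrow <- c(rep(2L, 6), rep(3L, 4), rep(1L, 2))
  z <- array(rep(zrow, each = S), c(S, D, n))
  for (d in 1:D) z[, d, ] <- matrix(zrow, S, n, byrow = TRUE)
  beta <- array(0, c(S, 3, 3)); X <- array(0, c(S, 3, 3, 2))
  for (s in 1:S) beta[s, , ] <- matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 3), 3)
  fit <- manual_tsbm_fit(z, beta, X, divs = c(7, 10), devices = c("d1", "d2"))
  summ <- relabel_by_size(fit)
  expect_equal(summ$community_sizes, c(12L, 8L, 4L))
  expect_equal(summ$occupied_k, 3)
  expect_true(all(rowSums(summ$community_counts) == n))
  # old label 2 (beta 2) becomes label 1, old 3 -> 2, old 1 -> 3
  expect_equal(diag(summ$beta_mean), c(2, 3, 1))

  perm <- c(2L, 3L, 1L)
  zp <- z; zp[] <- perm[z]
  inv <- order(perm)
  betap <- beta[, inv, inv, drop = FALSE]
  Xp <- X[, inv, inv, , drop = FALSE]
  fitp <- manual_tsbm_fit(zp, betap, Xp, divs = c(7, 10),
                          devices = c("d1", "d2"))
  summp <- relabel_by_size(fitp)
  expect_equal(summp$community_sizes, summ$community_sizes)
  expect_equal(summp$community_counts, summ$community_counts)
  expect_equal(summp$beta_mean, summ$beta_mean)
  expect_equal(summp$mode_z, summ$mode_z)
})

test_that("single-community traces summarise to one occupied community", {
  S <- 10; D <- 2; n <- 6
  z <- array(1L, c(S, D, n))
  beta <- array(0, c(S, 2, 2)); X <- array(0, c(S, 2, 2, 3))
  fit <- manual_tsbm_fit(z, beta, X, divs = c(7, 10, 14),
                         devices = c("d1", "d2"))
  summ <- relabel_by_size(fit)
  expect_equal(summ$occupied_k, 1)
  expect_equal(summ$community_counts[, 1], c(d1 = 6L, d2 = 6L))
})

test_that("posterior eta of a zero trace is one half with coherent bands", {
  S <- 25
  z <- array(1L, c(S, 1, 4))
  beta <- array(0, c(S, 2, 2)); X <- array(0, c(S, 2, 2, 3))
  fit <- manual_tsbm_fit(z, beta, X, divs = c(7, 10, 14), devices = "d1")
  pe <- posterior_eta(fit)
  expect_true(all(pe$mean == 0.5))
  expect_true(all(pe$lower <= pe$mean & pe$mean <= pe$upper))
})

test_that("GP prediction interpolates exactly at training DIVs when eps = 0", {
  truth <- small_truth()
  fit <- fit_tsbm(truth$panel, k = 2,
                  mcmc = mcmc_config(n_chains = 1, n_samples = 100,
                                     n_warmup = 150, seed = 21),
                  priors = tsbm_priors(eps = 0))
  pe_train <- posterior_eta(fit)
  pred <- predict_eta(fit, t_new = fit$divs)
  merged <- dplyr::inner_join(pe_train, pred, by = c("i", "j", "div"),
                              suffix = c("_train", "_pred"))
  expect_equal(merged$mean_pred, merged$mean_train, tolerance = 1e-8)
})

test_that("far-future predictions revert toward the prior with a warning", {
  truth <- small_truth()
  fit <- small_fit()
  expect_warning(pred <- predict_eta(fit, t_new = 500), "beyond 3 length")
  # the latent reverts to N(0, sigma^2); with small sigma the mean reverts
  # to plogis(beta) and intervals widen relative to in-sample ones
  pe <- posterior_eta(fit)
  w_in <- mean(pe$upper - pe$lower)
  w_out <- mean(pred$upper - pred$lower)
  expect_gt(w_out, w_in / 2)
})

test_that("interpolation between DIVs lands between neighbouring means", {
  truth <- small_truth()
  fit <- small_fit()
  pred <- predict_eta(fit, t_new = 11.5)   # between training DIVs 10 and 13
  pe <- posterior_eta(fit)
  for (pp in seq_len(nrow(pred))) {
    nb <- dplyr::filter(pe, i == pred$i[pp], j == pred$j[pp],
                        .data$div %in% c(10, 13))
    lo <- min(nb$mean); hi <- max(nb$mean)
    margin <- 0.1 + 0.5 * (hi - lo)
    expect_gt(pred$mean[pp], lo - margin)
    expect_lt(pred$mean[pp], hi + margin)
  }
})

test_that("predictive log-likelihood has its closed form under eta = 0.5", {
  S <- 12; n <- 8
  z <- array(1L, c(S, 1, n))
  eta <- array(0.5, c(S, 1, 1))
  fit <- structure(
    list(model = "static_sbm", k = 1, devices = "d1", divs = 1, n = n,
         channels = as.character(1:n),
         config = mcmc_config(n_chains = 1, n_samples = S, seed = 1),
         priors = tsbm_priors(),
         draws = list(z = z, eta = eta, pi = matrix(1, S, 1),
                      loglik = numeric(S)),
         chain = rep(1L, S),
         diagnostics = tibble::tibble(parameter = character(), mean = numeric(),
                                      sd = numeric(), rhat = numeric(),
                                      ess = numeric())),
    class = c("static_sbm_fit", "sbm_fit"))
  set.seed(4)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(choose(n, 2), 1, 0.5)
  adj <- adj + t(adj)
  net <- functional_network(adj, as.character(1:n), "d1", 5L)
  expect_equal(predictive_loglik(fit, list(net)),
               -choose(n, 2) * log(2))
})

test_that("select_k picks the smallest non-saturated candidate", {
  truth <- small_truth()
  cfg <- mcmc_config(n_chains = 1, n_samples = 120, n_warmup = 150, seed = 31)
  res <- select_k(truth$panel, k_grid = c(4, 6), mcmc = cfg)
  expect_true(all(res$report$occupied_k <= res$report$k))
  expect_lte(res$report$occupied_k[1], 3)   # two planted communities
  expect_equal(res$chosen_k, 4)
  res1 <- select_k(truth$panel, k_grid = 4, mcmc = cfg)
  expect_equal(res1$chosen_k, 4)
})
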