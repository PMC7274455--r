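test_that("trend classification follows the stated rules", {
  expect_equal(classify_community_trend(c(0.01, 0.02, 0.01)), "inactive")
  expect_equal(classify_community_trend(c(0.1, 0.9, 0.1)), "transient")
  expect_equal(classify_community_trend(c(0.1, 0.3, 0.6, 0.8)), "increasing")
  expect_equal(classify_community_trend(c(0.8, 0.9, 0.85, 0.95)), "persistent")
  expect_equal(classify_community_trend(c(0.9, 0.1, 0.9, 0.1)), "mixed")
  expect_error(classify_community_trend(c(0.1, 0.2)), "3 DIVs")
})

test_that("trend labels are invariant to padding with duplicate DIV columns", {
  curves <- list(c(0.01, 0.02, 0.01), c(0.1, 0.9, 0.1),
                 c(0.1, 0.3, 0.6, 0.8), c(0.8, 0.9, 0.85, 0.95),
                 c(0.9, 0.1, 0.9, 0.1))
  for (cv in curves) {
    base <- classify_community_trend(cv)
    expect_equal(classify_community_trend(c(cv[1], cv)), base)
    expect_equal(classify_community_trend(c(cv, cv[length(cv)])), base)
    expect_equal(classify_community_trend(rep(cv, each = 2)), base)
  }
})

test_that("inactive communities are flagged from the eta summary", {
  S <- 10
  z <- array(rep(rep(1:2, each = 4), each = S), c(S, 1, 8))
  beta <- array(0, c(S, 2, 2)); X <- array(0, c(S, 2, 2, 3))
  for (s in 1:S) {
    beta[s, , ] <- matrix(qlogis(c(0.01, 0.01, 0.01, 0.6)), 2)
  }
  fit <- manual_tsbm_fit(z, beta, X, divs = c(7, 10, 14), devices = "d1")
  summ <- relabel_by_size(fit)
  # the flagged community is the one whose every pairwise curve stays low
  flagged <- inactive_community(summ)
  expect_false(is.na(flagged))
  expect_true(all(summ$eta_mean[flagged, , ] < 0.05))

  # a single high DIV disqualifies
  beta2 <- beta
  for (s in 1:S) beta2[s, 1, 1] <- qlogis(0.9)
  X2 <- X
  fit2 <- manual_tsbm_fit(z, beta2, X2, divs = c(7, 10, 14), devices = "d1")
  summ2 <- relabel_by_size(fit2)
  expect_true(is.na(inactive_community(summ2)))
})

test_that("firing-rate versus degree behaves at the edge cases", {
  # rates exactly proportional to degree -> rho = 1
  n <- 8
  adj <- matrix(0L, n, n)
  adj[1, 2:5] <- 1L; adj[2, 3:4] <- 1L; adj[6, 7] <- 1L
  adj <- adj + t(adj); diag(adj) <- 0L
  deg <- colSums(adj)
  spikes <- lapply(setNames(seq_len(n), as.character(seq_len(n))), function(i) {
    if (deg[i] == 0) return(0.5)           # avoid empty channels, keep order
    sort(runif(deg[i] * 10, 0, 100))
  })
  set.seed(10)
  rec <- make_recording(spikes, duration = 100, device = "d1", div = 7L)
  net <- functional_network(adj, as.character(1:n), "d1", 7L)
  panel <- network_panel(list(net))
  res <- firing_rate_vs_degree(list(rec), panel)
  expect_gt(res$rho, 0.9)

  # all-equal degrees: undefined, reported as NA
  ring <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    ring[i, j] <- ring[j, i] <- 1L
  }
  netr <- functional_network(ring, as.character(1:n), "d1", 7L)
  resr <- firing_rate_vs_degree(list(rec), network_panel(list(netr)))
  expect_true(is.na(resr$rho))
})

test_that("independent rates and degrees give a CI covering zero", {
  set.seed(77)
  n <- 30
  spikes <- lapply(setNames(seq_len(n), as.character(seq_len(n))), function(i) {
    sort(runif(sample(5:50, 1), 0, 100))
  })
  rec <- make_recording(spikes, duration = 100, device = "d1", div = 7L)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(choose(n, 2), 1, 0.2)
  adj <- adj + t(adj)
  net <- functional_network(adj, as.character(1:n), "d1", 7L)
  res <- firing_rate_vs_degree(list(rec), network_panel(list(net)))
  expect_lt(res$conf_low, 0)
  expect_gt(res$conf_high, 0)
})

test_that("a full study contrasts simple and complex conditions end to end", {
  # condition A devices use 2 active communities; condition B devices
  # activate 2 extra ones (same node set, same joint model)
  divs <- c(10, 13, 17)
  kp <- kernel_params(0.2, 3, 0.01)
  n <- 20
  beta_a <- matrix(-3, 4, 4); diag(beta_a)[1:2] <- 1.5
  beta_b <- matrix(-3, 4, 4); diag(beta_b) <- 1.5
  za <- rep(c(1, 2, 1, 2), each = 5)
  zb <- rep(1:4, each = 5)
  nets <- list()
  for (i in 1:2) {
    tr <- sample_tsbm(n_nodes = n, n_devices = 1, divs = divs, k = 4,
                      kernel_in = kp, kernel_out = kp, beta = beta_a, z = za,
                      seed = 400 + i, device_ids = paste0("a", i))
    nets <- c(nets, tr$panel$networks)
  }
  for (i in 1:2) {
    tr <- sample_tsbm(n_nodes = n, n_devices = 1, divs = divs, k = 4,
                      kernel_in = kp, kernel_out = kp, beta = beta_b, z = zb,
                      seed = 500 + i, device_ids = paste0("b", i))
    nets <- c(nets, tr$panel$networks)
  }
  panel <- network_panel(nets)
  out_dir <- withr::local_tempdir()
  cfg <- study_config(
    conditions = list(simple = c("a1", "a2"), complex = c("b1", "b2")),
    panel = panel, k = 6,
    mcmc = mcmc_config(n_chains = 1, n_samples = 150, n_warmup = 250,
                       seed = 13),
    out_dir = out_dir, seed = 13)
  rep1 <- run_study(cfg)
  occ_a <- rep1$conditions$simple$community_counts$n_communities
  occ_b <- rep1$conditions$complex$community_counts$n_communities
  expect_gt(mean(occ_b), mean(occ_a))
  expect_true(all(rowSums(rep1$summary$community_counts) == n))
  expect_true(file.exists(file.path(out_dir, "community_counts.csv")))
  expect_true(file.exists(file.path(out_dir, "eta_curves.csv")))
  expect_true(file.exists(file.path(out_dir, "diagnostics.json")))

  # determinism: same config, same tables
  rep2 <- run_study(cfg)
  expect_equal(rep2$summary$community_counts, rep1$summary$community_counts)
  expect_equal(rep2$eta_curves, rep1$eta_curves)

  # missing device is named
  bad <- study_config(conditions = list(x = "nope"), panel = panel,
                      mcmc = cfg$mcmc, seed = 1)
  expect_error(run_study(bad), "nope")
})
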