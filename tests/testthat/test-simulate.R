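test_that("simulation is reproducible and adjacencies are valid graphs", {
  a <- validation_scenario(seed = 9)
  b <- validation_scenario(seed = 9)
  for (key in names(a$panel$networks)) {
    expect_identical(a$panel$networks[[key]]$adjacency,
                     b$panel$networks[[key]]$adjacency)
  }
  expect_equal(a$params$X, b$params$X)
  for (nw in a$panel$networks) {
    adj <- nw$adjacency
    expect_true(all(adj %in% 0:1))
    expect_equal(adj, t(adj))
    expect_true(all(diag(adj) == 0))
  }
})

test_that("eta is the sigmoid of beta plus the latent path, symmetric in pairs", {
  truth <- validation_scenario(seed = 4)
  p <- truth$params
  for (tt in seq_along(p$divs)) {
    expect_equal(p$eta[, , tt], plogis(p$beta + p$X[, , tt]))
    expect_equal(p$eta[, , tt], t(p$eta[, , tt]))
    expect_equal(p$X[, , tt], t(p$X[, , tt]))
  }
  expect_equal(sum(p$pi), 1)
})

test_that("extreme negative offsets give empty graphs", {
  truth <- sample_tsbm(n_nodes = 10, n_devices = 2, divs = c(7, 10), k = 2,
                       beta = matrix(-50, 2, 2), z = rep(1:2, each = 5),
                       seed = 8)
  for (nw in truth$panel$networks) expect_equal(sum(nw$adjacency), 0L)
})

test_that("cross-community edge counts match the closed-form expectation", {
  # X pinned near zero by a tiny output scale, so eta_12 = plogis(-2)
  kp0 <- kernel_params(1e-8, 3, 0)
  truth <- sample_tsbm(n_nodes = 20, n_devices = 300, divs = 14, k = 2,
                       kernel_in = kp0, kernel_out = kp0,
                       beta = matrix(c(0.5, -2, -2, 0.7), 2),
                       z = rep(1:2, each = 10), seed = 77)
  cross <- vapply(truth$panel$networks, function(nw) {
    sum(nw$adjacency[1:10, 11:20])
  }, 1)
  expected <- 100 * plogis(-2)                  # 11.92 per device
  se <- sqrt(100 * plogis(-2) * (1 - plogis(-2)) / length(cross))
  expect_lt(abs(mean(cross) - expected), 3 * se)
})

test_that("simulated panels under the validation parameters are modular", {
  ok <- vapply(1:50, function(sd) {
    truth <- validation_scenario(seed = 6000 + sd)
    w <- b <- 0; nw_ <- 0; nb_ <- 0
    for (nw in truth$panel$networks) {
      adj <- nw$adjacency
      blocks <- list(1:10, 11:20)
      for (bl in blocks) {
        sub <- adj[bl, bl]
        w <- w + sum(sub[upper.tri(sub)]); nw_ <- nw_ + sum(upper.tri(sub))
      }
      b <- b + sum(adj[1:10, 11:20]); nb_ <- nb_ + 100
    }
    (w / nw_) > (b / nb_)
  }, TRUE)
  expect_true(all(ok))
})

test_that("static SBM simulation reduces to known special cases", {
  # k = 1 is Erdos-Renyi at eta_11
  one <- sample_static_sbm(n_nodes = 60, n_devices = 30, k = 1,
                           eta = matrix(0.3, 1, 1), z = rep(1, 60), seed = 3)
  dens <- vapply(one$networks, function(nw) {
    mean(nw$adjacency[upper.tri(nw$adjacency)])
  }, 1)
  se <- sqrt(0.3 * 0.7 / (30 * choose(60, 2)))
  expect_lt(abs(mean(dens) - 0.3), 4 * se)

  # near-degenerate eta gives disjoint cliques matching z
  cl <- sample_static_sbm(n_nodes = 12, n_devices = 1, k = 3,
                          eta = matrix(1e-12, 3, 3) + diag(3) * (1 - 2e-12),
                          z = rep(1:3, each = 4), seed = 5)
  adj <- cl$networks[[1]]$adjacency
  same <- outer(rep(1:3, each = 4), rep(1:3, each = 4), "==")
  diag(same) <- FALSE
  expect_equal(adj == 1L, same, ignore_attr = TRUE)

  # a = b = 1 draws eta uniformly
  set.seed(10)
  draws <- replicate(400, {
    sample_static_sbm(n_nodes = 2, n_devices = 1, k = 1, a = 1, b = 1,
                      z = matrix(1, 1, 2))$params$eta[1, 1]
  })
  expect_gt(stats::ks.test(draws, "punif")$p.value, 1e-3)
})

test_that("log-likelihood matches closed forms", {
  # eta = 0.5 everywhere
  truth <- validation_scenario(seed = 12)
  p <- truth$params
  p0 <- tsbm_params(p$k, p$alpha, p$pi, p$z, p$kernel_in, p$kernel_out,
                    beta = matrix(0, 2, 2), divs = p$divs,
                    X = array(0, dim(p$X)))
  n_terms <- length(truth$panel$networks) * choose(20, 2)
  expect_equal(log_likelihood(truth$panel, p0), -n_terms * log(2))

  # single dyad with an edge under eta = 0.9
  net <- functional_network(matrix(c(0, 1, 1, 0), 2), c("a", "b"), "d1", 7L)
  panel1 <- network_panel(list(net))
  p1 <- tsbm_params(1, 1, 1, matrix(1, 1, 2), kernel_params(0.25, 3, 0.01),
                    kernel_params(0.25, 3, 0.01),
                    beta = matrix(qlogis(0.9), 1, 1), divs = 7,
                    X = array(0, c(1, 1, 1)))
  expect_equal(log_likelihood(panel1, p1), log(0.9))
})

test_that("the generating parameters beat corrupted ones in likelihood", {
  set.seed(55)
  wins <- vapply(1:20, function(i) {
    truth <- sample_tsbm(n_nodes = 16, n_devices = 2, divs = c(7, 10, 14),
                         k = 2, beta = matrix(c(1, -1.5, -1.5, 0.8), 2),
                         z = rep(1:2, each = 8), seed = 900 + i)
    p <- truth$params
    pc <- tsbm_params(p$k, p$alpha, p$pi, p$z, p$kernel_in, p$kernel_out,
                      beta = -p$beta, divs = p$divs, X = p$X)
    log_likelihood(truth$panel, p) > log_likelihood(truth$panel, pc)
  }, TRUE)
  expect_gt(mean(wins), 0.9)
})

test_that("empirical block densities approach eta as devices grow", {
  kp <- kernel_params(0.25, 3, 0.01)
  truth <- sample_tsbm(n_nodes = 20, n_devices = 200,
                       divs = c(11, 14, 18, 21, 25, 28, 31), k = 2,
                       kernel_in = kp, kernel_out = kp,
                       beta = matrix(c(0.5, -2, -2, 0.7), 2),
                       z = rep(1:2, each = 10), seed = 31)
  eta <- truth$params$eta
  divs <- truth$params$divs
  for (tt in seq_along(divs)) {
    m11 <- m12 <- m22 <- 0
    for (d in seq_len(200)) {
      adj <- tsbm:::panel_get(truth$panel, paste0("dev", d), divs[tt])$adjacency
      m11 <- m11 + sum(adj[1:10, 1:10][upper.tri(adj[1:10, 1:10])])
      m22 <- m22 + sum(adj[11:20, 11:20][upper.tri(adj[11:20, 11:20])])
      m12 <- m12 + sum(adj[1:10, 11:20])
    }
    for (spec in list(list(m11, 45 * 200, eta[1, 1, tt]),
                      list(m12, 100 * 200, eta[1, 2, tt]),
                      list(m22, 45 * 200, eta[2, 2, tt]))) {
      phat <- spec[[1]] / spec[[2]]
      se <- sqrt(spec[[3]] * (1 - spec[[3]]) / spec[[2]])
      expect_lt(abs(phat - spec[[3]]), 3.5 * se)
    }
  }
})
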