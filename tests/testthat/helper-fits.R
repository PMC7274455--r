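# Shared fixtures for the inference tests. Expensive fits are memoised in a
# session-local cache so several test files can reuse them.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# small, strongly separated two-block panel plus a short fit
small_truth <- function() {
  cached("small_truth", {
    sample_tsbm(
      n_nodes = 12, n_devices = 2, divs = c(10, 13, 17, 20), k = 2,
      kernel_in = kernel_params(0.25, 3, 0.01),
      kernel_out = kernel_params(0.25, 3, 0.01),
      beta = matrix(c(1.5, -2.5, -2.5, 1.2), 2, 2),
      z = rep(1:2, each = 6), seed = 301)
  })
}

small_fit <- function() {
  cached("small_fit", {
    fit_tsbm(small_truth()$panel, k = 2,
             mcmc = mcmc_config(n_chains = 2, n_samples = 250,
                                n_warmup = 250, seed = 11))
  })
}

# the synthetic validation experiment: panel generated under the study's
# stated conditions, fitted with two chains
validation_fit <- function() {
  cached("validation_fit", {
    truth <- validation_scenario(seed = 2024)
    fit <- fit_tsbm(truth$panel, k = 2,
                    mcmc = mcmc_config(n_chains = 2, n_samples = 1000,
                                       n_warmup = 1000, seed = 12))
    list(truth = truth, fit = fit,
         summary = relabel_by_size(fit, reference = truth$params$z))
  })
}

# hand-built minimal sbm_fit objects for label-invariance and closed-form
# checks (no sampling involved)
manual_tsbm_fit <- function(z_draws, beta_draws, X_draws, divs, devices,
                            kernel = NULL, chain = NULL) {
  S <- dim(z_draws)[1]; k <- dim(beta_draws)[2]
  n <- dim(z_draws)[3]
  if (is.null(kernel)) {
    kernel <- matrix(rep(c(0.25, 3, 0.25, 3), each = S), S, 4,
                     dimnames = list(NULL, c("sigma_in", "ell_in",
                                             "sigma_out", "ell_out")))
  }
  draws <- list(z = z_draws, beta = beta_draws, X = X_draws,
                kernel = kernel,
                pi = matrix(1 / k, S, k), loglik = numeric(S))
  structure(
    list(model = "tsbm", k = k, devices = devices, divs = divs,
         channels = as.character(seq_len(n)), n = n,
         config = mcmc_config(n_chains = 1, n_samples = S, seed = 1),
         priors = tsbm_priors(),
         draws = draws, chain = chain %||% rep(1L, S),
         diagnostics = tibble::tibble(parameter = character(),
                                      mean = numeric(), sd = numeric(),
                                      rhat = numeric(), ess = numeric())),
    class = c("tsbm_fit", "sbm_fit"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
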