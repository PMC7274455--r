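#' Squared-exponential kernel with a diagonal nugget
#'
#' Covariance of the latent connectivity process between two days in vitro
#' (DIV). The kernel is \eqn{\kappa(t, t') = \sigma^2 \exp(-(t - t')^2 /
#' (2\ell^2))}, with the nugget \eqn{\epsilon} added only when \eqn{t = t'},
#' so that Gram matrices over a DIV grid are positive definite.
#'
#' @param t,t_prime numeric vectors of DIVs (recycled).
#' @param kp a [kernel_params()] object (or list with `sigma`, `ell`, `eps`).
#' @return covariance values, same length as the longer of `t`, `t_prime`.
#' @examples
#' se_kernel(11, 11, kernel_params(sigma = 0.25, ell = 3, eps = 0.01))
#' @export
se_kernel <- function(t, t_prime, kp) {
  kp <- as_kernel_params(kp)
  d <- t - t_prime
  kp$sigma^2 * exp(-d^2 / (2 * kp$ell^2)) + ifelse(d == 0, kp$eps, 0)
}

#' Kernel hyperparameters
#'
#' @param sigma output scale, > 0.
#' @param ell length scale in DIV units, > 0.
#' @param eps nugget variance, >= 0 (0 gives exact interpolation).
#' @return a `kernel_params` list.
#' @export
kernel_params <- function(sigma, ell, eps = 0) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(ell, "ell", lower = 0, strict_lower = TRUE)
  check_number(eps, "eps", lower = 0)
  structure(list(sigma = sigma, ell = ell, eps = eps), class = "kernel_params")
}

as_kernel_params <- function(x) {
  if (inherits(x, "kernel_params")) return(x)
  kernel_params(x$sigma, x$ell, x$eps %||% 0)
}

#' Gram matrix of the squared-exponential kernel over a DIV grid
#'
#' @inheritParams se_kernel
#' @param divs numeric vector of DIVs.
#' @return a symmetric positive-definite matrix (for `eps > 0` and distinct
#'   DIVs).
#' @export
se_gram <- function(divs, kp) {
  kp <- as_kernel_params(kp)
  d <- outer(divs, divs, "-")
  kp$sigma^2 * exp(-d^2 / (2 * kp$ell^2)) + diag(kp$eps, length(divs))
}

# Lower Cholesky factor of the Gram matrix, with a tiny jitter fallback so
# eps = 0 grids remain factorizable.
se_chol <- function(divs, kp) {
  g <- se_gram(divs, kp)
  ch <- tryCatch(chol(g), error = function(e) chol(g + diag(1e-10, nrow(g))))
  t(ch)
}

#' Logistic link from offset and latent value to an edge probability
#'
#' The connection probability between communities i and j at time t is
#' `plogis(beta_ij + x_ij(t))`, strictly inside (0, 1).
#'
#' @param beta_ij community-pair offset (logit scale).
#' @param x latent Gaussian-process value.
#' @return probabilities in (0, 1).
#' @examples
#' link_eta(0, 0)    # 0.5
#' link_eta(-2, 0)   # cross-community level used in the validation scenario
#' @export
link_eta <- function(beta_ij, x) {
  plogis(beta_ij + x)
}
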