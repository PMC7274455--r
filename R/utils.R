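#' @importFrom stats plogis qlogis rnorm runif rbeta rgamma dnorm cor sd
#'   quantile setNames aggregate isoreg cor.test optimize var
#' @importFrom rlang .data
#' @import tibble
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Numerically stable log Bernoulli mass on the logit scale
#'
#' @param q logit of the success probability
#' @param a observation in {0, 1}
#' @noRd
log_bern_logit <- function(q, a) {
  # log eta = plogis(q, log = TRUE); log(1 - eta) = plogis(-q, log = TRUE)
  a * plogis(q, log.p = TRUE) + (1 - a) * plogis(-q, log.p = TRUE)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x), call. = FALSE)
  }
  invisible(x)
}

symmetrize_upper <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
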