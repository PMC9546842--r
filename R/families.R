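FAMILIES <- c("normal", "poisson", "zip", "hurdle")

#' Normalize an observation-family name
#'
#' Accepted names are `normal`, `poisson`, `zip`, `zap` and `hurdle`.
#' `zap` (zero-altered Poisson) is an alias for `hurdle`: in the count-model
#' literature the zero-altered and hurdle Poisson are the same family.
#'
#' @param family character name.
#' @return Canonical family name.
#' @export
normalize_family <- function(family) {
  family <- tolower(as.character(family)[1])
  if (family == "zap") family <- "hurdle"
  if (!family %in% FAMILIES)
    stop("unknown family '", family, "'; allowed: ",
         paste(c(FAMILIES, "zap"), collapse = ", "))
  family
}

#' Log-likelihood of a count vector under a latent linear predictor
#'
#' Computes sum_i log p(y_i | .) for the supported observation families with
#' log link (identity for `normal`):
#' \itemize{
#'   \item `poisson`: y log(lambda) - lambda - log(y!), lambda = exp(l).
#'   \item `zip`: log( pi 1\{y=0\} + (1 - pi) Pois(y | lambda) ).
#'   \item `hurdle`: log(pi) for y = 0; log(1 - pi) + log Pois(y | lambda) -
#'     log(1 - exp(-lambda)) for y > 0 (zero-truncated Poisson).
#'   \item `normal`: Gaussian density of y about l with variance `sigma2`.
#' }
#' All terms are evaluated in log space and remain finite for lambda spanning
#' many orders of magnitude.
#'
#' @param family family name (see [normalize_family]).
#' @param y observed counts (raw responses for `normal`).
#' @param l latent linear predictor, same length as `y`.
#' @param pi scalar structural-zero probability in \[0, 1\] (`zip`/`hurdle`
#'   only; must be `NULL` otherwise).
#' @param sigma2 observation variance (`normal` only).
#' @return Scalar log-likelihood.
#' @export
family_loglik <- function(family, y, l, pi = NULL, sigma2 = NULL) {
  family <- normalize_family(family)
  if (length(y) != length(l)) stop("y and l must have equal length")
  if (family %in% c("poisson", "normal") && !is.null(pi))
    stop("pi must not be supplied for the ", family, " family")
  if (family %in% c("zip", "hurdle")) {
    if (is.null(pi)) stop("pi is required for the ", family, " family")
    if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  }
  sum(family_loglik_pointwise(family, y, l, pi, sigma2))
}

## Per-observation log-density; shared by the full-likelihood and the
## site-wise Metropolis update.
family_loglik_pointwise <- function(family, y, l, pi = NULL, sigma2 = NULL) {
  switch(family,
    poisson = stats::dpois(y, exp(l), log = TRUE),
    normal = {
      if (is.null(sigma2)) stop("sigma2 is required for the normal family")
      stats::dnorm(y, mean = l, sd = sqrt(sigma2), log = TRUE)
    },
    zip = {
      if (any(y < 0 | y != floor(y))) stop("zip requires integer counts >= 0")
      lp <- stats::dpois(y, exp(l), log = TRUE)
      out <- log1p(-pi) + lp
      zero <- y == 0
      if (any(zero)) {
        # log(pi + (1-pi) e^{-lambda}) via log-sum-exp; handles pi in {0,1}
        a <- rep(log(pi), sum(zero))
        b <- log1p(-pi) + lp[zero]
        out[zero] <- pmax(a, b) + log1p(exp(-abs(a - b)))
        out[zero][is.infinite(a) & is.infinite(b)] <- -Inf
        if (pi == 1) out[zero] <- 0
        if (pi == 0) out[zero] <- lp[zero]
      }
      if (pi == 1 && any(!zero)) out[!zero] <- -Inf
      out
    },
    hurdle = {
      if (any(y < 0 | y != floor(y))) stop("hurdle requires integer counts >= 0")
      lambda <- exp(l)
      out <- numeric(length(y))
      zero <- y == 0
      out[zero] <- log(pi)
      if (any(!zero)) {
        # zero-truncated Poisson: Pois(y|lambda) / (1 - e^{-lambda});
        # -log(1 - e^{-lambda}) = -log(-expm1(-lambda)), stable for small lambda
        out[!zero] <- log1p(-pi) + stats::dpois(y[!zero], lambda[!zero], log = TRUE) -
          log(-expm1(-lambda[!zero]))
      }
      out
    },
    stop("unknown family"))
}

#' Deviance (-2 log-likelihood) of a fitted latent predictor
#'
#' @inheritParams family_loglik
#' @return Scalar deviance, `-2 * family_loglik(...)`.
#' @export
family_deviance <- function(family, y, l, pi = NULL, sigma2 = NULL) {
  -2 * family_loglik(family, y, l, pi = pi, sigma2 = sigma2)
}
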