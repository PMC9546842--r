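#' MCMC sampler configuration
#'
#' Defaults reproduce the full analysis protocol: 2,000,000 sweeps, the first
#' 100,000 discarded as burn-in, and every tenth retained draw kept
#' thereafter. Tests and exploratory fits use much shorter chains.
#'
#' @param iterations total number of MCMC sweeps.
#' @param burn_in sweeps discarded before retention; must be < `iterations`.
#' @param thin retain one draw per `thin` sweeps after burn-in.
#' @param seed integer RNG seed; identical seed and inputs give identical chains.
#' @param latent_step initial random-walk proposal scale for the latent
#'   update, or `"adaptive"` (Robbins-Monro adaptation during burn-in toward
#'   `target_accept`, frozen afterwards).
#' @param target_accept target site-wise acceptance rate in (0, 1).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(iterations = 2e6, burn_in = 1e5, thin = 10,
                           seed = 1L, latent_step = "adaptive",
                           target_accept = 0.44) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1L) stop("thin must be >= 1")
  if (!identical(latent_step, "adaptive")) {
    latent_step <- as.numeric(latent_step)
    if (latent_step <= 0) stop("latent_step must be positive or 'adaptive'")
  }
  if (target_accept <= 0 || target_accept >= 1)
    stop("target_accept must lie in (0, 1)")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), latent_step = latent_step,
                 target_accept = target_accept),
            class = "sampler_config")
}

#' Retained draw count implied by a sampler configuration
#' @param config a [sampler_config].
#' @export
n_retained <- function(config) {
  (config$iterations - config$burn_in) %/% config$thin
}

#' Model specification: family, blocks and prior hyperparameters
#'
#' Fixed effects get a flat Gaussian prior N(0, `prior_var_b` I). Each
#' variance component sigma2_k ~ IG(alpha_k/2, alpha_k beta_k/2). Defaults
#' follow the published protocol: alpha = beta = 0.001 for the four
#' random-effect blocks, alpha_e = 0.001 and beta_e = 1e8 for the log-scale
#' error. The beta_e default makes the error prior informative at small n;
#' pass `hyper = list(e = c(0.001, 0.001))` for a weak error prior.
#'
#' @param family observation family (see [normalize_family]).
#' @param include_blocks random-effect blocks to include.
#' @param prior_var_b Gaussian prior variance of the fixed effects.
#' @param hyper named list of `(alpha, beta)` pairs for `u1..u4` and `e`;
#'   missing entries take the defaults above.
#' @param pi_prior Beta(a, b) prior for the structural-zero probability
#'   (`zip`/`hurdle` only).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = "poisson",
                       include_blocks = c("u1", "u2", "u3", "u4"),
                       prior_var_b = 1e8,
                       hyper = list(),
                       pi_prior = c(1, 1)) {
  family <- normalize_family(family)
  if (length(include_blocks))
    include_blocks <- match.arg(include_blocks, c("u1", "u2", "u3", "u4"),
                                several.ok = TRUE)
  if (prior_var_b <= 0) stop("prior_var_b must be > 0")
  h <- list(u1 = c(0.001, 0.001), u2 = c(0.001, 0.001),
            u3 = c(0.001, 0.001), u4 = c(0.001, 0.001),
            e = c(0.001, 1e8))
  for (k in names(hyper)) {
    if (!k %in% names(h)) stop("unknown hyperparameter block '", k, "'")
    if (length(hyper[[k]]) != 2L || any(hyper[[k]] <= 0))
      stop("hyper$", k, " must be a positive (alpha, beta) pair")
    h[[k]] <- as.numeric(hyper[[k]])
  }
  if (length(pi_prior) != 2L || any(pi_prior <= 0))
    stop("pi_prior must be a positive (a, b) pair")
  structure(list(family = family, include_blocks = include_blocks,
                 prior_var_b = prior_var_b, hyper = h,
                 pi_prior = as.numeric(pi_prior)),
            class = "model_spec")
}

#' Draw a variance component from its inverse-gamma full conditional
#'
#' With prior sigma2 ~ IG(alpha/2, alpha beta/2) and effects
#' u ~ N(0, sigma2 I), the full conditional is
#' IG(alpha/2 + q/2, alpha beta/2 + u'u / 2), q = length(u). An empty block
#' (q = 0) returns a prior draw.
#'
#' @param u_block current effect vector.
#' @param hyper numeric `(alpha, beta)` with both entries > 0.
#' @param n_draws number of draws (default 1; >1 is used by tests).
#' @return Sampled variance(s), strictly positive.
#' @export
update_variance <- function(u_block, hyper, n_draws = 1L) {
  alpha <- hyper[[1]]; beta <- hyper[[2]]
  if (alpha <= 0 || beta <= 0) stop("hyperparameters must be positive")
  q <- length(u_block)
  shape <- alpha / 2 + q / 2
  rate <- alpha * beta / 2 + sum(u_block^2) / 2
  1 / stats::rgamma(n_draws, shape = shape, rate = rate)
}

#' Draw a Gaussian effect block from its full conditional
#'
#' For the conditional model resid = M theta + e, e ~ N(0, sigma2_e I) with
#' prior theta ~ N(0, sigma2_block I), draws from
#' N(V M' resid / sigma2_e, V), V = (M'M / sigma2_e + I / sigma2_block)^-1,
#' via a Cholesky factorization of the precision (no explicit inverse).
#' Used both for the fixed effects (with `sigma2_block = prior_var_b`) and
#' for the random-effect blocks.
#'
#' @param resid working residual: the latent vector minus all other model
#'   components.
#' @param M design matrix of the block (dense or sparse incidence).
#' @param sigma2_block prior/block variance (> 0).
#' @param sigma2_e error variance (> 0).
#' @return One draw of the block effect vector.
#' @export
update_gaussian_block <- function(resid, M, sigma2_block, sigma2_e) {
  if (sigma2_block <= 0 || sigma2_e <= 0) stop("variances must be positive")
  q <- ncol(M)
  prec <- as.matrix(Matrix::crossprod(M)) / sigma2_e
  diag(prec) <- diag(prec) + 1 / sigma2_block
  R <- tryCatch(chol(prec), error = function(e)
    stop("singular full-conditional precision for block with ", q, " levels"))
  rhs <- as.numeric(Matrix::crossprod(M, resid)) / sigma2_e
  mean <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  drop(mean + backsolve(R, stats::rnorm(q)))
}

## Fast equivalent of update_gaussian_block for 0/1 incidence blocks, where
## M'M is diagonal with the per-level replication counts. `s` holds the
## per-level sums of the working residual (see seg_sums).
update_incidence_block <- function(s, level_counts, sigma2_block, sigma2_e) {
  prec <- level_counts / sigma2_e + 1 / sigma2_block
  mean <- (s / sigma2_e) / prec
  stats::rnorm(length(s), mean, sqrt(1 / prec))
}

## Per-level sums of x for an incidence index, via cumulative sums over the
## pre-sorted order: ord = order(index), ends = cumsum(tabulate(index, q)).
seg_sums <- function(x, ord, ends) {
  cs <- c(0, cumsum(x[ord]))[ends + 1L]  # ends may be 0 for empty levels
  cs - c(0, cs[-length(cs)])
}

#' Site-wise Metropolis random-walk update of the latent vector
#'
#' Each latent site l_i independently targets
#' p(l_i) proportional to family(y_i | l_i, pi)^weight_i * N(l_i | mu_i, sigma2_e)
#' via a Gaussian random-walk proposal. With `weight = 0` the family term
#' drops and the chain targets the Gaussian prior exactly (used as a
#' correctness check). Detailed balance holds site-wise because the proposal
#' is symmetric.
#'
#' @param y observed counts.
#' @param l current latent vector.
#' @param mu conditional (systematic) mean vector.
#' @param sigma2_e error variance.
#' @param family count family evaluated at the sites (`poisson`, `zip`,
#'   `hurdle`).
#' @param pi structural-zero probability (`zip`/`hurdle`).
#' @param step proposal standard deviation (scalar or per-site vector).
#' @param weight likelihood weight per site (scalar or vector in \[0, 1\]).
#' @return List with `l` (updated vector) and `accept` (logical per site).
#' @export
update_latent <- function(y, l, mu, sigma2_e, family = "poisson", pi = NULL,
                          step = 0.5, weight = 1) {
  if (any(!is.finite(mu))) stop("non-finite conditional mean in latent update")
  family <- normalize_family(family)
  n <- length(l)
  prop <- l + stats::rnorm(n, 0, step)
  w <- rep_len(weight, n)
  ll_cur <- ll_prop <- numeric(n)
  active <- w > 0
  if (any(active)) {
    ll_cur[active] <- mh_loglik_kernel(family, y[active], l[active], pi)
    ll_prop[active] <- mh_loglik_kernel(family, y[active], prop[active], pi)
  }
  log_ratio <- w * (ll_prop - ll_cur) +
    ((l - mu)^2 - (prop - mu)^2) / (2 * sigma2_e)
  accept <- log(stats::runif(n)) < log_ratio
  l[accept] <- prop[accept]
  list(l = l, accept = accept)
}

## Family log-likelihood up to terms constant in l (log(y!) and pure-pi
## terms cancel in the Metropolis ratio); agrees with
## family_loglik_pointwise up to a per-site constant.
mh_loglik_kernel <- function(family, y, l, pi = NULL) {
  lambda <- exp(l)
  switch(family,
    poisson = y * l - lambda,
    zip = {
      out <- y * l - lambda
      zero <- y == 0
      if (any(zero) && pi > 0)
        out[zero] <- log(pi + (1 - pi) * exp(-lambda[zero]))
      out
    },
    hurdle = {
      out <- numeric(length(y))
      pos <- y > 0
      out[pos] <- y[pos] * l[pos] - lambda[pos] - log(-expm1(-lambda[pos]))
      out
    },
    stop("unsupported family in latent update: ", family))
}

#' Update the zero-modification layer of zip and hurdle models
#'
#' For `zip`, draws the structural-zero indicators
#' z_i | rest ~ Bernoulli( pi / (pi + (1 - pi) exp(-lambda_i)) ) at y_i = 0
#' (z_i = 0 wherever y_i > 0), then pi | z ~ Beta(a + sum z, b + n - sum z).
#' For `hurdle`, pi | y ~ Beta(a + #\{y = 0\}, b + #\{y > 0\}) directly.
#'
#' @param y observed counts.
#' @param l latent vector (lambda = exp(l)).
#' @param z current indicators (`zip`; ignored for `hurdle`).
#' @param pi current zero probability.
#' @param pi_prior Beta(a, b) prior parameters.
#' @param family `"zip"` or `"hurdle"`.
#' @return List with `z` (updated indicators, `NULL` for hurdle) and `pi`.
#' @export
update_zero_layer <- function(y, l, z = NULL, pi, pi_prior, family) {
  family <- normalize_family(family)
  if (!family %in% c("zip", "hurdle"))
    stop("update_zero_layer applies to zip and hurdle families only")
  a <- pi_prior[1]; b <- pi_prior[2]
  n <- length(y)
  if (family == "zip") {
    z <- integer(n)
    zero <- y == 0
    if (any(zero)) {
      # P(z=1 | y=0) on the log scale: pi vs (1-pi) e^{-lambda}
      la <- log(pi)
      lb <- log1p(-pi) - exp(l[zero])
      p1 <- 1 / (1 + exp(lb - la))
      z[zero] <- stats::rbinom(sum(zero), 1L, p1)
    }
    pi_new <- stats::rbeta(1, a + sum(z), b + n - sum(z))
    list(z = z, pi = pi_new)
  } else {
    n0 <- sum(y == 0)
    list(z = NULL, pi = stats::rbeta(1, a + n0, b + n - n0))
  }
}

#' Run the Metropolis-within-Gibbs chain for the latent-Gaussian count model
#'
#' Executes the full update cycle per sweep — latent vector (count families),
#' fixed effects, each included random-effect block, all variance components,
#' and the zero layer for zip/hurdle — and retains one thinned draw per
#' `config$thin` sweeps after `config$burn_in`. For the `normal` family the
#' response is modelled directly as y = Xb + sum Z_k u_k + e with sigma2_e the
#' observation variance (no latent layer). Identical seed and inputs yield a
#' bit-identical result.
#'
#' @param table a [count_table] (one grain; a mixed-grain table is pooled with
#'   a warning).
#' @param spec a [model_spec].
#' @param config a [sampler_config].
#' @param design optionally, a prebuilt `factorial_design` (must match the
#'   table).
#' @return An object of class `chain_result`: retained draws of `b`, `u`
#'   (per block), `sigma2`, `l`, `pi`, plus the design, spec, config and the
#'   mean latent acceptance rate.
#' @export
run_chain <- function(table, spec, config, design = NULL) {
  stopifnot(inherits(table, "count_table"), inherits(spec, "model_spec"),
            inherits(config, "sampler_config"))
  if (length(unique(table$metadata$grain)) > 1L)
    warning("count table contains multiple grains; fitting a pooled model")
  if (is.null(design))
    design <- build_design(table, include_blocks = spec$include_blocks)
  set.seed(config$seed)

  y <- design$y
  X <- design$X
  n <- design$n
  p <- ncol(X)
  family <- spec$family
  blocks <- names(design$Z)
  idx <- design$index
  nlev <- vapply(design$Z, ncol, 0L)
  lev_counts <- lapply(design$Z, function(Z) as.numeric(Matrix::colSums(Z)))
  ord <- lapply(idx, order)
  ends <- lapply(blocks, function(k) cumsum(tabulate(idx[[k]], nlev[[k]])))
  names(ends) <- blocks
  XtX <- crossprod(X)

  if (family == "poisson" && all(y == 0))
    warning("all counts are zero; the Poisson posterior concentrates at small lambda")

  # neutral starts: quasi-likelihood intercept, zero effects, unit variances
  b <- c(log(mean(y) + 0.5), rep(0, p - 1L))
  if (family == "normal") b[1] <- mean(y)
  u <- lapply(blocks, function(k) numeric(nlev[[k]])); names(u) <- blocks
  sigma2 <- stats::setNames(rep(1, length(blocks) + 1L), c(blocks, "e"))
  l <- if (family == "normal") drop(X %*% b) else log(y + 0.5)
  pi_cur <- if (family %in% c("zip", "hurdle"))
    min(max(mean(y == 0), 0.02), 0.98) else NULL

  adaptive <- identical(config$latent_step, "adaptive")
  step <- rep(if (adaptive) 0.8 else config$latent_step, n)

  n_keep <- n_retained(config)
  draws <- list(
    b = matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X))),
    u = lapply(blocks, function(k) matrix(NA_real_, n_keep, nlev[[k]])),
    sigma2 = matrix(NA_real_, n_keep, length(sigma2),
                    dimnames = list(NULL, names(sigma2))),
    l = matrix(NA_real_, n_keep, n),
    pi = if (!is.null(pi_cur)) numeric(n_keep) else NULL
  )
  names(draws$u) <- blocks

  zu <- lapply(blocks, function(k) u[[k]][idx[[k]]]); names(zu) <- blocks
  sum_zu <- function() {
    if (!length(blocks)) return(numeric(n))
    Reduce(`+`, zu)
  }
  fit_fixed <- drop(X %*% b)
  kept <- 0L
  acc_sum <- 0; acc_n <- 0L

  for (sweep in seq_len(config$iterations)) {
    zt <- sum_zu()

    if (family != "normal") {
      upd <- update_latent(y, l, fit_fixed + zt, sigma2[["e"]],
                           family = family, pi = pi_cur, step = step)
      l <- upd$l
      if (sweep <= config$burn_in && adaptive) {
        gain <- 1 / max(10, sweep)^0.6
        step <- step * exp(gain * (as.numeric(upd$accept) - config$target_accept))
        step <- pmin(pmax(step, 1e-3), 50)
      } else {
        acc_sum <- acc_sum + mean(upd$accept); acc_n <- acc_n + 1L
      }
    }
    target <- if (family == "normal") y else l

    # fixed effects: conjugate Gaussian with flat prior N(0, prior_var_b I)
    resid <- target - zt
    prec <- XtX / sigma2[["e"]]
    diag(prec) <- diag(prec) + 1 / spec$prior_var_b
    R <- chol(prec)
    rhs <- crossprod(X, resid) / sigma2[["e"]]
    bmean <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    b <- drop(bmean + backsolve(R, stats::rnorm(p)))
    fit_fixed <- drop(X %*% b)

    for (k in blocks) {
      resid <- target - fit_fixed - (zt - zu[[k]])
      s <- seg_sums(resid, ord[[k]], ends[[k]])
      u[[k]] <- update_incidence_block(s, lev_counts[[k]],
                                       sigma2[[k]], sigma2[["e"]])
      zu_new <- u[[k]][idx[[k]]]
      zt <- zt - zu[[k]] + zu_new
      zu[[k]] <- zu_new
    }

    for (k in blocks)
      sigma2[[k]] <- update_variance(u[[k]], spec$hyper[[k]])
    e_vec <- target - fit_fixed - zt
    he <- spec$hyper$e
    sigma2[["e"]] <- 1 / stats::rgamma(1, he[1] / 2 + n / 2,
                                       rate = he[1] * he[2] / 2 + sum(e_vec^2) / 2)

    if (family %in% c("zip", "hurdle")) {
      zl <- update_zero_layer(y, l, pi = pi_cur, pi_prior = spec$pi_prior,
                              family = family)
      pi_cur <- zl$pi
    }
    if (family == "normal") l <- fit_fixed + zt

    if (!all(is.finite(b)) || !all(is.finite(l)) || !all(is.finite(unlist(sigma2))))
      stop("sampler diverged (non-finite state) at sweep ", sweep)

    if (sweep > config$burn_in &&
        (sweep - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      draws$b[kept, ] <- b
      for (k in blocks) draws$u[[k]][kept, ] <- u[[k]]
      draws$sigma2[kept, ] <- unlist(sigma2)
      draws$l[kept, ] <- l
      if (!is.null(pi_cur)) draws$pi[kept] <- pi_cur
    }
  }

  structure(list(draws = draws, config = config, spec = spec,
                 design = design, family = family,
                 acceptance_rate = if (acc_n > 0) acc_sum / acc_n else NA_real_,
                 seed = config$seed),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat("chain_result:", x$family, "family,",
      nrow(x$draws$b), "retained draws,",
      "blocks:", paste(names(x$draws$u), collapse = ", "), "\n")
  if (!is.na(x$acceptance_rate))
    cat("  mean latent acceptance rate:", round(x$acceptance_rate, 3), "\n")
  invisible(x)
}
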