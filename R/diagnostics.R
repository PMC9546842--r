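## Spectral density of a chain at frequency zero, estimated from an AR fit
## (standard Geweke practice): s0 = var.pred / (1 - sum(phi))^2.
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  ord <- min(length(x) - 1L, floor(10 * log10(length(x))))
  fit <- stats::ar(x, aic = TRUE, order.max = ord)
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic for a scalar chain
#'
#' Compares the means of an early window (first `first` fraction of the
#' chain) and a late window (last `last` fraction) with a z statistic whose
#' window variances are spectral-density-at-zero estimates:
#' z = (m_A - m_B) / sqrt(s_A/n_A + s_B/n_B). Under convergence z is
#' approximately standard normal.
#'
#' @param chain numeric draw sequence (length >= 100).
#' @param first,last window fractions in (0, 1) with `first + last <= 1`.
#' @return The z score (scalar).
#' @export
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop("chain must have at least 100 draws")
  if (first <= 0 || last <= 0 || first >= 1 || last >= 1 || first + last > 1)
    stop("window fractions must lie in (0,1) and not overlap")
  a <- chain[seq_len(floor(first * n))]
  b <- chain[seq.int(n - floor(last * n) + 1L, n)]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate chain: a comparison window has zero variance")
  sa <- spectrum0_ar(a); sb <- spectrum0_ar(b)
  (mean(a) - mean(b)) / sqrt(sa / length(a) + sb / length(b))
}

#' Geweke diagnostics for every scalar parameter of a fitted chain
#'
#' @param result a `chain_result` from [run_chain].
#' @param first,last window fractions (see [geweke_z]).
#' @return A data.frame with columns `parameter` and `z`; constant chains
#'   yield `NA` with a warning. The window fractions are recorded as
#'   attributes `window_first` and `window_last`.
#' @export
geweke_report <- function(result, first = 0.1, last = 0.5) {
  stopifnot(inherits(result, "chain_result"))
  chains <- c(
    stats::setNames(asplit(result$draws$b, 2),
                    paste0("b:", colnames(result$draws$b))),
    stats::setNames(asplit(result$draws$sigma2, 2),
                    paste0("sigma2:", colnames(result$draws$sigma2))),
    if (!is.null(result$draws$pi)) list("pi" = result$draws$pi)
  )
  z <- vapply(chains, function(ch) {
    tryCatch(geweke_z(ch, first, last), error = function(e) NA_real_)
  }, 0)
  if (anyNA(z)) warning("degenerate (constant) chains yielded NA z scores")
  out <- data.frame(parameter = names(z), z = unname(z),
                    stringsAsFactors = FALSE)
  attr(out, "window_first") <- first
  attr(out, "window_last") <- last
  out
}

#' Deviance information criterion of a fitted chain
#'
#' Two conditioning variants are available; which one the published analysis
#' used is not identifiable from its description, so the report always
#' carries a `variant` flag.
#' \itemize{
#'   \item `"latent"` (conditional-on-latent, the default): the deviance is a
#'     function of the latent vector l (and pi; and sigma2_e for the normal
#'     family). Cheap and standard, but because the deviance never sees the
#'     latent prior, a count family can absorb arbitrary misfit — including
#'     structural zeros — into the free per-observation latent, which makes
#'     this variant unsuitable for comparing observation families.
#'   \item `"marginal"`: the deviance is a function of (b, u, sigma2_e, pi)
#'     with the log-scale error integrated out by Gauss-Hermite quadrature,
#'     i.e. the observation model is the Poisson-log-normal (or its
#'     zero-modified variant). This is the variant used for family selection.
#' }
#' In both cases Dbar is the posterior mean deviance over retained draws,
#' Dhat the deviance at the posterior means, pD = Dbar - Dhat and
#' DIC = Dbar + pD.
#'
#' @param result a `chain_result`.
#' @param table optional [count_table]; if supplied, its counts must match
#'   the counts the chain was fitted to.
#' @param conditioning `"latent"` or `"marginal"` (see above).
#' @param gh_nodes number of Gauss-Hermite nodes for the marginal variant.
#' @return An object of class `dic_report`: list with `dbar`, `dhat`, `pd`,
#'   `dic`, `family`, `include_blocks` and `variant`.
#' @export
compute_dic <- function(result, table = NULL,
                        conditioning = c("latent", "marginal"),
                        gh_nodes = 20L) {
  stopifnot(inherits(result, "chain_result"))
  conditioning <- match.arg(conditioning)
  nd <- nrow(result$draws$l)
  if (nd < 100L) stop("compute_dic requires at least 100 retained draws")
  y <- result$design$y
  if (!is.null(table)) {
    stopifnot(inherits(table, "count_table"))
    d2 <- build_design(table, include_blocks = result$spec$include_blocks)
    if (!identical(d2$y, y))
      stop("count table does not match the data the chain was fitted to")
  }
  family <- result$family
  has_pi <- !is.null(result$draws$pi)

  if (conditioning == "latent" || family == "normal") {
    dev_draw <- function(i) {
      family_deviance(family, y, result$draws$l[i, ],
                      pi = if (has_pi) result$draws$pi[i] else NULL,
                      sigma2 = if (family == "normal")
                        result$draws$sigma2[i, "e"] else NULL)
    }
    devs <- vapply(seq_len(nd), dev_draw, 0)
    dbar <- mean(devs)
    dhat <- family_deviance(family, y, colMeans(result$draws$l),
                            pi = if (has_pi) mean(result$draws$pi) else NULL,
                            sigma2 = if (family == "normal")
                              mean(result$draws$sigma2[, "e"]) else NULL)
    variant <- if (family == "normal") "marginal" else "conditional-on-latent"
  } else {
    mu_draws <- systematic_draws(result)
    gh <- pracma::gaussHermite(gh_nodes)
    dev_m <- function(mu, s2e, pi)
      marginal_deviance(family, y, mu, s2e, pi, gh)
    devs <- vapply(seq_len(nd), function(i)
      dev_m(mu_draws[i, ], result$draws$sigma2[i, "e"],
            if (has_pi) result$draws$pi[i] else NULL), 0)
    dbar <- mean(devs)
    dhat <- dev_m(colMeans(mu_draws), mean(result$draws$sigma2[, "e"]),
                  if (has_pi) mean(result$draws$pi) else NULL)
    variant <- "marginal"
  }
  pd <- dbar - dhat
  structure(list(dbar = dbar, dhat = dhat, pd = pd, dic = dbar + pd,
                 family = family,
                 include_blocks = result$spec$include_blocks,
                 variant = variant),
            class = "dic_report")
}

## Draws of the systematic part mu = Xb + sum_k Z_k u_k (no error term).
systematic_draws <- function(result) {
  des <- result$design
  out <- result$draws$b %*% t(des$X)
  for (k in names(result$draws$u))
    out <- out + result$draws$u[[k]][, des$index[[k]], drop = FALSE]
  out
}

## -2 log-likelihood with the log-scale error integrated out numerically:
## p(y_i) = sum_k w_k/sqrt(pi) * f(y_i | lambda = exp(mu_i + sqrt(2 s2e) x_k))
marginal_deviance <- function(family, y, mu, s2e, pi, gh) {
  n <- length(y)
  s <- sqrt(2 * s2e)
  p <- numeric(n)
  for (k in seq_along(gh$x)) {
    lam <- exp(mu + s * gh$x[k])
    fk <- switch(family,
      poisson = stats::dpois(y, lam),
      zip = {
        f <- (1 - pi) * stats::dpois(y, lam)
        f[y == 0] <- f[y == 0] + pi
        f
      },
      hurdle = {
        f <- numeric(n)
        pos <- y > 0
        f[pos] <- (1 - pi) * stats::dpois(y[pos], lam[pos]) /
          -expm1(-lam[pos])
        f[!pos] <- pi
        f
      },
      stop("unsupported family for marginal deviance: ", family))
    p <- p + gh$w[k] * fk
  }
  p <- p / sqrt(base::pi)
  -2 * sum(log(pmax(p, 1e-300)))
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("DIC (%s): %.2f  [Dbar %.2f, Dhat %.2f, pD %.2f; %s; blocks: %s]\n",
              x$family, x$dic, x$dbar, x$dhat, x$pd, x$variant,
              paste(x$include_blocks, collapse = ",")))
  invisible(x)
}

#' Pick the smallest-DIC model from a set of reports
#'
#' Ties are broken toward the model with fewer included random-effect
#' blocks, then by lexicographic family name.
#'
#' @param reports list of `dic_report` objects.
#' @return List with `winner` (the selected report) and `ranking` (data.frame
#'   ordered best to worst).
#' @export
select_model <- function(reports) {
  if (!length(reports)) stop("select_model needs a non-empty report list")
  stopifnot(all(vapply(reports, inherits, TRUE, "dic_report")))
  tab <- data.frame(
    family = vapply(reports, `[[`, "", "family"),
    blocks = vapply(reports, function(r)
      paste(r$include_blocks, collapse = ","), ""),
    n_blocks = vapply(reports, function(r) length(r$include_blocks), 0L),
    dbar = vapply(reports, `[[`, 0, "dbar"),
    pd = vapply(reports, `[[`, 0, "pd"),
    dic = vapply(reports, `[[`, 0, "dic"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$dic, tab$n_blocks, tab$family)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(winner = reports[[ord[1]]], ranking = tab)
}

#' Candidate random-effect structures respecting marginality
#'
#' All subsets of \{u1, u2, u3, u4\} in which u2/u3 require u1 and u4
#' requires u2 and u3: six candidates from `u1` alone up to the full set.
#' @return List of character vectors.
#' @export
candidate_structures <- function() {
  list(c("u1"),
       c("u1", "u2"),
       c("u1", "u3"),
       c("u1", "u2", "u3"),
       c("u1", "u2", "u3", "u4"),
       character(0))
}
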