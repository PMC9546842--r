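#' Posterior draws of every inoculant-by-period cell mean
#'
#' For each (inoculant, period) cell, each retained draw's cell value is the
#' fixed-effect part (intercept + period contrast + inoculant contrast) plus
#' the average over taxa of the included random-effect contributions for that
#' cell (taxon, taxon-by-period, taxon-by-inoculant, taxon-by-period-by-
#' inoculant). Tables of abundance report one number per cell despite
#' taxon-level random effects, so taxa are aggregated by a balanced average;
#' `scale = "response"` applies exp() draw-wise.
#'
#' @param result a `chain_result` fitted with period and inoculant fixed
#'   effects.
#' @param scale `"response"` (count scale, default) or `"latent"` (log scale).
#' @return Matrix of draws (rows) by cells (columns), with a `cells`
#'   attribute data.frame giving each column's inoculant and period.
#' @export
cell_draws <- function(result, scale = c("response", "latent")) {
  stopifnot(inherits(result, "chain_result"))
  scale <- match.arg(scale)
  des <- result$design
  periods <- des$period_levels
  inocs <- des$inoculant_levels
  taxa <- des$taxa
  TT <- length(taxa); P <- length(periods); I <- length(inocs)
  b <- result$draws$b
  nd <- nrow(b)
  Xcols <- colnames(b)

  cells <- expand.grid(period_days = periods, inoculant = inocs,
                       stringsAsFactors = FALSE)
  out <- matrix(NA_real_, nd, nrow(cells))
  colnames(out) <- paste(cells$inoculant, cells$period_days, sep = "@")

  u <- result$draws$u
  # balanced taxon averages of each block's draws, per cell component
  u1_bar <- if (!is.null(u$u1)) rowMeans(u$u1) else 0
  for (ci in seq_len(nrow(cells))) {
    p <- match(cells$period_days[ci], periods)
    i <- match(cells$inoculant[ci], inocs)
    lat <- b[, 1]
    pc <- paste0("period_days", periods[p])
    if (pc %in% Xcols) lat <- lat + b[, pc]
    ic <- paste0("inoculant", inocs[i])
    if (ic %in% Xcols) lat <- lat + b[, ic]
    lat <- lat + u1_bar
    # incidence levels are ordered taxon-major (taxon slowest)
    if (!is.null(u$u2))
      lat <- lat + rowMeans(u$u2[, (seq_len(TT) - 1L) * P + p, drop = FALSE])
    if (!is.null(u$u3))
      lat <- lat + rowMeans(u$u3[, (seq_len(TT) - 1L) * I + i, drop = FALSE])
    if (!is.null(u$u4))
      lat <- lat + rowMeans(u$u4[, ((seq_len(TT) - 1L) * P + (p - 1L)) * I + i,
                                 drop = FALSE])
    out[, ci] <- if (scale == "response") exp(lat) else lat
  }
  attr(out, "cells") <- cells
  attr(out, "scale") <- scale
  out
}

#' Pairwise credibility-interval separation of posterior cell draws
#'
#' For every unordered pair of cells, the equal-tailed `level` credibility
#' interval of the draw-wise difference; a pair is flagged different iff that
#' interval excludes zero.
#'
#' @param draws matrix of posterior draws (rows) by cells (columns), e.g.
#'   a subset of [cell_draws] columns.
#' @param level credibility level in (0, 1), default 0.95.
#' @return List with `pairs` (data.frame: a, b, diff_mean, lower, upper,
#'   different) and `flags` (symmetric logical matrix).
#' @export
pairwise_separate <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  draws <- as.matrix(draws)
  k <- ncol(draws)
  if (k < 2L) stop("need at least 2 cells to compare")
  nm <- colnames(draws)
  if (is.null(nm)) nm <- paste0("cell", seq_len(k))
  alpha <- (1 - level) / 2
  flags <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    d <- draws[, i] - draws[, j]
    q <- unname(stats::quantile(d, c(alpha, 1 - alpha)))
    diff <- q[1] > 0 || q[2] < 0
    flags[i, j] <- flags[j, i] <- diff
    rows[[length(rows) + 1L]] <- data.frame(
      a = nm[i], b = nm[j], diff_mean = mean(d),
      lower = q[1], upper = q[2], different = diff,
      stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, rows), flags = flags)
}

#' Compact letter display from pairwise difference flags
#'
#' Cells are sorted by descending mean and letter groups are grown by the
#' insert-and-absorb algorithm: two cells share a letter iff they are not
#' flagged different. Letters are a, b, c, ... in sorted order.
#'
#' @param means numeric cell means (named or in column order of `flags`).
#' @param flags symmetric, irreflexive logical matrix of "different" flags.
#' @return Character vector of letter codes, one per cell, in the input order.
#' @export
letter_display <- function(means, flags) {
  flags <- as.matrix(flags)
  k <- length(means)
  if (!all(dim(flags) == k)) stop("flags must be a k x k matrix")
  if (!isTRUE(all(flags == t(flags))))
    stop("inconsistent flags: matrix must be symmetric")
  if (any(diag(flags))) stop("inconsistent flags: diagonal must be FALSE")

  ord <- order(means, decreasing = TRUE)
  # insert-and-absorb on the sorted cells: start from one all-inclusive
  # group, split on each significant pair, drop absorbed (subset) groups
  groups <- list(ord)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    ci <- ord[i]; cj <- ord[j]
    if (!flags[ci, cj]) next
    new_groups <- list()
    for (g in groups) {
      if (ci %in% g && cj %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, ci)), list(setdiff(g, cj)))
      } else new_groups <- c(new_groups, list(g))
    }
    # absorb: remove groups contained in another group
    keep <- rep(TRUE, length(new_groups))
    for (a in seq_along(new_groups)) for (b in seq_along(new_groups)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_groups[[a]] %in% new_groups[[b]]) &&
          !(all(new_groups[[b]] %in% new_groups[[a]]) && a < b))
        keep[a] <- FALSE
    }
    groups <- new_groups[keep]
  }
  groups <- groups[vapply(groups, length, 0L) > 0L]
  # order letters by the best-ranked member of each group
  first_rank <- vapply(groups, function(g) min(match(g, ord)), 0)
  groups <- groups[order(first_rank)]
  letters_out <- rep("", k)
  for (gi in seq_along(groups)) {
    lab <- letters[gi]
    for (cell in groups[[gi]])
      letters_out[cell] <- paste0(letters_out[cell], lab)
  }
  if (any(letters_out == "")) stop("internal error: unlettered cell")
  letters_out
}

#' Posterior coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) of the draws divided by
#' their mean, on the same scale as the mean.
#'
#' @param draws numeric posterior draws.
#' @return Scalar CV.
#' @export
posterior_cv <- function(draws) {
  if (!length(draws)) stop("empty draw vector")
  m <- mean(draws)
  if (m == 0) stop("undefined CV: posterior mean is zero")
  stats::sd(draws) / m
}

#' Posterior cell summary table with credibility-interval mean separation
#'
#' Reproduces the layout of factorial abundance tables: one row per
#' (inoculant, period) cell with posterior mean, CV, equal-tailed bounds and
#' compact letters. With `direction = "inoculants-within-period"` the letters
#' compare inoculants within each fermentation period; with
#' `"periods-within-inoculant"` they compare periods within each inoculant.
#'
#' @param result a `chain_result`.
#' @param direction comparison direction (see above).
#' @param level credibility level, default 0.95.
#' @param scale `"response"` or `"latent"` (see [cell_draws]).
#' @return data.frame with columns inoculant, period_days, mean, cv, lower,
#'   upper, letters; attribute `direction`.
#' @export
cell_summary_table <- function(result,
                               direction = c("inoculants-within-period",
                                             "periods-within-inoculant"),
                               level = 0.95,
                               scale = c("response", "latent")) {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  draws <- cell_draws(result, scale = scale)
  cells <- attr(draws, "cells")
  alpha <- (1 - level) / 2
  out <- cells
  out$mean <- colMeans(draws)
  out$cv <- apply(draws, 2, posterior_cv)
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  out$lower <- qs[1, ]; out$upper <- qs[2, ]
  out$letters <- NA_character_

  group_var <- if (direction == "inoculants-within-period") "period_days" else "inoculant"
  for (g in unique(cells[[group_var]])) {
    sel <- which(cells[[group_var]] == g)
    if (length(sel) < 2L) { out$letters[sel] <- "a"; next }
    ps <- pairwise_separate(draws[, sel, drop = FALSE], level = level)
    out$letters[sel] <- letter_display(out$mean[sel], ps$flags)
  }
  attr(out, "direction") <- direction
  attr(out, "scale") <- scale
  out
}
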