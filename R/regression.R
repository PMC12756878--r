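#' @include bioenergetics.R
NULL

#' Symmetric (inverted) regression of paired measurements
#'
#' Fits y on x and x on y by ordinary least squares, re-expresses the second
#' fit in y-on-x form (slope \code{b_X = 1/beta_X}, intercept
#' \code{a_X = -alpha_X/beta_X}) and averages: mean slope
#' \code{b_bar = (b_Y + b_X)/2}, mean intercept \code{a_bar = (a_Y + a_X)/2}.
#' Because neither variable is privileged, the construction is symmetric:
#' swapping x and y exchanges the roles of the two fits. For positively
#' correlated data \code{b_Y <= b_bar <= b_X}; on exactly collinear data all
#' three slopes coincide. Fits are unweighted.
#'
#' @param x,y numeric vectors of equal length (n >= 3), both with positive
#'   variance.
#' @return An \linkS4class{InvertedRegressionFit}.
#' @export
invertedRegression <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  fy <- stats::lsfit(x, y)
  b_Y <- unname(fy$coefficients[2]); a_Y <- unname(fy$coefficients[1])
  fx <- stats::lsfit(y, x)
  beta_X <- unname(fx$coefficients[2]); alpha_X <- unname(fx$coefficients[1])
  if (beta_X == 0) stop("x-on-y slope is zero; inverted fit undefined")
  b_X <- 1 / beta_X
  a_X <- -alpha_X / beta_X
  new("InvertedRegressionFit",
      b_Y = b_Y, a_Y = a_Y, b_X = b_X, a_X = a_X,
      b_bar = (b_Y + b_X) / 2, a_bar = (a_Y + a_X) / 2,
      n = as.integer(n), r = stats::cor(x, y))
}

#' Technical-repeat agreement of comparable states
#'
#' Pools comparable-state rate pairs (e.g. from parallel runs of the two
#' reference protocols across samples), fits the symmetric regression, and
#' summarizes agreement with the theoretical line of correspondence
#' (identity): the mean slope against 1, the mean intercept against 0, and
#' per-pair relative differences \code{2 (r1 - r2) / (r1 + r2)}.
#'
#' @param pairs data.frame with columns \code{rate_rp1}, \code{rate_rp2}
#'   (e.g. rbind of \code{\link{comparableStatePairs}} results).
#' @return list with \code{fit} (an \linkS4class{InvertedRegressionFit}),
#'   \code{slope_dev} (b_bar - 1), \code{intercept_dev} (a_bar),
#'   \code{rel_diff} (per pair), \code{median_rel_diff},
#'   \code{max_abs_rel_diff}.
#' @export
repeatAgreement <- function(pairs) {
  if (nrow(pairs) < 3)
    stop("need at least 3 comparable-state pairs (have ", nrow(pairs), ")")
  fit <- invertedRegression(pairs$rate_rp1, pairs$rate_rp2)
  rd <- 2 * (pairs$rate_rp1 - pairs$rate_rp2) /
        (pairs$rate_rp1 + pairs$rate_rp2)
  list(fit = fit,
       slope_dev = fit@b_bar - 1,
       intercept_dev = fit@a_bar,
       rel_diff = rd,
       median_rel_diff = stats::median(rd),
       max_abs_rel_diff = max(abs(rd)))
}

#' Compare paired clusters by symmetric regression
#'
#' Fits the inverted regression per group and pooled, and classifies the
#' groups as isolinear (representable by one line) or heterolinear. The
#' published practice classifies clusters visually; here two explicit
#' criteria are computed and reported: (1) the relative spread of per-group
#' mean slopes against a threshold, and (2) disjointness of seeded bootstrap
#' confidence intervals of the mean slope.
#'
#' @param groups named list of data.frames, each with columns \code{x},
#'   \code{y} and at least 3 rows.
#' @param slope_threshold relative slope-difference threshold for
#'   heterolinearity, default 0.2.
#' @param n_boot bootstrap resamples for slope confidence intervals.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{fits} (per group), \code{pooled},
#'   \code{slope_spread} (max relative difference between group slopes),
#'   \code{slope_ci} (per group), \code{ci_disjoint},
#'   \code{classification} ("isolinear"/"heterolinear"; NULL for a single
#'   group).
#' @export
clusterCompare <- function(groups, slope_threshold = 0.2, n_boot = 1000,
                           conf = 0.95, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1)
  too_small <- vapply(groups, function(g) nrow(g) < 3, logical(1))
  if (any(too_small))
    stop("group(s) too small (need n >= 3): ",
         paste(names(groups)[too_small], collapse = ", "))
  fits <- lapply(groups, function(g) invertedRegression(g$x, g$y))
  pooled_df <- do.call(rbind, lapply(groups, function(g) g[, c("x", "y")]))
  pooled <- invertedRegression(pooled_df$x, pooled_df$y)
  if (length(groups) < 2)
    return(list(fits = fits, pooled = pooled, slope_spread = NA_real_,
                slope_ci = NULL, ci_disjoint = NA, classification = NULL))

  slopes <- vapply(fits, function(f) f@b_bar, numeric(1))
  spread <- (max(slopes) - min(slopes)) / mean(abs(slopes))

  set.seed(seed)
  ci <- lapply(groups, function(g) {
    bs <- replicate(n_boot, {
      i <- sample.int(nrow(g), replace = TRUE)
      tryCatch(invertedRegression(g$x[i], g$y[i])@b_bar,
               error = function(e) NA_real_)
    })
    stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    na.rm = TRUE, names = FALSE)
  })
  disjoint <- FALSE
  nm <- names(groups)
  for (i in seq_along(ci)) for (j in seq_along(ci)) {
    if (i < j && (ci[[i]][2] < ci[[j]][1] || ci[[j]][2] < ci[[i]][1]))
      disjoint <- TRUE
  }
  hetero <- spread > slope_threshold || disjoint
  list(fits = fits, pooled = pooled, slope_spread = spread,
       slope_ci = stats::setNames(ci, nm), ci_disjoint = disjoint,
       classification = if (hetero) "heterolinear" else "isolinear")
}
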