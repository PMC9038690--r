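#' Two-phase (segmented) linear regression
#'
#' Fits a continuous piecewise-linear model with one breakpoint to a metric
#' series: \code{y = b0 + b1*x + b2*(x - xb)+}.  The breakpoint is chosen by
#' exhaustive search over the observed \code{x} values admitting at least
#' \code{min_seg} points per side, minimizing the residual sum of squares
#' (ties: earliest candidate).  Phase slopes are \code{b1} and
#' \code{b1 + b2}; 95 percent confidence intervals and p-values are
#' standard least-squares inference conditional on the selected breakpoint.
#' With \code{continuous = FALSE}, two unconstrained lines are fitted on the
#' two sides instead (break between points).
#'
#' @param x Strictly increasing predictor (transition indices or times).
#' @param y Metric values.
#' @param min_seg Minimum points per phase (default 3).
#' @param continuous Enforce continuity at the breakpoint (default TRUE).
#' @return Object of class \code{segmented_fit}: list with
#'   \code{breakpoint} (x value), \code{breakpoint_index}, \code{slopes},
#'   \code{intercepts}, \code{ci} (2 x 2: phase rows, lower/upper),
#'   \code{p_values}, \code{r_squared}, \code{rss}, \code{residuals},
#'   \code{fitted}, \code{continuous}.
#' @export
fit_two_phase <- function(x, y, min_seg = 3L, continuous = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("invalid input: x and y lengths differ")
  if (n < 2L * min_seg) stop("invalid input: too few points")
  if (any(diff(x) <= 0)) stop("invalid input: x must be strictly increasing")
  cand <- seq.int(min_seg, n - min_seg + 1L)
  best <- NULL
  for (i in cand) {
    xb <- x[i]
    if (continuous) {
      h <- pmax(x - xb, 0)
      fit <- stats::lm(y ~ x + h)
      rss <- sum(stats::residuals(fit)^2)
    } else {
      # discontinuous: the break falls between points i and i+1
      left <- seq_len(i); right <- seq.int(i + 1L, n)
      if (length(right) < min_seg) next
      f1 <- stats::lm(y[left] ~ x[left]); f2 <- stats::lm(y[right] ~ x[right])
      fit <- list(f1, f2)
      rss <- sum(stats::residuals(f1)^2) + sum(stats::residuals(f2)^2)
    }
    if (is.null(best) || rss < best$rss - 1e-15 * max(1, best$rss))
      best <- list(i = i, xb = xb, fit = fit, rss = rss)
  }
  tss <- sum((y - mean(y))^2)
  if (continuous) {
    fit <- best$fit
    cf <- stats::coef(fit)
    # suppressed warning: zero-residual (perfect) fits are legitimate here
    V <- suppressWarnings(stats::vcov(fit))
    s1 <- cf[["x"]]; s2 <- cf[["x"]] + cf[["h"]]
    se1 <- sqrt(V["x", "x"])
    se2 <- sqrt(V["x", "x"] + V["h", "h"] + 2 * V["x", "h"])
    dfres <- fit$df.residual
    tq <- stats::qt(0.975, dfres)
    ci <- rbind(phase1 = c(s1 - tq * se1, s1 + tq * se1),
                phase2 = c(s2 - tq * se2, s2 + tq * se2))
    pv <- 2 * stats::pt(-abs(c(s1 / se1, s2 / se2)), dfres)
    intercepts <- c(cf[["(Intercept)"]],
                    cf[["(Intercept)"]] - cf[["h"]] * best$xb)
    fitted <- as.numeric(stats::fitted(fit))
    resid <- as.numeric(stats::residuals(fit))
  } else {
    f1 <- best$fit[[1L]]; f2 <- best$fit[[2L]]
    s1 <- stats::coef(f1)[[2L]]; s2 <- stats::coef(f2)[[2L]]
    ci <- suppressWarnings(
      rbind(phase1 = as.numeric(stats::confint(f1)[2L, ]),
            phase2 = as.numeric(stats::confint(f2)[2L, ])))
    pv <- suppressWarnings(
      c(stats::summary.lm(f1)$coefficients[2L, 4L],
        stats::summary.lm(f2)$coefficients[2L, 4L]))
    intercepts <- c(stats::coef(f1)[[1L]], stats::coef(f2)[[1L]])
    fitted <- c(stats::fitted(f1), stats::fitted(f2))
    resid <- y - fitted
  }
  colnames(ci) <- c("lower", "upper")
  structure(list(
    breakpoint = best$xb, breakpoint_index = best$i,
    slopes = c(phase1 = s1, phase2 = s2),
    intercepts = c(phase1 = intercepts[1L], phase2 = intercepts[2L]),
    ci = ci, p_values = c(phase1 = pv[1L], phase2 = pv[2L]),
    r_squared = if (tss > 0) 1 - best$rss / tss else 1,
    rss = best$rss, residuals = resid, fitted = fitted,
    continuous = continuous
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "two-phase fit: break at x = %g; slopes %.4g [%.4g, %.4g] then %.4g [%.4g, %.4g]; r2 = %.3f\n",
    x$breakpoint, x$slopes[1L], x$ci[1L, 1L], x$ci[1L, 2L],
    x$slopes[2L], x$ci[2L, 1L], x$ci[2L, 2L], x$r_squared))
  invisible(x)
}

#' Pooled-variance two-sample two-sided t-test
#'
#' Accepts either raw samples or summary statistics (mean, sd, n) per
#' group; both routes give identical results for the same summaries.
#'
#' @param a,b Numeric samples (raw route).
#' @param summary_a,summary_b Numeric vectors \code{c(mean, sd, n)}
#'   (summary route; used when \code{a}/\code{b} are NULL).
#' @return List: \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_diff}.
#' @export
two_sample_t <- function(a = NULL, b = NULL,
                         summary_a = NULL, summary_b = NULL) {
  s <- function(v, sm) {
    if (!is.null(v)) c(mean(v), stats::sd(v), length(v)) else as.numeric(sm)
  }
  ga <- s(a, summary_a); gb <- s(b, summary_b)
  if (anyNA(ga) || anyNA(gb)) stop("invalid input: provide samples or summaries")
  if (ga[3L] < 2 || gb[3L] < 2) stop("invalid input: need n >= 2 per group")
  if (ga[2L] <= 0 && gb[2L] <= 0)
    stop("invalid input: at least one group must have positive sd")
  df <- ga[3L] + gb[3L] - 2
  sp2 <- ((ga[3L] - 1) * ga[2L]^2 + (gb[3L] - 1) * gb[2L]^2) / df
  se <- sqrt(sp2 * (1 / ga[3L] + 1 / gb[3L]))
  tstat <- (ga[1L] - gb[1L]) / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       mean_diff = ga[1L] - gb[1L])
}

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk per group and Bartlett across groups, with the conventional
#' p > 0.05 pass rule used before parametric testing.
#'
#' @param samples List of numeric vectors (>= 3 values each).
#' @return List: \code{shapiro_p} (per group), \code{bartlett_p},
#'   \code{pass} (all p > 0.05).
#' @export
assumption_checks <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("invalid input: need a list of >= 2 samples")
  if (any(vapply(samples, length, 1L) < 3L))
    stop("invalid input: need n >= 3 per sample")
  sw <- vapply(samples, function(v) stats::shapiro.test(v)$p.value, 1)
  bt <- stats::bartlett.test(samples)$p.value
  list(shapiro_p = sw, bartlett_p = bt,
       pass = all(sw > 0.05) && bt > 0.05)
}

#' Transition-to-transition stability analysis
#'
#' For replicate metric series across environmental transitions, computes
#' per-replicate differences between subsequent transitions
#' (\code{d_t = m_t - m_(t-1)}), the across-replicate variance of the
#' differences at each transition, and the first transition at which that
#' variance falls to \code{tol} or below (the stability point).
#'
#' @param series Matrix, replicates x transitions (>= 2 replicates, >= 3
#'   transitions; all replicates the same length).
#' @param tol Variance threshold.
#' @return List: \code{differences} (replicates x (T-1)),
#'   \code{variance} (length T-1, named by the later transition index),
#'   \code{stable_at} (transition index, or NA if never).
#' @export
transition_stability <- function(series, tol) {
  if (is.list(series)) {
    len <- vapply(series, length, 1L)
    if (length(unique(len)) != 1L)
      stop("invalid input: ragged replicate lengths")
    series <- do.call(rbind, series)
  }
  series <- as.matrix(series)
  if (nrow(series) < 2L) stop("invalid input: need >= 2 replicates")
  if (ncol(series) < 3L) stop("invalid input: need >= 3 transitions")
  d <- t(apply(series, 1L, diff))
  v <- apply(d, 2L, stats::var)
  names(v) <- as.character(seq.int(2L, ncol(series)))
  hit <- which(v <= tol)
  list(differences = d, variance = v,
       stable_at = if (length(hit)) as.integer(names(v)[hit[1L]]) else NA_integer_)
}

#' Fit two-phase models to a metrics table
#'
#' Convenience layer over \code{\link{fit_two_phase}} for tidy metric CSVs
#' (as written by the quantification tools): one fit per metric column,
#' replicates pooled by default or fitted separately.
#'
#' @param metrics Data frame with a \code{transition} column and one column
#'   per metric; optional \code{replicate} column.
#' @param columns Metric columns to fit (default: all numeric except
#'   transition/replicate).
#' @param pooled Pool replicates into one fit per metric (default TRUE).
#' @param min_seg Passed to \code{\link{fit_two_phase}}.
#' @return Data frame: metric, replicate ("pooled" or id), phase, slope,
#'   ci_lower, ci_upper, p, r_squared, breakpoint.
#' @export
fit_metric_dynamics <- function(metrics, columns = NULL, pooled = TRUE,
                                min_seg = 3L) {
  stopifnot(is.data.frame(metrics), "transition" %in% names(metrics))
  if (is.null(columns))
    columns <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                       c("transition", "replicate"))
  groups <- if (pooled || is.null(metrics$replicate)) list(pooled = metrics)
            else split(metrics, metrics$replicate)
  out <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    agg <- stats::aggregate(df[columns], list(transition = df$transition),
                            mean)
    for (cl in columns) {
      f <- fit_two_phase(agg$transition, agg[[cl]], min_seg = min_seg)
      out[[length(out) + 1L]] <- data.frame(
        metric = cl, replicate = g, phase = c("phase1", "phase2"),
        slope = unname(f$slopes), ci_lower = f$ci[, "lower"],
        ci_upper = f$ci[, "upper"], p = unname(f$p_values),
        r_squared = f$r_squared, breakpoint = f$breakpoint)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
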