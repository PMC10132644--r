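# In vitro cleavage kinetics: fraction cleaved from gel band fractions,
# first-order rate fitting (k_obs), replicate summaries, and condition
# comparisons.

#' Fraction cleaved from gel band densitometry
#'
#' Total cleaved DNA (nicked + linear) over total DNA
#' (nicked + linear + supercoiled). Homogeneous in the band intensities:
#' any common scaling cancels.
#'
#' @param supercoiled,nicked,linear Nonnegative band intensities or
#'   fractions (vectorised).
#' @return Fraction cleaved in [0, 1].
#' @export
fraction_cleaved <- function(supercoiled, nicked, linear) {
  if (any(supercoiled < 0 | nicked < 0 | linear < 0)) {
    stop("band intensities must be nonnegative")
  }
  total <- supercoiled + nicked + linear
  if (any(total == 0)) {
    stop_escape("empty_lane", "all three band intensities are zero")
  }
  (nicked + linear) / total
}

#' Fit a first-order cleavage rate
#'
#' Least-squares fit of the first-order rate equation
#' \deqn{f(t) = A (1 - e^{-k t})}
#' to a fraction-cleaved time course, yielding the observed rate constant
#' `k_obs` and (unless fixed) the plateau amplitude A. The optimiser is
#' started from a fixed grid of initial rates (1e-4 to 1 per second) and
#' the best residual sum of squares wins, so the fit is deterministic.
#' `k` is constrained nonnegative and A to [0, 1].
#'
#' A time course that is flat at zero returns the degenerate fit
#' k = 0, A = 0. When cleavage is already >= 99% of the plateau at the
#' first timepoint, the rate is only bounded from below by the sampling
#' grid; such fits carry `lower_bound = TRUE`.
#'
#' @param tc A [emit_timecourse()] result, or any data.frame with
#'   columns `time_s` and `fraction_cleaved` (>= 3 timepoints).
#' @param fix_plateau Optional fixed plateau in [0, 1]; when `NULL`
#'   (default) A is fitted.
#' @return Object of class `rate_fit`: list with `k_obs`, `plateau`,
#'   `rss`, `converged`, `degenerate`, `lower_bound`, `n_timepoints`.
#' @export
fit_first_order <- function(tc, fix_plateau = NULL) {
  stopifnot(all(c("time_s", "fraction_cleaved") %in% names(tc)))
  t <- tc$time_s
  f <- tc$fraction_cleaved
  if (length(t) < 3L) stop("at least 3 timepoints are required")
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  if (any(diff(t) <= 0)) stop("timepoints must be strictly increasing")
  if (!is.null(fix_plateau)) {
    stopifnot(fix_plateau >= 0, fix_plateau <= 1)
  }
  if (all(f == 0)) {
    return(rate_fit(k_obs = 0, plateau = fix_plateau %||% 0, rss = 0,
                    converged = TRUE, degenerate = TRUE,
                    t_min = min(t), n = length(t)))
  }
  k_grid <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
  best <- NULL
  for (k0 in k_grid) {
    fit <- if (is.null(fix_plateau)) {
      try(minpack.lm::nlsLM(
        f ~ A * (1 - exp(-k * t)),
        start = list(A = min(max(max(f), 1e-3), 1), k = k0),
        lower = c(A = 0, k = 0), upper = c(A = 1, k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
    } else {
      A_fixed <- fix_plateau
      try(minpack.lm::nlsLM(
        f ~ A_fixed * (1 - exp(-k * t)),
        start = list(k = k0),
        lower = c(k = 0), upper = c(k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(k = unname(cf[["k"]]),
                   A = if (is.null(fix_plateau)) unname(cf[["A"]]) else fix_plateau,
                   rss = rss, converged = fit$convInfo$isConv %||% TRUE)
    }
  }
  if (is.null(best)) {
    # fall back to direct RSS minimisation so a result is always reported
    obj <- function(p) {
      A <- if (is.null(fix_plateau)) p[1] else fix_plateau
      k <- p[length(p)]
      sum((f - A * (1 - exp(-k * t)))^2)
    }
    p0 <- if (is.null(fix_plateau)) c(min(max(f), 1), 1e-2) else 1e-2
    lower <- if (is.null(fix_plateau)) c(0, 0) else 0
    upper <- if (is.null(fix_plateau)) c(1, Inf) else Inf
    opt <- stats::optim(p0, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper)
    best <- list(k = opt$par[length(opt$par)],
                 A = if (is.null(fix_plateau)) opt$par[1] else fix_plateau,
                 rss = opt$value, converged = FALSE)
  }
  rate_fit(k_obs = best$k, plateau = best$A, rss = best$rss,
           converged = isTRUE(best$converged),
           degenerate = FALSE, t_min = min(t), n = length(t))
}

rate_fit <- function(k_obs, plateau, rss, converged, degenerate, t_min, n) {
  lower_bound <- !degenerate && plateau > 0 &&
    (1 - exp(-k_obs * t_min)) >= 0.99
  structure(
    list(k_obs = k_obs, plateau = plateau, rss = rss,
         converged = converged, degenerate = degenerate,
         lower_bound = lower_bound, n_timepoints = n),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k_obs = %.4g /s, plateau = %.3f, rss = %.3g%s%s\n",
              x$k_obs, x$plateau, x$rss,
              if (!x$converged) " (not converged)" else "",
              if (x$lower_bound) " (k is a lower bound: saturated by first timepoint)" else ""))
  invisible(x)
}

#' Summarise replicate rate fits
#'
#' Arithmetic mean and sample SD of `k_obs` over converged replicate
#' fits, mirroring triplicate rate reporting.
#'
#' @param fits List of [fit_first_order()] results.
#' @return List with `mean_k_obs`, `sd_k_obs` (NA for a single
#'   replicate), `n`.
#' @export
summarize_replicates <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) {
    stop_escape("no_converged_fits", "no converged replicate fits to summarise")
  }
  k <- vapply(conv, `[[`, numeric(1), "k_obs")
  list(mean_k_obs = mean(k),
       sd_k_obs = if (length(k) > 1L) stats::sd(k) else NA_real_,
       n = length(k))
}

#' Compare k_obs between two conditions
#'
#' Classical unpaired two-tailed two-sample t test on observed rate
#' constants; equal-variance (pooled) form by default, Welch optionally.
#' Two groups with zero variance and equal means return t = 0, p = 1
#' with a `degenerate` flag instead of an error.
#'
#' @param group_a,group_b Numeric vectors of k_obs values (n >= 2 each).
#' @param var_equal Use the pooled equal-variance form (default TRUE).
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
compare_conditions <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, p = 1,
                  df = length(group_a) + length(group_b) - 2L,
                  degenerate = TRUE))
    }
    return(list(t = Inf * sign(mean(group_a) - mean(group_b)), p = 0,
                df = length(group_a) + length(group_b) - 2L,
                degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}
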