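#' Normalized FRAP recovery trace
#'
#' @param t_s time in seconds, 0 at the first post-bleach sample (prebleach
#'   samples carry negative times); strictly increasing.
#' @param y normalized intensity (prebleach mean = 1).
#' @param n_prebleach number of prebleach samples at the head of the trace.
#' @param background background level subtracted during normalization.
#' @return object of class `frap_trace`.
#' @export
frap_trace <- function(t_s, y, n_prebleach = 3L, background = 0) {
  if (length(t_s) != length(y)) stopf("t_s and y lengths differ")
  if (any(diff(t_s) <= 0)) stopf("t_s must be strictly increasing")
  structure(list(t_s = t_s, y = y, n_prebleach = as.integer(n_prebleach),
                 background = background),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  post <- x$t_s >= 0
  cat(sprintf("<frap_trace> %d prebleach + %d post-bleach samples, %.3g s span\n",
              x$n_prebleach, sum(post), max(x$t_s)))
  invisible(x)
}

#' Normalize a raw photobleaching trace
#'
#' Background-subtracted intensities are normalized to the mean of the
#' prebleach samples and time is re-zeroed at the first post-bleach sample.
#'
#' @param raw_intensities raw intensities, prebleach samples first.
#' @param raw_times acquisition times (s), strictly increasing.
#' @param background background intensity (must be below the prebleach mean).
#' @param n_prebleach number of leading prebleach samples (>= 3).
#' @return a [frap_trace].
#' @export
normalize_trace <- function(raw_intensities, raw_times, background = 0,
                            n_prebleach = 3L) {
  if (n_prebleach < 3) stopf("need >= 3 prebleach samples")
  if (length(raw_intensities) <= n_prebleach) stopf("no post-bleach samples")
  pre <- mean(raw_intensities[seq_len(n_prebleach)])
  if (background >= pre) stopf("background (%g) must be below the prebleach mean (%g)",
                               background, pre)
  y <- (raw_intensities - background) / (pre - background)
  t0 <- raw_times[n_prebleach + 1]
  frap_trace(raw_times - t0, y, n_prebleach, background)
}

#' Generate a synthetic FRAP trace with known kinetics
#'
#' Prebleach plateau at 1 (three samples), an instantaneous drop to the
#' bleach floor, then single-exponential recovery
#' `Y(t) = Ymin + (Ymax - Ymin) (1 - exp(-k t))` sampled every `dt_s`
#' (default 255 ms), with additive Gaussian noise.
#'
#' @param k_per_s recovery rate constant (1/s).
#' @param mobile_fraction fraction of the bleached signal that recovers,
#'   `(Ymax - Ymin) / (1 - Ymin)` in `[0, 1]`.
#' @param bleach_depth fraction of prebleach intensity removed by the bleach
#'   (0.5 = bleached to half); `Ymin = 1 - bleach_depth`.
#' @param dt_s sampling interval (s).
#' @param t_max_s post-bleach duration (s).
#' @param noise_sd additive Gaussian noise sd (on the normalized scale).
#' @param seed integer seed.
#' @param n_prebleach prebleach samples.
#' @return list with `trace` (a [frap_trace]) and `truth` (k, t_half, Ymin,
#'   Ymax, mobile_fraction, noise_sd, seed).
#' @export
gen_frap_trace <- function(k_per_s, mobile_fraction = 0.7, bleach_depth = 0.5,
                           dt_s = 0.255, t_max_s = 30, noise_sd = 0,
                           seed = 0, n_prebleach = 3L) {
  if (mobile_fraction < 0 || mobile_fraction > 1) stopf("mobile_fraction in [0,1]")
  if (bleach_depth <= 0 || bleach_depth >= 1) stopf("bleach_depth in (0,1)")
  ymin <- 1 - bleach_depth
  ymax <- ymin + mobile_fraction * (1 - ymin)
  t_post <- seq(0, t_max_s, by = dt_s)
  t_pre <- -rev(seq_len(n_prebleach)) * dt_s
  y_post <- ymin + (ymax - ymin) * (1 - exp(-k_per_s * t_post))
  y_pre <- rep(1, n_prebleach)
  y <- c(y_pre, y_post)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  list(trace = frap_trace(c(t_pre, t_post), y, n_prebleach),
       truth = list(k_per_s = k_per_s, t_half_s = log(2) / k_per_s,
                    Ymin = ymin, Ymax = ymax,
                    mobile_fraction = mobile_fraction,
                    noise_sd = noise_sd, dt_s = dt_s, seed = seed))
}

#' Fit single-exponential FRAP recovery kinetics
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `Y(t) = (Ymax - Ymin)(1 - exp(-k t)) + Ymin` over the post-bleach samples.
#' Start values: `Ymin` = first post-bleach sample, `Ymax` = mean of the last
#' 10% of samples, `k = ln 2 /` (time to reach the midpoint between them).
#' The half-time `t_half = ln 2 / k` and the mobile fraction
#' `(Ymax - Ymin)/(1 - Ymin)` are derived; the mobile fraction is clamped to
#' `[0, 1]` with the clamp recorded in `$clamped`.
#'
#' @param trace a [frap_trace].
#' @param tol parameter convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `frap_fit` with `Ymin`, `Ymax`, `k_per_s`,
#'   `t_half_s`, `mobile_fraction`, `rss`, `recovered` (FALSE when the trace
#'   shows no recovery), `clamped`, and the fitted trace.
#' @export
fit_recovery <- function(trace, tol = 1e-8, max_iter = 500L) {
  post <- trace$t_s >= 0
  t <- trace$t_s[post]
  y <- trace$y[post]
  n <- length(t)
  if (n < 10) stopf("need >= 10 post-bleach samples, have %d", n)
  ymin0 <- y[1]
  ymax0 <- mean(y[t >= stats::quantile(t, 0.9)])
  if (ymax0 <= ymin0 + 1e-4) {
    return(new_frap_fit(ymin0, ymax0, NA_real_, trace, rss = sum((y - mean(y))^2),
                        recovered = FALSE))
  }
  mid <- (ymin0 + ymax0) / 2
  i_mid <- which(y >= mid)[1]
  t_mid <- if (!is.na(i_mid) && t[i_mid] > 0) t[i_mid] else max(t) / 4
  k0 <- log(2) / t_mid
  if (max(t) < 2 * log(2) / k0)
    warning(sprintf("post-bleach window (%.3g s) spans < 2 estimated half-times", max(t)))
  fit <- minpack.lm::nlsLM(
    y ~ (Ymax - Ymin) * (1 - exp(-k * t)) + Ymin,
    start = list(Ymin = ymin0, Ymax = ymax0, k = k0),
    lower = c(-Inf, -Inf, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                         ptol = tol)
  )
  p <- stats::coef(fit)
  if (p["Ymax"] <= p["Ymin"]) {
    return(new_frap_fit(p["Ymin"], p["Ymax"], NA_real_, trace,
                        rss = sum(stats::resid(fit)^2), recovered = FALSE))
  }
  new_frap_fit(p["Ymin"], p["Ymax"], p["k"], trace,
               rss = sum(stats::resid(fit)^2), recovered = TRUE)
}

new_frap_fit <- function(ymin, ymax, k, trace, rss, recovered) {
  ymin <- unname(ymin); ymax <- unname(ymax); k <- unname(k)
  mf_raw <- if (recovered) (ymax - ymin) / (1 - ymin) else 0
  clamped <- recovered && (mf_raw < 0 || mf_raw > 1)
  structure(list(Ymin = ymin, Ymax = ymax, k_per_s = k,
                 t_half_s = if (recovered) log(2) / k else NA_real_,
                 mobile_fraction = min(1, max(0, mf_raw)),
                 mobile_fraction_raw = mf_raw, clamped = clamped,
                 rss = rss, recovered = recovered, trace = trace),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$recovered) {
    cat("<frap_fit> no recovery detected (flat post-bleach trace)\n")
  } else {
    cat(sprintf("<frap_fit> k = %.4g /s, t1/2 = %.4g s, mobile fraction = %.3f%s\n  Ymin = %.3f, Ymax = %.3f, RSS = %.3g\n",
                x$k_per_s, x$t_half_s, x$mobile_fraction,
                if (x$clamped) " (clamped)" else "", x$Ymin, x$Ymax, x$rss))
  }
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(Ymin = object$Ymin, Ymax = object$Ymax, k = object$k_per_s)
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$trace$t_s[object$trace$t_s >= 0]
       else if (is.list(newdata)) newdata$t_s else newdata
  if (!object$recovered) return(rep(object$Ymin, length(t)))
  (object$Ymax - object$Ymin) * (1 - exp(-object$k_per_s * t)) + object$Ymin
}

#' @export
fitted.frap_fit <- function(object, ...) predict(object)

#' @export
residuals.frap_fit <- function(object, ...) {
  post <- object$trace$t_s >= 0
  object$trace$y[post] - predict(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$trace$t_s, x$trace$y, pch = 16, cex = 0.5,
                 xlab = "time after bleach (s)", ylab = "normalized intensity",
                 ...)
  if (x$recovered) {
    tt <- seq(0, max(x$trace$t_s), length.out = 200)
    graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  }
  invisible(x)
}
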