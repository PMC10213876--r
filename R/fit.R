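#' Fit the individualized QT-RR regression
#'
#' Ordinary least squares of template-level QT on the paired mean RR of the
#' same 30-s window: `QT = alpha * RR + beta`. The fitted line evaluated at
#' an RR interval of 1,000 ms is the individualized QT interval (QTi), the
#' subject-level statistic; `alpha` is the QT-RR slope quantifying QT rate
#' dependence, and the Pearson correlation of the same points is reported as
#' the quality of the linear relation. Input points flagged anything other
#' than `"ok"` are dropped before fitting.
#'
#' @param x A `qti_measure` from [measure_recording()], a data frame with
#'   columns `qt_ms`, `rr_ms` (and optionally `quality`), or a numeric
#'   vector of QT values (ms).
#' @param rr_ms Numeric vector of RR values (ms) when `x` is a QT vector.
#' @param min_points Minimum number of ok-quality points required (default
#'   480, i.e. 4 h of valid 30-s windows, aligning regression validity with
#'   recording validity).
#' @param ... Unused.
#' @return An object of class `qti_fit`: a list with `alpha`, `beta` (ms),
#'   `pearson_r`, `n_points`, `rr_range` (ms), `qti_1000` (ms),
#'   `sigma` (residual SD, ms), `status` (`"ok"`, `"too_few_points"` or
#'   `"no_rr_spread"`) and the fitted points in `data`.
#' @examples
#' rr <- seq(600, 1200, by = 10)
#' fit <- fit_qt_rr(0.2 * rr + 199, rr, min_points = 10)
#' coef(fit)
#' predict(fit, rr_ms = c(600, 1000, 1400))
#' @seealso [qti_at()], [subject_qti()]
#' @export
fit_qt_rr <- function(x, rr_ms = NULL, min_points = 480, ...) {
  if (inherits(x, "qti_measure")) x <- x$measurements
  if (is.data.frame(x)) {
    if ("quality" %in% names(x)) x <- x[x$quality == "ok", , drop = FALSE]
    qt <- x$qt_ms
    rr <- x$rr_ms
  } else {
    qt <- as.numeric(x)
    rr <- as.numeric(rr_ms)
    if (length(qt) != length(rr)) stop("qt and rr vectors must have equal length")
  }
  keep <- is.finite(qt) & is.finite(rr)
  qt <- qt[keep]
  rr <- rr[keep]
  n <- length(qt)

  failed <- function(status) {
    structure(list(alpha = NA_real_, beta = NA_real_, pearson_r = NA_real_,
                   n_points = n, rr_range = if (n) range(rr) else c(NA_real_, NA_real_),
                   qti_1000 = NA_real_, sigma = NA_real_,
                   data = data.frame(qt_ms = qt, rr_ms = rr),
                   status = status, call = sys.call(-1L)),
              class = "qti_fit")
  }
  if (n < max(2L, min_points)) return(failed("too_few_points"))
  if (stats::sd(rr) == 0) return(failed("no_rr_spread"))

  fit <- stats::lm.fit(cbind(beta = 1, alpha = rr), qt)
  alpha <- unname(fit$coefficients["alpha"])
  beta <- unname(fit$coefficients["beta"])
  res <- fit$residuals
  # degenerate case: constant QT has no linear association (r := 0)
  r <- if (stats::sd(qt) == 0) 0 else stats::cor(rr, qt)
  structure(
    list(alpha = alpha, beta = beta,
         pearson_r = r,
         n_points = n, rr_range = range(rr),
         qti_1000 = alpha * 1000 + beta,
         sigma = sqrt(sum(res^2) / max(n - 2L, 1L)),
         data = data.frame(qt_ms = qt, rr_ms = rr),
         status = "ok", call = sys.call(-1L)),
    class = "qti_fit"
  )
}

#' Evaluate a fitted QT-RR line at given RR intervals
#'
#' Returns `alpha * rr_ms + beta`. Extrapolation beyond the observed RR range
#' is permitted (subjects whose heart rate never reaches 60 bpm still get a
#' QTi) but is flagged in the `"extrapolated"` attribute.
#'
#' @param reg A `qti_fit`.
#' @param rr_ms RR interval(s) in ms (default 1,000).
#' @return Numeric vector of QT values (ms) with attribute `extrapolated`.
#' @export
qti_at <- function(reg, rr_ms = 1000) {
  stopifnot(inherits(reg, "qti_fit"))
  if (reg$status != "ok") stop("cannot evaluate a failed fit (status: ", reg$status, ")")
  out <- reg$alpha * rr_ms + reg$beta
  attr(out, "extrapolated") <- rr_ms < reg$rr_range[1] | rr_ms > reg$rr_range[2]
  out
}

#' @rdname qti_at
#' @param object A `qti_fit`.
#' @param ... Unused.
#' @export
predict.qti_fit <- function(object, rr_ms = 1000, ...) {
  qti_at(object, rr_ms)
}

#' @export
coef.qti_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
fitted.qti_fit <- function(object, ...) {
  object$alpha * object$data$rr_ms + object$beta
}

#' @export
residuals.qti_fit <- function(object, ...) {
  object$data$qt_ms - fitted(object)
}

#' @export
print.qti_fit <- function(x, digits = 4, ...) {
  cat("Individualized QT-RR regression\n")
  if (x$status != "ok") {
    cat(sprintf("  fit failed: %s (n = %d)\n", x$status, x$n_points))
    return(invisible(x))
  }
  cat(sprintf("  QT = %.*g * RR + %.*g   (QT-RR slope alpha, intercept beta in ms)\n",
              digits, x$alpha, digits, x$beta))
  cat(sprintf("  QTi (RR = 1000 ms): %.1f ms\n", x$qti_1000))
  cat(sprintf("  Pearson r = %.3f on %d points, RR range %.0f-%.0f ms\n",
              x$pearson_r, x$n_points, x$rr_range[1], x$rr_range[2]))
  invisible(x)
}

#' @export
summary.qti_fit <- function(object, rr_grid = c(seq(600, 900, 100),
                                                seq(1100, 1400, 100)), ...) {
  out <- list(fit = object)
  if (object$status == "ok") {
    g <- qti_at(object, rr_grid)
    out$grid <- data.frame(rr_ms = rr_grid, qt_ms = as.numeric(g),
                           extrapolated = attr(g, "extrapolated"))
  }
  class(out) <- "summary.qti_fit"
  out
}

#' @export
print.summary.qti_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$grid)) {
    cat("  QT at alternative RR intervals:\n")
    for (i in seq_len(nrow(x$grid))) {
      cat(sprintf("    RR %4.0f ms: %.1f ms%s\n", x$grid$rr_ms[i], x$grid$qt_ms[i],
                  if (x$grid$extrapolated[i]) "  (extrapolated)" else ""))
    }
  }
  invisible(x)
}

#' @export
plot.qti_fit <- function(x, ...) {
  if (x$status != "ok") stop("nothing to plot: fit status is ", x$status)
  graphics::plot(x$data$rr_ms, x$data$qt_ms, pch = 16, cex = 0.4,
                 col = "grey40", xlab = "RR (ms)", ylab = "QT (ms)", ...)
  graphics::abline(x$beta, x$alpha, col = "firebrick", lwd = 2)
  graphics::points(1000, x$qti_1000, pch = 4, cex = 1.4, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("QTi = %.1f ms   alpha = %.3f   r = %.3f",
                          x$qti_1000, x$alpha, x$pearson_r), cex = 0.8)
  invisible(x)
}

#' Simulate QT points from a fitted QT-RR relation
#'
#' Draws new template-level QT values at the observed RR intervals from the
#' fitted line plus Gaussian residual noise at the fitted residual SD.
#'
#' @param object A `qti_fit` with status `"ok"`.
#' @param nsim Number of simulated replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with one column per replicate (`sim_1`, ...), rows
#'   matching `object$data`.
#' @export
simulate.qti_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(object$status == "ok")
  mu <- fitted(object)
  with_seed(seed, {
    out <- as.data.frame(
      vapply(seq_len(nsim),
             function(i) mu + stats::rnorm(length(mu), 0, object$sigma),
             numeric(length(mu)))
    )
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Per-subject QTi from a raw recording
#'
#' Composition of [measure_recording()] and [fit_qt_rr()]: the complete
#' per-subject pipeline from signal to QTi. Invalid-recording status (less
#' than `min_useful_h` hours of useful registration) is propagated: no
#' regression is fitted.
#'
#' @param recording A [ecg_recording()] or [generate_recording()] output.
#' @param min_points Passed to [fit_qt_rr()].
#' @param ... Passed to [measure_recording()] (e.g. `min_useful_h`,
#'   `channel`).
#' @return A list with `fit` (a `qti_fit`, or `NULL` when invalid),
#'   `measure` (the `qti_measure`) and `status`.
#' @export
subject_qti <- function(recording, min_points = 480, ...) {
  m <- measure_recording(recording, ...)
  if (m$report$status != "ok") {
    return(list(fit = NULL, measure = m, status = "invalid_recording"))
  }
  fit <- fit_qt_rr(m, min_points = min_points)
  list(fit = fit, measure = m,
       status = if (fit$status == "ok") "ok" else fit$status)
}
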