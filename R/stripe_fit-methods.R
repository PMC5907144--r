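#' @export
print.stripe_fit <- function(x, ...) {
  cat("Stripe-slope GC-bias correction\n")
  cat(sprintf("  segments: %d\n", x$n_segments))
  cat(sprintf("  anchor line: slope %.4f, intercept %.4f\n",
              x$anchor_slope, x$anchor_intercept))
  cat(sprintf("  MAP slope: %.4f (log posterior %.4f)\n",
              x$map_slope, x$map_log_posterior))
  cat(sprintf("  stripes (density peaks): %d\n", nrow(x$peaks)))
  invisible(x)
}

#' Summarize a stripe-slope fit
#'
#' @param object A `stripe_fit`.
#' @param ... Unused.
#' @return A list of class `summary.stripe_fit` with the MAP estimate,
#'   posterior slope quantiles, acceptance rate and stripe table.
#' @export
summary.stripe_fit <- function(object, ...) {
  qs <- if (length(object$slope_samples))
    stats::quantile(object$slope_samples, c(0.025, 0.25, 0.5, 0.75, 0.975))
  else stats::setNames(rep(object$map_slope, 5),
                       c("2.5%", "25%", "50%", "75%", "97.5%"))
  stripes <- data.frame(
    stripe = seq_len(nrow(object$peaks)),
    location = object$peaks$location,
    n_segments = tabulate(object$stripe, nbins = nrow(object$peaks)))
  structure(list(map_slope = object$map_slope,
                 anchor_slope = object$anchor_slope,
                 slope_quantiles = qs,
                 acceptance_rate = if (nrow(object$chain))
                   mean(object$chain$accepted) else NA_real_,
                 n_segments = object$n_segments,
                 stripes = stripes),
            class = "summary.stripe_fit")
}

#' @export
print.summary.stripe_fit <- function(x, ...) {
  cat("Stripe-slope GC-bias correction\n\n")
  cat(sprintf("MAP slope: %.4f  (anchor slope %.4f)\n",
              x$map_slope, x$anchor_slope))
  cat("Posterior slope quantiles:\n")
  print(round(x$slope_quantiles, 4))
  cat(sprintf("Metropolis acceptance rate: %.2f\n", x$acceptance_rate))
  cat(sprintf("\nStripes (%d segments):\n", x$n_segments))
  print(x$stripes, row.names = FALSE)
  invisible(x)
}

#' @export
coef.stripe_fit <- function(object, ...) {
  c(slope = object$map_slope, intercept = object$anchor_intercept)
}

#' Predicted GC trend of a stripe-slope fit
#'
#' @param object A `stripe_fit`.
#' @param newdata Optional vector of GC fractions or a data frame / segment
#'   table with a `gc` column; defaults to the fitted segments.
#' @param ... Unused.
#' @return The trend line \eqn{m \cdot gc + c} at the MAP slope.
#' @export
predict.stripe_fit <- function(object, newdata = NULL, ...) {
  gc <- if (is.null(newdata)) object$gc
  else if (is.data.frame(newdata)) newdata$gc
  else newdata
  object$map_slope * gc + object$anchor_intercept
}

#' @export
residuals.stripe_fit <- function(object, ...) {
  object$y - predict(object)
}

#' Before/after GC-bias scatter of a stripe-slope fit
#'
#' Two panels: GC versus raw log-ratio Y with the anchor and MAP trend
#' lines, and GC versus corrected Y'.  Point colour follows the stripe
#' label.
#'
#' @param x A `stripe_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.stripe_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  col <- x$stripe %% 8 + 1
  if (length(x$gc)) {
    graphics::plot(x$gc, x$y, col = col, pch = 20,
                   xlab = "GC fraction", ylab = "log ratio Y",
                   main = "before correction", ...)
    graphics::abline(x$anchor_intercept, x$anchor_slope,
                     col = "grey40", lty = 2)
    graphics::abline(x$anchor_intercept, x$map_slope, col = "red")
    graphics::legend("topright", lty = c(2, 1), col = c("grey40", "red"),
                     legend = c("anchor", "MAP"), bty = "n", cex = 0.8)
    graphics::plot(x$gc, x$y_corrected, col = col, pch = 20,
                   xlab = "GC fraction", ylab = "corrected Y'",
                   main = "after correction", ...)
    graphics::abline(h = x$peaks$location, col = "grey80", lty = 3)
  } else {
    graphics::plot.new(); graphics::title("no segments")
    graphics::plot.new()
  }
  invisible(x)
}
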