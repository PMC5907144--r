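#' Construct a tumor/normal GC-bias model
#'
#' The expected depth of a segment with GC fraction \eqn{g} is modelled as
#' \deqn{D^N = f(g)\, d_1\, g\, e^{-a_1 g}, \qquad
#'       D^S = f(g)\, d_2\, g\, e^{-a_2 g},}
#' i.e. a GC response \eqn{f} shared by the two libraries, multiplied by a
#' sample-specific factor \eqn{d\,g\,e^{-a g}}.  The curvatures \eqn{a_1}
#' (normal) and \eqn{a_2} (tumor) are the quantities that matter downstream:
#' both \eqn{f} and the scales \eqn{d} cancel in the tumor/normal ratio, so
#' the log-ratio of a segment depends on GC only through the slope
#' \eqn{a_1 - a_2}.
#'
#' @param a1,d1 Curvature and scale of the normal library (`d1 > 0`).
#' @param a2,d2 Curvature and scale of the tumor library (`d2 > 0`).
#' @param f Shared GC-response specification: either `"constant"` or
#'   `"gaussian_bump"`, or a list with elements `shape`, `r0`, and (for the
#'   bump) `g0`, `sigma`.  The bump form
#'   \eqn{f(g) = r_0 \exp(-(g-g_0)^2 / 2\sigma^2)} mimics the unimodal
#'   coverage-versus-GC curves seen in whole-genome data.
#' @return An object of class `bias_model`.
#' @examples
#' bm <- bias_model(a1 = 1.3, d1 = 2.3, a2 = 2, d2 = 3)
#' expected_depth(0.5, bm, "tumor")
#' @export
bias_model <- function(a1 = 1.3, d1 = 2.3, a2 = 2, d2 = 3, f = "constant") {
  if (is.character(f)) f <- list(shape = f)
  stopifnot(is.list(f), !is.null(f$shape))
  f$shape <- match.arg(f$shape, c("constant", "gaussian_bump"))
  if (is.null(f$r0)) f$r0 <- 1000
  if (f$shape == "gaussian_bump") {
    if (is.null(f$g0)) f$g0 <- 0.45
    if (is.null(f$sigma)) f$sigma <- 0.10
    if (f$sigma <= 0) stop("f$sigma must be positive")
  }
  if (f$r0 <= 0) stop("f$r0 must be positive")
  if (d1 <= 0 || d2 <= 0) stop("scale parameters d1, d2 must be positive")
  structure(list(a1 = a1, d1 = d1, a2 = a2, d2 = d2, f = f),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("GC-bias model\n")
  cat(sprintf("  normal: a1 = %g, d1 = %g\n", x$a1, x$d1))
  cat(sprintf("  tumor:  a2 = %g, d2 = %g\n", x$a2, x$d2))
  cat(sprintf("  shared response f: %s", x$f$shape))
  if (x$f$shape == "gaussian_bump")
    cat(sprintf(" (r0 = %g, g0 = %g, sigma = %g)", x$f$r0, x$f$g0, x$f$sigma))
  else
    cat(sprintf(" (r0 = %g)", x$f$r0))
  cat(sprintf("\n  implied log-ratio slope a1 - a2 = %g\n", x$a1 - x$a2))
  invisible(x)
}

#' Evaluate the shared GC response f(gc)
#' @param gc GC fractions.
#' @param model A [bias_model()].
#' @return Positive response values, same length as `gc`.
#' @export
gc_response <- function(gc, model) {
  f <- model$f
  switch(f$shape,
         constant = rep(f$r0, length(gc)),
         gaussian_bump = f$r0 * exp(-(gc - f$g0)^2 / (2 * f$sigma^2)))
}

#' Expected depth under the GC-bias model
#'
#' @param gc GC fraction(s) in (0, 1]; `gc = 0` is a domain error because the
#'   sample factor divides by `d * gc`.
#' @param model A [bias_model()].
#' @param sample `"normal"` or `"tumor"`.
#' @return Expected depth \eqn{f(g)\, d\, g\, e^{-a g}}, vectorized over `gc`.
#' @export
expected_depth <- function(gc, model, sample = c("normal", "tumor")) {
  sample <- match.arg(sample)
  if (any(gc <= 0) || any(gc > 1))
    stop("gc must lie in (0, 1]: the model divides by d * gc")
  a <- if (sample == "normal") model$a1 else model$a2
  d <- if (sample == "normal") model$d1 else model$d2
  gc_response(gc, model) * d * gc * exp(-a * gc)
}

#' Predicted gap between two segments' log read-count ratios
#'
#' For segments i and j with average copy numbers `cbar_i`, `cbar_j` and GC
#' fractions `gc_i`, `gc_j`,
#' \deqn{Y_i - Y_j = \log(\bar C_i / \bar C_j) + (a_2 - a_1)(g_j - g_i),}
#' so at equal copy number the log-ratio falls on a line in GC with slope
#' \eqn{a_1 - a_2}.
#'
#' @param cbar_i,cbar_j Average copy numbers (must be positive).
#' @param gc_i,gc_j GC fractions.
#' @param model A [bias_model()].
#' @return The predicted difference \eqn{Y_i - Y_j}.
#' @export
log_ratio_gap <- function(cbar_i, cbar_j, gc_i, gc_j, model) {
  if (any(cbar_i <= 0) || any(cbar_j <= 0))
    stop("average copy numbers must be positive")
  log(cbar_i / cbar_j) + (model$a2 - model$a1) * (gc_j - gc_i)
}

#' Subclone state: copy number, B-allele copies and cell fraction
#'
#' @param phi Subclone frequency in \[0, 1\] (fraction of cells carrying the
#'   alteration; purity for the dominant clone).
#' @param copy_number Integer tumor copy number \eqn{C \ge 0}.
#' @param b_copies Integer B-allele copies in the tumor genotype,
#'   \eqn{0 \le b \le C}.
#' @return An object of class `subclone_state`.
#' @export
subclone_state <- function(phi, copy_number, b_copies) {
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (copy_number < 0 || copy_number != round(copy_number))
    stop("copy_number must be a non-negative integer")
  if (b_copies < 0 || b_copies > copy_number)
    stop("b_copies must lie in [0, copy_number]")
  structure(list(phi = phi, copy_number = as.integer(copy_number),
                 b_copies = as.integer(b_copies)),
            class = "subclone_state")
}

#' Average copy number of a mixed tumor/normal cell population
#'
#' \eqn{\bar C = \phi C + (1 - \phi)\,2}: the cell-fraction-weighted copy
#' number, with normal cells contributing 2 copies.
#'
#' @param state A [subclone_state()].
#' @return \eqn{\bar C \ge 0}.
#' @export
average_copy_number <- function(state) {
  state$phi * state$copy_number + (1 - state$phi) * 2
}

#' Expected tumor-sample B-allele frequency of an SCNA segment
#'
#' \deqn{\xi = \frac{\phi C \mu + (1-\phi)\, 2 \cdot \tfrac12}{\bar C}}
#' with \eqn{\mu = b/C} the tumor-genotype BAF.  The copy-neutral
#' heterozygous state (C = 2, b = 1) gives \eqn{\xi = 1/2} at every
#' \eqn{\phi}; swapping \eqn{b \mapsto C - b} reflects \eqn{\xi} about 1/2.
#'
#' @param state A [subclone_state()].
#' @return \eqn{\xi \in [0, 1]}.
#' @export
tumor_baf <- function(state) {
  cbar <- average_copy_number(state)
  if (cbar <= 0)
    stop("average copy number is zero: BAF undefined (phi = 1, C = 0)")
  mu_term <- if (state$copy_number > 0)
    state$phi * state$copy_number * (state$b_copies / state$copy_number)
  else 0
  (mu_term + (1 - state$phi) * 2 * 0.5) / cbar
}

#' Estimate subclonal frequency from a corrected log-ratio
#'
#' The corrected log-ratio of a segment relative to the copy-neutral baseline
#' estimates \eqn{\log(\bar C / 2)}; inverting
#' \eqn{\bar C = \phi C + (1-\phi) 2} gives
#' \eqn{\phi = (\bar C - 2)/(C - 2)} for \eqn{C \ne 2}.
#'
#' @param y_corrected Corrected log-ratio(s) \eqn{Y'} of the segment(s).
#' @param y_baseline Baseline mean corrected log-ratio (from [baseline_fit()]).
#' @param copy_number Assumed integer copy number of the segment's alteration;
#'   `copy_number = 2` is an error (any \eqn{\phi} yields \eqn{\bar C = 2},
#'   e.g. copy-neutral LOH carries no ratio signal).
#' @return A list with `phi` (clamped to \[0, 1\]), `phi_raw` (unclamped, for
#'   diagnostics) and `cbar` (implied average copy number).
#' @export
estimate_subclonal_freq <- function(y_corrected, y_baseline, copy_number) {
  if (copy_number == 2)
    stop("copy_number = 2 leaves the subclonal frequency undefined")
  cbar <- 2 * exp(y_corrected - y_baseline)
  phi_raw <- (cbar - 2) / (copy_number - 2)
  list(phi = pmin(1, pmax(0, phi_raw)), phi_raw = phi_raw, cbar = cbar)
}

#' Read or write a bias model as config keys
#'
#' Serializes to the flat key set `f.shape, f.r0, f.g0, f.sigma, normal.a,
#' normal.d, tumor.a, tumor.d` used in YAML run configs.
#'
#' @param model A [bias_model()].
#' @return For `bias_model_to_config`, a named list; for
#'   `bias_model_from_config`, a [bias_model()].
#' @export
bias_model_to_config <- function(model) {
  out <- list(f = list(shape = model$f$shape, r0 = model$f$r0),
              normal = list(a = model$a1, d = model$d1),
              tumor = list(a = model$a2, d = model$d2))
  if (model$f$shape == "gaussian_bump") {
    out$f$g0 <- model$f$g0
    out$f$sigma <- model$f$sigma
  }
  out
}

#' @param config A nested list as produced by [bias_model_to_config()].
#' @rdname bias_model_to_config
#' @export
bias_model_from_config <- function(config) {
  bias_model(a1 = config$normal$a, d1 = config$normal$d,
             a2 = config$tumor$a, d2 = config$tumor$d,
             f = config$f)
}
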