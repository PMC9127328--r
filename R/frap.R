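#' FRAP trace container
#'
#' Raw intensities of the bleached ROI, a background ROI and an unbleached
#' reference ROI over the recording, with the number of prebleach frames.
#' The standard acquisition holds 3 prebleach and 117 postbleach frames.
#'
#' @param times_s strictly increasing acquisition times (s).
#' @param bleach,background,reference raw mean ROI intensities per frame.
#' @param n_prebleach number of leading prebleach frames.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times_s, bleach, background, reference,
                       n_prebleach = 3L) {
  n <- length(times_s)
  stopifnot(n >= n_prebleach + 10L,
            length(bleach) == n, length(background) == n,
            length(reference) == n, n_prebleach >= 1L)
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  structure(list(times_s = as.numeric(times_s),
                 bleach = as.numeric(bleach),
                 background = as.numeric(background),
                 reference = as.numeric(reference),
                 n_prebleach = as.integer(n_prebleach),
                 normalized = NULL, excluded = FALSE,
                 excluded_reason = NA_character_),
            class = "frap_trace")
}

#' Read FRAP traces from CSV
#'
#' Expects columns `time_s`, `bleach`, `background`, `reference`.
#'
#' @param path CSV path.
#' @param n_prebleach number of prebleach frames.
#' @return A `frap_trace`.
#' @export
read_frap_trace <- function(path, n_prebleach = 3L) {
  tb <- utils::read.csv(path)
  stopifnot(all(c("time_s", "bleach", "background", "reference") %in%
                  names(tb)))
  frap_trace(tb$time_s, tb$bleach, tb$background, tb$reference, n_prebleach)
}

#' Normalize a FRAP trace
#'
#' Background-corrects the bleach signal frame by frame and divides by the
#' mean of the corrected prebleach values, so the prebleach level is 1 by
#' construction.
#'
#' @param trace a [frap_trace()].
#' @return The trace with `normalized` filled in.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  corr <- trace$bleach - trace$background
  pre <- mean(corr[seq_len(trace$n_prebleach)])
  if (!is.finite(pre) || pre <= 0)
    stop("prebleach corrected signal is not positive; cannot normalize")
  trace$normalized <- corr / pre
  trace
}

#' Focal-drift quality control
#'
#' A recording is excluded when the unbleached reference ROI varies by more
#' than 15% over the recording, measured as (max - min) / mean; this flags
#' vertical drift of the focal plane. The comparison is strict, so exactly
#' 15% variation is retained.
#'
#' @param trace a [frap_trace()].
#' @param max_variation exclusion threshold (default 0.15).
#' @return The trace with `excluded` / `excluded_reason` set.
#' @export
qc_exclude <- function(trace, max_variation = 0.15) {
  stopifnot(inherits(trace, "frap_trace"))
  ref <- trace$reference
  variation <- (max(ref) - min(ref)) / mean(ref)
  if (variation > max_variation) {
    trace$excluded <- TRUE
    trace$excluded_reason <- sprintf("reference variation %.3f > %.2f",
                                     variation, max_variation)
  }
  trace
}

#' Average normalized traces from one biological replicate
#'
#' Excluded traces are dropped; the remaining normalized traces (which must
#' share the time base) are averaged frame-wise before fitting.
#'
#' @param traces list of normalized [frap_trace()]s.
#' @return A `frap_trace` carrying the averaged normalized signal.
#' @export
average_traces <- function(traces) {
  traces <- Filter(function(t) !t$excluded, traces)
  if (length(traces) == 0L) stop("no traces left after QC exclusion")
  norm <- lapply(traces, function(t) {
    if (is.null(t$normalized)) t <- normalize_trace(t)
    t$normalized
  })
  if (length(unique(vapply(norm, length, integer(1)))) != 1L)
    stop("traces have different lengths; cannot average")
  avg <- traces[[1L]]
  avg$normalized <- Reduce(`+`, norm) / length(norm)
  avg
}

#' Fit the hyperbolic recovery model
#'
#' Least-squares fit of `y(t) = offset + R * t / (t + t_half)` to the
#' postbleach points of a normalized trace. Time is measured from the
#' bleach, with the first postbleach frame at one frame interval, so the
#' model's `y(0) = offset` is the bleach floor. The fit is run from three
#' different `t_half` starting values and the best sum of squares kept;
#' parameters are bounded (`offset`, `R` in `[0, 1.5]`, `t_half` up to ten
#' recording lengths) and a fit ending at a bound or with a vanishing
#' recovery amplitude is flagged.
#'
#' @param trace a normalized [frap_trace()] (or one to be normalized).
#' @return An object of class `frap_fit`: list with `offset`,
#'   `maximal_recovery`, `t_half_s`, `r2`, `flag` (`NA` when clean).
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (is.null(trace$normalized)) trace <- normalize_trace(trace)
  np <- trace$n_prebleach
  post <- seq.int(np + 1L, length(trace$times_s))
  if (length(post) < 10L) stop("need at least 10 postbleach points")
  t <- trace$times_s[post] - trace$times_s[np]
  y <- trace$normalized[post]
  T_tot <- max(t)
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-20)
    return(structure(list(offset = mean(y), maximal_recovery = 0,
                          t_half_s = NA_real_, r2 = NA_real_,
                          flag = "flat trace: t_half unidentifiable"),
                     class = "frap_fit"))
  best <- NULL
  for (th0 in c(0.05, 0.2, 0.5) * T_tot) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ off + R * t / (t + th),
                        start = list(off = max(min(y), 0), R = max(y) - min(y),
                                     th = th0),
                        lower = c(off = 0, R = 0, th = 1e-6),
                        upper = c(off = 1.5, R = 1.5, th = 10 * T_tot),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop("recovery fit did not converge")
  cf <- stats::coef(best$fit)
  flag <- NA_character_
  if (cf["R"] < 1e-3) flag <- "flat trace: t_half unidentifiable"
  else if (cf["th"] >= 10 * T_tot - 1e-6) flag <- "t_half at upper bound"
  else if (cf["th"] <= 2e-6) flag <- "t_half at lower bound"
  structure(list(offset = unname(cf["off"]),
                 maximal_recovery = unname(cf["R"]),
                 t_half_s = unname(cf["th"]),
                 r2 = if (sst > 0) 1 - best$ss / sst else NA_real_,
                 flag = flag),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> offset %.3f | maximal recovery %.3f | t1/2 %.2f s | R2 %.4f%s\n",
    x$offset, x$maximal_recovery, x$t_half_s, x$r2,
    if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}
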