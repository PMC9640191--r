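#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of `cutoff_mv` (default 0 mV); its time is
#' the local maximum of the following suprathreshold excursion.
#'
#' @param trace a `vc_trace`, or a numeric voltage vector.
#' @param cutoff_mv detection level (mV).
#' @param dt_ms sample interval when `trace` is a bare vector.
#' @return tibble with columns `t_ms`, `peak_mv`.
#' @export
detect_spikes <- function(trace, cutoff_mv = 0, dt_ms = NULL) {
  if (inherits(trace, "vc_trace") || is.data.frame(trace)) {
    v <- trace$v_mV
    t <- trace$t_ms
  } else {
    v <- as.numeric(trace)
    dt_ms <- dt_ms %||% 1
    t <- (seq_along(v) - 1) * dt_ms
  }
  above <- v >= cutoff_mv
  if (!any(above)) return(tibble(t_ms = numeric(), peak_mv = numeric()))
  d <- diff(c(FALSE, above))
  starts <- which(d == 1)
  ends <- c(which(d == -1) - 1, if (above[length(v)]) length(v))
  ends <- ends[seq_along(starts)]
  peaks <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(v[seg])]
  }, integer(1))
  tibble(t_ms = t[peaks], peak_mv = v[peaks])
}

#' Membrane potential at action-potential threshold
#'
#' Two conventions are provided. `"boundary"` (the default used for quantal
#' sweeps) reports the peak depolarization of the largest subthreshold trial,
#' i.e. the voltage at the sub/suprathreshold boundary that a conductance
#' sweep actually measures. `"dvdt"` reports, on a single suprathreshold
#' trace, the voltage at the first sample where dV/dt exceeds
#' `dvdt_mv_ms` (default 20 mV/ms) before the spike peak.
#'
#' @param traces for `"boundary"`: a list of `vc_trace`s ordered by
#'   increasing stimulus strength; for `"dvdt"`: a single suprathreshold
#'   `vc_trace`.
#' @param method `"boundary"` or `"dvdt"`.
#' @param dvdt_mv_ms rate criterion for `"dvdt"` (mV/ms).
#' @return threshold voltage (mV), or `NA` if it cannot be measured.
#' @export
ap_threshold <- function(traces, method = c("boundary", "dvdt"),
                         dvdt_mv_ms = 20) {
  method <- match.arg(method)
  if (method == "boundary") {
    spiked <- vapply(traces, function(tr) nrow(detect_spikes(tr)) > 0, logical(1))
    if (!any(spiked) || all(spiked)) return(NA_real_)
    last_sub <- max(which(!spiked & seq_along(spiked) < which(spiked)[1]))
    return(max(traces[[last_sub]]$v_mV))
  }
  tr <- if (is.data.frame(traces)) traces else traces[[1]]
  sp <- detect_spikes(tr)
  if (nrow(sp) == 0) return(NA_real_)
  dt <- attr(tr, "dt_ms") %||% (tr$t_ms[2] - tr$t_ms[1])
  pk <- which(tr$t_ms == sp$t_ms[1])
  dv <- diff(tr$v_mV) / dt
  idx <- which(dv[seq_len(pk - 1)] >= dvdt_mv_ms)
  if (length(idx) == 0) return(NA_real_)
  tr$v_mV[idx[1]]
}

#' Explained variance of a prediction
#'
#' `1 - mean((pred - truth)^2) / var(truth)`: 1 for a perfect prediction,
#' 0 for predicting the mean, negative for predictions worse than the mean.
#'
#' @param pred,truth numeric vectors of equal length.
#' @return a fraction (may be negative).
#' @export
explained_variance <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("`pred` and `truth` must have equal length")
  vt <- mean((truth - mean(truth))^2)
  if (vt == 0) abort("`truth` has zero variance; explained variance is undefined")
  1 - mean((pred - truth)^2) / vt
}

#' Match predicted against ground-truth spikes
#'
#' Greedy one-to-one matching of spike times within a temporal window:
#' candidate pairs are accepted in order of ascending |Delta t|, each spike
#' matched at most once; a pair counts as a true positive when
#' |Delta t| <= `window_ms / 2`. Precision = TP/(TP+FP), recall =
#' TP/(TP+FN). With no predicted spikes precision is reported as 0 and with
#' no true spikes recall as 1, both flagged as degenerate.
#'
#' @param pred,truth `vc_trace`s, spike tibbles from [detect_spikes()], or
#'   numeric spike-time vectors (ms).
#' @param window_ms total matching window (default 10 ms, i.e. +/-5 ms).
#' @return an object of class `vc_spike_match`: a list with counts `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `shifts_ms` (signed, pred - truth),
#'   and `degenerate`.
#' @export
spike_match <- function(pred, truth, window_ms = 10) {
  get_times <- function(x) {
    if (is.numeric(x)) return(sort(as.numeric(x)))
    if (is.data.frame(x) && "v_mV" %in% names(x)) return(detect_spikes(x)$t_ms)
    if (is.data.frame(x)) return(sort(x$t_ms))
    abort("cannot interpret spike input")
  }
  tp_ <- get_times(pred)
  tt_ <- get_times(truth)
  half <- window_ms / 2
  pairs <- NULL
  if (length(tp_) > 0 && length(tt_) > 0) {
    cand <- tidyr::expand_grid(i = seq_along(tp_), j = seq_along(tt_))
    cand$dt <- tp_[cand$i] - tt_[cand$j]
    cand <- cand[abs(cand$dt) <= half, , drop = FALSE]
    cand <- cand[order(abs(cand$dt)), , drop = FALSE]
    used_i <- logical(length(tp_)); used_j <- logical(length(tt_))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_i[i] && !used_j[j]) {
        keep[k] <- TRUE
        used_i[i] <- TRUE; used_j[j] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- length(tp_) - tp
  fn <- length(tt_) - tp
  degenerate <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "no_predicted_spikes"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "no_true_spikes"); 1
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 shifts_ms = if (is.null(pairs)) numeric() else sort(pairs$dt),
                 window_ms = window_ms, degenerate = degenerate),
            class = "vc_spike_match")
}

#' @export
print.vc_spike_match <- function(x, ...) {
  cat(sprintf("<vc_spike_match> TP %d FP %d FN %d | precision %.3f recall %.3f",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  if (x$tp > 0) cat(sprintf(" | shift %.2f +/- %.2f ms",
                            mean(x$shifts_ms), sd(x$shifts_ms)))
  if (length(x$degenerate)) cat(" [", paste(x$degenerate, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' @export
tidy.vc_spike_match <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn,
         precision = x$precision, recall = x$recall,
         mean_shift_ms = if (x$tp > 0) mean(x$shifts_ms) else NA_real_,
         sd_shift_ms = if (x$tp > 1) sd(x$shifts_ms) else NA_real_)
}

#' Fit firing-response curves
#'
#' Least-squares fits of a line `y = a + b x` (compatible with subtractive
#' or divisive-subtractive inhibition) and a four-parameter logistic
#' `y = A2 + (A1 - A2) / (1 + exp((x - x0)/dx))` (divisive normalization)
#' to an input-rate vs output-rate table, compared by AIC in the
#' Gaussian-likelihood form `n log(RSS/n) + 2k`.
#'
#' @param data data frame with the predictor and response columns.
#' @param x,y column names (character) of input and output rate.
#' @return an object of class `vc_firing_fit` with elements `linear`,
#'   `logistic` (fit objects or NULL), `aic` (named vector), `best`,
#'   `fallback` (TRUE when the logistic did not converge).
#' @export
fit_firing_models <- function(data, x = "rate_hz", y = "out_hz") {
  d <- data.frame(x = data[[x]], y = data[[y]])
  d <- d[complete.cases(d), ]
  if (nrow(d) < 5) abort("need at least 5 points to fit firing models")
  lin <- lm(y ~ x, data = d)
  rss_lin <- sum(residuals(lin)^2)
  n <- nrow(d)
  aic_ls <- function(rss, k) n * log(rss / n) + 2 * k
  logi <- tryCatch({
    start <- list(A1 = max(d$y), A2 = min(d$y),
                  x0 = stats::median(d$x), dx = -diff(range(d$x)) / 8)
    minpack.lm::nlsLM(y ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx)),
                      data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  aic <- c(linear = aic_ls(rss_lin, 2))
  if (!is.null(logi)) {
    aic["logistic"] <- aic_ls(sum(residuals(logi)^2), 4)
  }
  best <- names(aic)[which.min(aic)]
  structure(list(linear = lin, logistic = logi, aic = aic, best = best,
                 fallback = is.null(logi), n = n, data = as_tibble(d)),
            class = "vc_firing_fit")
}

#' @export
print.vc_firing_fit <- function(x, ...) {
  cat(sprintf("<vc_firing_fit> n = %d, best: %s (dAIC %.2f)%s\n",
              x$n, x$best,
              if (length(x$aic) > 1) abs(diff(x$aic)) else NA,
              if (x$fallback) " [logistic fell back]" else ""))
  invisible(x)
}

#' @export
tidy.vc_firing_fit <- function(x, ...) {
  out <- tibble(model = "linear",
                term = c("a", "b"),
                estimate = unname(coef(x$linear)))
  if (!is.null(x$logistic)) {
    cf <- coef(x$logistic)
    out <- dplyr::bind_rows(out, tibble(model = "logistic",
                                        term = names(cf),
                                        estimate = unname(cf)))
  }
  out
}

#' @export
glance.vc_firing_fit <- function(x, ...) {
  tibble(n = x$n, best = x$best,
         aic_linear = x$aic[["linear"]],
         aic_logistic = if ("logistic" %in% names(x$aic)) x$aic[["logistic"]] else NA_real_,
         logistic_converged = !x$fallback)
}

#' Predict from the fitted logistic component
#' @param object a `vc_firing_fit`.
#' @param newdata numeric vector of input rates.
#' @param ... unused.
#' @export
predict.vc_firing_fit <- function(object, newdata, ...) {
  if (object$best == "logistic" && !is.null(object$logistic)) {
    predict(object$logistic, newdata = data.frame(x = newdata))
  } else {
    predict(object$linear, newdata = data.frame(x = newdata))
  }
}

#' Summarize a quantal conductance sweep
#'
#' Runs over the sweep traces, measures the peak depolarization of every
#' subthreshold trial, fits amplitude vs quantal conductance by ordinary
#' least squares, and reports the AP threshold (boundary convention, see
#' [ap_threshold()]) when the sweep contains suprathreshold trials.
#'
#' @param traces list of `vc_trace`s, one per conductance.
#' @param g_ns numeric vector of quantal conductances (nS), parallel to
#'   `traces`.
#' @param v_rest resting potential used as amplitude baseline; defaults to
#'   the first sample of the first trace.
#' @return a list of class `vc_iv_summary`: `slope_mv_ns`, `intercept_mv`,
#'   `r`, `threshold_mv` (NA when no trial spiked), `first_suprathreshold_ns`,
#'   `n_sub`, and the per-trial table `trials`.
#' @export
iv_summary <- function(traces, g_ns, v_rest = NULL) {
  if (length(traces) != length(g_ns)) abort("`traces` and `g_ns` lengths differ")
  v_rest <- v_rest %||% traces[[1]]$v_mV[1]
  trials <- tibble(
    g_ns = g_ns,
    peak_mv = vapply(traces, function(tr) max(tr$v_mV) - v_rest, numeric(1)),
    spiked = vapply(traces, function(tr) nrow(detect_spikes(tr)) > 0, logical(1))
  )
  sub <- trials[!trials$spiked, ]
  if (nrow(sub) < 2) abort("no (or too few) subthreshold trials in sweep")
  fit <- lm(peak_mv ~ g_ns, data = sub)
  thr <- if (any(trials$spiked)) ap_threshold(traces, method = "boundary") else NA_real_
  structure(list(
    slope_mv_ns = unname(coef(fit)[2]),
    intercept_mv = unname(coef(fit)[1]),
    r = stats::cor(sub$g_ns, sub$peak_mv),
    threshold_mv = thr,
    first_suprathreshold_ns = if (any(trials$spiked)) min(trials$g_ns[trials$spiked]) else NA_real_,
    n_sub = nrow(sub), trials = trials
  ), class = "vc_iv_summary")
}

#' @export
print.vc_iv_summary <- function(x, ...) {
  cat(sprintf(
    "<vc_iv_summary> slope %.3f mV/nS (r = %.4f, n_sub = %d); AP threshold %s\n",
    x$slope_mv_ns, x$r, x$n_sub,
    if (is.na(x$threshold_mv)) "absent (all subthreshold)"
    else sprintf("%.2f mV at %.2g nS", x$threshold_mv, x$first_suprathreshold_ns)))
  invisible(x)
}

#' @export
glance.vc_iv_summary <- function(x, ...) {
  tibble(slope_mv_ns = x$slope_mv_ns, intercept_mv = x$intercept_mv, r = x$r,
         threshold_mv = x$threshold_mv,
         first_suprathreshold_ns = x$first_suprathreshold_ns, n_sub = x$n_sub)
}
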