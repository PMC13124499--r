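new_peak_integration <- function(apex_rt, left, right, area, detected,
                                 apex_intensity = NA_real_,
                                 baseline = NA_real_, reason = "") {
  structure(list(apex_rt = apex_rt, left = left, right = right,
                 area = area, detected = detected,
                 apex_intensity = apex_intensity, baseline = baseline,
                 reason = reason), class = "peak_integration")
}

#' @export
print.peak_integration <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<peak> apex %.3f min, bounds [%.3f, %.3f], area %.4g\n",
                x$apex_rt, x$left, x$right, x$area))
  } else {
    cat(sprintf("<peak> not detected (%s)\n",
                if (nzchar(x$reason)) x$reason else "below S/N"))
  }
  invisible(x)
}

#' Detect a chromatographic peak in a retention-time window
#'
#' Median baseline over the window is subtracted, the trace is smoothed with
#' a 3-point moving median, and the apex is the maximum smoothed intensity
#' in the window (or, with `anchor_rt` set, the local maximum nearest the
#' anchor - standard practice for the light channel, whose retention time is
#' defined by the heavy standard). Peak boundaries are where the smoothed
#' signal falls below `boundary_frac` of the apex (or the window edge).
#' Detection requires apex signal-to-baseline-noise >= `sn_min`.
#'
#' @param trace a `chrom_trace`.
#' @param rt_window numeric length-2 window (minutes); defaults to the full
#'   trace.
#' @param sn_min minimum apex signal/noise (default 3).
#' @param boundary_frac boundary threshold as a fraction of apex (default
#'   0.05).
#' @param anchor_rt optional retention time to anchor peak selection to.
#' @return a `peak_integration`.
#' @export
detect_peak <- function(trace, rt_window = NULL, sn_min = 3,
                        boundary_frac = 0.05, anchor_rt = NULL) {
  stopifnot(inherits(trace, "chrom_trace"))
  if (is.null(rt_window)) rt_window <- range(trace$rt)
  if (rt_window[1] > max(trace$rt) || rt_window[2] < min(trace$rt)) {
    stop("window lies outside the trace time range")
  }
  w <- which(trace$rt >= rt_window[1] & trace$rt <= rt_window[2])
  if (length(w) < 5) stop("fewer than 5 samples in the window")
  rt <- trace$rt[w]
  y <- trace$intensity[w]
  baseline <- stats::median(y)
  sub <- y - baseline
  sm <- stats::runmed(sub, 3)
  noise <- stats::mad(y - stats::runmed(y, 3))
  if (noise == 0) {
    tail_vals <- sub[sm < max(sm) * boundary_frac]
    noise <- if (length(tail_vals) > 1) stats::mad(tail_vals) else 0
  }
  if (is.na(noise)) noise <- 0

  # candidate apexes: local maxima of the smoothed signal
  n <- length(sm)
  is_max <- sm >= c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & sm > 0
  cand <- which(is_max)
  if (length(cand) == 0) {
    return(new_peak_integration(NA, NA, NA, 0, FALSE,
                                reason = "no positive signal"))
  }
  apex_i <- if (!is.null(anchor_rt)) {
    # among candidates within 10x of the strongest, take the nearest
    strong <- cand[sm[cand] >= max(sm[cand]) / 10]
    strong[which.min(abs(rt[strong] - anchor_rt))]
  } else {
    cand[which.max(sm[cand])]
  }
  apex_sub <- sm[apex_i]
  detected <- if (noise > 0) (apex_sub / noise) >= sn_min else apex_sub > 0
  if (!detected) {
    return(new_peak_integration(rt[apex_i], NA, NA, 0, FALSE,
                                apex_intensity = y[apex_i],
                                baseline = baseline,
                                reason = "signal-to-noise below threshold"))
  }
  thr <- boundary_frac * apex_sub
  li <- apex_i
  while (li > 1 && sm[li - 1] >= thr && sm[li - 1] <= sm[li] * 1.5) li <- li - 1
  ri <- apex_i
  while (ri < n && sm[ri + 1] >= thr && sm[ri + 1] <= sm[ri] * 1.5) ri <- ri + 1
  area <- integrate_peak(trace, rt[li], rt[ri])
  new_peak_integration(rt[apex_i], rt[li], rt[ri], area, TRUE,
                       apex_intensity = y[apex_i], baseline = baseline)
}

#' Trapezoidal peak area with linear baseline subtraction
#'
#' Integrates the samples inside `[left, right]` by the trapezoidal rule
#' after subtracting the straight line between the boundary intensities,
#' floored at zero.
#'
#' @param trace a `chrom_trace`.
#' @param left,right boundary retention times (minutes), `left < right`,
#'   inside the trace.
#' @return area in intensity x minutes.
#' @export
integrate_peak <- function(trace, left, right) {
  if (left >= right) stop("inverted integration boundaries")
  if (left < min(trace$rt) || right > max(trace$rt)) {
    stop("boundaries outside the trace")
  }
  w <- which(trace$rt >= left & trace$rt <= right)
  rt <- trace$rt[w]
  y <- trace$intensity[w]
  base <- y[1] + (y[length(y)] - y[1]) * (rt - rt[1]) / (rt[length(rt)] - rt[1])
  s <- pmax(y - base, 0)
  sum(diff(rt) * (s[-1] + s[-length(s)]) / 2)
}

#' Absolute amount from a light/heavy area ratio
#'
#' @param auc_light,auc_heavy integrated areas of the endogenous (light) and
#'   spiked heavy-standard peaks.
#' @param spike_amount heavy-standard amount, fmol.
#' @return amount in fmol: `spike_amount * auc_light / auc_heavy`.
#' @export
absolute_amount <- function(auc_light, auc_heavy, spike_amount) {
  if (is.na(auc_heavy) || auc_heavy <= 0) {
    stop("heavy standard not detected; quantification failed")
  }
  spike_amount * auc_light / auc_heavy
}

#' Co-elution check for a light/heavy peak pair
#'
#' @param light,heavy `peak_integration` objects.
#' @param rt_tol apex time tolerance in minutes (default 0.2, inclusive).
#' @return TRUE when both peaks are detected and their apexes agree within
#'   `rt_tol`; FALSE (with a `reason` attribute) otherwise.
#' @export
co_elution_check <- function(light, heavy, rt_tol = 0.2) {
  if (!isTRUE(light$detected) || !isTRUE(heavy$detected)) {
    out <- FALSE
    attr(out, "reason") <- "peak not detected in one or both channels"
    return(out)
  }
  abs(light$apex_rt - heavy$apex_rt) <= rt_tol
}

#' Quantify one light/heavy chromatogram pair
#'
#' The heavy channel (known retention time, strong signal) is detected
#' first; the light peak is then anchored to the heavy apex. Returns the
#' absolute amount together with the co-elution flag.
#'
#' @param light,heavy `chrom_trace` pair.
#' @param spike_amount heavy spike, fmol.
#' @param rt_window optional retention-time window.
#' @param rt_tol co-elution tolerance, minutes.
#' @param ... passed to [detect_peak()].
#' @return list(amount, detected, co_elution_ok, light_peak, heavy_peak);
#'   `amount` is NA with `detected = FALSE` when the heavy standard is not
#'   found, and 0 when the light channel holds no peak.
#' @export
quantify_pair <- function(light, heavy, spike_amount, rt_window = NULL,
                          rt_tol = 0.2, ...) {
  hp <- detect_peak(heavy, rt_window = rt_window, ...)
  if (!hp$detected) {
    return(list(amount = NA_real_, detected = FALSE, co_elution_ok = FALSE,
                light_peak = NULL, heavy_peak = hp))
  }
  lp <- detect_peak(light, rt_window = rt_window, anchor_rt = hp$apex_rt, ...)
  if (!lp$detected) {
    return(list(amount = 0, detected = TRUE, co_elution_ok = FALSE,
                light_peak = lp, heavy_peak = hp))
  }
  list(amount = absolute_amount(lp$area, hp$area, spike_amount),
       detected = TRUE, co_elution_ok = co_elution_check(lp, hp, rt_tol),
       light_peak = lp, heavy_peak = hp)
}

#' Summarize per-transition amounts into timepoint means
#'
#' @param amounts data.frame with columns analyte, timepoint, transition,
#'   amount, and optionally `detected` (undetected transitions are excluded
#'   from the mean with the exclusion counted).
#' @return data.frame per analyte/timepoint: n_detected, n_excluded,
#'   mean_amount, se (sd/sqrt(n), NA for n < 2).
#' @export
summarize_timepoints <- function(amounts) {
  stopifnot(all(c("analyte", "timepoint", "transition", "amount") %in%
                  names(amounts)))
  if (!"detected" %in% names(amounts)) amounts$detected <- !is.na(amounts$amount)
  groups <- split(amounts, paste(amounts$analyte, amounts$timepoint, sep = "\r"))
  out <- do.call(rbind, lapply(groups, function(g) {
    ok <- g$detected & !is.na(g$amount)
    n <- sum(ok)
    data.frame(analyte = g$analyte[1], timepoint = g$timepoint[1],
               n_detected = n, n_excluded = nrow(g) - n,
               mean_amount = if (n > 0) mean(g$amount[ok]) else NA_real_,
               se = if (n >= 2) stats::sd(g$amount[ok]) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$analyte, out$timepoint), , drop = FALSE]
}

#' Paired pre/post-surgery test across analytes
#'
#' Classical paired Student's t test on per-analyte differences between the
#' presurgical means and the first postsurgical timepoint, two-sided. Zero
#' variance of the differences yields a degenerate flag instead of a number.
#'
#' @param pre,post named numeric vectors of per-analyte mean amounts; names
#'   are analyte ids and must pair up.
#' @return list(t, p, df, degenerate, n).
#' @export
paired_pre_post_test <- function(pre, post) {
  if (is.null(names(pre)) || is.null(names(post))) {
    if (length(pre) != length(post)) stop("unpaired analyte vectors")
    names(pre) <- names(post) <- paste0("analyte", seq_along(pre))
  }
  if (!setequal(names(pre), names(post))) {
    stop("analyte ids do not pair up between pre and post")
  }
  post <- post[names(pre)]
  if (length(pre) < 2) stop("need >= 2 paired analytes")
  d <- pre - post
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                degenerate = TRUE, n = length(d)))
  }
  tt <- stats::t.test(pre, post, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE, n = length(d))
}
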