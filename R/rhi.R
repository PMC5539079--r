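#' Per-beat pulse amplitudes within a signal interval
#'
#' Locates cardiac beats as local maxima of the pulse-amplitude signal,
#' enforcing a minimum peak separation of half the estimated beat period
#' (taken from the dominant spectral component of the interval, which is
#' robust to additive noise), and measures each beat as peak minus the
#' following trough (the minimum before the next peak). The last peak, which
#' has no following trough, is dropped.
#'
#' @param signal a [pat_signal()].
#' @param interval phase name (`"baseline"`, `"occlusion"`, `"post"`) or a
#'   half-open 1-based index interval `c(start, end)`.
#' @return numeric vector of per-beat peak-to-trough amplitudes.
#' @export
beat_amplitudes <- function(signal, interval = "baseline") {
  stopifnot(inherits(signal, "pat_signal"))
  if (is.character(interval)) {
    stopifnot(interval %in% names(signal$phases))
    interval <- signal$phases[[interval]]
  }
  stopifnot(length(interval) == 2L, interval[1] >= 1,
            interval[2] <= length(signal$samples) + 1, interval[1] < interval[2])
  x <- signal$samples[interval[1]:(interval[2] - 1)]
  n <- length(x)
  if (n < 3) stop("interval too short for beat detection", call. = FALSE)

  # candidate peaks: strict local maxima in the upper half of the range
  up <- which(diff(sign(diff(x))) < 0) + 1L
  floor_level <- min(x) + 0.5 * (max(x) - min(x))
  cand <- up[x[up] > floor_level]
  if (length(cand) < 2)
    stop("fewer than 2 beats detected in interval; signal unusable", call. = FALSE)

  # beat-period estimate: dominant non-DC spectral component of the interval
  spec <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:max(2, floor(n / 2))
  period <- n / (half[which.max(spec[half])] - 1)
  min_sep <- max(1, floor(0.5 * period))
  # greedy: keep the tallest peaks subject to the separation constraint
  keep <- logical(length(cand))
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 2)
    stop("fewer than 2 beats detected in interval; signal unusable", call. = FALSE)

  amp <- numeric(length(peaks) - 1L)
  for (i in seq_len(length(peaks) - 1L)) {
    trough <- min(x[peaks[i]:peaks[i + 1L]])
    amp[i] <- x[peaks[i]] - trough
  }
  amp
}

# peak-to-trough amplitude proxy from signal power (exact for a sinusoid)
rms_amplitude <- function(x) 2 * sqrt(2) * sqrt(mean((x - mean(x))^2))

#' Reactive hyperemia index from a pulse-amplitude recording
#'
#' The RHI is the ratio of the post-occlusion to the pre-occlusion (baseline)
#' average pulse amplitude. By default the amplitude of each phase is the
#' mean per-beat peak-to-trough amplitude ([beat_amplitudes()]); an
#' RMS-envelope alternative is available. An advisory flag `occlusion_ok`
#' reports whether the residual pulse during occlusion stayed below 10% of
#' the baseline amplitude (a quality check, not a failure condition).
#'
#' @param signal a [pat_signal()].
#' @param post_window optional analysis window within the post-occlusion
#'   phase, `c(start_s, end_s)` in seconds from the start of the post phase;
#'   default is the entire post phase.
#' @param method `"beats"` (per-beat peak-to-trough, default) or `"rms"`.
#' @return An object of class `rhi_result`: `pre_avg`, `post_avg`, `rhi`,
#'   `beats_pre`, `beats_post`, `occlusion_ok`.
#' @examples
#' sig <- generate_pat(pat_spec(hyperemia_ratio = 1.5, noise_sd = 0))
#' compute_rhi(sig)
#' @export
compute_rhi <- function(signal, post_window = NULL, method = c("beats", "rms")) {
  stopifnot(inherits(signal, "pat_signal"))
  method <- match.arg(method)

  post_iv <- signal$phases$post
  if (!is.null(post_window)) {
    stopifnot(length(post_window) == 2L, post_window[1] >= 0,
              post_window[1] < post_window[2])
    s <- post_iv[1] + round(post_window[1] * signal$sample_rate)
    e <- min(post_iv[1] + round(post_window[2] * signal$sample_rate), post_iv[2])
    if (s >= e) stop("`post_window` lies outside the post phase", call. = FALSE)
    post_iv <- c(s, e)
  }

  if (method == "beats") {
    pre <- beat_amplitudes(signal, "baseline")
    post <- beat_amplitudes(signal, post_iv)
    pre_avg <- mean(pre); post_avg <- mean(post)
    beats_pre <- length(pre); beats_post <- length(post)
  } else {
    b <- signal$phases$baseline
    pre_avg <- rms_amplitude(signal$samples[b[1]:(b[2] - 1)])
    post_avg <- rms_amplitude(signal$samples[post_iv[1]:(post_iv[2] - 1)])
    beats_pre <- beats_post <- NA_integer_
  }
  if (pre_avg <= 0)
    stop("pre-occlusion average amplitude is zero; RHI undefined", call. = FALSE)

  occ <- signal$phases$occlusion
  occ_amp <- rms_amplitude(signal$samples[occ[1]:(occ[2] - 1)])
  structure(list(pre_avg = pre_avg, post_avg = post_avg,
                 rhi = post_avg / pre_avg,
                 beats_pre = beats_pre, beats_post = beats_post,
                 occlusion_ok = occ_amp < 0.1 * pre_avg),
            class = "rhi_result")
}

#' @export
print.rhi_result <- function(x, ...) {
  cat(sprintf("<rhi_result> RHI = %.4f (pre %.4f, post %.4f; beats %s/%s; occlusion %s)\n",
              x$rhi, x$pre_avg, x$post_avg, x$beats_pre, x$beats_post,
              if (isTRUE(x$occlusion_ok)) "ok" else "FLAGGED"))
  invisible(x)
}
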