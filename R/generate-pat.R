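#' Specification for a synthetic pulse-amplitude (PAT) recording
#'
#' Emulates a fingertip peripheral-arterial-tone recording around a
#' reactive-hyperemia challenge: a baseline phase, a cuff-occlusion phase in
#' which the pulse is almost abolished, and a post-occlusion phase whose pulse
#' amplitude is the baseline amplitude times the true hyperemic ratio.
#' Defaults use desk-scale phase durations (60/30/30 s); the full clinical
#' protocol (600/300/300 s) is a matter of changing `durations`. The noise-free
#' index is invariant to proportional shortening of the phases. The default
#' beat rate (1.25 Hz) is an exact divisor of the default sample rate so that
#' sampling hits every oscillation peak and trough exactly.
#'
#' @param sample_rate sampling frequency, Hz.
#' @param durations numeric(3): baseline, occlusion and post-occlusion
#'   durations in seconds.
#' @param beat_rate cardiac frequency, Hz.
#' @param baseline_amplitude half peak-to-trough pulse amplitude during
#'   baseline, arbitrary units.
#' @param hyperemia_ratio true post/pre envelope amplitude ratio (> 0).
#' @param occlusion_residual residual envelope fraction during occlusion
#'   (must be below 0.1).
#' @param noise_sd SD of additive white Gaussian noise, same units as the
#'   signal.
#' @param seed integer RNG seed.
#' @return An object of class `pat_spec`.
#' @export
pat_spec <- function(sample_rate = 100, durations = c(60, 30, 30),
                     beat_rate = 1.25, baseline_amplitude = 1,
                     hyperemia_ratio = 1.73, occlusion_residual = 0.05,
                     noise_sd = 0.01, seed = 1L) {
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  stopifnot(length(durations) == 3L, all(durations > 0))
  stop_if_not_scalar_pos(beat_rate, "beat_rate")
  stop_if_not_scalar_pos(baseline_amplitude, "baseline_amplitude")
  stop_if_not_scalar_pos(hyperemia_ratio, "hyperemia_ratio")
  if (occlusion_residual < 0 || occlusion_residual >= 0.1)
    stop("`occlusion_residual` must lie in [0, 0.1)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(sample_rate = sample_rate, durations = durations,
                 beat_rate = beat_rate, baseline_amplitude = baseline_amplitude,
                 hyperemia_ratio = hyperemia_ratio,
                 occlusion_residual = occlusion_residual,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "pat_spec")
}

#' Construct a phase-annotated pulse-amplitude signal
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate Hz.
#' @param phases named list with elements `baseline`, `occlusion`, `post`,
#'   each a half-open 1-based index interval `c(start, end)` (end exclusive).
#'   Intervals must be ordered, non-overlapping and within bounds.
#' @return An object of class `pat_signal`.
#' @export
pat_signal <- function(samples, sample_rate, phases) {
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  stopifnot(is.numeric(samples), length(samples) > 0,
            setequal(names(phases), c("baseline", "occlusion", "post")))
  phases <- lapply(phases, function(p) as.integer(round(p)))
  iv <- rbind(phases$baseline, phases$occlusion, phases$post)
  if (any(iv[, 1] >= iv[, 2]) || any(iv[, 1] < 1) || any(iv[, 2] > length(samples) + 1))
    stop("phase intervals must be non-empty, 1-based and within the signal", call. = FALSE)
  if (iv[1, 2] > iv[2, 1] || iv[2, 2] > iv[3, 1])
    stop("phase intervals must be ordered baseline < occlusion < post and non-overlapping",
         call. = FALSE)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 phases = phases), class = "pat_signal")
}

#' Generate a synthetic PAT recording
#'
#' Produces an amplitude-modulated sinusoid at the cardiac beat rate whose
#' per-phase envelope is `baseline_amplitude * c(1, occlusion_residual,
#' hyperemia_ratio)`, plus optional white noise, with phase boundary indices
#' recorded in the output.
#'
#' @param spec a [pat_spec()].
#' @return A [pat_signal()].
#' @examples
#' sig <- generate_pat(pat_spec(hyperemia_ratio = 2, noise_sd = 0))
#' compute_rhi(sig)$rhi
#' @export
generate_pat <- function(spec) {
  stopifnot(inherits(spec, "pat_spec"))
  n_phase <- round(spec$durations * spec$sample_rate)
  n <- sum(n_phase)
  t <- (seq_len(n) - 1) / spec$sample_rate
  env <- rep(spec$baseline_amplitude * c(1, spec$occlusion_residual, spec$hyperemia_ratio),
             times = n_phase)
  x <- env * sin(2 * pi * spec$beat_rate * t)
  if (spec$noise_sd > 0)
    x <- x + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  b <- cumsum(c(1, n_phase))
  pat_signal(x, spec$sample_rate,
             phases = list(baseline = c(b[1], b[2]),
                           occlusion = c(b[2], b[3]),
                           post = c(b[3], b[4])))
}

#' @export
print.pat_signal <- function(x, ...) {
  cat("<pat_signal> ", length(x$samples), " samples @ ", x$sample_rate, " Hz; phases ",
      paste(vapply(x$phases[c("baseline", "occlusion", "post")],
                   function(p) sprintf("[%d,%d)", p[1], p[2]), ""), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
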