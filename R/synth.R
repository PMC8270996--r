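#' Default 12-class rhythm morphology palette
#'
#' Per-class parameters of the Gaussian-wavelet P-QRS-T generator used by
#' [synthesize_segment()]. Classes come in pairs that share a base sinus
#' morphology and differ in exactly one clinically meaningful feature
#' (rate, RR irregularity, ST offset, P-wave presence, QRS width, signal
#' quality), so the two classes of a class-incremental task are symmetric
#' in difficulty while the pairs themselves span a range from gross
#' contrasts (rate doubling, signal quality) to subtle ones (P-wave
#' absence), giving tasks a genuine spread of difficulty.
#'
#' @param n_classes number of classes to return (2..12), the first
#'   `n_classes` rows of the palette.
#' @return a data.frame with one row per class: `class` (0-based id),
#'   `name`, `rate_bpm` (mean heart rate), `rr_cv` (coefficient of variation
#'   of RR intervals), `qrs_width` (seconds), `st_offset` (baseline shift
#'   between S and T, mV-like units), `p_amp`, `r_amp`, `t_amp` (wavelet
#'   amplitudes) and `extra_noise` (class-specific additive noise sd).
#' @export
default_morphologies <- function(n_classes = 12L) {
  stopifnot(n_classes >= 2L, n_classes <= 12L)
  pal <- data.frame(
    class      = 0:11,
    name       = c("nsr", "svt",                 # rate contrast
                   "sinus_regular", "afib",      # RR irregularity
                   "sinus_baseline", "st_elevation",  # ST offset
                   "sinus_pwave", "junctional",  # P-wave presence (subtle)
                   "sinus_narrow", "bbb_wide",   # QRS width
                   "sinus_clean", "low_quality"),# signal quality (gross)
    rate_bpm   = c(72, 150, 80, 80, 66, 66, 76, 76, 62, 62, 85, 85),
    rr_cv      = c(0.05, 0.05, 0.04, 0.30, 0.05, 0.05, 0.05, 0.05,
                   0.05, 0.05, 0.06, 0.06),
    qrs_width  = c(0.08, 0.08, 0.08, 0.08, 0.09, 0.09, 0.09, 0.09,
                   0.08, 0.15, 0.08, 0.08),
    st_offset  = c(0, 0, 0, 0, 0, 0.30, 0, 0, 0, 0, 0, 0),
    p_amp      = c(0.15, 0.12, 0.15, 0.00, 0.15, 0.15, 0.15, 0.00,
                   0.15, 0.12, 0.15, 0.10),
    r_amp      = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
                   1.1, 0.35),
    t_amp      = c(0.30, 0.28, 0.30, 0.28, 0.30, 0.35, 0.30, 0.30,
                   0.30, 0.24, 0.32, 0.15),
    extra_noise = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.40),
    stringsAsFactors = FALSE
  )
  pal[seq_len(n_classes), , drop = FALSE]
}

#' Synthesize one single-lead ECG-like segment
#'
#' Builds a quasi-periodic trace as a sum of Gaussian wavelets (P, Q, R, S, T)
#' per beat on a flat baseline. Beat-to-beat R-wave onsets follow the
#' configured mean rate with multiplicative RR jitter; an ST baseline offset
#' is blended in between the S and T wavelets; white noise is added on top.
#'
#' @param params a one-row data.frame or list with fields `rate_bpm`,
#'   `rr_cv`, `qrs_width`, `st_offset`, `p_amp`, `r_amp`, `t_amp` and
#'   optionally `extra_noise` (see [default_morphologies()]).
#' @param noise_sd additive white-noise standard deviation.
#' @param L segment length in samples.
#' @param fs sampling rate in Hz.
#' @param seed optional integer; when given the segment is generated under a
#'   temporary RNG state so that identical calls are bitwise identical.
#' @return numeric vector of length `L` with attribute `onsets`: the 0-based
#'   sample indices of the R-wave centers that fall inside the segment.
#' @export
synthesize_segment <- function(params, noise_sd, L, fs, seed = NULL) {
  params <- as.list(params)
  rate <- params$rate_bpm
  if (!is.numeric(rate) || rate <= 0) stop("heart rate must be positive")
  if (!is.numeric(L) || L < 1) stop("segment length L must be positive")
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate fs must be positive")
  cv <- params$rr_cv %||% 0
  if (cv < 0 || cv >= 1) stop("RR coefficient of variation must be in [0, 1)")
  with_seed(seed, {
    L <- as.integer(L)
    t <- (seq_len(L) - 1) / fs
    dur <- L / fs
    rr_mean <- 60 / rate
    # R-wave centers: first beat at t = 0, then jittered RR intervals.
    onsets <- 0
    repeat {
      rr <- rr_mean * max(0.3, 1 + cv * rnorm(1))
      nxt <- onsets[length(onsets)] + rr
      if (nxt >= dur) break
      onsets <- c(onsets, nxt)
    }
    sig <- numeric(L)
    qw <- params$qrs_width %||% 0.08
    gauss <- function(center, width_sd, amp) amp * exp(-(t - center)^2 / (2 * width_sd^2))
    for (tr in onsets) {
      sig <- sig +
        gauss(tr - 0.17, 0.030, params$p_amp %||% 0) +
        gauss(tr - qw / 2, 0.012, -0.12 * (params$r_amp %||% 1)) +
        gauss(tr, qw / 4, params$r_amp %||% 1) +
        gauss(tr + qw / 2, 0.015, -0.20 * (params$r_amp %||% 1)) +
        gauss(tr + 0.30, 0.070, params$t_amp %||% 0)
      st <- params$st_offset %||% 0
      if (st != 0) {
        # smooth plateau between end of QRS and onset of T
        sig <- sig + st * stats::plogis((t - tr - qw / 2 - 0.02) / 0.01) *
          stats::plogis(-(t - tr - 0.24) / 0.02)
      }
    }
    total_sd <- sqrt(noise_sd^2 + (params$extra_noise %||% 0)^2)
    if (total_sd > 0) sig <- sig + rnorm(L, 0, total_sd)
    structure(sig, onsets = round(onsets * fs))
  })
}

#' Configuration of the synthetic ECG stream generator
#'
#' @param n_classes number of rhythm classes drawn from the morphology
#'   palette (>= 2).
#' @param L segment length in samples (default 2500).
#' @param fs sampling rate in Hz (default 250; the default segment is 10 s).
#' @param n_train,n_val,n_test instances per split and task.
#' @param noise_sd baseline additive noise sd.
#' @param label_noise fraction of instances whose label is flipped to another
#'   class of the same task, emulating imperfect annotation.
#' @param artifact_frac fraction of instances replaced by artifact-only
#'   recordings (baseline wander plus heavy noise, no discernible beats)
#'   that keep their rhythm label, emulating motion-artifact segments that
#'   annotators label from surrounding context (default 0.08).
#' @param jitter logical; apply per-instance morphology jitter (rate and
#'   amplitude variability across instances of a class).
#' @param jitter_sd lognormal sd of the per-instance heart-rate jitter
#'   (default 0.15; resting rates within a rhythm class easily span +-30%).
#' @param amp_jitter half-width of the uniform per-instance amplitude scale
#'   (default 0.25, i.e. wavelet amplitudes scaled by U(0.75, 1.25),
#'   emulating electrode-contact variability).
#' @param noise_jitter half-width of the uniform per-instance noise
#'   multiplier (default 0.7: each recording's noise sd is
#'   `noise_sd * U(0.3, 1.7)`, emulating the heteroscedastic quality of
#'   ambulatory recordings; instance difficulty then varies within every
#'   class, not just between classes).
#' @param morphologies palette data.frame; defaults to
#'   [default_morphologies()] truncated to `n_classes`.
#' @param seed integer seed governing stream synthesis.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_classes = 12L, L = 2500L, fs = 250,
                             n_train = 64L, n_val = 24L, n_test = 48L,
                             noise_sd = 0.05, label_noise = 0.05,
                             artifact_frac = 0.08,
                             jitter = TRUE, jitter_sd = 0.15,
                             amp_jitter = 0.25, noise_jitter = 0.7,
                             morphologies = NULL, seed = 1L) {
  if (n_classes < 2L) stop("need at least two classes")
  if (L < 1L || fs <= 0) stop("L and fs must be positive")
  if (n_train < 1L || n_val < 1L || n_test < 1L) stop("n per split must be positive")
  if (label_noise < 0 || label_noise >= 1) stop("label_noise must be in [0, 1)")
  if (artifact_frac < 0 || artifact_frac >= 1)
    stop("artifact_frac must be in [0, 1)")
  structure(list(
    n_classes = as.integer(n_classes), L = as.integer(L), fs = fs,
    n_train = as.integer(n_train), n_val = as.integer(n_val),
    n_test = as.integer(n_test), noise_sd = noise_sd,
    label_noise = label_noise, artifact_frac = artifact_frac,
    jitter = jitter,
    jitter_sd = jitter_sd, amp_jitter = amp_jitter,
    noise_jitter = noise_jitter,
    morphologies = morphologies %||% default_morphologies(n_classes),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Per-instance jitter of a palette row. Rate, amplitude and the
# discriminative morphology features (QRS width, ST offset, RR
# irregularity) all vary across instances of a class, so every class
# contains a continuum from prototypical to borderline examples.
jitter_params <- function(p, jitter = TRUE, jitter_sd = 0.15,
                          amp_jitter = 0.25) {
  p <- as.list(p)
  if (!jitter) return(p)
  p$rate_bpm <- p$rate_bpm * exp(rnorm(1, 0, jitter_sd))
  f <- runif(1, 1 - amp_jitter, 1 + amp_jitter)
  p$r_amp <- p$r_amp * f
  p$p_amp <- p$p_amp * f
  p$t_amp <- p$t_amp * f
  p$qrs_width <- p$qrs_width * runif(1, 0.8, 1.25)
  p$st_offset <- p$st_offset * runif(1, 0.4, 1.6)
  p$rr_cv <- min(0.95, p$rr_cv * runif(1, 0.5, 1.5))
  p
}
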