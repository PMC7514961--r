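# Synthetic phonocardiogram generator. Each cardiac cycle contains an S1 and
# an S2 transient (Gaussian-enveloped tone bursts); the abnormal class adds a
# band-limited systolic murmur between S1 and S2. White measurement noise is
# optional. All randomness is driven by the config seed and the caller's RNG
# state is left untouched.

#' Synthesis configuration for artificial heart-sound records
#'
#' Defaults describe a plausible resting phonocardiogram: 5 s at 2000 Hz,
#' 60 bpm, S1 centred near 50 Hz and S2 near 80 Hz, a 100-400 Hz systolic
#' murmur band, and a small amount of broadband sensor noise.
#'
#' @param duration_s Record duration in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz.
#' @param heart_rate_bpm Heart rate in beats per minute (20-220).
#' @param s1_freq_hz,s2_freq_hz Centre frequencies of the S1/S2 bursts (Hz).
#' @param murmur_amplitude Peak amplitude of the systolic murmur (0 disables;
#'   used only for abnormal records).
#' @param murmur_band_hz Length-2 frequency interval of the murmur noise (Hz).
#' @param noise_sd Standard deviation of additive white noise (amplitude units).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(duration_s = 5, sampling_rate = 2000,
                             heart_rate_bpm = 60,
                             s1_freq_hz = 50, s2_freq_hz = 80,
                             murmur_amplitude = 0.15,
                             murmur_band_hz = c(100, 400),
                             noise_sd = 0.02, seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (heart_rate_bpm < 20 || heart_rate_bpm > 220) {
    stop("`heart_rate_bpm` must lie in [20, 220]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (murmur_amplitude < 0) stop("`murmur_amplitude` must be >= 0", call. = FALSE)
  stopifnot(sampling_rate > 0, length(murmur_band_hz) == 2L,
            murmur_band_hz[1] < murmur_band_hz[2])
  structure(
    list(duration_s = duration_s, sampling_rate = sampling_rate,
         heart_rate_bpm = heart_rate_bpm,
         s1_freq_hz = s1_freq_hz, s2_freq_hz = s2_freq_hz,
         murmur_amplitude = murmur_amplitude,
         murmur_band_hz = murmur_band_hz,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthesis_config"
  )
}

# Evaluate code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Gaussian-enveloped tone burst centred at t0 (seconds), zero elsewhere in
# effect (envelope truncated at 4 sd).
tone_burst <- function(t, t0, freq, sd_s, amp) {
  env <- exp(-0.5 * ((t - t0) / sd_s)^2)
  env[abs(t - t0) > 4 * sd_s] <- 0
  amp * env * sin(2 * pi * freq * (t - t0))
}

# Band-limited white noise via FFT masking; deterministic given the RNG state.
bandlimited_noise <- function(n, rate, band) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * rate
  freqs <- pmin(freqs, rate - freqs)  # two-sided spectrum
  f[freqs < band[1] | freqs > band[2]] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# 1/f-shaped ("pink") band noise for friction/motion artifacts: same FFT
# masking but with a 1/sqrt(f) amplitude envelope, unit variance.
pink_noise <- function(n, rate, band) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * rate
  freqs <- pmin(freqs, rate - freqs)
  shape <- ifelse(freqs >= band[1] & freqs <= band[2],
                  1 / sqrt(pmax(freqs, band[1])), 0)
  y <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Synthesize a labelled phonocardiogram
#'
#' Generates one record: per-beat S1 and S2 Gaussian-enveloped tone bursts at
#' the configured heart rate, plus (for `label = "abnormal"`) a band-limited
#' murmur confined to the systolic interval between S1 and S2, plus white
#' noise. Identical configs (including seed) yield bit-identical waveforms,
#' and the normal/abnormal pair for one seed differs only inside systole.
#'
#' @param config A [synthesis_config()].
#' @param label `"normal"` or `"abnormal"`.
#' @param record_id Identifier; default derived from label and seed.
#' @return A [heart_sound_record()] with the label attached.
#' @export
#' @examples
#' r <- synthesize_pcg(synthesis_config(seed = 7), "abnormal")
synthesize_pcg <- function(config, label = c("normal", "abnormal"),
                           record_id = NULL) {
  stopifnot(inherits(config, "synthesis_config"))
  label <- match.arg(label)
  n <- round(config$duration_s * config$sampling_rate)
  t <- (seq_len(n) - 1) / config$sampling_rate
  period <- 60 / config$heart_rate_bpm
  systole <- min(0.35 * period, 0.35)  # systolic interval length, seconds

  beat_starts <- seq(0, config$duration_s, by = period)
  s1_centres <- beat_starts + 0.06
  s1_centres <- s1_centres[s1_centres < config$duration_s]
  s2_centres <- beat_starts + 0.06 + systole
  s2_centres <- s2_centres[s2_centres < config$duration_s]

  x <- numeric(n)
  for (c1 in s1_centres) x <- x + tone_burst(t, c1, config$s1_freq_hz, 0.022, 1.0)
  for (c2 in s2_centres) x <- x + tone_burst(t, c2, config$s2_freq_hz, 0.016, 0.8)

  with_seed(config$seed, {
    # murmur noise is always drawn so that normal/abnormal share the RNG
    # stream; only its amplitude depends on the label
    murmur <- bandlimited_noise(n, config$sampling_rate, config$murmur_band_hz)
    sensor <- stats::rnorm(n)
  })

  # systolic window: raised cosine between the end of S1 and the start of S2
  env <- numeric(n)
  for (k in seq_along(s1_centres)) {
    a <- s1_centres[k] + 0.05
    b <- s1_centres[k] + systole - 0.04
    if (b <= a) next
    inside <- t >= a & t <= b
    env[inside] <- pmax(env[inside], 0.5 - 0.5 * cos(2 * pi * (t[inside] - a) / (b - a)))
  }
  m_amp <- if (label == "abnormal") config$murmur_amplitude else 0
  x <- x + m_amp * env * murmur + config$noise_sd * sensor

  if (is.null(record_id)) {
    record_id <- sprintf("synth_%s_%04d", label, config$seed %% 10000L)
  }
  heart_sound_record(x, config$sampling_rate, record_id, label)
}

#' Synthesize a labelled two-class dataset
#'
#' Draws `n_normal` normal and `n_abnormal` abnormal records emulating an
#' auscultation cohort. Each record is a [synthesize_pcg()] waveform (S1/S2
#' bursts; abnormal records add a loud systolic murmur, amplitude uniform on
#' 0.35-0.6) with per-record physiological and instrumental variation:
#' heart rate uniform on 45-120 bpm, S1 centre frequency uniform on
#' 35-65 Hz, S2 on 65-105 Hz, and a log-uniform recording gain on 0.3-3
#' (uncalibrated devices; scale-dependent features see it, scale-invariant
#' ones do not). On top of the cardiac signal every record carries three
#' contaminants routinely present in phonocardiograms: continuous benign
#' flow/respiratory noise in the murmur band (flat spectrum; amplitude
#' uniform on 0.09-0.19 for healthy subjects, 0.03-0.08 for patients, whose
#' loud murmur dominates the band instead), 1/f friction/motion artifact
#' over 20-450 Hz (amplitude uniform on 0.01-0.04), and white sensor noise
#' (sd 0.005). The amplitude ranges are chosen so that the two classes have
#' overlapping band-energy distributions: what separates them is chiefly
#' how the band energy is organised in time (murmurs are locked to systole,
#' flow noise is diffuse), not how much of it there is.
#'
#' @param n_normal,n_abnormal Number of records per class.
#' @param seed Integer seed controlling the whole dataset.
#' @param base_config A [synthesis_config()] supplying the fixed parameters
#'   (duration, sampling rate, murmur band).
#' @return A list of [heart_sound_record()]s, normals first.
#' @export
synthesize_dataset <- function(n_normal, n_abnormal, seed = 1L,
                               base_config = synthesis_config()) {
  stopifnot(n_normal >= 0, n_abnormal >= 0, n_normal + n_abnormal > 0)
  n_tot <- n_normal + n_abnormal
  labels <- c(rep("normal", n_normal), rep("abnormal", n_abnormal))
  pars <- with_seed(seed, {
    list(
      hr = stats::runif(n_tot, 45, 120),
      gain = exp(stats::runif(n_tot, log(0.3), log(3))),
      s1f = stats::runif(n_tot, 35, 65),
      s2f = stats::runif(n_tot, 65, 105),
      murmur = stats::runif(n_tot, 0.35, 0.6),
      flow = ifelse(labels == "normal", stats::runif(n_tot, 0.09, 0.19),
                    stats::runif(n_tot, 0.03, 0.08)),
      artifact = stats::runif(n_tot, 0.01, 0.04),
      seeds = sample.int(2^30, n_tot)
    )
  })
  records <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    cfg <- synthesis_config(
      duration_s = base_config$duration_s,
      sampling_rate = base_config$sampling_rate,
      heart_rate_bpm = pars$hr[i],
      s1_freq_hz = pars$s1f[i],
      s2_freq_hz = pars$s2f[i],
      murmur_amplitude = pars$murmur[i],
      murmur_band_hz = base_config$murmur_band_hz,
      noise_sd = 0.005,
      seed = pars$seeds[i]
    )
    rec <- synthesize_pcg(cfg, labels[i],
                          record_id = sprintf("synth%04d_%s", i, labels[i]))
    contam <- with_seed(pars$seeds[i] + 1L, {
      n <- length(rec$samples)
      pars$flow[i] * bandlimited_noise(n, cfg$sampling_rate, cfg$murmur_band_hz) +
        pars$artifact[i] * pink_noise(n, cfg$sampling_rate, c(20, 450))
    })
    rec$samples <- pars$gain[i] * (rec$samples + contam)
    records[[i]] <- rec
  }
  records
}
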