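#' A state schedule for the synthetic generator
#'
#' Ordered segments of mental state, emulating a relax / stress / relax
#' laboratory protocol. The default alternates Basal, Stress and Relax
#' segments of 100 s each, twice, giving a register with balanced-ish
#' classes.
#'
#' @param segments Named numeric vector: durations in seconds, names in
#'   `{Relax, Basal, Stress}`. Names may repeat.
#' @return Tibble with columns `state`, `duration`, `t_start`, `t_end`.
#' @export
#' @examples
#' synth_schedule(c(Basal = 120, Stress = 120, Relax = 120))
synth_schedule <- function(segments = c(Basal = 100, Stress = 100, Relax = 100,
                                        Basal = 100, Stress = 100, Relax = 100)) {
  states <- names(segments)
  if (is.null(states) || !all(states %in% c("Relax", "Basal", "Stress"))) {
    stop("segments must be named with states in {Relax, Basal, Stress}",
         call. = FALSE)
  }
  if (any(segments <= 0)) stop("segment durations must be positive", call. = FALSE)
  ends <- cumsum(as.numeric(segments))
  tibble::tibble(state = states, duration = as.numeric(segments),
                 t_start = c(0, head(ends, -1)), t_end = ends)
}

#' Synthetic register configuration
#'
#' State-dependent parameters of the generator. RR intervals follow
#' `state mean + RSA sinusoid + AR(1) noise`; EDA is a piecewise-linear
#' tonic drift plus bi-exponential skin-conductance responses (SCRs) at
#' Poisson event times plus white noise. Defaults encode the physiology the
#' classifier assumes: long RR intervals and falling EDA in relaxation,
#' short RR and frequent SCRs under stress, Basal in between and partially
#' overlapping both neighbours (the hard intermediate class). EDA on its
#' own separates stress well but confuses Relax with Basal; the RR side
#' carries the relax/basal distinction.
#'
#' @param rr_mean Mean RR interval per state (s).
#' @param rsa_amplitude Respiratory sinus arrhythmia amplitude per state
#'   (s); larger when the parasympathetic side dominates.
#' @param rsa_freq Respiratory frequency (Hz), default 0.25.
#' @param rr_noise_sd Marginal sd of the AR(1) beat noise (s).
#' @param rr_noise_phi AR(1) coefficient of the beat noise.
#' @param eda_baseline Starting tonic level (uS).
#' @param eda_tonic_slope Tonic drift per state (uS/s).
#' @param scr_rate SCR event rate per state (events/min).
#' @param scr_amplitude Typical SCR peak amplitude (uS).
#' @param scr_rise,scr_decay SCR kernel time constants (s).
#' @param eda_noise_sd White measurement noise on EDA (uS).
#' @param eda_fs EDA sampling rate (Hz).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(rr_mean = c(Relax = 1.00, Basal = 0.80, Stress = 0.62),
                         rsa_amplitude = c(Relax = 0.05, Basal = 0.03,
                                           Stress = 0.015),
                         rsa_freq = 0.25,
                         rr_noise_sd = 0.02,
                         rr_noise_phi = 0.4,
                         eda_baseline = 6,
                         eda_tonic_slope = c(Relax = -0.012, Basal = -0.004,
                                             Stress = 0.025),
                         scr_rate = c(Relax = 1.5, Basal = 2, Stress = 8),
                         scr_amplitude = 0.3,
                         scr_rise = 2,
                         scr_decay = 8,
                         eda_noise_sd = 0.01,
                         eda_fs = 8) {
  stopifnot(all(rr_mean > 0), all(scr_rate >= 0), rr_noise_sd >= 0,
            eda_fs > 0)
  structure(
    list(rr_mean = rr_mean, rsa_amplitude = rsa_amplitude,
         rsa_freq = rsa_freq, rr_noise_sd = rr_noise_sd,
         rr_noise_phi = rr_noise_phi, eda_baseline = eda_baseline,
         eda_tonic_slope = eda_tonic_slope, scr_rate = scr_rate,
         scr_amplitude = scr_amplitude, scr_rise = scr_rise,
         scr_decay = scr_decay, eda_noise_sd = eda_noise_sd,
         eda_fs = eda_fs),
    class = "synth_config"
  )
}

#' Shrink the between-state separation of a configuration
#'
#' Every state-dependent parameter is pulled toward its across-state mean
#' by the given factor: 1 leaves the configuration unchanged, 0 makes the
#' three states statistically identical (class recovery must then fall to
#' chance). Noise scales are untouched.
#'
#' @param config A [synth_config()].
#' @param factor Separation multiplier in `[0, 1]`.
#' @return A new `synth_config`.
#' @export
scale_separation <- function(config, factor) {
  stopifnot(inherits(config, "synth_config"), factor >= 0)
  shrink <- function(v) mean(v) + factor * (v - mean(v))
  config$rr_mean <- shrink(config$rr_mean)
  config$rsa_amplitude <- shrink(config$rsa_amplitude)
  config$eda_tonic_slope <- shrink(config$eda_tonic_slope)
  config$scr_rate <- pmax(shrink(config$scr_rate), 0)
  config
}

state_at <- function(schedule, t) {
  i <- findInterval(t, schedule$t_start, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), nrow(schedule))
  schedule$state[i]
}

#' Generate a labelled synthetic register
#'
#' Beats are generated sequentially: the interval at beat time `t` is the
#' state's mean RR plus an RSA sinusoid plus AR(1) noise, truncated below
#' at 0.25 s. EDA is sampled at `config$eda_fs`: a tonic component
#' integrating the state drift, SCR kernels
#' `exp(-t/decay) - exp(-t/rise)` scaled to the configured peak amplitude
#' at Poisson event times, and white noise. The schedule becomes the
#' register's annotations (`Relax -> Relax-RResp` etc.). The same seed
#' reproduces the register bit for bit.
#'
#' @param schedule A [synth_schedule()].
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @return A [physio_register()].
#' @export
#' @examples
#' reg <- generate_register(synth_schedule(c(Basal = 60)), seed = 1)
generate_register <- function(schedule, config = synth_config(), seed,
                              subject_id = sprintf("synth-%d", seed)) {
  stopifnot(inherits(config, "synth_config"))
  if (!tibble::is_tibble(schedule)) schedule <- synth_schedule(schedule)
  set.seed(as.integer(seed))
  total <- max(schedule$t_end)

  ## --- RR beats ---
  beat_time <- numeric(0)
  rr <- numeric(0)
  t <- 0
  e <- 0
  innov_sd <- config$rr_noise_sd * sqrt(1 - config$rr_noise_phi^2)
  repeat {
    st <- state_at(schedule, t)
    e <- config$rr_noise_phi * e +
      if (innov_sd > 0) rnorm(1, 0, innov_sd) else 0
    interval <- config$rr_mean[[st]] +
      config$rsa_amplitude[[st]] * sin(2 * pi * config$rsa_freq * t) + e
    interval <- max(interval, 0.25)
    t <- t + interval
    if (t > total) break
    beat_time <- c(beat_time, t)
    rr <- c(rr, interval)
  }

  ## --- EDA ---
  tg <- seq(0, total, by = 1 / config$eda_fs)
  slopes <- config$eda_tonic_slope[state_at(schedule, tg)]
  tonic <- config$eda_baseline +
    cumsum(c(0, head(slopes, -1)) / config$eda_fs)
  phasic <- numeric(length(tg))
  for (i in seq_len(nrow(schedule))) {
    rate <- config$scr_rate[[schedule$state[i]]]
    n_ev <- rpois(1, rate * schedule$duration[i] / 60)
    if (n_ev == 0) next
    ev <- sort(runif(n_ev, schedule$t_start[i], schedule$t_end[i]))
    amp <- config$scr_amplitude * runif(n_ev, 0.5, 1.5)
    for (j in seq_len(n_ev)) {
      dt <- tg - ev[j]
      k <- exp(-pmax(dt, 0) / config$scr_decay) -
        exp(-pmax(dt, 0) / config$scr_rise)
      k[dt < 0] <- 0
      pk <- max(k)
      if (pk > 0) phasic <- phasic + amp[j] * k / pk
    }
  }
  noise <- if (config$eda_noise_sd > 0) {
    rnorm(length(tg), 0, config$eda_noise_sd)
  } else 0
  eda <- unname(pmax(tonic + phasic + noise, 0.05))

  ann <- tibble::tibble(
    t_start = schedule$t_start, t_end = schedule$t_end,
    label = c(Relax = "Relax-RResp", Basal = "Basal-RResp",
              Stress = "Stress-RResp")[schedule$state]
  )
  physio_register(subject_id,
                  eda = tibble::tibble(t = tg, eda = eda),
                  rr_beats = tibble::tibble(beat_time = beat_time, rr = rr),
                  annotations = ann,
                  meta = list(seed = seed, schedule = schedule,
                              config = config))
}

#' Generate a cohort feature table
#'
#' Convenience wrapper: generates `n_subjects` registers with derived seeds
#' and row-binds their labelled feature tables.
#'
#' With `counterbalance = TRUE` each subject receives the schedule's
#' segments in an independently permuted order, as counterbalanced
#' protocols do. This breaks the association between elapsed register time
#' and the mental state that a shared segment order would imprint on every
#' subject (slow drifts such as the tonic EDA level otherwise predict the
#' state through the clock, not the physiology).
#'
#' @param n_subjects Number of registers.
#' @param schedule A [synth_schedule()] shared by all subjects.
#' @param config A [synth_config()].
#' @param seed Base seed; subject `i` uses a seed derived from it.
#' @param counterbalance Permute segment order per subject, default `FALSE`.
#' @param ... Passed to [build_feature_table()].
#' @return Feature-table tibble over all subjects.
#' @export
synth_cohort_table <- function(n_subjects, schedule = synth_schedule(),
                               config = synth_config(), seed = 1,
                               counterbalance = FALSE, ...) {
  tabs <- purrr::map(seq_len(n_subjects), function(i) {
    sched <- schedule
    if (counterbalance) {
      set.seed(derive_seed(seed, 77, i))
      perm <- sample(nrow(schedule))
      sched <- synth_schedule(stats::setNames(schedule$duration[perm],
                                              schedule$state[perm]))
    }
    reg <- generate_register(sched, config, seed = derive_seed(seed, i),
                             subject_id = sprintf("synth-%d-%d", seed, i))
    build_feature_table(reg, ...)
  })
  out <- dplyr::bind_rows(tabs)
  attr(out, "feature_cols") <- all_feature_names()
  out
}
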