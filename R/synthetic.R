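# Synthetic multi-subject multimodal generator. Emulates the statistical
# structure of a video-stimulation valence study (24 subjects, 16 men / 8
# women, 14 trials of 43-78 s interleaved with 30 s baselines) with planted,
# configurable condition effects in each modality, so that every downstream
# stage of the pipeline can be exercised and power-tested without access to
# raw recordings.

#' Study design parameters
#'
#' @param n_subjects number of subjects (default 24).
#' @param n_men number of male subjects (default 16); subjects `1..n_men` are
#'   men, the rest women.
#' @param trials_per_subject number of video trials per subject (default 14),
#'   balanced between positive and negative valence (must be even).
#' @param trial_duration_s `c(min, max)` clip duration range in seconds
#'   (default 43-78).
#' @param baseline_duration_s black-screen baseline between clips in seconds
#'   (default 30).
#' @param ecg_fs ECG sampling rate in Hz (default 256).
#' @param temp_fs temperature sampling rate in Hz (default 1).
#' @param eeg_fs raw-EEG sampling rate in Hz (default 1000; band-power
#'   features are synthesised directly, this matters only for tiny raw-EEG
#'   fixtures).
#' @param eeg_window_s,eeg_window_overlap EEG analysis sub-window length (s)
#'   and fractional overlap used to multiply within-trial observations
#'   (defaults 4 s, 50%).
#' @return validated list of class `study_design`.
#' @export
study_design <- function(n_subjects = 24, n_men = 16, trials_per_subject = 14,
                         trial_duration_s = c(43, 78),
                         baseline_duration_s = 30, ecg_fs = 256, temp_fs = 1,
                         eeg_fs = 1000, eeg_window_s = 4,
                         eeg_window_overlap = 0.5) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_men <- check_count(n_men, "n_men", min = 0L)
  if (n_men > n_subjects) stop_config("n_men", "cannot exceed n_subjects")
  trials_per_subject <- check_count(trials_per_subject, "trials_per_subject",
                                    min = 2L)
  if (trials_per_subject %% 2 != 0)
    stop_config("trials_per_subject", "must be even (balanced classes)")
  if (length(trial_duration_s) != 2 || any(trial_duration_s <= 0) ||
      trial_duration_s[1] > trial_duration_s[2])
    stop_config("trial_duration_s", "must be an increasing positive range")
  baseline_duration_s <- check_pos(baseline_duration_s, "baseline_duration_s")
  structure(list(n_subjects = n_subjects, n_men = n_men,
                 trials_per_subject = trials_per_subject,
                 trial_duration_s = as.numeric(trial_duration_s),
                 baseline_duration_s = baseline_duration_s,
                 ecg_fs = check_pos(ecg_fs, "ecg_fs"),
                 temp_fs = check_pos(temp_fs, "temp_fs"),
                 eeg_fs = check_pos(eeg_fs, "eeg_fs"),
                 eeg_window_s = check_pos(eeg_window_s, "eeg_window_s"),
                 eeg_window_overlap = eeg_window_overlap),
            class = "study_design")
}

#' Planted condition-effect model
#'
#' Magnitudes of the condition effects the generator plants, chosen to mirror
#' the qualitative findings the pipeline is meant to recover: more large
#' beat-to-beat differences on positive trials in men, larger long-term IBI
#' variability (SD2) on negative trials in women, slightly warmer skin on
#' negative trials (carried by women) with a clear stimulus-vs-baseline rise,
#' prefrontal leftward EEG lateralization for positive valence (reversed
#' occipitally), and strong inter-subject heterogeneity of the EEG response.
#'
#' @param nn50_male_shift expected extra count of successive-IBI differences
#'   over 50 ms per positive trial, men only (default 5).
#' @param sd2_female_shift ms added to long-term IBI variability (SD2) on
#'   negative trials, women only (default 20).
#' @param temp_neg_shift degrees C added on negative trials, women only
#'   (default 0.08).
#' @param temp_task_shift degrees C added during any stimulus relative to
#'   baseline (default 1.72).
#' @param eeg_asym_shift population-consistent log-power asymmetry magnitude:
#'   prefrontal left-up/right-down for positive valence, occipital reversed
#'   (default 0.3).
#' @param eeg_subject_shift magnitude of each subject's own log-power valence
#'   response per feature (default 1.2); its sign is random per subject and
#'   feature when `eeg_heterogeneous` is `TRUE`.
#' @param subject_heterogeneity standard deviation of the per-subject effect
#'   multiplier `~ Normal(1, .)`, truncated below at 0.1 (default 0.3).
#' @param eeg_heterogeneous logical; random per-subject response signs
#'   (default `TRUE`), the regime in which subject-dependent models succeed
#'   while subject-independent ones fail.
#' @param seed integer RNG seed; identical seed and parameters give a
#'   bit-identical dataset.
#' @return validated list of class `effect_model`.
#' @export
effect_model <- function(nn50_male_shift = 5, sd2_female_shift = 20,
                         temp_neg_shift = 0.08, temp_task_shift = 1.72,
                         eeg_asym_shift = 0.3, eeg_subject_shift = 1.2,
                         subject_heterogeneity = 0.3,
                         eeg_heterogeneous = TRUE, seed = 1) {
  structure(list(
    nn50_male_shift = check_nonneg(nn50_male_shift, "nn50_male_shift"),
    sd2_female_shift = check_nonneg(sd2_female_shift, "sd2_female_shift"),
    temp_neg_shift = check_nonneg(temp_neg_shift, "temp_neg_shift"),
    temp_task_shift = check_nonneg(temp_task_shift, "temp_task_shift"),
    eeg_asym_shift = check_nonneg(eeg_asym_shift, "eeg_asym_shift"),
    eeg_subject_shift = check_nonneg(eeg_subject_shift, "eeg_subject_shift"),
    subject_heterogeneity = check_nonneg(subject_heterogeneity,
                                         "subject_heterogeneity"),
    eeg_heterogeneous = isTRUE(eeg_heterogeneous),
    seed = check_count(seed, "seed", min = 0L)), class = "effect_model")
}

#' Effect model with every planted shift set to zero
#'
#' The null generator: no feature differs between valence conditions beyond
#' sampling noise, used for statistical calibration.
#'
#' @param seed integer RNG seed.
#' @param subject_heterogeneity kept available because heterogeneity alone
#'   does not break the null (default 0.3).
#' @return an [effect_model()].
#' @export
null_effects <- function(seed = 1, subject_heterogeneity = 0.3) {
  effect_model(nn50_male_shift = 0, sd2_female_shift = 0, temp_neg_shift = 0,
               temp_task_shift = 0, eeg_asym_shift = 0, eeg_subject_shift = 0,
               subject_heterogeneity = subject_heterogeneity, seed = seed)
}

# Baseline cardiovascular parameters of the IBI generative model: AR(1)
# short-term dynamics plus respiratory (HF), baroreflex-range (LF) and very
# slow (VLF) oscillations, amplitudes in ms.
ibi_params <- function(base_rr = 850, ar_sd = 25, ar_phi = 0.8,
                       hf_amp = 20, hf_freq = 0.25, lf_amp = 15,
                       lf_freq = 0.08, vlf_amp = 10, vlf_freq = 0.02) {
  list(base_rr = base_rr, ar_sd = ar_sd, ar_phi = ar_phi, hf_amp = hf_amp,
       hf_freq = hf_freq, lf_amp = lf_amp, lf_freq = lf_freq,
       vlf_amp = vlf_amp, vlf_freq = vlf_freq)
}

# Probability that a successive-IBI difference exceeds 50 ms under the
# generative model (AR(1) diff ~ Normal, oscillatory diffs ~ fixed-amplitude
# sinusoids at uniform phase), by quadrature over the phases of the two
# largest oscillatory components.
nn50_base_prob <- function(p, scale = 1, pulse = 0) {
  sd_ar_d <- scale * p$ar_sd * sqrt(2 * (1 - p$ar_phi))
  dt <- p$base_rr / 1000
  a_hf <- scale * 2 * p$hf_amp * abs(sin(pi * p$hf_freq * dt))
  a_lf <- scale * 2 * p$lf_amp * abs(sin(pi * p$lf_freq * dt))
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  grid <- expand.grid(t1 = th, t2 = th)
  mu <- pulse + a_hf * sin(grid$t1) + a_lf * sin(grid$t2)
  mean(pnorm(-50, mu, sd_ar_d) + pnorm(50, mu, sd_ar_d, lower.tail = FALSE))
}

# Expected SD2 of the generated series, from the model's component variances.
sd2_base_value <- function(p, scale = 1) {
  dt <- p$base_rr / 1000
  v <- (scale^2) * (p$ar_sd^2 + p$hf_amp^2 / 2 + p$lf_amp^2 / 2 +
                    p$vlf_amp^2 / 2)
  vd <- (scale^2) * (2 * p$ar_sd^2 * (1 - p$ar_phi) +
    (2 * p$hf_amp * sin(pi * p$hf_freq * dt))^2 / 2 +
    (2 * p$lf_amp * sin(pi * p$lf_freq * dt))^2 / 2 +
    (2 * p$vlf_amp * sin(pi * p$vlf_freq * dt))^2 / 2)
  sqrt(max(2 * v - 0.5 * vd, 0))
}

#' Synthesise an inter-beat-interval series
#'
#' First-order autoregressive beat-to-beat dynamics plus respiratory-band
#' (0.25 Hz), low-frequency (0.08 Hz) and very-low-frequency (0.02 Hz)
#' oscillations, so that all frequency-domain measures are nondegenerate.
#' Optional planted effects: `nn50_extra` expected additional over-50 ms
#' successive differences (injected as sparse large isolated pulses whose
#' count is calibrated analytically against the model's baseline crossing
#' probability), and `sd2_extra` ms of additional long-term variability
#' (injected as a slow 1/30 Hz oscillation whose amplitude is solved from the
#' model's expected SD2).
#'
#' @param n number of intervals (>= 2).
#' @param base_rr mean interval in ms (default 850).
#' @param scale multiplier on all variability components (default 1).
#' @param nn50_extra,sd2_extra planted effect sizes (defaults 0).
#' @param params baseline model parameters, see internals (`ibi_params`).
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return an [ibi_series()].
#' @export
synthesize_ibi <- function(n, base_rr = 850, scale = 1, nn50_extra = 0,
                           sd2_extra = 0, params = NULL, seed = NULL) {
  if (n < 2) stop("synthesize_ibi needs n >= 2", call. = FALSE)
  p <- params %||% ibi_params(base_rr = base_rr)
  p$base_rr <- base_rr
  gen <- function() {
    # NN50 planting uses zero-sum adjacent pulse pairs [+d, -d]: three
    # successive differences (+d, -2d, +d) cross the 50 ms criterion per
    # pair. The expected number of pairs is calibrated by quadrature against
    # the model's baseline crossing probability, and all stochastic
    # components are shrunk by a factor c solved so that the expected SD2 is
    # unchanged by the injected pulse variance (the planted NN50 effect is
    # a short-term effect and must not masquerade as a long-term one).
    csc <- 1; np <- 0L; pulse <- 100
    if (nn50_extra > 0 && n >= 10) {
      np_exp <- 0
      q_ref <- nn50_base_prob(p, scale)  # baseline rate of unshifted trials
      for (it in 1:3) {
        c2 <- max(1 - np_exp * pulse^2 /
                    (n * sd2_base_value(p, scale)^2), 0.3)
        csc <- sqrt(c2)
        q0 <- nn50_base_prob(p, scale * csc)
        g <- 2 * (nn50_base_prob(p, scale * csc, pulse = pulse) - q0) +
             (nn50_base_prob(p, scale * csc, pulse = 2 * pulse) - q0)
        # the contrast is against unshifted trials, whose baseline crossing
        # rate differs from the variance-compensated one
        np_exp <- (nn50_extra - (n - 1) * (q0 - q_ref)) / max(g, 1e-6)
        np_exp <- max(np_exp, 0)
      }
      np <- floor(np_exp) + rbinom(1, 1, np_exp - floor(np_exp))
    }
    eff_scale <- scale * csc
    innov_sd <- p$ar_sd * sqrt(1 - p$ar_phi^2) * eff_scale
    ar <- as.numeric(stats::filter(
      c(rnorm(1, 0, p$ar_sd * eff_scale), rnorm(n - 1, 0, innov_sd)),
      p$ar_phi, method = "recursive"))
    tk <- (seq_len(n) - 1) * base_rr / 1000
    x <- base_rr + ar +
      eff_scale * p$hf_amp * sin(2 * pi * p$hf_freq * tk + runif(1, 0, 2 * pi)) +
      eff_scale * p$lf_amp * sin(2 * pi * p$lf_freq * tk + runif(1, 0, 2 * pi)) +
      eff_scale * p$vlf_amp * sin(2 * pi * p$vlf_freq * tk + runif(1, 0, 2 * pi))
    if (sd2_extra > 0) {
      s0 <- sd2_base_value(p, eff_scale)
      amp <- sqrt((s0 + sd2_extra)^2 - s0^2)  # variance amp^2/2, doubled in SD2^2
      x <- x + amp * sin(2 * pi * tk / 30 + runif(1, 0, 2 * pi))
    }
    if (np > 0) {
      pos <- integer(0)
      for (k in sample(seq(3, n - 3))) {
        if (length(pos) >= np) break
        if (all(abs(k - pos) >= 4)) pos <- c(pos, k)
      }
      x[pos] <- x[pos] + pulse
      x[pos + 1] <- x[pos + 1] - pulse
    }
    ibi_series(pmax(x, 300))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthesise an ECG trace from known inter-beat intervals
#'
#' Places one QRS-like deflection (a Gaussian-derivative wavelet of ~80 ms
#' width, 1 mV amplitude) at each cumulative interval time over a small
#' amount of measurement noise, so that an R-peak detector applied to the
#' output recovers the intervals.
#'
#' @param rr_intervals intervals in ms, all within \[300, 2000\].
#' @param fs sampling rate in Hz.
#' @param noise_sd white measurement noise in mV (default 0.01).
#' @return an [ecg_trace()].
#' @export
synthesize_ecg <- function(rr_intervals, fs, noise_sd = 0.01) {
  if (length(rr_intervals) == 0)
    stop("rr_intervals must be non-empty", call. = FALSE)
  if (any(rr_intervals < 300 | rr_intervals > 2000))
    stop("intervals outside the physiological range [300, 2000] ms",
         call. = FALSE)
  beat_t <- cumsum(c(0.5, rr_intervals / 1000))  # first beat at 0.5 s
  dur <- max(beat_t) + 0.5
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1) / fs
  x <- rnorm(n, 0, noise_sd)
  s <- 0.02  # Gaussian sd in s; wavelet support ~ 80 ms
  half <- round(0.06 * fs)
  for (bt in beat_t) {
    c_idx <- round(bt * fs) + 1  # beat rendered on the sample grid
    idx <- max(1, c_idx - half):min(n, c_idx + half)
    tt <- t[idx] - (c_idx - 1) / fs
    x[idx] <- x[idx] - (tt / s) * exp(-tt^2 / (2 * s^2)) * exp(0.5)
  }
  ecg_trace(x, fs)
}

# Per-subject continuous skin-temperature trace: mean-reverting drift around
# the subject baseline plus white sensor noise, a smooth task-evoked rise
# during stimulation, the women-carried negative-valence shift, and sparse
# large spike artifacts that exercise the scaled-MAD cleaning rule.
synthesize_temperature <- function(total_s, fs, baseline_c, trials,
                                   task_shift, neg_shift, spike_rate = 1 / 300) {
  n <- ceiling(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  phi <- 0.95
  innov <- 0.1 * sqrt(1 - phi^2)
  drift <- as.numeric(stats::filter(
    c(rnorm(1, 0, 0.1), rnorm(n - 1, 0, innov)),
    phi, method = "recursive"))
  x <- baseline_c + drift + rnorm(n, 0, 0.05)
  for (k in seq_len(nrow(trials))) {
    i <- t >= trials$onset_s[k] & t < trials$onset_s[k] + trials$duration_s[k]
    x[i] <- x[i] + task_shift +
      if (trials$label[k] == "negative") neg_shift else 0
  }
  spikes <- which(runif(n) < spike_rate)
  x[spikes] <- x[spikes] + sample(c(-1, 1), length(spikes), TRUE) * runif(length(spikes), 3, 8)
  list(time_s = t, celsius = x, fs = fs)
}

# EEG log-power generative model over the 24 region-band features. See the
# methods vignette for the full decomposition.
eeg_feature_template <- function() {
  feats <- c(eeg_primary_features(), eeg_auxiliary_features())
  asym <- setNames(rep(0, length(feats)), feats)
  asym[grep("^PF_left", feats)] <- 1    # positive valence: PF left up
  asym[grep("^PF_right", feats)] <- -1
  asym[grep("^O_left", feats)] <- -1    # occipital pattern reversed
  asym[grep("^O_right", feats)] <- 1
  base <- setNames(rep(2, length(feats)), feats)
  base[grep("alpha$", feats)] <- 3
  base[grep("beta1$", feats)] <- 2.5
  base[grep("beta2$", feats)] <- 2
  base[grep("gamma$", feats)] <- 1.5
  list(features = feats, asym = asym, base = base)
}

#' Generate a complete synthetic multimodal dataset
#'
#' Draws the full cohort: per-subject gender, per-trial valence labels
#' (balanced, shuffled), subjective valence/arousal ratings from truncated
#' normals matching the study-level summary statistics, per-trial inter-beat
#' interval series (optionally rendered as raw ECG traces), a continuous
#' skin-temperature trace per subject, and per-window EEG band-power
#' features, with all planted effects of the [effect_model()] applied.
#'
#' @param design a [study_design()].
#' @param effects an [effect_model()].
#' @param render_ecg also synthesise raw ECG traces from the IBI series
#'   (default `TRUE`; turn off for fast statistical sweeps that operate at
#'   the IBI level).
#' @param missing optional named list of subject ids to deliberately deprive
#'   of a modality, e.g. `list(ecg = c(2, 5))`.
#' @return object of class `multimodal_dataset`: `design`, `effects`,
#'   `subjects` (id, gender), `trials` (subject, trial, label, ratings,
#'   onset/duration), `ibi` (per subject per trial [ibi_series()]), `ecg`
#'   (per subject per trial trace, if rendered), `temperature` (per subject
#'   continuous trace), `eeg_features` (per-window band-power table).
#' @export
generate_dataset <- function(design = study_design(),
                             effects = effect_model(),
                             render_ecg = TRUE, missing = list()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_model"))
  with_seed(derive_seed(effects$seed, 1), {
    d <- design; e <- effects
    subjects <- data.frame(
      subject = seq_len(d$n_subjects),
      gender = rep(c("M", "F"), c(d$n_men, d$n_subjects - d$n_men)))
    tmpl <- eeg_feature_template()
    nf <- length(tmpl$features)
    trials_all <- list(); ibi_all <- list(); ecg_all <- list()
    temp_all <- list(); eeg_rows <- list()
    for (s in subjects$subject) {
      sc <- as.character(s)
      gender <- subjects$gender[s]
      mult <- max(rnorm(1, 1, e$subject_heterogeneity), 0.1)   # effect scale
      physio <- max(rnorm(1, 1, e$subject_heterogeneity), 0.1) # trait scale
      base_rr <- rnorm(1, 850, 50)
      baseline_c <- runif(1, 26.1, 28.1)
      half <- d$trials_per_subject / 2
      labels <- sample(rep(c("positive", "negative"), half))
      durs <- round(runif(d$trials_per_subject, d$trial_duration_s[1],
                          d$trial_duration_s[2]))
      onsets <- d$baseline_duration_s +
        cumsum(c(0, head(durs, -1) + d$baseline_duration_s))
      v_rat <- ifelse(labels == "positive",
                      rtruncnorm(d$trials_per_subject, 7.51, 1.6, 1, 9),
                      rtruncnorm(d$trials_per_subject, 2.91, 0.98, 1, 9))
      a_rat <- ifelse(labels == "positive",
                      rtruncnorm(d$trials_per_subject, 3.76, 1.62, 1, 9),
                      rtruncnorm(d$trials_per_subject, 5.47, 1.35, 1, 9))
      tr <- data.frame(subject = s, trial = seq_len(d$trials_per_subject),
                       label = labels, valence_rating = v_rat,
                       arousal_rating = a_rat, onset_s = onsets,
                       duration_s = durs)
      trials_all[[sc]] <- tr
      # --- cardiac ---
      ibi_s <- list(); ecg_s <- list()
      for (k in seq_len(d$trials_per_subject)) {
        nb <- max(2, floor(durs[k] * 1000 / base_rr))
        nn_extra <- if (gender == "M" && labels[k] == "positive")
          e$nn50_male_shift * mult else 0
        sd2_extra <- if (gender == "F" && labels[k] == "negative")
          e$sd2_female_shift * mult else 0
        ser <- synthesize_ibi(nb, base_rr = base_rr, scale = physio,
                              nn50_extra = nn_extra, sd2_extra = sd2_extra)
        ibi_s[[k]] <- ser
        if (render_ecg && !(s %in% (missing$ecg %||% integer(0))))
          ecg_s[[k]] <- synthesize_ecg(ser$intervals, d$ecg_fs)
      }
      if (!(s %in% (missing$ecg %||% integer(0)))) {
        ibi_all[[sc]] <- ibi_s
        if (render_ecg) ecg_all[[sc]] <- ecg_s
      }
      # --- temperature ---
      if (!(s %in% (missing$temperature %||% integer(0)))) {
        total_s <- max(onsets + durs) + d$baseline_duration_s
        temp_all[[sc]] <- synthesize_temperature(
          total_s, d$temp_fs, baseline_c, tr,
          task_shift = e$temp_task_shift,
          neg_shift = if (gender == "F") e$temp_neg_shift * mult else 0)
      }
      # --- EEG band-power features ---
      if (!(s %in% (missing$eeg %||% integer(0)))) {
        subj_base <- rnorm(nf, 0, 0.3)
        g_sign <- if (e$eeg_heterogeneous)
          sample(c(-1, 1), nf, TRUE) else rep(1, nf)
        resp <- mult * (e$eeg_asym_shift / 2 * tmpl$asym +
                        e$eeg_subject_shift / 2 * g_sign)
        step <- d$eeg_window_s * (1 - d$eeg_window_overlap)
        for (k in seq_len(d$trials_per_subject)) {
          nw <- max(1L, floor((durs[k] - d$eeg_window_s) / step) + 1L)
          v <- if (labels[k] == "positive") 1 else -1
          trial_noise <- rnorm(nf, 0, 0.2)
          mu <- tmpl$base + subj_base + v * resp + trial_noise
          win_noise <- matrix(rnorm(nw * nf, 0, 0.3), nw, nf)
          pows <- exp(sweep(win_noise, 2, mu, `+`))
          eeg_rows[[length(eeg_rows) + 1L]] <- cbind(
            data.frame(subject = s, gender = gender, trial = k,
                       window = seq_len(nw), label = labels[k],
                       valence_rating = v_rat[k]),
            as.data.frame(pows))
        }
      }
    }
    eeg_features <- if (length(eeg_rows) > 0) {
      ef <- do.call(rbind, eeg_rows)
      names(ef) <- c("subject", "gender", "trial", "window", "label",
                     "valence_rating", tmpl$features)
      ef
    } else NULL
    trials <- do.call(rbind, trials_all)
    rownames(trials) <- NULL
    structure(list(design = d, effects = e, subjects = subjects,
                   trials = trials, ibi = ibi_all,
                   ecg = if (render_ecg) ecg_all else NULL,
                   temperature = temp_all, eeg_features = eeg_features),
              class = "multimodal_dataset")
  })
}

#' Temperature trial/baseline annotations of a dataset subject
#'
#' Builds the annotation table consumed by [segment_temperature()]: one row
#' per stimulus trial (condition = valence label) and one per inter-trial
#' baseline period.
#'
#' @param dataset a [generate_dataset()] result.
#' @param subject subject id.
#' @return data frame `trial`, `onset_s`, `duration_s`, `condition`.
#' @export
temperature_annotations <- function(dataset, subject) {
  tr <- dataset$trials[dataset$trials$subject == subject, ]
  bl <- data.frame(trial = NA_integer_,
                   onset_s = c(0, tr$onset_s + tr$duration_s),
                   duration_s = dataset$design$baseline_duration_s,
                   condition = "baseline")
  stim <- data.frame(trial = tr$trial, onset_s = tr$onset_s,
                     duration_s = tr$duration_s, condition = tr$label)
  out <- rbind(stim, bl)
  out[order(out$onset_s), ]
}
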