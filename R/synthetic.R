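#' Configuration for the synthetic signal generator
#'
#' The generator emulates smartphone-pocket accelerometry: a constant 1 g
#' gravity vector at a random orientation, activity-specific dynamics on
#' top, white sensor noise, per-subject gain/offset effects, and clipping
#' at the sensor range. Falls follow the two-phase morphology seen in real
#' traces: build-up oscillation of about +/-0.5 g while balance is lost, a
#' brief free-fall dip of the resultant toward 0 g, a sharp impact spike of
#' 1 g and above (default 1.8 g, near smartphone saturation), then rest.
#' Fall duration is uniform on 1-3 s.
#'
#' @param rate sampling rate in Hz (default 50).
#' @param range_g sensor range in g (default 2).
#' @param n_subjects number of simulated wearers.
#' @param falls_per_subject,adls_per_subject event counts per subject for
#'   [gen_event_dataset()]; the 20/80 default gives a 1:4 class imbalance.
#' @param adl_mix named weights over the ADL subtypes `walk`, `sit_down`,
#'   `jump`, `lie_still`, `transition`; normalised to sum to 1.
#' @param pre_osc_amp_g pre-impact oscillation amplitude in g.
#' @param impact_amp_g impact spike amplitude in g (clipped at the range).
#' @param noise_sd_g white noise standard deviation in g.
#' @param subject_effect_sd sd of the per-subject multiplicative gain
#'   jitter; the additive per-axis offset sd is half of it. Set to 0 for
#'   subject-homogeneous data.
#' @param seed root RNG seed; all generation is bit-reproducible under it.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(rate = 50, range_g = 2, n_subjects = 10,
                             falls_per_subject = 20, adls_per_subject = 80,
                             adl_mix = c(walk = 0.3, sit_down = 0.2, jump = 0.1,
                                         lie_still = 0.2, transition = 0.2),
                             pre_osc_amp_g = 0.5, impact_amp_g = 1.8,
                             noise_sd_g = 0.05, subject_effect_sd = 0.1,
                             seed = 1) {
  known <- c("walk", "sit_down", "jump", "lie_still", "transition")
  if (is.null(names(adl_mix)) || !all(names(adl_mix) %in% known)) {
    abort_usage(sprintf("adl_mix names must be among: %s", paste(known, collapse = ", ")))
  }
  if (any(adl_mix < 0) || sum(adl_mix) <= 0) abort_usage("adl_mix weights must be >= 0 and not all 0")
  if (pre_osc_amp_g <= 0 || impact_amp_g <= 0) abort_usage("amplitudes must be > 0")
  if (rate <= 0 || range_g <= 0 || noise_sd_g < 0 || subject_effect_sd < 0) {
    abort_usage("rate and range_g must be > 0; sds must be >= 0")
  }
  structure(list(
    rate = rate, range_g = range_g, n_subjects = as.integer(n_subjects),
    falls_per_subject = as.integer(falls_per_subject),
    adls_per_subject = as.integer(adls_per_subject),
    adl_mix = adl_mix / sum(adl_mix),
    pre_osc_amp_g = pre_osc_amp_g, impact_amp_g = impact_amp_g,
    fall_duration_range_s = c(1, 3),
    noise_sd_g = noise_sd_g, subject_effect_sd = subject_effect_sd,
    seed = seed
  ), class = "synthetic_config")
}

random_unit_vec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# deterministic per-subject sensor gain, offset, and habitual device
# orientation (the dominant inter-subject effect in pocket accelerometry:
# each wearer carries the phone in their own typical orientation)
subject_effects <- function(cfg, subject) {
  withr::with_seed(derive_seed(cfg$seed, 5000L + as.integer(subject)), {
    list(scale = max(0.5, 1 + stats::rnorm(1, 0, cfg$subject_effect_sd)),
         offset = stats::rnorm(3, 0, cfg$subject_effect_sd / 2),
         g_dir = random_unit_vec())
  })
}

# per-event wobble around the subject's habitual orientation
jitter_orientation <- function(g_dir, sd = 0.3) {
  v <- g_dir + stats::rnorm(3, 0, sd)
  v / sqrt(sum(v^2))
}

half_sine <- function(n) sin(pi * (seq_len(n) - 0.5) / n)

# n x 3 fall signal (gravity included, no noise / subject effects);
# must be called inside an RNG context
synth_fall_signal <- function(cfg, rate, n, g0 = random_unit_vec()) {
  tt <- (seq_len(n) - 1L) / rate
  sig <- outer(rep(1, n), g0)
  impact_t <- stats::runif(1, 1.7, 2.55)
  d <- stats::runif(1, cfg$fall_duration_range_s[1], cfg$fall_duration_range_s[2])
  ts <- max(0.05, impact_t - d)
  dip_len <- 0.15
  # phase 1: balance-loss oscillation, building toward the impact
  osc_idx <- which(tt >= ts & tt < impact_t - dip_len)
  if (length(osc_idx) > 0) {
    env <- seq(0.3, 1, length.out = length(osc_idx))
    for (ax in 1:3) {
      f <- stats::runif(1, 2, 5); ph <- stats::runif(1, 0, 2 * pi)
      amp <- cfg$pre_osc_amp_g * stats::runif(1, 0.6, 1)
      sig[osc_idx, ax] <- sig[osc_idx, ax] + env * amp * sin(2 * pi * f * tt[osc_idx] + ph)
    }
  }
  # free-fall dip: resultant magnitude collapses toward 0 g
  dip_idx <- which(tt >= impact_t - dip_len & tt < impact_t)
  if (length(dip_idx) > 0) {
    fade <- seq(1, 0.05, length.out = length(dip_idx))
    sig[dip_idx, ] <- sig[dip_idx, ] * fade
  }
  # impact spike: ground-contact deceleration dominates the residual
  # gravity reading, so the spike amplitude sets the resultant magnitude
  # regardless of its direction relative to the device axes
  w <- max(2L, round(0.12 * rate))
  imp_idx <- which(tt >= impact_t)[seq_len(w)]
  imp_idx <- imp_idx[!is.na(imp_idx)]
  dir <- random_unit_vec()
  sig[imp_idx, ] <- 0.15 * sig[imp_idx, ] +
    outer(cfg$impact_amp_g * half_sine(length(imp_idx)), dir)
  # rest at a new orientation (lying: rotated away from the habitual one)
  g1 <- jitter_orientation(g0, 0.8)
  rest_idx <- which(tt >= impact_t + w / rate)
  if (length(rest_idx) > 0) sig[rest_idx, ] <- outer(rep(1, length(rest_idx)), g1)
  sig
}

# n x 3 ADL signal by subtype; must be called inside an RNG context
synth_adl_signal <- function(cfg, subtype, rate, n, g0 = random_unit_vec()) {
  tt <- (seq_len(n) - 1L) / rate
  base <- outer(rep(1, n), g0)
  switch(subtype,
    walk = {
      # ~2 Hz vertical bobbing plus a weaker lateral sway
      f <- 2 + stats::runif(1, -0.15, 0.15)
      ph <- stats::runif(1, 0, 2 * pi)
      perp <- random_unit_vec(); perp <- perp - sum(perp * g0) * g0
      perp <- perp / max(sqrt(sum(perp^2)), 1e-9)
      base * (1 + 0.25 * sin(2 * pi * f * tt + ph)) +
        outer(0.10 * sin(2 * pi * f * tt + ph + pi / 3), perp)
    },
    sit_down = {
      # the designed hard negative: one moderate impact spike (chair contact)
      tc <- stats::runif(1, 0.8, 2.2)
      w <- max(2L, round(0.3 * rate))
      idx <- which(tt >= tc)[seq_len(w)]
      idx <- idx[!is.na(idx)]
      dir <- random_unit_vec()
      sig <- base
      sig[idx, ] <- sig[idx, ] +
        outer(0.5 * cfg$impact_amp_g * half_sine(length(idx)), dir)
      sig
    },
    jump = {
      sig <- base
      starts <- stats::runif(1, 0.1, 0.5) + (0:2) * stats::runif(1, 0.8, 1.0)
      for (tc in starts) {
        w <- max(2L, round(0.15 * rate))
        idx <- which(tt >= tc)[seq_len(w)]
        idx <- idx[!is.na(idx)]
        if (length(idx) == 0) next
        dir <- random_unit_vec()
        sig[idx, ] <- sig[idx, ] +
          outer(0.55 * cfg$impact_amp_g * half_sine(length(idx)), dir)
      }
      sig
    },
    lie_still = base,
    transition = {
      # slow re-orientation of the gravity vector across the segment
      g1 <- jitter_orientation(g0, 0.6)
      a <- (seq_len(n) - 1L) / max(n - 1L, 1L)
      sig <- (1 - a) %o% g0 + a %o% g1
      nrm <- sqrt(rowSums(sig^2))
      sig / pmax(nrm, 1e-9)
    },
    abort_usage(sprintf("unknown ADL subtype '%s'", subtype))
  )
}

finalize_trace <- function(cfg, sig, rate, subject, eff, annotations = NULL) {
  n <- nrow(sig)
  sig <- eff$scale * sig + matrix(eff$offset, n, 3, byrow = TRUE)
  sig <- sig + matrix(stats::rnorm(3L * n, 0, cfg$noise_sd_g), n, 3)
  sig <- pmin(pmax(sig, -cfg$range_g), cfg$range_g)
  triaxial_trace(sig[, 1], sig[, 2], sig[, 3], rate = rate, range_g = cfg$range_g,
                 subject_id = sprintf("S%02d", as.integer(subject)),
                 position = "pocket", annotations = annotations)
}

#' Generate a single 3 s fall window
#'
#' @param cfg a [synthetic_config()].
#' @param subject subject index (drives the deterministic per-subject
#'   gain/offset effects).
#' @param seed event seed; the same `(cfg, subject, seed)` always yields a
#'   bit-identical trace.
#' @return a 3 s [triaxial_trace()] labeled by its caller as `FALL`.
#' @export
gen_fall_window <- function(cfg = synthetic_config(), subject = 1, seed = 1) {
  n <- as.integer(round(3 * cfg$rate))
  eff <- subject_effects(cfg, subject)
  withr::with_seed(seed, {
    g0 <- jitter_orientation(eff$g_dir)
    sig <- synth_fall_signal(cfg, cfg$rate, n, g0)
    finalize_trace(cfg, sig, cfg$rate, subject, eff)
  })
}

#' Generate a single 3 s ADL window
#'
#' Subtypes: `walk` (~2 Hz gait oscillation), `sit_down` (single moderate
#' impact spike — the designed hard negative), `jump` (repeated spikes),
#' `lie_still` (gravity plus noise), `transition` (slow re-orientation).
#'
#' @param cfg a [synthetic_config()].
#' @param subtype one of the names of `cfg$adl_mix`.
#' @param subject subject index.
#' @param seed event seed.
#' @return a 3 s [triaxial_trace()].
#' @export
gen_adl_window <- function(cfg = synthetic_config(), subtype = "walk",
                           subject = 1, seed = 1) {
  n <- as.integer(round(3 * cfg$rate))
  eff <- subject_effects(cfg, subject)
  withr::with_seed(seed, {
    g0 <- jitter_orientation(eff$g_dir)
    sig <- synth_adl_signal(cfg, subtype, cfg$rate, n, g0)
    finalize_trace(cfg, sig, cfg$rate, subject, eff)
  })
}

#' Generate a labeled single-event dataset
#'
#' Per subject, `falls_per_subject` fall windows and `adls_per_subject`
#' ADL windows with subtypes drawn from `adl_mix`. Regeneration under the
#' same config (including its seed) is bit-identical.
#'
#' @param cfg a [synthetic_config()].
#' @return a tibble with columns `event_id`, `subject_id`, `label`
#'   (`"FALL"` / `"ADL"`), `subtype`, and list-column `trace`.
#' @export
gen_event_dataset <- function(cfg = synthetic_config()) {
  rows <- list()
  ev <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    subtypes <- withr::with_seed(derive_seed(cfg$seed, 9000L + s), {
      sample(names(cfg$adl_mix), cfg$adls_per_subject, replace = TRUE,
             prob = cfg$adl_mix)
    })
    for (i in seq_len(cfg$falls_per_subject)) {
      ev <- ev + 1L
      rows[[ev]] <- tibble::tibble(
        event_id = ev, subject_id = sprintf("S%02d", s),
        label = "FALL", subtype = "fall",
        trace = list(gen_fall_window(cfg, s, derive_seed(cfg$seed, ev)))
      )
    }
    for (i in seq_len(cfg$adls_per_subject)) {
      ev <- ev + 1L
      rows[[ev]] <- tibble::tibble(
        event_id = ev, subject_id = sprintf("S%02d", s),
        label = "ADL", subtype = subtypes[i],
        trace = list(gen_adl_window(cfg, subtypes[i], s, derive_seed(cfg$seed, ev)))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a long continuous recording with annotated falls
#'
#' Stitches variable-length background segments of ADL subtypes, then
#' overwrites `n_falls` non-overlapping 3 s stretches with fall signals,
#' each annotated with its true interval. Emulates long free-living
#' recordings (e.g. 1200 s with a single real fall).
#'
#' @param cfg a [synthetic_config()].
#' @param duration_s recording length in seconds (default 1200).
#' @param n_falls number of falls to insert.
#' @param seed recording seed.
#' @param subject subject index.
#' @param rate optional rate override (e.g. 20 or 100 Hz to emulate
#'   sensor heterogeneity); defaults to `cfg$rate`.
#' @return an annotated [triaxial_trace()].
#' @export
gen_continuous_recording <- function(cfg = synthetic_config(), duration_s = 1200,
                                     n_falls = 1, seed = 1, subject = 1,
                                     rate = NULL) {
  rate <- rate %||% cfg$rate
  n_total <- as.integer(round(duration_s * rate))
  fall_len_s <- 3
  if (n_falls * 10 > duration_s) abort_usage("cannot pack that many falls into the recording")
  eff <- subject_effects(cfg, subject)
  withr::with_seed(seed, {
    # fall start times, >= 6 s apart, away from the edges
    starts <- numeric(0)
    tries <- 0L
    while (length(starts) < n_falls) {
      cand <- stats::runif(1, 5, duration_s - fall_len_s - 5)
      if (all(abs(cand - starts) >= 2 * fall_len_s)) starts <- c(starts, cand)
      tries <- tries + 1L
      if (tries > 1000L * n_falls) abort_usage("cannot pack falls without overlap")
    }
    starts <- sort(starts)
    # background: stitched ADL segments
    sig <- matrix(0, n_total, 3)
    pos <- 0L
    while (pos < n_total) {
      seg_s <- stats::runif(1, 5, 15)
      seg_n <- min(as.integer(round(seg_s * rate)), n_total - pos)
      subtype <- sample(names(cfg$adl_mix), 1L, prob = cfg$adl_mix)
      g0 <- jitter_orientation(eff$g_dir)
      sig[(pos + 1L):(pos + seg_n), ] <- synth_adl_signal(cfg, subtype, rate, seg_n, g0)
      pos <- pos + seg_n
    }
    # overwrite with falls
    nf <- as.integer(round(fall_len_s * rate))
    for (t0 in starts) {
      i0 <- as.integer(round(t0 * rate))
      sig[(i0 + 1L):(i0 + nf), ] <- synth_fall_signal(cfg, rate, nf,
                                                      jitter_orientation(eff$g_dir))
    }
    ann <- tibble::tibble(start_s = round(starts * rate) / rate,
                          end_s = round(starts * rate) / rate + fall_len_s,
                          label = "fall")
    finalize_trace(cfg, sig, rate, subject, eff, annotations = ann)
  })
}
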