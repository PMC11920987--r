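#' Specification of a parametric synthetic listener
#'
#' Describes the acoustic structure of a synthetic listener's DTF set: a main
#' spectral notch whose center frequency rises monotonically with polar angle
#' over the frontal range (the dominant elevation cue of real pinnae), a
#' high-frequency spectral peak, a rear trajectory mirrored from the front
#' with an octave offset (controlling front-back similarity and hence the
#' attainable quadrant error rate), a small fixed inter-ear notch offset plus
#' a lateral-angle-dependent spectral tilt between the ears, and smooth
#' random spectral jitter per direction and ear.
#'
#' @param notch_start_freq Notch center (Hz) at polar angle -30 deg.
#' @param notch_octaves_per_90deg Rise of the notch center in octaves per 90
#'   deg of polar angle.
#' @param notch_depth Notch depth in dB (negative).
#' @param notch_width Notch Gaussian SD in octaves.
#' @param peak_freq,peak_gain Center (Hz) and maximum gain (dB) of a
#'   high-frequency pinna peak.
#' @param peak_gain_mod Relative modulation of the peak gain with polar
#'   angle (0 = static peak; 1 = gain swings between 0 and twice
#'   `peak_gain`). An elevation-dependent peak concentrates spatial variance
#'   in the bands above the main notch region, as observed in measured DTF
#'   sets.
#' @param rear_offset_octaves Octave offset applied to the mirrored rear
#'   notch trajectory (nonzero values create front-rear spectral contrast).
#' @param rear_depth_factor,rear_width_factor Multipliers on notch depth and
#'   width for rear directions, so rear spectra differ from the front in
#'   shape and not only in notch position (controls front-back
#'   confusability).
#' @param ear_asymmetry_db Scale (dB per octave at 90 deg lateral) of the
#'   opposite spectral tilt applied to the two ears.
#' @param ear_notch_offset_oct Fixed inter-ear offset of the notch center in
#'   octaves.
#' @param spectral_jitter_sd SD (dB) of smooth random spectral jitter.
#' @param rng_seed Seed controlling all randomness of the listener.
#' @return A list of class `synthetic_listener_spec`.
#' @export
synthetic_listener_spec <- function(notch_start_freq = 6000,
                                    notch_octaves_per_90deg = 1,
                                    notch_depth = -25,
                                    notch_width = 0.25,
                                    peak_freq = 12500,
                                    peak_gain = 8,
                                    peak_gain_mod = 0.8,
                                    rear_offset_octaves = -0.4,
                                    rear_depth_factor = 0.7,
                                    rear_width_factor = 1.6,
                                    ear_asymmetry_db = 1,
                                    ear_notch_offset_oct = 0.1,
                                    spectral_jitter_sd = 1,
                                    rng_seed = 1) {
  stopifnot(notch_depth < 0, is.finite(peak_gain), notch_width > 0,
            spectral_jitter_sd >= 0)
  structure(as.list(environment()), class = "synthetic_listener_spec")
}

# main-notch center frequency (Hz) at polar angle theta for one ear
notch_trajectory <- function(spec, theta, ear) {
  ear_off <- if (ear == "left") -spec$ear_notch_offset_oct / 2 else
    spec$ear_notch_offset_oct / 2
  front <- ifelse(theta <= 90, theta, 180 - theta)  # mirror rear into front
  oct <- spec$notch_octaves_per_90deg * (front + 30) / 90 +
    ifelse(theta <= 90, 0, spec$rear_offset_octaves) + ear_off
  spec$notch_start_freq * 2^oct
}

# smooth random dB curve over log-frequency from a handful of seeded knots
smooth_jitter <- function(freq_hz, sd, n_knots = 8) {
  if (sd == 0) return(rep(0, length(freq_hz)))
  lf <- log2(freq_hz)
  knots <- seq(min(lf), max(lf), length.out = n_knots)
  stats::spline(knots, stats::rnorm(n_knots, 0, sd), xout = lf)$y
}

#' Generate a synthetic listener's DTF set and templates
#'
#' Builds smooth dB magnitude spectra for every direction and ear according
#' to a [synthetic_listener_spec()], runs them through the peripheral stage
#' ([magnitude_profile()] + [psg()]) and returns both the raw DTFs and the
#' resulting [template_set()]. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_listener_spec()].
#' @param polar_grid Polar template grid in degrees (default 5-deg spacing
#'   over `[-90, 270)`).
#' @param lateral_planes Lateral angles (deg) of the sagittal planes to
#'   generate.
#' @param grid An [erb_bands()] grid.
#' @param freq_hz Frequency axis for the raw spectra.
#' @param subject_id Listener identifier.
#' @return A list with elements `templates` (a [template_set()]) and `dtf`
#'   (list with `freq_hz` and per-plane dB magnitude matrices per ear).
#' @export
make_dtf_set <- function(spec,
                         polar_grid = seq(-90, 265, by = 5),
                         lateral_planes = 0,
                         grid = erb_bands(),
                         freq_hz = seq(500, 20000, length.out = 480),
                         subject_id = "synthetic") {
  traj <- c(notch_trajectory(spec, polar_grid, "left"),
            notch_trajectory(spec, polar_grid, "right"))
  if (min(traj) < 700 || max(traj) > 18000)
    stop("notch trajectory leaves the 700 Hz - 18 kHz band range; ",
         "adjust the listener spec", call. = FALSE)
  lf <- log2(freq_hz)
  peak_shape <- exp(-0.5 * ((lf - log2(spec$peak_freq)) / 0.4)^2)
  withr::with_seed(spec$rng_seed, {
    planes <- lapply(lateral_planes, function(lat) {
      spect <- function(ear) {
        tilt_sign <- if (ear == "left") 1 else -1
        tilt <- tilt_sign * spec$ear_asymmetry_db * (lat / 90) * (lf - log2(700))
        t(vapply(polar_grid, function(th) {
          fc <- notch_trajectory(spec, th, ear)
          depth <- spec$notch_depth * if (th > 90) spec$rear_depth_factor else 1
          width <- spec$notch_width * if (th > 90) spec$rear_width_factor else 1
          notch <- depth * exp(-0.5 * ((lf - log2(fc)) / width)^2)
          # pinna peak strongest overhead, weakest below; circularly smooth
          peak <- spec$peak_gain *
            (1 + spec$peak_gain_mod * sin(th * pi / 180)) * peak_shape
          notch + peak + tilt + smooth_jitter(freq_hz, spec$spectral_jitter_sd)
        }, numeric(length(freq_hz))))
      }
      list(lateral = lat, theta = polar_grid,
           left_db = spect("left"), right_db = spect("right"))
    })
  })
  names(planes) <- as.character(lateral_planes)
  tpl_planes <- lapply(planes, function(p) {
    band_psg <- function(db) {
      t(apply(db, 1, function(row)
        psg(magnitude_profile(freq_hz, 10^(row / 20), grid))))
    }
    list(lateral = p$lateral, theta = p$theta,
         left = band_psg(p$left_db), right = band_psg(p$right_db))
  })
  list(templates = template_set(subject_id, grid, tpl_planes),
       dtf = list(freq_hz = freq_hz,
                  planes = lapply(planes, function(p)
                    p[c("lateral", "theta", "left_db", "right_db")])))
}

#' Evenly spaced targets within a sagittal plane
#'
#' @param lateral Lateral angle of the plane (deg).
#' @param spacing Polar spacing in degrees.
#' @return Tibble with columns `lat`, `pol`.
#' @export
uniform_targets <- function(lateral = 0, spacing = 15) {
  tibble::tibble(lat = lateral, pol = seq(-90, 270 - spacing, by = spacing))
}

#' Simulate localization responses from the model
#'
#' Draws polar-angle responses i.i.d. from the model-predicted PMV of each
#' target, emulating a virtual-source localization experiment in which the
#' stimulus is the listener's own DTF-filtered flat-spectrum noise.
#'
#' @param templates A [template_set()].
#' @param scheme Generating [weighting_scheme()].
#' @param params Generating [model_params()].
#' @param targets Tibble with columns `lat`, `pol`; all `lat` values must
#'   match template planes.
#' @param n_total Total number of trials, allocated as evenly as possible
#'   across targets (in target order).
#' @param seed Integer seed; same seed gives an identical response table.
#' @param phi_scale Binaural weighting scale (deg).
#' @return Tibble of class `response_set` with columns `subject_id`,
#'   `target_lat`, `target_pol`, `response_lat`, `response_pol`.
#' @export
simulate_responses <- function(templates, scheme, params,
                               targets = uniform_targets(), n_total = 300,
                               seed = 1, phi_scale = 13) {
  stopifnot(n_total >= 1)
  nt <- nrow(targets)
  counts <- rep(n_total %/% nt, nt)
  extra <- n_total %% nt
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  out <- withr::with_seed(seed, {
    purrr::map_dfr(split(targets, targets$lat), function(tg) {
      m <- pmv_matrix(templates, tg, params, scheme,
                      lateral_plane = tg$lat[1], phi_scale = phi_scale)
      idx <- match(paste(tg$lat, tg$pol), paste(targets$lat, targets$pol))
      purrr::map_dfr(seq_len(nrow(tg)), function(j) {
        n <- counts[idx[j]]
        tibble::tibble(subject_id = templates$subject_id,
                       target_lat = tg$lat[j], target_pol = tg$pol[j],
                       response_lat = tg$lat[j],
                       response_pol = sample(m$theta, n, replace = TRUE,
                                             prob = m$pmv[, j]))
      })
    })
  })
  class(out) <- c("response_set", class(out))
  out
}

#' Simulate a cohort of synthetic listeners
#'
#' Generates `n_subjects` independent listeners with specs jittered around
#' the defaults, draws per-subject model parameters around the supplied base
#' values, simulates responses under the chosen generating scheme, and emits
#' a ground-truth ledger alongside the data.
#'
#' @param n_subjects Number of listeners (default 17, a typical analyzed
#'   pool size for this paradigm).
#' @param true_scheme Generating scheme name: one of `"Flat"`, `"NR"`,
#'   `"DT"`, `"SV"` (subject-level, from each listener's own templates) or
#'   `"LP"`; may be a vector of length `n_subjects`.
#' @param base_params [model_params()] around which per-subject true
#'   parameters are jittered (gamma: 15% log-normal; s: SD 0.15; epsilon:
#'   SD 1.5 deg, clipped to (3, 50)).
#' @param n_per_subject Trials per subject (median plane).
#' @param targets Target table (see [uniform_targets()]).
#' @param lateral_planes Planes to generate templates for.
#' @param seed Master seed; every listener derives its own stream from it.
#' @return List with `listeners` (list of [template_set()]), `responses`
#'   (one bound response tibble), and `truth` (per-subject ledger tibble with
#'   scheme, parameters and seeds).
#' @export
make_cohort <- function(n_subjects = 17, true_scheme = "NR",
                        base_params = model_params(6, 0.7, 12.79),
                        n_per_subject = 300,
                        targets = uniform_targets(),
                        lateral_planes = 0, seed = 1) {
  scheme_names <- rep(true_scheme, length.out = n_subjects)
  draws <- withr::with_seed(seed, list(
    sub_seed  = sample.int(.Machine$integer.max, n_subjects),
    resp_seed = sample.int(.Machine$integer.max, n_subjects),
    # truncated so every jittered trajectory stays inside 700 Hz - 18 kHz
    notch     = exp(pmin(pmax(stats::rnorm(n_subjects, 0, 0.05), -0.08), 0.08)),
    oct       = pmin(pmax(stats::rnorm(n_subjects, 0, 0.03), -0.05), 0.05),
    gamma     = base_params$gamma * exp(stats::rnorm(n_subjects, 0, 0.15)),
    s         = base_params$s + stats::rnorm(n_subjects, 0, 0.15),
    eps       = pmin(pmax(base_params$epsilon +
                            stats::rnorm(n_subjects, 0, 1.5), 3.5), 49)
  ))
  grid <- erb_bands()
  subjects <- purrr::map(seq_len(n_subjects), function(i) {
    spec <- synthetic_listener_spec(
      notch_start_freq = 6000 * draws$notch[i],
      notch_octaves_per_90deg = 1 + draws$oct[i],
      rng_seed = draws$sub_seed[i])
    id <- sprintf("S%02d", i)
    tpl <- make_dtf_set(spec, lateral_planes = lateral_planes, grid = grid,
                        subject_id = id)$templates
    sch <- switch(scheme_names[i],
                  Flat = scheme_flat(grid),
                  NR   = scheme_nr(grid),
                  DT   = scheme_dt(grid),
                  LP   = scheme_lp(grid),
                  SV   = scheme_sv(spatial_variance(tpl, 0), grid, id),
                  stop("unknown scheme: ", scheme_names[i], call. = FALSE))
    par <- model_params(draws$gamma[i], draws$s[i], draws$eps[i])
    resp <- simulate_responses(tpl, sch, par, targets, n_per_subject,
                               seed = draws$resp_seed[i])
    list(templates = tpl, responses = resp,
         truth = tibble::tibble(subject_id = id, scheme = scheme_names[i],
                                gamma = par$gamma, s = par$s,
                                epsilon = par$epsilon,
                                listener_seed = draws$sub_seed[i],
                                response_seed = draws$resp_seed[i]))
  })
  list(listeners = purrr::map(subjects, "templates"),
       responses = purrr::map_dfr(subjects, "responses"),
       truth     = purrr::map_dfr(subjects, "truth"))
}
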