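# Seeded generators for occlusion experiments and human-style CTG traces.
# All randomness goes through R's RNG; a given seed reproduces a trace
# bit-for-bit.

MAX_EXPERIMENT_S <- 4 * 3600   # occlusions repeat for at most 4 h
MAP_STOP_MMHG <- 20            # stop after two successive minima below this
FHR_RANGE <- c(30, 250)        # plausible fetal heart-rate range, bpm

#' Simulation parameters for one fetal sheep
#'
#' Phenomenological knobs of the occlusion-experiment generator. The
#' generator is not a mechanistic cardiovascular model: it produces traces
#' whose extractable features (deceleration depth/duration, per-occlusion
#' minimum blood pressure, post-occlusion overshoot, progressive
#' hypotension, noise and dropout) mimic the experimental recordings, with
#' the latent per-occlusion minimum FBP retained as ground truth.
#'
#' @param baseline_fhr Baseline fetal heart rate, bpm.
#' @param baseline_fbp Baseline (inter-occlusion) mean arterial pressure,
#'   mmHg; must lie in (10, 80).
#' @param hypotension_rate Decline of the latent per-occlusion minimum FBP,
#'   mmHg per occlusion.
#' @param coupling_depth Extra deceleration depth per mmHg of FBP decline,
#'   bpm/mmHg. Zero decouples the heart-rate trace from blood pressure.
#' @param overshoot_gain Amplitude scale of the post-occlusion FHR
#'   overshoot, bpm (applied only in groups N2-5 and H1-5, scaled by the
#'   current latent FBP so the overshoot is most pronounced while pressure
#'   is still high).
#' @param fhr_noise_sd Gaussian noise on the FHR samples, bpm.
#' @param gap_prob Expected fraction of missing samples (dropout occurs in
#'   contiguous runs with geometric lengths).
#' @param base_decel_depth Deceleration depth at zero FBP decline, bpm.
#' @param fbp_jitter_sd SD of the seeded jitter on the latent minimum FBP
#'   sequence, mmHg.
#' @param fbp_noise_sd Gaussian measurement noise on the FBP samples, mmHg.
#' @param gap_len_mean Mean length of a dropout run, seconds.
#' @param seed Integer seed.
#' @return A `sheep_sim_params` list.
#' @export
sheep_sim_params <- function(baseline_fhr = 160, baseline_fbp = 55,
                             hypotension_rate = 0.8, coupling_depth = 1.2,
                             overshoot_gain = 20, fhr_noise_sd = 2,
                             gap_prob = 0.005, base_decel_depth = 25,
                             fbp_jitter_sd = 1, fbp_noise_sd = 0,
                             gap_len_mean = 10, seed = 1L) {
  p <- list(baseline_fhr = baseline_fhr, baseline_fbp = baseline_fbp,
            hypotension_rate = hypotension_rate,
            coupling_depth = coupling_depth,
            overshoot_gain = overshoot_gain, fhr_noise_sd = fhr_noise_sd,
            gap_prob = gap_prob, base_decel_depth = base_decel_depth,
            fbp_jitter_sd = fbp_jitter_sd, fbp_noise_sd = fbp_noise_sd,
            gap_len_mean = gap_len_mean, seed = as.integer(seed))
  nonneg <- c("hypotension_rate", "coupling_depth", "overshoot_gain",
              "fhr_noise_sd", "gap_prob", "base_decel_depth",
              "fbp_jitter_sd", "fbp_noise_sd")
  for (f in nonneg) {
    if (p[[f]] < 0) stop("parameter '", f, "' must be nonnegative")
  }
  if (p$baseline_fbp <= 10 || p$baseline_fbp >= 80) {
    stop("baseline_fbp must lie in (10, 80) mmHg")
  }
  class(p) <- "sheep_sim_params"
  p
}

#' Construct an experiment trace container
#'
#' @param fhr,fbp Numeric vectors at 1 Hz (NA marks missing samples); must
#'   have equal length. FBP may be NULL for FHR-only (human-style) traces.
#' @param first_occlusion_start Start time of the first occlusion, seconds.
#' @param group A `group_spec`, or NULL for human traces.
#' @param sheep_id Identifier label.
#' @param truth_min_fbp Optional latent per-occlusion minimum FBP (mmHg),
#'   synthetic traces only.
#' @return An `experiment_trace` list.
#' @export
experiment_trace <- function(fhr, fbp = NULL, first_occlusion_start = 0,
                             group = NULL, sheep_id = "sheep",
                             truth_min_fbp = NULL) {
  if (!is.null(fbp) && length(fbp) != length(fhr)) {
    stop("fhr and fbp must have the same length")
  }
  ok <- fhr[!is.na(fhr)]
  if (length(ok) && (min(ok) < FHR_RANGE[1] || max(ok) > FHR_RANGE[2])) {
    stop("non-missing FHR must lie in [30, 250] bpm")
  }
  structure(list(fhr = fhr, fbp = fbp,
                 first_occlusion_start = first_occlusion_start,
                 group = group, sheep_id = sheep_id,
                 truth_min_fbp = truth_min_fbp),
            class = "experiment_trace")
}

#' @export
print.experiment_trace <- function(x, ...) {
  cat(sprintf("<experiment_trace '%s'%s: %d s, %s occlusions>\n",
              x$sheep_id,
              if (!is.null(x$group)) paste0(" [", x$group$name, "]") else "",
              length(x$fhr),
              if (is.null(x$truth_min_fbp)) "?" else
                length(x$truth_min_fbp)))
  invisible(x)
}

# Latent minimum-FBP sequence with the 4 h / MAP stop rule applied.
latent_min_fbp <- function(params, spacing) {
  max_occ <- floor(MAX_EXPERIMENT_S / spacing) + 1L
  m <- numeric(0)
  for (k in seq_len(max_occ) - 1L) {
    mk <- params$baseline_fbp - params$hypotension_rate * k +
      stats::rnorm(1, 0, params$fbp_jitter_sd)
    mk <- min(max(mk, 2), params$baseline_fbp)  # a dip, never a rise
    m <- c(m, mk)
    if (k >= 1L && m[k + 1L] < MAP_STOP_MMHG && m[k] < MAP_STOP_MMHG) break
  }
  m
}

# Contiguous dropout mask: runs start at rate gap_prob/gap_len_mean and
# have geometric lengths with the given mean.
dropout_mask <- function(n, gap_prob, gap_len_mean) {
  miss <- logical(n)
  if (gap_prob <= 0) return(miss)
  p_start <- gap_prob / gap_len_mean
  starts <- which(stats::runif(n) < p_start)
  for (s in starts) {
    len <- 1L + stats::rgeom(1, 1 / gap_len_mean)
    miss[s:min(n, s + len - 1L)] <- TRUE
  }
  miss
}

#' Simulate one umbilical-occlusion experiment
#'
#' Generates paired 1 Hz FHR/FBP traces for one animal under a group
#' protocol: complete occlusions of `occlusion_length` seconds repeated
#' every `occlusion_spacing` seconds, for at most 4 hours or until the
#' latent minimum arterial pressure falls below 20 mmHg on two successive
#' occlusions. During each occlusion the FHR decelerates to a nadir whose
#' depth grows as the latent minimum FBP declines
#' (`base_decel_depth + coupling_depth * (baseline_fbp - min_fbp)` bpm);
#' the FBP dips to the latent minimum (holding a 20 s floor at the end of
#' the occlusion) and recovers between occlusions. Groups with 2-min
#' occlusions (N2-5) and the chronically hypoxic group (H1-5) show a
#' post-occlusion FHR overshoot scaled by the current latent FBP.
#'
#' @param group A `group_spec` (or group name).
#' @param params A `sheep_sim_params`.
#' @param first_occlusion_start Start of the first occlusion, seconds.
#' @param sheep_id Identifier stored on the trace.
#' @return An `experiment_trace` with `truth_min_fbp` filled in.
#' @export
simulate_sheep <- function(group, params = sheep_sim_params(),
                           first_occlusion_start = 60, sheep_id = NULL) {
  if (is.character(group)) group <- group_spec(group)
  stopifnot(inherits(group, "group_spec"),
            inherits(params, "sheep_sim_params"))
  if (is.null(sheep_id)) sheep_id <- paste0(group$name, "-01")

  set.seed(params$seed)
  spacing <- group$occlusion_spacing
  len <- group$occlusion_length
  m <- latent_min_fbp(params, spacing)
  K <- length(m)
  starts <- first_occlusion_start + (seq_len(K) - 1L) * spacing

  # Reject parameterisations whose deepest deceleration leaves [30, 250].
  max_depth <- params$base_decel_depth +
    params$coupling_depth * (params$baseline_fbp - min(m))
  if (params$baseline_fhr - max_depth < FHR_RANGE[1]) {
    stop("parameters drive FHR below 30 bpm (deepest nadir ",
         round(params$baseline_fhr - max_depth, 1), " bpm)")
  }
  if (params$baseline_fhr + params$overshoot_gain > FHR_RANGE[2]) {
    stop("parameters drive FHR above 250 bpm")
  }

  n <- starts[K] + 150 + 16   # room for the widest time-offset segment
  t <- seq_len(n) - 1         # 0-based seconds
  fhr <- rep(params$baseline_fhr, n)
  fbp <- rep(params$baseline_fbp, n)
  overshoot_on <- group$name %in% c("N2-5", "H1-5")

  for (k in seq_len(K)) {
    s <- starts[k]
    depth <- params$base_decel_depth +
      params$coupling_depth * (params$baseline_fbp - m[k])
    nadir <- params$baseline_fhr - depth
    # FHR: 20 s drop, nadir plateau for the occlusion, 20 s recovery
    for (dt in 0:min(len + 19, n - 1 - s)) {
      i <- s + dt + 1L
      fhr[i] <- if (dt < 20) {
        params$baseline_fhr - depth * dt / 20
      } else if (dt < len) {
        nadir
      } else {
        nadir + depth * (dt - len + 1) / 20
      }
    }
    if (overshoot_on) {
      amp <- params$overshoot_gain * m[k] / params$baseline_fbp
      dts <- (len + 20):min(len + 80, n - 1 - s)
      idx <- s + dts + 1L
      bump <- amp * exp(-((dts - len - 40)^2) / (2 * 12^2))
      fhr[idx] <- pmin(fhr[idx] + bump, FHR_RANGE[2])
    }
    # FBP: linear fall, 20 s floor at the latent minimum, 60 s recovery
    for (dt in 0:min(len + 59, n - 1 - s)) {
      i <- s + dt + 1L
      fbp[i] <- if (dt < len - 20) {
        params$baseline_fbp -
          (params$baseline_fbp - m[k]) * dt / (len - 20)
      } else if (dt < len) {
        m[k]
      } else {
        m[k] + (params$baseline_fbp - m[k]) * (dt - len + 1) / 60
      }
    }
  }

  if (params$fhr_noise_sd > 0) {
    fhr <- fhr + stats::rnorm(n, 0, params$fhr_noise_sd)
    fhr <- pmin(pmax(fhr, FHR_RANGE[1]), FHR_RANGE[2])
  }
  if (params$fbp_noise_sd > 0) {
    fbp <- fbp + stats::rnorm(n, 0, params$fbp_noise_sd)
  }
  fhr[dropout_mask(n, params$gap_prob, params$gap_len_mean)] <- NA
  fbp[dropout_mask(n, params$gap_prob, params$gap_len_mean)] <- NA

  experiment_trace(fhr, fbp, first_occlusion_start, group, sheep_id,
                   truth_min_fbp = m)
}

#' Simulate a cohort of occlusion experiments
#'
#' One trace per animal, with per-animal parameter jitter around
#' group-typical values drawn from a single seeded generator.
#'
#' @param groups Data.frame like [sheep_group_table()] (columns `name`,
#'   `n_sheep`); defaults to the four-group protocol table.
#' @param base_params `sheep_sim_params` template jittered per animal.
#' @param seed Integer seed for the whole cohort.
#' @param hypotension_rates Named group-typical decline rates, mmHg per
#'   occlusion (2-min occlusions deplete pressure faster).
#' @param baseline_fhr_sd,baseline_fbp_sd Between-animal SD of the
#'   baseline heart rate (bpm) and blood pressure (mmHg).
#' @return List of `experiment_trace`, `n_sheep` per group, unique ids.
#' @export
simulate_cohort <- function(groups = sheep_group_table(),
                            base_params = sheep_sim_params(),
                            seed = 1L,
                            hypotension_rates = c("N1-5" = 0.8,
                                                  "H1-5" = 0.9,
                                                  "N1-2.5" = 0.6,
                                                  "N2-5" = 1.8),
                            baseline_fhr_sd = 6, baseline_fbp_sd = 3) {
  stopifnot(all(groups$n_sheep >= 1))
  set.seed(seed)
  traces <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- group_spec(groups$name[gi])
    for (si in seq_len(groups$n_sheep[gi])) {
      p <- base_params
      p$baseline_fhr <- base_params$baseline_fhr +
        stats::rnorm(1, 0, baseline_fhr_sd)
      p$baseline_fbp <- min(max(
        base_params$baseline_fbp + stats::rnorm(1, 0, baseline_fbp_sd),
        35), 75)
      rate <- hypotension_rates[[g$name]]
      p$hypotension_rate <- max(rate * stats::runif(1, 0.8, 1.2), 0.05)
      p$coupling_depth <- max(
        base_params$coupling_depth * stats::runif(1, 0.9, 1.1), 0)
      p$seed <- sample.int(2^31 - 1, 1)
      id <- sprintf("%s-%02d", g$name, si)
      traces[[id]] <- simulate_sheep(g, p, sheep_id = id)
    }
  }
  traces
}

#' Irreducible error scale of a simulated cohort
#'
#' First-order lower bound on the mean absolute error achievable by any
#' leave-one-animal-out predictor of the labelled minimum FBP, summing the
#' generator's error sources that no model can remove:
#' the between-animal baseline-FBP offset, unidentifiable from a single
#' heart-rate segment (`E|N(0, baseline_fbp_sd)| = baseline_fbp_sd *
#' sqrt(2/pi)`); the FBP measurement noise entering the percentile label
#' (`fbp_noise_sd`); and the FHR sample noise mapped through the
#' depth-per-mmHg coupling (`fhr_noise_sd / coupling_depth`).
#'
#' @param params The cohort's base `sheep_sim_params`.
#' @param baseline_fbp_sd Between-animal baseline-FBP SD used by
#'   [simulate_cohort()], mmHg.
#' @return Noise floor, mmHg (MAE scale).
#' @export
generator_noise_floor <- function(params, baseline_fbp_sd = 3) {
  baseline_fbp_sd * sqrt(2 / pi) + params$fbp_noise_sd +
    params$fhr_noise_sd / max(params$coupling_depth, 1e-9)
}

#' Simulate a human-style CTG heart-rate trace
#'
#' FHR-only 1 Hz trace emulating the final stretch of an intrapartum CTG:
#' irregularly spaced decelerations of variable depth and duration (some
#' closer together than 150 s), a latent per-deceleration minimum FBP that
#' declines over the trace (progressive hypotension) and is lowered further
#' by a latent `severity` in [0, 1], which also sets the adverse-outcome
#' flag. Deceleration depth is coupled to the latent FBP with the same
#' convention as the sheep generator, so models trained on sheep segments
#' transfer.
#'
#' @param duration_s Trace length, seconds (default 90 min).
#' @param severity Latent compromise severity in [0, 1].
#' @param baseline_fhr Baseline heart rate, bpm.
#' @param fhr_noise_sd Gaussian sample noise, bpm.
#' @param gap_prob Expected missing fraction (contiguous runs).
#' @param mean_gap_s Mean onset-to-onset gap between decelerations, seconds.
#' @param seed Integer seed.
#' @return List with `fhr`, `decel_starts` (0-based seconds),
#'   `truth_min_fbp` per deceleration, `severity`, `outcome`
#'   (TRUE = severe), and `trace_id`.
#' @export
simulate_human_trace <- function(duration_s = 5400, severity = 0,
                                 baseline_fhr = 140, fhr_noise_sd = 2,
                                 gap_prob = 0.005, mean_gap_s = 180,
                                 seed = 1L, trace_id = "ctg-01") {
  stopifnot(severity >= 0, severity <= 1, duration_s > 0)
  set.seed(seed)
  n <- as.integer(duration_s)
  fhr <- rep(baseline_fhr, n)

  # irregular onsets; enforce a short refractory gap only
  onsets <- integer(0)
  t <- 30 + stats::rexp(1, 1 / mean_gap_s)
  while (t + 60 < n - 30) {
    onsets <- c(onsets, as.integer(round(t)))
    t <- t + max(45, stats::rexp(1, 1 / mean_gap_s))
  }
  J <- length(onsets)
  truth <- numeric(J)
  if (J) {
    for (j in seq_len(J)) {
      # latent minimum FBP: severity and within-trace progression lower it
      truth[j] <- 48 - 18 * severity - 10 * (j - 1) / max(J - 1, 1) +
        stats::rnorm(1, 0, 1.5)
      truth[j] <- max(truth[j], 12)
      depth <- 25 + 1.2 * (55 - truth[j])
      dur <- round(stats::runif(1, 40, 90))
      s <- onsets[j]
      for (dt in 0:min(dur + 14, n - 1 - s)) {
        i <- s + dt + 1L
        v <- if (dt < 15) {
          baseline_fhr - depth * dt / 15
        } else if (dt < dur) {
          baseline_fhr - depth
        } else {
          baseline_fhr - depth + depth * (dt - dur + 1) / 15
        }
        fhr[i] <- min(fhr[i], v)
      }
    }
  }
  if (fhr_noise_sd > 0) {
    fhr <- fhr + stats::rnorm(n, 0, fhr_noise_sd)
    fhr <- pmin(pmax(fhr, FHR_RANGE[1]), FHR_RANGE[2])
  }
  fhr[dropout_mask(n, gap_prob, 10)] <- NA

  list(fhr = fhr, decel_starts = onsets, truth_min_fbp = truth,
       severity = severity, outcome = severity >= 0.5, trace_id = trace_id)
}
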