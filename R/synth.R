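#' Extracellular amplitude-distance decay model
#'
#' Exponential decay `A(d) = A0 * exp(-d / lambda)` of peak-to-peak EAP
#' amplitude with distance from the nearest electrode, calibrated on two
#' anchor observations from paired recordings: 38 uV at 50 um and 5 uV at
#' 150 um (so lambda = 100 / ln(38/5) ~ 49.3 um and A0 ~ 104.8 uV).  The
#' functional form is a modelling choice of the generator, not an empirical
#' fit; only the two anchors are observational.
#'
#' @param d_um distance(s) from the nearest electrode site, micrometres.
#' @return peak-to-peak amplitude scale in microvolts.
#' @examples
#' amplitude_at_distance(50)   # 38
#' amplitude_at_distance(150)  # 5
#' @export
amplitude_at_distance <- function(d_um) {
  stopifnot(all(d_um >= 0))
  lambda <- 100 / log(38 / 5)
  a0 <- 38 * exp(50 / lambda)
  a0 * exp(-d_um / lambda)
}

#' Decay constant of the amplitude-distance model (micrometres)
#' @export
amplitude_decay_lambda <- function() 100 / log(38 / 5)

#' Spike waveform templates
#'
#' Continuous-time spike templates built from Gaussian lobes, peak-to-peak
#' normalized to 1, with near-zero mean outside the spike core.  Juxtacellular
#' (cell-attached) spikes are biphasic positive-before-negative; extracellular
#' somatic spikes are negative-before-positive; `triphasic` adds a small late
#' positive lobe.
#'
#' @param shape `biphasic` or `triphasic`.
#' @param duration_ms template support, ms (>= 1).
#' @param rate_hz sampling rate for the discrete samples.
#' @param polarity `positive-first` or `negative-first`.
#' @return object of class `spike_template`: `fun(t_s)` (continuous evaluator,
#'   t in seconds relative to the template start), `samples` (discrete
#'   waveform), `peak_offset_s` (time of the alignment peak from template
#'   start), `duration_s`.
#' @export
make_template <- function(shape = c("biphasic", "triphasic"), duration_ms = 2,
                          rate_hz = 30000,
                          polarity = c("positive-first", "negative-first")) {
  shape <- match.arg(shape)
  polarity <- match.arg(polarity)
  if (duration_ms < 1) stop("template duration must be >= 1 ms")
  dur <- duration_ms / 1000
  s1 <- dur / 14; s2 <- dur / 9       # first lobe sharper than second
  t1 <- dur * 0.35; t2 <- dur * 0.52
  lobes <- function(t) {
    w <- exp(-(t - t1)^2 / (2 * s1^2)) - 0.75 * exp(-(t - t2)^2 / (2 * s2^2))
    if (shape == "triphasic")
      w <- w + 0.18 * exp(-(t - dur * 0.72)^2 / (2 * (dur / 7)^2))
    w
  }
  tt <- seq(0, dur, length.out = 4096)
  v <- lobes(tt)
  p2p <- max(v) - min(v)
  sgn <- if (polarity == "positive-first") 1 else -1
  fun <- function(t_s) {
    out <- numeric(length(t_s))
    inside <- t_s >= 0 & t_s <= dur
    out[inside] <- sgn * lobes(t_s[inside]) / p2p
    out
  }
  vv <- sgn * v / p2p
  peak_idx <- if (polarity == "positive-first") which.max(vv) else which.min(vv)
  n <- round(dur * rate_hz)
  structure(list(fun = fun,
                 samples = fun(seq(0, by = 1 / rate_hz, length.out = n)),
                 peak_offset_s = tt[peak_idx],
                 duration_s = dur, shape = shape, polarity = polarity),
            class = "spike_template")
}

#' Neuron specification for the synthetic scene
#'
#' @param position_um length-3 position (x lateral, y perpendicular distance
#'   from the probe plane, z axial), micrometres; the probe sites lie in the
#'   y = 0 plane.
#' @param rate_hz mean firing rate, Hz.
#' @param p2p_scale_uv peak-to-peak amplitude the neuron would have at
#'   distance 0; per-site amplitudes follow
#'   `p2p_scale_uv / amplitude_at_distance(0) * amplitude_at_distance(d_site)`.
#'   Default `amplitude_at_distance(0)`, i.e. the decay model verbatim.
#' @param shape template shape.
#' @param duration_ms template duration.
#' @param velocity_m_s axial propagation speed of the negative peak (sign =
#'   direction of increasing axial coordinate).
#' @param is_juxta_target whether this neuron is the one on the juxtacellular
#'   pipette (at most one per scene).
#' @return object of class `neuron_spec`.
#' @export
neuron_spec <- function(position_um, rate_hz = 1,
                        p2p_scale_uv = amplitude_at_distance(0),
                        shape = "biphasic", duration_ms = 2,
                        velocity_m_s = 0.55, is_juxta_target = FALSE) {
  stopifnot(rate_hz >= 0, length(position_um) == 3)
  structure(list(position_um = as.numeric(position_um), rate_hz = rate_hz,
                 p2p_scale_uv = p2p_scale_uv, shape = shape,
                 duration_ms = duration_ms, velocity_m_s = velocity_m_s,
                 is_juxta_target = is_juxta_target),
            class = "neuron_spec")
}

#' Synthetic paired-recording scene configuration
#'
#' Defaults emulate the reference recording conditions: 30 kHz sampling,
#' ~4 mV peak-to-peak biphasic juxtacellular spikes at ~1 Hz with a 1-ms
#' refractory period, extracellular EAP amplitudes following the
#' [amplitude_at_distance()] decay, white Gaussian extracellular noise of
#' 6 uV SD, Poisson background units, and an optional all-channel cross-talk
#' artifact below 5 uV.
#'
#' @param geometry a [probe_geometry()].
#' @param duration_s scene duration, seconds.
#' @param rate_hz sampling rate (default 30000).
#' @param noise_sd_uv extracellular white-noise SD, microvolts.
#' @param juxta_noise_sd_mv juxtacellular noise SD, millivolts.
#' @param juxta_p2p_mv juxtacellular spike peak-to-peak amplitude, mV.
#' @param neurons list of [neuron_spec()]s; at most one `is_juxta_target`.
#' @param background_count number of additional background neurons placed
#'   uniformly in a 200-um slab in front of the probe with rates 0.5-5 Hz.
#' @param crosstalk_uv peak-to-peak amplitude of the common-mode cross-talk
#'   artifact added to every channel at target spike times; 0 disables; must
#'   stay below the 5-uV artifact floor.
#' @param seed integer master seed; all randomness flows from it through
#'   named substreams (placement, spikes, noise).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(geometry, duration_s = 10, rate_hz = 30000,
                         noise_sd_uv = 6, juxta_noise_sd_mv = 0.05,
                         juxta_p2p_mv = 4, neurons = list(),
                         background_count = 0, crosstalk_uv = 0, seed = 1L) {
  stopifnot(inherits(geometry, "probe_geometry"), duration_s > 0,
            noise_sd_uv >= 0)
  if (crosstalk_uv < 0 || crosstalk_uv >= 5)
    stop("crosstalk_uv must be in [0, 5): the artifact is below the 5-uV floor")
  if (sum(vapply(neurons, `[[`, FALSE, "is_juxta_target")) > 1)
    stop("at most one juxtacellular target neuron per scene")
  structure(list(geometry = geometry, duration_s = duration_s,
                 rate_hz = rate_hz, noise_sd_uv = noise_sd_uv,
                 juxta_noise_sd_mv = juxta_noise_sd_mv,
                 juxta_p2p_mv = juxta_p2p_mv, neurons = neurons,
                 background_count = background_count,
                 crosstalk_uv = crosstalk_uv, seed = as.integer(seed)),
            class = "synth_config")
}

# substream seed derivation, kept below 2^31
.sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Poisson spike times (seconds) with absolute refractory period.
.poisson_train <- function(rate_hz, duration_s, refractory_s = 0.001) {
  if (rate_hz <= 0) return(numeric(0))
  n_guess <- max(10, ceiling(rate_hz * duration_s * 2 + 20))
  gaps <- stats::rexp(n_guess, rate_hz) + refractory_s
  t <- cumsum(gaps)
  while (length(t) && t[length(t)] < duration_s) {
    gaps <- stats::rexp(n_guess, rate_hz) + refractory_s
    t <- c(t, t[length(t)] + cumsum(gaps))
  }
  t[t < duration_s - 0.005 & t > 0.005]   # keep clear of the edges
}

#' Generate a synthetic paired recording with known ground truth
#'
#' Assembles the scene described by a [synth_config()]: seeded Poisson spike
#' trains per neuron (1-ms refractory); an extracellular trace that sums each
#' neuron's template scaled per site by the amplitude-distance decay, with a
#' per-site propagation delay `(z_site - z_soma) / velocity`, plus white
#' Gaussian noise and the optional common-mode cross-talk artifact; and a
#' juxtacellular trace carrying the target neuron's spikes at ~4 mV
#' peak-to-peak.  Bit-reproducible given the config seed.
#'
#' @param config a [synth_config()].
#' @return object of class `ground_truth_bundle`: `extracellular`
#'   (channels x time matrix, microvolts), `juxta` (numeric vector, mV),
#'   `true_spikes` (list of [spike_train()] per neuron, sample indices of the
#'   juxtacellular alignment peak), `neurons`, `metadata` (pair_table row with
#'   the true tip-to-nearest-site distance), `rate_hz`, `geometry`.
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  geom <- config$geometry
  nch <- length(geom$site_ids)
  nt <- round(config$duration_s * config$rate_hz)
  neurons <- config$neurons

  # background placement substream
  if (config$background_count > 0) {
    bg <- .with_seed(.sub_seed(config$seed, "placement"), {
      lapply(seq_len(config$background_count), function(i) {
        pos <- c(stats::runif(1, min(geom$site_xz_um[, 1]) - 50,
                              max(geom$site_xz_um[, 1]) + 50),
                 stats::runif(1, 10, 200),
                 stats::runif(1, min(geom$site_xz_um[, 2]) - 50,
                              max(geom$site_xz_um[, 2]) + 50))
        neuron_spec(pos, rate_hz = stats::runif(1, 0.5, 5))
      })
    })
    neurons <- c(neurons, bg)
  }
  if (!length(neurons)) stop("scene has no neurons")

  # spike-time substreams
  trains_s <- lapply(seq_along(neurons), function(i)
    .with_seed(.sub_seed(config$seed, paste0("spikes", i)),
               .poisson_train(neurons[[i]]$rate_hz, config$duration_s)))

  extra <- matrix(0, nch, nt)
  sample_t <- NULL  # site waveforms are added sparsely, window by window
  for (i in seq_along(neurons)) {
    nrn <- neurons[[i]]
    if (!length(trains_s[[i]])) next
    tmpl <- make_template(nrn$shape, nrn$duration_ms, config$rate_hz,
                          polarity = "negative-first")
    d_site <- sqrt(colSums((t(cbind(geom$site_xz_um[, 1], 0,
                                    geom$site_xz_um[, 2])) - nrn$position_um)^2))
    amp <- nrn$p2p_scale_uv / amplitude_at_distance(0) * amplitude_at_distance(d_site)
    delay_s <- if (is.finite(nrn$velocity_m_s) && nrn$velocity_m_s != 0)
      (geom$site_xz_um[, 2] - nrn$position_um[3]) * 1e-6 / nrn$velocity_m_s
      else rep(0, nch)
    wlen <- ceiling((tmpl$duration_s + max(abs(delay_s))) * config$rate_hz) + 2
    for (ts in trains_s[[i]]) {
      # ts is the time of the neuron's alignment peak; template starts earlier
      start_s <- ts - tmpl$peak_offset_s
      i0 <- floor(start_s * config$rate_hz)
      idx <- i0:(i0 + wlen)
      keep <- idx >= 0 & idx < nt
      if (!any(keep)) next
      tgrid <- idx[keep] / config$rate_hz
      for (ch in seq_len(nch)) {
        if (amp[ch] < 1e-3) next
        extra[ch, idx[keep] + 1] <- extra[ch, idx[keep] + 1] +
          amp[ch] * tmpl$fun(tgrid - start_s - delay_s[ch])
      }
    }
  }

  # noise substream
  extra <- extra + .with_seed(.sub_seed(config$seed, "noise"),
                              matrix(stats::rnorm(nch * nt, 0, config$noise_sd_uv),
                                     nch, nt))

  target_i <- which(vapply(neurons, `[[`, FALSE, "is_juxta_target"))
  juxta <- numeric(nt)
  jt_tmpl <- make_template("biphasic", 2, config$rate_hz, "positive-first")
  if (length(target_i)) {
    tgt_times <- trains_s[[target_i]]
    for (ts in tgt_times) {
      start_s <- ts - jt_tmpl$peak_offset_s
      i0 <- floor(start_s * config$rate_hz)
      idx <- i0:(i0 + length(jt_tmpl$samples) + 1)
      keep <- idx >= 0 & idx < nt
      tgrid <- idx[keep] / config$rate_hz
      juxta[idx[keep] + 1] <- juxta[idx[keep] + 1] +
        config$juxta_p2p_mv * jt_tmpl$fun(tgrid - start_s)
      if (config$crosstalk_uv > 0)
        extra[, idx[keep] + 1] <- extra[, idx[keep] + 1] +
          rep(config$crosstalk_uv * jt_tmpl$fun(tgrid - start_s),
              each = nch)
    }
  }
  juxta <- juxta + .with_seed(.sub_seed(config$seed, "juxta_noise"),
                              stats::rnorm(nt, 0, config$juxta_noise_sd_mv))

  true_spikes <- lapply(trains_s, function(ts)
    spike_train(round(ts * config$rate_hz) + 1, config$rate_hz))
  dist_um <- if (length(target_i)) {
    pos <- neurons[[target_i]]$position_um
    min(sqrt((geom$site_xz_um[, 1] - pos[1])^2 + pos[2]^2 +
             (geom$site_xz_um[, 2] - pos[3])^2))
  } else NA_real_
  md <- pair_metadata(pair_id = sprintf("synthetic_seed%d", config$seed),
                      distance_um = if (is.na(dist_um)) 0 else dist_um,
                      juxta_threshold = config$juxta_p2p_mv / 4,
                      notes = "synthetic")
  structure(list(extracellular = extra, juxta = juxta,
                 true_spikes = true_spikes, neurons = neurons,
                 target_index = if (length(target_i)) target_i else NA_integer_,
                 metadata = md, rate_hz = config$rate_hz, geometry = geom,
                 config = config),
            class = "ground_truth_bundle")
}

#' @export
print.ground_truth_bundle <- function(x, ...) {
  cat(sprintf("Synthetic pair '%s': %d ch x %.3g s, %d neurons, target distance %.1f um\n",
              x$metadata$pair_id, nrow(x$extracellular),
              ncol(x$extracellular) / x$rate_hz, length(x$neurons),
              x$metadata$distance_um))
  invisible(x)
}

#' Random small misalignment map for calibration scenes
#'
#' Composition of small rotations about each axis (magnitudes between
#' `min_rot_deg` and `max_rot_deg`, random sign), per-axis scale errors
#' (within `scale_tol`) and a zeroing offset (up to `max_offset_um` per
#' axis).  The defaults are calibrated so raw (pre-correction) distance
#' errors over a 5-mm working volume concentrate in the tens of micrometres,
#' the scale observed when two mechanically aligned manipulators are
#' compared; a perfectly aligned draw is excluded because mechanical
#' alignment never is.
#'
#' @param seed integer seed.
#' @param min_rot_deg,max_rot_deg,scale_tol,max_offset_um misalignment
#'   magnitudes.
#' @return an `affine_correction`-shaped truth object (linear + offset).
#' @export
random_misalignment <- function(seed, min_rot_deg = 0.25, max_rot_deg = 0.75,
                                scale_tol = 0.01, max_offset_um = 50) {
  .with_seed(.sub_seed(seed, "misalign"), {
    ang <- stats::runif(3, min_rot_deg, max_rot_deg) *
      sample(c(-1, 1), 3, replace = TRUE) * pi / 180
    rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                   0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
    ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                   -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
    rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                   0, 0, 1), 3, byrow = TRUE)
    sc <- diag(1 + stats::runif(3, -scale_tol, scale_tol))
    structure(list(linear = rx %*% ry %*% rz %*% sc,
                   offset = stats::runif(3, -max_offset_um, max_offset_um),
                   fit_residual_mean = NA_real_, fit_residual_sd = NA_real_,
                   n_pairs = 0L),
              class = "affine_correction")
  })
}

#' Generate a synthetic calibration scene
#'
#' Reference positions are a seeded subsample of the calibration lattice;
#' the tilted manipulator's readings are the inverse-mapped reference
#' positions (through the inverse misalignment, then the tilt transform)
#' plus per-axis Gaussian measurement noise.  Fitting
#' [fit_affine_correction()] to the returned pairs should recover
#' `true_affine` up to noise.
#'
#' @param true_affine the misalignment truth (e.g. [random_misalignment()]):
#'   `reference = linear %*% tilt(moving_true) + offset`.
#' @param n_points number of calibration points (>= 4; reference setup used
#'   15).
#' @param noise_sd_um per-axis Gaussian measurement noise, micrometres.
#' @param seed integer seed.
#' @param theta_deg manipulator tilt (default 48.2).
#' @param extent_um,step_um lattice parameters (default 5,000-um cube in
#'   1,000-um steps).
#' @return list of [calibration_pair()] objects.
#' @export
generate_calibration_scene <- function(true_affine, n_points = 15,
                                       noise_sd_um = 3, seed = 1L,
                                       theta_deg = DEFAULT_THETA_DEG,
                                       extent_um = c(5000, 5000, 5000),
                                       step_um = 1000) {
  stopifnot(inherits(true_affine, "affine_correction"), n_points >= 4)
  if (abs(det(true_affine$linear)) < 1e-12)
    stop("degenerate true_affine: singular linear map")
  ref <- calibration_grid(extent_um, step_um, n_points,
                          seed = .sub_seed(seed, "grid"))
  ainv <- solve(true_affine$linear)
  tm <- tilt_matrix(theta_deg)   # involution: also the inverse tilt
  noise <- .with_seed(.sub_seed(seed, "calnoise"),
                      matrix(stats::rnorm(3 * n_points, 0, noise_sd_um),
                             n_points, 3))
  lapply(seq_len(n_points), function(i) {
    p_ref_frame <- ainv %*% (ref[i, ] - true_affine$offset)
    native <- as.numeric(tm %*% p_ref_frame) + noise[i, ]
    calibration_pair(ref[i, ], manipulator_reading(native[1], native[2],
                                                   native[3], theta_deg))
  })
}

#' Write a ground-truth bundle to disk in the package's exchange formats
#'
#' Raw int16 binary for the extracellular data (microvolts divided by the
#' scale, rounded), a single-channel raw binary for the juxtacellular trace
#' (mV / 1e-3 scale), CSVs of ground-truth spike times per neuron, the pair
#' metadata table, and the probe geometry.
#'
#' @param bundle a `ground_truth_bundle`.
#' @param dir output directory (created if missing).
#' @param scale_uv_per_bit quantization step for the extracellular binary.
#' @return invisibly, the list of written paths.
#' @export
write_bundle <- function(bundle, dir, scale_uv_per_bit = 0.195) {
  stopifnot(inherits(bundle, "ground_truth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  q <- pmin(pmax(round(bundle$extracellular / scale_uv_per_bit), -32768), 32767)
  write_raw(raw_recording(q, scale_uv_per_bit, bundle$rate_hz), p("extracellular.bin"))
  jq <- pmin(pmax(round(bundle$juxta / 0.001), -32768), 32767)
  write_raw(raw_recording(matrix(jq, 1), 0.001, bundle$rate_hz), p("juxta.bin"))
  st <- do.call(rbind, lapply(seq_along(bundle$true_spikes), function(i)
    if (length(bundle$true_spikes[[i]]$times))
      data.frame(neuron = i, peak_sample = bundle$true_spikes[[i]]$times,
                 is_target = identical(i, as.integer(bundle$target_index)))))
  utils::write.csv(st, p("true_spikes.csv"), row.names = FALSE)
  write_pair_table(bundle$metadata, p("pair_metadata.csv"))
  write_probe_csv(bundle$geometry, p("probe.csv"))
  invisible(list(extracellular = p("extracellular.bin"), juxta = p("juxta.bin"),
                 true_spikes = p("true_spikes.csv"),
                 metadata = p("pair_metadata.csv"), probe = p("probe.csv")))
}
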