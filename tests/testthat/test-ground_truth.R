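rate <- 30000

test_that("juxtacellular spike detection finds injected peaks and enforces isolation", {
  expect_equal(length(detect_juxta_spikes(rep(0, 1000), 1, rate)$times), 0)
  expect_error(detect_juxta_spikes(numeric(0), 1, rate), "empty")

  tmpl <- make_template("biphasic", 2, rate, "positive-first")
  set.seed(4)
  n <- 5 * rate
  trace <- rnorm(n, sd = 0.05)
  true_pk <- sort(round(seq(0.2, 4.6, length.out = 10) * rate))
  for (pk in true_pk) {
    i0 <- pk - round(tmpl$peak_offset_s * rate)
    idx <- seq_along(tmpl$samples) + i0 - 1
    trace[idx] <- trace[idx] + 4 * tmpl$samples
  }
  st <- detect_juxta_spikes(trace, 1, rate)
  expect_equal(length(st$times), 10)
  expect_true(all(abs(st$times - true_pk) <= 1))

  # two crossings 0.5 ms apart with 1-ms isolation: both rejected
  x <- rep(0, 3000)
  x[1000] <- 2; x[1015] <- 2
  expect_equal(length(detect_juxta_spikes(x, 1, rate, isolation_ms = 1)$times), 0)
  expect_equal(length(detect_juxta_spikes(x, 1, rate, isolation_ms = 0.4)$times), 2)

  # negative-first polarity aligns to the minimum
  xn <- rep(0, 3000); xn[500] <- -3
  stn <- detect_juxta_spikes(xn, 1, rate, polarity = "negative-first")
  expect_equal(stn$times, 500)
})

test_that("JTA equals an injected template at zero noise and converges as sigma over sqrt(n)", {
  nch <- 4
  tmpl <- sin(2 * pi * seq(0, 1, length.out = 61))  # 2 ms at 30 kHz
  gains <- c(1, 0.5, 2, 0.1)
  n_ev <- 200
  set.seed(21)
  times <- sort(sample(200:(200000 - 200), n_ev))
  times <- times[c(diff(times) > 130, TRUE)]
  clean <- matrix(0, nch, 200000)
  for (tt in times)
    clean[, (tt - 30):(tt + 30)] <- clean[, (tt - 30):(tt + 30)] +
      outer(gains, tmpl)
  st <- spike_train(times, rate)
  jta0 <- compute_jta(clean, st)
  pad0 <- matrix(0, nch, 30)   # template spans the middle 61 of 121 samples
  expected <- cbind(pad0, outer(gains, tmpl), pad0)
  expect_equal(jta0$waveforms, expected, tolerance = 1e-12)
  expect_equal(jta0$n_events, length(times))

  # single event: JTA is that window verbatim
  one <- compute_jta(clean, spike_train(times[1], rate))
  expect_equal(one$waveforms, clean[, (times[1] - 60):(times[1] + 60)])

  # edge-clipped events are excluded and counted
  st_edge <- spike_train(c(10, times), rate)
  jta_e <- compute_jta(clean, st_edge)
  expect_equal(jta_e$n_excluded, 1)
  expect_equal(jta_e$n_events, length(times))

  # noise: RMS(JTA - template) <= 1.5 sigma / sqrt(n) over 20 seeds
  sigma <- 5
  ok <- sapply(1:20, function(s) {
    set.seed(s)
    noisy <- clean + matrix(rnorm(length(clean), sd = sigma), nch)
    j <- compute_jta(noisy, st)
    err <- j$waveforms - expected
    sqrt(mean(err^2)) <= 1.5 * sigma / sqrt(length(times))
  })
  expect_true(all(ok))
})

test_that("JTA of signal plus noise converges to the signal JTA as n grows", {
  tmpl <- sin(2 * pi * seq(0, 1, length.out = 61))
  times <- seq(500, by = 400, length.out = 400)
  clean <- matrix(0, 2, 200000)
  for (tt in times)
    clean[, (tt - 30):(tt + 30)] <- clean[, (tt - 30):(tt + 30)] + rbind(tmpl, tmpl)
  set.seed(99)
  noisy <- clean + matrix(rnorm(length(clean), sd = 8), 2)
  expected <- cbind(matrix(0, 2, 30), rbind(tmpl, tmpl), matrix(0, 2, 30))
  errs <- sapply(c(10, 100, 400), function(n) {
    j <- compute_jta(noisy, spike_train(times[1:n], rate))
    sqrt(mean((j$waveforms - expected)^2))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("peak-to-peak footprint windows, offsets and scaling behave", {
  w <- matrix(0, 2, 121)   # +/- 2 ms JTA
  jta <- structure(list(waveforms = w, t_ms = seq(-60, 60) / 30,
                        n_events = 1, n_excluded = 0, rate_hz = rate,
                        window_ms = 2, p2p_uv = NULL), class = "jta_result")
  expect_equal(p2p_footprint(jta), c(0, 0))

  # one sine cycle of amplitude a inside the +/-1 ms window -> 2a
  a <- 7
  jta$waveforms[1, 31:91] <- a * sin(2 * pi * seq(0, 1, length.out = 61))
  expect_equal(p2p_footprint(jta)[1], 2 * a, tolerance = 1e-6)

  # a deeper trough at +1.5 ms is outside the +/-1 ms core
  jta$waveforms[2, 31:91] <- 3 * sin(2 * pi * seq(0, 1, length.out = 61))
  jta$waveforms[2, 106] <- -20
  expect_equal(p2p_footprint(jta, 1)[2], 6, tolerance = 1e-6)
  expect_gt(p2p_footprint(jta, 2)[2], 20)

  # invariance to constant offset, linear in scale
  jta2 <- jta
  jta2$waveforms <- 3 * jta$waveforms + 11
  expect_equal(p2p_footprint(jta2), 3 * p2p_footprint(jta), tolerance = 1e-9)
  expect_error(p2p_footprint(jta, 5), "exceeds")
})

test_that("footprint interpolation is exact at sites and has linear precision", {
  g <- make_probe_32ch_poly3()
  uni <- interpolate_footprint(rep(4, 32), g, resolution_um = 5)
  expect_equal(range(uni$values, na.rm = TRUE), c(4, 4), tolerance = 1e-9)

  # linear field in the shank plane reproduced exactly
  field <- function(p) 2 + 0.03 * p[, 1] + 0.05 * p[, 2]
  amps <- field(g$site_xz_um)
  fp <- interpolate_footprint(amps, g, resolution_um = 5)
  grid <- as.matrix(expand.grid(fp$x_um, fp$z_um))
  want <- field(grid)
  got <- as.numeric(fp$values)
  inside <- !is.na(got)
  expect_gt(mean(inside), 0.8)
  expect_lt(max(abs(got[inside] - want[inside]) / abs(want[inside])), 1e-6)

  # exact at the site positions themselves
  at_sites <- footprint_at(fp, g$site_xz_um)
  expect_equal(at_sites, amps, tolerance = 1e-6)

  collinear <- probe_geometry(1:4, cbind(0, c(0, 25, 50, 75)), 177)
  expect_error(interpolate_footprint(rep(1, 4), collinear, 5), "collinear")
  expect_error(interpolate_footprint(rep(1, 3), g, 5), "one amplitude per site")
})

test_that("amplitude-distance curve flags sub-5-uV pairs and decays on the synthetic cohort", {
  co <- synth_cohort()
  curve <- amplitude_distance_curve(lapply(co, function(x) x[c("metadata", "jta")]))
  expect_equal(nrow(curve), 20)
  expect_true(!is.unsorted(curve$distance_um))
  # below the artifact floor -> flagged
  expect_true(all(curve$artifact_flagged[curve$max_p2p_uv < 5]))
  expect_false(any(curve$artifact_flagged[curve$max_p2p_uv >= 5]))
  # distance is the dominant factor: strong negative rank correlation
  expect_lt(cor(curve$distance_um, curve$max_p2p_uv, method = "spearman"), -0.8)
  # near neuron beats every neuron beyond 150 um
  near <- curve$max_p2p_uv[which.min(abs(curve$distance_um - 48))]
  expect_true(all(near > curve$max_p2p_uv[curve$distance_um > 150]))
})

test_that("fitted decay constant on the cohort is close to the generator's lambda", {
  co <- synth_cohort()
  curve <- amplitude_distance_curve(lapply(co, function(x) x[c("metadata", "jta")]))
  # exponential decay plus an additive floor: the max-over-channels p2p of an
  # averaged recording never falls below the JTA noise level
  fit <- nls(max_p2p_uv ~ A * exp(-distance_um / lambda) + floor_uv,
             data = curve, start = list(A = 100, lambda = 60, floor_uv = 2))
  expect_equal(coef(fit)[["lambda"]], amplitude_decay_lambda(), tolerance = 0.15)
  expect_equal(coef(fit)[["A"]], amplitude_at_distance(0), tolerance = 0.15)
})

test_that("JTA max p2p matches the generator's programmed site amplitude", {
  co <- synth_cohort()
  for (x in co[c(2, 6, 10)]) {   # points where signal clears the noise floor
    programmed <- amplitude_at_distance(x$true_distance)
    se <- 6 / sqrt(x$jta$n_events)        # scene noise sd over sqrt(n)
    expect_lt(abs(max(x$jta$p2p_uv) - programmed), max(3 * 2 * se, 0.15 * programmed))
  }
})

test_that("propagation velocity: worked example, antisymmetry, errors", {
  # two noise-free waveforms, negative peaks 0.5 ms apart, sites 275 um apart
  g <- make_probe_32ch_poly3()
  t_ms <- seq(-60, 60) / 30
  wf <- matrix(0, 32, 121)
  # truncated downward parabola: 3-point parabolic peak refinement is exact
  shape <- function(t0) {
    d <- (t_ms - t0) / 0.3
    ifelse(abs(d) < 1, -(1 - d^2), 0)
  }
  wf[1, ] <- shape(-0.25)    # site 1: axial 0
  wf[12, ] <- shape(0.25)    # site 12: axial 275
  jta <- structure(list(waveforms = wf, t_ms = t_ms, n_events = 1,
                        n_excluded = 0, rate_hz = rate, window_ms = 2,
                        p2p_uv = NULL), class = "jta_result")
  v <- propagation_velocity(jta, 1, 12, g)
  expect_equal(v, 0.55, tolerance = 1e-6)
  expect_equal(propagation_velocity(jta, 12, 1, g), -v, tolerance = 1e-9)

  wf[12, ] <- wf[1, ]
  jta$waveforms <- wf
  expect_error(propagation_velocity(jta, 1, 12, g), "zero delay")
  wf[12, ] <- abs(wf[12, ])
  jta$waveforms <- wf
  expect_error(propagation_velocity(jta, 1, 12, g), "no negative peak")
})

test_that("velocity recovered from a propagating synthetic neuron beats sample quantization", {
  g <- mini_probe()
  cfg <- synth_config(g, duration_s = 4, noise_sd_uv = 0, juxta_noise_sd_mv = 0,
                      neurons = list(neuron_spec(c(11, 20, 60), rate_hz = 3,
                                                 velocity_m_s = 0.67,
                                                 is_juxta_target = TRUE)),
                      seed = 12)
  b <- generate_pair(cfg)
  jta <- compute_jta(b$extracellular, b$true_spikes[[1]])
  v <- propagation_velocity(jta, 1, 11, g)   # sites (0,0) and (0,112.5)
  d_um <- 112.5
  true_delay_ms <- d_um * 1e-3 / 0.67
  one_sample_ms <- 1000 / rate
  v_lo <- d_um * 1e-3 / (true_delay_ms + one_sample_ms)
  v_hi <- d_um * 1e-3 / (true_delay_ms - one_sample_ms)
  expect_gte(v, v_lo)
  expect_lte(v, v_hi)
})
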