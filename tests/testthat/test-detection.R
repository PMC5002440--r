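rate <- 30000

# 4-channel line probe, 25-um spacing, neighbours = adjacent sites only
line_probe <- function(nch = 4) {
  probe_geometry(seq_len(nch), cbind(0, (seq_len(nch) - 1) * 25), 177,
                 adjacency_radius_um = 30, name = "line")
}

test_that("flood-fill finds a constructed multi-channel spike and obeys thresholds", {
  g <- line_probe(4)
  set.seed(5)
  sigma_true <- 5
  x <- matrix(rnorm(4 * 6000, sd = sigma_true), 4)
  sig <- apply(x, 1, sd)
  # spike: 6 sigma on channel 2, 2.5 sigma on its neighbours 1 and 3
  depth <- c(2.5, 6, 2.5, 0) * sig
  for (ch in 1:3) x[ch, 2998:3002] <- x[ch, 2998:3002] - depth[ch] * c(0.4, 0.8, 1, 0.8, 0.4)
  ev <- detect_floodfill(x, detection_params(), g, sigma = sig, rate_hz = rate)
  hit <- ev[abs(ev$peak_time - 3000) <= 3, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$peak_channel, 2)
  expect_equal(hit$n_channels, 3)
  expect_setequal(hit$channels[[1]], 1:3)

  # an isolated 3-sigma dip (above weak, below strong) yields no event
  y <- matrix(rnorm(4 * 6000, sd = sigma_true), 4)
  sigy <- apply(y, 1, sd)
  y[2, 3000] <- -3 * sigy[2]
  evy <- detect_floodfill(y, detection_params(), g, sigma = sigy, rate_hz = rate)
  expect_false(any(abs(evy$peak_time - 3000) <= 2))

  # flat channel errors by name
  y[3, ] <- 0
  expect_error(detect_floodfill(y, detection_params(), g, rate_hz = rate),
               "sigma = 0.*site 3")
})

test_that("flood-fill equals the brute-force connected-component oracle", {
  for (s in 1:6) {
    set.seed(s)
    nch <- sample(3:8, 1)
    g <- line_probe(nch)
    x <- matrix(rnorm(nch * 2000, sd = 4), nch)
    # sprinkle a few strong multi-channel deflections
    for (k in 1:5) {
      t0 <- sample(50:1950, 1); c0 <- sample(seq_len(nch), 1)
      span <- max(1, c0 - 1):min(nch, c0 + 1)
      x[span, t0:(t0 + 2)] <- x[span, t0:(t0 + 2)] - sample(c(10, 30), 1)
    }
    sig <- apply(x, 1, sd)
    oracle <- brute_floodfill(x, 4.5, 2, g, sig)
    ev <- detect_floodfill(x, detection_params(min_separation_ms = 0), g,
                           sigma = sig, rate_hz = rate)
    expect_equal(nrow(ev), length(oracle))
    if (length(oracle)) {
      # same events: compare peak times and channel sets
      opk <- vapply(oracle, function(m) {
        defl <- -x
        v <- defl[m]
        m[which.max(v), 2]
      }, 0)
      expect_setequal(ev$peak_time, opk)
      ochans <- lapply(oracle, function(m) sort(unique(m[, 1])))
      for (i in seq_len(nrow(ev))) {
        j <- which(opk == ev$peak_time[i])[1]
        expect_equal(ev$channels[[i]], ochans[[j]])
      }
    }
  }
})

test_that("noise-only data yields few events, none spanning 3+ channels", {
  g <- line_probe(6)
  set.seed(77)
  x <- matrix(rnorm(6 * 60000, sd = 8), 6)
  ev <- detect_floodfill(x, detection_params(), g, rate_hz = rate)
  # every event needs a strong (4.5 sigma) sample; bound by the expected
  # number of supra-threshold samples plus 4 Poisson SDs
  expected_strong <- 6 * 60000 * pnorm(-4.5)
  expect_lte(nrow(ev), expected_strong + 4 * sqrt(expected_strong) + 1)
  expect_true(all(ev$n_channels < 3))
})

test_that("raising the strong threshold never increases the event count", {
  g <- line_probe(5)
  set.seed(13)
  x <- matrix(rnorm(5 * 30000, sd = 6), 5)
  for (k in 1:20) {
    t0 <- sample(100:29900, 1); c0 <- sample(1:5, 1)
    x[c0, t0:(t0 + 3)] <- x[c0, t0:(t0 + 3)] - runif(1, 10, 45)
  }
  sig <- apply(x, 1, sd)
  counts <- sapply(c(3, 4, 4.5, 5.5, 7), function(th)
    nrow(detect_floodfill(x, detection_params(strong_sd = th), g,
                          sigma = sig, rate_hz = rate)))
  expect_true(all(diff(counts) <= 0))
})

test_that("PETH bins are centred on 0 ms and conserve counts", {
  ref <- spike_train(seq(3000, 270000, by = 3000), rate)
  p <- compute_peth(ref$times, ref)
  expect_equal(p$zero_bin_count, length(ref$times))
  expect_equal(sum(p$counts), length(ref$times))
  expect_true(0 %in% p$bin_centers_ms)

  shifted <- compute_peth(ref$times + 0.005 * rate, ref)  # +5 ms
  expect_equal(p$bin_centers_ms[which.max(shifted$counts)], 5)
  expect_equal(shifted$zero_bin_count, 0)
  expect_error(compute_peth(1:10, spike_train(numeric(0), rate)), "empty")
})

test_that("PETH of independent Poisson events is flat and refines consistently", {
  set.seed(41)
  dur <- 120; r_det <- 20
  ref <- spike_train(sort(sample(60000:(dur * rate - 60000), 100)), rate)
  det <- cumsum(rexp(dur * r_det * 2, r_det))
  det <- det[det < dur] * rate
  p <- compute_peth(det, ref, bin_ms = 1, half_range_ms = 20)
  expected <- length(ref$times) * r_det * 1e-3
  expect_true(all(abs(p$counts - expected) <= 4 * sqrt(expected) + 1))
  # 3x bin refinement (centres stay centred) conserves counts, bin by bin
  fine <- compute_peth(det, ref, bin_ms = 1 / 3, half_range_ms = 20.4)
  expect_equal(sum(fine$counts), sum(p$counts))
  regroup <- vapply(p$bin_centers_ms, function(cc)
    sum(fine$counts[abs(fine$bin_centers_ms - cc) < 0.5]), 0)
  expect_equal(regroup, p$counts)
  expect_equal(sum(fine$counts[abs(fine$bin_centers_ms) < 0.5]),
               p$zero_bin_count)
})

test_that("greedy matching mirrors the spiking scenarios and the assignment oracle", {
  ref <- spike_train(seq(1000, 150000, by = 1000), rate)  # 150 reference spikes
  m_id <- match_events(ref$times, ref)
  expect_equal(m_id$hits, 150)
  expect_equal(m_id$misses, 0)

  # 35 of 150 found (within tolerance) plus distant extras
  set.seed(3)
  found <- sort(sample(150, 35))
  det <- c(ref$times[found] + sample(-5:5, 35, TRUE), 200000 + (1:50) * 600)
  m <- match_events(det, ref, tolerance_ms = 0.5)
  expect_equal(m$hits, 35)
  expect_equal(m$misses, 115)
  expect_equal(m$hit_rate, 35 / 150, tolerance = 1e-12)

  # two detections flank one reference: nearest wins, other is an in-window FP
  one <- spike_train(5000, rate)
  m2 <- match_events(c(4998, 5004), one)
  expect_equal(m2$hits, 1)
  expect_equal(m2$matched$detected, 4998)
  expect_equal(m2$false_positives_in_window, 1)

  # oracle checks: an independent O(n^2) re-implementation of the greedy rule
  # agrees exactly, and greedy never exceeds the optimal assignment count
  greedy_oracle <- function(det, ref, tol) {
    lag <- abs(outer(det, ref, "-"))
    lag[lag > tol] <- NA
    hits <- 0L
    while (any(!is.na(lag))) {
      ij <- which(lag == min(lag, na.rm = TRUE), arr.ind = TRUE)[1, ]
      hits <- hits + 1L
      lag[ij[1], ] <- NA; lag[, ij[2]] <- NA
    }
    hits
  }
  optimal_oracle <- function(det, ref, tol) {
    adj <- abs(outer(det, ref, "-")) <= tol
    match_r <- rep(NA_integer_, length(ref))
    try_aug <- function(i, seen) {
      for (j in which(adj[i, ])) {
        if (seen[j]) next
        seen[j] <- TRUE
        if (is.na(match_r[j]) || try_aug(match_r[j], seen)) {
          match_r[j] <<- i
          return(TRUE)
        }
      }
      FALSE
    }
    sum(vapply(seq_len(nrow(adj)), function(i)
      try_aug(i, rep(FALSE, length(ref))), FALSE))
  }
  tol <- 0.5e-3 * rate
  for (s in 1:10) {
    set.seed(s)
    refx <- spike_train(sort(sample(10000, 30) * 10), rate)
    detx <- sort(sample(100000, 60))
    mg <- match_events(detx, refx)
    expect_equal(mg$hits, greedy_oracle(detx, refx$times, tol))
    expect_lte(mg$hits, optimal_oracle(detx, refx$times, tol))
    expect_equal(mg$hits + mg$misses, 30)
  }
})
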