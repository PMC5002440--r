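#' Dual-threshold flood-fill detection parameters
#'
#' Standard settings of the detection stage: band-pass 500-14,250 Hz, strong
#' and weak threshold levels of 4.5 and 2 times the per-channel standard
#' deviation.  The strong threshold seeds an event on a single channel; the
#' weak threshold grows it across neighbouring channels and contiguous
#' samples.
#'
#' @param strong_sd strong threshold multiplier (default 4.5).
#' @param weak_sd weak threshold multiplier (default 2).
#' @param band a [filter_spec()]; default [detection_band()].
#' @param adjacency_radius_um override of the probe's neighbour radius
#'   (`NULL` uses the geometry's own).
#' @param min_separation_ms events whose peaks are closer than this on
#'   overlapping channel sets are merged (default 0.5).
#' @param polarity `negative` (default; extracellular somatic spikes deflect
#'   negative-first) or `both`.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(strong_sd = 4.5, weak_sd = 2,
                             band = detection_band(),
                             adjacency_radius_um = NULL,
                             min_separation_ms = 0.5,
                             polarity = c("negative", "both")) {
  if (!(strong_sd > weak_sd && weak_sd > 0))
    stop("need strong_sd > weak_sd > 0")
  structure(list(strong_sd = strong_sd, weak_sd = weak_sd, band = band,
                 adjacency_radius_um = adjacency_radius_um,
                 min_separation_ms = min_separation_ms,
                 polarity = match.arg(polarity)),
            class = "detection_params")
}

# Union-find with path compression.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Flood-fill spike detection on a filtered multichannel trace
#'
#' Extracts spikes as spatiotemporally localized events: (1) per-channel
#' deflections exceeding `weak_sd` x sigma form a boolean mask; (2) connected
#' components of that mask are taken over temporal sample adjacency and the
#' probe's channel-adjacency graph (sites within the adjacency radius);
#' (3) only components containing at least one sample above `strong_sd` x
#' sigma survive; (4) each component yields one event at its largest absolute
#' deflection, and events closer than `min_separation_ms` with overlapping
#' channel sets are merged.
#'
#' @param data channels x time matrix, microvolts, already filtered with
#'   `params$band`.
#' @param params a [detection_params()].
#' @param geometry the [probe_geometry()] matching the rows of `data`.
#' @param sigma optional per-channel noise SDs; estimated from `data` with
#'   [estimate_noise_sd()] when `NULL`.
#' @param rate_hz sampling rate, Hz (used for the merge window).
#' @return data.frame of class `detected_events`: `peak_time` (sample index),
#'   `peak_channel` (site id), `n_channels`, `peak_uv`, plus a `channels`
#'   list-column of site-id sets.
#' @export
detect_floodfill <- function(data, params = detection_params(), geometry,
                             sigma = NULL, rate_hz = 30000) {
  stopifnot(inherits(params, "detection_params"),
            inherits(geometry, "probe_geometry"))
  data <- as.matrix(data)
  nch <- nrow(data)
  if (nch != length(geometry$site_ids))
    stop("data has ", nch, " channels but geometry has ",
         length(geometry$site_ids), " sites")
  if (is.null(sigma)) sigma <- apply(data, 1, estimate_noise_sd)
  flat <- which(sigma <= 0)
  if (length(flat))
    stop("flat channel (sigma = 0): site ", geometry$site_ids[flat[1]])
  defl <- if (params$polarity == "negative") -data else abs(data)
  geom <- geometry
  if (!is.null(params$adjacency_radius_um))
    geom$adjacency_radius_um <- params$adjacency_radius_um
  adj <- channel_adjacency(geom)

  # runs of weak-mask samples per channel
  runs <- vector("list", nch)
  nruns <- 0L
  for (ch in seq_len(nch)) {
    above <- defl[ch, ] > params$weak_sd * sigma[ch]
    if (!any(above)) { runs[[ch]] <- matrix(0, 0, 2); next }
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs[[ch]] <- cbind(starts[r$values], ends[r$values])
    nruns <- nruns + sum(r$values)
  }
  if (nruns == 0L) return(.empty_events())
  # flatten runs; per-run peak and strong flag
  rch <- integer(nruns); rs <- integer(nruns); re <- integer(nruns)
  rpk <- numeric(nruns); rpt <- integer(nruns); rstrong <- logical(nruns)
  k <- 0L
  offset <- integer(nch)
  for (ch in seq_len(nch)) {
    offset[ch] <- k
    rr <- runs[[ch]]
    if (!nrow(rr)) next
    for (j in seq_len(nrow(rr))) {
      k <- k + 1L
      seg <- rr[j, 1]:rr[j, 2]
      v <- defl[ch, seg]
      rch[k] <- ch; rs[k] <- rr[j, 1]; re[k] <- rr[j, 2]
      im <- which.max(v)
      rpk[k] <- v[im]; rpt[k] <- seg[im]
      rstrong[k] <- rpk[k] > params$strong_sd * sigma[ch]
    }
  }
  # union runs on adjacent channels whose time intervals touch (+/-1 sample)
  parent <- .uf_new(nruns)
  union2 <- function(a, b) {
    ra <- .uf_find(parent, a); rb <- .uf_find(parent, b)
    if (ra != rb) parent[rb] <<- ra
    invisible()
  }
  for (ch in seq_len(nch)) {
    na <- nrow(runs[[ch]])
    if (!na) next
    for (nb in adj[[ch]]) {
      if (nb <= ch) next
      nbn <- nrow(runs[[nb]])
      if (!nbn) next
      i <- 1L; j <- 1L
      while (i <= na && j <= nbn) {
        a1 <- runs[[ch]][i, 1]; a2 <- runs[[ch]][i, 2]
        b1 <- runs[[nb]][j, 1]; b2 <- runs[[nb]][j, 2]
        if (b1 <= a2 + 1L && a1 <= b2 + 1L)
          union2(offset[ch] + i, offset[nb] + j)
        if (a2 < b2) i <- i + 1L else j <- j + 1L
      }
    }
  }
  roots <- vapply(seq_len(nruns), function(i) .uf_find(parent, i), integer(1))
  comp <- split(seq_len(nruns), roots)
  evs <- lapply(comp, function(idx) {
    if (!any(rstrong[idx])) return(NULL)
    im <- idx[which.max(rpk[idx])]
    list(peak_time = rpt[im],
         peak_channel = geometry$site_ids[rch[im]],
         channels = sort(unique(geometry$site_ids[rch[idx]])),
         peak_uv = if (params$polarity == "negative") -rpk[im] else
           data[rch[im], rpt[im]])
  })
  evs <- Filter(Negate(is.null), evs)
  if (!length(evs)) return(.empty_events())
  evs <- evs[order(vapply(evs, `[[`, 0, "peak_time"))]
  # merge near-coincident events sharing channels
  min_sep <- params$min_separation_ms / 1000 * rate_hz
  merged <- list(evs[[1]])
  for (e in evs[-1]) {
    last <- merged[[length(merged)]]
    if (e$peak_time - last$peak_time < min_sep &&
        length(intersect(e$channels, last$channels))) {
      keep <- if (abs(e$peak_uv) > abs(last$peak_uv)) e else last
      keep$channels <- sort(unique(c(e$channels, last$channels)))
      merged[[length(merged)]] <- keep
    } else merged <- c(merged, list(e))
  }
  out <- data.frame(peak_time = vapply(merged, `[[`, 0, "peak_time"),
                    peak_channel = vapply(merged, `[[`, 0, "peak_channel"),
                    n_channels = vapply(merged, function(e) length(e$channels), 0L),
                    peak_uv = vapply(merged, `[[`, 0, "peak_uv"))
  out$channels <- lapply(merged, `[[`, "channels")
  class(out) <- c("detected_events", "data.frame")
  out
}

.empty_events <- function() {
  out <- data.frame(peak_time = numeric(0), peak_channel = integer(0),
                    n_channels = integer(0), peak_uv = numeric(0))
  out$channels <- list()
  class(out) <- c("detected_events", "data.frame")
  out
}

#' Peri-event time histogram of detected events around reference spikes
#'
#' Histogram of lags (detected minus reference) pooled over every reference
#' spike, in bins of `bin_ms` aligned so that one bin is centred at 0 ms
#' (spanning -bin/2 to +bin/2).
#'
#' @param detected detected event times (sample indices), or a
#'   `detected_events` data.frame.
#' @param reference a [spike_train()] of juxtacellular spike peaks.
#' @param bin_ms bin width, ms (default 1).
#' @param half_range_ms histogram half-range, ms (default 50).
#' @return object of class `peth_result`: `bin_centers_ms`, `bin_edges_ms`,
#'   `counts`, `n_juxta`, `zero_bin_count`.
#' @export
compute_peth <- function(detected, reference, bin_ms = 1, half_range_ms = 50) {
  stopifnot(inherits(reference, "spike_train"))
  if (!length(reference$times)) stop("empty reference spike train")
  if (inherits(detected, "detected_events")) detected <- detected$peak_time
  nb <- floor(half_range_ms / bin_ms)
  edges <- (seq(-nb, nb + 1) - 0.5) * bin_ms
  lags <- as.numeric(outer(detected, reference$times, "-")) /
    reference$rate_hz * 1000
  lags <- lags[lags >= edges[1] & lags < edges[length(edges)]]
  counts <- if (length(lags))
    as.numeric(table(cut(lags, edges, right = FALSE))) else
      numeric(length(edges) - 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(bin_centers_ms = centers, bin_edges_ms = edges,
                 counts = counts, n_juxta = length(reference$times),
                 zero_bin_count = counts[which.min(abs(centers))]),
            class = "peth_result")
}

#' @export
print.peth_result <- function(x, ...) {
  cat(sprintf("PETH: %d bins x %g ms, %d reference spikes, 0-ms bin count %d\n",
              length(x$counts), diff(x$bin_edges_ms[1:2]), x$n_juxta,
              x$zero_bin_count))
  invisible(x)
}

#' Match detected events to reference spikes
#'
#' Greedy nearest-neighbour matching: candidate (detected, reference) pairs
#' within `tolerance_ms` are assigned in order of increasing absolute lag;
#' each detected event matches at most one reference spike and vice versa.
#' `hits + misses == n_reference` always.
#'
#' @param detected detected event times (sample indices) or a
#'   `detected_events` data.frame.
#' @param reference a [spike_train()].
#' @param tolerance_ms matching half-window, ms (default 0.5, the 0-ms PETH
#'   bin).
#' @return list: `hits`, `misses`, `false_positives_in_window` (unmatched
#'   detected events that still fell within tolerance of some reference
#'   spike), `n_detected`, `hit_rate`, `matched` (data.frame of matched
#'   detected/reference times).
#' @export
match_events <- function(detected, reference, tolerance_ms = 0.5) {
  stopifnot(inherits(reference, "spike_train"))
  if (inherits(detected, "detected_events")) detected <- detected$peak_time
  tol <- tolerance_ms / 1000 * reference$rate_hz
  nr <- length(reference$times)
  nd <- length(detected)
  if (!nd || !nr)
    return(list(hits = 0L, misses = nr, false_positives_in_window = 0L,
                n_detected = nd, hit_rate = if (nr) 0 else NA_real_,
                matched = data.frame(detected = numeric(0), reference = numeric(0))))
  cand <- which(abs(outer(detected, reference$times, "-")) <= tol, arr.ind = TRUE)
  used_d <- logical(nd); used_r <- logical(nr)
  md <- numeric(0); mr <- numeric(0)
  if (nrow(cand)) {
    lag <- abs(detected[cand[, 1]] - reference$times[cand[, 2]])
    cand <- cand[order(lag), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_d[i] && !used_r[j]) {
        used_d[i] <- TRUE; used_r[j] <- TRUE
        md <- c(md, detected[i]); mr <- c(mr, reference$times[j])
      }
    }
  }
  in_window_unmatched <- if (nrow(cand))
    length(unique(cand[!used_d[cand[, 1]], 1])) else 0L
  hits <- sum(used_r)
  list(hits = hits, misses = nr - hits,
       false_positives_in_window = in_window_unmatched,
       n_detected = nd, hit_rate = hits / nr,
       matched = data.frame(detected = md, reference = mr))
}

#' Export detected events as CSV
#' @param events a `detected_events` data.frame.
#' @param rate_hz sampling rate, used to convert peak sample to seconds.
#' @param path CSV path.
#' @export
write_events_csv <- function(events, rate_hz, path) {
  utils::write.csv(data.frame(peak_time_s = events$peak_time / rate_hz,
                              peak_channel = events$peak_channel,
                              n_channels = events$n_channels,
                              peak_uv = events$peak_uv),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a PETH as CSV (bin_center_ms, count)
#' @param peth a `peth_result`.
#' @param path CSV path.
#' @export
write_peth_csv <- function(peth, path) {
  utils::write.csv(data.frame(bin_center_ms = peth$bin_centers_ms,
                              count = peth$counts),
                   path, row.names = FALSE)
  invisible(path)
}
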