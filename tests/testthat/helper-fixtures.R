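# Shared fixtures, built in code at test time.

# Small 12-site, 2-column probe for fast synthetic scenes.
mini_probe <- function() {
  xz <- as.matrix(expand.grid(x_um = c(0, 22.5), z_um = seq(0, by = 22.5, length.out = 6)))
  probe_geometry(seq_len(12), xz, site_area_um2 = 400, adjacency_radius_um = 30,
                 name = "mini-12ch")
}

# Minimal 2 x 2 probe for long-duration scenes where channel count is cost.
quad_probe <- function() {
  probe_geometry(1:4, as.matrix(expand.grid(x_um = c(0, 22.5), z_um = c(0, 22.5))),
                 site_area_um2 = 400, adjacency_radius_um = 30, name = "quad")
}

# Brute-force connected-component oracle for the flood-fill detector:
# BFS over the boolean weak mask, channel adjacency by distance, temporal
# adjacency +/- 1 sample.  Returns a list of components, each a 2-column
# matrix (channel, time), with the same strong-sample filter.
brute_floodfill <- function(data, strong_sd, weak_sd, geometry, sigma) {
  defl <- -data
  nch <- nrow(data); nt <- ncol(data)
  weak <- defl > weak_sd * sigma
  strong <- defl > strong_sd * sigma
  d <- as.matrix(stats::dist(geometry$site_xz_um)); diag(d) <- 0
  adj <- d <= geometry$adjacency_radius_um   # includes self
  seen <- matrix(FALSE, nch, nt)
  comps <- list()
  for (c0 in seq_len(nch)) for (t0 in seq_len(nt)) {
    if (!weak[c0, t0] || seen[c0, t0]) next
    queue <- list(c(c0, t0)); seen[c0, t0] <- TRUE
    members <- matrix(0L, 0, 2)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      members <- rbind(members, cur)
      for (ch in which(adj[cur[1], ])) for (tt in (cur[2] - 1):(cur[2] + 1)) {
        if (tt < 1 || tt > nt || seen[ch, tt] || !weak[ch, tt]) next
        seen[ch, tt] <- TRUE
        queue <- c(queue, list(c(ch, tt)))
      }
    }
    if (any(strong[members])) comps <- c(comps, list(unname(members)))
  }
  comps
}

# Synthetic amplitude-distance cohort, built once per test run and cached:
# one scene per neuron, distances spanning 20-200 um, JTA computed against
# the generator's true spike times.
.cohort_cache <- new.env(parent = emptyenv())
synth_cohort <- function() {
  if (!is.null(.cohort_cache$cohort)) return(.cohort_cache$cohort)
  geom <- mini_probe()
  distances <- seq(20, 200, length.out = 20)
  cohort <- lapply(seq_along(distances), function(i) {
    cfg <- synth_config(geom, duration_s = 20, rate_hz = 30000,
                        neurons = list(neuron_spec(c(11, distances[i], 60),
                                                   rate_hz = 3,
                                                   is_juxta_target = TRUE)),
                        seed = 100 + i)
    b <- generate_pair(cfg)
    jta <- compute_jta(b$extracellular, b$true_spikes[[1]])
    list(metadata = b$metadata, jta = jta,
         true_distance = b$metadata$distance_um)
  })
  .cohort_cache$cohort <- cohort
  cohort
}
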