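#' Probe geometry container
#'
#' Per-site coordinates on the shank plane: `x_um` is the lateral coordinate,
#' `z_um` the axial coordinate (increasing with depth, 0 at the top-most
#' site).  `adjacency_radius_um` is the maximum centre-to-centre distance at
#' which two sites count as neighbours for flood-fill detection.
#'
#' @param site_ids ordered channel identifiers (integer).
#' @param site_xz_um n x 2 matrix of (lateral, axial) positions, micrometres.
#' @param site_area_um2 electrode area per site (recycled), square micrometres.
#' @param adjacency_radius_um neighbour radius, micrometres.
#' @param name optional probe name.
#' @return object of class `probe_geometry`.
#' @export
probe_geometry <- function(site_ids, site_xz_um, site_area_um2,
                           adjacency_radius_um = 30, name = "custom") {
  site_xz_um <- as.matrix(site_xz_um)
  stopifnot(ncol(site_xz_um) == 2, nrow(site_xz_um) == length(site_ids))
  if (anyDuplicated(site_xz_um, MARGIN = 1))
    stop("site positions must be unique")
  if (anyDuplicated(site_ids)) stop("site ids must be unique")
  colnames(site_xz_um) <- c("x_um", "z_um")
  structure(list(site_ids = as.integer(site_ids),
                 site_xz_um = site_xz_um,
                 site_area_um2 = rep_len(site_area_um2, length(site_ids)),
                 adjacency_radius_um = adjacency_radius_um,
                 name = name),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("Probe '%s': %d sites, axial span %.1f um, adjacency radius %g um\n",
              x$name, length(x$site_ids), axial_span(x), x$adjacency_radius_um))
  invisible(x)
}

#' Axial span of a probe (max - min axial coordinate)
#' @param geometry a [probe_geometry()].
#' @return span in micrometres.
#' @export
axial_span <- function(geometry) {
  diff(range(geometry$site_xz_um[, "z_um"]))
}

#' Per-site nearest-neighbour distances
#' @param geometry a [probe_geometry()].
#' @return numeric vector, one entry per site.
#' @export
nearest_neighbor_distances <- function(geometry) {
  d <- as.matrix(stats::dist(geometry$site_xz_um))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Channel adjacency list under the probe's neighbour radius
#' @param geometry a [probe_geometry()].
#' @return list (one entry per site, in site order) of neighbouring site
#'   indices (row indices, not ids).
#' @export
channel_adjacency <- function(geometry) {
  d <- as.matrix(stats::dist(geometry$site_xz_um))
  diag(d) <- Inf
  lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= geometry$adjacency_radius_um))
}

#' 32-channel, 3-column staggered polytrode layout
#'
#' Emulates a commercial 32-channel "poly3" probe: 177-um^2 iridium sites in
#' three staggered columns with 22-25 um nearest-neighbour pitch and a 275-um
#' axial span.  The probe drawing does not tabulate coordinates, so the exact
#' stagger is a package convention: a 12-site centre column at 25-um axial
#' pitch (axial 0-275 um) flanked by two 10-site columns at lateral +/-20 um,
#' offset axially by half a pitch.  Channel ids run down the centre column
#' then down each flank.
#'
#' @return a [probe_geometry()] with 32 sites.
#' @export
make_probe_32ch_poly3 <- function() {
  pitch <- 25
  centre <- cbind(0, seq(0, by = pitch, length.out = 12))
  left   <- cbind(-20, seq(pitch / 2, by = pitch, length.out = 10))
  right  <- cbind(20, seq(pitch / 2, by = pitch, length.out = 10))
  xz <- rbind(centre, left, right)
  probe_geometry(seq_len(32), xz, site_area_um2 = 177,
                 adjacency_radius_um = 30, name = "poly3-32ch")
}

#' 128-channel regular-grid CMOS probe layout
#'
#' Square 20 x 20 um (400 um^2) titanium-nitride sites on a regular grid at
#' 22.5-um pitch in both directions.
#'
#' @param columns number of site columns; must divide 128.
#' @return a [probe_geometry()] with 128 sites.
#' @export
make_probe_128ch <- function(columns = 4) {
  if (columns < 1 || 128 %% columns != 0)
    stop("columns must divide 128, got ", columns)
  rows <- 128 / columns
  pitch <- 22.5
  xz <- as.matrix(expand.grid(x_um = (seq_len(columns) - 1) * pitch,
                              z_um = (seq_len(rows) - 1) * pitch))
  probe_geometry(seq_len(128), xz, site_area_um2 = 400,
                 adjacency_radius_um = 30, name = sprintf("cmos-128ch-%dcol", columns))
}

#' Read and write probe geometry as CSV
#'
#' Columns: `site_id, x_um, z_um, area_um2`; the adjacency radius and name
#' are stored as `# key: value` comment lines at the top.
#'
#' @param geometry a [probe_geometry()].
#' @param path CSV path.
#' @export
write_probe_csv <- function(geometry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name: %s", geometry$name),
               sprintf("# adjacency_radius_um: %g", geometry$adjacency_radius_um)),
             con)
  utils::write.csv(data.frame(site_id = geometry$site_ids,
                              x_um = geometry$site_xz_um[, 1],
                              z_um = geometry$site_xz_um[, 2],
                              area_um2 = geometry$site_area_um2),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_csv
#' @export
read_probe_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("site_id", "x_um", "z_um", "area_um2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("probe CSV missing column(s): ", paste(miss, collapse = ", "))
  probe_geometry(df$site_id, cbind(df$x_um, df$z_um), df$area_um2,
                 adjacency_radius_um = as.numeric(get_meta("adjacency_radius_um", 30)),
                 name = get_meta("name", "custom"))
}

#' Raw multichannel recording
#'
#' `samples` is a channels x time integer matrix in acquisition units;
#' multiply by `scale_uv_per_bit` to obtain microvolts.
#'
#' @param samples channels x time matrix of integers within int16 range.
#' @param scale_uv_per_bit microvolts per integer step (amplifier-dependent;
#'   0.195 uV/bit is the usual step of the acquisition chip family and is the
#'   configurable default, not a constant).
#' @param rate_hz sampling rate, Hz.
#' @param channel_order mapping from file row order to geometry site ids;
#'   defaults to 1:n.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(samples, scale_uv_per_bit = 0.195, rate_hz = 30000,
                          channel_order = NULL) {
  samples <- as.matrix(samples)
  if (length(samples) && (max(samples) > 32767 || min(samples) < -32768))
    stop("sample values exceed 16-bit signed range")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (is.null(channel_order)) channel_order <- seq_len(nrow(samples))
  structure(list(samples = samples, scale_uv_per_bit = scale_uv_per_bit,
                 rate_hz = rate_hz, channel_order = as.integer(channel_order)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Raw recording: %d channels x %d samples @ %g Hz (%.3g s), %g uV/bit\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              ncol(x$samples) / x$rate_hz, x$scale_uv_per_bit))
  invisible(x)
}

#' Convert a raw recording to microvolts
#' @param recording a [raw_recording()].
#' @return channels x time numeric matrix, microvolts.
#' @export
recording_uv <- function(recording) {
  recording$samples * recording$scale_uv_per_bit
}

#' Read and write flat binary recordings
#'
#' Format: 16-bit signed little-endian integers, channel-interleaved in
#' sample-major order (all channels of sample 0, then all channels of sample
#' 1, ...), no header.  The round-trip is bit-exact.
#'
#' @param path binary file path (conventionally `.bin` or `.dat`).
#' @param n_channels number of interleaved channels.
#' @param scale_uv_per_bit,rate_hz stored on the returned recording.
#' @return `read_raw` returns a [raw_recording()].
#' @export
read_raw <- function(path, n_channels, scale_uv_per_bit = 0.195,
                     rate_hz = 30000) {
  nbytes <- file.size(path)
  if (is.na(nbytes)) stop("cannot read raw file: ", path)
  if (nbytes %% (2 * n_channels) != 0)
    stop("truncated raw file: ", nbytes, " bytes is not a multiple of 2 x ",
         n_channels, " channels (", 2 * n_channels, " bytes per sample frame)")
  v <- readBin(path, what = "integer", n = nbytes / 2, size = 2,
               signed = TRUE, endian = "little")
  raw_recording(matrix(v, nrow = n_channels),
                scale_uv_per_bit = scale_uv_per_bit, rate_hz = rate_hz)
}

#' @rdname read_raw
#' @param recording a [raw_recording()] to write.
#' @export
write_raw <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  writeBin(as.integer(recording$samples), path, size = 2, endian = "little")
  invisible(path)
}

# Two pairs in the reference dataset whose pipette recordings showed
# extracellular-like negative-before-positive spikes; used as the default
# polarity when a metadata table carries no polarity column.
NEGATIVE_FIRST_PAIR_IDS <- c("2015_09_04_Pair 5.0", "2015_09_03_Pair 9.0")

#' Pair metadata table I/O
#'
#' CSV mirror of a paired-recording summary table.  Required columns:
#' `pair_id, distance_um, depth_um, juxta_threshold`.  Optional:
#' `distance_err_um` (default 10.5, the positioning uncertainty of the
#' calibrated setup), `polarity` (`positive-first` or `negative-first`;
#' when absent, pairs on the documented negative-first list default to
#' `negative-first`), `notes`.  Unknown columns are folded into `notes`.
#'
#' @param path CSV path.
#' @return `read_pair_table` returns a data.frame of validated rows with
#'   class `pair_table`.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(pair_id = "character"))
  need <- c("pair_id", "distance_um", "depth_um", "juxta_threshold")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pair table missing required column(s): ", paste(miss, collapse = ", "))
  if (!"distance_err_um" %in% names(df)) df$distance_err_um <- 10.5
  if (!"polarity" %in% names(df))
    df$polarity <- ifelse(df$pair_id %in% NEGATIVE_FIRST_PAIR_IDS,
                          "negative-first", "positive-first")
  if (!"notes" %in% names(df)) df$notes <- ""
  extra <- setdiff(names(df), c(need, "distance_err_um", "polarity", "notes"))
  if (length(extra)) {
    for (col in extra)
      df$notes <- paste0(df$notes, ifelse(nzchar(df$notes), "; ", ""),
                         col, "=", df[[col]])
    df <- df[setdiff(names(df), extra)]
  }
  validate_pair_table(df)
}

#' @rdname read_pair_table
#' @param table a pair-table data.frame.
#' @export
write_pair_table <- function(table, path) {
  table <- validate_pair_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_pair_table
#' @export
validate_pair_table <- function(table) {
  if (any(table$distance_um < 0))
    stop("invalid pair table: distance_um must be >= 0 (row ",
         which(table$distance_um < 0)[1], ")")
  if (anyDuplicated(table$pair_id))
    stop("invalid pair table: duplicate pair_id '",
         table$pair_id[duplicated(table$pair_id)][1], "'")
  if (!all(table$polarity %in% c("positive-first", "negative-first")))
    stop("invalid pair table: polarity must be positive-first or negative-first")
  class(table) <- c("pair_table", "data.frame")
  table
}

#' Single pair-metadata record
#'
#' @param pair_id identifier, e.g. "2014_11_25_Pair3.0".
#' @param distance_um tip-to-nearest-site Euclidean distance, micrometres.
#' @param depth_um cortical depth of the pair, micrometres.
#' @param juxta_threshold juxtacellular detection threshold used for this pair
#'   (same units as the juxtacellular trace).
#' @param distance_err_um positioning uncertainty (default 10.5 um).
#' @param polarity juxtacellular spike polarity.
#' @param notes free text.
#' @return one-row `pair_table` data.frame.
#' @export
pair_metadata <- function(pair_id, distance_um, depth_um = NA_real_,
                          juxta_threshold = NA_real_, distance_err_um = 10.5,
                          polarity = c("positive-first", "negative-first"),
                          notes = "") {
  polarity <- match.arg(polarity)
  validate_pair_table(data.frame(pair_id = pair_id, distance_um = distance_um,
                                 depth_um = depth_um,
                                 juxta_threshold = juxta_threshold,
                                 distance_err_um = distance_err_um,
                                 polarity = polarity, notes = notes,
                                 stringsAsFactors = FALSE))
}
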