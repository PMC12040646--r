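# Marker kinematics: irregularly sampled 3D ultrasound-marker tracks to
# uniform-rate sagittal segment angles.
#
# Coordinate convention (receiver frame): y = anteroposterior axis of
# platform motion (positive forward), z = vertical, x = lateral.

#' Resample a marker track onto a uniform time grid
#'
#' Ultrasound marker acquisition runs at a dynamic 80-200 Hz rate depending on
#' momentary marker visibility; analysis requires a uniform rate. Linear
#' interpolation is applied over the overlap of the original time span (no
#' extrapolation). Gaps longer than `max_gap_s` are flagged: samples that fall
#' inside such a gap get `valid = FALSE` so downstream block segmentation can
#' exclude them.
#'
#' @param track A data frame with columns `time_s` (strictly increasing) and
#'   one or more coordinate columns (any of `x_cm`, `y_cm`, `z_cm`).
#' @param rate Target sample rate, Hz (default 100).
#' @param max_gap_s Longest acquisition gap bridged by interpolation, seconds.
#' @return A tibble on the uniform grid with the same coordinate columns plus
#'   a logical `valid` column.
#' @examples
#' tr <- tibble::tibble(time_s = sort(runif(200, 0, 2)), y_cm = runif(200))
#' resample_uniform(tr, rate = 100)
#' @export
resample_uniform <- function(track, rate = 100, max_gap_s = 0.25) {
  if (!"time_s" %in% names(track))
    stop("`track` needs a `time_s` column.", call. = FALSE)
  t0 <- track$time_s
  if (length(t0) < 2L)
    stop("`track` needs a `time_s` column with at least 2 samples.", call. = FALSE)
  if (any(diff(t0) <= 0))
    stop("`time_s` must be strictly increasing.", call. = FALSE)
  coord_cols <- intersect(c("x_cm", "y_cm", "z_cm"), names(track))
  if (length(coord_cols) == 0L)
    stop("`track` has no coordinate columns (x_cm, y_cm, z_cm).", call. = FALSE)
  dt <- 1 / rate
  # grid within the data span only: no extrapolation
  grid <- seq(ceiling(t0[1] / dt) * dt, t0[length(t0)] + 1e-12, by = dt)
  grid <- grid[grid <= t0[length(t0)] + 1e-9]
  if (length(grid) == 0L)
    stop("Track time span too short for the requested rate.", call. = FALSE)
  out <- tibble::tibble(time_s = grid)
  for (cc in coord_cols) {
    if (any(!is.finite(track[[cc]])))
      stop("Non-finite coordinates in `", cc, "`; clean the track first.",
           call. = FALSE)
    out[[cc]] <- stats::approx(t0, track[[cc]], xout = grid, rule = 1)$y
  }
  gaps <- which(diff(t0) > max_gap_s)
  valid <- rep(TRUE, length(grid))
  for (g in gaps) valid[grid > t0[g] & grid < t0[g + 1L]] <- FALSE
  out$valid <- valid
  if ("marker_id" %in% names(track)) out$marker_id <- track$marker_id[1]
  out
}

#' Midsagittal track from a left/right marker pair
#'
#' Left and right markers at head and shoulder level are combined by
#' coordinate-wise averaging to give the midsagittal position. Both tracks
#' must already be on the same uniform grid.
#'
#' @param left,right Resampled tracks sharing an identical `time_s` grid.
#' @return A tibble with the averaged coordinates; `valid` is the conjunction
#'   of the inputs' validity.
#' @export
midsagittal <- function(left, right) {
  if (nrow(left) != nrow(right) ||
      max(abs(left$time_s - right$time_s)) > 1e-9)
    stop("`left` and `right` must share the same time grid; resample first.",
         call. = FALSE)
  coord_cols <- intersect(c("x_cm", "y_cm", "z_cm"),
                          intersect(names(left), names(right)))
  out <- tibble::tibble(time_s = left$time_s)
  for (cc in coord_cols) out[[cc]] <- (left[[cc]] + right[[cc]]) / 2
  out$valid <- (if ("valid" %in% names(left)) left$valid else TRUE) &
    (if ("valid" %in% names(right)) right$valid else TRUE)
  out
}

#' Sagittal segment angle in space from a marker track
#'
#' Converts the anteroposterior excursion of a marker into the sway angle of
#' the segment it rides on, about the ankle axis: `angle(t) = atan2(y(t) -
#' y_ref, h)` in degrees, where `y_ref` is the quiet-stance mean position and
#' `h` the marker height above the ankle axis. Positive angles are forward
#' lean. The small-angle regime (|angle| < 15 deg) is expected throughout.
#'
#' @param track Uniform-rate midsagittal track with a `y_cm` column.
#' @param pivot_height_cm Marker height above the ankle axis, cm (> 0).
#' @param reference_epoch Length-2 numeric, the `time_s` window whose mean
#'   `y_cm` defines quiet-stance `y_ref`; `NULL` uses the whole track mean.
#' @param segment Label attached to the output (`"head"`, `"shoulder"`,
#'   `"hip"`, or any string).
#' @return A tibble `time_s`, `angle_deg`, `segment` (class
#'   `segment_angle_series`, sample rate in attribute `rate_hz`).
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 2, 0.01),
#'                      y_cm = 150 * tanpi(1 / 180) * sin(seq(0, 2, 0.01)))
#' segment_angle(tr, pivot_height_cm = 150)
#' @export
segment_angle <- function(track, pivot_height_cm, reference_epoch = NULL,
                          segment = "head") {
  if (!is.numeric(pivot_height_cm) || pivot_height_cm <= 0)
    stop("`pivot_height_cm` must be positive.", call. = FALSE)
  if (!"y_cm" %in% names(track))
    stop("`track` needs a `y_cm` column.", call. = FALSE)
  dts <- diff(track$time_s)
  if (length(dts) < 1L || max(abs(dts - dts[1])) > 1e-9)
    stop("`track` must be uniformly sampled; use resample_uniform().",
         call. = FALSE)
  y <- track$y_cm
  if (is.null(reference_epoch)) {
    y_ref <- mean(y)
  } else {
    sel <- track$time_s >= reference_epoch[1] & track$time_s <= reference_epoch[2]
    if (!any(sel)) stop("`reference_epoch` contains no samples.", call. = FALSE)
    y_ref <- mean(y[sel])
  }
  out <- tibble::tibble(
    time_s = track$time_s,
    angle_deg = atan2(y - y_ref, pivot_height_cm) * 180 / pi,
    segment = segment
  )
  attr(out, "rate_hz") <- 1 / dts[1]
  attr(out, "y_ref_cm") <- y_ref
  class(out) <- c("segment_angle_series", class(out))
  out
}

#' Probability distribution of head position along the platform axis
#'
#' Histograms the anteroposterior position of the central head marker relative
#' to its quiet-stance mean, over +/- `half_range_cm`, normalised to unit
#' total mass. Samples beyond the range are clipped into the edge bins.
#'
#' @param track Uniform-rate track of the central head marker (`y_cm`).
#' @param half_range_cm Half-width of the histogram support, cm (default 10).
#' @param bin_width_cm Bin width, cm (default 1).
#' @param reference_epoch Optional `time_s` window defining the quiet-stance
#'   mean; `NULL` uses the whole track.
#' @return A tibble `bin_center_cm`, `probability` summing to 1.
#' @export
head_position_histogram <- function(track, half_range_cm = 10, bin_width_cm = 1,
                                    reference_epoch = NULL) {
  if (!"y_cm" %in% names(track) || nrow(track) == 0L)
    stop("`track` must contain `y_cm` samples.", call. = FALSE)
  y <- track$y_cm
  if (is.null(reference_epoch)) {
    y_ref <- mean(y)
  } else {
    sel <- track$time_s >= reference_epoch[1] & track$time_s <= reference_epoch[2]
    if (!any(sel)) stop("`reference_epoch` contains no samples.", call. = FALSE)
    y_ref <- mean(y[sel])
  }
  dev <- y - y_ref
  dev <- pmin(pmax(dev, -half_range_cm + 1e-12), half_range_cm - 1e-12)
  breaks <- seq(-half_range_cm, half_range_cm, by = bin_width_cm)
  counts <- graphics::hist(dev, breaks = breaks, plot = FALSE)$counts
  tibble::tibble(
    bin_center_cm = (breaks[-1] + breaks[-length(breaks)]) / 2,
    probability = counts / sum(counts)
  )
}

#' Amplitude summary of a segment-angle series
#'
#' Root-mean-square of the mean-removed angle over the analysed epoch, with
#' the peak-to-peak excursion alongside. For a pure sinusoid of amplitude A
#' the RMS is A/sqrt(2).
#'
#' @param series A `segment_angle_series` (or any data frame with `angle_deg`).
#' @return A tibble with `segment`, `rms_deg`, `peak_to_peak_deg`.
#' @export
excursion_amplitude <- function(series) {
  if (!"angle_deg" %in% names(series))
    stop("`series` needs an `angle_deg` column.", call. = FALSE)
  a <- series$angle_deg
  tibble::tibble(
    segment = if ("segment" %in% names(series)) series$segment[1] else NA_character_,
    rms_deg = sqrt(mean((a - mean(a))^2)),
    peak_to_peak_deg = diff(range(a))
  )
}

#' Read a long-format marker file
#'
#' Reads delimited text with columns `time_s`, `marker_id`, `x_cm`, `y_cm`,
#' `z_cm` (one row per marker detection) and splits it into per-marker tracks.
#'
#' @param path Path to the marker file (tab- or comma-separated).
#' @return A named list of per-marker tibbles ordered by time.
#' @export
read_marker_file <- function(path) {
  df <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("time_s", "marker_id", "x_cm", "y_cm", "z_cm")
  if (!all(need %in% names(df)))
    stop("Marker file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- dplyr::arrange(df, .data$marker_id, .data$time_s)
  split(tibble::as_tibble(df), df$marker_id)
}

#' Segment angles for one trial recording
#'
#' Full kinematic chain for one recording: resample each marker to a uniform
#' rate, average left/right pairs into midsagittal tracks (head uses the two
#' lateral ear markers, shoulder the outer trunk markers), and convert the
#' head, shoulder and hip tracks to sagittal sway angles about the ankle axis
#' using the subject's marker heights.
#'
#' @param markers Named list of marker tracks as from [read_marker_file()].
#'   Expected names: `head_vertex`, `head_left`, `head_right`, `trunk_1`,
#'   `trunk_2`, `trunk_3`, `hip`, `knee_left`, `knee_right`.
#' @param heights_cm Named numeric vector of marker heights above the ankle
#'   axis: `head`, `shoulder`, `hip` (cm).
#' @param rate Analysis sample rate, Hz.
#' @param reference_epoch Quiet-stance window for the positional reference.
#' @return A tibble `time_s`, `segment`, `angle_deg` in long format.
#' @export
trial_segment_angles <- function(markers, heights_cm, rate = 100,
                                 reference_epoch = NULL) {
  need <- c("head_left", "head_right", "trunk_1", "trunk_3", "hip")
  missing <- setdiff(need, names(markers))
  if (length(missing) > 0L)
    stop("Missing marker tracks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (h in c("head", "shoulder", "hip"))
    if (is.na(heights_cm[h]) || heights_cm[h] <= 0)
      stop("`heights_cm` must contain positive `", h, "`.", call. = FALSE)

  rs <- function(id) resample_uniform(markers[[id]], rate = rate)
  head_mid <- midsagittal(rs("head_left"), rs("head_right"))
  shoulder_mid <- midsagittal(rs("trunk_1"), rs("trunk_3"))
  hip_tr <- rs("hip")

  # align all three onto the common overlap of their grids
  t_lo <- max(head_mid$time_s[1], shoulder_mid$time_s[1], hip_tr$time_s[1])
  t_hi <- min(dplyr::last(head_mid$time_s), dplyr::last(shoulder_mid$time_s),
              dplyr::last(hip_tr$time_s))
  clip <- function(tr) tr[tr$time_s >= t_lo - 1e-9 & tr$time_s <= t_hi + 1e-9, ]

  dplyr::bind_rows(
    segment_angle(clip(head_mid), heights_cm[["head"]], reference_epoch, "head"),
    segment_angle(clip(shoulder_mid), heights_cm[["shoulder"]], reference_epoch,
                  "shoulder"),
    segment_angle(clip(hip_tr), heights_cm[["hip"]], reference_epoch, "hip")
  )
}
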