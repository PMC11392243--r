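# LV contour extraction from wall masks, the 7ths-based segment partition
# of its left/right arms, and per-segment displacement curves relative to
# the first frame.

#' Extract the endocardial LV contour from a wall mask
#'
#' Casts rays from the cavity centroid and takes the first wall pixel per
#' angle, giving the inner (endocardial) edge as an ordered open curve. The
#' open arc of the U-shaped wall (the valve plane) appears as the angular
#' gap; the contour runs from the left basal end, through the apex, to the
#' right basal end. The apex is the arc-length midpoint of the curve, which
#' splits it into the left arm (length `L`) and right arm (`R`).
#'
#' @param mask Binary matrix with exactly one foreground component.
#' @param n_angles Angular sampling density of the ray cast.
#' @param smooth Half-width (in angle samples) of the circular running-mean
#'   applied to the radius profile to suppress pixel quantisation.
#' @param frame_index Frame index used in error messages.
#' @return An `lv_contour`: `points` (n x 2 matrix, row/col), cumulative
#'   `arc` lengths, arm lengths `L` and `R`, and `apex_index`.
#' @export
extract_contour <- function(mask, n_angles = 720L, smooth = 4L, frame_index = NA) {
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) {
    stop(sprintf("empty mask%s: no wall to trace",
                 if (is.na(frame_index)) "" else sprintf(" at frame %d", frame_index)))
  }
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1L) {
    stop(sprintf("mask%s has %d components; expected one",
                 if (is.na(frame_index)) "" else sprintf(" at frame %d", frame_index),
                 max(lab)))
  }
  cy <- mean(fg[, 1])
  cx <- mean(fg[, 2])
  rmax <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  radii <- rep(NA_real_, n_angles)
  steps <- seq(1, rmax, by = 0.5)
  for (a in seq_len(n_angles)) {
    di <- -cos(angles[a])  # angle 0 points "up" (decreasing row), clockwise
    dj <- sin(angles[a])
    ii <- round(cy + steps * di)
    jj <- round(cx + steps * dj)
    ok <- ii >= 1 & ii <= nrow(mask) & jj >= 1 & jj <= ncol(mask)
    iic <- pmin(pmax(ii, 1L), nrow(mask))
    jjc <- pmin(pmax(jj, 1L), ncol(mask))
    hit <- which(ok & mask[cbind(iic, jjc)] > 0)
    if (length(hit) > 0) radii[a] <- steps[hit[1]]
  }
  miss <- which(is.na(radii))
  if (length(miss) == 0L) {
    stop("wall mask is angularly closed; expected an open (U-shaped) wall")
  }
  # longest circular run of missing angles = the opening
  is_miss <- is.na(radii)
  ext <- c(is_miss, is_miss)
  runs <- rle(ext)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gap <- which(runs$values & starts <= n_angles)
  best <- gap[which.max(runs$lengths[gap])]
  gap_end <- ends[best]  # last missing index (possibly wrapped)
  ord <- ((gap_end + seq_len(n_angles) - 1L) %% n_angles) + 1L
  ord <- ord[!is.na(radii[ord])]

  # circular-free smoothing of the radius profile along the ordered arc
  r <- radii[ord]
  if (smooth > 0L && length(r) > 2L * smooth + 1L) {
    k <- 2L * smooth + 1L
    rpad <- c(rep(r[1], smooth), r, rep(r[length(r)], smooth))
    r <- stats::filter(rpad, rep(1 / k, k), sides = 2)[smooth + seq_along(r)]
  }
  pts <- cbind(row = cy - r * cos(angles[ord]), col = cx + r * sin(angles[ord]))

  # orient so the curve starts at the basal LEFT end (smaller mean column
  # in its first half)
  n <- nrow(pts)
  if (mean(pts[seq_len(floor(n / 2)), 2]) > mean(pts[(floor(n / 2) + 1):n, 2])) {
    pts <- pts[n:1, , drop = FALSE]
  }
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[n]
  if (total <= 0) stop("degenerate contour: zero arc length")
  apex_index <- which.min(abs(arc - total / 2))
  L <- arc[apex_index]
  R <- total - L
  if (L <= 0 || R <= 0) stop("degenerate contour: an arm has zero length")
  structure(list(points = pts, arc = arc, L = L, R = R, apex_index = apex_index),
            class = "lv_contour")
}

#' Partition the LV contour into myocardial segments
#'
#' Per arm, one apical span of length `arm/7` and three spans of length
#' `2*arm/7`, ordered base-to-apex; the spans tile each arm exactly. Span
#' coordinates are arc lengths along the contour (left base = 0).
#'
#' @param contour An `lv_contour`.
#' @return A `segment_partition` data.frame with columns `segment_id`,
#'   `side`, `start`, `end` (arc-length units).
#' @export
partition_segments <- function(contour) {
  L <- contour$L
  R <- contour$R
  if (L <= 0 || R <= 0) stop("degenerate contour: both arms must be positive")
  lf <- cumsum(c(0, 2, 2, 2, 1)) / 7 * L
  left <- data.frame(segment_id = c("l1", "l2", "l3", "l4"), side = "left",
                     start = lf[1:4], end = lf[2:5])
  # right spans measured base->apex from the right end of the curve
  rf <- cumsum(c(0, 2, 2, 2, 1)) / 7 * R
  right <- data.frame(segment_id = c("r1", "r2", "r3", "r4"), side = "right",
                      start = (L + R) - rf[2:5], end = (L + R) - rf[1:4])
  out <- rbind(left, right)
  structure(out, class = c("segment_partition", "data.frame"))
}

# resample a contour at fixed normalized arc-length positions s in [0, 1]
resample_contour <- function(contour, s) {
  total <- contour$arc[length(contour$arc)]
  tgt <- s * total
  ri <- stats::approx(contour$arc, contour$points[, 1], xout = tgt, rule = 2)$y
  ci <- stats::approx(contour$arc, contour$points[, 2], xout = tgt, rule = 2)$y
  cbind(row = ri, col = ci)
}

#' Per-segment displacement curves
#'
#' For each frame t and segment, the displacement is the mean Euclidean
#' distance between arc-length-matched boundary points of frame t and frame
#' 1 within the segment's span (points correspond through normalized arc
#' length, so position s on frame t maps to s on the first frame). The
#' partition is taken on the first frame.
#'
#' @param contours List of per-frame `lv_contour`s (>= 2).
#' @param partition Optional `segment_partition`; defaults to
#'   `partition_segments(contours[[1]])`.
#' @param n_samples Number of resampled boundary points.
#' @return A `displacement_curves` object: `values` (segments x frames
#'   matrix, pixels, first column 0), `maxima`, and the partition used.
#' @export
displacement_curves <- function(contours, partition = NULL, n_samples = 257L) {
  if (length(contours) < 2L) stop("need at least two frames of contours")
  ref <- contours[[1]]
  if (is.null(partition)) partition <- partition_segments(ref)
  s <- seq(0, 1, length.out = n_samples)
  p0 <- resample_contour(ref, s)
  total0 <- ref$arc[length(ref$arc)]
  seg_idx <- lapply(seq_len(nrow(partition)), function(k) {
    which(s * total0 >= partition$start[k] - 1e-9 &
            s * total0 <= partition$end[k] + 1e-9)
  })
  values <- matrix(0, nrow(partition), length(contours))
  rownames(values) <- partition$segment_id
  for (t in seq_along(contours)) {
    if (t == 1L) next
    pt <- resample_contour(contours[[t]], s)
    # guard against an orientation flip of the traced contour
    pt_rev <- pt[nrow(pt):1, , drop = FALSE]
    if (mean(rowSums((pt_rev - p0)^2)) < mean(rowSums((pt - p0)^2))) pt <- pt_rev
    d <- sqrt(rowSums((pt - p0)^2))
    for (k in seq_len(nrow(partition))) values[k, t] <- mean(d[seg_idx[[k]]])
  }
  structure(list(values = values, maxima = apply(values, 1, max),
                 partition = partition),
            class = "displacement_curves")
}

#' Contours for every frame of a mask list
#'
#' @param masks List of per-frame binary wall masks.
#' @param ... Passed to [extract_contour()].
#' @return List of `lv_contour`s; extraction failures are reported with the
#'   frame index.
#' @export
contour_sequence <- function(masks, ...) {
  lapply(seq_along(masks), function(t) extract_contour(masks[[t]], frame_index = t, ...))
}

#' Write displacement curves as tidy CSV
#'
#' @param curves A `displacement_curves`.
#' @param path Output CSV path.
#' @param subject,view Identifier columns.
#' @return The path, invisibly.
#' @export
write_displacement_csv <- function(curves, path, subject = "subject", view = "A4C") {
  df <- data.frame(
    subject = subject, view = view,
    segment = rep(rownames(curves$values), ncol(curves$values)),
    frame = rep(seq_len(ncol(curves$values)), each = nrow(curves$values)),
    displacement = as.vector(curves$values)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
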