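# Synthetic beating-heart phantom: a U-shaped (open-top) bright LV wall on a
# dark background, contracting radially with a sinusoidal cycle, with
# per-segment motion amplitudes, multiplicative speckle and paired
# ground-truth wall masks. This is the fixture generator for every
# downstream stage.

#' Phantom myocardial segment identifiers
#'
#' Segment ids in contour order, from the basal right end of the wall,
#' through the apex, to the basal left end. The apical segments (`r4`,
#' `l4`) span 1/7 of their side's arc; the others span 2/7 each.
#'
#' @return Character vector of the 8 segment ids.
#' @export
phantom_segment_ids <- function() c("r1", "r2", "r3", "r4", "l4", "l3", "l2", "l1")

# fractions of the full wall arc covered by each segment, in contour order
phantom_segment_fractions <- function() c(2, 2, 2, 1, 1, 2, 2, 2) / 14

#' Phantom configuration
#'
#' Parameters of the synthetic echo phantom. Defaults mirror a typical
#' apical-view loop: 224 x 224 frames, around 25 frames per cardiac cycle,
#' three beats.
#'
#' @param image_size Frame side length in pixels.
#' @param frames_per_cycle Frames covering one cardiac cycle (>= 2).
#' @param n_cycles Number of cycles in the loop (>= 1).
#' @param wall_thickness Myocardial wall thickness in pixels.
#' @param base_amplitude Peak radial endocardial excursion in pixels for a
#'   normokinetic segment. Must be below `image_size / 4`.
#' @param hypokinetic_segments Indices (1..8, contour order, see
#'   [phantom_segment_ids()]) or segment ids whose motion amplitude is
#'   reduced.
#' @param hypokinesia_factor Multiplier in `[0, 1]` applied to the amplitude
#'   of hypokinetic segments (0 = akinetic).
#' @param segment_scales Optional per-segment amplitude multipliers (length
#'   8, contour order); lets phantoms carry distinct true amplitudes per
#'   segment. Default all 1.
#' @param speckle_sigma Severity (>= 0) of multiplicative Rayleigh speckle;
#'   0 disables noise.
#' @param seed Integer seed; all phantom randomness derives from it.
#' @param mid_radius Mid-wall radius in pixels (default `0.28 * image_size`).
#' @param center Wall centre as `c(row, col)` (default slightly below the
#'   frame centre).
#' @param rotation Rotation of the wall opening away from "up", radians.
#' @param opening_angle Angular width of the open top, degrees.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 224L, frames_per_cycle = 25L,
                           n_cycles = 3L, wall_thickness = 12,
                           base_amplitude = 8,
                           hypokinetic_segments = integer(),
                           hypokinesia_factor = 1,
                           segment_scales = rep(1, 8),
                           speckle_sigma = 0.25, seed = 1L,
                           mid_radius = NULL, center = NULL, rotation = 0,
                           opening_angle = 60) {
  cfg <- list(
    image_size = as.integer(image_size), frames_per_cycle = as.integer(frames_per_cycle),
    n_cycles = as.integer(n_cycles), wall_thickness = wall_thickness,
    base_amplitude = base_amplitude,
    hypokinetic_segments = phantom_resolve_segments(hypokinetic_segments),
    hypokinesia_factor = hypokinesia_factor,
    segment_scales = segment_scales, speckle_sigma = speckle_sigma,
    seed = as.integer(seed),
    mid_radius = if (is.null(mid_radius)) 0.28 * image_size else mid_radius,
    center = if (is.null(center)) c(0.53, 0.5) * image_size else center,
    rotation = rotation, opening_angle = opening_angle
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

phantom_resolve_segments <- function(segs) {
  if (length(segs) == 0L) return(integer())
  ids <- phantom_segment_ids()
  if (is.character(segs)) {
    idx <- match(segs, ids)
    if (anyNA(idx)) stop_config("hypokinetic_segments", "contains unknown segment ids")
    return(sort(idx))
  }
  sort(as.integer(segs))
}

validate_phantom_config <- function(cfg) {
  if (!is_scalar_number(cfg$image_size) || cfg$image_size < 16) {
    stop_config("image_size", "must be a number >= 16")
  }
  if (!is_scalar_number(cfg$frames_per_cycle) || cfg$frames_per_cycle < 2) {
    stop_config("frames_per_cycle", "must be >= 2")
  }
  if (!is_scalar_number(cfg$n_cycles) || cfg$n_cycles < 1) {
    stop_config("n_cycles", "must be >= 1")
  }
  if (!is_scalar_number(cfg$hypokinesia_factor) || cfg$hypokinesia_factor < 0 ||
      cfg$hypokinesia_factor > 1) {
    stop_config("hypokinesia_factor", "must lie in [0, 1]")
  }
  if (!is_scalar_number(cfg$base_amplitude) || cfg$base_amplitude < 0 ||
      cfg$base_amplitude >= cfg$image_size / 4) {
    stop_config("base_amplitude", "must lie in [0, image_size / 4)")
  }
  if (!is_scalar_number(cfg$wall_thickness) || cfg$wall_thickness < 2) {
    stop_config("wall_thickness", "must be >= 2 pixels")
  }
  if (!is_scalar_number(cfg$speckle_sigma) || cfg$speckle_sigma < 0) {
    stop_config("speckle_sigma", "must be >= 0")
  }
  if (length(cfg$segment_scales) != 8L || any(!is.finite(cfg$segment_scales)) ||
      any(cfg$segment_scales < 0)) {
    stop_config("segment_scales", "must be 8 non-negative numbers")
  }
  if (length(cfg$hypokinetic_segments) > 0 &&
      (min(cfg$hypokinetic_segments) < 1 || max(cfg$hypokinetic_segments) > 8)) {
    stop_config("hypokinetic_segments", "indices must lie in 1..8")
  }
  if (!is_scalar_number(cfg$opening_angle) || cfg$opening_angle <= 0 ||
      cfg$opening_angle >= 180) {
    stop_config("opening_angle", "must lie in (0, 180) degrees")
  }
  invisible(cfg)
}

# Effective peak amplitude per segment (pixels): base x per-segment scale,
# further scaled by the hypokinesia factor on affected segments.
phantom_segment_amplitudes <- function(cfg) {
  amp <- cfg$base_amplitude * cfg$segment_scales
  amp[cfg$hypokinetic_segments] <- amp[cfg$hypokinetic_segments] * cfg$hypokinesia_factor
  names(amp) <- phantom_segment_ids()
  amp
}

# Smooth amplitude profile over the wall-arc coordinate psi in [0, 1]
# (0 = basal right end, 1 = basal left end): cosine interpolation between
# segment midpoints, so motion varies smoothly across segment boundaries.
phantom_amplitude_profile <- function(cfg, psi) {
  amp <- phantom_segment_amplitudes(cfg)
  frac <- phantom_segment_fractions()
  edges <- c(0, cumsum(frac))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  out <- numeric(length(psi))
  out[psi <= mids[1]] <- amp[1]
  out[psi >= mids[8]] <- amp[8]
  for (s in seq_len(7)) {
    in_span <- psi > mids[s] & psi < mids[s + 1]
    if (any(in_span)) {
      tau <- (psi[in_span] - mids[s]) / (mids[s + 1] - mids[s])
      out[in_span] <- amp[s] + (amp[s + 1] - amp[s]) * (1 - cos(pi * tau)) / 2
    }
  }
  out
}

# Per-frame fractional contraction: 0 at frame 1 (end-diastole), 1 at
# mid-cycle (end-systole), sinusoidal with period frames_per_cycle.
phantom_phase <- function(cfg, t) {
  (1 - cos(2 * pi * (t - 1) / cfg$frames_per_cycle)) / 2
}

# geometry fields shared by frame rendering and the mask oracle
phantom_polar_fields <- function(cfg) {
  S <- cfg$image_size
  cy <- cfg$center[1]
  cx <- cfg$center[2]
  dy <- matrix(seq_len(S) - cy, S, S)
  dx <- matrix(seq_len(S) - cx, S, S, byrow = TRUE)
  rr <- sqrt(dx^2 + dy^2)
  # angle clockwise from "up", rotated; mapped to [0, 2*pi)
  ang <- (atan2(dx, -dy) - cfg$rotation) %% (2 * pi)
  list(rr = rr, ang = ang)
}

phantom_render_frame <- function(cfg, polar, t, noiseless = FALSE) {
  a0 <- cfg$opening_angle * pi / 180 / 2
  span <- 2 * pi - 2 * a0
  inside <- polar$ang >= a0 & polar$ang <= 2 * pi - a0
  psi <- pmin(pmax((polar$ang - a0) / span, 0), 1)

  disp <- phantom_amplitude_profile(cfg, psi) * phantom_phase(cfg, t)
  r_in <- cfg$mid_radius - cfg$wall_thickness / 2 - disp
  r_out <- r_in + cfg$wall_thickness

  bg <- 0.05
  wall <- 0.85
  cover <- pmin(pmax(pmin(polar$rr - r_in + 0.5, r_out - polar$rr + 0.5), 0), 1)
  cover[!inside] <- 0
  frame <- bg + (wall - bg) * cover
  mask <- matrix(0L, cfg$image_size, cfg$image_size)
  mask[inside & polar$rr >= r_in & polar$rr <= r_out] <- 1L

  if (!noiseless && cfg$speckle_sigma > 0) {
    # multiplicative unit-mean Rayleigh speckle
    ray <- sqrt(-2 * log(pmax(runif(length(frame)), 1e-12))) / sqrt(pi / 2)
    frame <- frame * (1 + cfg$speckle_sigma * (matrix(ray, nrow(frame)) - 1))
    frame <- pmin(pmax(frame, 0), 1)
  }
  list(frame = frame, mask = mask)
}

#' Generate one phantom echo loop with ground truth
#'
#' Renders a full loop of `frames_per_cycle * n_cycles` frames. The wall
#' radius oscillates sinusoidally with period `frames_per_cycle`; in
#' hypokinetic segments the radial excursion is scaled by
#' `hypokinesia_factor`. Deterministic for a fixed config seed.
#'
#' @param config A [phantom_config()].
#' @param view `"A2C"` or `"A4C"` tag carried by the sequence.
#' @param subject_id Identifier stored on the sequence.
#' @param label Optional label override; by default `"RWMA"` when any
#'   segment is hypokinetic and `"non-RWMA"` otherwise.
#' @return A list with `sequence` (an `echo_sequence`: frames in `[0, 1]`,
#'   view, subject id, label) and `truth` (a `phantom_truth`: per-frame
#'   binary wall masks, per-segment true peak displacements in pixels, and
#'   per-segment normal/hypokinetic flags).
#' @export
generate_sequence <- function(config, view = c("A4C", "A2C"),
                              subject_id = "phantom", label = NULL) {
  view <- match.arg(view)
  validate_phantom_config(config)
  n_frames <- config$frames_per_cycle * config$n_cycles
  polar <- phantom_polar_fields(config)

  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  with_seed(config$seed, {
    for (t in seq_len(n_frames)) {
      fr <- phantom_render_frame(config, polar, t)
      frames[[t]] <- fr$frame
      masks[[t]] <- fr$mask
    }
  })

  if (is.null(label)) {
    label <- if (length(config$hypokinetic_segments) > 0) "RWMA" else "non-RWMA"
  }
  seq_obj <- structure(
    list(frames = frames, view = view, subject_id = subject_id, label = label),
    class = "echo_sequence"
  )

  amp <- phantom_segment_amplitudes(config)
  seg_labels <- rep("normal", 8)
  seg_labels[config$hypokinetic_segments] <- "hypokinetic"
  names(seg_labels) <- phantom_segment_ids()
  r_in0 <- config$mid_radius - config$wall_thickness / 2
  truth <- structure(
    list(
      wall_masks = masks,
      segment_amplitudes = amp,
      segment_labels = seg_labels,
      geometry = list(
        center = config$center, inner_radius = r_in0,
        thickness = config$wall_thickness,
        opening_angle = config$opening_angle, rotation = config$rotation,
        arc_span = 2 * pi - config$opening_angle * pi / 180,
        inner_arc_length = (2 * pi - config$opening_angle * pi / 180) * r_in0
      )
    ),
    class = "phantom_truth"
  )
  list(sequence = seq_obj, truth = truth)
}

#' @export
print.echo_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<echo_sequence> %s view %s, %d frames of %dx%d, label %s\n",
              x$subject_id, x$view, length(x$frames), d[1], d[2], x$label))
  invisible(x)
}

#' Generate a multi-view phantom cohort plan
#'
#' Builds a cohort of paired A2C/A4C phantom subjects. RWMA subjects carry
#' 1-3 hypokinetic segments (the same anatomical segments in both views);
#' normal subjects carry none. Per-subject geometry (radius, thickness,
#' amplitude, centre, rotation) is jittered reproducibly from the cohort
#' seed. Sequences are materialised lazily with [phantom_realize()] to keep
#' memory bounded for large cohorts.
#'
#' @param n_rwma,n_normal Subject counts per class.
#' @param config Template [phantom_config()]; per-subject parameters jitter
#'   around it.
#' @param seed Cohort seed.
#' @return A `phantom_cohort`: list of subject entries (id, label, per-view
#'   configs) plus the template.
#' @export
generate_cohort <- function(n_rwma, n_normal, config = phantom_config(), seed = 1L) {
  stopifnot(n_rwma >= 0, n_normal >= 0)
  validate_phantom_config(config)
  labels <- c(rep("RWMA", n_rwma), rep("non-RWMA", n_normal))
  subjects <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sid <- sprintf("S%03d", i)
    subjects[[i]] <- with_seed(derive_seed(seed, sid), {
      hypo <- if (labels[i] == "RWMA") sample(1:8, sample(1:3, 1)) else integer()
      views <- lapply(c(A2C = "A2C", A4C = "A4C"), function(v) {
        cfg <- config
        cfg$mid_radius <- config$mid_radius * runif(1, 0.93, 1.07)
        cfg$wall_thickness <- config$wall_thickness * runif(1, 0.9, 1.1)
        cfg$base_amplitude <- config$base_amplitude * runif(1, 0.9, 1.1)
        cfg$center <- config$center + runif(2, -0.02, 0.02) * config$image_size
        cfg$rotation <- config$rotation + runif(1, -0.08, 0.08)
        cfg$hypokinetic_segments <- hypo
        cfg$seed <- derive_seed(seed, paste0(sid, v))
        validate_phantom_config(cfg)
        cfg
      })
      list(subject_id = sid, label = labels[i], configs = views,
           hypokinetic_segments = hypo)
    })
  }
  structure(list(subjects = subjects, template = config, seed = seed),
            class = "phantom_cohort")
}

#' Materialise both views of one cohort subject
#'
#' @param subject One element of `phantom_cohort$subjects`.
#' @return List with `A2C` and `A4C`, each a `list(sequence, truth)` as
#'   returned by [generate_sequence()].
#' @export
phantom_realize <- function(subject) {
  lapply(c(A2C = "A2C", A4C = "A4C"), function(v) {
    generate_sequence(subject$configs[[v]], view = v,
                      subject_id = subject$subject_id, label = subject$label)
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, character(1), "label")
  cat(sprintf("<phantom_cohort> %d subjects (%d RWMA / %d non-RWMA), %dx%d frames\n",
              length(labs), sum(labs == "RWMA"), sum(labs == "non-RWMA"),
              x$template$image_size, x$template$image_size))
  invisible(x)
}
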