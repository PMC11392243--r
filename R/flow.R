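# Dense optical flow between consecutive masked echo frames, and the 8-bit
# encoding of the horizontal/vertical flow components used downstream by
# the temporal network.

#' Dense optical flow parameters
#'
#' Pyramidal polynomial-expansion (Farneback-style) flow settings.
#'
#' @param levels Pyramid levels.
#' @param winsize Averaging window (odd) for the flow normal equations.
#' @param iters Refinement iterations per level.
#' @param poly_n Half-width of the polynomial-expansion window.
#' @param poly_sigma Gaussian applicability sigma for the expansion.
#' @return A `flow_params` list.
#' @export
flow_params <- function(levels = 3L, winsize = 15L, iters = 3L, poly_n = 5L,
                        poly_sigma = 1.1) {
  structure(list(levels = as.integer(levels), winsize = as.integer(winsize),
                 iters = as.integer(iters), poly_n = as.integer(poly_n),
                 poly_sigma = poly_sigma),
            class = "flow_params")
}

#' Dense optical flow between two frames
#'
#' Estimates the per-pixel displacement field taking `frame_t` onto
#' `frame_t1` under brightness constancy and local smoothness. Coordinate
#' convention: `u` is horizontal displacement, positive rightward
#' (increasing column); `v` is vertical, positive downward (increasing
#' row); origin at the top-left.
#'
#' @param frame_t,frame_t1 Same-shape grayscale matrices.
#' @param params A [flow_params()].
#' @param t Index of the earlier frame, stored on the result.
#' @return An `ef_flow_field` with matrices `u`, `v` and index `t`.
#' @export
dense_flow <- function(frame_t, frame_t1, params = flow_params(), t = 1L) {
  if (!all(dim(frame_t) == dim(frame_t1))) stop("frame shapes differ")
  arr <- array(c(frame_t, frame_t1), c(dim(frame_t), 2L))
  f <- flow_stack_cpp(arr, params$levels, params$winsize, params$iters,
                      params$poly_n, params$poly_sigma)
  structure(list(u = f[, , 1, 1], v = f[, , 2, 1], t = t), class = "ef_flow_field")
}

#' Optical flow over a whole sequence
#'
#' @param sequence An `echo_sequence` (typically background-masked) or a
#'   list of frames.
#' @param params A [flow_params()].
#' @return List of `n_frames - 1` `ef_flow_field`s, ordered.
#' @export
flow_sequence <- function(sequence, params = flow_params()) {
  frames <- if (inherits(sequence, "echo_sequence")) sequence$frames else sequence
  if (length(frames) < 2L) stop("need at least two frames for flow")
  arr <- frames_to_array(frames)
  f <- flow_stack_cpp(arr, params$levels, params$winsize, params$iters,
                      params$poly_n, params$poly_sigma)
  lapply(seq_len(dim(f)[4]), function(t) {
    structure(list(u = f[, , 1, t], v = f[, , 2, t], t = t),
              class = "ef_flow_field")
  })
}

#' Encode a flow field as 8-bit frame pair
#'
#' Clips both components to `[-clip, clip]` and maps them affinely onto
#' 0..255, with zero motion at 128. The quantisation error of a decode is
#' at most `clip / 255`.
#'
#' @param field An `ef_flow_field`.
#' @param clip Maximum encoded magnitude (pixels/frame), > 0.
#' @return An `ef_flow_encoding` with integer matrices `x_frame`,
#'   `y_frame` and the affine `scale`/`offset` used.
#' @export
encode_flow_frames <- function(field, clip = 20) {
  if (!is_scalar_number(clip) || clip <= 0) stop("clip must be > 0")
  enc1 <- function(m) {
    m <- pmin(pmax(m, -clip), clip)
    matrix(as.integer(round((m + clip) / (2 * clip) * 255)), nrow(m))
  }
  structure(list(x_frame = enc1(field$u), y_frame = enc1(field$v),
                 scale = 2 * clip / 255, offset = -clip, t = field$t),
            class = "ef_flow_encoding")
}

#' Decode an 8-bit flow encoding back to a flow field
#'
#' @param enc An `ef_flow_encoding`.
#' @return An `ef_flow_field` (values within quantisation error of the
#'   clipped original).
#' @export
decode_flow_frames <- function(enc) {
  dec1 <- function(m) m * enc$scale + enc$offset
  structure(list(u = dec1(enc$x_frame), v = dec1(enc$y_frame), t = enc$t),
            class = "ef_flow_field")
}

#' Encode every field of a flow sequence
#'
#' @param fields List of `ef_flow_field`s.
#' @param clip Encoding clip, see [encode_flow_frames()].
#' @return List of `ef_flow_encoding`s.
#' @export
encode_flow_sequence <- function(fields, clip = 20) {
  lapply(fields, encode_flow_frames, clip = clip)
}
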