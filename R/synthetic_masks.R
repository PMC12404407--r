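# Procedural generation of IDC-like region masks: star-shaped blobs with
# smooth sinusoidal boundary perturbations, emulating the character of a
# segmented dense-tissue region (stroma + IDC surrounded by adipose) without
# reproducing any particular specimen.

#' Generate a dense-tissue mask and a nested IDC mask
#'
#' Both regions are star-shaped blobs: `r(theta) = r0 * (1 + sum_k a_k *
#' cos(k * theta + phi_k))` with harmonics k = 2..6 and amplitudes drawn
#' uniformly (dense blob up to 0.18, IDC blob up to 0.25), giving lobed
#' outlines with boundary features down to the 100 um scale at typical
#' pitches. The IDC blob is placed inside the dense blob and clipped to it.
#'
#' @param shape Length-2 mask shape (nx, ny) in pixels.
#' @param pitch_um Lateral pitch (dx, dy) in micrometres.
#' @param seed Integer seed.
#' @param dense_radius_frac Dense blob base radius as a fraction of the
#'   half-extent (default 0.55).
#' @param idc_radius_frac IDC blob base radius as a fraction of the dense
#'   radius (default 0.4).
#' @return List with logical matrices `dense` and `idc` (idc subset of
#'   dense).
#' @export
make_synthetic_masks <- function(shape = c(96, 96), pitch_um = c(40, 40),
                                 seed = 1, dense_radius_frac = 0.55,
                                 idc_radius_frac = 0.4) {
  set.seed(as.integer(seed))
  cx <- (shape[1] + 1) / 2
  cy <- (shape[2] + 1) / 2
  half <- min(shape) / 2
  dense <- star_blob(shape, c(cx, cy), half * dense_radius_frac,
                     amp_max = 0.18)
  # IDC blob offset from centre, inside the dense blob
  off <- stats::runif(2, -0.15, 0.15) * half
  idc <- star_blob(shape, c(cx + off[1], cy + off[2]),
                   half * dense_radius_frac * idc_radius_frac,
                   amp_max = 0.25)
  idc <- idc & dense
  list(dense = dense, idc = idc)
}

star_blob <- function(shape, centre, r0, amp_max, harmonics = 2:6) {
  a <- stats::runif(length(harmonics), 0, amp_max / sqrt(length(harmonics)))
  phi <- stats::runif(length(harmonics), 0, 2 * pi)
  x <- matrix(seq_len(shape[1]), shape[1], shape[2]) - centre[1]
  y <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) -
    centre[2]
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  rb <- r0 * (1 + Reduce(`+`, lapply(seq_along(harmonics), function(i)
    a[i] * cos(harmonics[i] * th + phi[i]))))
  r <= rb
}
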