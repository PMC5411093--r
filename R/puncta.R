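#' Expected punctum size
#'
#' The physical extent a marker's fluorescent punctum is expected to have,
#' given in micrometres: an in-plane extent (isotropic in x/y) and an axial
#' extent. Published queries use in-plane sizes around 0.2 um and axial sizes
#' of 0.07-0.21 um (one to three 70 nm sections).
#'
#' @param xy_um Expected in-plane extent in micrometres.
#' @param z_um Expected axial extent in micrometres.
#' @return An object of class `punctum_spec`.
#' @export
punctum_spec <- function(xy_um, z_um) {
  if (!is.numeric(xy_um) || length(xy_um) != 1L || xy_um <= 0)
    stop("'xy_um' must be a single positive number", call. = FALSE)
  if (!is.numeric(z_um) || length(z_um) != 1L || z_um <= 0)
    stop("'z_um' must be a single positive number", call. = FALSE)
  structure(list(xy_um = as.numeric(xy_um), z_um = as.numeric(z_um)),
            class = "punctum_spec")
}

#' @export
print.punctum_spec <- function(x, ...) {
  cat(sprintf("punctum: %g x %g um in-plane, %g um axial\n",
              x$xy_um, x$xy_um, x$z_um))
  invisible(x)
}

#' Convert a punctum size to window geometry at a given resolution
#'
#' The in-plane neighbourhood used by the punctum product is a symmetric
#' square window of odd full width `2W + 1`; a size that maps to an even
#' pixel count rounds up to the next odd width (so 0.2 um at 100 nm/px gives
#' 2 px and hence a 3 x 3 window, the smallest symmetric window covering it).
#' The axial extent maps to the number of slices the punctum is expected to
#' span; the slice offsets compared by the span factor split that extent
#' symmetrically, with the extra comparison placed before the slice when the
#' count is even.
#'
#' @param spec A [punctum_spec()].
#' @param resolution A [voxel_resolution()].
#' @return An object of class `window_geometry` with fields `half_width_px`,
#'   `n_slices`, `j_before`, `j_after`.
#' @export
spec_to_geometry <- function(spec, resolution) {
  stopifnot(inherits(spec, "punctum_spec"),
            inherits(resolution, "voxel_resolution"))
  n_px <- max(1L, as.integer(round(spec$xy_um * 1000 / resolution$xy_nm)))
  half_width_px <- as.integer(max(0, ceiling((n_px - 1) / 2)))
  n_slices <- max(1L, as.integer(round(spec$z_um * 1000 / resolution$z_nm)))
  structure(list(half_width_px = half_width_px,
                 n_slices = n_slices,
                 j_before = as.integer(ceiling((n_slices - 1) / 2)),
                 j_after = as.integer(floor((n_slices - 1) / 2))),
            class = "window_geometry")
}

#' @export
print.window_geometry <- function(x, ...) {
  cat(sprintf("window: %d x %d px in-plane, %d slice%s (compare %d before / %d after)\n",
              2 * x$half_width_px + 1, 2 * x$half_width_px + 1, x$n_slices,
              if (x$n_slices == 1) "" else "s", x$j_before, x$j_after))
  invisible(x)
}

# Probability floor applied before taking logarithms; far below any
# meaningful probability but keeps log() finite.
PROB_FLOOR <- 1e-12

# Windowed sum over a (2w+1)x(2w+1) neighbourhood with replicate (nearest)
# padding, via a summed-area table. Replicate padding equals clamping each
# window index to the matrix bounds.
box_sum <- function(m, w) {
  if (w == 0L) return(m)
  ny <- nrow(m); nx <- ncol(m)
  p <- m[c(rep(1L, w), seq_len(ny), rep(ny, w)),
         c(rep(1L, w), seq_len(nx), rep(nx, w)), drop = FALSE]
  S <- apply(p, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  S <- rbind(0, cbind(0, S))
  k <- 2L * w + 1L
  S[seq_len(ny) + k, seq_len(nx) + k, drop = FALSE] -
    S[seq_len(ny) + k, seq_len(nx), drop = FALSE] -
    S[seq_len(ny), seq_len(nx) + k, drop = FALSE] +
    S[seq_len(ny), seq_len(nx), drop = FALSE]
}

#' 2D punctum probability (windowed probability product)
#'
#' A single bright voxel usually reflects noise; photons from a genuine
#' punctum arrive across a small neighbourhood. Each voxel's foreground
#' probability is therefore multiplied by that of all its in-plane neighbours
#' in a `(2W+1) x (2W+1)` window, computed slice by slice. The product is
#' evaluated as a box filter on the logarithm of the probability map (with
#' probabilities clamped to `[1e-12, 1]` before the log), which is exactly
#' equivalent and runs in constant time per voxel. Borders use replicate
#' (nearest) padding, so edge voxels are not spuriously suppressed.
#'
#' The result can never exceed the smallest single-voxel probability in the
#' window, and a window containing a (clamped) zero is annihilated.
#'
#' @param pf Foreground [probability_volume()] (or bare 3D array).
#' @param geom A [window_geometry()] (only `half_width_px` is used here).
#' @return Punctum probabilities, same type and shape as `pf`.
#' @export
puncta_2d <- function(pf, geom) {
  stopifnot(inherits(geom, "window_geometry"))
  arr <- vol_data(pf)
  L <- log(pmin(pmax(arr, PROB_FLOOR), 1))
  out <- array(0, dim(arr))
  for (k in seq_len(dim(arr)[3L])) {
    out[, , k] <- exp(box_sum(L[, , k], geom$half_width_px))
  }
  out[out > 1] <- 1   # guard against rounding just above 1
  wrap_like(pf, out, name = "p_P")
}

#' Slice-span attenuation factor
#'
#' Puncta that span several physical sections are more likely to be synaptic
#' than single-section flashes. For each voxel the 2D punctum probability is
#' compared with the same in-plane position in the `j_before` slices before
#' and `j_after` slices after; the factor
#' \eqn{f = \exp(-\sum_j (p_P(z) - p_P(z+j))^2)} is 1 when the punctum
#' probability is maintained across the compared slices and decays towards
#' `exp(-n)` as the compared slices disagree. Missing neighbours at the top
#' and bottom of the stack are treated as copies of the edge slice
#' (replicate padding), contributing zero difference. A single-slice query
#' (`n_slices = 1`) compares nothing and returns 1 everywhere.
#'
#' @param pp 2D punctum [probability_volume()] (or bare 3D array).
#' @param geom A [window_geometry()] providing `j_before`/`j_after`.
#' @return Attenuation factors in (0, 1], same type and shape as `pp`.
#' @export
slice_span_factor <- function(pp, geom) {
  stopifnot(inherits(geom, "window_geometry"))
  arr <- vol_data(pp)
  nz <- dim(arr)[3L]
  ssd <- array(0, dim(arr))
  offs <- c(seq_len(geom$j_before) * -1L, seq_len(geom$j_after))
  for (j in offs) {
    zidx <- pmin(pmax(seq_len(nz) + j, 1L), nz)
    ssd <- ssd + (arr - arr[, , zidx, drop = FALSE])^2
  }
  wrap_like(pp, exp(-ssd), name = "f")
}

#' 3D punctum probability
#'
#' Multiplies the 2D punctum probability map by the slice-span factor,
#' yielding a map in which only puncta that actually span the required number
#' of sections retain high probability.
#'
#' @param pp 2D punctum probabilities.
#' @param f Slice-span factors from [slice_span_factor()].
#' @return Elementwise product, same type and shape as `pp`; never exceeds
#'   `pp`.
#' @export
puncta_3d <- function(pp, f) {
  a <- vol_data(pp); b <- vol_data(f)
  if (!identical(dim(a), dim(b)))
    stop("'pp' and 'f' differ in shape", call. = FALSE)
  wrap_like(pp, a * b, name = "p_3DP")
}
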