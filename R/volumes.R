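#' Voxel resolution of an imaging volume
#'
#' Array-tomography volumes have an isotropic in-plane pixel pitch set by the
#' camera/optics and an axial pitch set by the physical section thickness
#' (typically 70 nm, i.e. well below the light-microscopic diffraction limit).
#'
#' @param xy_nm Lateral (in-plane) voxel pitch in nanometres.
#' @param z_nm Slice (section) thickness in nanometres.
#' @return An object of class `voxel_resolution`.
#' @examples
#' voxel_resolution(100, 70)
#' @export
voxel_resolution <- function(xy_nm, z_nm) {
  if (!is.numeric(xy_nm) || length(xy_nm) != 1L || !is.finite(xy_nm) || xy_nm <= 0)
    stop("'xy_nm' must be a single positive number", call. = FALSE)
  if (!is.numeric(z_nm) || length(z_nm) != 1L || !is.finite(z_nm) || z_nm <= 0)
    stop("'z_nm' must be a single positive number", call. = FALSE)
  structure(list(xy_nm = as.numeric(xy_nm), z_nm = as.numeric(z_nm)),
            class = "voxel_resolution")
}

#' @export
print.voxel_resolution <- function(x, ...) {
  cat(sprintf("voxel resolution: %g x %g nm in-plane, %g nm per slice\n",
              x$xy_nm, x$xy_nm, x$z_nm))
  invisible(x)
}

#' @export
format.voxel_resolution <- function(x, ...) {
  sprintf("%g nm xy / %g nm z", x$xy_nm, x$z_nm)
}

same_resolution <- function(a, b, tol = 1e-9) {
  abs(a$xy_nm - b$xy_nm) <= tol && abs(a$z_nm - b$z_nm) <= tol
}

#' A single-marker intensity volume
#'
#' One antibody channel of a co-registered multi-channel stack. The data array
#' is indexed `[row, column, slice]` = (y, x, z); slice `k` is the k-th
#' physical section.
#'
#' @param name Marker identifier, e.g. `"synapsin"` or `"PSD-95"`. Channel
#'   names are case-sensitive exact keys: they must match the query entries
#'   verbatim (this avoids silently confusing, say, VGluT1 with VGluT2).
#' @param data 3D numeric array of non-negative intensities, dim `(ny, nx, nz)`.
#' @param resolution A [voxel_resolution()].
#' @return An object of class `channel_volume`.
#' @export
channel_volume <- function(name, data, resolution) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("channel 'name' must be a non-empty string", call. = FALSE)
  data <- as_volume_array(data, what = paste0("channel '", name, "'"))
  if (any(data < 0))
    stop("channel '", name, "': negative intensities are not allowed",
         call. = FALSE)
  stopifnot(inherits(resolution, "voxel_resolution"))
  structure(list(name = name, data = data, resolution = resolution),
            class = "channel_volume")
}

#' A per-voxel probability volume
#'
#' Same-shape companion of a [channel_volume()] holding per-voxel
#' probabilities in \[0, 1\] (foreground, punctum, or synapse probabilities,
#' depending on the pipeline stage).
#'
#' @param data 3D numeric array with all values in \[0, 1\].
#' @param resolution A [voxel_resolution()].
#' @param name Optional label describing what probability the map encodes.
#' @return An object of class `probability_volume`.
#' @export
probability_volume <- function(data, resolution, name = NULL) {
  data <- as_volume_array(data, what = "probability volume")
  if (any(data < 0) || any(data > 1))
    stop("probability values must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(resolution, "voxel_resolution"))
  structure(list(name = name, data = data, resolution = resolution),
            class = "probability_volume")
}

as_volume_array <- function(data, what = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop(what, ": expected 3 dimensions, got ",
         if (is.array(data)) length(dim(data)) else "a non-array", call. = FALSE)
  if (!is.numeric(data)) stop(what, ": data must be numeric", call. = FALSE)
  if (any(!is.finite(data))) stop(what, ": non-finite values", call. = FALSE)
  storage.mode(data) <- "double"
  data
}

# Pull the bare array out of a channel/probability volume or pass arrays through.
vol_data <- function(x) {
  if (is.array(x)) return(x)
  if (is.list(x) && !is.null(x$data)) return(x$data)
  stop("expected a volume object or a 3D array", call. = FALSE)
}

vol_resolution <- function(x, default = NULL) {
  if (is.list(x) && inherits(x$resolution, "voxel_resolution")) return(x$resolution)
  default
}

# Return y of the same flavour as x (probability_volume in -> out).
wrap_like <- function(x, data, name = NULL) {
  if (is.array(x)) return(data)
  probability_volume(data, x$resolution, name = name %||% x$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.channel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("channel '%s': %d x %d pixels, %d slice%s (%s)\n",
              x$name, d[1], d[2], d[3], if (d[3] == 1) "" else "s",
              format(x$resolution)))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.probability_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("probability volume%s: %d x %d pixels, %d slice%s (%s)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              d[1], d[2], d[3], if (d[3] == 1) "" else "s",
              format(x$resolution)))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.channel_volume <- function(x) dim(x$data)

#' @export
dim.probability_volume <- function(x) dim(x$data)

#' @export
as.array.channel_volume <- function(x, ...) x$data

#' @export
as.array.probability_volume <- function(x, ...) x$data

#' Read one antibody channel from a multi-page TIFF
#'
#' Each TIFF page is one physical section. Integer TIFFs (8/16 bit) are read
#' losslessly as integers; 32-bit float TIFFs (as written by [write_volume()]
#' for probability maps) are read as-is.
#'
#' @param path Path to a multi-page TIFF file.
#' @param name Marker identifier for the resulting channel.
#' @param resolution A [voxel_resolution()].
#' @return A [channel_volume()].
#' @export
read_channel <- function(path, name, resolution) {
  arr <- read_tiff_stack(path, what = paste0("channel '", name, "'"))
  channel_volume(name, arr, resolution)
}

#' Read a probability map written by [write_volume()]
#'
#' @inheritParams read_channel
#' @param name Optional label for the map.
#' @return A [probability_volume()].
#' @export
read_probability_map <- function(path, resolution, name = NULL) {
  arr <- read_tiff_stack(path, what = "probability map")
  probability_volume(arr, resolution, name = name)
}

read_tiff_stack <- function(path, what = "volume") {
  if (!file.exists(path)) stop(what, ": file not found: ", path, call. = FALSE)
  info <- tiff::readTIFF(path, payload = FALSE)
  # 32-bit pages are IEEE float; 'as.is' only applies to integer samples
  # (and corrupts float reads), so branch on the declared bit depth.
  is_float <- any(info$bits.per.sample == 32)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1L]])
  if (length(d2) != 2L)
    stop(what, ": expected single-sample (grayscale) pages, got ",
         length(d2), "-dimensional pages", call. = FALSE)
  arr <- array(0, c(d2[1L], d2[2L], length(pages)))
  for (k in seq_along(pages)) {
    pk <- pages[[k]]
    if (!identical(dim(pk), d2))
      stop(what, ": page ", k, " has a different shape", call. = FALSE)
    arr[, , k] <- pk
  }
  arr
}

#' Write a volume to a multi-page TIFF
#'
#' Probability volumes are written as 32-bit float pages (lossless at float32
#' precision); channel volumes are written as 16-bit integer pages, which
#' round-trips integer intensities in \[0, 65535\] exactly.
#'
#' @param vol A [channel_volume()] or [probability_volume()].
#' @param path Output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  arr <- vol_data(vol)
  nz <- dim(arr)[3L]
  if (inherits(vol, "probability_volume")) {
    pages <- lapply(seq_len(nz), function(k) arr[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    if (any(arr > 65535))
      stop("intensities exceed the 16-bit range; rescale before writing",
           call. = FALSE)
    pages <- lapply(seq_len(nz), function(k) round(arr[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Check that channels share one voxel grid
#'
#' Synapse queries compare pre- and postsynaptic markers voxel-by-voxel, which
#' presumes all channels live on one co-registered grid. This check fails
#' loudly on any shape or resolution mismatch.
#'
#' @param channels List of [channel_volume()] objects (at least one).
#' @return Invisibly `TRUE` if all channels match.
#' @export
check_coregistered <- function(channels) {
  if (length(channels) < 1L) stop("need at least one channel", call. = FALSE)
  ref <- channels[[1L]]
  for (ch in channels[-1L]) {
    if (!identical(dim(ch$data), dim(ref$data)))
      stop(sprintf("channels '%s' (%s) and '%s' (%s) differ in shape",
                   ref$name, paste(dim(ref$data), collapse = "x"),
                   ch$name, paste(dim(ch$data), collapse = "x")), call. = FALSE)
    if (!same_resolution(ch$resolution, ref$resolution))
      stop(sprintf("channels '%s' and '%s' differ in voxel resolution (%s vs %s)",
                   ref$name, ch$name, format(ref$resolution),
                   format(ch$resolution)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a channel manifest
#'
#' A manifest is a JSON file mapping channel names to TIFF paths and recording
#' the shared voxel resolution:
#' `{"xy_nm": 100, "z_nm": 70, "channels": {"synapsin": "synapsin.tif", ...}}`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest JSON.
#' @return Named list of [channel_volume()] objects.
#' @export
read_channel_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(m$xy_nm) || is.null(m$z_nm) || is.null(m$channels))
    stop("manifest must contain xy_nm, z_nm and channels", call. = FALSE)
  res <- voxel_resolution(m$xy_nm, m$z_nm)
  paths <- unlist(m$channels)
  base <- dirname(normalizePath(path))
  out <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_channel(p, nm, res)
  })
  names(out) <- names(paths)
  check_coregistered(out)
  out
}

#' Write channels plus a manifest to a directory
#'
#' @param channels Named list of [channel_volume()] objects.
#' @param dir Output directory (created if absent).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_channel_manifest <- function(channels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  check_coregistered(channels)
  res <- channels[[1L]]$resolution
  files <- vapply(channels, function(ch) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", ch$name), ".tif")
    write_volume(ch, file.path(dir, fn))
    fn
  }, character(1))
  manifest <- list(xy_nm = res$xy_nm, z_nm = res$z_nm,
                   channels = as.list(files))
  mpath <- file.path(dir, "channels.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
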