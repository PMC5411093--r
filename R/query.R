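#' Define a synapse query
#'
#' A query is the user's molecular-morphological definition of a synapse
#' subtype: which presynaptic and postsynaptic markers must be present, and
#' how large their puncta are expected to be. The detector is unsupervised —
#' the query *is* the model.
#'
#' @param presynaptic Named list mapping presynaptic channel names to
#'   [punctum_spec()] objects (or `c(xy_um, z_um)` pairs).
#' @param postsynaptic Named list for postsynaptic channels, same format.
#' @param k_pre Grid subdivisions per axis for the presynaptic search
#'   (odd, default 3: presynaptic signal is looked for in a 3 x 3 x 3-cell
#'   grid around each postsynaptic voxel).
#' @param k_post Grid subdivisions for postsynaptic co-localization (odd,
#'   default 1: postsynaptic markers are expected to co-localize tightly, so
#'   their maps are combined voxelwise).
#' @param threshold Optional detection threshold in \[0, 1\] carried as
#'   query metadata (e.g. the published operating points 0.55/0.6 for
#'   excitatory and 0.7 for inhibitory queries).
#' @return An object of class `synapse_query`.
#' @examples
#' synapse_query(
#'   presynaptic  = list(synapsin  = punctum_spec(0.2, 0.21)),
#'   postsynaptic = list("PSD-95"  = punctum_spec(0.2, 0.21)))
#' @export
synapse_query <- function(presynaptic, postsynaptic, k_pre = 3L, k_post = 1L,
                          threshold = NULL) {
  presynaptic <- normalize_marker_list(presynaptic, "presynaptic")
  postsynaptic <- normalize_marker_list(postsynaptic, "postsynaptic")
  for (k in c(k_pre, k_post)) {
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k %% 2 != 1)
      stop("'k_pre' and 'k_post' must be odd integers >= 1", call. = FALSE)
  }
  if (!is.null(threshold) &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 1))
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  structure(list(presynaptic = presynaptic, postsynaptic = postsynaptic,
                 k_pre = as.integer(k_pre), k_post = as.integer(k_post),
                 threshold = threshold),
            class = "synapse_query")
}

normalize_marker_list <- function(x, side) {
  if (!is.list(x) || length(x) < 1L || is.null(names(x)) ||
      any(!nzchar(names(x))))
    stop("'", side, "' must be a non-empty named list", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate channel names in '", side, "'", call. = FALSE)
  lapply(x, function(s) {
    if (inherits(s, "punctum_spec")) s
    else if (is.numeric(s) && length(s) %in% c(2L, 3L))
      # accept (xy, z) or the published (x, y, z) triple with x = y
      punctum_spec(s[[1L]], s[[length(s)]])
    else stop("each ", side, " entry must be a punctum_spec or a numeric ",
              "size vector", call. = FALSE)
  })
}

#' @export
print.synapse_query <- function(x, ...) {
  cat("synapse query\n")
  fmt <- function(side) {
    for (nm in names(side)) {
      s <- side[[nm]]
      cat(sprintf("    %-12s %g x %g x %g um\n", nm, s$xy_um, s$xy_um, s$z_um))
    }
  }
  cat("  presynaptic (k =", x$k_pre, "):\n"); fmt(x$presynaptic)
  cat("  postsynaptic (k =", x$k_post, "):\n"); fmt(x$postsynaptic)
  if (!is.null(x$threshold)) cat("  suggested threshold:", x$threshold, "\n")
  invisible(x)
}

#' Read / write a synapse query as JSON
#'
#' Schema:
#' \preformatted{
#' {"presynaptic":  [{"channel": "synapsin", "size_um": [0.2, 0.2, 0.21]}],
#'  "postsynaptic": [{"channel": "PSD-95",   "size_um": [0.2, 0.2, 0.21]}],
#'  "k_pre": 3, "k_post": 1, "threshold": null}
#' }
#' `size_um` is the (x, y, z) punctum size; x and y must agree (in-plane
#' isotropy). Example files for the published excitatory and inhibitory query
#' sets ship under `system.file("extdata/queries", package = "synapsequery")`.
#'
#' @param path JSON file path.
#' @return For `read_query`, a [synapse_query()].
#' @export
read_query <- function(path) {
  if (!file.exists(path)) stop("query file not found: ", path, call. = FALSE)
  q <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  side <- function(entries, what) {
    if (is.null(entries) || length(entries) == 0)
      stop("query has no ", what, " entries", call. = FALSE)
    out <- lapply(entries, function(e) {
      sz <- as.numeric(unlist(e$size_um))
      punctum_spec(sz[1L], sz[length(sz)])
    })
    names(out) <- vapply(entries, function(e) as.character(e$channel),
                         character(1))
    out
  }
  synapse_query(presynaptic = side(q$presynaptic, "presynaptic"),
                postsynaptic = side(q$postsynaptic, "postsynaptic"),
                k_pre = q$k_pre %||% 3L, k_post = q$k_post %||% 1L,
                threshold = q$threshold)
}

#' @rdname read_query
#' @param query A [synapse_query()].
#' @export
write_query <- function(query, path) {
  side <- function(x) lapply(names(x), function(nm) {
    s <- x[[nm]]
    list(channel = nm, size_um = c(s$xy_um, s$xy_um, s$z_um))
  })
  jsonlite::write_json(
    list(presynaptic = side(query$presynaptic),
         postsynaptic = side(query$postsynaptic),
         k_pre = query$k_pre, k_post = query$k_post,
         threshold = query$threshold),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Grid geometry for the adjacency search
#'
#' Around each anchor voxel a rectangular grid is laid out in the partner
#' channel and subdivided into `k x k` in-plane subregions spanning
#' `z_extent` slices (one slice per axial cell), i.e. `k * k * z_extent`
#' cells in total. Each cell's in-plane extent equals the partner punctum
#' window `(2W + 1)` so one cell is one punctum-sized neighbourhood.
#'
#' @param subregion_half_width_px Half-width `W` of one grid cell in pixels.
#' @param k Subdivisions per in-plane axis (odd, >= 1).
#' @param z_extent Number of slices spanned by the grid (odd; defaults to
#'   `k`, matching a k x k grid spanning k slices).
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(subregion_half_width_px, k, z_extent = k) {
  if (k < 1 || k %% 2 != 1) stop("'k' must be an odd integer >= 1", call. = FALSE)
  if (z_extent < 1 || z_extent %% 2 != 1)
    stop("'z_extent' must be an odd integer >= 1", call. = FALSE)
  if (subregion_half_width_px < 0)
    stop("'subregion_half_width_px' must be >= 0", call. = FALSE)
  structure(list(subregion_half_width_px = as.integer(subregion_half_width_px),
                 k = as.integer(k), z_extent = as.integer(z_extent)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cw <- 2L * x$subregion_half_width_px + 1L
  cat(sprintf("grid: %d x %d cells of %d x %d px, spanning %d slice%s\n",
              x$k, x$k, cw, cw, x$z_extent, if (x$z_extent == 1) "" else "s"))
  invisible(x)
}

#' Presynaptic grid search around every anchor voxel
#'
#' For each voxel (anchored on the postsynaptic grid) a centred grid is laid
#' over the presynaptic 3D punctum probability map and partitioned into
#' punctum-sized subregions (see [grid_geometry()]). Each subregion is scored
#' by the mean of `log p` over its voxels — i.e. its geometric-mean
#' probability, which keeps the score in \[0, 1\] and ranks subregions
#' identically to the raw log-sum — and the best subregion wins:
#' `p_pres = exp(max_k score)`. Searching a grid rather than a single voxel
#' makes the detector robust to slight channel misalignment and to the exact
#' placement of the presynaptic punctum relative to the postsynaptic one.
#'
#' Anchors near the volume border use replicate padding (indices clamped to
#' the volume), so there is no detection dead zone at edges.
#'
#' @param p3dp Presynaptic 3D punctum [probability_volume()] (or array).
#' @param grid A [grid_geometry()].
#' @return Same type and shape as `p3dp`.
#' @export
presyn_grid_probability <- function(p3dp, grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  arr <- vol_data(p3dp)
  d <- dim(arr)
  cw <- 2L * grid$subregion_half_width_px + 1L
  if (grid$k * cw > min(d[1L], d[2L]) || grid$z_extent > d[3L])
    stop(sprintf(paste0(
      "grid (%d x %d px in-plane, %d slices) exceeds the volume ",
      "(%d x %d x %d); use a larger input or a smaller grid"),
      grid$k * cw, grid$k * cw, grid$z_extent, d[1L], d[2L], d[3L]),
      call. = FALSE)
  L <- log(pmin(pmax(arr, PROB_FLOOR), 1))
  # geometric-mean score of a punctum-sized cell centred at every voxel
  M <- array(0, d)
  for (k in seq_len(d[3L]))
    M[, , k] <- box_sum(L[, , k], grid$subregion_half_width_px) / cw^2
  offs_xy <- (seq_len(grid$k) - (grid$k + 1L) / 2L) * cw
  offs_z <- seq_len(grid$z_extent) - (grid$z_extent + 1L) / 2L
  best <- array(-Inf, d)
  iy0 <- seq_len(d[1L]); ix0 <- seq_len(d[2L]); iz0 <- seq_len(d[3L])
  for (oz in offs_z) {
    iz <- pmin(pmax(iz0 + oz, 1L), d[3L])
    for (oy in offs_xy) {
      iy <- pmin(pmax(iy0 + oy, 1L), d[1L])
      for (ox in offs_xy) {
        ix <- pmin(pmax(ix0 + ox, 1L), d[2L])
        best <- pmax(best, M[iy, ix, iz, drop = FALSE])
      }
    }
  }
  out <- exp(best)
  out[out > 1] <- 1
  wrap_like(p3dp, out, name = "p_pres")
}

#' Combine per-channel probability maps
#'
#' Multi-marker queries are conjunctive: a synapse of the queried subtype
#' must express *all* listed markers, so per-channel maps are combined by
#' elementwise product (probabilistic AND under independence). A single map
#' passes through unchanged; any zero annihilates.
#'
#' @param maps List of [probability_volume()] objects (or arrays) of one
#'   shape.
#' @return Combined map, same type as the first element.
#' @export
combine_channels <- function(maps) {
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  out <- vol_data(maps[[1L]])
  for (m in maps[-1L]) {
    a <- vol_data(m)
    if (!identical(dim(a), dim(out)))
      stop("probability maps differ in shape", call. = FALSE)
    out <- out * a
  }
  wrap_like(maps[[1L]], out, name = "combined")
}

#' Run a synapse query over a set of channels
#'
#' The full pipeline: for every channel named by the query, fit the per-slice
#' background model, compute foreground probabilities, promote 2D puncta,
#' attenuate puncta that do not span the required sections, then combine the
#' channels — postsynaptic maps voxelwise (for `k_post = 1`; larger odd
#' `k_post` uses the same grid machinery as the presynaptic search),
#' presynaptic maps through the punctum-sized grid search — and multiply the
#' combined presynaptic and postsynaptic maps into the final per-voxel
#' synapse probability. The map is anchored at postsynaptic voxels: a
#' detection's reported position is the postsynaptic side of the synapse.
#'
#' @param channels List (ideally named) of [channel_volume()] objects; must
#'   include every channel the query names, all co-registered.
#' @param query A [synapse_query()].
#' @param keep_intermediates If `TRUE`, per-channel intermediate maps
#'   (foreground, 2D/3D punctum probabilities) are retained on the result for
#'   inspection or export.
#' @return A `synapse_map`: a [probability_volume()] subclass carrying the
#'   query and (optionally) intermediates, with print/summary/plot methods.
#' @export
run_query <- function(channels, query, keep_intermediates = FALSE) {
  stopifnot(inherits(query, "synapse_query"))
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- vapply(channels, function(ch) ch$name, character(1))
  needed <- c(names(query$presynaptic), names(query$postsynaptic))
  missing <- setdiff(needed, names(channels))
  if (length(missing))
    stop("query channel(s) ", paste0("'", missing, "'", collapse = ", "),
         " not provided; available: ",
         paste0("'", names(channels), "'", collapse = ", "), call. = FALSE)
  used <- channels[unique(needed)]
  check_coregistered(used)
  res <- used[[1L]]$resolution

  intermediates <- if (keep_intermediates) list() else NULL
  p3dp_for <- function(nm, spec) {
    geom <- spec_to_geometry(spec, res)
    pf <- foreground_probability(channels[[nm]])
    pp <- puncta_2d(pf, geom)
    f <- slice_span_factor(pp, geom)
    p3 <- puncta_3d(pp, f)
    if (keep_intermediates)
      intermediates[[nm]] <<- list(foreground = pf, puncta2d = pp,
                                   span_factor = f, puncta3d = p3,
                                   geometry = geom)
    list(p3dp = p3, geom = geom)
  }

  pre_maps <- lapply(names(query$presynaptic), function(nm) {
    r <- p3dp_for(nm, query$presynaptic[[nm]])
    grid <- grid_geometry(r$geom$half_width_px, query$k_pre)
    presyn_grid_probability(r$p3dp, grid)
  })
  post_maps <- lapply(names(query$postsynaptic), function(nm) {
    r <- p3dp_for(nm, query$postsynaptic[[nm]])
    if (query$k_post > 1L) {
      grid <- grid_geometry(r$geom$half_width_px, query$k_post)
      presyn_grid_probability(r$p3dp, grid)
    } else r$p3dp
  })

  p_pres <- combine_channels(pre_maps)
  p_post <- combine_channels(post_maps)
  psynap <- vol_data(p_pres) * vol_data(p_post)

  structure(list(name = "p_synap", data = psynap, resolution = res,
                 query = query, channel_names = names(used),
                 intermediates = intermediates),
            class = c("synapse_map", "probability_volume"))
}

#' @export
print.synapse_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("synapse probability map: %d x %d pixels, %d slices (%s)\n",
              d[1], d[2], d[3], format(x$resolution)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("  p_synap range [%.3g, %.3g]; voxels > 0.5: %d\n",
              min(x$data), max(x$data), sum(x$data > 0.5)))
  invisible(x)
}

#' Summarise a synapse probability map
#'
#' Reports the map's extent, probability quantiles, and — if a threshold is
#' supplied or carried by the query — the detections it yields.
#'
#' @param object A `synapse_map` from [run_query()].
#' @param threshold Detection threshold; defaults to the query's, if any.
#' @param min_voxels Minimum detection size in voxels.
#' @param ... Unused.
#' @return A list of class `summary.synapse_map`.
#' @export
summary.synapse_map <- function(object, threshold = object$query$threshold,
                                min_voxels = 2L, ...) {
  d <- dim(object$data)
  vol_um3 <- prod(d) * voxel_um3(object$resolution)
  out <- list(dim = d, volume_um3 = vol_um3,
              quantiles = stats::quantile(object$data,
                                          c(0.5, 0.9, 0.99, 0.999, 1)),
              threshold = threshold)
  if (!is.null(threshold)) {
    det <- extract_detections(object, threshold, min_voxels = min_voxels)
    out$n_detections <- nrow(det)
    out$density_per_um3 <- nrow(det) / vol_um3
  }
  structure(out, class = "summary.synapse_map")
}

#' @export
print.summary.synapse_map <- function(x, ...) {
  cat(sprintf("synapse map %d x %d x %d (%.1f um^3)\n",
              x$dim[1], x$dim[2], x$dim[3], x$volume_um3))
  cat("  probability quantiles:\n")
  print(signif(x$quantiles, 3))
  if (!is.null(x$threshold) && !is.null(x$n_detections))
    cat(sprintf("  at threshold %.3g: %d detections (%.3g per um^3)\n",
                x$threshold, x$n_detections, x$density_per_um3))
  invisible(x)
}

#' Plot one slice of a probability map
#'
#' @param x A `synapse_map` or [probability_volume()].
#' @param slice Slice index (defaults to the slice containing the global
#'   maximum).
#' @param ... Passed to [graphics::image()].
#' @export
plot.synapse_map <- function(x, slice = NULL, ...) {
  arr <- vol_data(x)
  if (is.null(slice))
    slice <- arrayInd(which.max(arr), dim(arr))[1L, 3L]
  m <- arr[, , slice]
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "inferno"), axes = FALSE,
                  main = sprintf("p_synap, slice %d", slice), ...)
  invisible(x)
}

#' @export
plot.probability_volume <- plot.synapse_map

voxel_um3 <- function(resolution) {
  (resolution$xy_nm / 1000)^2 * (resolution$z_nm / 1000)
}
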