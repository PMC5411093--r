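#' Extract discrete detections from a probability map
#'
#' Voxels at or above the threshold are grouped into connected components
#' (26-connectivity in 3D by default — faces, edges and corners all count as
#' adjacent; 6-connectivity is available for comparison). Components smaller
#' than `min_voxels` are discarded: a single supra-threshold voxel usually
#' reflects noise, so the default minimum is 2. Each detection reports its
#' size, its peak probability, and its unweighted centroid both in voxel
#' units and in micrometres (voxel centre convention: voxel `i` has
#' continuous coordinate `i - 0.5`).
#'
#' @param psynap A `synapse_map`, [probability_volume()], or bare 3D array.
#' @param threshold Detection threshold in (0, 1).
#' @param min_voxels Minimum component size in voxels (default 2).
#' @param connectivity 26 (default) or 6.
#' @param resolution Required if `psynap` is a bare array.
#' @return A data.frame of class `synapse_detections` with one row per
#'   detection: `id`, `n_voxels`, `peak_probability`, centroid columns
#'   `centroid_y`, `centroid_x`, `centroid_z` (voxels) and
#'   `centroid_y_um`, `centroid_x_um`, `centroid_z_um`. The member voxel
#'   indices of each detection are kept in `attr(, "voxels")`.
#' @export
extract_detections <- function(psynap, threshold, min_voxels = 2L,
                               connectivity = 26L, resolution = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly within (0, 1)", call. = FALSE)
  arr <- vol_data(psynap)
  res <- vol_resolution(psynap, resolution)
  if (is.null(res)) stop("supply 'resolution' for bare arrays", call. = FALSE)
  d <- dim(arr)
  idx <- which(arr >= threshold)
  empty <- detections_frame(NULL, res)
  if (length(idx) == 0L) return(empty)

  membership <- label_components(idx, d, connectivity)
  coords <- arrayInd(idx, d)
  sizes <- tabulate(membership)
  keep_comp <- which(sizes >= min_voxels)
  if (length(keep_comp) == 0L) return(empty)

  rows <- lapply(seq_along(keep_comp), function(i) {
    comp <- keep_comp[i]
    sel <- membership == comp
    cen <- colMeans(coords[sel, , drop = FALSE]) - 0.5
    data.frame(id = i, n_voxels = sizes[comp],
               peak_probability = max(arr[idx[sel]]),
               centroid_y = cen[1L], centroid_x = cen[2L], centroid_z = cen[3L])
  })
  out <- do.call(rbind, rows)
  # order by peak probability, strongest first; re-id
  ord <- order(-out$peak_probability)
  out <- out[ord, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  voxels <- lapply(keep_comp[ord], function(comp) idx[membership == comp])
  detections_frame(out, res, voxels = voxels, threshold = threshold)
}

detections_frame <- function(df, resolution, voxels = list(), threshold = NULL) {
  if (is.null(df))
    df <- data.frame(id = integer(), n_voxels = integer(),
                     peak_probability = numeric(), centroid_y = numeric(),
                     centroid_x = numeric(), centroid_z = numeric())
  df$centroid_y_um <- df$centroid_y * resolution$xy_nm / 1000
  df$centroid_x_um <- df$centroid_x * resolution$xy_nm / 1000
  df$centroid_z_um <- df$centroid_z * resolution$z_nm / 1000
  structure(df, class = c("synapse_detections", "data.frame"),
            voxels = voxels, resolution = resolution, threshold = threshold)
}

#' @export
print.synapse_detections <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(nrow(x), "detection(s)",
      if (!is.null(thr)) sprintf("at threshold %.3g", thr) else "", "\n")
  if (nrow(x) > 0)
    print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                     digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

# Label connected components among the voxels with linear indices idx in a
# volume of dim d. Returns an integer membership vector along idx.
label_components <- function(idx, d, connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("'connectivity' must be 6 or 26", call. = FALSE)
  n <- length(idx)
  if (n == 1L) return(1L)
  coords <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  edges <- integer(0)
  pos <- seq_len(n)
  for (r in seq_len(nrow(offs))) {
    ny <- coords[, 1L] + offs[r, 1L]
    nx <- coords[, 2L] + offs[r, 2L]
    nz <- coords[, 3L] + offs[r, 3L]
    ok <- ny >= 1L & ny <= d[1L] & nx >= 1L & nx <= d[2L] &
      nz >= 1L & nz <= d[3L]
    if (!any(ok)) next
    nlin <- (nz[ok] - 1L) * d[1L] * d[2L] + (nx[ok] - 1L) * d[1L] + ny[ok]
    hit <- match(nlin, idx)
    found <- !is.na(hit)
    if (any(found))
      edges <- c(edges, rbind(pos[ok][found], hit[found]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$membership)
}

# Half set of neighbour offsets (each unordered pair visited once).
neighbor_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), ncol = 3L, byrow = TRUE)
  } else {
    g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
    keep <- g[, 3L] > 0L | (g[, 3L] == 0L & g[, 2L] > 0L) |
      (g[, 3L] == 0L & g[, 2L] == 0L & g[, 1L] > 0L)
    g[keep, , drop = FALSE]
  }
}

#' Detection density across thresholds
#'
#' Counts detections at each threshold and converts to synapses per cubic
#' micrometre of analysed tissue. Density is non-increasing in the
#' threshold, tracing out the curve used to pick an operating point from an
#' expected synaptic density (about 0.9/um^3 for cortical excitatory and
#' 0.1/um^3 for inhibitory synapses).
#'
#' @param psynap Probability map (see [extract_detections()]).
#' @param thresholds Strictly increasing vector of thresholds in (0, 1).
#' @param min_voxels Minimum detection size in voxels.
#' @param resolution Required for bare arrays.
#' @return A data.frame of class `density_curve`: `threshold`,
#'   `n_detections`, `density_per_um3`.
#' @export
density_curve <- function(psynap, thresholds, min_voxels = 2L,
                          resolution = NULL) {
  if (length(thresholds) == 0L)
    stop("'thresholds' must be non-empty", call. = FALSE)
  if (any(diff(thresholds) <= 0))
    stop("'thresholds' must be strictly increasing", call. = FALSE)
  arr <- vol_data(psynap)
  res <- vol_resolution(psynap, resolution)
  if (is.null(res)) stop("supply 'resolution' for bare arrays", call. = FALSE)
  vol_um3 <- prod(dim(arr)) * voxel_um3(res)
  n <- vapply(thresholds, function(t) {
    nrow(extract_detections(arr, t, min_voxels = min_voxels, resolution = res))
  }, numeric(1))
  structure(data.frame(threshold = thresholds, n_detections = n,
                       density_per_um3 = n / vol_um3),
            class = c("density_curve", "data.frame"), volume_um3 = vol_um3)
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("density curve over %.1f um^3\n", attr(x, "volume_um3")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.density_curve <- function(x, target = NULL, ...) {
  graphics::plot(x$threshold, x$density_per_um3, type = "b", pch = 16,
                 xlab = "threshold", ylab = "detections per um^3", ...)
  if (!is.null(target)) graphics::abline(h = target, col = 2, lty = 2)
  invisible(x)
}

#' Choose an operating threshold from a density curve
#'
#' Returns the threshold whose detection density is closest to the target
#' density; ties break towards the higher (more conservative) threshold.
#'
#' @param curve A `density_curve` from [density_curve()].
#' @param target_density Expected density in detections per um^3.
#' @return A single threshold value.
#' @export
choose_threshold_by_density <- function(curve, target_density) {
  if (nrow(curve) == 0L) stop("empty density curve", call. = FALSE)
  err <- abs(curve$density_per_um3 - target_density)
  # tolerance guards against floating-point asymmetry in |d - target|
  cand <- which(err <= min(err) + 1e-12)
  curve$threshold[cand[which.max(curve$threshold[cand])]]
}

#' Match detections to ground-truth positions and score precision/recall
#'
#' Greedy nearest-neighbour one-to-one matching: all (detection, truth)
#' pairs within `tolerance_um` are sorted by centroid distance and accepted
#' in order whenever both members are still unmatched. Accepted pairs are
#' true positives; leftover detections are false positives; leftover truths
#' are false negatives. Precision is tp / (tp + fp) and recall is
#' tp / (tp + fn), each with an Agresti-Coull 95% confidence interval.
#'
#' @param detections A `synapse_detections` data.frame (needs
#'   `centroid_y_um`, `centroid_x_um`, `centroid_z_um`), or any data.frame
#'   with those columns.
#' @param truth Data.frame of ground-truth centroids with columns `y_um`,
#'   `x_um`, `z_um` (the simulator's truth table works directly).
#' @param tolerance_um Maximum centroid distance for a match, in
#'   micrometres; default 0.3 (about one punctum diameter).
#' @param confidence Confidence level for the intervals.
#' @return A list of class `synapse_evaluation`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `precision_ci`, `recall_ci`, `tolerance_um`,
#'   `matches` (data.frame of accepted pairs).
#' @export
match_detections <- function(detections, truth, tolerance_um = 0.3,
                             confidence = 0.95) {
  if (tolerance_um <= 0) stop("'tolerance_um' must be > 0", call. = FALSE)
  dmat <- as.matrix(as.data.frame(detections)[, c("centroid_y_um",
                                                  "centroid_x_um",
                                                  "centroid_z_um"),
                                              drop = FALSE])
  tmat <- as.matrix(as.data.frame(truth)[, c("y_um", "x_um", "z_um"),
                                         drop = FALSE])
  nd <- nrow(dmat); nt <- nrow(tmat)
  matches <- data.frame(detection = integer(), truth = integer(),
                        distance_um = numeric())
  if (nd > 0 && nt > 0) {
    dist2 <- outer(rowSums(dmat^2), rowSums(tmat^2), "+") -
      2 * dmat %*% t(tmat)
    dist <- sqrt(pmax(dist2, 0))
    cand <- which(dist <= tolerance_um, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dist[cand])
      used_d <- logical(nd); used_t <- logical(nt)
      for (i in ord) {
        di <- cand[i, 1L]; ti <- cand[i, 2L]
        if (!used_d[di] && !used_t[ti]) {
          used_d[di] <- TRUE; used_t[ti] <- TRUE
          matches <- rbind(matches,
                           data.frame(detection = di, truth = ti,
                                      distance_um = dist[di, ti]))
        }
      }
    }
  }
  tp <- nrow(matches); fp <- nd - tp; fn <- nt - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
    precision_ci = if (tp + fp > 0)
      agresti_coull_interval(tp, tp + fp, confidence) else c(NA_real_, NA_real_),
    recall_ci = if (tp + fn > 0)
      agresti_coull_interval(tp, tp + fn, confidence) else c(NA_real_, NA_real_),
    tolerance_um = tolerance_um, confidence = confidence, matches = matches),
    class = "synapse_evaluation")
}

#' @export
print.synapse_evaluation <- function(x, ...) {
  cat(sprintf("detection evaluation (tolerance %.3g um)\n", x$tolerance_um))
  cat(sprintf("  tp = %d, fp = %d, fn = %d\n", x$tp, x$fp, x$fn))
  ci <- function(v) sprintf("[%.3f, %.3f]", v[1], v[2])
  cat(sprintf("  precision = %.3f %s\n", x$precision, ci(x$precision_ci)))
  cat(sprintf("  recall    = %.3f %s\n", x$recall, ci(x$recall_ci)))
  invisible(x)
}

#' Agresti-Coull binomial confidence interval
#'
#' The adjusted-Wald interval: with `z` the two-sided normal quantile for
#' the confidence level, add `z^2` pseudo-trials and `z^2 / 2`
#' pseudo-successes, then apply the normal approximation around the adjusted
#' proportion. Bounds are clipped to \[0, 1\]. The quantile is computed from
#' the requested level (1.959964 at 95%), so other levels are supported.
#'
#' @param successes Number of successes (0 <= successes <= trials).
#' @param trials Number of trials (>= 1).
#' @param confidence Confidence level, default 0.95.
#' @return Numeric `c(low, high)`.
#' @examples
#' agresti_coull_interval(88, 100)   # approximately (0.800, 0.931)
#' @export
agresti_coull_interval <- function(successes, trials, confidence = 0.95) {
  if (trials < 1) stop("'trials' must be >= 1", call. = FALSE)
  if (successes < 0 || successes > trials)
    stop("'successes' must lie in [0, trials]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n_tilde <- trials + z^2
  p_tilde <- (successes + z^2 / 2) / n_tilde
  half <- z * sqrt(p_tilde * (1 - p_tilde) / n_tilde)
  c(max(0, p_tilde - half), min(1, p_tilde + half))
}

#' Write detections to CSV / evaluation to JSON
#'
#' @param detections A `synapse_detections` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(as.data.frame(detections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @param evaluation A `synapse_evaluation` from [match_detections()].
#' @export
write_evaluation_json <- function(evaluation, path) {
  jsonlite::write_json(
    list(tp = evaluation$tp, fp = evaluation$fp, fn = evaluation$fn,
         precision = evaluation$precision, recall = evaluation$recall,
         precision_ci = evaluation$precision_ci,
         recall_ci = evaluation$recall_ci,
         tolerance_um = evaluation$tolerance_um,
         confidence = evaluation$confidence),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
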