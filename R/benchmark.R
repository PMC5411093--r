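#' Run a query on a scene and evaluate against its ground truth
#'
#' End-to-end harness: computes the synapse probability map, traces the
#' density-versus-threshold curve, picks the operating threshold whose
#' detection density is closest to the target (by default the planted
#' synapse density — the same density-matching procedure used to set
#' thresholds on real volumes from the expected cortical density), extracts
#' detections, and matches them to the planted synapses.
#'
#' @param scene A `synapse_scene` from [generate_scene()] or
#'   [default_benchmark_scene()].
#' @param query A [synapse_query()]; defaults to `scene$query`.
#' @param thresholds Candidate thresholds for the density curve.
#' @param tolerance_um Match tolerance for evaluation (default 0.3 um).
#' @param min_voxels Minimum detection size.
#' @param target_density Target density per um^3; defaults to the planted
#'   density of `population` (or of all synapses).
#' @param population Restrict evaluation to one planted population (its
#'   synapses are the positives; others are ignored as truth but count
#'   against precision if detected).
#' @return A list of class `scene_evaluation`: `map`, `curve`, `threshold`,
#'   `detections`, `evaluation`, `distractor_rates` (named vector of the
#'   fraction of planted distractors of each type lying within
#'   `tolerance_um` of a detection), `target_density`.
#' @export
evaluate_scene <- function(scene, query = scene$query,
                           thresholds = seq(0.02, 0.9, by = 0.02),
                           tolerance_um = 0.3, min_voxels = 2L,
                           target_density = NULL, population = NULL) {
  if (is.null(query)) stop("no query supplied and none on the scene", call. = FALSE)
  truth <- scene$truth
  syn <- truth[truth$type == "synapse", , drop = FALSE]
  if (!is.null(population))
    syn <- syn[syn$population == population, , drop = FALSE]
  map <- run_query(scene$channels, query)
  vol_um3 <- prod(dim(map$data)) * voxel_um3(map$resolution)
  if (is.null(target_density)) target_density <- nrow(syn) / vol_um3
  curve <- density_curve(map, thresholds, min_voxels = min_voxels)
  threshold <- choose_threshold_by_density(curve, target_density)
  detections <- extract_detections(map, threshold, min_voxels = min_voxels)
  evaluation <- match_detections(detections, syn, tolerance_um = tolerance_um)
  rates <- c()
  for (ty in c("single_channel", "single_slice")) {
    dis <- truth[truth$type == ty, , drop = FALSE]
    if (nrow(dis))
      rates[ty] <- distractor_detection_rate(detections, dis, tolerance_um)
  }
  structure(list(map = map, curve = curve, threshold = threshold,
                 detections = detections, evaluation = evaluation,
                 distractor_rates = rates, target_density = target_density,
                 volume_um3 = vol_um3),
            class = "scene_evaluation")
}

#' Fraction of planted distractors picked up by the detector
#'
#' A distractor counts as detected if any detection centroid lies within
#' `tolerance_um` of its planted centroid.
#'
#' @param detections A `synapse_detections` data.frame.
#' @param distractors Truth rows (needs `y_um`, `x_um`, `z_um`).
#' @param tolerance_um Distance tolerance in micrometres.
#' @return A fraction in \[0, 1\].
#' @export
distractor_detection_rate <- function(detections, distractors,
                                      tolerance_um = 0.3) {
  if (nrow(distractors) == 0L) return(NA_real_)
  if (nrow(detections) == 0L) return(0)
  dmat <- as.matrix(as.data.frame(detections)[, c("centroid_y_um",
                                                  "centroid_x_um",
                                                  "centroid_z_um")])
  tmat <- as.matrix(as.data.frame(distractors)[, c("y_um", "x_um", "z_um")])
  hit <- vapply(seq_len(nrow(tmat)), function(i) {
    min(sqrt(colSums((t(dmat) - tmat[i, ])^2))) <= tolerance_um
  }, logical(1))
  mean(hit)
}

#' @export
print.scene_evaluation <- function(x, ...) {
  cat(sprintf("scene evaluation: threshold %.3g (target density %.3g/um^3, %.0f um^3)\n",
              x$threshold, x$target_density, x$volume_um3))
  print(x$evaluation)
  if (length(x$distractor_rates)) {
    cat("  distractor detection rates:\n")
    for (nm in names(x$distractor_rates))
      cat(sprintf("    %-15s %.3f\n", nm, x$distractor_rates[[nm]]))
  }
  invisible(x)
}
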