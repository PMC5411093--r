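#' Describe a synthetic multi-channel scene
#'
#' The simulator emulates the statistical regime the detector assumes: a
#' Gaussian background per channel, sparse (a few percent of voxels)
#' foreground made of blob-shaped puncta spanning one to a few sections, and
#' synapses appearing as a presynaptic punctum placed adjacent to a
#' postsynaptic one. It does not model optics (no PSF convolution, shot
#' noise, or deconvolution ringing) — it is a benchmark generator, not an
#' image formation model.
#'
#' @param height,width,n_slices Volume shape in voxels (rows, columns,
#'   slices).
#' @param resolution A [voxel_resolution()].
#' @param channels Character vector of channel names.
#' @param background Per-channel Gaussian background: either a single
#'   `list(mu=, sigma=)` applied to all channels or a named list of such
#'   lists.
#' @param populations List of [synapse_population()] descriptors; each
#'   plants `count` synapses whose puncta appear in that population's pre-
#'   and postsynaptic channels.
#' @param distractors `list(single_channel =, single_slice =)`:
#'   `single_channel` full-span puncta are planted per channel in that
#'   channel only (they violate the query's marker conjunction);
#'   `single_slice` plants pre/post punctum pairs confined to one section
#'   (they violate the slice-span requirement). Both use the first
#'   population's punctum parameters.
#' @param min_separation_um Minimum 3D distance between planted anchor
#'   centroids (default 0.6 um, comfortably above twice the punctum sigma).
#' @param seed Integer RNG seed; identical specs generate bit-identical
#'   scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height, width, n_slices, resolution, channels,
                       background = list(mu = 100, sigma = 20),
                       populations = list(),
                       distractors = list(single_channel = 0L,
                                          single_slice = 0L),
                       min_separation_um = 0.6, seed = 1L) {
  stopifnot(height >= 8, width >= 8, n_slices >= 1,
            inherits(resolution, "voxel_resolution"),
            is.character(channels), length(channels) >= 1)
  if (anyDuplicated(channels)) stop("duplicate channel names", call. = FALSE)
  if (!is.null(background$mu)) {
    background <- stats::setNames(rep(list(background), length(channels)),
                                  channels)
  }
  if (!setequal(names(background), channels))
    stop("'background' must cover exactly the scene channels", call. = FALSE)
  for (pop in populations) {
    stopifnot(inherits(pop, "synapse_population"))
    bad <- setdiff(c(pop$pre_channels, pop$post_channels), channels)
    if (length(bad))
      stop("population '", pop$name, "' references unknown channel(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  distractors$single_channel <- as.integer(distractors$single_channel %||% 0L)
  distractors$single_slice <- as.integer(distractors$single_slice %||% 0L)
  if (distractors$single_channel + distractors$single_slice > 0 &&
      length(populations) == 0)
    stop("distractors need at least one population (for punctum parameters)",
         call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_slices = as.integer(n_slices), resolution = resolution,
                 channels = channels, background = background,
                 populations = populations, distractors = distractors,
                 min_separation_um = min_separation_um,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Describe one planted synapse population
#'
#' @param name Population label (e.g. `"excitatory"`).
#' @param count Number of synapses to plant.
#' @param pre_channels,post_channels Channels carrying the presynaptic /
#'   postsynaptic punctum of each synapse.
#' @param snr Punctum amplitude in units of the channel's background sigma.
#' @param sigma_xy_um In-plane Gaussian sigma of a punctum in micrometres
#'   (default 0.15 um: FWHM about 0.35 um). The 0.2 um size in a query is
#'   the *smallest* expected punctum — it sets the detection window — so
#'   typical planted puncta are somewhat larger than that minimum, as real
#'   puncta are.
#' @param slice_span Number of sections a punctum spans (axial weights are
#'   Gaussian with FWHM equal to the span, truncated to the span).
#' @param max_offset_um Presynaptic centroids are drawn uniformly in an
#'   in-plane disc of this radius around the postsynaptic centroid (default
#'   0.15 um — within one grid subregion, exercising the adjacency search
#'   without guaranteeing perfect apposition).
#' @return An object of class `synapse_population`.
#' @export
synapse_population <- function(name, count, pre_channels, post_channels,
                               snr = 5, sigma_xy_um = 0.15, slice_span = 3L,
                               max_offset_um = 0.15) {
  stopifnot(count >= 0, snr > 0, sigma_xy_um > 0, slice_span >= 1,
            max_offset_um >= 0, length(pre_channels) >= 1,
            length(post_channels) >= 1)
  structure(list(name = name, count = as.integer(count),
                 pre_channels = pre_channels, post_channels = post_channels,
                 snr = snr, sigma_xy_um = sigma_xy_um,
                 slice_span = as.integer(slice_span),
                 max_offset_um = max_offset_um),
            class = "synapse_population")
}

#' Generate a synthetic scene with ground truth
#'
#' Backgrounds are i.i.d. Gaussian per voxel per channel, clipped at zero.
#' Every planted object adds an anisotropic Gaussian blob (in-plane sigma
#' from its population, truncated at 3 sigma; Gaussian axial weights over
#' its slice span) at a continuously drawn centroid; presynaptic centroids
#' are offset from postsynaptic ones within the population's offset disc.
#' Object anchors are rejection-sampled to keep at least
#' `min_separation_um` apart (10,000 attempts per object before failing
#' loudly) and to fit inside the volume with a margin. Intensities are
#' rounded to integers and clipped to the 16-bit range on export, so a
#' given spec (including seed) reproduces bit-identical volumes.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synapse_scene`: `channels` (named list of
#'   [channel_volume()]), `truth` (data.frame, one row per planted object:
#'   `id`, `type` ("synapse", "single_channel", "single_slice"),
#'   `population`, `channel`, anchor centroid `y`, `x`, `z` in continuous
#'   voxel units plus `y_um`, `x_um`, `z_um`, and presynaptic centroid
#'   `pre_y`, `pre_x`, `pre_z` where applicable), and `spec`. The realised
#'   foreground voxel fraction is attached as `attr(truth, "foreground_fraction")`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  ny <- spec$height; nx <- spec$width; nz <- spec$n_slices
  res <- spec$resolution
  xy_px_per_um <- 1000 / res$xy_nm

  # signal (pre-noise) accumulators, one per channel
  signal <- stats::setNames(
    lapply(spec$channels, function(ch) array(0, c(ny, nx, nz))),
    spec$channels)

  anchors <- matrix(numeric(0), ncol = 3L)   # um coordinates, for separation
  truth_rows <- list()
  next_id <- 1L

  place_anchor <- function(margin_px, margin_z) {
    if (ny - 2 * margin_px <= 0 || nx - 2 * margin_px <= 0 ||
        nz - 2 * margin_z < 0)
      stop("volume too small for planted objects with the required margin",
           call. = FALSE)
    for (attempt in seq_len(10000L)) {
      cy <- stats::runif(1, margin_px, ny - margin_px)
      cx <- stats::runif(1, margin_px, nx - margin_px)
      cz <- stats::runif(1, margin_z, nz - margin_z)
      p_um <- c(cy / xy_px_per_um, cx / xy_px_per_um, cz * res$z_nm / 1000)
      if (nrow(anchors) == 0 ||
          min(sqrt(colSums((t(anchors) - p_um)^2))) >= spec$min_separation_um) {
        anchors <<- rbind(anchors, p_um)
        return(c(cy, cx, cz))
      }
    }
    stop("could not place an object after 10000 attempts; reduce counts or ",
         "min_separation_um", call. = FALSE)
  }

  add_punctum <- function(channel, cy, cx, cz, amplitude, sigma_px, span) {
    r <- ceiling(3 * sigma_px)
    ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
    xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
    dy <- (ys - 0.5) - cy
    dx <- (xs - 0.5) - cx
    d2 <- outer(dy^2, dx^2, "+")
    w <- exp(-d2 / (2 * sigma_px^2))
    w[d2 > (3 * sigma_px)^2] <- 0          # truncate at 3 sigma
    szc <- ceiling(cz)
    dzs <- (-ceiling((span - 1) / 2)):(floor((span - 1) / 2))
    sigma_z <- max(span, 1) / 2.355        # FWHM = slice span
    for (dz in dzs) {
      sz <- szc + dz
      if (sz < 1L || sz > nz) next
      wz <- exp(-dz^2 / (2 * sigma_z^2))
      signal[[channel]][ys, xs, sz] <<-
        signal[[channel]][ys, xs, sz] + amplitude * wz * w
    }
  }

  record <- function(type, population, channel, post, pre = NULL) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      id = next_id, type = type,
      population = population %||% NA_character_,
      channel = channel %||% NA_character_,
      y = post[1L], x = post[2L], z = post[3L],
      y_um = post[1L] / xy_px_per_um, x_um = post[2L] / xy_px_per_um,
      z_um = post[3L] * res$z_nm / 1000,
      pre_y = if (is.null(pre)) NA_real_ else pre[1L],
      pre_x = if (is.null(pre)) NA_real_ else pre[2L],
      pre_z = if (is.null(pre)) NA_real_ else pre[3L])
    next_id <<- next_id + 1L
  }

  pop_margins <- function(pop) {
    sigma_px <- pop$sigma_xy_um * xy_px_per_um
    margin_px <- ceiling(3 * sigma_px + pop$max_offset_um * xy_px_per_um) + 5L
    margin_z <- ceiling((pop$slice_span - 1) / 2) + 2L
    list(px = margin_px, z = margin_z, sigma_px = sigma_px)
  }

  draw_offset <- function(pop) {
    r_px <- pop$max_offset_um * xy_px_per_um * sqrt(stats::runif(1))
    theta <- stats::runif(1, 0, 2 * pi)
    c(r_px * cos(theta), r_px * sin(theta))
  }

  for (pop in spec$populations) {
    m <- pop_margins(pop)
    for (i in seq_len(pop$count)) {
      post <- place_anchor(m$px, m$z)
      off <- draw_offset(pop)
      pre <- c(post[1L] + off[1L], post[2L] + off[2L], post[3L])
      for (ch in pop$post_channels)
        add_punctum(ch, post[1L], post[2L], post[3L],
                    pop$snr * spec$background[[ch]]$sigma, m$sigma_px,
                    pop$slice_span)
      for (ch in pop$pre_channels)
        add_punctum(ch, pre[1L], pre[2L], pre[3L],
                    pop$snr * spec$background[[ch]]$sigma, m$sigma_px,
                    pop$slice_span)
      record("synapse", pop$name, NULL, post, pre)
    }
  }

  if (length(spec$populations)) {
    ref <- spec$populations[[1L]]
    m <- pop_margins(ref)
    # single-channel distractors: full-span puncta violating the conjunction
    for (ch in spec$channels) {
      for (i in seq_len(spec$distractors$single_channel)) {
        p <- place_anchor(m$px, m$z)
        add_punctum(ch, p[1L], p[2L], p[3L],
                    ref$snr * spec$background[[ch]]$sigma, m$sigma_px,
                    ref$slice_span)
        record("single_channel", NULL, ch, p)
      }
    }
    # single-slice distractors: paired pre/post puncta violating the span
    for (i in seq_len(spec$distractors$single_slice)) {
      post <- place_anchor(m$px, m$z)
      off <- draw_offset(ref)
      pre <- c(post[1L] + off[1L], post[2L] + off[2L], post[3L])
      for (ch in ref$post_channels)
        add_punctum(ch, post[1L], post[2L], post[3L],
                    ref$snr * spec$background[[ch]]$sigma, m$sigma_px, 1L)
      for (ch in ref$pre_channels)
        add_punctum(ch, pre[1L], pre[2L], pre[3L],
                    ref$snr * spec$background[[ch]]$sigma, m$sigma_px, 1L)
      record("single_slice", NULL, NULL, post, pre)
    }
  }

  fg_voxels <- 0
  channels <- stats::setNames(vector("list", length(spec$channels)),
                              spec$channels)
  for (ch in spec$channels) {
    bg <- spec$background[[ch]]
    noise <- array(stats::rnorm(ny * nx * nz, bg$mu, bg$sigma), c(ny, nx, nz))
    fg_voxels <- fg_voxels + sum(signal[[ch]] > bg$sigma)
    arr <- pmin(pmax(round(noise + signal[[ch]]), 0), 65535)
    channels[[ch]] <- channel_volume(ch, arr, res)
  }
  fg_fraction <- fg_voxels / (length(spec$channels) * ny * nx * nz)
  if (fg_fraction > 0.05)
    warning(sprintf("foreground fraction %.1f%% exceeds the ~5%% sparsity ",
                    100 * fg_fraction),
            "the background model assumes", call. = FALSE)

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(id = integer(), type = character(), population = character(),
               channel = character(), y = numeric(), x = numeric(),
               z = numeric(), y_um = numeric(), x_um = numeric(),
               z_um = numeric(), pre_y = numeric(), pre_x = numeric(),
               pre_z = numeric())
  rownames(truth) <- NULL
  attr(truth, "foreground_fraction") <- fg_fraction
  structure(list(channels = channels, truth = truth, spec = spec),
            class = "synapse_scene")
}

#' @export
print.synapse_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d x %d x %d voxels, %d channel(s) [%s]\n",
              x$spec$height, x$spec$width, x$spec$n_slices,
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  tab <- table(x$truth$type)
  if (length(tab))
    cat("  planted:", paste(sprintf("%s = %d", names(tab), tab),
                            collapse = ", "), "\n")
  cat(sprintf("  foreground fraction: %.2f%%\n",
              100 * attr(x$truth, "foreground_fraction")))
  invisible(x)
}

#' The default end-to-end benchmark scene
#'
#' A fixed two-channel (synapsin-like presynaptic, PSD-95-like postsynaptic)
#' 256 x 256 x 20 scene at 100 nm in-plane / 70 nm axial resolution: 50
#' synapses at SNR 5 spanning three sections, plus 25 single-channel
#' distractors per channel and 25 single-slice pre/post distractor pairs.
#' Paired with the matching excitatory query (0.2 um in-plane, 0.21 um =
#' three 70 nm sections axially, k_pre = 3, k_post = 1).
#'
#' @param seed RNG seed (default 1337, the frozen benchmark).
#' @return A `synapse_scene` with an extra `query` element.
#' @export
default_benchmark_scene <- function(seed = 1337L) {
  spec <- scene_spec(
    height = 256L, width = 256L, n_slices = 20L,
    resolution = voxel_resolution(100, 70),
    channels = c("synapsin", "PSD-95"),
    background = list(mu = 100, sigma = 20),
    populations = list(
      synapse_population("excitatory", 50L,
                         pre_channels = "synapsin",
                         post_channels = "PSD-95",
                         snr = 5, sigma_xy_um = 0.15, slice_span = 3L,
                         max_offset_um = 0.15)),
    distractors = list(single_channel = 25L, single_slice = 25L),
    seed = seed)
  scene <- generate_scene(spec)
  scene$query <- synapse_query(
    presynaptic = list(synapsin = punctum_spec(0.2, 0.21)),
    postsynaptic = list(`PSD-95` = punctum_spec(0.2, 0.21)),
    k_pre = 3L, k_post = 1L)
  scene
}

#' A mixed excitatory/inhibitory scene
#'
#' Three channels (a shared synapsin-like presynaptic marker plus PSD-95-like
#' and gephyrin-like postsynaptic markers) carrying two synapse populations
#' at the roughly ten-to-one excitatory:inhibitory ratio observed in cortex.
#' Running the excitatory and inhibitory queries on the same scene recovers
#' the planted ratio.
#'
#' @param seed RNG seed.
#' @param n_excitatory,n_inhibitory Planted counts (default 50:5).
#' @return A `synapse_scene` with an extra `queries` element (named list
#'   `excitatory` / `inhibitory`).
#' @export
default_mixed_scene <- function(seed = 1L, n_excitatory = 50L,
                                n_inhibitory = 5L) {
  spec <- scene_spec(
    height = 192L, width = 192L, n_slices = 20L,
    resolution = voxel_resolution(100, 70),
    channels = c("synapsin", "PSD-95", "gephyrin"),
    background = list(mu = 100, sigma = 20),
    populations = list(
      synapse_population("excitatory", n_excitatory,
                         pre_channels = "synapsin",
                         post_channels = "PSD-95"),
      synapse_population("inhibitory", n_inhibitory,
                         pre_channels = "synapsin",
                         post_channels = "gephyrin")),
    seed = seed)
  scene <- generate_scene(spec)
  size <- punctum_spec(0.2, 0.21)
  scene$queries <- list(
    excitatory = synapse_query(
      presynaptic = list(synapsin = size),
      postsynaptic = list(`PSD-95` = size)),
    inhibitory = synapse_query(
      presynaptic = list(synapsin = size),
      postsynaptic = list(gephyrin = size)))
  scene
}

#' Write a scene to disk (TIFFs, manifest, truth CSV)
#'
#' @param scene A `synapse_scene`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  write_channel_manifest(scene$channels, dir)
  utils::write.csv(as.data.frame(scene$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a scene specification from JSON
#'
#' Schema mirrors [scene_spec()] / [synapse_population()]; see the shipped
#' example `system.file("extdata", "benchmark_scene.json",
#' package = "synapsequery")`.
#'
#' @param path JSON file path.
#' @param seed Optional seed overriding the one in the file.
#' @return A [scene_spec()].
#' @export
scene_spec_from_json <- function(path, seed = NULL) {
  s <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pops <- lapply(s$populations, function(p)
    synapse_population(p$name, p$count,
                       pre_channels = unlist(p$pre_channels),
                       post_channels = unlist(p$post_channels),
                       snr = p$snr %||% 5,
                       sigma_xy_um = p$sigma_xy_um %||% 0.15,
                       slice_span = p$slice_span %||% 3L,
                       max_offset_um = p$max_offset_um %||% 0.15))
  background <- if (!is.null(s$background$mu)) s$background else
    lapply(s$background, function(b) list(mu = b$mu, sigma = b$sigma))
  scene_spec(height = s$height, width = s$width, n_slices = s$n_slices,
             resolution = voxel_resolution(s$xy_nm, s$z_nm),
             channels = unlist(s$channels), background = background,
             populations = pops,
             distractors = list(
               single_channel = s$distractors$single_channel %||% 0L,
               single_slice = s$distractors$single_slice %||% 0L),
             min_separation_um = s$min_separation_um %||% 0.6,
             seed = seed %||% s$seed %||% 1L)
}
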