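res_at <- voxel_resolution(100, 70)

q_excit <- function() synapse_query(
  presynaptic = list(synapsin = punctum_spec(0.2, 0.21)),
  postsynaptic = list(`PSD-95` = punctum_spec(0.2, 0.21)))

test_that("query construction enforces its invariants", {
  expect_error(synapse_query(list(), list(a = punctum_spec(0.2, 0.2))),
               "non-empty")
  expect_error(synapse_query(list(a = punctum_spec(0.2, 0.2)),
                             list(b = punctum_spec(0.2, 0.2)), k_pre = 2),
               "odd")
  expect_error(synapse_query(list(a = punctum_spec(0.2, 0.2),
                                  a = punctum_spec(0.2, 0.2)),
                             list(b = punctum_spec(0.2, 0.2))),
               "duplicate")
  # published (x, y, z) size triples are accepted directly
  q <- synapse_query(presynaptic = list(synapsin = c(0.2, 0.2, 0.21)),
                     postsynaptic = list(gephyrin = c(0.2, 0.2, 0.07)))
  expect_equal(q$presynaptic$synapsin$z_um, 0.21)
  expect_equal(q$postsynaptic$gephyrin$z_um, 0.07)
})

test_that("query JSON round trips and shipped query sets parse", {
  td <- withr::local_tempdir()
  q <- synapse_query(
    presynaptic = list(synapsin = punctum_spec(0.2, 0.21),
                       VGluT1 = punctum_spec(0.2, 0.07)),
    postsynaptic = list(`PSD-95` = punctum_spec(0.2, 0.07)),
    threshold = 0.6)
  f <- file.path(td, "q.json")
  write_query(q, f)
  back <- read_query(f)
  expect_equal(back, q)

  shipped <- list.files(system.file("extdata", "queries",
                                    package = "synapsequery"),
                        full.names = TRUE)
  expect_gte(length(shipped), 16)
  for (path in shipped) expect_s3_class(read_query(path), "synapse_query")
})

test_that("grid search scores subregions by their geometric mean", {
  grid <- grid_geometry(1, 3)        # 3x3 cells of 3x3 px over 3 slices

  ones <- probability_volume(array(1, c(24, 24, 5)), res_at)
  expect_equal(presyn_grid_probability(ones, grid)$data,
               array(1, c(24, 24, 5)))

  # one uniformly bright cell among floor-level background: the maximum
  # picks it and the geometric mean of a constant cell is that constant
  arr <- array(1e-12, c(24, 24, 5))
  arr[11:13, 11:13, 3] <- 0.8        # exactly one 3x3 cell, centred at (12,12)
  pv <- probability_volume(arr, res_at)
  out <- presyn_grid_probability(pv, grid)
  expect_equal(out$data[12, 12, 3], 0.8, tolerance = 1e-9)
  # anchors one subregion width away still see the bright cell in their grid
  expect_equal(out$data[12, 15, 3], 0.8, tolerance = 1e-9)
  expect_equal(out$data[9, 12, 4], 0.8, tolerance = 1e-9)
  # anchors beyond the grid's reach do not
  expect_lt(out$data[12, 24, 3], 1e-6)

  expect_error(presyn_grid_probability(
    probability_volume(array(0.5, c(6, 6, 2)), res_at), grid),
    "larger input or a smaller grid")
})

test_that("grid search equals exhaustive subregion enumeration", {
  grid <- grid_geometry(1, 3)
  set.seed(202)
  for (i in 1:3) {
    arr <- array(runif(24 * 24 * 5), c(24, 24, 5))
    fast <- presyn_grid_probability(arr, grid)
    slow <- oracle_grid_search(arr, W = 1, k = 3)
    expect_lt(max(abs(fast - slow) / pmax(slow, 1e-300)), 1e-9)
  }
})

test_that("channel combination is a probabilistic AND", {
  a <- probability_volume(array(0.9, c(4, 4, 2)), res_at)
  b <- probability_volume(array(0.8, c(4, 4, 2)), res_at)
  expect_equal(combine_channels(list(a))$data, a$data)
  expect_equal(combine_channels(list(a, b))$data[1, 1, 1], 0.72)
  zero <- probability_volume(array(0, c(4, 4, 2)), res_at)
  expect_equal(max(combine_channels(list(a, b, zero))$data), 0)
  bad <- probability_volume(array(1, c(4, 4, 3)), res_at)
  expect_error(combine_channels(list(a, bad)), "shape")
})

test_that("run_query needs every queried channel and reports what exists", {
  ch <- channel_volume("synapsin", noise_array(c(32, 32, 5), seed = 1), res_at)
  err <- tryCatch(run_query(list(synapsin = ch), q_excit()),
                  error = conditionMessage)
  expect_match(err, "PSD-95")
  expect_match(err, "available")
  expect_match(err, "synapsin")
})

test_that("an adjacent pre/post pair creates the dominant peak, and the map
           matches an independent trace of the whole pipeline", {
  d <- c(48, 48, 9)
  syn <- add_blob(noise_array(d, seed = 21), 24.3, 23.6, 5.2,
                  amplitude = 100, sigma_px = 1.5, span = 3)
  psd <- add_blob(noise_array(d, seed = 22), 23.2, 24.8, 5.2,
                  amplitude = 100, sigma_px = 1.5, span = 3)
  channels <- list(
    synapsin = channel_volume("synapsin", round(syn), res_at),
    `PSD-95` = channel_volume("PSD-95", round(psd), res_at))
  map <- run_query(channels, q_excit())

  # the global maximum sits at the planted postsynaptic punctum
  pk <- arrayInd(which.max(map$data), d)
  expect_lte(sqrt(sum((pk[1:2] - c(23.2, 24.8))^2)), 3)
  expect_equal(pk[3], 5, tolerance = 1)
  # and towers over the rest of the map
  expect_gt(max(map$data), 100 * median(map$data))

  # independent end-to-end trace with the loop oracles
  trace_channel <- function(ch) {
    m <- fit_background(ch)
    pf <- array(0, d)
    for (k in seq_len(d[3]))
      pf[, , k] <- pnorm(ch$data[, , k], m$mu[k], m$sigma[k])
    pp <- oracle_puncta2d(pf, 1)
    pp * oracle_span_factor(pp, 1, 1)
  }
  p_pres_o <- oracle_grid_search(trace_channel(channels$synapsin), W = 1, k = 3)
  manual <- p_pres_o * trace_channel(channels$`PSD-95`)
  expect_lt(max(abs(map$data - manual)), 1e-9)
})

test_that("query semantics are conjunctive: losing one marker kills the map", {
  d <- c(48, 48, 9)
  syn <- add_blob(noise_array(d, seed = 31), 24, 24, 5,
                  amplitude = 100, sigma_px = 1.5, span = 3)
  psd <- add_blob(noise_array(d, seed = 32), 23, 25, 5,
                  amplitude = 100, sigma_px = 1.5, span = 3)
  both <- list(synapsin = channel_volume("synapsin", round(syn), res_at),
               `PSD-95` = channel_volume("PSD-95", round(psd), res_at))
  peak_both <- max(run_query(both, q_excit())$data)

  # postsynaptic punctum with no presynaptic partner anywhere
  no_pre <- both
  no_pre$synapsin <- channel_volume("synapsin",
                                    round(noise_array(d, seed = 31)), res_at)
  peak_no_pre <- max(run_query(no_pre, q_excit())$data)
  # presynaptic punctum with no postsynaptic partner
  no_post <- both
  no_post$`PSD-95` <- channel_volume("PSD-95",
                                     round(noise_array(d, seed = 32)), res_at)
  peak_no_post <- max(run_query(no_post, q_excit())$data)

  # with the marker absent only noise evidence remains; the conjunction
  # collapses the peak by the missing factor (the grid's best noise cell
  # keeps the residual from reaching the clamp floor exactly)
  expect_gt(peak_both, 0.1)
  expect_lt(peak_no_pre, peak_both / 5)
  expect_lt(peak_no_post, peak_both / 5)
  expect_lt(peak_no_pre, 0.05)
  expect_lt(peak_no_post, 0.05)
})

test_that("the grid tolerates small pre/post offsets but not distant pairs", {
  d <- c(64, 64, 9)
  base <- noise_array(d, seed = 41)
  psd <- add_blob(noise_array(d, seed = 42), 32, 32, 5,
                  amplitude = 100, sigma_px = 1.5, span = 3)
  peak_at_offset <- function(dx) {
    syn <- add_blob(base, 32, 32 + dx, 5,
                    amplitude = 100, sigma_px = 1.5, span = 3)
    ch <- list(synapsin = channel_volume("synapsin", round(syn), res_at),
               `PSD-95` = channel_volume("PSD-95", round(psd), res_at))
    m <- run_query(ch, q_excit())$data
    max(m[29:35, 29:35, 4:6])
  }
  perfect <- peak_at_offset(0)
  near <- peak_at_offset(3)      # one subregion width away
  far <- peak_at_offset(25)      # beyond the 9x9 px grid reach
  expect_gt(near, 0.3 * perfect)
  expect_lt(far, perfect / 50)
})

test_that("the synapse map is translation-equivariant in the interior", {
  d <- c(40, 40, 7)
  mk <- function(shift_y, shift_x) {
    syn <- add_blob(array(150, d), 20 + shift_y, 20 + shift_x, 4,
                    amplitude = 100, sigma_px = 1.5, span = 3)
    psd <- add_blob(array(150, d), 21 + shift_y, 19 + shift_x, 4,
                    amplitude = 100, sigma_px = 1.5, span = 3)
    # flat background: per-slice moments are then invariant under in-plane
    # translation of the blobs, so the maps must translate exactly
    list(synapsin = channel_volume("synapsin", syn, res_at),
         `PSD-95` = channel_volume("PSD-95", psd, res_at))
  }
  m0 <- run_query(mk(0, 0), q_excit())$data
  m1 <- run_query(mk(2, 3), q_excit())$data
  # compare interior windows around the two peak locations
  expect_equal(m1[(14:28) + 2, (14:28) + 3, 3:5], m0[14:28, 14:28, 3:5],
               tolerance = 1e-6)
})
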