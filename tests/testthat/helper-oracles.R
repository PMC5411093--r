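# Independent brute-force oracles. These deliberately avoid the package's
# integral-image / vectorised code paths: everything here is naive nested
# loops, so agreement with the fast implementations is evidence, not
# tautology.

clampi <- function(i, n) pmin(pmax(i, 1L), n)

# Windowed probability product with replicate padding, by direct looping.
oracle_puncta2d <- function(pf, W, floor = 1e-12) {
  d <- dim(pf)
  pfc <- pmin(pmax(pf, floor), 1)
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    acc <- 1
    for (dy in -W:W) for (dx in -W:W)
      acc <- acc * pfc[clampi(y + dy, d[1]), clampi(x + dx, d[2]), z]
    out[y, x, z] <- acc
  }
  out
}

# Slice-span factor by direct looping with replicate padding in z.
oracle_span_factor <- function(pp, j_before, j_after) {
  d <- dim(pp)
  out <- array(0, d)
  offs <- c(if (j_before > 0) -seq_len(j_before), if (j_after > 0) seq_len(j_after))
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    s <- 0
    for (j in offs)
      s <- s + (pp[y, x, z] - pp[y, x, clampi(z + j, d[3])])^2
    out[y, x, z] <- exp(-s)
  }
  out
}

# Grid search by exhaustive subregion enumeration: for every anchor, every
# k x k x z_extent cell's geometric-mean probability (window sums computed
# naively), maximum wins.
oracle_grid_search <- function(p3dp, W, k, z_extent = k, floor = 1e-12) {
  d <- dim(p3dp)
  cw <- 2L * W + 1L
  L <- log(pmin(pmax(p3dp, floor), 1))
  # naive cell geometric-mean score centred at each voxel
  M <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    s <- 0
    for (dy in -W:W) for (dx in -W:W)
      s <- s + L[clampi(y + dy, d[1]), clampi(x + dx, d[2]), z]
    M[y, x, z] <- s / cw^2
  }
  offs <- (seq_len(k) - (k + 1L) / 2L) * cw
  dzs <- seq_len(z_extent) - (z_extent + 1L) / 2L
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    best <- -Inf
    for (oz in dzs) for (oy in offs) for (ox in offs) {
      v <- M[clampi(y + oy, d[1]), clampi(x + ox, d[2]), clampi(z + oz, d[3])]
      if (v > best) best <- v
    }
    out[y, x, z] <- exp(best)
  }
  out
}

# Stack-based flood fill labelling of a logical mask.
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- list(as.integer(arrayInd(start, d)))
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1L) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Size of the maximum one-to-one matching between detections and truths
# given a logical nd x nt "within tolerance" matrix, by exhaustive recursion
# (fine for <= 8 objects).
oracle_max_matching <- function(ok) {
  nd <- nrow(ok)
  rec <- function(i, used) {
    if (i > nd) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  if (nd == 0L || ncol(ok) == 0L) return(0L)
  rec(1L, rep(FALSE, ncol(ok)))
}

# Adjusted-Wald interval written out from the formula, independent of the
# package implementation.
oracle_agresti_coull <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n_adj <- n + z * z
  p_adj <- (x + z * z / 2) / n_adj
  hw <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  c(max(0, p_adj - hw), min(1, p_adj + hw))
}

# Deterministic Gaussian blob, for constructing controlled fixtures without
# the simulator (in-plane sigma in px, truncated at 3 sigma; Gaussian axial
# weights with FWHM = span).
add_blob <- function(arr, y, x, z, amplitude, sigma_px = 1.5, span = 3L) {
  d <- dim(arr)
  r <- ceiling(3 * sigma_px)
  ys <- max(1L, floor(y - r)):min(d[1], ceiling(y + r))
  xs <- max(1L, floor(x - r)):min(d[2], ceiling(x + r))
  d2 <- outer(((ys - 0.5) - y)^2, ((xs - 0.5) - x)^2, "+")
  w <- exp(-d2 / (2 * sigma_px^2))
  w[d2 > (3 * sigma_px)^2] <- 0
  sigma_z <- max(span, 1) / 2.355
  for (dz in (-ceiling((span - 1) / 2)):(floor((span - 1) / 2))) {
    sz <- ceiling(z) + dz
    if (sz < 1L || sz > d[3]) next
    arr[ys, xs, sz] <- arr[ys, xs, sz] + amplitude * exp(-dz^2 / (2 * sigma_z^2)) * w
  }
  arr
}

noise_array <- function(d, mu = 100, sigma = 20, seed = 1L) {
  set.seed(seed)
  pmax(array(stats::rnorm(prod(d), mu, sigma), d), 0)
}
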