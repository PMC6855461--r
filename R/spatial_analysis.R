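#' Dwell-normalized firing-rate map
#'
#' Bins the arena into `bin`-sized squares (default 3 cm), accumulates dwell
#' time and spike counts, and divides spikes by dwell. Optionally smooths
#' with a 5x5 moving boxcar; unvisited bins are excluded from the smoothing
#' average (not treated as zeros) and keep rate 0.
#'
#' @param spikes a `spike_train` (spike positions are interpolated from the
#'   trajectory by time if absent).
#' @param traj the [trajectory] the spikes were recorded on.
#' @param bin bin side in meters (default 0.03).
#' @param smooth apply the 5x5 boxcar (default TRUE).
#' @return object of class `rate_map`: list with matrices `rates` (Hz),
#'   `dwell` (s), `counts`, plus `bin`, `arena_side`, `smoothed`.
#' @export
rate_map <- function(spikes, traj, bin = 0.03, smooth = TRUE) {
  L <- attr(traj, "arena_side")
  dt_pos <- attr(traj, "dt_pos")
  nb <- ceiling(L / bin - 1e-9)
  bx <- pmin(pmax(floor(traj$x / bin), 0), nb - 1) + 1
  by <- pmin(pmax(floor(traj$y / bin), 0), nb - 1) + 1
  dwell <- matrix(0, nb, nb)
  tab <- table(factor(bx, levels = 1:nb), factor(by, levels = 1:nb))
  dwell <- matrix(as.numeric(tab), nb, nb) * dt_pos
  counts <- matrix(0, nb, nb)
  times <- spikes$times
  if (length(times) > 0) {
    if (any(times < min(traj$t) - 1e-9 | times > max(traj$t) + 1e-9))
      stop("data error: spike time outside trajectory span")
    sx <- spikes$x; sy <- spikes$y
    if (is.null(sx)) {
      sx <- approx(traj$t, traj$x, times, rule = 2)$y
      sy <- approx(traj$t, traj$y, times, rule = 2)$y
    }
    sbx <- pmin(pmax(floor(sx / bin), 0), nb - 1) + 1
    sby <- pmin(pmax(floor(sy / bin), 0), nb - 1) + 1
    stab <- table(factor(sbx, levels = 1:nb), factor(sby, levels = 1:nb))
    counts <- matrix(as.numeric(stab), nb, nb)
  }
  rates <- matrix(0, nb, nb)
  vis <- dwell > 0
  rates[vis] <- counts[vis] / dwell[vis]
  if (smooth) rates <- boxcar_smooth(rates, vis, k = 5)
  structure(list(rates = rates, dwell = dwell, counts = counts, bin = bin,
                 arena_side = L, smoothed = smooth),
            class = "rate_map")
}

# 5x5 boxcar mean restricted to visited bins, window truncated at the edges
boxcar_smooth <- function(r, vis, k = 5) {
  h <- (k - 1) / 2
  n1 <- nrow(r); n2 <- ncol(r)
  num <- matrix(0, n1, n2); den <- matrix(0, n1, n2)
  rv <- r; rv[!vis] <- 0
  w <- matrix(0, n1, n2); w[vis] <- 1
  for (di in -h:h) {
    si <- max(1, 1 + di):min(n1, n1 + di)
    ti <- max(1, 1 - di):min(n1, n1 - di)
    for (dj in -h:h) {
      sj <- max(1, 1 + dj):min(n2, n2 + dj)
      tj <- max(1, 1 - dj):min(n2, n2 - dj)
      num[ti, tj] <- num[ti, tj] + rv[si, sj]
      den[ti, tj] <- den[ti, tj] + w[si, sj]
    }
  }
  out <- matrix(0, n1, n2)
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out[!vis] <- 0
  out
}

#' @export
print.rate_map <- function(x, ...) {
  cat("Rate map: ", nrow(x$rates), "x", ncol(x$rates), " bins of ",
      x$bin * 100, " cm, peak ", sprintf("%.2f", max(x$rates)), " Hz",
      if (x$smoothed) " (smoothed)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
plot.rate_map <- function(x, ...) {
  image(seq(0, x$arena_side, length.out = nrow(x$rates)),
        seq(0, x$arena_side, length.out = ncol(x$rates)),
        x$rates, asp = 1, xlab = "x (m)", ylab = "y (m)",
        col = hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Detect firing fields
#'
#' Connected components (4-connectivity) of bins whose smoothed rate is at
#' least `peak_fraction` of the map peak. Components smaller than `min_bins`
#' bins are discarded. A field is viable when its area lies between
#' `min_area_cm2` and `max_fraction` of the arena.
#'
#' @param rmap a [rate_map] (should be smoothed).
#' @param peak_fraction rate threshold relative to the map peak.
#' @param min_bins minimum number of adjacent bins forming a field.
#' @param max_fraction maximum viable field area as a fraction of the arena.
#' @param min_area_cm2 lower viability bound in cm^2.
#' @return object of class `field_set`: list of fields, each with `bins`
#'   (index matrix), `n_bins`, `area` (cm^2), `peak_rate`, `centroid`
#'   (meters), `viable`.
#' @export
detect_fields <- function(rmap, peak_fraction = 0.2, min_bins = 15,
                          max_fraction = 0.6, min_area_cm2 = 240) {
  r <- rmap$rates
  mx <- max(r)
  out <- structure(list(fields = list(), bin = rmap$bin,
                        arena_side = rmap$arena_side), class = "field_set")
  if (mx <= 0) return(out)
  thr <- peak_fraction * mx
  lab <- label_components(r >= thr)
  arena_cm2 <- (rmap$arena_side * 100)^2
  bin_cm2 <- (rmap$bin * 100)^2
  for (id in seq_len(max(lab))) {
    bins <- which(lab == id, arr.ind = TRUE)
    if (nrow(bins) < min_bins) next
    area <- nrow(bins) * bin_cm2
    rates <- r[bins]
    centroid <- c(x = sum((bins[, 1] - 0.5) * rates) / sum(rates) * rmap$bin,
                  y = sum((bins[, 2] - 0.5) * rates) / sum(rates) * rmap$bin)
    viable <- area >= min_area_cm2 && area <= max_fraction * arena_cm2
    out$fields[[length(out$fields) + 1]] <-
      list(bins = bins, n_bins = nrow(bins), area = area,
           peak_rate = max(rates), centroid = centroid, viable = viable)
  }
  out
}

# 4-connected component labelling by flood fill
label_components <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  cur <- 0L
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        a <- p[1] + d[1]; b <- p[2] + d[2]
        if (a >= 1 && a <= n1 && b >= 1 && b <= n2 &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- cur
          stack[[length(stack) + 1]] <- c(a, b)
        }
      }
    }
  }
  lab
}

#' @export
print.field_set <- function(x, ...) {
  nv <- sum(vapply(x$fields, function(f) f$viable, logical(1)))
  cat("Field set: ", length(x$fields), " fields (", nv, " viable)\n", sep = "")
  for (f in x$fields)
    cat(sprintf("  %4d bins, %7.1f cm2, peak %6.2f Hz, centroid (%.2f, %.2f) m%s\n",
                f$n_bins, f$area, f$peak_rate, f$centroid[1], f$centroid[2],
                if (f$viable) " [viable]" else ""))
  invisible(x)
}

#' Spatial autocorrelogram
#'
#' Full 2-D spatial autocorrelation of a rate map. For each lag the value is
#' the Pearson correlation of the map with its shifted copy over the
#' overlapping region (the convention required by grid-score analysis); lags
#' with fewer than `min_overlap` overlapping bins are set to `NA`. The raw
#' unnormalized cross-sum `sum X(m,n) X(m-k, n-l)` is available with
#' `normalize = FALSE`.
#'
#' @param rmap a [rate_map] or a plain numeric matrix.
#' @param normalize Pearson-per-lag (default) or raw cross-sum.
#' @param min_overlap minimum overlapping bins per lag.
#' @return object of class `autocorrelogram`: list with `c`
#'   ((2M-1) x (2N-1) matrix), `center` (index of zero lag), `bin`.
#' @export
autocorrelogram <- function(rmap, normalize = TRUE, min_overlap = 20) {
  X <- if (inherits(rmap, "rate_map")) rmap$rates else rmap
  bin <- if (inherits(rmap, "rate_map")) rmap$bin else 1
  M <- nrow(X); N <- ncol(X)
  if (stats::sd(as.numeric(X)) == 0) {
    warning("constant map: autocorrelogram undefined, returning zeros")
    cc <- matrix(0, 2 * M - 1, 2 * N - 1)
    if (!normalize) cc <- matrix(0, 2 * M - 1, 2 * N - 1)
    return(structure(list(c = cc, center = c(M, N), bin = bin,
                          normalized = normalize),
                     class = "autocorrelogram"))
  }
  cc <- matrix(NA_real_, 2 * M - 1, 2 * N - 1)
  for (k in -(M - 1):(M - 1)) {
    i1 <- max(1, 1 + k):min(M, M + k)   # indices into X (shifted)
    i0 <- i1 - k                        # indices into X (reference)
    for (l in -(N - 1):(N - 1)) {
      j1 <- max(1, 1 + l):min(N, N + l)
      j0 <- j1 - l
      a <- X[i0, j0]; b <- X[i1, j1]
      if (!normalize) {
        cc[M + k, N + l] <- sum(a * b)
      } else {
        nov <- length(a)
        if (nov < min_overlap) next
        sa <- stats::sd(a); sb <- stats::sd(b)
        if (sa == 0 || sb == 0) next
        cc[M + k, N + l] <- stats::cor(as.numeric(a), as.numeric(b))
      }
    }
  }
  structure(list(c = cc, center = c(M, N), bin = bin, normalized = normalize),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat("Autocorrelogram: ", nrow(x$c), "x", ncol(x$c), " lags",
      if (x$normalized) " (Pearson per lag)" else " (raw cross-sum)",
      "\n", sep = "")
  invisible(x)
}

# local maxima of the autocorrelogram outside the center, 3x3 neighborhood,
# correlation >= min_corr, duplicates within merge_dist bins merged; lags
# whose overlap region is below min_overlap_frac of the map are unstable
# and excluded
acorr_peaks <- function(acorr, min_corr = 0.1, merge_dist = 2,
                        min_overlap_frac = 0.2) {
  cc <- acorr$c
  ctr <- acorr$center
  nr <- nrow(cc); nc <- ncol(cc)
  M <- ctr[1]; N <- ctr[2]
  k_lag <- abs(row(cc) - ctr[1]); l_lag <- abs(col(cc) - ctr[2])
  frac <- (M - k_lag) * (N - l_lag) / (M * N)
  cc[frac < min_overlap_frac] <- NA
  cand <- which(!is.na(cc) & cc >= min_corr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    nb <- cc[max(1, a - 1):min(nr, a + 1), max(1, b - 1):min(nc, b + 1)]
    keep[i] <- cc[a, b] >= max(nb, na.rm = TRUE)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  ord <- order(-cc[cand])
  cand <- cand[ord, , drop = FALSE]
  sel <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!sel[i]) next
    if (i < nrow(cand)) {
      d <- sqrt((cand[(i + 1):nrow(cand), 1] - cand[i, 1])^2 +
                  (cand[(i + 1):nrow(cand), 2] - cand[i, 2])^2)
      sel[(i + 1):nrow(cand)][d <= merge_dist] <- FALSE
    }
  }
  cand <- cand[sel, , drop = FALSE]
  # drop the central peak (and anything merged into it)
  d_ctr <- sqrt((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2)
  cand[d_ctr > merge_dist, , drop = FALSE]
}

#' Grid spacing and field area
#'
#' Spacing is the mean distance (cm) from the autocorrelogram center to the
#' up-to-six nearest off-center peaks; with fewer than six peaks the circle
#' through the outermost detected peak is used as the fallback. Field area
#' is the mean area of the fields detected on the rate map.
#'
#' @param acorr an [autocorrelogram].
#' @param rmap the underlying [rate_map] (for field areas); optional.
#' @param min_bins minimum bins per field passed to [detect_fields()].
#' @return list with `spacing_cm` (NA if no off-center peak),
#'   `field_area_cm2`, `n_peaks`, `peaks` (lag indices).
#' @export
grid_spacing_and_area <- function(acorr, rmap = NULL, min_bins = 15) {
  pk <- acorr_peaks(acorr)
  out <- list(spacing_cm = NA_real_, field_area_cm2 = NA_real_,
              n_peaks = nrow(pk), peaks = pk)
  if (nrow(pk) > 0) {
    d <- sqrt((pk[, 1] - acorr$center[1])^2 + (pk[, 2] - acorr$center[2])^2) *
      acorr$bin * 100
    d <- sort(d)
    out$spacing_cm <- if (length(d) >= 6) mean(d[1:6]) else max(d)
  }
  if (!is.null(rmap)) {
    fs <- detect_fields(rmap, min_bins = min_bins, min_area_cm2 = 0,
                        max_fraction = 1)
    if (length(fs$fields) > 0)
      out$field_area_cm2 <-
        mean(vapply(fs$fields, function(f) f$area, numeric(1)))
  }
  out
}

# rotate a matrix about its center by ang (radians), bilinear interpolation;
# cells falling outside become NA
rotate_matrix <- function(m, ang) {
  nr <- nrow(m); nc <- ncol(m)
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  out <- matrix(NA_real_, nr, nc)
  co <- cos(ang); si <- sin(ang)
  jj <- rep(seq_len(nc), each = nr)
  ii <- rep(seq_len(nr), nc)
  # source coordinates under inverse rotation
  x <- co * (ii - ci) + si * (jj - cj) + ci
  y <- -si * (ii - ci) + co * (jj - cj) + cj
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 + 1 <= nr & y0 >= 1 & y0 + 1 <= nc
  val <- rep(NA_real_, length(ii))
  idx <- function(i, j) (j - 1) * nr + i
  v00 <- m[idx(x0[ok], y0[ok])]; v10 <- m[idx(x0[ok] + 1, y0[ok])]
  v01 <- m[idx(x0[ok], y0[ok] + 1)]; v11 <- m[idx(x0[ok] + 1, y0[ok] + 1)]
  val[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) + v10 * fx[ok] * (1 - fy[ok]) +
    v01 * (1 - fx[ok]) * fy[ok] + v11 * fx[ok] * fy[ok]
  out[] <- val
  out
}

#' Grid score
#'
#' Rotational-symmetry statistic of the autocorrelogram: the map is rotated
#' in 6-degree steps and correlated with the original over an annulus
#' excluding the central peak; the score is
#' `min(corr(60), corr(120)) - max(corr(30), corr(90), corr(150))`.
#' Positive values indicate 60-degree (hexagonal) symmetry.
#'
#' @param acorr an [autocorrelogram].
#' @param inner_radius,outer_radius annulus radii in lag bins; by default
#'   derived from the detected peaks (inner = half the nearest-peak
#'   distance, outer = outermost peak + 2 bins).
#' @return grid score (dimensionless), or NA when the annulus is degenerate.
#' @export
grid_score <- function(acorr, inner_radius = NULL, outer_radius = NULL) {
  cc <- acorr$c
  ctr <- acorr$center
  if (is.null(inner_radius) || is.null(outer_radius)) {
    pk <- acorr_peaks(acorr)
    if (nrow(pk) == 0) return(NA_real_)
    d <- sqrt((pk[, 1] - ctr[1])^2 + (pk[, 2] - ctr[2])^2)
    if (is.null(inner_radius)) inner_radius <- min(d) / 2
    if (is.null(outer_radius)) outer_radius <- max(d) + 2
  }
  if (outer_radius <= inner_radius) return(NA_real_)
  # conventional estimator: the rotated (bilinearly interpolated) map is
  # correlated against the original over the annulus
  nr <- nrow(cc); nc <- ncol(cc)
  ii <- rep(seq_len(nr), nc); jj <- rep(seq_len(nc), each = nr)
  rad <- sqrt((ii - ctr[1])^2 + (jj - ctr[2])^2)
  annulus <- rad >= inner_radius & rad <= outer_radius
  if (sum(annulus) < 20) return(NA_real_)
  base <- as.numeric(cc)
  corr_at <- vapply(seq(30, 150, by = 30), function(deg) {
    rot <- as.numeric(rotate_matrix(cc, deg * pi / 180))
    ok <- annulus & !is.na(base) & !is.na(rot)
    if (sum(ok) < 20) return(NA_real_)
    stats::cor(base[ok], rot[ok])
  }, numeric(1))
  names(corr_at) <- seq(30, 150, by = 30)
  min(corr_at["60"], corr_at["120"]) -
    max(corr_at["30"], corr_at["90"], corr_at["150"])
}

# bilinear interpolation of matrix m at fractional indices (x, y)
interp_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 + 1 <= nr & y0 >= 1 & y0 + 1 <= nc
  out <- rep(NA_real_, length(x))
  idx <- function(i, j) (j - 1) * nr + i
  v00 <- m[idx(x0[ok], y0[ok])]; v10 <- m[idx(x0[ok] + 1, y0[ok])]
  v01 <- m[idx(x0[ok], y0[ok] + 1)]; v11 <- m[idx(x0[ok] + 1, y0[ok] + 1)]
  out[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) + v10 * fx[ok] * (1 - fy[ok]) +
    v01 * (1 - fx[ok]) * fy[ok] + v11 * fx[ok] * fy[ok]
  out
}
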