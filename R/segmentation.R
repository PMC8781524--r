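#' Otsu threshold of an intensity histogram
#'
#' Classical Otsu thresholding: the returned threshold `t` maximizes the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2` over all splits of the
#' histogram into a background class (bins `< t`) and a foreground class
#' (bins `>= t`). Bins are indexed from 0. Co-optimal thresholds are resolved
#' to the smallest qualifying `t`.
#'
#' @param histogram Integer/numeric vector of bin counts (typically 256 bins).
#' @return Integer threshold `t` in `1 .. length(histogram) - 1`: pixels in
#'   bins `>= t` are foreground.
#' @export
#' @examples
#' h <- numeric(256); h[11] <- 40; h[201] <- 60  # mass at bins 10 and 200
#' otsu_threshold(h)  # 11: splits {10} from {200}
otsu_threshold <- function(histogram) {
  counts <- as.numeric(histogram)
  if (any(counts < 0) || !length(counts)) abort("Histogram counts must be >= 0.")
  nb <- length(counts)
  if (sum(counts > 0) < 2L) {
    abort("Otsu threshold undefined: fewer than two occupied bins.")
  }
  total <- sum(counts)
  bins <- seq_len(nb) - 1           # bin values 0 .. nb-1
  # cumulative weight/mean of the background class for each candidate split
  w0 <- cumsum(counts)[-nb] / total # background = bins < t, t = 1..nb-1
  m0 <- cumsum(counts * bins)[-nb] / total
  mt <- sum(counts * bins) / total
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[ok] <- (mt * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  which.max(sigma_b)                # first maximum = smallest co-optimal t
}

# 3x3 vectorized median via Paeth's 19-exchange network; edge-replicated.
median3x3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- x
  pad[1L, ] <- pad[2L, ]; pad[nr + 2L, ] <- pad[nr + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, nc + 2L] <- pad[, nc + 1L]
  p <- vector("list", 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    p[[k]] <- pad[(1L + di):(nr + di), (1L + dj):(nc + dj)]
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

median_filter <- function(x, halfwidth = 1L) {
  halfwidth <- as.integer(halfwidth)
  if (halfwidth <= 0L) return(x)
  if (halfwidth == 1L) return(median3x3(x))
  # general (slow) fallback for larger windows
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (j in seq_len(nc)) {
    js <- max(1L, j - halfwidth):min(nc, j + halfwidth)
    for (i in seq_len(nr)) {
      is <- max(1L, i - halfwidth):min(nr, i + halfwidth)
      out[i, j] <- median(x[is, js])
    }
  }
  out
}

# log-compress linear intensity over a 60-dB display range (floor at 1e-6 of
# the image maximum); standard OCT display scale used before thresholding
log_compress <- function(intensity) {
  m <- max(intensity)
  if (m <= 0) return(intensity * 0)
  log10(pmax(intensity, m * 1e-6))
}

binarize_otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) abort("Single-valued image: no separable classes.")
  b <- pmin(as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * nbins)),
            nbins - 1L)
  h <- tabulate(b + 1L, nbins)
  t <- otsu_threshold(h)
  list(mask = matrix(b >= t, nrow(x), ncol(x)), threshold_bin = t)
}

#' Detect top and bottom sample surfaces in a B-scan
#'
#' Surface segmentation by intensity thresholding: the log-compressed
#' intensity image is median-smoothed, binarized at the Otsu threshold of its
#' 256-bin histogram, and scanned per column. The top surface is the first
#' pixel of the first run of at least `min_run` consecutive suprathreshold
#' pixels; the bottom surface is the last pixel of the last such run. When
#' the suprathreshold region extends to the bottom of the imaging window the
#' bottom surface is not visible; the deepest suprathreshold pixel is then
#' recorded as the maximum detection depth instead. Columns with no
#' qualifying run are flagged invalid (never an error).
#'
#' @param pair A `psoct_bscan`.
#' @param smoothing_halfwidth Median-filter half-width in pixels (`1` = 3x3,
#'   `0` = no smoothing).
#' @param min_run Minimum run length of suprathreshold pixels, px.
#' @param nbins Number of histogram bins for Otsu.
#' @param use_log Threshold the log-compressed (60-dB) intensity rather than
#'   the linear intensity; recommended (and default) because OCT intensity
#'   spans several decades with depth.
#' @return A `psoct_segmentation`: a tibble with one row per column
#'   (`column`, `top`, `bottom`, `max_depth`, `valid`); `bottom` is `NA` when
#'   not visible, in which case `max_depth` holds the deepest suprathreshold
#'   row.
#' @export
detect_surfaces <- function(pair, smoothing_halfwidth = 1L, min_run = 3L,
                            nbins = 256L, use_log = TRUE) {
  stopifnot(inherits(pair, "psoct_bscan"))
  img <- if (use_log) log_compress(pair$intensity) else pair$intensity
  img <- median_filter(img, smoothing_halfwidth)
  bin <- binarize_otsu(img, nbins)
  mask <- bin$mask
  D <- nrow(mask); W <- ncol(mask)

  res <- purrr::map_dfr(seq_len(W), function(j) {
    col <- mask[, j]
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    good <- which(r$values & r$lengths >= min_run)
    if (!length(good)) {
      return(tibble(column = j, top = NA_integer_, bottom = NA_integer_,
                    max_depth = NA_integer_, valid = FALSE))
    }
    top <- starts[good[1]]
    last_end <- ends[good[length(good)]]
    if (last_end >= D) {
      tibble(column = j, top = top, bottom = NA_integer_,
             max_depth = as.integer(last_end), valid = TRUE)
    } else {
      tibble(column = j, top = top, bottom = as.integer(last_end),
             max_depth = as.integer(last_end), valid = TRUE)
    }
  })
  structure(res,
    class = c("psoct_segmentation", class(res)),
    threshold_bin = bin$threshold_bin
  )
}

#' Flatten a B-scan to its detected surface
#'
#' Shifts every valid column upward so that its detected top surface lands on
#' row 1, making the sample surface perfectly horizontal. Shifts are whole
#' pixels (no resampling, so retardation values are untouched). Pixels with
#' no data after the shift, pixels beyond each column's bottom/maximum
#' detection depth, and all pixels of invalid columns are set to the `NA`
#' sentinel and excluded from downstream averages. The original arrays are
#' recoverable exactly via [unflatten()].
#'
#' @param pair A `psoct_bscan`.
#' @param seg The [detect_surfaces()] result for `pair`.
#' @param mask_below_max_depth Mask pixels deeper than the detected
#'   bottom / maximum detection depth (default `TRUE`).
#' @return A `psoct_flat` object: `intensity` and `retardation` matrices with
#'   the surface at row 1, per-column `shifts`, the per-column `depth_extent`
#'   (number of in-sample rows), `valid` flags and the `config`.
#' @export
flatten <- function(pair, seg, mask_below_max_depth = TRUE) {
  stopifnot(inherits(pair, "psoct_bscan"), inherits(seg, "psoct_segmentation"))
  D <- nrow(pair$intensity); W <- ncol(pair$intensity)
  if (nrow(seg) != W) abort("Segmentation does not match the B-scan shape.")
  flat_i <- matrix(NA_real_, D, W)
  flat_r <- matrix(NA_real_, D, W)
  shifts <- integer(W)
  extent <- rep(NA_integer_, W)
  for (j in seq_len(W)) {
    if (!seg$valid[j]) next
    top <- seg$top[j]
    shifts[j] <- top - 1L
    nkeep <- D - top + 1L
    flat_i[seq_len(nkeep), j] <- pair$intensity[top:D, j]
    flat_r[seq_len(nkeep), j] <- pair$retardation[top:D, j]
    extent[j] <- seg$max_depth[j] - top + 1L
    if (mask_below_max_depth && extent[j] < D) {
      drop <- (extent[j] + 1L):D
      flat_i[drop, j] <- NA_real_
      flat_r[drop, j] <- NA_real_
    }
  }
  structure(
    list(
      intensity = flat_i,
      retardation = flat_r,
      shifts = shifts,
      depth_extent = extent,
      valid = seg$valid,
      config = pair$config,
      original = list(intensity = pair$intensity,
                      retardation = pair$retardation,
                      provenance = pair$provenance)
    ),
    class = "psoct_flat"
  )
}

#' Undo a flattening
#'
#' Inverts the per-column shifts applied by [flatten()], restoring the
#' original co-registered B-scan pair exactly (flattening is lossless: the
#' rows cropped and masked during flattening are retained internally).
#'
#' @param flat A `psoct_flat`.
#' @return The original `psoct_bscan`.
#' @export
unflatten <- function(flat) {
  stopifnot(inherits(flat, "psoct_flat"))
  D <- nrow(flat$intensity); W <- ncol(flat$intensity)
  intensity <- flat$original$intensity
  retardation <- flat$original$retardation
  # verify the shift bookkeeping actually reproduces the unmasked region
  for (j in seq_len(W)) {
    if (!flat$valid[j]) next
    s <- flat$shifts[j]
    keep <- which(!is.na(flat$retardation[, j]))
    if (length(keep) &&
        !identical(flat$retardation[keep, j], retardation[keep + s, j])) {
      abort("Flattened data inconsistent with recorded shifts.")
    }
  }
  new_bscan_pair(intensity, retardation, flat$config,
                 flat$original$provenance)
}

#' Convert an axial pixel count to physical thickness
#'
#' Axial pixels sample optical path in air; dividing by the refractive index
#' converts the optical path to physical thickness inside the sample. The
#' conventional assumed index is 1.4.
#'
#' @param pixel_count Number of axial pixels, `>= 0`.
#' @param config An [imaging_config()].
#' @param refractive_index Assumed group refractive index, `>= 1`.
#' @return Physical thickness in micrometres.
#' @export
#' @examples
#' pixels_to_physical_thickness(140, imaging_config())  # 140 * 2.75 / 1.4 = 275
pixels_to_physical_thickness <- function(pixel_count, config,
                                         refractive_index = 1.4) {
  stopifnot(inherits(config, "psoct_config"))
  if (any(pixel_count < 0)) abort("`pixel_count` must be >= 0.")
  if (refractive_index < 1) abort("`refractive_index` must be >= 1.")
  pixel_count * config$axial_pixel_spacing_um / refractive_index
}
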