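#' Canonical ordering of the 54 object features
#'
#' 6 morphological features, 35 intensity statistics (minimum, maximum,
#' mean, median, standard deviation for each of the 7 channels), and 13
#' Haralick texture features computed on the DAB channel.
#'
#' @return Character vector of length 54.
#' @export
feature_names <- function() {
  morph <- c("area_um2", "circularity", "length_um",
             "max_diameter_um", "min_diameter_um", "solidity")
  stats <- c("min", "max", "mean", "median", "sd")
  intens <- as.vector(vapply(
    channel_names(),
    function(ch) paste(ch, stats, sep = "_"),
    character(5)
  ))
  har <- c("asm", "contrast", "correlation", "variance", "idm",
           "sum_average", "sum_variance", "sum_entropy", "entropy",
           "difference_variance", "difference_entropy", "imc1", "imc2")
  c(morph, intens, paste0("haralick_", har))
}

#' Grey-level co-occurrence parameters for Haralick features
#'
#' Defaults are standard texture-analysis settings: 32 grey levels after
#' per-object min-max rescaling, pixel distance 1, the four symmetric
#' directions (0, 45, 90, 135 degrees), base-2 logarithms.
#'
#' @param levels Number of grey levels (>= 2).
#' @param distance Pixel offset distance (>= 1).
#' @param directions Integer 1, 2 or 4: which of the standard offsets
#'   (0, 45, 90, 135 degrees) to accumulate; features are averaged over
#'   directions.
#' @param symmetric Accumulate each pair in both orders.
#' @param rescale Min-max normalise grey values per object before
#'   quantisation.
#' @return A list of class `glcm_params`.
#' @export
glcm_params <- function(levels = 32, distance = 1, directions = 4,
                        symmetric = TRUE, rescale = TRUE) {
  stopifnot(levels >= 2, distance >= 1, directions %in% c(1, 2, 4))
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 directions = as.integer(directions), symmetric = symmetric,
                 rescale = rescale),
            class = "glcm_params")
}

# Quantise values to integer levels 0..(levels-1); constant inputs map to 0.
quantize_levels <- function(x, levels, rescale = TRUE) {
  if (rescale) {
    rng <- range(x)
    if (rng[2] > rng[1]) {
      q <- floor((x - rng[1]) / (rng[2] - rng[1]) * levels)
    } else {
      q <- rep(0, length(x))
    }
  } else {
    q <- floor(pmin(pmax(x, 0), 1) * levels)
  }
  as.integer(pmin(q, levels - 1L))
}

# Accumulate a normalised (optionally symmetric) GLCM for one offset over
# pixel pairs that are both inside the mask. Returns NULL when no pair
# exists for this offset.
glcm_one_offset <- function(qimg, inmask, dr, dc, levels, symmetric) {
  nr <- nrow(qimg); nc <- ncol(qimg)
  idx <- which(inmask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  r2 <- rows + dr; c2 <- cols + dc
  ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
  nb <- idx[ok] + dr + dc * nr
  ok2 <- inmask[nb]
  a <- qimg[idx[ok][ok2]]
  b <- qimg[nb[ok2]]
  if (length(a) == 0) return(NULL)
  k <- a * levels + b + 1L
  tab <- tabulate(k, nbins = levels * levels)
  p <- matrix(tab, levels, levels, byrow = TRUE)
  if (symmetric) p <- p + t(p)
  p / sum(p)
}

# The 13 classical Haralick features from a normalised GLCM, base-2 logs.
haralick_from_glcm <- function(p) {
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum((0:(L - 1)) * px)
  mu_y <- sum((0:(L - 1)) * py)
  sd_x <- sqrt(sum(((0:(L - 1)) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((0:(L - 1)) - mu_y)^2 * py))
  log2z <- function(x) ifelse(x > 0, log2(x), 0)
  # p_{x+y}(k), k = 0..2L-2 ; p_{x-y}(k), k = 0..L-1
  pxy_sum <- vapply(0:(2 * L - 2), function(k) sum(p[i + j == k]), numeric(1))
  pxy_diff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  variance <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  ks <- 0:(2 * L - 2)
  sum_average <- sum(ks * pxy_sum)
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  sum_entropy <- -sum(pxy_sum * log2z(pxy_sum))
  entropy <- -sum(p * log2z(p))
  kd <- 0:(L - 1)
  dmu <- sum(kd * pxy_diff)
  difference_variance <- sum((kd - dmu)^2 * pxy_diff)
  difference_entropy <- -sum(pxy_diff * log2z(pxy_diff))
  hx <- -sum(px * log2z(px))
  hy <- -sum(py * log2z(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2)
}

# Limits for a constant (single grey level) object: deterministic GLCM with
# one cell, so ASM = IDM = 1 and every spread/entropy term is 0.
haralick_degenerate <- function() {
  c(asm = 1, contrast = 0, correlation = 0, variance = 0, idm = 1,
    sum_average = 0, sum_variance = 0, sum_entropy = 0, entropy = 0,
    difference_variance = 0, difference_entropy = 0, imc1 = 0, imc2 = 0)
}

#' Haralick texture features of one object
#'
#' Grey values under the mask are min-max rescaled and quantised, a
#' symmetric normalised grey-level co-occurrence matrix is accumulated per
#' direction over pixel pairs that both lie inside the mask, the 13
#' classical features are computed per direction and averaged.
#'
#' @param img Numeric matrix (typically the DAB OD channel).
#' @param pixels Column-major linear indices of the object's pixels
#'   (>= 2 pixels).
#' @param params A [glcm_params()] object.
#' @return Named numeric vector of 13 features (asm, contrast, correlation,
#'   variance, idm, sum_average, sum_variance, sum_entropy, entropy,
#'   difference_variance, difference_entropy, imc1, imc2).
#' @export
haralick_features <- function(img, pixels, params = glcm_params()) {
  if (length(pixels) < 2) stop("Haralick features need at least 2 pixels")
  vals <- img[pixels]
  q <- quantize_levels(vals, params$levels, params$rescale)
  if (length(unique(q)) == 1L) return(haralick_degenerate())
  qimg <- matrix(0L, nrow(img), ncol(img))
  qimg[pixels] <- q
  inmask <- matrix(FALSE, nrow(img), ncol(img))
  inmask[pixels] <- TRUE
  d <- params$distance
  offsets <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))[seq_len(params$directions)]
  feats <- list()
  for (off in offsets) {
    p <- glcm_one_offset(qimg, inmask, off[1], off[2], params$levels,
                         params$symmetric)
    if (!is.null(p)) feats[[length(feats) + 1L]] <- haralick_from_glcm(p)
  }
  if (length(feats) == 0) return(haralick_degenerate())
  colMeans(do.call(rbind, feats))
}

# Convex hull of the pixel-corner points, as an (x, y) matrix (0-based
# corners, y down). Used for solidity and the calliper diameters.
pixel_hull <- function(pixels, dims) {
  nr <- dims[1]
  rows <- ((pixels - 1L) %% nr)       # 0-based top corner
  cols <- ((pixels - 1L) %/% nr)
  pts <- unique(rbind(
    cbind(cols, rows), cbind(cols + 1L, rows),
    cbind(cols + 1L, rows + 1L), cbind(cols, rows + 1L)
  ))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Rotating-calliper diameters of a convex polygon: (max, min) width.
calliper_diameters <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(c(max = 0, min = 0))
  dmax <- 0
  for (a in 1:(n - 1)) {
    d2 <- (hull[(a + 1):n, 1] - hull[a, 1])^2 + (hull[(a + 1):n, 2] - hull[a, 2])^2
    dmax <- max(dmax, sqrt(max(d2)))
  }
  dmin <- Inf
  for (a in 1:n) {
    b <- if (a == n) 1 else a + 1
    e <- hull[b, ] - hull[a, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    dist <- abs((hull[, 1] - hull[a, 1]) * e[2] - (hull[, 2] - hull[a, 2]) * e[1]) / len
    dmin <- min(dmin, max(dist))
  }
  if (!is.finite(dmin)) dmin <- 0
  c(max = dmax, min = dmin)
}

#' Morphological features of one object
#'
#' Area is the calibrated pixel count. Length is the boundary perimeter of
#' the pixel mask (total length of exposed pixel edges, including hole
#' boundaries). Circularity is `4 * pi * area / length^2`. Maximum and
#' minimum diameters are the rotating-calliper (Feret) diameters of the
#' convex hull of the pixel corners. Solidity is the mask area over the
#' convex-hull area.
#'
#' @param pixels Column-major linear indices of the object's pixels.
#' @param dims Image dimensions `c(rows, cols)`.
#' @param mpp Microns per pixel.
#' @return Named numeric vector: `area_um2`, `circularity`, `length_um`,
#'   `max_diameter_um`, `min_diameter_um`, `solidity`.
#' @export
morphology_features <- function(pixels, dims, mpp) {
  if (length(pixels) == 0) stop("empty object mask")
  area_px <- length(pixels)
  perim_px <- exposed_edges(pixels, dims)
  hull <- pixel_hull(pixels, dims)
  cal <- calliper_diameters(hull)
  hull_area <- polygon_area(hull)
  c(
    area_um2 = area_px * mpp^2,
    circularity = 4 * pi * area_px / perim_px^2,
    length_um = perim_px * mpp,
    max_diameter_um = cal[["max"]] * mpp,
    min_diameter_um = cal[["min"]] * mpp,
    solidity = area_px / hull_area
  )
}

#' Per-channel intensity statistics of one object
#'
#' Minimum, maximum, mean, median and population standard deviation
#' (divisor n) of each of the 7 channels over the object's pixels.
#'
#' @param stack A [channel_stack()].
#' @param pixels Column-major linear indices of the object's pixels.
#' @return Named numeric vector of 35 values, ordered channel-major
#'   (red_min, red_max, ..., saturation_sd).
#' @export
intensity_features <- function(stack, pixels) {
  if (length(pixels) == 0) stop("empty object mask")
  out <- numeric(0)
  for (ch in channel_names()) {
    v <- stack[[ch]][pixels]
    n <- length(v)
    s <- c(min(v), max(v), mean(v), stats::median(v),
           sqrt(sum((v - mean(v))^2) / n))
    names(s) <- paste(ch, c("min", "max", "mean", "median", "sd"), sep = "_")
    out <- c(out, s)
  }
  out
}

#' Assemble the 54-feature vectors for detected objects
#'
#' Computes the morphology, intensity and Haralick blocks for every object
#' and returns them as one tidy table in the canonical
#' [feature_names()] order, ready to serialise as CSV.
#'
#' @param objects A `tau_objects` tibble from [detect_objects()].
#' @param stack The [channel_stack()] of the source tile.
#' @param glcm A [glcm_params()] object.
#' @return A tibble with `object_id`, `tile_id`, `region_group` and the 54
#'   feature columns.
#' @export
extract_features <- function(objects, stack, glcm = glcm_params()) {
  if (nrow(objects) > 0 &&
      !all(dim(stack$red) == c(objects$img_h[1], objects$img_w[1]))) {
    stop("channel stack shape must match the objects' tile")
  }
  rows <- lapply(seq_len(nrow(objects)), function(i) {
    px <- objects$pixels[[i]]
    c(
      morphology_features(px, c(objects$img_h[i], objects$img_w[i]),
                          objects$mpp[i]),
      intensity_features(stack, px),
      if (length(px) >= 2) {
        stats::setNames(haralick_features(stack$dab, px, glcm),
                        paste0("haralick_", names(haralick_degenerate())))
      } else {
        stats::setNames(haralick_degenerate(),
                        paste0("haralick_", names(haralick_degenerate())))
      }
    )
  })
  feats <- if (length(rows)) {
    tibble::as_tibble(do.call(rbind, rows))[, feature_names()]
  } else {
    tibble::as_tibble(matrix(numeric(0), 0, 54,
                             dimnames = list(NULL, feature_names())))
  }
  dplyr::bind_cols(
    objects[, intersect(c("object_id", "tile_id", "region_group"),
                        names(objects)), drop = FALSE],
    feats
  )
}
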