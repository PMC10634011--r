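#' Standard H-DAB stain matrix
#'
#' Optical-density unit vectors for haematoxylin and DAB in brightfield
#' H-DAB immunohistochemistry, with a residual third vector computed as the
#' normalised cross-product of the two dye vectors. Rows are stains
#' (haematoxylin, DAB, residual), columns are (R, G, B).
#'
#' @param hematoxylin,dab Numeric length-3 OD vectors over (R, G, B);
#'   normalised to unit length internally.
#' @param residual Optional length-3 residual vector; defaults to the
#'   normalised cross-product of the two dye vectors.
#' @return A 3x3 numeric matrix of class `stain_matrix`, rows named
#'   `hematoxylin`, `dab`, `residual`, each row unit-norm.
#' @examples
#' hdab_stain_matrix()
#' @export
hdab_stain_matrix <- function(hematoxylin = c(0.65, 0.70, 0.29),
                              dab = c(0.27, 0.57, 0.78),
                              residual = NULL) {
  unit <- function(v) v / sqrt(sum(v^2))
  h <- unit(hematoxylin)
  d <- unit(dab)
  if (is.null(residual)) {
    residual <- c(
      h[2] * d[3] - h[3] * d[2],
      h[3] * d[1] - h[1] * d[3],
      h[1] * d[2] - h[2] * d[1]
    )
  }
  r <- unit(abs(residual))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("R", "G", "B")
  if (any(m < 0) || any(!is.finite(m))) {
    stop("stain vectors must be non-negative and finite")
  }
  if (abs(det(m)) < 1e-8) stop("stain matrix is singular")
  class(m) <- c("stain_matrix", class(m))
  m
}

#' Convert transmitted RGB intensities to optical density
#'
#' Applies the Beer-Lambert convention `OD = -log10((I + eps) / i0)` per
#' channel, clipped at zero so that full transmission maps to zero
#' absorbance. The default guard `eps = i0/255` corresponds to one grey
#' level on an 8-bit scale and keeps OD finite at zero intensity.
#'
#' @param rgb Numeric array `[h, w, 3]` (or matrix/vector recycled per
#'   channel) of intensities in `[0, i0]`.
#' @param i0 White-reference intensity (default 1 for unit-scaled tiles;
#'   pass 255 for 8-bit data).
#' @param eps Additive guard on the intensity scale.
#' @return Array of optical densities, same shape as `rgb`, all `>= 0`.
#' @seealso [od_to_rgb()] for the exact inverse (when `eps` matches).
#' @export
rgb_to_od <- function(rgb, i0 = 1, eps = i0 / 255) {
  if (i0 <= 0) stop("white reference i0 must be > 0")
  if (is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] != 3) {
    stop("expected an RGB input with 3 channels")
  }
  od <- -log10((rgb + eps) / i0)
  od[od < 0] <- 0
  od
}

#' Invert optical density back to transmitted intensity
#'
#' @inheritParams rgb_to_od
#' @param od Optical-density array.
#' @return Intensities `I = i0 * 10^(-od) - eps`, clipped to `[0, i0]`.
#' @export
od_to_rgb <- function(od, i0 = 1, eps = i0 / 255) {
  out <- i0 * 10^(-od) - eps
  out[out < 0] <- 0
  out[out > i0] <- i0
  out
}

#' Unmix an optical-density image into stain densities
#'
#' Solves `od = t(M) %*% c` per pixel for the stain density vector `c`
#' (haematoxylin, DAB, residual). With an invertible 3x3 stain matrix this
#' is the exact linear solve; negative solutions are clipped to zero since
#' absorbance is non-negative.
#'
#' @param od Numeric array `[h, w, 3]` of optical densities.
#' @param stains A [stain_matrix][hdab_stain_matrix] (rows = stains).
#' @return Array `[h, w, 3]` of per-stain densities in the row order of
#'   `stains`.
#' @export
deconvolve <- function(od, stains = hdab_stain_matrix()) {
  if (abs(det(unclass(stains))) < 1e-8) stop("stain matrix is singular")
  dm <- dim(od)
  if (length(dm) != 3 || dm[3] != 3) stop("od must be an [h, w, 3] array")
  px <- matrix(od, ncol = 3)              # pixels x RGB
  dens <- px %*% solve(unclass(stains))   # solves dens %*% M = px
  dens[dens < 0] <- 0
  array(dens, dim = dm)
}

#' Mix stain densities into an optical-density image
#'
#' The forward Beer-Lambert model: `od = t(M) %*% c` per pixel.
#'
#' @param densities Array `[h, w, 3]` of per-stain densities.
#' @inheritParams deconvolve
#' @return Optical-density array `[h, w, 3]`.
#' @export
mix_stains <- function(densities, stains = hdab_stain_matrix()) {
  dm <- dim(densities)
  if (length(dm) != 3 || dm[3] != 3) stop("densities must be [h, w, 3]")
  px <- matrix(densities, ncol = 3) %*% unclass(stains)
  array(px, dim = dm)
}

#' Brightness and saturation channels of an RGB tile
#'
#' Brightness is the RGB mean; saturation is `(max - min) / max`, defined
#' as 0 where the maximum channel is 0.
#'
#' @param rgb Numeric array `[h, w, 3]` with values in `[0, 1]`.
#' @return List with matrices `brightness` and `saturation`, both in
#'   `[0, 1]`.
#' @export
derived_channels <- function(rgb) {
  dm <- dim(rgb)
  if (length(dm) != 3 || dm[3] != 3) stop("rgb must be an [h, w, 3] array")
  r <- array(rgb[, , 1], dm[1:2])
  g <- array(rgb[, , 2], dm[1:2])
  b <- array(rgb[, , 3], dm[1:2])
  brightness <- (r + g + b) / 3
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  saturation <- ifelse(mx > 0, (mx - mn) / mx, 0)
  list(brightness = brightness, saturation = saturation)
}

#' Build the 7-channel stack used by feature extraction
#'
#' Channels: red, green, blue (unit scale), DAB OD, haematoxylin OD,
#' brightness, saturation, plus the microns-per-pixel calibration.
#'
#' @param rgb Numeric array `[h, w, 3]` with values in `[0, 1]`.
#' @param mpp Microns per pixel (> 0).
#' @inheritParams deconvolve
#' @return Object of class `channel_stack`: a named list of 7 matrices
#'   (`red`, `green`, `blue`, `dab`, `hematoxylin`, `brightness`,
#'   `saturation`) and the scalar `mpp`.
#' @export
channel_stack <- function(rgb, mpp, stains = hdab_stain_matrix()) {
  if (mpp <= 0) stop("mpp must be > 0")
  od <- rgb_to_od(rgb)
  dens <- deconvolve(od, stains)
  ds <- derived_channels(rgb)
  dm <- dim(rgb)[1:2]
  out <- list(
    red = array(rgb[, , 1], dm), green = array(rgb[, , 2], dm),
    blue = array(rgb[, , 3], dm),
    dab = array(dens[, , 2], dm), hematoxylin = array(dens[, , 1], dm),
    brightness = ds$brightness, saturation = ds$saturation,
    mpp = mpp
  )
  structure(out, class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf(
    "<channel_stack> %d x %d px, %.4g um/px, channels: %s\n",
    nrow(x$red), ncol(x$red), x$mpp,
    paste(setdiff(names(x), "mpp"), collapse = ", ")
  ))
  invisible(x)
}

#' Names of the 7 feature-extraction channels
#' @return Character vector of channel names in canonical order.
#' @export
channel_names <- function() {
  c("red", "green", "blue", "dab", "hematoxylin", "brightness", "saturation")
}
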