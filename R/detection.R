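#' Detection parameters for DAB thresholding
#'
#' Defaults mirror a standard brightfield thresholder configuration:
#' no Gaussian pre-filter (`sigma = 0`), DAB optical-density threshold
#' 0.25 (strictly greater than), minimum object size 5 square microns,
#' 8-connectivity so that thin diagonal tau threads stay connected.
#'
#' @param threshold DAB OD threshold; pixels with OD strictly above it are
#'   foreground. Must be > 0.
#' @param min_area_um2 Minimum object area in square microns (>= 0);
#'   components smaller than this are discarded.
#' @param sigma Gaussian smoothing sigma in pixels; 0 skips smoothing.
#' @param connectivity Pixel connectivity, 4 or 8.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(threshold = 0.25, min_area_um2 = 5,
                             sigma = 0, connectivity = 8) {
  stopifnot(threshold > 0, min_area_um2 >= 0, sigma >= 0,
            connectivity %in% c(4L, 8L))
  structure(list(threshold = threshold, min_area_um2 = min_area_um2,
                 sigma = sigma, connectivity = as.integer(connectivity)),
            class = "detection_params")
}

# Separable Gaussian smoothing with edge replication.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# Label connected components of a logical matrix. Returns an integer matrix
# with 0 background and components numbered by the scan order (column-major)
# of their first pixel.
label_components <- function(bin, connectivity = 8L) {
  nr <- nrow(bin); nc <- ncol(bin)
  idx <- which(bin)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) {
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  }
  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    nb <- idx + off[1] + off[2] * nr
    ok <- rows + off[1] >= 1L & rows + off[1] <= nr &
      nb >= 1L & nb <= nr * nc
    ok[ok] <- bin[nb[ok]]
    from <- c(from, pos[idx[ok]])
    to <- c(to, pos[nb[ok]])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber by first (column-major) pixel of each component
  first <- tapply(seq_along(idx), comp, min)
  renum <- integer(length(first))
  renum[order(first)] <- seq_along(first)
  lab[idx] <- renum[comp]
  lab
}

# Count exposed (crack) edges of a pixel set: edges adjacent to background
# or to the image border. Used for the boundary length.
exposed_edges <- function(pixels, dims) {
  nr <- dims[1]; nc <- dims[2]
  inmask <- logical(nr * nc)
  inmask[pixels] <- TRUE
  rows <- ((pixels - 1L) %% nr) + 1L
  cols <- ((pixels - 1L) %/% nr) + 1L
  n <- 0L
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    outside <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
    nb <- pixels + off[1] + off[2] * nr
    exposed <- outside | !inmask[pmax(pmin(nb, nr * nc), 1L)]
    n <- n + sum(exposed)
  }
  n
}

# Trace the crack boundary of a pixel set into closed rings. Pixel (r, c)
# occupies the unit square x in [c-1, c], y in [r-1, r] (0-based corner
# coordinates, y down). Directed so the object interior is on the left.
# Returns a list of rings, each an (n+1) x 2 matrix (closed, x then y).
trace_boundary <- function(pixels, dims) {
  nr <- dims[1]; nc <- dims[2]
  inmask <- logical(nr * nc)
  inmask[pixels] <- TRUE
  rows <- ((pixels - 1L) %% nr) + 1L
  cols <- ((pixels - 1L) %/% nr) + 1L
  has_nb <- function(dr, dc) {
    r2 <- rows + dr; c2 <- cols + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    res <- logical(length(pixels))
    res[ok] <- inmask[pixels[ok] + dr + dc * nr]
    res
  }
  segs <- list()
  # each exposed side contributes a directed edge (interior on left, y down)
  top <- !has_nb(-1L, 0L)
  segs$top <- cbind(cols[top] - 1L, rows[top] - 1L, cols[top], rows[top] - 1L)
  right <- !has_nb(0L, 1L)
  segs$right <- cbind(cols[right], rows[right] - 1L, cols[right], rows[right])
  bottom <- !has_nb(1L, 0L)
  segs$bottom <- cbind(cols[bottom], rows[bottom], cols[bottom] - 1L, rows[bottom])
  left <- !has_nb(0L, -1L)
  segs$left <- cbind(cols[left] - 1L, rows[left], cols[left] - 1L, rows[left] - 1L)
  e <- do.call(rbind, segs)
  if (is.null(e) || nrow(e) == 0) return(list())
  key <- function(x, y) paste(x, y, sep = ",")
  starts <- key(e[, 1], e[, 2])
  lookup <- split(seq_len(nrow(e)), starts)
  used <- logical(nrow(e))
  rings <- list()
  for (i in seq_len(nrow(e))) {
    if (used[i]) next
    ring <- list(e[i, 1:2])
    cur <- i
    repeat {
      used[cur] <- TRUE
      ring[[length(ring) + 1L]] <- e[cur, 3:4]
      nxt <- lookup[[key(e[cur, 3], e[cur, 4])]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      if (length(nxt) > 1) {
        # corner where two boundaries touch: take the sharpest left turn so
        # each ring stays on its own side
        din <- c(e[cur, 3] - e[cur, 1], e[cur, 4] - e[cur, 2])
        turn <- vapply(nxt, function(j) {
          dout <- c(e[j, 3] - e[j, 1], e[j, 4] - e[j, 2])
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        nxt <- nxt[which.min(turn)]
      }
      cur <- nxt
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  rings
}

#' Detect tau objects by thresholding the DAB channel
#'
#' Pixels whose (optionally Gaussian-smoothed) DAB optical density is
#' strictly above the threshold and inside the region mask are grouped
#' into connected components; components smaller than the minimum area are
#' discarded. Components are returned in a stable, deterministic order
#' (scan order of their first pixel).
#'
#' @param dab Numeric matrix of DAB optical densities.
#' @param mask Logical matrix (same shape) delimiting the region of
#'   interest; `NULL` means the whole tile.
#' @param params A [detection_params()] object.
#' @param mpp Microns per pixel (> 0).
#' @param tile_id Optional identifier copied onto every object.
#' @param region_group Optional region-group label (`cortex`, `putamen`,
#'   `STN_GP` or `dentate`) copied onto every object.
#' @return A tibble of class `tau_objects`, one row per detected object:
#'   `object_id`, `tile_id`, `region_group`, `n_pixels`, `area_um2`
#'   (exactly `n_pixels * mpp^2`), 0-based centroid (`centroid_x` = column,
#'   `centroid_y` = row), bounding box, `mpp`, image dims, and list columns
#'   `pixels` (column-major linear indices) and `polygon` (boundary rings
#'   in 0-based pixel-corner coordinates).
#' @export
detect_objects <- function(dab, mask = NULL, params = detection_params(),
                           mpp = 0.25, tile_id = NA_character_,
                           region_group = NA_character_) {
  stopifnot(is.matrix(dab), mpp > 0)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dab), ncol(dab))
  if (!all(dim(mask) == dim(dab))) stop("mask shape must match the image")
  img <- gaussian_smooth(dab, params$sigma)
  bin <- (img > params$threshold) & mask
  lab <- label_components(bin, params$connectivity)
  n <- max(lab)
  if (n == 0) return(empty_objects(mpp, dim(dab), tile_id, region_group))
  pix <- unname(split(which(lab > 0), lab[lab > 0]))
  keep <- vapply(pix, length, integer(1)) * mpp^2 >= params$min_area_um2
  pix <- pix[keep]
  if (length(pix) == 0) return(empty_objects(mpp, dim(dab), tile_id, region_group))
  nr <- nrow(dab)
  rows_of <- function(p) ((p - 1L) %% nr) + 1L
  cols_of <- function(p) ((p - 1L) %/% nr) + 1L
  tibble::tibble(
    object_id = seq_along(pix),
    tile_id = tile_id,
    region_group = region_group,
    n_pixels = vapply(pix, length, integer(1)),
    area_um2 = vapply(pix, length, integer(1)) * mpp^2,
    centroid_x = vapply(pix, function(p) mean(cols_of(p)) - 1, numeric(1)),
    centroid_y = vapply(pix, function(p) mean(rows_of(p)) - 1, numeric(1)),
    min_row = vapply(pix, function(p) min(rows_of(p)), integer(1)),
    max_row = vapply(pix, function(p) max(rows_of(p)), integer(1)),
    min_col = vapply(pix, function(p) min(cols_of(p)), integer(1)),
    max_col = vapply(pix, function(p) max(cols_of(p)), integer(1)),
    mpp = mpp,
    img_h = nrow(dab),
    img_w = ncol(dab),
    pixels = unname(pix),
    polygon = lapply(unname(pix), trace_boundary, dims = dim(dab))
  ) -> out
  class(out) <- c("tau_objects", class(out))
  out
}

empty_objects <- function(mpp, dims, tile_id, region_group) {
  out <- tibble::tibble(
    object_id = integer(0), tile_id = character(0),
    region_group = character(0), n_pixels = integer(0),
    area_um2 = numeric(0), centroid_x = numeric(0), centroid_y = numeric(0),
    min_row = integer(0), max_row = integer(0), min_col = integer(0),
    max_col = integer(0), mpp = numeric(0), img_h = integer(0),
    img_w = integer(0), pixels = list(), polygon = list()
  )
  class(out) <- c("tau_objects", class(out))
  out
}

#' Remove objects falling inside an exclusion mask
#'
#' Mask-based artefact removal: objects whose centroid lies in the
#' exclusion mask are dropped; the number removed is reported via message.
#'
#' @param objects A `tau_objects` tibble from [detect_objects()].
#' @param exclusion Logical matrix, `TRUE` where objects are excluded.
#' @param quiet Suppress the removal-count message.
#' @return The filtered `tau_objects` tibble.
#' @export
exclude_artefact_zones <- function(objects, exclusion, quiet = FALSE) {
  if (nrow(objects) == 0) return(objects)
  if (!all(dim(exclusion) == c(objects$img_h[1], objects$img_w[1]))) {
    stop("exclusion mask shape must match the tile")
  }
  r <- pmin(pmax(round(objects$centroid_y) + 1L, 1L), nrow(exclusion))
  c_ <- pmin(pmax(round(objects$centroid_x) + 1L, 1L), ncol(exclusion))
  drop <- exclusion[cbind(r, c_)]
  if (!quiet && any(drop)) {
    message(sprintf("excluded %d object(s) in artefact zones", sum(drop)))
  }
  objects[!drop, , drop = FALSE]
}

#' Export detected objects as a GeoJSON FeatureCollection
#'
#' Boundary rings are written as RFC 7946 polygons in pixel-corner
#' coordinates (x right, y down), with `id`, `area_um2`, `region_group`
#' and, when present, classification label and scores as properties.
#'
#' @param objects A `tau_objects` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_objects_geojson <- function(objects, path) {
  feats <- lapply(seq_len(nrow(objects)), function(i) {
    rings <- lapply(objects$polygon[[i]], function(m) {
      lapply(seq_len(nrow(m)), function(j) c(m[j, 1], m[j, 2]))
    })
    props <- list(
      id = objects$object_id[i],
      area_um2 = objects$area_um2[i],
      region_group = objects$region_group[i]
    )
    if ("label" %in% names(objects)) props$label <- objects$label[i]
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = rings),
      properties = props
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Rasterise detected objects into a label image
#'
#' @param objects A `tau_objects` tibble.
#' @return Integer matrix with background 0 and each object's id.
#' @export
objects_to_label_image <- function(objects) {
  if (nrow(objects) == 0) stop("no objects to rasterise")
  lab <- matrix(0L, objects$img_h[1], objects$img_w[1])
  for (i in seq_len(nrow(objects))) {
    lab[objects$pixels[[i]]] <- objects$object_id[i]
  }
  lab
}
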