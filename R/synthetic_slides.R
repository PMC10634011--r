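#' Specification of a synthetic H-DAB tile
#'
#' Describes one brightfield tile to simulate: tile geometry, how many
#' objects of each class to plant (coiled bodies `CB`, neurofibrillary
#' tangles `NFT`, tufted astrocytes `TA`, tau fragments `TF`, and non-tau
#' brown artefacts), haematoxylin nuclei, per-class morphology and
#' optical-density parameters, and the background noise level.
#'
#' Default morphology parameters encode the qualitative descriptions of
#' the four tau types: CB are small compact round or annular bodies, NFT
#' are mid-sized elongated flames, TA are large stellate shapes with
#' radial arms, TF are thin short curvilinear threads. Non-tau artefacts
#' are compact granules rendered with substantial residual-channel
#' absorbance, off the pure DAB colour vector.
#'
#' @param width,height Tile size in pixels.
#' @param mpp Microns per pixel (default 0.25, a 40x scan).
#' @param counts Named integer vector of planted object counts with names
#'   `CB`, `NFT`, `TA`, `TF`, `non_tau` (all >= 0).
#' @param nuclei Number of haematoxylin nuclei.
#' @param class_params Named list of per-class parameter lists; see
#'   [default_class_params()]. Entries override the defaults.
#' @param nucleus_od Range of haematoxylin OD for nuclei.
#' @param noise_sd SD of additive Gaussian optical-density noise (applied
#'   per RGB channel before exponentiation, clipped at 0).
#' @param seed Random seed used by [generate_tile()].
#' @return A list of class `slide_spec`.
#' @export
slide_spec <- function(width = 512, height = 512, mpp = 0.25,
                       counts = c(CB = 5, NFT = 3, TA = 2, TF = 15,
                                  non_tau = 5),
                       nuclei = 20,
                       class_params = list(),
                       nucleus_od = c(0.4, 0.9),
                       noise_sd = 0.02,
                       seed = 1L) {
  stopifnot(width > 0, height > 0, mpp > 0, nuclei >= 0, noise_sd >= 0)
  cnt <- c(CB = 0L, NFT = 0L, TA = 0L, TF = 0L, non_tau = 0L)
  cnt[names(counts)] <- as.integer(counts)
  if (any(cnt < 0)) stop("object counts must be >= 0")
  cp <- default_class_params()
  for (nm in names(class_params)) cp[[nm]] <- utils::modifyList(cp[[nm]], class_params[[nm]])
  for (nm in names(cp)) {
    if (any(unlist(cp[[nm]][grepl("od", names(cp[[nm]]))]) < 0)) {
      stop("OD ranges must be non-negative")
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 mpp = mpp, counts = cnt, nuclei = as.integer(nuclei),
                 class_params = cp, nucleus_od = nucleus_od,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "slide_spec")
}

#' Default per-class morphology and staining parameters
#'
#' Areas are in square microns, ODs are DAB optical densities (non-tau
#' additionally carries residual-channel OD), `texture_sd` is the relative
#' SD of multiplicative within-object density variation.
#'
#' @return Named list with entries `CB`, `NFT`, `TA`, `TF`, `non_tau`.
#' @export
default_class_params <- function() {
  list(
    CB = list(area_um2 = c(20, 60), annulus_prob = 0.5,
              hole_frac = c(0.3, 0.45), od = c(0.6, 1.1), texture_sd = 0.08),
    NFT = list(area_um2 = c(70, 160), aspect = c(2.5, 4),
               od = c(0.5, 1.0), texture_sd = 0.12),
    TA = list(area_um2 = c(200, 450), arms = c(5, 9), core_frac = 0.35,
              od = c(0.45, 0.9), texture_sd = 0.18),
    TF = list(length_um = c(10, 40), width_px = c(1, 2),
              od = c(0.4, 0.8), texture_sd = 0.10),
    non_tau = list(area_um2 = c(10, 80), od = c(0.5, 0.9),
                   od_residual = c(0.5, 1.0), texture_sd = 0.15)
  )
}

# --- shape rasterisers: return unique (dr, dc) integer offsets ------------

shape_disc <- function(area_px, hole_frac = 0) {
  r <- sqrt(area_px / pi / max(1e-9, 1 - hole_frac^2))
  rr <- ceiling(r)
  g <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 <= r^2 & d2 >= (hole_frac * r)^2
  as.matrix(g[keep, , drop = FALSE])
}

shape_ellipse <- function(area_px, aspect, angle) {
  a <- sqrt(area_px * aspect / pi)
  b <- a / aspect
  rr <- ceiling(a)
  g <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  u <- g$dc * cos(angle) + g$dr * sin(angle)
  v <- -g$dc * sin(angle) + g$dr * cos(angle)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[keep, c("dr", "dc"), drop = FALSE])
}

shape_stellate <- function(area_px, n_arms, core_frac) {
  core_r <- sqrt(area_px * core_frac / pi)
  arm_len <- 2.8 * core_r
  rr <- ceiling(arm_len)
  g <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  d <- sqrt(g$dr^2 + g$dc^2)
  theta <- atan2(g$dr, g$dc)
  # radial arms as angular lobes decaying outward from the core
  lobe <- abs(cos(n_arms * theta / 2))^6
  rmax <- core_r + (arm_len - core_r) * lobe
  keep <- d <= rmax
  as.matrix(g[keep, c("dr", "dc"), drop = FALSE])
}

shape_thread <- function(length_px, width_px) {
  theta <- stats::runif(1, 0, 2 * pi)
  pos <- c(0, 0)
  pts <- matrix(0, nrow = length_px, ncol = 2)
  for (i in seq_len(length_px)) {
    theta <- theta + stats::rnorm(1, 0, 0.25)
    pos <- pos + c(sin(theta), cos(theta))
    pts[i, ] <- round(pos)
  }
  if (width_px > 1) {
    pts <- rbind(pts, sweep(pts, 2, c(1, 0), "+"), sweep(pts, 2, c(0, 1), "+"),
                 sweep(pts, 2, c(1, 1), "+"))
  }
  unique(pts)
}

sample_shape <- function(class, p, mpp) {
  area_px <- function(rng) {
    round(stats::runif(1, rng[1], rng[2]) / mpp^2)
  }
  switch(class,
    CB = {
      hole <- if (stats::runif(1) < p$annulus_prob) {
        stats::runif(1, p$hole_frac[1], p$hole_frac[2])
      } else 0
      shape_disc(area_px(p$area_um2), hole)
    },
    NFT = shape_ellipse(area_px(p$area_um2),
                        stats::runif(1, p$aspect[1], p$aspect[2]),
                        stats::runif(1, 0, pi)),
    TA = shape_stellate(area_px(p$area_um2),
                        sample(p$arms[1]:p$arms[2], 1), p$core_frac),
    TF = shape_thread(max(3L, round(stats::runif(1, p$length_um[1], p$length_um[2]) / mpp)),
                      sample(p$width_px[1]:p$width_px[2], 1)),
    non_tau = shape_disc(area_px(p$area_um2)),
    stop("unknown class: ", class)
  )
}

#' Render one synthetic H-DAB tile with exact ground truth
#'
#' Plants the requested objects without overlap (1-pixel separation so
#' components stay distinct under 8-connectivity), paints per-stain density
#' images, and renders the RGB tile by Beer-Lambert mixing: transmitted
#' intensity `I = 10^(-t(M) c)` per pixel with additive Gaussian OD noise
#' (clipped at 0) before exponentiation. Tau classes absorb in the DAB
#' channel; non-tau artefacts absorb in DAB plus residual so their colour
#' is off the DAB stain vector; nuclei absorb in haematoxylin.
#'
#' @param spec A [slide_spec()].
#' @param seed Random seed; defaults to `spec$seed`.
#' @param stains Stain matrix used for rendering.
#' @return A list of class `synthetic_tile`: `rgb` (`[h, w, 3]` in
#'   `[0, 1]`), `truth` (tibble: `object_id`, `class`, `n_pixels`,
#'   `area_um2`, `centroid_x`, `centroid_y`, list column `pixels`),
#'   `densities` (`[h, w, 3]` per-stain density images), `mpp`, `spec`.
#' @export
generate_tile <- function(spec, seed = spec$seed,
                          stains = hdab_stain_matrix()) {
  stopifnot(inherits(spec, "slide_spec"))
  withr::local_seed(seed)
  h <- spec$height; w <- spec$width
  dens <- array(0, dim = c(h, w, 3))   # hematoxylin, dab, residual
  occupied <- matrix(FALSE, h, w)
  truth <- list()
  oid <- 0L
  place <- function(offsets) {
    for (try in 1:200) {
      r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
      rr <- offsets[, 1] + r0; cc <- offsets[, 2] + c0
      if (any(rr < 2 | rr > h - 1 | cc < 2 | cc > w - 1)) next
      lin <- rr + (cc - 1L) * h
      # 1-px dilated occupancy check for 8-connectivity separation
      block <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        if (any(occupied[lin + dr + dc * h])) { block <- TRUE; break }
      }
      if (block) next
      return(lin)
    }
    NULL
  }
  for (cls in names(spec$counts)) {
    p <- spec$class_params[[cls]]
    n <- spec$counts[[cls]]
    if (n == 0) next
    for (k in seq_len(n)) {
      lin <- place(sample_shape(cls, p, spec$mpp))
      if (is.null(lin)) {
        stop(sprintf("could not place %s object %d: tile too crowded", cls, k))
      }
      occupied[lin] <- TRUE
      base <- stats::runif(1, p$od[1], p$od[2])
      vals <- base * (1 + stats::rnorm(length(lin), 0, p$texture_sd))
      vals <- pmax(vals, 0.35)
      dens[, , 2][lin] <- vals
      if (cls == "non_tau") {
        res <- stats::runif(1, p$od_residual[1], p$od_residual[2])
        dens[, , 3][lin] <- res * (1 + stats::rnorm(length(lin), 0, p$texture_sd))
      }
      oid <- oid + 1L
      truth[[oid]] <- tibble::tibble(
        object_id = oid, class = cls, n_pixels = length(lin),
        area_um2 = length(lin) * spec$mpp^2,
        centroid_x = mean((lin - 1L) %/% h),
        centroid_y = mean((lin - 1L) %% h),
        pixels = list(sort(lin))
      )
    }
  }
  if (spec$nuclei > 0) {
    for (k in seq_len(spec$nuclei)) {
      lin <- place(shape_disc(round(stats::runif(1, 15, 40) / spec$mpp^2)))
      if (is.null(lin)) next  # nuclei are scenery; skip if crowded
      occupied[lin] <- TRUE
      base <- stats::runif(1, spec$nucleus_od[1], spec$nucleus_od[2])
      dens[, , 1][lin] <- base * (1 + stats::rnorm(length(lin), 0, 0.1))
    }
  }
  dens[dens < 0] <- 0
  od <- mix_stains(dens, stains)
  if (spec$noise_sd > 0) {
    od <- od + array(stats::rnorm(length(od), 0, spec$noise_sd), dim = dim(od))
  }
  od[od < 0] <- 0
  rgb <- 10^(-od)
  truth_tbl <- if (length(truth)) {
    dplyr::bind_rows(truth)
  } else {
    tibble::tibble(object_id = integer(0), class = character(0),
                   n_pixels = integer(0), area_um2 = numeric(0),
                   centroid_x = numeric(0), centroid_y = numeric(0),
                   pixels = list())
  }
  structure(list(rgb = rgb, truth = truth_tbl, densities = dens,
                 mpp = spec$mpp, spec = spec, seed = seed),
            class = "synthetic_tile")
}

#' @export
print.synthetic_tile <- function(x, ...) {
  cat(sprintf("<synthetic_tile> %d x %d px, %.3g um/px, %d objects\n",
              nrow(x$rgb), ncol(x$rgb), x$mpp, nrow(x$truth)))
  invisible(x)
}

#' Region groups of the staging scheme covered by the pipeline
#' @return `c("cortex", "putamen", "STN_GP", "dentate")`.
#' @export
region_groups <- function() c("cortex", "putamen", "STN_GP", "dentate")

#' Generate a multi-donor, multi-region synthetic cohort
#'
#' Renders `tiles_per_region` tiles per donor and region group from the
#' per-region tile specifications. Tufted astrocytes are essentially
#' absent from the subthalamic nucleus / globus pallidus and the dentate
#' nucleus, so profiles for those region groups must request `TA = 0`.
#'
#' @param profiles Named list of [slide_spec()]s covering all four
#'   [region_groups()].
#' @param n_donors Number of donors (>= 0).
#' @param seed Base seed; every tile derives its own sub-seed from it, so
#'   a fixed seed reproduces the dataset exactly.
#' @param tiles_per_region Tiles per donor and region.
#' @return A list of class `synthetic_cohort`: `manifest` (tibble: donor,
#'   region_group, tile_num, seed) and `tiles` (list of `synthetic_tile`,
#'   aligned with the manifest rows).
#' @export
generate_cohort <- function(profiles, n_donors, seed = 1L,
                            tiles_per_region = 1L) {
  if (!setequal(names(profiles), region_groups())) {
    stop("profiles must cover exactly the region groups: ",
         paste(region_groups(), collapse = ", "))
  }
  for (rg in c("STN_GP", "dentate")) {
    if (profiles[[rg]]$counts[["TA"]] > 0) {
      stop(sprintf("TA objects requested for %s, where TA is not quantifiable", rg))
    }
  }
  stopifnot(n_donors >= 0, tiles_per_region >= 1)
  manifest <- tidyr::expand_grid(
    donor = seq_len(n_donors),
    region_group = region_groups(),
    tile_num = seq_len(tiles_per_region)
  )
  if (nrow(manifest) == 0) {
    return(structure(list(manifest = manifest[, ], tiles = list()),
                     class = "synthetic_cohort"))
  }
  manifest$seed <- (as.integer(seed) + 9973L * (seq_len(nrow(manifest)) - 1L)) %%
    2147483647L
  tiles <- lapply(seq_len(nrow(manifest)), function(i) {
    generate_tile(profiles[[manifest$region_group[i]]],
                  seed = manifest$seed[i])
  })
  structure(list(manifest = manifest, tiles = tiles),
            class = "synthetic_cohort")
}

#' Detect, label and featurise every tile of a synthetic cohort
#'
#' Runs DAB-threshold detection on each tile, matches detections to the
#' planted ground truth by mask overlap (intersection over union), and
#' extracts the 54-feature vector for each detected object.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param params [detection_params()] used for detection.
#' @param glcm [glcm_params()] used for texture features.
#' @param min_iou Minimum intersection-over-union with a planted object to
#'   inherit its class label; unmatched detections get class `NA`.
#' @return Tibble: `donor`, `region_group`, `tile_num`, `object_id`,
#'   `class` (ground-truth class) and the 54 feature columns.
#' @export
harvest_cohort <- function(cohort, params = detection_params(),
                           glcm = glcm_params(), min_iou = 0.5) {
  out <- lapply(seq_len(nrow(cohort$manifest)), function(i) {
    tile <- cohort$tiles[[i]]
    stack <- channel_stack(tile$rgb, tile$mpp)
    objs <- detect_objects(stack$dab, params = params, mpp = tile$mpp,
                           region_group = cohort$manifest$region_group[i])
    if (nrow(objs) == 0) return(NULL)
    feats <- extract_features(objs, stack, glcm)
    feats$class <- match_truth(objs, tile$truth, min_iou)
    feats$donor <- cohort$manifest$donor[i]
    feats$tile_num <- cohort$manifest$tile_num[i]
    feats
  })
  dplyr::bind_rows(out)
}

# Label detections by maximum-IoU match against ground-truth masks.
match_truth <- function(objects, truth, min_iou = 0.5) {
  vapply(objects$pixels, function(px) {
    best <- 0; lab <- NA_character_
    for (j in seq_len(nrow(truth))) {
      tp <- truth$pixels[[j]]
      inter <- length(intersect(px, tp))
      if (inter == 0) next
      iou <- inter / (length(px) + length(tp) - inter)
      if (iou > best) { best <- iou; lab <- truth$class[j] }
    }
    if (best >= min_iou) lab else NA_character_
  }, character(1))
}

#' Write a tile as an 8-bit PNG
#' @param tile A `synthetic_tile` or an `[h, w, 3]` array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tile_png <- function(tile, path) {
  rgb <- if (inherits(tile, "synthetic_tile")) tile$rgb else tile
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read a PNG tile as an `[h, w, 3]` array in `[0, 1]`
#' @param path PNG file path.
#' @return Numeric array `[h, w, 3]`.
#' @export
read_tile_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  x[, , 1:3, drop = FALSE]
}
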