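#' Tau types quantified by the pipeline
#' @return `c("CB", "NFT", "TA", "TF")`.
#' @export
tau_types <- function() c("CB", "NFT", "TA", "TF")

#' Per-region tau density from object counts
#'
#' Density is the number of objects per square micron of quantified region
#' area. Total tau counts all four types; the hallmark aggregate is all tau
#' excluding tau fragments (CB + NFT + TA). Ambiguous objects are excluded
#' from every numerator but the region area is unchanged.
#'
#' @param counts Named numeric vector with any of `CB`, `NFT`, `TA`, `TF`
#'   (missing types count 0) and optionally `Ambiguous`.
#' @param area_um2 Region area in square microns (> 0).
#' @param donor,region Optional identifiers carried into the output.
#' @return One-row tibble of class `region_density`: per-type counts and
#'   densities, `total_count`, `hallmark_count`, `total_density`,
#'   `hallmark_density`, `ambiguous_count`, `area_um2`.
#' @export
region_density <- function(counts, area_um2, donor = NA, region = NA) {
  if (area_um2 <= 0) stop("region area must be > 0")
  full <- stats::setNames(numeric(4), tau_types())
  full[intersect(names(counts), tau_types())] <-
    counts[intersect(names(counts), tau_types())]
  if (any(full < 0)) stop("counts must be >= 0")
  amb <- if ("Ambiguous" %in% names(counts)) counts[["Ambiguous"]] else 0
  total <- sum(full)
  hallmark <- total - full[["TF"]]
  out <- tibble::tibble(
    donor = donor, region = region, area_um2 = area_um2,
    CB_count = full[["CB"]], NFT_count = full[["NFT"]],
    TA_count = full[["TA"]], TF_count = full[["TF"]],
    ambiguous_count = amb,
    total_count = total, hallmark_count = hallmark,
    CB_density = full[["CB"]] / area_um2,
    NFT_density = full[["NFT"]] / area_um2,
    TA_density = full[["TA"]] / area_um2,
    TF_density = full[["TF"]] / area_um2,
    total_density = total / area_um2,
    hallmark_density = hallmark / area_um2
  )
  class(out) <- c("region_density", class(out))
  out
}

#' Densities for a table of labelled objects
#'
#' Aggregates classified objects (one row per object, with a `label`
#' column) into per donor x region densities. `"Ambiguous"` labels are
#' counted but excluded from densities; `NA` labels (screened-out objects)
#' are dropped.
#'
#' @param objects Data frame with columns `donor`, `region_group`, `label`.
#' @param areas Data frame with columns `donor`, `region_group`,
#'   `area_um2` giving the quantified region area per donor and region.
#' @return Tibble with one row per donor x region (class
#'   `region_density`).
#' @export
density_table <- function(objects, areas) {
  objects <- dplyr::filter(objects, !is.na(.data$label))
  joined <- dplyr::left_join(
    areas,
    dplyr::count(objects, .data$donor, .data$region_group, .data$label),
    by = c("donor", "region_group")
  )
  rows <- joined |>
    dplyr::group_by(.data$donor, .data$region_group, .data$area_um2) |>
    dplyr::group_map(function(g, key) {
      cnt <- stats::setNames(g$n, g$label)
      cnt <- cnt[!is.na(names(cnt))]
      region_density(cnt, key$area_um2, donor = key$donor,
                     region = key$region_group)
    })
  dplyr::bind_rows(rows)
}

#' Log10 transform of tau densities with a zero policy
#'
#' Tau density distributions are strongly right-skewed, so densities are
#' log10-transformed before regression. Zeros are handled by a configurable
#' floor; the default adds half the smallest positive density observed in
#' the input before logging.
#'
#' @param density Non-negative densities.
#' @param floor Positive floor used for zeros; `NULL` uses half the
#'   smallest positive value in `density`.
#' @return Numeric vector of log10 densities; attribute `"floor"` records
#'   the policy actually applied.
#' @export
log_density <- function(density, floor = NULL) {
  if (any(density < 0, na.rm = TRUE)) stop("densities must be >= 0")
  if (is.null(floor)) {
    pos <- density[density > 0 & !is.na(density)]
    floor <- if (length(pos)) min(pos) / 2 else NA_real_
  }
  out <- ifelse(density > 0, log10(density), log10(floor))
  attr(out, "floor") <- floor
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average ranks (ties handled by mid-ranks), with
#' a two-sided p-value from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Pairs with missing values are
#' dropped listwise.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined: zero variance input")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Correlation of tau densities with staging
#'
#' Spearman correlations between per-donor tau density (per type plus the
#' total and hallmark aggregates) and an ordinal severity measure (the
#' overall pathological stage, or a per-region severity rating), for a
#' chosen region grouping. Cells where a tau type is not quantifiable in
#' the grouping (no region with any density, e.g. tufted astrocytes
#' outside cortex/putamen) are flagged not-applicable.
#'
#' @param densities A [density_table()] result.
#' @param staging Data frame with `donor` and the rating column.
#' @param rating Name of the staging column (default `"stage"`).
#' @param regions Character vector of region groups to pool (densities are
#'   averaged per donor over these regions); default all.
#' @param grouping Label describing the grouping in the output.
#' @return Tibble: `tau_type`, `grouping`, `rho`, `p_value`, `n`,
#'   `applicable`.
#' @export
correlate_staging <- function(densities, staging, rating = "stage",
                              regions = NULL, grouping = "all regions") {
  if (!is.null(regions)) {
    densities <- dplyr::filter(densities, .data$region %in% regions)
  }
  joined <- dplyr::inner_join(densities, staging, by = "donor")
  if (nrow(joined) == 0) stop("no donors in common between densities and staging")
  meas <- c(CB = "CB_density", NFT = "NFT_density", TA = "TA_density",
            TF = "TF_density", total = "total_density",
            hallmark = "hallmark_density")
  out <- lapply(names(meas), function(tt) {
    per_donor <- joined |>
      dplyr::group_by(.data$donor) |>
      dplyr::summarise(
        d = mean(.data[[meas[[tt]]]]),
        r = .data[[rating]][1],
        .groups = "drop"
      )
    if (all(per_donor$d == 0) || stats::sd(per_donor$d) == 0) {
      return(tibble::tibble(tau_type = tt, grouping = grouping,
                            rho = NA_real_, p_value = NA_real_,
                            n = nrow(per_donor), applicable = FALSE))
    }
    sc <- spearman_cor(per_donor$d, per_donor$r)
    tibble::tibble(tau_type = tt, grouping = grouping, rho = sc$rho,
                   p_value = sc$p_value, n = sc$n, applicable = TRUE)
  })
  dplyr::bind_rows(out)
}

#' Staging correlation table across region groupings
#'
#' Convenience wrapper mirroring the standard presentation: correlations of
#' each tau type with overall stage for all regions, cortical regions only,
#' and subcortical regions only.
#'
#' @inheritParams correlate_staging
#' @param cortical,subcortical Region names forming the two sub-groupings.
#' @return Tibble with one row per tau type x grouping.
#' @export
staging_correlation_table <- function(densities, staging, rating = "stage",
                                      cortical = "cortex",
                                      subcortical = c("putamen", "STN_GP",
                                                      "dentate")) {
  dplyr::bind_rows(
    correlate_staging(densities, staging, rating, NULL, "all regions"),
    correlate_staging(densities, staging, rating, cortical, "cortical regions"),
    correlate_staging(densities, staging, rating, subcortical,
                      "subcortical regions")
  )
}
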