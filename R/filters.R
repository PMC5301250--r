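#' Count forest pixels of a land-cover grid inside a PA
#'
#' Centre-point zonal count of cells whose class is in the forest set
#' (classes 1-8 in the GLC2000 convention).
#'
#' @param landcover categorical \code{pa_grid}.
#' @param geometry polygon vertex matrix.
#' @param forest_classes integer class codes counted as forest.
#' @return Integer pixel count.
#' @export
count_forest_pixels <- function(landcover, geometry,
                                forest_classes = FOREST_CLASSES) {
  stopifnot(inherits(landcover, "pa_grid"),
            landcover$kind == "categorical")
  zonal_stats(landcover, geometry,
              predicate = function(v) v %in% forest_classes)$pred_count
}

#' Apply the PA inclusion filters
#'
#' PAs enter the accounting cohort only if (in this order, each PA
#' carrying the first failing rule): recorded GIS area at least
#' \code{area_threshold_km2}; at least \code{min_forest_pixels} land-cover
#' pixels classed as forest; and forest-pixel area at least
#' \code{min_forest_fraction} of the recorded GIS area. The area rule is
#' inclusive (a 10 km^2 PA is kept at the default threshold). Forest
#' fraction is forest-pixel area over recorded GIS area; where
#' rasterisation makes it exceed 1 it is capped at 1 with a warning, so
#' the downstream correction multiplier never drops below 1.
#'
#' @param records a \code{\link{pa_records}} frame.
#' @param landcover categorical \code{pa_grid} at the land-cover map's
#'   native resolution.
#' @param area_threshold_km2,min_forest_pixels,min_forest_fraction the
#'   three thresholds (defaults 10 km^2, 10 pixels, 0.5).
#' @param statuses designation statuses admitted before any other rule
#'   (default: both).
#' @param forest_classes integer class codes counted as forest.
#' @return A data frame (one row per input PA, same order): \code{id},
#'   \code{kept}, \code{reason} (\code{none}, \code{status_excluded},
#'   \code{too_small}, \code{too_few_forest_pixels},
#'   \code{forest_fraction_below_half}), \code{forest_pixels},
#'   \code{forest_fraction}.
#' @export
apply_inclusion_filters <- function(records, landcover,
                                    area_threshold_km2 = 10,
                                    min_forest_pixels = 10,
                                    min_forest_fraction = 0.5,
                                    statuses = c("designated", "proposed"),
                                    forest_classes = FOREST_CLASSES) {
  stopifnot(inherits(records, "pa_records"),
            area_threshold_km2 > 0, min_forest_pixels > 0,
            min_forest_fraction > 0)
  n <- nrow(records)
  px_area_km2 <- landcover$px^2 / 1e6
  fp <- vapply(records$geometry, function(g)
    count_forest_pixels(landcover, g, forest_classes), 0L)
  frac <- fp * px_area_km2 / records$gis_area_km2
  over <- frac > 1 + 1e-12
  if (any(over)) {
    warning(sprintf(paste0("%d PA(s) have rasterised forest area exceeding ",
                           "their recorded GIS area; forest fraction capped ",
                           "at 1"), sum(over)))
    frac[over] <- 1
  }
  reason <- rep("none", n)
  reason[frac < min_forest_fraction] <- "forest_fraction_below_half"
  reason[fp < min_forest_pixels] <- "too_few_forest_pixels"
  reason[records$gis_area_km2 < area_threshold_km2] <- "too_small"
  reason[!(records$status %in% statuses)] <- "status_excluded"
  data.frame(id = records$id, kept = reason == "none", reason = reason,
             forest_pixels = fp, forest_fraction = frac,
             stringsAsFactors = FALSE)
}

#' Removal audit of a filter outcome
#'
#' Tabulates removals by reason, mirroring the audit style of published
#' WDPA-based cohorts ("removing N = ... observations").
#'
#' @param outcome result of \code{\link{apply_inclusion_filters}}.
#' @return Data frame with columns \code{reason} and \code{n}.
#' @export
filter_audit <- function(outcome) {
  tab <- table(factor(outcome$reason,
                      levels = c("none", "status_excluded", "too_small",
                                 "too_few_forest_pixels",
                                 "forest_fraction_below_half")))
  data.frame(reason = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
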