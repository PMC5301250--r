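#' Build the common working-resolution stack
#'
#' Harmonises the scene's layers on one working grid: land cover and
#' biomass are resampled by nearest neighbour (values unchanged), and the
#' fine binary loss grid is area-averaged into per-pixel loss fractions.
#' The default working pixel is a quarter of the coarse pixel (250 m for
#' a 1 km coarse grid) - fine enough to limit PA-edge overlap error,
#' coarse enough to stay cheap - and must be an integer multiple of the
#' fine loss pixel.
#'
#' @param scene a \code{pa_scene}.
#' @param working_px working pixel size; default \code{coarse_px / 4}.
#' @return List of class \code{pa_stack} with grids \code{landcover},
#'   \code{agb}, \code{bgb} (nearest-resampled) and \code{loss_frac}
#'   (fraction kind), all at \code{working_px}.
#' @export
working_stack <- function(scene, working_px = NULL) {
  stopifnot(inherits(scene, "pa_scene"))
  for (layer in c("landcover", "agb", "bgb", "loss"))
    if (is.null(scene[[layer]]))
      stop("scene is missing layer '", layer, "'")
  wpx <- working_px %||% (scene$coarse_px / 4)
  fpx <- scene$loss$px
  factor <- wpx / fpx
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf(paste0("working pixel (%g) must be an integer multiple of ",
                        "the fine loss pixel (%g)"), wpx, fpx))
  structure(list(landcover = resample_nearest(scene$landcover, wpx),
                 agb = resample_nearest(scene$agb, wpx),
                 bgb = resample_nearest(scene$bgb, wpx),
                 loss_frac = aggregate_fraction(scene$loss, round(factor)),
                 working_px = wpx), class = "pa_stack")
}

#' Per-PA carbon stock and loss summary
#'
#' The accounting core for one PA: centre-point extraction on the working
#' stack gives the forest area, the forest fraction f (forest area over
#' recorded GIS area, capped at 1), the correction multiplier m = 1/f
#' (forced to 1 in the uncorrected sensitivity mode), mean AGB/BGB over
#' forest pixels, the carbon stock, the raw and corrected loss
#' proportions, the carbon loss with propagated errors, and the
#' annualised quantities.
#'
#' @param record one-row slice of a \code{\link{pa_records}} frame.
#' @param stack a \code{\link{working_stack}}.
#' @param budget an \code{\link{error_budget}}.
#' @param corrected logical; \code{FALSE} forces the multiplier to 1.
#' @param years accounting period (default 12, for 2000-2012).
#' @return One-row data frame of per-PA quantities (unit-bearing names).
#' @export
summarise_pa <- function(record, stack, budget = error_budget(),
                         corrected = TRUE, years = 12) {
  stopifnot(inherits(stack, "pa_stack"))
  geom <- record$geometry[[1]]
  wpx <- stack$working_px
  idx <- zone_cells(stack$landcover, geom)
  lc <- stack$landcover$values[idx]
  forest <- lc %in% FOREST_CLASSES
  gis_m2 <- record$gis_area_km2 * 1e6
  forest_m2 <- sum(forest) * wpx^2
  forest_ha <- forest_m2 / 1e4
  f <- min(forest_m2 / gis_m2, 1)
  if (f <= 0)
    stop("PA ", record$id, " has no forest pixels at the working resolution")
  m <- if (corrected) correction_multiplier(f) else 1
  mean_agb <- if (any(forest)) mean(stack$agb$values[idx][forest]) else 0
  mean_bgb <- if (any(forest)) mean(stack$bgb$values[idx][forest]) else 0
  p_raw <- min(sum(stack$loss_frac$values[idx]) * wpx^2 / gis_m2, 1)
  stock <- total_carbon(forest_ha, mean_agb, mean_bgb)
  agb_c <- forest_ha * mean_agb * 0.5
  bgb_c <- forest_ha * mean_bgb * 0.5
  err <- propagate_errors(agb_c, bgb_c, budget)
  loss <- carbon_loss(stock, p_raw, m, years)
  p_corr <- min(m * p_raw, 1)
  data.frame(id = record$id, name = record$name, country = record$country,
             iucn_cat = record$iucn_cat, status = record$status,
             gis_area_km2 = record$gis_area_km2,
             forest_area_ha = forest_ha,
             forest_area_km2 = forest_m2 / 1e6,
             forest_fraction = f, multiplier = m,
             mean_agb_mg_ha = mean_agb, mean_bgb_mg_ha = mean_bgb,
             agb_carbon_mg = agb_c, bgb_carbon_mg = bgb_c,
             carbon_stock_mg = stock, stock_err_mg = err$stock_err,
             loss_prop_raw = p_raw, loss_prop_corrected = p_corr,
             carbon_loss_mg = loss$total,
             loss_err_mg = loss$total * ifelse(is.na(err$rel_stock_err), 0,
                                               err$rel_stock_err),
             annual_loss_mg_yr = loss$annual,
             annual_co2_mg_yr = to_co2(loss$annual),
             annual_loss_rate_pct_yr = annualise_rate(p_corr, years),
             stringsAsFactors = FALSE)
}

#' Run the full accounting pipeline on a scene
#'
#' Filters the PA cohort on the native land-cover grid, harmonises the
#' layers on the working grid, and summarises every kept PA. The removal
#' audit (counts by reason) is returned alongside the per-PA results.
#'
#' @param scene a \code{pa_scene}.
#' @param records a \code{\link{pa_records}} frame.
#' @param budget an \code{\link{error_budget}}.
#' @param working_px working pixel size (default \code{coarse_px / 4}).
#' @param corrected logical; apply the forest-fraction correction.
#' @param years accounting period.
#' @param area_threshold_km2,min_forest_pixels,min_forest_fraction,statuses
#'   filter thresholds, passed to \code{\link{apply_inclusion_filters}}.
#' @return List of class \code{pa_cohort}: \code{results} (per-PA data
#'   frame), \code{filter} (per-PA filter outcome), \code{audit}
#'   (removals by reason), \code{params} (thresholds and mode flags
#'   sufficient to re-run).
#' @export
pa_pipeline <- function(scene, records, budget = error_budget(),
                        working_px = NULL, corrected = TRUE, years = 12,
                        area_threshold_km2 = 10, min_forest_pixels = 10,
                        min_forest_fraction = 0.5,
                        statuses = c("designated", "proposed")) {
  outcome <- apply_inclusion_filters(records, scene$landcover,
                                     area_threshold_km2, min_forest_pixels,
                                     min_forest_fraction, statuses)
  stack <- working_stack(scene, working_px)
  kept <- which(outcome$kept)
  if (!length(kept)) {
    warning("no PA passed the inclusion filters; results are empty")
    results <- summarise_pa(records[1, , drop = FALSE], stack,
                            budget, corrected, years)[0, ]
  } else {
    results <- do.call(rbind, lapply(kept, function(i)
      summarise_pa(records[i, , drop = FALSE], stack, budget,
                   corrected, years)))
  }
  rownames(results) <- NULL
  structure(list(results = results, filter = outcome,
                 audit = filter_audit(outcome),
                 params = list(working_px = stack$working_px,
                               corrected = corrected, years = years,
                               area_threshold_km2 = area_threshold_km2,
                               min_forest_pixels = min_forest_pixels,
                               min_forest_fraction = min_forest_fraction,
                               statuses = statuses,
                               budget = unclass(budget))),
            class = "pa_cohort")
}

#' @export
print.pa_cohort <- function(x, ...) {
  r <- x$results
  cat(sprintf("<pa_cohort> %d of %d PAs kept (%s mode)\n",
              nrow(r), nrow(x$filter),
              if (x$params$corrected) "corrected" else "uncorrected"))
  rm <- x$audit[x$audit$reason != "none" & x$audit$n > 0, ]
  if (nrow(rm))
    cat("  removed:", paste(sprintf("%s N=%d", rm$reason, rm$n),
                            collapse = ", "), "\n")
  if (nrow(r)) {
    cat(sprintf("  stock: %.3g +/- %.3g Pg C; loss: %.3g Pg C (%.3g Tg C yr^-1)\n",
                mg_to_pg(sum(r$carbon_stock_mg)), mg_to_pg(sum(r$stock_err_mg)),
                mg_to_pg(sum(r$carbon_loss_mg)),
                mg_to_tg(sum(r$annual_loss_mg_yr))))
    cat(sprintf("  mean loss rate: %.3g %% yr^-1\n",
                mean(r$annual_loss_rate_pct_yr)))
  }
  invisible(x)
}
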