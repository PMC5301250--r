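#' Relative-error budget for the carbon accounting
#'
#' Relative errors applied multiplicatively to the stock components:
#' a land-cover/area misclassification error (default 5%, from a 95%
#' accurate land-cover product), and the maximum relative errors of the
#' biomass map's continuous error layer (43.9% for AGB, 21% for BGB,
#' a conservative choice). The budget is additive, not in quadrature:
#' AGB-carbon error is AGB-carbon x (0.439 + 0.05), BGB-carbon error is
#' BGB-carbon x (0.21 + 0.05), and the total stock error is their sum.
#'
#' @param landcover,agb,bgb relative errors in [0, 1).
#' @return A list of class \code{error_budget}.
#' @export
error_budget <- function(landcover = 0.05, agb = 0.439, bgb = 0.21) {
  vals <- c(landcover = landcover, agb = agb, bgb = bgb)
  if (any(vals < 0) || any(vals >= 1))
    stop("relative errors must lie in [0, 1)")
  structure(as.list(vals), class = "error_budget")
}

#' Forest-fraction correction multiplier
#'
#' The loss proportion observed over a whole PA is rescaled to its
#' forested portion by m = 1/f, with f the forest fraction. Under the
#' >= 50% forest-cover inclusion rule, m never exceeds 2.
#'
#' @param f forest fraction, in (0, 1].
#' @return 1/f.
#' @examples
#' correction_multiplier(0.5)   # the bound: exactly 2
#' @export
correction_multiplier <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("forest fraction must be positive")
  if (any(f > 1)) stop("forest fraction cannot exceed 1 (cap it first)")
  1 / f
}

#' Total carbon stock of a PA
#'
#' Carbon is taken as 50% of biomass: stock = forest area (ha) x
#' (mean AGB + mean BGB, Mg ha^-1) x 0.5.
#'
#' @param forest_area_ha forest area in hectares.
#' @param mean_agb,mean_bgb mean biomass densities over forest, Mg ha^-1.
#' @return Stock in Mg C.
#' @examples
#' total_carbon(100, 200, 50)   # 12500 Mg C
#' @export
total_carbon <- function(forest_area_ha, mean_agb, mean_bgb) {
  if (any(forest_area_ha < 0) || any(mean_agb < 0) || any(mean_bgb < 0))
    stop("inputs must be non-negative")
  forest_area_ha * (mean_agb + mean_bgb) * 0.5
}

#' Carbon loss from a corrected loss proportion
#'
#' Total loss = stock x min(multiplier x raw loss proportion, 1); a PA
#' cannot lose more carbon than it holds. Annual loss divides the
#' 2000-2012 total evenly over the period.
#'
#' @param total_c carbon stock, Mg C.
#' @param p_raw raw loss proportion (fraction of whole-PA area lost).
#' @param multiplier forest-fraction correction multiplier (1 for the
#'   uncorrected sensitivity mode).
#' @param years length of the accounting period (default 12).
#' @return List with \code{total} (Mg C) and \code{annual} (Mg C yr^-1).
#' @export
carbon_loss <- function(total_c, p_raw, multiplier = 1, years = 12) {
  if (any(total_c < 0)) stop("total_c must be non-negative")
  if (any(p_raw < 0) || any(p_raw > 1)) stop("p_raw must lie in [0, 1]")
  if (any(multiplier < 1)) stop("multiplier must be >= 1")
  if (years <= 0) stop("years must be positive")
  total <- total_c * pmin(multiplier * p_raw, 1)
  list(total = total, annual = total / years)
}

#' Annualised loss rate
#'
#' Linear annualisation (no compounding): a total loss proportion over
#' \code{years} becomes 100 x proportion / years, in % yr^-1.
#'
#' @param total_loss_proportion proportion in [0, 1].
#' @param years period length.
#' @return Rate in % yr^-1.
#' @examples
#' annualise_rate(0.0203)   # ~0.17 % yr^-1
#' @export
annualise_rate <- function(total_loss_proportion, years = 12) {
  if (any(total_loss_proportion < 0) || any(total_loss_proportion > 1))
    stop("total_loss_proportion must lie in [0, 1]")
  100 * total_loss_proportion / years
}

#' Propagate the error budget to absolute stock and loss errors
#'
#' Component errors are relative and additive: the AGB-carbon error is
#' AGB-carbon x (agb + landcover) relative error, likewise for BGB; the
#' stock error is the sum of the two (not quadrature), and any loss error
#' scales the loss by the stock's relative error.
#'
#' @param agb_carbon,bgb_carbon component stocks (any mass unit; vectors).
#' @param budget an \code{\link{error_budget}}.
#' @return Data frame with \code{agb_err}, \code{bgb_err},
#'   \code{stock_err} (same unit) and \code{rel_stock_err} (NA where the
#'   stock is zero).
#' @examples
#' propagate_errors(28.0, 7.8)   # Pg C in, Pg C errors out
#' @export
propagate_errors <- function(agb_carbon, bgb_carbon, budget = error_budget()) {
  stopifnot(inherits(budget, "error_budget"))
  if (any(agb_carbon < 0) || any(bgb_carbon < 0))
    stop("carbon components must be non-negative")
  agb_err <- agb_carbon * (budget$agb + budget$landcover)
  bgb_err <- bgb_carbon * (budget$bgb + budget$landcover)
  stock <- agb_carbon + bgb_carbon
  stock_err <- agb_err + bgb_err
  data.frame(agb_err = agb_err, bgb_err = bgb_err, stock_err = stock_err,
             rel_stock_err = ifelse(stock > 0, stock_err / stock, NA_real_))
}

#' Carbon mass to CO2 mass
#'
#' Molar-mass conversion, 44/12.
#'
#' @param mass_c carbon mass (any unit).
#' @return CO2 mass in the same unit.
#' @export
to_co2 <- function(mass_c) {
  if (any(mass_c < 0)) stop("mass must be non-negative")
  mass_c * 44 / 12
}

#' Unit helpers: megagrams to teragrams / petagrams
#' @param x mass in Mg (= tonnes).
#' @return Mass in Tg (x 1e-6) or Pg (x 1e-9).
#' @export
mg_to_tg <- function(x) x * 1e-6

#' @rdname mg_to_tg
#' @export
mg_to_pg <- function(x) x * 1e-9
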