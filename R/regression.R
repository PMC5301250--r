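#' Log-log regression of emissions on initial forest area
#'
#' Fits ordinary least squares of log10(emissions) on log10(forest area),
#' the allometry-style model used to judge whether a PA emits more than
#' its size predicts. PAs with zero (or negative) area or emissions
#' cannot enter a log regression; they are excluded from the fit and
#' reported separately rather than offset-shifted, keeping the slope
#' interpretable.
#'
#' @param area forest area per PA (km^2; any consistent unit).
#' @param emissions carbon emissions per PA (annual or period total; the
#'   outlier flags are invariant to that choice, which only shifts the
#'   intercept).
#' @param ids optional PA identifiers (default positional).
#' @return An object of class \code{loglog_fit}: the underlying
#'   \code{lm} fit, the fitted data, the excluded rows, \code{r_squared}
#'   and \code{n}.
#' @seealso \code{\link{classify_outliers}}, \code{\link{concentration}}
#' @export
fit_loglog <- function(area, emissions, ids = NULL) {
  if (length(area) != length(emissions))
    stop("area and emissions must have equal length")
  ids <- ids %||% as.character(seq_along(area))
  usable <- is.finite(area) & is.finite(emissions) & area > 0 & emissions > 0
  d <- data.frame(id = ids, area = area, emissions = emissions,
                  stringsAsFactors = FALSE)
  fit_d <- d[usable, , drop = FALSE]
  if (nrow(fit_d) < 3L) stop("need at least 3 PAs with positive area and emissions")
  if (diff(range(log10(fit_d$area))) == 0)
    stop("degenerate predictor: all areas equal")
  fit_d$log_area <- log10(fit_d$area)
  fit_d$log_emissions <- log10(fit_d$emissions)
  model <- stats::lm(log_emissions ~ log_area, data = fit_d)
  r2 <- suppressWarnings(summary(model)$r.squared)  # exact fits warn
  structure(list(model = model, data = fit_d,
                 excluded = d[!usable, , drop = FALSE],
                 r_squared = r2,
                 n = nrow(fit_d)), class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cf <- stats::coef(x$model)
  cat(sprintf("<loglog_fit> log10(E) = %.3f + %.3f log10(A), r2 = %.3f, n = %d\n",
              cf[1], cf[2], x$r_squared, x$n))
  if (nrow(x$excluded))
    cat(sprintf("  (%d PA(s) with zero/undefined emissions excluded from the fit)\n",
                nrow(x$excluded)))
  invisible(x)
}

#' @export
summary.loglog_fit <- function(object, ...) {
  s <- summary(object$model)
  cat(sprintf("Log-log emissions model: n = %d, excluded = %d\n",
              object$n, nrow(object$excluded)))
  print(s$coefficients)
  cat(sprintf("r-squared: %.4f   residual sd: %.4f (dex)\n",
              s$r.squared, s$sigma))
  invisible(s)
}

#' @export
coef.loglog_fit <- function(object, ...) {
  cf <- stats::coef(object$model)
  c(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' @export
fitted.loglog_fit <- function(object, ...) stats::fitted(object$model)

#' Residuals of a log-log emissions fit
#'
#' \code{"studentised"} (the default) are internally studentised
#' residuals, raw residual / (s * sqrt(1 - h)), with s the residual
#' standard deviation and h the leverage - the scale on which the 2-sigma
#' outlier rule operates. \code{"external"} are the leave-one-out
#' (deleted) variant; \code{"raw"} are plain residuals in dex.
#' Exactly-determined points (leverage 1) give \code{NaN}, reported as
#' such.
#'
#' @param object a \code{loglog_fit}.
#' @param type one of "studentised", "external", "raw".
#' @param ... unused.
#' @return Named numeric vector (names are PA ids).
#' @export
residuals.loglog_fit <- function(object,
                                 type = c("studentised", "external", "raw"),
                                 ...) {
  type <- match.arg(type)
  s <- suppressWarnings(summary(object$model)$sigma)  # exact fits warn
  scale0 <- s < 1e-10 * max(1, max(abs(object$data$log_emissions)))
  r <- if (type == "raw") stats::residuals(object$model)
  else if (scale0) rep(0, object$n)   # perfect fit: zero on any scale
  else if (type == "studentised") stats::rstandard(object$model)
  else stats::rstudent(object$model)
  stats::setNames(as.numeric(r), object$data$id)
}

#' @export
predict.loglog_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(10^stats::fitted(object$model))
  stopifnot(is.numeric(newdata), all(newdata > 0))
  10^stats::predict(object$model,
                    newdata = data.frame(log_area = log10(newdata)))
}

#' @export
plot.loglog_fit <- function(x, threshold = 2, ...) {
  d <- x$data
  r <- residuals(x, "studentised")
  col <- ifelse(r > threshold, "red", ifelse(r < -threshold, "darkgreen", "grey40"))
  graphics::plot(d$log_area, d$log_emissions, col = col, pch = 19,
                 xlab = "log10 forest area", ylab = "log10 emissions", ...)
  graphics::abline(x$model, lwd = 2)
  invisible(x)
}

#' Flag disproportionately emitting PAs
#'
#' Applies the studentised-residual rule: PAs with residual strictly
#' above \code{+threshold} emit significantly more than their forest area
#' predicts (the high set); strictly below \code{-threshold},
#' significantly less (the low set). Shares of the cohort, of total
#' forest area and of total emissions are reported for each set,
#' including any zero-emission PAs excluded from the fit in the
#' denominators.
#'
#' @param fit a \code{\link{fit_loglog}} result.
#' @param threshold flagging threshold in studentised-residual units
#'   (default 2; strict inequality, so a residual of exactly 2 is not
#'   flagged).
#' @return List of class \code{outlier_report}: \code{high} and
#'   \code{low} data frames (id, area, emissions, residual), counts and
#'   the three share measures per set.
#' @export
classify_outliers <- function(fit, threshold = 2) {
  stopifnot(inherits(fit, "loglog_fit"), threshold >= 0)
  r <- residuals(fit, "studentised")
  d <- fit$data
  tot_n <- nrow(d) + nrow(fit$excluded)
  tot_area <- sum(d$area) + sum(pmax(fit$excluded$area, 0))
  tot_em <- sum(d$emissions) + sum(pmax(fit$excluded$emissions, 0))
  pick <- function(sel) {
    out <- d[sel, c("id", "area", "emissions"), drop = FALSE]
    out$residual <- r[sel]
    rownames(out) <- NULL
    out
  }
  mk <- function(set) list(
    n = nrow(set),
    cohort_share = nrow(set) / tot_n,
    area_share = sum(set$area) / tot_area,
    emission_share = sum(set$emissions) / tot_em)
  high <- pick(!is.na(r) & r > threshold)
  low <- pick(!is.na(r) & r < -threshold)
  structure(list(high = high, low = low, threshold = threshold,
                 high_stats = mk(high), low_stats = mk(low),
                 n_total = tot_n, undefined = sum(is.na(r))),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> |studentised residual| > %g of %d PAs\n",
              x$threshold, x$n_total))
  cat(sprintf("  high emitters: n = %d (%.1f%% of cohort, %.1f%% of area, %.1f%% of emissions)\n",
              x$high_stats$n, 100 * x$high_stats$cohort_share,
              100 * x$high_stats$area_share, 100 * x$high_stats$emission_share))
  cat(sprintf("  low emitters:  n = %d (%.1f%% of cohort, %.1f%% of area, %.1f%% of emissions)\n",
              x$low_stats$n, 100 * x$low_stats$cohort_share,
              100 * x$low_stats$area_share, 100 * x$low_stats$emission_share))
  invisible(x)
}

#' Concentration of emissions across PAs
#'
#' Sorts emissions in descending order (ties keep original order) and
#' finds the smallest prefix of PAs whose cumulative share reaches the
#' target - the "X% of PAs cause 80% of emissions" statistic.
#'
#' @param emissions non-negative vector, not all zero.
#' @param target_share cumulative share to reach (default 0.8).
#' @param ids optional identifiers.
#' @return List of class \code{concentration_result}: \code{n_pas},
#'   \code{fraction} of the cohort, \code{subset_emissions},
#'   \code{subset_ids} and the full non-decreasing \code{cumulative_share}
#'   vector (ending at 1).
#' @export
concentration <- function(emissions, target_share = 0.8, ids = NULL) {
  if (any(emissions < 0)) stop("emissions must be non-negative")
  if (all(emissions == 0)) stop("all emissions are zero")
  stopifnot(target_share > 0, target_share <= 1)
  ids <- ids %||% as.character(seq_along(emissions))
  ord <- order(-emissions)            # radix: stable for ties
  cum <- cumsum(emissions[ord]) / sum(emissions)
  k <- which(cum >= target_share - 1e-12)[1]
  structure(list(n_pas = k, fraction = k / length(emissions),
                 target_share = target_share,
                 subset_emissions = sum(emissions[ord[seq_len(k)]]),
                 subset_ids = ids[ord[seq_len(k)]],
                 cumulative_share = cum),
            class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("<concentration> %d PAs (%.1f%% of cohort) reach %.0f%% of emissions\n",
              x$n_pas, 100 * x$fraction, 100 * x$target_share))
  invisible(x)
}

#' IUCN-category and country summaries
#'
#' Per IUCN category: PA count, mean carbon density over the reported
#' forest area (Mg C ha^-1), and the distribution of annual loss rates
#' (mean, median, quartiles by linear interpolation, and 1.5 x IQR
#' whiskers clamped to observed values, the usual box-plot convention).
#' Per country: totals of stock and loss and the proportional loss of
#' year-2000 protected carbon (country loss over country stock).
#'
#' @param results the per-PA results frame of a \code{\link{pa_cohort}}.
#' @return List with data frames \code{by_category} and
#'   \code{by_country}.
#' @export
summarise_categories <- function(results) {
  if (!nrow(results)) stop("empty cohort")
  dens <- results$carbon_stock_mg / results$forest_area_ha
  rate <- results$annual_loss_rate_pct_yr
  cats <- c("Ia", "Ib", "II", "III", "IV", "V", "VI")
  present <- cats[cats %in% results$iucn_cat]
  if (length(setdiff(cats, present)))
    warning("categories with zero PAs omitted: ",
            paste(setdiff(cats, present), collapse = ", "))
  by_category <- do.call(rbind, lapply(present, function(cc) {
    i <- results$iucn_cat == cc
    q <- stats::quantile(rate[i], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    inrange <- rate[i][rate[i] >= q[1] - 1.5 * iqr & rate[i] <= q[3] + 1.5 * iqr]
    data.frame(iucn_cat = cc, n = sum(i),
               mean_carbon_density_mg_ha = mean(dens[i]),
               mean_rate_pct_yr = mean(rate[i]),
               median_rate_pct_yr = q[2],
               q1_rate = q[1], q3_rate = q[3],
               whisker_low = min(inrange), whisker_high = max(inrange),
               stringsAsFactors = FALSE)
  }))
  by_country <- do.call(rbind, lapply(sort(unique(results$country)), function(cc) {
    i <- results$country == cc
    stock <- sum(results$carbon_stock_mg[i])
    loss <- sum(results$carbon_loss_mg[i])
    data.frame(country = cc, n = sum(i),
               carbon_stock_mg = stock, carbon_loss_mg = loss,
               annual_co2_mg_yr = sum(results$annual_co2_mg_yr[i]),
               prop_protected_carbon_lost = if (stock > 0) loss / stock else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(by_category) <- rownames(by_country) <- NULL
  list(by_category = by_category, by_country = by_country)
}
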