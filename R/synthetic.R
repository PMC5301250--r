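#' Synthetic-scene configuration
#'
#' Describes a synthetic tropical landscape mirroring the data stack the
#' accounting pipeline consumes: a ~1 km categorical land-cover grid
#' (forest classes 1-8, non-forest 20), ~1 km above- and below-ground
#' biomass grids (Mg ha^-1, zero outside forest), a fine binary
#' forest-loss grid nested \code{subdivision} times inside the coarse
#' grid, and rectangular PA polygons with recorded GIS areas equal to
#' their exact geometric areas. Baseline per-PA loss is a Beta-distributed
#' fraction of the PA's forest; a configurable number of "outlier" PAs
#' have that fraction multiplied to emulate disproportionately emitting
#' reserves.
#'
#' @param width,height scene size in coarse pixels.
#' @param coarse_px coarse pixel edge (map units; 1000 emulates 1 km).
#' @param subdivision integer fine cells per coarse cell edge (32 emulates
#'   ~30 m loss data inside 1 km cells).
#' @param n_pa number of protected areas.
#' @param pa_area_range_km2 min/max PA area (km^2).
#' @param forest_fraction_range min/max target forest fraction per PA.
#' @param loss_mean,loss_concentration mean and concentration of the Beta
#'   distribution of the per-PA 12-year fraction of forest lost
#'   (shape1 = mean x concentration, shape2 = (1 - mean) x concentration).
#' @param n_outliers number of injected high-loss PAs.
#' @param outlier_multiplier factor applied to the baseline loss fraction
#'   of injected PAs (capped at 0.95).
#' @param agb_mean,agb_sd mean/sd of per-cell AGB over forest (Mg ha^-1,
#'   truncated positive).
#' @param bgb_ratio below-ground biomass as a fixed ratio of AGB.
#' @param background_forest probability that a coarse cell outside every
#'   PA is forest.
#' @param snap \code{"working"} aligns PA edges to the quarter-coarse
#'   working grid so ground truth is exact under centre-point extraction;
#'   \code{"none"} leaves edges unaligned, exercising true rasterisation
#'   error.
#' @param working_divisor coarse-to-working subdivision used by
#'   \code{snap = "working"}; must divide \code{subdivision}.
#' @param seed integer RNG seed; a fixed seed makes the scene, polygons
#'   and truth byte-identical across runs.
#' @return A validated list of class \code{scene_config}.
#' @export
scene_config <- function(width = 180, height = 180, coarse_px = 1000,
                         subdivision = 32, n_pa = 100,
                         pa_area_range_km2 = c(25, 150),
                         forest_fraction_range = c(0.60, 0.95),
                         loss_mean = 0.02, loss_concentration = 300,
                         n_outliers = 5, outlier_multiplier = 20,
                         agb_mean = 180, agb_sd = 45, bgb_ratio = 0.28,
                         background_forest = 0.3,
                         snap = c("working", "none"), working_divisor = 4,
                         seed = 1) {
  snap <- match.arg(snap)
  cfg <- list(width = as.integer(width), height = as.integer(height),
              coarse_px = coarse_px, subdivision = as.integer(subdivision),
              n_pa = as.integer(n_pa),
              pa_area_range_km2 = as.numeric(pa_area_range_km2),
              forest_fraction_range = as.numeric(forest_fraction_range),
              loss_mean = loss_mean, loss_concentration = loss_concentration,
              n_outliers = as.integer(n_outliers),
              outlier_multiplier = outlier_multiplier,
              agb_mean = agb_mean, agb_sd = agb_sd, bgb_ratio = bgb_ratio,
              background_forest = background_forest, snap = snap,
              working_divisor = as.integer(working_divisor),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(width >= 4, height >= 4, coarse_px > 0, subdivision >= 1,
              n_pa >= 1, n_outliers >= 0, n_outliers <= n_pa,
              outlier_multiplier >= 1, agb_mean > 0, agb_sd >= 0,
              bgb_ratio >= 0, working_divisor >= 1)
    if (subdivision %% working_divisor != 0L)
      stop("working_divisor must divide subdivision")
    if (any(pa_area_range_km2 <= 0) || diff(pa_area_range_km2) < 0)
      stop("pa_area_range_km2 must be positive and ordered")
    if (any(forest_fraction_range < 0) || any(forest_fraction_range > 1) ||
        diff(forest_fraction_range) < 0)
      stop("forest_fraction_range must lie in [0, 1] and be ordered")
    if (loss_mean < 0 || loss_mean > 1)
      stop("loss_mean must lie in [0, 1]")
    if (background_forest < 0 || background_forest > 1)
      stop("background_forest must lie in [0, 1]")
  })
  structure(cfg, class = "scene_config")
}

FOREST_CLASSES <- 1:8
NONFOREST_CLASS <- 20

# inclusive fine column range of cells whose centre x is in [lo, hi)
fine_cols <- function(lo, hi, f) {
  c0 <- ceiling(lo / f + 0.5)
  c1 <- ceiling(hi / f + 0.5) - 1
  if (c1 < c0) integer(0) else seq.int(c0, c1)
}

# inclusive fine row range (top-down distance t) of centres with t in (lo, hi]
fine_rows <- function(lo, hi, f) {
  r0 <- floor(lo / f + 0.5) + 1
  r1 <- floor(hi / f + 0.5)
  if (r1 < r0) integer(0) else seq.int(r0, r1)
}

#' Generate a synthetic scene with analytic ground truth
#'
#' Builds the full raster stack, the PA polygons, and a truth table whose
#' values are computed from the construction itself (cell-by-cell overlap
#' areas, drawn loss cells), never through the extraction pipeline, so the
#' pipeline can be tested against it.
#'
#' @param config a \code{\link{scene_config}}.
#' @return A list of class \code{pa_sim} with elements \code{scene} (class
#'   \code{pa_scene}: grids \code{landcover}, \code{agb}, \code{bgb} at the
#'   coarse resolution and binary \code{loss} at the fine resolution),
#'   \code{records} (a \code{\link{pa_records}} frame) and \code{truth}
#'   (one row per PA: exact forest area, forest fraction, mean biomass over
#'   forest, carbon stock, corrected loss proportion, carbon loss, outlier
#'   flag).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  C <- config$coarse_px
  W <- config$width * C; H <- config$height * C
  wpx <- C / config$working_divisor
  margin <- C

  ## ---- place rectangles (snapped to the working grid by default) ----
  rects <- matrix(NA_real_, config$n_pa, 4,
                  dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
  for (i in seq_len(config$n_pa)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      a_km2 <- stats::runif(1, config$pa_area_range_km2[1],
                            config$pa_area_range_km2[2])
      aspect <- stats::runif(1, 0.6, 1.6)
      w <- sqrt(a_km2 * 1e6 * aspect)
      h <- a_km2 * 1e6 / w
      if (config$snap == "working") {
        w <- max(wpx, round(w / wpx) * wpx)
        h <- max(wpx, round(h / wpx) * wpx)
      }
      if (w + 2 * margin > W || h + 2 * margin > H) next
      x0 <- stats::runif(1, margin, W - margin - w)
      y0 <- stats::runif(1, margin, H - margin - h)
      if (config$snap == "working") {
        x0 <- round(x0 / wpx) * wpx
        y0 <- round(y0 / wpx) * wpx
      }
      cand <- c(x0, y0, x0 + w, y0 + h)
      ok <- TRUE
      if (i > 1L) {
        p <- rects[seq_len(i - 1L), , drop = FALSE]
        ok <- all(cand[1] - margin >= p[, "xmax"] | cand[3] + margin <= p[, "xmin"] |
                    cand[2] - margin >= p[, "ymax"] | cand[4] + margin <= p[, "ymin"])
      }
      if (ok) { rects[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(paste0("cannot pack PA %d of %d into a %d x %d coarse-pixel ",
                          "scene with areas %g-%g km2 and a one-pixel margin; ",
                          "enlarge the scene or reduce n_pa/pa_area_range_km2"),
                   i, config$n_pa, config$width, config$height,
                   config$pa_area_range_km2[1], config$pa_area_range_km2[2]))
  }
  gis_area_km2 <- (rects[, "xmax"] - rects[, "xmin"]) *
    (rects[, "ymax"] - rects[, "ymin"]) / 1e6

  ## ---- attributes ----
  countries <- c("Brazil", "Indonesia", "Cambodia", "Guatemala", "Honduras",
                 "Peru", "DR Congo", "Mozambique", "Colombia", "Vietnam")
  iucn_levels <- c("Ia", "Ib", "II", "III", "IV", "V", "VI")
  iucn_w <- c(207, 69, 552, 36, 413, 357, 384)   # plausible cohort mix
  records <- pa_records(
    id = sprintf("PA%03d", seq_len(config$n_pa)),
    name = sprintf("Synthetic Reserve %03d", seq_len(config$n_pa)),
    country = sample(countries, config$n_pa, replace = TRUE),
    iucn_cat = sample(iucn_levels, config$n_pa, replace = TRUE, prob = iucn_w),
    status = sample(c("designated", "proposed"), config$n_pa,
                    replace = TRUE, prob = c(0.9, 0.1)),
    gis_area_km2 = gis_area_km2,
    geometry = lapply(seq_len(config$n_pa), function(i)
      rect_poly(rects[i, "xmin"], rects[i, "ymin"],
                rects[i, "xmax"], rects[i, "ymax"])))

  ## ---- coarse land cover: background, then per-PA forest assignment ----
  nr <- config$height; nc <- config$width
  lc <- matrix(ifelse(stats::runif(nr * nc) < config$background_forest,
                      sample(FOREST_CLASSES, nr * nc, replace = TRUE),
                      NONFOREST_CLASS), nr, nc)
  pa_cells <- vector("list", config$n_pa)    # per PA: forest cells + overlaps
  f_target <- stats::runif(config$n_pa, config$forest_fraction_range[1],
                           config$forest_fraction_range[2])
  for (i in seq_len(config$n_pa)) {
    xmin <- rects[i, "xmin"]; xmax <- rects[i, "xmax"]
    ymin <- rects[i, "ymin"]; ymax <- rects[i, "ymax"]
    cols <- seq.int(floor(xmin / C) + 1L, ceiling(xmax / C - 1e-9))
    rows <- seq.int(floor((H - ymax) / C) + 1L, ceiling((H - ymin) / C - 1e-9))
    cells <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
    ox <- pmin(cells$col * C, xmax) - pmax((cells$col - 1) * C, xmin)
    cell_ytop <- H - (cells$row - 1) * C
    oy <- pmin(cell_ytop, ymax) - pmax(cell_ytop - C, ymin)
    overlap <- ox * oy
    keep <- overlap > 1e-9
    cells <- cells[keep, , drop = FALSE]; overlap <- overlap[keep]
    ord <- sample.int(nrow(cells))
    cum <- cumsum(overlap[ord])
    need <- f_target[i] * gis_area_km2[i] * 1e6
    n_forest <- if (need <= 1e-6) 0L else which(cum >= need - 1e-6)[1]
    if (is.na(n_forest)) n_forest <- nrow(cells)
    fsel <- ord[seq_len(n_forest)]
    idx <- (cells$col - 1L) * nr + cells$row
    lc[idx] <- NONFOREST_CLASS
    lc[idx[fsel]] <- sample(FOREST_CLASSES, n_forest, replace = TRUE)
    pa_cells[[i]] <- list(rows = cells$row[fsel], cols = cells$col[fsel],
                          overlap = overlap[fsel],
                          rect = rects[i, ])
  }

  ## ---- biomass over forest ----
  forest_idx <- which(lc %in% FOREST_CLASSES)
  agb <- matrix(0, nr, nc)
  draw <- stats::rnorm(length(forest_idx), config$agb_mean, config$agb_sd)
  while (any(draw <= 0))
    draw[draw <= 0] <- stats::rnorm(sum(draw <= 0), config$agb_mean,
                                    config$agb_sd)
  agb[forest_idx] <- draw
  bgb <- agb * config$bgb_ratio

  ## ---- fine loss grid + truth ----
  sub <- config$subdivision
  fpx <- C / sub
  fnr <- nr * sub; fnc <- nc * sub
  fine_area_ha <- fpx^2 / 1e4
  loss <- matrix(0L, fnr, fnc)
  outlier <- rep(FALSE, config$n_pa)
  outlier[sample.int(config$n_pa, config$n_outliers)] <- TRUE
  q_base <- if (config$loss_mean <= 0) rep(0, config$n_pa)
  else if (config$loss_mean >= 1) rep(1, config$n_pa)
  else stats::rbeta(config$n_pa,
                    config$loss_mean * config$loss_concentration,
                    (1 - config$loss_mean) * config$loss_concentration)
  q <- ifelse(outlier, pmin(q_base * config$outlier_multiplier, 0.95), q_base)

  truth <- data.frame(id = records$id,
                      forest_area_ha = NA_real_, forest_fraction = NA_real_,
                      mean_agb = NA_real_, mean_bgb = NA_real_,
                      carbon_stock_mg = NA_real_,
                      loss_prop_corrected = NA_real_,
                      carbon_loss_mg = NA_real_,
                      outlier = outlier, stringsAsFactors = FALSE)
  for (i in seq_len(config$n_pa)) {
    pc <- pa_cells[[i]]
    xmin <- pc$rect["xmin"]; xmax <- pc$rect["xmax"]
    ymin <- pc$rect["ymin"]; ymax <- pc$rect["ymax"]
    ncell <- length(pc$rows)
    fidx <- vector("list", ncell)
    for (k in seq_len(ncell)) {
      cxmin <- (pc$cols[k] - 1) * C; cymax <- H - (pc$rows[k] - 1) * C
      fc <- fine_cols(max(cxmin, xmin), min(cxmin + C, xmax), fpx)
      fr <- fine_rows(max(H - cymax, H - ymax), min(H - cymax + C, H - ymin), fpx)
      fidx[[k]] <- as.vector(outer(fr, (fc - 1L) * fnr, `+`))
    }
    ncell_fine <- lengths(fidx)
    all_fine <- unlist(fidx, use.names = FALSE)
    n_forest_fine <- length(all_fine)
    n_loss <- round(q[i] * n_forest_fine)
    dens <- (agb[cbind(pc$rows, pc$cols)] + bgb[cbind(pc$rows, pc$cols)]) * 0.5
    if (n_loss > 0) {
      sel <- sample.int(n_forest_fine, n_loss)
      loss[all_fine[sel]] <- 1L
      grp <- rep.int(seq_len(ncell), ncell_fine)[sel]
      lost_per_cell <- tabulate(grp, nbins = ncell)
    } else lost_per_cell <- rep(0L, ncell)
    w <- pc$overlap
    farea_ha <- sum(w) / 1e4
    truth$forest_area_ha[i] <- farea_ha
    truth$forest_fraction[i] <- sum(w) / (gis_area_km2[i] * 1e6)
    truth$mean_agb[i] <- if (ncell) sum(w * agb[cbind(pc$rows, pc$cols)]) / sum(w) else 0
    truth$mean_bgb[i] <- if (ncell) sum(w * bgb[cbind(pc$rows, pc$cols)]) / sum(w) else 0
    truth$carbon_stock_mg[i] <-
      farea_ha * (truth$mean_agb[i] + truth$mean_bgb[i]) * 0.5
    truth$loss_prop_corrected[i] <-
      if (n_forest_fine > 0) n_loss / n_forest_fine else 0
    truth$carbon_loss_mg[i] <- sum(lost_per_cell * fine_area_ha * dens)
  }

  scene <- structure(list(
    landcover = pa_grid(lc, origin = c(0, H), px = C, kind = "categorical"),
    agb = pa_grid(agb, origin = c(0, H), px = C, kind = "continuous"),
    bgb = pa_grid(bgb, origin = c(0, H), px = C, kind = "continuous"),
    loss = pa_grid(loss, origin = c(0, H), px = fpx, kind = "categorical"),
    coarse_px = C, subdivision = sub, config = config), class = "pa_scene")
  structure(list(scene = scene, records = records, truth = truth),
            class = "pa_sim")
}

#' @export
print.pa_scene <- function(x, ...) {
  cat(sprintf("<pa_scene> %d x %d coarse px @ %g; loss grid @ %g (x%d)\n",
              nrow(x$landcover$values), ncol(x$landcover$values),
              x$coarse_px, x$loss$px, x$subdivision))
  invisible(x)
}

#' @export
print.pa_sim <- function(x, ...) {
  print(x$scene)
  cat(sprintf("  %d PAs, %d injected outliers; total true stock %.3g Mg C, loss %.3g Mg C\n",
              nrow(x$records), sum(x$truth$outlier),
              sum(x$truth$carbon_stock_mg), sum(x$truth$carbon_loss_mg)))
  invisible(x)
}

#' Write / read a synthetic scene as plain-text files
#'
#' Rasters go to ESRI ASCII grids, polygons to GeoJSON, the truth table to
#' CSV, and the scene frame (pixel sizes, subdivision) to a small JSON
#' sidecar, so a fixture round-trips losslessly through
#' \code{read_fixture}.
#'
#' @param sim a \code{pa_sim} from \code{\link{generate_scene}}.
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written (invisibly for
#'   \code{write_fixture}); \code{read_fixture} returns a \code{pa_sim}.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "pa_sim"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", dir)
  paths <- c(landcover = file.path(dir, "landcover.asc"),
             agb = file.path(dir, "agb.asc"),
             bgb = file.path(dir, "bgb.asc"),
             loss = file.path(dir, "loss.asc"),
             pas = file.path(dir, "pas.geojson"),
             truth = file.path(dir, "truth.csv"),
             meta = file.path(dir, "scene.json"))
  write_ascii_grid(sim$scene$landcover, paths["landcover"])
  write_ascii_grid(sim$scene$agb, paths["agb"])
  write_ascii_grid(sim$scene$bgb, paths["bgb"])
  write_ascii_grid(sim$scene$loss, paths["loss"])
  write_geojson(sim$records, paths["pas"])
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  writeLines(jsonlite::toJSON(list(coarse_px = sim$scene$coarse_px,
                                   subdivision = sim$scene$subdivision),
                              auto_unbox = TRUE, digits = NA), paths["meta"])
  invisible(paths)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "scene.json"))
  scene <- structure(list(
    landcover = read_ascii_grid(file.path(dir, "landcover.asc"), "categorical"),
    agb = read_ascii_grid(file.path(dir, "agb.asc"), "continuous"),
    bgb = read_ascii_grid(file.path(dir, "bgb.asc"), "continuous"),
    loss = read_ascii_grid(file.path(dir, "loss.asc"), "categorical"),
    coarse_px = meta$coarse_px, subdivision = meta$subdivision,
    config = NULL), class = "pa_scene")
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  structure(list(scene = scene,
                 records = read_geojson(file.path(dir, "pas.geojson")),
                 truth = truth), class = "pa_sim")
}
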