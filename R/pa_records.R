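#' Protected-area records
#'
#' A cohort of PAs is a data frame with one row per PA carrying the
#' attributes recorded in PA databases (name, country, IUCN management
#' category Ia-VI, designation status, recorded GIS area in km^2) plus a
#' \code{geometry} list-column of polygon vertex matrices in the scene's
#' planar frame.
#'
#' @param id,name,country character vectors (recycled as needed).
#' @param iucn_cat IUCN category, one of Ia, Ib, II, III, IV, V, VI.
#' @param status "designated" or "proposed".
#' @param gis_area_km2 recorded GIS area (> 0), km^2.
#' @param geometry list of two-column vertex matrices.
#' @return A data frame of class \code{c("pa_records", "data.frame")}.
#' @export
pa_records <- function(id, name, country, iucn_cat, status, gis_area_km2,
                       geometry) {
  iucn_levels <- c("Ia", "Ib", "II", "III", "IV", "V", "VI")
  if (!all(iucn_cat %in% iucn_levels))
    stop("iucn_cat must be one of: ", paste(iucn_levels, collapse = ", "))
  if (!all(status %in% c("designated", "proposed")))
    stop("status must be 'designated' or 'proposed'")
  if (!all(gis_area_km2 > 0)) stop("gis_area_km2 must be positive")
  if (!is.list(geometry) || length(geometry) != length(id))
    stop("geometry must be a list of vertex matrices, one per PA")
  geometry <- lapply(geometry, check_polygon)
  df <- data.frame(id = as.character(id), name = as.character(name),
                   country = as.character(country),
                   iucn_cat = as.character(iucn_cat),
                   status = as.character(status),
                   gis_area_km2 = as.numeric(gis_area_km2),
                   stringsAsFactors = FALSE)
  df$geometry <- geometry
  class(df) <- c("pa_records", "data.frame")
  df
}

#' @export
print.pa_records <- function(x, ...) {
  cat(sprintf("<pa_records> %d protected areas, %.0f-%.0f km2\n",
              nrow(x), min(x$gis_area_km2), max(x$gis_area_km2)))
  print.data.frame(utils::head(x[, setdiff(names(x), "geometry")], 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write / read PA polygons as GeoJSON
#'
#' One Feature per PA with a Polygon geometry (closed ring) and the
#' properties \code{id, name, country, iucn_cat, status, gis_area_km2}.
#' Coordinates are the scene's planar coordinates.
#'
#' @param records a \code{pa_records} data frame.
#' @param path output file.
#' @return \code{write_geojson} returns \code{path} invisibly;
#'   \code{read_geojson} a \code{pa_records} data frame.
#' @export
write_geojson <- function(records, path) {
  stopifnot(inherits(records, "pa_records"))
  feats <- lapply(seq_len(nrow(records)), function(i) {
    ring <- records$geometry[[i]]
    ring <- rbind(ring, ring[1L, ])              # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(id = records$id[i], name = records$name[i],
                           country = records$country[i],
                           iucn_cat = records$iucn_cat[i],
                           status = records$status[i],
                           gis_area_km2 = records$gis_area_km2[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring))))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  props <- lapply(fc$features, `[[`, "properties")
  geoms <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    colnames(m) <- c("x", "y")
    m[-nrow(m), , drop = FALSE]                  # reopen the ring
  })
  get <- function(k) vapply(props, function(p) as.character(p[[k]]), "")
  pa_records(id = get("id"), name = get("name"), country = get("country"),
             iucn_cat = get("iucn_cat"), status = get("status"),
             gis_area_km2 = vapply(props, function(p)
               as.numeric(p$gis_area_km2), 0), geometry = geoms)
}
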