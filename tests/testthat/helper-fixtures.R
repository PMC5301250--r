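# Shared fixtures, built in code. The small scene is cached per test run.

small_config <- function(seed = 7, ...) {
  scene_config(width = 60, height = 60, n_pa = 15,
               pa_area_range_km2 = c(12, 60), subdivision = 8,
               n_outliers = 2, seed = seed, ...)
}

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- generate_scene(small_config())
  .sim_cache$sim
}

random_grid <- function(nr, nc, px = 1000, kind = "categorical",
                        values = sample(c(1:8, 20), nr * nc, replace = TRUE)) {
  pa_grid(matrix(values, nr, nc), origin = c(0, nr * px), px = px, kind = kind)
}

# brute-force zonal over an axis-aligned rectangle: per-pixel centre loop
# using the bottom/left-inclusive boundary rule, written independently of
# the package's polygon machinery
brute_zonal_rect <- function(g, xmin, ymin, xmax, ymax) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  vals <- c()
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      x <- (cc - 0.5) * g$px
      y <- nr * g$px - (r - 0.5) * g$px
      if (x >= xmin && x < xmax && y >= ymin && y < ymax)
        vals <- c(vals, g$values[r, cc])
    }
  }
  list(count = length(vals),
       mean = if (length(vals)) mean(vals) else NA_real_,
       sum = if (length(vals)) sum(vals) else 0)
}
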