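# Internal helpers shared across modules.

# Haversine distance in meters between lon/lat points. Thin wrapper so all
# great-circle math funnels through one (well-tested) backend.
haversine_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

# Deterministic 31-bit seed derived from a root seed and a string id, so
# adding users never perturbs the random stream of existing ones.
derive_seed <- function(seed, id) {
  codes <- utf8ToInt(paste0("u:", id))
  h <- as.numeric(seed %% 2147483647)
  for (k in codes) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (strict && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

# Local tangent-plane projection (equirectangular) around an origin; adequate
# at the km scales of daily mobility. Returns/accepts meters east & north.
ll_to_xy <- function(lat, lon, origin) {
  r <- 6371008.8
  x <- (lon - origin[["lon"]]) * pi / 180 * r * cos(origin[["lat"]] * pi / 180)
  y <- (lat - origin[["lat"]]) * pi / 180 * r
  cbind(x = x, y = y)
}

xy_to_ll <- function(xy, origin) {
  r <- 6371008.8
  lat <- origin[["lat"]] + (xy[, 2] / r) * 180 / pi
  lon <- origin[["lon"]] +
    (xy[, 1] / (r * cos(origin[["lat"]] * pi / 180))) * 180 / pi
  cbind(lat = lat, lon = lon)
}

# Order activity labels: core classes first in fixed order, then manual
# labels alphabetically. Used for deterministic tie-breaking.
activity_rank <- function(labels) {
  core <- match(labels, .activity_levels)
  extra <- match(labels, sort(unique(labels[is.na(core)])))
  ifelse(is.na(core), length(.activity_levels) + extra, core)
}

is_lifelog <- function(x) inherits(x, "lifelog")

as_lifelog_tbl <- function(x) {
  x <- as_tibble(x)
  class(x) <- c("lifelog", class(x))
  x
}
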