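# Conversion between local planar coordinates (metres, east/north) and
# geographic coordinates. An equirectangular projection about a fixed anchor
# is accurate to well under a centimetre over the few kilometres a lap course
# spans, which keeps round-trips exact at the precision GNSS provides.

EARTH_M_PER_DEG <- 111320  # metres per degree of latitude

# Default anchor: Gjoevik, Norway, a typical venue latitude for the sport.
DEFAULT_ANCHOR <- c(lat = 60.795, lon = 10.692)

planar_to_geo <- function(x, y, anchor = DEFAULT_ANCHOR) {
  lat <- anchor[["lat"]] + y / EARTH_M_PER_DEG
  lon <- anchor[["lon"]] + x / (EARTH_M_PER_DEG * cos(anchor[["lat"]] * pi / 180))
  list(lat = lat, lon = lon)
}

geo_to_planar <- function(lat, lon, anchor = DEFAULT_ANCHOR) {
  y <- (lat - anchor[["lat"]]) * EARTH_M_PER_DEG
  x <- (lon - anchor[["lon"]]) * EARTH_M_PER_DEG * cos(anchor[["lat"]] * pi / 180)
  list(x = x, y = y)
}
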