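# Shared fixtures: planar CRS shortcut, a degree cell on the sphere, and an
# independent raster oracle for intersection areas (mgcv-based point-in-polygon,
# no use of the package's clipping engine).

km <- function() crs_planar("km", "test planar km")

# closed-form spherical area of a lon/lat cell, authalic radius (km^2)
spherical_cell_area <- function(lon0, lon1, lat0, lat1, R = 6371.0071809) {
  R^2 * (lon1 - lon0) * pi / 180 * (sin(lat1 * pi / 180) - sin(lat0 * pi / 180))
}

geo_cell <- function(lon0, lat0, dlon = 1, dlat = 1) {
  geom_rect(lon0, lat0, lon0 + dlon, lat0 + dlat)
}

# brute-force intersection area: count grid centres inside both polygons
raster_intersection_area <- function(a, b, cell = 0.25) {
  in_geom <- function(g, pts) {
    inside <- numeric(nrow(pts))
    for (p in g$parts) {
      for (i in seq_along(p)) {
        r <- p[[i]]
        inside <- inside + (if (i == 1) 1 else -1) *
          mgcv::in.out(rbind(r, r[1, ]), pts)
      }
    }
    inside > 0
  }
  bb <- function(g) {
    xy <- do.call(rbind, unlist(g$parts, recursive = FALSE))
    c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  }
  ba <- bb(a); bbx <- bb(b)
  lo <- pmax(ba[1:2], bbx[1:2]); hi <- pmin(ba[3:4], bbx[3:4])
  if (any(hi <= lo)) return(0)
  xs <- seq(lo[1] + cell / 2, hi[1], by = cell)
  ys <- seq(lo[2] + cell / 2, hi[2], by = cell)
  if (!length(xs) || !length(ys)) return(0)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  sum(in_geom(a, pts) & in_geom(b, pts)) * cell^2
}

toy_metadata <- function(world) {
  data.frame(species_id = names(world$iucn), iucn_category = unname(world$iucn),
             stringsAsFactors = FALSE)
}

# The published class/score table, frozen here entry by entry as the test
# reference (rows: category; columns: very_high, high, medium, basic).
reference_matrix <- function() {
  txt <- "
  EW 1 25  1 20  2 17  2 16
  CR 1 22  2 17  2 14  2 13
  EN 1 20  2 15  3 12  3 11
  VU 2 18  2 13  3 10  4  9
  NT 2 16  3 11  4  8  4  7
  LC 3 11  4  6  4  3  4  2"
  rows <- strsplit(trimws(strsplit(txt, "\n")[[1]]), "\\s+")
  rows <- Filter(length, rows)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(category = r[1],
               nr = c("very_high", "high", "medium", "basic"),
               cp_class = as.integer(r[c(2, 4, 6, 8)]),
               score = as.integer(r[c(3, 5, 7, 9)]),
               stringsAsFactors = FALSE)
  }))
}
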