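# Planar polygon engine: shoelace areas, ear-clipping triangulation and
# Sutherland-Hodgman convex clipping. Geometries are stored as lists of parts,
# each part a list of rings (first ring outer, later rings holes), each ring an
# unclosed n x 2 coordinate matrix normalised to counter-clockwise orientation.
# Boolean *area* operations are computed on a signed triangle soup: outer rings
# contribute +1 triangles, holes -1, and intersection of two soups is the
# pairwise clip of convex pieces with multiplied signs. This is exact for the
# area measure whenever holes are nested inside their outer rings.

cross2 <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]

#' Signed ring area (shoelace formula)
#'
#' Positive for counter-clockwise rings. Coordinates are planar; the result is
#' in squared coordinate units.
#'
#' @param m unclosed n x 2 coordinate matrix.
#' @return signed area, a scalar.
#' @keywords internal
ring_area_signed <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 3L) return(0)
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Drop a closing vertex and consecutive duplicates; orient counter-clockwise.
normalize_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("a ring must be an n x 2 coordinate matrix")
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) >= 2L) {
    keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 3L) return(NULL)
  if (ring_area_signed(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

ring_close <- function(m) rbind(m, m[1L, , drop = FALSE])

# O(n^2) proper-crossing test between non-adjacent edges.
ring_self_intersects <- function(m) {
  n <- nrow(m)
  if (n < 4L) return(FALSE)
  seg <- function(i) list(p = m[i, ], q = m[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 2L)) {
    si <- seg(i)
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      sj <- seg(j)
      d1 <- cross2(si$q - si$p, sj$p - si$p)
      d2 <- cross2(si$q - si$p, sj$q - si$p)
      d3 <- cross2(sj$q - sj$p, si$p - sj$p)
      d4 <- cross2(sj$q - sj$p, si$q - sj$p)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Construct a polygon geometry
#'
#' @param parts list of parts; each part is a list of rings (first outer, the
#'   rest holes); each ring an n x 2 coordinate matrix. A bare matrix or a bare
#'   list of matrices is promoted to a single part.
#' @return an object of class `nra_geom`.
#' @examples
#' g <- nra_geom(cbind(c(0, 4, 4, 0), c(0, 0, 3, 3)))
#' geom_area_planar(g)  # 12
#' @export
nra_geom <- function(parts = list()) {
  if (is.matrix(parts)) parts <- list(list(parts))
  if (length(parts) && is.matrix(parts[[1L]])) parts <- list(parts)
  parts <- lapply(parts, function(p) {
    p <- lapply(p, normalize_ring)
    p[!vapply(p, is.null, logical(1L))]
  })
  parts <- parts[lengths(parts) > 0L]
  structure(list(parts = parts), class = "nra_geom")
}

#' @export
print.nra_geom <- function(x, ...) {
  nr <- sum(lengths(x$parts))
  nv <- sum(unlist(lapply(x$parts, function(p) vapply(p, nrow, 0L))), 0L)
  cat(sprintf("<nra_geom: %d part(s), %d ring(s), %d vertices>\n",
              length(x$parts), nr, nv))
  invisible(x)
}

#' Axis-aligned rectangle geometry
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return an `nra_geom` with one rectangular part.
#' @export
geom_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  nra_geom(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

geom_is_empty <- function(g) length(g$parts) == 0L

geom_bbox <- function(g) {
  if (geom_is_empty(g)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  xy <- do.call(rbind, unlist(g$parts, recursive = FALSE))
  c(min(xy[, 1L]), min(xy[, 2L]), max(xy[, 1L]), max(xy[, 2L]))
}

# Merge several geometries into one multi-part geometry (no dissolving of
# shared boundaries; valid as a union only for non-overlapping inputs).
geom_combine <- function(geoms) {
  nra_geom(unlist(lapply(geoms, function(g) g$parts), recursive = FALSE))
}

# Planar area in squared coordinate units: sum over parts of |outer| - sum|holes|.
geom_area_planar <- function(g) {
  if (inherits(g, "nra_tris")) return(tris_area_planar(g))
  s <- 0
  for (p in g$parts) {
    a <- vapply(p, function(r) abs(ring_area_signed(r)), 0)
    s <- s + a[1L] - sum(a[-1L])
  }
  s
}

# Edge semantics: rings are bounded by segments that are straight in lon/lat
# space (the same convention the clipping engine uses). Before the ellipsoidal
# area call each edge is densified to short steps so that the measured path
# follows the lon/lat-linear edge rather than the great circle between its
# endpoints; this keeps areas additive under clipping-based subdivision.
densify_ring <- function(m, step = 0.05) {
  n <- nrow(m)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- m[i, ]
    q <- m[if (i == n) 1L else i + 1L, ]
    k <- max(1L, ceiling(max(abs(q - p)) / step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(p[1L] + t * (q[1L] - p[1L]), p[2L] + t * (q[2L] - p[2L]))
  }
  do.call(rbind, out)
}

ring_area_ellipsoid <- function(r) {
  abs(geosphere::areaPolygon(ring_close(densify_ring(r))))
}

# Ellipsoidal area in km^2 for lon/lat geometries (WGS84, via geosphere).
geom_area_geodesic <- function(g) {
  if (inherits(g, "nra_tris")) return(tris_area_geodesic(g))
  s <- 0
  for (p in g$parts) {
    a <- vapply(p, ring_area_ellipsoid, 0)
    s <- s + a[1L] - sum(a[-1L])
  }
  s / 1e6
}

# ---- triangulation ---------------------------------------------------------

point_in_tri_strict <- function(p, a, b, c, tol) {
  d1 <- cross2(b - a, p - a)
  d2 <- cross2(c - b, p - b)
  d3 <- cross2(a - c, p - c)
  d1 > tol && d2 > tol && d3 > tol
}

# Ear-clipping triangulation of a simple CCW ring. Collinear vertices are
# tolerated; self-intersecting rings abort.
triangulate_ring <- function(m) {
  n <- nrow(m)
  if (n < 3L) return(list())
  tol <- 1e-12 * (max(abs(m)) + 1)^2
  idx <- seq_len(n)
  tris <- vector("list", n - 2L)
  nt <- 0L
  while (length(idx) > 3L) {
    ni <- length(idx)
    progressed <- FALSE
    for (k in seq_len(ni)) {
      i0 <- idx[if (k == 1L) ni else k - 1L]
      i1 <- idx[k]
      i2 <- idx[if (k == ni) 1L else k + 1L]
      a <- m[i0, ]; b <- m[i1, ]; c <- m[i2, ]
      cr <- cross2(b - a, c - a)
      if (cr <= tol) next                      # reflex or degenerate corner
      blocked <- FALSE
      for (j in setdiff(idx, c(i0, i1, i2))) {
        if (point_in_tri_strict(m[j, ], a, b, c, -tol)) { blocked <- TRUE; break }
      }
      if (blocked) next
      nt <- nt + 1L
      tris[[nt]] <- rbind(a, b, c)
      idx <- idx[-k]
      progressed <- TRUE
      break
    }
    if (!progressed) {
      # only reflex/degenerate corners remain: drop a zero-area corner if any
      dropped <- FALSE
      for (k in seq_len(ni)) {
        i0 <- idx[if (k == 1L) ni else k - 1L]
        i1 <- idx[k]
        i2 <- idx[if (k == ni) 1L else k + 1L]
        cr <- cross2(m[i1, ] - m[i0, ], m[i2, ] - m[i0, ])
        if (abs(cr) <= tol) { idx <- idx[-k]; dropped <- TRUE; break }
      }
      if (!dropped) stop("triangulation failed; ring is not simple")
    }
  }
  if (length(idx) == 3L) {
    a <- m[idx[1L], ]; b <- m[idx[2L], ]; c <- m[idx[3L], ]
    if (cross2(b - a, c - a) > tol) {
      nt <- nt + 1L
      tris[[nt]] <- rbind(a, b, c)
    }
  }
  tris[seq_len(nt)]
}

# Signed convex-piece soup: rings (convex CCW matrices) + signs (+1 outer, -1 hole).
as_tris <- function(g) {
  if (inherits(g, "nra_tris")) return(g)
  rings <- list(); sign <- numeric(0)
  for (p in g$parts) {
    for (i in seq_along(p)) {
      tt <- triangulate_ring(p[[i]])
      if (length(tt)) {
        rings <- c(rings, tt)
        sign <- c(sign, rep(if (i == 1L) 1 else -1, length(tt)))
      }
    }
  }
  structure(list(rings = rings, sign = sign), class = "nra_tris")
}

tris_area_planar <- function(tr) {
  if (!length(tr$rings)) return(0)
  sum(tr$sign * vapply(tr$rings, function(r) abs(ring_area_signed(r)), 0))
}

tris_area_geodesic <- function(tr) {
  if (!length(tr$rings)) return(0)
  a <- vapply(tr$rings, ring_area_ellipsoid, 0)
  sum(tr$sign * a) / 1e6
}

# ---- convex clipping -------------------------------------------------------

# Sutherland-Hodgman: clip `subject` (convex CCW ring) against `clip` (convex
# CCW ring). Returns the clipped ring matrix (possibly with < 3 rows).
clip_convex <- function(subject, clip) {
  tol <- 1e-12 * (max(abs(subject), abs(clip)) + 1)^2
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    A <- clip[i, ]
    B <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- B[1L] - A[1L]; ey <- B[2L] - A[2L]
    side <- ex * (out[, 2L] - A[2L]) - ey * (out[, 1L] - A[1L])
    np <- nrow(out)
    res <- matrix(0, 2L * np, 2L)
    nr <- 0L
    for (k in seq_len(np)) {
      kn <- if (k == np) 1L else k + 1L
      sP <- side[k]; sQ <- side[kn]
      if (sP >= -tol) {
        nr <- nr + 1L
        res[nr, ] <- out[k, ]
      }
      if ((sP > tol && sQ < -tol) || (sP < -tol && sQ > tol)) {
        t <- sP / (sP - sQ)
        nr <- nr + 1L
        res[nr, ] <- out[k, ] + t * (out[kn, ] - out[k, ])
      }
    }
    out <- res[seq_len(nr), , drop = FALSE]
    if (nr >= 2L) {
      keep <- c(TRUE, rowSums(abs(diff(out))) > 0)
      if (all(abs(out[nr, ] - out[1L, ]) == 0)) keep[nr] <- FALSE
      out <- out[keep, , drop = FALSE]
    }
  }
  if (is.null(out) || nrow(out) < 3L) NULL else out
}

#' Geometric intersection of two polygon sets
#'
#' Computes the intersection region of two geometries as a signed soup of
#' convex pieces, suitable for area measurement in planar or geodesic mode and
#' for further intersection. Holes are handled by sign bookkeeping, so the area
#' of the result is exact for valid nested-ring inputs.
#'
#' @param a,b `nra_geom` objects (or piece soups from a previous intersection).
#' @return an object of class `nra_tris`; measure it with [polygon_area()].
#' @export
geom_intersection <- function(a, b) {
  ta <- as_tris(a); tb <- as_tris(b)
  na <- length(ta$rings); nb <- length(tb$rings)
  if (na == 0L || nb == 0L) {
    return(structure(list(rings = list(), sign = numeric(0)), class = "nra_tris"))
  }
  bba <- t(vapply(ta$rings, function(r) c(min(r[, 1L]), min(r[, 2L]), max(r[, 1L]), max(r[, 2L])), numeric(4L)))
  bbb <- t(vapply(tb$rings, function(r) c(min(r[, 1L]), min(r[, 2L]), max(r[, 1L]), max(r[, 2L])), numeric(4L)))
  rings <- list(); sign <- numeric(0)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (bba[i, 1L] >= bbb[j, 3L] || bbb[j, 1L] >= bba[i, 3L] ||
          bba[i, 2L] >= bbb[j, 4L] || bbb[j, 2L] >= bba[i, 4L]) next
      piece <- clip_convex(ta$rings[[i]], tb$rings[[j]])
      if (!is.null(piece) && abs(ring_area_signed(piece)) > 0) {
        rings[[length(rings) + 1L]] <- piece
        sign <- c(sign, ta$sign[i] * tb$sign[j])
      }
    }
  }
  structure(list(rings = rings, sign = sign), class = "nra_tris")
}

#' Random convex polygon
#'
#' Convex hull of `n` points drawn uniformly in a bounding box, using the
#' caller's RNG state. Used by the validation oracle tests.
#'
#' @param n number of points to draw (the hull has at most `n` vertices).
#' @param xmin,ymin,xmax,ymax sampling window.
#' @return an `nra_geom` with a single convex part.
#' @export
random_convex_polygon <- function(n = 12L, xmin = 0, ymin = 0, xmax = 50, ymax = 50) {
  stopifnot(n >= 3L)
  repeat {
    x <- stats::runif(n, xmin, xmax)
    y <- stats::runif(n, ymin, ymax)
    h <- grDevices::chull(x, y)
    if (length(h) >= 3L) return(nra_geom(cbind(x[h], y[h])))
  }
}
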