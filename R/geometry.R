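# Planar polygon primitives and the KarstExtent container.
#
# All geometry is done in projected kilometre space (see projection.R).
# Polygons are n x 2 matrices of vertices, counter-clockwise, not closed
# (the last vertex is not repeated). Karst blobs are convex by construction,
# which keeps buffering and overlap arithmetic exact.

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area by the shoelace formula
#' @param poly n x 2 vertex matrix.
#' @return area (square units of the coordinates).
#' @export
polygon_area <- function(poly) abs(signed_area(poly))

polygon_perimeter <- function(poly) {
  d <- poly[c(2:nrow(poly), 1), ] - poly
  sum(sqrt(rowSums(d^2)))
}

ensure_ccw <- function(poly) {
  if (signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Test points against a polygon (ray casting)
#'
#' @param px,py point coordinates (vectors).
#' @param poly n x 2 vertex matrix.
#' @return logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # boundary: points within a hair of an edge count as inside
  onb <- point_segment_dist_any(px, py, poly) < 1e-9
  inside | onb
}

# min distance from each point to the polygon boundary
point_segment_dist_any <- function(px, py, poly) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
    j <- i
  }
  dmin
}

#' Distance from points to a polygon (0 inside)
#' @inheritParams point_in_polygon
#' @return numeric distances.
#' @export
point_polygon_distance <- function(px, py, poly) {
  d <- point_segment_dist_any(px, py, poly)
  d[point_in_polygon(px, py, poly)] <- 0
  d
}

# separating-axis test for two convex polygons
polygons_overlap <- function(p, q) {
  axes <- function(poly) {
    e <- poly[c(2:nrow(poly), 1), ] - poly
    cbind(-e[, 2], e[, 1])
  }
  for (ax in list(axes(p), axes(q))) {
    for (i in seq_len(nrow(ax))) {
      a <- ax[i, ]
      pp <- p %*% a; qq <- q %*% a
      if (max(pp) < min(qq) || max(qq) < min(pp)) return(FALSE)
    }
  }
  TRUE
}

# min boundary distance between two non-overlapping convex polygons
polygon_min_distance <- function(p, q) {
  if (polygons_overlap(p, q)) return(0)
  min(point_segment_dist_any(p[, 1], p[, 2], q),
      point_segment_dist_any(q[, 1], q[, 2], p))
}

# Sutherland-Hodgman clip of convex `subject` by convex `clip` (both CCW);
# returns the intersection polygon or NULL when empty
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  j <- nc
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[j, ]; b <- clip[i, ]
    # inside = left of directed edge a->b (CCW polygon)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- NULL
    np <- nrow(inp)
    sprev <- side(inp[np, ])
    prev <- inp[np, ]
    res <- list()
    for (k in seq_len(np)) {
      cur <- inp[k, ]
      scur <- side(cur)
      if (scur >= 0) {
        if (sprev < 0) {
          t <- sprev / (sprev - scur)
          res[[length(res) + 1L]] <- prev + t * (cur - prev)
        }
        res[[length(res) + 1L]] <- cur
      } else if (sprev >= 0) {
        t <- sprev / (sprev - scur)
        res[[length(res) + 1L]] <- prev + t * (cur - prev)
      }
      prev <- cur; sprev <- scur
    }
    if (length(res) >= 3) out <- do.call(rbind, res)
    j <- i
  }
  out
}

# Buffer a convex CCW polygon by radius r: offset edges joined by
# discretized vertex arcs. The discretized boundary is used for membership
# and distance tests; areas use the exact closed form (see extent_area).
buffer_convex <- function(poly, r, arc_points = 1024L) {
  if (r == 0) return(poly)
  n <- nrow(poly)
  step <- 2 * pi / arc_points
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  out <- list()
  for (i in seq_len(n)) {
    ein <- poly[i, ] - poly[prv[i], ]
    eout <- poly[nxt[i], ] - poly[i, ]
    a1 <- atan2(-ein[1], ein[2])   # outward normal angle of incoming edge
    a2 <- atan2(-eout[1], eout[2]) # outward normal angle of outgoing edge
    while (a2 < a1) a2 <- a2 + 2 * pi
    k <- max(2L, ceiling((a2 - a1) / step) + 1L)
    ang <- seq(a1, a2, length.out = k)
    out[[i]] <- cbind(poly[i, 1] + r * cos(ang), poly[i, 2] + r * sin(ang))
  }
  do.call(rbind, out)
}

#' KarstExtent: a labelled set of polygons with area bookkeeping
#'
#' @param polygons list of n x 2 vertex matrices (convex, any orientation).
#' @param label one of "NBZ", "BZ5", "study_area", "custom".
#' @param buffer_km buffer already applied, km.
#' @param exact_areas optional per-polygon exact areas overriding the
#'   shoelace value (used to carry closed-form buffered areas past the
#'   boundary discretization).
#' @return an object of class `karst_extent` with fields `polygons`,
#'   `label`, `buffer_km`, `area_km2`.
#' @export
karst_extent <- function(polygons, label = "custom", buffer_km = 0,
                         exact_areas = NULL) {
  if (!length(polygons)) stop("extent must contain at least one polygon")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 3) stop("polygon needs >= 3 vertices")
    if (isTRUE(all.equal(p[1, ], p[nrow(p), ]))) p <- p[-nrow(p), , drop = FALSE]
    ensure_ccw(p)
  })
  ext <- structure(
    list(polygons = polygons, label = label, buffer_km = buffer_km,
         exact_areas = exact_areas, area_km2 = NA_real_),
    class = "karst_extent")
  ext$area_km2 <- extent_area(ext)
  ext
}

#' @export
print.karst_extent <- function(x, ...) {
  cat(sprintf("<karst_extent '%s': %d polygon(s), buffer %g km, area %.3f km^2>\n",
              x$label, length(x$polygons), x$buffer_km, x$area_km2))
  invisible(x)
}

extent_bbox <- function(extent) {
  xy <- do.call(rbind, extent$polygons)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

bbox_overlap <- function(p, q) {
  !(max(p[, 1]) < min(q[, 1]) || max(q[, 1]) < min(p[, 1]) ||
    max(p[, 2]) < min(q[, 2]) || max(q[, 2]) < min(p[, 2]))
}

#' Total area of an extent (union of its polygons)
#'
#' Exact (shoelace or closed-form buffered area) when polygons are pairwise
#' disjoint; pairwise inclusion-exclusion with convex clipping when only
#' isolated pairs overlap; a fine-grid union count when triple overlaps are
#' possible.
#'
#' @param extent a `karst_extent`.
#' @param grid_res resolution (km) for the grid fallback.
#' @return area in km^2.
#' @export
extent_area <- function(extent, grid_res = 0.25) {
  polys <- extent$polygons
  areas <- if (!is.null(extent$exact_areas)) extent$exact_areas
           else vapply(polys, polygon_area, 0)
  np <- length(polys)
  if (np == 1L) return(areas)
  ov <- matrix(FALSE, np, np)
  for (i in seq_len(np - 1)) for (j in (i + 1):np)
    if (bbox_overlap(polys[[i]], polys[[j]]) && polygons_overlap(polys[[i]], polys[[j]]))
      ov[i, j] <- ov[j, i] <- TRUE
  if (!any(ov)) return(sum(areas))
  # triple-overlap check: any polygon overlapping >= 2 mutually-overlapping others
  triple <- FALSE
  for (i in seq_len(np)) {
    nb <- which(ov[i, ])
    if (length(nb) >= 2)
      for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b && ov[nb[a], nb[b]]) triple <- TRUE
  }
  if (!triple) {
    inter <- 0
    for (i in seq_len(np - 1)) for (j in (i + 1):np) if (ov[i, j]) {
      cl <- clip_convex(polys[[i]], polys[[j]])
      if (!is.null(cl)) inter <- inter + polygon_area(cl)
    }
    return(sum(areas) - inter)
  }
  grid_union_area(polys, grid_res)
}

# union area by counting occupied fine-grid cells (exactness documented)
grid_union_area <- function(polys, res) {
  keys <- NULL
  for (p in polys) {
    xr <- range(p[, 1]); yr <- range(p[, 2])
    xs <- seq(floor(xr[1] / res), ceiling(xr[2] / res)) * res + res / 2
    ys <- seq(floor(yr[1] / res), ceiling(yr[2] / res)) * res + res / 2
    g <- expand.grid(x = xs, y = ys)
    inp <- point_in_polygon(g$x, g$y, p)
    keys <- c(keys, paste(round(g$x[inp] / res), round(g$y[inp] / res)))
  }
  length(unique(keys)) * res^2
}

#' Buffer a karst extent outward
#'
#' Euclidean buffer in projected space. The buffered area of each convex
#' polygon is exact (A + P*r + pi*r^2); overlapping buffered polygons are
#' handled by `extent_area()`.
#'
#' @param extent a `karst_extent`.
#' @param buffer_km non-negative buffer, km.
#' @return a `karst_extent` labelled "BZ5" when `buffer_km == 5`.
#' @export
buffer_extent <- function(extent, buffer_km) {
  if (!is.numeric(buffer_km) || length(buffer_km) != 1 || is.na(buffer_km) ||
      buffer_km < 0)
    stop("'buffer_km' must be a single non-negative number")
  if (buffer_km == 0)
    return(karst_extent(extent$polygons, extent$label, 0))
  polys <- lapply(extent$polygons, buffer_convex, r = buffer_km)
  exact <- vapply(extent$polygons, function(p)
    polygon_area(p) + polygon_perimeter(p) * buffer_km + pi * buffer_km^2, 0)
  label <- if (buffer_km == 5) "BZ5" else paste0("BZ", buffer_km)
  karst_extent(polys, label, buffer_km, exact_areas = exact)
}

#' Axis-aligned bounding box of an extent (the study area)
#' @param extent a `karst_extent`.
#' @return a `karst_extent` labelled "study_area" holding one rectangle.
#' @export
bounding_box <- function(extent) {
  if (!length(extent$polygons)) stop("empty extent")
  bb <- extent_bbox(extent)
  rect <- rbind(c(bb["xmin"], bb["ymin"]), c(bb["xmax"], bb["ymin"]),
                c(bb["xmax"], bb["ymax"]), c(bb["xmin"], bb["ymax"]))
  karst_extent(list(rect), "study_area", 0)
}

#' Membership of points in an extent
#' @param x,y projected coordinates (km).
#' @param extent a `karst_extent`.
#' @return logical vector.
#' @export
point_in_extent <- function(x, y, extent) {
  inside <- logical(length(x))
  for (p in extent$polygons) {
    cand <- which(!inside &
                    x >= min(p[, 1]) & x <= max(p[, 1]) &
                    y >= min(p[, 2]) & y <= max(p[, 2]))
    if (length(cand))
      inside[cand] <- point_in_polygon(x[cand], y[cand], p)
  }
  inside
}

#' Distance from points to the nearest polygon of an extent (0 inside)
#' @inheritParams point_in_extent
#' @return numeric distances, km.
#' @export
dist_to_extent <- function(x, y, extent) {
  d <- rep(Inf, length(x))
  for (p in extent$polygons)
    d <- pmin(d, point_polygon_distance(x, y, p))
  d
}

#' Connected components of an extent
#'
#' Two polygons belong to one component when they overlap or touch; used to
#' verify that buffering merges shapes whose gap is below twice the buffer.
#'
#' @param extent a `karst_extent`.
#' @return integer component label per polygon.
#' @export
extent_components <- function(extent) {
  polys <- extent$polygons
  np <- length(polys)
  comp <- seq_len(np)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (np > 1)
    for (i in seq_len(np - 1)) for (j in (i + 1):np)
      if (bbox_overlap(polys[[i]], polys[[j]]) &&
          polygons_overlap(polys[[i]], polys[[j]])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
  roots <- vapply(seq_len(np), find, integer(1))
  match(roots, unique(roots))
}

#' Write an extent as GeoJSON
#' @param extent a `karst_extent`.
#' @param path output file.
#' @export
write_extent_geojson <- function(extent, path) {
  feats <- lapply(seq_along(extent$polygons), function(i) {
    p <- extent$polygons[[i]]
    ring <- rbind(p, p[1, ])
    list(type = "Feature",
         properties = list(label = extent$label, id = i,
                           buffer_km = extent$buffer_km),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an extent from GeoJSON
#' @param path GeoJSON file written by [write_extent_geojson()].
#' @return a `karst_extent`.
#' @export
read_extent_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features) || !length(gj$features))
    stop("not a polygon FeatureCollection: ", path)
  polys <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    m[-nrow(m), , drop = FALSE]
  })
  label <- gj$features[[1]]$properties$label %||% "custom"
  buffer <- gj$features[[1]]$properties$buffer_km %||% 0
  karst_extent(polys, label, buffer)
}
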