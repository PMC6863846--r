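# Equal-area projection and the square-grid tessellation.
#
# Two projections are supported: a planar passthrough (synthetic landscapes
# are generated directly in kilometre space) and the spherical Albers
# equal-area conic with the standard South America parameters (central
# meridian -60, standard parallels -5 and -42, latitude of origin -32).

#' Create a projection specification
#'
#' @param type "planar" (coordinates already in km) or "albers".
#' @param lon0,lat0 central meridian and latitude of origin (degrees).
#' @param lat1,lat2 standard parallels (degrees).
#' @param R earth radius, km (authalic sphere).
#' @return an object of class `ea_projection`.
#' @export
ea_projection <- function(type = c("planar", "albers"),
                          lon0 = -60, lat0 = -32, lat1 = -5, lat2 = -42,
                          R = 6371.0072) {
  type <- match.arg(type)
  p <- list(type = type)
  if (type == "albers") {
    r1 <- lat1 * pi / 180; r2 <- lat2 * pi / 180; r0 <- lat0 * pi / 180
    n <- (sin(r1) + sin(r2)) / 2
    C <- cos(r1)^2 + 2 * n * sin(r1)
    p <- c(p, list(lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2,
                   R = R, n = n, C = C,
                   rho0 = R / n * sqrt(C - 2 * n * sin(r0))))
  }
  structure(p, class = "ea_projection")
}

#' Project lon/lat (or pass planar km through)
#'
#' @param lon,lat coordinates: degrees for "albers", km for "planar".
#' @param proj an `ea_projection`.
#' @return two-column matrix of projected km.
#' @export
project_points <- function(lon, lat, proj) {
  if (proj$type == "planar") return(cbind(x = lon, y = lat))
  lam <- (lon - proj$lon0) * pi / 180
  phi <- lat * pi / 180
  rho <- proj$R / proj$n * sqrt(proj$C - 2 * proj$n * sin(phi))
  th <- proj$n * lam
  cbind(x = rho * sin(th), y = proj$rho0 - rho * cos(th))
}

#' Inverse projection
#' @param x,y projected km.
#' @param proj an `ea_projection`.
#' @return two-column matrix (lon, lat): degrees for "albers", km for "planar".
#' @export
unproject_points <- function(x, y, proj) {
  if (proj$type == "planar") return(cbind(lon = x, lat = y))
  sn <- sign(proj$n)
  rho <- sqrt(x^2 + (proj$rho0 - y)^2)
  th <- atan2(sn * x, sn * (proj$rho0 - y))
  phi <- asin((proj$C - (rho * proj$n / proj$R)^2) / (2 * proj$n))
  lam <- th / proj$n
  cbind(lon = proj$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}

#' Define an equal-area square grid
#'
#' Cells are half-open: [x0 + i*s, x0 + (i+1)*s) x [y0 + j*s, y0 + (j+1)*s),
#' indexed by zero-based (col, row), so every finite point belongs to exactly
#' one cell and boundary points go to the higher-index cell.
#'
#' @param origin numeric length-2, projected km of the grid corner.
#' @param cell_size_km cell side, km (50 and 10 in the analysis).
#' @param projection an `ea_projection` (default planar passthrough).
#' @return an object of class `ea_grid`.
#' @export
equal_area_grid <- function(origin, cell_size_km,
                            projection = ea_projection("planar")) {
  stopifnot(length(origin) == 2, is.finite(origin),
            cell_size_km > 0)
  structure(list(origin = as.numeric(origin), cell_size_km = cell_size_km,
                 projection = projection),
            class = "ea_grid")
}

#' Grid anchored to an extent
#'
#' Origin = projected bounding-box minimum floored to the nearest cell
#' multiple, so cell indices are reproducible for a given extent.
#'
#' @param extent a `karst_extent` (already projected).
#' @param cell_size_km cell side, km.
#' @param projection projection spec carried by the grid.
#' @return an `ea_grid`.
#' @export
grid_for_extent <- function(extent, cell_size_km,
                            projection = ea_projection("planar")) {
  bb <- extent_bbox(extent)
  origin <- floor(bb[c("xmin", "ymin")] / cell_size_km) * cell_size_km
  equal_area_grid(origin, cell_size_km, projection)
}

#' Assign points to grid cells
#'
#' @param x,y coordinates in the grid's input space (km for planar,
#'   degrees for albers).
#' @param grid an `ea_grid`.
#' @param ids optional record identifiers used in error messages.
#' @return data.frame with columns `col`, `row` (zero-based) and `cell`
#'   (a "col_row" key).
#' @export
assign_cells <- function(x, y, grid, ids = NULL) {
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("non-finite coordinates for record(s): ", who)
  }
  p <- project_points(x, y, grid$projection)
  s <- grid$cell_size_km
  col <- floor((p[, 1] - grid$origin[1]) / s)
  row <- floor((p[, 2] - grid$origin[2]) / s)
  data.frame(col = as.integer(col), row = as.integer(row),
             cell = paste(as.integer(col), as.integer(row), sep = "_"),
             stringsAsFactors = FALSE)
}

#' Count occupied 10 km subcells per 50 km cell
#'
#' Approximates the sampled area of each coarse cell by the number of its
#' non-empty fine cells (0 to 25 for the 50/10 km pair). Empty coarse cells
#' are absent from the result.
#'
#' @param x,y record coordinates.
#' @param grid_coarse,grid_fine nested grids (shared origin, integer size
#'   ratio, same projection type).
#' @return data.frame with `cell` (coarse key) and `n_subcells`.
#' @export
subcell_occupancy <- function(x, y, grid_coarse, grid_fine) {
  ratio <- grid_coarse$cell_size_km / grid_fine$cell_size_km
  if (!isTRUE(all.equal(ratio, round(ratio))) ||
      !isTRUE(all.equal(grid_coarse$origin, grid_fine$origin)) ||
      grid_coarse$projection$type != grid_fine$projection$type)
    stop("grids are not nested (shared origin and integer size ratio required)")
  cc <- assign_cells(x, y, grid_coarse)
  cf <- assign_cells(x, y, grid_fine)
  key <- paste(cc$cell, cf$cell)
  occ <- tapply(cf$cell[!duplicated(key)], cc$cell[!duplicated(key)],
                length)
  data.frame(cell = names(occ), n_subcells = as.integer(occ),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize a grid definition over a set of occupied cells
#' @param grid an `ea_grid`.
#' @param cells character "col_row" keys.
#' @param path output CSV.
#' @export
write_grid_csv <- function(grid, cells, path) {
  cr <- do.call(rbind, strsplit(cells, "_"))
  col <- as.integer(cr[, 1]); row <- as.integer(cr[, 2])
  hdr <- sprintf("# projection=%s cell_size_km=%g origin=%g,%g",
                 grid$projection$type, grid$cell_size_km,
                 grid$origin[1], grid$origin[2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(
    col = col, row = row,
    minx = grid$origin[1] + col * grid$cell_size_km,
    miny = grid$origin[2] + row * grid$cell_size_km), con, row.names = FALSE)
  invisible(path)
}
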