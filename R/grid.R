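#' Regular planar grid
#'
#' Defines a regular raster grid on a local planar coordinate system in
#' kilometres. The origin is the lower-left corner of the lower-left cell;
#' cell `(ix, iy)` covers the half-open square
#' `[origin + (ix-1)*cell, origin + ix*cell)` in each dimension, so a point
#' sitting exactly on a shared edge belongs to the cell on its upper/right
#' side (and the outermost upper/right edge is clamped into the grid).
#'
#' @param origin_x,origin_y Lower-left corner coordinates (km).
#' @param cell_size Cell edge length (km).
#' @param nx,ny Number of columns / rows (each >= 2).
#' @return An object of class `pm_grid`.
#' @export
pm_grid <- function(origin_x = 0, origin_y = 0, cell_size = 1, nx = 20, ny = 20) {
  stopifnot(cell_size > 0, nx >= 2, ny >= 2)
  structure(
    list(origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, nx = as.integer(nx), ny = as.integer(ny)),
    class = "pm_grid"
  )
}

#' @export
print.pm_grid <- function(x, ...) {
  cat(sprintf("pm_grid: %d x %d cells of %g km, origin (%g, %g)\n",
              x$nx, x$ny, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell index of planar points
#'
#' Maps points to column/row indices under the half-open cell convention
#' documented in [pm_grid()]. Points outside the grid get `NA` unless
#' `clamp = TRUE`, in which case they are assigned the nearest border cell.
#'
#' @param grid A `pm_grid`.
#' @param x,y Coordinate vectors (km).
#' @param clamp Clamp out-of-grid points to the nearest border cell?
#' @return A list with integer vectors `ix`, `iy` and linear index
#'   `cell` (column-major: `ix + (iy-1)*nx`).
#' @export
grid_cell_index <- function(grid, x, y, clamp = FALSE) {
  ix <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  iy <- floor((y - grid$origin_y) / grid$cell_size) + 1L
  # points exactly on the far edge belong to the last cell
  ix[x == grid$origin_x + grid$nx * grid$cell_size] <- grid$nx
  iy[y == grid$origin_y + grid$ny * grid$cell_size] <- grid$ny
  if (clamp) {
    ix <- pmin(pmax(ix, 1L), grid$nx)
    iy <- pmin(pmax(iy, 1L), grid$ny)
  } else {
    bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
    ix[bad] <- NA_integer_
    iy[bad] <- NA_integer_
  }
  list(ix = as.integer(ix), iy = as.integer(iy),
       cell = as.integer(ix + (iy - 1L) * grid$nx))
}

#' Cell-center coordinates
#'
#' @param grid A `pm_grid`.
#' @return A data.frame with `ix`, `iy`, `x`, `y` for all cells in
#'   column-major order (ix fastest).
#' @export
grid_centers <- function(grid) {
  ix <- rep(seq_len(grid$nx), times = grid$ny)
  iy <- rep(seq_len(grid$ny), each = grid$nx)
  data.frame(
    ix = ix, iy = iy,
    x = grid$origin_x + (ix - 0.5) * grid$cell_size,
    y = grid$origin_y + (iy - 0.5) * grid$cell_size
  )
}

#' Daily concentration surface
#'
#' One day's gridded concentration field. `values` is stored as an
#' `ny x nx` matrix with row 1 = southernmost row (ascending y), matching
#' the column-major cell ordering of [grid_centers()] after transposition.
#'
#' @param grid A `pm_grid`.
#' @param values Numeric matrix (`ny` rows, `nx` cols) of concentrations
#'   (ug/m3), or a vector of length `nx*ny` in column-major cell order.
#' @param date Date of the surface.
#' @param model_tag Surface provenance: 0 = single-sourced (ordinary
#'   kriging), 1 = multi-sourced (regression-kriging), NA = truth/other.
#' @return An object of class `pm_surface`.
#' @export
pm_surface <- function(grid, values, date = NA, model_tag = NA_integer_) {
  if (is.null(dim(values))) {
    stopifnot(length(values) == grid$nx * grid$ny)
    values <- matrix(values, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  }
  stopifnot(nrow(values) == grid$ny, ncol(values) == grid$nx,
            all(is.finite(values)))
  structure(
    list(grid = grid, values = values, date = date,
         model_tag = as.integer(model_tag)),
    class = "pm_surface"
  )
}

#' @export
print.pm_surface <- function(x, ...) {
  cat(sprintf("pm_surface (%s, model %s): %d x %d cells, range [%.3f, %.3f] ug/m3\n",
              as.character(x$date), ifelse(is.na(x$model_tag), "truth", x$model_tag),
              x$grid$nx, x$grid$ny, min(x$values), max(x$values)))
  invisible(x)
}

#' Extract surface values at planar points
#'
#' Nearest-cell lookup (no interpolation): each point takes the value of the
#' cell that contains it.
#'
#' @param surface A `pm_surface`.
#' @param x,y Coordinate vectors (km).
#' @param clamp Clamp out-of-grid points to the nearest border cell?
#' @return Numeric vector of concentrations; `NA` for out-of-grid points
#'   when `clamp = FALSE`.
#' @export
surface_value_at <- function(surface, x, y, clamp = FALSE) {
  idx <- grid_cell_index(surface$grid, x, y, clamp = clamp)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$ix)
  out[ok] <- surface$values[cbind(idx$iy[ok], idx$ix[ok])]
  out
}

#' Write a surface as an ESRI ASCII grid
#'
#' @param surface A `pm_surface`.
#' @param path Output file path.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path, digits = 8) {
  g <- surface$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$nx),
    sprintf("nrows %d", g$ny),
    # header is in the grid's native km units
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y),
    sprintf("cellsize %.10g", g$cell_size),
    "NODATA_value -9999"
  ), con)
  # ESRI ASCII rows run north -> south
  for (r in seq(g$ny, 1L)) {
    writeLines(paste(signif(surface$values[r, ], digits), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid as a surface
#'
#' @param path File path.
#' @param date Date to attach.
#' @param model_tag Model tag to attach (see [pm_surface()]).
#' @return A `pm_surface`.
#' @export
read_ascii_grid <- function(path, date = NA, model_tag = NA_integer_) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == nx * ny)
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  m <- m[seq(ny, 1L), , drop = FALSE]  # back to south-up storage
  grid <- pm_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nx, ny)
  pm_surface(grid, m, date = date, model_tag = model_tag)
}

#' Spatial mean and standard deviation of a surface
#'
#' @param surface A `pm_surface`.
#' @return Named numeric vector `c(mean, sd)` over all cells.
#' @export
surface_spatial_summary <- function(surface) {
  v <- as.vector(surface$values)
  c(mean = mean(v), sd = stats::sd(v))
}
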