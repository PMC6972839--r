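#' Minimal planar raster grid
#'
#' A lightweight single-band raster: a numeric matrix plus a planar origin and
#' a square cell size. Row 1 is the northernmost row; missing cells are `NA`.
#' All layers of a landscape share one grid, so alignment checks reduce to
#' comparing these four fields.
#'
#' @param values numeric matrix (rows = north to south).
#' @param xmin,ymin planar coordinates (m) of the lower-left corner.
#' @param res cell size in metres (cells are square).
#' @return an object of class `rsf_raster`.
#' @export
rsf_raster <- function(values, xmin = 0, ymin = 0, res = 30) {
  stopifnot(is.matrix(values), res > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res),
    class = "rsf_raster"
  )
}

#' @export
print.rsf_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<rsf_raster> %d x %d cells, %g m resolution\n", nrow(v), ncol(v), x$res))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$res, x$ymin, x$ymin + nrow(v) * x$res))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%g, %g], %d NA\n", min(fin), max(fin), sum(is.na(v))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @export
dim.rsf_raster <- function(x) dim(x$values)

raster_like <- function(template, values) {
  stopifnot(identical(dim(values), dim(template$values)))
  rsf_raster(values, template$xmin, template$ymin, template$res)
}

ymax_of <- function(r) r$ymin + nrow(r$values) * r$res

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$res), c(b$xmin, b$ymin, b$res)))
}

stop_unless_aligned <- function(...) {
  rs <- list(...)
  for (i in seq_along(rs)[-1]) {
    if (!same_grid(rs[[1]], rs[[i]])) stop("rasters are not on the same grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param r an `rsf_raster`.
#' @param rows,cols optional integer vectors of cell indices; defaults to all cells
#'   in column-major order.
#' @return two-column matrix of x, y cell-center coordinates.
#' @export
cell_centers <- function(r, rows = NULL, cols = NULL) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (is.null(rows)) {
    idx <- arrayInd(seq_len(nr * nc), c(nr, nc))
    rows <- idx[, 1]; cols <- idx[, 2]
  }
  cbind(x = r$xmin + (cols - 0.5) * r$res,
        y = ymax_of(r) - (rows - 0.5) * r$res)
}

#' Map planar coordinates to cell row/column
#'
#' Points outside the extent get `NA` indices.
#'
#' @param r an `rsf_raster`.
#' @param xy two-column matrix of coordinates.
#' @return two-column integer matrix (row, col).
#' @export
cell_of <- function(r, xy) {
  xy <- as.matrix(xy)
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((xy[, 1] - r$xmin) / r$res) + 1L
  row <- floor((ymax_of(r) - xy[, 2]) / r$res) + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param r an `rsf_raster`.
#' @param xy two-column matrix of coordinates.
#' @return numeric vector; `NA` outside the extent or on nodata cells.
#' @export
extract_at <- function(r, xy) {
  rc <- cell_of(r, xy)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by rows of
#' values from north to south.
#'
#' @param r an `rsf_raster`.
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns an `rsf_raster`.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin), sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$res), sprintf("nodata_value %.10g", nodata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == val[["nrows"]], ncol(v) == val[["ncols"]])
  v[v == val[["nodata_value"]]] <- NA_real_
  rsf_raster(v, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]])
}
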