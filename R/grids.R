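#' Gridded predictor stacks
#'
#' Landscapes are represented as plain numeric matrices on an abstract
#' planar equal-area grid. Row 1 is the northern edge; cell (r, c) has its
#' center at x = (c - 0.5) * cell_size, y = (nrow - r + 0.5) * cell_size,
#' both in km. Missing data are NA. A `pred_stack` bundles co-registered
#' named layers with the cell size and an optional categorical country
#' layer (integer codes + level names) used to attach country random
#' intercepts during projection.
#'
#' @param layers named list of numeric matrices, all the same dimension
#' @param cell_size_km cell edge length in km (> 0)
#' @param country optional list(grid = integer matrix, levels = character)
#' @param crs free-text tag describing the (abstract) projection
#' @return an object of class `pred_stack`
#' @export
pred_stack <- function(layers, cell_size_km = 1,
                       country = NULL, crs = "synthetic-equal-area") {
  if (!is.list(layers) || is.null(names(layers)) || any(names(layers) == "")) {
    fail("'layers' must be a named list of matrices")
  }
  dims <- lapply(layers, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L) {
    fail("all layers must share the same dimensions")
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L ||
      !is.finite(cell_size_km) || cell_size_km <= 0) {
    fail("'cell_size_km' must be a single positive number")
  }
  if (!is.null(country)) {
    if (!identical(dim(country$grid), dims[[1]])) {
      fail("country grid dimensions do not match the layers")
    }
  }
  structure(list(layers = layers, cell_size_km = cell_size_km,
                 country = country, crs = crs),
            class = "pred_stack")
}

#' @export
dim.pred_stack <- function(x) dim(x$layers[[1]])

#' @export
print.pred_stack <- function(x, ...) {
  d <- dim(x)
  cat("pred_stack:", d[1], "x", d[2], "cells @", x$cell_size_km, "km\n")
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (!is.null(x$country)) {
    cat("countries:", length(x$country$levels), "levels\n")
  }
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param nr,nc grid dimensions
#' @param cell_size_km cell edge length (km)
#' @return list with matrices `x` and `y` of cell-center coordinates (km)
#' @export
cell_centers <- function(nr, nc, cell_size_km = 1) {
  x <- matrix(rep((seq_len(nc) - 0.5) * cell_size_km, each = nr), nr, nc)
  y <- matrix(rep((nr - seq_len(nr) + 0.5) * cell_size_km, times = nc), nr, nc)
  list(x = x, y = y)
}

#' Read a single-band Esri ASCII grid
#'
#' Plain-text raster interchange used throughout the package (nodata cells
#' become NA; the registered nodata value is restored bit-exactly on write).
#'
#' @param path file path
#' @return list(grid = numeric matrix, cell_size_km, xll, yll, nodata)
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    fail("ASCII grid header incomplete: need ", paste(need, collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) fail("ASCII grid has wrong number of values")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  list(grid = m, cell_size_km = hdr$cellsize,
       xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
       nodata = nodata)
}

#' Write a single-band Esri ASCII grid
#'
#' @param grid numeric matrix (NA = nodata)
#' @param path output path
#' @param cell_size_km cell edge length
#' @param xll,yll lower-left corner coordinates
#' @param nodata value written for NA cells
#' @export
write_ascii_grid <- function(grid, path, cell_size_km = 1,
                             xll = 0, yll = 0, nodata = -9999) {
  stopifnot(is.matrix(grid))
  g <- grid
  g[is.na(g)] <- nodata
  hdr <- c(paste("ncols", ncol(g)), paste("nrows", nrow(g)),
           paste("xllcorner", xll), paste("yllcorner", yll),
           paste("cellsize", cell_size_km), paste("NODATA_value", nodata))
  body <- apply(g, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Check that two grids are co-registered
#' @noRd
check_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b))) fail("geometry mismatch between ", what)
  invisible(TRUE)
}
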