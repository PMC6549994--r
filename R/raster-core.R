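#' @useDynLib landmarkov, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm.fit quantile runif rnorm setNames complete.cases cor
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# Raster data model
#
# Grids are plain R matrices in row-major map orientation: row 1 is the map's
# northern (top) edge, column 1 its western edge. The affine transform is the
# minimal (xllcorner, yllcorner, cellsize) triple of the ESRI ASCII grid
# header; pixel centres are used for every distance or coordinate computation.
# ---------------------------------------------------------------------------

#' Construct a categorical raster
#'
#' A categorical raster couples an integer-coded class grid with a legend, a
#' nodata sentinel and a minimal georeference (lower-left corner and square
#' pixel size, as in the ESRI ASCII grid header).
#'
#' @param values integer matrix of class codes; row 1 = top of map.
#' @param legend a legend as returned by [new_legend()]; every non-nodata
#'   code in `values` must appear in it.
#' @param nodata integer sentinel for missing cells.
#' @param xll,yll map coordinates of the grid's lower-left corner.
#' @param cellsize pixel edge length in map units (must be > 0).
#' @param crs_tag free-text identifier of the coordinate reference system.
#' @return an object of class `CategoricalRaster`.
#' @export
new_categorical_raster <- function(values, legend, nodata = -9999L,
                                   xll = 0, yll = 0, cellsize = 25,
                                   crs_tag = "local") {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("raster grid must be non-empty")
  if (cellsize <= 0) stop("cellsize must be strictly positive")
  storage.mode(values) <- "integer"
  codes <- unique(values[!is.na(values) & values != nodata])
  unknown <- setdiff(codes, legend$code)
  if (length(unknown) > 0L) {
    stop("class code(s) not in legend: ", paste(sort(unknown), collapse = ", "))
  }
  structure(
    list(values = values, legend = legend, nodata = as.integer(nodata),
         xll = xll, yll = yll, cellsize = cellsize, crs_tag = crs_tag),
    class = "CategoricalRaster")
}

#' Construct a continuous raster
#'
#' @param values numeric matrix; `NA` marks missing cells.
#' @param xll,yll,cellsize,crs_tag georeference, see [new_categorical_raster()].
#' @param units free-text unit label.
#' @return an object of class `ContinuousRaster`.
#' @export
new_continuous_raster <- function(values, xll = 0, yll = 0, cellsize = 25,
                                  crs_tag = "local", units = "") {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("raster grid must be non-empty")
  if (cellsize <= 0) stop("cellsize must be strictly positive")
  storage.mode(values) <- "double"
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         crs_tag = crs_tag, units = units),
    class = "ContinuousRaster")
}

#' Construct a class legend
#'
#' The legend's order is load-bearing: it defines the row/column order of every
#' transition matrix produced downstream.
#'
#' @param code integer class codes (unique).
#' @param name class names (unique).
#' @return an object of class `Legend`: a data.frame with columns `code`, `name`.
#' @export
new_legend <- function(code, name) {
  code <- as.integer(code)
  name <- as.character(name)
  if (anyDuplicated(code)) stop("legend codes must be unique")
  if (anyDuplicated(name)) stop("legend names must be unique")
  structure(data.frame(code = code, name = name, stringsAsFactors = FALSE),
            class = c("Legend", "data.frame"))
}

#' Read a legend from a `code,name` CSV
#' @param path CSV file with header `code,name`.
#' @return a [new_legend()] object, in file order.
#' @export
read_legend <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(df))) {
    stop("legend CSV must have columns 'code' and 'name': ", path)
  }
  new_legend(df$code, df$name)
}

#' @export
print.CategoricalRaster <- function(x, ...) {
  cat(sprintf("CategoricalRaster %d x %d, cellsize %g, %d classes, nodata %d\n",
              nrow(x$values), ncol(x$values), x$cellsize, nrow(x$legend),
              x$nodata))
  invisible(x)
}

#' @export
print.ContinuousRaster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("ContinuousRaster %d x %d, cellsize %g, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$cellsize, rng[1], rng[2]))
  invisible(x)
}

is_categorical <- function(x) inherits(x, "CategoricalRaster")

# logical matrix of valid (non-missing) cells
valid_mask <- function(r) {
  if (is_categorical(r)) !is.na(r$values) & r$values != r$nodata
  else !is.na(r$values)
}

# pixel-centre map coordinates; row 1 is the northern edge
pixel_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  x <- r$xll + (seq_len(nc) - 0.5) * r$cellsize
  y <- r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(x = x, y = y)
}

# pixel area in hectares (map units assumed metres)
cell_area_ha <- function(r) r$cellsize^2 / 1e4

#' Verify two rasters share grid, georeference and CRS
#'
#' All cross-raster operations require co-registration: equal shape, equal
#' transform (corner + cellsize) and equal `crs_tag`.
#'
#' @param a,b rasters.
#' @return invisibly `TRUE`; errors naming the differing property otherwise.
#' @export
assert_coregistered <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop(sprintf("rasters are not co-registered: shape %dx%d vs %dx%d",
                 nrow(a$values), ncol(a$values),
                 nrow(b$values), ncol(b$values)))
  }
  if (!isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                        c(b$xll, b$yll, b$cellsize), tolerance = 1e-9))) {
    stop("rasters are not co-registered: transform (xll/yll/cellsize) differs")
  }
  if (!identical(a$crs_tag, b$crs_tag)) {
    stop("rasters are not co-registered: crs_tag differs ('",
         a$crs_tag, "' vs '", b$crs_tag, "')")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O
# ---------------------------------------------------------------------------

#' Read a raster from an ESRI ASCII grid
#'
#' Supports the standard six-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`). GeoTIFF is not supported by this build; co-registered
#' ASCII grids are the exchange format.
#'
#' @param path file path.
#' @param kind `"categorical"` or `"continuous"`.
#' @param legend for categorical rasters, a [new_legend()]; if `NULL` a legend
#'   is synthesized from the codes present (`class_<code>`).
#' @param crs_tag free-text CRS identifier attached to the raster.
#' @return a `CategoricalRaster` or `ContinuousRaster`.
#' @export
read_raster <- function(path, kind = c("categorical", "continuous"),
                        legend = NULL, crs_tag = "local") {
  kind <- match.arg(kind)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF is not supported by this build; convert '", path,
         "' to an ESRI ASCII grid (.asc)")
  }
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("missing georeference header (ncols/nrows/cellsize) in: ", path)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  half <- hdr$cellsize / 2
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - half
         else stop("missing xllcorner/xllcenter in: ", path)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - half
         else stop("missing yllcorner/yllcenter in: ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d cells, found %d in: %s", nr * nc,
                 length(vals), path))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (kind == "categorical") {
    body <- m[m != nodata]
    if (any(abs(body - round(body)) > 1e-9)) {
      stop("non-integer values in categorical raster: ", path)
    }
    m <- round(m)
    if (is.null(legend)) {
      codes <- sort(unique(as.integer(m[m != nodata])))
      legend <- new_legend(codes, paste0("class_", codes))
    }
    new_categorical_raster(m, legend, nodata = as.integer(nodata),
                           xll = xll, yll = yll, cellsize = hdr$cellsize,
                           crs_tag = crs_tag)
  } else {
    m[m == nodata] <- NA_real_
    new_continuous_raster(m, xll = xll, yll = yll, cellsize = hdr$cellsize,
                          crs_tag = crs_tag)
  }
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r a `CategoricalRaster` or `ContinuousRaster`.
#' @param path output file path.
#' @param nodata sentinel written for missing cells of continuous rasters.
#' @return invisibly `path`.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  m <- r$values
  if (is_categorical(r)) {
    nodata <- r$nodata
    m[is.na(m)] <- nodata
  } else {
    m[is.na(m)] <- nodata
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(r$xll, scientific = FALSE)),
    paste("yllcorner", format(r$yll, scientific = FALSE)),
    paste("cellsize", format(r$cellsize, scientific = FALSE)),
    paste("NODATA_value", format(nodata, scientific = FALSE))), con)
  fmt <- if (is_categorical(r)) function(v) format(v, scientific = FALSE)
         else function(v) formatC(v, digits = 10, format = "g")
  for (i in seq_len(nrow(m))) writeLines(paste(fmt(m[i, ]), collapse = " "), con)
  invisible(path)
}
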