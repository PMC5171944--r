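#' Read a tower-centred elevation quadrat
#'
#' Reads a square digital-elevation grid, either an ESRI ASCII grid
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header, case
#' insensitive) or a headerless whitespace-separated matrix. The default
#' quadrat is 27 x 27 pixels of 90 m (2,430 m on a side) centred at the
#' eddy-covariance tower; other square sizes are accepted.
#'
#' @param path file path
#' @param cellsize pixel size in metres, used for headerless files
#'   (ESRI headers carry their own)
#' @return object of class `dem_quadrat`: list(elevations = matrix
#'   (row-major, north-up), cellsize)
#' @export
read_dem_quadrat <- function(path, cellsize = 90) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nodata <- NA_real_
  if (grepl("^[a-zA-Z]", first[1])) {
    hdr <- list()
    i <- 1
    while (grepl("^[a-zA-Z]", strsplit(trimws(lines[i]), "\\s+")[[1]][1])) {
      kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
      i <- i + 1
    }
    if (!is.null(hdr$cellsize)) cellsize <- hdr$cellsize
    if (!is.null(hdr$nodata_value)) nodata <- hdr$nodata_value
    body <- lines[i:length(lines)]
  } else {
    body <- lines
  }
  vals <- lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  ncol <- length(vals[[1]])
  if (any(lengths(vals) != ncol)) {
    stop("ragged elevation grid: unequal row lengths")
  }
  m <- do.call(rbind, vals)
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  dem_quadrat(m, cellsize)
}

#' Construct an elevation quadrat
#'
#' @param elevations numeric matrix of elevations in metres (row-major,
#'   north-up)
#' @param cellsize pixel size in metres
#' @return object of class `dem_quadrat`
#' @export
dem_quadrat <- function(elevations, cellsize = 90) {
  stopifnot(is.matrix(elevations), cellsize > 0)
  structure(list(elevations = elevations, cellsize = cellsize),
            class = "dem_quadrat")
}

check_quadrat <- function(q) {
  stopifnot(inherits(q, "dem_quadrat"))
  if (anyNA(q$elevations) || any(!is.finite(q$elevations))) {
    stop("elevation quadrat has missing cells (no interpolation is done)")
  }
}

#' Elevation variability of a quadrat
#'
#' The standard deviation of all pixel elevations in the quadrat,
#' population form (divisor n): the pixels are the complete quadrat, not a
#' sample from it.
#'
#' @param q a `dem_quadrat`
#' @return standard deviation in metres
#' @export
elevation_variability <- function(q) {
  check_quadrat(q)
  z <- as.vector(q$elevations)
  sqrt(mean((z - mean(z))^2))
}

#' Topographic slope of a quadrat
#'
#' The elevation drop between the highest and lowest pixels divided by the
#' planar distance between their centres, in percent:
#' 100 * (z_max - z_min) / d. Ties are broken by first occurrence in
#' row-major (north-up, west-east) order. A flat quadrat returns 0.
#'
#' @param q a `dem_quadrat`
#' @return slope in percent
#' @export
topographic_slope <- function(q) {
  check_quadrat(q)
  z <- q$elevations
  if (max(z) == min(z)) return(0)
  # row-major first occurrence: scan transpose so columns vary fastest
  zt <- t(z)
  imax <- which.max(zt); imin <- which.min(zt)
  rc <- function(i) {
    c(row = (i - 1) %/% ncol(z) + 1, col = (i - 1) %% ncol(z) + 1)
  }
  pmax <- rc(imax); pmin <- rc(imin)
  d <- sqrt(sum((pmax - pmin)^2)) * q$cellsize
  100 * (max(z) - min(z)) / d
}

#' Topographic indices for a quadrat
#'
#' @param q a `dem_quadrat`
#' @return tibble with elevation_variability (m) and topographical_slope
#'   (percent)
#' @export
topographic_indices <- function(q) {
  tibble(elevation_variability = elevation_variability(q),
         topographical_slope = topographic_slope(q))
}
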