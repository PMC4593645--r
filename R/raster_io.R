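#' Construct an environmental raster
#'
#' A regular geographic grid of one predictor. `z` has one row per latitude
#' (ascending) and one column per longitude (ascending); `NA` marks missing
#' cells (e.g. land in an oceanographic layer).
#'
#' @param name Layer name, e.g. "SST".
#' @param lon,lat Cell-centre coordinate vectors (regular spacing).
#' @param z Value matrix, `length(lat)` x `length(lon)`.
#' @param units Unit string for documentation.
#' @return An `env_raster`.
#' @export
env_raster <- function(name, lon, lat, z, units = "") {
  stopifnot(nrow(z) == length(lat), ncol(z) == length(lon))
  structure(list(name = name, lon = lon, lat = lat, z = z, units = units),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat("<env_raster>", x$name, "-", length(x$lat), "x", length(x$lon),
      "cells;", sum(is.na(x$z)), "missing\n")
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat))
}

#' Read an ESRI ASCII grid
#' @param path `.asc` file.
#' @param name Layer name (defaults to the file stem).
#' @return An `env_raster`.
#' @export
read_ascii_grid <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows; cs <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  m <- m[nr:1, , drop = FALSE]               # file is north-to-south
  lon <- hdr$xllcorner + cs * (seq_len(nc) - 0.5)
  lat <- hdr$yllcorner + cs * (seq_len(nr) - 0.5)
  env_raster(if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
             lon, lat, m)
}

#' Write an ESRI ASCII grid
#' @param raster An `env_raster`.
#' @param path Output `.asc` file.
#' @export
write_ascii_grid <- function(raster, path) {
  cs <- diff(raster$lon[1:2])
  m <- raster$z[length(raster$lat):1, , drop = FALSE]
  m[is.na(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(raster$lon[1] - cs / 2, digits = 12)),
    paste("yllcorner", format(raster$lat[1] - cs / 2, digits = 12)),
    paste("cellsize", format(cs, digits = 12)),
    "NODATA_value -9999"), con)
  write.table(format(m, trim = TRUE, digits = 10), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
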