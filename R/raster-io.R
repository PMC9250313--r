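## Single-band GeoTIFF I/O and grid alignment.
##
## The on-disk dialect is deliberately narrow: uncompressed single-band
## float32 TIFF 6.0 with ModelPixelScale/ModelTiepoint georeferencing,
## a minimal GeoKey directory, and a GDAL-style nodata tag ("nan").
## Masked cells are stored as IEEE NaN. Multi-band or compressed files are
## rejected with an explicit unsupported-format error.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

#' Read a single-band GeoTIFF
#'
#' Reads an uncompressed single-band float32 GeoTIFF into a
#' [RasterLayer-class]. Nodata cells (NaN, or the value named by the GDAL
#' nodata tag) become masked (`NA`) cells. Grid geometry is reconstructed
#' from the ModelPixelScale and ModelTiepoint tags.
#'
#' @param path file path.
#' @return A [RasterLayer-class].
#' @seealso [writeRaster()] for the inverse operation.
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else stop("not a TIFF file: ", path)
  rd <- function(off, what, n, size) readBin(raw[(off + 1):length(raw)], what,
                                             n = n, size = size,
                                             endian = endian,
                                             signed = size >= 4)
  if (rd(2, "integer", 1, 2) != 42L) stop("not a TIFF file: ", path)
  ifdOff <- rd(4, "integer", 1, 4)

  nEntries <- rd(ifdOff, "integer", 1, 2)
  tags <- list()
  for (i in seq_len(nEntries)) {
    e <- ifdOff + 2 + (i - 1) * 12
    tag <- rd(e, "integer", 1, 2)
    type <- rd(e + 2, "integer", 1, 2)
    count <- rd(e + 4, "integer", 1, 4)
    nbytes <- TIFF_TYPE_SIZES[type] * count
    valOff <- if (nbytes <= 4) e + 8 else rd(e + 8, "integer", 1, 4)
    val <- switch(as.character(type),
      "1" = as.integer(raw[(valOff + 1):(valOff + count)]),
      "2" = rawToChar(raw[(valOff + 1):(valOff + count)][
              raw[(valOff + 1):(valOff + count)] != as.raw(0)]),
      "3" = rd(valOff, "integer", count, 2),
      "4" = rd(valOff, "integer", count, 4),
      "11" = rd(valOff, "double", count, 4),
      "12" = rd(valOff, "double", count, 8),
      NULL)
    tags[[as.character(tag)]] <- val
  }
  if (rd(ifdOff + 2 + nEntries * 12, "integer", 1, 4) != 0L)
    stop("unsupported format: multi-page TIFF: ", path)

  tg <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  ncol <- tg(256); nrow <- tg(257)
  if (is.null(ncol) || is.null(nrow)) stop("missing image dimensions: ", path)
  spp <- tg(277, 1L)
  if (spp != 1L) stop("unsupported format: multi-band TIFF (", spp,
                      " samples/pixel): ", path)
  if (tg(259, 1L) != 1L) stop("unsupported format: compressed TIFF: ", path)
  bps <- tg(258, 1L)
  fmt <- tg(339, 1L)
  if (bps != 32L || fmt != 3L)
    stop("unsupported format: expected 32-bit float samples, got ",
         bps, "-bit format ", fmt, ": ", path)

  offs <- tg(273); counts <- tg(279, rep(nrow * ncol * 4, length(offs)))
  vals <- numeric(0)
  for (i in seq_along(offs))
    vals <- c(vals, rd(offs[i], "double", counts[i] / 4, 4))
  if (length(vals) != nrow * ncol) stop("truncated pixel data: ", path)

  nodata <- tg(42113)
  if (!is.null(nodata)) {
    nd <- suppressWarnings(as.numeric(nodata))
    if (is.finite(nd)) vals[vals == nd] <- NA_real_
  }
  vals[is.nan(vals)] <- NA_real_

  scale <- tg(33550); tie <- tg(33922)
  if (!is.null(scale) && !is.null(tie)) {
    res <- scale[1]
    xmin <- tie[4] - tie[1] * res
    ymax <- tie[5] + tie[2] * res
    grid <- new("GridSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
                xmin = xmin, ymin = ymax - nrow * res,
                xmax = xmin + ncol * res, ymax = ymax,
                res = res, crs = .crsFromGeoKeys(tg(34735)))
  } else {
    warning("no georeferencing tags in ", path, "; assuming a unit grid")
    grid <- gridSpec(nrow, ncol)
  }
  rasterLayer(matrix(vals, nrow, ncol, byrow = TRUE), grid)
}

.crsFromGeoKeys <- function(keys) {
  if (is.null(keys) || length(keys) < 8) return("EPSG:4326")
  nk <- keys[4]
  for (i in seq_len(nk)) {
    k <- keys[4 * i + 1:4]
    if (k[1] == 2048 || k[1] == 3072) return(paste0("EPSG:", k[4]))
  }
  "EPSG:4326"
}

#' Write a RasterLayer as a single-band GeoTIFF
#'
#' Stores values as float32 with masked cells as NaN (declared via the GDAL
#' nodata tag), plus ModelPixelScale/ModelTiepoint and a minimal GeoKey
#' directory carrying the EPSG code.
#'
#' @param layer a [RasterLayer-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(layer, path) {
  stopifnot(is(layer, "RasterLayer"))
  g <- layer@grid
  v <- as.vector(t(layer@values))    # row-major, row 1 (north) first
  v[is.na(v)] <- NaN
  dataSize <- length(v) * 4L
  dataOff <- 8L
  ifdOff <- dataOff + dataSize
  if (ifdOff %% 2L == 1L) ifdOff <- ifdOff + 1L

  epsg <- 4326L
  m <- regmatches(g@crs, regexec("EPSG:([0-9]+)", g@crs))[[1]]
  if (length(m) == 2) epsg <- as.integer(m[2])
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 2,     # geographic model
                          1025, 0, 1, 1,     # pixel-is-area
                          2048, 0, 1, epsg))
  entries <- list(
    list(256L, 4L, 1L, g@ncol),
    list(257L, 4L, 1L, g@nrow),
    list(258L, 3L, 1L, 32L),
    list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, 1L),
    list(273L, 4L, 1L, dataOff),
    list(277L, 3L, 1L, 1L),
    list(278L, 4L, 1L, g@nrow),
    list(279L, 4L, 1L, dataSize),
    list(284L, 3L, 1L, 1L),
    list(339L, 3L, 1L, 3L),
    list(33550L, 12L, 3L, c(g@res, g@res, 0)),
    list(33922L, 12L, 6L, c(0, 0, 0, g@xmin, g@ymax, 0)),
    list(34735L, 3L, length(geokeys), geokeys),
    list(42113L, 2L, 4L, "nan")
  )
  nE <- length(entries)
  extraOff <- ifdOff + 2L + nE * 12L + 4L

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write raster: ", path,
                                           " (", conditionMessage(e), ")"))
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con); w16(42L); w32(ifdOff)
  writeBin(v, con, size = 4, endian = "little")
  if (ifdOff > dataOff + dataSize) writeBin(as.raw(0), con)

  w16(nE)
  extra <- list(); cursor <- extraOff
  for (e in entries) {
    tag <- e[[1]]; type <- e[[2]]; count <- e[[3]]; val <- e[[4]]
    w16(tag); w16(type); w32(count)
    nbytes <- TIFF_TYPE_SIZES[type] * count
    if (nbytes <= 4) {
      if (type == 2L) {
        r <- c(charToRaw(val), as.raw(0))
        writeBin(c(r, rep(as.raw(0), 4 - length(r))), con)
      } else if (type == 3L) {
        w16(val); if (count == 1L) w16(0L)
      } else w32(val)
    } else {
      w32(cursor)
      extra[[length(extra) + 1]] <- e
      cursor <- cursor + nbytes
    }
  }
  w32(0L)  # no next IFD
  for (e in extra) {
    type <- e[[2]]; val <- e[[4]]
    if (type == 12L) writeBin(as.numeric(val), con, size = 8, endian = "little")
    else if (type == 3L) w16(val)
    else if (type == 2L) writeBin(c(charToRaw(val), as.raw(0)), con)
  }
  invisible(path)
}

#' Co-register rasters onto a target grid
#'
#' Brings layers at heterogeneous native resolutions onto one grid.
#' `"mean"` averages the valid source cells whose centers fall inside each
#' target cell (the default for continuous climate fields; preserves means);
#' `"nearest"` samples the source cell containing each target cell center
#' (for categorical layers). A target cell with no valid source cell is
#' masked.
#'
#' @param layers a [RasterStack-class] or list of [RasterLayer-class].
#' @param target target [GridSpec-class].
#' @param method `"mean"` (aggregate) or `"nearest"`.
#' @param labels layer labels for the output stack.
#' @return A [RasterStack-class] on `target`.
#' @export
alignStack <- function(layers, target, method = c("mean", "nearest"),
                       labels = NULL) {
  method <- match.arg(method)
  if (is(layers, "RasterStack")) {
    if (is.null(labels)) labels <- layers@labels
    layers <- layers@layers
  }
  if (is(layers, "RasterLayer")) layers <- list(layers)
  if (is.null(labels)) labels <- names(layers)
  if (is.null(labels)) labels <- paste0("layer", seq_along(layers))

  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    sg <- l@grid
    if (sg@xmin >= target@xmax || sg@xmax <= target@xmin ||
        sg@ymin >= target@ymax || sg@ymax <= target@ymin)
      stop("layer '", labels[i], "' does not overlap the target extent")
    if (method == "mean") {
      cc <- cellCenters(sg)
      idx <- cellFromXY(target, cc$lon, cc$lat)
      vals <- cellValues(l)
      ok <- !is.na(idx) & !is.na(vals)
      sums <- rep(NA_real_, target@nrow * target@ncol)
      if (any(ok)) {
        agg <- rowsum(vals[ok], idx[ok])
        cnt <- rowsum(rep(1, sum(ok)), idx[ok])
        sums[as.integer(rownames(agg))] <- agg / cnt
      }
      out[[i]] <- layerFromVec(sums, target)
    } else {
      cc <- cellCenters(target)
      idx <- cellFromXY(sg, cc$lon, cc$lat)
      vals <- cellValues(l)
      v <- rep(NA_real_, length(idx))
      v[!is.na(idx)] <- vals[idx[!is.na(idx)]]
      out[[i]] <- layerFromVec(v, target)
    }
  }
  new("RasterStack", grid = target, layers = out, labels = as.character(labels))
}
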