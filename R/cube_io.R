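#' Wavelength grid
#'
#' A wavelength grid is the band-center axis of a hyperspectral cube:
#' a strictly increasing vector of band centers in nanometres.
#'
#' @param centers Numeric vector of band centers in nm, strictly increasing.
#' @return An object of class `wavelength_grid` (a numeric vector of
#'   centers with a `count` attribute available via `length()`).
#' @export
wavelength_grid <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) < 1L || anyNA(centers)) {
    stop("invalid grid: need at least one finite band center")
  }
  if (length(centers) > 1L && any(diff(centers) <= 0)) {
    stop("invalid grid: band centers must be strictly increasing")
  }
  structure(centers, class = "wavelength_grid")
}

#' Build a uniform, endpoint-inclusive wavelength grid
#'
#' The instrument convention used throughout this package is a uniform grid
#' that includes both endpoints, e.g. 128 bands over 400--1000 nm gives a
#' spacing of 600/127 (about 4.72 nm).
#'
#' @param start_nm First band center in nm.
#' @param stop_nm Last band center in nm; must exceed `start_nm`.
#' @param n Number of bands, at least 2.
#' @return A [wavelength_grid()].
#' @examples
#' g <- make_wavelength_grid(400, 1000, 128)
#' diff(g)[1]  # ~4.724 nm
#' @export
make_wavelength_grid <- function(start_nm, stop_nm, n) {
  if (length(n) != 1L || is.na(n) || n < 2L || n != round(n)) {
    stop("invalid grid: n must be an integer >= 2")
  }
  if (!(stop_nm > start_nm)) {
    stop("invalid grid: stop_nm must exceed start_nm")
  }
  wavelength_grid(seq(start_nm, stop_nm, length.out = n))
}

#' Hyperspectral cube
#'
#' A rows x cols x bands intensity raster (raw counts or calibrated
#' reflectance) bound to a [wavelength_grid()] plus free-form provenance
#' metadata.
#'
#' @param data Numeric 3-D array, rows x cols x bands.
#' @param grid A [wavelength_grid()] whose length equals `dim(data)[3]`.
#' @param meta Named list of provenance key/value pairs (serialized into the
#'   ENVI header on write).
#' @return An object of class `hs_cube` with fields `data`, `grid`, `meta`.
#' @export
hs_cube <- function(data, grid, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("cube data must be a 3-D array (rows x cols x bands)")
  }
  grid <- if (inherits(grid, "wavelength_grid")) grid else wavelength_grid(grid)
  if (dim(data)[3] != length(grid)) {
    stop(sprintf("band dimension (%d) does not match grid length (%d)",
                 dim(data)[3], length(grid)))
  }
  if (dim(data)[1] < 1L || dim(data)[2] < 1L) stop("cube must have spatial extent")
  structure(list(data = data, grid = grid, meta = meta), class = "hs_cube")
}

#' @export
print.hs_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hs_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$grid), max(x$grid)))
  invisible(x)
}

#' Label mask
#'
#' Per-pixel class raster with the fixed code set 0 = clean, 1 =
#' contaminated, 255 = unlabeled. Used both for ground truth and for
#' classification maps.
#'
#' @param labels Integer matrix with values in \{0, 1, 255\}.
#' @return An object of class `label_mask` (an integer matrix).
#' @export
label_mask <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  bad <- !(labels %in% c(0L, 1L, 255L))
  if (any(bad)) {
    stop(sprintf("mask format error: %d pixel(s) outside the code set {0, 1, 255}",
                 sum(bad)))
  }
  structure(labels, class = "label_mask")
}

MASK_CLEAN <- 0L
MASK_CONTAMINATED <- 1L
MASK_UNLABELED <- 255L

# ---- ENVI format ------------------------------------------------------------

# Supported subset: little-endian, data type 4 (float32) / 12 (uint16),
# interleave bsq/bil/bip on read, bsq on write.
.envi_data_types <- c("4" = "float32", "5" = "float64", "12" = "uint16")

.envi_binary_path <- function(header_path) {
  stem <- sub("\\.hdr$", "", header_path)
  for (ext in c("", ".img", ".raw", ".dat")) {
    cand <- paste0(stem, ext)
    if (cand != header_path && file.exists(cand)) return(cand)
  }
  stop(sprintf("ENVI format error: no binary companion found for '%s'", header_path))
}

.parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0L || toupper(trimws(lines[1])) != "ENVI") {
    stop("ENVI format error: header does not start with 'ENVI'")
  }
  fields <- list()
  i <- 2L
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("=", line, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*$", "", line)))
      val <- trimws(sub("^[^=]*=", "", line))
      # brace-delimited values may span multiple lines
      while (grepl("\\{", val) && !grepl("\\}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      fields[[key]] <- val
    }
    i <- i + 1L
  }
  fields
}

.envi_list_field <- function(val) {
  val <- gsub("[{}\n]", " ", val)
  parts <- trimws(strsplit(val, ",")[[1]])
  parts[nzchar(parts)]
}

#' Read an ENVI hyperspectral cube
#'
#' Reads the text header and raw binary raster of an ENVI-format cube.
#' Supports little-endian float32 (data type 4) and uint16 (data type 12)
#' rasters in BSQ, BIL or BIP interleave. Wavelengths are taken from the
#' header's `wavelength` list; `meta_*` header keys are restored into the
#' cube's `meta` field.
#'
#' @param header_path Path to the `.hdr` header file; the binary companion
#'   is located by stripping the extension (optionally `.img`/`.raw`/`.dat`).
#' @return An [hs_cube()].
#' @seealso [write_envi_cube()]
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path)) {
    stop(sprintf("ENVI format error: header '%s' not found", header_path))
  }
  h <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(need, names(h))
  if (length(missing)) {
    stop(sprintf("ENVI format error: header missing field(s): %s",
                 paste(missing, collapse = ", ")))
  }
  cols <- as.integer(h[["samples"]])
  rows <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  dtype <- trimws(h[["data type"]])
  interleave <- tolower(trimws(h[["interleave"]]))
  byte_order <- if (!is.null(h[["byte order"]])) as.integer(h[["byte order"]]) else 0L
  if (byte_order != 0L) stop("ENVI format error: only little-endian (byte order 0) supported")
  if (!dtype %in% names(.envi_data_types)) {
    stop(sprintf("ENVI format error: unsupported data type %s", dtype))
  }
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop(sprintf("ENVI format error: unknown interleave '%s'", interleave))
  }
  wl <- NULL
  if (!is.null(h[["wavelength"]])) {
    wl <- as.numeric(.envi_list_field(h[["wavelength"]]))
    if (length(wl) != bands) {
      stop(sprintf("ENVI format error: %d bands declared but %d wavelengths listed",
                   bands, length(wl)))
    }
  } else {
    stop("ENVI format error: header lacks a wavelength list")
  }
  bin <- .envi_binary_path(header_path)
  n <- rows * cols * bands
  con <- file(bin, "rb")
  on.exit(close(con))
  values <- switch(.envi_data_types[[dtype]],
    float32 = readBin(con, what = "numeric", n = n, size = 4L, endian = "little"),
    float64 = readBin(con, what = "numeric", n = n, size = 8L, endian = "little"),
    uint16 = readBin(con, what = "integer", n = n, size = 2L, signed = FALSE,
                     endian = "little"))
  if (length(values) != n) {
    stop("ENVI format error: binary raster shorter than declared dimensions")
  }
  data <- switch(interleave,
    bsq = aperm(array(values, dim = c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(values, dim = c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(values, dim = c(bands, cols, rows)), c(3, 2, 1))
  )
  meta <- list()
  meta_keys <- grep("^meta_", names(h), value = TRUE)
  for (k in meta_keys) {
    meta[[sub("^meta_", "", k)]] <- trimws(gsub("[{}]", "", h[[k]]))
  }
  hs_cube(data, wavelength_grid(wl), meta = meta)
}

#' Write an ENVI hyperspectral cube
#'
#' Writes a text header (`<path>.hdr` unless `path` already ends in `.hdr`)
#' and a BSQ little-endian binary raster. With `data_type = "auto"`,
#' integer-valued data within \[0, 65535\] is stored as uint16 (data type
#' 12) and anything else as float64 (data type 5), so round-trips through
#' [read_envi_cube()] are bit-exact; `"float32"` (data type 4) is available
#' for compact storage.
#'
#' @param cube An [hs_cube()].
#' @param path Output path; the header gets extension `.hdr`, the raster
#'   `.img`.
#' @param data_type `"auto"`, `"float64"`, `"float32"` or `"uint16"`.
#' @return The header path, invisibly.
#' @export
write_envi_cube <- function(cube, path,
                            data_type = c("auto", "float64", "float32", "uint16")) {
  stopifnot(inherits(cube, "hs_cube"))
  data_type <- match.arg(data_type)
  stem <- sub("\\.hdr$", "", path)
  header_path <- paste0(stem, ".hdr")
  bin_path <- paste0(stem, ".img")
  d <- dim(cube$data)
  vals <- as.vector(aperm(cube$data, c(2, 1, 3)))  # BSQ: sample, line, band
  if (data_type == "auto") {
    is_int <- all(vals == round(vals)) && all(vals >= 0) && all(vals <= 65535)
    data_type <- if (is_int) "uint16" else "float64"
  }
  dtype_code <- switch(data_type, float32 = 4L, float64 = 5L, uint16 = 12L)
  header <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype_code),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(format(as.numeric(cube$grid), digits = 15, trim = TRUE),
                  collapse = ", "))
  )
  if (length(cube$meta)) {
    for (k in names(cube$meta)) {
      header <- c(header, sprintf("meta_%s = { %s }", k, as.character(cube$meta[[k]])))
    }
  }
  con <- file(header_path, "wb")
  writeLines(header, con)
  close(con)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  if (data_type == "float32") {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  } else if (data_type == "float64") {
    writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  } else {
    v <- as.integer(round(vals))
    # writeBin has no unsigned 16-bit mode; map [32768, 65535] to negative
    # two's-complement halves so the little-endian byte image is correct
    v <- ifelse(v > 32767L, v - 65536L, v)
    writeBin(v, con, size = 2L, endian = "little")
  }
  invisible(header_path)
}

#' Read a label mask from an 8-bit grayscale PNG
#'
#' @param path PNG path. The raster must be single-channel 8-bit with pixel
#'   values restricted to \{0, 1, 255\}.
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) stop("mask format error: expected single-channel PNG")
    img <- img[, , 1]
  }
  label_mask(matrix(as.integer(round(img * 255)), nrow = nrow(img)))
}

#' Write a label mask to an 8-bit grayscale PNG
#'
#' @param mask A [label_mask()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- label_mask(unclass(mask))
  png::writePNG(matrix(as.numeric(mask) / 255, nrow = nrow(mask)), path)
  invisible(path)
}

#' Export pixel spectra to CSV
#'
#' One row per pixel, columns named by band center; optional `row`/`col`
#' coordinates prepended.
#'
#' @param m A [spectrum_matrix()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_spectra_csv <- function(m, path) {
  df <- as.data.frame(m$values)
  names(df) <- sprintf("%.4f", as.numeric(m$grid))
  if (!is.null(m$labels)) df <- cbind(label = m$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
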