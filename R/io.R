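#' @include AllClasses.R
NULL

#' Pixel / physical coordinate conversion
#'
#' The package-wide convention: physical positions are in nm, pixel indices
#' are 1-based in R, and a pixel's physical position is its centre, i.e.
#' `nm = (index - 0.5) * pixelSize`. This avoids the half-pixel bias that a
#' corner convention would introduce into registration.
#'
#' @param index 1-based pixel index (may be fractional).
#' @param nm physical coordinate in nm.
#' @param pixelSize pixel size in nm.
#' @return the converted coordinate(s).
#' @export
pxToNm <- function(index, pixelSize) (index - 0.5) * pixelSize

#' @rdname pxToNm
#' @export
nmToPx <- function(nm, pixelSize) nm / pixelSize + 0.5

.default_dialect <- function() {
  list(x = "x", y = "y", z = "z", frame = "frame",
       I_cam1 = "I_cam1", I_cam2 = "I_cam2", ratio = "ratio", fluor = "fluor")
}

#' Construct a localisation table
#'
#' @param x,y,z coordinates in nm (z defaults to 0).
#' @param frame 0-based acquisition frame index.
#' @param I_cam1,I_cam2 per-camera photon counts (NA when unavailable).
#' @param ratio photon ratio (NA when undefined; see [computePhotonRatio()]).
#' @param fluor fluorophore labels (unassigned/fluorA/fluorB/rejected).
#' @return a [LocalizationTable-class].
#' @export
localizationTable <- function(x = numeric(), y = numeric(),
                              z = rep(0, length(x)),
                              frame = rep(0L, length(x)),
                              I_cam1 = rep(NA_real_, length(x)),
                              I_cam2 = rep(NA_real_, length(x)),
                              ratio = rep(NA_real_, length(x)),
                              fluor = rep("unassigned", length(x))) {
  rec <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                    frame = as.numeric(frame),
                    I_cam1 = as.numeric(I_cam1), I_cam2 = as.numeric(I_cam2),
                    ratio = as.numeric(ratio),
                    fluor = factor(as.character(fluor), levels = .FLUOR_LEVELS))
  new("LocalizationTable", records = rec)
}

.parse_numeric_column <- function(values, name) {
  was_na <- is.na(values) | values == ""
  num <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(num) & !was_na)
  if (length(bad)) {
    stop(sprintf("parse error in column '%s': non-numeric value '%s' at row %d",
                 name, values[bad[1]], bad[1]))
  }
  num
}

#' Read a localisation table from CSV
#'
#' Vendor CSV dialects vary; a user-supplied column-name map is used instead
#' of sniffing so that parsing is deterministic. Columns x, y and frame are
#' mandatory; z defaults to 0 and absent camera intensities leave the photon
#' ratio undefined and the fluorophore unassigned (and downstream demixing
#' raises a clear error rather than silently defaulting). Row order is
#' preserved.
#'
#' @param path CSV file with a header row.
#' @param dialect named list mapping canonical names (x, y, z, frame, I_cam1,
#'   I_cam2, ratio, fluor) to the file's column names; omitted entries use the
#'   canonical names themselves.
#' @return a [LocalizationTable-class] with coordinates in nm.
#' @export
readLocalizations <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("localisation file not found: ", path)
  dia <- utils::modifyList(.default_dialect(), dialect)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  for (col in c("x", "y", "frame")) {
    if (!dia[[col]] %in% names(raw)) {
      stop(sprintf("format error: mandatory column '%s' (mapped to '%s') not found",
                   col, dia[[col]]))
    }
  }
  n <- nrow(raw)
  get_num <- function(col, default) {
    if (dia[[col]] %in% names(raw)) {
      .parse_numeric_column(raw[[dia[[col]]]], dia[[col]])
    } else {
      rep(default, n)
    }
  }
  fluor <- if (dia$fluor %in% names(raw)) {
    vals <- raw[[dia$fluor]]
    bad <- setdiff(unique(vals), .FLUOR_LEVELS)
    if (length(bad)) {
      stop("format error: unknown fluorophore label(s): ",
           paste(bad, collapse = ", "))
    }
    vals
  } else {
    rep("unassigned", n)
  }
  localizationTable(
    x = .parse_numeric_column(raw[[dia$x]], dia$x),
    y = .parse_numeric_column(raw[[dia$y]], dia$y),
    z = get_num("z", 0),
    frame = get_num("frame", 0),
    I_cam1 = get_num("I_cam1", NA_real_),
    I_cam2 = get_num("I_cam2", NA_real_),
    ratio = get_num("ratio", NA_real_),
    fluor = fluor)
}

#' Write a localisation table to CSV
#'
#' Numeric values are written with 17 significant digits so that a read /
#' write round trip reproduces the table bit-exactly.
#'
#' @param table a [LocalizationTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLocalizations <- function(table, path) {
  stopifnot(is(table, "LocalizationTable"))
  rec <- records(table)
  out <- data.frame(lapply(rec, function(col) {
    if (is.numeric(col)) {
      ifelse(is.na(col), "NA", sprintf("%.17g", col))
    } else {
      as.character(col)
    }
  }), check.names = FALSE)
  if (!nrow(out)) {
    out <- data.frame(matrix(character(), 0, ncol(rec),
                             dimnames = list(NULL, names(rec))))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing localisations: ", conditionMessage(ok))
  invisible(path)
}

# ---------------------------------------------------------------------------
# TIFF
# ---------------------------------------------------------------------------

# Minimal uncompressed little-endian TIFF writer (32-bit IEEE float,
# greyscale, multipage). Full-range float storage is required for intensity
# round trips; an ImageDescription tag records the pixel size.
.write_tiff_float <- function(pages, path, pixelSize = NA_real_) {
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("I/O error: cannot open '", path, "' for writing")
  })
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  has_desc <- !is.na(pixelSize)
  desc_raw <- raw()
  desc_count <- 0L
  if (has_desc) {
    desc <- sprintf("pixel_size_nm=%.10g", pixelSize)
    desc_raw <- c(charToRaw(desc), as.raw(0L))
    desc_count <- length(desc_raw)        # ASCII count includes the NUL
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  writeChar("II", con, eos = NULL)
  w(42L, 2)
  offset <- 8L                      # running file offset after the header
  w(offset + 0L, 4)                 # placeholder, patched below per page
  # We lay out each page as [pixel data][description][IFD]; the first IFD
  # offset is known once page 1's data size is known, so compute up front.
  n_entries <- if (has_desc) 10L else 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  page_offsets <- integer(length(pages))
  data_offsets <- integer(length(pages))
  pos <- 8L
  for (p in seq_along(pages)) {
    nbytes <- length(pages[[p]]) * 4L
    data_offsets[p] <- pos
    page_offsets[p] <- pos + nbytes + length(desc_raw)
    pos <- page_offsets[p] + ifd_size
  }
  seek(con, 4L)
  w(page_offsets[1], 4)
  seek(con, 8L)
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    w(as.numeric(t(m)), 4)          # row-major pixel data as float32
    if (has_desc) writeBin(desc_raw, con)
    entry <- function(tag, type, count, value) {
      w(as.integer(tag), 2); w(as.integer(type), 2); w(as.integer(count), 4)
      if (type == 3L && count == 1L) { w(as.integer(value), 2); w(0L, 2) }
      else w(as.integer(value), 4)
    }
    w(n_entries, 2)
    entry(256L, 3L, 1L, ncol(m))                       # ImageWidth
    entry(257L, 3L, 1L, nrow(m))                       # ImageLength
    entry(258L, 3L, 1L, 32L)                           # BitsPerSample
    entry(259L, 3L, 1L, 1L)                            # no compression
    entry(262L, 3L, 1L, 1L)                            # black is zero
    if (has_desc) {
      entry(270L, 2L, desc_count,
            data_offsets[p] + length(m) * 4L)          # ImageDescription
    }
    entry(273L, 4L, 1L, data_offsets[p])               # StripOffsets
    entry(278L, 3L, 1L, nrow(m))                       # RowsPerStrip
    entry(279L, 4L, 1L, length(m) * 4L)                # StripByteCounts
    entry(339L, 3L, 1L, 3L)                            # SampleFormat: IEEE float
    w(if (p < length(pages)) page_offsets[p + 1] else 0L, 4)
  }
  invisible(path)
}

#' Write a 2D intensity image as TIFF
#'
#' Stores the image as full-range 32-bit float greyscale TIFF with the pixel
#' size recorded in the ImageDescription tag (`pixel_size_nm=...`).
#'
#' @param image 2D numeric matrix.
#' @param path output TIFF path.
#' @param pixelSize pixel size in nm, recorded in the file metadata.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path, pixelSize = NA_real_) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("contract error: 'image' must be a 2D numeric matrix")
  }
  .write_tiff_float(list(image), path, pixelSize)
}

#' Write a fluorescence movie as a multi-page TIFF
#'
#' @param movie a [FluorescenceMovie-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(movie, path) {
  stopifnot(is(movie, "FluorescenceMovie"))
  d <- dim(movie@data)
  pages <- lapply(seq_len(d[3]), function(f) movie@data[, , f])
  .write_tiff_float(pages, path, movie@pixelSize)
}

#' Read a 2D TIFF image
#'
#' @param path TIFF file with a single page.
#' @return numeric matrix with attributes `pixelSize` (nm, NA when the file
#'   does not record one) carried from the ImageDescription tag.
#' @export
readImage <- function(path) {
  pages <- .read_tiff_pages(path)
  img <- pages$pages[[1]]
  attr(img, "pixelSize") <- pages$pixelSize
  img
}

.read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  # as.is keeps raw integer values for integer TIFFs; float TIFFs (our own
  # writer's output) are already stored at full range and reject as.is
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("format error: TIFF pages have inconsistent shapes: ",
         paste(unique(shapes), collapse = ", "))
  }
  desc <- attr(pages[[1]], "description")
  px <- NA_real_
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("pixel_size_nm=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2L) px <- as.numeric(m[2])
  }
  pages <- lapply(pages, function(p) {
    storage.mode(p) <- "double"
    attributes(p) <- list(dim = dim(p))
    p
  })
  list(pages = pages, pixelSize = px)
}

#' Read a multi-page TIFF as a fluorescence movie
#'
#' Pages become frames; acquisition metadata (pixel size, frame rate,
#' stimulus frame) is attached from the configuration, as TIFF exports of
#' live acquisitions rarely carry it reliably.
#'
#' @param path multi-page TIFF of constant frame shape.
#' @param channel "G" or "R".
#' @param config a [PipelineConfig-class] supplying the metadata.
#' @return a [FluorescenceMovie-class]. A single-page file yields a 1-frame
#'   movie (usable for rendering, not as a time series).
#' @export
readImageStack <- function(path, channel = "G", config = pipelineConfig()) {
  pg <- .read_tiff_pages(path)
  d <- dim(pg$pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(pg$pages)))
  for (f in seq_along(pg$pages)) arr[, , f] <- pg$pages[[f]]
  new("FluorescenceMovie", data = arr, channel = channel,
      pixelSize = config@livePixelSize, frameRate = config@liveFrameRate,
      stimFrame = config@stimFrame)
}
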