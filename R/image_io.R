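# Image and mask carriers.
#
# Clinical mammograms travel as DICOM; synthetic data as 16-bit PNG (or
# TIFF); masks as 8-bit PNG or NRRD as exported by 3D Slicer. None of the
# guaranteed runtime packages read these formats, so small self-contained
# codecs live here: grayscale-only, single-frame, uncompressed (NRRD also
# accepts gzip). Every codec is round-trip tested and the PNG writer has
# been verified against an independent reader.

le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

rd_u16 <- function(r, pos, n = 1) {
  readBin(r[pos:(pos + 2 * n - 1)], "integer", n = n, size = 2,
          endian = "little", signed = FALSE)
}
rd_u32 <- function(r, pos, n = 1) {
  v <- readBin(r[pos:(pos + 4 * n - 1)], "integer", n = n, size = 4,
               endian = "little")
  ifelse(v < 0, v + 2^32, v)
}

# --- PNG (via the C++ codec) ------------------------------------------------

#' Write a grayscale PNG
#'
#' @param image integer matrix (rows x cols) of pixel values in
#'   `[0, 2^bit_depth - 1]`.
#' @param path output file.
#' @param bit_depth 8 or 16.
#' @export
write_png <- function(image, path, bit_depth = 16) {
  storage.mode(image) <- "integer"
  cpp_png_write(path, image, as.integer(bit_depth))
  invisible(path)
}

#' Read a grayscale PNG
#'
#' @param path file path.
#' @return list with `image` (integer matrix) and `bit_depth`.
#' @export
read_png <- function(path) cpp_png_read(path)

# --- TIFF (uncompressed grayscale, single strip) ----------------------------

#' Write an uncompressed grayscale TIFF
#'
#' @inheritParams write_png
#' @export
write_tiff <- function(image, path, bit_depth = 16) {
  h <- nrow(image); w <- ncol(image)
  bytes <- bit_depth / 8
  px <- as.integer(t(image))                     # row-major strip
  data <- writeBin(px, raw(), size = bytes, endian = "little")
  entry <- function(tag, type, count, value) {
    c(le16(tag), le16(type), le32(count),
      if (type == 3) c(le16(value), le16(0)) else le32(value))
  }
  entries <- list(
    entry(256, 4, 1, w),                         # ImageWidth
    entry(257, 4, 1, h),                         # ImageLength
    entry(258, 3, 1, bit_depth),                 # BitsPerSample
    entry(259, 3, 1, 1),                         # Compression: none
    entry(262, 3, 1, 1),                         # Photometric: BlackIsZero
    entry(273, 4, 1, 8),                         # StripOffsets
    entry(277, 3, 1, 1),                         # SamplesPerPixel
    entry(278, 4, 1, h),                         # RowsPerStrip
    entry(279, 4, 1, length(data))               # StripByteCounts
  )
  ifd_offset <- 8 + length(data)
  out <- c(charToRaw("II"), le16(42), le32(ifd_offset), data,
           le16(length(entries)), do.call(c, entries), le32(0))
  writeBin(out, path)
  invisible(path)
}

#' Read an uncompressed grayscale TIFF
#'
#' @param path file path.
#' @return list with `image` (integer matrix) and `bit_depth`.
#' @export
read_tiff <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (rawToChar(r[1:2]) != "II") stop("only little-endian TIFF supported")
  ifd <- rd_u32(r, 5) + 1
  n <- rd_u16(r, ifd)
  tags <- list()
  for (i in seq_len(n)) {
    at <- ifd + 2 + (i - 1) * 12
    tag <- rd_u16(r, at); type <- rd_u16(r, at + 2)
    val <- if (type == 3) rd_u16(r, at + 8) else rd_u32(r, at + 8)
    tags[[as.character(tag)]] <- val
  }
  need <- function(t, default = NULL) {
    v <- tags[[as.character(t)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", t)
      default
    } else v
  }
  if (need(259, 1) != 1) stop("compressed TIFF not supported")
  w <- need(256); h <- need(257); depth <- need(258, 8)
  if (!depth %in% c(8, 16)) stop("only 8/16-bit TIFF supported")
  off <- need(273)
  bytes <- depth / 8
  px <- readBin(r[(off + 1):(off + h * w * bytes)], "integer", n = h * w,
                size = bytes, endian = "little", signed = FALSE)
  list(image = matrix(px, h, w, byrow = TRUE), bit_depth = depth)
}

# --- DICOM (single-frame, Explicit VR Little Endian) ------------------------

#' Construct a vendor lookup table
#'
#' A VOI LUT is a monotone non-decreasing map from stored pixel values to
#' presentation values; non-monotone tables are rejected at load, never at
#' application time.
#'
#' @param first_mapped stored value mapped by the first table entry; smaller
#'   inputs clamp to the first entry, larger to the last.
#' @param table numeric vector of output values, monotone non-decreasing.
#' @return an object of class `dcis_lut`.
#' @export
new_lut <- function(first_mapped, table) {
  if (any(diff(table) < 0)) {
    stop("LUT table must be monotone non-decreasing", call. = FALSE)
  }
  structure(list(first_mapped = as.integer(first_mapped),
                 table = as.numeric(table)), class = "dcis_lut")
}

#' Apply a lookup table to an image
#'
#' @param image numeric matrix of stored values.
#' @param lut a [new_lut()] object.
#' @return numeric matrix of mapped values.
#' @export
apply_lut <- function(image, lut) {
  idx <- clamp(round(image) - lut$first_mapped + 1, 1, length(lut$table))
  out <- lut$table[idx]
  dim(out) <- dim(image)
  out
}

# UI values pad with NUL, text values with space, to even length
dcm_str <- function(s, pad = c("text", "ui")) {
  pad <- match.arg(pad)
  v <- charToRaw(s)
  if (length(v) %% 2) v <- c(v, if (pad == "ui") as.raw(0) else charToRaw(" "))
  v
}

dcm_elem <- function(group, elem, vr, value) {
  tag <- c(le16(group), le16(elem))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(tag, charToRaw(vr), raw(2), le32(length(value)), value)
  } else {
    c(tag, charToRaw(vr), le16(length(value)), value)
  }
}

#' Write a minimal single-frame grayscale DICOM file
#'
#' Explicit VR Little Endian, MONOCHROME1 or MONOCHROME2, 16 bits
#' allocated, with an optional VOI LUT sequence. Intended for synthetic
#' data and round-trip testing, not for PACS interoperability.
#'
#' @param image integer matrix of stored pixel values (row/col layout).
#' @param path output file.
#' @param photometric `"MONOCHROME2"` (higher value = brighter, default) or
#'   `"MONOCHROME1"`.
#' @param bits_stored number of significant bits (<= 16).
#' @param lut_family optional list of [new_lut()] objects written as a VOI
#'   LUT sequence.
#' @export
write_dicom <- function(image, path, photometric = "MONOCHROME2",
                        bits_stored = 16, lut_family = NULL) {
  h <- nrow(image); w <- ncol(image)
  px <- as.integer(t(image))                     # DICOM pixel data is row-major
  if (any(px < 0 | px > 2^bits_stored - 1)) {
    stop("pixel values out of range for bits_stored")
  }
  us <- function(x) le16(x)

  body <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.7", "ui")),
    dcm_elem(0x0008, 0x0018, "UI", dcm_str("1.2.826.0.1.3680043.9.7433.1", "ui")),
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("MG")),
    dcm_elem(0x0028, 0x0002, "US", us(1)),
    dcm_elem(0x0028, 0x0004, "CS", dcm_str(photometric)),
    dcm_elem(0x0028, 0x0010, "US", us(h)),
    dcm_elem(0x0028, 0x0011, "US", us(w)),
    dcm_elem(0x0028, 0x0100, "US", us(16)),
    dcm_elem(0x0028, 0x0101, "US", us(bits_stored)),
    dcm_elem(0x0028, 0x0102, "US", us(bits_stored - 1)),
    dcm_elem(0x0028, 0x0103, "US", us(0))
  )
  if (length(lut_family)) {
    items <- lapply(lut_family, function(l) {
      content <- c(
        dcm_elem(0x0028, 0x3002, "US",
                 le16(c(length(l$table), l$first_mapped, 16))),
        dcm_elem(0x0028, 0x3006, "US", le16(round(l$table)))
      )
      c(le16(0xFFFE), le16(0xE000), le32(length(content)), content)
    })
    body <- c(body, dcm_elem(0x0028, 0x3010, "SQ", do.call(c, items)))
  }
  body <- c(body, dcm_elem(0x7FE0, 0x0010, "OW",
                           writeBin(px, raw(), size = 2, endian = "little")))

  meta_body <- c(
    dcm_elem(0x0002, 0x0002, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.7", "ui")),
    dcm_elem(0x0002, 0x0003, "UI", dcm_str("1.2.826.0.1.3680043.9.7433.1", "ui")),
    dcm_elem(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1", "ui"))
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", le32(length(meta_body))), meta_body)
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}

# Parse a run of Explicit-VR-LE data elements in r[(pos):(end)].
# Returns a named list keyed "group,elem" holding raw value fields
# (sequences become lists of item element sets).
dcm_parse <- function(r, pos, end) {
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= end) {
    group <- rd_u16(r, pos); elem <- rd_u16(r, pos + 2)
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- rd_u32(r, pos + 8)
      pos <- pos + 12
    } else {
      len <- rd_u16(r, pos + 6)
      pos <- pos + 8
    }
    if (len == 2^32 - 1) stop("undefined-length DICOM elements not supported")
    key <- sprintf("%04x,%04x", group, elem)
    if (vr == "SQ") {
      items <- list()
      ipos <- pos
      while (ipos < pos + len) {
        if (rd_u16(r, ipos) != 0xFFFE || rd_u16(r, ipos + 2) != 0xE000) {
          stop("malformed DICOM sequence item")
        }
        ilen <- rd_u32(r, ipos + 4)
        items[[length(items) + 1]] <- dcm_parse(r, ipos + 8, ipos + 8 + ilen - 1)
        ipos <- ipos + 8 + ilen
      }
      out[[key]] <- items
    } else {
      out[[key]] <- if (len > 0) r[pos:(pos + len - 1)] else raw(0)
    }
    pos <- pos + len
  }
  out
}

#' Read a single-frame grayscale DICOM file
#'
#' Pixels are normalised so that a higher value is brighter: MONOCHROME1
#' images are inverted relative to their stored values (about the stored
#' dynamic range `2^bits_stored - 1`). A VOI LUT sequence, when present, is
#' parsed into a family of [new_lut()] objects.
#'
#' @param path file path.
#' @return list with `image` (integer matrix, brightness-normalised),
#'   `photometric`, `bits_stored`, `lut_family`.
#' @export
read_dicom <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM") {
    stop("'", path, "' is not a DICOM file")
  }
  # file meta group: read its group length, then skip to the dataset
  meta_head <- dcm_parse(r, 133, 144)
  meta_len <- rd_u32(meta_head[["0002,0000"]], 1)
  ds <- dcm_parse(r, 133 + 12 + meta_len, length(r))

  need <- function(key) {
    v <- ds[[key]]
    if (is.null(v)) stop("DICOM missing element (", key, ")")
    v
  }
  h <- rd_u16(need("0028,0010"), 1)
  w <- rd_u16(need("0028,0011"), 1)
  bits <- rd_u16(need("0028,0101"), 1)
  photometric <- trimws(rawToChar(need("0028,0004")))
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2")) {
    stop("unsupported photometric interpretation '", photometric,
         "' (format dialect, not corruption)")
  }
  px <- rd_u16(need("7fe0,0010"), 1, n = h * w)
  img <- matrix(px, h, w, byrow = TRUE)
  if (photometric == "MONOCHROME1") img <- as.integer(2^bits - 1) - img

  lut_family <- NULL
  if (!is.null(ds[["0028,3010"]])) {
    lut_family <- lapply(ds[["0028,3010"]], function(item) {
      desc <- rd_u16(item[["0028,3002"]], 1, n = 3)
      n_entries <- if (desc[1] == 0) 2^16 else desc[1]
      new_lut(desc[2], rd_u16(item[["0028,3006"]], 1, n = n_entries))
    })
  }
  list(image = img, photometric = photometric, bits_stored = bits,
       lut_family = lut_family)
}

# --- NRRD (3D Slicer-style mask export) -------------------------------------

#' Write a binary mask as NRRD
#'
#' `unsigned char` data, axis order x-fastest (`sizes: W H 1`), raw or gzip
#' encoding — the dialect written by 3D Slicer / pynrrd for label maps.
#'
#' @param mask integer/binary matrix (rows x cols).
#' @param path output file.
#' @param encoding `"raw"` or `"gzip"`.
#' @export
write_nrrd <- function(mask, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  header <- paste0(
    "NRRD0004\n",
    "# Complete NRRD file format specification at:\n",
    "# http://teem.sourceforge.net/nrrd/format.html\n",
    "type: unsigned char\n",
    "dimension: 3\n",
    "sizes: ", ncol(mask), " ", nrow(mask), " 1\n",
    "encoding: ", encoding, "\n",
    "endian: little\n\n")
  data <- as.raw(as.integer(t(mask)))
  if (encoding == "gzip") data <- memCompress(data, "gzip")
  writeBin(c(charToRaw(header), data), path)
  invisible(path)
}

#' Read an NRRD mask file
#'
#' Accepts `unsigned char`/`uchar`/`uint8` data with raw or gzip encoding;
#' a singleton third dimension is squeezed.
#'
#' @param path file path.
#' @return integer matrix (rows x cols).
#' @export
read_nrrd <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  nl <- which(r == as.raw(10))
  hdr_end <- NA
  for (i in seq_along(nl)[-1]) {
    if (nl[i] == nl[i - 1] + 1) { hdr_end <- nl[i]; break }
  }
  if (is.na(hdr_end)) stop("NRRD header terminator not found")
  lines <- strsplit(rawToChar(r[1:hdr_end]), "\n")[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file")
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^#", ln) || !nzchar(ln)) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) fields[[tolower(kv[1])]] <- kv[2]
  }
  type <- tolower(fields[["type"]])
  if (!type %in% c("unsigned char", "uchar", "uint8", "uint8_t")) {
    stop("only 8-bit unsigned NRRD supported, got '", type, "'")
  }
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  if (length(sizes) == 3 && sizes[3] == 1) sizes <- sizes[1:2]
  if (length(sizes) != 2) stop("NRRD must be 2D (or 2D with singleton axis)")
  enc <- tolower(fields[["encoding"]])
  data <- r[(hdr_end + 1):length(r)]
  if (enc %in% c("gzip", "gz")) data <- memDecompress(data, "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding '", enc, "'")
  v <- as.integer(data[seq_len(sizes[1] * sizes[2])])
  matrix(v, nrow = sizes[2], ncol = sizes[1], byrow = TRUE)
}

# --- typed carriers ---------------------------------------------------------

#' Construct a mammogram sample
#'
#' One 2D grayscale image plus acquisition metadata. Intensities are in
#' vendor units (pre-rescaling); `lesion_center` is a 0-based
#' `(row, col)` pixel coordinate and must fall inside the image.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param patient_id opaque string.
#' @param view one of `"CC"`, `"MLO"`, `"OTHER"`.
#' @param laterality `"L"` or `"R"`.
#' @param lesion_center numeric length-2 `(row, col)`, 0-based.
#' @param lut_family optional list of [new_lut()] objects.
#' @param degenerate set `TRUE` to allow a constant image.
#' @return an object of class `mammogram_sample`.
#' @export
mammogram_sample <- function(image, patient_id, view, laterality,
                             lesion_center, lut_family = NULL,
                             degenerate = FALSE) {
  view <- match.arg(view, c("CC", "MLO", "OTHER"))
  laterality <- match.arg(laterality, c("L", "R"))
  if (any(lesion_center < 0) || lesion_center[1] > nrow(image) - 1 ||
      lesion_center[2] > ncol(image) - 1) {
    stop("lesion_center outside image bounds", call. = FALSE)
  }
  if (!degenerate && length(unique(as.vector(image))) < 2) {
    stop("image has fewer than 2 distinct values; flag degenerate = TRUE",
         call. = FALSE)
  }
  structure(list(image = image, patient_id = patient_id, view = view,
                 laterality = laterality,
                 lesion_center = as.numeric(lesion_center),
                 lut_family = lut_family),
            class = "mammogram_sample")
}

#' @export
print.mammogram_sample <- function(x, ...) {
  cat(sprintf("<mammogram_sample> patient %s, %s/%s, %dx%d, center (%g, %g)%s\n",
              x$patient_id, x$view, x$laterality, nrow(x$image), ncol(x$image),
              x$lesion_center[1], x$lesion_center[2],
              if (length(x$lut_family)) sprintf(", %d LUTs", length(x$lut_family))
              else ""))
  invisible(x)
}

#' Read a mammogram image with its metadata
#'
#' Dispatches on file extension: `.dcm` (DICOM, brightness-normalised, LUT
#' family attached), `.png`, `.tif`/`.tiff`. For non-DICOM formats the
#' acquisition metadata comes from the sidecar manifest row.
#'
#' @param path image file.
#' @param meta a manifest row (or named list) with `patient_id`, `view`,
#'   `laterality`, `lesion_center_row`, `lesion_center_col`.
#' @return a [mammogram_sample()].
#' @export
read_image <- function(path, meta) {
  ext <- tolower(tools::file_ext(path))
  lut_family <- NULL
  if (ext == "dcm") {
    d <- read_dicom(path)
    img <- d$image
    lut_family <- d$lut_family
  } else if (ext == "png") {
    img <- read_png(path)$image
  } else if (ext %in% c("tif", "tiff")) {
    img <- read_tiff(path)$image
  } else {
    stop("unsupported image format '.", ext, "'", call. = FALSE)
  }
  mammogram_sample(img, patient_id = as.character(meta$patient_id),
                   view = as.character(meta$view),
                   laterality = as.character(meta$laterality),
                   lesion_center = c(meta$lesion_center_row,
                                     meta$lesion_center_col),
                   lut_family = lut_family)
}

#' Read a lesion mask
#'
#' 8-bit PNG or NRRD; any nonzero value maps to 1. A declared image shape
#' mismatch and an all-zero mask on an annotated row are both signalled,
#' never silently repaired.
#'
#' @param path mask file (`.png` or `.nrrd`).
#' @param expected_dim optional `c(rows, cols)` of the paired image.
#' @param annotated if `TRUE` (default), an empty mask is an error.
#' @return binary integer matrix in `{0, 1}`.
#' @export
read_mask <- function(path, expected_dim = NULL, annotated = TRUE) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") read_png(path)$image
       else if (ext == "nrrd") read_nrrd(path)
       else stop("unsupported mask format '.", ext, "'", call. = FALSE)
  m <- (m != 0) + 0L
  if (!is.null(expected_dim) && !identical(dim(m), as.integer(expected_dim))) {
    stop(sprintf("mask shape %dx%d does not match declared image shape %dx%d",
                 nrow(m), ncol(m), expected_dim[1], expected_dim[2]),
         call. = FALSE)
  }
  if (annotated && sum(m) == 0) {
    stop("all-zero mask for an annotated lesion", call. = FALSE)
  }
  m
}
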