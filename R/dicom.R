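# Minimal DICOM Part-10 support: Explicit VR Little Endian only, no
# sequences, uncompressed 16-bit grayscale pixel data. This is deliberately
# a small self-contained subset -- enough to round-trip the phantom's
# Secondary Capture-style CT slices and to read any file written to the
# same profile. Unsupported transfer syntaxes fail loudly rather than
# guessing.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
UID_IMPLEMENTATION <- "1.2.826.0.1.3680043.9717.0.1"

raw_uint16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
raw_uint32 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")

pad_even <- function(r, pad_byte) {
  if (length(r) %% 2L == 1L) c(r, pad_byte) else r
}

dicom_element <- function(group, elem, vr, value_raw) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  value_raw <- pad_even(value_raw, pad)
  head <- c(raw_uint16(group), raw_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), raw_uint32(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534L)
      stop_ctphase("DICOM element value too long for short VR",
                   "ctphase_write_error")
    c(head, raw_uint16(length(value_raw)), value_raw)
  }
}

dicom_str_element <- function(group, elem, vr, s) {
  dicom_element(group, elem, vr, charToRaw(as.character(s)))
}

#' Write one CT slice as a DICOM Part-10 file
#'
#' Explicit VR Little Endian, MONOCHROME2, 16-bit signed pixels; HU values
#' are rounded to integers and stored with RescaleSlope 1 / Intercept 0.
#'
#' @param path output file path.
#' @param pixels_hu numeric matrix of HU values (rows = image rows).
#' @param meta list with `study_uid`, `series_uid`, `sop_uid`,
#'   `instance_number`, `z_position`, `series_description`, `manufacturer`.
#' @return `path`, invisibly.
#' @export
dicom_write_slice <- function(path, pixels_hu, meta) {
  stopifnot(is.matrix(pixels_hu))
  stored <- as.integer(pmin(pmax(round(pixels_hu), -32768), 32767))
  # DICOM pixel data is row-major; R matrices are column-major
  pix_raw <- writeBin(as.integer(t(matrix(stored, nrow(pixels_hu)))),
                      raw(), size = 2, endian = "little")
  ds <- c(
    dicom_str_element(0x0008, 0x0016, "UI", UID_SECONDARY_CAPTURE),
    dicom_str_element(0x0008, 0x0018, "UI", meta$sop_uid),
    dicom_str_element(0x0008, 0x0060, "CS", "CT"),
    dicom_str_element(0x0008, 0x0070, "LO", meta$manufacturer %||% ""),
    dicom_str_element(0x0008, 0x103E, "LO", meta$series_description %||% ""),
    dicom_str_element(0x0020, 0x000D, "UI", meta$study_uid),
    dicom_str_element(0x0020, 0x000E, "UI", meta$series_uid),
    dicom_str_element(0x0020, 0x0013, "IS", as.character(meta$instance_number)),
    dicom_str_element(0x0020, 0x0032, "DS",
                      sprintf("0\\0\\%.6g", meta$z_position)),
    dicom_str_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dicom_element(0x0028, 0x0002, "US", raw_uint16(1L)),
    dicom_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", raw_uint16(nrow(pixels_hu))),
    dicom_element(0x0028, 0x0011, "US", raw_uint16(ncol(pixels_hu))),
    dicom_element(0x0028, 0x0100, "US", raw_uint16(16L)),
    dicom_element(0x0028, 0x0101, "US", raw_uint16(16L)),
    dicom_element(0x0028, 0x0102, "US", raw_uint16(15L)),
    dicom_element(0x0028, 0x0103, "US", raw_uint16(1L)),
    dicom_str_element(0x0028, 0x1052, "DS", "0"),
    dicom_str_element(0x0028, 0x1053, "DS", "1"),
    dicom_element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  meta_body <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dicom_str_element(0x0002, 0x0002, "UI", UID_SECONDARY_CAPTURE),
    dicom_str_element(0x0002, 0x0003, "UI", meta$sop_uid),
    dicom_str_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    dicom_str_element(0x0002, 0x0012, "UI", UID_IMPLEMENTATION)
  )
  out <- c(raw(128L), charToRaw("DICM"),
           dicom_element(0x0002, 0x0000, "UL", raw_uint32(length(meta_body))),
           meta_body, ds)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

read_u16 <- function(r, i) {
  readBin(r[i:(i + 1L)], "integer", size = 2, endian = "little", signed = FALSE)
}
read_u32 <- function(r, i) {
  v <- readBin(r[i:(i + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 4294967296
  v
}

dicom_parse_elements <- function(r) {
  n <- length(r)
  i <- 133L
  els <- list()
  while (i + 7L <= n) {
    group <- read_u16(r, i); elem <- read_u16(r, i + 2L)
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- read_u32(r, i + 8L)
      vstart <- i + 12L
    } else {
      len <- read_u16(r, i + 6L)
      vstart <- i + 8L
    }
    if (len == 4294967295)
      stop_ctphase("undefined-length DICOM elements are not supported",
                   "ctphase_dicom_error")
    if (vstart + len - 1L > n)
      stop_ctphase("truncated DICOM element", "ctphase_dicom_error")
    val <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
    els[[sprintf("%04X,%04X", group, elem)]] <- list(vr = vr, value = val)
    i <- vstart + len
  }
  els
}

el_str <- function(els, key, default = NA_character_) {
  e <- els[[key]]
  if (is.null(e)) return(default)
  s <- rawToChar(e$value[e$value != as.raw(0L)])
  trimws(s)
}
el_num <- function(els, key, default = NA_real_) {
  s <- el_str(els, key, NA_character_)
  if (is.na(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
el_u16 <- function(els, key, default = NA_integer_) {
  e <- els[[key]]
  if (is.null(e) || length(e$value) < 2L) return(default)
  read_u16(e$value, 1L)
}

#' Read one DICOM file
#'
#' Parses an Explicit VR Little Endian Part-10 file and returns pixel data
#' converted to HU via RescaleSlope/RescaleIntercept plus the metadata this
#' package uses. Files that are not DICOM, or use another transfer syntax,
#' raise `ctphase_dicom_error`.
#'
#' @param path file path.
#' @return List: `pixels` (HU matrix), `z_position`, `instance_number`,
#'   `study_uid`, `series_uid`, `sop_uid`, `series_description`,
#'   `manufacturer`, `modality`.
#' @export
dicom_read_slice <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140L || !identical(rawToChar(r[129:132]), "DICM"))
    stop_ctphase(paste0("not a DICOM Part-10 file: ", path),
                 "ctphase_dicom_error")
  els <- dicom_parse_elements(r)
  ts <- el_str(els, "0002,0010")
  if (!is.na(ts) && ts != UID_EXPLICIT_VR_LE)
    stop_ctphase(paste0("unsupported transfer syntax ", ts, " in ", path),
                 "ctphase_dicom_error")
  rows <- el_u16(els, "0028,0010"); cols <- el_u16(els, "0028,0011")
  pix_el <- els[["7FE0,0010"]]
  if (is.null(pix_el) || is.na(rows) || is.na(cols))
    stop_ctphase(paste0("no image pixel data in ", path), "ctphase_dicom_error")
  bits <- el_u16(els, "0028,0100", 16L)
  if (bits != 16L)
    stop_ctphase("only 16-bit pixel data is supported", "ctphase_dicom_error")
  signed <- identical(el_u16(els, "0028,0103", 0L), 1L)
  stored <- readBin(pix_el$value, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = signed)
  if (length(stored) != rows * cols)
    stop_ctphase(paste0("pixel data size mismatch in ", path),
                 "ctphase_dicom_error")
  slope <- el_num(els, "0028,1053", 1)[1]
  intercept <- el_num(els, "0028,1052", 0)[1]
  hu <- matrix(stored * slope + intercept, nrow = rows, byrow = TRUE)
  ipp <- el_num(els, "0020,0032")
  list(pixels = hu,
       z_position = if (length(ipp) >= 3) ipp[3] else NA_real_,
       instance_number = as.integer(el_num(els, "0020,0013", NA_real_)[1]),
       study_uid = el_str(els, "0020,000D"),
       series_uid = el_str(els, "0020,000E"),
       sop_uid = el_str(els, "0008,0018"),
       series_description = el_str(els, "0008,103E", ""),
       manufacturer = el_str(els, "0008,0070", ""),
       modality = el_str(els, "0008,0060", ""))
}
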