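# Minimal DICOM Part-10 codec for single-frame CT image objects,
# Explicit VR Little Endian only. Covers exactly what the package needs:
# writing phantom/denoised volumes as a CT series and reading them (or any
# conforming single-frame CT series) back with correct HU rescaling,
# geometry, and through-plane ordering.

DCM_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"  # Explicit VR Little Endian
DCM_CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
DCM_UID_ROOT <- "1.2.826.0.1.3680043.9.7431"

# VRs using the 2-byte length form; everything else (OB, OW, OF, SQ, UT, UN)
# uses the 4-byte form with 2 reserved bytes
DCM_SHORT_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                   "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                   "UI", "UL", "US")

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# format a number as a DICOM DS (decimal string, <= 16 chars)
dcm_ds <- function(x) {
  s <- formatC(x, format = "fg", digits = 10, width = 1)
  if (nchar(s) > 16L) s <- formatC(x, format = "g", digits = 8, width = 1)
  s
}

dcm_element <- function(group, element, vr, value) {
  if (vr %in% c("UI")) {
    v <- dcm_pad(charToRaw(paste(value, collapse = "\\")), as.raw(0x00))
  } else if (vr %in% c("CS", "DS", "IS", "LO", "SH", "DA", "TM", "PN")) {
    v <- dcm_pad(charToRaw(paste(value, collapse = "\\")))
  } else if (vr == "US") {
    v <- uint16le(value)
  } else if (vr == "UL") {
    v <- uint32le(value)
  } else if (vr %in% c("OW", "OB")) {
    v <- value  # already raw
  } else {
    stop_atvseg("unsupported VR in writer: ", vr)
  }
  head <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% DCM_SHORT_VRS) {
    c(head, uint16le(length(v)), v)
  } else {
    c(head, as.raw(c(0, 0)), uint32le(length(v)), v)
  }
}

dcm_file_meta <- function(sop_instance_uid) {
  body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_element(0x0002, 0x0002, "UI", DCM_CT_SOP_CLASS),
    dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_element(0x0002, 0x0010, "UI", DCM_TRANSFER_SYNTAX),
    dcm_element(0x0002, 0x0012, "UI", paste0(DCM_UID_ROOT, ".1"))
  )
  c(dcm_element(0x0002, 0x0000, "UL", length(body)), body)
}

#' Write a CT volume as a DICOM series
#'
#' Writes one single-frame CT image file per slice (Explicit VR Little
#' Endian), with pixel spacing, slice thickness, per-slice through-plane
#' position, and rescale slope/intercept so that a subsequent
#' [read_ct_series()] recovers the HU values up to the integer quantization
#' of the 16-bit storage type.
#'
#' @param volume A [ct_volume()].
#' @param path Output directory (created if missing).
#' @param slope,intercept Rescale mapping `HU = slope * stored + intercept`.
#'   Stored values are `round((HU - intercept) / slope)` as signed 16-bit
#'   integers; HU outside the representable range is an error.
#' @param series_uid Optional fixed Series Instance UID (generated otherwise).
#' @return Invisibly, the vector of file paths written (one per slice).
#' @seealso [read_ct_series()]
#' @export
write_ct_series <- function(volume, path, slope = 1, intercept = -1024,
                            series_uid = NULL) {
  if (!inherits(volume, "ct_volume")) stop_atvseg("`volume` must be a ct_volume")
  if (!is_number(slope) || slope == 0) stop_atvseg("`slope` must be nonzero")
  stored_all <- (volume$data - intercept) / slope
  if (any(!is.finite(stored_all))) stop_atvseg("non-finite HU values")
  if (any(round(stored_all) < -32768 | round(stored_all) > 32767)) {
    stop_atvseg("HU values not representable as signed 16-bit after inverse rescale")
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (file.access(path, mode = 2L) != 0L) {
    stop_atvseg("output directory is not writable: ", path)
  }
  if (is.null(series_uid)) {
    series_uid <- paste0(DCM_UID_ROOT, ".2.",
                         format(as.integer(Sys.time())), ".",
                         sample.int(.Machine$integer.max, 1))
  }
  study_uid <- paste0(series_uid, ".0")
  d <- dim(volume$data)
  kvp <- volume$metadata$kvp %||% 120
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    sop_uid <- paste0(series_uid, ".", k)
    z <- (k - 1) * volume$slice_thickness
    stored <- as.integer(round(stored_all[, , k]))
    # DICOM pixel order is row-major (fastest along x); R matrices are
    # column-major, so transpose before serializing
    pix <- writeBin(as.vector(t(matrix(stored, d[1], d[2]))),
                    raw(), size = 2, endian = "little")
    ds <- c(
      dcm_element(0x0008, 0x0016, "UI", DCM_CT_SOP_CLASS),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(volume$slice_thickness)),
      dcm_element(0x0018, 0x0060, "DS", dcm_ds(kvp)),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS", c("0", "0", dcm_ds(z))),
      dcm_element(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[1]),           # Rows
      dcm_element(0x0028, 0x0011, "US", d[2]),           # Columns
      # PixelSpacing is (row spacing, column spacing) = (dy, dx)
      dcm_element(0x0028, 0x0030, "DS",
                  c(dcm_ds(volume$spacing[2]), dcm_ds(volume$spacing[1]))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),             # signed
      dcm_element(0x0028, 0x1052, "DS", dcm_ds(intercept)),
      dcm_element(0x0028, 0x1053, "DS", dcm_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix)
    )
    out <- c(raw(128), charToRaw("DICM"), dcm_file_meta(sop_uid), ds)
    files[k] <- file.path(path, sprintf("slice_%04d.dcm", k))
    writeBin(out, files[k])
  }
  invisible(files)
}

# --- reader ---------------------------------------------------------------

read_uint <- function(bytes, pos, size) {
  readBin(bytes[pos:(pos + size - 1)], "integer", size = size,
          signed = size >= 4, endian = "little")
}

# parse one Explicit-VR-LE dataset starting at `pos`; returns a named list
# keyed "GGGG,EEEE" with raw values plus parsed VRs
dcm_parse_elements <- function(bytes, pos) {
  n <- length(bytes)
  out <- list()
  while (pos + 7L <= n + 1L && pos <= n - 7L) {
    group <- read_uint(bytes, pos, 2)
    element <- read_uint(bytes, pos + 2, 2)
    vr_bytes <- as.integer(bytes[(pos + 4):(pos + 5)])
    if (any(vr_bytes < 65L | vr_bytes > 90L)) {
      stop_atvseg("not an Explicit-VR-Little-Endian element at byte ", pos,
                  " (implicit VR or corrupt file?)")
    }
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% DCM_SHORT_VRS) {
      len <- read_uint(bytes, pos + 6, 2)
      vpos <- pos + 8L
    } else {
      len <- read_uint(bytes, pos + 8, 4)
      vpos <- pos + 12L
    }
    if (len < 0 || vr == "SQ") {
      stop_atvseg("unsupported DICOM element (sequence or undefined length): ",
                  sprintf("(%04X,%04X)", group, element))
    }
    key <- sprintf("%04X,%04X", group, element)
    value <- if (len > 0) bytes[vpos:(vpos + len - 1L)] else raw(0)
    out[[key]] <- list(vr = vr, raw = value)
    pos <- vpos + len
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$raw[el$raw != as.raw(0)]))
}

dcm_num <- function(el) {
  if (is.null(el)) return(NULL)
  if (el$vr == "US") {
    readBin(el$raw, "integer", n = length(el$raw) / 2, size = 2,
            signed = FALSE, endian = "little")
  } else {
    as.numeric(strsplit(dcm_str(el), "\\", fixed = TRUE)[[1]])
  }
}

dcm_read_file <- function(file) {
  bytes <- readBin(file, raw(), n = file.size(file))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop_atvseg("not a DICOM part-10 file: ", file)
  }
  els <- dcm_parse_elements(bytes, 133L)
  ts <- dcm_str(els[["0002,0010"]])
  if (!is.null(ts) && ts != DCM_TRANSFER_SYNTAX) {
    stop_atvseg("unsupported transfer syntax ", ts, " in ", file,
                " (only Explicit VR Little Endian is supported)")
  }
  els
}

#' Read a DICOM CT series into a volume
#'
#' Reads every file in `path` as a single-frame CT image object, converts
#' stored values to HU through the file's Rescale Slope/Intercept, and stacks
#' the slices sorted by their through-plane (z) position regardless of file
#' name order.
#'
#' @param path Directory holding exactly one CT series.
#' @return A [ct_volume()]; `metadata` records kVp (if present) and the
#'   Series Instance UID.
#' @details Errors are raised (never silently defaulted) when the directory
#'   mixes two Series Instance UIDs, when in-plane shapes differ between
#'   slices, or when the rescale tags are absent.
#' @seealso [write_ct_series()]
#' @export
read_ct_series <- function(path) {
  if (!dir.exists(path)) stop_atvseg("no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop_atvseg("no files in ", path)
  parsed <- lapply(files, dcm_read_file)

  series <- vapply(parsed, function(e) dcm_str(e[["0020,000E"]]) %||% "",
                   character(1))
  if (length(unique(series)) > 1L) {
    u <- unique(series)
    stop_atvseg("directory mixes multiple series: ", u[1], " and ", u[2])
  }

  slices <- lapply(seq_along(parsed), function(i) {
    e <- parsed[[i]]
    rows <- dcm_num(e[["0028,0010"]])
    cols <- dcm_num(e[["0028,0011"]])
    if (is.null(rows) || is.null(cols)) {
      stop_atvseg("missing Rows/Columns in ", files[i])
    }
    slope <- dcm_num(e[["0028,1053"]])
    intercept <- dcm_num(e[["0028,1052"]])
    if (is.null(slope) || is.null(intercept)) {
      stop_atvseg("missing Rescale Slope/Intercept in ", files[i],
                  "; refusing to guess HU calibration")
    }
    bits <- dcm_num(e[["0028,0100"]]) %||% 16
    if (bits != 16) stop_atvseg("only 16-bit pixel data supported: ", files[i])
    signed <- (dcm_num(e[["0028,0103"]]) %||% 1) == 1
    pix_el <- e[["7FE0,0010"]]
    if (is.null(pix_el)) stop_atvseg("missing Pixel Data in ", files[i])
    stored <- readBin(pix_el$raw, "integer", n = rows * cols, size = 2,
                      signed = signed, endian = "little")
    if (length(stored) != rows * cols) {
      stop_atvseg("pixel data length mismatch in ", files[i])
    }
    pos <- dcm_num(e[["0020,0032"]])
    z <- if (!is.null(pos) && length(pos) >= 3) pos[3]
         else (dcm_num(e[["0020,0013"]]) %||% i)
    sp <- dcm_num(e[["0028,0030"]])  # (row spacing, col spacing)
    list(
      pixels = t(matrix(as.numeric(stored) * slope + intercept, cols, rows)),
      z = z,
      spacing = if (!is.null(sp)) c(sp[2], sp[1]) else c(1, 1),
      thickness = dcm_num(e[["0018,0050"]]) %||% 1,
      kvp = dcm_num(e[["0018,0060"]])
    )
  })

  shp <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    stop_atvseg(sprintf(
      "inconsistent in-plane shapes in series: %dx%d vs %dx%d",
      shp[1, 1], shp[2, 1],
      shp[1, which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])[1]],
      shp[2, which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])[1]]
    ))
  }

  ord <- order(vapply(slices, `[[`, numeric(1), "z"))
  slices <- slices[ord]
  data <- array(unlist(lapply(slices, `[[`, "pixels")),
                c(shp[1, 1], shp[2, 1], length(slices)))
  ct_volume(
    data,
    spacing = slices[[1]]$spacing,
    slice_thickness = slices[[1]]$thickness,
    metadata = list(kvp = slices[[1]]$kvp, series_uid = unique(series))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
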