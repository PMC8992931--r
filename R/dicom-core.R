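# Minimal DICOM codec: Explicit VR Little Endian with defined lengths.
#
# Covers exactly the subset of the CT Image, RT Plan, RT Structure Set and
# RT Dose IODs that cone-plan MU verification needs. It is not a general
# DICOM library: one transfer syntax, defined-length sequences only, no
# character-set handling beyond ASCII.

.DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.1247"

.SOP_CT      <- "1.2.840.10008.5.1.4.1.1.2"
.SOP_RTDOSE  <- "1.2.840.10008.5.1.4.1.1.481.2"
.SOP_RTSS    <- "1.2.840.10008.5.1.4.1.1.481.3"
.SOP_RTPLAN  <- "1.2.840.10008.5.1.4.1.1.481.5"

# VRs that use the 12-byte (reserved + 32-bit length) header form
.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# DS (decimal string) formatting: <= 16 bytes per value, 10 significant digits
.ds_chr <- function(x) vapply(x, function(v) sprintf("%.10g", v), character(1))

.dcm_pad <- function(b, pad) if (length(b) %% 2L == 1L) c(b, pad) else b

# Encode one data element as raw bytes.
# value: character vector (string VRs), numeric (DS/IS/US/UL/FL/FD),
#        raw (OB/OW), or list of raw item payloads (SQ).
dcm_element <- function(group, element, vr, value) {
  body <- switch(vr,
    UI = .dcm_pad(charToRaw(paste(value, collapse = "\\")), as.raw(0L)),
    DS = .dcm_pad(charToRaw(paste(.ds_chr(value), collapse = "\\")), charToRaw(" ")),
    IS = .dcm_pad(charToRaw(paste(format(as.integer(value), scientific = FALSE,
                                         trim = TRUE), collapse = "\\")),
                  charToRaw(" ")),
    US = .u16raw(value),
    UL = .u32raw(value),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    OB = .dcm_pad(as.raw(value), as.raw(0L)),
    OW = as.raw(value),
    SQ = {
      items <- lapply(value, function(payload)
        c(.u16raw(0xFFFE), .u16raw(0xE000), .u32raw(length(payload)), payload))
      do.call(c, c(items, list(raw(0)))
      )
    },
    # default: space-padded string VR
    .dcm_pad(charToRaw(paste(value, collapse = "\\")), charToRaw(" "))
  )
  stopifnot(length(body) %% 2L == 0L)
  head <- c(.u16raw(group), .u16raw(element), charToRaw(vr))
  if (vr %in% .vr_long) {
    c(head, as.raw(c(0L, 0L)), .u32raw(length(body)), body)
  } else {
    if (length(body) > 65534L)
      stop("element value too long for short-form VR ", vr)
    c(head, .u16raw(length(body)), body)
  }
}

# Assemble a dataset from a list of elements: each list(group, element, vr, value).
# Elements must already be in ascending tag order.
dcm_dataset <- function(elements) {
  do.call(c, lapply(elements, function(e) dcm_element(e[[1]], e[[2]], e[[3]], e[[4]])))
}

# Write a complete Part-10 file (preamble + file meta + dataset).
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset_raw) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", c(0L, 1L)),
    dcm_element(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_element(0x0002, 0x0010, "UI", .DCM_TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", paste0(.DCM_UID_ROOT, ".1"))
  )
  grouplen <- dcm_element(0x0002, 0x0000, "UL", length(meta))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta, dataset_raw), con)
  invisible(path)
}

.rd_u16 <- function(b, pos) {
  as.integer(b[pos]) + 256L * as.integer(b[pos + 1L])
}
.rd_u32 <- function(b, pos) {
  as.integer(b[pos]) + 256 * as.integer(b[pos + 1L]) +
    65536 * as.integer(b[pos + 2L]) + 16777216 * as.integer(b[pos + 3L])
}

.dcm_key <- function(group, element) sprintf("%04X,%04X", group, element)

# Parse an Explicit VR LE dataset from bytes[pos..end] into a named list:
# names "GGGG,EEEE", values list(vr = , val = parsed value).
.dcm_parse <- function(b, pos, end) {
  out <- list()
  while (pos <= end - 7L) {
    group <- .rd_u16(b, pos); element <- .rd_u16(b, pos + 2L)
    vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
    if (vr %in% .vr_long) {
      len <- .rd_u32(b, pos + 8L); pos <- pos + 12L
    } else {
      len <- .rd_u16(b, pos + 6L); pos <- pos + 8L
    }
    if (vr == "SQ" && len == 4294967295)
      stop("undefined-length DICOM sequences are not supported by this reader")
    val <- if (vr == "SQ") {
      items <- list()
      sq_end <- pos + len - 1L
      while (pos <= sq_end - 7L) {
        itag_g <- .rd_u16(b, pos); itag_e <- .rd_u16(b, pos + 2L)
        ilen <- .rd_u32(b, pos + 4L)
        if (itag_g != 0xFFFE || itag_e != 0xE000)
          stop("malformed DICOM sequence item")
        items[[length(items) + 1L]] <- .dcm_parse(b, pos + 8L, pos + 7L + ilen)
        pos <- pos + 8L + ilen
      }
      pos <- sq_end + 1L
      items
    } else {
      chunk <- if (len > 0L) b[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      switch(vr,
        DS = as.numeric(strsplit(trimws(rawToChar(chunk)), "\\", fixed = TRUE)[[1]]),
        IS = as.integer(strsplit(trimws(rawToChar(chunk)), "\\", fixed = TRUE)[[1]]),
        US = readBin(chunk, "integer", n = len / 2L, size = 2,
                     endian = "little", signed = FALSE),
        UL = readBin(chunk, "integer", n = len / 4L, size = 4, endian = "little"),
        FL = readBin(chunk, "double", n = len / 4L, size = 4, endian = "little"),
        FD = readBin(chunk, "double", n = len / 8L, size = 8, endian = "little"),
        OW = chunk,
        OB = chunk,
        UI = rawToChar(chunk[chunk != as.raw(0L)]),
        # remaining string VRs are space padded
        trimws(rawToChar(chunk))
      )
    }
    out[[.dcm_key(group, element)]] <- list(vr = vr, val = val)
  }
  out
}

# Read a Part-10 DICOM file written in Explicit VR Little Endian.
dcm_read_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140) stop("not a DICOM file: ", path)
  b <- readBin(path, raw(), n = n)
  if (rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  # file meta group (always explicit VR)
  meta <- list()
  while (pos <= n - 7L && .rd_u16(b, pos) == 0x0002) {
    group <- .rd_u16(b, pos); element <- .rd_u16(b, pos + 2L)
    vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
    if (vr %in% .vr_long) { len <- .rd_u32(b, pos + 8L); pos <- pos + 12L }
    else { len <- .rd_u16(b, pos + 6L); pos <- pos + 8L }
    chunk <- if (len > 0L) b[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    if (vr == "UI") meta[[.dcm_key(group, element)]] <-
        rawToChar(chunk[chunk != as.raw(0L)])
  }
  ts <- meta[["0002,0010"]]
  if (!is.null(ts) && ts != .DCM_TS_EXPLICIT_LE)
    stop("unsupported DICOM transfer syntax: ", ts)
  ds <- .dcm_parse(b, pos, n)
  attr(ds, "meta") <- meta
  ds
}

# Fetch the parsed value of tag (group, element) from a parsed dataset, or
# `default` when absent.
dcm_get <- function(ds, group, element, default = NULL) {
  e <- ds[[.dcm_key(group, element)]]
  if (is.null(e)) default else e$val
}

# Deterministic UID generator: seeded counter under the package root.
dcm_uid_factory <- function(seed = 0L) {
  counter <- 0L
  base <- paste0(.DCM_UID_ROOT, ".", as.integer(seed) %% 1000000L)
  function() {
    counter <<- counter + 1L
    paste0(base, ".", counter)
  }
}
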