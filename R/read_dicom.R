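# Minimal single-frame DICOM reader.
#
# Scope: part-10 files (128-byte preamble + "DICM"), little-endian transfer
# syntaxes (implicit 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1),
# uncompressed MONOCHROME pixel data, 8 or 16 bits allocated, single frame.
# That covers typical exported B-mode stills; anything else errors clearly.
# 16-bit data is windowed to 8 bits by linear min-max scaling.

read_dicom <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM") {
    stop("not a part-10 DICOM file (missing DICM marker): ", path)
  }
  u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1L])
  u32 <- function(i) {
    as.numeric(buf[i]) + 256 * as.numeric(buf[i + 1L]) +
      65536 * as.numeric(buf[i + 2L]) + 16777216 * as.numeric(buf[i + 3L])
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  tags <- list()
  pos <- 133L
  explicit <- TRUE   # file meta group is always explicit little endian
  ts <- NULL
  n <- length(buf)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (group != 2L && !is.null(ts)) {
      # dataset encoding per transfer syntax
      explicit <- ts != "1.2.840.10008.1.2"
    }
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    val_at <- pos + hdr

    if (len == 4294967295) {
      # undefined length (sequence / encapsulation): skip to the matching
      # sequence delimitation item FFFE,E0DD
      delim <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0))
      found <- NA_integer_
      j <- val_at
      while (j + 7L <= n) {
        if (buf[j] == delim[1L] && buf[j + 1L] == delim[2L] &&
            buf[j + 2L] == delim[3L] && buf[j + 3L] == delim[4L]) {
          found <- j; break
        }
        j <- j + 1L
      }
      if (is.na(found)) stop("unterminated undefined-length element in DICOM")
      pos <- found + 8L
      next
    }

    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0002,0010", "0028,0010", "0028,0011", "0028,0030",
                   "0028,0100", "0028,0103", "0028,0004", "7fe0,0010")) {
      tags[[key]] <- buf[val_at:(val_at + len - 1L)]
    }
    if (key == "0002,0010") {
      ts <- sub("\\x00+$", "", rawToChar(tags[[key]]))
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
        stop("unsupported DICOM transfer syntax: ", ts,
             " (only uncompressed little endian is supported)")
      }
    }
    pos <- val_at + len
    if (key == "7fe0,0010") break
  }
  if (is.null(ts)) ts <- "1.2.840.10008.1.2.1"

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("DICOM is missing ", what)
    tags[[key]]
  }
  dec_u16 <- function(r) as.integer(r[1L]) + 256L * as.integer(r[2L])
  rows <- dec_u16(need("0028,0010", "Rows"))
  cols <- dec_u16(need("0028,0011", "Columns"))
  bits <- dec_u16(need("0028,0100", "BitsAllocated"))
  signed <- !is.null(tags[["0028,0103"]]) && dec_u16(tags[["0028,0103"]]) == 1L

  spacing <- NULL
  if (!is.null(tags[["0028,0030"]])) {
    parts <- as.numeric(strsplit(trimws(rawToChar(tags[["0028,0030"]])),
                                 "\\\\")[[1L]])
    parts <- parts[is.finite(parts)]
    if (length(parts) >= 1L) {
      if (length(parts) >= 2L && abs(parts[1L] - parts[2L]) > 1e-9) {
        warning("anisotropic DICOM pixel spacing; averaging row/col values")
      }
      spacing <- mean(parts)
    }
  }

  pd <- need("7fe0,0010", "PixelData")
  npx <- rows * cols
  v <- if (bits == 8L) {
    as.integer(pd[seq_len(npx)])
  } else if (bits == 16L) {
    readBin(pd, what = "integer", n = npx, size = 2L,
            signed = signed, endian = "little")
  } else {
    stop("unsupported BitsAllocated: ", bits)
  }
  # pixel data is stored row by row, left to right
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  if (bits == 16L || min(m) < 0 || max(m) > 255) {
    rng <- range(m)
    m <- if (rng[2L] > rng[1L]) {
      round_half_up((m - rng[1L]) * (255 / (rng[2L] - rng[1L])))
    } else {
      matrix(0L, rows, cols)
    }
  }
  list(pixels = m, spacing = spacing)
}
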