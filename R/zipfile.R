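# Minimal zip writer/reader. Written by hand because USDZ requires exact
# control the usual tools don't give: every entry stored (method 0) and
# every entry's payload aligned to a 64-byte boundary via local-header
# extra-field padding. Timestamps are fixed so identical input produces
# byte-identical archives.

zip_u16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

zip_u32 <- function(x) {
  # x may exceed .Machine$integer.max (CRCs); work in doubles
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

zip_dos_datetime <- function() {
  # fixed 2020-01-01 00:00:00 for reproducible archives
  list(time = 0L, date = bitwOr(bitwOr(bitwShiftL(40L, 9L), bitwShiftL(1L, 5L)), 1L))
}

# entries: named list of raw vectors, order preserved. align: payload
# alignment in bytes (64 for USDZ) or NULL for none. Returns a raw vector.
zip_build <- function(entries, align = NULL) {
  stopifnot(length(entries) > 0, !is.null(names(entries)))
  dt <- zip_dos_datetime()
  out <- list()
  central <- list()
  offset <- 0

  for (nm in names(entries)) {
    data <- entries[[nm]]
    stopifnot(is.raw(data))
    name_raw <- charToRaw(nm)
    crc <- .crc32_raw(data)
    extra <- raw(0)
    if (!is.null(align)) {
      pad <- (align - (offset + 30 + length(name_raw)) %% align) %% align
      if (pad > 0 && pad < 4) pad <- pad + align
      if (pad > 0) {
        extra <- c(as.raw(c(0xff, 0xff)), zip_u16(pad - 4L), raw(pad - 4L))
      }
    }
    header <- c(
      zip_u32(0x04034b50), zip_u16(20L), zip_u16(0L), zip_u16(0L),
      zip_u16(dt$time), zip_u16(dt$date), zip_u32(crc),
      zip_u32(length(data)), zip_u32(length(data)),
      zip_u16(length(name_raw)), zip_u16(length(extra)),
      name_raw, extra
    )
    central[[nm]] <- c(
      zip_u32(0x02014b50), zip_u16(20L), zip_u16(20L), zip_u16(0L), zip_u16(0L),
      zip_u16(dt$time), zip_u16(dt$date), zip_u32(crc),
      zip_u32(length(data)), zip_u32(length(data)),
      zip_u16(length(name_raw)), zip_u16(0L), zip_u16(0L),
      zip_u16(0L), zip_u16(0L), zip_u32(0L), zip_u32(offset),
      name_raw
    )
    out[[length(out) + 1L]] <- header
    out[[length(out) + 1L]] <- data
    offset <- offset + length(header) + length(data)
  }

  cd <- do.call(c, central)
  eocd <- c(
    zip_u32(0x06054b50), zip_u16(0L), zip_u16(0L),
    zip_u16(length(entries)), zip_u16(length(entries)),
    zip_u32(length(cd)), zip_u32(offset), zip_u16(0L)
  )
  c(do.call(c, out), cd, eocd)
}

read_u16 <- function(x, at) as.integer(x[at]) + 256L * as.integer(x[at + 1L])
read_u32 <- function(x, at) {
  as.numeric(x[at]) + 256 * as.numeric(x[at + 1L]) +
    65536 * as.numeric(x[at + 2L]) + 16777216 * as.numeric(x[at + 3L])
}

# List the central directory of a zip file (path or raw vector): entry
# names, compression method, sizes, CRC and the absolute offset at which
# each entry's payload starts (for alignment checks).
zip_list <- function(zip) {
  x <- if (is.raw(zip)) zip else readBin(zip, "raw", file.info(zip)$size)
  # locate end-of-central-directory record
  tail_start <- max(1L, length(x) - 65557L)
  eocd <- NA
  for (at in (length(x) - 21L):tail_start) {
    if (read_u32(x, at) == 0x06054b50) { eocd <- at; break }
  }
  if (is.na(eocd)) abort_mf("molforge_io_error", "not a zip archive (no EOCD)")
  n_entries <- read_u16(x, eocd + 10L)
  cd_off <- read_u32(x, eocd + 16L) + 1
  res <- data.frame(name = character(n_entries), method = integer(n_entries),
                    crc = numeric(n_entries), size = numeric(n_entries),
                    header_offset = numeric(n_entries),
                    data_offset = numeric(n_entries), stringsAsFactors = FALSE)
  at <- cd_off
  for (k in seq_len(n_entries)) {
    stopifnot(read_u32(x, at) == 0x02014b50)
    nlen <- read_u16(x, at + 28L)
    elen <- read_u16(x, at + 30L)
    clen <- read_u16(x, at + 32L)
    hdr_off <- read_u32(x, at + 42L)
    res$name[k] <- rawToChar(x[(at + 46L):(at + 45L + nlen)])
    res$method[k] <- read_u16(x, at + 10L)
    res$crc[k] <- read_u32(x, at + 16L)
    res$size[k] <- read_u32(x, at + 24L)
    res$header_offset[k] <- hdr_off
    # payload offset needs the local header's own name/extra lengths
    lh <- hdr_off + 1
    res$data_offset[k] <- hdr_off + 30 + read_u16(x, lh + 26L) + read_u16(x, lh + 28L)
    at <- at + 46L + nlen + elen + clen
  }
  res
}

# Extract one entry's payload from a (stored-entries) zip.
zip_extract <- function(zip, name) {
  x <- if (is.raw(zip)) zip else readBin(zip, "raw", file.info(zip)$size)
  listing <- zip_list(x)
  i <- match(name, listing$name)
  if (is.na(i)) abort_mf("molforge_io_error", sprintf("no zip entry %s", name))
  if (listing$method[i] != 0L) {
    abort_mf("molforge_io_error", "zip_extract only handles stored entries")
  }
  if (listing$size[i] == 0) return(raw(0))
  x[(listing$data_offset[i] + 1):(listing$data_offset[i] + listing$size[i])]
}
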