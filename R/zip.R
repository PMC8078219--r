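# Minimal ZIP container support for roi.zip archives.
#
# Entries are written uncompressed ("stored") with fixed DOS timestamps so that
# archives built from the same inputs are byte-identical. Reading goes through
# base R's unzip(), which understands both stored and deflated entries, so
# archives produced by ImageJ/Fiji are accepted as well.

.crc_env <- new.env(parent = emptyenv())

# 32-bit ops on doubles (R integers are signed 32-bit, too small for CRC work)
xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  as.numeric(hi) * 65536 + as.numeric(lo)
}

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  tab <- numeric(256)
  for (n in 0:255) {
    c <- as.numeric(n)
    for (k in 1:8) {
      c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
    }
    tab[n + 1] <- c
  }
  .crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(as.integer(crc %% 256), b[i])
    crc <- xor32(crc %/% 256, tab[idx + 1])
  }
  xor32(crc, 4294967295)
}

le_bytes <- function(x, n) {
  out <- raw(n)
  x <- as.numeric(x)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# entries: named list of raw vectors
zip_write <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  nm <- names(entries)
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(nm[i])
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    hdr <- c(
      le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(33, 2),        # fixed DOS time/date (1980-01-01)
      le_bytes(crcs[i], 4), le_bytes(length(data), 4), le_bytes(length(data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2)
    )
    writeBin(hdr, con)
    writeBin(name, con)
    if (length(data)) writeBin(data, con)
    pos <- pos + length(hdr) + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(nm[i])
    cdr <- c(
      le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(33, 2),
      le_bytes(crcs[i], 4), le_bytes(length(data), 4), le_bytes(length(data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4), le_bytes(offsets[i], 4)
    )
    writeBin(cdr, con)
    writeBin(name, con)
    pos <- pos + length(cdr) + length(name)
  }
  eocd <- c(
    le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(entries), 2), le_bytes(length(entries), 2),
    le_bytes(pos - cd_start, 4), le_bytes(cd_start, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

# -> named list of raw vectors, in archive order
zip_read <- function(path) {
  # a zero-entry archive is just the 22-byte end-of-central-directory record,
  # which utils::unzip refuses to list
  sz <- file.info(path)$size
  if (!is.na(sz) && sz <= 22) {
    head <- readBin(path, "raw", n = 4)
    if (length(head) == 4 && identical(head, as.raw(c(0x50, 0x4b, 0x05, 0x06))))
      return(structure(list(), names = character(0)))
  }
  info <- utils::unzip(path, list = TRUE)
  if (nrow(info) == 0) return(structure(list(), names = character(0)))
  tmp <- tempfile("zipx")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, exdir = tmp)
  out <- lapply(seq_len(nrow(info)), function(i) {
    f <- file.path(tmp, info$Name[i])
    readBin(f, "raw", n = file.info(f)$size)
  })
  names(out) <- info$Name
  out
}
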