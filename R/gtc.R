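# GTC codec: the little-endian table-of-contents layout of Illumina GTC v3+,
# restricted to the entries this pipeline consumes (genotypes, GenCall scores,
# raw X/Y, normalization transforms, sample name) plus a per-record transform
# index table. All multi-byte integers little-endian; strings are int32
# length-prefixed UTF-8.

.gtc_magic   <- charToRaw("gtc")
.gtc_version <- 5L

.gtc_id_num_snps        <- 1L    # scalar: value stored in the TOC offset slot
.gtc_id_sample_name     <- 10L
.gtc_id_transforms      <- 400L
.gtc_id_transform_index <- 401L
.gtc_id_raw_x           <- 1000L
.gtc_id_raw_y           <- 1001L
.gtc_id_genotypes       <- 1002L
.gtc_id_scores          <- 1004L

.gtc_gtypes <- c("NC", "AA", "AB", "BB")   # byte codes 0..3

# Pass doubles through float32 so values we later write to disk compare
# exactly with values read back.
.quantize_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          "numeric", n = length(x), size = 4, endian = "little")
}

.write_u16 <- function(con, v) {
  v <- as.integer(round(v))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, con, size = 2, endian = "little")
}

.write_string <- function(con, s) {
  b <- charToRaw(enc2utf8(s))
  writeBin(length(b), con, size = 4, endian = "little")
  writeBin(b, con)
}

#' Write a GTC fixture file
#'
#' Serializes genotype-call records and their normalization transforms in the
#' documented little-endian table-of-contents GTC dialect read by
#' [read_gtc()]. Intended for building test fixtures and simulated batches;
#' the round trip `read_gtc(write_gtc(...))` is the identity on every exposed
#' field.
#'
#' @param records Data frame with one row per SNP in array order and columns
#'   `gtype` (`"NC"`, `"AA"`, `"AB"`, `"BB"`), `score` (GenCall score in
#'   `[0, 1]`; stored as float32), `x_raw`, `y_raw` (raw intensities in
#'   `[0, 65535]`; stored as uint16) and `transform_index` (1-based index
#'   into `transforms`).
#' @param transforms Transforms as produced by [normalization_transform()]
#'   (rows row-bound for several).
#' @param path Output file path.
#' @param sample_name Sample identifier embedded in the file.
#' @return `path`, invisibly.
#' @export
write_gtc <- function(records, transforms, path, sample_name = "sample") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    abort_parameter("records must be a non-empty data frame")
  need <- c("gtype", "score", "x_raw", "y_raw", "transform_index")
  miss <- setdiff(need, names(records))
  if (length(miss))
    abort_parameter("records is missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(records$gtype %in% .gtc_gtypes))
    abort_parameter("invalid genotype code(s): %s",
                    paste(unique(setdiff(records$gtype, .gtc_gtypes)), collapse = ", "))
  if (any(!is.finite(records$score)) || any(records$score < 0) || any(records$score > 1))
    abort_parameter("scores must lie in [0, 1]")
  if (any(records$x_raw < 0) || any(records$x_raw > 65535) ||
      any(records$y_raw < 0) || any(records$y_raw > 65535))
    abort_parameter("raw intensities must lie in [0, 65535]")
  ti <- as.integer(records$transform_index)
  if (any(is.na(ti)) || any(ti < 1L) || any(ti > nrow(transforms)))
    abort_parameter("transform_index out of range")

  n  <- nrow(records)
  nt <- nrow(transforms)
  name_b <- charToRaw(enc2utf8(sample_name))

  # Fixed layout: 8-byte header, 8 TOC entries of 6 bytes each, then sections.
  toc <- data.frame(
    id   = c(.gtc_id_num_snps, .gtc_id_sample_name, .gtc_id_transforms,
             .gtc_id_transform_index, .gtc_id_raw_x, .gtc_id_raw_y,
             .gtc_id_genotypes, .gtc_id_scores),
    size = c(NA, 4L + length(name_b), 4L + nt * 28L, 4L + n * 2L,
             4L + n * 2L, 4L + n * 2L, 4L + n, 4L + n * 4L)
  )
  data_start <- 8L + nrow(toc) * 6L
  offsets <- integer(nrow(toc))
  pos <- data_start
  for (i in seq_len(nrow(toc))) {
    if (toc$id[i] == .gtc_id_num_snps) { offsets[i] <- n; next }  # scalar entry
    offsets[i] <- pos
    pos <- pos + toc$size[i]
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.gtc_magic, con)
  writeBin(as.integer(.gtc_version), con, size = 1)
  writeBin(nrow(toc), con, size = 4, endian = "little")
  for (i in seq_len(nrow(toc))) {
    .write_u16(con, toc$id[i])
    writeBin(as.integer(offsets[i]), con, size = 4, endian = "little")
  }
  .write_string(con, sample_name)
  writeBin(nt, con, size = 4, endian = "little")
  for (i in seq_len(nt)) {
    writeBin(as.integer(transforms$version[i]), con, size = 4, endian = "little")
    writeBin(as.numeric(c(transforms$offset_x[i], transforms$offset_y[i],
                          transforms$scale_x[i], transforms$scale_y[i],
                          transforms$shear[i], transforms$theta[i])),
             con, size = 4, endian = "little")
  }
  writeBin(n, con, size = 4, endian = "little"); .write_u16(con, ti)
  writeBin(n, con, size = 4, endian = "little"); .write_u16(con, records$x_raw)
  writeBin(n, con, size = 4, endian = "little"); .write_u16(con, records$y_raw)
  writeBin(n, con, size = 4, endian = "little")
  writeBin(as.integer(match(records$gtype, .gtc_gtypes) - 1L), con, size = 1)
  writeBin(n, con, size = 4, endian = "little")
  writeBin(as.numeric(records$score), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a GTC genotype-call file
#'
#' Parses the little-endian table-of-contents GTC dialect (see [write_gtc()]
#' for the layout). Unknown table-of-contents entries are skipped with a
#' warning; truncated or malformed files raise a format error naming the byte
#' offset.
#'
#' @param path Path to a GTC file.
#' @return A list with `sample_name` (string or `NA`), `records` (data frame
#'   with columns `snp_index`, `gtype`, `score`, `x_raw`, `y_raw`,
#'   `transform_index`) and `transforms` (data frame of normalization
#'   transforms).
#' @export
read_gtc <- function(path) {
  if (!file.exists(path)) abort_parameter("no such file: %s", path)
  sz <- file.info(path)$size
  bytes <- readBin(path, "raw", n = sz)
  len <- length(bytes)
  if (len < 8L) abort_format("%s: truncated GTC header (file is %d bytes)", path, len)
  if (!identical(bytes[1:3], .gtc_magic))
    abort_format("%s: bad magic bytes at offset 0", path)
  version <- as.integer(bytes[4])
  if (version < 3L) abort_format("%s: unsupported GTC version %d at offset 3", path, version)

  con <- rawConnection(bytes)
  on.exit(close(con))
  rd <- function(what, n, size, signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  seek(con, 4L)
  n_entries <- rd("integer", 1L, 4L)
  if (n_entries < 1L || len < 8L + n_entries * 6L)
    abort_format("%s: truncated table of contents at offset 4", path)
  ids <- integer(n_entries); offs <- integer(n_entries)
  for (i in seq_len(n_entries)) {
    ids[i]  <- rd("integer", 1L, 2L, signed = FALSE)
    offs[i] <- rd("integer", 1L, 4L)
  }

  at <- function(id) { w <- which(ids == id); if (length(w)) offs[w[1]] else NA_integer_ }
  check_off <- function(off, need) {
    if (is.na(off) || off < 0L || off + need > len)
      abort_format("%s: section truncated at byte offset %d", path, off)
  }
  read_counted <- function(off, what, size, signed = TRUE) {
    check_off(off, 4L)
    seek(con, off)
    n <- rd("integer", 1L, 4L)
    if (n < 0L) abort_format("%s: negative element count at byte offset %d", path, off)
    check_off(off + 4L, n * max(size, 1L))
    rd(what, n, size, signed = signed)
  }

  known <- c(.gtc_id_num_snps, .gtc_id_sample_name, .gtc_id_transforms,
             .gtc_id_transform_index, .gtc_id_raw_x, .gtc_id_raw_y,
             .gtc_id_genotypes, .gtc_id_scores)
  for (id in setdiff(ids, known))
    warning(sprintf("%s: unknown GTC table-of-contents entry id %d skipped", path, id))

  n_snps <- at(.gtc_id_num_snps)   # scalar: the offset slot holds the value
  if (is.na(n_snps)) abort_format("%s: missing SNP-count entry", path)

  sample_name <- NA_character_
  off <- at(.gtc_id_sample_name)
  if (!is.na(off)) {
    check_off(off, 4L)
    seek(con, off)
    nb <- rd("integer", 1L, 4L)
    check_off(off + 4L, nb)
    sample_name <- rawToChar(rd("raw", nb, 1L))
  }

  off <- at(.gtc_id_transforms)
  if (is.na(off)) abort_format("%s: missing normalization-transform section", path)
  check_off(off, 4L)
  seek(con, off)
  nt <- rd("integer", 1L, 4L)
  check_off(off + 4L, nt * 28L)
  transforms <- do.call(rbind, lapply(seq_len(nt), function(i) {
    v <- rd("integer", 1L, 4L)
    f <- rd("numeric", 6L, 4L)
    data.frame(version = v, offset_x = f[1], offset_y = f[2], theta = f[6],
               shear = f[5], scale_x = f[3], scale_y = f[4])
  }))

  tindex <- read_counted(at(.gtc_id_transform_index), "integer", 2L, signed = FALSE)
  x_raw  <- read_counted(at(.gtc_id_raw_x), "integer", 2L, signed = FALSE)
  y_raw  <- read_counted(at(.gtc_id_raw_y), "integer", 2L, signed = FALSE)
  gcode  <- as.integer(read_counted(at(.gtc_id_genotypes), "raw", 1L))
  scores <- read_counted(at(.gtc_id_scores), "numeric", 4L)

  lens <- c(length(tindex), length(x_raw), length(y_raw), length(gcode), length(scores))
  if (any(lens != n_snps))
    abort_format("%s: section lengths (%s) disagree with SNP count %d",
                 path, paste(lens, collapse = "/"), n_snps)
  if (any(gcode > 3L))
    abort_format("%s: invalid genotype byte code %d", path, max(gcode))

  list(sample_name = sample_name,
       records = data.frame(snp_index = seq_len(n_snps),
                            gtype = .gtc_gtypes[gcode + 1L],
                            score = scores, x_raw = x_raw, y_raw = y_raw,
                            transform_index = tindex),
       transforms = transforms)
}
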