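# Manifest and cluster-file readers. Both come in two dialects carrying the
# same fields: a plain TSV and a small length-prefixed binary subset (the
# full vendor BPM/EGT layouts hold much more than this pipeline consumes).

.manifest_magic <- charToRaw("MANB")
.cluster_magic  <- charToRaw("EGTB")
.cluster_gtypes <- c("AA", "AB", "BB")

.detect_dialect <- function(path, magic) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0L) abort_format("%s: empty file", path)
  head <- readBin(path, "raw", n = min(4L, sz))
  if (length(head) == 4L && identical(head, magic)) "binary" else "tabular"
}

#' Read a SNP manifest
#'
#' The manifest describes every SNP marker on the array: name, chromosome
#' token (autosome number, `"X"`, `"Y"`, `"MT"`, or `"0"` for non-genomic
#' placement), base-pair position, the generic A/B allele designation, and
#' whether the probe is intensity-only (copy-number signal, no genotype).
#' Nothing is filtered here; intensity-only and chromosome-`"0"` markers are
#' preserved verbatim for [filter_informative()] to act on later.
#'
#' @param path Path to a manifest in the tabular (TSV) or binary dialect.
#' @param dialect `"auto"` (detect from the magic bytes), `"tabular"` or
#'   `"binary"`.
#' @return Data frame with columns `name`, `chromosome` (character),
#'   `position`, `alleles`, `intensity_only`, one row per SNP.
#' @export
read_manifest <- function(path, dialect = c("auto", "tabular", "binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_parameter("no such file: %s", path)
  if (dialect == "auto") dialect <- .detect_dialect(path, .manifest_magic)

  if (dialect == "binary") {
    m <- .read_manifest_binary(path)
  } else {
    sz <- file.info(path)$size
    if (sz == 0L) abort_format("%s: empty file", path)
    m <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE,
                        colClasses = c(chromosome = "character")),
      error = function(e) abort_format("%s: not a tabular manifest (%s)",
                                       path, conditionMessage(e)))
    need <- c("name", "chromosome", "position", "alleles", "intensity_only")
    miss <- setdiff(need, names(m))
    if (length(miss))
      abort_format("%s: manifest is missing column(s): %s",
                   path, paste(miss, collapse = ", "))
    m <- m[need]
    m$intensity_only <- as.logical(m$intensity_only)
  }
  if (anyDuplicated(m$name))
    abort_integrity("%s: duplicate SNP name(s): %s", path,
                    paste(unique(m$name[duplicated(m$name)])[1:3], collapse = ", "))
  if (any(m$position < 0)) abort_integrity("%s: negative base-pair position", path)
  m
}

.read_manifest_binary <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 9L || !identical(bytes[1:4], .manifest_magic))
    abort_format("%s: bad manifest magic bytes at offset 0", path)
  con <- rawConnection(bytes); on.exit(close(con))
  seek(con, 4L)
  ver <- readBin(con, "integer", 1L, size = 1)
  if (ver != 1L) abort_format("%s: unsupported binary manifest version %d", path, ver)
  n <- readBin(con, "integer", 1L, size = 4, endian = "little")
  rd_str <- function() {
    nb <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (length(nb) == 0L || nb < 0L)
      abort_format("%s: truncated record at byte offset %d", path, seek(con))
    rawToChar(readBin(con, "raw", nb))
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- rd_str(); chr <- rd_str()
    pos <- readBin(con, "integer", 1L, size = 4, endian = "little")
    al <- rd_str()
    io <- readBin(con, "integer", 1L, size = 1)
    if (length(io) == 0L)
      abort_format("%s: truncated record %d at byte offset %d", path, i, seek(con))
    recs[[i]] <- data.frame(name = nm, chromosome = chr, position = pos,
                            alleles = al, intensity_only = io != 0L)
  }
  do.call(rbind, recs)
}

#' Write a SNP manifest fixture
#'
#' @param manifest Data frame as returned by [read_manifest()].
#' @param path Output path.
#' @param dialect `"tabular"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, dialect = c("tabular", "binary")) {
  dialect <- match.arg(dialect)
  need <- c("name", "chromosome", "position", "alleles", "intensity_only")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) abort_parameter("manifest missing column(s): %s",
                                    paste(miss, collapse = ", "))
  if (dialect == "tabular") {
    utils::write.table(manifest[need], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(.manifest_magic, con)
    writeBin(1L, con, size = 1)
    writeBin(nrow(manifest), con, size = 4, endian = "little")
    for (i in seq_len(nrow(manifest))) {
      .write_string(con, manifest$name[i])
      .write_string(con, as.character(manifest$chromosome[i]))
      writeBin(as.integer(manifest$position[i]), con, size = 4, endian = "little")
      .write_string(con, manifest$alleles[i])
      writeBin(as.integer(manifest$intensity_only[i]), con, size = 1)
    }
  }
  invisible(path)
}

#' Read a genotype-cluster file
#'
#' Population-derived per-SNP genotype cluster statistics in the MA feature
#' plane: for each SNP, the AA/AB/BB cluster centres (`mean_m`, `mean_a`) and
#' dispersions (`sd_m`, `sd_a`) in log2-intensity units.
#'
#' @inheritParams read_manifest
#' @return Long data frame with columns `snp_name`, `genotype`, `mean_m`,
#'   `mean_a`, `sd_m`, `sd_a` and exactly three rows (AA, AB, BB) per SNP.
#' @export
read_cluster <- function(path, dialect = c("auto", "tabular", "binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_parameter("no such file: %s", path)
  if (dialect == "auto") dialect <- .detect_dialect(path, .cluster_magic)

  if (dialect == "binary") {
    cl <- .read_cluster_binary(path)
  } else {
    if (file.info(path)$size == 0L) abort_format("%s: empty file", path)
    cl <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                   error = function(e) abort_format("%s: not a tabular cluster file (%s)",
                                                    path, conditionMessage(e)))
    need <- c("snp_name", "genotype", "mean_m", "mean_a", "sd_m", "sd_a")
    miss <- setdiff(need, names(cl))
    if (length(miss))
      abort_format("%s: cluster file is missing column(s): %s",
                   path, paste(miss, collapse = ", "))
    cl <- cl[need]
  }
  counts <- table(cl$snp_name)
  bad <- names(counts)[counts != 3L]
  if (length(bad) == 0L) {
    per <- tapply(cl$genotype, cl$snp_name,
                  function(g) identical(sort(g), .cluster_gtypes))
    bad <- names(per)[!per]
  }
  if (length(bad))
    abort_integrity("%s: SNP(s) without exactly one AA/AB/BB cluster each: %s",
                    path, paste(utils::head(bad, 3), collapse = ", "))
  if (any(cl$sd_m <= 0) || any(cl$sd_a <= 0))
    abort_integrity("%s: non-positive cluster dispersion for SNP(s): %s", path,
                    paste(utils::head(unique(cl$snp_name[cl$sd_m <= 0 | cl$sd_a <= 0]), 3),
                          collapse = ", "))
  cl
}

.read_cluster_binary <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 9L || !identical(bytes[1:4], .cluster_magic))
    abort_format("%s: bad cluster-file magic bytes at offset 0", path)
  con <- rawConnection(bytes); on.exit(close(con))
  seek(con, 4L)
  ver <- readBin(con, "integer", 1L, size = 1)
  if (ver != 1L) abort_format("%s: unsupported binary cluster version %d", path, ver)
  n <- readBin(con, "integer", 1L, size = 4, endian = "little")
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (length(nb) == 0L || nb < 0L)
      abort_format("%s: truncated record %d at byte offset %d", path, i, seek(con))
    nm <- rawToChar(readBin(con, "raw", nb))
    f <- readBin(con, "numeric", 12L, size = 4, endian = "little")
    if (length(f) < 12L)
      abort_format("%s: truncated statistics for SNP %s", path, nm)
    recs[[i]] <- data.frame(snp_name = nm, genotype = .cluster_gtypes,
                            mean_m = f[c(1, 5, 9)], mean_a = f[c(2, 6, 10)],
                            sd_m = f[c(3, 7, 11)], sd_a = f[c(4, 8, 12)])
  }
  do.call(rbind, recs)
}

#' Write a genotype-cluster fixture file
#'
#' @param clusters Long data frame as returned by [read_cluster()].
#' @inheritParams write_manifest
#' @return `path`, invisibly.
#' @export
write_cluster <- function(clusters, path, dialect = c("tabular", "binary")) {
  dialect <- match.arg(dialect)
  need <- c("snp_name", "genotype", "mean_m", "mean_a", "sd_m", "sd_a")
  miss <- setdiff(need, names(clusters))
  if (length(miss)) abort_parameter("clusters missing column(s): %s",
                                    paste(miss, collapse = ", "))
  if (dialect == "tabular") {
    utils::write.table(clusters[need], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    snps <- unique(clusters$snp_name)
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(.cluster_magic, con)
    writeBin(1L, con, size = 1)
    writeBin(length(snps), con, size = 4, endian = "little")
    for (s in snps) {
      sub <- clusters[clusters$snp_name == s, ]
      sub <- sub[match(.cluster_gtypes, sub$genotype), ]
      .write_string(con, s)
      writeBin(as.numeric(t(as.matrix(sub[c("mean_m", "mean_a", "sd_m", "sd_a")]))),
               con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' A user-provided CSV mapping sample identifiers to GTC files, optionally
#' with `individual` (the grouping key for per-individual model fitting;
#' defaults to the sample id when absent) and `family` metadata. Both the
#' vendor style with a `[Data]` section header and a plain headered CSV are
#' accepted; relative GTC paths are resolved against the sheet's directory.
#'
#' @param path Path to the sample-sheet CSV.
#' @return Data frame with columns `sample_id`, `gtc_path`, `individual`,
#'   `family` (`NA` when the sheet has no family column), in file order.
#' @export
read_samplesheet <- function(path) {
  if (!file.exists(path)) abort_parameter("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) abort_format("%s: empty file", path)
  dat <- which(tolower(trimws(lines)) == "[data]")
  if (length(dat)) {
    if (dat[1] == length(lines)) abort_format("%s: no rows after [Data] section", path)
    lines <- lines[(dat[1] + 1L):length(lines)]
  }
  sheet <- tryCatch(utils::read.csv(text = paste(lines, collapse = "\n"),
                                    stringsAsFactors = FALSE),
                    error = function(e) abort_format("%s: not a CSV sample sheet (%s)",
                                                     path, conditionMessage(e)))
  lc <- tolower(names(sheet))
  pick <- function(...) { w <- which(lc %in% c(...)); if (length(w)) sheet[[w[1]]] else NULL }
  sample_id <- pick("sample_id", "sampleid", "sample.id")
  gtc_path  <- pick("path", "gtc_path", "gtc")
  if (is.null(sample_id)) abort_format("%s: no sample id column", path)
  if (is.null(gtc_path))  abort_format("%s: no GTC path column", path)
  individual <- pick("individual"); family <- pick("family")
  out <- data.frame(sample_id = as.character(sample_id),
                    gtc_path = as.character(gtc_path),
                    individual = if (is.null(individual)) as.character(sample_id)
                                 else as.character(individual),
                    family = if (is.null(family)) NA_character_
                             else as.character(family))
  if (anyDuplicated(out$sample_id))
    abort_integrity("%s: duplicate sample id(s): %s", path,
                    paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  rel <- !file.exists(out$gtc_path)
  out$gtc_path[rel] <- file.path(dirname(path), out$gtc_path[rel])
  missing <- which(!file.exists(out$gtc_path))
  if (length(missing))
    abort_integrity("%s: row %d: GTC file not found: %s",
                    path, missing[1], out$gtc_path[missing[1]])
  out
}

#' Assemble a long-format genotype table from a sample batch
#'
#' Reads every GTC file named in the sample sheet, checks its record count
#' against the manifest, applies each record's affine normalization transform
#' and joins the manifest and sheet metadata into one long table with a row
#' per (sample, SNP).
#'
#' @param sheet Sample sheet as returned by [read_samplesheet()].
#' @param manifest Manifest as returned by [read_manifest()].
#' @param clusters Optional genotype-cluster table ([read_cluster()]);
#'   attached as the `"clusters"` attribute for downstream use.
#' @return Data frame with columns `sample_id`, `individual`, `family`,
#'   `Chr`, `Name`, `position`, `intensity_only`, `gtype`, `score`,
#'   `x_raw`, `y_raw`, `x`, `y`. Row count is `nrow(sheet) * nrow(manifest)`.
#' @export
assemble_table <- function(sheet, manifest, clusters = NULL) {
  n_snps <- nrow(manifest)
  parts <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    g <- read_gtc(sheet$gtc_path[i])
    if (nrow(g$records) != n_snps)
      abort_integrity("sample %s: GTC has %d records but the manifest lists %d SNPs",
                      sheet$sample_id[i], nrow(g$records), n_snps)
    r <- g$records
    x <- numeric(n_snps); y <- numeric(n_snps)
    for (ti in unique(r$transform_index)) {
      idx <- r$transform_index == ti
      norm <- apply_normalization(r$x_raw[idx], r$y_raw[idx], g$transforms[ti, ])
      x[idx] <- norm$x; y[idx] <- norm$y
    }
    parts[[i]] <- data.frame(
      sample_id = sheet$sample_id[i], individual = sheet$individual[i],
      family = sheet$family[i],
      Chr = manifest$chromosome, Name = manifest$name,
      position = manifest$position, intensity_only = manifest$intensity_only,
      gtype = r$gtype, score = r$score,
      x_raw = as.numeric(r$x_raw), y_raw = as.numeric(r$y_raw), x = x, y = y)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (!is.null(clusters)) attr(out, "clusters") <- clusters
  out
}

#' Write or read an assembled genotype table as CSV
#'
#' Thin CSV (de)serialization keeping the chromosome token a string (so
#' `"0"` survives a round trip) and the exact column names used throughout
#' the pipeline.
#'
#' @param t Genotype table ([assemble_table()]).
#' @param path CSV path.
#' @return `write_genotype_table()` returns `path` invisibly;
#'   `read_genotype_table()` returns the table.
#' @export
write_genotype_table <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) abort_parameter("no such file: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(Chr = "character"))
}
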