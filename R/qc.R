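#' Keep only informative, genotype-bearing SNPs
#'
#' Drops the records that carry no genotype information: chromosome token
#' `"0"` (non-genomic placement), SNP names containing the substring `"cnv"`
#' (case-sensitive, the naming convention for copy-number probes) and, when
#' the table carries the manifest flag, `intensity_only` probes. Idempotent.
#'
#' @param t Genotype table with `Chr` and `Name` columns.
#' @return The filtered table (possibly empty).
#' @export
filter_informative <- function(t) {
  if (!all(c("Chr", "Name") %in% names(t)))
    abort_parameter("table must have Chr and Name columns")
  keep <- t$Chr != "0" & !grepl("cnv", t$Name, fixed = TRUE)
  if ("intensity_only" %in% names(t)) keep <- keep & !t$intensity_only
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.gtype_levels <- c("AA", "AB", "BB", "NC")

.group_key <- function(t, group_by) {
  unknown <- setdiff(group_by, names(t))
  if (length(unknown))
    abort_parameter("unknown grouping column(s): %s", paste(unknown, collapse = ", "))
  if (!length(group_by)) return(rep("all", nrow(t)))
  do.call(paste, c(t[group_by], list(sep = "\r")))
}

.split_key <- function(keys, group_by) {
  if (!length(group_by)) return(data.frame(row.names = seq_along(keys)))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- group_by
  out
}

#' Genotype call rates by group
#'
#' For every group, the proportion of records in each genotype class (AA, AB,
#' BB, NC) over all records of the group, no-calls included in the
#' denominator. Proportions within a group therefore sum to 1.
#'
#' @param t Genotype table with a `gtype` column.
#' @param group_by Character vector of grouping columns (default
#'   `"individual"`).
#' @return Long data frame with the grouping columns, `gtype` and `Callrate`.
#' @export
#' @examples
#' t <- data.frame(individual = "a", gtype = c("AA", "AA", "AB", "NC"))
#' callrate(t)   # AA 0.50, AB 0.25, BB 0.00, NC 0.25
callrate <- function(t, group_by = "individual") {
  if (!"gtype" %in% names(t)) abort_parameter("table must have a gtype column")
  key <- .group_key(t, group_by)
  tab <- table(key, factor(t$gtype, levels = .gtype_levels))
  prop <- tab / rowSums(tab)
  keys <- rownames(prop)
  out <- cbind(
    .split_key(rep(keys, each = length(.gtype_levels)), group_by),
    data.frame(gtype = rep(.gtype_levels, times = length(keys)),
               Callrate = as.vector(t(unclass(prop)))))
  rownames(out) <- NULL
  out
}

#' Heterozygous-call fraction by group
#'
#' The AB fraction among called genotypes only (AA + AB + BB; NC excluded
#' from the denominator — deliberately a different contract from
#' [callrate()]). In haploid cells every AB call is an error, so this is a
#' direct read-out of allele drop-in noise. Groups with no called genotypes
#' report `NA`.
#'
#' @inheritParams callrate
#' @return Data frame with the grouping columns, `n_called` and `ab_fraction`.
#' @export
heterozygosity <- function(t, group_by = "individual") {
  if (!"gtype" %in% names(t)) abort_parameter("table must have a gtype column")
  key <- .group_key(t, group_by)
  called <- t$gtype != "NC"
  n_called <- tapply(called, key, sum)
  n_ab <- tapply(t$gtype == "AB", key, sum)
  keys <- names(n_called)
  out <- cbind(.split_key(keys, group_by),
               data.frame(n_called = as.integer(n_called),
                          ab_fraction = ifelse(n_called > 0,
                                               n_ab / n_called, NA_real_)))
  rownames(out) <- NULL
  out
}

#' PCA over complete-case genotype dosages
#'
#' Builds a samples-by-SNPs matrix from the SNPs called (non-NC) in every
#' sample, codes genotypes as allele-B dosage (AA = 0, AB = 1, BB = 2),
#' centres each SNP column and computes the top-`k` principal components.
#' Run on the whole table it validates sample kinship (families separate);
#' run per chromosome it can flag aneuploid chromosomes.
#'
#' @param t Genotype table with `sample_id`, `Name`, `Chr`, `gtype` columns.
#' @param k Number of components to keep.
#' @param by_chrom If `TRUE`, repeat the analysis independently per
#'   chromosome token.
#' @return An object of class `"genotype_pca"`: list with `scores` (data
#'   frame: `sample_id`, optionally `chrom`, `PC1..PCk`), `explained`
#'   (fractions of total variance; a named list per chromosome when
#'   `by_chrom`), `n_snps`, `k`, `by_chrom`.
#' @export
genotype_pca <- function(t, k = 2L, by_chrom = FALSE) {
  need <- c("sample_id", "Name", "gtype")
  if (by_chrom) need <- c(need, "Chr")
  miss <- setdiff(need, names(t))
  if (length(miss)) abort_parameter("table is missing column(s): %s",
                                    paste(miss, collapse = ", "))
  if (by_chrom) {
    chroms <- unique(t$Chr)
    per <- lapply(chroms, function(ch)
      genotype_pca(t[t$Chr == ch, , drop = FALSE], k = k, by_chrom = FALSE))
    scores <- do.call(rbind, Map(function(p, ch)
      cbind(data.frame(chrom = ch), p$scores), per, chroms))
    rownames(scores) <- NULL
    explained <- stats::setNames(lapply(per, `[[`, "explained"), chroms)
    n_snps <- stats::setNames(vapply(per, `[[`, 0L, "n_snps"), chroms)
    return(structure(list(scores = scores, explained = explained,
                          n_snps = n_snps, k = k, by_chrom = TRUE),
                     class = "genotype_pca"))
  }
  samples <- unique(t$sample_id)
  if (length(samples) < 2L) abort_parameter("PCA requires at least 2 samples")
  nc_snps <- unique(t$Name[t$gtype == "NC"])
  keep <- !(t$Name %in% nc_snps)
  if (!any(keep))
    abort_parameter("no SNP is called in every sample; nothing to decompose")
  sub <- t[keep, c("sample_id", "Name", "gtype")]
  dosage <- c(AA = 0, AB = 1, BB = 2)[sub$gtype]
  snps <- unique(sub$Name)
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(snps),
              dimnames = list(samples, snps))
  m[cbind(match(sub$sample_id, samples), match(sub$Name, snps))] <- dosage
  if (anyNA(m))
    abort_integrity("genotype table has missing (sample, SNP) combinations")
  k_eff <- min(k, nrow(m) - 1L, ncol(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = k_eff)
  scores <- data.frame(sample_id = samples, pc$x[, seq_len(k_eff), drop = FALSE])
  rownames(scores) <- NULL
  structure(list(scores = scores,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 n_snps = length(snps), k = k_eff, by_chrom = FALSE),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  if (x$by_chrom) {
    cat("Genotype PCA per chromosome:", length(x$explained), "chromosomes,",
        "k =", x$k, "\n")
  } else {
    cat("Genotype PCA:", nrow(x$scores), "samples,", x$n_snps,
        "complete-case SNPs, k =", x$k, "\n")
    ev <- x$explained[seq_len(x$k)]
    cat("Explained variance:", paste(sprintf("PC%d %.1f%%", seq_along(ev),
                                             100 * ev), collapse = ", "), "\n")
  }
  invisible(x)
}
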