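# Generative model of single-cell SNP-array batches under whole-genome
# amplification noise. Haploid mode emulates a sperm batch: each sample
# inherits one allele per SNP from its family's donor, so any heterozygous
# call is by construction an allele drop-in error. The emitted fixture set
# (manifest, cluster file, sample sheet, one GTC per sample) feeds the same
# loaders as a real batch, and the truth table labels every call.

.sim_gtype_keys <- c("AA", "AB", "BB", "ADI", "NC")

#' Default cluster geometry for the simulator
#'
#' Cluster centres and dispersions in the (m, a) log2 feature plane:
#' homozygotes on the +4 / -4 ridges at high average intensity, true
#' heterozygotes at m = 0, and the allele drop-in artifact cluster at m near
#' 0 with low a and inflated variance. The NC row places no-call records in
#' the same low-intensity region.
#'
#' @return Data frame with columns `genotype`, `mean_m`, `mean_a`, `sd_m`,
#'   `sd_a`.
#' @export
sim_geometry <- function() {
  data.frame(genotype = .sim_gtype_keys,
             mean_m = c(4, 0, -4, 0, 0),
             mean_a = c(10, 10, 10, 7, 7),
             sd_m = c(0.5, 0.5, 0.5, 0.8, 1.0),
             sd_a = c(0.5, 0.5, 0.5, 0.8, 1.0))
}

#' Simulation configuration
#'
#' Bundles the generative parameters of a synthetic batch. The defaults are
#' the package's standard study conditions: 23 haploid (sperm) single-cell
#' samples from two families on a 20,000-SNP array, multiple-displacement
#' amplification noise with allele drop-out rate 0.20 (within the up-to-30%
#' prevalence reported for WGA; inert in haploid mode, where no true
#' heterozygote exists), allele drop-in rate 0.10 and a 5% baseline no-call
#' rate.
#'
#' @param n_samples,n_snps Batch dimensions.
#' @param ploidy `"haploid"` (sperm-like; true genotypes are AA/BB only) or
#'   `"diploid"` (Hardy-Weinberg draws).
#' @param families Data frame with columns `name` and `n` (sample counts
#'   summing to `n_samples`), or `NULL` to split `n_samples` near-evenly
#'   over `n_families`.
#' @param n_families Number of families when `families` is `NULL`.
#' @param ado_rate Probability a true heterozygous template drops to a
#'   homozygous call (allele drop-out).
#' @param adi_rate Probability a true homozygous template acquires a
#'   spurious heterozygous call (allele drop-in).
#' @param nc_rate Baseline no-call probability per call.
#' @param intensity_only_fraction Fraction of markers that are
#'   intensity-only copy-number probes (named `cnvi*`, chromosome `"0"`,
#'   always NC).
#' @param geometry Cluster geometry, see [sim_geometry()].
#' @param score_shapes Beta shape pairs for the simulated GenCall score:
#'   list with `correct`, `error` and `nc` components. The defaults put the
#'   correct-call mode near 0.8 and the error mode near 0.45, giving the
#'   baseline score genuine but imperfect discrimination.
#' @param seed Master seed; every random sub-stream derives from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 23L, n_snps = 20000L,
                       ploidy = c("haploid", "diploid"),
                       families = NULL, n_families = 2L,
                       ado_rate = 0.20, adi_rate = 0.10, nc_rate = 0.05,
                       intensity_only_fraction = 0.01,
                       geometry = sim_geometry(),
                       score_shapes = list(correct = c(8, 2.75),
                                           error = c(5.5, 6.5),
                                           nc = c(2, 8)),
                       seed = 1L) {
  ploidy <- match.arg(ploidy)
  rates <- c(ado_rate = ado_rate, adi_rate = adi_rate, nc_rate = nc_rate,
             intensity_only_fraction = intensity_only_fraction)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    abort_parameter("rates must lie in [0, 1]")
  if (is.null(families)) {
    n_fam <- as.integer(n_families)
    base <- n_samples %/% n_fam
    extra <- n_samples %% n_fam
    families <- data.frame(name = paste0("F", seq_len(n_fam)),
                           n = base + as.integer(seq_len(n_fam) <= extra))
  }
  if (!all(c("name", "n") %in% names(families)) || sum(families$n) != n_samples)
    abort_parameter("families must have name and n columns with counts summing to n_samples")
  need <- c("genotype", "mean_m", "mean_a", "sd_m", "sd_a")
  if (!all(need %in% names(geometry)) ||
      !all(.sim_gtype_keys %in% geometry$genotype))
    abort_parameter("geometry must define mean/sd rows for %s",
                    paste(.sim_gtype_keys, collapse = ", "))
  if (any(geometry$sd_m <= 0) || any(geometry$sd_a <= 0))
    abort_parameter("cluster geometry dispersions must be strictly positive")
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 ploidy = ploidy, families = families,
                 ado_rate = ado_rate, adi_rate = adi_rate, nc_rate = nc_rate,
                 intensity_only_fraction = intensity_only_fraction,
                 geometry = geometry, score_shapes = score_shapes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic batch:", x$n_samples, x$ploidy, "samples x", x$n_snps,
      "SNPs,", nrow(x$families), "families\n")
  cat(sprintf("ADO %.2f  ADI %.2f  NC %.2f  intensity-only %.3f  seed %d\n",
              x$ado_rate, x$adi_rate, x$nc_rate, x$intensity_only_fraction,
              x$seed))
  invisible(x)
}

#' Simulate a single-cell SNP-array batch with WGA noise
#'
#' Draws true genotypes per family allele-frequency profile (haploid: one
#' allele inherited from the family donor; diploid: Hardy-Weinberg), applies
#' allele drop-out then drop-in corruption plus baseline no-calls, draws
#' each observed call's (m, a) features from its cluster Gaussian (drop-in
#' errors from the low-a artifact cluster), back-transforms to normalized
#' intensities, inverts a randomly drawn per-sample affine transform to
#' produce the raw intensities, and assigns GenCall-like Beta scores (higher
#' for correct calls). The fixture set written to `dir` loads through the
#' regular pipeline: manifest TSV, cluster TSV, sample sheet CSV, one GTC
#' per sample, truth-table CSV and the effective configuration as YAML.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the fixture paths (`manifest`, `cluster`,
#'   `samplesheet`, `gtc`, `truth_path`, `config_path`, `dir`) and the truth
#'   table itself (`truth`: columns `sample_id`, `Name`, `true_gtype`,
#'   `observed_gtype`, `error_class`).
#' @export
simulate_batch <- function(config = sim_config(), dir = tempfile("scgeno_batch")) {
  if (!inherits(config, "sim_config")) abort_parameter("config must be a sim_config")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  n_io <- round(config$intensity_only_fraction * config$n_snps)
  n_inf <- config$n_snps - n_io
  manifest <- data.frame(
    name = c(sprintf("rs%07d", seq_len(n_inf)),
             if (n_io) sprintf("cnvi%05d", seq_len(n_io))),
    chromosome = c(sample(as.character(1:22), n_inf, replace = TRUE),
                   rep("0", n_io)),
    position = sample.int(240000000L, config$n_snps, replace = TRUE),
    alleles = "AB",
    intensity_only = rep(c(FALSE, TRUE), c(n_inf, n_io)))

  freq <- stats::rbeta(n_inf, 2, 2)   # population B-allele frequency
  fam_of_sample <- rep(config$families$name, config$families$n)
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))

  # Family-level genetics: in haploid mode each family has a diploid donor
  # whose two allele columns the samples inherit from; in diploid mode each
  # family perturbs the population frequency on the logit scale.
  fam_gen <- lapply(seq_len(nrow(config$families)), function(i) {
    if (config$ploidy == "haploid") {
      list(a1 = stats::rbinom(n_inf, 1L, freq), a2 = stats::rbinom(n_inf, 1L, freq))
    } else {
      list(freq = stats::plogis(stats::qlogis(freq) + stats::rnorm(n_inf, 0, 0.5)))
    }
  })
  names(fam_gen) <- config$families$name

  geo <- config$geometry[match(.sim_gtype_keys, config$geometry$genotype), ]
  rownames(geo) <- geo$genotype

  gtc_paths <- character(config$n_samples)
  truth_parts <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    fam <- fam_gen[[fam_of_sample[s]]]
    if (config$ploidy == "haploid") {
      pick <- stats::rbinom(n_inf, 1L, 0.5)
      allele <- ifelse(pick == 1L, fam$a2, fam$a1)
      true_g <- ifelse(allele == 1L, "BB", "AA")
    } else {
      dosage <- stats::rbinom(n_inf, 2L, fam$freq)
      true_g <- c("AA", "AB", "BB")[dosage + 1L]
    }

    obs <- true_g
    cls <- rep("correct", n_inf)
    u_nc <- stats::runif(n_inf); u_err <- stats::runif(n_inf)
    flip <- stats::runif(n_inf)
    is_nc <- u_nc < config$nc_rate
    is_ado <- !is_nc & true_g == "AB" & u_err < config$ado_rate
    is_adi <- !is_nc & true_g != "AB" & u_err < config$adi_rate
    obs[is_ado] <- ifelse(flip[is_ado] < 0.5, "AA", "BB")
    cls[is_ado] <- "ADO"
    obs[is_adi] <- "AB"
    cls[is_adi] <- "ADI"
    obs[is_nc] <- "NC"
    cls[is_nc] <- "NC"

    # intensity-only probes never yield a genotype
    obs_all <- c(obs, rep("NC", n_io))
    cls_all <- c(cls, rep("NC", n_io))
    true_all <- c(true_g, rep(NA_character_, n_io))

    cluster_key <- ifelse(cls_all == "ADI", "ADI",
                          ifelse(cls_all == "NC", "NC", obs_all))
    m <- stats::rnorm(config$n_snps, geo[cluster_key, "mean_m"],
                      geo[cluster_key, "sd_m"])
    a <- stats::rnorm(config$n_snps, geo[cluster_key, "mean_a"],
                      geo[cluster_key, "sd_a"])
    shapes <- config$score_shapes
    sc_key <- ifelse(cls_all == "correct", "correct",
                     ifelse(cls_all == "NC", "nc", "error"))
    sc_par <- do.call(rbind, shapes)[sc_key, , drop = FALSE]
    score <- .quantize_float32(stats::rbeta(config$n_snps, sc_par[, 1], sc_par[, 2]))

    tr <- normalization_transform(
      offset_x = stats::runif(1, 0, 60), offset_y = stats::runif(1, 0, 60),
      theta = stats::runif(1, -0.08, 0.08), shear = stats::runif(1, 0, 0.05),
      scale_x = stats::runif(1, 0.9, 1.1), scale_y = stats::runif(1, 0.9, 1.1))
    raw <- invert_normalization(2^(a + m / 2), 2^(a - m / 2), tr)
    x_raw <- pmin(pmax(round(raw$x_raw), 0), 65535)
    y_raw <- pmin(pmax(round(raw$y_raw), 0), 65535)

    gtc_paths[s] <- file.path(dir, paste0(sample_ids[s], ".gtc"))
    write_gtc(data.frame(gtype = obs_all, score = score,
                         x_raw = x_raw, y_raw = y_raw,
                         transform_index = 1L),
              tr, gtc_paths[s], sample_name = sample_ids[s])
    truth_parts[[s]] <- data.frame(sample_id = sample_ids[s],
                                   Name = manifest$name,
                                   true_gtype = true_all,
                                   observed_gtype = obs_all,
                                   error_class = cls_all)
  }
  truth <- do.call(rbind, truth_parts)
  rownames(truth) <- NULL

  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  clusters <- data.frame(
    snp_name = rep(manifest$name[seq_len(n_inf)], each = 3L),
    genotype = rep(c("AA", "AB", "BB"), n_inf),
    mean_m = rep(geo[c("AA", "AB", "BB"), "mean_m"], n_inf),
    mean_a = rep(geo[c("AA", "AB", "BB"), "mean_a"], n_inf),
    sd_m = rep(geo[c("AA", "AB", "BB"), "sd_m"], n_inf),
    sd_a = rep(geo[c("AA", "AB", "BB"), "sd_a"], n_inf))
  cluster_path <- file.path(dir, "cluster.tsv")
  write_cluster(clusters, cluster_path)

  sheet_path <- file.path(dir, "samplesheet.csv")
  writeLines(c("[Data]",
               "Sample_ID,Path,Individual,Family",
               paste(sample_ids, basename(gtc_paths), sample_ids,
                     fam_of_sample, sep = ",")),
             sheet_path)

  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    n_samples = config$n_samples, n_snps = config$n_snps,
    ploidy = config$ploidy,
    families = as.list(stats::setNames(config$families$n, config$families$name)),
    ado_rate = config$ado_rate, adi_rate = config$adi_rate,
    nc_rate = config$nc_rate,
    intensity_only_fraction = config$intensity_only_fraction,
    geometry = lapply(split(config$geometry, config$geometry$genotype),
                      function(g) as.list(g[c("mean_m", "mean_a", "sd_m", "sd_a")])),
    score_shapes = config$score_shapes,
    seed = config$seed), config_path)

  invisible(list(dir = dir, manifest = manifest_path, cluster = cluster_path,
                 samplesheet = sheet_path, gtc = gtc_paths,
                 truth = truth, truth_path = truth_path,
                 config_path = config_path, config = config))
}

#' Correctness labels for a genotype table from a truth table
#'
#' Joins a truth table onto an assembled genotype table (by sample and SNP)
#' and returns, per row, whether the observed call is correct: called
#' (non-NC) and equal to the true genotype. No-call rows get `NA` (their
#' correctness is undefined; they are excluded from forest training).
#'
#' @param t Genotype table with `sample_id` and `Name`.
#' @param truth Truth table from [simulate_batch()].
#' @return Logical vector, one entry per row of `t`.
#' @export
truth_labels <- function(t, truth) {
  key_t <- paste(t$sample_id, t$Name, sep = "\r")
  key_u <- paste(truth$sample_id, truth$Name, sep = "\r")
  idx <- match(key_t, key_u)
  if (anyNA(idx))
    abort_integrity("%d table row(s) have no matching truth record", sum(is.na(idx)))
  correct <- t$gtype != "NC" & t$gtype == truth$true_gtype[idx]
  correct[t$gtype == "NC"] <- NA
  correct
}

#' Precision, recall and error retention against simulation truth
#'
#' Applies [set_threshold()] at the given threshold for each score column
#' and measures, against the truth table: precision (correct retained /
#' all retained), recall (correct retained / all correct calls) and the
#' retention of allele drop-in errors (ADI retained / all ADI).
#'
#' @param scored Unthresholded genotype table carrying the score columns.
#' @param truth Truth table from [simulate_batch()].
#' @param score_cols Score columns to evaluate, one result row each.
#' @param threshold Threshold applied to each score column.
#' @return Data frame with columns `alg`, `threshold`, `precision`,
#'   `recall`, `adi_retention`, `n_retained`, `n_called`.
#' @export
evaluate_against_truth <- function(scored, truth,
                                   score_cols = c("rfgda_score", "score"),
                                   threshold = 0.5) {
  key_t <- paste(scored$sample_id, scored$Name, sep = "\r")
  key_u <- paste(truth$sample_id, truth$Name, sep = "\r")
  idx <- match(key_t, key_u)
  if (anyNA(idx))
    abort_integrity("%d scored row(s) have no matching truth record", sum(is.na(idx)))
  tru <- truth[idx, ]
  called <- scored$gtype != "NC"
  correct <- called & scored$gtype == tru$true_gtype
  is_adi <- tru$error_class == "ADI" & called

  out <- lapply(score_cols, function(alg) {
    st <- set_threshold(scored, alg, threshold)
    retained <- called & st$gtype != "NC"
    data.frame(alg = alg, threshold = threshold,
               precision = sum(correct & retained) / sum(retained),
               recall = sum(correct & retained) / sum(correct),
               adi_retention = if (any(is_adi))
                 sum(is_adi & retained) / sum(is_adi) else NA_real_,
               n_retained = sum(retained), n_called = sum(called))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
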