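test_that("noise-free limit: every call correct, observed equals truth", {
  batch <- small_batch(n_samples = 3L, n_snps = 1000L, seed = 51L,
                       ado_rate = 0, adi_rate = 0, nc_rate = 0,
                       intensity_only_fraction = 0)
  expect_true(all(batch$truth$error_class == "correct"))
  expect_identical(batch$truth$observed_gtype, batch$truth$true_gtype)
  t <- load_batch(batch)
  expect_true(all(t$gtype != "NC"))
})

test_that("error taxonomy matches its definitions and haploid truth never holds AB", {
  batch <- small_batch(n_samples = 5L, n_snps = 3000L, seed = 52L,
                       ploidy = "haploid")
  tr <- batch$truth
  expect_false(any(tr$true_gtype == "AB", na.rm = TRUE))
  adi <- tr[tr$error_class == "ADI", ]
  expect_true(all(adi$true_gtype %in% c("AA", "BB") & adi$observed_gtype == "AB"))
  expect_true(all(tr$observed_gtype[tr$error_class == "NC"] == "NC"))

  dip <- small_batch(n_samples = 4L, n_snps = 3000L, seed = 53L,
                     ploidy = "diploid")
  ado <- dip$truth[dip$truth$error_class == "ADO", ]
  expect_gt(nrow(ado), 0)
  expect_true(all(ado$true_gtype == "AB" &
                    ado$observed_gtype %in% c("AA", "BB")))
})

test_that("marginal error rates converge to the configured rates", {
  batch <- simulate_batch(sim_config(n_samples = 1L, n_snps = 20000L,
                                     ploidy = "diploid", n_families = 1L,
                                     ado_rate = 0.2, adi_rate = 0.1,
                                     nc_rate = 0.05,
                                     intensity_only_fraction = 0, seed = 54L),
                          tempfile())
  tr <- batch$truth
  n <- nrow(tr)
  band <- function(p) 3 * sqrt(p * (1 - p) / n)
  nc <- mean(tr$error_class == "NC")
  expect_lt(abs(nc - 0.05), band(0.05))
  het <- tr$true_gtype == "AB" & tr$error_class != "NC"
  expect_lt(abs(mean(tr$error_class[het] == "ADO") - 0.2),
            3 * sqrt(0.2 * 0.8 / sum(het)))
  hom <- tr$true_gtype != "AB" & tr$error_class != "NC"
  expect_lt(abs(mean(tr$error_class[hom] == "ADI") - 0.1),
            3 * sqrt(0.1 * 0.9 / sum(hom)))
})

test_that("assembling the emitted fixtures reproduces the generated calls exactly", {
  batch <- small_batch(n_samples = 3L, n_snps = 800L, seed = 55L)
  t <- load_batch(batch)
  expect_equal(nrow(t), 3L * 800L)
  key_t <- paste(t$sample_id, t$Name)
  key_u <- paste(batch$truth$sample_id, batch$truth$Name)
  idx <- match(key_t, key_u)
  expect_false(anyNA(idx))
  expect_identical(t$gtype, batch$truth$observed_gtype[idx])
})

test_that("the default preset is the 23-sample two-family haploid study design", {
  cfg <- sim_config()
  expect_equal(cfg$n_samples, 23L)
  expect_equal(cfg$n_snps, 20000L)
  expect_identical(cfg$ploidy, "haploid")
  expect_equal(cfg$families$n, c(12L, 11L))
  expect_equal(cfg$adi_rate, 0.10)
  expect_equal(cfg$ado_rate, 0.20)
  expect_lte(cfg$ado_rate, 0.30)

  batch <- small_batch(n_samples = 23L, n_snps = 120L, seed = 56L)
  sheet <- read_samplesheet(batch$samplesheet)
  expect_equal(nrow(sheet), 23L)
  expect_equal(sort(unique(sheet$family)), c("F1", "F2"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(adi_rate = 1.5), class = "scgeno_parameter_error")
  geo <- sim_geometry(); geo$sd_m[1] <- 0
  expect_error(sim_config(geometry = geo), class = "scgeno_parameter_error")
  expect_error(sim_config(families = data.frame(name = "F1", n = 5L),
                          n_samples = 23L),
               class = "scgeno_parameter_error")
})

test_that("truth evaluation: boundary thresholds and a perfect scorer", {
  batch <- small_batch(n_samples = 3L, n_snps = 1500L, seed = 57L)
  t <- filter_informative(load_batch(batch))
  idx <- match(paste(t$sample_id, t$Name),
               paste(batch$truth$sample_id, batch$truth$Name))
  t$oracle <- as.numeric(t$gtype != "NC" &
                           t$gtype == batch$truth$true_gtype[idx])

  # threshold 0 retains every called genotype
  ev0 <- evaluate_against_truth(t, batch$truth, "score", threshold = 0)
  expect_equal(ev0$recall, 1)
  expect_equal(ev0$n_retained, ev0$n_called)

  # the correctness indicator as score gives perfect precision at 0.5
  ev <- evaluate_against_truth(t, batch$truth, "oracle", threshold = 0.5)
  expect_equal(ev$precision, 1)
  expect_equal(ev$adi_retention, 0)

  # a random score has precision near the base correctness rate
  set.seed(58); t$noise <- runif(nrow(t))
  evr <- evaluate_against_truth(t, batch$truth, "noise", threshold = 0.5)
  base <- mean(t$oracle[t$gtype != "NC"])
  expect_lt(abs(evr$precision - base), 0.03)

  expect_error(evaluate_against_truth(t[1:10, ], batch$truth[1:5, ], "score"),
               class = "scgeno_integrity_error")
})

test_that("identical seeds give byte-identical fixture sets", {
  cfg <- sim_config(n_samples = 3L, n_snps = 500L, seed = 59L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_batch(cfg, d1)
  simulate_batch(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})
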