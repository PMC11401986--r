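test_that("informative filter keeps exactly the genotype-bearing rows and is idempotent", {
  t <- data.frame(Chr = c("1", "0", "5", "X"),
                  Name = c("rs1", "rs2", "cnvi123", "rs3"))
  f <- filter_informative(t)
  expect_equal(f$Name, c("rs1", "rs3"))
  expect_identical(filter_informative(f), f)

  # no offending rows: unchanged
  clean <- data.frame(Chr = c("1", "2"), Name = c("rs1", "rs2"))
  expect_identical(filter_informative(clean), clean)

  # all rows chromosome "0": empty result, no error
  expect_equal(nrow(filter_informative(data.frame(Chr = "0", Name = "rs1"))), 0L)

  # the match is case-sensitive, as in the naming convention
  upper <- data.frame(Chr = "1", Name = "CNVI1")
  expect_equal(nrow(filter_informative(upper)), 1L)

  # manifest intensity-only flag also drops rows
  flagged <- data.frame(Chr = "1", Name = c("rs1", "rs9"),
                        intensity_only = c(FALSE, TRUE))
  expect_equal(filter_informative(flagged)$Name, "rs1")
})

test_that("call rate is the per-class proportion over all records including no-calls", {
  t <- toy_table(c("AA", "AA", "AB", "NC"))
  cr <- callrate(t)
  expect_equal(cr$Callrate[match(c("AA", "AB", "BB", "NC"), cr$gtype)],
               c(0.50, 0.25, 0.00, 0.25))

  all_nc <- callrate(toy_table(rep("NC", 5)))
  expect_equal(all_nc$Callrate[all_nc$gtype == "NC"], 1)
  expect_equal(sum(all_nc$Callrate), 1)

  expect_error(callrate(t, group_by = "nonexistent"),
               class = "scgeno_parameter_error")
})

test_that("grouped call rates match an independent tally and sum to one", {
  set.seed(21)
  for (rep in 1:20) {
    t <- data.frame(individual = sample(letters[1:3], 200, replace = TRUE),
                    gtype = sample(c("AA", "AB", "BB", "NC"), 200,
                                   replace = TRUE,
                                   prob = runif(4)))
    cr <- callrate(t)
    sums <- tapply(cr$Callrate, cr$individual, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
    oracle <- callrate_oracle(t, "individual")
    merged <- merge(cr, oracle, by.x = c("individual", "gtype"),
                    by.y = c("group", "gtype"))
    expect_equal(merged$Callrate, merged$prop)
  }
})

test_that("heterozygosity uses called genotypes only and flags empty groups", {
  expect_equal(heterozygosity(toy_table(c("AA", "AB", "NC", "BB", "AB")))$ab_fraction,
               0.5)
  expect_equal(heterozygosity(toy_table(rep("AA", 4)))$ab_fraction, 0)
  expect_true(is.na(heterozygosity(toy_table(rep("NC", 3)))$ab_fraction))
})

test_that("haploid ADI simulation yields the configured heterozygosity", {
  batch <- small_batch(n_samples = 4L, n_snps = 5000L, seed = 31L,
                       adi_rate = 0.1, ado_rate = 0, nc_rate = 0,
                       intensity_only_fraction = 0)
  t <- filter_informative(load_batch(batch))
  het <- heterozygosity(t, group_by = character(0))
  # binomial tolerance: 3 SDs around the drop-in rate
  tol <- 3 * sqrt(0.1 * 0.9 / nrow(t))
  expect_lt(abs(het$ab_fraction - 0.1), tol)
})

test_that("PCA places duplicated samples at the same point", {
  set.seed(5)
  g <- sample(c("AA", "AB", "BB"), 50, replace = TRUE)
  t <- data.frame(sample_id = rep(c("s1", "s2", "s3"), each = 50),
                  Name = rep(sprintf("rs%d", 1:50), 3),
                  gtype = c(g, g, sample(c("AA", "AB", "BB"), 50, TRUE)))
  p <- genotype_pca(t, k = 2)
  xy <- as.matrix(p$scores[, c("PC1", "PC2")])
  expect_equal(xy[1, ], xy[2, ], tolerance = 1e-9)
  expect_true(all(diff(p$explained) < 1e-12))   # non-increasing
  expect_lte(sum(p$explained), 1 + 1e-12)
})

test_that("PCA is invariant to row order up to component sign", {
  batch <- small_batch(n_samples = 5L, n_snps = 800L, seed = 13L)
  t <- filter_informative(load_batch(batch))
  p1 <- genotype_pca(t, k = 2)
  set.seed(1)
  p2 <- genotype_pca(t[sample.int(nrow(t)), ], k = 2)
  m2 <- as.matrix(p2$scores[match(p1$scores$sample_id, p2$scores$sample_id),
                            c("PC1", "PC2")])
  m1 <- as.matrix(p1$scores[, c("PC1", "PC2")])
  for (j in 1:2)
    expect_equal(unname(abs(m1[, j])), unname(abs(m2[, j])), tolerance = 1e-9)
})

test_that("per-chromosome PCA returns one decomposition per chromosome", {
  set.seed(6)
  t <- data.frame(sample_id = rep(c("s1", "s2", "s3"), each = 60),
                  Chr = rep(rep(c("1", "2", "3"), each = 20), 3),
                  Name = rep(sprintf("rs%d", 1:60), 3),
                  gtype = sample(c("AA", "AB", "BB"), 180, replace = TRUE))
  p <- genotype_pca(t, k = 2, by_chrom = TRUE)
  expect_length(p$explained, 3L)
  expect_equal(sort(unique(p$scores$chrom)), c("1", "2", "3"))
  expect_equal(nrow(p$scores), 9L)
})

test_that("PCA fails informatively with no complete-case SNPs or one sample", {
  t <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                  Name = rep(c("rs1", "rs2"), 2),
                  gtype = c("AA", "NC", "NC", "AA"))
  expect_error(genotype_pca(t), "every sample", class = "scgeno_parameter_error")
  expect_error(genotype_pca(t[t$sample_id == "s1", ]),
               class = "scgeno_parameter_error")
})

test_that("two simulated families separate in the first two components", {
  t <- study_table()
  p <- genotype_pca(t, k = 2)
  fam <- t$family[match(p$scores$sample_id, t$sample_id)]
  d <- as.matrix(p$scores[, c("PC1", "PC2")])
  within <- mean(dist(d[fam == fam[1], ]))
  between <- mean(as.matrix(dist(d))[fam == fam[1], fam != fam[1]])
  expect_gt(between, within)
})
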