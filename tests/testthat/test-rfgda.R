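# Feature tables drawn from two known Gaussian classes in the (m, a) plane,
# with an oracle first layer (probability = class indicator).
gda_toy <- function(n, mu_pos = c(4, 10), mu_neg = c(0, 7),
                    sd_pos = 0.5, sd_neg = 0.8, individual = "a", seed = 1) {
  set.seed(seed)
  n_pos <- round(0.8 * n); n_neg <- n - n_pos
  data.frame(
    individual = individual,
    gtype = "AA",
    m = c(rnorm(n_pos, mu_pos[1], sd_pos), rnorm(n_neg, mu_neg[1], sd_neg)),
    a = c(rnorm(n_pos, mu_pos[2], sd_pos), rnorm(n_neg, mu_neg[2], sd_neg)),
    rf_prob = rep(c(1, 0), c(n_pos, n_neg)),
    truth = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}

test_that("forest separates disjoint classes and is deterministic under a fixed seed", {
  t <- gda_toy(2000, seed = 2)
  rf <- train_rf(t, t$truth, features = c("m", "a"), seed = 5)
  p <- predict(rf, t)
  expect_gt(mean((p > 0.5) == t$truth), 0.99)
  rf2 <- train_rf(t, t$truth, features = c("m", "a"), seed = 5)
  expect_identical(predict(rf2, t), p)
})

test_that("forest trained on permuted labels has no out-of-sample skill", {
  t <- gda_toy(3000, seed = 3)
  set.seed(9)
  shuffled <- sample(t$truth)
  rf <- train_rf(t[1:2000, ], shuffled[1:2000], features = c("m", "a"), seed = 5)
  p <- predict(rf, t[2001:3000, ])
  acc <- mean((p > 0.5) == t$truth[2001:3000])
  base <- max(mean(t$truth[2001:3000]), 1 - mean(t$truth[2001:3000]))
  expect_lt(abs(acc - base), 0.35)   # no better than majority guessing
})

test_that("single-class labels are a training error", {
  t <- gda_toy(100)
  expect_error(train_rf(t, rep(TRUE, nrow(t)), features = c("m", "a")),
               class = "scgeno_model_error")
})

test_that("GDA recovers the generating class means", {
  t <- gda_toy(20000, seed = 4)
  g <- fit_gda(t, prob_col = "rf_prob", features = c("m", "a"))
  l <- g$layers[["a"]]
  # standard errors of the class means
  se_pos <- 0.5 / sqrt(l$n_pos); se_neg <- 0.8 / sqrt(l$n_neg)
  expect_lt(max(abs(l$mu_pos - c(4, 10))), 3 * se_pos)
  expect_lt(max(abs(l$mu_neg - c(0, 7))), 3 * se_neg)
  expect_equal(l$pi_pos + l$pi_neg, 1)
  expect_identical(l$source, "individual")
})

test_that("individuals below the minimum class count fall back to a flagged pooled layer", {
  big <- gda_toy(5000, individual = "big", seed = 6)
  small <- gda_toy(10, individual = "tiny", seed = 7)
  g <- fit_gda(rbind(big, small), prob_col = "rf_prob", features = c("m", "a"))
  expect_identical(g$layers[["tiny"]]$source, "pooled")
  expect_identical(g$pooled_individuals, "tiny")
  expect_identical(g$layers[["big"]]$source, "individual")

  # nothing reaches the minimum even pooled: model error
  expect_error(fit_gda(small, prob_col = "rf_prob", features = c("m", "a")),
               class = "scgeno_model_error")
})

test_that("identical data for two individuals yields identical layers", {
  a <- gda_toy(3000, individual = "a", seed = 8)
  b <- a; b$individual <- "b"
  g <- fit_gda(rbind(a, b), prob_col = "rf_prob", features = c("m", "a"))
  la <- g$layers[["a"]]; lb <- g$layers[["b"]]
  expect_identical(la[c("mu_pos", "Sigma_pos", "mu_neg", "Sigma_neg", "pi_pos")],
                   lb[c("mu_pos", "Sigma_pos", "mu_neg", "Sigma_neg", "pi_pos")])
})

test_that("corrupting one individual's features leaves the other layers untouched", {
  a <- gda_toy(3000, individual = "a", seed = 10)
  b <- gda_toy(3000, individual = "b", seed = 11)
  g1 <- fit_gda(rbind(a, b), prob_col = "rf_prob", features = c("m", "a"))
  b_bad <- b; b_bad$m <- b_bad$m + 50   # gross outliers in one individual
  g2 <- fit_gda(rbind(a, b_bad), prob_col = "rf_prob", features = c("m", "a"))
  expect_identical(g1$layers[["a"]], g2$layers[["a"]])
  expect_false(identical(g1$layers[["b"]], g2$layers[["b"]]))
})

test_that("posterior geometry: mean dominance, midpoint symmetry, complement rule", {
  # mirrored construction: both classes share the same centred cloud, so the
  # fitted covariances are equal and the midpoint is exactly equidistant
  set.seed(12)
  Z <- matrix(rnorm(2 * 2000, sd = 0.5), ncol = 2)
  mu1 <- c(4, 10); mu2 <- c(0, 7)
  t <- data.frame(individual = "a", gtype = "AA",
                  m = c(Z[, 1] + mu1[1], Z[, 1] + mu2[1]),
                  a = c(Z[, 2] + mu1[2], Z[, 2] + mu2[2]),
                  rf_prob = rep(c(1, 0), each = 2000))
  g <- fit_gda(t, prob_col = "rf_prob", features = c("m", "a"))
  rf_dummy <- train_rf(t, t$rf_prob == 1, features = c("m", "a"), seed = 1)
  model <- structure(list(rf = rf_dummy, gda = g, features = c("m", "a")),
                     class = "rfgda")
  l <- model$gda$layers[["a"]]

  at <- function(p) data.frame(individual = "a", m = p[1], a = p[2])
  expect_gt(predict(model, at(l$mu_pos)), 0.5)
  mid <- (l$mu_pos + l$mu_neg) / 2
  expect_equal(as.numeric(predict(model, at(mid))), 0.5, tolerance = 1e-9)

  set.seed(13)
  pts <- data.frame(individual = "a", m = runif(500, -10, 15), a = runif(500, 0, 20))
  post <- predict(model, pts, type = "posterior")
  expect_true(all(post >= 0 & post <= 1))
  expect_equal(rowSums(post), rep(1, 500), tolerance = 1e-12)
})

test_that("posterior agrees with a direct two-density oracle", {
  skip_if_not_installed("mclust")
  t <- gda_toy(4000, seed = 14)
  rf_dummy <- train_rf(t, t$truth, features = c("m", "a"), seed = 1)
  model <- rfgda(t, rf = rf_dummy, min_count = 100)
  l <- model$gda$layers[["a"]]

  set.seed(15)
  pts <- data.frame(individual = "a", m = runif(1000, -5, 10), a = runif(1000, 2, 15))
  got <- predict(model, pts)
  X <- as.matrix(pts[, c("m", "a")])
  num <- l$pi_pos * mclust::dmvnorm(X, l$mu_pos, l$Sigma_pos)
  den <- num + l$pi_neg * mclust::dmvnorm(X, l$mu_neg, l$Sigma_neg)
  expect_equal(got, num / den, tolerance = 1e-10)
})

test_that("save/load round trip reproduces scoring bit-for-bit and rejects bad files", {
  t <- gda_toy(2000, seed = 16)
  model <- rfgda(t, labels = t$truth, features = c("m", "a"),
                 min_count = 100, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict(back, t), predict(model, t))

  garbage <- tempfile()
  writeLines("not a model", garbage)
  expect_error(load_model(garbage), class = "scgeno_format_error")

  wrong_version <- tempfile()
  saveRDS(list(format = "scgeno_rfgda", version = 99L, model = model), wrong_version)
  expect_error(load_model(wrong_version), "version", class = "scgeno_format_error")
})

test_that("scoring an unseen individual errors without, and warns with, a pooled layer", {
  t <- gda_toy(3000, seed = 17)
  model <- rfgda(t, labels = t$truth, features = c("m", "a"),
                 min_count = 100, seed = 3)
  other <- gda_toy(50, individual = "zz", seed = 18)
  expect_error(predict(model, other), class = "scgeno_model_error")

  with_small <- rbind(gda_toy(3000, individual = "a", seed = 19),
                      gda_toy(12, individual = "tiny", seed = 20))
  model2 <- rfgda(with_small, labels = with_small$truth, features = c("m", "a"),
                  min_count = 100, seed = 3)
  expect_warning(predict(model2, other), "pooled")
})

test_that("ranking by the two-layer score beats the simulated GenCall score", {
  batch <- small_batch(n_samples = 6L, n_snps = 4000L, seed = 23L)
  t <- calculate_ma(filter_informative(load_batch(batch)))
  model <- rfgda(t, labels = truth_labels(t, batch$truth), seed = 3)
  scored <- score_genotypes(t, model)
  called <- scored[scored$gtype != "NC", ]
  truth <- batch$truth
  key <- paste(truth$sample_id, truth$Name)
  correct <- called$gtype == truth$true_gtype[match(paste(called$sample_id, called$Name), key)]
  for (q in c(0.95, 0.9)) {
    prec_at <- function(s) {
      keep <- s >= quantile(s, 1 - q)
      sum(correct & keep) / sum(keep)
    }
    expect_gt(prec_at(called$rfgda_score), prec_at(called$score))
  }
})
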