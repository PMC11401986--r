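# Independent oracles, kept deliberately naive and separate from the code
# paths they check.

# Four-stage affine normalization, one stage at a time, scalar arithmetic.
norm_oracle <- function(x, y, tr) {
  x1 <- x - tr$offset_x
  y1 <- y - tr$offset_y
  x2 <- cos(tr$theta) * x1 + sin(tr$theta) * y1
  y2 <- -sin(tr$theta) * x1 + cos(tr$theta) * y1
  x3 <- x2 - tr$shear * y2
  x4 <- x3 / tr$scale_x
  y4 <- y2 / tr$scale_y
  c(max(x4, 0), max(y4, 0))
}

# MA transform written out longhand.
ma_oracle <- function(x, y, eps) {
  c(m = log2(x + eps) - log2(y + eps),
    a = (log2(x + eps) + log2(y + eps)) / 2)
}

# Groupwise tally of genotype-class proportions, loops and division only.
callrate_oracle <- function(t, group_col) {
  out <- list()
  for (g in unique(t[[group_col]])) {
    sub <- t[t[[group_col]] == g, ]
    for (gt in c("AA", "AB", "BB", "NC")) {
      out[[length(out) + 1L]] <- data.frame(
        group = g, gtype = gt, prop = sum(sub$gtype == gt) / nrow(sub))
    }
  }
  do.call(rbind, out)
}

# Random GTC record set for round-trip property tests.
random_gtc_records <- function(n, n_transforms = 1L) {
  data.frame(
    gtype = sample(c("NC", "AA", "AB", "BB"), n, replace = TRUE),
    score = scgeno:::.quantize_float32(runif(n)),
    x_raw = sample(0:65535, n, replace = TRUE),
    y_raw = sample(0:65535, n, replace = TRUE),
    transform_index = sample.int(n_transforms, n, replace = TRUE))
}

random_transforms <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i)
    normalization_transform(offset_x = runif(1, -50, 50),
                            offset_y = runif(1, -50, 50),
                            theta = runif(1, -0.3, 0.3),
                            shear = runif(1, -0.2, 0.2),
                            scale_x = runif(1, 0.5, 2),
                            scale_y = runif(1, 0.5, 2))))
}
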