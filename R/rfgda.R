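# Two-layer confidence scorer for single-cell genotype calls.
#
# Layer 1: a random forest over the MA features, trained on calls with known
# correctness labels, emits the probability a call is correct. Layer 2: for
# each individual separately, the forest's confident calls (probability above
# p_hi / below p_lo) seed a two-class Gaussian discriminant model
# (correct vs. error, full covariances); the GDA posterior that a call is
# correct is the final quality score. Fitting the second layer per individual
# rather than on the pooled batch keeps one individual's outliers from
# biasing everyone else's scoring function.

.rfgda_default_features <- c("m", "a", "m_raw", "a_raw")

.check_features <- function(t, features) {
  miss <- setdiff(features, names(t))
  if (length(miss))
    abort_parameter("table is missing feature column(s): %s",
                    paste(miss, collapse = ", "))
  X <- as.matrix(t[features])
  if (!all(is.finite(X))) abort_parameter("feature columns contain non-finite values")
  X
}

#' Train the random-forest first layer
#'
#' Fits a probability forest over the MA features predicting whether a
#' genotype call is correct. Training data come from batches with known
#' ground truth (in this package, simulated batches with their truth tables).
#' Fully reproducible given a fixed seed (the forest runs single-threaded).
#'
#' @param t Genotype table with the MA feature columns (see
#'   [calculate_ma()]).
#' @param labels Logical vector, one per row of `t`: `TRUE` when the called
#'   genotype equals the true genotype (and is not NC).
#' @param features Feature columns to train on.
#' @param num_trees Number of trees.
#' @param max_depth Depth limit per tree; 0 means unlimited.
#' @param seed Integer seed.
#' @return An object of class `"rf_layer"` wrapping the fitted ensemble.
#' @export
train_rf <- function(t, labels, features = .rfgda_default_features,
                     num_trees = 100L, max_depth = 0L, seed = 1L) {
  X <- .check_features(t, features)
  if (length(labels) != nrow(X))
    abort_parameter("labels must have one entry per row of t")
  labels <- as.logical(labels)
  if (anyNA(labels)) abort_parameter("labels must not contain NA")
  if (length(unique(labels)) < 2L)
    abort_model("training labels contain a single class; need both correct and error calls")
  y <- factor(ifelse(labels, "correct", "error"), levels = c("error", "correct"))
  fit <- ranger::ranger(x = as.data.frame(X), y = y, probability = TRUE,
                        num.trees = num_trees, max.depth = max_depth,
                        seed = seed, num.threads = 1L)
  structure(list(forest = fit, features = features, num_trees = num_trees,
                 max_depth = max_depth, seed = seed, n_train = nrow(X)),
            class = "rf_layer")
}

#' Probability a call is correct, from the first layer
#'
#' @param object An `"rf_layer"` from [train_rf()].
#' @param newdata Genotype table with the layer's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.rf_layer <- function(object, newdata, ...) {
  X <- .check_features(newdata, object$features)
  p <- stats::predict(object$forest, data = as.data.frame(X),
                      num.threads = 1L)$predictions
  as.numeric(p[, "correct"])
}

#' @export
print.rf_layer <- function(x, ...) {
  cat("Random-forest first layer:", x$num_trees, "trees over",
      paste(x$features, collapse = ", "), "\n")
  cat("Trained on", x$n_train, "labelled calls (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

.gda_fit_class <- function(X, ridge) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  Sigma <- crossprod(Xc) / nrow(X) + diag(ridge, ncol(X))
  list(mu = mu, Sigma = Sigma)
}

.log_dmvnorm <- function(X, mu, Sigma) {
  R <- chol(Sigma)
  z <- backsolve(R, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

.gda_fit_one <- function(X_pos, X_neg, ridge) {
  pos <- .gda_fit_class(X_pos, ridge)
  neg <- .gda_fit_class(X_neg, ridge)
  n_pos <- nrow(X_pos); n_neg <- nrow(X_neg)
  list(mu_pos = pos$mu, Sigma_pos = pos$Sigma,
       mu_neg = neg$mu, Sigma_neg = neg$Sigma,
       pi_pos = n_pos / (n_pos + n_neg), pi_neg = n_neg / (n_pos + n_neg),
       n_pos = n_pos, n_neg = n_neg)
}

# Posterior P(correct | x) and its complement from one fitted layer.
.gda_posterior <- function(X, layer) {
  lp <- .log_dmvnorm(X, layer$mu_pos, layer$Sigma_pos) + log(layer$pi_pos)
  ln <- .log_dmvnorm(X, layer$mu_neg, layer$Sigma_neg) + log(layer$pi_neg)
  mx <- pmax(lp, ln)
  ep <- exp(lp - mx); en <- exp(ln - mx)
  cbind(pos = ep / (ep + en), neg = en / (ep + en))
}

#' Fit the per-individual Gaussian discriminant layer
#'
#' For each individual independently: calls the first layer rated at or above
#' `p_hi` form the "correct" training set and those at or below `p_lo` the
#' "error" set; each class gets a full-covariance Gaussian by maximum
#' likelihood (covariance regularized as `Sigma + ridge * I`) with priors
#' from the training-set counts. Individuals with fewer than `min_count`
#' calls in either class fall back to a pooled layer fitted on all
#' individuals together and are flagged. No-call records never enter the
#' training sets.
#'
#' @param t Genotype table carrying the first-layer probabilities.
#' @param prob_col Name of the probability column (default `"rf_prob"`).
#' @param features Feature columns.
#' @param p_hi,p_lo Selection thresholds, `p_lo < p_hi`.
#' @param ridge Covariance regularizer.
#' @param min_count Minimum per-class training count before the pooled
#'   fallback engages.
#' @return An object of class `"gda_layers"`: per-individual Gaussian class
#'   parameters, the pooled layer when any individual needed it, and the
#'   fitting provenance.
#' @export
fit_gda <- function(t, prob_col = "rf_prob", features = .rfgda_default_features,
                    p_hi = 0.9, p_lo = 0.15, ridge = 1e-6, min_count = 200L) {
  if (!prob_col %in% names(t))
    abort_parameter("no such probability column: %s", prob_col)
  if (!is.numeric(p_hi) || !is.numeric(p_lo) || p_lo >= p_hi)
    abort_parameter("selection thresholds must satisfy p_lo < p_hi")
  if (!"individual" %in% names(t))
    abort_parameter("table must have an individual column")
  X <- .check_features(t, features)
  prob <- t[[prob_col]]
  eligible <- if ("gtype" %in% names(t)) t$gtype != "NC" else rep(TRUE, nrow(t))
  pos_sel <- eligible & prob >= p_hi
  neg_sel <- eligible & prob <= p_lo

  indiv <- as.character(t$individual)
  ids <- unique(indiv)
  layers <- stats::setNames(vector("list", length(ids)), ids)
  short <- character(0)
  for (id in ids) {
    w <- indiv == id
    np <- sum(pos_sel & w); nn <- sum(neg_sel & w)
    if (np >= min_count && nn >= min_count) {
      layers[[id]] <- c(.gda_fit_one(X[pos_sel & w, , drop = FALSE],
                                     X[neg_sel & w, , drop = FALSE], ridge),
                        list(source = "individual"))
    } else {
      short <- c(short, id)
    }
  }
  pooled <- NULL
  if (length(short)) {
    np <- sum(pos_sel); nn <- sum(neg_sel)
    if (np < min_count || nn < min_count)
      abort_model(paste("no individual reaches %d confident calls per class,",
                        "even pooled (correct: %d, error: %d)"),
                  min_count, np, nn)
    pooled <- c(.gda_fit_one(X[pos_sel, , drop = FALSE],
                             X[neg_sel, , drop = FALSE], ridge),
                list(source = "pooled"))
    for (id in short) layers[[id]] <- pooled
  }
  structure(list(layers = layers, pooled = pooled, pooled_individuals = short,
                 features = features, p_hi = p_hi, p_lo = p_lo,
                 ridge = ridge, min_count = min_count),
            class = "gda_layers")
}

#' Fit the two-layer confidence model
#'
#' The main fitting entry point. Either trains the random-forest first layer
#' on `data` using correctness `labels`, or reuses a pretrained layer
#' (`rf`); then computes first-layer probabilities for every record of
#' `data` and fits the per-individual Gaussian discriminant second layer on
#' them. The fitted object scores the batch it was fitted on (see
#' [predict.rfgda()] / [score_genotypes()]); scoring a new batch with the
#' same trained forest is done by refitting on that batch with `rf =
#' model$rf`.
#'
#' @param data Genotype table with MA features and an `individual` column.
#' @param labels Optional logical correctness labels (one per row; rows with
#'   `NA` — e.g. no-calls — are excluded from forest training). Exactly one
#'   of `labels` and `rf` must be supplied.
#' @param rf Optional pretrained `"rf_layer"`.
#' @param features Feature columns (default `m`, `a`, `m_raw`, `a_raw`).
#' @param num_trees,max_depth Forest hyperparameters (when training here).
#' @param p_hi,p_lo,ridge,min_count Second-layer controls; see [fit_gda()].
#' @param seed Integer seed covering all randomness.
#' @return An object of class `"rfgda"` with components `rf`, `gda`,
#'   `features`, `fitted` (the scores of `data`), `seed`, `n`.
#' @export
#' @seealso [score_genotypes()], [save_model()], [load_model()]
rfgda <- function(data, labels = NULL, rf = NULL,
                  features = .rfgda_default_features,
                  num_trees = 100L, max_depth = 0L,
                  p_hi = 0.9, p_lo = 0.15, ridge = 1e-6, min_count = 200L,
                  seed = 1L) {
  if (is.null(rf) == is.null(labels))
    abort_parameter("supply exactly one of labels (to train the forest) or rf (pretrained)")
  if (is.null(rf)) {
    use <- !is.na(labels)
    rf <- train_rf(data[use, , drop = FALSE], labels[use], features = features,
                   num_trees = num_trees, max_depth = max_depth, seed = seed)
  } else {
    if (!inherits(rf, "rf_layer")) abort_parameter("rf must be an rf_layer object")
    features <- rf$features
  }
  prob <- predict(rf, data)
  data$.rf_prob <- prob
  gda <- fit_gda(data, prob_col = ".rf_prob", features = features,
                 p_hi = p_hi, p_lo = p_lo, ridge = ridge, min_count = min_count)
  obj <- structure(list(rf = rf, gda = gda, features = features,
                        seed = seed, n = nrow(data), fitted = NULL),
                   class = "rfgda")
  obj$fitted <- predict(obj, data)
  obj
}

#' Quality scores from a fitted two-layer model
#'
#' The score of a call is the posterior probability that it is correct under
#' that individual's two-class Gaussian discriminant layer:
#' `pi_pos * N(x | mu_pos, Sigma_pos) / sum_k pi_k * N(x | mu_k, Sigma_k)`.
#' Individuals unseen at fit time are scored with the pooled layer when one
#' exists (with a warning), and are an error otherwise.
#'
#' @param object A fitted `"rfgda"` model.
#' @param newdata Genotype table to score; omitted, the fitted scores of the
#'   training batch are returned.
#' @param type `"score"` (posterior that the call is correct),
#'   `"posterior"` (two-column matrix, correct and error posteriors) or
#'   `"rf"` (first-layer probabilities).
#' @param ... Unused.
#' @return Numeric vector (or matrix for `type = "posterior"`).
#' @export
predict.rfgda <- function(object, newdata = NULL,
                          type = c("score", "posterior", "rf"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "score" && !is.null(object$fitted)) return(object$fitted)
    abort_parameter("newdata is required for type = %s", type)
  }
  if (type == "rf") return(predict(object$rf, newdata))
  X <- .check_features(newdata, object$features)
  if (!"individual" %in% names(newdata))
    abort_parameter("newdata must have an individual column")
  indiv <- as.character(newdata$individual)
  post <- matrix(NA_real_, nrow = nrow(X), ncol = 2L,
                 dimnames = list(NULL, c("pos", "neg")))
  unseen <- setdiff(unique(indiv), names(object$gda$layers))
  if (length(unseen)) {
    if (is.null(object$gda$pooled))
      abort_model("individual(s) not covered by the model and no pooled fallback: %s",
                  paste(unseen, collapse = ", "))
    warning(sprintf("scoring unseen individual(s) with the pooled layer: %s",
                    paste(unseen, collapse = ", ")))
  }
  for (id in unique(indiv)) {
    layer <- object$gda$layers[[id]]
    if (is.null(layer)) layer <- object$gda$pooled
    w <- indiv == id
    post[w, ] <- .gda_posterior(X[w, , drop = FALSE], layer)
  }
  if (type == "posterior") post else as.numeric(post[, "pos"])
}

#' Append the quality-score column to a genotype table
#'
#' Convenience wrapper around [predict.rfgda()]: scores every record
#' (no-calls included, for diagnostics — their genotype stays NC) and
#' appends the result as the `rfgda_score` column.
#'
#' @param t Genotype table with the model's feature columns.
#' @param model A fitted `"rfgda"` model.
#' @return `t` with an `rfgda_score` column in `[0, 1]`.
#' @export
score_genotypes <- function(t, model) {
  if (!inherits(model, "rfgda")) abort_parameter("model must be an rfgda object")
  t$rfgda_score <- predict(model, t)
  t
}

#' @export
print.rfgda <- function(x, ...) {
  cat("Two-layer genotype confidence model (random forest + per-individual GDA)\n")
  cat("  features   :", paste(x$features, collapse = ", "), "\n")
  cat("  first layer:", x$rf$num_trees, "trees,", x$rf$n_train, "labelled calls\n")
  cat("  individuals:", length(x$gda$layers),
      sprintf("(%d on the pooled fallback)\n", length(x$gda$pooled_individuals)))
  invisible(x)
}

#' @export
summary.rfgda <- function(object, ...) {
  ly <- object$gda$layers
  tab <- data.frame(
    individual = names(ly),
    n_correct = vapply(ly, `[[`, 0, "n_pos"),
    n_error = vapply(ly, `[[`, 0, "n_neg"),
    prior_correct = vapply(ly, `[[`, 0, "pi_pos"),
    pooled = vapply(ly, function(l) l$source == "pooled", NA),
    row.names = NULL)
  structure(list(individuals = tab, features = object$features,
                 p_hi = object$gda$p_hi, p_lo = object$gda$p_lo,
                 num_trees = object$rf$num_trees, n = object$n),
            class = "summary.rfgda")
}

#' @export
print.summary.rfgda <- function(x, ...) {
  cat("Two-layer confidence model over", paste(x$features, collapse = ", "), "\n")
  cat("First layer:", x$num_trees, "trees;",
      "second layer seeded at p_hi =", x$p_hi, ", p_lo =", x$p_lo, "\n")
  cat("Scored batch size:", x$n, "calls\n\n")
  print(x$individuals, digits = 3)
  invisible(x)
}

#' @export
coef.rfgda <- function(object, ...) {
  ly <- object$gda$layers
  do.call(rbind, lapply(names(ly), function(id) {
    l <- ly[[id]]
    out <- data.frame(individual = id, class = c("correct", "error"),
                      prior = c(l$pi_pos, l$pi_neg),
                      pooled = l$source == "pooled")
    mus <- rbind(l$mu_pos, l$mu_neg)
    colnames(mus) <- paste0("mu_", object$features)
    cbind(out, as.data.frame(mus, row.names = FALSE))
  }))
}

.model_format <- "scgeno_rfgda"
.model_version <- 1L

#' Save / load a fitted two-layer model
#'
#' The container is versioned; loading a file written by an incompatible
#' version, or a corrupted file, is an explicit error rather than a silently
#' broken model. The round trip is exact: a reloaded model reproduces
#' scoring output bit-for-bit.
#'
#' @param model A fitted `"rfgda"` model.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "rfgda")) abort_parameter("model must be an rfgda object")
  saveRDS(list(format = .model_format, version = .model_version, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort_parameter("no such file: %s", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) abort_format("%s: not a readable model file (%s)",
                                                   path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, .model_format))
    abort_format("%s: not a %s model container", path, .model_format)
  if (!identical(obj$version, .model_version))
    abort_format("%s: incompatible model file version %s (this build reads version %d)",
                 path, as.character(obj$version), .model_version)
  if (!inherits(obj$model, "rfgda"))
    abort_format("%s: corrupted model payload", path)
  obj$model
}
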