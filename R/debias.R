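# ---- small CART regression trees + LAD gradient boosting ----
#
# No gradient-boosting package ships with this stack, so the ensemble is
# implemented here: least-squares split search on the working response
# (sign residuals), terminal values set to the median residual per leaf
# (classic LAD TreeBoost), shrinkage nu per tree.

# nodes: parallel vectors; feature = 0 marks a leaf
fit_tree <- function(X, g, r, max_depth = 3L, min_node = 10L) {
  nodes <- list(feature = integer(), threshold = numeric(),
                left = integer(), right = integer(), value = numeric())
  add_node <- function() {
    i <- length(nodes$feature) + 1L
    nodes$feature[i] <<- 0L; nodes$threshold[i] <<- NA_real_
    nodes$left[i] <<- 0L; nodes$right[i] <<- 0L; nodes$value[i] <<- NA_real_
    i
  }
  build <- function(rows, depth) {
    id <- add_node()
    make_leaf <- function() {
      nodes$value[id] <<- median(r[rows])
      id
    }
    if (depth >= max_depth || length(rows) < 2L * min_node) return(make_leaf())
    best <- list(score = -Inf)
    gi <- g[rows]
    tot <- sum(gi)
    n <- length(rows)
    for (f in seq_len(ncol(X))) {
      xs <- X[rows, f]
      ord <- order(xs)
      xs_s <- xs[ord]
      cg <- cumsum(gi[ord])
      cand <- which(xs_s[-n] < xs_s[-1])  # split between distinct values
      cand <- cand[cand >= min_node & (n - cand) >= min_node]
      if (length(cand) == 0) next
      sc <- cg[cand]^2 / cand + (tot - cg[cand])^2 / (n - cand)
      i_best <- cand[which.max(sc)]
      if (max(sc) > best$score) {
        best <- list(score = max(sc), feature = f,
                     threshold = (xs_s[i_best] + xs_s[i_best + 1]) / 2,
                     left_rows = rows[ord[seq_len(i_best)]],
                     right_rows = rows[ord[(i_best + 1):n]])
      }
    }
    if (!is.finite(best$score)) return(make_leaf())
    nodes$feature[id] <<- best$feature
    nodes$threshold[id] <<- best$threshold
    nodes$left[id] <<- build(best$left_rows, depth + 1L)
    nodes$right[id] <<- build(best$right_rows, depth + 1L)
    id
  }
  build(seq_len(nrow(X)), 0L)
  nodes
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (tree$feature[node] != 0L) {
      node <- if (X[i, tree$feature[node]] <= tree$threshold[node])
        tree$left[node] else tree$right[node]
    }
    out[i] <- tree$value[node]
  }
  out
}

DEBIAS_FEATURES <- c("ani", "chunk_ani_sd", "ref_p90_contig_len",
                     "query_p90_contig_len", "mean_chain_len")
DEBIAS_MODEL_VERSION <- 1L

#' Extract debiasing features from a comparison result
#'
#' The five features: the chaining ANI itself, the standard deviation of the
#' per-chunk ANI estimates (0 when fewer than two chunks), the 90th
#' percentile contig length of reference and of query, and the mean
#' reference-coordinate chain span.
#'
#' @param result An `ani_result` with a present ANI.
#' @return One-row data.frame with the five feature columns (fixed order).
#' @export
extract_features <- function(result) {
  if (is.null(result$features) || is.na(result$ani_raw)) {
    stop("cannot extract features: result has no ANI")
  }
  as.data.frame(result$features)[, DEBIAS_FEATURES]
}

#' Train the ANI debiasing model
#'
#' Gradient-boosted regression trees with absolute-deviation (LAD) loss,
#' mapping the five comparison features to a ground-truth ANI. Ground truth
#' here is the synthetic generator's known `1 - theta`; a fraction of the
#' pairs is held out to report corrected vs uncorrected mean absolute
#' deviation.
#'
#' @param features data.frame with the columns of [extract_features()]
#'   (>= 100 rows).
#' @param truth Numeric vector of true ANIs.
#' @param c_value The seed sampling rate `c` the training comparisons used
#'   (stored for model selection).
#' @param n_trees,learning_rate,max_depth,min_node Boosting hyperparameters.
#' @param holdout_frac Fraction of rows held out for evaluation.
#' @param seed RNG seed for the holdout split.
#' @return An object of class `debias_model` with the fitted ensemble and
#'   training metadata (`c_value`, `holdout_mad`, `baseline_mad`, feature
#'   order, version).
#' @export
train_debias <- function(features, truth, c_value = 125, n_trees = 100L,
                         learning_rate = 0.1, max_depth = 3L, min_node = 10L,
                         holdout_frac = 0.2, seed = 1L) {
  if (nrow(features) < 100) stop("need at least 100 training pairs")
  if (!all(DEBIAS_FEATURES %in% colnames(features))) {
    stop("features must contain columns: ",
         paste(DEBIAS_FEATURES, collapse = ", "))
  }
  X <- as.matrix(features[, DEBIAS_FEATURES])
  y <- as.numeric(truth)
  stopifnot(length(y) == nrow(X), all(is.finite(X)), all(is.finite(y)))
  if (sd(y) == 0) stop("degenerate training targets: truth is constant")

  n <- nrow(X)
  hold <- with_seed(seed, sample.int(n, max(1L, round(holdout_frac * n))))
  tr <- setdiff(seq_len(n), hold)

  init <- median(y[tr])
  fit <- rep(init, length(tr))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    resid <- y[tr] - fit
    tree <- fit_tree(X[tr, , drop = FALSE], sign(resid), resid,
                     max_depth = max_depth, min_node = min_node)
    fit <- fit + learning_rate * predict_tree(tree, X[tr, , drop = FALSE])
    trees[[t]] <- tree
  }
  model <- structure(list(trees = trees, init = init, nu = learning_rate,
                          feature_names = DEBIAS_FEATURES, c_value = c_value,
                          version = DEBIAS_MODEL_VERSION,
                          loss = "absolute deviation"),
                     class = "debias_model")
  pred_h <- predict(model, features[hold, , drop = FALSE])
  model$holdout_mad <- mean(abs(y[hold] - pred_h))
  model$baseline_mad <- mean(abs(y[hold] - X[hold, "ani"]))
  model
}

#' @export
predict.debias_model <- function(object, newdata, ...) {
  if (!identical(object$version, DEBIAS_MODEL_VERSION) ||
      !identical(object$feature_names, DEBIAS_FEATURES)) {
    stop("incompatible debias model (feature order or version mismatch)")
  }
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names])
  out <- rep(object$init, nrow(X))
  for (tree in object$trees) {
    out <- out + object$nu * predict_tree(tree, X)
  }
  pmin(1, pmax(0, out))
}

#' @export
print.debias_model <- function(x, ...) {
  cat(sprintf("LAD gradient-boosted debias model: %d trees, nu = %g, c = %g\n",
              length(x$trees), x$nu, x$c_value))
  if (!is.null(x$holdout_mad)) {
    cat(sprintf("  held-out MAD %.5f (uncorrected %.5f)\n",
                x$holdout_mad, x$baseline_mad))
  }
  invisible(x)
}

#' Apply the learned ANI correction
#'
#' The correction fires only when a model is present, the chaining ANI
#' exceeds `debias_ani_gate` (90%), more than `debias_min_aligned` bases
#' (150 kb) are aligned, and either `params$c >= debias_auto_c` or the user
#' forces it (small `c` shows little edge bias, so debiasing is off for slow
#' presets). The correction is clamped to ±0.02 of the raw estimate and to
#' `[0, 1]`; the result's `debiased` flag records whether it fired.
#'
#' @param model A `debias_model` or `NULL` (identity).
#' @param result An `ani_result`.
#' @param params A [sketch_params()] object.
#' @param force Apply even when `params$c < debias_auto_c`.
#' @return The (possibly corrected) `ani_result`.
#' @export
apply_debias <- function(model, result, params = result$params,
                         force = FALSE) {
  if (is.null(model)) return(result)
  if (!inherits(model, "debias_model") ||
      !identical(model$version, DEBIAS_MODEL_VERSION) ||
      !identical(model$feature_names, DEBIAS_FEATURES)) {
    stop("incompatible debias model (feature order or version mismatch)")
  }
  if (is.na(result$ani_raw) || is.null(result$features)) return(result)
  gate <- result$ani_raw > params$debias_ani_gate &&
    result$aligned_bases > params$debias_min_aligned &&
    (force || params$c >= params$debias_auto_c)
  if (!gate) return(result)
  raw <- result$ani_raw
  corrected <- predict(model, extract_features(result))
  corrected <- min(raw + 0.02, max(raw - 0.02, corrected))
  corrected <- min(1, max(0, corrected))
  result$ani_raw <- raw
  if (!is.na(result$ani)) result$ani <- corrected
  result$debiased <- TRUE
  result$ani_debiased <- corrected
  result
}

#' Select the debias model nearest a given c
#'
#' Among available models (trained at specific `c` values), picks the one
#' whose training `c` is closest to the `c` in use; ties break toward the
#' smaller `c`.
#'
#' @param models List of `debias_model` objects (may be empty).
#' @param c_used The `c` parameter of the current run.
#' @return A `debias_model`, or `NULL` when `models` is empty.
#' @export
select_model <- function(models, c_used) {
  if (length(models) == 0) return(NULL)
  cs <- vapply(models, function(m) m$c_value, 0)
  d <- abs(cs - c_used)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(cs[best])]
  models[[best]]
}

#' Write / read a debias model file
#'
#' Versioned serialized ensemble; reading back yields identical predictions.
#'
#' @param model A `debias_model`.
#' @param path File path.
#' @return `write_debias_model` returns `path` invisibly; `read_debias_model`
#'   the model.
#' @export
write_debias_model <- function(model, path) {
  stopifnot(inherits(model, "debias_model"))
  saveRDS(list(magic = "chainani-debias", version = DEBIAS_MODEL_VERSION,
               model = model), path, version = 3)
  invisible(path)
}

#' @rdname write_debias_model
#' @export
read_debias_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable model file: ", path))
  if (!is.list(payload) || !identical(payload$magic, "chainani-debias")) {
    stop("not a chainani debias model file: ", path)
  }
  payload$model
}

#' Generate debias training data from synthetic genome pairs
#'
#' Runs the full pipeline on simulated pairs over a grid of substitution
#' rates and fragmentation levels and returns the feature matrix together
#' with the known ground truth `1 - theta`. Pairs whose comparison yields no
#' ANI are dropped.
#'
#' @param n_per_cell Replicates per (theta, n50) grid cell.
#' @param thetas Substitution rates to simulate.
#' @param n50s Target contig N50s for the degraded copy (`Inf` = intact).
#' @param genome_length Base genome length in bases.
#' @param params A [sketch_params()] object.
#' @param seed Integer seed.
#' @return data.frame with the five feature columns, `truth`, and
#'   `base_genome` (index of the underlying base genome, for disjoint
#'   holdout splits).
#' @export
debias_training_data <- function(n_per_cell = 5L,
                                 thetas = c(0.005, 0.01, 0.02, 0.04),
                                 n50s = c(Inf, 30000),
                                 genome_length = 2e5,
                                 params = sketch_params(), seed = 1L) {
  rows <- list()
  base_idx <- 0L
  for (th in thetas) for (n50 in n50s) for (rep in seq_len(n_per_cell)) {
    base_idx <- base_idx + 1L
    sp <- sim_spec(base_length = genome_length, theta = th, target_n50 = n50,
                   seed = seed + 1000L * base_idx)
    pair <- sim_genome_pair(sp)
    a <- sketch_genome(pair$original, params, genome_id = "base")
    b <- sketch_genome(pair$derived, params, genome_id = "derived")
    res <- compare_pair(a, b, params)
    if (is.na(res$ani_raw)) next
    f <- extract_features(res)
    f$truth <- 1 - th
    f$base_genome <- base_idx
    rows[[length(rows) + 1L]] <- f
  }
  do.call(rbind, rows)
}
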