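#' Build a feature table from trajectories
#'
#' Runs [trajectory_features()] on each trajectory and assembles the rows
#' into a feature table (one row per trajectory, columns `id` + the 17
#' [feature_names()] + optional `label`).  Trajectories on which any
#' feature fails (e.g. a constant trajectory, whose exponent fit is
#' undefined) are excluded and reported in a warning carrying the failing
#' feature's message; if every row fails, an error is raised.
#'
#' @param trajs list of [trajectory()] objects, or the list returned by
#'   [generate_labeled_set()] (in which case `labels` is taken from it).
#' @param labels optional character vector of per-trajectory labels from
#'   the vocabulary of [diffusion_modes()].
#' @param ids optional character vector of row ids; defaults to the
#'   trajectories' own ids or their positions.
#' @return a data frame feature table (see [write_feature_table()]).
#' @export
build_feature_table <- function(trajs, labels = NULL, ids = NULL) {
  if (is.list(trajs) && !is.null(trajs$trajectories)) {
    if (is.null(labels)) labels <- trajs$labels
    trajs <- trajs$trajectories
  }
  if (!is.list(trajs) || length(trajs) == 0L)
    stop("'trajs' must be a non-empty list of trajectories")
  n <- length(trajs)
  if (!is.null(labels) && length(labels) != n)
    stop("'labels' must have one entry per trajectory")
  if (is.null(ids)) {
    ids <- vapply(seq_len(n), function(i) {
      if (!is.null(trajs[[i]]$id)) trajs[[i]]$id else sprintf("traj_%03d", i)
    }, character(1))
  }
  rows <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(trajectory_features(trajs[[i]]),
                          error = function(e) conditionMessage(e))
    if (is.character(rows[[i]]))
      failures <- c(failures, sprintf("%s (%s)", ids[i], rows[[i]]))
  }
  ok <- vapply(rows, is.numeric, logical(1))
  if (!any(ok))
    stop("feature extraction failed for every trajectory; first failure: ",
         failures[1L])
  if (length(failures))
    warning("excluded ", length(failures), " trajectory(ies): ",
            paste(failures, collapse = "; "))
  tab <- as.data.frame(do.call(rbind, rows[ok]))
  tab <- cbind(id = ids[ok], tab, stringsAsFactors = FALSE)
  if (!is.null(labels)) tab$label <- as.character(labels)[ok]
  validate_feature_table(tab)
  rownames(tab) <- NULL
  tab
}

## ---- shared preprocessing --------------------------------------------------

## Feature matrix from a table; non-finite entries (the Katz Inf sentinel)
## are imputed to the column's maximum finite value, recorded per column so
## prediction-time data use the training imputation.
feature_matrix <- function(table) {
  validate_feature_table(table)
  x <- as.matrix(table[, feature_names(), drop = FALSE])
  storage.mode(x) <- "double"
  x
}

impute_nonfinite <- function(x, impute = NULL) {
  if (is.null(impute)) {
    impute <- apply(x, 2L, function(col) {
      fin <- col[is.finite(col)]
      if (length(fin)) max(fin) else 0
    })
  }
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- impute[j]
  }
  list(x = x, impute = impute)
}

standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(x, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## ---- classifier ------------------------------------------------------------

lda_method <- function() {
  list(
    fit = function(x, y, seed) suppressWarnings(MASS::lda(x, grouping = y)),
    predict = function(fit, x) {
      pr <- stats::predict(fit, x)
      list(class = as.character(pr$class), scores = pr$posterior)
    },
    name = "linear discriminant analysis"
  )
}

#' Train a diffusion-mode classifier
#'
#' Standardizes the features (z-score on the training rows, after imputing
#' non-finite sentinel values to the column's maximum finite training
#' value and dropping zero-variance columns), fits the decision model and
#' estimates held-out accuracy by stratified k-fold cross-validation (the
#' standardization is refit inside every fold).  The default model is
#' linear discriminant analysis; any model plugs in through `method =
#' list(fit = function(x, y, seed), predict = function(fit, x))` where
#' `predict` returns `list(class =, scores =)` with per-class scores
#' summing to 1.
#'
#' @param table a labelled feature table: every row must carry a `label`
#'   from [diffusion_modes()], with at least 2 classes and at least 5 rows
#'   per class.
#' @param seed integer seed controlling the fold assignment (and any
#'   stochastic plug-in model).
#' @param folds number of cross-validation folds (default 5).
#' @param method a fit/predict list as above, or `NULL` for the default.
#' @return object of class `"diffusion_classifier"` with elements `fit`,
#'   `center`, `scale`, `impute`, `features`, `classes`, `cv_accuracy`,
#'   `n_per_class`, `folds`, `seed` and `method_name`.
#' @export
train_classifier <- function(table, seed = 1, folds = 5, method = NULL) {
  validate_feature_table(table)
  if (!"label" %in% names(table))
    stop("training requires a labelled feature table")
  y <- as.character(table$label)
  counts <- table(y)
  if (length(counts) < 2L)
    stop("training requires at least 2 classes, got ", length(counts))
  if (any(counts < 5L))
    stop("training requires >= 5 rows per class; smallest class has ",
         min(counts))
  if (is.null(method)) method <- lda_method()
  imp <- impute_nonfinite(feature_matrix(table))
  keep <- apply(imp$x, 2L, function(col) stats::sd(col) > 0)
  if (sum(keep) < 2L) stop("fewer than 2 features with nonzero variance")
  x <- imp$x[, keep, drop = FALSE]
  std <- standardize(x)
  fit <- method$fit(std$x, factor(y), seed)

  cv_acc <- with_seed(seed, {
    fold <- stratified_folds(y, folds)
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      std_f <- standardize(x[tr, , drop = FALSE])
      fit_f <- method$fit(std_f$x, factor(y[tr]), seed)
      x_te <- standardize(x[!tr, , drop = FALSE],
                          center = std_f$center, scale = std_f$scale)$x
      pred <- method$predict(fit_f, x_te)$class
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  })

  structure(list(fit = fit, method = method, method_name = method$name,
                 center = std$center, scale = std$scale,
                 impute = imp$impute, features = colnames(x),
                 classes = sort(unique(y)), cv_accuracy = cv_acc,
                 n_per_class = as.list(counts), folds = folds, seed = seed),
            class = "diffusion_classifier")
}

#' @export
print.diffusion_classifier <- function(x, ...) {
  cat(sprintf(paste0("<diffusion_classifier: %s, %d classes (%s), ",
                     "%d features, %d-fold CV accuracy %.3f>\n"),
              x$method_name, length(x$classes),
              paste(x$classes, collapse = ", "),
              length(x$features), x$folds, x$cv_accuracy))
  invisible(x)
}

#' Classify trajectories from their features
#'
#' Applies a trained [train_classifier()] model to a feature table.  The
#' table must carry exactly the 17 canonical feature columns the model was
#' trained on; any mismatch is a schema error.  Per-row class scores sum
#' to 1.
#'
#' @param model a `"diffusion_classifier"`.
#' @param table a feature table (labels, if present, are ignored).
#' @return data frame with `id`, `label` (predicted) and one `score.<class>`
#'   column per class.
#' @export
classify <- function(model, table) {
  if (!inherits(model, "diffusion_classifier"))
    stop("'model' must be a diffusion_classifier")
  validate_feature_table(table)
  missing <- setdiff(model$features, names(table))
  if (length(missing))
    stop("feature table does not match the model's training features; ",
         "missing: ", paste(missing, collapse = ", "))
  x <- impute_nonfinite(feature_matrix(table), model$impute)$x
  x <- x[, model$features, drop = FALSE]
  x <- standardize(x, center = model$center, scale = model$scale)$x
  pred <- model$method$predict(model$fit, x)
  scores <- as.data.frame(pred$scores)
  names(scores) <- paste0("score.", colnames(pred$scores))
  ids <- if ("id" %in% names(table)) as.character(table$id)
  else as.character(seq_len(nrow(table)))
  out <- cbind(data.frame(id = ids, label = pred$class,
                          stringsAsFactors = FALSE), scores)
  rownames(out) <- NULL
  out
}

#' @export
predict.diffusion_classifier <- function(object, newdata, ...) {
  classify(object, newdata)
}

#' Save / load a trained classifier
#'
#' Serializes the model to a single artifact file with an embedded format
#' version, feature names and class vocabulary; `load_classifier()`
#' validates them on the way back in.
#'
#' @param model a `"diffusion_classifier"`.
#' @param path artifact file path.
#' @return `save_classifier()` returns `path` invisibly;
#'   `load_classifier()` the model.
#' @export
save_classifier <- function(model, path) {
  if (!inherits(model, "diffusion_classifier"))
    stop("'model' must be a diffusion_classifier")
  saveRDS(list(format = "trackfeat_classifier", version = 1L,
               features = model$features, classes = model$classes,
               model = model), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "trackfeat_classifier"))
    stop("not a trackfeat classifier artifact: ", path)
  obj$model
}

## ---- PCA projection --------------------------------------------------------

#' Two-component principal projection of a feature table
#'
#' Z-scores the features (after sentinel imputation, dropping zero-variance
#' columns) and projects every row onto the top two principal components.
#' Component signs are fixed (largest-magnitude loading positive) so the
#' projection is fully deterministic.  On the default synthetic training
#' set the four diffusion modes appear as well-separated clusters in this
#' plane.
#'
#' @param table a feature table with >= 3 rows and >= 2 features of
#'   nonzero variance.
#' @return object of class `"trajectory_pca"`: `scores` (n x 2),
#'   `explained` (variance fractions, component 1 >= 2), `rotation`,
#'   `labels` (if the table had them) and `ids`.
#' @export
pca_projection <- function(table) {
  validate_feature_table(table)
  if (nrow(table) < 3L) stop("PCA projection needs at least 3 rows")
  x <- impute_nonfinite(feature_matrix(table))$x
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (sum(keep) < 2L)
    stop("PCA projection needs at least 2 features with nonzero variance")
  z <- standardize(x[, keep, drop = FALSE])$x
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pr$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    lead <- which.max(abs(rot[, j]))
    if (abs(rot[lead, j]) > 1e-12 && rot[lead, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- z %*% rot
  colnames(scores) <- c("pc1", "pc2")
  total_var <- sum(pr$sdev^2)
  structure(list(scores = scores,
                 explained = (pr$sdev[1:2]^2) / total_var,
                 rotation = rot,
                 labels = if ("label" %in% names(table))
                   as.character(table$label) else NULL,
                 ids = if ("id" %in% names(table)) as.character(table$id)
                 else as.character(seq_len(nrow(table)))),
            class = "trajectory_pca")
}

#' @export
print.trajectory_pca <- function(x, ...) {
  cat(sprintf("<trajectory_pca: %d points, explained variance %.1f%% + %.1f%%>\n",
              nrow(x$scores), 100 * x$explained[1L], 100 * x$explained[2L]))
  invisible(x)
}

#' @export
plot.trajectory_pca <- function(x, ...) {
  col <- if (is.null(x$labels)) 1L else as.integer(factor(x$labels))
  graphics::plot(x$scores, col = col, pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2L]), ...)
  if (!is.null(x$labels))
    graphics::legend("topright", legend = levels(factor(x$labels)),
                     col = seq_along(levels(factor(x$labels))), pch = 16,
                     cex = 0.8)
  invisible(x)
}

## ---- group comparison ------------------------------------------------------

#' Two-sample comparison of one feature between groups
#'
#' Compares one feature between two feature tables (e.g. control vs
#' treated trajectories) with per-group mean/SD, the mean difference and a
#' two-sided Wilcoxon rank-sum test.  The rank-based default is deliberate:
#' trajectory-feature distributions are typically skewed.
#'
#' @param table_a,table_b feature tables with >= 3 rows each.
#' @param feature one of [feature_names()].
#' @return object of class `"group_comparison"`: `feature`, `n`, `means`,
#'   `sds`, `difference` (mean A - mean B), `statistic` (Wilcoxon W),
#'   `p_value`, `method`.
#' @export
compare_groups <- function(table_a, table_b, feature) {
  if (!feature %in% feature_names())
    stop("unknown feature '", feature, "'; see feature_names()")
  for (tab in list(table_a, table_b)) {
    validate_feature_table(tab)
    if (nrow(tab) < 3L)
      stop("group comparison needs at least 3 rows per group")
  }
  a <- table_a[[feature]]
  b <- table_b[[feature]]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("group comparison needs at least 3 finite values per group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  structure(list(feature = feature,
                 n = c(a = length(a), b = length(b)),
                 means = c(a = mean(a), b = mean(b)),
                 sds = c(a = stats::sd(a), b = stats::sd(b)),
                 difference = mean(a) - mean(b),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = "two-sided Wilcoxon rank-sum"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Comparison of '%s' (%s)\n", x$feature, x$method))
  cat(sprintf("  group A: n = %d, mean = %.4g (SD %.4g)\n",
              x$n["a"], x$means["a"], x$sds["a"]))
  cat(sprintf("  group B: n = %d, mean = %.4g (SD %.4g)\n",
              x$n["b"], x$means["b"], x$sds["b"]))
  cat(sprintf("  difference (A - B) = %.4g, W = %g, p = %.3g\n",
              x$difference, x$statistic, x$p_value))
  invisible(x)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' from the contingency-table form: 1 for identical partitions, ~0 for
#' independent ones.  Used to quantify how well clustering the
#' two-component projection recovers the true diffusion-mode labels.
#'
#' @param x,y vectors of cluster/class assignments of equal length.
#' @return the adjusted Rand index (<= 1).
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  tab <- table(x, y)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  expected <- sum_a * sum_b / (n * (n - 1) / 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
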