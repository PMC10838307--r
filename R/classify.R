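#' Labeling policy for training-set construction
#'
#' Two ways of assigning ground-truth labels to cultured cells:
#'
#' * `assumption`: every cell from a senescence-induced (treated) culture is
#'   labelled senescent and every control cell normal.
#' * `marker`: treated cells are first filtered to marker-positive ones and
#'   control cells to marker-negative ones (e.g. SA-beta-Gal activity via
#'   C12FDG fluorescence), then labelled. The marker rule is
#'   `value comparator threshold`; when `threshold` is `NULL` it is taken as
#'   the `control_percentile` quantile of the pooled control-cell channel
#'   (default 95th percentile, reflecting that positivity cutoffs for
#'   fluorescent markers are set against control wells).
#'
#' @param mode `"assumption"` or `"marker"`.
#' @param channel Marker column name (marker mode).
#' @param comparator `">"` or `"<"`; positive cells satisfy it.
#' @param threshold Absolute threshold, or `NULL` to derive from controls.
#' @param control_percentile Percentile of the control distribution used
#'   when `threshold` is `NULL`.
#' @return An object of class `labeling_policy`.
#' @export
labeling_policy <- function(mode = c("assumption", "marker"), channel = NULL,
                            comparator = ">", threshold = NULL,
                            control_percentile = 0.95) {
  mode <- match.arg(mode)
  if (mode == "marker") {
    if (is.null(channel)) {
      stop("marker mode requires a 'channel'", call. = FALSE)
    }
    if (!comparator %in% c(">", "<")) {
      stop("comparator must be '>' or '<'", call. = FALSE)
    }
    if (is.null(threshold)) {
      assert_scalar_number(control_percentile, "control_percentile", 0, 1)
    } else {
      assert_scalar_number(threshold, "threshold")
    }
  }
  structure(list(mode = mode, channel = channel, comparator = comparator,
                 threshold = threshold,
                 control_percentile = control_percentile),
            class = "labeling_policy")
}

marker_positive <- function(values, comparator, threshold) {
  if (comparator == ">") values > threshold else values < threshold
}

#' Build a balanced training set
#'
#' Samples exactly `n_per_class` cells per class (without replacement) from
#' control and treated feature tables, after applying the labeling policy.
#' When a class pool is a list of tables (several conditions, as for a
#' general multi-condition classifier), the quota is split as evenly as
#' possible across conditions (remainder to the first conditions, in
#' order).
#'
#' @param control Data frame of control cells, or named list of them.
#' @param treated Data frame of treated cells, or named list of them.
#' @param policy A [labeling_policy()].
#' @param n_per_class Cells sampled per class (default 10000).
#' @param feature_set Schema; defaults to the `feature_set` attribute of
#'   the first table.
#' @param seed Integer seed for subsampling.
#' @param allow_smaller Accept pools smaller than `n_per_class` (the class
#'   then contributes its whole pool).
#' @return An object of class `training_set`: list with `x` (feature data
#'   frame), `y` (0/1 integer labels), `provenance` (condition and labeling
#'   mode per row), `feature_set`, `seed`, `class_counts`.
#' @export
build_training_set <- function(control, treated,
                               policy = labeling_policy("assumption"),
                               n_per_class = 10000L, feature_set = NULL,
                               seed = 1L, allow_smaller = FALSE) {
  stopifnot(inherits(policy, "labeling_policy"))
  assert_scalar_number(n_per_class, "n_per_class", lower = 1)
  if (is.data.frame(control)) control <- list(control = control)
  if (is.data.frame(treated)) treated <- list(treated = treated)
  fset <- as_feature_set(feature_set %||% attr(control[[1]], "feature_set") %||%
                           "core7")
  for (tab in c(control, treated)) validate_feature_columns(tab, fset)

  if (policy$mode == "marker") {
    ch <- policy$channel
    for (tab in c(control, treated)) {
      if (!ch %in% names(tab)) {
        stop("marker channel '", ch, "' not present in all tables",
             call. = FALSE)
      }
    }
    thr <- policy$threshold %||% stats::quantile(
      unlist(lapply(control, function(t) t[[ch]])),
      policy$control_percentile, names = FALSE)
    control <- lapply(control, function(t) {
      t[!marker_positive(t[[ch]], policy$comparator, thr), , drop = FALSE]
    })
    treated <- lapply(treated, function(t) {
      t[marker_positive(t[[ch]], policy$comparator, thr), , drop = FALSE]
    })
  }

  sample_class <- function(pools, quota) {
    sizes <- vapply(pools, nrow, integer(1))
    share <- rep(quota %/% length(pools), length(pools))
    extra <- quota - sum(share)
    if (extra > 0) share[seq_len(extra)] <- share[seq_len(extra)] + 1L
    deficit <- share > sizes
    if (any(deficit) && !allow_smaller) {
      stop("class pool too small: need ", paste(share[deficit], collapse = ", "),
           " but have ", paste(sizes[deficit], collapse = ", "),
           " (conditions: ",
           paste(names(pools)[deficit], collapse = ", "),
           "); pass allow_smaller = TRUE to accept", call. = FALSE)
    }
    share <- pmin(share, sizes)
    picked <- mapply(function(tab, k) {
      tab[sample.int(nrow(tab), k), fset$features, drop = FALSE]
    }, pools, share, SIMPLIFY = FALSE)
    list(x = do.call(rbind, picked),
         condition = rep(names(pools) %||% seq_along(pools), share))
  }

  with_seed(child_seed(seed, "training"), {
    neg <- sample_class(control, as.integer(n_per_class))
    pos <- sample_class(treated, as.integer(n_per_class))
    x <- rbind(neg$x, pos$x)
    rownames(x) <- NULL
    y <- rep(c(0L, 1L), c(nrow(neg$x), nrow(pos$x)))
    structure(list(
      x = x, y = y,
      provenance = data.frame(condition = c(neg$condition, pos$condition),
                              mode = policy$mode),
      feature_set = fset, seed = as.integer(seed),
      class_counts = c(normal = nrow(neg$x), senescent = nrow(pos$x))
    ), class = "training_set")
  })
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set>", nrow(x$x), "cells (",
      x$class_counts[1], "normal /", x$class_counts[2], "senescent ),",
      format(x$feature_set), "\n")
  invisible(x)
}

split_holdout <- function(n, fraction) {
  m <- as.integer(round(n * fraction))
  test <- sample.int(n, m)
  list(train = setdiff(seq_len(n), test), test = test)
}

new_model <- function(kind, fset, fit, cutoff, metadata) {
  structure(list(kind = kind, feature_set = fset, fit = fit,
                 cutoff = cutoff, metadata = metadata),
            class = "senescence_model")
}

#' Train a pruned classification-tree senescence classifier
#'
#' Grows a Gini CART on the training portion, computes the weakest-link
#' cost-complexity sequence, and returns the subtree whose complexity
#' parameter alpha maximizes holdout accuracy (ties resolved to the larger
#' alpha, i.e. the simpler tree). Holdout accuracy and AUC are recorded in
#' the model metadata.
#'
#' @param ts A [build_training_set()] result.
#' @param holdout Fraction held out for alpha selection (default 0.3).
#' @param min_split,min_bucket,max_depth Tree growing controls.
#' @param seed Seed for the holdout split.
#' @return A `senescence_model` of kind `"tree"`.
#' @export
train_tree <- function(ts, holdout = 0.3, min_split = 20L, min_bucket = 7L,
                       max_depth = 30L, seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  assert_scalar_number(holdout, "holdout")
  if (holdout <= 0 || holdout >= 1) {
    stop("holdout fraction must be in (0, 1)", call. = FALSE)
  }
  if (length(unique(ts$y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- as.matrix(ts$x)
  with_seed(child_seed(seed, "holdout"), {
    sp <- split_holdout(nrow(X), holdout)
    full <- grow_cart(X[sp$train, , drop = FALSE], ts$y[sp$train],
                      min_split = min_split, min_bucket = min_bucket,
                      max_depth = max_depth)
    seqs <- cart_ccp_sequence(full, length(sp$train))
    y_test <- ts$y[sp$test]
    accs <- vapply(seqs, function(s) {
      pr <- predict_cart(s$tree, X[sp$test, , drop = FALSE])
      mean(as.integer(pr > 0.5) == y_test)
    }, numeric(1))
    # ties -> larger alpha (simpler tree); sequence is ordered by alpha
    best <- max(which(accs >= max(accs) - 1e-12))
    tree <- seqs[[best]]$tree
    prob <- predict_cart(tree, X[sp$test, , drop = FALSE])
    auc <- if (length(unique(y_test)) == 2L) auc_mann_whitney(prob, y_test)
    else NA_real_
    new_model("tree", ts$feature_set, tree, cutoff = 0.5, metadata = list(
      alpha = seqs[[best]]$alpha,
      alpha_grid = vapply(seqs, `[[`, numeric(1), "alpha"),
      holdout_accuracy = accs[best], holdout_auc = auc,
      n_leaves = cart_n_leaves(tree), seed = seed,
      holdout_fraction = holdout, class_counts = ts$class_counts,
      params = list(min_split = min_split, min_bucket = min_bucket,
                    max_depth = max_depth)
    ))
  })
}

#' Train a random-forest senescence classifier
#'
#' Bagged CART forest with per-split feature sampling. The per-cell
#' senescence probability is the fraction of trees voting senescent; a cell
#' is labelled senescent when the probability strictly exceeds the cutoff
#' (default 0.5, strict, so a cell exactly at the cutoff is called normal).
#'
#' @param ts A [build_training_set()] result.
#' @param holdout Holdout fraction for performance estimation (default 0.5).
#' @param n_trees Number of trees (default 100).
#' @param mtry Features sampled per split; default `floor(sqrt(p))`.
#' @param min_bucket,max_depth Tree growing controls (trees are unpruned).
#' @param cutoff Probability cutoff in (0, 1).
#' @param seed Seed for holdout split and bootstraps.
#' @return A `senescence_model` of kind `"forest"`.
#' @export
train_forest <- function(ts, holdout = 0.5, n_trees = 100L, mtry = NULL,
                         min_bucket = 5L, max_depth = 30L, cutoff = 0.5,
                         seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  if (holdout <= 0 || holdout >= 1) {
    stop("holdout fraction must be in (0, 1)", call. = FALSE)
  }
  assert_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must be in (0, 1)", call. = FALSE)
  }
  if (length(unique(ts$y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- as.matrix(ts$x)
  p <- ncol(X)
  mtry <- as.integer(mtry %||% max(1L, floor(sqrt(p))))
  with_seed(child_seed(seed, "forest"), {
    sp <- split_holdout(nrow(X), holdout)
    Xtr <- X[sp$train, , drop = FALSE]
    ytr <- ts$y[sp$train]
    trees <- lapply(seq_len(n_trees), function(b) {
      boot <- sample.int(length(ytr), length(ytr), replace = TRUE)
      grow_cart(Xtr[boot, , drop = FALSE], ytr[boot],
                min_split = 2L * min_bucket, min_bucket = min_bucket,
                max_depth = max_depth, mtry = mtry)
    })
    prob <- forest_prob(trees, X[sp$test, , drop = FALSE])
    y_test <- ts$y[sp$test]
    acc <- mean(as.integer(prob > cutoff) == y_test)
    auc <- if (length(unique(y_test)) == 2L) auc_mann_whitney(prob, y_test)
    else NA_real_
    new_model("forest", ts$feature_set, trees, cutoff = cutoff,
              metadata = list(
                n_trees = n_trees, mtry = mtry,
                holdout_accuracy = acc, holdout_auc = auc, seed = seed,
                holdout_fraction = holdout, class_counts = ts$class_counts,
                params = list(min_bucket = min_bucket, max_depth = max_depth)
              ))
  })
}

forest_prob <- function(trees, X) {
  votes <- vapply(trees, function(tr) {
    as.integer(predict_cart(tr, X) > 0.5)
  }, integer(nrow(X)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(X))
  rowMeans(votes)
}

#' @export
print.senescence_model <- function(x, ...) {
  cat("<senescence_model>", x$kind, "on", format(x$feature_set), "\n")
  if (x$kind == "tree") {
    cat("  leaves:", x$metadata$n_leaves, " alpha:",
        signif(x$metadata$alpha, 3), "\n")
  } else {
    cat("  trees:", x$metadata$n_trees, " mtry:", x$metadata$mtry, "\n")
  }
  cat("  holdout accuracy:", round(x$metadata$holdout_accuracy, 3),
      " AUC:", round(x$metadata$holdout_auc, 3), "\n")
  invisible(x)
}

model_matrix <- function(object, newdata) {
  fset <- object$feature_set
  missing <- setdiff(fset$features, colnames(newdata))
  if (length(missing) > 0L) {
    stop("prediction table is missing model features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(as.data.frame(newdata)[, fset$features, drop = FALSE])
}

#' Predict senescence per cell
#'
#' @param object A `senescence_model`.
#' @param newdata Feature table conforming to the model's schema.
#' @param type `"label"` (0/1 integer) or `"prob"`.
#' @param ... Unused.
#' @return Integer labels or numeric probabilities, one per row. Forest
#'   labels use the strict rule `probability > cutoff`.
#' @export
predict.senescence_model <- function(object, newdata,
                                     type = c("label", "prob"), ...) {
  type <- match.arg(type)
  X <- model_matrix(object, newdata)
  prob <- if (object$kind == "tree") {
    predict_cart(object$fit, X)
  } else {
    forest_prob(object$fit, X)
  }
  if (type == "prob") prob else as.integer(prob > object$cutoff)
}

#' Equal-weight voting consensus of senescence classifiers
#'
#' A democratic voting system with equal weight per member classifier: a
#' cell is called senescent if and only if strictly more than half of the
#' members vote senescent. With an even member count an exact tie is
#' resolved to non-senescent (conservative calling).
#'
#' @param models List of >= 2 `senescence_model` objects sharing one
#'   feature schema.
#' @return An object of class `consensus_ensemble`.
#' @export
consensus_ensemble <- function(models) {
  if (length(models) < 2L) {
    stop("a consensus needs at least 2 member models", call. = FALSE)
  }
  for (m in models) stopifnot(inherits(m, "senescence_model"))
  fsets <- unique(vapply(models, function(m) m$feature_set$name, character(1)))
  if (length(fsets) != 1L) {
    stop("all member models must share one feature set; got: ",
         paste(fsets, collapse = ", "), call. = FALSE)
  }
  structure(list(models = models, feature_set = models[[1]]$feature_set),
            class = "consensus_ensemble")
}

#' @export
predict.consensus_ensemble <- function(object, newdata,
                                       type = c("label", "votes"), ...) {
  type <- match.arg(type)
  votes <- vapply(object$models, function(m) {
    predict(m, newdata, type = "label")
  }, integer(nrow(newdata)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(newdata))
  total <- rowSums(votes)
  if (type == "votes") return(total)
  as.integer(total > length(object$models) / 2)
}

#' Summarize per-cell predictions per well
#'
#' @param labels 0/1 per-cell predicted labels.
#' @param wells Well assignment per cell (vector or factor; factor levels
#'   with no cells are reported as empty wells).
#' @return Data frame with `well`, `n_cells`, `n_senescent`,
#'   `pct_senescent` (percentage; `NA` for empty wells) and `empty` flag.
#' @export
summarize_wells <- function(labels, wells) {
  if (length(labels) != length(wells)) {
    stop("labels and wells must have equal length", call. = FALSE)
  }
  wells <- as.factor(wells)
  n <- as.integer(table(wells))
  n_sen <- as.integer(tapply(labels, wells, sum, default = 0L))
  data.frame(
    well = levels(wells),
    n_cells = n,
    n_senescent = n_sen,
    pct_senescent = ifelse(n > 0, 100 * n_sen / n, NA_real_),
    empty = n == 0L
  )
}

#' Save / load a senescence model
#'
#' Versioned single-file serialization (RDS with a schema tag); the feature
#' schema and training metadata travel with the model.
#'
#' @param model A `senescence_model` or `consensus_ensemble`.
#' @param path File path.
#' @return `save_model` the path, invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("senescence_model", "consensus_ensemble")))
  payload <- list(format = "senomorph-model", version = 1L, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "senomorph-model")) {
    stop("not a senomorph model file: ", path, call. = FALSE)
  }
  payload$model
}
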