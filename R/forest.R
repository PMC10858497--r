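#' Honest-forest configuration
#'
#' Bundles the tuning parameters of the honest regression forest. The
#' defaults for `practice = "reduced_till"` and `practice = "cover_crop"` are
#' the fitted-parameter sets used for forecasting county adoption rates of
#' tillage-reduction and cover-cropping practices; either can be overridden
#' field by field.
#'
#' @param practice `"reduced_till"`, `"cover_crop"`, or `NULL` for neutral
#'   defaults.
#' @param num_trees number of trees.
#' @param sample_fraction fraction of rows subsampled (without replacement)
#'   per tree.
#' @param mtry number of candidate predictors per split.
#' @param min_node_size minimum estimation-half observations per leaf.
#' @param alpha minimum fraction of a node's split-half observations that
#'   each child must retain (< 0.5).
#' @param imbalance_penalty non-negative penalty scaling
#'   `1/n_left + 1/n_right` in the split objective.
#' @param honesty_fraction fraction of each tree's subsample used to choose
#'   splits; the remainder estimates leaf means.
#' @param seed integer seed controlling all forest randomness.
#' @return A list of class `forest_config`.
#' @examples
#' forest_config("cover_crop", num_trees = 200)
#' @export
forest_config <- function(practice = NULL, num_trees = 2000,
                          sample_fraction = NULL, mtry = NULL,
                          min_node_size = NULL, alpha = NULL,
                          imbalance_penalty = NULL, honesty_fraction = 0.8,
                          seed = 1L) {
  defaults <- switch(
    if (is.null(practice)) "none" else practice,
    reduced_till = list(sample_fraction = 0.38, mtry = 10L,
                        min_node_size = 3L, alpha = 0.08,
                        imbalance_penalty = 0.72),
    cover_crop = list(sample_fraction = 0.45, mtry = 7L, min_node_size = 7L,
                      alpha = 0.14, imbalance_penalty = 0.36),
    none = list(sample_fraction = 0.5, mtry = 5L, min_node_size = 5L,
                alpha = 0.05, imbalance_penalty = 0),
    stop("unknown practice: ", practice, call. = FALSE)
  )
  cfg <- list(
    num_trees = as.integer(num_trees),
    sample_fraction = sample_fraction %||% defaults$sample_fraction,
    mtry = as.integer(mtry %||% defaults$mtry),
    min_node_size = as.integer(min_node_size %||% defaults$min_node_size),
    alpha = alpha %||% defaults$alpha,
    imbalance_penalty = imbalance_penalty %||% defaults$imbalance_penalty,
    honesty_fraction = honesty_fraction,
    seed = as.integer(seed)
  )
  stopifnot(cfg$num_trees >= 1,
            cfg$sample_fraction > 0, cfg$sample_fraction <= 1,
            cfg$honesty_fraction > 0, cfg$honesty_fraction < 1,
            cfg$mtry >= 1, cfg$min_node_size >= 1,
            cfg$alpha > 0, cfg$alpha < 0.5, cfg$imbalance_penalty >= 0)
  structure(cfg, class = "forest_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Log-ratio growth target
#'
#' The modelled outcome is the log ratio of practice acres across a census
#' wave pair, `ln(y_t / y_prev)`. Both arguments must be strictly positive;
#' rows with non-positive acreage are excluded upstream when assembling the
#' design matrix.
#'
#' @param y_t acres in the later wave.
#' @param y_prev acres in the earlier wave.
#' @return `log(y_t / y_prev)`, vectorized.
#' @examples
#' build_target(120, 100)  # log(1.2)
#' @export
build_target <- function(y_t, y_prev) {
  if (any(y_t <= 0) || any(y_prev <= 0)) {
    stop("build_target requires strictly positive acreage", call. = FALSE)
  }
  log(y_t / y_prev)
}

prepare_predictors <- function(data, predictors, medians = NULL) {
  X <- data[predictors]
  X[] <- lapply(X, as.numeric)
  has_na <- vapply(X, anyNA, logical(1))
  if (is.null(medians)) {
    medians <- vapply(X, function(col) {
      m <- median(col, na.rm = TRUE)
      if (is.na(m)) 0 else m
    }, numeric(1))
    indicator_cols <- predictors[has_na]
  } else {
    indicator_cols <- attr(medians, "indicator_cols")
  }
  for (nm in names(which(vapply(X, anyNA, logical(1))))) {
    X[[nm]][is.na(X[[nm]])] <- medians[[nm]]
  }
  for (nm in indicator_cols) {
    X[[paste0(nm, "_missing")]] <- as.numeric(is.na(data[[nm]]))
  }
  attr(medians, "indicator_cols") <- indicator_cols
  list(X = as.matrix(X), medians = medians)
}

#' Fit an honest regression forest
#'
#' Grows `config$num_trees` trees, each on a without-replacement subsample of
#' `sample_fraction * n` rows. The subsample is partitioned into a split half
#' (`honesty_fraction`) used to choose splits and a disjoint estimation half
#' used to compute leaf means, so leaf estimates never reuse observations
#' that shaped the tree ("honesty"). At each node `mtry` predictors are drawn
#' at random and the chosen split maximises the variance reduction of the
#' split-half responses minus `imbalance_penalty * (1/n_left + 1/n_right)`,
#' subject to each child holding at least `alpha` of the parent's split-half
#' points and at least `min_node_size` estimation-half points.
#'
#' Missing predictor cells are median-imputed from the training data and
#' accompanied by a per-column missingness-indicator predictor, so structured
#' missingness remains visible to the forest.
#'
#' @param data a data frame holding the target column, an id column, and
#'   numeric predictors (everything else).
#' @param config a [forest_config()].
#' @param target name of the target column (default `"target"`).
#' @param id_col name of the identifier column carried through but not used
#'   as a predictor (default `"county_id"`).
#' @return An object of class `honest_forest`.
#' @export
fit_honest_forest <- function(data, config = forest_config(),
                              target = "target", id_col = "county_id") {
  stopifnot(inherits(config, "forest_config"))
  if (!target %in% names(data)) {
    stop("target column `", target, "` not found", call. = FALSE)
  }
  y <- as.numeric(data[[target]])
  if (anyNA(y)) stop("missing values in the target", call. = FALSE)
  predictors <- setdiff(names(data), c(target, id_col))
  if (length(predictors) == 0) stop("no predictor columns", call. = FALSE)
  prep <- prepare_predictors(data, predictors)
  X <- prep$X
  cfg <- config
  if (cfg$mtry > ncol(X)) {
    message("mtry reduced to the number of predictors (", ncol(X), ")")
    cfg$mtry <- ncol(X)
  }
  n <- nrow(X)
  s <- floor(cfg$sample_fraction * n)
  if (floor(cfg$honesty_fraction * s) < 1 ||
      s - round(cfg$honesty_fraction * s) < cfg$min_node_size) {
    stop("sample too small for the requested honesty_fraction/min_node_size",
         call. = FALSE)
  }
  trees <- hf_fit(X, y, cfg$num_trees, cfg$sample_fraction, cfg$mtry,
                  cfg$min_node_size, cfg$alpha, cfg$imbalance_penalty,
                  cfg$honesty_fraction, as.integer(cfg$seed))
  structure(
    list(
      trees = trees,
      config = cfg,
      predictors = colnames(X),
      raw_predictors = predictors,
      medians = prep$medians,
      n_train = n,
      train_ids = if (id_col %in% names(data)) data[[id_col]] else NULL,
      target = target,
      id_col = id_col
    ),
    class = "honest_forest"
  )
}

#' @export
print.honest_forest <- function(x, ...) {
  cat(sprintf(
    "<honest_forest> %d trees, %d training rows, %d predictors\n",
    length(x$trees), x$n_train, length(x$predictors)
  ))
  invisible(x)
}

#' Predict from an honest forest
#'
#' @param object an `honest_forest`.
#' @param newdata data frame with the model's predictor columns; omit (or
#'   pass the training data) with `oob = TRUE` for out-of-bag predictions,
#'   where each training row is averaged only over trees whose subsample
#'   excluded it.
#' @param oob logical; return out-of-bag predictions on the training rows.
#' @param ... unused.
#' @return A tibble with `prediction` and `n_trees_used` (plus the id column
#'   when available). OOB rows with no eligible tree are `NA` and counted in
#'   the `n_missing_oob` attribute.
#' @export
predict.honest_forest <- function(object, newdata = NULL, oob = FALSE, ...) {
  if (oob) {
    if (is.null(newdata)) {
      stop("supply the training data to `newdata` for OOB predictions",
           call. = FALSE)
    }
    X <- conform_matrix(object, newdata)
    res <- hf_predict_oob(object$trees, X)
    out <- tibble::tibble(
      prediction = res$prediction,
      n_trees_used = res$n_oob_trees
    )
    attr(out, "n_missing_oob") <- sum(is.na(res$prediction))
  } else {
    if (is.null(newdata)) stop("`newdata` is required", call. = FALSE)
    X <- conform_matrix(object, newdata)
    out <- tibble::tibble(
      prediction = hf_predict(object$trees, X),
      n_trees_used = length(object$trees)
    )
  }
  if (!is.null(object$id_col) && object$id_col %in% names(newdata)) {
    out <- dplyr::bind_cols(
      tibble::tibble(!!object$id_col := newdata[[object$id_col]]), out
    )
  }
  out
}

conform_matrix <- function(object, newdata) {
  missing_cols <- setdiff(object$raw_predictors, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  prep <- prepare_predictors(newdata, object$raw_predictors, object$medians)
  X <- prep$X[, object$predictors, drop = FALSE]
  X
}

#' Depth-weighted split-frequency importance
#'
#' Importance of a predictor is the weighted count of splits it makes in the
#' forest's top four levels, with weight `1/depth` (root depth 1), normalised
#' to sum to one. This operationalises "most frequently used to make splits"
#' deterministically and scale-free.
#'
#' @param model an `honest_forest`.
#' @param max_depth deepest level counted (default 4).
#' @return A tibble `(predictor, importance)` sorted by decreasing
#'   importance. If the forest made no splits all importances are zero and
#'   the `pathological` attribute is set.
#' @export
split_importance <- function(model, max_depth = 4L) {
  counts <- numeric(length(model$predictors))
  for (tree in model$trees) {
    sel <- tree$split_var >= 0 & tree$depth <= max_depth
    if (!any(sel)) next
    w <- 1 / tree$depth[sel]
    v <- tree$split_var[sel] + 1L  # 0-based in C++
    for (k in seq_along(v)) counts[v[k]] <- counts[v[k]] + w[k]
  }
  total <- sum(counts)
  out <- tibble::tibble(
    predictor = model$predictors,
    importance = if (total > 0) counts / total else counts
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$predictor)
  if (total == 0) attr(out, "pathological") <- TRUE
  out
}

#' Two-stage forest fit with variable selection
#'
#' Fits an initial forest on all predictors, retains the predictors whose
#' depth-weighted split importance is at least the uniform share `1/p`
#' (`p` = number of predictors the initial forest saw), and refits the final
#' forest on the retained set with a fresh seed offset. This iterative
#' procedure guards predictive performance when many predictors are noise.
#' If no predictor clears the threshold (degenerate fits), the top
#' `ceiling(p/4)` predictors are retained instead, with a warning.
#'
#' @inheritParams fit_honest_forest
#' @return A list of class `iterative_forest` with elements `model` (the
#'   final `honest_forest`), `selected` (retained predictor names, as columns
#'   of `data`), `initial_importance`, and `initial_model`.
#' @export
iterative_train <- function(data, config = forest_config(),
                            target = "target", id_col = "county_id") {
  stage1 <- fit_honest_forest(data, config, target, id_col)
  imp <- split_importance(stage1)
  p <- length(stage1$predictors)
  keep <- imp$predictor[imp$importance >= 1 / p]
  if (length(keep) == 0) {
    warning("no predictor reached the 1/p importance threshold; ",
            "retaining the top ceiling(p/4) predictors")
    keep <- head(imp$predictor, ceiling(p / 4))
  }
  # map derived missingness indicators back to their source columns
  raw_keep <- unique(vapply(keep, function(nm) {
    if (nm %in% stage1$raw_predictors) nm else sub("_missing$", "", nm)
  }, character(1)))
  raw_keep <- intersect(stage1$raw_predictors, raw_keep)
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  cfg2$mtry <- min(config$mtry, length(raw_keep))
  keep_cols <- c(intersect(c(id_col, target), names(data)), raw_keep)
  stage2 <- fit_honest_forest(data[keep_cols], cfg2, target, id_col)
  structure(
    list(model = stage2, selected = raw_keep, initial_importance = imp,
         initial_model = stage1),
    class = "iterative_forest"
  )
}

#' @export
print.iterative_forest <- function(x, ...) {
  cat(sprintf(
    "<iterative_forest> %d of %d predictors retained\n",
    length(x$selected), length(x$initial_model$raw_predictors)
  ))
  print(x$model)
  invisible(x)
}

#' Out-of-bag calibration test
#'
#' Regresses the observed targets on two regressors without an intercept:
#' the overall mean out-of-bag prediction (a constant) and the demeaned
#' per-row out-of-bag prediction. A mean-prediction coefficient near 1 says
#' the forest's average level is right; a differential-prediction coefficient
#' near 1 says the forest's heterogeneity is neither over- nor under-stated.
#' Standard errors are heteroskedasticity-robust (HC3); p-values are
#' one-sided (`Pr(>t)`).
#'
#' @param oob_predictions numeric vector of out-of-bag predictions (NAs
#'   dropped pairwise with `y`).
#' @param y observed targets, same length.
#' @return An object of class `calibration_test`; use [tidy()] for the
#'   coefficient table.
#' @export
calibration_test <- function(oob_predictions, y) {
  stopifnot(length(oob_predictions) == length(y))
  ok <- !is.na(oob_predictions) & !is.na(y)
  p <- oob_predictions[ok]
  yy <- y[ok]
  if (length(yy) < 10) {
    stop("need at least 10 non-missing out-of-bag predictions",
         call. = FALSE)
  }
  mean_pred <- mean(p)
  mean_reg <- rep(mean_pred, length(p))
  diff_reg <- p - mean_pred
  degenerate <- var(diff_reg) == 0 || mean_pred == 0
  if (var(diff_reg) == 0) {
    fit <- lm(yy ~ 0 + mean_reg)
    ct <- lmtest::coeftest(fit, vcov = sandwich::vcovHC(fit, type = "HC3"))
    est <- c(ct[1, 1], NA)
    se <- c(ct[1, 2], NA)
  } else {
    fit <- lm(yy ~ 0 + mean_reg + diff_reg)
    ct <- lmtest::coeftest(fit, vcov = sandwich::vcovHC(fit, type = "HC3"))
    est <- ct[, 1]
    se <- ct[, 2]
  }
  tval <- est / se
  df <- length(yy) - sum(!is.na(est))
  structure(
    list(
      estimates = tibble::tibble(
        term = c("mean_forest_prediction", "differential_forest_prediction"),
        estimate = unname(est),
        std.error = unname(se),
        t.value = unname(tval),
        p.value = unname(pt(tval, df, lower.tail = FALSE))
      ),
      n = length(yy),
      df = df,
      mean_oob_prediction = mean_pred,
      degenerate = degenerate
    ),
    class = "calibration_test"
  )
}

#' @export
print.calibration_test <- function(x, ...) {
  cat(sprintf("<calibration_test> n = %d out-of-bag observations\n", x$n))
  print(as.data.frame(x$estimates), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname calibration_test
#' @param x a `calibration_test`.
#' @param ... unused.
#' @export
tidy.calibration_test <- function(x, ...) x$estimates

#' @rdname calibration_test
#' @export
glance.calibration_test <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    mean_oob_prediction = x$mean_oob_prediction,
    degenerate = x$degenerate
  )
}

#' @rdname fit_honest_forest
#' @param x an `honest_forest` (for `tidy`/`glance`).
#' @param ... unused.
#' @details `tidy()` on an `honest_forest` returns the split-importance
#'   table; `glance()` returns one row of fit metadata.
#' @export
tidy.honest_forest <- function(x, ...) split_importance(x)

#' @rdname fit_honest_forest
#' @export
glance.honest_forest <- function(x, ...) {
  n_nodes <- vapply(x$trees, function(t) length(t$split_var), integer(1))
  tibble::tibble(
    num_trees = length(x$trees),
    n_train = x$n_train,
    n_predictors = length(x$predictors),
    mean_nodes_per_tree = mean(n_nodes),
    seed = x$config$seed
  )
}

#' Persist an honest forest to plain-text tables
#'
#' Writes `manifest.json` (config, predictor manifest, imputation medians)
#' plus `nodes.csv` (one row per tree node) and `subsamples.csv` (per-tree
#' subsample membership with the split/estimation role of each row).
#'
#' @param model an `honest_forest`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_forest_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(model$config),
    predictors = model$predictors,
    raw_predictors = model$raw_predictors,
    medians = as.list(model$medians),
    indicator_cols = attr(model$medians, "indicator_cols"),
    n_train = model$n_train,
    target = model$target,
    id_col = model$id_col
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  nodes <- purrr::imap_dfr(model$trees, function(tr, t) {
    tibble::tibble(
      tree = t, node = seq_along(tr$split_var) - 1L,
      split_var = tr$split_var, split_val = tr$split_val,
      left = tr$left, right = tr$right,
      leaf_value = tr$leaf_value, depth = tr$depth, n_est = tr$n_est
    )
  })
  readr::write_csv(nodes, file.path(dir, "nodes.csv"))
  subs <- purrr::imap_dfr(model$trees, function(tr, t) {
    tibble::tibble(
      tree = t, row = tr$subsample,
      role = ifelse(tr$subsample %in% tr$split_idx, "split", "estimate")
    )
  })
  readr::write_csv(subs, file.path(dir, "subsamples.csv"))
  invisible(dir)
}

#' Read back a persisted honest forest
#'
#' @param dir directory written by [write_forest_model()].
#' @return An `honest_forest`.
#' @export
read_forest_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"),
                           show_col_types = FALSE)
  subs <- readr::read_csv(file.path(dir, "subsamples.csv"),
                          show_col_types = FALSE)
  trees <- lapply(sort(unique(nodes$tree)), function(t) {
    nd <- nodes[nodes$tree == t, ]
    sb <- subs[subs$tree == t, ]
    list(
      split_var = as.integer(nd$split_var), split_val = nd$split_val,
      left = as.integer(nd$left), right = as.integer(nd$right),
      leaf_value = nd$leaf_value, depth = as.integer(nd$depth),
      n_est = as.integer(nd$n_est),
      subsample = as.integer(sb$row),
      split_idx = as.integer(sb$row[sb$role == "split"]),
      est_idx = as.integer(sb$row[sb$role == "estimate"])
    )
  })
  cfg <- structure(manifest$config, class = "forest_config")
  cfg$num_trees <- as.integer(cfg$num_trees)
  cfg$mtry <- as.integer(cfg$mtry)
  cfg$min_node_size <- as.integer(cfg$min_node_size)
  cfg$seed <- as.integer(cfg$seed)
  medians <- unlist(manifest$medians)
  attr(medians, "indicator_cols") <- manifest$indicator_cols %||% character(0)
  structure(
    list(
      trees = trees, config = cfg, predictors = manifest$predictors,
      raw_predictors = manifest$raw_predictors, medians = medians,
      n_train = manifest$n_train, train_ids = NULL,
      target = manifest$target, id_col = manifest$id_col
    ),
    class = "honest_forest"
  )
}
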