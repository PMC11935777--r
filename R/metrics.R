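# Confusion counts, the eight-metric suite, stratified folds and
# end-to-end cross-validation.

#' Confusion counts from two label vectors
#'
#' @param y_true,y_pred Equal-length vectors with values in \{0, 1\}.
#' @return A tibble with one row: columns `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_input("y_true and y_pred must have equal length")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop_input("labels must be in {0, 1}")
  }
  tibble::tibble(tp = sum(y_true == 1 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0))
}

#' Metric suite from confusion counts
#'
#' Computes accuracy, precision, recall (sensitivity), specificity, F1,
#' Matthews correlation coefficient, false-positive rate and false-negative
#' rate. FPR and FNR are derived from the identities `1 - specificity` and
#' `1 - recall`. Any metric whose denominator is zero is reported as 0 and
#' listed in the `flagged` column.
#'
#' @param counts A one-row data frame with columns `tp`, `tn`, `fp`, `fn`
#'   (e.g. from [confusion_counts()]), or a named vector/list.
#' @return A one-row tibble with the eight metrics, the four counts and a
#'   `flagged` character column (comma-separated zero-denominator metrics,
#'   `""` if none).
#' @export
#' @examples
#' compute_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)))
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  need <- c("tp", "tn", "fp", "fn")
  if (!all(need %in% names(counts))) {
    stop_input("counts must provide tp, tn, fp, fn")
  }
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) stop_input("counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total == 0) stop_input("no evaluated pairs (all counts zero)")
  flagged <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) {
      flagged <<- c(flagged, what)
      0
    } else num / den
  }
  accuracy <- (tp + tn) / total
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- max(-1, min(1, safe(tp * tn - fp * fn, mcc_den, "mcc")))
  tibble::tibble(accuracy = accuracy, precision = precision, recall = recall,
                 specificity = specificity, f1 = f1, mcc = mcc,
                 fpr = 1 - specificity, fnr = 1 - recall,
                 tp = tp, tn = tn, fp = fp, fn = fn,
                 flagged = paste(flagged, collapse = ","))
}

#' Stratified fold assignment
#'
#' Splits observations into `k` disjoint folds preserving class proportions:
#' per class, fold sizes differ by at most one, and the leftover
#' observations of the classes are spread cyclically over a seeded random
#' fold order so total fold sizes also differ by at most one. Deterministic
#' given `seed`.
#'
#' @param labels Vector of class labels (any type).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, one per observation.
#' @export
#' @examples
#' table(stratified_folds(rep(c(0, 1), c(40, 60)), k = 10, seed = 1),
#'       rep(c(0, 1), c(40, 60)))
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop_input("k must be >= 2")
  tab <- table(labels)
  if (any(tab < k)) {
    stop_input(paste0("class(es) smaller than k: ",
                      paste(names(tab)[tab < k], collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_order <- sample.int(k)   # receives the per-class leftovers cyclically
  assignment <- integer(length(labels))
  extra_ptr <- 0L
  for (cl in names(tab)) {
    members <- which(labels == cl)
    members <- members[sample.int(length(members))]
    n_c <- length(members)
    base <- n_c %/% k
    r <- n_c %% k
    sizes <- rep(base, k)
    if (r > 0L) {
      take <- fold_order[((extra_ptr + seq_len(r) - 1L) %% k) + 1L]
      sizes[take] <- sizes[take] + 1L
      extra_ptr <- extra_ptr + r
    }
    assignment[members] <- rep(seq_len(k), times = sizes)
  }
  assignment
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold: per-protein features are computed, the pair matrix is
#' assembled, a standardizer and the classifier are fitted on the training
#' 90% only, and the held-out 10% is scored. When the PSSM block is enabled
#' it is, by default, refitted within each fold on the sequences referenced
#' by the training pairs only (no information from held-out pairs leaks
#' into the features); `pssm_fit = "all"` reproduces a single global fit on
#' the whole collection. All other blocks depend only on the individual
#' sequence and are computed once.
#'
#' @param dataset A [pair_dataset()].
#' @param encoder An [encoder_config()].
#' @param model A [model_config()]; each fold trains with seed
#'   `model$seed + fold`.
#' @param aaindex An `aaindex_table` when the AAindex block is enabled.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param pssm_fit `"train"` (default, per-fold leakage-free fit) or
#'   `"all"` (single fit on every sequence).
#' @param symmetric Passed to [assemble_pair_features()] for the training
#'   rows (held-out rows are never augmented).
#' @param keep_fold_details Keep per-fold standardizer summaries and
#'   held-out probabilities (used by diagnostics; default `FALSE`).
#' @param progress Emit a message per fold.
#' @return An object of class `cv_report`: per-fold metrics (`folds`),
#'   fold-mean and fold-sd aggregates (`summary`), metrics of the pooled
#'   confusion matrix (`pooled`), the fold `assignments`, and the
#'   configurations used.
#' @export
cross_validate <- function(dataset, encoder = encoder_config(),
                           model = model_config(), aaindex = NULL,
                           k = 10L, seed = 1L,
                           pssm_fit = c("train", "all"),
                           symmetric = FALSE,
                           keep_fold_details = FALSE,
                           progress = FALSE) {
  pssm_fit <- match.arg(pssm_fit)
  if (!inherits(dataset, "pair_dataset")) {
    stop_input("'dataset' must be a pair_dataset")
  }
  if (encoder$use_aaindex && is.null(aaindex)) {
    stop_input("AAindex block enabled but no AAindex table given")
  }
  pairs <- dataset$pairs
  assignments <- stratified_folds(pairs$label, k = k, seed = seed)

  # Blocks other than the PSSM depend only on the sequence: compute once.
  static_cfg <- disable_blocks(encoder, "pssm")
  have_static <- any(c(static_cfg$use_ct, static_cfg$use_sct,
                       static_cfg$use_aaindex, static_cfg$use_hydropathy,
                       static_cfg$use_aapd))
  static <- if (have_static) {
    protein_feature_blocks(dataset$sequences, static_cfg, aaindex = aaindex)
  } else NULL

  global_pssm_block <- NULL
  if (encoder$use_pssm && pssm_fit == "all") {
    gp <- build_dataset_pssm(dataset$sequences, encoder)
    global_pssm_block <- .pssm_block_matrix(dataset$sequences, gp, encoder)
  }

  fold_rows <- vector("list", k)
  details <- vector("list", k)
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (fold in seq_len(k)) {
    test_rows <- which(assignments == fold)
    train_rows <- which(assignments != fold)
    features <- .fold_feature_matrix(dataset, encoder, static,
                                     global_pssm_block, train_rows)
    ds_train <- pair_dataset(pairs[train_rows, ], dataset$sequences)
    ds_test <- pair_dataset(pairs[test_rows, ], dataset$sequences)
    tr <- assemble_pair_features(ds_train, features, symmetric = symmetric)
    te <- assemble_pair_features(ds_test, features)
    fold_cfg <- model
    fold_cfg$seed <- model$seed + fold
    fit <- tryCatch(
      train_classifier(x = tr$x, y = tr$y, config = fold_cfg,
                       schema = attr(tr$x, "schema")),
      error = function(e) {
        rlang::abort(paste0("fold ", fold, ": ", conditionMessage(e)),
                     class = class(e)[1])
      })
    pred <- predict(fit, te$x)
    cm <- confusion_counts(te$y, pred$label)
    pooled <- pooled + unlist(cm)
    fold_rows[[fold]] <- dplyr::bind_cols(tibble::tibble(fold = fold),
                                          compute_metrics(cm))
    if (keep_fold_details) {
      xs_train <- apply_standardizer(fit$standardizer, tr$x)
      xs_test <- apply_standardizer(fit$standardizer, te$x)
      details[[fold]] <- list(
        train_feature_mean_max = max(abs(colMeans(xs_train))),
        test_feature_mean_max = max(abs(colMeans(xs_test))),
        prob = pred$prob, y = te$y, best_epoch = fit$best_epoch)
    }
    if (progress) {
      message(sprintf("fold %d/%d: accuracy %.3f", fold, k,
                      fold_rows[[fold]]$accuracy))
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("accuracy", "precision", "recall", "specificity",
                   "f1", "mcc", "fpr", "fnr")
  summary <- tidyr::pivot_longer(folds[, c("fold", metric_cols)],
                                 -"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metric_cols))
  structure(list(folds = folds, summary = summary,
                 pooled = compute_metrics(as.list(pooled)),
                 assignments = assignments, seed = seed, k = k,
                 encoder = encoder, model = model, pssm_fit = pssm_fit,
                 details = if (keep_fold_details) details else NULL),
            class = "cv_report")
}

# per-protein PSSM block matrix for a fitted pssm
.pssm_block_matrix <- function(records, pssm, config) {
  first <- pssm_features(records$seq[[1]], pssm, config)
  m <- matrix(0, nrow = nrow(records), ncol = length(first),
              dimnames = list(records$id, names(first)))
  m[1, ] <- first
  if (nrow(records) > 1L) {
    for (i in 2:nrow(records)) {
      m[i, ] <- pssm_features(records$seq[[i]], pssm, config)
    }
  }
  m
}

# assemble the per-protein feature matrix for one fold, refitting the PSSM
# on training-pair sequences when required
.fold_feature_matrix <- function(dataset, encoder, static,
                                 global_pssm_block, train_rows) {
  pssm_block <- NULL
  if (encoder$use_pssm) {
    pssm_block <- global_pssm_block
    if (is.null(pssm_block)) {
      train_ids <- unique(c(dataset$pairs$id_a[train_rows],
                            dataset$pairs$id_b[train_rows]))
      train_recs <- dataset$sequences[dataset$sequences$id %in% train_ids, ]
      pssm <- build_dataset_pssm(train_recs, encoder)
      pssm_block <- .pssm_block_matrix(dataset$sequences, pssm, encoder)
    }
  }
  order_all <- c("ct", "sct", "pssm", "aaindex", "hydropathy", "aapd")
  blocks <- list()
  for (nm in order_all) {
    if (nm == "pssm") {
      if (!is.null(pssm_block)) blocks$pssm <- pssm_block
    } else if (!is.null(static) && nm %in% names(static$blocks)) {
      blocks[[nm]] <- static$blocks[[nm]]
    }
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- dataset$sequences$id
  dims <- vapply(blocks, ncol, integer(1))
  attr(x, "schema") <- tibble::tibble(
    block = names(dims), dim = as.integer(dims),
    offset = cumsum(c(0L, utils::head(as.integer(dims), -1))))
  x
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$k, "-fold stratified cross-validation (seed ",
      x$seed, ")\n", sep = "")
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("  mean accuracy %.4f (sd %.4f); pooled accuracy %.4f\n",
              acc$mean, acc$sd, x$pooled$accuracy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(tibble::as_tibble(wide),
                   tibble::tibble(k = x$k, seed = x$seed,
                                  pooled_accuracy = x$pooled$accuracy))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  metric_cols <- c("accuracy", "precision", "recall", "specificity",
                   "f1", "mcc")
  df <- tidyr::pivot_longer(object$folds[, c("fold", metric_cols)], -"fold",
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6,
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Value",
                  title = "Per-fold cross-validation metrics",
                  subtitle = "Red bar: fold mean") +
    ggplot2::theme_minimal()
}

#' Table-style summary of a cross-validation report
#'
#' One row per metric with fold-mean, fold-sd and pooled value, convenient
#' for writing a benchmark-style TSV.
#'
#' @param report A `cv_report`.
#' @return A tibble with columns `metric`, `mean`, `sd`, `pooled`.
#' @export
cv_summary_table <- function(report) {
  if (!inherits(report, "cv_report")) stop_input("not a cv_report")
  pooled <- report$pooled
  dplyr::mutate(report$summary,
                pooled = vapply(.data$metric,
                                function(m) pooled[[m]], numeric(1)))
}
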