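#' Confusion counts and classification metrics
#'
#' `confusion_counts` tabulates true/false positives/negatives of binary
#' predictions; `accuracy` and `f1` compute
#' `(TP + TN) / (TP + TN + FP + FN)` and `2 TP / (2 TP + FP + FN)`.
#' With no positives anywhere (`2 TP + FP + FN = 0`) the F1 score is
#' undefined and returned as `NA` with a warning.
#'
#' @param truth 0/1 vector of actual labels
#' @param pred 0/1 vector of predicted labels
#' @return `confusion_counts`: list with `TP`, `FP`, `TN`, `FN`
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) == 0L) stop("confusion_counts: empty evaluation set")
  if (length(truth) != length(pred))
    stop("confusion_counts: length mismatch")
  list(TP = sum(truth == 1 & pred == 1), FP = sum(truth == 0 & pred == 1),
       TN = sum(truth == 0 & pred == 0), FN = sum(truth == 1 & pred == 0))
}

#' @param counts a list with `TP`, `FP`, `TN`, `FN`
#' @rdname confusion_counts
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("accuracy: empty evaluation set")
  (counts$TP + counts$TN) / tot
}

#' @rdname confusion_counts
#' @export
f1 <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) {
    warning("f1: no positive labels or predictions; F1 undefined (NA)")
    return(NA_real_)
  }
  2 * counts$TP / den
}

#' Random k-fold cross-validation splits
#'
#' Random 80/20-style partitions: the indices are shuffled once and split
#' into `k` disjoint test sets whose union is the whole population.
#'
#' @param n population size (number of segments)
#' @param k number of folds
#' @param seed RNG seed
#' @return list of `k` lists with integer `train` and `test` index vectors
#' @export
kfold_splits <- function(n, k = 5L, seed = 1L) {
  if (k > n) stop("kfold_splits: k = ", k, " exceeds population size ", n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ord <- sample.int(n)
  fold_of <- rep(seq_len(k), length.out = n)[order(ord)]
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Pool trial sets into the segment-level feature table
#'
#' Runs baseline calibration (when a baseline window is present),
#' segmentation and band-PSD feature extraction on each subject and pools
#' the per-segment features with their inherited trial labels.
#'
#' @param trialsets list of `crgcn_trialset`
#' @param task `"valence"` or `"arousal"`
#' @param window_seconds,stride_seconds segmentation parameters
#' @param bands band definitions
#' @param psd_method PSD estimator
#' @param tie_rule rating tie rule, see [binarize_labels()]
#' @return list with `values` (`segments x channels x bands`), `labels`,
#'   `subject` (integer index per segment), `trial`
#' @export
pool_features <- function(trialsets, task = "valence",
                          window_seconds = 6, stride_seconds = 3,
                          bands = default_bands(), psd_method = "welch",
                          tie_rule = "low") {
  if (inherits(trialsets, "crgcn_trialset")) trialsets <- list(trialsets)
  vals <- NULL; labels <- integer(0); subject <- integer(0)
  trial <- integer(0)
  for (s in seq_along(trialsets)) {
    ts <- trialsets[[s]]
    if (ts$baseline_seconds > 0) ts <- calibrate_baseline(ts)
    segs <- segment_trials(ts, window_seconds, stride_seconds)
    fe <- extract_features(segs, bands = bands, method = psd_method)
    tl <- binarize_labels(ts$ratings, axis = task, tie_rule = tie_rule)
    sl <- tl[fe$trial]
    vals <- if (is.null(vals)) fe$values else
      abind_first(vals, fe$values)
    labels <- c(labels, sl)
    subject <- c(subject, rep(s, length(sl)))
    trial <- c(trial, fe$trial + (s - 1L) * dim(ts$data)[1L])
  }
  list(values = vals, labels = labels, subject = subject, trial = trial)
}

# bind two segments x channels x bands arrays along the first margin
abind_first <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1L] == db[-1L]))
  out <- array(0, dim = c(da[1L] + db[1L], da[2L], da[3L]))
  out[seq_len(da[1L]), , ] <- a
  out[da[1L] + seq_len(db[1L]), , ] <- b
  out
}

# one CV fold: normalize, build graph variant from the train split, train,
# evaluate on the test split
run_fold <- function(pool, split, adjacency, lambda, normalize, montage,
                     config) {
  tr <- split$train; te <- split$test
  if (normalize) {
    norm <- fit_normalizer(pool$values[tr, , , drop = FALSE])
    vals <- apply_normalizer(pool$values, norm)
  } else {
    vals <- pool$values
  }
  n_ch <- dim(vals)[2L]
  if (length(montage$channels) > n_ch)
    montage <- subset_montage(montage, seq_len(n_ch))
  g <- switch(adjacency,
    distance = distance_adjacency(montage),
    connectivity = connectivity_adjacency(vals[tr, , , drop = FALSE],
                                          lambda = lambda),
    fused = fuse_adjacency(
      distance_adjacency(montage),
      connectivity_adjacency(vals[tr, , , drop = FALSE], lambda = lambda)),
    stop("unknown adjacency variant: ", adjacency))
  if (nrow(g$adjacency) != n_ch)
    stop("run_fold: montage (", nrow(g$adjacency), " channels) does not ",
         "match features (", n_ch, ")")
  model <- train_crgcn(vals[tr, , , drop = FALSE], pool$labels[tr], g,
                       config)
  pred <- predict(model, vals[te, , , drop = FALSE])
  counts <- confusion_counts(pool$labels[te], pred)
  list(accuracy = accuracy(counts), f1 = f1(counts), counts = counts,
       n_test = length(te))
}

#' Run a cross-validated classification experiment
#'
#' The full pipeline under random k-fold cross-validation: per fold, the
#' feature normalizer and the functional-connectivity matrix are fitted on
#' the training split only, the chosen adjacency variant is assembled,
#' the classifier is trained, and accuracy/F1 are measured on the held-out
#' split. In `"subject-dependent"` mode the CV runs within each subject
#' separately; in `"subject-independent"` mode all subjects' segments are
#' pooled before splitting.
#'
#' @param trialsets list of `crgcn_trialset` (or one trial set)
#' @param task `"valence"` or `"arousal"`
#' @param mode `"subject-independent"` or `"subject-dependent"`
#' @param k folds
#' @param adjacency `"fused"`, `"distance"` or `"connectivity"`
#' @param lambda correlation retention threshold for the connectivity matrix
#' @param normalize z-score features (fitted on the training split)
#' @param montage electrode montage for the distance matrix
#' @param config a `crgcn_model_config`
#' @param window_seconds,stride_seconds,bands,psd_method feature options
#' @param shuffle_labels permute segment labels before splitting (null runs)
#' @param seed seed for splits (and the label shuffle)
#' @param pool precomputed [pool_features()] output (skips extraction; used
#'   by the ablation harness to share features and splits across variants)
#' @return a `crgcn_eval_report`: per-fold data.frame plus mean/min/max
#'   aggregates
#' @export
run_experiment <- function(trialsets, task = "valence",
                           mode = c("subject-independent",
                                    "subject-dependent"),
                           k = 5L, adjacency = "fused", lambda = 0.98,
                           normalize = TRUE, montage = default_montage(),
                           config = model_config(),
                           window_seconds = 6, stride_seconds = 3,
                           bands = default_bands(), psd_method = "welch",
                           shuffle_labels = FALSE, seed = 1L,
                           pool = NULL) {
  mode <- match.arg(mode)
  if (is.null(pool))
    pool <- pool_features(trialsets, task, window_seconds, stride_seconds,
                          bands, psd_method)
  if (shuffle_labels) {
    old <- .Random.seed_save()
    set.seed(seed + 104729L)
    pool$labels <- sample(pool$labels)
    .Random.seed_restore(old)
  }
  groups <- if (mode == "subject-dependent")
    split(seq_along(pool$labels), pool$subject) else
      list(pooled = seq_along(pool$labels))

  rows <- list(); split_ids <- character(0)
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    sub_pool <- list(values = pool$values[idx, , , drop = FALSE],
                     labels = pool$labels[idx])
    splits <- kfold_splits(length(idx), k = k, seed = seed + gi)
    for (f in seq_along(splits)) {
      cfg_f <- config
      cfg_f$seed <- config$seed + 1000L * gi + f
      res <- run_fold(sub_pool, splits[[f]], adjacency, lambda, normalize,
                      montage, cfg_f)
      rows[[length(rows) + 1L]] <-
        data.frame(group = names(groups)[gi] %||% as.character(gi),
                   fold = f, accuracy = res$accuracy, f1 = res$f1,
                   n_test = res$n_test)
      split_ids <- c(split_ids,
                     paste0(gi, ":", f, ":", sum(splits[[f]]$test),
                            ":", length(splits[[f]]$test)))
    }
  }
  folds <- do.call(rbind, rows)
  f1v <- folds$f1[!is.na(folds$f1)]
  structure(list(task = task, mode = mode, adjacency = adjacency,
                 normalize = normalize, lambda = lambda, folds = folds,
                 split_id = paste(split_ids, collapse = ";"),
                 summary = list(
                   mean_accuracy = mean(folds$accuracy),
                   min_accuracy = min(folds$accuracy),
                   max_accuracy = max(folds$accuracy),
                   mean_f1 = if (length(f1v)) mean(f1v) else NA_real_,
                   min_f1 = if (length(f1v)) min(f1v) else NA_real_,
                   max_f1 = if (length(f1v)) max(f1v) else NA_real_)),
            class = "crgcn_eval_report")
}

#' @export
print.crgcn_eval_report <- function(x, ...) {
  s <- x$summary
  cat("<crgcn_eval_report> ", x$task, ", ", x$mode, ", adjacency = ",
      x$adjacency, if (!is.null(x$lambda)) paste0(" (lambda = ", x$lambda, ")"),
      ", normalization ", if (x$normalize) "on" else "off", "\n",
      "  accuracy mean ", sprintf("%.4f", s$mean_accuracy),
      " [", sprintf("%.4f", s$min_accuracy), ", ",
      sprintf("%.4f", s$max_accuracy), "]  F1 mean ",
      sprintf("%.4f", s$mean_f1), "\n", sep = "")
  invisible(x)
}

#' Ablation harness over adjacency variants and normalization
#'
#' Evaluates several pipeline variants on identical features and identical
#' cross-validation splits (shared seed), so that differences in the
#' reported accuracies are attributable to the variant alone.
#'
#' @param trialsets list of `crgcn_trialset`
#' @param variants list of lists with elements `adjacency`
#'   (`"distance"`/`"connectivity"`/`"fused"`), `lambda`, `normalize` and
#'   optionally `name`
#' @param ... options forwarded to [run_experiment()] (task, k, config,
#'   seed, ...)
#' @return list of class `crgcn_ablation`: `reports` (one
#'   `crgcn_eval_report` per variant) and `table` (variant summary
#'   data.frame)
#' @export
run_ablation <- function(trialsets,
                         variants = list(
                           list(name = "distance", adjacency = "distance",
                                normalize = TRUE),
                           list(name = "cc>0.5", adjacency = "connectivity",
                                lambda = 0.5, normalize = TRUE),
                           list(name = "cc>0.98", adjacency = "connectivity",
                                lambda = 0.98, normalize = TRUE),
                           list(name = "distance+cc>0.5", adjacency = "fused",
                                lambda = 0.5, normalize = TRUE),
                           list(name = "distance+cc>0.98", adjacency = "fused",
                                lambda = 0.98, normalize = TRUE)),
                         ...) {
  dots <- list(...)
  pool_args <- list(trialsets = trialsets,
                    task = dots$task %||% "valence",
                    window_seconds = dots$window_seconds %||% 6,
                    stride_seconds = dots$stride_seconds %||% 3,
                    bands = dots$bands %||% default_bands(),
                    psd_method = dots$psd_method %||% "welch")
  pool <- do.call(pool_features, pool_args)
  reports <- lapply(variants, function(v) {
    args <- c(list(trialsets = trialsets,
                   adjacency = v$adjacency %||% "fused",
                   lambda = v$lambda %||% 0.98,
                   normalize = v$normalize %||% TRUE,
                   pool = pool),
              dots)
    do.call(run_experiment, args)
  })
  names(reports) <- vapply(variants, function(v)
    v$name %||% v$adjacency, character(1))
  tab <- data.frame(
    variant = names(reports),
    adjacency = vapply(reports, function(r) r$adjacency, character(1)),
    normalize = vapply(reports, function(r) r$normalize, logical(1)),
    lambda = vapply(reports, function(r) r$lambda %||% NA_real_,
                    numeric(1)),
    mean_accuracy = vapply(reports, function(r) r$summary$mean_accuracy,
                           numeric(1)),
    mean_f1 = vapply(reports, function(r) r$summary$mean_f1, numeric(1)),
    row.names = NULL)
  structure(list(reports = reports, table = tab), class = "crgcn_ablation")
}

#' @export
print.crgcn_ablation <- function(x, ...) {
  cat("<crgcn_ablation> ", nrow(x$table), " variants\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}
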