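# Confusion-matrix arithmetic and end-to-end pipeline orchestration.

#' Two-class confusion matrix (rows = predicted, columns = actual)
#'
#' @param pred,truth equal-length vectors of `"good"`/`"ng"` labels.
#' @return an integer 2 x 2 matrix of class `"confusion2"` with
#'   dimnames `predicted` x `actual`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth) || !length(pred))
    stop("pred and truth must have equal, nonzero length")
  classes <- c("good", "ng")
  pred <- factor(as.character(pred), levels = classes)
  truth <- factor(as.character(truth), levels = classes)
  if (anyNA(pred) || anyNA(truth)) stop("labels must be 'good' or 'ng'")
  cm <- table(predicted = pred, actual = truth)
  structure(unclass(cm), class = "confusion2")
}

#' Per-class and overall accuracy of a confusion matrix
#'
#' Per-class accuracy is the correctly classified fraction of each actual
#' class (column); overall accuracy is the pooled fraction correct, i.e.
#' the sample-weighted mean of the per-class accuracies. All three are
#' reported as percentages rounded to 2 decimals.
#'
#' @param cm a `"confusion2"` matrix, or any 2 x 2 matrix in the same
#'   orientation (rows = predicted, columns = actual, order good then ng).
#' @return named numeric vector `acc_good`, `acc_ng`, `acc_overall` (%).
#' @export
accuracies <- function(cm) {
  m <- unclass(cm)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0))
  tot <- colSums(m)
  if (any(tot == 0)) stop("empty actual class column")
  c(acc_good = round(100 * m[1, 1] / tot[[1]], 2),
    acc_ng = round(100 * m[2, 2] / tot[[2]], 2),
    acc_overall = round(100 * (m[1, 1] + m[2, 2]) / sum(m), 2))
}

#' @export
print.confusion2 <- function(x, ...) {
  cat("confusion matrix (rows predicted, columns actual):\n")
  print(matrix(unclass(x), 2, 2,
               dimnames = list(predicted = c("good", "ng"),
                               actual = c("good", "ng"))))
  acc <- accuracies(x)
  cat(sprintf("accuracy: good %.2f%%, NG %.2f%%, overall %.2f%%\n",
              acc[1], acc[2], acc[3]))
  invisible(x)
}

#' Classify segmented frames with the dual-network AND rule
#'
#' For each frame: segment, extract the 27 descriptors per seed, feed the
#' shape network its selected shape features and the color-texture network
#' its selected color/texture features, and combine the two decisions with
#' the AND rule (good only if both networks say good). Frames that yield
#' no region are skipped with a message.
#'
#' @param frames list of H x W x 3 arrays (or a single frame).
#' @param shape_model,colortex_model fitted [bpnn()] models whose
#'   `feature_names` name the selected columns.
#' @param config segmentation/feature parameters, see [default_config()].
#' @param truth optional vector of per-seed ground-truth labels (in
#'   region order across frames); when given the report includes a
#'   confusion matrix.
#' @return list with `labels` data frame (frame, region, shape_label,
#'   colortex_label, label) and, when `truth` is given, `confusion` and
#'   `accuracy`.
#' @export
run_pipeline <- function(frames, shape_model, colortex_model,
                         config = default_config(), truth = NULL) {
  if (is.array(frames)) frames <- list(frames)
  rows <- list()
  for (fi in seq_along(frames)) {
    regions <- segment_frame(frames[[fi]],
                             method = config$threshold_mode,
                             fixed_t = config$fixed_t,
                             radius = config$morph_radius,
                             min_area = config$min_area)
    if (!length(regions)) {
      message(sprintf("frame %d: no regions found, skipped", fi))
      next
    }
    for (ri in seq_along(regions)) {
      feats <- extract_features(regions[[ri]],
                                d = config$glcm_distance,
                                levels = config$glcm_levels,
                                similarity_t = config$lsp_similarity_t,
                                coarseness_kmax = config$coarseness_kmax)
      fv <- as.data.frame(as.list(feats))
      sl <- as.character(predict(shape_model, fv)$label)
      cl <- as.character(predict(colortex_model, fv)$label)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fi, region = ri, shape_label = sl, colortex_label = cl,
        label = combine_labels(sl, cl), stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, rows)
  out <- list(labels = labels)
  if (!is.null(truth)) {
    cm <- confusion(labels$label, truth)
    out$confusion <- cm
    out$accuracy <- accuracies(cm)
  }
  out
}

#' Train the dual-network classifier with feature selection
#'
#' Runs SFFS over the shape pool (basic feature: out-of-roundness, No. 9)
#' and the color-texture pool (basic feature: mean gray, No. 6) against
#' validation accuracy, then refits one network per pool on its selected
#' subset.
#'
#' @param train,validation labeled feature tables from
#'   [make_feature_dataset()] (disjoint rows).
#' @param cfg [train_config()] used for the subset criterion fits.
#' @param final_cfg [train_config()] for the final refits (defaults to
#'   `cfg`).
#' @param shape_basic,colortex_basic basic (starting) feature numbers.
#' @param max_steps SFFS step budget per pool.
#' @return list with `shape`/`colortex` fitted models, the two
#'   `sffs_trace` objects, and the selected feature numbers.
#' @export
train_seed_classifier <- function(train, validation,
                                  cfg = train_config(max_epochs = 300L),
                                  final_cfg = NULL,
                                  shape_basic = 9L, colortex_basic = 6L,
                                  max_steps = 30L) {
  if (is.null(final_cfg)) final_cfg <- cfg
  tr_s <- sffs(1:15, shape_basic,
               make_subset_criterion(train, validation, "shape", cfg),
               max_steps = max_steps)
  tr_c <- sffs(1:12, colortex_basic,
               make_subset_criterion(train, validation, "colortex", cfg),
               max_steps = max_steps)
  cols_s <- pool_columns("shape", tr_s$best_subset)
  cols_c <- pool_columns("colortex", tr_c$best_subset)
  both <- rbind(train, validation)
  fit_s <- suppressWarnings(
    bpnn(as.matrix(both[, cols_s, drop = FALSE]), both$label, cfg = final_cfg))
  fit_c <- suppressWarnings(
    bpnn(as.matrix(both[, cols_c, drop = FALSE]), both$label, cfg = final_cfg))
  list(shape = fit_s, colortex = fit_c,
       shape_trace = tr_s, colortex_trace = tr_c,
       shape_subset = tr_s$best_subset, colortex_subset = tr_c$best_subset)
}
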