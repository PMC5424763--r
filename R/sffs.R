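# Sequential floating forward selection (SFFS) over a feature pool
# against a classifier-accuracy criterion.

.subset_key <- function(s) paste(sort(s), collapse = ",")

#' Sequential floating forward selection
#'
#' Starting from a single basic feature, repeatedly (i) adds the feature
#' with the largest criterion gain, then (ii) conditionally removes
#' features while removal strictly improves the best criterion previously
#' recorded at the smaller subset size (classic floating behavior; the
#' feature just added is never removed immediately). The search stops when
#' the pool is exhausted, when `max_steps` subsets have been visited, or
#' when the best available addition fails to strictly improve on the best
#' criterion previously seen at the resulting subset size. Ties are broken
#' toward the lowest feature number. Criterion values are cached, so a
#' deterministic criterion yields a deterministic trace.
#'
#' @param pool integer vector of candidate feature numbers.
#' @param basic the starting feature (must be in `pool`).
#' @param criterion function(subset) -> accuracy fraction in \[0, 1\];
#'   must be deterministic for reproducible traces (see
#'   [make_subset_criterion()]).
#' @param max_steps maximum number of recorded steps (default 30).
#' @return an object of class `"sffs_trace"`: `steps` (data frame with
#'   `step`, `action`, `criterion`, `subset` as comma-joined string),
#'   `best_subset` (integer vector), `best_criterion`.
#' @export
sffs <- function(pool, basic, criterion, max_steps = 30L) {
  pool <- sort(unique(as.integer(pool)))
  if (!length(pool)) stop("empty feature pool")
  basic <- as.integer(basic)
  if (!basic %in% pool) stop("basic feature must be in the pool")

  cache <- new.env(parent = emptyenv())
  crit <- function(s) {
    key <- .subset_key(s)
    if (is.null(cache[[key]])) cache[[key]] <- criterion(sort(s))
    cache[[key]]
  }
  best_at <- numeric(length(pool) + 1L)  # best criterion seen per size
  best_at[] <- -Inf
  steps <- list()
  record <- function(action, s, val) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = length(steps) + 1L, action = action, criterion = val,
      subset = .subset_key(s), stringsAsFactors = FALSE)
    if (val > best_at[length(s)]) best_at[length(s)] <<- val
  }

  s <- basic
  record("start", s, crit(s))
  last_added <- basic
  while (length(steps) < max_steps && length(s) < length(pool)) {
    cand <- setdiff(pool, s)
    vals <- vapply(cand, function(f) crit(c(s, f)), 0)
    add <- cand[which.max(vals)]          # which.max: first (lowest) on ties
    gain <- max(vals)
    if (is.finite(best_at[length(s) + 1L]) && gain <= best_at[length(s) + 1L])
      break                                # no improving addition
    s <- sort(c(s, add))
    record("add", s, gain)
    last_added <- add
    # conditional backward removals
    first_back <- TRUE
    while (length(s) > 2L && length(steps) < max_steps) {
      rem_cand <- s
      rvals <- vapply(rem_cand, function(f) crit(setdiff(s, f)), 0)
      worst <- rem_cand[which.max(rvals)]  # least significant feature
      if (first_back && worst == last_added) break
      if (rvals[which.max(rvals)] <= best_at[length(s) - 1L]) break
      s <- setdiff(s, worst)
      record("remove", s, max(rvals))
      first_back <- FALSE
    }
  }

  trace <- do.call(rbind, steps)
  ibest <- which.max(trace$criterion)
  structure(list(
    steps = trace,
    best_subset = as.integer(strsplit(trace$subset[ibest], ",")[[1]]),
    best_criterion = trace$criterion[ibest]
  ), class = "sffs_trace")
}

#' @export
print.sffs_trace <- function(x, ...) {
  cat("SFFS trace:\n")
  df <- x$steps
  df$criterion <- sprintf("%.2f%%", 100 * df$criterion)
  print(df, row.names = FALSE)
  cat(sprintf("best: {%s} at %.2f%%\n", paste(x$best_subset, collapse = ", "),
              100 * x$best_criterion))
  invisible(x)
}

#' Write an SFFS trace as CSV (step, accuracy, subset)
#'
#' @param trace an `"sffs_trace"`.
#' @param path output CSV path.
#' @export
write_sffs_trace <- function(trace, path) {
  utils::write.csv(trace$steps, path, row.names = FALSE)
  invisible(path)
}

#' Map pool feature numbers to feature-table column names
#'
#' The shape pool numbers 1-15 map to `shape_01..shape_15`; the joint
#' color-texture pool numbers 1-12 map to `color_01..color_06` then
#' `tex_07..tex_12`.
#'
#' @param pool `"shape"` or `"colortex"`.
#' @param numbers integer feature numbers.
#' @return character vector of column names.
#' @export
pool_columns <- function(pool = c("shape", "colortex"), numbers) {
  pool <- match.arg(pool)
  if (pool == "shape") {
    stopifnot(all(numbers >= 1 & numbers <= 15))
    sprintf("shape_%02d", numbers)
  } else {
    stopifnot(all(numbers >= 1 & numbers <= 12))
    ifelse(numbers <= 6, sprintf("color_%02d", numbers),
           sprintf("tex_%02d", numbers))
  }
}

#' Subset-accuracy criterion from a train/validation split
#'
#' Trains a [bpnn()] on the training rows restricted to a feature subset
#' (hidden layer sized by [hidden_nodes()] from the subset size) and
#' returns the validation accuracy. Fully seeded via `cfg$rng_seed`, so
#' the same subset always scores the same.
#'
#' @param subset integer feature numbers within the pool.
#' @param train,validation data frames with the pool's feature columns and
#'   a `label` column (`good`/`ng`); rows must be disjoint.
#' @param pool `"shape"` or `"colortex"`.
#' @param cfg a [train_config()].
#' @return validation accuracy fraction.
#' @export
evaluate_subset <- function(subset, train, validation,
                            pool = c("shape", "colortex"),
                            cfg = train_config()) {
  pool <- match.arg(pool)
  if (!length(subset)) stop("empty feature subset")
  if (length(unique(train$label)) < 2L)
    stop("a class is absent from the training split")
  cols <- pool_columns(pool, subset)
  fit <- suppressWarnings(
    bpnn(as.matrix(train[, cols, drop = FALSE]), train$label, cfg = cfg))
  pred <- predict(fit, as.matrix(validation[, cols, drop = FALSE]))$label
  mean(as.character(pred) == as.character(validation$label))
}

#' @rdname evaluate_subset
#' @return `make_subset_criterion` returns a function(subset) -> accuracy
#'   suitable as the [sffs()] criterion.
#' @export
make_subset_criterion <- function(train, validation,
                                  pool = c("shape", "colortex"),
                                  cfg = train_config()) {
  pool <- match.arg(pool)
  force(train); force(validation); force(cfg)
  function(subset) evaluate_subset(subset, train, validation, pool, cfg)
}
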