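# Movement metrics over configurable time lags and a cross-validated
# random-forest classifier separating foraging from non-foraging fixes.

#' Compute movement metrics from a GPS track
#'
#' For each lag `L = k * fix_interval` and fix `i`, computes the linear
#' displacement (straight-line distance from fix `i - k` to fix `i`), the
#' cumulative distance (sum of the `k` inter-fix path lengths), and the
#' turning angle (absolute heading change between the segments
#' `i - 2k -> i - k` and `i - k -> i`, in degrees within [0, 180]). Fixes
#' without enough history, and turning angles at zero-length segments, are
#' `NA`.
#'
#' @param track A `gs_track` tibble (`t_s`, `x_m`, `y_m`), time-sorted at a
#'   constant fix interval.
#' @param lags Time lags in seconds; each must be a positive multiple of the
#'   fix interval. Default 100-800 s.
#' @return A tibble with `fix_index`, `t_s`, and per-lag columns
#'   `ld_<L>` (linear, m), `cd_<L>` (cumulative, m), `ta_<L>` (degrees).
#' @examples
#' tr <- tibble::tibble(t_s = c(0, 50, 100), x_m = c(0, 3, 6), y_m = c(0, 4, 8))
#' attr(tr, "fix_interval") <- 50
#' compute_features(tr, lags = 100)
#' @export
compute_features <- function(track, lags = c(100, 200, 400, 800)) {
  dt <- attr(track, "fix_interval")
  if (is.null(dt)) dt <- stats::median(diff(track$t_s))
  if (is.unsorted(track$t_s, strictly = TRUE)) {
    stop("track must have strictly increasing timestamps", call. = FALSE)
  }
  ks <- lags / dt
  if (any(ks < 1 | abs(ks - round(ks)) > 1e-9)) {
    stop("every lag must be a positive multiple of the fix interval (",
      dt, " s)",
      call. = FALSE
    )
  }
  ks <- as.integer(round(ks))

  n <- nrow(track)
  x <- track$x_m
  y <- track$y_m
  step_d <- c(NA_real_, sqrt(diff(x)^2 + diff(y)^2))
  cum_d <- cumsum(ifelse(is.na(step_d), 0, step_d))

  out <- tibble::tibble(fix_index = seq_len(n), t_s = track$t_s)
  for (j in seq_along(ks)) {
    k <- ks[j]
    L <- lags[j]
    lag_k <- function(v, k) c(rep(NA_real_, min(k, n)), v[seq_len(max(0, n - k))])
    xk <- lag_k(x, k)
    yk <- lag_k(y, k)
    x2k <- lag_k(x, 2L * k)
    y2k <- lag_k(y, 2L * k)

    ld <- sqrt((x - xk)^2 + (y - yk)^2)
    cd <- cum_d - lag_k(cum_d, k)
    cd[seq_len(min(k, n))] <- NA_real_

    h1 <- atan2(yk - y2k, xk - x2k)
    h2 <- atan2(y - yk, x - xk)
    seg1_zero <- (xk == x2k & yk == y2k)
    seg2_zero <- (x == xk & y == yk)
    ta <- abs(((h2 - h1 + pi) %% (2 * pi)) - pi) * 180 / pi
    ta[seg1_zero | seg2_zero] <- NA_real_

    out[[paste0("ld_", L)]] <- ld
    out[[paste0("cd_", L)]] <- cd
    out[[paste0("ta_", L)]] <- ta
  }
  out
}

feature_columns <- function(features) {
  grep("^(ld|cd|ta)_\\d+$", names(features), value = TRUE)
}

# Stratified fold assignment: rows sorted by class (shuffled within class),
# folds assigned cyclically, so fold sizes differ by at most one overall and
# within each class.
stratified_folds <- function(labels, n_folds) {
  n <- length(labels)
  ord <- order(labels, stats::runif(n))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(n_folds), n)
  folds
}

#' Fit a random-forest foraging classifier with cross-validation
#'
#' Trains a random forest (500 trees, sqrt(p) candidate features per split)
#' on complete-feature fixes and evaluates it by stratified k-fold
#' cross-validation. The accuracy confidence interval is the percentile
#' interval over fold accuracies.
#'
#' @param features Feature table from [compute_features()].
#' @param labels Character/factor vector of per-fix labels (two classes,
#'   e.g. `"foraging"` / `"non-foraging"`), aligned with `features` rows.
#' @param n_folds Folds (default 10).
#' @param num_trees Trees in the forest (default 500).
#' @param seed Integer seed controlling folds and forests.
#' @return A `gs_classifier`: the fitted forest, the feature schema, and a
#'   `cv` report (overall accuracy, 95% CI, per-fold accuracies, confusion
#'   counts).
#' @export
fit_behavior_classifier <- function(features, labels, n_folds = 10,
                                    num_trees = 500, seed = 1) {
  stopifnot(nrow(features) == length(labels))
  cols <- feature_columns(features)
  if (length(cols) == 0) stop("no feature columns found", call. = FALSE)
  complete <- stats::complete.cases(features[cols]) & !is.na(labels)
  dat <- features[complete, cols, drop = FALSE]
  lab <- factor(labels[complete])
  if (nlevels(lab) < 2) {
    stop("need at least two behavior classes to train a classifier", call. = FALSE)
  }
  if (nrow(dat) < n_folds) {
    stop("fewer labeled complete-feature fixes than folds", call. = FALSE)
  }

  mtry <- max(1L, floor(sqrt(length(cols))))
  with_substream(seed, "classifier", {
    folds <- stratified_folds(lab, n_folds)
    oof <- factor(rep(NA_character_, nrow(dat)), levels = levels(lab))
    fold_acc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr_idx <- folds != f
      fit_f <- ranger::ranger(
        x = dat[tr_idx, , drop = FALSE], y = lab[tr_idx],
        num.trees = num_trees, mtry = mtry,
        seed = substream_seed(seed, paste0("rf-fold-", f))
      )
      pred_f <- stats::predict(fit_f, data = dat[!tr_idx, , drop = FALSE])$predictions
      oof[!tr_idx] <- pred_f
      fold_acc[f] <- mean(pred_f == lab[!tr_idx])
    }
    overall <- mean(oof == lab)
    ci <- stats::quantile(fold_acc, c(0.025, 0.975), names = FALSE, type = 1)
    confusion <- table(truth = lab, predicted = oof)

    final <- ranger::ranger(
      x = dat, y = lab, num.trees = num_trees, mtry = mtry,
      seed = substream_seed(seed, "rf-final")
    )
    structure(
      list(
        forest = final,
        schema = cols,
        classes = levels(lab),
        n_trained = nrow(dat),
        n_excluded_missing = sum(!complete),
        cv = list(
          overall_accuracy = overall,
          ci_low = ci[1], ci_high = ci[2],
          fold_accuracies = fold_acc,
          confusion = confusion,
          n_folds = n_folds
        )
      ),
      class = "gs_classifier"
    )
  })
}

#' @export
print.gs_classifier <- function(x, ...) {
  cat(sprintf(
    "<gs_classifier> random forest on %d features, %d fixes (%d excluded incomplete)\n",
    length(x$schema), x$n_trained, x$n_excluded_missing
  ))
  cat(sprintf(
    "  %d-fold CV accuracy %.3f (95%% CI %.3f-%.3f)\n",
    x$cv$n_folds, x$cv$overall_accuracy, x$cv$ci_low, x$cv$ci_high
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gs_classifier <- function(x, ...) {
  tibble::tibble(
    accuracy = x$cv$overall_accuracy,
    ci_low = x$cv$ci_low, ci_high = x$cv$ci_high,
    n_folds = x$cv$n_folds, n_fixes = x$n_trained,
    n_excluded = x$n_excluded_missing
  )
}

#' @exportS3Method generics::tidy
tidy.gs_classifier <- function(x, ...) {
  tibble::tibble(
    fold = seq_along(x$cv$fold_accuracies),
    accuracy = x$cv$fold_accuracies
  )
}

#' Classify fixes with a fitted behavior classifier
#'
#' @param classifier A `gs_classifier` from [fit_behavior_classifier()].
#' @param features Feature table with the training schema's columns.
#' @return Tibble `fix_index`, `label` (`NA` for incomplete-feature fixes),
#'   `source = "predicted"`.
#' @export
classify_track <- function(classifier, features) {
  missing_cols <- setdiff(classifier$schema, names(features))
  if (length(missing_cols) > 0) {
    stop(
      "features lack columns used in training: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    fix_index = features$fix_index,
    label = NA_character_,
    source = "predicted"
  )
  if (nrow(features) == 0) return(out)
  complete <- stats::complete.cases(features[classifier$schema])
  if (any(complete)) {
    pred <- stats::predict(
      classifier$forest,
      data = features[complete, classifier$schema, drop = FALSE]
    )$predictions
    out$label[complete] <- as.character(pred)
  }
  out
}
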