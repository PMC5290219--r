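#' Percentage-wise split plan
#'
#' The subject-wise cross-validation schedule: training fractions counting
#' down from 90% to 50% in 5% steps (nine fractions), each repeated 20
#' times with fresh random subject assignments.
#'
#' @param fractions strictly decreasing training proportions in `(0, 1)`.
#' @param repetitions repetitions per fraction.
#' @param seed integer seed governing all splits.
#' @return A list of class `"split_plan"`.
#' @export
split_plan <- function(fractions = seq(0.90, 0.50, by = -0.05),
                       repetitions = 20L, seed = 1L) {
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(diff(fractions) >= 0)) {
    stop("fractions must be strictly decreasing", call. = FALSE)
  }
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  structure(list(fractions = as.numeric(fractions),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Subject-wise train/test split
#'
#' Assigns `round(fraction * n)` participants (round half up) to the
#' training set, sampling without replacement; every participant's data
#' lands entirely on one side, so no individual leaks across the split.
#'
#' @param ids participant identifiers.
#' @param fraction training proportion.
#' @return A list with disjoint `train` and `test` id vectors.
#' @export
subjectwise_split <- function(ids, fraction) {
  n <- length(ids)
  n_train <- round_half_up(fraction * n)
  if (n_train < 1L || n_train >= n) {
    stop(sprintf("fraction %.2f leaves an empty train or test set for n = %d",
                 fraction, n), call. = FALSE)
  }
  train <- sample(ids, n_train)
  list(train = train, test = setdiff(ids, train))
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 with class 1 (2-back) positive.
#' Precision and recall are 0 when their denominators vanish; F1 is 0 when
#' precision + recall is 0, else their harmonic mean.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return A list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = mean(y_true == y_pred), precision = precision,
       recall = recall, f1 = f1)
}

#' SNC classifier wrapper for the evaluation harness
#'
#' @param tau scaling threshold.
#' @param degree polynomial degree (overridden per cell when the harness
#'   sweeps degrees).
#' @param bias append a constant column after expansion.
#' @return A classifier object with `fit(X, y, degree)` / `predict(model, X)`.
#' @export
snc_classifier <- function(tau = 0.5, degree = 0L, bias = FALSE) {
  structure(list(
    name = "snc",
    fit = function(X, y, degree_override = NULL) {
      snc_fit(X, y, tau = tau, degree = degree_override %||% degree,
              bias = bias)
    },
    predict = function(model, X) predict(model, X)
  ), class = "snc_adapter")
}

baseline_names <- c("knn", "svm_linear", "svm_rbf", "decision_tree",
                    "random_forest", "naive_bayes", "lda", "qda", "logistic")

#' Baseline classifier adapters
#'
#' Wraps the standard comparison classifiers behind the same `fit`/`predict`
#' contract as [snc_classifier()], with the conventional benchmark settings:
#' KNN with 3 neighbors, decision tree of depth 3, random forest with 10
#' trees, logistic regression essentially unpenalized (C = 1e5), linear SVM
#' with cost 0.025 and RBF SVM with cost 1.0.
#'
#' @param name one of `"knn"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"decision_tree"`, `"random_forest"`, `"naive_bayes"`, `"lda"`,
#'   `"qda"`, `"logistic"`.
#' @param params named list overriding the defaults (`k`, `cost`,
#'   `maxdepth`, `ntree`).
#' @return A classifier adapter.
#' @export
baseline_adapter <- function(name, params = list()) {
  if (!name %in% baseline_names) {
    stop(sprintf("unknown classifier '%s'; valid names: %s", name,
                 paste(baseline_names, collapse = ", ")), call. = FALSE)
  }
  fit_fn <- switch(name,
    knn = {
      k <- params$k %||% 3L
      function(X, y) list(X = X, y = y, k = k)
    },
    svm_linear = {
      cost <- params$cost %||% 0.025
      function(X, y) e1071::svm(X, factor(y, levels = 0:1), kernel = "linear",
                                cost = cost, scale = FALSE)
    },
    svm_rbf = {
      cost <- params$cost %||% 1.0
      function(X, y) e1071::svm(X, factor(y, levels = 0:1), kernel = "radial",
                                cost = cost, scale = FALSE)
    },
    decision_tree = {
      maxdepth <- params$maxdepth %||% 3L
      function(X, y) {
        df <- data.frame(y = factor(y, levels = 0:1), X)
        rpart::rpart(y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(maxdepth = maxdepth,
                                                    minsplit = 2, cp = 0))
      }
    },
    random_forest = {
      ntree <- params$ntree %||% 10L
      function(X, y) randomForest::randomForest(X, factor(y, levels = 0:1),
                                                ntree = ntree)
    },
    naive_bayes = function(X, y) e1071::naiveBayes(X, factor(y, levels = 0:1)),
    lda = function(X, y) MASS::lda(X, grouping = factor(y, levels = 0:1)),
    qda = function(X, y) MASS::qda(X, grouping = factor(y, levels = 0:1)),
    logistic = function(X, y) {
      df <- data.frame(y = y, X)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    }
  )
  predict_fn <- switch(name,
    knn = function(model, X) {
      as.integer(as.character(class::knn(model$X, X, factor(model$y), k = model$k)))
    },
    svm_linear = ,
    svm_rbf = function(model, X) as.integer(as.character(predict(model, X))),
    decision_tree = function(model, X) {
      as.integer(as.character(predict(model, data.frame(X), type = "class")))
    },
    random_forest = function(model, X) as.integer(as.character(predict(model, X))),
    naive_bayes = function(model, X) as.integer(as.character(predict(model, X))),
    lda = ,
    qda = function(model, X) as.integer(as.character(predict(model, X)$class)),
    logistic = function(model, X) {
      p <- suppressWarnings(predict(model, data.frame(X), type = "response"))
      as.integer(p >= 0.5)
    }
  )
  structure(list(name = name,
                 fit = function(X, y, degree_override = NULL) fit_fn(X, y),
                 predict = predict_fn),
            class = "snc_adapter")
}

#' Percentage-wise, subject-wise cross-validation harness
#'
#' For every combination of channel, feature family, training fraction and
#' repetition (and, for SNC, polynomial degree), splits the cohort by
#' participant, fits the classifier on the training participants' feature
#' rows and scores it on the held-out participants. Features are extracted
#' once per `(family, channel)` pair (extraction is per-participant and
#' deterministic, so precomputation cannot leak across the split). The
#' split for a given (fraction, repetition) is shared across channels,
#' families and degrees, keeping configurations comparable.
#'
#' Cells whose training labels collapse to a single class are marked
#' invalid: excluded from the averages but counted in `step_count`.
#'
#' @param cohort a (typically preprocessed) `"nirs_cohort"`.
#' @param classifier an [snc_classifier()] or [baseline_adapter()].
#' @param families feature families to sweep.
#' @param channels channel names to sweep.
#' @param plan a [split_plan()].
#' @param degrees polynomial degrees to sweep (SNC only; `NULL` disables
#'   the sweep).
#' @param rows row granularity passed to [extract_features()].
#' @param window moving-average window (samples).
#' @param eps_floor optional DE variance floor.
#' @return A list of class `"snc_eval_report"` with `cells` (one row per
#'   evaluation), `summary` (per-configuration means), `best`, `step_count`
#'   and `plan`.
#' @export
run_algorithm1 <- function(cohort, classifier,
                           families = c("SMSS", "CNR", "MOVAVG", "DE"),
                           channels = colnames(cohort[[1L]]$channels),
                           plan = split_plan(), degrees = NULL,
                           rows = "task", window = 10L, eps_floor = NULL) {
  stopifnot(inherits(classifier, "snc_adapter"))
  ids <- vapply(cohort, function(r) r$participant_id, character(1))
  n <- length(ids)

  feats <- list()
  for (fam in families) for (ch in channels) {
    feats[[paste(fam, ch, sep = "|")]] <-
      extract_features(cohort, fam, ch, rows = rows, window = window,
                       eps_floor = eps_floor)
  }

  degree_set <- if (is.null(degrees)) NA_integer_ else as.integer(degrees)
  n_frac <- length(plan$fractions)
  n_rep <- plan$repetitions

  # One split per (fraction, repetition), shared across configurations.
  split_seeds <- derive_seeds(plan$seed, n_frac * n_rep)
  splits <- vector("list", n_frac * n_rep)
  for (fi in seq_len(n_frac)) for (rep in seq_len(n_rep)) {
    idx <- (fi - 1L) * n_rep + rep
    set.seed(split_seeds[[idx]])
    splits[[idx]] <- subjectwise_split(ids, plan$fractions[fi])
  }

  n_cells <- length(families) * length(channels) * n_frac * n_rep *
    length(degree_set)
  cells <- data.frame(
    channel = character(n_cells), family = character(n_cells),
    degree = integer(n_cells), fraction = numeric(n_cells),
    repetition = integer(n_cells), accuracy = numeric(n_cells),
    precision = numeric(n_cells), recall = numeric(n_cells),
    f1 = numeric(n_cells), valid = logical(n_cells),
    stringsAsFactors = FALSE
  )

  row_i <- 0L
  for (fam in families) for (ch in channels) {
    fset <- feats[[paste(fam, ch, sep = "|")]]
    for (deg in degree_set) {
      for (fi in seq_len(n_frac)) for (rep in seq_len(n_rep)) {
        sp <- splits[[(fi - 1L) * n_rep + rep]]
        stopifnot(length(intersect(sp$train, sp$test)) == 0L)  # no leakage
        tr <- fset$participant %in% sp$train
        te <- fset$participant %in% sp$test
        row_i <- row_i + 1L
        cells$channel[row_i] <- ch
        cells$family[row_i] <- fam
        cells$degree[row_i] <- deg
        cells$fraction[row_i] <- plan$fractions[fi]
        cells$repetition[row_i] <- rep

        y_tr <- fset$y[tr]
        if (length(unique(y_tr)) < 2L) {
          cells$valid[row_i] <- FALSE
          cells[row_i, c("accuracy", "precision", "recall", "f1")] <- NA_real_
          next
        }
        model <- tryCatch(
          classifier$fit(fset$X[tr, , drop = FALSE], y_tr,
                         degree_override = if (is.na(deg)) NULL else deg),
          error = function(e) NULL)
        if (is.null(model)) {
          cells$valid[row_i] <- FALSE
          cells[row_i, c("accuracy", "precision", "recall", "f1")] <- NA_real_
          next
        }
        y_hat <- classifier$predict(model, fset$X[te, , drop = FALSE])
        m <- compute_metrics(fset$y[te], y_hat)
        cells$valid[row_i] <- TRUE
        cells$accuracy[row_i] <- m$accuracy
        cells$precision[row_i] <- m$precision
        cells$recall[row_i] <- m$recall
        cells$f1[row_i] <- m$f1
      }
    }
  }

  key <- paste(cells$channel, cells$family, cells$degree, sep = "|")
  keys <- unique(key)
  summary <- do.call(rbind, lapply(keys, function(k) {
    sub <- cells[key == k & cells$valid, , drop = FALSE]
    first <- cells[match(k, key), ]
    data.frame(channel = first$channel, family = first$family,
               degree = first$degree,
               mean_accuracy = if (nrow(sub)) mean(sub$accuracy) else NA_real_,
               mean_precision = if (nrow(sub)) mean(sub$precision) else NA_real_,
               mean_recall = if (nrow(sub)) mean(sub$recall) else NA_real_,
               mean_f1 = if (nrow(sub)) mean(sub$f1) else NA_real_,
               n_valid = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  best_i <- which.max(summary$mean_accuracy)
  best <- list(channel = summary$channel[best_i],
               family = summary$family[best_i],
               degree = summary$degree[best_i],
               mean_accuracy = summary$mean_accuracy[best_i])

  structure(list(cells = cells, summary = summary, best = best,
                 step_count = n_cells, plan = plan,
                 classifier = classifier$name),
            class = "snc_eval_report")
}

#' @export
print.snc_eval_report <- function(x, ...) {
  cat(sprintf("<snc_eval_report> %s: %d cells (%d invalid)\n", x$classifier,
              x$step_count, sum(!x$cells$valid)))
  cat(sprintf("  best: channel %s, family %s%s, mean accuracy %.4f\n",
              x$best$channel, x$best$family,
              if (!is.na(x$best$degree)) sprintf(", degree %d", x$best$degree) else "",
              x$best$mean_accuracy))
  invisible(x)
}

#' Segment every task block of a cohort
#'
#' Splits each task block into `s^d` equal contiguous sub-blocks, each
#' inheriting the parent label and participant; any remainder samples at
#' the block tail are dropped. `d = 0` returns the cohort unchanged. This is
#' the sample-inflation device whose effect on measured accuracy the
#' segmentation demonstration quantifies.
#'
#' @param cohort a `"nirs_cohort"`.
#' @param d segmentation depth (>= 0).
#' @param s segments per level (>= 2).
#' @return The segmented cohort.
#' @export
segment_cohort <- function(cohort, d, s = 2L) {
  d <- as.integer(d); s <- as.integer(s)
  if (d < 0L) stop("segmentation depth d must be >= 0", call. = FALSE)
  if (s < 2L) stop("segments per level s must be >= 2", call. = FALSE)
  if (d == 0L) return(cohort)
  k <- as.integer(round(s^d))
  out <- lapply(cohort, function(rec) {
    blocks <- rec$task_blocks
    new_blocks <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
      L <- blocks$end[b] - blocks$start[b]
      len <- L %/% k
      if (len < 1L) {
        stop(sprintf("block %d too short to segment into %d parts", b, k),
             call. = FALSE)
      }
      data.frame(label = blocks$label[b],
                 start = blocks$start[b] + (0:(k - 1L)) * len,
                 end = blocks$start[b] + (1:k) * len,
                 stringsAsFactors = FALSE)
    }))
    rec$task_blocks <- new_blocks
    rec
  })
  class(out) <- "nirs_cohort"
  attr(out, "config") <- attr(cohort, "config")
  out
}

#' Segmentation-degradation demonstration
#'
#' Runs the evaluation harness on progressively deeper segmentations of the
#' same cohort (each sub-block a sample, one feature row per block) and
#' tabulates the mean cross-validated accuracy per depth. On cohorts that
#' contain misleading participants, accuracy does not improve with depth:
#' segmentation multiplies the misleading samples along with the rest while
#' shortening every analysis window.
#'
#' @param cohort a (typically preprocessed) `"nirs_cohort"` — preprocess
#'   before segmenting so the filter sees full-length series.
#' @param classifier a classifier adapter.
#' @param depths segmentation depths to evaluate.
#' @param s segments per level.
#' @param plan a [split_plan()].
#' @param families,channels configuration grid (defaults to a single
#'   family/channel for a focused demonstration).
#' @param ... passed to [run_algorithm1()].
#' @return A data frame with `depth` and `mean_accuracy` (mean over all
#'   valid cells), plus the per-depth reports as attribute `"reports"`.
#' @export
segmentation_degradation_demo <- function(cohort, classifier,
                                          depths = c(0L, 1L, 2L), s = 2L,
                                          plan = split_plan(),
                                          families = "DE",
                                          channels = "Left1", ...) {
  if (length(depths) == 0L) {
    return(data.frame(depth = integer(0), mean_accuracy = numeric(0)))
  }
  reports <- lapply(depths, function(d) {
    seg <- segment_cohort(cohort, d, s)
    run_algorithm1(seg, classifier, families = families, channels = channels,
                   plan = plan, rows = "block", ...)
  })
  res <- data.frame(
    depth = as.integer(depths),
    mean_accuracy = vapply(reports, function(rp) {
      mean(rp$cells$accuracy[rp$cells$valid])
    }, numeric(1))
  )
  attr(res, "reports") <- reports
  res
}
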