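#' Expected ratio of dissimilarity between two task spaces
#'
#' The ratio of the mean Euclidean norms of the feature vectors in the two
#' task spaces: `r = mean(||p||, p in T1) / mean(||p||, p in T2)`. `r = 1`
#' iff the two spaces carry the same norm mass; `r = 0` flags a degenerate
#' (all-zero) first space.
#'
#' @param T1,T2 numeric matrices, one feature vector per row (T1 holds the
#'   label-0 class, T2 the label-1 class).
#' @return The scalar ratio `r >= 0`.
#' @export
dissimilarity_ratio <- function(T1, T2) {
  T1 <- as.matrix(T1); T2 <- as.matrix(T2)
  if (nrow(T1) == 0L || nrow(T2) == 0L) {
    stop("both task spaces must be non-empty", call. = FALSE)
  }
  denom <- mean(row_norms(T2))
  if (denom == 0) {
    stop("dissimilarity ratio undefined: mean norm of T2 is zero", call. = FALSE)
  }
  mean(row_norms(T1)) / denom
}

#' Class-wise rescaling of the task spaces
#'
#' Multiplies every T1 vector by `r` and every T2 vector by
#' `max(tau, 1 - r)`, broadening the dissimilarity between the two classes.
#' Each class is scaled by a single factor (an affine map with zero offset),
#' so within-class distance ratios are preserved exactly. The threshold
#' `tau` keeps the T2 factor away from zero when `r` is close to 1.
#'
#' @param T1,T2 numeric matrices, one feature vector per row.
#' @param tau threshold in `(0, 1]`; default 0.5.
#' @return A list with `T1`, `T2` (scaled), and `scaling` (a list with `r`,
#'   `tau`, `factor_T1`, `factor_T2`).
#' @export
scale_task_spaces <- function(T1, T2, tau = 0.5) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]", call. = FALSE)
  r <- dissimilarity_ratio(T1, T2)
  f1 <- r
  f2 <- max(tau, 1 - r)
  list(T1 = as.matrix(T1) * f1, T2 = as.matrix(T2) * f2,
       scaling = list(r = r, tau = tau, factor_T1 = f1, factor_T2 = f2))
}

#' Geometric median by Weiszfeld iteration
#'
#' The point minimizing the sum of Euclidean distances to the rows of `X`
#' (equal weights), computed by Weiszfeld's fixed-point iteration started at
#' the centroid. When an iterate lands on a data point the modified
#' (Vardi-Zhang) update is used, which either certifies the point as the
#' minimizer or steps off it; the distance-sum objective is non-increasing
#' throughout.
#'
#' @param X numeric matrix, one point per row (a vector is taken as a single
#'   point).
#' @param tolerance stop when the iterate's Euclidean displacement falls
#'   below `tolerance * max(1, ||iterate||)` (relative beyond unit scale,
#'   so convergence is attainable for arbitrarily scaled data).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   last iterate.
#' @param trace if `TRUE`, attach the per-iteration distance-sum objective
#'   as attribute `"objective_trace"` of the result.
#' @return The geometric median (numeric vector).
#' @export
geometric_median <- function(X, tolerance = 1e-8, max_iter = 100000L,
                             trace = FALSE) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  n <- nrow(X)
  if (n == 0L) stop("geometric_median needs at least one point", call. = FALSE)
  if (n == 1L) return(as.numeric(X[1L, ]))

  obj_trace <- if (trace) numeric(0)
  finish <- function(y) {
    y <- as.numeric(y)
    if (trace) attr(y, "objective_trace") <- c(obj_trace, gm_objective(y, X))
    y
  }
  # Optimality check at the data points themselves: p_j minimizes the
  # distance sum iff || sum_{p_i != p_j} (p_i - p_j) / d_ij || <= m_j, the
  # multiplicity of p_j. Weiszfeld converges sublinearly toward such a
  # point, so settle these cases exactly up front (this also covers the
  # two-point problem, whose minimizers are the whole segment).
  dmat <- as.matrix(stats::dist(X))
  eps0 <- .Machine$double.eps^0.5
  for (j in seq_len(n)) {
    others <- which(dmat[j, ] > eps0)
    if (length(others) == 0L) return(finish(X[j, ]))  # all points coincide
    m_j <- n - length(others)
    Rv <- colSums((X[others, , drop = FALSE] -
                     rep(X[j, ], each = length(others))) / dmat[j, others])
    if (sqrt(sum(Rv^2)) <= m_j) return(finish(X[j, ]))
  }

  y <- colMeans(X)
  for (iter in seq_len(max_iter)) {
    if (trace) obj_trace[iter] <- gm_objective(y, X)
    d <- sqrt(colSums((t(X) - y)^2))
    at_point <- d < .Machine$double.eps^0.75
    if (any(at_point)) {
      # Vardi-Zhang modified update at a data point.
      j <- which(at_point)[1L]
      dj <- d[-j]
      Rvec <- colSums((X[-j, , drop = FALSE] - rep(y, each = n - 1L)) / dj)
      rnorm_ <- sqrt(sum(Rvec^2))
      if (rnorm_ <= 1) return(finish(y))  # data point is the minimizer
      Tj <- colSums(X[-j, , drop = FALSE] / dj) / sum(1 / dj)
      y_new <- max(0, 1 - 1 / rnorm_) * Tj + min(1, 1 / rnorm_) * y
    } else {
      w <- 1 / d
      y_new <- colSums(X * w) / sum(w)
    }
    if (sqrt(sum((y_new - y)^2)) <
        tolerance * max(1, sqrt(sum(y_new^2)))) {
      return(finish(y_new))
    }
    y <- y_new
  }
  stop(sprintf(
    "Weiszfeld iteration did not converge in %d iterations (last iterate: %s)",
    max_iter, paste(signif(y, 6), collapse = ", ")), call. = FALSE)
}

# Sum-of-distances objective the geometric median minimizes.
gm_objective <- function(y, X) {
  sum(sqrt(colSums((t(X) - y)^2)))
}

#' One-step normal-equation weights
#'
#' The least-squares solution of `X W ~ y`. When `t(X) %*% X` is singular
#' the minimum-norm solution is returned via the SVD pseudo-inverse, so a
#' weight vector is always defined.
#'
#' @param X numeric feature matrix (already class-scaled and
#'   polynomial-expanded).
#' @param y numeric label vector.
#' @return Weight vector `W` of length `ncol(X)`.
#' @export
fit_weights <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty feature matrix", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dinv * (t(sv$u) %*% y)))
}

#' Midpoint of the class geometric medians
#'
#' @param median_T1,median_T2 geometric medians of the two task spaces.
#' @return Coordinate-wise mean of the two medians.
#' @export
snc_midpoint <- function(median_T1, median_T2) {
  if (length(median_T1) != length(median_T2)) {
    stop("median dimensionality mismatch", call. = FALSE)
  }
  (median_T1 + median_T2) / 2
}

#' Sigmoid decision boundary
#'
#' `beta = sigmoid(W . midpoint)`, the score of the midpoint of the class
#' medians; new points scoring at or above `beta` are assigned the positive
#' (2-back) label.
#'
#' @param W weight vector.
#' @param midpoint midpoint of the class medians.
#' @return `beta` in `(0, 1)`.
#' @export
snc_boundary <- function(W, midpoint) {
  if (length(W) != length(midpoint)) {
    stop("W and midpoint dimensionality mismatch", call. = FALSE)
  }
  stats::plogis(sum(W * midpoint))
}

#' Element-wise polynomial feature expansion
#'
#' Degree 0 (and 1) return `X` unchanged; degree `d >= 2` appends the
#' element-wise powers `X^2, ..., X^d` as column blocks after the original
#' columns. No interaction terms are formed.
#'
#' @param X numeric matrix.
#' @param degree integer in `[0, 12]` by convention.
#' @return The expanded matrix.
#' @export
polynomial_expand <- function(X, degree) {
  X <- as.matrix(X)
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be >= 0", call. = FALSE)
  if (degree <= 1L) return(X)
  do.call(cbind, c(list(X), lapply(2:degree, function(p) X^p)))
}

#' Fit the Sigmoid Normal-form Classifier
#'
#' Pipeline: polynomial expansion; split into the two task spaces by label;
#' dissimilarity-ratio scaling; geometric medians of the scaled spaces;
#' normal-equation weights on the scaled, expanded data; midpoint of the
#' medians; sigmoid boundary. Entirely deterministic.
#'
#' @param X numeric feature matrix (raw, unexpanded).
#' @param y 0/1 label vector (1 = 2-back, the positive class).
#' @param tau scaling threshold in `(0, 1]`.
#' @param degree polynomial expansion degree.
#' @param bias append a constant 1 column after expansion (off by default;
#'   the normal-equation formulation carries no intercept).
#' @return An object of class `"snc"`.
#' @export
snc_fit <- function(X, y, tau = 0.5, degree = 0L, bias = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both task spaces must be present: single-class labels", call. = FALSE)
  }
  Xe <- polynomial_expand(X, degree)
  if (bias) Xe <- cbind(Xe, 1)
  sc <- scale_task_spaces(Xe[y == 0L, , drop = FALSE],
                          Xe[y == 1L, , drop = FALSE], tau)
  if (sc$scaling$r == 0) {
    stop("degenerate scaling: dissimilarity ratio r = 0 collapses T1 to the origin",
         call. = FALSE)
  }
  m1 <- geometric_median(sc$T1)
  m2 <- geometric_median(sc$T2)
  Xs <- Xe
  Xs[y == 0L, ] <- sc$T1
  Xs[y == 1L, ] <- sc$T2
  W <- fit_weights(Xs, y)
  xbar <- snc_midpoint(m1, m2)
  beta <- snc_boundary(W, xbar)
  structure(list(scaling = sc$scaling, degree = as.integer(degree),
                 bias = isTRUE(bias), W = W, median_T1 = m1, median_T2 = m2,
                 midpoint = xbar, beta = beta, raw_dim = ncol(X)),
            class = "snc")
}

#' Predict task labels with a fitted SNC model
#'
#' New vectors are polynomial-expanded with the model's degree and scored
#' with the sigmoid of the weighted sum; scores at or above the model's
#' boundary `beta` yield label 1 (ties fire positive). No class-conditional
#' scaling is applied at prediction time: the class is unknown.
#'
#' @param object a fitted `"snc"` model.
#' @param newdata numeric matrix (or single vector) of raw feature vectors.
#' @param ... unused.
#' @return Integer 0/1 labels, one per row.
#' @export
predict.snc <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(X) != object$raw_dim) {
    stop(sprintf("expected %d raw features, got %d", object$raw_dim, ncol(X)),
         call. = FALSE)
  }
  Xe <- polynomial_expand(X, object$degree)
  if (object$bias) Xe <- cbind(Xe, 1)
  scores <- stats::plogis(as.numeric(Xe %*% object$W))
  as.integer(scores >= object$beta)
}

#' @export
print.snc <- function(x, ...) {
  cat(sprintf(
    "<snc> r = %.4f, tau = %.2f, degree = %d, beta = %.4f, %d weights\n",
    x$scaling$r, x$scaling$tau, x$degree, x$beta, length(x$W)))
  invisible(x)
}

#' Select the polynomial degree by brute force
#'
#' Evaluates every candidate degree with the supplied harness function and
#' returns the degree with the highest accuracy; ties go to the smallest
#' degree. The default harness is the training-set accuracy of an SNC fit on
#' `(X, y)`.
#'
#' @param X,y training data.
#' @param degrees candidate degrees (default the 12 effective degrees
#'   `c(0, 2:12)`; degree 1 duplicates degree 0 under element-wise powers).
#' @param eval_fn `function(degree) -> accuracy`; overrides the default
#'   harness.
#' @param tau scaling threshold passed to the default harness.
#' @return The selected degree (integer).
#' @export
select_degree <- function(X, y, degrees = c(0L, 2:12), eval_fn = NULL,
                          tau = 0.5) {
  if (length(degrees) == 0L) stop("no candidate degrees", call. = FALSE)
  if (is.null(eval_fn)) {
    eval_fn <- function(d) {
      model <- snc_fit(X, y, tau = tau, degree = d)
      mean(predict(model, X) == y)
    }
  }
  acc <- vapply(degrees, eval_fn, numeric(1))
  ord <- order(-acc, degrees)
  as.integer(degrees[ord[1L]])
}

#' Serialize / deserialize an SNC model as JSON
#'
#' @param model a fitted `"snc"`.
#' @param path JSON file path.
#' @param feature_family,channel optional provenance stored alongside the
#'   parameters.
#' @return `path` (write) or an `"snc"` model (read).
#' @export
write_snc_model <- function(model, path, feature_family = NULL, channel = NULL) {
  stopifnot(inherits(model, "snc"))
  payload <- list(
    format_version = 1L,
    r = model$scaling$r, tau = model$scaling$tau,
    degree = model$degree, bias = model$bias,
    W = model$W, median_T1 = model$median_T1, median_T2 = model$median_T2,
    midpoint = model$midpoint, beta = model$beta, raw_dim = model$raw_dim,
    feature_family = feature_family, channel = channel
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snc_model
#' @export
read_snc_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) || p$format_version != 1L) {
    stop("unsupported model format_version", call. = FALSE)
  }
  structure(list(
    scaling = list(r = p$r, tau = p$tau,
                   factor_T1 = p$r, factor_T2 = max(p$tau, 1 - p$r)),
    degree = as.integer(p$degree), bias = isTRUE(p$bias),
    W = as.numeric(p$W), median_T1 = as.numeric(p$median_T1),
    median_T2 = as.numeric(p$median_T2), midpoint = as.numeric(p$midpoint),
    beta = p$beta, raw_dim = as.integer(p$raw_dim),
    feature_family = p$feature_family, channel = p$channel
  ), class = "snc")
}
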