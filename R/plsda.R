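# ---- scaling ----------------------------------------------------------------

#' Column scaling specification for discriminant modelling
#'
#' @param center Mean-center columns (default `TRUE`).
#' @param scale `"uv"` (unit variance), `"pareto"` (divide by the square root
#'   of the standard deviation) or `"none"`.
#' @return An object of class `scale_spec`.
#' @export
scale_spec <- function(center = TRUE, scale = c("uv", "pareto", "none")) {
  structure(list(center = center, scale = match.arg(scale)),
            class = "scale_spec")
}

as_scale_spec <- function(x) {
  if (inherits(x, "scale_spec")) return(x)
  if (is.character(x)) return(scale_spec(scale = x))
  abort("`scaling` must be a scale_spec or one of 'uv', 'pareto', 'none'")
}

# returns list(X, center, scale, keep); drops constant columns with a warning
fit_scaling <- function(X, spec) {
  ctr <- if (spec$center) colMeans(X) else rep(0, ncol(X))
  sds <- apply(X, 2, sd)
  keep <- rep(TRUE, ncol(X))
  scl <- rep(1, ncol(X))
  if (spec$scale != "none") {
    keep <- sds > 1e-12
    if (!all(keep)) {
      warn(sprintf("dropping %d constant column(s) before scaling",
                   sum(!keep)))
    }
    scl[keep] <- if (spec$scale == "uv") sds[keep] else sqrt(sds[keep])
  }
  list(center = ctr, scale = scl, keep = keep)
}

apply_scaling <- function(X, sc) {
  X <- sweep(X[, sc$keep, drop = FALSE], 2, sc$center[sc$keep])
  sweep(X, 2, sc$scale[sc$keep], `/`)
}

# ---- NIPALS core ------------------------------------------------------------

# sequential NIPALS PLS2 on pre-scaled X and centered Y
nipals_pls <- function(X, Y, A, tol = 1e-12, max_iter = 500) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- P <- matrix(0, p, A)
  C <- matrix(0, q, A)
  Tm <- U <- matrix(0, n, A)
  ssy0 <- sum(Y^2)
  ssy_explained <- numeric(A)
  ssy_prev <- ssy0
  for (a in seq_len(A)) {
    u <- Y[, which.max(colSums(Y^2))]
    t <- t_old <- rep(0, n)
    w <- rep(0, p)
    cc <- rep(0, q)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t <- as.vector(X %*% w)
      cc <- crossprod(Y, t) / sum(t^2)
      u <- as.vector(Y %*% cc) / sum(cc^2)
      if (sum((t - t_old)^2) < tol * sum(t^2)) break
      t_old <- t
    }
    if (sum(t^2) < 1e-300) break  # X or Y exhausted; later components stay zero
    pp <- crossprod(X, t) / sum(t^2)
    X <- X - tcrossprod(t, pp)
    Y <- Y - tcrossprod(t, cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- t; U[, a] <- u
    ssy_now <- sum(Y^2)
    ssy_explained[a] <- ssy_prev - ssy_now
    ssy_prev <- ssy_now
  }
  list(W = W, P = P, C = C, scores = Tm, U = U,
       ssy0 = ssy0, ssy_explained = ssy_explained,
       r2y_cum = 100 * cumsum(ssy_explained) / ssy0)
}

# regression coefficients of the first `a` components (scaled X -> centered Y)
pls_coef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  C <- fit$C[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W), t(C))
}

# centered one-hot class matrix
class_dummy <- function(y) {
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  sweep(Y, 2, colMeans(Y))
}

# ---- PLS-DA -----------------------------------------------------------------

#' Partial least squares discriminant analysis of a cohort
#'
#' Fits a NIPALS PLS2 model of the (scaled) bucket matrix on the centered
#' one-hot class-membership matrix. Reports the cumulative percent of class
#' variance explained (`R2Y`), the stratified 7-fold cross-validated
#' predictive ability (`Q2`, as `1 - PRESS/SS`), per-bucket VIP scores and the
#' component scores. Optionally an OSC filter ([osc_filter()]) is applied
#' first.
#'
#' @param data Cohort table (typically one time point of a study).
#' @param class_col Design column holding the class factor (default `"dose"`).
#' @param ncomp Number of latent variables, or `"auto"` to add components
#'   while the cross-validated Q2 gains at least 0.01.
#' @param scaling A [scale_spec()] or one of `"uv"`, `"pareto"`, `"none"`.
#' @param osc Number of OSC components to remove before modelling (0 = none).
#' @param cv Compute cross-validated Q2 (default `TRUE`).
#' @param folds Cross-validation folds (default 7).
#' @param seed RNG seed for the fold assignment.
#' @return Object of class `plsda`: components, scores, weights, loadings,
#'   `R2Y` (percent, cumulative), `Q2` (cumulative), `vip`, the scaling and
#'   any OSC model. Methods: [tidy()], [glance()], [autoplot()], [vip()].
#' @export
plsda <- function(data, class_col = "dose", ncomp = 2, scaling = "uv",
                  osc = 0, cv = TRUE, folds = 7, seed = NULL) {
  data <- tibble::as_tibble(data)
  y <- droplevels(factor(data[[class_col]]))
  if (nlevels(y) < 2) abort("need at least 2 classes")
  spec <- as_scale_spec(scaling)
  osc_model <- NULL
  if (osc > 0) {
    flt <- osc_filter(data, class_col = class_col, n_osc = osc)
    data <- flt$data
    osc_model <- flt$model
  }
  X <- bucket_matrix(data)
  auto <- identical(ncomp, "auto")
  max_a <- if (auto) min(10, qr(X)$rank) else ncomp
  if (!auto && ncomp > qr(X)$rank) abort("ncomp exceeds the rank of X")

  sc <- fit_scaling(X, spec)
  Xs <- apply_scaling(X, sc)
  Y <- class_dummy(y)

  q2_cum <- NULL
  if (cv || auto) {
    q2_cum <- cv_q2(X, y, max_a, spec, folds = folds, seed = seed)
  }
  A <- if (auto) {
    gains <- diff(c(0, q2_cum))
    a <- which(gains >= 0.01)
    if (length(a) == 0) 1L else max(a)
  } else ncomp

  fit <- nipals_pls(Xs, Y, A)
  vip_scores <- vip_from_fit(fit, A)
  names(vip_scores) <- colnames(Xs)

  score_m <- fit$scores
  colnames(score_m) <- paste0("comp", seq_len(A))
  scores <- dplyr::bind_cols(
    data[intersect(c("sample_id", "dose", "time", "animal_id"), names(data))],
    tibble::as_tibble(score_m))

  structure(list(
    ncomp = A,
    fit = fit,
    scores = scores,
    weights = fit$W, loadings = fit$P, y_loadings = fit$C,
    R2Y = fit$r2y_cum[A], R2Y_cum = fit$r2y_cum[seq_len(A)],
    Q2 = if (!is.null(q2_cum)) q2_cum[A] else NA_real_,
    Q2_cum = if (!is.null(q2_cum)) q2_cum[seq_len(A)] else NULL,
    vip = vip_scores,
    classes = y, class_col = class_col, class_levels = levels(y),
    scaling = spec, scaling_fit = sc,
    osc_model = osc_model,
    n = nrow(X)
  ), class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d samples, %d classes, A = %d\n",
              x$n, length(x$class_levels), x$ncomp))
  cat(sprintf("  R2Y = %.1f%%, Q2 = %s\n", x$R2Y,
              ifelse(is.na(x$Q2), "not computed", sprintf("%.3f", x$Q2))))
  invisible(x)
}

#' @rdname plsda
#' @param x,object A `plsda` object.
#' @param ... Unused.
#' @export
tidy.plsda <- function(x, ...) {
  tibble::tibble(
    bucket = names(x$vip),
    vip = unname(x$vip),
    loading_1 = x$loadings[, 1],
    weight_1 = x$weights[, 1]
  )
}

#' @rdname plsda
#' @export
glance.plsda <- function(x, ...) {
  tibble::tibble(n = x$n, ncomp = x$ncomp, R2Y = x$R2Y, Q2 = x$Q2)
}

#' @rdname plsda
#' @export
autoplot.plsda <- function(object, ...) {
  df <- object$scores
  ell <- hotelling_ellipse(as.matrix(df[, c("comp1", "comp2")]))
  ep <- ellipse_points(ell)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2)) +
    ggplot2::geom_path(data = ep, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[object$class_col]])) +
    ggplot2::labs(x = "t[1]", y = "t[2]",
                  title = sprintf("PLS-DA scores (R2Y = %.1f%%)", object$R2Y)) +
    ggplot2::theme_minimal()
}

#' Variable importance in the projection
#'
#' Per-bucket VIP scores: the component weights squared, weighted by the class
#' variance each component explains, scaled so that the mean squared VIP over
#' buckets is exactly 1. Buckets with VIP > 1 are conventionally considered
#' discriminant.
#'
#' @param model A fitted [plsda()] model.
#' @return Named numeric vector of VIP scores (one per bucket used).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  model$vip
}

vip_from_fit <- function(fit, A) {
  ssy <- fit$ssy_explained[seq_len(A)]
  if (sum(ssy) <= 0) return(rep(NA_real_, nrow(fit$W)))
  W <- fit$W[, seq_len(A), drop = FALSE]
  Wn <- sweep(W, 2, sqrt(colSums(W^2) + 1e-300), `/`)
  p <- nrow(W)
  sqrt(p * as.vector(Wn^2 %*% ssy) / sum(ssy))
}

# ---- cross-validation -------------------------------------------------------

# stratified fold assignment: shuffle within class, deal out cyclically
stratified_folds <- function(y, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    i <- sample(which(y == lv))
    fold[i] <- rep_len(seq_len(folds), length(i))
  }
  fold
}

# Q2 per cumulative component; scaling refit within each training fold
cv_q2 <- function(X, y, A, spec, folds = 7, seed = NULL) {
  fold <- stratified_folds(y, folds, seed)
  press <- numeric(A)
  ss <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < nlevels(y)) {
      abort("a class is absent from a training fold; use fewer folds")
    }
    sc <- fit_scaling(X[tr, , drop = FALSE], spec)
    Xtr <- apply_scaling(X[tr, , drop = FALSE], sc)
    Xte <- apply_scaling(X[!tr, , drop = FALSE], sc)
    Ytr_raw <- stats::model.matrix(~ y[tr] - 1)
    ymeans <- colMeans(Ytr_raw)
    Ytr <- sweep(Ytr_raw, 2, ymeans)
    Yte <- sweep(stats::model.matrix(~ y[!tr] - 1), 2, ymeans)
    fit <- nipals_pls(Xtr, Ytr, A)
    for (a in seq_len(A)) {
      Yhat <- Xte %*% pls_coef(fit, a)
      press[a] <- press[a] + sum((Yte - Yhat)^2)
    }
    ss <- ss + sum(Yte^2)
  }
  1 - press / ss
}

#' Cross-validated predictive ability of a PLS-DA model
#'
#' Stratified k-fold cross-validation of `Q2 = 1 - PRESS/SS`, cumulative over
#' components. Scaling statistics are computed on the training folds only.
#'
#' @inheritParams plsda
#' @return Numeric vector `Q2_cum` of length `ncomp` (cumulative Q2 after each
#'   component).
#' @export
cross_validate_q2 <- function(data, class_col = "dose", ncomp = 2,
                              scaling = "uv", folds = 7, seed = NULL) {
  y <- droplevels(factor(data[[class_col]]))
  X <- bucket_matrix(data)
  cv_q2(X, y, ncomp, as_scale_spec(scaling), folds = folds, seed = seed)
}

# ---- permutation validation -------------------------------------------------

#' Permutation validation of a PLS-DA model
#'
#' Refits the model `n` times with randomly permuted class labels, records
#' each permuted model's R2 and Q2 against the correlation between the
#' permuted and original class-membership matrices, and extrapolates both to
#' zero label correlation by least squares (the R2/Q2 intercepts, i.e. the
#' expected performance of a purely random model). The model is judged
#' *robust* when the Q2 intercept is negative.
#'
#' @inheritParams plsda
#' @param n Number of permutations (at least 20; 200 is conventional).
#' @return Object of class `plsda_permutation`: tibble `permutations`
#'   (`correlation`, `R2`, `Q2`; fractions), `R2_intercept`, `Q2_intercept`,
#'   the original `R2`/`Q2`, the `robust` verdict (negative Q2 intercept) and
#'   the composite `valid` verdict (R2 > 50%, Q2 > 0.4 and a negative Q2
#'   intercept — the full validity standard, which a signal-free dataset
#'   practically never meets).
#' @export
permutation_validate <- function(data, class_col = "dose", ncomp = 2,
                                 scaling = "uv", n = 200, folds = 7,
                                 seed = NULL, osc = 0) {
  if (n < 20) abort("at least 20 permutations are required")
  if (!is.null(seed)) set.seed(seed)
  data <- tibble::as_tibble(data)
  y0 <- droplevels(factor(data[[class_col]]))
  Y0 <- class_dummy(y0)

  fit_once <- function(yy) {
    d <- data
    d[[class_col]] <- yy
    m <- plsda(d, class_col = class_col, ncomp = ncomp, scaling = scaling,
               osc = osc, cv = TRUE, folds = folds)
    c(R2 = m$R2Y / 100, Q2 = m$Q2)
  }
  orig <- fit_once(y0)
  perms <- purrr::map_dfr(seq_len(n), function(b) {
    yp <- sample(y0)
    r <- cor(as.vector(class_dummy(yp)), as.vector(Y0))
    v <- fit_once(yp)
    tibble::tibble(correlation = r, R2 = v[["R2"]], Q2 = v[["Q2"]])
  })
  all_pts <- dplyr::bind_rows(
    perms,
    tibble::tibble(correlation = 1, R2 = orig[["R2"]], Q2 = orig[["Q2"]]))
  r2_int <- unname(stats::coef(stats::lm(R2 ~ correlation, data = all_pts))[1])
  q2_int <- unname(stats::coef(stats::lm(Q2 ~ correlation, data = all_pts))[1])
  structure(list(
    permutations = perms,
    n = n,
    R2 = orig[["R2"]], Q2 = orig[["Q2"]],
    R2_intercept = r2_int, Q2_intercept = q2_int,
    robust = q2_int < 0,
    # full validity standard: explained variance above 50%, predictive
    # ability above 0.4, and a negative Q2 intercept
    valid = orig[["R2"]] > 0.5 && orig[["Q2"]] > 0.4 && q2_int < 0
  ), class = "plsda_permutation")
}

#' @export
print.plsda_permutation <- function(x, ...) {
  cat(sprintf("<plsda_permutation> %d iterations\n", x$n))
  cat(sprintf("  R2 = %.3f (intercept %.3f), Q2 = %.3f (intercept %.3f)\n",
              x$R2, x$R2_intercept, x$Q2, x$Q2_intercept))
  cat(sprintf("  verdict: %s, %s\n",
              ifelse(x$robust, "robust (Q2 intercept < 0)", "not robust"),
              ifelse(x$valid, "valid", "not valid")))
  invisible(x)
}

#' @rdname permutation_validate
#' @param x,object A `plsda_permutation` object.
#' @param ... Unused.
#' @export
glance.plsda_permutation <- function(x, ...) {
  tibble::tibble(n = x$n, R2 = x$R2, Q2 = x$Q2,
                 R2_intercept = x$R2_intercept,
                 Q2_intercept = x$Q2_intercept, robust = x$robust,
                 valid = x$valid)
}

#' @rdname permutation_validate
#' @export
autoplot.plsda_permutation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$permutations, c("R2", "Q2"),
                            names_to = "criterion")
  orig <- tibble::tibble(correlation = 1,
                         criterion = c("R2", "Q2"),
                         value = c(object$R2, object$Q2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$correlation, y = .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = orig, shape = 17, size = 3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         fullrange = TRUE) +
    ggplot2::labs(x = "correlation with original class matrix", y = NULL) +
    ggplot2::theme_minimal()
}

#' One-row validation report for a dataset
#'
#' Emits the conventional model-report row (N, number of components, R2,
#' Q2, permutation intercepts and the robustness verdict) in machine-readable
#' form.
#'
#' @inheritParams permutation_validate
#' @param dataset Optional label for the row.
#' @return One-row tibble.
#' @export
plsda_report <- function(data, class_col = "dose", ncomp = 2, scaling = "uv",
                         n = 200, folds = 7, seed = NULL, osc = 0,
                         dataset = NA_character_) {
  pv <- permutation_validate(data, class_col = class_col, ncomp = ncomp,
                             scaling = scaling, n = n, folds = folds,
                             seed = seed, osc = osc)
  tibble::tibble(dataset = dataset, N = nrow(data), A = ncomp,
                 R2_pct = 100 * pv$R2, Q2 = pv$Q2,
                 R2_intercept = pv$R2_intercept,
                 Q2_intercept = pv$Q2_intercept,
                 robust = pv$robust, valid = pv$valid)
}

# ---- Hotelling ellipse ------------------------------------------------------

#' Hotelling's T-squared confidence ellipse for a 2-D score plot
#'
#' Computes the `(1 - alpha)` confidence ellipse of two-component scores from
#' the F-distribution scaling of Hotelling's T-squared statistic:
#' `T2_crit = 2 (n - 1) / (n - 2) * qf(1 - alpha, 2, n - 2)`.
#'
#' @param scores Two-column numeric matrix or data frame of scores.
#' @param alpha Significance level (default 0.05 for a 95% ellipse).
#' @return Object of class `hotelling_ellipse`: `center`, `semi_axes`
#'   (descending), `angle` (radians, first axis), `covariance`, `t2_critical`,
#'   `n`. Use [ellipse_points()] to draw it.
#' @export
hotelling_ellipse <- function(scores, alpha = 0.05) {
  S <- as.matrix(scores)
  if (ncol(S) != 2) abort("`scores` must have exactly 2 columns")
  n <- nrow(S)
  if (n < 3) abort("need at least 3 samples")
  V <- cov(S)
  if (!all(is.finite(V)) || abs(det(V)) < 1e-300 ||
      min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("singular score covariance")
  }
  t2 <- 2 * (n - 1) / (n - 2) * qf(1 - alpha, 2, n - 2)
  ev <- eigen(V, symmetric = TRUE)
  structure(list(
    center = colMeans(S),
    semi_axes = sqrt(ev$values * t2),
    angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
    covariance = V,
    t2_critical = t2,
    n = n, alpha = alpha
  ), class = "hotelling_ellipse")
}

#' Points on a Hotelling ellipse outline
#'
#' @param ellipse A [hotelling_ellipse()].
#' @param n_points Number of outline points.
#' @return Tibble with columns `x`, `y`.
#' @export
ellipse_points <- function(ellipse, n_points = 181) {
  th <- seq(0, 2 * pi, length.out = n_points)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  rot <- ellipse$angle
  x <- a * cos(th) * cos(rot) - b * sin(th) * sin(rot) + ellipse$center[1]
  y <- a * cos(th) * sin(rot) + b * sin(th) * cos(rot) + ellipse$center[2]
  tibble::tibble(x = x, y = y)
}
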