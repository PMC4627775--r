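#' Orthogonal signal correction (OSC) filtering
#'
#' Removes from the bucket matrix the dominant variation that is orthogonal to
#' the class structure (physiological, experimental or instrumental variation
#' not linked to treatment), before discriminant modelling. The filter is the
#' Wold-style iterative one: a candidate score (the dominant principal
#' component) is repeatedly orthogonalized against the class-membership matrix
#' and regressed back onto the data until convergence; the final removal
#' weights are obtained by pseudo-inverse projection so that the removed score
#' is exactly orthogonal to the class matrix and the stored model reproduces
#' the filtered training data.
#'
#' @param data Cohort table.
#' @param class_col Design column holding the class factor (default `"dose"`).
#' @param n_osc Number of orthogonal components to remove (default 1).
#' @param max_iter,tol Convergence controls for the power iteration.
#' @return List with `data` (filtered cohort tibble, on the original scale)
#'   and `model` (class `osc_model`: removal weights `W`, loadings `P`,
#'   removed scores `scores`, percent variance removed per component, column
#'   means). Apply the model to new samples with [predict()].
#' @export
osc_filter <- function(data, class_col = "dose", n_osc = 1,
                       max_iter = 500, tol = 1e-12) {
  if (n_osc < 1) abort("`n_osc` must be at least 1")
  data <- tibble::as_tibble(data)
  y <- data[[class_col]]
  if (is.null(y)) abort(paste0("no column '", class_col, "'"))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) abort("need at least 2 classes")
  X <- bucket_matrix(data)
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  rk <- qr(Xc)$rank
  if (n_osc > rk) {
    abort(sprintf("n_osc = %d exceeds the rank (%d) of the centered matrix",
                  n_osc, rk))
  }
  Yd <- stats::model.matrix(~ y - 1)
  Yd <- sweep(Yd, 2, colMeans(Yd))
  qy <- qr(Yd)
  ss_total <- sum(Xc^2)

  W <- P <- NULL
  Tm <- NULL
  var_removed <- numeric(0)
  for (comp in seq_len(n_osc)) {
    sv <- svd(Xc, nu = 1, nv = 0)
    t <- sv$u[, 1] * sv$d[1]
    prev <- t / sqrt(sum(t^2))
    null_comp <- FALSE
    for (it in seq_len(max_iter)) {
      t_o <- t - qr.fitted(qy, t)
      nt <- sqrt(sum(t_o^2))
      if (nt < 1e-10 * sqrt(sum(t^2) + 1e-300)) { null_comp <- TRUE; break }
      w <- crossprod(Xc, t_o)
      t <- as.vector(Xc %*% w)
      t <- t / sqrt(sum(t^2))
      if (sum((t - prev)^2) < tol || sum((t + prev)^2) < tol) break
      prev <- t
    }
    if (null_comp) {
      W <- cbind(W, rep(0, ncol(Xc)))
      P <- cbind(P, rep(0, ncol(Xc)))
      Tm <- cbind(Tm, rep(0, n))
      var_removed <- c(var_removed, 0)
      next
    }
    t_o <- t - qr.fitted(qy, t)
    # pseudo-inverse weights: with centered t_o in the column space of Xc,
    # Xc %*% w reproduces t_o exactly and remains Y-orthogonal
    sx <- svd(Xc)
    pos <- sx$d > sx$d[1] * 1e-10
    w <- sx$v[, pos, drop = FALSE] %*%
      ((crossprod(sx$u[, pos, drop = FALSE], t_o)) / sx$d[pos])
    t_rem <- as.vector(Xc %*% w)
    p_load <- crossprod(Xc, t_rem) / sum(t_rem^2)
    Xc <- Xc - tcrossprod(t_rem, p_load)
    W <- cbind(W, w)
    P <- cbind(P, p_load)
    Tm <- cbind(Tm, t_rem)
    var_removed <- c(var_removed, 100 * sum(tcrossprod(t_rem, p_load)^2) / ss_total)
  }

  model <- structure(list(W = W, P = P, scores = Tm, center = mu,
                          var_removed = var_removed,
                          class_levels = levels(y), class_col = class_col),
                     class = "osc_model")
  out <- data
  bc <- bucket_cols(data)
  out[bc] <- tibble::as_tibble(sweep(Xc, 2, mu, `+`))
  list(data = out, model = model)
}

#' @export
print.osc_model <- function(x, ...) {
  cat(sprintf("<osc_model> %d component(s), variance removed: %s\n",
              ncol(x$W),
              paste(sprintf("%.1f%%", x$var_removed), collapse = ", ")))
  invisible(x)
}

#' Apply a fitted OSC filter to new samples
#'
#' @param object An `osc_model` from [osc_filter()].
#' @param newdata Cohort table with the same bucket columns as the training
#'   data.
#' @param ... Unused.
#' @return The filtered cohort tibble.
#' @export
predict.osc_model <- function(object, newdata, ...) {
  X <- bucket_matrix(newdata)
  if (ncol(X) != length(object$center)) {
    abort("newdata bucket columns do not match the training grid")
  }
  Xc <- sweep(X, 2, object$center)
  for (a in seq_len(ncol(object$W))) {
    t <- as.vector(Xc %*% object$W[, a])
    Xc <- Xc - tcrossprod(t, object$P[, a])
  }
  out <- tibble::as_tibble(newdata)
  out[bucket_cols(newdata)] <- tibble::as_tibble(sweep(Xc, 2, object$center, `+`))
  out
}
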