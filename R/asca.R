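# ---- internal machinery -----------------------------------------------------

# per-level means of Xc for a factor; returns list(means, counts, expand index)
level_means <- function(Xc, f) {
  M <- rowsum(Xc, f)
  cnt <- as.vector(table(f)[rownames(M)])
  list(means = M / cnt, counts = cnt, idx = match(as.character(f), rownames(M)))
}

# sums of squares of the four effect blocks for a two-way layout.
# Main effects are estimated from marginal level means of the centered data;
# the interaction is the cell mean minus both main effects (Jansen-style
# estimator, exact ANOVA decomposition for balanced designs).
asca_ssq <- function(Xc, time_f, dose_f, cell_f, cell_time, cell_dose,
                     which = c("time", "dose", "interaction")) {
  out <- c(time = NA_real_, dose = NA_real_, interaction = NA_real_)
  lt <- ld <- NULL
  if (any(c("time", "interaction") %in% which)) {
    lt <- level_means(Xc, time_f)
    if ("time" %in% which) out["time"] <- sum(lt$counts * rowSums(lt$means^2))
  }
  if (any(c("dose", "interaction") %in% which)) {
    ld <- level_means(Xc, dose_f)
    if ("dose" %in% which) out["dose"] <- sum(ld$counts * rowSums(ld$means^2))
  }
  if ("interaction" %in% which) {
    lc <- level_means(Xc, cell_f)
    im <- lc$means - lt$means[cell_time, , drop = FALSE] -
      ld$means[cell_dose, , drop = FALSE]
    out["interaction"] <- sum(lc$counts * rowSums(im^2))
  }
  out[which]
}

# time/dose level of each design cell, in rowsum's group order (for factors,
# rowsum sorts groups by level order, i.e. levels(cell_f))
cell_maps <- function(time_f, dose_f, cell_f) {
  i <- match(levels(cell_f), as.character(cell_f))
  list(cell_time = as.character(time_f)[i],
       cell_dose = as.character(dose_f)[i])
}

# ---- decomposition ----------------------------------------------------------

#' ANOVA-simultaneous component analysis of a two-way cohort
#'
#' Splits the grand-mean-centered samples-by-buckets matrix into additive
#' effect blocks for the Time factor, the Dose factor, their interaction, and
#' a residual:
#' \deqn{X = X_{Time} + X_{Dose} + X_{Time \times Dose} + X_{Residual}}
#' Main effects are estimated from marginal factor-level means of the centered
#' data; interaction effects are cell means minus both main effects; the
#' residual is what remains. Block sums of squares (squared Frobenius norms)
#' are reported as percent contributions to the total centered variation. For
#' balanced designs the blocks are mutually orthogonal and the percentages add
#' to 100; for unbalanced designs the (small) additivity deviation is reported
#' in `additivity_deviation`, not hidden. Optionally, permutation tests assess
#' the significance of each factor: whole data rows are permuted against the
#' fixed design and the tested factor's sum of squares is recomputed, with
#' \eqn{p = (\#\{SSQ_{perm} \ge SSQ_{obs}\} + 1)/(n_{perm} + 1)}.
#'
#' @param data Cohort table: design columns (`sample_id`, `dose`, `time`) plus
#'   bucket columns.
#' @param n_perm Number of permutations per tested factor (0 = no test).
#' @param seed Optional RNG seed for the permutations.
#' @param factors Factors to test, a subset of
#'   `c("time", "dose", "interaction")`.
#' @param dose_col,time_col Names of the design columns holding the dose and
#'   time factors.
#' @return An object of class `asca` with elements `effects` (named list of
#'   the four n-by-p effect matrices), `centered` (the centered data), `ssq`,
#'   `percent`, `p_values`, `n_perm`, `design`, `additivity_deviation` and
#'   `degenerate`. Use [tidy()] / [glance()] / [sca()] / [autoplot()] on it.
#' @examples
#' cohort <- simulate_cohort(synth_config(n_metabolites = 8), seed = 1)$cohort
#' fit <- asca(cohort, n_perm = 99, seed = 1)
#' tidy(fit)
#' @export
asca <- function(data, n_perm = 0, seed = NULL,
                 factors = c("time", "dose", "interaction"),
                 dose_col = "dose", time_col = "time") {
  data <- tibble::as_tibble(data)
  data$dose <- data[[dose_col]]
  data$time <- data[[time_col]]
  data <- check_design(data)
  factors <- match.arg(factors, several.ok = TRUE)
  time_f <- data$time
  dose_f <- data$dose
  if (nlevels(time_f) < 2 || nlevels(dose_f) < 2) {
    abort("both factors need at least 2 observed levels")
  }
  tab <- table(time_f, dose_f)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: time %s, dose %s",
                  rownames(tab)[empty[1]], colnames(tab)[empty[2]]))
  }
  if (all(tab == 1)) {
    warn("single sample per cell: interaction is confounded with the residual")
  }
  X <- bucket_matrix(data)
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ssq_total <- sum(Xc^2)
  degenerate <- ssq_total <= 1e-12 * length(Xc)

  cell_f <- interaction(time_f, dose_f, drop = TRUE, sep = " / ")
  maps <- cell_maps(time_f, dose_f, cell_f)

  lt <- level_means(Xc, time_f)
  ld <- level_means(Xc, dose_f)
  lc <- level_means(Xc, cell_f)
  E_time <- lt$means[lt$idx, , drop = FALSE]
  E_dose <- ld$means[ld$idx, , drop = FALSE]
  E_cell <- lc$means[lc$idx, , drop = FALSE]
  E_int <- E_cell - E_time - E_dose
  E_res <- Xc - E_cell
  dimnames(E_time) <- dimnames(E_dose) <- dimnames(E_int) <-
    dimnames(E_res) <- dimnames(Xc)

  ssq <- c(time = sum(E_time^2), dose = sum(E_dose^2),
           interaction = sum(E_int^2), residual = sum(E_res^2))
  percent <- if (degenerate) rep(NA_real_, 4) else 100 * ssq / ssq_total
  names(percent) <- names(ssq)
  additivity <- if (degenerate) NA_real_ else (sum(ssq) - ssq_total) / ssq_total

  p_values <- setNames(rep(NA_real_, 3), c("time", "dose", "interaction"))
  if (n_perm > 0 && !degenerate) {
    if (n_perm < 99) abort("use at least 99 permutations")
    if (!is.null(seed)) set.seed(seed)
    obs <- ssq[factors]
    exceed <- setNames(numeric(length(factors)), factors)
    for (b in seq_len(n_perm)) {
      Xp <- Xc[sample.int(n), , drop = FALSE]
      sp <- asca_ssq(Xp, time_f, dose_f, cell_f,
                     maps$cell_time, maps$cell_dose, which = factors)
      exceed <- exceed + (sp >= obs - 1e-12)
    }
    p_values[factors] <- (exceed + 1) / (n_perm + 1)
  }

  structure(list(
    effects = list(time = E_time, dose = E_dose, interaction = E_int,
                   residual = E_res),
    centered = Xc,
    grand_mean = mu,
    ssq = ssq,
    ssq_total = ssq_total,
    percent = percent,
    p_values = p_values,
    n_perm = n_perm,
    design = data[intersect(c("sample_id", "dose", "time", "animal_id"),
                            names(data))],
    additivity_deviation = additivity,
    degenerate = degenerate
  ), class = "asca")
}

#' @export
print.asca <- function(x, ...) {
  cat(sprintf("<asca> %d samples x %d buckets\n",
              nrow(x$centered), ncol(x$centered)))
  if (x$degenerate) {
    cat("  degenerate: data constant over samples\n")
    return(invisible(x))
  }
  df <- tidy(x)
  print(as.data.frame(df), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname asca
#' @param x An `asca` object.
#' @param ... Unused.
#' @export
tidy.asca <- function(x, ...) {
  tibble::tibble(
    term = names(x$ssq),
    ssq = unname(x$ssq),
    percent = unname(x$percent),
    p_value = unname(x$p_values[match(names(x$ssq), names(x$p_values))])
  )
}

#' @rdname asca
#' @export
glance.asca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$centered),
    n_buckets = ncol(x$centered),
    n_perm = x$n_perm,
    additivity_deviation = x$additivity_deviation,
    degenerate = x$degenerate
  )
}

#' @rdname asca
#' @param object An `asca` object.
#' @export
autoplot.asca <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = c("time", "dose", "interaction", "residual"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of centered variation",
                  title = "A-SCA effect contributions") +
    ggplot2::theme_minimal()
}

# ---- per-block component analysis ------------------------------------------

#' Principal-component sub-model of one A-SCA effect block
#'
#' Performs the simultaneous-component step: a singular value decomposition of
#' one effect matrix, giving per-sample component scores, per-bucket loadings
#' and the percent of the block's variation explained per component.
#'
#' @param x An [asca()] object.
#' @param block One of `"time"`, `"dose"`, `"interaction"`, `"residual"`.
#' @return An object of class `sca`: list with `block`, `scores` (tibble of
#'   sample scores joined to the design), `loadings` (buckets-by-components
#'   matrix), `explained` (percent per component) and `degenerate`.
#' @export
sca <- function(x, block = c("time", "dose", "interaction", "residual")) {
  stopifnot(inherits(x, "asca"))
  block <- match.arg(block)
  E <- x$effects[[block]]
  tot <- sum(E^2)
  if (tot <= 1e-24) {
    return(structure(list(block = block, scores = NULL, loadings = NULL,
                          explained = numeric(0), degenerate = TRUE),
                     class = "sca"))
  }
  sv <- svd(E)
  keep <- sv$d > sv$d[1] * 1e-9
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  colnames(scores) <- paste0("PC", seq_along(d))
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(E)
  colnames(loadings) <- paste0("PC", seq_along(d))
  sc <- dplyr::bind_cols(x$design, tibble::as_tibble(scores))
  structure(list(block = block, scores = sc, loadings = loadings,
                 explained = 100 * d^2 / sum(sv$d^2), degenerate = FALSE),
            class = "sca")
}

#' @export
print.sca <- function(x, ...) {
  cat(sprintf("<sca> block '%s'", x$block))
  if (x$degenerate) {
    cat(" (degenerate: zero block)\n")
  } else {
    cat(sprintf(", PC1 explains %.1f%%\n", x$explained[1]))
  }
  invisible(x)
}

#' Mean interaction score per (time, dose) cell
#'
#' Aggregates the first-component scores of the interaction sub-model to
#' cell means, the data behind score-profile line plots showing how the dose
#' response evolves over time.
#'
#' @param submodel An [sca()] sub-model, normally for the `"interaction"`
#'   block.
#' @param component Which component to profile (default 1).
#' @return Tibble with columns `time`, `dose`, `score`, ordered by time
#'   within dose.
#' @export
interaction_score_profile <- function(submodel, component = 1) {
  stopifnot(inherits(submodel, "sca"))
  if (submodel$degenerate) {
    return(tibble::tibble(time = factor(), dose = factor(), score = numeric()))
  }
  pc <- paste0("PC", component)
  submodel$scores |>
    dplyr::group_by(.data$dose, .data$time) |>
    dplyr::summarise(score = mean(.data[[pc]]), .groups = "drop") |>
    dplyr::arrange(.data$dose, .data$time) |>
    dplyr::select("time", "dose", "score")
}

#' Line plot of interaction score profiles
#'
#' @param profile Tibble from [interaction_score_profile()].
#' @return A ggplot object: mean interaction score against time, one line per
#'   dose.
#' @export
plot_interaction_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$time, y = .data$score,
                               colour = .data$dose,
                               group = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time point", y = "interaction score (PC1)",
                  colour = "dose") +
    ggplot2::theme_minimal()
}

# ---- combinatorial subset search -------------------------------------------

#' Search time-point and dose subsets for significant interactions
#'
#' Enumerates every combination of `k` time levels (`k_range`) and `h` dose
#' levels (`h_range`), re-runs the A-SCA decomposition on the corresponding
#' sample subset, and permutation-tests the Time-by-Dose interaction. On a
#' full 5-by-5 design with `k_range = 3:5`, `h_range = 2:5` this enumerates
#' 416 combinations. Combinations with an empty design cell are skipped with a
#' message.
#'
#' @inheritParams asca
#' @param k_range Sizes of the time subsets (at least 3 time points each).
#' @param h_range Sizes of the dose subsets.
#' @param n_perm Permutations per combination (0 = contributions only, no
#'   p-values).
#' @param alpha Significance level used to flag records.
#' @param fdr If `TRUE`, append a Benjamini-Hochberg adjusted p column across
#'   all analyzed combinations (off by default; raw p-values are primary).
#' @return An object of class `interaction_search`: a tibble with one row per
#'   analyzed combination (`time_set`, `dose_set` in canonical level order,
#'   `k`, `h`, `n`, percent contributions per block, `p_interaction`,
#'   `significant`) plus attributes `n_enumerated`, `n_skipped`, `n_perm`.
#' @export
search_interaction <- function(data, k_range = 3:5, h_range = 2:5,
                               n_perm = 999, alpha = 0.05, seed = NULL,
                               fdr = FALSE,
                               dose_col = "dose", time_col = "time") {
  data <- tibble::as_tibble(data)
  data$dose <- data[[dose_col]]
  data$time <- data[[time_col]]
  data <- check_design(data)
  if (min(k_range) < 3) abort("time subsets must contain at least 3 time points")
  tl <- levels(data$time)
  dl <- levels(data$dose)
  if (max(k_range) > length(tl) || max(h_range) > length(dl)) {
    abort("requested subset sizes exceed the observed factor cardinalities")
  }
  if (!is.null(seed)) set.seed(seed)
  X <- bucket_matrix(data)

  time_sets <- purrr::list_flatten(purrr::map(
    k_range, \(k) apply(combn(tl, k), 2, identity, simplify = FALSE)))
  dose_sets <- purrr::list_flatten(purrr::map(
    h_range, \(h) apply(combn(dl, h), 2, identity, simplify = FALSE)))

  n_enum <- 0L
  n_skip <- 0L
  rows <- list()
  for (ts in time_sets) {
    for (ds in dose_sets) {
      n_enum <- n_enum + 1L
      sel <- data$time %in% ts & data$dose %in% ds
      tf <- droplevels(data$time[sel])
      df_ <- droplevels(data$dose[sel])
      if (nlevels(tf) < length(ts) || nlevels(df_) < length(ds) ||
          any(table(tf, df_) == 0)) {
        n_skip <- n_skip + 1L
        inform(sprintf("skipping %s x %s: empty cell",
                       paste(ts, collapse = "+"), paste(ds, collapse = "+")))
        next
      }
      Xs <- X[sel, , drop = FALSE]
      Xc <- sweep(Xs, 2, colMeans(Xs))
      cf <- interaction(tf, df_, drop = TRUE, sep = " / ")
      maps <- cell_maps(tf, df_, cf)
      s3 <- asca_ssq(Xc, tf, df_, cf, maps$cell_time, maps$cell_dose)
      tot <- sum(Xc^2)
      lc <- level_means(Xc, cf)
      ssq_cell <- sum(lc$counts * rowSums(lc$means^2))
      obs_int <- s3[["interaction"]]
      p <- NA_real_
      if (n_perm > 0) {
        exceed <- 0L
        ns <- nrow(Xc)
        for (b in seq_len(n_perm)) {
          sp <- asca_ssq(Xc[sample.int(ns), , drop = FALSE], tf, df_, cf,
                         maps$cell_time, maps$cell_dose, which = "interaction")
          exceed <- exceed + (sp[["interaction"]] >= obs_int - 1e-12)
        }
        p <- (exceed + 1) / (n_perm + 1)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        time_set = paste(tl[tl %in% ts], collapse = "+"),
        dose_set = paste(dl[dl %in% ds], collapse = "+"),
        k = length(ts), h = length(ds), n = nrow(Xs),
        pct_time = 100 * s3[["time"]] / tot,
        pct_dose = 100 * s3[["dose"]] / tot,
        pct_interaction = 100 * obs_int / tot,
        pct_residual = 100 * (tot - ssq_cell) / tot,
        p_interaction = p
      )
    }
  }
  res <- dplyr::distinct(dplyr::bind_rows(rows))
  res$significant <- !is.na(res$p_interaction) & res$p_interaction < alpha
  if (fdr) res$p_adjusted <- p.adjust(res$p_interaction, method = "BH")
  structure(res, class = c("interaction_search", class(res)),
            n_enumerated = n_enum, n_skipped = n_skip,
            n_perm = n_perm, alpha = alpha)
}
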