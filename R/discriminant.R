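#' Select candidate discriminant buckets by importance score
#'
#' @param scores Named numeric vector (e.g. [vip()] output) or a tibble with
#'   columns `bucket` and a score column.
#' @param threshold Minimum score for selection. The standard convention for
#'   VIP is 1; for A-SCA loadings an absolute-loading quantile (e.g. the 95th
#'   percentile) is common.
#' @param mode Label recorded with the selection (`"vip"` or `"loading"`).
#'   When `mode = "loading"` the absolute value of the score is used.
#' @return Character vector of selected bucket labels (possibly empty, with a
#'   warning).
#' @export
select_candidates <- function(scores, threshold = 1,
                              mode = c("vip", "loading")) {
  mode <- match.arg(mode)
  if (is.data.frame(scores)) {
    sc_col <- setdiff(names(scores), "bucket")[1]
    v <- setNames(scores[[sc_col]], scores$bucket)
  } else {
    v <- scores
  }
  if (is.null(names(v))) abort("`scores` must be named by bucket")
  if (mode == "loading") v <- abs(v)
  sel <- names(v)[!is.na(v) & v >= threshold]
  if (length(sel) == 0) warn("no buckets reach the selection threshold")
  sel
}

#' Kruskal-Wallis rank test for one bucket across groups
#'
#' Thin wrapper around [stats::kruskal.test()] returning a tidy row, with an
#' explicit degenerate flag when all values are tied (H undefined; p reported
#' as 1).
#'
#' @param data Data frame with the value and group columns.
#' @param value_col,group_col Column names.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `degenerate`.
#' @export
kruskal_wallis <- function(data, value_col, group_col) {
  v <- data[[value_col]]
  g <- droplevels(factor(data[[group_col]]))
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("need at least 2 samples per group")
  if (length(unique(v)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L,
                          p_value = 1, degenerate = TRUE))
  }
  kt <- kruskal.test(v, g)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value, degenerate = FALSE)
}

# Dunn's rank-based post-hoc z test of group i vs j, with tie correction
dunn_z <- function(v, g, a, b) {
  r <- rank(v)
  N <- length(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  ra <- mean(r[g == a]); rb <- mean(r[g == b])
  na <- sum(g == a); nb <- sum(g == b)
  se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
  z <- (ra - rb) / se
  2 * pnorm(-abs(z))
}

#' Pairwise post-hoc comparisons of each group against a reference
#'
#' Compares every non-reference group with the reference group (conventionally
#' each exposed group against Control) after a significant overall
#' Kruskal-Wallis test, using Dunn's rank-based z test (default) or pairwise
#' Mann-Whitney tests, with multiple-testing correction across the
#' comparisons. Direction signs (`"+"`/`"-"`, group mean above/below the
#' reference mean) are reported only for comparisons passing the significance
#' threshold.
#'
#' @param data Data frame with value and group columns.
#' @param value_col,group_col Column names.
#' @param reference Reference group level (default `"Control"`).
#' @param method `"dunn"` or `"wilcox"` (Mann-Whitney).
#' @param correction A [stats::p.adjust()] method (default `"BH"`).
#' @param gate_p Overall Kruskal-Wallis p-value threshold gatekeeping the
#'   post-hoc tests (default 0.05); if the overall test is not significant an
#'   empty table is returned.
#' @param alpha Significance threshold for reporting a direction sign.
#' @return Tibble with one row per comparison: `group`, `p_value`,
#'   `p_adjusted`, `direction` (`"+"`, `"-"` or `NA`), `group_mean`,
#'   `reference_mean`, plus the overall KW columns.
#' @export
pairwise_posthoc <- function(data, value_col, group_col,
                             reference = "Control",
                             method = c("dunn", "wilcox"),
                             correction = "BH", gate_p = 0.05, alpha = 0.05) {
  method <- match.arg(method)
  v <- data[[value_col]]
  g <- droplevels(factor(data[[group_col]]))
  if (!reference %in% levels(g)) {
    abort(paste0("reference group '", reference, "' not present"))
  }
  kw <- kruskal_wallis(data, value_col, group_col)
  others <- setdiff(levels(g), reference)
  if (kw$p_value >= gate_p) {
    return(tibble::tibble(group = character(), p_value = numeric(),
                          p_adjusted = numeric(), direction = character(),
                          group_mean = numeric(), reference_mean = numeric(),
                          kw_statistic = numeric(), kw_p = numeric()))
  }
  p <- vapply(others, function(b) {
    switch(method,
      dunn = dunn_z(v, g, b, reference),
      wilcox = suppressWarnings(
        wilcox.test(v[g == b], v[g == reference])$p.value))
  }, numeric(1))
  padj <- p.adjust(p, method = correction)
  gm <- vapply(others, function(b) mean(v[g == b]), numeric(1))
  rm_ <- mean(v[g == reference])
  tibble::tibble(
    group = others,
    p_value = unname(p),
    p_adjusted = unname(padj),
    direction = ifelse(padj < alpha, ifelse(gm > rm_, "+", "-"), NA_character_),
    group_mean = unname(gm),
    reference_mean = rm_,
    kw_statistic = kw$statistic,
    kw_p = kw$p_value
  )
}

#' Per-bucket discriminant statistics for a set of candidate buckets
#'
#' Runs the Kruskal-Wallis gatekeeper and reference post-hoc comparisons for
#' each candidate bucket of a cohort.
#'
#' @param data Cohort table.
#' @param buckets Character vector of bucket labels (e.g. from
#'   [select_candidates()]).
#' @param group_col Grouping design column (default `"dose"`).
#' @param scores Optional named selection-score vector carried into the output.
#' @inheritParams pairwise_posthoc
#' @return Tibble with one row per (bucket, comparison).
#' @export
discriminant_records <- function(data, buckets, group_col = "dose",
                                 reference = "Control", scores = NULL,
                                 method = "dunn", correction = "BH",
                                 gate_p = 0.05, alpha = 0.05) {
  purrr::map_dfr(buckets, function(b) {
    res <- pairwise_posthoc(data, b, group_col, reference = reference,
                            method = method, correction = correction,
                            gate_p = gate_p, alpha = alpha)
    if (nrow(res) == 0) return(res)
    dplyr::bind_cols(
      tibble::tibble(bucket = b,
                     score = if (!is.null(scores)) unname(scores[b]) else NA_real_),
      res)
  })
}

#' Aggregate bucket-level discriminant records to metabolites
#'
#' Maps bucket records onto metabolite annotations and aggregates resonances
#' of the same metabolite: maximum selection score, one direction sign per
#' comparison (with a conflict flag when resonances disagree), and the
#' minimum adjusted p. Significant buckets without an annotation are reported
#' as `"unassigned d <lo>-<hi>"` using their bucket interval.
#'
#' @param records Tibble from [discriminant_records()].
#' @param annotation Annotation tibble (`metabolite`, `ppm_lo`, `ppm_hi`), see
#'   [read_annotation()].
#' @param grid The [bucket_grid()] the buckets live on.
#' @return Tibble with one row per (metabolite, comparison group):
#'   `metabolite`, `group`, `conflict`, `direction`, `score`, `p_adjusted`,
#'   `n_buckets`.
#' @export
annotate_and_summarize <- function(records, annotation, grid) {
  if (nrow(records) == 0) {
    return(tibble::tibble(metabolite = character(), group = character(),
                          direction = character(), conflict = logical(),
                          score = numeric(), p_adjusted = numeric(),
                          n_buckets = integer()))
  }
  ab <- annotation_buckets(annotation, grid)
  w <- grid$width
  dec <- max(0L, -as.integer(floor(log10(w))) + 1L)
  lab <- function(b) {
    ctr <- as.numeric(b)
    sprintf("unassigned d %s-%s",
            formatC(ctr - w / 2, format = "f", digits = dec),
            formatC(ctr + w / 2, format = "f", digits = dec))
  }
  joined <- dplyr::left_join(records, ab, by = "bucket",
                             relationship = "many-to-many")
  joined$metabolite[is.na(joined$metabolite)] <-
    vapply(joined$bucket[is.na(joined$metabolite)], lab, character(1))
  joined |>
    dplyr::group_by(.data$metabolite, .data$group) |>
    dplyr::summarise(
      conflict = length(unique(stats::na.omit(.data$direction))) > 1,
      direction = {
        d <- unique(stats::na.omit(.data$direction))
        if (length(d) == 0) NA_character_ else paste(d, collapse = "/")
      },
      score = max(.data$score),
      p_adjusted = min(.data$p_adjusted),
      n_buckets = dplyr::n_distinct(.data$bucket),
      .groups = "drop"
    )
}
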