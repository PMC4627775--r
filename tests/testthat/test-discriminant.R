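test_that("candidate selection honors thresholds and modes", {
  v <- setNames(c(0.5, 0.5, 0.5), c("b1", "b2", "b3"))
  expect_warning(sel <- select_candidates(v, threshold = 1), "threshold")
  expect_length(sel, 0)
  expect_setequal(select_candidates(v, threshold = 0), names(v))
  l <- setNames(c(-2, 0.1, 0.5), c("b1", "b2", "b3"))
  expect_setequal(select_candidates(l, threshold = 1, mode = "loading"), "b1")
})

test_that("selection recovers the single informative bucket at VIP > 1", {
  set.seed(1)
  n <- 200; p <- 15
  cls <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * p, 0, 0.3), n, p)
  X[, 4] <- X[, 4] + ifelse(cls == "A", 2, -2)
  co <- make_cohort(X, cls, rep("t", n))
  m <- plsda(co, ncomp = 1, cv = FALSE)
  sel <- select_candidates(vip(m), threshold = 1)
  expect_identical(sel, names(vip(m))[4])
})

test_that("Kruskal-Wallis matches the hand-ranked oracle", {
  df <- data.frame(y = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                   g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(df, "y", "g")
  # hand computation: ranks 1..9, group mean ranks 2/5/8,
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 7.2
  expect_equal(kw$statistic, 7.2, tolerance = 1e-9)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-9)
  tied <- data.frame(y = rep(1, 6), g = rep(c("a", "b"), 3))
  kt <- kruskal_wallis(tied, "y", "g")
  expect_true(kt$degenerate)
  expect_equal(kt$p_value, 1)
})

test_that("KW p-values are uniform under the null", {
  set.seed(2)
  ps <- replicate(500, {
    df <- data.frame(y = rnorm(24), g = rep(c("a", "b", "c"), each = 8))
    kruskal_wallis(df, "y", "g")$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("group renaming leaves the statistic unchanged", {
  set.seed(3)
  df <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), 10))
  h1 <- kruskal_wallis(df, "y", "g")$statistic
  df$g <- c(a = "z", b = "x", c = "w")[df$g]
  expect_equal(kruskal_wallis(df, "y", "g")$statistic, h1)
})

test_that("post-hoc flags exactly the shifted dose with the right sign", {
  set.seed(4)
  doses <- c("Control", "BPA0.25", "BPA2.5", "BPA25", "BPA250")
  df <- data.frame(g = rep(doses, each = 12))
  df$y <- rnorm(60, 0, 0.5) + ifelse(df$g == "BPA25", 3, 0)
  res <- pairwise_posthoc(df, "y", "g", reference = "Control")
  hit <- res[res$group == "BPA25", ]
  expect_identical(unname(hit$direction), "+")
  expect_lt(hit$p_adjusted, 0.05)
  expect_true(all(is.na(res$direction[res$group != "BPA25"])))
  # downward shift flips the sign
  df$y <- rnorm(60, 0, 0.5) + ifelse(df$g == "BPA2.5", -3, 0)
  res2 <- pairwise_posthoc(df, "y", "g", reference = "Control")
  expect_identical(unname(res2$direction[res2$group == "BPA2.5"]), "-")
})

test_that("a non-significant overall test gates out the post-hoc", {
  set.seed(5)
  df <- data.frame(y = rnorm(40), g = rep(c("Control", "b", "c", "d"), 10))
  kw <- kruskal_wallis(df, "y", "g")
  res <- pairwise_posthoc(df, "y", "g", reference = "Control")
  expect_gt(kw$p_value, 0.05)
  expect_identical(nrow(res), 0L)
})

test_that("Bonferroni correction is min(1, m p)", {
  set.seed(6)
  doses <- c("Control", "d1", "d2", "d3", "d4")
  df <- data.frame(g = rep(doses, each = 10))
  df$y <- rnorm(50) + ifelse(df$g == "d1", 2.5, 0)
  res <- pairwise_posthoc(df, "y", "g", reference = "Control",
                          correction = "bonferroni")
  expect_equal(res$p_adjusted, pmin(1, 4 * res$p_value), tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("corrected per-bucket false positives stay at the nominal level", {
  set.seed(7)
  doses <- c("Control", "d1", "d2", "d3", "d4")
  n_sig <- replicate(500, {
    df <- data.frame(g = rep(doses, each = 8), y = rnorm(40))
    res <- pairwise_posthoc(df, "y", "g", reference = "Control",
                            correction = "BH")
    if (nrow(res) == 0) 0L else sum(res$p_adjusted < 0.05)
  })
  # fraction of null buckets with any significant comparison after the
  # KW gate and BH correction must stay at or below the nominal level
  rate <- mean(n_sig > 0)
  expect_lte(rate, 0.05 + 2.6 * sqrt(0.05 * 0.95 / 500))
})

test_that("metabolite aggregation merges resonances and flags conflicts", {
  g <- test_grid()
  ann <- tibble::tibble(metabolite = "glucose",
                        ppm_lo = c(0.51, 0.61), ppm_hi = c(0.56, 0.66))
  rec <- tibble::tibble(
    bucket = c("0.525", "0.625"), score = c(1.4, 1.9),
    group = "BPA25", p_value = c(0.01, 0.02), p_adjusted = c(0.02, 0.03),
    direction = c("+", "+"), group_mean = 1, reference_mean = 0,
    kw_statistic = 10, kw_p = 0.001)
  out <- annotate_and_summarize(rec, ann, g)
  expect_identical(nrow(out), 1L)
  expect_identical(out$direction, "+")
  expect_false(out$conflict)
  expect_equal(out$score, 1.9)
  # conflicting signs are both reported with a flag
  rec$direction <- c("+", "-")
  out2 <- annotate_and_summarize(rec, ann, g)
  expect_true(out2$conflict)
  expect_match(out2$direction, "\\+.*-|-.*\\+")
  # unannotated buckets become explicit unassigned intervals
  rec2 <- rec[1, ]; rec2$bucket <- "3.475"
  out3 <- annotate_and_summarize(rec2, ann, g)
  expect_match(out3$metabolite, "unassigned d 3\\.450-3\\.500")
})

test_that("an injected multiplet aggregates with the injected direction", {
  cfg <- synth_config(dose_amplitude = 1.5, frac_dose = 1, time_amplitude = 0,
                      interaction_amplitude = 0, sigma = 0.1,
                      n_metabolites = 4, buckets_per_metabolite = 3,
                      n_doses = 2, n_times = 2, n_per_cell = 12,
                      dose_levels = c("Control", "BPA25"))
  sim <- simulate_cohort(cfg, seed = 12)
  d <- dplyr::filter(sim$cohort, time == levels(sim$cohort$time)[1])
  m <- plsda(d, class_col = "dose", ncomp = 1, cv = FALSE)
  sel <- select_candidates(vip(m), threshold = 1)
  rec <- discriminant_records(d, sel, group_col = "dose",
                              reference = "Control", scores = vip(m))
  ann <- dplyr::mutate(
    dplyr::group_by(sim$truth$bucket_map, metabolite),
    ppm_lo = as.numeric(bucket) - 0.001, ppm_hi = as.numeric(bucket) + 0.001)
  ann <- dplyr::ungroup(ann)[c("metabolite", "ppm_lo", "ppm_hi")]
  out <- annotate_and_summarize(rec, ann, sim$config$grid)
  expect_gt(nrow(out), 0)
  # each reported metabolite carries a single, unconflicted direction
  expect_true(all(!out$conflict))
  expect_true(all(out$direction %in% c("+", "-")))
})
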