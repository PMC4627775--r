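test_that("first PLS weight matches the X'y oracle for a single response", {
  set.seed(1)
  n <- 30; p <- 25
  X <- matrix(rnorm(n * p), n, p)
  cls <- rep(c("A", "B"), length.out = n)
  co <- make_cohort(X, cls, rep("t", n))
  m <- plsda(co, ncomp = 1, scaling = "uv", cv = FALSE)
  # oracle: w proportional to X'y on the scaled data
  Xs <- scale(X)
  y <- scale(ifelse(cls == "A", 1, 0), scale = FALSE)
  w_oracle <- crossprod(Xs, y)[, 1]
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  cosine <- abs(sum(m$weights[, 1] * w_oracle))
  expect_gt(cosine, 0.999)
})

test_that("two separable classes give a 1-component model with R2Y near 100%", {
  cls <- rep(c("A", "B"), each = 10)
  X <- cbind(ifelse(cls == "A", 1, -1) + rnorm(20, 0, 0.01),
             rnorm(20, 0, 0.01))
  co <- make_cohort(X, cls, rep("t", 20))
  m <- plsda(co, ncomp = 1, scaling = "uv", cv = FALSE)
  expect_gt(m$R2Y, 99)
})

test_that("sample order does not change the model beyond row permutation", {
  sim <- simulate_cohort(synth_config(dose_amplitude = 0.6, frac_dose = 0.6,
                                      sigma = 0.1, n_metabolites = 12,
                                      buckets_per_metabolite = c(1, 2)),
                         seed = 2)
  d <- dplyr::filter(sim$cohort, time == "PND50")
  set.seed(3)
  perm <- sample(nrow(d))
  m1 <- plsda(d, ncomp = 2, cv = FALSE)
  m2 <- plsda(d[perm, ], ncomp = 2, cv = FALSE)
  expect_equal(abs(m2$scores$comp1[order(perm)] * sign(cor(
    m2$scores$comp1[order(perm)], m1$scores$comp1))),
    abs(m1$scores$comp1), tolerance = 1e-6)
  expect_equal(vip(m1), vip(m2), tolerance = 1e-6)
})

test_that("mixOmics agrees with the NIPALS implementation on scores and VIP", {
  sim <- simulate_cohort(synth_config(dose_amplitude = 0.8, frac_dose = 0.6,
                                      sigma = 0.15, n_metabolites = 15,
                                      buckets_per_metabolite = c(1, 2)),
                         seed = 5)
  d <- dplyr::filter(sim$cohort, time == "PND90")
  m <- plsda(d, ncomp = 2, cv = FALSE)
  X <- as.matrix(d[bucket_cols(d)])
  ref <- mixOmics::plsda(X, d$dose, ncomp = 2, scale = TRUE)
  expect_gt(abs(cor(m$scores$comp1, ref$variates$X[, 1])), 0.99)
  expect_gt(abs(cor(m$scores$comp2, ref$variates$X[, 2])), 0.99)
  expect_gt(cor(vip(m), mixOmics::vip(ref)[, 2]), 0.99)
})

test_that("the mean squared VIP equals one and VIP ignores label names", {
  sim <- simulate_cohort(synth_config(n_metabolites = 10,
                                      buckets_per_metabolite = c(1, 2)),
                         seed = 6)
  d <- dplyr::filter(sim$cohort, time == "PND140")
  m <- plsda(d, ncomp = 3, cv = FALSE)
  expect_equal(mean(vip(m)^2), 1, tolerance = 1e-10)
  d2 <- d
  d2$dose <- factor(paste0("grp_", as.integer(d$dose)))
  m2 <- plsda(d2, ncomp = 3, cv = FALSE)
  expect_equal(unname(vip(m)), unname(vip(m2)), tolerance = 1e-8)
})

test_that("a lone informative bucket attains the maximal VIP", {
  set.seed(7)
  n <- 40; p <- 20
  cls <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * p, 0, 0.2), n, p)
  X[, 7] <- X[, 7] + ifelse(cls == "A", 2, -2)
  co <- make_cohort(X, cls, rep("t", n))
  m <- plsda(co, ncomp = 1, cv = FALSE)
  expect_equal(which.max(vip(m)), 7L, ignore_attr = TRUE)
  expect_gt(max(vip(m)), 1)
})

test_that("cross-validated Q2 is negative for noise and bounded by one", {
  set.seed(8)
  q2 <- replicate(20, {
    X <- matrix(rnorm(35 * 15), 35, 15)
    co <- make_cohort(X, sample(rep(c("A", "B"), length.out = 35)),
                      rep("t", 35))
    cross_validate_q2(co, ncomp = 2, seed = 1)[2]
  })
  expect_lt(mean(q2), 0.05)   # no predictive ability in expectation
  expect_true(all(q2 <= 1))
})

test_that("Q2 is high for a strong synthetic class signal", {
  sim <- simulate_cohort(synth_config(dose_amplitude = 1.2, frac_dose = 0.8,
                                      sigma = 0.1, n_metabolites = 20,
                                      buckets_per_metabolite = c(1, 2)),
                         seed = 21)
  d <- dplyr::filter(sim$cohort, time == "PND50")
  q2 <- cross_validate_q2(d, ncomp = 3, seed = 2)
  expect_gt(q2[3], 0.4)
})

test_that("stratification errors when a class cannot reach every fold", {
  co <- make_cohort(matrix(rnorm(30), 10, 3),
                    c(rep("A", 9), "B"), rep("t", 10))
  expect_error(cross_validate_q2(co, ncomp = 1, folds = 7, seed = 1),
               "absent from a training fold|fewer folds")
})

test_that("permutation validation requires enough iterations", {
  co <- make_cohort(matrix(rnorm(30), 10, 3),
                    rep(c("A", "B"), 5), rep("t", 10))
  expect_error(permutation_validate(co, n = 0), "at least 20")
  expect_error(permutation_validate(co, n = 19), "at least 20")
})

test_that("informative data is robust; null labels sit inside the cloud", {
  sim <- simulate_cohort(synth_config(dose_amplitude = 1.2, frac_dose = 0.8,
                                      sigma = 0.1, n_metabolites = 20,
                                      buckets_per_metabolite = c(1, 2)),
                         seed = 21)
  d <- dplyr::filter(sim$cohort, time == "PND50")
  pv <- permutation_validate(d, ncomp = 3, n = 40, seed = 3)
  expect_lt(pv$Q2_intercept, 0)
  expect_true(pv$robust)
  expect_true(pv$valid)
  # already-random labels: the original Q2 is not an outlier of the cloud
  d0 <- d
  set.seed(9)
  d0$dose <- sample(d0$dose)
  pv0 <- permutation_validate(d0, ncomp = 2, n = 40, seed = 4)
  expect_false(pv0$valid)
  expect_lt(pv0$Q2, max(pv0$permutations$Q2))
})

test_that("hotelling ellipse geometry: isotropy, equivariance, limits", {
  set.seed(10)
  S <- matrix(rnorm(4000), 2000, 2)
  e <- hotelling_ellipse(S)
  expect_lt(abs(e$semi_axes[1] / e$semi_axes[2] - 1), 0.1)
  e3 <- hotelling_ellipse(3 * S)
  expect_equal(e3$semi_axes, 3 * e$semi_axes, tolerance = 1e-9)
  e_deg <- hotelling_ellipse(S, alpha = 1)
  expect_equal(unname(e_deg$semi_axes), c(0, 0))
  expect_error(hotelling_ellipse(S[1:2, ]), "at least 3")
  expect_error(hotelling_ellipse(cbind(1:10, 2 * (1:10))), "singular")
  # the 95% ellipse contains roughly 95% of gaussian scores
  inside <- mahalanobis(S, e$center, e$covariance) <= e$t2_critical
  expect_gt(mean(inside), 0.93)
  expect_lt(mean(inside), 0.97)
})

test_that("auto component selection stops when Q2 stalls", {
  sim <- simulate_cohort(synth_config(dose_amplitude = 1.0, frac_dose = 0.6,
                                      sigma = 0.15, n_metabolites = 15,
                                      buckets_per_metabolite = c(1, 2)),
                         seed = 11)
  d <- dplyr::filter(sim$cohort, time == "PND90")
  m <- plsda(d, ncomp = "auto", seed = 5)
  expect_gte(m$ncomp, 1)
  expect_lte(m$ncomp, 10)
  if (m$ncomp > 1) {
    gains <- diff(c(0, m$Q2_cum))
    expect_gte(gains[m$ncomp], 0.01)
  }
})
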