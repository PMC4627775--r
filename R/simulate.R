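#' Configuration for the synthetic-cohort generator
#'
#' Describes a two-way longitudinal design (doses crossed with sacrifice time
#' points, separate animals per cell) and the effect structure to inject on
#' the log-concentration scale. Defaults mirror a 5-dose-by-5-time rat study
#' with 6 to 10 animals per cell and a Time-dominated variance budget (large
#' dynamic variation over age, small dose main effect, modest interaction),
#' the structure typical of perinatal dose-response NMR metabolomics.
#'
#' Effects enter additively on the log scale, so concentrations stay positive
#' and the noise model is multiplicative, as is standard for NMR intensities.
#' Time trajectories are seeded low-order (linear/quadratic) shapes per
#' affected metabolite; dose responses are monotone or U-shaped (non-monotone
#' responses being a hallmark of endocrine disruptors); interaction patterns
#' are cell-specific and double-centered, so they are pure interactions.
#'
#' @param n_doses,n_times Factor cardinalities (default 5 and 5).
#' @param n_per_cell Animals per design cell: a single count, a length-2 range
#'   sampled per cell (default `c(6, 10)`, unbalanced), or an
#'   `n_times`-by-`n_doses` matrix of counts.
#' @param n_metabolites Number of latent metabolites (default 30).
#' @param buckets_per_metabolite Range of resonances (distinct buckets) per
#'   metabolite (default `c(1, 4)`).
#' @param time_amplitude,dose_amplitude,interaction_amplitude Maximum absolute
#'   effect of each term on the log-concentration scale (standardized units).
#' @param frac_time,frac_dose,frac_interaction Fraction of metabolites
#'   affected by each term.
#' @param sigma Standard deviation of the multiplicative (log-normal) noise.
#' @param noise_floor Scale of the additive baseline noise added to every
#'   bucket (half-normal).
#' @param grid [bucket_grid()] on which resonances are placed; default is a
#'   60-bucket demonstration grid. Pass the full serum grid to emulate
#'   738-bucket vectors.
#' @param dose_levels,time_levels Factor level labels (defaults
#'   `Control`/`BPA0.25`/`BPA2.5`/`BPA25`/`BPA250` and `PND21`...`PND200`).
#' @param interaction_times,interaction_doses Optional level subsets: when
#'   given, interaction effects are injected only into these cells (the
#'   pattern is double-centered within the sub-block, hence a pure interaction
#'   in the full design too). Used to create a known target for the subset
#'   search.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_doses = 5, n_times = 5, n_per_cell = c(6, 10),
                         n_metabolites = 30, buckets_per_metabolite = c(1, 4),
                         time_amplitude = 0.4, dose_amplitude = 0.1,
                         interaction_amplitude = 0.2,
                         frac_time = 0.6, frac_dose = 0.3,
                         frac_interaction = 0.3,
                         sigma = 0.2, noise_floor = 1e-4,
                         grid = bucket_grid(c(0.5, 3.5), 0.05),
                         dose_levels = NULL, time_levels = NULL,
                         interaction_times = NULL, interaction_doses = NULL) {
  if (any(c(time_amplitude, dose_amplitude, interaction_amplitude) < 0)) {
    abort("effect amplitudes must be non-negative")
  }
  fr <- c(frac_time, frac_dose, frac_interaction)
  if (any(fr < 0 | fr > 1)) abort("affected fractions must lie in [0, 1]")
  if (is.null(dose_levels)) {
    dose_levels <- if (n_doses == 5) {
      c("Control", "BPA0.25", "BPA2.5", "BPA25", "BPA250")
    } else paste0("D", seq_len(n_doses))
  }
  if (is.null(time_levels)) {
    time_levels <- if (n_times == 5) {
      c("PND21", "PND50", "PND90", "PND140", "PND200")
    } else paste0("T", seq_len(n_times))
  }
  stopifnot(length(dose_levels) == n_doses, length(time_levels) == n_times)
  if (!is.null(interaction_times)) {
    stopifnot(all(interaction_times %in% time_levels),
              length(interaction_times) >= 2)
  }
  if (!is.null(interaction_doses)) {
    stopifnot(all(interaction_doses %in% dose_levels),
              length(interaction_doses) >= 2)
  }
  structure(list(
    n_doses = n_doses, n_times = n_times, n_per_cell = n_per_cell,
    n_metabolites = n_metabolites,
    buckets_per_metabolite = buckets_per_metabolite,
    time_amplitude = time_amplitude, dose_amplitude = dose_amplitude,
    interaction_amplitude = interaction_amplitude,
    frac_time = frac_time, frac_dose = frac_dose,
    frac_interaction = frac_interaction,
    sigma = sigma, noise_floor = noise_floor, grid = grid,
    dose_levels = dose_levels, time_levels = time_levels,
    interaction_times = interaction_times,
    interaction_doses = interaction_doses
  ), class = "synth_config")
}

# centered, max-|.|-scaled shape over nl ordered levels
random_shape <- function(nl, kind = c("linear", "quadratic"), amplitude) {
  kind <- match.arg(kind)
  x <- seq(-1, 1, length.out = nl)
  z <- switch(kind, linear = x, quadratic = x^2)
  z <- z - mean(z)
  if (max(abs(z)) < 1e-12) z <- x - mean(x)  # quadratic is flat on 2 levels
  z <- z / max(abs(z)) * amplitude
  z * sample(c(-1, 1), 1)
}

# double-center a matrix (zero row and column means)
double_center <- function(M) {
  M <- sweep(M, 1, rowMeans(M))
  sweep(M, 2, colMeans(M))
}

#' Simulate a longitudinal dose-response cohort with known ground truth
#'
#' Generates per-animal metabolite concentrations as
#' `baseline * exp(time effect + dose effect + interaction + noise)`, maps
#' them onto bucket resonances of the configured grid, adds a baseline noise
#' floor, and total-area normalizes each sample. The "truth" record holds the
#' ANOVA effect matrices of the noise-free pipeline output (which satisfy the
#' decomposition's zero-sum constraints exactly and reconstruct the noise-free
#' data with zero residual), the per-metabolite affected flags and the true
#' effect-block variance shares.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed; the seed fully determines the output.
#' @return List with elements `cohort` (noisy cohort tibble, normalized),
#'   `noise_free` (same layout, no noise), `truth` (class `synth_truth`: list
#'   with `effects`, `percent`, `effect_shares`, `affected`, `bucket_map`,
#'   `signs`) and `config`.
#' @examples
#' sim <- simulate_cohort(synth_config(n_metabolites = 6), seed = 7)
#' dplyr::count(sim$cohort, dose, time)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- config$n_times
  h <- config$n_doses
  tl <- config$time_levels
  dl <- config$dose_levels
  p <- n_buckets(config$grid)
  m <- config$n_metabolites

  npc <- config$n_per_cell
  ncell <- if (is.matrix(npc)) {
    stopifnot(nrow(npc) == k, ncol(npc) == h)
    npc
  } else if (length(npc) == 1) {
    matrix(npc, k, h)
  } else {
    matrix(sample(seq(npc[1], npc[2]), k * h, replace = TRUE), k, h)
  }
  design <- tidyr::expand_grid(time = seq_len(k), dose = seq_len(h)) |>
    dplyr::mutate(n = as.vector(t(ncell))[
      (.data$time - 1) * h + .data$dose]) |>
    tidyr::uncount(.data$n)
  n <- nrow(design)

  # place resonances on the grid
  bpm <- config$buckets_per_metabolite
  r_m <- if (length(bpm) == 1) rep(bpm, m) else
    sample(seq(bpm[1], bpm[2]), m, replace = TRUE)
  if (sum(r_m) > p) {
    abort(sprintf("grid too small: %d buckets for %d requested resonances",
                  p, sum(r_m)))
  }
  pos <- sample.int(p, sum(r_m))
  met_of <- rep(seq_len(m), r_m)
  W <- matrix(0, m, p)  # metabolite -> bucket mapping weights
  wt <- runif(sum(r_m), 0.3, 1)
  for (i in seq_along(pos)) W[met_of[i], pos[i]] <- wt[i]
  W <- W / rowSums(W)

  baseline <- rnorm(m, 0, 0.5)
  affected <- tibble::tibble(
    metabolite = paste0("M", seq_len(m)),
    time = runif(m) < config$frac_time,
    dose = runif(m) < config$frac_dose,
    interaction = runif(m) < config$frac_interaction
  )

  TE <- matrix(0, k, m)
  DE <- matrix(0, h, m)
  IE <- array(0, c(k, h, m))
  for (j in seq_len(m)) {
    if (affected$time[j] && config$time_amplitude > 0) {
      TE[, j] <- random_shape(k, sample(c("linear", "quadratic"), 1),
                              config$time_amplitude)
    }
    if (affected$dose[j] && config$dose_amplitude > 0) {
      DE[, j] <- random_shape(h, sample(c("linear", "quadratic"), 1),
                              config$dose_amplitude)
    }
    if (affected$interaction[j] && config$interaction_amplitude > 0) {
      M <- matrix(0, k, h)
      if (!is.null(config$interaction_times) &&
          !is.null(config$interaction_doses)) {
        it <- match(config$interaction_times, tl)
        id <- match(config$interaction_doses, dl)
        # centered alternating contrasts: every selected cell carries signal
        st <- rep_len(c(1, -1), length(it))
        st <- st - mean(st)
        sd_ <- rep_len(c(1, -1), length(id))
        sd_ <- sd_ - mean(sd_)
        M[it, id] <- outer(st, sd_)
      } else {
        M <- double_center(matrix(rnorm(k * h), k, h))
      }
      if (max(abs(M)) > 0) {
        M <- M / max(abs(M)) * config$interaction_amplitude
      }
      IE[, , j] <- M * sample(c(-1, 1), 1)
    }
  }

  idx <- cbind(design$time, design$dose)
  logC0 <- matrix(baseline, n, m, byrow = TRUE) +
    TE[design$time, , drop = FALSE] + DE[design$dose, , drop = FALSE] +
    matrix(apply(IE, 3, function(M) M[idx]), n, m)
  eps <- matrix(rnorm(n * m, 0, config$sigma), n, m)
  floor_noise <- matrix(abs(rnorm(n * p, 0, config$noise_floor)), n, p)

  B_noisy <- exp(logC0 + eps) %*% W + floor_noise
  B_free <- exp(logC0) %*% W

  labels <- config$grid$labels
  make_cohort <- function(B) {
    out <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      dose = factor(dl[design$dose], levels = dl),
      time = factor(tl[design$time], levels = tl),
      animal_id = sprintf("A%03d", seq_len(n))
    )
    colnames(B) <- labels
    out <- dplyr::bind_cols(out, tibble::as_tibble(B))
    normalize_total_area(out)
  }
  cohort <- make_cohort(B_noisy)
  noise_free <- make_cohort(B_free)

  truth_fit <- asca(noise_free)
  eff_ssq <- truth_fit$ssq[c("time", "dose", "interaction")]
  shares <- if (sum(eff_ssq) > 0) 100 * eff_ssq / sum(eff_ssq) else
    setNames(rep(NA_real_, 3), names(eff_ssq))

  truth <- structure(list(
    effects = truth_fit$effects,
    percent = truth_fit$percent,
    effect_shares = shares,
    affected = affected,
    bucket_map = tibble::tibble(metabolite = paste0("M", met_of),
                                bucket = labels[pos],
                                weight = W[cbind(met_of, pos)]),
    time_effects = TE, dose_effects = DE, interaction_effects = IE
  ), class = "synth_truth")

  list(cohort = cohort, noise_free = noise_free, truth = truth,
       config = config)
}

#' Run an analysis hook over many null cohorts
#'
#' Type-I-error harness: simulates `n_datasets` cohorts from `config`
#' (normally a null configuration with all effect amplitudes 0), applies
#' `hook` to each cohort, and reports the empirical rejection rate of the
#' returned p-values at a nominal level.
#'
#' @param config A [synth_config()]; set the amplitudes to 0 for a null batch.
#' @param n_datasets Number of simulated datasets.
#' @param hook Function taking a cohort tibble and returning a (possibly
#'   named) vector of p-values.
#' @param level Nominal significance level (default 0.05).
#' @param seed RNG seed controlling both the per-dataset seeds and anything
#'   the hook draws.
#' @return List with `p_values` (tibble: `dataset` plus one column per
#'   p-value returned by the hook), `rejection_rate` (named, per column) and
#'   `level`.
#' @export
simulate_null_batch <- function(config, n_datasets, hook, level = 0.05,
                                seed = NULL) {
  stopifnot(is.function(hook), n_datasets >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_datasets)
  res <- purrr::map(seq_len(n_datasets), function(i) {
    sim <- simulate_cohort(config, seed = seeds[i])
    p <- tryCatch(hook(sim$cohort), error = function(e) {
      abort(sprintf("hook failed on dataset %d: %s", i, conditionMessage(e)))
    })
    if (is.null(names(p))) names(p) <- paste0("p", seq_along(p))
    tibble::as_tibble_row(c(dataset = i, p))
  })
  pv <- dplyr::bind_rows(res)
  rates <- colMeans(pv[-1] <= level)
  list(p_values = pv, rejection_rate = rates, level = level)
}
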