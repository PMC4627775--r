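# shared fixtures, built in code at test time

# a small grid used by most cohort fixtures (60 buckets of 0.05 ppm)
test_grid <- function() bucket_grid(c(0.5, 3.5), 0.05)

# a bare cohort table from a numeric matrix and design vectors
make_cohort <- function(X, dose, time, animal = NULL) {
  grid_labels <- formatC(seq(0.5 + 0.025, by = 0.05, length.out = ncol(X)),
                         format = "f", digits = 3)
  colnames(X) <- grid_labels
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(nrow(X))),
      dose = factor(dose, levels = unique(dose)),
      time = factor(time, levels = unique(time)),
      animal_id = if (is.null(animal)) sprintf("A%03d", seq_len(nrow(X))) else animal),
    tibble::as_tibble(X))
}

# balanced two-way cohort with given cell means (list over time of list over
# dose of mean vectors), n per cell, iid gaussian noise
make_twoway <- function(cell_means, n_per_cell, sigma = 0, seed = 1) {
  set.seed(seed)
  k <- length(cell_means); h <- length(cell_means[[1]])
  p <- length(cell_means[[1]][[1]])
  rows <- list(); dose <- time <- character(0)
  for (t in seq_len(k)) for (d in seq_len(h)) for (r in seq_len(n_per_cell)) {
    rows[[length(rows) + 1]] <- cell_means[[t]][[d]] + rnorm(p, 0, sigma)
    time <- c(time, paste0("T", t)); dose <- c(dose, paste0("D", d))
  }
  make_cohort(do.call(rbind, rows), dose, time)
}

# null-configuration generator (no injected effects), small grid
null_config <- function(n_metabolites = 20, ...) {
  synth_config(time_amplitude = 0, dose_amplitude = 0,
               interaction_amplitude = 0, n_metabolites = n_metabolites,
               buckets_per_metabolite = c(1, 2), ...)
}

# ---- independent oracles ----------------------------------------------------

# textbook two-way ANOVA sums of squares via stats::aov, one response column
# at a time (independent of the package's estimator)
aov_ssq <- function(data) {
  bc <- bucket_cols(data)
  out <- c(time = 0, dose = 0, interaction = 0, residual = 0)
  for (b in bc) {
    df <- data.frame(y = data[[b]], time = data$time, dose = data$dose)
    tab <- summary(stats::aov(y ~ time * dose, data = df))[[1]]
    ss <- tab[["Sum Sq"]]
    out <- out + c(ss[1], ss[2], ss[3], ss[4])
  }
  out
}

# brute-force lightest-path oracle: DFS enumeration of all simple paths in a
# directed node-cost graph (edge weight = cost of head node)
brute_force_path <- function(edges, node_type, from, to,
                             weighting = "degree", side_compounds = character()) {
  nodes <- unique(c(edges$from, edges$to))
  deg <- table(c(edges$from, edges$to))  # total degree in the full graph
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  cost <- function(v) {
    if (node_type[[v]] == "reaction") 1
    else if (weighting == "degree") as.numeric(deg[[v]]) else 1
  }
  blocked <- setdiff(side_compounds, c(from, to))
  best <- list(weight = Inf, path = NULL)
  recurse <- function(v, visited, w) {
    if (w >= best$weight) return()
    if (v == to) { best <<- list(weight = w, path = visited); return() }
    for (nx in adj[[v]]) {
      if (is.null(nx) || nx %in% visited || nx %in% blocked) next
      recurse(nx, c(visited, nx), w + cost(nx))
    }
  }
  recurse(from, from, 0)
  best
}

# toy linear chain a -[r1]- b -[r2]- c -[r3]- d written as TSV; returns path
toy_chain_tsv <- function(path) {
  readr::write_tsv(tibble::tibble(
    source = c("a", "r1", "b", "r2", "c", "r3"),
    target = c("r1", "b", "r2", "c", "r3", "d"),
    type = c("substrate", "product", "substrate", "product",
             "substrate", "product")), path, progress = FALSE)
  path
}

# diamond: a -> b (via hub metabolite "atp" on the short branch, 2 reactions)
# and a -> b via low-degree intermediates (2 reactions); the hub's degree is
# inflated by pendant reactions so degree weighting routes around it
toy_diamond_edges <- function() {
  tibble::tibble(
    from = c("a", "r1", "atp", "r2",
             "a", "r3", "m1", "r4",
             # pendant reactions inflating atp's degree (12 nodes total)
             "atp", "r5", "atp", "r6"),
    to = c("r1", "atp", "r2", "b",
           "r3", "m1", "r4", "b",
           "r5", "x5", "r6", "x6"),
    role = c("substrate", "product", "substrate", "product",
             "substrate", "product", "substrate", "product",
             "substrate", "product", "substrate", "product"))
}

toy_diamond_tsv <- function(path) {
  e <- toy_diamond_edges()
  readr::write_tsv(tibble::tibble(source = e$from, target = e$to,
                                  type = e$role), path, progress = FALSE)
  path
}

edges_node_types <- function(edges) {
  met <- unique(c(edges$from[edges$role == "substrate"],
                  edges$to[edges$role == "product"]))
  all <- unique(c(edges$from, edges$to))
  setNames(ifelse(all %in% met, "metabolite", "reaction"), all)
}
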