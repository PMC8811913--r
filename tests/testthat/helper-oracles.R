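# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (lm() per pair, eigen() by hand, elementwise loops)
# so they share no code with the implementation they check.

# Exhaustive pairwise regression: one lm() per compound-gene combination.
oracle_pair_screen <- function(C, G, slope_window = c(0.95, 1.05),
                               alpha = 0.05) {
  out <- list()
  for (ci in rownames(C)) for (gi in rownames(G)) {
    x <- G[gi, ]; y <- C[ci, ]
    if (stats::sd(x) == 0) next
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    slope <- sm["x", "Estimate"]
    p <- sm["x", "Pr(>|t|)"]
    if (is.nan(p)) p <- 0
    out[[length(out) + 1L]] <- data.frame(
      compound_id = ci, gene_id = gi, slope = slope,
      intercept = sm["(Intercept)", "Estimate"], p_value = p,
      retained = abs(slope) >= slope_window[1] &
        abs(slope) <= slope_window[2] & p < alpha)
  }
  do.call(rbind, out)
}

# Eigen-decomposition PCA oracle on a row-observation matrix.
oracle_pca_variance <- function(z) {
  ev <- eigen(stats::cov(z), symmetric = TRUE)$values
  pmax(ev, 0) / sum(pmax(ev, 0))
}

# Small omics matrices for filter/screen unit tests.
make_lfc <- function(values, days, kind = "transcript", fdr = NULL) {
  omics_matrix(values, days, kind = kind, log2fc = TRUE, fdr = fdr)
}

ari <- function(a, b) mclust::adjustedRandIndex(as.character(a),
                                                as.character(b))

# One simulated default trajectory shared across tests (deterministic).
default_traj <- local({
  traj <- NULL
  function() {
    if (is.null(traj)) traj <<- simulate_turbidostat(turbidostat_config())
    traj
  }
})
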