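# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the AUC oracle enumerates all event/non-event
# pairs, and the logistic MLE oracle is an iteratively refined dense grid
# search, not IRLS.

# Exhaustive all-pairs concordance, ties counted one half.
oracle_auc <- function(y, p) {
  pe <- p[y == 1]
  pn <- p[y == 0]
  total <- 0
  for (a in pe) {
    total <- total + sum(a > pn) + 0.5 * sum(a == pn)
  }
  total / (length(pe) * length(pn))
}

oracle_bernoulli_ll <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Dense grid search for the two-parameter logistic recalibration MLE
# (alpha, beta) of P(y=1) = plogis(alpha + beta * S): a 41x41 grid,
# zoomed five times around the running optimum.
oracle_grid_mle <- function(y, S, a_range = c(-6, 6), b_range = c(-6, 6)) {
  best <- c(mean(a_range), mean(b_range))
  wa <- diff(a_range) / 2
  wb <- diff(b_range) / 2
  for (it in 1:6) {
    as <- seq(best[1] - wa, best[1] + wa, length.out = 41)
    bs <- seq(best[2] - wb, best[2] + wb, length.out = 41)
    ll <- outer(as, bs, Vectorize(function(a, b) {
      oracle_bernoulli_ll(y, stats::plogis(a + b * S))
    }))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(as[idx[1]], bs[idx[2]])
    wa <- wa / 8
    wb <- wb / 8
  }
  c(alpha = best[1], beta = best[2])
}

# Grid search for the best constant predicted probability.
oracle_best_constant_p <- function(y, grid = seq(0.005, 0.995, by = 0.0005)) {
  ll <- vapply(grid, function(p) oracle_bernoulli_ll(y, rep(p, length(y))),
               numeric(1))
  grid[which.max(ll)]
}

# A minimal valid cohort frame around given predictor values.
toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    dmean_oral_cavity = runif(n, 5, 70),
    dmean_pcm_superior = runif(n, 5, 75),
    dmean_pcm_medium = runif(n, 5, 75),
    dmean_pcm_inferior = runif(n, 5, 75),
    tumour_location = rbinom(n, 1, 0.68),
    baseline_dysphagia = rbinom(n, 1, 0.15),
    modality = sample(c("photon", "photon_chemo", "proton"), n, TRUE),
    outcome = rbinom(n, 1, 0.4)
  )
}

# Average Table-1 predictor rows used in hand-evaluated examples.
avg_photon_patient <- function() {
  data.frame(dmean_oral_cavity = 33.2, dmean_pcm_superior = 55.5,
             dmean_pcm_medium = 50.2, dmean_pcm_inferior = 38.2,
             tumour_location = 1, baseline_dysphagia = 0)
}

avg_proton_patient <- function() {
  data.frame(dmean_oral_cavity = 24.1, dmean_pcm_superior = 35.1,
             dmean_pcm_medium = 41.2, dmean_pcm_inferior = 37.5,
             tumour_location = 1, baseline_dysphagia = 0)
}
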