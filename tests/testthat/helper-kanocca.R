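# shared fixtures built in code

# published per-attribute summary rows of the vaccine-messaging case study
study_rows <- function() vaccine_messaging_results()

# tally from a percentage row (percentages used as counts, n = row sum)
row_tally <- function(row) {
  kano_tally(c(
    A = row$A, O = row$O, M = row$M, I = row$I, R = row$R, Q = row$Q
  ))
}

# the subset of printed rows whose percentages sum to exactly 100 and can
# therefore be reconstructed as exact 100-respondent fixtures
exact_fixture_rows <- function() {
  rows <- study_rows()[, c("attribute_id", "A", "O", "M", "I", "R", "Q")]
  rows[rowSums(rows[, -1]) == 100, ]
}

# a quick, well-behaved GCM fit for tests that need a fitted object
small_gcm_fit <- function(n = 60, m = 8, seed = 7, ...) {
  set.seed(seed)
  params <- gcm_params(
    theta = rbeta(n, 8, 4), # competent cohort
    g = rbeta(n, 3, 4),
    delta = runif(m, 0.15, 0.45),
    z = rep_len(c(1L, 0L, 1L, 1L, 0L), m)
  )
  data <- simulate_gcm(params)
  fit <- suppressWarnings(fit_gcm(
    data,
    chains = 2, samples = 1500, burnin = 500, thin = 5, seed = seed + 1, ...
  ))
  list(params = params, data = data, fit = fit)
}
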