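#' Posterior-predictive check of a GCM fit
#'
#' Draws parameter vectors from the fit's stored posterior samples,
#' simulates a replicate response matrix from each, and computes the
#' first-to-second eigenvalue ratio of the respondent correlation matrix
#' (the same statistic the scree analysis uses). If the one-culture model
#' fits, the observed ratio should sit comfortably inside the replicate
#' distribution; data generated by several distinct answer keys push the
#' observed ratio into a tail.
#'
#' @param fit A [fit_gcm()] result (with stored draws).
#' @param data The observed binary matrix the model was fitted to.
#' @param n_replicates Number of posterior-predictive replicates
#'   (default 200).
#' @param seed Integer seed.
#' @return An object of class `gcm_ppc` with the observed statistic, the
#'   replicate statistics, and the observed value's posterior-predictive
#'   percentile.
#' @export
posterior_predictive_check <- function(fit, data, n_replicates = 200, seed = 1) {
  stopifnot(inherits(fit, "gcm_fit"))
  if (n_replicates < 1) stop("`n_replicates` must be positive", call. = FALSE)
  data <- as.matrix(data)
  if (nrow(data) < 3) stop("need at least 3 respondents", call. = FALSE)

  stat <- function(X) {
    keep <- apply(X, 1, function(r) var(r) > 0)
    if (sum(keep) < 3) {
      return(NA_real_)
    }
    R <- cor(t(X[keep, , drop = FALSE]))
    R[is.na(R)] <- 0
    ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
      decreasing = TRUE
    )
    ev[1] / max(ev[2], .Machine$double.eps)
  }

  observed <- stat(data)
  set.seed(seed)
  chains <- length(fit$draws)
  nstore <- nrow(fit$draws[[1]]$theta_draws)
  reps <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    ch <- sample.int(chains, 1)
    it <- sample.int(nstore, 1)
    d <- fit$draws[[ch]]
    p <- gcm_params(
      theta = d$theta_draws[it, ], g = d$g_draws[it, ],
      delta = d$delta_draws[it, ], z = d$z_draws[it, ]
    )
    reps[r] <- stat(simulate_gcm(p))
  }
  reps <- reps[!is.na(reps)]
  percentile <- mean(reps <= observed)
  structure(
    list(
      observed = observed, replicates = reps, percentile = percentile,
      n_replicates = n_replicates
    ),
    class = "gcm_ppc"
  )
}

#' @export
print.gcm_ppc <- function(x, ...) {
  cat(sprintf(
    "<gcm_ppc> observed eigenvalue ratio %.2f at posterior-predictive percentile %.1f%% (%d replicates)\n",
    x$observed, 100 * x$percentile, length(x$replicates)
  ))
  invisible(x)
}
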