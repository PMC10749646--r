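# Split-Rhat (potential scale reduction) for a draws array organised as a
# list of iteration x parameter matrices, one per chain. Each chain is split
# in half, giving 2 * chains sequences per parameter.
.split_rhat <- function(chain_mats) {
  nit <- nrow(chain_mats[[1]])
  half <- nit %/% 2
  halves <- list()
  for (cm in chain_mats) {
    halves[[length(halves) + 1]] <- cm[seq_len(half), , drop = FALSE]
    halves[[length(halves) + 1]] <- cm[seq_len(half) + (nit - half), , drop = FALSE]
  }
  m <- length(halves)
  n <- half
  means <- sapply(halves, colMeans) # params x m
  vars <- sapply(halves, function(h) apply(h, 2, var))
  if (is.null(dim(means))) { # single parameter
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  B <- n * apply(means, 1, var)
  W <- rowMeans(vars)
  vhat <- (n - 1) / n * W + B / n
  out <- sqrt(vhat / W)
  out[W < .Machine$double.eps] <- 1 # constant chains: treat as converged
  out
}

#' Fit the General Condorcet Model by MCMC
#'
#' Gibbs-within-Metropolis sampler: exact Gibbs updates for the latent item
#' truths, adaptive random-walk Metropolis (target acceptance ~0.44,
#' adaptation during burn-in only) for the continuous parameters. By
#' default respondent competencies and guessing biases get hierarchical
#' Beta priors, `theta[i] ~ Beta(mu*kappa, (1-mu)*kappa)` with flat
#' hyperpriors (`mu` uniform on (0,1), `kappa` uniform on (2, 200)); with
#' only a handful of items per respondent this partial pooling is what
#' keeps cohort-level summaries (mean competency, mean bias) identified —
#' independent flat priors pull every poorly-informed respondent toward
#' 0.5. Set `prior = "uniform"` for independent uniform priors instead.
#' Item difficulties always carry uniform priors and truths a
#' Bernoulli(0.5) prior.
#'
#' @param data Integer 0/1 matrix, respondents in rows, items in columns
#'   (at least 2 of each). Non-binary input is an error; constant rows or
#'   columns trigger a warning but the fit proceeds.
#' @param chains Number of chains (default 3).
#' @param samples Post-burn-in iterations per chain (default 10000).
#' @param burnin Burn-in iterations per chain (default 2000).
#' @param thin Storage thinning for diagnostic draws (posterior means use
#'   every post-burn-in iteration regardless).
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param prior `"hierarchical"` (default) or `"uniform"` priors for
#'   competencies and guessing biases.
#' @return An object of class `gcm_fit` with elements
#'   \describe{
#'     \item{item_truth}{posterior mean of each item's truth bit}
#'     \item{binary_truth}{`as.integer(item_truth > 0.5)`}
#'     \item{delta_mean}{posterior-mean item difficulties}
#'     \item{theta, g}{per-respondent posterior means}
#'     \item{theta_mean, theta_sd, g_mean, g_sd}{cohort summaries: mean and
#'       sd across respondents of the per-respondent posterior means}
#'     \item{rhat}{split-Rhat for every continuous parameter}
#'     \item{draws}{thinned per-chain draws (used for diagnostics and
#'       posterior-predictive checks)}
#'     \item{settings}{chains/samples/burnin/thin/seed/prior echo}
#'   }
#' @export
fit_gcm <- function(data, chains = 3, samples = 10000, burnin = 2000,
                    thin = 10, seed = 1,
                    prior = c("hierarchical", "uniform")) {
  prior <- match.arg(prior)
  data <- as.matrix(data)
  if (!all(data %in% c(0L, 1L))) {
    stop("`data` must be a binary 0/1 matrix with no missing cells", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  n <- nrow(data)
  m <- ncol(data)
  if (n < 2 || m < 2) stop("need at least 2 respondents and 2 items", call. = FALSE)
  if (samples < thin) stop("`samples` must be at least `thin`", call. = FALSE)
  const_rows <- sum(apply(data, 1, function(r) length(unique(r)) == 1))
  const_cols <- sum(apply(data, 2, function(r) length(unique(r)) == 1))
  if (const_rows > 0 || const_cols > 0) {
    warning(
      const_rows, " constant row(s) and ", const_cols,
      " constant column(s) in the data; fit proceeds",
      call. = FALSE
    )
  }

  set.seed(seed)
  chain_seeds <- sample.int(2147483646L, chains)
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    runs[[ch]] <- .gcm_chain_cpp(
      data, samples, burnin, thin,
      prior == "hierarchical", 200
    )
  }

  avg <- function(field) Reduce(`+`, lapply(runs, `[[`, field)) / chains
  theta_post <- setNames(avg("theta_mean"), rownames(data))
  g_post <- setNames(avg("g_mean"), rownames(data))
  delta_post <- setNames(avg("delta_mean"), colnames(data))
  item_truth <- setNames(avg("z_mean"), colnames(data))

  cont_draws <- lapply(runs, function(r) {
    d <- cbind(r$theta_draws, r$g_draws, r$delta_draws)
    if (prior == "hierarchical") d <- cbind(d, r$hyper_draws)
    d
  })
  par_names <- c(
    paste0("theta[", seq_len(n), "]"),
    paste0("g[", seq_len(n), "]"),
    paste0("delta[", seq_len(m), "]"),
    if (prior == "hierarchical") c("mu_theta", "kappa_theta", "mu_g", "kappa_g")
  )
  rhat <- setNames(.split_rhat(cont_draws), par_names)

  structure(
    list(
      item_truth = item_truth,
      binary_truth = setNames(as.integer(item_truth > 0.5), colnames(data)),
      delta_mean = delta_post,
      theta = theta_post, g = g_post,
      theta_mean = mean(theta_post), theta_sd = sd(theta_post),
      g_mean = mean(g_post), g_sd = sd(g_post),
      rhat = rhat,
      accept_theta = mean(vapply(runs, `[[`, numeric(1), "accept_theta")),
      draws = lapply(runs, function(r) {
        r[c("theta_draws", "g_draws", "delta_draws", "z_draws", "hyper_draws")]
      }),
      dim = c(n = n, m = m),
      settings = list(
        chains = chains, samples = samples, burnin = burnin, thin = thin,
        seed = seed, chain_seeds = chain_seeds, prior = prior
      )
    ),
    class = "gcm_fit"
  )
}

#' @export
print.gcm_fit <- function(x, ...) {
  cat(
    "<gcm_fit>", x$dim["n"], "respondents x", x$dim["m"], "items;",
    x$settings$chains, "chains x", x$settings$samples, "samples (burnin",
    paste0(x$settings$burnin, ")"), "\n"
  )
  cat(sprintf(
    "  competency: mean %.3f (sd %.3f); guessing bias: mean %.3f (sd %.3f)\n",
    x$theta_mean, x$theta_sd, x$g_mean, x$g_sd
  ))
  cat(sprintf("  max split-Rhat: %.3f\n", max(x$rhat)))
  cat("  item truth:", paste(sprintf("%.2f", x$item_truth), collapse = " "), "\n")
  invisible(x)
}

#' Posterior summary table of a GCM fit
#'
#' @param object A [fit_gcm()] result.
#' @param ... Unused.
#' @return A tibble with one row per item: `item`, `item_truth`,
#'   `binary_truth`, `difficulty`.
#' @export
summary.gcm_fit <- function(object, ...) {
  tibble::tibble(
    item = names(object$item_truth),
    item_truth = unname(object$item_truth),
    binary_truth = unname(object$binary_truth),
    difficulty = unname(object$delta_mean)
  )
}
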