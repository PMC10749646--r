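test_that("fit_gcm validates input", {
  expect_error(fit_gcm(matrix(c(0, 2, 1, 0), 2)), "binary")
  expect_error(fit_gcm(matrix(0:1, 2, 1)), "at least 2")
  X <- rbind(c(1, 1, 1), c(0, 1, 0), c(1, 0, 1))
  expect_warning(
    fit_gcm(X, chains = 1, samples = 50, burnin = 20, thin = 5),
    "constant"
  )
})

test_that("noiseless data concentrates the truth posterior on the generating key", {
  set.seed(21)
  z <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  p <- gcm_params(
    theta = rep(1, 40), g = runif(40), delta = rep(0.5, 8), z = z
  )
  X <- simulate_gcm(p)
  fit <- suppressWarnings(
    fit_gcm(X, chains = 2, samples = 1000, burnin = 400, thin = 5, seed = 2)
  )
  expect_identical(unname(fit$binary_truth), z)
  expect_true(all(abs(fit$item_truth - z) < 0.05))
})

test_that("full-length chains converge on well-identified data", {
  set.seed(17)
  m <- 16
  params <- gcm_params(
    theta = rbeta(60, 8, 4), g = rbeta(60, 3, 4),
    delta = runif(m, 0.1, 0.4), z = rep_len(c(1L, 0L), m)
  )
  data <- simulate_gcm(params)
  fit <- suppressWarnings(fit_gcm(
    data,
    chains = 3, samples = 10000, burnin = 2000, thin = 10, seed = 18
  ))
  expect_true(all(fit$rhat < 1.1))
  expect_identical(unname(fit$binary_truth), params$z)
  # the answer key is sharply identified even where cohort-level
  # competency/bias locations are not (see the methods vignette)
  expect_true(all(abs(fit$item_truth - params$z) < 0.2))
})

test_that("the fit is reproducible under a fixed master seed", {
  set.seed(31)
  p <- gcm_params(rbeta(25, 4, 3), rbeta(25, 3, 3), runif(6, 0.2, 0.5),
    z = c(1L, 0L, 1L, 0L, 1L, 1L)
  )
  X <- simulate_gcm(p)
  f1 <- fit_gcm(X, chains = 2, samples = 400, burnin = 200, thin = 4, seed = 9)
  f2 <- fit_gcm(X, chains = 2, samples = 400, burnin = 200, thin = 4, seed = 9)
  expect_identical(f1$item_truth, f2$item_truth)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$rhat, f2$rhat)
})

test_that("posterior agrees with an independent JAGS implementation of the model", {
  skip_if_not_installed("rjags")
  set.seed(13)
  p <- gcm_params(
    theta = rbeta(50, 6, 4), g = rbeta(50, 3, 4),
    delta = runif(12, 0.15, 0.45), z = rep_len(c(1L, 0L), 12)
  )
  Y <- simulate_gcm(p)
  fit <- suppressWarnings(
    fit_gcm(Y, chains = 3, samples = 8000, burnin = 2000, thin = 10, seed = 5)
  )

  model <- "
  model {
    for (i in 1:n) {
      theta[i] ~ dbeta(mu_t*kap_t, (1-mu_t)*kap_t)
      g[i] ~ dbeta(mu_g*kap_g, (1-mu_g)*kap_g)
      for (k in 1:m) {
        D[i,k] <- theta[i]*(1-delta[k]) /
                  (theta[i]*(1-delta[k]) + delta[k]*(1-theta[i]))
        pr[i,k] <- z[k]*(D[i,k] + (1-D[i,k])*g[i]) + (1-z[k])*(1-D[i,k])*g[i]
        Y[i,k] ~ dbern(pr[i,k])
      }
    }
    for (k in 1:m) {
      delta[k] ~ dunif(0.001, 0.999)
      z[k] ~ dbern(0.5)
    }
    mu_t ~ dunif(0.001, 0.999); kap_t ~ dunif(2, 200)
    mu_g ~ dunif(0.001, 0.999); kap_g ~ dunif(2, 200)
  }"
  # pin the oracle's chain RNGs: the cohort-level estimates lie along a
  # weakly identified ridge, so an unseeded oracle run has sizeable
  # Monte-Carlo spread of its own
  inits <- lapply(1:3, function(c) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 100 + c)
  })
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(Y = Y, n = nrow(Y), m = ncol(Y)),
    inits = inits, n.chains = 3, n.adapt = 1000, quiet = TRUE
  )
  update(jm, 3000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("theta", "g", "z"),
    n.iter = 12000, thin = 12, progress.bar = "none"
  )
  sm <- summary(s)$statistics
  j_theta <- mean(sm[grep("^theta", rownames(sm)), "Mean"])
  j_g <- mean(sm[grep("^g\\[", rownames(sm)), "Mean"])
  j_z <- sm[grep("^z", rownames(sm)), "Mean"]

  expect_equal(fit$theta_mean, j_theta, tolerance = 0.04)
  expect_equal(fit$g_mean, j_g, tolerance = 0.05)
  expect_true(all(abs(fit$item_truth - j_z) < 0.1))
})

test_that("posterior summary table has one row per item", {
  h <- small_gcm_fit(seed = 17)
  tab <- summary(h$fit)
  expect_identical(nrow(tab), ncol(h$data))
  expect_true(all(tab$item_truth >= 0 & tab$item_truth <= 1))
  expect_identical(tab$binary_truth, as.integer(tab$item_truth > 0.5))
})
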