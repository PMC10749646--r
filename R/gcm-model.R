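#' Construct General Condorcet Model parameters
#'
#' The General Condorcet Model (GCM) describes binary "is this item
#' relevant?" answers of respondents who share one latent answer key. Each
#' respondent i has a competency `theta[i]` (probability of knowing the
#' culturally true answer) and a guessing bias `g[i]` (probability of
#' answering 1 when not knowing); each item k has a difficulty `delta[k]`
#' and a latent truth bit `z[k]`.
#'
#' @param theta Numeric vector of respondent competencies in \[0, 1\].
#' @param g Numeric vector of respondent guessing biases in \[0, 1\]
#'   (recycled to `length(theta)`).
#' @param delta Numeric vector of item difficulties in \[0, 1\].
#' @param z Integer vector of latent truth bits in \{0, 1\} (length
#'   `length(delta)`).
#' @return An object of class `gcm_params`.
#' @export
gcm_params <- function(theta, g, delta, z) {
  g <- rep_len(g, length(theta))
  chk <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  chk(theta, "theta")
  chk(g, "g")
  chk(delta, "delta")
  if (length(z) != length(delta)) {
    stop("`z` and `delta` must have the same length", call. = FALSE)
  }
  if (!all(z %in% c(0, 1))) stop("`z` must be 0/1", call. = FALSE)
  if (length(theta) < 1 || length(delta) < 1) {
    stop("need at least one respondent and one item", call. = FALSE)
  }
  structure(
    list(theta = as.numeric(theta), g = as.numeric(g),
         delta = as.numeric(delta), z = as.integer(z)),
    class = "gcm_params"
  )
}

#' @export
print.gcm_params <- function(x, ...) {
  cat(
    "<gcm_params>", length(x$theta), "respondents x", length(x$delta),
    "items; mean theta =", round(mean(x$theta), 3),
    "mean g =", round(mean(x$g), 3), "\n"
  )
  invisible(x)
}

#' GCM response probability
#'
#' The competency/difficulty composition yields the effective accuracy
#' `D = theta*(1-delta) / (theta*(1-delta) + delta*(1-theta))` (a
#' Rasch-type contest between ability and difficulty; the degenerate 0/0
#' case is defined as D = 0.5). A respondent answers 1 with probability
#' `D + (1-D)*g` when the item's truth is 1, and `(1-D)*g` when it is 0:
#' with probability D the truth is reproduced, otherwise the respondent
#' guesses 1 with probability g.
#'
#' @param theta,g,delta Probabilities in \[0, 1\] (vectors recycled).
#' @param z Truth bit(s) in \{0, 1\}.
#' @return Probability vector of answering 1.
#' @export
#' @examples
#' gcm_response_probability(1, 0.9, 0.5, 1) # perfect competency -> 1
#' gcm_response_probability(0, 0.3, 0.5, 0) # pure guessing -> 0.3
gcm_response_probability <- function(theta, g, delta, z) {
  n <- max(length(theta), length(g), length(delta), length(z))
  theta <- rep_len(as.numeric(theta), n)
  g <- rep_len(as.numeric(g), n)
  delta <- rep_len(as.numeric(delta), n)
  z <- rep_len(z, n)
  if (any(theta < 0 | theta > 1 | g < 0 | g > 1 | delta < 0 | delta > 1)) {
    stop("theta, g and delta must lie in [0, 1]", call. = FALSE)
  }
  if (!all(z %in% c(0, 1))) stop("`z` must be 0/1", call. = FALSE)
  num <- theta * (1 - delta)
  den <- num + delta * (1 - theta)
  D <- ifelse(den <= 0, 0.5, num / den)
  ifelse(z == 1, D + (1 - D) * g, (1 - D) * g)
}

#' Simulate a binary response matrix from the GCM
#'
#' Independent Bernoulli draws per respondent-item cell from
#' [gcm_response_probability()].
#'
#' @param params A [gcm_params()].
#' @param seed Optional integer seed (set via [set.seed()]); when `NULL`
#'   the current RNG state is used.
#' @return Integer 0/1 matrix, respondents in rows, items in columns.
#' @export
simulate_gcm <- function(params, seed = NULL) {
  stopifnot(inherits(params, "gcm_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(params$theta)
  m <- length(params$delta)
  P <- matrix(0, n, m)
  for (k in seq_len(m)) {
    P[, k] <- gcm_response_probability(
      params$theta, params$g, params$delta[k], params$z[k]
    )
  }
  matrix(rbinom(n * m, 1L, P), n, m,
    dimnames = list(
      sprintf("r%03d", seq_len(n)),
      sprintf("item%02d", seq_len(m))
    )
  )
}
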