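#' Eigenvalue scree analysis of a binary response matrix
#'
#' Classic consensus-analysis check for a single shared answer key:
#' respondents with zero variance across items are omitted (their Pearson
#' correlation is undefined), the respondent-respondent Pearson
#' correlation matrix is computed across items, and its eigenvalue
#' spectrum examined. A dominant first eigenvalue — first-to-second ratio
#' at or above `ratio_threshold` — indicates one consensus group;
#' otherwise the data are flagged as containing two or more groups (the
#' method detects multiplicity, it does not count groups beyond "more
#' than one").
#'
#' A dominant first eigenvalue alone is not sufficient: two groups with
#' strongly *opposed* answer keys are mutually anti-correlated, which also
#' produces one dominant (bipolar) eigenvalue. The one-group verdict
#' therefore additionally requires the first-eigenvector loadings to share
#' one sign — the classical companion check. Loadings of magnitude at most
#' 0.1 are treated as negligible, and a bipolar split is declared when at
#' least 5% of respondents (and no fewer than 2) load in each direction.
#'
#' Note that with many more respondents than items the correlation matrix
#' is rank-deficient and its trailing eigenvalues are exactly zero while
#' the leading "noise" eigenvalues are inflated, which deflates the ratio;
#' see the package vignette for how to read the threshold in that regime.
#'
#' @param data Integer 0/1 matrix, respondents in rows.
#' @param ratio_threshold Minimal first/second eigenvalue ratio for a
#'   one-group verdict (default 3, the classical rule of thumb).
#' @return An object of class `scree_result` with elements `eigenvalues`
#'   (descending, clamped at 0), `n_omitted`, `ratio_first_second`,
#'   `n_cultures` (1, or 2 meaning ">= 2") and `ratio_threshold`.
#' @export
scree_analysis <- function(data, ratio_threshold = 3) {
  data <- as.matrix(data)
  if (!all(data[!is.na(data)] %in% c(0, 1))) {
    stop("`data` must be a binary 0/1 matrix", call. = FALSE)
  }
  keep <- apply(data, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) >= 2 && var(r) > 0
  })
  n_omitted <- sum(!keep)
  if (all(!keep)) {
    stop("all respondents have zero variance; no correlation matrix exists",
      call. = FALSE
    )
  }
  X <- data[keep, , drop = FALSE]
  if (nrow(X) < 3) {
    stop("need at least 3 respondents with nonzero variance", call. = FALSE)
  }
  R <- cor(t(X), use = "pairwise.complete.obs")
  R[is.na(R)] <- 0
  dec <- eigen(R, symmetric = TRUE)
  ev <- pmax(dec$values, 0) # symmetric eigen() already sorts descending
  ratio <- ev[1] / ev[2]

  loadings <- sqrt(ev[1]) * dec$vectors[, 1]
  if (sum(loadings) < 0) loadings <- -loadings # orient majority positive
  min_side <- max(2, ceiling(0.05 * nrow(X)))
  bipolar <- sum(loadings > 0.1) >= min_side && sum(loadings < -0.1) >= min_side

  structure(
    list(
      eigenvalues = ev,
      n_omitted = n_omitted,
      ratio_first_second = ratio,
      loadings = setNames(loadings, rownames(X)),
      bipolar = bipolar,
      n_cultures = if (ratio >= ratio_threshold && !bipolar) 1L else 2L,
      ratio_threshold = ratio_threshold
    ),
    class = "scree_result"
  )
}

#' @export
print.scree_result <- function(x, ...) {
  cat(
    "<scree_result>", length(x$eigenvalues), "eigenvalues;",
    x$n_omitted, "zero-variance respondent(s) omitted\n"
  )
  cat(sprintf(
    "  lambda1/lambda2 = %.2f (threshold %.2f)%s -> %s consensus group(s)\n",
    x$ratio_first_second, x$ratio_threshold,
    if (x$bipolar) ", bipolar first factor" else "",
    if (x$n_cultures == 1) "1" else ">= 2"
  ))
  invisible(x)
}
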