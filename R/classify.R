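# Priority-ordered argmax over a subset of categories. Returns the winning
# symbol plus whether more than one category attained the maximum.
.prio_max <- function(counts, subset) {
  x <- counts[subset] # subset given in priority order
  win <- names(x)[which.max(x)] # which.max takes the first maximum
  list(category = win, tie = sum(x == max(x)) > 1)
}

.with_tie <- function(category, tie) {
  structure(category, tie = tie)
}

#' Did a classification involve a tie?
#'
#' The classification rules return the winning category with a `tie`
#' attribute recording whether any step of the rule was a tie (broken by
#' the fixed priority M > O > A > I > R > Q, or by the else-branch of a
#' pooled comparison). Fragile classifications can thereby be surfaced in
#' reports instead of silently resolved.
#'
#' @param classification Return value of [classify_original()],
#'   [classify_revised()] or [classify_cca()].
#' @return Logical scalar.
#' @export
classification_tie <- function(classification) {
  isTRUE(attr(classification, "tie"))
}

#' Original (modal) Kano classification
#'
#' The attribute is labelled with the most frequent individual category.
#' Ties on the maximal count are broken by the fixed priority
#' M > O > A > I > R > Q and flagged (see [classification_tie()]).
#'
#' @param tally A [kano_tally()].
#' @return Length-1 character category with a `tie` attribute.
#' @export
#' @examples
#' classify_original(kano_tally(c(A = 10, O = 57, M = 22, I = 11)))
classify_original <- function(tally) {
  stopifnot(is_kano_tally(tally))
  r <- .prio_max(tally$counts, kano_categories())
  .with_tie(r$category, r$tie)
}

#' Revised (Blauth) Kano classification
#'
#' Pools the high-relevancy categories (M, O, A) against the low-relevancy
#' ones (I, R, Q): if (M+O+A) > (I+R+Q), the grade is the largest of M, O,
#' A, otherwise the largest of I, R, Q. The comparison is strict, so an
#' exact 50/50 split falls to the low-relevancy branch and raises the tie
#' flag (as do ties within the winning pool).
#'
#' @param tally A [kano_tally()].
#' @return Length-1 character category with a `tie` attribute.
#' @export
classify_revised <- function(tally) {
  stopifnot(is_kano_tally(tally))
  cnt <- tally$counts
  high <- sum(cnt[c("M", "O", "A")])
  low <- sum(cnt[c("I", "R", "Q")])
  r <- if (high > low) {
    .prio_max(cnt, c("M", "O", "A"))
  } else {
    .prio_max(cnt, c("I", "R", "Q"))
  }
  .with_tie(r$category, r$tie || high == low)
}

#' Consensus-based (CCA) Kano classification
#'
#' Uses the posterior item truth of the consensus model: if the item truth
#' exceeds 0.5 the attribute is culturally relevant and graded as the
#' largest of M, O, A; otherwise as the largest of I, R, Q. The comparison
#' is strict, so item truth exactly 0.5 takes the low-relevancy branch and
#' raises the tie flag.
#'
#' @param tally A [kano_tally()].
#' @param item_truth Posterior probability in \[0, 1\] that the attribute's
#'   culturally true answer is "relevant" (e.g. from [fit_gcm()]).
#' @return Length-1 character category with a `tie` attribute.
#' @export
classify_cca <- function(tally, item_truth) {
  stopifnot(is_kano_tally(tally))
  if (!is.numeric(item_truth) || length(item_truth) != 1 ||
    is.na(item_truth) || item_truth < 0 || item_truth > 1) {
    stop("`item_truth` must be a single probability in [0, 1]", call. = FALSE)
  }
  cnt <- tally$counts
  r <- if (item_truth > 0.5) {
    .prio_max(cnt, c("M", "O", "A"))
  } else {
    .prio_max(cnt, c("I", "R", "Q"))
  }
  .with_tie(r$category, r$tie || item_truth == 0.5)
}

#' Dichotomize Kano categories into relevance bits
#'
#' Two schemes are used in consensus analyses of Kano data:
#' `"relevance"` maps M, O, A to 1 and I, R, Q to 0; the
#' `"relevance_with_reverse"` variant additionally counts reverse
#' classifications as relevant (M, O, A, R to 1; I, Q to 0), to avoid
#' underestimating respondents for whom an attribute matters negatively.
#'
#' @param category Character vector of category symbols (`NA` propagates).
#' @param scheme `"relevance"` (default) or `"relevance_with_reverse"`.
#' @return Integer vector of 0/1 bits.
#' @export
#' @examples
#' dichotomize(c("M", "R", "Q"), "relevance") # 1 0 0
#' dichotomize(c("M", "R", "Q"), "relevance_with_reverse") # 1 1 0
dichotomize <- function(category, scheme = c("relevance", "relevance_with_reverse")) {
  scheme <- match.arg(scheme)
  bad <- setdiff(unique(category[!is.na(category)]), kano_categories())
  if (length(bad) > 0) {
    stop("unknown Kano categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  high <- if (scheme == "relevance") c("M", "O", "A") else c("M", "O", "A", "R")
  out <- ifelse(is.na(category), NA_integer_, as.integer(category %in% high))
  out
}

#' Binary relevance matrix of a survey
#'
#' Applies [dichotomize()] to the per-respondent [category_matrix()].
#'
#' @param survey A [kano_survey()].
#' @inheritParams dichotomize
#' @return Integer matrix (respondents x analysis ids) of 0/1 bits, `NA`
#'   where the pair is missing.
#' @export
relevance_matrix <- function(survey, scheme = c("relevance", "relevance_with_reverse")) {
  scheme <- match.arg(scheme)
  cm <- category_matrix(survey)
  out <- matrix(dichotomize(as.vector(cm), scheme),
    nrow = nrow(cm), dimnames = dimnames(cm)
  )
  out
}

#' Classify every attribute under all three rules
#'
#' @param tallies Named list of [kano_tally()] objects (e.g. from
#'   [tally_all()]), or a [kano_survey()].
#' @param item_truth Optional named numeric vector of posterior item truths
#'   (names matching the tally names). When absent the `cca` column is
#'   `NA`.
#' @return A tibble with columns `attribute_id`, the six category
#'   percentages, `original`, `revised`, `cca` and `tie_flag` (TRUE when
#'   any applied rule hit a tie).
#' @export
classification_table <- function(tallies, item_truth = NULL) {
  if (inherits(tallies, "kano_survey")) tallies <- tally_all(tallies)
  stopifnot(length(tallies) > 0, all(vapply(tallies, is_kano_tally, logical(1))))
  ids <- names(tallies)
  rows <- lapply(ids, function(id) {
    tl <- tallies[[id]]
    orig <- classify_original(tl)
    rev <- classify_revised(tl)
    tie <- classification_tie(orig) || classification_tie(rev)
    cca <- NA_character_
    if (!is.null(item_truth) && id %in% names(item_truth)) {
      cc <- classify_cca(tl, unname(item_truth[[id]]))
      cca <- as.character(cc)
      tie <- tie || classification_tie(cc)
    }
    pct <- tally_percentages(tl)
    tibble::tibble(
      attribute_id = id, n = tl$n,
      A = pct[["A"]], O = pct[["O"]], M = pct[["M"]],
      I = pct[["I"]], R = pct[["R"]], Q = pct[["Q"]],
      original = as.character(orig), revised = as.character(rev), cca = cca,
      tie_flag = tie
    )
  })
  do.call(rbind, rows)
}
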