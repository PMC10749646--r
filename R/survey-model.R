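#' The five Kano response options
#'
#' Both the functional ("how would you feel if attribute X were present?")
#' and the dysfunctional ("... were not present?") question offer the same
#' five answers. Codes 1--5 follow the conventional ordering from
#' "I like it that way" (1) to "I dislike it that way" (5); survey CSV files
#' store the codes, not the labels.
#'
#' @return A tibble with columns `code` (integer 1--5) and `label`
#'   (`"Like"`, `"MustBe"`, `"Neutral"`, `"LiveWith"`, `"Dislike"`).
#' @export
#' @examples
#' response_options()
response_options <- function() {
  tibble::tibble(
    code = 1:5,
    label = c("Like", "MustBe", "Neutral", "LiveWith", "Dislike")
  )
}

#' The six Kano categories, in tie-break priority order
#'
#' Must-be (M), one-dimensional (O), attractive (A), indifferent (I),
#' reverse (R) and questionable (Q). The order returned here is also the
#' fixed priority used to break ties in the classification rules:
#' M > O > A > I > R > Q.
#'
#' @return Character vector of the six category symbols.
#' @export
kano_categories <- function() c("M", "O", "A", "I", "R", "Q")

# Pair-classification grid: rows = functional answer code, columns =
# dysfunctional answer code. E.g. functional "Like" (1) with dysfunctional
# "Dislike" (5) is one-dimensional.
.kano_grid <- matrix(
  c(
    "Q", "A", "A", "A", "O",
    "R", "I", "I", "I", "M",
    "R", "I", "I", "I", "M",
    "R", "I", "I", "I", "M",
    "R", "R", "R", "R", "Q"
  ),
  nrow = 5, byrow = TRUE,
  dimnames = list(functional = 1:5, dysfunctional = 1:5)
)

.check_codes <- function(x, what) {
  if (!all(x[!is.na(x)] %in% 1:5)) {
    bad <- unique(x[!is.na(x) & !(x %in% 1:5)])
    stop(sprintf(
      "%s answer codes must be integers in 1..5 (got: %s)",
      what, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  as.integer(x)
}

#' Classify one functional/dysfunctional answer pair
#'
#' Maps a pair of answer codes to one of the six Kano categories via the
#' standard 5x5 assignment grid. The mapping is total: every one of the 25
#' possible pairs has a category, with cell census
#' A = 3, O = 1, M = 3, I = 9, R = 7, Q = 2.
#'
#' @param functional,dysfunctional Integer answer codes in 1--5 (vectors are
#'   recycled to common length). `NA` propagates.
#' @return Character vector of category symbols (`"A"`, `"O"`, `"M"`, `"I"`,
#'   `"R"`, `"Q"`).
#' @export
#' @examples
#' classify_pair(1, 5) # Like if present, Dislike if absent -> one-dimensional
#' classify_pair(3, 3) # Neutral both ways -> indifferent
classify_pair <- function(functional, dysfunctional) {
  f <- .check_codes(functional, "functional")
  d <- .check_codes(dysfunctional, "dysfunctional")
  n <- max(length(f), length(d))
  f <- rep_len(f, n)
  d <- rep_len(d, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(f) & !is.na(d)
  out[ok] <- .kano_grid[cbind(f[ok], d[ok])]
  out
}

#' Swap functional and dysfunctional answers (reverse recoding)
#'
#' Attributes whose presence annoys most respondents (modal reverse
#' classification) are conventionally re-analysed as their own negation by
#' treating the functional question as dysfunctional and vice versa. The
#' operation is an involution: applying it twice restores the original pair.
#'
#' @inheritParams classify_pair
#' @return A tibble with swapped `functional` and `dysfunctional` columns.
#' @export
#' @examples
#' recode_reverse(5, 1) # becomes (1, 5): reverse pair turns one-dimensional
recode_reverse <- function(functional, dysfunctional) {
  f <- .check_codes(functional, "functional")
  d <- .check_codes(dysfunctional, "dysfunctional")
  tibble::tibble(functional = d, dysfunctional = f)
}

#' Construct a per-attribute category tally
#'
#' @param counts Either a character vector of category symbols (tallied), or
#'   a named nonnegative numeric vector of counts over (a subset of) the six
#'   categories. Counts are usually integers; percentage rows from published
#'   summary tables can be supplied as-is for fixture-style analyses.
#' @return An object of class `kano_tally`: a list with `counts` (named
#'   numeric vector over all six categories, in `kano_categories()` order)
#'   and `n` (their sum).
#' @export
#' @examples
#' kano_tally(c(A = 10, O = 57, M = 22, I = 11))
#' kano_tally(classify_pair(c(1, 1, 3), c(5, 5, 3)))
kano_tally <- function(counts) {
  cats <- kano_categories()
  if (is.character(counts)) {
    bad <- setdiff(unique(counts), cats)
    if (length(bad) > 0) {
      stop("unknown Kano categories: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    counts <- table(factor(counts, levels = cats))
    counts <- setNames(as.numeric(counts), cats)
  } else {
    if (is.null(names(counts)) || !all(names(counts) %in% cats)) {
      stop("`counts` must be named with Kano category symbols", call. = FALSE)
    }
    full <- setNames(numeric(6), cats)
    full[names(counts)] <- as.numeric(counts)
    counts <- full
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("a tally needs at least one response", call. = FALSE)
  structure(list(counts = counts, n = n), class = "kano_tally")
}

#' @export
print.kano_tally <- function(x, ...) {
  cat("<kano_tally> n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' @rdname kano_tally
#' @param x Object to test.
#' @export
is_kano_tally <- function(x) inherits(x, "kano_tally")

#' Percentages of a tally
#'
#' @param tally A [kano_tally()].
#' @return Named numeric vector of percentages (counts / n * 100).
#' @export
tally_percentages <- function(tally) {
  stopifnot(is_kano_tally(tally))
  100 * tally$counts / tally$n
}
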