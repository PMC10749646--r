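#' Timko better/worse importance coefficients
#'
#' The better coefficient (A+O)/(A+O+M+I) measures how much end-user
#' satisfaction rises when the attribute is provided; the worse coefficient
#' (O+M)/(A+O+M+I) how much satisfaction falls when it is not. Reverse and
#' questionable classifications enter neither numerator nor denominator.
#' Both coefficients lie in \[0, 1\]; the worse coefficient is reported as a
#' magnitude (without its conventional negative sign). When an attribute's
#' responses are entirely R/Q the coefficients are undefined and an error
#' is raised.
#'
#' @param tally A [kano_tally()].
#' @return Numeric scalar in \[0, 1\].
#' @export
#' @examples
#' better_coefficient(kano_tally(c(A = 10, O = 57, M = 22, I = 11))) # 0.67
#' worse_coefficient(kano_tally(c(A = 10, O = 57, M = 22, I = 11))) # 0.79
better_coefficient <- function(tally) {
  stopifnot(is_kano_tally(tally))
  cnt <- tally$counts
  den <- sum(cnt[c("A", "O", "M", "I")])
  if (den == 0) {
    stop("Timko coefficients undefined: all responses are R or Q", call. = FALSE)
  }
  unname(sum(cnt[c("A", "O")]) / den)
}

#' @rdname better_coefficient
#' @export
worse_coefficient <- function(tally) {
  stopifnot(is_kano_tally(tally))
  cnt <- tally$counts
  den <- sum(cnt[c("A", "O", "M", "I")])
  if (den == 0) {
    stop("Timko coefficients undefined: all responses are R or Q", call. = FALSE)
  }
  unname(sum(cnt[c("O", "M")]) / den)
}

#' Quadrant placement of a better/worse coordinate pair
#'
#' The coefficient plane is split at 0.5 on each axis: high better and high
#' worse is one-dimensional (top right), high better only attractive (top
#' left), high worse only must-be (bottom right), neither indifferent
#' (bottom left). Coordinates exactly at 0.5 fall to the lower/left side,
#' so boundary attributes are surfaced as indifferent/must-be rather than
#' silently promoted.
#'
#' @param better,worse Numeric vectors in \[0, 1\] (recycled).
#' @return Character vector with values `"attractive_topleft"`,
#'   `"one_dimensional_topright"`, `"must_be_bottomright"`,
#'   `"indifferent_bottomleft"`; `NA` in, `NA` out.
#' @export
quadrant_of <- function(better, worse) {
  n <- max(length(better), length(worse))
  b <- rep_len(as.numeric(better), n)
  w <- rep_len(as.numeric(worse), n)
  if (any(b < 0 | b > 1 | w < 0 | w > 1, na.rm = TRUE)) {
    stop("coefficients must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  ok <- !is.na(b) & !is.na(w)
  out[ok & b > 0.5 & w > 0.5] <- "one_dimensional_topright"
  out[ok & b > 0.5 & w <= 0.5] <- "attractive_topleft"
  out[ok & b <= 0.5 & w > 0.5] <- "must_be_bottomright"
  out[ok & b <= 0.5 & w <= 0.5] <- "indifferent_bottomleft"
  out
}

#' Coefficient table for a whole survey
#'
#' One [better_coefficient()]/[worse_coefficient()]/[quadrant_of()] row per
#' attribute — the plot data behind the usual satisfaction/dissatisfaction
#' scatter.
#'
#' @param x A [kano_survey()] or a named list of [kano_tally()] objects.
#' @param undefined `"error"` (default) aborts with the offending attribute
#'   id when a coefficient is undefined (all responses R/Q); `"na"` keeps
#'   the row with `NA` coefficients as an explicit undefined marker, with a
#'   warning.
#' @return A tibble with columns `attribute_id`, `better`, `worse`,
#'   `quadrant`.
#' @export
coefficient_table <- function(x, undefined = c("error", "na")) {
  undefined <- match.arg(undefined)
  tallies <- if (inherits(x, "kano_survey")) tally_all(x) else x
  if (length(tallies) == 0) {
    return(tibble::tibble(
      attribute_id = character(), better = numeric(),
      worse = numeric(), quadrant = character()
    ))
  }
  stopifnot(all(vapply(tallies, is_kano_tally, logical(1))))
  rows <- lapply(names(tallies), function(id) {
    tl <- tallies[[id]]
    b <- tryCatch(better_coefficient(tl), error = function(e) e)
    if (inherits(b, "error")) {
      if (undefined == "error") {
        stop("attribute ", id, ": ", conditionMessage(b), call. = FALSE)
      }
      warning("attribute ", id, ": ", conditionMessage(b), call. = FALSE)
      return(tibble::tibble(
        attribute_id = id, better = NA_real_, worse = NA_real_,
        quadrant = NA_character_
      ))
    }
    w <- worse_coefficient(tl)
    tibble::tibble(
      attribute_id = id, better = b, worse = w,
      quadrant = quadrant_of(b, w)
    )
  })
  do.call(rbind, rows)
}

#' Scatter plot of Timko coefficients
#'
#' Renders the coefficient plane (worse on the x axis, better on the y
#' axis, quadrants split at 0.5) with one labelled point per attribute.
#' Requires ggplot2.
#'
#' @param coefficients Output of [coefficient_table()] (or a report's
#'   `timko` element).
#' @return A ggplot object.
#' @export
plot_timko <- function(coefficients) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_timko() requires the ggplot2 package", call. = FALSE)
  }
  df <- coefficients[!is.na(coefficients$better), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = worse, y = better,
    label = attribute_id
  )) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Worse (dissatisfaction if absent)",
      y = "Better (satisfaction if present)"
    ) +
    ggplot2::theme_minimal()
}
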