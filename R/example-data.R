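#' Attribute manifest of the vaccine-messaging case study
#'
#' The package's worked example is a published Kano survey on quality
#' attributes of vaccine-confidence messaging, administered to 205
#' caregivers of under-five children in the Philippines. Fourteen
#' attributes were assessed, grouped into intervention characteristics
#' (A1--A6), distribution (B1--B6) and content (C1--C2). The privacy
#' attribute B4 ("watch the product alone") drew mostly reverse
#' classifications and is analysed as its negation (company while
#' watching, reported as B4R), hence its `reverse_recoded` flag.
#'
#' @return A tibble with columns `id`, `label`, `group`,
#'   `reverse_recoded`, usable as the `manifest` argument of
#'   [kano_survey()].
#' @seealso [vaccine_messaging_results()]
#' @export
vaccine_messaging_manifest <- function() {
  tibble::tibble(
    id = c(
      "A1", "A2", "A3", "A4", "A5", "A6",
      "B1", "B2", "B3", "B4", "B5", "B6",
      "C1", "C2"
    ),
    label = c(
      "video", "cartoon", "short duration", "text",
      "resource information", "key message summaries",
      "shareability", "trusted messenger", "health center location",
      "privacy", "national logo", "international logo",
      "fact-based", "story-based"
    ),
    group = rep(c("characteristics", "distribution", "content"), c(6, 6, 2)),
    reverse_recoded = c(rep(FALSE, 9), TRUE, rep(FALSE, 4))
  )
}

#' Published per-attribute results of the vaccine-messaging case study
#'
#' The per-attribute summary table of the same published study (see
#' [vaccine_messaging_manifest()]): the percentage of the 205 respondents
#' whose individual answer pair fell in each of the six Kano categories,
#' the attribute classification under the original (modal), revised
#' (Blauth) and consensus (CCA) rules, and the consensus-model estimates
#' (binary truth value, posterior item truth, item difficulty).
#'
#' Percentages are printed rounded to integers; some rows therefore sum to
#' 98--101 rather than 100. Only rows summing to exactly 100 can be turned
#' into exact respondent-level fixtures by [fixture_from_percentages()].
#'
#' @return A tibble with one row per analysed attribute (reverse-recoded
#'   attributes carry their `"R"` suffix, e.g. `B4R`) and columns
#'   `attribute_id`, `A`, `O`, `M`, `I`, `R`, `Q`, `original`, `revised`,
#'   `cca`, `binary_truth`, `item_truth`, `item_difficulty`.
#' @export
vaccine_messaging_results <- function() {
  tibble::tribble(
    ~attribute_id, ~A, ~O, ~M, ~I, ~R, ~Q, ~original, ~revised, ~cca,
    ~binary_truth, ~item_truth, ~item_difficulty,
    "A1", 31, 6, 4, 38, 11, 11, "I", "I", "I", 0L, 0.02, 0.74,
    "A2", 13, 1, 8, 42, 28, 8, "I", "I", "I", 0L, 0.00, 0.30,
    "A3", 6, 2, 12, 52, 22, 5, "I", "I", "I", 0L, 0.00, 0.24,
    "A4", 24, 20, 26, 25, 3, 0, "M", "M", "M", 1L, 1.00, 0.42,
    "A5", 29, 21, 18, 29, 1, 1, "A", "A", "A", 1L, 1.00, 0.48,
    "A6", 22, 23, 20, 33, 1, 1, "I", "O", "O", 1L, 1.00, 0.53,
    "B1", 27, 20, 17, 30, 5, 2, "I", "A", "A", 1L, 1.00, 0.59,
    "B2", 11, 12, 27, 36, 4, 10, "I", "M", "M", 1L, 0.69, 0.88,
    "B3", 29, 13, 9, 31, 2, 16, "I", "A", "I", 1L, 0.45, 0.88,
    "B4R", 23, 9, 7, 38, 10, 13, "I", "I", "I", 0L, 0.01, 0.72,
    "B5", 19, 40, 19, 20, 1, 0, "O", "O", "O", 1L, 1.00, 0.25,
    "B6", 18, 24, 22, 34, 1, 1, "I", "O", "O", 1L, 1.00, 0.54,
    "C1", 10, 57, 22, 11, 0, 0, "O", "O", "O", 1L, 1.00, 0.09,
    "C2", 13, 30, 29, 26, 1, 1, "O", "O", "O", 1L, 1.00, 0.40
  )
}

#' Cohort-level consensus estimates of the vaccine-messaging case study
#'
#' The study's reported cohort-level General Condorcet Model estimates:
#' mean respondent competency 0.34 (sd 0.14) and mean guessing bias 0.34
#' (sd 0.172), across the 205 respondents. These values are the default
#' generating levels of [cohort_gcm_params()].
#'
#' @return A named list with `competency_mean`, `competency_sd`,
#'   `bias_mean`, `bias_sd`, `n_respondents`.
#' @export
vaccine_messaging_cohort <- function() {
  list(
    competency_mean = 0.34, competency_sd = 0.14,
    bias_mean = 0.34, bias_sd = 0.172,
    n_respondents = 205L
  )
}
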