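# One fixed answer-pair cell per category: the "canonical" cell used by the
# deterministic generators, chosen so classify_pair() maps it back to the
# category exactly.
.canonical_cells <- list(
  A = c(1L, 3L), # Like / Neutral
  O = c(1L, 5L), # Like / Dislike
  M = c(2L, 5L), # MustBe / Dislike
  I = c(3L, 3L), # Neutral / Neutral
  R = c(5L, 1L), # Dislike / Like
  Q = c(1L, 1L) # Like / Like
)

#' Canonical answer pair of a Kano category
#'
#' @param category Character vector of category symbols.
#' @return Tibble with `functional` and `dysfunctional` codes; feeding them
#'   through [classify_pair()] returns `category` again.
#' @export
canonical_pair <- function(category) {
  bad <- setdiff(unique(category), kano_categories())
  if (length(bad) > 0) {
    stop("unknown Kano categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cells <- do.call(rbind, .canonical_cells[category])
  tibble::tibble(functional = cells[, 1], dysfunctional = cells[, 2])
}

#' Emission model bridging binary relevance to Kano categories
#'
#' The synthetic generators first draw a binary relevance bit per
#' respondent-item cell from the GCM, then emit a six-way Kano category:
#' from `high` (a distribution over M, O, A) when the bit is 1 and from
#' `low` (over I, R, Q) when it is 0. The defaults put equal mass on the
#' three high-relevancy categories and concentrate low-relevancy mass on
#' indifferent, loosely matching how empirical low-relevancy answers are
#' dominated by I. Categories are then placed as answer pairs, either at
#' the category's single canonical cell (`cells = "canonical"`, fully
#' deterministic given the category) or uniformly across all grid cells of
#' that category (`cells = "uniform"`, for stress tests).
#'
#' @param high Named probability vector over `c("M", "O", "A")`.
#' @param low Named probability vector over `c("I", "R", "Q")`.
#' @param cells `"canonical"` or `"uniform"`.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(high = c(M = 1 / 3, O = 1 / 3, A = 1 / 3),
                           low = c(I = 0.8, R = 0.1, Q = 0.1),
                           cells = c("canonical", "uniform")) {
  cells <- match.arg(cells)
  chk <- function(p, want, nm) {
    if (!setequal(names(p), want) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
      stop("`", nm, "` must be a probability distribution over {",
        paste(want, collapse = ", "), "}",
        call. = FALSE
      )
    }
    p[want]
  }
  structure(
    list(
      high = chk(high, c("M", "O", "A"), "high"),
      low = chk(low, c("I", "R", "Q"), "low"),
      cells = cells
    ),
    class = "emission_model"
  )
}

# place categories as answer pairs under an emission model's cell rule
.emit_pairs <- function(category, emission) {
  if (emission$cells == "canonical") {
    return(canonical_pair(category))
  }
  grid_cells <- which(.kano_grid != "", arr.ind = TRUE) # all 25
  out_f <- integer(length(category))
  out_d <- integer(length(category))
  for (cat in unique(category)) {
    idx <- which(category == cat)
    cells <- which(.kano_grid == cat, arr.ind = TRUE)
    pick <- sample.int(nrow(cells), length(idx), replace = TRUE)
    out_f[idx] <- cells[pick, 1]
    out_d[idx] <- cells[pick, 2]
  }
  tibble::tibble(functional = out_f, dysfunctional = out_d)
}

#' Deterministic survey fixture from printed percentage rows
#'
#' Reconstructs a respondent-level survey whose per-attribute tallies
#' reproduce a table of printed category percentages exactly. Each
#' attribute's `percentage * n_respondents / 100` responses per category
#' are placed at that category's canonical answer pair, so
#' `fixture -> tally` round-trips to the input row. Rows whose percentages
#' do not yield integer counts summing to `n_respondents` (e.g. printed
#' rows summing to 99 or 101 after rounding) are rejected with an error
#' naming the row.
#'
#' @param rows Data frame with columns `attribute_id`, `A`, `O`, `M`, `I`,
#'   `R`, `Q` (percentages).
#' @param n_respondents Number of respondents (default 100).
#' @return A [kano_survey()].
#' @export
#' @examples
#' rows <- vaccine_messaging_results()[, c("attribute_id", "A", "O", "M", "I", "R", "Q")]
#' ok <- rowSums(rows[, -1]) == 100
#' sv <- fixture_from_percentages(rows[ok, ])
#' tally_attribute(sv, "B2")
fixture_from_percentages <- function(rows, n_respondents = 100) {
  rows <- as.data.frame(rows)
  req <- c("attribute_id", "A", "O", "M", "I", "R", "Q")
  miss <- setdiff(req, names(rows))
  if (length(miss) > 0) {
    stop("rows lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cats <- c("A", "O", "M", "I", "R", "Q")
  resp_ids <- sprintf("r%03d", seq_len(n_respondents))
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    pct <- as.numeric(rows[i, cats])
    if (any(pct < 0)) {
      stop("negative percentage in row ", rows$attribute_id[i], call. = FALSE)
    }
    counts <- pct * n_respondents / 100
    if (any(abs(counts - round(counts)) > 1e-9) ||
      sum(round(counts)) != n_respondents) {
      stop(
        "row ", rows$attribute_id[i],
        ": percentages do not give integer counts summing to ",
        n_respondents,
        call. = FALSE
      )
    }
    counts <- round(counts)
    category <- rep(cats, counts)
    # deterministic cyclic shift per attribute: keeps each attribute's
    # marginal tally exact while avoiding the degenerate alignment where
    # the same respondents get the same category for every attribute
    shift <- ((i - 1) * 37) %% n_respondents
    if (shift > 0) {
      category <- c(
        category[(shift + 1):n_respondents], category[1:shift]
      )
    }
    pairs <- canonical_pair(category)
    out[[i]] <- tibble::tibble(
      respondent_id = resp_ids,
      attribute_id = rows$attribute_id[i],
      functional = pairs$functional,
      dysfunctional = pairs$dysfunctional
    )
  }
  responses <- do.call(rbind, out)
  ids <- unique(rows$attribute_id)
  kano_survey(responses, manifest = tibble::tibble(
    id = ids, label = ids, group = NA_character_, reverse_recoded = FALSE
  ))
}

# Beta shape parameters matching a mean/sd pair
.beta_moments <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("sd too large for a Beta distribution with mean ", mean, call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Draw study-scale GCM parameters
#'
#' Generates a parameter set at the levels of the vaccine-messaging case
#' study: competencies and guessing biases drawn from Beta distributions
#' moment-matched to the reported cohort mean/sd (see
#' [vaccine_messaging_cohort()]), and by default the study's 14 item
#' difficulties and binary truth values (see
#' [vaccine_messaging_results()]).
#'
#' @param n_respondents Number of respondents (default 205).
#' @param truths Integer 0/1 vector of item truths (default: the study's
#'   binary truth column).
#' @param difficulties Item difficulties in \[0, 1\] (default: the study's
#'   difficulty column).
#' @param competency_mean,competency_sd,bias_mean,bias_sd Generating
#'   moments (defaults: the study's cohort estimates).
#' @param seed Optional integer seed.
#' @return A [gcm_params()].
#' @export
cohort_gcm_params <- function(n_respondents = 205,
                              truths = vaccine_messaging_results()$binary_truth,
                              difficulties = vaccine_messaging_results()$item_difficulty,
                              competency_mean = 0.34, competency_sd = 0.14,
                              bias_mean = 0.34, bias_sd = 0.172,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- .beta_moments(competency_mean, competency_sd)
  sg <- .beta_moments(bias_mean, bias_sd)
  gcm_params(
    theta = rbeta(n_respondents, st[1], st[2]),
    g = rbeta(n_respondents, sg[1], sg[2]),
    delta = difficulties,
    z = truths
  )
}

#' Generate a synthetic Kano survey from the GCM
#'
#' Draws a binary relevance matrix from [simulate_gcm()], emits a Kano
#' category per cell via the emission model, and places each category's
#' answer pair. The returned binary matrix and survey are exactly
#' consistent: dichotomizing the survey under the `"relevance"` scheme
#' reproduces the matrix for every seed.
#'
#' @param params A [gcm_params()].
#' @param emission An [emission_model()].
#' @param seed Optional integer seed.
#' @param attribute_ids Optional attribute id vector (default
#'   `item01..itemNN`).
#' @return List with `survey` (a [kano_survey()]), `relevance` (the binary
#'   matrix) and `params`.
#' @export
generate_gcm_survey <- function(params, emission = emission_model(),
                                seed = NULL, attribute_ids = NULL) {
  stopifnot(inherits(params, "gcm_params"), inherits(emission, "emission_model"))
  if (!is.null(seed)) set.seed(seed)
  B <- simulate_gcm(params)
  if (!is.null(attribute_ids)) {
    stopifnot(length(attribute_ids) == ncol(B))
    colnames(B) <- attribute_ids
  }
  n <- nrow(B)
  m <- ncol(B)
  bits <- as.vector(B) # column-major
  category <- character(n * m)
  category[bits == 1] <- sample(names(emission$high), sum(bits == 1),
    replace = TRUE, prob = emission$high
  )
  category[bits == 0] <- sample(names(emission$low), sum(bits == 0),
    replace = TRUE, prob = emission$low
  )
  pairs <- .emit_pairs(category, emission)
  responses <- tibble::tibble(
    respondent_id = rep(rownames(B), times = m),
    attribute_id = rep(colnames(B), each = n),
    functional = pairs$functional,
    dysfunctional = pairs$dysfunctional
  )
  survey <- kano_survey(responses, manifest = tibble::tibble(
    id = colnames(B), label = colnames(B),
    group = NA_character_, reverse_recoded = FALSE
  ))
  list(survey = survey, relevance = B, params = params)
}

#' Generate a two-culture synthetic survey
#'
#' Splits respondents into two consensus groups with distinct latent truth
#' vectors and generates each group from its own GCM — the canonical
#' misfit input for consensus-group detection: with opposed truths and
#' decent competency the scree analysis should flag more than one group.
#'
#' @param params_a,params_b [gcm_params()] for the two cultures; they must
#'   share the item count, and warn when their truth vectors are
#'   identical (indistinguishable cultures). `params_a` sizes culture A's
#'   respondent pool, `params_b` culture B's.
#' @param mixing Proportion of respondents in culture A, strictly between
#'   0 and 1. The realised split is `round(mixing * n)` where `n` is the
#'   total respondent count implied by the two parameter sets.
#' @param emission An [emission_model()].
#' @param seed Optional integer seed.
#' @return List with `survey`, `relevance`, `labels` (culture letter per
#'   respondent, a partition of all respondents) and the two parameter
#'   sets.
#' @export
generate_two_culture_survey <- function(params_a, params_b, mixing = 0.5,
                                        emission = emission_model(),
                                        seed = NULL) {
  stopifnot(inherits(params_a, "gcm_params"), inherits(params_b, "gcm_params"))
  if (length(params_a$delta) != length(params_b$delta)) {
    stop("both cultures must have the same number of items", call. = FALSE)
  }
  if (!(mixing > 0 && mixing < 1)) {
    stop("`mixing` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (identical(params_a$z, params_b$z)) {
    warning("identical truth vectors: the two cultures are indistinguishable",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  n_total <- length(params_a$theta) + length(params_b$theta)
  n_a <- round(mixing * n_total)
  n_b <- n_total - n_a
  take <- function(p, n) {
    gcm_params(
      theta = rep_len(p$theta, n), g = rep_len(p$g, n),
      delta = p$delta, z = p$z
    )
  }
  Ba <- simulate_gcm(take(params_a, n_a))
  Bb <- simulate_gcm(take(params_b, n_b))
  B <- rbind(Ba, Bb)
  rownames(B) <- sprintf("r%03d", seq_len(n_total))
  labels <- setNames(rep(c("A", "B"), c(n_a, n_b)), rownames(B))

  bits <- as.vector(B)
  category <- character(length(bits))
  category[bits == 1] <- sample(names(emission$high), sum(bits == 1),
    replace = TRUE, prob = emission$high
  )
  category[bits == 0] <- sample(names(emission$low), sum(bits == 0),
    replace = TRUE, prob = emission$low
  )
  pairs <- .emit_pairs(category, emission)
  responses <- tibble::tibble(
    respondent_id = rep(rownames(B), times = ncol(B)),
    attribute_id = rep(colnames(B), each = nrow(B)),
    functional = pairs$functional,
    dysfunctional = pairs$dysfunctional
  )
  survey <- kano_survey(responses, manifest = tibble::tibble(
    id = colnames(B), label = colnames(B),
    group = NA_character_, reverse_recoded = FALSE
  ))
  list(
    survey = survey, relevance = B, labels = labels,
    params_a = params_a, params_b = params_b
  )
}
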