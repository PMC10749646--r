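#' Construct a Kano survey dataset
#'
#' Bundles long-format responses with an attribute manifest. Each row of
#' `responses` is one respondent's functional/dysfunctional answer pair for
#' one attribute; `NA` codes mark missing answers, which are excluded
#' pairwise at tally time (so the effective n can differ between
#' attributes).
#'
#' @param responses Data frame with columns `respondent_id`, `attribute_id`,
#'   `functional`, `dysfunctional` (codes 1--5 or `NA`).
#' @param manifest Data frame with columns `id`, `label`, `group`,
#'   `reverse_recoded` (logical); defaults to a manifest derived from the
#'   attribute ids present in `responses`.
#' @return An object of class `kano_survey`.
#' @export
kano_survey <- function(responses, manifest = NULL) {
  responses <- tibble::as_tibble(responses)
  req <- c("respondent_id", "attribute_id", "functional", "dysfunctional")
  miss <- setdiff(req, names(responses))
  if (length(miss) > 0) {
    stop("responses lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  responses$respondent_id <- as.character(responses$respondent_id)
  responses$attribute_id <- as.character(responses$attribute_id)
  responses$functional <- .check_codes(responses$functional, "functional")
  responses$dysfunctional <- .check_codes(responses$dysfunctional, "dysfunctional")
  if (nrow(responses) == 0) stop("survey has no responses", call. = FALSE)

  key <- paste(responses$respondent_id, responses$attribute_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- responses[duplicated(key), c("respondent_id", "attribute_id")]
    stop(
      "duplicate (respondent, attribute) pairs, e.g. (",
      dup$respondent_id[1], ", ", dup$attribute_id[1], ")",
      call. = FALSE
    )
  }

  if (is.null(manifest)) {
    ids <- unique(responses$attribute_id)
    manifest <- tibble::tibble(
      id = ids, label = ids, group = NA_character_, reverse_recoded = FALSE
    )
  } else {
    manifest <- tibble::as_tibble(manifest)
    reqm <- c("id", "label", "group", "reverse_recoded")
    missm <- setdiff(reqm, names(manifest))
    if (length(missm) > 0) {
      stop("manifest lacks column(s): ", paste(missm, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(manifest$id)) stop("manifest ids must be unique", call. = FALSE)
    unknown <- setdiff(unique(responses$attribute_id), manifest$id)
    if (length(unknown) > 0) {
      stop(
        "responses reference attribute id(s) absent from the manifest: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  manifest$reverse_recoded <- as.logical(manifest$reverse_recoded)

  structure(
    list(
      responses = responses,
      manifest = manifest,
      respondents = unique(responses$respondent_id)
    ),
    class = "kano_survey"
  )
}

#' @export
print.kano_survey <- function(x, ...) {
  cat(
    "<kano_survey>", length(x$respondents), "respondents x",
    nrow(x$manifest), "attributes,", nrow(x$responses), "response pairs\n"
  )
  invisible(x)
}

#' Analysis-time attribute ids
#'
#' Reverse-recoded attributes are renamed with an `"R"` suffix (e.g. a
#' privacy attribute `B4` analysed as its negation becomes `B4R`), so
#' reports show which attributes were flipped.
#'
#' @param survey A [kano_survey()].
#' @return Named character vector mapping manifest ids to analysis ids.
#' @export
analysis_ids <- function(survey) {
  stopifnot(inherits(survey, "kano_survey"))
  m <- survey$manifest
  setNames(ifelse(m$reverse_recoded, paste0(m$id, "R"), m$id), m$id)
}

#' Tally one attribute's individual classifications
#'
#' Classifies every non-missing answer pair for the attribute via
#' [classify_pair()] (after optionally swapping functional and dysfunctional
#' answers) and counts the six categories. Pairs with a missing answer on
#' either question are excluded, so `n` is the number of complete pairs.
#'
#' @param survey A [kano_survey()].
#' @param attribute_id Manifest id of the attribute.
#' @param apply_reverse Swap the two questions before classifying? Defaults
#'   to the manifest's `reverse_recoded` flag.
#' @return A [kano_tally()].
#' @export
tally_attribute <- function(survey, attribute_id, apply_reverse = NULL) {
  stopifnot(inherits(survey, "kano_survey"))
  if (!attribute_id %in% survey$manifest$id) {
    stop("unknown attribute id: ", attribute_id, call. = FALSE)
  }
  if (is.null(apply_reverse)) {
    apply_reverse <- survey$manifest$reverse_recoded[
      match(attribute_id, survey$manifest$id)
    ]
  }
  rows <- survey$responses[survey$responses$attribute_id == attribute_id, ]
  rows <- rows[!is.na(rows$functional) & !is.na(rows$dysfunctional), ]
  if (nrow(rows) == 0) {
    stop("attribute ", attribute_id, " has no complete response pairs", call. = FALSE)
  }
  f <- rows$functional
  d <- rows$dysfunctional
  if (isTRUE(apply_reverse)) {
    sw <- recode_reverse(f, d)
    f <- sw$functional
    d <- sw$dysfunctional
  }
  kano_tally(classify_pair(f, d))
}

#' Tally every manifest attribute
#'
#' @param survey A [kano_survey()].
#' @return Named list of [kano_tally()] objects, keyed by analysis id
#'   (reverse-recoded attributes carry their `"R"` suffix).
#' @export
tally_all <- function(survey) {
  ids <- analysis_ids(survey)
  out <- lapply(names(ids), function(id) tally_attribute(survey, id))
  setNames(out, unname(ids))
}

#' Per-respondent Kano category matrix
#'
#' @param survey A [kano_survey()].
#' @return Character matrix (respondents x analysis ids) of individual
#'   category symbols; `NA` where a pair is missing.
#' @export
category_matrix <- function(survey) {
  stopifnot(inherits(survey, "kano_survey"))
  ids <- analysis_ids(survey)
  resp <- survey$respondents
  out <- matrix(NA_character_,
    nrow = length(resp), ncol = length(ids),
    dimnames = list(resp, unname(ids))
  )
  for (mid in names(ids)) {
    rows <- survey$responses[survey$responses$attribute_id == mid, ]
    rows <- rows[!is.na(rows$functional) & !is.na(rows$dysfunctional), ]
    if (nrow(rows) == 0) next
    f <- rows$functional
    d <- rows$dysfunctional
    if (survey$manifest$reverse_recoded[match(mid, survey$manifest$id)]) {
      sw <- recode_reverse(f, d)
      f <- sw$functional
      d <- sw$dysfunctional
    }
    out[cbind(rows$respondent_id, ids[[mid]])] <- classify_pair(f, d)
  }
  out
}

#' Read a survey CSV
#'
#' Expected dialect: header row with columns `respondent_id`, `attribute_id`,
#' `functional_code`, `dysfunctional_code`; codes 1--5 (empty for missing);
#' UTF-8. Malformed rows are reported with their file line numbers.
#'
#' @param path CSV file path.
#' @param manifest Optional manifest data frame (see [kano_survey()]).
#' @return A [kano_survey()].
#' @export
read_survey <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0) stop("survey file is empty: ", path, call. = FALSE)
  req <- c("respondent_id", "attribute_id", "functional_code", "dysfunctional_code")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop("survey CSV lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L # header is line 1
  parse_code <- function(x) {
    x[x == ""] <- NA_character_
    suppressWarnings(as.integer(x))
  }
  f <- parse_code(raw$functional_code)
  d <- parse_code(raw$dysfunctional_code)
  bad_f <- !is.na(raw$functional_code) & raw$functional_code != "" &
    (is.na(f) | !(f %in% 1:5))
  bad_d <- !is.na(raw$dysfunctional_code) & raw$dysfunctional_code != "" &
    (is.na(d) | !(d %in% 1:5))
  bad <- bad_f | bad_d
  if (any(bad)) {
    stop(
      "invalid answer codes (must be 1..5) on line(s): ",
      paste(line[bad], collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(raw$respondent_id, raw$attribute_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop(
      "duplicate (respondent, attribute) rows on line(s): ",
      paste(line[duplicated(key)], collapse = ", "),
      call. = FALSE
    )
  }
  kano_survey(
    tibble::tibble(
      respondent_id = raw$respondent_id,
      attribute_id = raw$attribute_id,
      functional = f,
      dysfunctional = d
    ),
    manifest = manifest
  )
}

#' Write a survey CSV
#'
#' Inverse of [read_survey()]: the write/read round trip preserves every
#' pair.
#'
#' @param survey A [kano_survey()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  stopifnot(inherits(survey, "kano_survey"))
  out <- data.frame(
    respondent_id = survey$responses$respondent_id,
    attribute_id = survey$responses$attribute_id,
    functional_code = survey$responses$functional,
    dysfunctional_code = survey$responses$dysfunctional
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an attribute manifest CSV
#'
#' Columns: `id`, `label`, `group`, `reverse_recoded` (TRUE/FALSE).
#'
#' @param path CSV file path.
#' @return A tibble usable as the `manifest` argument of [kano_survey()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  req <- c("id", "label", "group", "reverse_recoded")
  miss <- setdiff(req, names(m))
  if (length(miss) > 0) {
    stop("manifest CSV lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  m$reverse_recoded <- as.logical(m$reverse_recoded)
  m
}
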