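#' Pipeline configuration
#'
#' Bundles every setting of [run_pipeline()]. The seed is mandatory
#' because the consensus stage is stochastic; a config plus seed fixes
#' every number in the report, and the settings are echoed into the
#' report's metadata (and every written output's header).
#'
#' @param seed Master seed for all stochastic stages.
#' @param scheme Dichotomization scheme feeding the consensus model
#'   (default `"relevance"`: M, O, A = 1).
#' @param scree_scheme Scheme feeding the scree analysis (default
#'   `"relevance_with_reverse"`: M, O, A, R = 1, so respondents for whom an
#'   attribute matters negatively still count as caring).
#' @param chains,samples,burnin,thin MCMC settings (defaults 3 / 10000 /
#'   2000 / 10).
#' @param prior Prior family for [fit_gcm()].
#' @param ratio_threshold Eigenvalue-ratio threshold of [scree_analysis()].
#' @param drop_items Analysis ids to drop in a resilience rerun (empty:
#'   no rerun).
#' @param n_ppc_replicates Posterior-predictive replicates (0 disables the
#'   check).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            scheme = "relevance",
                            scree_scheme = "relevance_with_reverse",
                            chains = 3, samples = 10000, burnin = 2000,
                            thin = 10,
                            prior = c("hierarchical", "uniform"),
                            ratio_threshold = 3,
                            drop_items = character(),
                            n_ppc_replicates = 0) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` is mandatory: every stochastic stage derives from it", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      scheme = match.arg(scheme, c("relevance", "relevance_with_reverse")),
      scree_scheme = match.arg(
        scree_scheme,
        c("relevance_with_reverse", "relevance")
      ),
      chains = chains, samples = samples, burnin = burnin, thin = thin,
      prior = match.arg(prior),
      ratio_threshold = ratio_threshold,
      drop_items = drop_items,
      n_ppc_replicates = n_ppc_replicates
    ),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

# complete-case binary matrix for the consensus stages; reports how many
# respondents were dropped for having any missing pair
.complete_relevance <- function(survey, scheme) {
  B <- relevance_matrix(survey, scheme)
  complete <- !apply(B, 1, anyNA)
  list(matrix = B[complete, , drop = FALSE], n_dropped = sum(!complete))
}

#' Run the full Kano + consensus pipeline
#'
#' Stages, in order: per-attribute tallying (with reverse recoding from
#' the manifest) — original and revised classification — dichotomization —
#' eigenvalue scree analysis — General Condorcet Model fit — consensus
#' (CCA) classification — Timko coefficients — optional resilience rerun
#' on an item subset. Identical survey, config and seed give identical
#' reports.
#'
#' @param survey A [kano_survey()].
#' @param config A [pipeline_config()].
#' @return An object of class `kano_report`: a list with
#'   `table` (per-attribute classifications, percentages, consensus
#'   estimates, Timko coefficients), `scree`, `fit`, `ppc` (when
#'   requested), `resilience` (when requested), and `meta`.
#' @export
run_pipeline <- function(survey, config) {
  stopifnot(inherits(survey, "kano_survey"), inherits(config, "pipeline_config"))

  tallies <- .stage("tally", tally_all(survey))
  cls <- .stage("classify", classification_table(tallies))

  scree_in <- .stage(
    "dichotomize",
    .complete_relevance(survey, config$scree_scheme)
  )
  gcm_in <- .stage(
    "dichotomize",
    .complete_relevance(survey, config$scheme)
  )

  scree <- .stage(
    "scree",
    scree_analysis(scree_in$matrix, ratio_threshold = config$ratio_threshold)
  )
  fit <- .stage("gcm_fit", suppressWarnings(fit_gcm(
    gcm_in$matrix,
    chains = config$chains, samples = config$samples,
    burnin = config$burnin, thin = config$thin,
    seed = config$seed, prior = config$prior
  )))

  cls <- .stage(
    "cca_classify",
    classification_table(tallies, item_truth = fit$item_truth)
  )
  timko <- .stage("timko", coefficient_table(tallies, undefined = "na"))

  tab <- merge(cls, timko, by = "attribute_id", sort = FALSE)
  tab <- merge(
    tab,
    tibble::tibble(
      attribute_id = names(fit$item_truth),
      item_truth = unname(fit$item_truth),
      binary_truth = unname(fit$binary_truth),
      item_difficulty = unname(fit$delta_mean)
    ),
    by = "attribute_id", all.x = TRUE, sort = FALSE
  )
  tab <- tibble::as_tibble(tab[match(cls$attribute_id, tab$attribute_id), ])

  ppc <- NULL
  if (config$n_ppc_replicates > 0) {
    ppc <- .stage("ppc", posterior_predictive_check(
      fit, gcm_in$matrix,
      n_replicates = config$n_ppc_replicates,
      seed = config$seed + 1L
    ))
  }

  report <- structure(
    list(
      table = tab, scree = scree, fit = fit, ppc = ppc, resilience = NULL,
      meta = list(
        config = unclass(config),
        n_respondents = length(survey$respondents),
        n_attributes = nrow(survey$manifest),
        n_dropped_scree_input = scree_in$n_dropped,
        n_dropped_gcm_input = gcm_in$n_dropped,
        n_omitted_zero_variance = scree$n_omitted,
        package_version = as.character(packageVersion("kanocca"))
      )
    ),
    class = "kano_report"
  )

  if (length(config$drop_items) > 0) {
    report$resilience <- .stage(
      "resilience",
      resilience_rerun(survey, config$drop_items, config, baseline = report)
    )
  }
  report
}

#' @export
print.kano_report <- function(x, ...) {
  cat("<kano_report>", x$meta$n_respondents, "respondents,",
    x$meta$n_attributes, "attributes\n\n")
  df <- as.data.frame(x$table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(df, row.names = FALSE)
  cat("\n")
  print(x$scree)
  cat(sprintf(
    "competency: mean %.3f (sd %.3f); guessing bias: mean %.3f (sd %.3f); max Rhat %.3f\n",
    x$fit$theta_mean, x$fit$theta_sd, x$fit$g_mean, x$fit$g_sd, max(x$fit$rhat)
  ))
  if (!is.null(x$resilience)) {
    ch <- x$resilience$changed
    cat(
      "resilience rerun (dropped ",
      paste(x$resilience$dropped, collapse = ", "), "): ",
      sum(ch), " of ", length(ch), " remaining classifications changed\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Rerun scree and consensus analysis on an item subset
#'
#' Mirrors the resilience analysis of dropping high-difficulty items with
#' ambiguous truth values: the full pipeline is rerun with the listed
#' attributes removed and the remaining attributes' classifications are
#' compared against the full run.
#'
#' @param survey A [kano_survey()].
#' @param drop_item_ids Analysis ids to drop (e.g. `c("A1", "B2", "B3",
#'   "B4R")`). Unknown ids are an error, as is dropping so many that
#'   fewer than 2 items remain.
#' @param config A [pipeline_config()]; its own `drop_items` entry is
#'   ignored here.
#' @param baseline Optional full-run `kano_report` to compare against
#'   (computed when absent).
#' @return A list with `scree`, `fit`, `table` (reduced-run
#'   classifications), `changed` (named logical: did any of the three
#'   classifications change for a remaining attribute) and `dropped`.
#' @export
resilience_rerun <- function(survey, drop_item_ids, config, baseline = NULL) {
  stopifnot(inherits(survey, "kano_survey"), inherits(config, "pipeline_config"))
  ids <- analysis_ids(survey) # manifest id -> analysis id
  unknown <- setdiff(drop_item_ids, unname(ids))
  if (length(unknown) > 0) {
    stop("unknown item id(s) in drop list: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  keep_manifest <- names(ids)[!(ids %in% drop_item_ids)]
  if (length(keep_manifest) < 2) {
    stop("resilience rerun needs at least 2 remaining items", call. = FALSE)
  }

  sub <- kano_survey(
    survey$responses[survey$responses$attribute_id %in% keep_manifest, ],
    manifest = survey$manifest[survey$manifest$id %in% keep_manifest, ]
  )
  sub_config <- config
  sub_config$drop_items <- character()
  sub_report <- run_pipeline(sub, sub_config)

  if (is.null(baseline)) {
    base_config <- config
    base_config$drop_items <- character()
    baseline <- run_pipeline(survey, base_config)
  }
  base_tab <- baseline$table
  red_tab <- sub_report$table
  common <- red_tab$attribute_id
  bi <- match(common, base_tab$attribute_id)
  changed <- setNames(
    red_tab$original != base_tab$original[bi] |
      red_tab$revised != base_tab$revised[bi] |
      red_tab$cca != base_tab$cca[bi],
    common
  )
  list(
    scree = sub_report$scree, fit = sub_report$fit, table = red_tab,
    changed = changed, dropped = drop_item_ids
  )
}

#' Write a report to CSV + JSON files
#'
#' Writes `report.csv` (the per-attribute table, full precision),
#' `timko.csv` (plot data), `eigenvalues.csv`, `posterior.csv` (per-item
#' consensus estimates plus cohort summaries) and `run_metadata.json`
#' (config echo, seeds, version).
#'
#' @param report A `kano_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "kano_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    report = file.path(dir, "report.csv"),
    timko = file.path(dir, "timko.csv"),
    eigenvalues = file.path(dir, "eigenvalues.csv"),
    posterior = file.path(dir, "posterior.csv"),
    metadata = file.path(dir, "run_metadata.json")
  )
  write.csv(report$table, paths["report"], row.names = FALSE)
  write.csv(
    report$table[, c("attribute_id", "better", "worse", "quadrant")],
    paths["timko"],
    row.names = FALSE
  )
  write.csv(
    data.frame(
      rank = seq_along(report$scree$eigenvalues),
      eigenvalue = report$scree$eigenvalues
    ),
    paths["eigenvalues"],
    row.names = FALSE
  )
  post <- summary(report$fit)
  write.csv(post, paths["posterior"], row.names = FALSE)
  meta <- report$meta
  meta$cohort <- list(
    competency_mean = report$fit$theta_mean, competency_sd = report$fit$theta_sd,
    bias_mean = report$fit$g_mean, bias_sd = report$fit$g_sd,
    max_rhat = max(report$fit$rhat)
  )
  meta$scree <- list(
    ratio_first_second = report$scree$ratio_first_second,
    n_cultures = report$scree$n_cultures,
    n_omitted = report$scree$n_omitted
  )
  jsonlite::write_json(meta, paths["metadata"],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
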