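test_that("canonical pairs classify back to their own category", {
  cats <- kano_categories()
  cp <- canonical_pair(cats)
  expect_identical(classify_pair(cp$functional, cp$dysfunctional), cats)
})

test_that("percentage fixtures round-trip exactly through tallying", {
  rows <- exact_fixture_rows()
  expect_gt(nrow(rows), 0)
  sv <- fixture_from_percentages(rows)
  for (i in seq_len(nrow(rows))) {
    tl <- tally_attribute(sv, rows$attribute_id[i])
    expect_identical(tl$n, 100)
    expect_equal(
      unname(tl$counts[c("A", "O", "M", "I", "R", "Q")]),
      as.numeric(rows[i, c("A", "O", "M", "I", "R", "Q")]),
      label = paste("fixture row", rows$attribute_id[i])
    )
  }
})

test_that("the trusted-messenger fixture reproduces its printed distribution", {
  rows <- exact_fixture_rows()
  sv <- fixture_from_percentages(rows[rows$attribute_id == "B2", ])
  tl <- tally_attribute(sv, "B2")
  expect_equal(
    unname(tl$counts[c("A", "O", "M", "I", "R", "Q")]),
    c(11, 12, 27, 36, 4, 10)
  )
  expect_equal(unname(tally_percentages(tl)[["M"]]), 27)
})

test_that("rows with rounding drift are rejected by name", {
  rows <- study_rows()[, c("attribute_id", "A", "O", "M", "I", "R", "Q")]
  a1 <- rows[rows$attribute_id == "A1", ] # sums to 101
  expect_error(fixture_from_percentages(a1), "A1")
  # all-indifferent row is fine
  ok <- tibble::tibble(attribute_id = "Z", A = 0, O = 0, M = 0, I = 100, R = 0, Q = 0)
  sv <- fixture_from_percentages(ok)
  expect_identical(unname(tally_attribute(sv, "Z")$counts[["I"]]), 100)
})

test_that("emission model validates its distributions", {
  expect_error(emission_model(high = c(M = 0.5, O = 0.5)), "high")
  expect_error(emission_model(low = c(I = 0.5, R = 0.2, Q = 0.2)), "low")
})

test_that("generated surveys and relevance matrices are exactly consistent", {
  for (seed in c(3, 17, 92)) {
    p <- cohort_gcm_params(n_respondents = 40, seed = seed)
    out <- generate_gcm_survey(p, seed = seed + 1)
    expect_identical(
      unname(relevance_matrix(out$survey, "relevance")[
        rownames(out$relevance), colnames(out$relevance)
      ]),
      unname(out$relevance)
    )
  }
})

test_that("perfect competency emits high-relevancy categories exactly where z = 1", {
  z <- c(1L, 0L, 1L, 0L)
  p <- gcm_params(rep(1, 15), 0.4, rep(0.5, 4), z)
  out <- generate_gcm_survey(p, seed = 5)
  cm <- category_matrix(out$survey)
  for (k in seq_along(z)) {
    if (z[k] == 1) {
      expect_true(all(cm[, k] %in% c("M", "O", "A")))
    } else {
      expect_true(all(cm[, k] %in% c("I", "R", "Q")))
    }
  }
})

test_that("emitted category frequencies follow the emission distributions", {
  em <- emission_model(
    high = c(M = 0.5, O = 0.3, A = 0.2),
    low = c(I = 0.7, R = 0.2, Q = 0.1)
  )
  p <- gcm_params(rep(1, 500), 0.5, rep(0.2, 20), rep(c(1L, 0L), 10))
  out <- generate_gcm_survey(p, emission = em, seed = 44)
  cm <- category_matrix(out$survey)
  high_cats <- table(cm[, seq(1, 20, by = 2)])
  low_cats <- table(cm[, seq(2, 20, by = 2)])
  p_high <- chisq.test(high_cats[c("M", "O", "A")], p = c(0.5, 0.3, 0.2))$p.value
  p_low <- chisq.test(low_cats[c("I", "R", "Q")], p = c(0.7, 0.2, 0.1))$p.value
  expect_gt(p_high, 0.001)
  expect_gt(p_low, 0.001)
})

test_that("cohort parameter draws match the target moments", {
  set.seed(303)
  p <- cohort_gcm_params(n_respondents = 20000)
  expect_equal(mean(p$theta), 0.34, tolerance = 0.01)
  expect_equal(sd(p$theta), 0.14, tolerance = 0.01)
  expect_equal(mean(p$g), 0.34, tolerance = 0.01)
  expect_equal(sd(p$g), 0.172, tolerance = 0.01)
})

test_that("two-culture generation validates mixing and labels all respondents", {
  mk <- function(z) {
    gcm_params(rbeta(30, 8, 3), 0.4, runif(6, 0.1, 0.4), z)
  }
  za <- c(1L, 0L, 1L, 0L, 1L, 0L)
  expect_error(
    generate_two_culture_survey(mk(za), mk(1L - za), mixing = 1),
    "strictly between"
  )
  expect_warning(
    generate_two_culture_survey(mk(za), mk(za), mixing = 0.5, seed = 2),
    "indistinguishable"
  )
  out <- generate_two_culture_survey(mk(za), mk(1L - za), mixing = 0.4, seed = 9)
  expect_identical(length(out$labels), 60L)
  expect_identical(sort(unique(out$labels)), c("A", "B"))
  expect_identical(unname(table(out$labels)[["A"]]), as.integer(round(0.4 * 60)))
  expect_setequal(names(out$labels), out$survey$respondents)
})
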