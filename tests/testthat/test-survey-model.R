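# independently transcribed pair-assignment grid: functional code, then the
# category for dysfunctional codes 1..5
grid_oracle <- rbind(
  c("Q", "A", "A", "A", "O"), # functional: Like
  c("R", "I", "I", "I", "M"), # MustBe
  c("R", "I", "I", "I", "M"), # Neutral
  c("R", "I", "I", "I", "M"), # LiveWith
  c("R", "R", "R", "R", "Q") # Dislike
)

test_that("classify_pair matches the assignment grid on all 25 cells", {
  for (f in 1:5) {
    for (d in 1:5) {
      expect_identical(classify_pair(f, d), grid_oracle[f, d])
    }
  }
})

test_that("category census over the full grid is A=3 O=1 M=3 I=9 R=7 Q=2", {
  all_pairs <- expand.grid(f = 1:5, d = 1:5)
  census <- table(classify_pair(all_pairs$f, all_pairs$d))
  expect_equal(
    as.vector(census[c("A", "O", "M", "I", "R", "Q")]),
    c(3, 1, 3, 9, 7, 2)
  )
})

test_that("classify_pair validates codes and propagates NA", {
  expect_error(classify_pair(6, 1), "1\\.\\.5")
  expect_error(classify_pair(1, 0), "1\\.\\.5")
  expect_identical(classify_pair(NA, 3), NA_character_)
  expect_identical(classify_pair(c(1, NA), c(5, 5)), c("O", NA))
})

test_that("recode_reverse swaps the questions and is an involution", {
  sw <- recode_reverse(5, 1)
  expect_identical(c(sw$functional, sw$dysfunctional), c(1L, 5L))
  all_pairs <- expand.grid(f = 1:5, d = 1:5)
  once <- recode_reverse(all_pairs$f, all_pairs$d)
  twice <- recode_reverse(once$functional, once$dysfunctional)
  expect_identical(twice$functional, as.integer(all_pairs$f))
  expect_identical(twice$dysfunctional, as.integer(all_pairs$d))
})

test_that("recoding flips a reverse pair into a one-dimensional one", {
  expect_identical(classify_pair(5, 1), "R")
  sw <- recode_reverse(5, 1)
  expect_identical(classify_pair(sw$functional, sw$dysfunctional), "O")
})

test_that("kano_tally counts categories and validates input", {
  tl <- kano_tally(c("O", "O", "M"))
  expect_identical(tl$n, 3)
  expect_identical(unname(tl$counts[c("O", "M", "A")]), c(2, 1, 0))
  expect_true(is_kano_tally(tl))
  expect_error(kano_tally(c("O", "X")), "unknown")
  expect_error(kano_tally(c(A = -1, O = 2)), "nonnegative")
  expect_error(kano_tally(character(0)), "at least one")
  expect_equal(sum(tally_percentages(tl)), 100)
})

test_that("tally_attribute counts classified pairs and excludes missing", {
  sv <- kano_survey(tibble::tibble(
    respondent_id = c("r1", "r2", "r3", "r4"),
    attribute_id = "X1",
    functional = c(1L, 1L, 1L, NA),
    dysfunctional = c(5L, 5L, 5L, 3L)
  ))
  tl <- tally_attribute(sv, "X1")
  expect_identical(tl$n, 3)
  expect_identical(unname(tl$counts[["O"]]), 3)
  expect_error(tally_attribute(sv, "nope"), "unknown attribute")
})

test_that("tally_attribute applies reverse recoding from the manifest", {
  sv <- kano_survey(
    tibble::tibble(
      respondent_id = c("r1", "r2"),
      attribute_id = "B4",
      functional = c(5L, 5L),
      dysfunctional = c(1L, 1L)
    ),
    manifest = tibble::tibble(
      id = "B4", label = "privacy", group = "distribution",
      reverse_recoded = TRUE
    )
  )
  tl <- tally_attribute(sv, "B4")
  expect_identical(unname(tl$counts[["O"]]), 2) # (5,1) swapped -> (1,5) -> O
  expect_identical(names(tally_all(sv)), "B4R")
  raw <- tally_attribute(sv, "B4", apply_reverse = FALSE)
  expect_identical(unname(raw$counts[["R"]]), 2)
})

test_that("tally errors when no complete pairs remain", {
  sv <- kano_survey(tibble::tibble(
    respondent_id = c("r1", "r2"),
    attribute_id = c("X1", "X2"),
    functional = c(NA, 1L),
    dysfunctional = c(3L, 5L)
  ))
  expect_error(tally_attribute(sv, "X1"), "no complete")
})

test_that("survey construction rejects duplicates and unknown attributes", {
  resp <- tibble::tibble(
    respondent_id = c("r1", "r1"), attribute_id = c("X1", "X1"),
    functional = 1L, dysfunctional = 5L
  )
  expect_error(kano_survey(resp), "duplicate")
  expect_error(
    kano_survey(
      tibble::tibble(
        respondent_id = "r1", attribute_id = "X9",
        functional = 1L, dysfunctional = 5L
      ),
      manifest = tibble::tibble(
        id = "X1", label = "x", group = NA_character_, reverse_recoded = FALSE
      )
    ),
    "absent from the manifest"
  )
})
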