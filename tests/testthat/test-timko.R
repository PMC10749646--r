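test_that("an all-attractive attribute gives better = 1 and worse = 0", {
  tl <- kano_tally(c(A = 205))
  expect_identical(better_coefficient(tl), 1)
  expect_identical(worse_coefficient(tl), 0)
})

test_that("coefficients on the fact-based row match direct arithmetic", {
  c1 <- kano_tally(c(A = 10, O = 57, M = 22, I = 11))
  expect_equal(better_coefficient(c1), 0.67) # (10+57)/100
  expect_equal(worse_coefficient(c1), 0.79) # (57+22)/100
})

test_that("all-indifferent gives 0/0 coefficients and all-must-be worse = 1", {
  expect_identical(better_coefficient(kano_tally(c(I = 7))), 0)
  expect_identical(worse_coefficient(kano_tally(c(I = 7))), 0)
  expect_identical(worse_coefficient(kano_tally(c(M = 7))), 1)
})

test_that("coefficients are scale-invariant and bounded in [0, 1]", {
  set.seed(99)
  for (rep in 1:100) {
    cnt <- setNames(rpois(6, 4), kano_categories())
    if (sum(cnt[c("A", "O", "M", "I")]) == 0) next
    tl <- kano_tally(cnt)
    b <- better_coefficient(tl)
    w <- worse_coefficient(tl)
    expect_true(b >= 0 && b <= 1 && w >= 0 && w <= 1)
    k <- sample(2:9, 1)
    expect_equal(better_coefficient(kano_tally(cnt * k)), b)
    expect_equal(worse_coefficient(kano_tally(cnt * k)), w)
  }
})

test_that("entirely reverse/questionable responses are an undefined-coefficient error", {
  tl <- kano_tally(c(R = 3, Q = 2))
  expect_error(better_coefficient(tl), "undefined")
  expect_error(worse_coefficient(tl), "undefined")
  expect_error(coefficient_table(list(rq = tl)), "rq")
  expect_warning(out <- coefficient_table(list(rq = tl), undefined = "na"), "rq")
  expect_true(is.na(out$better) && is.na(out$worse))
})

test_that("quadrant split is at 0.5 with the boundary falling lower/left", {
  expect_identical(quadrant_of(0.9, 0.9), "one_dimensional_topright")
  expect_identical(quadrant_of(0.9, 0.2), "attractive_topleft")
  expect_identical(quadrant_of(0.2, 0.9), "must_be_bottomright")
  expect_identical(quadrant_of(0.2, 0.2), "indifferent_bottomleft")
  expect_identical(quadrant_of(0.5, 0.5), "indifferent_bottomleft")
  expect_identical(quadrant_of(0.5, 0.9), "must_be_bottomright")
  expect_error(quadrant_of(1.2, 0), "\\[0, 1\\]")
})

test_that("case-study quadrant placements match the published reading", {
  rows <- study_rows()
  tallies <- setNames(
    lapply(seq_len(nrow(rows)), function(i) row_tally(rows[i, ])),
    rows$attribute_id
  )
  tab <- coefficient_table(tallies)
  q <- setNames(tab$quadrant, tab$attribute_id)
  expect_identical(unname(q[c("A5", "B3")]), rep("attractive_topleft", 2))
  expect_identical(unname(q[c("B5", "C1")]), rep("one_dimensional_topright", 2))
  expect_identical(unname(q["C2"]), "must_be_bottomright")
  # B1 sits exactly on the vertical boundary on the rounded percentages and
  # therefore falls left/low by convention
  b1 <- tab[tab$attribute_id == "B1", ]
  expect_equal(b1$better, 0.5)
  expect_identical(b1$quadrant, "indifferent_bottomleft")
})

test_that("coefficient_table on an empty list returns an empty table", {
  out <- coefficient_table(list())
  expect_identical(nrow(out), 0L)
  expect_identical(
    names(out),
    c("attribute_id", "better", "worse", "quadrant")
  )
})
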