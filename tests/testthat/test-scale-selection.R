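test_that("heterogeneity sums absolute pairwise differences of medians", {
  expect_equal(heterogeneity(c(2, 2, 2, 2)), 0)
  expect_equal(heterogeneity(c(0, 1, 2, 3)), 10)
  set.seed(8)
  v <- rnorm(4)
  expect_equal(heterogeneity(v), heterogeneity(sample(v)))
  expect_equal(heterogeneity(v + 17.3), heterogeneity(v), tolerance = 1e-12)
  expect_equal(heterogeneity(2.5 * v), 2.5 * heterogeneity(v),
               tolerance = 1e-12)
  expect_error(heterogeneity(1), ">= 2")
})

median_table <- function(values, conditions = c("DL0", "DL005", "DL01", "DL1"),
                         scales = 1:20) {
  tbl <- tidyr::expand_grid(condition = conditions, scale = scales)
  tbl$delta_pct <- values
  tbl
}

test_that("select_scale takes the argmax with smallest-scale tie-breaking", {
  # H strictly increasing over scales -> scale 20
  tbl <- median_table(rep(1:20, times = 4) * rep(c(0, 1, 2, 3), each = 20))
  expect_equal(select_scale(tbl)$selected_scale, 20)
  # all H equal -> scale 1
  flat <- median_table(rep(c(0, 1, 2, 3), each = 20))
  expect_equal(select_scale(flat)$selected_scale, 1)
  # H profile is exposed for audit
  sel <- select_scale(flat)
  expect_equal(sel$profile$H, rep(10, 20))
  expect_equal(nrow(sel$profile), 20)
})

test_that("select_scale agrees with the exhaustive-search oracle", {
  set.seed(303)
  for (k in 1:100) {
    tbl <- median_table(rnorm(80, sd = 10))
    expect_equal(select_scale(tbl)$selected_scale, select_scale_oracle(tbl))
  }
})

test_that("selection is invariant to condition order and scaling", {
  set.seed(9)
  tbl <- median_table(rnorm(80))
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(select_scale(shuffled)$selected_scale,
               select_scale(tbl)$selected_scale)
  tbl2 <- tbl
  tbl2$delta_pct <- tbl2$delta_pct * 3.7
  expect_equal(select_scale(tbl2)$selected_scale,
               select_scale(tbl)$selected_scale)
})

test_that("select_scale rejects incomplete tables", {
  tbl <- median_table(rnorm(80))
  expect_error(select_scale(tbl[-5, ]), "every condition")
  expect_error(select_scale(tbl[tbl$condition == "DL0", ]), ">= 2")
})
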