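write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("load_responses recodes a yes/no CSV and preserves row order", {
  cb <- item_codebook(c("A", "B"), community = "knowledge",
                      response_type = "yes_no",
                      key = c("positive", "negative"))
  path <- write_fixture_csv(c("A,B", "Yes,No", "No,Yes", "Yes,Yes"))
  X <- load_responses(path, cb)
  expect_equal(unname(X$values),
               matrix(c(1L, 0L, 1L,   # A: yes keyed
                        1L, 0L, 0L),  # B: no keyed
                      ncol = 2))
})

test_that("missing cells and absent columns are hard errors naming the spot", {
  cb <- item_codebook(c("A", "B"), community = "knowledge",
                      response_type = "yes_no")
  path <- write_fixture_csv(c("A,B", "Yes,No", "Yes,", "No,No"))
  expect_error(load_responses(path, cb), "row 2, item 'B'")
  path2 <- write_fixture_csv(c("A", "Yes", "No"))
  expect_error(load_responses(path2, cb), "lacks codebook column")
})

test_that("likert items are dichotomized during loading", {
  cb <- item_codebook(c("S1", "S2"), community = "stigma",
                      response_type = "likert4",
                      key = c("positive", "negative"))
  path <- write_fixture_csv(c("S1,S2", "1,1", "2,2", "3,3", "4,4"))
  X <- load_responses(path, cb)
  expect_equal(unname(X$values),
               matrix(c(1L, 1L, 0L, 0L,
                        0L, 0L, 1L, 1L), ncol = 2))
})

test_that("zero-variance and non-binary inputs are rejected", {
  cb <- item_codebook(c("A", "B"), community = "knowledge",
                      response_type = "yes_no")
  path <- write_fixture_csv(c("A,B", "Yes,No", "Yes,Yes", "Yes,No"))
  expect_error(load_responses(path, cb), "zero-variance.*A")
  expect_error(response_matrix(matrix(c(0, 1, 2, 1), 2)), "non-binary")
  expect_error(response_matrix(matrix(c(0, 1, NA, 1), 2)), "missing")
})

test_that("descriptive percentages use half-up rounding to 2 decimals", {
  X <- matrix(0L, 800, 2, dimnames = list(NULL, c("a", "b")))
  X[1, 1] <- 1L          # 1/800 = 0.125% -> 0.13 under half-up
  X[1:300, 2] <- 1L      # 37.50%
  d <- descriptive_table(response_matrix(X, check_variance = FALSE))
  expect_equal(d$pct_endorsed, c(0.13, 37.50))
  expect_equal(d$n_endorsed + d$n_not_endorsed, c(800L, 800L))

  all0 <- matrix(0L, 5, 1, dimnames = list(NULL, "z"))
  expect_equal(descriptive_table(all0)$pct_endorsed, 0)
  expect_error(descriptive_table(matrix(integer(), 0, 0)), "empty")
})

test_that("responses round-trip through raw labels and a codebook", {
  cb <- item_codebook(c("A", "K", "S"),
                      community = c("knowledge", "knowledge", "stigma"),
                      response_type = c("yes_no", "know_dontknow", "likert4"),
                      key = c("negative", "positive", "positive"))
  set.seed(11)
  V <- matrix(rbinom(30, 1, 0.5), 10, 3, dimnames = list(NULL, cb$item_id))
  X <- response_matrix(V, check_variance = FALSE)
  path <- tempfile(fileext = ".csv")
  write_responses(X, path, codebook = cb)
  back <- load_responses(path, cb)
  expect_equal(back$values, X$values)
})
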