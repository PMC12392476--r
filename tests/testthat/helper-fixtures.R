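# Six-transaction toy set used throughout the miner tests; small enough
# that every itemset support was counted by hand:
#   T1 {A,B,D}  T2 {A,B,D}  T3 {A,D}  T4 {B}  T5 {D}  T6 {A,B,D}
toy_tset <- function() {
  transaction_set(list(
    c("A", "B", "D"), c("A", "B", "D"), c("A", "D"),
    "B", "D", c("A", "B", "D")
  ))
}

# random binary transaction set over single-letter items; the target item
# "A" is guaranteed to occur at least once
random_tset <- function(n_items, n_trans) {
  p <- stats::runif(n_items, 0.1, 0.7)
  m <- matrix(stats::rbinom(n_trans * n_items, 1L, rep(p, each = n_trans)),
              nrow = n_trans)
  if (sum(m[, 1]) == 0) m[1, 1] <- 1L
  items <- LETTERS[seq_len(n_items)]
  transaction_set(lapply(seq_len(n_trans), function(i) items[m[i, ] == 1L]))
}

# random small binary cohort (for io round-trip / counting properties)
random_cohort <- function(n = 50, n_vars = 5) {
  d <- as.data.frame(matrix(stats::rbinom(n * n_vars, 1L, 0.4), nrow = n))
  names(d) <- paste0("V", seq_len(n_vars))
  d$Outcome <- stats::rbinom(n, 1L, 0.5)
  cohort(d, outcome = "Outcome")
}

# rule sets are canonically ordered by construction, so equality is
# column-wise comparison of keys and metrics
expect_same_rules <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$lhs_key, b$lhs_key)
  expect_identical(a$rhs, b$rhs)
  expect_equal(a$support, b$support, tolerance = tol)
  expect_equal(a$confidence, b$confidence, tolerance = tol)
  expect_equal(a$lift, b$lift, tolerance = tol)
}

# write a cohort data.frame (possibly with string tokens) to a temp CSV
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
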