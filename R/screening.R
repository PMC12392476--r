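#' Construct a 2x2 exposure-by-outcome table
#'
#' Cell naming follows the exposure(-/+) x outcome(-/+) layout:
#' `c_en` exposure-/outcome-, `c_ep` exposure-/outcome+,
#' `c_pn` exposure+/outcome-, `c_pp` exposure+/outcome+.
#'
#' @param c_en,c_ep,c_pn,c_pp non-negative cell counts.
#' @param exposure,outcome labels.
#' @return an object of class `two_by_two`.
#' @export
two_by_two <- function(c_en, c_ep, c_pn, c_pp,
                       exposure = "exposure", outcome = "outcome") {
  counts <- c(c_en = c_en, c_ep = c_ep, c_pn = c_pn, c_pp = c_pp)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(
    list(c_en = c_en, c_ep = c_ep, c_pn = c_pn, c_pp = c_pp,
         exposure = exposure, outcome = outcome),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- as_matrix_two_by_two(x)
  cat("<two_by_two> ", x$exposure, " x ", x$outcome, "\n", sep = "")
  print(m)
  invisible(x)
}

as_matrix_two_by_two <- function(x) {
  matrix(c(x$c_en, x$c_ep, x$c_pn, x$c_pp), nrow = 2, byrow = TRUE,
         dimnames = list(exposure = c("0", "1"), outcome = c("0", "1")))
}

#' Cross-tabulate a symptom against the outcome
#'
#' @param x a `cohort`.
#' @param exposure name of a binary column.
#' @param outcome name of the outcome column (defaults to the cohort's).
#' @return a [two_by_two()] whose counts partition the cohort.
#' @export
crosstab <- function(x, exposure, outcome = x$outcome) {
  stopifnot(inherits(x, "cohort"))
  for (col in c(exposure, outcome)) {
    if (!col %in% names(x$data)) stop("column '", col, "' not found", call. = FALSE)
    if (col %in% x$continuous) {
      stop("column '", col, "' is continuous, not binary", call. = FALSE)
    }
  }
  e <- x$data[[exposure]]
  o <- x$data[[outcome]]
  two_by_two(
    c_en = sum(e == 0L & o == 0L),
    c_ep = sum(e == 0L & o == 1L),
    c_pn = sum(e == 1L & o == 0L),
    c_pp = sum(e == 1L & o == 1L),
    exposure = exposure, outcome = outcome
  )
}

#' Pearson chi-square test of a 2x2 table
#'
#' Uncorrected Pearson X^2 (no Yates continuity correction) with one degree
#' of freedom. The uncorrected form is what reproduces the printed
#' screening p-values from this family of symptom tables.
#'
#' @param table a `two_by_two`.
#' @return list with `statistic`, `df` (always 1) and `p_value`.
#' @export
chi_square <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  m <- as_matrix_two_by_two(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin: expected counts undefined", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = 1L,
       p_value = unname(res$p.value))
}

#' ROC analysis with Youden-optimal cutoff
#'
#' The AUC is computed by the rank (Mann-Whitney) construction with ties
#' counted one half; its p-value tests AUC = 0.5 via the normal
#' approximation to the rank-sum statistic with tie correction. The cutoff
#' is the midpoint between adjacent distinct score values that maximizes
#' Youden's J = sensitivity + specificity - 1 (smallest such midpoint on
#' ties); a case is classified positive when its score exceeds the cutoff.
#'
#' @param scores numeric per-patient values (e.g. age in years).
#' @param outcome 0/1 per-patient outcome, same length as `scores`.
#' @return list with `auc`, `p_value`, `cutoff`, `sensitivity`,
#'   `specificity`.
#' @export
roc_cutoff <- function(scores, outcome) {
  stopifnot(length(scores) == length(outcome), all(outcome %in% c(0, 1)))
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be non-empty", call. = FALSE)
  if (length(unique(scores)) < 2) {
    stop("constant scores: ROC undefined", call. = FALSE)
  }
  r <- rank(scores)                      # midranks: ties get the average
  rank_sum <- sum(r[outcome == 1])
  u <- rank_sum - n1 * (n1 + 1) / 2      # Mann-Whitney U with ties as 1/2
  auc <- u / (n1 * n0)

  n <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
  z <- (u - n1 * n0 / 2) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))

  vals <- sort(unique(scores))
  cand <- (vals[-length(vals)] + vals[-1]) / 2
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  sens <- vapply(cand, function(ct) mean(pos > ct), numeric(1))
  spec <- vapply(cand, function(ct) mean(neg <= ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # smallest cutoff among ties

  list(auc = auc, p_value = p, cutoff = cand[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Frequency table of cohort variables
#'
#' For every binary variable: count of positives, percent of the cohort,
#' and percent positive within the outcome-positive stratum. Percents are
#' rounded half-up to one decimal, the display convention of descriptive
#' tables.
#'
#' @param x a `cohort`.
#' @return data.frame with columns `variable`, `count`, `percent`,
#'   `pct_within_positive`.
#' @export
frequency_table <- function(x) {
  stopifnot(inherits(x, "cohort"))
  cols <- setdiff(names(x$data), x$continuous)
  n <- nrow(x$data)
  pos <- x$data[[x$outcome]] == 1L
  n_pos <- sum(pos)
  count <- vapply(cols, function(col) sum(x$data[[col]]), integer(1))
  within <- vapply(cols, function(col) sum(x$data[[col]][pos]), integer(1))
  data.frame(
    variable = cols,
    count = unname(count),
    percent = round_half_up(100 * unname(count) / n, 1),
    pct_within_positive = if (n_pos > 0) {
      round_half_up(100 * unname(within) / n_pos, 1)
    } else rep(0, length(cols)),
    row.names = NULL
  )
}

#' Compare a continuous variable between outcome groups
#'
#' Two-sample pooled-variance t-test (the groups in the motivating cohort
#' report equal standard deviations, so the equal-variance form is used).
#'
#' @param values numeric per-patient values.
#' @param outcome 0/1 per-patient outcome.
#' @return list with per-group means and sds, `t`, `df` and `p_value`.
#' @export
compare_group_means <- function(values, outcome) {
  stopifnot(length(values) == length(outcome), all(outcome %in% c(0, 1)))
  g1 <- values[outcome == 1]
  g0 <- values[outcome == 0]
  if (length(g1) < 2 || length(g0) < 2) {
    stop("each outcome group needs at least 2 observations", call. = FALSE)
  }
  sp2 <- ((length(g1) - 1) * stats::var(g1) + (length(g0) - 1) * stats::var(g0)) /
    (length(g1) + length(g0) - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero", call. = FALSE)
  res <- stats::t.test(g1, g0, var.equal = TRUE)
  list(
    mean_positive = mean(g1), mean_negative = mean(g0),
    sd_positive = stats::sd(g1), sd_negative = stats::sd(g0),
    t = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value
  )
}

#' Screen every symptom against the outcome
#'
#' Builds the 2x2 table and uncorrected chi-square test for each binary
#' variable other than the outcome itself.
#'
#' @param x a `cohort`.
#' @return data.frame with one row per symptom: the four cell counts,
#'   `statistic` and `p_value`.
#' @export
screen_symptoms <- function(x) {
  stopifnot(inherits(x, "cohort"))
  cols <- setdiff(names(x$data), c(x$outcome, x$continuous))
  rows <- lapply(cols, function(col) {
    tab <- crosstab(x, col)
    chi <- chi_square(tab)
    data.frame(variable = col, c_en = tab$c_en, c_ep = tab$c_ep,
               c_pn = tab$c_pn, c_pp = tab$c_pp,
               statistic = chi$statistic, p_value = chi$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
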