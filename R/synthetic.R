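# Published 2x2 margins of the 16 symptoms against the diabetes outcome:
# counts are (exposure-/outcome-, exposure-/outcome+, exposure+/outcome-,
# exposure+/outcome+) over 520 patients (200 outcome-negative, 320
# outcome-positive).
table2_counts <- function() {
  m <- rbind(
    Gender               = c(181, 147, 19, 173),
    Polyuria             = c(185,  77, 15, 243),
    Polydipsia           = c(192,  95,  8, 225),
    sudden.weight.loss   = c(171, 132, 29, 188),
    weakness             = c(113, 102, 87, 218),
    Polyphagia           = c(152, 131, 48, 189),
    Genital.thrush       = c(167, 237, 33,  83),
    visual.blurring      = c(142, 145, 58, 175),
    Itching              = c(101, 166, 99, 154),
    Irritability         = c(184, 210, 16, 110),
    delayed.healing      = c(114, 167, 86, 153),
    partial.paresis      = c(168, 128, 32, 192),
    muscle.stiffness     = c(140, 185, 60, 135),
    Alopecia             = c( 99, 242, 101, 78),
    Obesity              = c(173, 259, 27,  61),
    Age                  = c(121, 139, 79, 181)
  )
  colnames(m) <- c("c_en", "c_ep", "c_pn", "c_pp")
  m
}

#' Deterministic fixture cohort embedding the published 2x2 margins
#'
#' A 520-row, 17-column binary cohort: rows 1-320 are outcome-positive,
#' rows 321-520 outcome-negative. For each of the 16 symptoms, exactly its
#' published outcome-positive count of 1s occupies the first rows of the
#' positive block and its outcome-negative count the first rows of the
#' negative block, so every [crosstab()] of a symptom against the outcome
#' reproduces its published counts exactly. Construction is deterministic
#' (no randomness), so the fixture is identical across runs and platforms.
#'
#' Only pairwise symptom-outcome quantities are faithful to the study;
#' joint distributions of three or more symptoms are artifacts of the
#' block construction and must not be read as study results.
#'
#' @return a [cohort()] with outcome column `Diabetes`.
#' @export
table2_fixture <- function() {
  counts <- table2_counts()
  n_pos <- 320L
  n_neg <- 200L
  d <- data.frame(Diabetes = c(rep(1L, n_pos), rep(0L, n_neg)))
  for (sym in rownames(counts)) {
    pos_block <- c(rep(1L, counts[sym, "c_pp"]),
                   rep(0L, n_pos - counts[sym, "c_pp"]))
    neg_block <- c(rep(1L, counts[sym, "c_pn"]),
                   rep(0L, n_neg - counts[sym, "c_pn"]))
    d[[sym]] <- c(pos_block, neg_block)
  }
  cohort(d, outcome = "Diabetes")
}

#' Specification for a synthetic cohort
#'
#' Defines the generative model: outcome prevalence, per-symptom presence
#' probabilities conditional on outcome, optional implications (itemsets
#' forced to imply outcome = 1), a seed and a cohort size. Defaults are the
#' study conditions: 520 patients, prevalence 320/520, and conditional
#' probabilities taken from the published 2x2 margins.
#'
#' @param n cohort size (>= 1).
#' @param prevalence P(outcome = 1), in \[0, 1\].
#' @param cond_probs matrix or data.frame with one row per symptom and
#'   columns `p_pos` = P(symptom = 1 | outcome = 1) and
#'   `p_neg` = P(symptom = 1 | outcome = 0); row names are symptom names.
#' @param implications list of character vectors; wherever all items of a
#'   vector are 1, the outcome is forced to 1 after generation.
#' @param outcome name of the outcome column.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 520,
                           prevalence = 320 / 520,
                           cond_probs = NULL,
                           implications = list(),
                           outcome = "Diabetes",
                           seed = 1L) {
  if (is.null(cond_probs)) {
    counts <- table2_counts()
    cond_probs <- data.frame(
      p_pos = counts[, "c_pp"] / 320,
      p_neg = counts[, "c_pn"] / 200,
      row.names = rownames(counts)
    )
  }
  cond_probs <- as.data.frame(cond_probs)
  stopifnot(n >= 1, all(c("p_pos", "p_neg") %in% names(cond_probs)),
            !is.null(rownames(cond_probs)), is.list(implications))
  probs <- c(prevalence, cond_probs$p_pos, cond_probs$p_neg)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence, cond_probs = cond_probs,
         implications = implications, outcome = outcome,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws the outcome Bernoulli(prevalence), then each symptom independently
#' given the outcome with its conditional probability (the
#' conditional-independence model: only pairwise symptom-outcome structure
#' is specified, so independence given outcome is the maximum-entropy
#' completion). Any configured implication is then enforced by setting the
#' outcome to 1 wherever all its items are present. Uses the Mersenne
#' Twister generator under the spec's seed; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return a [cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  n <- spec$n
  outcome <- stats::rbinom(n, 1L, spec$prevalence)
  d <- stats::setNames(data.frame(outcome), spec$outcome)
  for (sym in rownames(spec$cond_probs)) {
    p <- ifelse(outcome == 1L, spec$cond_probs[sym, "p_pos"],
                spec$cond_probs[sym, "p_neg"])
    d[[sym]] <- stats::rbinom(n, 1L, p)
  }
  out <- cohort(d, outcome = spec$outcome)
  for (imp in spec$implications) {
    out <- plant_implication(out, imp)
  }
  out
}

#' Force an itemset to imply the outcome
#'
#' Sets the outcome to 1 in every row where all the given columns are 1;
#' all other cells are unchanged. Creates a confidence-1 rule structure for
#' that itemset by construction.
#'
#' @param x a `cohort`.
#' @param itemset character vector of column names (bare names or
#'   `"Name=1"` tokens).
#' @return the modified `cohort`.
#' @export
plant_implication <- function(x, itemset) {
  stopifnot(inherits(x, "cohort"))
  cols <- sub("=1$", "", as.character(itemset))
  missing <- setdiff(cols, names(x$data))
  if (length(missing)) {
    stop("unknown column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  hit <- Reduce(`&`, lapply(cols, function(col) x$data[[col]] == 1L))
  x$data[[x$outcome]][hit] <- 1L
  x
}
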