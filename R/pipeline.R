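#' Pipeline configuration
#'
#' @param input path to the cohort CSV.
#' @param outcome name of the outcome column.
#' @param dialect token-to-0/1 mapping for string-coded files.
#' @param min_support,min_confidence,max_order mining thresholds, see
#'   [mining_config()].
#' @param age_cutoff threshold for dichotomizing continuous columns
#'   (strictly-above convention); `NULL` selects the Youden-optimal ROC
#'   cutoff per column.
#' @param out_dir output directory, created if needed.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the input was simulated).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, outcome = "Diabetes", dialect = uci_dialect(),
                       min_support = 0.03, min_confidence = 0.60,
                       max_order = Inf, age_cutoff = 46.5,
                       out_dir = ".", seed = NULL) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)
  structure(
    list(input = input, outcome = outcome, dialect = dialect,
         min_support = min_support, min_confidence = min_confidence,
         max_order = max_order, age_cutoff = age_cutoff,
         out_dir = out_dir, seed = seed),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Read and validate the cohort, dichotomize any continuous column, screen
#' every symptom against the outcome (frequency and 2x2/chi-square
#' reports), convert to transactions, mine outcome-targeted rules, and
#' write order-stratified sorted rule tables. All artifacts are computed
#' before anything is written, so a failing stage leaves no partial
#' output. Identical configurations produce byte-identical files.
#'
#' Artifacts written to `out_dir`: `frequency.tsv`, `screening.tsv`,
#' `rules_order<k>.tsv` (one per order), `rules.json` (all orders, raw and
#' rounded metrics) and `manifest.json` (input, thresholds, seed,
#' versions).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the cohort, screening tables, rule set
#'   and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  coh <- stage("read", read_cohort(config$input, outcome = config$outcome,
                                   dialect = config$dialect))
  roc <- list()
  for (col in coh$continuous) {
    r <- stage("roc", roc_cutoff(coh$data[[col]], coh$data[[coh$outcome]]))
    roc[[col]] <- r
    cut <- config$age_cutoff %||% r$cutoff
    coh <- stage("dichotomize", dichotomize(coh, col, cut))
  }
  freq <- stage("screen", frequency_table(coh))
  screen <- stage("screen", screen_symptoms(coh))
  tset <- stage("transactions", to_transactions(coh))
  cfg <- mining_config(min_support = config$min_support,
                       min_confidence = config$min_confidence,
                       target = paste0(config$outcome, "=1"),
                       max_order = config$max_order)
  rules <- stage("mine", mine_rules(tset, cfg))
  tables <- lapply(stratify_rules(rules), sort_rules)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths <- character(0)
  p <- file.path(config$out_dir, "frequency.tsv")
  fmt_tsv(freq, p); paths <- c(paths, p)
  p <- file.path(config$out_dir, "screening.tsv")
  fmt_tsv(screen, p); paths <- c(paths, p)
  for (k in names(tables)) {
    p <- file.path(config$out_dir, paste0("rules_order", k, ".tsv"))
    writeLines(sub("\n$", "", render_rules_table(tables[[k]], "tsv")), p)
    paths <- c(paths, p)
  }
  p <- file.path(config$out_dir, "rules.json")
  rules_json <- lapply(tables, function(tab) {
    jsonlite::fromJSON(render_rules_table(tab, "json"),
                       simplifyVector = FALSE)
  })
  jsonlite::write_json(rules_json, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  p <- file.path(config$out_dir, "manifest.json")
  manifest <- list(
    input = config$input, outcome = config$outcome,
    min_support = config$min_support,
    min_confidence = config$min_confidence,
    max_order = if (is.finite(config$max_order)) config$max_order else "all",
    age_cutoff = config$age_cutoff, seed = config$seed,
    roc = lapply(roc, function(r) r[c("auc", "p_value", "cutoff")]),
    n_patients = n_patients(coh), n_rules = nrow(rules),
    package_version = as.character(utils::packageVersion("symrules")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)

  invisible(list(cohort = coh, frequency = freq, screening = screen,
                 roc = roc, rules = rules, tables = tables, paths = paths))
}
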