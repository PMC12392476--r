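#' Stratify rules by order
#'
#' Partitions a rule set into per-order tables (order 2 = single-symptom
#' antecedents, order 3 = pairs, and so on), the layout used to report
#' binary, triple and higher associations.
#'
#' @param rules a `rule_set`.
#' @return named list mapping order (as character) to a `rule_table`: a
#'   `rule_set` carrying an `order` attribute.
#' @export
stratify_rules <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  if (nrow(rules) == 0) return(stats::setNames(list(), character(0)))
  orders <- sort(unique(rules$order))
  out <- lapply(orders, function(k) {
    tab <- rules[rules$order == k, , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "order") <- k
    class(tab) <- c("rule_table", class(rules))
    tab
  })
  stats::setNames(out, as.character(orders))
}

#' Sort a rule table
#'
#' Descending by raw support, ties broken by descending raw confidence,
#' then descending raw lift, then lexicographic antecedent. The sort is
#' stable and uses raw (unrounded) metrics, so display rounding never
#' affects row order.
#'
#' @param table a `rule_table` or `rule_set`.
#' @return the table, reordered.
#' @export
sort_rules <- function(table) {
  stopifnot(inherits(table, "rule_set"))
  ord <- order(-table$support, -table$confidence, -table$lift, table$lhs_key)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a rule table as text
#'
#' TSV output prints LHS, RHS, supp, conf and lift with metrics rounded
#' half-up to 2 decimals (the display convention of the published rule
#' tables); JSON output additionally carries the raw values.
#'
#' @param table a `rule_table` or `rule_set`.
#' @param format `"tsv"` or `"json"`.
#' @return a single character string.
#' @export
render_rules_table <- function(table, format = c("tsv", "json")) {
  stopifnot(inherits(table, "rule_set"))
  format <- match.arg(format)
  lhs_txt <- vapply(table$lhs, function(s) {
    paste0("{", paste(s, collapse = ","), "}")
  }, character(1))
  rhs_txt <- paste0("{", table$rhs, "}")
  supp <- round_half_up(table$support, 2)
  conf <- round_half_up(table$confidence, 2)
  lift <- round_half_up(table$lift, 2)
  if (format == "tsv") {
    header <- "LHS\tRHS\tsupp\tconf\tlift"
    if (nrow(table) == 0) return(paste0(header, "\n"))
    rows <- paste(lhs_txt, rhs_txt, sprintf("%.2f", supp),
                  sprintf("%.2f", conf), sprintf("%.2f", lift), sep = "\t")
    paste0(paste(c(header, rows), collapse = "\n"), "\n")
  } else {
    doc <- data.frame(
      lhs = I(unclass(table$lhs)), rhs = table$rhs, order = table$order,
      supp = supp, conf = conf, lift = lift,
      support_raw = table$support, confidence_raw = table$confidence,
      lift_raw = table$lift
    )
    as.character(jsonlite::toJSON(doc, auto_unbox = FALSE, digits = NA,
                                  pretty = TRUE))
  }
}
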