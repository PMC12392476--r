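#' Mining configuration
#'
#' Thresholds and target for outcome-directed rule mining. The defaults are
#' the analysis settings of the motivating study: minimum support 3%,
#' minimum confidence 60%, consequent fixed to the diabetes-positive item.
#'
#' @param min_support minimum rule support as a fraction in (0, 1].
#' @param min_confidence minimum rule confidence as a fraction in (0, 1].
#' @param target the consequent item token, e.g. `"Diabetes=1"`.
#' @param max_order largest rule order (|LHS| + 1) to emit; `Inf` for all.
#' @return an object of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.03, min_confidence = 0.60,
                          target = "Diabetes=1", max_order = Inf) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1,
            max_order >= 2)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 target = target, max_order = max_order),
            class = "mining_config")
}

#' Support of an itemset
#'
#' Fraction of transactions containing every item of the set. The empty
#' set is contained in every transaction, so its support is 1.
#'
#' @param items character vector of item tokens.
#' @param tset a `transaction_set`.
#' @return support fraction in \[0, 1\].
#' @export
itemset_support <- function(items, tset) {
  stopifnot(inherits(tset, "transaction_set"), tset$n > 0)
  items <- unique(as.character(items))
  if (length(items) == 0) return(1)
  if (!all(items %in% tset$item_universe)) return(0)
  hits <- vapply(tset$items, function(t) all(items %in% t), logical(1))
  sum(hits) / tset$n
}

#' Level-wise Apriori frequent-itemset mining
#'
#' Size-1 itemsets are filtered by support; size-k candidates are built by
#' joining size-(k-1) frequent sets that share a (k-2)-prefix under the
#' canonical item order, pruned when any (k-1)-subset is infrequent, then
#' support-counted and filtered. Support can only fall as items are added
#' (anti-monotonicity), which is what makes the prune exact.
#'
#' @param tset a `transaction_set` with at least one transaction.
#' @param min_support minimum support fraction, > 0.
#' @param max_size largest itemset size to enumerate.
#' @return data.frame of class `frequent_itemsets` with list-column
#'   `items`, integer `size` and numeric `support`; contains exactly the
#'   itemsets with support >= `min_support` and size <= `max_size`.
#' @export
frequent_itemsets <- function(tset, min_support, max_size = Inf) {
  stopifnot(inherits(tset, "transaction_set"))
  if (tset$n == 0) stop("empty transaction set", call. = FALSE)
  stopifnot(min_support > 0, min_support <= 1, max_size >= 1)

  inc <- incidence_matrix(tset)
  n <- tset$n
  support_of <- function(items) {
    if (length(items) == 1L) return(sum(inc[, items]) / n)
    sum(rowSums(inc[, items, drop = FALSE]) == length(items)) / n
  }

  # level 1
  supp1 <- colSums(inc) / n
  keep <- supp1 >= min_support
  level <- lapply(names(supp1)[keep], identity)
  supports <- unname(supp1[keep])
  ord <- order(vapply(level, itemset_key, character(1)), method = "radix")
  level <- level[ord]; supports <- supports[ord]

  all_items <- level
  all_supp <- supports
  all_size <- rep(1L, length(level))
  freq_keys <- vapply(level, itemset_key, character(1))

  k <- 2L
  while (length(level) >= 2 && k <= max_size) {
    keys <- vapply(level, itemset_key, character(1))
    # prefix join: pairs sharing the first k-2 items under canonical order
    prefixes <- vapply(level, function(s) itemset_key(s[-length(s)]), character(1))
    cand <- list()
    for (grp in split(seq_along(level), prefixes)) {
      if (length(grp) < 2) next
      for (ai in seq_len(length(grp) - 1)) {
        for (bi in seq((ai + 1), length(grp))) {
          a <- level[[grp[ai]]]; b <- level[[grp[bi]]]
          cand[[length(cand) + 1L]] <- sort_items(union(a, b))
        }
      }
    }
    if (length(cand) == 0) break
    # subset prune: every (k-1)-subset must itself be frequent
    pruned <- Filter(function(s) {
      subs <- vapply(seq_along(s), function(i) itemset_key(s[-i]), character(1))
      all(subs %in% freq_keys)
    }, cand)
    if (length(pruned) == 0) break
    supp <- vapply(pruned, support_of, numeric(1))
    keep <- supp >= min_support
    level <- pruned[keep]
    supports <- supp[keep]
    if (length(level) == 0) break
    ord <- order(vapply(level, itemset_key, character(1)), method = "radix")
    level <- level[ord]; supports <- supports[ord]
    all_items <- c(all_items, level)
    all_supp <- c(all_supp, supports)
    all_size <- c(all_size, rep(k, length(level)))
    freq_keys <- c(freq_keys, vapply(level, itemset_key, character(1)))
    k <- k + 1L
  }

  out <- data.frame(size = as.integer(all_size), support = all_supp)
  out$items <- all_items
  out$key <- vapply(all_items, itemset_key, character(1))
  class(out) <- c("frequent_itemsets", "data.frame")
  out
}

# internal rule-set constructor; canonical deterministic row order
new_rule_set <- function(lhs, rhs, support, confidence, lift) {
  out <- data.frame(
    rhs = as.character(rhs),
    order = vapply(lhs, length, integer(1)) + 1L,
    support = as.numeric(support),
    confidence = as.numeric(confidence),
    lift = as.numeric(lift),
    stringsAsFactors = FALSE
  )
  out$lhs <- lapply(lhs, sort_items)
  out$lhs_key <- vapply(out$lhs, itemset_key, character(1))
  ord <- order(out$order, out$lhs_key, method = "radix")
  out <- out[ord, c("lhs", "rhs", "order", "support", "confidence", "lift",
                    "lhs_key")]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Generate outcome-targeted association rules
#'
#' One candidate rule per frequent itemset containing the target item,
#' with the rest of the itemset as antecedent. Rule support is the support
#' of antecedent and consequent jointly; confidence is that support divided
#' by the antecedent's support; lift is confidence divided by the
#' consequent's support. Rules must meet both thresholds; lift is reported
#' but never filtered on (negative associations with lift < 1 are kept).
#'
#' @param frequent a `frequent_itemsets` table from [frequent_itemsets()].
#' @param tset the `transaction_set` the itemsets were mined from.
#' @param config a [mining_config()].
#' @return a `rule_set` data.frame with list-column `lhs` and columns
#'   `rhs`, `order`, `support`, `confidence`, `lift` (raw values; use
#'   [render_rules_table()] for the 2-decimal display form).
#' @export
generate_rules <- function(frequent, tset, config = mining_config()) {
  stopifnot(inherits(frequent, "frequent_itemsets"),
            inherits(tset, "transaction_set"),
            inherits(config, "mining_config"))
  target <- config$target
  if (!target %in% tset$item_universe) {
    stop("target item '", target, "' absent from every transaction",
         call. = FALSE)
  }
  supp_target <- itemset_support(target, tset)
  supp_by_key <- stats::setNames(frequent$support, frequent$key)

  has_target <- vapply(frequent$items, function(s) target %in% s, logical(1))
  cand <- frequent[has_target & frequent$size >= 2 &
                     frequent$size <= config$max_order, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(new_rule_set(list(), character(0), numeric(0), numeric(0),
                        numeric(0)))
  }
  lhs <- lapply(cand$items, function(s) sort_items(setdiff(s, target)))
  lhs_supp <- unname(supp_by_key[vapply(lhs, itemset_key, character(1))])
  conf <- cand$support / lhs_supp
  keep <- conf >= config$min_confidence   # support filter already applied
  new_rule_set(lhs[keep], rep(target, sum(keep)), cand$support[keep],
               conf[keep], conf[keep] / supp_target)
}

#' Mine outcome-targeted rules in one call
#'
#' Convenience wrapper: [frequent_itemsets()] followed by
#' [generate_rules()].
#'
#' @inheritParams generate_rules
#' @param tset a `transaction_set`.
#' @return a `rule_set`.
#' @export
mine_rules <- function(tset, config = mining_config()) {
  freq <- frequent_itemsets(tset, min_support = config$min_support,
                            max_size = config$max_order)
  generate_rules(freq, tset, config)
}

#' Rule metrics from a 2x2 table
#'
#' Closed-form support, confidence and lift of the single-antecedent rule
#' exposure=1 -> outcome=1 computed directly from contingency counts.
#'
#' @param table a `two_by_two`.
#' @return list with `support`, `confidence`, `lift` (raw values).
#' @export
rule_metrics_from_counts <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  n <- table$c_en + table$c_ep + table$c_pn + table$c_pp
  exp_pos <- table$c_pn + table$c_pp
  out_pos <- table$c_ep + table$c_pp
  if (exp_pos == 0) stop("zero exposure-positive margin: confidence undefined",
                         call. = FALSE)
  if (out_pos == 0) stop("zero outcome-positive margin: lift undefined",
                         call. = FALSE)
  # evaluated as ratios of support fractions (not count ratios) so the
  # result is bit-identical to the transaction-counting mining path
  supp_union <- table$c_pp / n
  confidence <- supp_union / (exp_pos / n)
  list(support = supp_union,
       confidence = confidence,
       lift = confidence / (out_pos / n))
}

#' Brute-force rule enumeration (testing oracle)
#'
#' Enumerates every antecedent subset of the item universe (target
#' excluded), computes support, confidence and lift directly by scanning
#' transactions, and filters by the thresholds. Exponential in the item
#' count, so it refuses universes larger than 15 items; its output is
#' set-equal to the Apriori path by construction and serves as the
#' independent oracle in tests.
#'
#' @inheritParams generate_rules
#' @param tset a `transaction_set` over at most 15 items.
#' @return a `rule_set` in the same canonical order as [generate_rules()].
#' @export
brute_force_rules <- function(tset, config = mining_config()) {
  stopifnot(inherits(tset, "transaction_set"),
            inherits(config, "mining_config"))
  if (length(tset$item_universe) > 15) {
    stop("item universe too large for exhaustive enumeration (> 15 items)",
         call. = FALSE)
  }
  target <- config$target
  if (!target %in% tset$item_universe) {
    stop("target item '", target, "' absent from every transaction",
         call. = FALSE)
  }
  inc <- incidence_matrix(tset)
  n <- tset$n
  count_of <- function(items) {
    sum(rowSums(inc[, items, drop = FALSE]) == length(items))
  }
  supp_target <- count_of(target) / n
  others <- sort_items(setdiff(tset$item_universe, target))
  max_lhs <- min(length(others), config$max_order - 1)

  lhs <- list(); supp <- conf <- numeric(0)
  for (k in seq_len(max_lhs)) {
    sets <- utils::combn(others, k, simplify = FALSE)
    for (s in sets) {
      s_union <- count_of(c(s, target)) / n
      if (s_union < config$min_support) next
      s_lhs <- count_of(s) / n
      cf <- s_union / s_lhs
      if (cf < config$min_confidence) next
      lhs[[length(lhs) + 1L]] <- s
      supp <- c(supp, s_union)
      conf <- c(conf, cf)
    }
  }
  new_rule_set(lhs, rep(target, length(lhs)), supp, conf, conf / supp_target)
}
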