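test_that("itemset_support counts containing transactions", {
  ts <- toy_tset()
  expect_equal(itemset_support(c("A", "B"), ts), 0.5)
  expect_equal(itemset_support(character(0), ts), 1)
  expect_equal(itemset_support("Z", ts), 0)

  fx_ts <- to_transactions(table2_fixture())
  expect_equal(itemset_support(c("Polyuria=1", "Diabetes=1"), fx_ts),
               243 / 520)
})

test_that("frequent_itemsets enumerates exactly the frequent sets", {
  ts <- toy_tset()
  fr <- frequent_itemsets(ts, min_support = 0.5, max_size = 3)
  got <- setNames(fr$support, fr$key)
  want <- c(A = 4 / 6, B = 4 / 6, D = 5 / 6,
            "A\x1fB" = 3 / 6, "A\x1fD" = 4 / 6, "B\x1fD" = 3 / 6,
            "A\x1fB\x1fD" = 3 / 6)
  expect_setequal(names(got), names(want))
  expect_equal(got[names(want)], want)

  fr1 <- frequent_itemsets(transaction_set(list(c("A", "B"))), 1)
  expect_setequal(fr1$key, c("A", "B", "A\x1fB"))
  expect_true(all(fr1$support == 1))

  expect_error(frequent_itemsets(transaction_set(list()), 0.1), "empty")

  # max_size truncates enumeration
  fr2 <- frequent_itemsets(ts, 0.5, max_size = 2)
  expect_true(all(fr2$size <= 2))
})

test_that("all 16 fixture symptoms are frequent at 3% support", {
  fx_ts <- to_transactions(table2_fixture())
  fr <- frequent_itemsets(fx_ts, min_support = 0.03, max_size = 1)
  expect_identical(nrow(fr), 17L)  # 16 symptoms + the outcome item
  # the rarest symptom still clears the threshold comfortably
  expect_equal(min(fr$support), 88 / 520)
})

test_that("generate_rules applies both thresholds and scores per formulas", {
  ts <- toy_tset()
  cfg <- mining_config(min_support = 0.3, min_confidence = 0.6, target = "D")
  rules <- generate_rules(frequent_itemsets(ts, 0.3), ts, cfg)
  ab <- rules[rules$lhs_key == "A\x1fB", ]
  expect_identical(nrow(ab), 1L)
  expect_equal(ab$support, 0.5)
  expect_equal(ab$confidence, 1)
  expect_equal(ab$lift, 1.2)
  # {B} -> D has confidence 0.75 and is kept; no empty-antecedent rule
  expect_true("B" %in% rules$lhs_key)
  expect_false("" %in% rules$lhs_key)

  expect_error(
    generate_rules(frequent_itemsets(ts, 0.3), ts,
                   mining_config(target = "Z")),
    "absent"
  )
})

test_that("fixture mining keeps the itching rule and drops alopecia", {
  fx_ts <- to_transactions(table2_fixture())
  rules <- mine_rules(fx_ts, mining_config(max_order = 2))
  itch <- rules[rules$lhs_key == "Itching=1", ]
  expect_identical(nrow(itch), 1L)
  expect_equal(itch$confidence, 154 / 253)
  expect_equal(itch$lift, (154 / 253) / (320 / 520))
  # alopecia confidence 78/179 sits below the 60% floor
  expect_false("Alopecia=1" %in% rules$lhs_key)
})

test_that("rule metrics from 2x2 counts follow the closed forms", {
  m <- rule_metrics_from_counts(two_by_two(192, 95, 8, 225))
  expect_equal(m$support, 225 / 520)
  expect_equal(m$confidence, 225 / 233)
  m <- rule_metrics_from_counts(two_by_two(181, 147, 19, 173))
  expect_equal(m$lift, (173 / 192) * 520 / 320)
  m <- rule_metrics_from_counts(two_by_two(0, 0, 0, 7))
  expect_equal(unlist(m), c(support = 1, confidence = 1, lift = 1))
  expect_error(rule_metrics_from_counts(two_by_two(5, 5, 0, 0)),
               "exposure-positive")
})

test_that("brute-force oracle agrees with Apriori on the toy set", {
  ts <- toy_tset()
  cfg <- mining_config(min_support = 0.3, min_confidence = 0.6, target = "D")
  expect_same_rules(mine_rules(ts, cfg), brute_force_rules(ts, cfg))

  # threshold above every observed support: both paths empty
  hi <- mining_config(min_support = 0.99, min_confidence = 0.6, target = "D")
  expect_identical(nrow(mine_rules(ts, hi)), 0L)
  expect_identical(nrow(brute_force_rules(ts, hi)), 0L)

  big <- transaction_set(list(paste0("I", 1:16)))
  expect_error(brute_force_rules(big, mining_config(target = "I1")),
               "too large")
})

test_that("oracle equivalence holds on random transaction sets", {
  set.seed(505)
  for (rep in 1:25) {
    ts <- random_tset(sample(3:10, 1), sample(20:120, 1))
    cfg <- mining_config(min_support = stats::runif(1, 0.05, 0.3),
                         min_confidence = stats::runif(1, 0.3, 0.9),
                         target = "A")
    expect_same_rules(mine_rules(ts, cfg), brute_force_rules(ts, cfg))
  }
})

test_that("support is anti-monotone under itemset growth", {
  set.seed(606)
  for (rep in 1:10) {
    ts <- random_tset(8, 80)
    u <- ts$item_universe
    for (draw in 1:10) {
      s <- sample(u, sample(1:4, 1))
      extra <- setdiff(u, s)
      if (length(extra) == 0) next
      s_big <- c(s, sample(extra, 1))
      expect_lte(itemset_support(s_big, ts), itemset_support(s, ts))
    }
  }
})

test_that("emitted rules satisfy the metric identities", {
  set.seed(707)
  for (rep in 1:8) {
    ts <- random_tset(sample(4:9, 1), sample(30:100, 1))
    cfg <- mining_config(min_support = 0.05, min_confidence = 0.3,
                         target = "A")
    rules <- mine_rules(ts, cfg)
    if (nrow(rules) == 0) next
    supp_rhs <- itemset_support("A", ts)
    expect_true(all(rules$support <= rules$confidence + 1e-15))
    expect_true(all(rules$confidence <= 1 + 1e-15))
    expect_equal(rules$lift * supp_rhs, rules$confidence, tolerance = 1e-12)
    # confidence-1 rules hit the lift ceiling 1/supp(rhs)
    certain <- rules$confidence == 1
    if (any(certain)) {
      expect_equal(rules$lift[certain],
                   rep(1 / supp_rhs, sum(certain)), tolerance = 1e-12)
    }
  }
})

test_that("adding an antecedent item never increases rule support", {
  ts <- to_transactions(table2_fixture())
  cfg <- mining_config(max_order = 3)
  rules <- mine_rules(ts, cfg)
  r2 <- rules[rules$order == 2, ]
  r3 <- rules[rules$order == 3, ]
  for (i in seq_len(nrow(r3))) {
    for (item in r3$lhs[[i]]) {
      parent <- r2[r2$lhs_key == item, ]
      if (nrow(parent) == 1) {
        expect_lte(r3$support[i], parent$support)
      }
    }
  }
})
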