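test_that("LIC is the ratio of extended to base lift", {
  # the worked ratio behind the printed 1.26: 1.76 / 1.40
  v <- lic(list(lhs = c("Speeding", "Limit speed > 80 km/h",
                        "Dr: fatigue/impaired"),
                rhs = "Lanes num > 2", lift = 1.76),
           list(lhs = c("Speeding", "Limit speed > 80 km/h"),
                rhs = "Lanes num > 2", lift = 1.40))
  expect_equal(v, 1.76 / 1.40)
  expect_equal(round(v, 2), 1.26)
  expect_equal(lic(list(lhs = c("A", "B"), rhs = "Y", lift = 2),
                   list(lhs = "A", rhs = "Y", lift = 2)), 1.0)
  expect_equal(lic(list(lhs = c("A", "B"), rhs = "Y", lift = 2.2),
                   list(lhs = "A", rhs = "Y", lift = 2.0)), 1.10)
})

test_that("LIC rejects non-nested rules and zero base lifts", {
  ext <- list(lhs = c("A", "B"), rhs = "Y", lift = 2)
  expect_error(lic(ext, list(lhs = "C", rhs = "Y", lift = 2)), "base antecedent")
  expect_error(lic(ext, list(lhs = "A", rhs = "Z", lift = 2)), "consequent")
  expect_error(lic(ext, list(lhs = "A", rhs = "Y", lift = 0)), "zero base lift")
})

test_that("LIC filter keeps genuine lift increases and prunes flat extensions", {
  # deterministic 20-record fixture:
  # {A,B} -> Y has a strictly higher lift than both A -> Y and B -> Y
  m <- cbind(
    A = c(rep(1, 10), rep(0, 10)),
    B = c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5)),
    Y = c(rep(1, 5), 1, 1, 0, 0, 0, 1, 1, 0, 0, 0, rep(0, 5)))
  tab <- transaction_table(m)
  rules <- rule_df(lhs = c("A;B", "A", "B"), rhs = "Y")
  for (i in 1:3) {
    met <- rule_metrics(tab, strsplit(rules$lhs[i], ";")[[1]], "Y")
    rules$support[i] <- met["support"]
    rules$confidence[i] <- met["confidence"]
    rules$lift[i] <- met["lift"]
  }
  expect_gt(rules$lift[1] / rules$lift[2], 1.03)
  out <- lic_filter(rules, tab, min_lic = 1.03)
  expect_true(out$kept[1])
  expect_equal(out$lic[1],
               min(rules$lift[1] / rules$lift[2], rules$lift[1] / rules$lift[3]))
  # single-antecedent rules pass vacuously with lic absent
  expect_true(all(out$kept[2:3]))
  expect_true(all(is.na(out$lic[2:3])))
})

test_that("LIC filter recomputes base lifts missing from the candidate list", {
  set.seed(8)
  tab <- random_table(200, 5, 0.5)
  full <- mine_rules(tab, mining_config(0.02, 0.1, 0))
  two <- full[nchar(gsub("[^;]", "", full$lhs)) == 1, ][1:3, ]  # 2-item lhs only
  out <- lic_filter(two, tab, min_lic = 1.03)
  for (i in seq_len(nrow(two))) {
    lhs <- strsplit(two$lhs[i], ";")[[1]]
    expected <- min(vapply(seq_along(lhs), function(j)
      two$lift[i] / rule_metrics(tab, lhs[-j], two$rhs[i])["lift"], 0))
    expect_equal(out$lic[i], expected)
  }
})

test_that("rules with LIC exactly 1 are rejected as redundant", {
  tab <- tt(A = rep(c(1, 0), 10), B = rep(1, 20),
            Y = rep(c(1, 0), 10))
  # B is always true so adding it cannot change the lift: LIC = 1
  rules <- rule_df(lhs = c("A", "A;B"), rhs = "Y")
  for (i in 1:2) {
    met <- rule_metrics(tab, strsplit(rules$lhs[i], ";")[[1]], "Y")
    rules$lift[i] <- met["lift"]
  }
  out <- lic_filter(rules, tab, min_lic = 1.03)
  expect_false(out$kept[2])
  expect_equal(out$rejection_reason[2], "lic")
})

test_that("fisher_p equals the exhaustive fixed-margins enumeration oracle", {
  expect_equal(fisher_p_counts(8, 2, 1, 9), oracle_fisher(8, 2, 1, 9))
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:60, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    expect_equal(fisher_p_counts(a, b, c, d), oracle_fisher(a, b, c, d),
                 tolerance = 1e-12)
  }
})

test_that("fisher_p agrees with stats::fisher.test one-sided", {
  set.seed(12)
  for (rep in 1:25) {
    cnt <- as.vector(stats::rmultinom(1, 40, c(0.3, 0.2, 0.2, 0.3)))
    ours <- fisher_p_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    ft <- stats::fisher.test(matrix(cnt, 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(ours, ft, tolerance = 1e-10)
  }
})

test_that("fisher_p handles degenerate margins and monotone-extreme tables", {
  expect_equal(fisher_p_counts(0, 0, 5, 5), 1)   # empty X row
  expect_equal(fisher_p_counts(5, 5, 0, 0), 1)   # X margin = n
  expect_equal(fisher_p_counts(0, 5, 0, 5), 1)   # empty Y column
  # all 30 X records are Y records, Y rare otherwise: overwhelming association
  expect_lt(fisher_p_counts(30, 0, 5, 65), 1e-6)
})

test_that("fisher p-values are near-uniform under independence", {
  set.seed(31)
  ps <- replicate(400, {
    x <- runif(120) < 0.5
    y <- runif(120) < 0.4
    fisher_p_counts(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  })
  # discrete conservative test: one-sided p stochastically >= uniform
  expect_lt(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps), 0.45)
})

test_that("Bonferroni thresholds follow alpha / m", {
  tab <- toy_ab()
  one <- rule_df("A", "B")
  one$kept <- TRUE; one$rejection_reason <- "none"
  out1 <- significance_filter(one, tab, alpha = 0.01)
  expect_equal(out1$p_value[1], fisher_p(tab, "A", "B"))
  # m = 1: threshold is exactly alpha

  # direct arithmetic at m = 100: p = 2e-4 rejected, p = 5e-5 kept
  m_tests <- 100
  expect_false(2e-4 < 0.01 / m_tests)
  expect_true(5e-5 < 0.01 / m_tests)
})

test_that("the significance stage rejects non-significant rules with reason", {
  set.seed(41)
  tab <- generate_independent(
    generator_config(300, setNames(rep(0.4, 6), LETTERS[1:6]), seed = 41))
  rules <- mine_rules(tab, mining_config(0.05, 0.2, 0))
  rules <- lic_filter(rules, tab, min_lic = 0.0001)  # let everything through
  out <- significance_filter(rules, tab, alpha = 0.01)
  rej <- out$rejection_reason == "significance"
  expect_true(any(rej))   # independent data: essentially nothing survives
  expect_true(all(!out$kept[rej]))
  expect_error(significance_filter(out[!out$kept, ], tab), "no rules enter")
})

test_that("meaningfulness blacklist rejects tautological category pairs only", {
  cat10 <- toy_catalog()
  rules <- rule_df(lhs = c("TimeEarly", "Speeding"),
                   rhs = c("NightNoLight", "NarrowLanes"))
  rules$kept <- TRUE; rules$rejection_reason <- "none"
  bl <- list(list(lhs = "Time", rhs = "Light"))
  out <- meaningfulness_filter(rules, blacklist = bl, catalog = cat10)
  expect_false(out$kept[1])
  expect_equal(out$rejection_reason[1], "meaningfulness")
  expect_true(out$kept[2])   # Speeding -> NarrowLanes unmatched
  # empty blacklist is the identity
  expect_identical(meaningfulness_filter(rules, blacklist = list()), rules)
})

test_that("default blacklist covers both tautology directions", {
  bl <- default_blacklist()
  pairs <- vapply(bl, function(e) paste(e$lhs, e$rhs, sep = "->"), "")
  expect_setequal(pairs, c("Time->Light", "Light->Time",
                           "Limit speed->Road category",
                           "Road category->Limit speed"))
})

test_that("full filter retains ~nothing on independent data, planted rules survive", {
  # null model
  tab0 <- generate_independent(
    generator_config(2000, setNames(rep(0.35, 8), LETTERS[1:8]), seed = 17))
  cand0 <- mine_rules(tab0, mining_config(0.02, 0.3, 1.05, 2))
  if (nrow(cand0)) {
    f0 <- filter_rules(cand0, tab0, filter_config())
    expect_lte(sum(f0$kept), ceiling(0.02 * nrow(cand0)))
  }
  # one strongly planted rule at n = 5000, lift >= 2
  spec <- planted_rule("A", "Y", 0.3, 0.9, 0.15)
  expect_gte(unname(expected_metrics(spec)["lift"]), 2)
  tab1 <- generate_with_planted_rules(generator_config(
    5000, background_items = c(B = 0.3, C = 0.3), planted = list(spec),
    seed = 18))
  cand1 <- mine_rules(tab1, mining_config(0.05, 0.5, 1.3, 2))
  f1 <- filter_rules(cand1, tab1, filter_config())
  k1 <- kept_rules(f1)
  expect_gt(nrow(k1), 0)
  hit <- k1[k1$lhs == "A" & k1$rhs == "Y", ]
  expect_equal(nrow(hit), 1)
  # only rules touching the planted items survive
  expect_true(all(grepl("A|Y", paste(k1$lhs, k1$rhs))))
})

test_that("filter stages are order-faithful and monotone", {
  set.seed(61)
  spec <- planted_rule(c("A", "B"), "Y", 0.25, 0.85, 0.2)
  tab <- generate_with_planted_rules(generator_config(
    3000, c(A = 0.5, B = 0.5, C = 0.4, D = 0.3), planted = list(spec),
    seed = 61))
  cand <- mine_rules(tab, mining_config(0.03, 0.4, 1.1, 3))
  s1 <- lic_filter(cand, tab, 1.03)
  s2 <- significance_filter(s1, tab, 0.01)
  s3 <- meaningfulness_filter(s2, default_blacklist())
  expect_lte(sum(s2$kept), sum(s1$kept))
  expect_lte(sum(s3$kept), sum(s2$kept))
  # pipeline equals the manual composition
  pipe <- filter_rules(cand, tab, filter_config())
  expect_equal(pipe$kept, s3$kept)
  expect_equal(pipe$rejection_reason, s3$rejection_reason)
  # kept <=> reason "none"
  expect_equal(pipe$kept, pipe$rejection_reason == "none")
})
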