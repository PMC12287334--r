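# The 26 printed expert rules in the canonical 12-slot order
# [pH, OC, EC, N, P, K, Fe, Mn, Zn, B, Cu, S]; the two source tables share
# one rule, so 25 distinct pairs are expected in the default base.
printed_rules <- list(
  list(c(1,0,0,0,0,0,0,0,0,0,0,0), 1), # pH Excessive-Acid
  list(c(0,0,4,0,0,0,0,0,0,0,0,0), 1), # EC Strongly-Saline
  list(c(0,1,0,1,0,0,0,0,0,0,0,0), 1), # OM Low & N Low
  list(c(0,0,0,0,0,0,0,0,1,1,0,0), 1), # Zn Low & B Low
  list(c(2,0,0,0,0,0,0,0,0,0,0,0), 2), # pH Acid
  list(c(0,1,0,0,0,0,0,0,0,0,0,0), 2), # OM Low
  list(c(0,0,2,1,0,0,0,0,0,0,0,0), 2), # EC Slightly & N Low
  list(c(0,0,0,0,1,2,0,0,0,0,0,0), 2), # P Low & K Sufficient
  list(c(3,0,0,0,0,0,0,0,0,0,0,0), 3), # pH Neutral
  list(c(0,2,0,0,0,0,0,0,0,0,0,0), 3), # OM Medium
  list(c(0,0,1,2,0,0,0,0,0,0,0,0), 3), # EC Non-saline & N Sufficient
  list(c(3,2,1,0,0,0,0,0,0,0,0,0), 3), # pH Neutral & OM Medium & EC Non
  list(c(3,3,0,3,0,0,0,0,0,0,0,0), 4), # pH Neutral & OM High & N High
  list(c(0,0,1,0,3,3,0,0,0,0,0,0), 4), # EC Non & P High & K High
  list(c(0,4,1,3,0,3,0,0,0,0,0,0), 4), # OM Very-high & EC Non & N High & K High
  list(c(0,0,0,0,0,0,2,0,3,3,0,0), 4), # Fe Medium & Zn High & B High
  list(c(2,1,0,1,0,0,0,0,0,0,0,0), 2), # pH Low & OC Low & N Low
  list(c(3,0,0,0,1,1,0,0,0,0,0,0), 2), # pH Medium & P Low & K Low
  list(c(4,2,0,2,0,0,0,0,0,0,0,0), 3), # pH High & OC Medium & N Medium
  list(c(0,0,4,0,0,0,0,1,1,0,0,0), 2), # EC High & Zn Low & Mn Low
  list(c(0,3,0,0,0,0,3,0,0,0,2,0), 4), # OC High & Fe High & Cu Medium
  list(c(0,0,0,1,2,3,0,0,0,0,0,0), 3), # N Low & P Medium & K High
  list(c(0,0,0,0,0,0,0,1,0,1,1,0), 2), # B Low & Cu Low & Mn Low
  list(c(0,0,0,0,3,3,0,0,3,0,0,0), 4), # P High & K High & Zn High
  list(c(0,0,2,0,0,0,2,0,0,1,0,0), 3), # EC Medium & Fe Medium & B Low
  list(c(3,3,0,3,0,0,0,0,0,0,0,0), 4)) # pH Medium & OC High & N High (dup)

test_that("the default rule base reproduces every printed rule slot-for-slot", {
  rb <- default_rule_base()
  expect_length(rb$rules, 25)
  keys <- vapply(rb$rules, function(r)
    paste(c(r$antecedent, r$consequent), collapse = ","), character(1))
  for (pr in printed_rules) {
    k <- paste(c(pr[[1]], pr[[2]]), collapse = ",")
    expect_true(k %in% keys, info = k)
  }
  expect_true(all(vapply(rb$rules, function(r) r$weight == 1, logical(1))))
  expect_true(all(vapply(rb$rules, function(r) r$connection == "AND",
                         logical(1))))
})

test_that("vector and clause forms round-trip to identical rules", {
  rb <- default_rule_base()
  clause_file <- withr::local_tempfile(fileext = ".txt")
  writeLines(rules_to_clauses(rb), clause_file)
  rb2 <- parse_rules(clause_file)
  expect_length(rb2$rules, length(rb$rules))
  for (i in seq_along(rb$rules)) {
    expect_identical(rb2$rules[[i]]$antecedent, rb$rules[[i]]$antecedent)
    expect_identical(rb2$rules[[i]]$consequent, rb$rules[[i]]$consequent)
    expect_identical(rb2$rules[[i]]$weight, rb$rules[[i]]$weight)
    expect_identical(rb2$rules[[i]]$connection, rb$rules[[i]]$connection)
  }
})

test_that("clause parsing resolves labels, synonyms and weights", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "IF P is High AND K is High AND Zn is High THEN fertility is High",
    "IF OM is Low AND N is Low THEN fertility is Unproductive",
    "IF pH is Neutral OR OC is Medium THEN fertility is Moderate [0.8]"), f)
  rb <- parse_rules(f)
  expect_identical(rb$rules[[1]]$antecedent,
                   as.integer(c(0,0,0,0,3,3,0,0,3,0,0,0)))
  expect_identical(rb$rules[[1]]$consequent, 4L)
  expect_identical(rb$rules[[2]]$antecedent,
                   as.integer(c(0,1,0,1,0,0,0,0,0,0,0,0)))
  expect_identical(rb$rules[[3]]$connection, "OR")
  expect_identical(rb$rules[[3]]$weight, 0.8)
})

test_that("malformed rule files fail with located errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("IF pH is Sourish THEN fertility is Low", f)
  expect_error(parse_rules(f), "line 1.*Sourish")
  writeLines("IF Moisture is Low THEN fertility is Low", f)
  expect_error(parse_rules(f), "unknown variable")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("antecedent,consequent,weight,connection",
               "1;0;0;0;0;0;0;0;0;0;0;0,7,1,AND"), g)
  expect_error(parse_rules(g), "consequent")
})

test_that("an empty rule file yields an empty base that inference refuses", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  rb <- parse_rules(f)
  expect_length(rb$rules, 0)
  mv <- fuzzify(list(A = 5, B = 5), tiny_vars())
  expect_error(infer(mv, rb), "empty rule base")
})

test_that("duplicate (antecedent, consequent) pairs are rejected", {
  r <- fuzzy_rule(c(1L, 0L), 2L)
  expect_error(tiny_rule_base(list(r, r)), "duplicate")
})

test_that("firing strength applies min/max connectives and the weight", {
  r_and <- fuzzy_rule(c(1L, 2L), 3L, weight = 1, connection = "AND")
  r_or <- fuzzy_rule(c(1L, 2L), 3L, weight = 1, connection = "OR")
  mv <- tiny_mv(0.7, 0, 0, 0.4)
  expect_identical(firing_strength(r_and, mv, c("A", "B")), 0.4)
  mv2 <- tiny_mv(0.2, 0, 0, 0.6)
  expect_identical(firing_strength(r_or, mv2, c("A", "B")), 0.6)
  mv3 <- tiny_mv(1, 0, 0, 1)
  expect_identical(firing_strength(r_and, mv3, c("A", "B")), 1)
  r_w <- fuzzy_rule(c(1L, 2L), 3L, weight = 0.5)
  expect_identical(firing_strength(r_w, mv3, c("A", "B")), 0.5)
  expect_error(
    firing_strength(r_and, structure(list(A = c(Low = 1, High = 0)),
                                     class = "membership_vector"),
                    c("A", "B")), "B")
})

test_that("firing strength never exceeds weight or any AND clause degree", {
  set.seed(21)
  for (i in 1:50) {
    w <- stats::runif(1, 0.1, 1)
    r <- fuzzy_rule(c(1L, 2L), 2L, weight = w)
    a <- stats::runif(1); b <- stats::runif(1)
    s <- firing_strength(r, tiny_mv(a, 0, 0, b), c("A", "B"))
    expect_lte(s, w)
    expect_lte(s, min(a, b) + 1e-15)
  }
})

test_that("the rule-space count is exact integer exponentiation", {
  expect_identical(rule_space_size(3, 12), 531441)
  expect_identical(rule_space_size(1, 7), 1)
  expect_identical(rule_space_size(2, 10), 1024)
  expect_error(rule_space_size(0, 3), "positive")
  expect_error(rule_space_size(2.5, 3), "positive")
})
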