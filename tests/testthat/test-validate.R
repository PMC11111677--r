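vocab <- demo_vocabulary()

test_that("validate_value enforces each validation type", {
  expect_length(validate_value("tissue", "BTO:0000759 liver", vocab), 0L)
  bad <- validate_value("tissue", "kidney", vocab)
  expect_length(bad, 1L)
  expect_identical(bad[[1]]$rule, "off-vocabulary")
  expect_identical(bad[[1]]$severity, "error")

  # multi-select validates per token
  expect_length(validate_value("timepoints", "0 h;24 h", vocab), 0L)
  two_bad <- validate_value("timepoints", "0 h;3 h;99 h", vocab)
  expect_length(two_bad, 2L)

  expect_length(validate_value("date", "15.01.2024", vocab), 0L)
  expect_identical(validate_value("date", "someday", vocab)[[1]]$rule,
                   "invalid-date")

  unk <- validate_value("flux capacitance", "1.21", vocab)
  expect_identical(unk[[1]]$rule, "unknown-key")
  expect_identical(unk[[1]]$severity, "warning")

  empty <- validate_value("tissue", "  ", vocab)
  expect_identical(empty[[1]]$rule, "empty-value")
  expect_identical(empty[[1]]$severity, "warning")
})

test_that("a complete fixture sheet validates clean", {
  fx <- generate_sheet(1)
  report <- validate_sheet(fx$sheet, fx$vocab, fx$registry)
  expect_true(report$ok)
  expect_length(report$issues, 0L)
})

test_that("final groups referencing undeclared instances are flagged", {
  fx <- generate_sheet(2)
  sheet <- fx$sheet
  # drop the first diet instance from planning while final groups still use it
  cg <- sheet$planning$comparison_groups[[1]]
  sheet$planning$comparison_groups[[1]] <-
    comparison_group(cg$category, cg$instances[-1])
  report <- validate_sheet(sheet, fx$vocab, fx$registry)
  expect_false(report$ok)
  rules <- vapply(report$issues, function(i) i$rule, character(1))
  expect_true("undeclared-instance" %in% rules)
})

test_that("downstream sections are blocked by upstream errors with a single issue", {
  fx <- generate_sheet(3)
  sheet <- fx$sheet
  # planning error: off-vocabulary genotype
  sheet$planning$system$dependent_values$genotype <- "mutantish"
  report <- validate_sheet(sheet, fx$vocab, fx$registry)
  expect_false(report$ok)
  rules <- vapply(report$issues, function(i) i$rule, character(1))
  expect_identical(sum(rules == "blocked-by-upstream"), 1L)
  sections <- vapply(report$issues, function(i) i$section, character(1))
  expect_false(any(sections == "matching"))
})

test_that("three division levels are rejected with the two-level limit", {
  fx <- generate_sheet(4, division_levels = 2, instances_per_group = 2,
                       replicates = 1)
  sheet <- fx$sheet
  d <- division_level(1, data.frame(label = "extra", protocol = "p",
                                    n_replicates = 1))
  # bypass the constructor guard to hit the validator's own check
  sheet$conduction$preparation$divisions <-
    c(sheet$conduction$preparation$divisions, list(d))
  report <- validate_sheet(sheet, fx$vocab, fx$registry)
  expect_false(report$ok)
  msgs <- vapply(report$issues, function(i) i$message, character(1))
  expect_true(any(grepl("two levels", msgs)))
})

test_that("injecting k off-vocabulary values yields exactly k such issues", {
  set.seed(404)
  # all slots sit in the Planning section: sequential gating would (by
  # design) suppress downstream findings once an upstream section is broken
  slots <- list(
    function(s) { s$planning$system$dependent_values$genotype <- "zzz"; s },
    function(s) { s$planning$system$dependent_values$tissue <- "zzz"; s },
    function(s) { s$planning$system$dependent_values$sex <- "zzz"; s },
    function(s) {
      cg <- s$planning$comparison_groups[[1]]
      cg$instances[[1]] <- group_instance("zzz", cg$instances[[1]]$details)
      s$planning$comparison_groups[[1]] <-
        comparison_group(cg$category, cg$instances)
      s
    })
  for (rep in 1:8) {
    k <- sample.int(4L, 1)
    fx <- generate_sheet(100 + rep)
    sheet <- fx$sheet
    for (f in sample(slots, k)) sheet <- f(sheet)
    report <- validate_sheet(sheet, fx$vocab, fx$registry)
    expect_rule_count(report, "off-vocabulary", k)
  }
})

test_that("missing dependent keys are completeness errors", {
  fx <- generate_sheet(6)
  sheet <- fx$sheet
  sheet$planning$system$dependent_values[["genotype"]] <- NULL
  report <- validate_sheet(sheet, fx$vocab, fx$registry)
  expect_rule_count(report, "missing-dependent-key", 1)
  expect_false(report$ok)
})

test_that("group vocabularies must restrict the master", {
  master <- vocabulary(list(
    vocab_entry("tissue", "dropdown", "", c("liver", "brain")),
    vocab_entry("weight", "freetext")))
  ok_group <- vocabulary(list(
    vocab_entry("tissue", "dropdown", "", "liver")), group_label = "g")
  expect_true(check_subset(ok_group, master)$ok)

  off <- vocabulary(list(vocab_entry("tissue", "dropdown", "", "kidney")),
                    group_label = "g")
  expect_false(check_subset(off, master)$ok)

  alien <- vocabulary(list(vocab_entry("color", "freetext")),
                      group_label = "g")
  rep_alien <- check_subset(alien, master)
  expect_false(rep_alien$ok)
  expect_identical(rep_alien$issues[[1]]$rule, "subset-unknown-key")

  clash <- vocabulary(list(vocab_entry("weight", "dropdown", "", "1")),
                      group_label = "g")
  expect_identical(check_subset(clash, master)$issues[[1]]$rule,
                   "subset-type-clash")

  # reflexivity: every vocabulary restricts itself
  expect_true(check_subset(master, master)$ok)
  expect_true(check_subset(demo_vocabulary(), demo_vocabulary())$ok)
})

test_that("vocabulary merge unions values, reports type clashes, and is symmetric on sets", {
  a <- vocabulary(list(vocab_entry("tissue", "dropdown", "", "liver"),
                       vocab_entry("weight", "freetext")))
  b <- vocabulary(list(vocab_entry("tissue", "dropdown", "",
                                   c("liver", "brain")),
                       vocab_entry("date", "date")))
  m <- merge_vocabularies(a, b)
  expect_identical(nrow(m$conflicts), 0L)
  expect_setequal(names(m$vocabulary$entries), c("tissue", "weight", "date"))
  expect_identical(m$vocabulary$entries$tissue$allowed_values,
                   c("liver", "brain"))

  # disjoint key sets: plain union
  c1 <- vocabulary(list(vocab_entry("a", "freetext")))
  c2 <- vocabulary(list(vocab_entry("b", "freetext")))
  expect_setequal(names(merge_vocabularies(c1, c2)$vocabulary$entries),
                  c("a", "b"))

  # type clash goes to the conflict report and is omitted from the merge
  d <- vocabulary(list(vocab_entry("weight", "dropdown", "", "1")))
  md <- merge_vocabularies(a, d)
  expect_identical(md$conflicts$key, "weight")
  expect_false("weight" %in% names(md$vocabulary$entries))

  # commutative up to value order; associative on conflict-free inputs
  ab <- merge_vocabularies(a, b)$vocabulary
  ba <- merge_vocabularies(b, a)$vocabulary
  expect_setequal(names(ab$entries), names(ba$entries))
  expect_setequal(ab$entries$tissue$allowed_values,
                  ba$entries$tissue$allowed_values)
  e <- vocabulary(list(vocab_entry("tissue", "dropdown", "", "spleen")))
  left <- merge_vocabularies(merge_vocabularies(a, b)$vocabulary, e)$vocabulary
  right <- merge_vocabularies(a, merge_vocabularies(b, e)$vocabulary)$vocabulary
  expect_setequal(names(left$entries), names(right$entries))
  expect_setequal(left$entries$tissue$allowed_values,
                  right$entries$tissue$allowed_values)
})
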