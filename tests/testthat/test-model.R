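test_that("canonicalize trims, collapses whitespace and is idempotent", {
  expect_identical(canonicalize("  liver "), "liver")
  expect_identical(canonicalize("BTO:0000759  liver"), "BTO:0000759 liver")
  expect_identical(canonicalize("a\t b\n c"), "a b c")
  cases <- c("  liver ", "BTO:0000759 liver", "", "  ", "High-Fat  Diet",
             "x y", "a;b; c")
  for (x in cases) {
    expect_identical(canonicalize(canonicalize(x)), canonicalize(x))
  }
})

test_that("vocabulary matching is case-insensitive on canonical forms and returns canonical spelling", {
  expect_identical(vocab_match("Liver", c("liver", "brain")), "liver")
  expect_identical(vocab_match(" BRAIN ", c("liver", "brain")), "brain")
  expect_identical(vocab_match("kidney", c("liver", "brain")), NA_character_)
})

test_that("model constructors reject invariant violations", {
  violations <- list(
    function() vocab_entry("tissue", "dropdown"),
    function() vocab_entry("tissue", "dropdown", allowed_values = character(0)),
    function() vocab_entry("weight", "freetext", allowed_values = "g"),
    function() vocab_entry("tissue", "dropdown",
                           allowed_values = c("liver", "Liver ")),
    function() vocabulary(list(vocab_entry("a", "freetext"),
                               vocab_entry("A", "freetext"))),
    function() dependent_registry(list(
      list(category = "assay", instance = "x", keys = "k"))),
    function() dependent_registry(list(
      list(category = "measurement_type", instance = "x", keys = "k"),
      list(category = "measurement_type", instance = " X ", keys = "j"))),
    function() general_info(linked_sheet_ids = "abc"),
    function() group_instance(""),
    function() comparison_group("diet", list()),
    function() comparison_group("weather", list(group_instance("x"))),
    function() comparison_group("diet", list(group_instance("a"),
                                             group_instance("A"))),
    function() final_group(c(diet = "chow"), 0L),
    function() final_group(unname(c("chow"))),
    function() covariate_spec("weight", role = "constant"),
    function() covariate_spec("weight", role = "covariate",
                              constant_value = "5"),
    function() timeline_spec(TRUE, kind = "continued"),
    function() timeline_spec(FALSE, kind = "continued"),
    function() division_level(2, data.frame(label = "a", protocol = "p",
                                            n_replicates = 1)),
    function() division_level(1, data.frame(label = "a", protocol = "p",
                                            n_replicates = 0)),
    function() preparation_spec("p", list(
      division_level(1, data.frame(label = "a", protocol = "p",
                                   n_replicates = 1)),
      division_level(1, data.frame(label = "b", protocol = "p",
                                   n_replicates = 1)),
      division_level(1, data.frame(label = "c", protocol = "p",
                                   n_replicates = 1)))),
    function() datafile_linkage("raw", "single_file_for_all", comment = ""),
    function() datafile_linkage("processed", "id_in_filename")
  )
  for (v in violations) expect_error(v())
})

test_that("id_table enforces ID uniqueness and parent references", {
  main <- matrix("", nrow = 5, ncol = 2,
                 dimnames = list(c("personal_ID", "final_group", "replicate",
                                   "subsamples", "subsubsamples"), NULL))
  main["personal_ID", ] <- c("S1", "S2")
  expect_s3_class(id_table(main), "ms_id_table")

  dup <- main
  dup["personal_ID", ] <- c("S1", "S1")
  expect_error(id_table(dup), "unique")

  sub <- matrix("", nrow = 4, ncol = 2,
                dimnames = list(c("parent_ID", "personal_ID", "instance",
                                  "replicate"), NULL))
  sub["parent_ID", ] <- c("S1", "S9")
  sub["personal_ID", ] <- c("U1", "U2")
  expect_error(id_table(main, subsample = sub), "one level up")
  sub["parent_ID", ] <- c("S1", "S2")
  expect_s3_class(id_table(main, subsample = sub), "ms_id_table")
  # a sub-sub table without the intermediate level is structural nonsense
  expect_error(id_table(main, subsubsample = sub), "requires")
})

test_that("dates normalize to ISO 8601 from common entry forms", {
  expect_identical(normalize_date("2024-01-15"), "2024-01-15")
  expect_identical(normalize_date("15.01.2024"), "2024-01-15")
  expect_identical(normalize_date("15/01/2024"), "2024-01-15")
  # spreadsheet serial day (1899-12-30 epoch)
  expect_identical(normalize_date("45306"), "2024-01-15")
  expect_identical(normalize_date("not a date"), NA_character_)
  expect_identical(normalize_date("2024-13-40"), NA_character_)
})

test_that("measurement IDs come from the deepest populated table", {
  fx <- generate_sheet(5, division_levels = 2, linkage_mode = "id_in_filename")
  tab <- fx$sheet$matching
  expect_identical(measurement_ids(fx$sheet),
                   unname(tab$subsubsample["personal_ID", ]))
  fx0 <- generate_sheet(5, division_levels = 0)
  expect_identical(measurement_ids(fx0$sheet),
                   unname(fx0$sheet$matching$main["personal_ID", ]))
})
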