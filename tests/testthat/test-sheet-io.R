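test_that("read_vocabulary parses the three-header-row layout", {
  grid <- cbind(c("DropDown", "choose organ", "tissue", "liver", "brain"),
                c("freetext", "", "weight", "", ""))
  v <- read_vocabulary(grid)
  expect_setequal(names(v$entries), c("tissue", "weight"))
  expect_identical(v$entries$tissue$vtype, "dropdown")
  expect_identical(v$entries$tissue$allowed_values, c("liver", "brain"))
  expect_identical(v$entries$tissue$help, "choose organ")
  expect_identical(v$entries$weight$vtype, "freetext")
  expect_null(v$entries$weight$allowed_values)

  bad <- cbind(c("DropDown_X", "", "tissue", "liver"))
  expect_error(read_vocabulary(bad), class = "ms_layout_error")
  expect_error(read_vocabulary(bad), "column 1")
})

test_that("read_dependent_fields parses the two-header-row layout", {
  grid <- cbind(c("experimental system", "mouse", "line", "genotype"),
                c("", "", "", ""),  # empty column is skipped
                c("measurement type", "bulk_RNA_seq", "instrument", ""))
  r <- read_dependent_fields(grid)
  expect_length(r$entries, 2L)
  keys <- insert_dependent_keys("experimental_system", "mouse", r)
  expect_identical(keys, c("line", "genotype"))

  dup <- cbind(c("experimental system", "mouse", "line"),
               c("experimental system", "Mouse", "genotype"))
  expect_error(read_dependent_fields(dup), class = "ms_layout_error")
  expect_error(read_dependent_fields(dup), "duplicate")
  unk <- cbind(c("species", "mouse", "line"))
  expect_error(read_dependent_fields(unk), class = "ms_layout_error")
})

test_that("workbooks round-trip field-for-field across varied designs", {
  vocabs_equal <- NULL
  cases <- list(
    list(seed = 11, n_groups = 1, instances_per_group = 6, replicates = 5),
    list(seed = 12, n_groups = 2, instances_per_group = c(3, 2),
         replicates = c(2, 3), n_covariates = 2),
    list(seed = 13, division_levels = 1, linkage_mode = "id_in_filename",
         instances_per_group = 2, replicates = 2),
    list(seed = 14, division_levels = 2, instances_per_group = 2,
         replicates = 1),
    list(seed = 15, linkage_mode = "changes", instances_per_group = 3,
         replicates = 2),
    list(seed = 16, n_groups = 3, instances_per_group = c(2, 2, 2),
         replicates = 1, n_covariates = 1))
  for (case in cases) {
    fx <- do.call(generate_sheet, case)
    path <- withr::local_tempfile(fileext = ".xlsx")
    write_metadatasheet(fx$sheet, fx$vocab, fx$registry, path)
    x <- read_metadatasheet(path)
    expect_length(x$issues, 0L)
    expect_equal(x$sheet, fx$sheet)
    expect_equal(x$vocab, fx$vocab)
    expect_equal(x$registry, fx$registry)
  }
})

test_that("a group-subset validation sheet round-trips alongside the master", {
  fx <- generate_sheet(21)
  gv <- vocabulary(list(
    vocab_entry("tissue", "dropdown", "choose organ (BTO terms)",
                "BTO:0000759 liver")), group_label = "LiverLab")
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_metadatasheet(fx$sheet, fx$vocab, fx$registry, path,
                      group_vocab = gv)
  x <- read_metadatasheet(path)
  expect_equal(x$group_vocab, gv)
})

test_that("export assigns a fresh UID once and keeps an existing one", {
  fx <- generate_sheet(31)
  sheet <- fx$sheet
  sheet$uid <- NULL
  path <- withr::local_tempfile(fileext = ".xlsx")
  written <- write_metadatasheet(sheet, fx$vocab, fx$registry, path)
  expect_match(written$uid,
               "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
  expect_identical(read_metadatasheet(path)$sheet$uid, written$uid)
  # re-export keeps the assigned uid
  path2 <- withr::local_tempfile(fileext = ".xlsx")
  rewritten <- write_metadatasheet(written, fx$vocab, fx$registry, path2)
  expect_identical(rewritten$uid, written$uid)
})

test_that("written workbooks are macro-free and blank templates parse empty", {
  fx <- generate_sheet(41)
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_metadatasheet(fx$sheet, fx$vocab, fx$registry, path)
  entries <- zip::zip_list(path)$filename
  expect_false(any(grepl("vba|macro", entries, ignore.case = TRUE)))

  blank_path <- withr::local_tempfile(fileext = ".xlsx")
  write_metadatasheet(new_blank(), fx$vocab, fx$registry, blank_path)
  x <- read_metadatasheet(blank_path)
  expect_length(x$issues, 0L)
  expect_null(x$sheet$matching)
  expect_length(x$sheet$conduction$final_groups, 0L)
})

test_that("missing required sheets are fatal layout errors", {
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_xlsx_grids(list(NotInput = matrix("x")), path)
  expect_error(read_metadatasheet(path), class = "ms_layout_error")
  expect_error(read_metadatasheet(path), "'Input'")

  path2 <- withr::local_tempfile(fileext = ".xlsx")
  write_xlsx_grids(list(Input = matrix("x")), path2)
  expect_error(read_metadatasheet(path2), "'Validation'")
})

test_that("a damaged segment becomes an issue on a partial parse, not an exception", {
  fx <- generate_sheet(51)
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_metadatasheet(fx$sheet, fx$vocab, fx$registry, path)
  # corrupt the timeline segment: interrupted must be yes/no
  grid <- metasheet:::input_grid(fx$sheet)
  grid[which(grid[, 1] == "interrupted"), 2] <- "maybe"
  write_xlsx_grids(list(Input = grid,
                        Validation = metasheet:::vocabulary_grid(fx$vocab),
                        dependentFields = metasheet:::registry_grid(fx$registry)),
                   path)
  x <- read_metadatasheet(path)
  expect_true(any(vapply(x$issues, function(i)
    i$rule == "unparseable-segment" && i$segment == "Timeline", logical(1))))
  # the rest of the sheet is intact
  expect_equal(x$sheet$planning, fx$sheet$planning)
})
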