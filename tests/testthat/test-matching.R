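test_that("CHANGES promotion collects exactly the promoted keys in document order", {
  fx <- generate_sheet(7, linkage_mode = "changes", instances_per_group = 2,
                       replicates = 2)
  expect_identical(collect_promoted_keys(fx$sheet), "filename")

  fx0 <- generate_sheet(8)
  expect_identical(collect_promoted_keys(fx0$sheet), character(0))

  sheet <- fx0$sheet
  sheet$conduction$covariates <- c(
    sheet$conduction$covariates,
    list(covariate_spec("batch", role = "constant",
                        constant_value = "CHANGES")))
  sheet$conduction$measurement$dependent_values$instrument <- "CHANGES"
  expect_identical(collect_promoted_keys(sheet), c("batch", "instrument"))

  # lowercase 'changes' is a value, not the keyword
  sheet$conduction$measurement$dependent_values$instrument <- "changes"
  expect_identical(collect_promoted_keys(sheet), "batch")
})

test_that("ID-table generation produces one column per replicate", {
  # showcase shape: 6 final groups x 5 replicates -> 30 columns
  fgs <- final_groups_with_reps(make_design(6), 5L)
  tab <- generate_id_table(fgs)
  expect_identical(ncol(tab$main), 30L)
  expect_identical(rownames(tab$main),
                   c("personal_ID", "final_group", "diet", "replicate",
                     "subsamples", "subsubsamples"))
  expect_true(all(tab$main["personal_ID", ] == ""))
  expect_true(all(tab$main["subsamples", ] == "no"))
  expect_identical(unname(tab$main["replicate", 1:5]), as.character(1:5))

  # minimal case
  tab1 <- generate_id_table(final_groups_with_reps(make_design(1), 1L))
  expect_identical(ncol(tab1$main), 1L)
  expect_identical(unname(tab1$main["subsubsamples", 1]), "no")

  # ragged replicate vector
  fgs3 <- final_groups_with_reps(make_design(3), c(2L, 3L, 4L))
  expect_identical(ncol(generate_id_table(fgs3)$main), 9L)
})

test_that("column counts equal the replicate sum on random designs", {
  set.seed(7)
  for (i in 1:25) {
    sizes <- random_sizes()
    reps <- sample.int(6L, prod(sizes), replace = TRUE)
    tab <- generate_id_table(final_groups_with_reps(make_design(sizes),
                                                    reps))
    expect_identical(ncol(tab$main), as.integer(sum(reps)))
  }
})

test_that("covariates and promoted keys become blank dynamic rows", {
  fgs <- final_groups_with_reps(make_design(2), 2L)
  covs <- list(covariate_spec("body weight", unit = "g"),
               covariate_spec("cell type", role = "constant",
                              constant_value = "Kupffer Cells"))
  tab <- generate_id_table(fgs, covariates = covs,
                           promoted_keys = "filename")
  expect_true(all(c("body weight", "filename") %in% rownames(tab$main)))
  # constants stay in place in the Conduction section, not in the table
  expect_false("cell type" %in% rownames(tab$main))
  expect_true(all(tab$main["body weight", ] == ""))
})

test_that("divisions expand into sub(sub)sample tables with replicate structure", {
  fgs <- final_groups_with_reps(make_design(2), 2L)  # 4 main columns
  prep <- preparation_spec("liver_prep.pdf", list(
    division_level(2, data.frame(label = c("hepatocytes", "Kupffer cells"),
                                 protocol = c("p1", "p2"),
                                 n_replicates = c(1, 2))),
    division_level(1, data.frame(label = "aliquot", protocol = "p3",
                                 n_replicates = 2))))
  tab <- generate_id_table(fgs, preparation = prep)
  expect_identical(unname(tab$main["subsamples", 1]), "yes")
  expect_identical(unname(tab$main["subsubsamples", 1]), "yes")
  expect_identical(ncol(tab$subsample), 4L * 3L)   # 1 + 2 reps per parent
  expect_identical(ncol(tab$subsubsample), 12L * 2L)
  expect_identical(unname(tab$subsample["instance", 1:3]),
                   c("hepatocytes", "Kupffer cells", "Kupffer cells"))
})

test_that("generation requires a valid conduction section", {
  expect_error(generate_id_table(list()), class = "ms_sequential_error")
  fgs <- generate_final_groups(make_design(2))  # replicates unset
  expect_error(generate_id_table(fgs), class = "ms_sequential_error")
})

test_that("regenerating a matching table with entered IDs warns", {
  fx <- generate_sheet(9)
  expect_warning(generate_matching(fx$sheet), "discards")
})

test_that("single_file_for_all maps every ID to the named file", {
  fx <- generate_sheet(10)
  root <- withr::local_tempdir()
  generate_datafiles(fx$sheet, root, seed = 10)
  res <- resolve_datafiles(fx$sheet$matching, fx$sheet$conduction$linkage,
                           root)
  expect_length(res, 30L)
  expect_true(all(vapply(res, identical, logical(1), "counts.tsv")))

  # absent comment file is a missing-file error
  unlink(file.path(root, "counts.tsv"))
  expect_error(resolve_datafiles(fx$sheet$matching,
                                 fx$sheet$conduction$linkage, root),
               "missing file")
})

test_that("id_in_filename matches by substring, agrees with an independent scan, sorted", {
  fx <- generate_sheet(11, linkage_mode = "id_in_filename",
                       instances_per_group = 2, replicates = 2)
  root <- withr::local_tempdir()
  # paired-end style: two files per ID
  ids <- measurement_ids(fx$sheet)
  for (id in ids) {
    file.create(file.path(root, paste0(id, "_R1.fastq")))
    file.create(file.path(root, paste0(id, "_R2.fastq")))
  }
  res <- resolve_datafiles(fx$sheet$matching, fx$sheet$conduction$linkage,
                           root)
  # independent substring scan over the directory listing
  listing <- list.files(root)
  for (id in ids) {
    oracle <- sort(listing[vapply(listing, function(f)
      grepl(id, f, fixed = TRUE), logical(1))])
    expect_identical(res[[id]], oracle)
    expect_length(res[[id]], 2L)
  }

  # an ID with no match is an unresolved-ID error naming it
  tab <- fx$sheet$matching
  tab$main["personal_ID", 1] <- "Z9"
  tab <- id_table(tab$main)
  expect_error(suppressWarnings(
    resolve_datafiles(tab, fx$sheet$conduction$linkage, root)),
    "Z9")
})

test_that("prefix-colliding IDs raise the ambiguity warning", {
  fgs <- final_groups_with_reps(make_design(2), 1L)
  tab <- generate_id_table(fgs)
  tab$main["personal_ID", ] <- c("S1", "S10")
  tab <- id_table(tab$main)
  root <- withr::local_tempdir()
  file.create(file.path(root, "S1_counts.tsv"))
  file.create(file.path(root, "S10_counts.tsv"))
  linkage <- datafile_linkage("raw", "id_in_filename")
  expect_warning(res <- resolve_datafiles(tab, linkage, root),
                 "ambiguous")
  # under plain substring matching S1 legitimately matches both files
  expect_setequal(res[["S1"]], c("S10_counts.tsv", "S1_counts.tsv"))
  expect_identical(res[["S10"]], "S10_counts.tsv")
})

test_that("changes mode resolves each ID through its promoted filename row", {
  fx <- generate_sheet(12, linkage_mode = "changes", instances_per_group = 3,
                       replicates = 1)
  root <- withr::local_tempdir()
  generate_datafiles(fx$sheet, root, seed = 12)
  res <- resolve_datafiles(fx$sheet$matching, fx$sheet$conduction$linkage,
                           root)
  ids <- measurement_ids(fx$sheet)
  expect_identical(unname(unlist(res)), paste0(ids, "_data.tsv"))
})
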