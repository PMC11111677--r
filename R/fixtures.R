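# Deterministic synthetic-sheet generator: builds complete,
# validation-clean metadata sheets (plus dummy measurement files) so every
# module is exercisable without any external download. The shipped demo
# vocabulary is seeded with showcase-style terms (mouse with 'line' and
# 'genotype' dependent keys, a BTO-style tissue CURIE, six diet labels).

#' Demo controlled vocabulary
#'
#' @return A [vocabulary()] with showcase-style keys.
#' @export
demo_vocabulary <- function() {
  vocabulary(list(
    vocab_entry("name", "freetext", "contact person"),
    vocab_entry("affiliation", "freetext"),
    vocab_entry("email", "freetext"),
    vocab_entry("project_title", "freetext"),
    vocab_entry("experimental_system", "dropdown", "choose the system",
                c("mouse", "rat", "human-derived", "cell-line", "patient")),
    vocab_entry("line", "freetext", "strain or cell line"),
    vocab_entry("genotype", "dropdown", "",
                c("wild type", "knockout", "heterozygous")),
    vocab_entry("tissue", "dropdown", "choose organ (BTO terms)",
                c("BTO:0000759 liver", "BTO:0000142 brain",
                  "BTO:0001239 white adipose tissue")),
    vocab_entry("sex", "dropdown", "", c("male", "female", "mixed")),
    vocab_entry("diet", "dropdown", "feeding scheme",
                c("chow", "high-fat", "high-fat high-sucrose", "western",
                  "ketogenic", "caloric restriction")),
    vocab_entry("treatment", "dropdown", "",
                c("LPS-treatment", "control-treatment", "vehicle")),
    vocab_entry("age", "freetext"),
    vocab_entry("temperature", "freetext"),
    vocab_entry("other", "freetext"),
    vocab_entry("measurement_type", "dropdown", "measurement technique",
                c("bulk_RNA_seq", "bulk-transcriptomics",
                  "bulk-metabolomics", "bulk-lipidomics", "FACS",
                  "single-cell RNAseq")),
    vocab_entry("instrument", "freetext"),
    vocab_entry("library_prep", "dropdown", "",
                c("poly-A", "ribo-depletion")),
    vocab_entry("used facility", "freetext"),
    vocab_entry("cell type", "freetext"),
    vocab_entry("protocol", "freetext"),
    vocab_entry("date", "date", "ISO date"),
    vocab_entry("timepoints", "dropdown_multi", "multi-select",
                c("0 h", "24 h", "48 h"))
  ))
}

#' Demo dependent-field registry
#'
#' @return A [dependent_registry()] covering the demo vocabulary's
#'   experimental systems and measurement types.
#' @export
demo_registry <- function() {
  dependent_registry(list(
    list(category = "experimental_system", instance = "mouse",
         keys = c("line", "genotype", "tissue", "sex")),
    list(category = "experimental_system", instance = "rat",
         keys = c("line", "genotype", "tissue")),
    list(category = "experimental_system", instance = "cell-line",
         keys = c("line", "tissue")),
    list(category = "experimental_system", instance = "human-derived",
         keys = c("tissue", "sex")),
    list(category = "experimental_system", instance = "patient",
         keys = c("tissue", "sex")),
    list(category = "measurement_type", instance = "bulk_RNA_seq",
         keys = c("instrument", "library_prep")),
    list(category = "measurement_type", instance = "bulk-transcriptomics",
         keys = c("instrument", "library_prep")),
    list(category = "measurement_type", instance = "bulk-metabolomics",
         keys = "instrument"),
    list(category = "measurement_type", instance = "bulk-lipidomics",
         keys = "instrument"),
    list(category = "measurement_type", instance = "FACS",
         keys = "instrument"),
    list(category = "measurement_type", instance = "single-cell RNAseq",
         keys = "instrument")
  ))
}

# instance-label pools per comparison category
fixture_label_pools <- function(vocab) {
  list(
    diet = vocab_get(vocab, "diet")$allowed_values,
    genotype = vocab_get(vocab, "genotype")$allowed_values,
    treatment = vocab_get(vocab, "treatment")$allowed_values,
    age = c("4 weeks", "8 weeks", "12 weeks", "16 weeks", "20 weeks"),
    temperature = c("22C", "30C", "4C", "18C", "26C"),
    other = paste("condition", LETTERS[1:6])
  )
}

# a valid filler value for a vocabulary key
fixture_fill_value <- function(vocab, key) {
  e <- vocab_get(vocab, key)
  if (is.null(e)) return("not recorded")
  switch(e$vtype,
         dropdown = e$allowed_values[[1]],
         dropdown_multi = e$allowed_values[[1]],
         date = "2024-01-15",
         "not recorded")
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a complete synthetic metadata sheet
#'
#' Builds a validation-clean sheet for the requested design. The same seed
#' and design parameters always produce identical output (including the
#' UID), so writing the result twice yields byte-identical workbooks.
#' The defaults mirror the showcase shape: one diet comparison group with
#' six instances and five replicates each, bulk RNA-seq, a single shared
#' counts file -- a 30-column matching table.
#'
#' @param seed Integer seed.
#' @param n_groups Number of comparison groups (1-6, categories in the
#'   fixed order diet, genotype, treatment, age, temperature, other).
#' @param instances_per_group Integer vector (recycled) of instance counts.
#' @param replicates Integer vector (recycled over final groups) of
#'   replicate counts.
#' @param n_covariates Number of per-measurement covariates (0-4).
#' @param division_levels Sample-partitioning levels, 0-2.
#' @param measurement_type Measurement type term from the demo vocabulary.
#' @param linkage_mode One of `"single_file_for_all"`, `"id_in_filename"`,
#'   `"changes"`.
#' @return List with `sheet`, `vocab`, `registry`.
#' @export
generate_sheet <- function(seed = 1L, n_groups = 1L,
                           instances_per_group = 6L, replicates = 5L,
                           n_covariates = 0L, division_levels = 0L,
                           measurement_type = "bulk_RNA_seq",
                           linkage_mode = "single_file_for_all") {
  if (division_levels < 0L || division_levels > 2L) {
    stop("division_levels must be 0, 1 or 2 (at most two levels of sample ",
         "partitioning)", call. = FALSE)
  }
  if (n_groups < 1L || n_groups > 6L) {
    stop("n_groups must be between 1 and 6", call. = FALSE)
  }
  if (n_covariates < 0L || n_covariates > 4L) {
    stop("n_covariates must be between 0 and 4", call. = FALSE)
  }
  linkage_mode <- match.arg(linkage_mode, LINKAGE_MODES)
  vocab <- demo_vocabulary()
  registry <- demo_registry()
  pools <- fixture_label_pools(vocab)
  cats <- c("diet", "genotype", "treatment", "age", "temperature",
            "other")[seq_len(n_groups)]
  sizes <- rep_len(as.integer(instances_per_group), n_groups)
  for (i in seq_len(n_groups)) {
    if (sizes[i] < 1L || sizes[i] > length(pools[[cats[i]]])) {
      stop("comparison group '", cats[i], "' supports 1-",
           length(pools[[cats[i]]]), " instances (", sizes[i], " requested)",
           call. = FALSE)
    }
  }

  run_seeded(seed, {
    groups <- lapply(seq_len(n_groups), function(i) {
      comparison_group(cats[i], lapply(pools[[cats[i]]][seq_len(sizes[i])],
                                       group_instance))
    })

    sys_keys <- insert_dependent_keys("experimental_system", "mouse",
                                      registry)
    sys_dep <- stats::setNames(
      lapply(sys_keys, function(k) fixture_fill_value(vocab, k)), sys_keys)
    sys_dep[["line"]] <- "C57BL/6J"

    planning <- list(
      general = general_info(
        name = "Jane Doe", affiliation = "Example University",
        email = "jane.doe@example.org",
        project_title = sprintf("Synthetic showcase study %d", seed)),
      system = experimental_system("mouse", sys_dep),
      comparison_groups = groups)

    fgs <- generate_final_groups(groups)
    reps <- rep_len(as.integer(replicates), length(fgs))
    fgs <- lapply(seq_along(fgs), function(i) {
      final_group(fgs[[i]]$assignment, reps[i])
    })

    cov_pool <- list(
      list(name = "body weight", unit = "g"),
      list(name = "blood glucose", unit = "mg/dL"),
      list(name = "prep day", unit = "day"),
      list(name = "serum color", unit = ""))
    covariates <- c(
      list(covariate_spec("cell type", unit = "", role = "constant",
                          constant_value = "Kupffer Cells")),
      lapply(seq_len(n_covariates), function(i) {
        covariate_spec(cov_pool[[i]]$name, unit = cov_pool[[i]]$unit,
                       role = "covariate")
      }))

    divisions <- list()
    if (division_levels >= 1L) {
      divisions[[1]] <- division_level(2L, data.frame(
        label = c("hepatocytes", "Kupffer cells"),
        protocol = c("hepatocyte_isolation.pdf", "kupffer_isolation.pdf"),
        n_replicates = c(1L, 1L), stringsAsFactors = FALSE))
    }
    if (division_levels >= 2L) {
      divisions[[2]] <- division_level(1L, data.frame(
        label = "technical replicate", protocol = "aliquoting.pdf",
        n_replicates = 2L, stringsAsFactors = FALSE))
    }

    me_keys <- registry_get(registry, "measurement_type",
                            measurement_type)$keys
    me_dep <- stats::setNames(
      lapply(me_keys, function(k) fixture_fill_value(vocab, k)), me_keys)
    if ("instrument" %in% names(me_dep)) me_dep[["instrument"]] <-
      "NovaSeq 6000"

    linkage <- datafile_linkage(
      availability = "raw", mode = linkage_mode,
      comment = if (linkage_mode == "single_file_for_all") "counts.tsv"
                else "")

    conduction <- list(final_groups = fgs, covariates = covariates,
                       timeline = timeline_spec(),
                       preparation = preparation_spec("liver_preparation.pdf",
                                                      divisions),
                       measurement = measurement_spec(measurement_type,
                                                      me_dep),
                       linkage = linkage)

    sheet <- metadatasheet(planning = planning, conduction = conduction,
                           uid = ms_uuid())
    sheet <- generate_matching(sheet)

    # fill IDs level by level; zero-padded so no ID is a substring of
    # another
    tab <- sheet$matching
    pad_ids <- function(prefix, n) {
      sprintf(paste0(prefix, "%0", max(2L, nchar(n)), "d"), seq_len(n))
    }
    tab$main["personal_ID", ] <- pad_ids("S", ncol(tab$main))
    if (!is.null(tab$subsample)) {
      n_sub <- ncol(tab$subsample)
      per_parent <- n_sub %/% ncol(tab$main)
      tab$subsample["personal_ID", ] <- pad_ids("U", n_sub)
      tab$subsample["parent_ID", ] <-
        tab$main["personal_ID", (seq_len(n_sub) - 1L) %/% per_parent + 1L]
    }
    if (!is.null(tab$subsubsample)) {
      n_ss <- ncol(tab$subsubsample)
      per_parent <- n_ss %/% ncol(tab$subsample)
      tab$subsubsample["personal_ID", ] <- pad_ids("V", n_ss)
      tab$subsubsample["parent_ID", ] <-
        tab$subsample["personal_ID", (seq_len(n_ss) - 1L) %/% per_parent + 1L]
    }
    # per-measurement covariate values
    for (i in seq_len(n_covariates)) {
      nm <- cov_pool[[i]]$name
      tab$main[nm, ] <- as.character(round(stats::runif(ncol(tab$main),
                                                        10, 40), 1))
    }
    if (linkage_mode == "changes") {
      deep <- deepest_table(tab)
      fns <- paste0(deep["personal_ID", ], "_data.tsv")
      if (is.null(tab$subsubsample) && is.null(tab$subsample)) {
        tab$main["filename", ] <- fns
      } else {
        # promoted row lives in the main table; measurement files belong to
        # the deepest level, so the fixture keeps 'changes' flat
        stop("fixture generator supports linkage_mode 'changes' only ",
             "without divisions", call. = FALSE)
      }
    }
    sheet$matching <- id_table(tab$main, subsample = tab$subsample,
                               subsubsample = tab$subsubsample)
    list(sheet = sheet, vocab = vocab, registry = registry)
  })
}

#' Generate dummy measurement files matching a sheet's linkage
#'
#' Writes seeded synthetic count data under `root` so that
#' [resolve_datafiles()] resolves every measurement ID: a single delimited
#' feature-by-ID matrix for `single_file_for_all`, or one small file per
#' ID (ID embedded in the filename) for `id_in_filename` / `changes`.
#' Counts are drawn from a negative-binomial distribution purely so bulk
#' matrices look realistic; the values carry no biological claim.
#'
#' @param sheet A [metadatasheet()] with filled personal IDs.
#' @param root Output directory (created if needed).
#' @param seed Integer seed for the count draws.
#' @param n_features Number of synthetic feature rows.
#' @return Character vector of the files written, invisibly.
#' @export
generate_datafiles <- function(sheet, root, seed = 1L, n_features = 50L) {
  stopifnot(inherits(sheet, "ms_metadatasheet"))
  ids <- measurement_ids(sheet)
  if (length(ids) == 0L || !all(nzchar(ids))) {
    stop("sheet has no filled personal IDs; generate and fill the matching ",
         "table first", call. = FALSE)
  }
  linkage <- sheet$conduction$linkage
  if (is.null(linkage)) stop("sheet has no DataFiles-Linkage segment",
                             call. = FALSE)
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  run_seeded(seed, {
    features <- sprintf("gene_%03d", seq_len(n_features))
    draw <- function(n) stats::rnbinom(n, size = 2, mu = 100)
    written <- character(0)
    if (linkage$mode == "single_file_for_all") {
      m <- matrix(draw(n_features * length(ids)), nrow = n_features,
                  dimnames = list(features, ids))
      df <- data.frame(feature = features, m, check.names = FALSE,
                       stringsAsFactors = FALSE)
      fn <- file.path(root, canonicalize(linkage$comment))
      utils::write.table(df, fn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- fn
    } else {
      deep <- deepest_table(sheet$matching)
      for (i in seq_along(ids)) {
        fn <- if (linkage$mode == "changes") deep["filename", i]
              else paste0(ids[i], "_counts.tsv")
        fn <- file.path(root, fn)
        utils::write.table(
          data.frame(feature = features, count = draw(n_features),
                     stringsAsFactors = FALSE),
          fn, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, fn)
      }
    }
    invisible(written)
  })
}
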