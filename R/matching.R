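# Measurement-Matching machinery: CHANGES promotion, ID-table generation
# (the workbook's second 'generate' button) and measurement data-file
# resolution from personal IDs.

#' Collect CHANGES-promoted keys from the Conduction section
#'
#' Any key whose value is the literal uppercase token `CHANGES` is promoted
#' from a key:value pair to a per-measurement row of the ID table. Keys are
#' returned in document order of the Conduction segments. Under linkage
#' mode `changes` the promoted key is `filename`.
#'
#' @param sheet A [metadatasheet()].
#' @return Ordered character vector of promoted keys.
#' @export
collect_promoted_keys <- function(sheet) {
  stopifnot(inherits(sheet, "ms_metadatasheet"))
  out <- character(0)
  is_changes <- function(v) identical(as.character(v), CHANGES_TOKEN)
  for (cv in sheet$conduction$covariates) {
    if (cv$role == "constant" && is_changes(cv$constant_value)) {
      out <- c(out, cv$name)
    }
  }
  prep <- sheet$conduction$preparation
  if (!is.null(prep) && is_changes(prep$protocol)) out <- c(out, "protocol")
  me <- sheet$conduction$measurement
  for (k in names(me$dependent_values)) {
    if (is_changes(me$dependent_values[[k]])) out <- c(out, k)
  }
  lk <- sheet$conduction$linkage
  if (!is.null(lk)) {
    if (lk$mode == "changes") out <- c(out, "filename")
    if (!is.null(lk$processing_procedure) &&
        is_changes(lk$processing_procedure)) {
      out <- c(out, "processing_procedure")
    }
  }
  unique(out)
}

#' Generate the ID-specific metadata table
#'
#' Builds the Measurement-Matching table from the Conduction section: one
#' column per measured unit (the sum of the final groups' replicate
#' counts), fixed rows (`personal_ID` left blank for the user to fill,
#' final-group label, one assignment row per comparison category, 1-based
#' replicate index, and literal `yes`/`no` subsample flags), one dynamic
#' row per declared covariate and per CHANGES-promoted key, and -- when the
#' Preparation segment declares divisions -- a subsample table per division
#' level with `parent_ID`, `instance` and replicate expansion.
#'
#' @param final_groups List of [final_group()]s, replicate counts set.
#' @param covariates List of [covariate_spec()]s; rows are added for
#'   `role = "covariate"` entries.
#' @param promoted_keys Character vector from [collect_promoted_keys()].
#' @param preparation A [preparation_spec()] or `NULL`.
#' @return An [id_table()].
#' @export
generate_id_table <- function(final_groups, covariates = list(),
                              promoted_keys = character(0),
                              preparation = NULL) {
  if (length(final_groups) == 0L) {
    sequential_error(paste0("cannot generate the matching table: no final ",
                            "groups in the Conduction section"))
  }
  reps <- vapply(final_groups, function(f) f$n_replicates, integer(1))
  if (anyNA(reps)) {
    sequential_error(paste0("cannot generate the matching table: final ",
                            "group(s) without replicate counts: ",
                            paste(which(is.na(reps)), collapse = ", ")))
  }
  cats <- names(final_groups[[1]]$assignment)
  divisions <- if (is.null(preparation)) list() else preparation$divisions

  n <- sum(reps)
  cov_rows <- vapply(Filter(function(c) c$role == "covariate", covariates),
                     function(c) c$name, character(1))
  promoted_keys <- setdiff(promoted_keys, c(cov_rows))
  row_names <- c("personal_ID", "final_group", cats, "replicate",
                 "subsamples", "subsubsamples", cov_rows, promoted_keys)
  main <- matrix("", nrow = length(row_names), ncol = n,
                 dimnames = list(row_names, NULL))
  col <- 0L
  for (g in seq_along(final_groups)) {
    fg <- final_groups[[g]]
    for (r in seq_len(reps[g])) {
      col <- col + 1L
      main["final_group", col] <- final_group_label(fg)
      for (cat in cats) main[cat, col] <- unname(fg$assignment[[cat]])
      main["replicate", col] <- as.character(r)
    }
  }
  main["subsamples", ] <- if (length(divisions) >= 1L) "yes" else "no"
  main["subsubsamples", ] <- if (length(divisions) >= 2L) "yes" else "no"

  expand_division <- function(parent_n, division) {
    inst <- division$instances
    per_parent <- sum(inst$n_replicates)
    cols <- parent_n * per_parent
    m <- matrix("", nrow = length(SUBTABLE_ROWS), ncol = cols,
                dimnames = list(SUBTABLE_ROWS, NULL))
    col <- 0L
    for (p in seq_len(parent_n)) {
      for (i in seq_len(nrow(inst))) {
        for (r in seq_len(inst$n_replicates[i])) {
          col <- col + 1L
          m["instance", col] <- inst$label[i]
          m["replicate", col] <- as.character(r)
        }
      }
    }
    m
  }

  subsample <- NULL
  subsubsample <- NULL
  if (length(divisions) >= 1L) {
    subsample <- expand_division(n, divisions[[1]])
    if (length(divisions) >= 2L) {
      subsubsample <- expand_division(ncol(subsample), divisions[[2]])
    }
  }
  id_table(main, subsample = subsample, subsubsample = subsubsample)
}

#' Generate the matching section of a sheet in place
#'
#' Convenience wrapper: derives covariates and promoted keys from the
#' Conduction section and attaches the generated [id_table()] to the
#' sheet. Regeneration replaces the section; a warning is raised when the
#' previous table already carried personal IDs.
#'
#' @param sheet A [metadatasheet()] with a valid Conduction section.
#' @return The sheet with `matching` set.
#' @export
generate_matching <- function(sheet) {
  stopifnot(inherits(sheet, "ms_metadatasheet"))
  if (!is.null(sheet$matching)) {
    old_ids <- measurement_ids(sheet)
    if (any(nzchar(old_ids))) {
      warning("regenerating the matching table discards ",
              sum(nzchar(old_ids)), " personal ID(s) already entered",
              call. = FALSE)
    }
  }
  sheet$matching <- generate_id_table(
    sheet$conduction$final_groups, sheet$conduction$covariates,
    collect_promoted_keys(sheet), sheet$conduction$preparation)
  sheet
}

#' Resolve measurement data files for every personal ID
#'
#' Maps each measurement ID (deepest table of the ID table) to its data
#' file(s) under `root`, per the DataFiles-Linkage mode:
#' `single_file_for_all` resolves every ID to the single filename in the
#' linkage comment; `id_in_filename` matches file basenames that contain
#' the ID as a substring (multiple matches, e.g. paired-end reads, are
#' legitimate and returned sorted); `changes` resolves each ID to the value
#' of the promoted `filename` row. All paths are interpreted relative to
#' `root` (the directory of the sheet). When one ID is a substring of
#' another, substring matching is ambiguous and a warning lists the
#' colliding IDs.
#'
#' @param table An [id_table()] with personal IDs filled.
#' @param linkage A [datafile_linkage()].
#' @param root Directory against which filenames are resolved.
#' @return Named list mapping each personal ID to a sorted character
#'   vector of paths relative to `root`.
#' @export
resolve_datafiles <- function(table, linkage, root) {
  stopifnot(inherits(table, "ms_id_table"),
            inherits(linkage, "ms_datafile_linkage"))
  if (!dir.exists(root)) {
    stop("root directory does not exist: ", root, call. = FALSE)
  }
  deepest <- deepest_table(table)
  ids <- unname(deepest["personal_ID", ])
  if (!all(nzchar(ids))) {
    stop("cannot resolve data files: personal_ID values are not all filled",
         call. = FALSE)
  }
  switch(linkage$mode,
    single_file_for_all = {
      fn <- canonicalize(linkage$comment)
      if (!file.exists(file.path(root, fn))) {
        stop("missing file: linkage names '", fn, "' but it does not exist ",
             "under ", root, call. = FALSE)
      }
      stats::setNames(rep(list(fn), length(ids)), ids)
    },
    id_in_filename = {
      longer <- outer(ids, ids, function(a, b)
        a != b & mapply(grepl, a, b, MoreArgs = list(fixed = TRUE)))
      if (any(longer)) {
        pairs <- which(longer, arr.ind = TRUE)
        msg <- paste(unique(apply(pairs, 1, function(p)
          paste0("'", ids[p[1]], "' ⊂ '", ids[p[2]], "'"))),
          collapse = ", ")
        warning("ambiguous IDs under substring matching: ", msg,
                call. = FALSE)
      }
      files <- sort(list.files(root, recursive = TRUE))
      out <- lapply(ids, function(id) {
        hits <- files[grepl(id, basename(files), fixed = TRUE)]
        if (length(hits) == 0L) {
          stop("unresolved ID '", id, "': no file under ", root,
               " contains it in its name", call. = FALSE)
        }
        sort(hits)
      })
      stats::setNames(out, ids)
    },
    changes = {
      if (!"filename" %in% rownames(deepest) &&
          !"filename" %in% rownames(table$main)) {
        stop("linkage mode 'changes' requires a promoted 'filename' row in ",
             "the ID table", call. = FALSE)
      }
      src <- if ("filename" %in% rownames(deepest)) deepest else table$main
      fns <- unname(src["filename", ])
      out <- lapply(seq_along(ids), function(i) {
        fn <- canonicalize(fns[i])
        if (!nzchar(fn) || !file.exists(file.path(root, fn))) {
          stop("unresolved ID '", ids[i], "': promoted filename '", fn,
               "' not found under ", root, call. = FALSE)
        }
        fn
      })
      stats::setNames(out, ids)
    })
}
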