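# Validation engine: value-level checks against the controlled vocabulary,
# segment- and cross-section integrity, sequential gating between sections,
# vocabulary subset checking and vocabulary merging.
#
# The engine never mutates or corrects values; it reports, callers decide.
# Severity policy: vocabulary and structural violations are errors;
# unknown-but-well-formed extra keys and not-yet-filled required values are
# warnings (the standard is extensible, and a sheet grows along the
# data-lifecycle -- incompleteness only hardens into an error at export).

issue_collector <- function() {
  issues <- list()
  list(
    add = function(..., severity = "error") {
      issues[[length(issues) + 1L]] <<- validation_issue(...,
                                                         severity = severity)
    },
    addi = function(i) issues[[length(issues) + 1L]] <<- i,
    has_errors = function() {
      any(vapply(issues, function(i) i$severity == "error", logical(1)))
    },
    n_errors_since = function(mark) {
      if (length(issues) <= mark) return(0L)
      sum(vapply(issues[(mark + 1L):length(issues)],
                 function(i) i$severity == "error", logical(1)))
    },
    mark = function() length(issues),
    issues = function() issues
  )
}

#' Validate a single value against the controlled vocabulary
#'
#' @param key The key the value was given for.
#' @param value The observed value (a single string).
#' @param vocab A [vocabulary()].
#' @param section,segment,column Optional location, carried into issues.
#' @return List of [validation_issue()]s; empty iff the value satisfies the
#'   key's validation type (freetext: any non-empty string; date: a
#'   parseable date; dropdown: member of the allowed values; multi-select
#'   dropdown: every `;`-separated token a member). An unknown key yields a
#'   warning-severity `unknown-key` issue, not an exception.
#' @export
validate_value <- function(key, value, vocab, section = "", segment = "",
                           column = NA_integer_) {
  loc <- function(rule, severity, message, val = value) {
    validation_issue(section = section, segment = segment, key = key,
                     column = column, value = val, rule = rule,
                     severity = severity, message = message)
  }
  entry <- vocab_get(vocab, key)
  if (is.null(entry)) {
    return(list(loc("unknown-key", "warning",
                    paste0("key '", key, "' is not in the controlled ",
                           "vocabulary"))))
  }
  value <- as.character(value)
  if (!nzchar(canonicalize(value))) {
    return(list(loc("empty-value", "warning",
                    paste0("no value given for key '", key, "'"))))
  }
  switch(entry$vtype,
    freetext = list(),
    date = {
      if (is.na(normalize_date(value))) {
        list(loc("invalid-date", "error",
                 paste0("'", value, "' is not a recognizable date for key '",
                        key, "'")))
      } else list()
    },
    dropdown = {
      if (is.na(vocab_match(value, entry$allowed_values))) {
        list(loc("off-vocabulary", "error",
                 paste0("value '", value, "' for key '", key,
                        "' is not in the controlled vocabulary")))
      } else list()
    },
    dropdown_multi = {
      tokens <- canonicalize(strsplit(value, ";", fixed = TRUE)[[1]])
      tokens <- tokens[nzchar(tokens)]
      bad <- tokens[vapply(tokens, function(t)
        is.na(vocab_match(t, entry$allowed_values)), logical(1))]
      lapply(bad, function(t)
        loc("off-vocabulary", "error",
            paste0("token '", t, "' for multi-select key '", key,
                   "' is not in the controlled vocabulary"), val = t))
    })
}

# vocabulary used for a key: group subset when it carries the key,
# master otherwise
effective_vocab <- function(key, vocab, group_vocab) {
  if (!is.null(group_vocab) && vocab_has(group_vocab, key)) group_vocab
  else vocab
}

check_value <- function(coll, key, value, vocab, group_vocab, section,
                        segment, column = NA_integer_) {
  v <- effective_vocab(key, vocab, group_vocab)
  for (i in validate_value(key, value, v, section = section,
                           segment = segment, column = column)) {
    coll$addi(i)
  }
}

check_dependent_block <- function(coll, category, instance, values, registry,
                                  vocab, group_vocab, section, segment) {
  entry <- registry_get(registry, category, instance)
  required <- if (is.null(entry)) character(0) else entry$keys
  have <- names(values) %||% character(0)
  for (k in setdiff(tolower(canonicalize(required)),
                    tolower(canonicalize(have)))) {
    coll$add(section = section, segment = segment, key = k,
             rule = "missing-dependent-key", severity = "error",
             message = paste0("dependent key '", k, "' required for ",
                              category, " '", instance, "' is missing"))
  }
  for (k in have) {
    if (!tolower(canonicalize(k)) %in% tolower(canonicalize(required))) {
      coll$add(section = section, segment = segment, key = k,
               rule = "extra-dependent-key", severity = "warning",
               message = paste0("key '", k, "' is not a registered ",
                                "dependent key of ", category, " '",
                                instance, "'"))
    }
    check_value(coll, k, values[[k]], vocab, group_vocab, section, segment)
  }
}

#' Validate a full metadata sheet
#'
#' Runs every check the workbook performs: value-level validation against
#' the controlled vocabulary (the group subset when supplied), dependent-key
#' completeness per the registry, structural model invariants (replicate
#' counts, the two-level division limit, ID uniqueness, parent references,
#' column counts) and sequential integrity -- the Conduction section is only
#' checked against a valid Planning section and Measurement-Matching only
#' against a valid Conduction section; when an upstream section has errors,
#' downstream checks are replaced by a single `blocked-by-upstream` issue.
#'
#' @param sheet A [metadatasheet()].
#' @param vocab Master [vocabulary()].
#' @param registry [dependent_registry()].
#' @param group_vocab Optional group-subset vocabulary; keys it carries are
#'   validated against it instead of the master.
#' @return A [validation_report()].
#' @export
validate_sheet <- function(sheet, vocab, registry, group_vocab = NULL) {
  stopifnot(inherits(sheet, "ms_metadatasheet"))
  coll <- issue_collector()

  # --- Planning -----------------------------------------------------------
  g <- sheet$planning$general
  for (f in c("name", "email", "project_title")) {
    if (!nzchar(canonicalize(g[[f]]))) {
      coll$add(section = "planning", segment = "General", key = f,
               rule = "missing-value", severity = "warning",
               message = paste0("general field '", f, "' is not filled"))
    }
  }

  es <- sheet$planning$system
  if (is.na(es$system) || !nzchar(canonicalize(es$system))) {
    coll$add(section = "planning", segment = "Experimental System",
             key = "experimental_system", rule = "missing-value",
             severity = "warning",
             message = "experimental system not chosen yet")
  } else {
    check_value(coll, "experimental_system", es$system, vocab, group_vocab,
                "planning", "Experimental System")
    check_dependent_block(coll, "experimental_system", es$system,
                          es$dependent_values, registry, vocab, group_vocab,
                          "planning", "Experimental System")
  }

  groups <- sheet$planning$comparison_groups
  if (length(groups) == 0L) {
    coll$add(section = "planning", segment = "Comparison Groups",
             rule = "missing-value", severity = "warning",
             message = "no comparison group declared yet")
  }
  if (anyDuplicated(vapply(groups, function(g) g$category, character(1)))) {
    coll$add(section = "planning", segment = "Comparison Groups",
             rule = "duplicate-category", severity = "error",
             message = "comparison-group categories must be unique")
  }
  for (cg in groups) {
    labels <- group_labels(cg)
    if (vocab_has(vocab, cg$category) || (!is.null(group_vocab) &&
                                          vocab_has(group_vocab, cg$category))) {
      for (j in seq_along(labels)) {
        check_value(coll, cg$category, labels[[j]], vocab, group_vocab,
                    "planning", "Comparison Groups", column = j)
      }
    }
    for (j in seq_along(cg$instances)) {
      det <- cg$instances[[j]]$details
      for (k in names(det)) {
        check_value(coll, k, det[[k]], vocab, group_vocab, "planning",
                    "Comparison Groups", column = j)
      }
    }
  }

  planning_ok <- !coll$has_errors()
  if (!planning_ok) {
    coll$add(section = "conduction", rule = "blocked-by-upstream",
             severity = "warning",
             message = paste0("Conduction not checked: the Planning ",
                              "section has errors"))
    return(validation_report(coll$issues()))
  }

  # --- Conduction ---------------------------------------------------------
  declared <- lapply(groups, group_labels)
  names(declared) <- vapply(groups, function(g) g$category, character(1))

  fgs <- sheet$conduction$final_groups
  if (length(fgs) == 0L && length(groups) > 0L) {
    coll$add(section = "conduction", segment = "Final Groups",
             rule = "missing-value", severity = "warning",
             message = "final groups not generated yet")
  }
  seen_assignments <- character(0)
  for (j in seq_along(fgs)) {
    fg <- fgs[[j]]
    cats <- names(fg$assignment)
    for (miss in setdiff(names(declared), cats)) {
      coll$add(section = "conduction", segment = "Final Groups", key = miss,
               column = j, rule = "missing-category",
               message = paste0("final group ", j, " lacks an assignment ",
                                "for comparison group '", miss, "'"))
    }
    for (extra in setdiff(cats, names(declared))) {
      coll$add(section = "conduction", segment = "Final Groups", key = extra,
               column = j, rule = "undeclared-category",
               message = paste0("final group ", j, " assigns category '",
                                extra, "' that Planning does not declare"))
    }
    for (cat in intersect(cats, names(declared))) {
      lab <- fg$assignment[[cat]]
      if (is.na(vocab_match(lab, declared[[cat]]))) {
        coll$add(section = "conduction", segment = "Final Groups", key = cat,
                 column = j, value = lab, rule = "undeclared-instance",
                 message = paste0("final group ", j, " assignment '", lab,
                                  "' references an instance not declared ",
                                  "for comparison group '", cat, "'"))
      }
    }
    if (is.na(fg$n_replicates)) {
      coll$add(section = "conduction", segment = "Final Groups",
               key = "n_replicates", column = j, rule = "missing-replicates",
               message = paste0("final group ", j, " has no replicate ",
                                "count (counts are never defaulted)"))
    }
    sig <- paste(tolower(fg$assignment[sort(names(fg$assignment))]),
                 collapse = "\x1f")
    if (sig %in% seen_assignments) {
      coll$add(section = "conduction", segment = "Final Groups", column = j,
               rule = "duplicate-assignment",
               message = paste0("final group ", j, " duplicates an earlier ",
                                "combination"))
    }
    seen_assignments <- c(seen_assignments, sig)
  }

  for (cv in sheet$conduction$covariates) {
    if (cv$role == "constant") {
      check_value(coll, cv$name, cv$constant_value, vocab, group_vocab,
                  "conduction", "Covariates")
    }
  }

  for (i in check_timeline(sheet$conduction$timeline %||% timeline_spec(),
                           groups)) {
    coll$addi(i)
  }

  prep <- sheet$conduction$preparation
  if (!is.null(prep) && length(prep$divisions) > 2L) {
    coll$add(section = "conduction", segment = "Preparation",
             rule = "too-many-divisions",
             message = paste0(length(prep$divisions), " division levels ",
                              "given; at most two levels of sample ",
                              "partitioning are accommodated"))
  }

  me <- sheet$conduction$measurement
  if (is.na(me$measurement_type) || !nzchar(canonicalize(me$measurement_type))) {
    coll$add(section = "conduction", segment = "Measurement",
             key = "measurement_type", rule = "missing-value",
             severity = "warning", message = "measurement type not chosen yet")
  } else {
    check_value(coll, "measurement_type", me$measurement_type, vocab,
                group_vocab, "conduction", "Measurement")
    check_dependent_block(coll, "measurement_type", me$measurement_type,
                          me$dependent_values, registry, vocab, group_vocab,
                          "conduction", "Measurement")
  }

  lk <- sheet$conduction$linkage
  if (is.null(lk)) {
    coll$add(section = "conduction", segment = "DataFiles-Linkage",
             rule = "missing-value", severity = "warning",
             message = "data-file linkage not specified yet")
  }

  conduction_ok <- !coll$has_errors()
  if (!conduction_ok) {
    coll$add(section = "matching", rule = "blocked-by-upstream",
             severity = "warning",
             message = paste0("Measurement-Matching not checked: the ",
                              "Conduction section has errors"))
    return(validation_report(coll$issues()))
  }

  # --- Measurement-Matching ----------------------------------------------
  tab <- sheet$matching
  if (is.null(tab)) {
    if (length(fgs) > 0L) {
      coll$add(section = "matching", segment = "ID Table",
               rule = "missing-value", severity = "warning",
               message = "measurement-matching table not generated yet")
    }
    return(validation_report(coll$issues()))
  }

  reps <- vapply(fgs, function(f) f$n_replicates, integer(1))
  if (length(reps) && !anyNA(reps)) {
    expected <- sum(reps)
    if (ncol(tab$main) != expected) {
      coll$add(section = "matching", segment = "ID Table",
               rule = "column-count",
               message = paste0("ID table has ", ncol(tab$main),
                                " columns but the final groups' replicate ",
                                "counts require ", expected))
    }
  }

  ids <- measurement_ids(tab)
  filled <- ids[nzchar(ids)]
  if (length(filled) < length(ids)) {
    coll$add(section = "matching", segment = "ID Table", key = "personal_ID",
             rule = "incomplete-ids", severity = "warning",
             message = paste0(length(ids) - length(filled),
                              " measurement ID(s) not yet filled"))
  }
  all_ids <- c(tab$main["personal_ID", ],
               if (!is.null(tab$subsample)) tab$subsample["personal_ID", ],
               if (!is.null(tab$subsubsample)) tab$subsubsample["personal_ID", ])
  all_ids <- all_ids[nzchar(all_ids)]
  if (anyDuplicated(all_ids)) {
    coll$add(section = "matching", segment = "ID Table", key = "personal_ID",
             rule = "duplicate-id",
             message = paste0("duplicate personal_ID value(s): ",
                              paste(unique(all_ids[duplicated(all_ids)]),
                                    collapse = ", ")))
  }

  check_parents <- function(child, parent, what) {
    refs <- child["parent_ID", ]
    refs <- refs[nzchar(refs)]
    bad <- setdiff(refs, parent["personal_ID", ])
    if (length(bad)) {
      coll$add(section = "matching", segment = what, key = "parent_ID",
               rule = "orphan-parent-ref",
               message = paste0(what, " parent_ID value(s) missing one ",
                                "level up: ",
                                paste(unique(bad), collapse = ", ")))
    }
  }
  if (!is.null(tab$subsample)) check_parents(tab$subsample, tab$main,
                                             "Subsample Table")
  if (!is.null(tab$subsubsample)) check_parents(tab$subsubsample,
                                                tab$subsample,
                                                "Subsubsample Table")

  flag <- function(row) tolower(canonicalize(tab$main[row, 1]))
  if (!is.null(tab$subsample) && flag("subsamples") != "yes") {
    coll$add(section = "matching", segment = "ID Table", key = "subsamples",
             rule = "flag-mismatch",
             message = "a subsample table is present but the subsamples flag is not 'yes'")
  }
  if (is.null(tab$subsample) && flag("subsamples") == "yes") {
    coll$add(section = "matching", segment = "ID Table", key = "subsamples",
             rule = "flag-mismatch",
             message = "subsamples flagged 'yes' but no subsample table is present")
  }

  # dynamic rows that the conduction section promises
  dyn_expected <- c(
    vapply(Filter(function(c) c$role == "covariate",
                  sheet$conduction$covariates),
           function(c) c$name, character(1)),
    collect_promoted_keys(sheet))
  fixed <- c(ID_FIXED_ROWS_HEAD, names(declared), ID_FIXED_ROWS_TAIL)
  for (k in dyn_expected) {
    if (!tolower(k) %in% tolower(rownames(tab$main))) {
      coll$add(section = "matching", segment = "ID Table", key = k,
               rule = "missing-row",
               message = paste0("the ID table lacks the row for '", k,
                                "' promised by the Conduction section"))
    }
  }
  for (cat in names(declared)) {
    if (!tolower(cat) %in% tolower(rownames(tab$main))) {
      coll$add(section = "matching", segment = "ID Table", key = cat,
               rule = "missing-row",
               message = paste0("the ID table lacks the assignment row for ",
                                "comparison group '", cat, "'"))
    }
  }
  # vocabulary checks on dynamic rows that carry vocabulary keys
  dyn_rows <- setdiff(rownames(tab$main), fixed)
  for (k in dyn_rows) {
    if (vocab_has(vocab, k) || (!is.null(group_vocab) &&
                                vocab_has(group_vocab, k))) {
      for (j in seq_len(ncol(tab$main))) {
        v <- tab$main[k, j]
        if (nzchar(v)) {
          check_value(coll, k, v, vocab, group_vocab, "matching", "ID Table",
                      column = j)
        }
      }
    }
  }

  validation_report(coll$issues())
}

#' Check that a group vocabulary is a subset of the master vocabulary
#'
#' The group-specific validation must be a restriction of the overall
#' validation: every key it carries must exist in the master with the same
#' validation type, and its allowed values must be a subset of the
#' master's.
#'
#' @param group_vocab,master_vocab [vocabulary()] objects.
#' @return A [validation_report()]; `ok` iff every entry restricts its
#'   master entry.
#' @export
check_subset <- function(group_vocab, master_vocab) {
  coll <- issue_collector()
  for (e in group_vocab$entries) {
    m <- vocab_get(master_vocab, e$key)
    if (is.null(m)) {
      coll$add(segment = "Validation", key = e$key, rule = "subset-unknown-key",
               message = paste0("group key '", e$key,
                                "' is absent from the master vocabulary"))
      next
    }
    if (m$vtype != e$vtype) {
      coll$add(segment = "Validation", key = e$key, rule = "subset-type-clash",
               message = paste0("group key '", e$key, "' has type ", e$vtype,
                                " but the master declares ", m$vtype))
      next
    }
    extra <- setdiff(tolower(canonicalize(e$allowed_values %||% character(0))),
                     tolower(canonicalize(m$allowed_values %||% character(0))))
    if (length(extra)) {
      coll$add(segment = "Validation", key = e$key,
               rule = "subset-extra-values",
               message = paste0("group key '", e$key, "' allows value(s) ",
                                "outside the master vocabulary: ",
                                paste(extra, collapse = ", ")))
    }
  }
  validation_report(coll$issues())
}

#' Merge two controlled vocabularies
#'
#' Unites two (differently extended) master vocabularies: the union of all
#' keys; for keys present in both with the same validation type, allowed
#' values are unioned preserving the first vocabulary's order followed by
#' the second's novel values. Keys whose validation types clash are left
#' out of the merge and reported as conflicts.
#'
#' @param a,b [vocabulary()] objects.
#' @return List with `vocabulary` (the merge) and `conflicts` (data frame
#'   with columns `key`, `vtype_a`, `vtype_b`; zero rows when conflict-free).
#' @export
merge_vocabularies <- function(a, b) {
  entries <- list()
  conflicts <- data.frame(key = character(0), vtype_a = character(0),
                          vtype_b = character(0), stringsAsFactors = FALSE)
  b_keys_l <- tolower(names(b$entries))
  for (ea in a$entries) {
    hit <- match(tolower(ea$key), b_keys_l)
    if (is.na(hit)) {
      entries[[length(entries) + 1L]] <- ea
      next
    }
    eb <- b$entries[[hit]]
    if (ea$vtype != eb$vtype) {
      conflicts <- rbind(conflicts, data.frame(
        key = ea$key, vtype_a = ea$vtype, vtype_b = eb$vtype,
        stringsAsFactors = FALSE))
      next
    }
    vals <- NULL
    if (ea$vtype %in% c("dropdown", "dropdown_multi")) {
      vals <- ea$allowed_values
      novel <- eb$allowed_values[!tolower(canonicalize(eb$allowed_values)) %in%
                                   tolower(canonicalize(vals))]
      vals <- c(vals, novel)
    }
    help <- if (nzchar(ea$help)) ea$help else eb$help
    entries[[length(entries) + 1L]] <-
      vocab_entry(ea$key, ea$vtype, help = help, allowed_values = vals)
  }
  a_keys_l <- tolower(names(a$entries))
  for (eb in b$entries) {
    if (!tolower(eb$key) %in% a_keys_l) {
      entries[[length(entries) + 1L]] <- eb
    }
  }
  list(vocabulary = vocabulary(entries), conflicts = conflicts)
}
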