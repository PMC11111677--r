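# Typed domain model for the metadata sheet: every section, segment and
# resource registry, with constructor-enforced invariants. I/O lives in
# sheet-io.R, cross-structure checks in validate.R.

#' Canonicalize a metadata value
#'
#' Trims leading/trailing whitespace and collapses internal whitespace runs
#' to a single space. Case is preserved; comparisons against controlled
#' vocabularies are case-insensitive on canonical forms (see
#' [vocab_match()]).
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @examples
#' canonicalize("  liver ")            # "liver"
#' canonicalize("BTO:0000759  liver")  # "BTO:0000759 liver"
#' @export
canonicalize <- function(x) {
  x <- as.character(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# case-insensitive equality on canonical forms
canon_eq <- function(a, b) tolower(canonicalize(a)) == tolower(canonicalize(b))

#' Match a value against a set of vocabulary values
#'
#' Case-insensitive comparison on canonical forms; returns the vocabulary's
#' canonical spelling of the matched value, or `NA_character_` when there is
#' no match.
#'
#' @param value A single string.
#' @param allowed Character vector of allowed values.
#' @return The matching element of `allowed`, or `NA_character_`.
#' @export
vocab_match <- function(value, allowed) {
  hit <- match(tolower(canonicalize(value)), tolower(canonicalize(allowed)))
  if (is.na(hit)) NA_character_ else allowed[[hit]]
}

VTYPES <- c("freetext", "date", "dropdown", "dropdown_multi")

# spreadsheet-facing tokens for the validation types
VTYPE_TOKENS <- c(
  freetext = "freetext", date = "date",
  dropdown = "DropDown", dropdown_multi = "DropDown_M"
)

#' Controlled-vocabulary entry
#'
#' One key of the controlled vocabulary: its validation type, help text and
#' (for the dropdown types) the ordered set of allowed values.
#'
#' @param key Identifier string (non-empty).
#' @param vtype One of `"freetext"`, `"date"`, `"dropdown"`,
#'   `"dropdown_multi"`.
#' @param help Free-text help string.
#' @param allowed_values Character vector; required (non-empty) iff `vtype`
#'   is a dropdown type, and must be absent otherwise. Values must be unique
#'   after canonicalization.
#' @return An object of class `ms_vocab_entry`.
#' @export
vocab_entry <- function(key, vtype, help = "", allowed_values = NULL) {
  key <- canonicalize(key)
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  vtype <- match.arg(vtype, VTYPES)
  if (vtype %in% c("dropdown", "dropdown_multi")) {
    if (is.null(allowed_values) || length(allowed_values) == 0L) {
      stop("vocab_entry: allowed_values required for dropdown key '", key, "'",
           call. = FALSE)
    }
    allowed_values <- canonicalize(allowed_values)
    if (anyDuplicated(tolower(allowed_values))) {
      stop("vocab_entry: duplicate allowed_values for key '", key, "'",
           call. = FALSE)
    }
  } else if (!is.null(allowed_values) && length(allowed_values) > 0L) {
    stop("vocab_entry: allowed_values not permitted for ", vtype, " key '",
         key, "'", call. = FALSE)
  } else {
    allowed_values <- NULL
  }
  structure(
    list(key = key, vtype = vtype, help = as.character(help),
         allowed_values = allowed_values),
    class = "ms_vocab_entry"
  )
}

#' Controlled vocabulary
#'
#' A keyed collection of [vocab_entry()] objects, optionally labelled as a
#' group-specific subset (`Validation_[Group]` sheet). Subset conformance
#' against a master vocabulary is checked by [check_subset()].
#'
#' @param entries List of `ms_vocab_entry` objects; keys must be unique
#'   (case-insensitively, on canonical forms).
#' @param group_label Optional group name for a group-specific subset.
#' @return An object of class `ms_vocabulary`.
#' @export
vocabulary <- function(entries = list(), group_label = NULL) {
  stopifnot(is.list(entries))
  for (e in entries) {
    if (!inherits(e, "ms_vocab_entry")) {
      stop("vocabulary: entries must be vocab_entry objects", call. = FALSE)
    }
  }
  keys <- vapply(entries, function(e) e$key, character(1))
  if (anyDuplicated(tolower(keys))) {
    stop("vocabulary: duplicate keys: ",
         paste(keys[duplicated(tolower(keys))], collapse = ", "),
         call. = FALSE)
  }
  names(entries) <- keys
  structure(list(entries = entries, group_label = group_label),
            class = "ms_vocabulary")
}

#' @export
print.ms_vocabulary <- function(x, ...) {
  cat("<vocabulary>", length(x$entries), "keys",
      if (!is.null(x$group_label)) paste0("(group: ", x$group_label, ")"),
      "\n")
  invisible(x)
}

# case-insensitive key lookup; NULL when absent
vocab_get <- function(vocab, key) {
  hit <- match(tolower(canonicalize(key)), tolower(names(vocab$entries)))
  if (is.na(hit)) NULL else vocab$entries[[hit]]
}

vocab_has <- function(vocab, key) !is.null(vocab_get(vocab, key))

REGISTRY_CATEGORIES <- c("experimental_system", "measurement_type")

reg_id <- function(category, instance) {
  paste(category, tolower(canonicalize(instance)), sep = "\x1f")
}

#' Dependent-field registry
#'
#' Maps an (category, instance) pair -- e.g. (`experimental_system`,
#' `mouse`) or (`measurement_type`, `bulk_RNA_seq`) -- to the ordered list
#' of dependent keys that must be filled once that instance is selected.
#'
#' @param entries List of entries, each a list with elements `category`
#'   (one of `"experimental_system"`, `"measurement_type"`), `instance`
#'   (string) and `keys` (ordered character vector).
#' @return An object of class `ms_registry`.
#' @export
dependent_registry <- function(entries = list()) {
  stopifnot(is.list(entries))
  ids <- character(0)
  for (e in entries) {
    stopifnot(is.list(e), all(c("category", "instance", "keys") %in% names(e)))
    if (!e$category %in% REGISTRY_CATEGORIES) {
      stop("dependent_registry: unknown category '", e$category, "'",
           call. = FALSE)
    }
    ids <- c(ids, reg_id(e$category, e$instance))
  }
  if (anyDuplicated(ids)) {
    stop("dependent_registry: duplicate (category, instance) entries",
         call. = FALSE)
  }
  names(entries) <- ids
  structure(list(entries = entries), class = "ms_registry")
}

registry_get <- function(registry, category, instance) {
  registry$entries[[reg_id(category, instance)]]
}

#' @export
print.ms_registry <- function(x, ...) {
  cat("<dependent-field registry>", length(x$entries), "entries\n")
  invisible(x)
}

#' General project information segment
#'
#' @param name,affiliation,email Contact fields (free text).
#' @param project_title Free text.
#' @param in_collection Logical: is this sheet part of a collection of
#'   linked sheets?
#' @param linked_sheet_ids Character vector of UIDs of linked sheets; must
#'   be empty unless `in_collection` is `TRUE`.
#' @return Object of class `ms_general_info`.
#' @export
general_info <- function(name = "", affiliation = "", email = "",
                         project_title = "", in_collection = FALSE,
                         linked_sheet_ids = character(0)) {
  stopifnot(is.logical(in_collection), length(in_collection) == 1L)
  linked_sheet_ids <- as.character(linked_sheet_ids)
  if (!in_collection && length(linked_sheet_ids) > 0L) {
    stop("general_info: linked_sheet_ids given but in_collection is FALSE",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), affiliation = as.character(affiliation),
         email = as.character(email),
         project_title = as.character(project_title),
         in_collection = in_collection,
         linked_sheet_ids = linked_sheet_ids),
    class = "ms_general_info"
  )
}

#' Experimental-system segment
#'
#' @param system Vocabulary term naming the system (mouse, rat,
#'   human-derived, cell-line, patient, ...).
#' @param dependent_values Named list/character of values for the system's
#'   dependent keys. Completeness against the registry is checked by
#'   [validate_sheet()].
#' @return Object of class `ms_experimental_system`.
#' @export
experimental_system <- function(system = NA_character_,
                                dependent_values = list()) {
  dependent_values <- as.list(dependent_values)
  if (length(dependent_values) &&
      (is.null(names(dependent_values)) || any(!nzchar(names(dependent_values))))) {
    stop("experimental_system: dependent_values must be named", call. = FALSE)
  }
  structure(list(system = as.character(system),
                 dependent_values = dependent_values),
            class = "ms_experimental_system")
}

COMPARISON_CATEGORIES <- c("diet", "treatment", "genotype", "age",
                           "temperature", "other")

#' One instance of a comparison group
#'
#' @param label Non-empty instance label (e.g. a diet name).
#' @param details Named list of key:value details for this instance (one
#'   column of the segment's second-level table).
#' @return Object of class `ms_group_instance`.
#' @export
group_instance <- function(label, details = list()) {
  label <- canonicalize(label)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("group_instance: label must be a non-empty string", call. = FALSE)
  }
  structure(list(label = label, details = as.list(details)),
            class = "ms_group_instance")
}

#' Comparison group
#'
#' A contrasting experimental setting: one of the six categories with at
#' least one named instance.
#'
#' @param category One of `"diet"`, `"treatment"`, `"genotype"`, `"age"`,
#'   `"temperature"`, `"other"`.
#' @param instances List of [group_instance()] objects (>= 1); labels must
#'   be unique within the group.
#' @return Object of class `ms_comparison_group`.
#' @export
comparison_group <- function(category, instances) {
  category <- match.arg(category, COMPARISON_CATEGORIES)
  if (!is.list(instances) || length(instances) == 0L) {
    stop("comparison_group: at least one instance required", call. = FALSE)
  }
  instances <- lapply(instances, function(i) {
    if (inherits(i, "ms_group_instance")) i else group_instance(i)
  })
  labels <- vapply(instances, function(i) i$label, character(1))
  if (anyDuplicated(tolower(labels))) {
    stop("comparison_group: duplicate instance labels in group '", category,
         "'", call. = FALSE)
  }
  structure(list(category = category, instances = instances),
            class = "ms_comparison_group")
}

group_labels <- function(group) {
  vapply(group$instances, function(i) i$label, character(1))
}

#' Final experimental group
#'
#' One element of the Cartesian product of the comparison groups: an
#' assignment of one instance label per declared category, plus the number
#' of replicates measured in that combination.
#'
#' @param assignment Named character vector, one element per comparison
#'   group category.
#' @param n_replicates Positive integer, or `NA` when not yet entered
#'   (replicate counts have no default; a missing count is a validation
#'   error, not an implicit 1).
#' @return Object of class `ms_final_group`.
#' @export
final_group <- function(assignment, n_replicates = NA_integer_) {
  assignment <- stats::setNames(
    vapply(assignment, canonicalize, character(1), USE.NAMES = FALSE),
    names(assignment))
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("final_group: assignment must be named by category", call. = FALSE)
  }
  if (!is.na(n_replicates)) {
    n_replicates <- as.integer(n_replicates)
    if (is.na(n_replicates) || n_replicates < 1L) {
      stop("final_group: n_replicates must be a positive integer",
           call. = FALSE)
    }
  } else {
    n_replicates <- NA_integer_
  }
  structure(list(assignment = assignment, n_replicates = n_replicates),
            class = "ms_final_group")
}

final_group_label <- function(fg) paste(fg$assignment, collapse = " × ")

#' Covariate or constant declaration
#'
#' @param name Name of the variable.
#' @param unit Unit string (may be empty).
#' @param role `"constant"` (single value, given in place) or
#'   `"covariate"` (per-measurement values live in the ID table).
#' @param constant_value Required iff `role = "constant"`.
#' @return Object of class `ms_covariate_spec`.
#' @export
covariate_spec <- function(name, unit = "", role = c("covariate", "constant"),
                           constant_value = NULL) {
  role <- match.arg(role)
  name <- canonicalize(name)
  stopifnot(nzchar(name))
  if (role == "constant") {
    if (is.null(constant_value) || length(constant_value) != 1L) {
      stop("covariate_spec: constant '", name,
           "' requires exactly one constant_value", call. = FALSE)
    }
    constant_value <- as.character(constant_value)
  } else if (!is.null(constant_value)) {
    stop("covariate_spec: covariate '", name,
         "' must not carry a constant_value (values live in the ID table)",
         call. = FALSE)
  }
  structure(list(name = name, unit = as.character(unit), role = role,
                 constant_value = constant_value),
            class = "ms_covariate_spec")
}

#' Time-dependence / timeline segment
#'
#' An interrupted timeline enriches one comparison group with temporal
#' detail: `"continued"` (annotation only, e.g. repeated glucose-tolerance
#' tests) or `"discontinued"` (a mid-course change such as switching
#' agents). All sub-fields are present iff `interrupted` is `TRUE`.
#'
#' @param interrupted Logical.
#' @param kind `"continued"` or `"discontinued"` (iff interrupted).
#' @param enriched_group Comparison-group category to enrich.
#' @param time_unit Unit of the time steps.
#' @param steps Data frame with columns `time` and `event`, non-empty when
#'   interrupted.
#' @return Object of class `ms_timeline_spec`.
#' @export
timeline_spec <- function(interrupted = FALSE, kind = NULL,
                          enriched_group = NULL, time_unit = NULL,
                          steps = NULL) {
  stopifnot(is.logical(interrupted), length(interrupted) == 1L)
  if (interrupted) {
    kind <- match.arg(kind, c("continued", "discontinued"))
    if (is.null(enriched_group) || !nzchar(enriched_group)) {
      stop("timeline_spec: interrupted timeline requires enriched_group",
           call. = FALSE)
    }
    if (is.null(time_unit) || !nzchar(time_unit)) {
      stop("timeline_spec: interrupted timeline requires time_unit",
           call. = FALSE)
    }
    if (is.null(steps) || !is.data.frame(steps) || nrow(steps) == 0L) {
      stop("timeline_spec: interrupted timeline requires non-empty steps",
           call. = FALSE)
    }
    if (!all(c("time", "event") %in% names(steps))) {
      stop("timeline_spec: steps needs columns 'time' and 'event'",
           call. = FALSE)
    }
    steps <- data.frame(time = as.character(steps$time),
                        event = as.character(steps$event),
                        stringsAsFactors = FALSE)
  } else {
    if (!is.null(kind) || !is.null(enriched_group) || !is.null(time_unit) ||
        !is.null(steps)) {
      stop("timeline_spec: sub-fields only permitted when interrupted",
           call. = FALSE)
    }
  }
  structure(list(interrupted = interrupted, kind = kind,
                 enriched_group = enriched_group, time_unit = time_unit,
                 steps = steps),
            class = "ms_timeline_spec")
}

#' One level of sample partitioning
#'
#' @param n_per_parent Positive integer; number of division instances
#'   derived from each parent sample.
#' @param instances Data frame with columns `label`, `protocol`
#'   (vocabulary term or filename) and `n_replicates` (positive integer);
#'   must have exactly `n_per_parent` rows with unique labels.
#' @return Object of class `ms_division_level`.
#' @export
division_level <- function(n_per_parent, instances) {
  n_per_parent <- as.integer(n_per_parent)
  stopifnot(!is.na(n_per_parent), n_per_parent >= 1L, is.data.frame(instances))
  if (!all(c("label", "protocol", "n_replicates") %in% names(instances))) {
    stop("division_level: instances needs label, protocol, n_replicates",
         call. = FALSE)
  }
  if (nrow(instances) != n_per_parent) {
    stop("division_level: ", nrow(instances), " instances given but ",
         "n_per_parent is ", n_per_parent, call. = FALSE)
  }
  labels <- canonicalize(instances$label)
  if (anyDuplicated(tolower(labels))) {
    stop("division_level: duplicate instance labels", call. = FALSE)
  }
  reps <- as.integer(instances$n_replicates)
  if (any(is.na(reps) | reps < 1L)) {
    stop("division_level: n_replicates must be positive integers",
         call. = FALSE)
  }
  instances <- data.frame(label = labels,
                          protocol = as.character(instances$protocol),
                          n_replicates = reps, stringsAsFactors = FALSE)
  structure(list(n_per_parent = n_per_parent, instances = instances),
            class = "ms_division_level")
}

#' Sample-preparation segment
#'
#' @param protocol Vocabulary term or filename (relative path) of the
#'   preparation protocol.
#' @param divisions List of [division_level()] objects; at most two levels
#'   of sample partitioning are accommodated.
#' @return Object of class `ms_preparation_spec`.
#' @export
preparation_spec <- function(protocol = "", divisions = list()) {
  if (length(divisions) > 2L) {
    stop("preparation_spec: at most two levels of sample partitioning ",
         "are supported (", length(divisions), " given)", call. = FALSE)
  }
  for (d in divisions) {
    if (!inherits(d, "ms_division_level")) {
      stop("preparation_spec: divisions must be division_level objects",
           call. = FALSE)
    }
  }
  structure(list(protocol = as.character(protocol), divisions = divisions),
            class = "ms_preparation_spec")
}

#' Measurement segment
#'
#' @param measurement_type Vocabulary term (e.g. `bulk_RNA_seq`).
#' @param dependent_values Named list of values for the type's dependent
#'   keys.
#' @return Object of class `ms_measurement_spec`.
#' @export
measurement_spec <- function(measurement_type = NA_character_,
                             dependent_values = list()) {
  dependent_values <- as.list(dependent_values)
  if (length(dependent_values) &&
      (is.null(names(dependent_values)) || any(!nzchar(names(dependent_values))))) {
    stop("measurement_spec: dependent_values must be named", call. = FALSE)
  }
  structure(list(measurement_type = as.character(measurement_type),
                 dependent_values = dependent_values),
            class = "ms_measurement_spec")
}

LINKAGE_MODES <- c("id_in_filename", "single_file_for_all", "changes")

#' Data-file linkage segment
#'
#' Declares how measurement files are identified from personal IDs:
#' `id_in_filename` (the ID occurs in the file name), `single_file_for_all`
#' (one file, named in `comment`), or `changes` (per-ID filenames are
#' promoted to a row of the ID table via the CHANGES keyword).
#'
#' @param availability `"raw"` or `"processed"`.
#' @param mode One of `"id_in_filename"`, `"single_file_for_all"`,
#'   `"changes"`.
#' @param comment Filename (required non-empty for `single_file_for_all`)
#'   or free text.
#' @param processing_procedure Vocabulary term or filename; required iff
#'   `availability = "processed"`.
#' @return Object of class `ms_datafile_linkage`.
#' @export
datafile_linkage <- function(availability = c("raw", "processed"),
                             mode = LINKAGE_MODES, comment = "",
                             processing_procedure = NULL) {
  availability <- match.arg(availability)
  mode <- match.arg(mode)
  comment <- as.character(comment)
  if (mode == "single_file_for_all" && !nzchar(canonicalize(comment))) {
    stop("datafile_linkage: mode 'single_file_for_all' requires the ",
         "filename in `comment`", call. = FALSE)
  }
  if (availability == "processed" &&
      (is.null(processing_procedure) || !nzchar(processing_procedure))) {
    stop("datafile_linkage: processed data requires processing_procedure",
         call. = FALSE)
  }
  structure(list(availability = availability, mode = mode, comment = comment,
                 processing_procedure = processing_procedure),
            class = "ms_datafile_linkage")
}

ID_FIXED_ROWS_HEAD <- c("personal_ID", "final_group")
ID_FIXED_ROWS_TAIL <- c("replicate", "subsamples", "subsubsamples")
SUBTABLE_ROWS <- c("parent_ID", "personal_ID", "instance", "replicate")

#' ID-specific metadata table (Measurement-Matching section)
#'
#' Character matrices with one column per measured unit. The main table's
#' fixed rows are `personal_ID`, `final_group`, one row per comparison
#' category, `replicate`, `subsamples`, `subsubsamples`; dynamic rows carry
#' covariate values and CHANGES-promoted keys. Sub(sub)sample tables carry
#' `parent_ID`, `personal_ID`, `instance`, `replicate`. The measurement ID
#' belongs to the deepest populated table.
#'
#' @param main Character matrix with rownames; must contain the fixed rows.
#' @param subsample,subsubsample Optional character matrices with rownames
#'   starting with `parent_ID`; `subsubsample` requires `subsample`.
#' @return Object of class `ms_id_table`.
#' @export
id_table <- function(main, subsample = NULL, subsubsample = NULL) {
  check_tab <- function(m, fixed, what) {
    if (!is.matrix(m) || !is.character(m) || is.null(rownames(m))) {
      stop("id_table: ", what, " must be a character matrix with rownames",
           call. = FALSE)
    }
    missing <- setdiff(fixed, rownames(m))
    if (length(missing)) {
      stop("id_table: ", what, " lacks required row(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    m
  }
  main <- check_tab(main, c(ID_FIXED_ROWS_HEAD, ID_FIXED_ROWS_TAIL), "main")
  if (!is.null(subsubsample) && is.null(subsample)) {
    stop("id_table: subsubsample table requires a subsample table",
         call. = FALSE)
  }
  if (!is.null(subsample)) {
    subsample <- check_tab(subsample, SUBTABLE_ROWS, "subsample")
  }
  if (!is.null(subsubsample)) {
    subsubsample <- check_tab(subsubsample, SUBTABLE_ROWS, "subsubsample")
  }
  ids <- c(main["personal_ID", ],
           if (!is.null(subsample)) subsample["personal_ID", ],
           if (!is.null(subsubsample)) subsubsample["personal_ID", ])
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    stop("id_table: personal_ID values must be unique across the sheet (",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), ")",
         call. = FALSE)
  }
  check_parents <- function(child, parent, what) {
    refs <- child["parent_ID", ]
    refs <- refs[nzchar(refs)]
    up <- parent["personal_ID", ]
    bad <- setdiff(refs, up)
    if (length(bad)) {
      stop("id_table: ", what, " parent_ID value(s) not found one level up: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(subsample)) check_parents(subsample, main, "subsample")
  if (!is.null(subsubsample)) check_parents(subsubsample, subsample,
                                            "subsubsample")
  structure(list(main = main, subsample = subsample,
                 subsubsample = subsubsample),
            class = "ms_id_table")
}

# deepest populated table holds the measurement IDs
deepest_table <- function(tab) {
  if (!is.null(tab$subsubsample)) tab$subsubsample
  else if (!is.null(tab$subsample)) tab$subsample
  else tab$main
}

#' Measurement IDs of a sheet
#'
#' Personal IDs of the deepest populated table of the ID table (the level
#' at which the measurement happens).
#'
#' @param sheet A `ms_metadatasheet` (or an `ms_id_table`).
#' @return Character vector (possibly with empty strings when IDs are not
#'   yet filled).
#' @export
measurement_ids <- function(sheet) {
  tab <- if (inherits(sheet, "ms_id_table")) sheet else sheet$matching
  if (is.null(tab)) return(character(0))
  unname(deepest_table(tab)["personal_ID", ])
}

#' Assemble a metadata sheet
#'
#' The full three-section document: Planning (general info, experimental
#' system, comparison groups), Conduction (final groups, covariates,
#' timeline, preparation, measurement, data-file linkage) and
#' Measurement-Matching (the ID table). Sections fill in order; referential
#' consistency across sections is checked by [validate_sheet()].
#'
#' @param planning List with elements `general` ([general_info()]),
#'   `system` ([experimental_system()]) and `comparison_groups` (list of
#'   [comparison_group()]).
#' @param conduction List with elements `final_groups` (list of
#'   [final_group()]), `covariates` (list of [covariate_spec()]),
#'   `timeline` ([timeline_spec()]), `preparation` ([preparation_spec()]),
#'   `measurement` ([measurement_spec()]) and `linkage`
#'   ([datafile_linkage()]); each may be `NULL`/empty while the sheet is
#'   still being filled.
#' @param matching An [id_table()] or `NULL`.
#' @param uid Optional unique identifier string (assigned automatically on
#'   export when unset).
#' @return Object of class `ms_metadatasheet`.
#' @export
metadatasheet <- function(planning = NULL, conduction = NULL, matching = NULL,
                          uid = NULL) {
  if (is.null(planning)) {
    planning <- list(general = general_info(), system = experimental_system(),
                     comparison_groups = list())
  }
  stopifnot(all(c("general", "system", "comparison_groups") %in%
                  names(planning)))
  if (is.null(conduction)) {
    conduction <- list(final_groups = list(), covariates = list(),
                       timeline = timeline_spec(), preparation = NULL,
                       measurement = measurement_spec(), linkage = NULL)
  }
  stopifnot(all(c("final_groups", "covariates", "timeline", "preparation",
                  "measurement", "linkage") %in% names(conduction)))
  if (!is.null(matching) && !inherits(matching, "ms_id_table")) {
    stop("metadatasheet: matching must be an id_table or NULL", call. = FALSE)
  }
  structure(list(planning = planning, conduction = conduction,
                 matching = matching,
                 uid = if (is.null(uid)) NULL else as.character(uid)),
            class = "ms_metadatasheet")
}

#' @export
print.ms_metadatasheet <- function(x, ...) {
  ncg <- length(x$planning$comparison_groups)
  nfg <- length(x$conduction$final_groups)
  ncol_main <- if (is.null(x$matching)) 0L else ncol(x$matching$main)
  cat("<metadatasheet>",
      if (!is.null(x$uid)) paste0("uid=", x$uid) else "uid unset", "\n",
      " planning:   system=", x$planning$system$system %||% NA,
      ", ", ncg, " comparison group(s)\n",
      " conduction: ", nfg, " final group(s), type=",
      x$conduction$measurement$measurement_type, "\n",
      " matching:   ", ncol_main, " measured unit column(s)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Located validation issue
#'
#' @param section,segment,key Location of the finding (strings; may be
#'   empty).
#' @param column Column index within a tabular segment, or `NA`.
#' @param value The observed value.
#' @param rule Stable machine-readable issue code (e.g.
#'   `"off-vocabulary"`, `"unknown-key"`, `"blocked-by-upstream"`).
#' @param severity `"error"` or `"warning"`.
#' @param message Human-readable description.
#' @return Object of class `ms_issue`.
#' @export
validation_issue <- function(section = "", segment = "", key = "",
                             column = NA_integer_, value = NA_character_,
                             rule = "invalid", severity = c("error", "warning"),
                             message = "") {
  severity <- match.arg(severity)
  structure(
    list(section = section, segment = segment, key = key,
         column = as.integer(column), value = as.character(value),
         rule = rule, severity = severity, message = message),
    class = "ms_issue"
  )
}

#' Validation report
#'
#' @param issues List of [validation_issue()] objects. `ok` is `TRUE` iff
#'   no issue has severity `"error"`.
#' @return Object of class `ms_report`.
#' @export
validation_report <- function(issues = list()) {
  for (i in issues) stopifnot(inherits(i, "ms_issue"))
  ok <- !any(vapply(issues, function(i) i$severity == "error", logical(1)))
  structure(list(issues = issues, ok = ok), class = "ms_report")
}

report_errors <- function(report) {
  Filter(function(i) i$severity == "error", report$issues)
}

#' Turn a validation report into a data frame
#'
#' @param x An `ms_report`.
#' @param ... Unused.
#' @return Data frame with one row per issue.
#' @export
as.data.frame.ms_report <- function(x, ...) {
  if (length(x$issues) == 0L) {
    return(data.frame(section = character(0), segment = character(0),
                      key = character(0), column = integer(0),
                      value = character(0), rule = character(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$issues, function(i) {
    data.frame(section = i$section, segment = i$segment, key = i$key,
               column = i$column, value = i$value, rule = i$rule,
               severity = i$severity, message = i$message,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.ms_report <- function(x, ...) {
  cat("<validation report> ok =", x$ok, "-", length(x$issues), "issue(s)\n")
  df <- as.data.frame(x)
  if (nrow(df)) print(df[, c("severity", "rule", "section", "key", "message")])
  invisible(x)
}

#' Normalize a date value to ISO 8601
#'
#' Accepts ISO `YYYY-MM-DD`, dotted `DD.MM.YYYY`, slashed `DD/MM/YYYY`, and
#' spreadsheet serial day numbers (1899-12-30 epoch), returning
#' `YYYY-MM-DD`, or `NA_character_` when the value is not a recognizable
#' date.
#'
#' @param x A single value (string or number).
#' @return ISO date string or `NA_character_`.
#' @export
normalize_date <- function(x) {
  x <- canonicalize(as.character(x))
  if (!nzchar(x) || is.na(x)) return(NA_character_)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    d <- tryCatch(as.Date(x), error = function(e) NA)
    return(if (is.na(d)) NA_character_ else format(d, "%Y-%m-%d"))
  }
  if (grepl("^\\d{1,2}[./]\\d{1,2}[./]\\d{4}$", x)) {
    sep <- if (grepl("\\.", x)) "." else "/"
    parts <- as.integer(strsplit(x, sep, fixed = TRUE)[[1]])
    d <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", parts[3], parts[2],
                                  parts[1])),
                  error = function(e) NA)
    return(if (is.na(d)) NA_character_ else format(d, "%Y-%m-%d"))
  }
  if (grepl("^\\d+(\\.\\d+)?$", x)) {
    serial <- as.numeric(x)
    if (serial >= 1 && serial < 200000) {
      return(format(as.Date(serial, origin = "1899-12-30"), "%Y-%m-%d"))
    }
  }
  NA_character_
}

# UUID v4 string drawn from R's RNG, so that seeded fixture generation is
# fully deterministic (byte-identical workbooks for the same seed).
ms_uuid <- function() {
  hex <- sample(c(0:9, letters[1:6]), 32, replace = TRUE)
  hex[13] <- "4"
  hex[17] <- sample(c("8", "9", "a", "b"), 1)
  paste0(paste(hex[1:8], collapse = ""), "-",
         paste(hex[9:12], collapse = ""), "-",
         paste(hex[13:16], collapse = ""), "-",
         paste(hex[17:20], collapse = ""), "-",
         paste(hex[21:32], collapse = ""))
}

# reserved token promoting a key:value pair into an ID-table row;
# matched case-sensitively, uppercase only
CHANGES_TOKEN <- "CHANGES"
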