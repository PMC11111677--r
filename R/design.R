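# Planning/Conduction machinery: automatic dependent-key insertion,
# registry + vocabulary extension, factorial final-group expansion (the
# workbook's first 'generate' button) and timeline coherence checks.

sequential_error <- function(msg) {
  stop(errorCondition(msg, class = c("ms_sequential_error", "error")))
}

#' Dependent keys to insert for a chosen instance
#'
#' Once the experimental system or measurement type is chosen, the
#' registry's ordered key list for that instance is returned, ready to be
#' materialized as empty entries in the target segment.
#'
#' @param category `"experimental_system"` or `"measurement_type"`.
#' @param instance The chosen instance (e.g. `"mouse"`, `"bulk_RNA_seq"`).
#' @param registry A [dependent_registry()].
#' @return Ordered character vector of keys.
#' @export
insert_dependent_keys <- function(category, instance, registry) {
  category <- match.arg(category, REGISTRY_CATEGORIES)
  entry <- registry_get(registry, category, instance)
  if (is.null(entry)) {
    stop("no dependent keys registered for ", category, " '", instance,
         "'; extend the registry with extend_registry() to add this ",
         "instance", call. = FALSE)
  }
  entry$keys
}

#' Extend the dependent-field registry and the vocabulary together
#'
#' Appends a new dependent key to an instance's key list and creates the
#' matching vocabulary entry, mirroring the workbook rule that dependent
#' key sets can be extended but never changed: existing keys and existing
#' vocabulary entries are left untouched, and an attempt to redefine an
#' existing key's validation type is refused.
#'
#' @param registry A [dependent_registry()].
#' @param vocab The master [vocabulary()].
#' @param category,instance The registry entry to extend; created when
#'   absent.
#' @param new_key Key to append.
#' @param vtype Validation type of the new key.
#' @param allowed_values Allowed values (required for dropdown types).
#' @param help Help text for the new vocabulary entry.
#' @return List with the updated `registry` and `vocab`.
#' @export
extend_registry <- function(registry, vocab, category, instance, new_key,
                            vtype, allowed_values = NULL, help = "") {
  category <- match.arg(category, REGISTRY_CATEGORIES)
  new_key <- canonicalize(new_key)
  entry <- registry_get(registry, category, instance)
  if (!is.null(entry) &&
      tolower(new_key) %in% tolower(canonicalize(entry$keys))) {
    warning("key '", new_key, "' already registered for ", category, " '",
            instance, "'; nothing to do", call. = FALSE)
    return(list(registry = registry, vocab = vocab))
  }
  existing <- vocab_get(vocab, new_key)
  if (!is.null(existing)) {
    if (existing$vtype != vtype) {
      stop("key '", new_key, "' already exists in the vocabulary with type ",
           existing$vtype, "; existing keys can be extended, not changed",
           call. = FALSE)
    }
  } else {
    vocab$entries[[new_key]] <-
      vocab_entry(new_key, vtype, help = help,
                  allowed_values = allowed_values)
  }
  if (is.null(entry)) {
    entry <- list(category = category, instance = canonicalize(instance),
                  keys = character(0))
  }
  entry$keys <- c(entry$keys, new_key)
  registry$entries[[reg_id(category, instance)]] <- entry
  list(registry = registry, vocab = vocab)
}

#' Generate all final groups from the declared comparison groups
#'
#' The Cartesian product of the instance labels across all declared
#' comparison groups, in row-major order of declaration (the last-declared
#' group varies fastest). Replicate counts are left unset -- they are
#' entered per group after generation and are never defaulted.
#'
#' @param comparison_groups List of [comparison_group()] objects.
#' @return List of [final_group()] objects of length
#'   `prod(instance counts)`.
#' @export
generate_final_groups <- function(comparison_groups) {
  if (!is.list(comparison_groups) || length(comparison_groups) == 0L) {
    sequential_error(paste0("cannot generate final groups: the Planning ",
                            "section declares no comparison group"))
  }
  for (cg in comparison_groups) {
    if (!inherits(cg, "ms_comparison_group")) {
      sequential_error("comparison_groups must be comparison_group objects")
    }
    if (length(cg$instances) == 0L) {
      sequential_error(paste0("cannot generate final groups: comparison ",
                              "group '", cg$category, "' has no instance"))
    }
  }
  cats <- vapply(comparison_groups, function(g) g$category, character(1))
  labels <- lapply(comparison_groups, group_labels)
  # expand.grid varies the first factor fastest; feed the groups reversed
  # so the LAST-declared group varies fastest, then restore column order
  grid <- expand.grid(rev(labels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(labels)), drop = FALSE]
  names(grid) <- cats
  lapply(seq_len(nrow(grid)), function(i) {
    final_group(stats::setNames(as.character(grid[i, ]), cats))
  })
}

#' Check the timeline segment against the declared comparison groups
#'
#' @param spec A [timeline_spec()].
#' @param groups List of [comparison_group()] objects from Planning.
#' @return List of [validation_issue()]s; empty when the timeline is not
#'   interrupted (and carries no sub-fields) or when the enriched group is
#'   declared and the steps are non-empty.
#' @export
check_timeline <- function(spec, groups) {
  stopifnot(inherits(spec, "ms_timeline_spec"))
  if (!spec$interrupted) return(list())
  issues <- list()
  cats <- vapply(groups, function(g) g$category, character(1))
  if (!tolower(canonicalize(spec$enriched_group)) %in% tolower(cats)) {
    issues[[length(issues) + 1L]] <- validation_issue(
      section = "conduction", segment = "Timeline", key = "enriched_group",
      value = spec$enriched_group, rule = "undeclared-group",
      severity = "error",
      message = paste0("timeline enriches comparison group '",
                       spec$enriched_group,
                       "' which the Planning section does not declare"))
  }
  if (is.null(spec$steps) || nrow(spec$steps) == 0L) {
    issues[[length(issues) + 1L]] <- validation_issue(
      section = "conduction", segment = "Timeline", key = "steps",
      rule = "missing-steps", severity = "error",
      message = "interrupted timeline declared without time steps")
  }
  issues
}
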