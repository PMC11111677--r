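# Workbook layout reader/writer. Sheets: `Input` (the metadata sheet
# itself), `Validation` (controlled vocabulary, three header rows:
# validation type / help text / key), optional `Validation_[Group]`
# (group-specific subset, same layout) and `dependentFields` (two header
# rows: category / instance, then the enumerated dependent keys).
#
# Segment boundaries in `Input` are recognized by a registry of canonical
# header strings ("[SECTION] ...", "[SEGMENT] ..."); the fixture corpus
# defines this reference dialect. A hidden `ResetSheet`, if present, is
# ignored on read and never written.

SECTION_PLANNING <- "[SECTION] Planning"
SECTION_CONDUCTION <- "[SECTION] Conduction"
SECTION_MATCHING <- "[SECTION] Measurement-Matching"

SEG <- function(x) paste("[SEGMENT]", x)
SEGMENTS <- c("General", "Experimental System", "Comparison Groups",
              "Final Groups", "Covariates", "Timeline", "Preparation",
              "Measurement", "DataFiles-Linkage", "ID Table",
              "Subsample Table", "Subsubsample Table")

MODE_TOKENS <- c(id_in_filename = "ID contained in filename",
                 single_file_for_all = "single file for all",
                 changes = "CHANGES")

bool_token <- function(x) if (isTRUE(x)) "yes" else "no"
parse_bool <- function(x) {
  x <- tolower(canonicalize(x %||% ""))
  if (x == "yes") TRUE else if (x %in% c("no", "")) FALSE else NA
}

layout_error <- function(msg) {
  stop(errorCondition(msg, class = c("ms_layout_error", "error")))
}

# ---------------------------------------------------------------------------
# grid helpers

pad_rows <- function(rows) {
  if (length(rows) == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  w <- max(vapply(rows, length, integer(1)))
  m <- do.call(rbind, lapply(rows, function(r)
    matrix(c(r, rep("", w - length(r))), nrow = 1)))
  m[is.na(m)] <- ""
  m
}

grid_cell <- function(grid, r, c) {
  if (r > nrow(grid) || c > ncol(grid)) return("")
  v <- grid[r, c]
  if (is.na(v)) "" else v
}

# strip trailing all-empty columns from a segment block
trim_block <- function(block) {
  if (ncol(block) == 0L) return(block)
  keep <- max(c(0L, which(apply(block, 2, function(col) any(nzchar(col))))))
  block[, seq_len(keep), drop = FALSE]
}

# ---------------------------------------------------------------------------
# vocabulary / dependent-fields grids

#' Read a controlled vocabulary from a cell grid
#'
#' The grid follows the three-header-row layout: per column the validation
#' type (`freetext`, `date`, `DropDown`, `DropDown_M`), a help text, the
#' key, and -- for the dropdown types -- the allowed values from row four
#' downward.
#'
#' @param grid Character matrix of cells.
#' @param group_label Optional group label for a `Validation_[Group]`
#'   subset sheet.
#' @return A [vocabulary()].
#' @export
read_vocabulary <- function(grid, group_label = NULL) {
  grid[is.na(grid)] <- ""
  entries <- list()
  for (col in seq_len(ncol(grid))) {
    token <- canonicalize(grid_cell(grid, 1L, col))
    key <- canonicalize(grid_cell(grid, 3L, col))
    if (!nzchar(token) && !nzchar(key)) next  # empty column
    vt <- names(VTYPE_TOKENS)[match(tolower(token), tolower(VTYPE_TOKENS))]
    if (is.na(vt) || length(vt) == 0L) {
      layout_error(paste0("Validation column ", col,
                          ": unknown validation-type token '", token, "'"))
    }
    if (!nzchar(key)) {
      layout_error(paste0("Validation column ", col, ": key missing"))
    }
    vals <- NULL
    if (vt %in% c("dropdown", "dropdown_multi")) {
      if (nrow(grid) >= 4L) {
        vals <- grid[4:nrow(grid), col]
        vals <- canonicalize(vals[nzchar(canonicalize(vals))])
      }
      if (length(vals) == 0L) {
        layout_error(paste0("Validation column ", col, " ('", key,
                            "'): dropdown without allowed values"))
      }
    }
    entries[[length(entries) + 1L]] <-
      vocab_entry(key, vt, help = grid_cell(grid, 2L, col),
                  allowed_values = vals)
  }
  vocabulary(entries, group_label = group_label)
}

#' Read a dependent-field registry from a cell grid
#'
#' Two header rows per column: the general category (`experimental system`
#' or `measurement type`) and the instance; the dependent keys are
#' enumerated below.
#'
#' @param grid Character matrix of cells.
#' @return A [dependent_registry()].
#' @export
read_dependent_fields <- function(grid) {
  grid[is.na(grid)] <- ""
  entries <- list()
  seen <- character(0)
  for (col in seq_len(ncol(grid))) {
    cat_token <- tolower(canonicalize(grid_cell(grid, 1L, col)))
    inst <- canonicalize(grid_cell(grid, 2L, col))
    if (!nzchar(cat_token) && !nzchar(inst)) next  # empty column
    category <- switch(gsub("[ _]", " ", cat_token),
                       "experimental system" = "experimental_system",
                       "measurement type" = "measurement_type",
                       NA_character_)
    if (is.na(category)) {
      layout_error(paste0("dependentFields column ", col,
                          ": unknown category token '", cat_token, "'"))
    }
    if (!nzchar(inst)) {
      layout_error(paste0("dependentFields column ", col,
                          ": instance missing"))
    }
    id <- reg_id(category, inst)
    if (id %in% seen) {
      layout_error(paste0("dependentFields column ", col,
                          ": duplicate entry for (", category, ", ", inst,
                          ")"))
    }
    seen <- c(seen, id)
    keys <- character(0)
    if (nrow(grid) >= 3L) {
      keys <- canonicalize(grid[3:nrow(grid), col])
      keys <- keys[nzchar(keys)]
    }
    entries[[length(entries) + 1L]] <-
      list(category = category, instance = inst, keys = keys)
  }
  dependent_registry(entries)
}

vocabulary_grid <- function(vocab) {
  rows <- list()
  n <- length(vocab$entries)
  if (n == 0L) return(matrix("", nrow = 3, ncol = 1))
  maxvals <- max(c(0L, vapply(vocab$entries, function(e)
    length(e$allowed_values %||% character(0)), integer(1))))
  grid <- matrix("", nrow = 3L + maxvals, ncol = n)
  for (j in seq_len(n)) {
    e <- vocab$entries[[j]]
    grid[1, j] <- VTYPE_TOKENS[[e$vtype]]
    grid[2, j] <- e$help
    grid[3, j] <- e$key
    av <- e$allowed_values %||% character(0)
    if (length(av)) grid[3L + seq_along(av), j] <- av
  }
  grid
}

registry_grid <- function(registry) {
  n <- length(registry$entries)
  if (n == 0L) return(matrix("", nrow = 2, ncol = 1))
  maxkeys <- max(vapply(registry$entries, function(e) length(e$keys),
                        integer(1)))
  grid <- matrix("", nrow = 2L + maxkeys, ncol = n)
  cat_token <- c(experimental_system = "experimental system",
                 measurement_type = "measurement type")
  for (j in seq_len(n)) {
    e <- registry$entries[[j]]
    grid[1, j] <- cat_token[[e$category]]
    grid[2, j] <- e$instance
    if (length(e$keys)) grid[2L + seq_along(e$keys), j] <- e$keys
  }
  grid
}

# ---------------------------------------------------------------------------
# Input sheet serialization

kv_row <- function(key, ...) c(key, as.character(c(...)))

input_grid <- function(sheet) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- kv_row(...)

  add(SECTION_PLANNING)
  add(SEG("General"))
  g <- sheet$planning$general
  add("name", g$name)
  add("affiliation", g$affiliation)
  add("email", g$email)
  add("project_title", g$project_title)
  add("in_collection", bool_token(g$in_collection))
  add("linked_sheet_ids", paste(g$linked_sheet_ids, collapse = ";"))
  add("UID", sheet$uid %||% "")

  add(SEG("Experimental System"))
  es <- sheet$planning$system
  add("experimental_system", if (is.na(es$system)) "" else es$system)
  for (k in names(es$dependent_values)) add(k, es$dependent_values[[k]])

  add(SEG("Comparison Groups"))
  for (cg in sheet$planning$comparison_groups) {
    add("comparison_group", cg$category)
    add("instance", group_labels(cg))
    detail_keys <- unique(unlist(lapply(cg$instances,
                                        function(i) names(i$details))))
    for (k in detail_keys %||% character(0)) {
      add(k, vapply(cg$instances, function(i)
        as.character(i$details[[k]] %||% ""), character(1)))
    }
  }

  add(SECTION_CONDUCTION)
  add(SEG("Final Groups"))
  fgs <- sheet$conduction$final_groups
  if (length(fgs)) {
    add("final_group", vapply(fgs, final_group_label, character(1)))
    for (cat in names(fgs[[1]]$assignment)) {
      add(cat, vapply(fgs, function(f) unname(f$assignment[[cat]]),
                      character(1)))
    }
    add("n_replicates", vapply(fgs, function(f)
      if (is.na(f$n_replicates)) "" else as.character(f$n_replicates),
      character(1)))
  }

  add(SEG("Covariates"))
  covs <- sheet$conduction$covariates
  if (length(covs)) {
    add("covariate", vapply(covs, function(x) x$name, character(1)))
    add("unit", vapply(covs, function(x) x$unit, character(1)))
    add("role", vapply(covs, function(x) x$role, character(1)))
    add("value", vapply(covs, function(x) x$constant_value %||% "",
                        character(1)))
  }

  add(SEG("Timeline"))
  tl <- sheet$conduction$timeline %||% timeline_spec()
  add("interrupted", bool_token(tl$interrupted))
  if (tl$interrupted) {
    add("kind", tl$kind)
    add("enriched_group", tl$enriched_group)
    add("time_unit", tl$time_unit)
    add("time", tl$steps$time)
    add("event", tl$steps$event)
  }

  add(SEG("Preparation"))
  prep <- sheet$conduction$preparation
  if (!is.null(prep)) {
    add("protocol", prep$protocol)
    for (i in seq_along(prep$divisions)) {
      d <- prep$divisions[[i]]
      add("division", as.character(i))
      add("n_per_parent", as.character(d$n_per_parent))
      add("instance", d$instances$label)
      add("instance_protocol", d$instances$protocol)
      add("instance_replicates", as.character(d$instances$n_replicates))
    }
  }

  add(SEG("Measurement"))
  me <- sheet$conduction$measurement
  add("measurement_type", if (is.na(me$measurement_type)) "" else
    me$measurement_type)
  for (k in names(me$dependent_values)) add(k, me$dependent_values[[k]])

  add(SEG("DataFiles-Linkage"))
  lk <- sheet$conduction$linkage
  if (!is.null(lk)) {
    add("availability", lk$availability)
    add("mode", MODE_TOKENS[[lk$mode]])
    add("comment", lk$comment)
    add("processing_procedure", lk$processing_procedure %||% "")
  }

  add(SECTION_MATCHING)
  tab <- sheet$matching
  if (!is.null(tab)) {
    add(SEG("ID Table"))
    for (r in rownames(tab$main)) add(r, tab$main[r, ])
    if (!is.null(tab$subsample)) {
      add(SEG("Subsample Table"))
      for (r in rownames(tab$subsample)) add(r, tab$subsample[r, ])
    }
    if (!is.null(tab$subsubsample)) {
      add(SEG("Subsubsample Table"))
      for (r in rownames(tab$subsubsample)) add(r, tab$subsubsample[r, ])
    }
  }

  pad_rows(rows)
}

# ---------------------------------------------------------------------------
# Input sheet parsing

# split the Input grid into named segment blocks (list of row lists)
split_segments <- function(grid) {
  grid[is.na(grid)] <- ""
  segs <- list()
  cur <- NULL
  for (r in seq_len(nrow(grid))) {
    head <- canonicalize(grid[r, 1])
    if (startsWith(head, "[SECTION]")) {
      cur <- NULL
      next
    }
    if (startsWith(head, "[SEGMENT]")) {
      cur <- sub("^\\[SEGMENT\\] *", "", head)
      segs[[cur]] <- list()
      next
    }
    if (is.null(cur) || !nzchar(head)) next
    vals <- if (ncol(grid) >= 2L) grid[r, -1] else character(0)
    keep <- max(c(0L, which(nzchar(vals))))
    segs[[cur]][[length(segs[[cur]]) + 1L]] <-
      list(key = head, values = as.character(vals[seq_len(keep)]))
  }
  segs
}

seg_rows <- function(seg, key) {
  Filter(function(r) canon_eq(r$key, key), seg %||% list())
}

seg_value <- function(seg, key, default = "") {
  rows <- seg_rows(seg, key)
  if (length(rows) == 0L || length(rows[[1]]$values) == 0L) return(default)
  rows[[1]]$values[[1]]
}

# rows of a segment as a character matrix (rownames = keys), uniform width
seg_matrix <- function(seg) {
  if (length(seg %||% list()) == 0L) return(NULL)
  keys <- vapply(seg, function(r) r$key, character(1))
  w <- max(vapply(seg, function(r) length(r$values), integer(1)))
  if (w == 0L) w <- 1L
  m <- do.call(rbind, lapply(seg, function(r)
    matrix(c(r$values, rep("", w - length(r$values))), nrow = 1)))
  m[is.na(m)] <- ""
  rownames(m) <- keys
  m
}

parse_input_grid <- function(grid) {
  issues <- list()
  note <- function(segment, rule, message, severity = "error") {
    issues[[length(issues) + 1L]] <<- validation_issue(
      section = "", segment = segment, rule = rule, severity = severity,
      message = message)
  }
  segs <- split_segments(grid)

  safely <- function(segment, default, expr) {
    tryCatch(expr, error = function(e) {
      note(segment, "unparseable-segment", conditionMessage(e))
      default
    })
  }

  general <- safely("General", general_info(), {
    g <- segs[["General"]]
    linked <- canonicalize(seg_value(g, "linked_sheet_ids"))
    linked <- if (nzchar(linked)) strsplit(linked, ";", fixed = TRUE)[[1]]
              else character(0)
    general_info(
      name = seg_value(g, "name"), affiliation = seg_value(g, "affiliation"),
      email = seg_value(g, "email"),
      project_title = seg_value(g, "project_title"),
      in_collection = isTRUE(parse_bool(seg_value(g, "in_collection"))),
      linked_sheet_ids = canonicalize(linked))
  })
  uid <- canonicalize(seg_value(segs[["General"]], "UID"))
  if (!nzchar(uid)) uid <- NULL

  system <- safely("Experimental System", experimental_system(), {
    s <- segs[["Experimental System"]]
    sys_val <- canonicalize(seg_value(s, "experimental_system"))
    dep <- list()
    for (r in s %||% list()) {
      if (canon_eq(r$key, "experimental_system")) next
      dep[[r$key]] <- if (length(r$values)) r$values[[1]] else ""
    }
    experimental_system(if (nzchar(sys_val)) sys_val else NA_character_, dep)
  })

  comparison_groups <- local({
    out <- list()
    s <- segs[["Comparison Groups"]] %||% list()
    # partition rows into per-group chunks at each 'comparison_group' row
    starts <- which(vapply(s, function(r)
      canon_eq(r$key, "comparison_group"), logical(1)))
    for (i in seq_along(starts)) {
      lo <- starts[i]
      hi <- if (i < length(starts)) starts[i + 1] - 1L else length(s)
      chunk <- s[lo:hi]
      g <- safely("Comparison Groups", NULL, {
        category <- canonicalize(chunk[[1]]$values[1] %||% "")
        labels <- canonicalize(seg_rows(chunk, "instance")[[1]]$values)
        details_rows <- Filter(function(r)
          !canon_eq(r$key, "comparison_group") && !canon_eq(r$key, "instance"),
          chunk)
        instances <- lapply(seq_along(labels), function(j) {
          det <- list()
          for (r in details_rows) {
            det[[r$key]] <- if (j <= length(r$values)) r$values[[j]] else ""
          }
          group_instance(labels[[j]], det)
        })
        comparison_group(category, instances)
      })
      if (!is.null(g)) out[[length(out) + 1L]] <- g
    }
    out
  })

  final_groups <- local({
    s <- segs[["Final Groups"]] %||% list()
    if (length(s) == 0L) return(list())
    safely("Final Groups", list(), {
      m <- seg_matrix(s)
      keys <- rownames(m)
      cat_rows <- setdiff(keys, c("final_group", "n_replicates"))
      n <- ncol(m)
      lapply(seq_len(n), function(j) {
        assignment <- vapply(cat_rows, function(k) m[k, j], character(1))
        reps <- canonicalize(m["n_replicates", j])
        final_group(assignment,
                    if (nzchar(reps)) as.integer(reps) else NA_integer_)
      })
    })
  })

  covariates <- local({
    s <- segs[["Covariates"]] %||% list()
    if (length(s) == 0L) return(list())
    safely("Covariates", list(), {
      m <- seg_matrix(s)
      n <- ncol(m)
      lapply(seq_len(n), function(j) {
        role <- tolower(canonicalize(m["role", j]))
        val <- m["value", j]
        covariate_spec(m["covariate", j], unit = m["unit", j], role = role,
                       constant_value = if (role == "constant") val else NULL)
      })
    })
  })

  timeline <- safely("Timeline", timeline_spec(), {
    s <- segs[["Timeline"]]
    interrupted <- parse_bool(seg_value(s, "interrupted"))
    if (is.na(interrupted)) {
      stop("interrupted must be yes or no", call. = FALSE)
    }
    if (!interrupted) timeline_spec() else {
      times <- seg_rows(s, "time")
      events <- seg_rows(s, "event")
      steps <- data.frame(
        time = if (length(times)) times[[1]]$values else character(0),
        event = if (length(events)) events[[1]]$values else character(0),
        stringsAsFactors = FALSE)
      timeline_spec(TRUE, kind = tolower(canonicalize(seg_value(s, "kind"))),
                    enriched_group = canonicalize(seg_value(s, "enriched_group")),
                    time_unit = seg_value(s, "time_unit"), steps = steps)
    }
  })

  preparation <- local({
    s <- segs[["Preparation"]] %||% list()
    if (length(s) == 0L) return(NULL)
    safely("Preparation", NULL, {
      divisions <- list()
      starts <- which(vapply(s, function(r) canon_eq(r$key, "division"),
                             logical(1)))
      for (i in seq_along(starts)) {
        lo <- starts[i]
        hi <- if (i < length(starts)) starts[i + 1] - 1L else length(s)
        chunk <- s[lo:hi]
        inst <- seg_rows(chunk, "instance")[[1]]$values
        prot <- seg_rows(chunk, "instance_protocol")[[1]]$values
        reps <- seg_rows(chunk, "instance_replicates")[[1]]$values
        divisions[[i]] <- division_level(
          as.integer(canonicalize(seg_value(chunk, "n_per_parent"))),
          data.frame(label = inst,
                     protocol = c(prot, rep("", length(inst) - length(prot))),
                     n_replicates = as.integer(reps),
                     stringsAsFactors = FALSE))
      }
      preparation_spec(seg_value(s, "protocol"), divisions)
    })
  })

  measurement <- safely("Measurement", measurement_spec(), {
    s <- segs[["Measurement"]]
    mt <- canonicalize(seg_value(s, "measurement_type"))
    dep <- list()
    for (r in s %||% list()) {
      if (canon_eq(r$key, "measurement_type")) next
      dep[[r$key]] <- if (length(r$values)) r$values[[1]] else ""
    }
    measurement_spec(if (nzchar(mt)) mt else NA_character_, dep)
  })

  linkage <- local({
    s <- segs[["DataFiles-Linkage"]] %||% list()
    if (length(s) == 0L) return(NULL)
    safely("DataFiles-Linkage", NULL, {
      token <- canonicalize(seg_value(s, "mode"))
      mode <- names(MODE_TOKENS)[match(tolower(token), tolower(MODE_TOKENS))]
      if (is.na(mode)) stop("unknown linkage mode token '", token, "'",
                            call. = FALSE)
      proc <- canonicalize(seg_value(s, "processing_procedure"))
      datafile_linkage(
        availability = tolower(canonicalize(seg_value(s, "availability"))),
        mode = mode, comment = seg_value(s, "comment"),
        processing_procedure = if (nzchar(proc)) proc else NULL)
    })
  })

  matching <- local({
    main <- segs[["ID Table"]]
    if (is.null(main) || length(main) == 0L) return(NULL)
    safely("ID Table", NULL, {
      id_table(seg_matrix(main),
               subsample = seg_matrix(segs[["Subsample Table"]]),
               subsubsample = seg_matrix(segs[["Subsubsample Table"]]))
    })
  })

  sheet <- metadatasheet(
    planning = list(general = general, system = system,
                    comparison_groups = comparison_groups),
    conduction = list(final_groups = final_groups, covariates = covariates,
                      timeline = timeline, preparation = preparation,
                      measurement = measurement, linkage = linkage),
    matching = matching, uid = uid)
  list(sheet = sheet, issues = issues)
}

# ---------------------------------------------------------------------------
# workbook-level read/write

read_sheet_grid <- function(path, sheet) {
  suppressMessages(
    df <- readxl::read_excel(path, sheet = sheet, col_names = FALSE,
                             col_types = "text",
                             .name_repair = "minimal"))
  if (nrow(df) == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  m <- as.matrix(df)
  m[is.na(m)] <- ""
  unname(m)
}

#' Read a metadata workbook
#'
#' Parses the `Input`, `Validation`, optional `Validation_[Group]` and
#' `dependentFields` sheets of a workbook into the typed model. Parsing is
#' total: unparseable segments are attached to the result as issues on a
#' partial model rather than raised; only a missing required sheet or a
#' malformed resource layout is fatal.
#'
#' @param path Path to an `.xlsx` workbook.
#' @return List with elements `sheet` ([metadatasheet()]), `vocab`
#'   ([vocabulary()]), `registry` ([dependent_registry()]), `group_vocab`
#'   (a group-subset [vocabulary()] or `NULL`) and `issues` (list of parse
#'   issues).
#' @export
read_metadatasheet <- function(path) {
  if (!file.exists(path)) layout_error(paste0("file not found: ", path))
  sheets <- readxl::excel_sheets(path)
  if (!"Input" %in% sheets) {
    layout_error("workbook has no 'Input' sheet")
  }
  if (!"Validation" %in% sheets) {
    layout_error(paste0("workbook has no 'Validation' sheet; supply the ",
                        "controlled-vocabulary resource"))
  }
  if (!"dependentFields" %in% sheets) {
    layout_error(paste0("workbook has no 'dependentFields' sheet; supply ",
                        "the dependent-field resource"))
  }
  vocab <- read_vocabulary(read_sheet_grid(path, "Validation"))
  registry <- read_dependent_fields(read_sheet_grid(path, "dependentFields"))
  group_vocab <- NULL
  group_sheets <- setdiff(grep("^Validation_", sheets, value = TRUE),
                          "Validation")
  if (length(group_sheets)) {
    group_vocab <- read_vocabulary(
      read_sheet_grid(path, group_sheets[[1]]),
      group_label = sub("^Validation_", "", group_sheets[[1]]))
  }
  parsed <- parse_input_grid(read_sheet_grid(path, "Input"))
  list(sheet = parsed$sheet, vocab = vocab, registry = registry,
       group_vocab = group_vocab, issues = parsed$issues)
}

#' Write a metadata workbook
#'
#' Writes a macro-free `.xlsx` workbook with the `Input`, `Validation`,
#' optional `Validation_[Group]` and `dependentFields` sheets.
#' Reading the written file back reproduces the model field-for-field. A
#' sheet without a UID is assigned a fresh one (UUID v4, drawn from R's
#' RNG) on export; an existing UID is kept unchanged.
#'
#' @param sheet A [metadatasheet()].
#' @param vocab The master [vocabulary()].
#' @param registry The [dependent_registry()].
#' @param path Output path.
#' @param group_vocab Optional group-subset vocabulary (written as
#'   `Validation_[Group]`).
#' @param force Write even if [validate_sheet()] reports errors.
#' @return The (possibly UID-assigned) sheet, invisibly.
#' @export
write_metadatasheet <- function(sheet, vocab, registry, path,
                                group_vocab = NULL, force = FALSE) {
  stopifnot(inherits(sheet, "ms_metadatasheet"))
  if (!force) {
    report <- validate_sheet(sheet, vocab, registry, group_vocab = group_vocab)
    if (!report$ok) {
      stop("refusing to write a sheet with validation errors (use force ",
           "= TRUE to override):\n",
           paste(vapply(report_errors(report), function(i) i$message,
                        character(1)), collapse = "\n"),
           call. = FALSE)
    }
  }
  if (is.null(sheet$uid)) sheet$uid <- ms_uuid()
  grids <- list(Input = input_grid(sheet),
                Validation = vocabulary_grid(vocab))
  if (!is.null(group_vocab)) {
    label <- group_vocab$group_label %||% "Group"
    grids[[paste0("Validation_", label)]] <- vocabulary_grid(group_vocab)
  }
  grids[["dependentFields"]] <- registry_grid(registry)
  write_xlsx_grids(grids, path)
  invisible(sheet)
}
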