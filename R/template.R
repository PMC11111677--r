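# Reset/template machinery, mirroring the workbook's Reset button: a blank
# sheet, or a new sheet seeded from an existing one with all crucial IDs
# cleared.

#' Create a blank metadata sheet
#'
#' All segments present, no values; final groups and the matching table
#' are absent (not empty tables). A blank sheet validates with only
#' incompleteness warnings.
#'
#' @param vocab,registry The sheet's resources (unused by the blank sheet
#'   itself, accepted so callers can thread them through).
#' @return A [metadatasheet()].
#' @export
new_blank <- function(vocab = NULL, registry = NULL) {
  metadatasheet()
}

#' Derive a new sheet from a template
#'
#' Copies the Planning and Conduction sections verbatim and regenerates the
#' Measurement-Matching structure with every `personal_ID` (and
#' `parent_ID`) cleared, so the one thing a template cannot hand down --
#' the crucial measurement IDs -- must be re-entered. Per-measurement
#' covariate values and promoted-row values are cleared too (they describe
#' the old samples); covariate declarations are kept. The UID is cleared
#' and reassigned on the next export. A template whose Conduction section
#' is invalid contributes its Planning section only, with a warning.
#'
#' @param template A [metadatasheet()] (complete or partial).
#' @return A new [metadatasheet()].
#' @export
from_template <- function(template) {
  stopifnot(inherits(template, "ms_metadatasheet"))
  out <- metadatasheet(planning = template$planning,
                       conduction = template$conduction,
                       matching = NULL, uid = NULL)

  fgs <- template$conduction$final_groups
  reps <- vapply(fgs, function(f) f$n_replicates, integer(1))
  conduction_usable <- length(fgs) > 0L && !anyNA(reps)

  if (is.null(template$matching)) {
    return(out)
  }
  if (!conduction_usable) {
    warning("template's Conduction section is incomplete; copying the ",
            "Planning section only", call. = FALSE)
    out$conduction <- list(final_groups = list(), covariates = list(),
                           timeline = timeline_spec(), preparation = NULL,
                           measurement = measurement_spec(), linkage = NULL)
    return(out)
  }

  clear_rows <- function(m, rows) {
    for (r in intersect(rows, rownames(m))) m[r, ] <- ""
    m
  }
  dyn <- setdiff(rownames(template$matching$main),
                 c(ID_FIXED_ROWS_HEAD,
                   names(fgs[[1]]$assignment),
                   ID_FIXED_ROWS_TAIL))
  tab <- template$matching
  tab$main <- clear_rows(tab$main, c("personal_ID", dyn))
  if (!is.null(tab$subsample)) {
    tab$subsample <- clear_rows(tab$subsample, c("personal_ID", "parent_ID"))
  }
  if (!is.null(tab$subsubsample)) {
    tab$subsubsample <- clear_rows(tab$subsubsample,
                                   c("personal_ID", "parent_ID"))
  }
  out$matching <- id_table(tab$main, subsample = tab$subsample,
                           subsubsample = tab$subsubsample)
  out
}
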