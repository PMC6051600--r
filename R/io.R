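#' Write a cohort table as CSV with a JSON schema sidecar
#'
#' Missing cells are encoded as empty fields. The sidecar (default
#' `<path>.schema.json`) records each column's kind and, for ordinals,
#' the category count, so the table round-trips with stable types.
#'
#' @param cohort Cohort data.frame.
#' @param path Output CSV path.
#' @param schema_path Sidecar path; default `paste0(path, ".schema.json")`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         schema_path = paste0(path, ".schema.json")) {
  vars <- fa_variables()
  schema <- lapply(names(cohort), function(cl) {
    i <- match(cl, vars$name)
    if (!is.na(i)) {
      s <- list(kind = vars$kind[i])
      if (!is.na(vars$n_categories[i])) {
        s$n_categories <- vars$n_categories[i]
      }
      s
    } else if (is.numeric(cohort[[cl]])) {
      list(kind = "numeric")
    } else {
      list(kind = "character")
    }
  })
  names(schema) <- names(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path CSV path.
#' @param schema_path Sidecar path; default `paste0(path, ".schema.json")`.
#' @return Cohort data.frame with numeric/character types restored and
#'   empty fields as `NA`.
#' @export
read_cohort <- function(path, schema_path = paste0(path, ".schema.json")) {
  schema <- if (file.exists(schema_path)) {
    jsonlite::read_json(schema_path)
  } else {
    NULL
  }
  tab <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (cl in intersect(names(schema), names(tab))) {
      kind <- schema[[cl]]$kind
      if (kind %in% c("binary", "ordinal")) {
        tab[[cl]] <- as.integer(tab[[cl]])
      } else if (kind %in% c("continuous", "numeric")) {
        tab[[cl]] <- as.numeric(tab[[cl]])
      }
    }
  }
  tab
}

#' Load a frailty model specification from JSON
#'
#' The package ships its three default model definitions under
#' `system.file("specs", package = "frailtyaudit")`; this reads one back
#' as an [fa_model_spec()].
#'
#' @param path Path to a model-spec JSON file.
#' @return An [fa_model_spec()].
#' @export
#' @examples
#' fa_load_model_spec(system.file("specs", "fd.json",
#'                                package = "frailtyaudit"))
fa_load_model_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  fa_model_spec(model_id = s$model_id, label = s$label,
                domains = s$domains, items = s$items,
                divisor = if (!is.null(s$divisor)) s$divisor else
                  length(s$items),
                index_range = s$index_range, cutoff = s$cutoff,
                age_eligibility = s$age_eligibility,
                input_columns = s$input_columns)
}
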