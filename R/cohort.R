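#' Declare the column roles of a cohort CSV
#'
#' A schema maps raw CSV columns onto the roles the fitters need: one
#' follow-up time column (months), one event-cause column, and a set of
#' covariate columns. Categorical covariates are declared with their level
#' set and a reference level, and are expanded to reference-coded indicator
#' columns on read (a variable with L levels yields L - 1 indicators; the
#' reference level is the all-zeros pattern).
#'
#' @param time Name of the follow-up time column (nonnegative, months).
#' @param cause Name of the event-cause column. Code 0 is always censoring;
#'   codes >= 1 are event causes.
#' @param causes Named integer vector mapping cause labels to codes, e.g.
#'   `c(censored = 0, relapse = 1, death = 2)`. Must contain a 0 code.
#' @param covariates Named list describing covariate columns. Each element is
#'   either `"numeric"` or a list with `levels` (character) and `ref`
#'   (the reference level, one of `levels`).
#' @param id Optional name of a subject identifier column.
#'
#' @return A `cohort_schema` list, accepted by [read_cohort()].
#' @seealso [read_cohort()], [schema_from_yaml()]
#' @export
#' @examples
#' cohort_schema(
#'   time = "months", cause = "status",
#'   causes = c(censored = 0, relapse = 1, death = 2),
#'   covariates = list(
#'     age = "numeric",
#'     plt = list(levels = c("<150k", "150k-400k", ">400k"), ref = ">400k")
#'   )
#' )
cohort_schema <- function(time, cause, causes, covariates, id = NULL) {
  stopifnot(is.character(time), length(time) == 1L,
            is.character(cause), length(cause) == 1L)
  causes <- vapply(causes, as.integer, integer(1))
  if (is.null(names(causes)) || any(!nzchar(names(causes)))) {
    stop("`causes` must be a named vector of integer codes", call. = FALSE)
  }
  if (!any(causes == 0L)) {
    stop("`causes` must include a 0 (censored) code", call. = FALSE)
  }
  if (anyDuplicated(causes)) stop("cause codes must be unique", call. = FALSE)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates)))) {
    stop("`covariates` must be a named list", call. = FALSE)
  }
  covariates <- lapply(covariates, function(cv) {
    if (is.character(cv) && length(cv) == 1L && cv == "numeric") return(cv)
    if (is.list(cv) && !is.null(cv$levels)) {
      if (is.null(cv$ref)) cv$ref <- cv$levels[length(cv$levels)]
      if (!cv$ref %in% cv$levels) {
        stop("reference level must be one of the declared levels", call. = FALSE)
      }
      return(cv[c("levels", "ref")])
    }
    stop("each covariate must be \"numeric\" or list(levels=, ref=)", call. = FALSE)
  })
  structure(list(time = time, cause = cause, causes = causes,
                 covariates = covariates, id = id),
            class = "cohort_schema")
}

#' Load a schema from a YAML (or JSON) config file
#'
#' @param path Path to a YAML/JSON file with fields `time`, `cause`, `causes`,
#'   `covariates` and optionally `id`, mirroring [cohort_schema()].
#' @return A `cohort_schema`.
#' @export
schema_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  causes <- unlist(cfg$causes)
  cohort_schema(time = cfg$time, cause = cfg$cause, causes = causes,
                covariates = cfg$covariates, id = cfg$id)
}

#' Build a cohort tibble from in-memory data
#'
#' Validates a data frame that already has numeric time, integer cause codes
#' and numeric covariate columns, and tags it with the cohort metadata the
#' rest of the package relies on. Rows with missing values in any declared
#' column are dropped (complete-case) with a message reporting the count.
#'
#' @param data A data frame.
#' @param time,cause Column names for follow-up time and cause code.
#' @param covariates Character vector of covariate column names.
#' @param causes Named integer vector of valid cause codes (0 = censored).
#' @param id Optional identifier column; a sequential id is created if absent.
#' @return A `cohort` tibble with canonical columns `id`, `time`, `cause`
#'   followed by the covariates.
#' @export
as_cohort <- function(data, time = "time", cause = "cause",
                      covariates = setdiff(names(data), c("id", time, cause)),
                      causes = c(censored = 0L, event = 1L, competing = 2L),
                      id = NULL) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(time, cause, covariates, id), names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    id = if (is.null(id)) as.character(seq_len(nrow(data))) else as.character(data[[id]]),
    time = as.numeric(data[[time]]),
    cause = as.integer(data[[cause]])
  )
  for (cv in covariates) out[[cv]] <- as.numeric(data[[cv]])

  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    out <- out[keep, ]
  }
  if (nrow(out) == 0L) stop("cohort has no complete rows", call. = FALSE)
  if (any(out$time < 0)) {
    stop("negative follow-up times in rows: ",
         paste(utils::head(which(out$time < 0), 10L), collapse = ", "),
         call. = FALSE)
  }
  causes <- vapply(causes, as.integer, integer(1))
  bad <- !out$cause %in% causes
  if (any(bad)) {
    stop("unknown cause codes ", paste(unique(out$cause[bad]), collapse = ", "),
         " in rows: ", paste(utils::head(which(bad), 10L), collapse = ", "),
         call. = FALSE)
  }
  new_cohort(out, covariates = covariates, causes = causes)
}

new_cohort <- function(data, covariates, causes, coding = NULL) {
  structure(
    tibble::as_tibble(data),
    covariates = covariates,
    causes = causes,
    coding = coding,
    class = c("cohort", class(tibble::tibble()))
  )
}

#' @export
print.cohort <- function(x, ...) {
  causes <- attr(x, "causes")
  cat("# A cohort: ", nrow(x), " subjects, ",
      length(attr(x, "covariates")), " covariate column(s)\n", sep = "")
  cat("# Causes: ", paste0(names(causes), "=", causes, collapse = ", "), "\n",
      sep = "")
  NextMethod()
}

cohort_covariates <- function(cohort) attr(cohort, "covariates")
cohort_causes <- function(cohort) attr(cohort, "causes")

# design matrix (no intercept) for the declared covariates
cohort_matrix <- function(cohort) {
  covs <- cohort_covariates(cohort)
  if (length(covs) == 0L) {
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  }
  as.matrix(cohort[covs])
}

#' Read and validate a cohort CSV
#'
#' Reads a header CSV, checks the declared schema columns exist, maps cause
#' labels to codes, expands categorical covariates to reference-coded
#' indicator columns, drops rows with missing declared values (with a
#' reported count), and rejects negative times or undeclared cause codes.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [cohort_schema()] (or path handled by [schema_from_yaml()]).
#' @return A validated `cohort` tibble. The indicator coding used for each
#'   categorical variable is stored in `attr(, "coding")`.
#' @export
read_cohort <- function(path, schema) {
  if (is.character(schema)) schema <- schema_from_yaml(schema)
  stopifnot(inherits(schema, "cohort_schema"))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  declared <- c(schema$time, schema$cause, names(schema$covariates), schema$id)
  missing_cols <- setdiff(declared, names(raw))
  if (length(missing_cols)) {
    stop("schema error: declared column(s) missing from CSV: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  cause_raw <- raw[[schema$cause]]
  if (is.character(cause_raw)) {
    code <- schema$causes[cause_raw]
    if (any(is.na(code) & !is.na(cause_raw))) {
      bad <- unique(cause_raw[is.na(code) & !is.na(cause_raw)])
      stop("unknown cause labels: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    cause <- as.integer(code)
  } else {
    cause <- as.integer(cause_raw)
  }

  out <- tibble::tibble(
    id = if (is.null(schema$id)) as.character(seq_len(nrow(raw)))
         else as.character(raw[[schema$id]]),
    time = as.numeric(raw[[schema$time]]),
    cause = cause
  )

  coding <- list()
  cov_cols <- character(0)
  for (nm in names(schema$covariates)) {
    cv <- schema$covariates[[nm]]
    if (identical(cv, "numeric")) {
      out[[nm]] <- as.numeric(raw[[nm]])
      cov_cols <- c(cov_cols, nm)
    } else {
      val <- as.character(raw[[nm]])
      bad <- !val %in% cv$levels & !is.na(val)
      if (any(bad)) {
        stop("variable ", nm, ": undeclared level(s) ",
             paste(unique(val[bad]), collapse = ", "), call. = FALSE)
      }
      non_ref <- setdiff(cv$levels, cv$ref)
      cols <- paste0(nm, "_", sanitize_level(non_ref))
      for (k in seq_along(non_ref)) {
        out[[cols[k]]] <- ifelse(is.na(val), NA_real_,
                                 as.numeric(val == non_ref[k]))
      }
      coding[[nm]] <- tibble::tibble(variable = nm, level = non_ref,
                                     ref = cv$ref, column = cols)
      cov_cols <- c(cov_cols, cols)
    }
  }

  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    out <- out[keep, ]
  }
  if (any(out$time < 0)) {
    stop("validation error: negative follow-up time in rows: ",
         paste(utils::head(which(out$time < 0), 10L), collapse = ", "),
         call. = FALSE)
  }
  bad <- !out$cause %in% schema$causes
  if (any(bad)) {
    stop("validation error: unknown cause code(s) ",
         paste(unique(out$cause[bad]), collapse = ", "), " in rows: ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  }
  new_cohort(out, covariates = cov_cols, causes = schema$causes,
             coding = if (length(coding)) dplyr::bind_rows(coding) else NULL)
}

#' Write a validated cohort back to CSV
#'
#' Writes the canonical (expanded) cohort table for provenance; reading the
#' file back with an all-numeric schema reproduces the table.
#'
#' @param cohort A `cohort` tibble.
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path, progress = FALSE)
  invisible(cohort)
}

#' Recode a competing-risks cohort cause-specifically
#'
#' For a cause-specific analysis of one event type, every other event is
#' treated as censoring: the returned cohort has cause 1 where the original
#' cause equals `target_cause` and 0 elsewhere, with times unchanged.
#'
#' @param cohort A `cohort` tibble.
#' @param target_cause Integer code (>= 1) or declared cause label.
#' @return A binary-cause `cohort` tibble.
#' @export
#' @examples
#' ch <- as_cohort(data.frame(time = c(5, 10, 2, 7), cause = c(0, 1, 2, 1),
#'                            x = c(1, 0, 1, 0)))
#' recode_cause_specific(ch, 1)$cause
recode_cause_specific <- function(cohort, target_cause) {
  causes <- cohort_causes(cohort)
  target_cause <- resolve_cause(target_cause, causes)
  out <- cohort
  out$cause <- as.integer(cohort$cause == target_cause)
  label <- names(causes)[match(target_cause, causes)]
  attr(out, "causes") <- c(censored = 0L, stats::setNames(1L, label))
  attr(out, "target_cause") <- target_cause
  out
}

resolve_cause <- function(target_cause, causes) {
  if (is.character(target_cause)) {
    if (!target_cause %in% names(causes)) {
      stop("unknown cause label: ", target_cause, call. = FALSE)
    }
    target_cause <- causes[[target_cause]]
  }
  target_cause <- as.integer(target_cause)
  if (!target_cause %in% causes || target_cause < 1L) {
    stop("target cause ", target_cause, " is not a declared event cause",
         call. = FALSE)
  }
  target_cause
}

# already-binary check used by the fitters
assert_binary_cause <- function(cohort) {
  if (!all(cohort$cause %in% c(0L, 1L))) {
    stop("cohort must be recoded to a binary cause (recode_cause_specific) ",
         "before fitting", call. = FALSE)
  }
  if (sum(cohort$cause) == 0L) {
    stop("no events of the target cause; cannot fit", call. = FALSE)
  }
  invisible(cohort)
}

sanitize_level <- function(x) gsub("[^[:alnum:]]+", "_", x)

#' @export
`[.cohort` <- function(x, ...) {
  out <- NextMethod()
  # row subsets (e.g. bootstrap resamples) keep the cohort metadata as long
  # as the structural columns survive
  if (is.data.frame(out) && all(c("time", "cause") %in% names(out)) &&
      all(attr(x, "covariates") %in% names(out))) {
    attr(out, "covariates") <- attr(x, "covariates")
    attr(out, "causes") <- attr(x, "causes")
    attr(out, "coding") <- attr(x, "coding")
    class(out) <- class(x)
  }
  out
}
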