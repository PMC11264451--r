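# Serialization and human-readable rendering of a cause-specific report.
# The markdown renderer consumes only the serializable core, so a report
# regenerated from its JSON round-trips byte-identically.

#' Serializable core of a cause-specific report
#'
#' Reduces a `cause_report` to plain tables and scalars (coefficient tables
#' with effect sizes, bootstrap CIs, tuning paths, comparison table,
#' convergence metadata) suitable for JSON round-tripping.
#'
#' @param report A `cause_report`.
#' @return A plain list.
#' @export
report_core <- function(report) {
  fit_core <- function(fit) {
    list(
      coefficients = as.data.frame(tidy(fit)),
      baseline = as.data.frame(fit$baseline),
      meta = list(penalty = fit$penalty$family, lambda = fit$penalty$lambda,
                  a = fit$penalty$a, n = fit$n, n_event = fit$n_event,
                  df = fit$df, loglik = fit$loglik, aic = fit$aic,
                  bic = fit$bic, converged = fit$converged,
                  iterations = fit$iter)
    )
  }
  list(
    cause = report$cause,
    criterion = report$criterion,
    full = fit_core(report$full),
    full_ci = if (!is.null(report$full_ci))
      as.data.frame(tibble::as_tibble(report$full_ci)),
    scad = fit_core(report$fits$scad),
    lasso = fit_core(report$fits$lasso),
    tuning = lapply(report$tunes, function(tn) as.data.frame(tn$path)),
    comparison = as.data.frame(report$comparison),
    settings = report$settings
  )
}

#' Write a cause-specific report to a directory
#'
#' Writes `report.json` (the serializable core), `report.md` (rendered
#' markdown), `comparison.csv`, `coefficients.csv`, per-penalty tuning
#' tables, and a `run_log.txt` with the settings and seed.
#'
#' @param report A `cause_report` (or the list from [report_core()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  core <- if (inherits(report, "cause_report")) report_core(report) else report
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(core, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  writeLines(render_report(core), file.path(dir, "report.md"))
  readr::write_csv(core$comparison, file.path(dir, "comparison.csv"),
                   progress = FALSE)
  coefs <- dplyr::bind_rows(
    dplyr::mutate(core$full$coefficients, method = "full", .before = 1),
    dplyr::mutate(core$scad$coefficients, method = "scad", .before = 1),
    dplyr::mutate(core$lasso$coefficients, method = "lasso", .before = 1)
  )
  readr::write_csv(coefs, file.path(dir, "coefficients.csv"),
                   progress = FALSE)
  for (fam in names(core$tuning)) {
    readr::write_csv(core$tuning[[fam]],
                     file.path(dir, paste0("tuning_", fam, ".csv")),
                     progress = FALSE)
  }
  if (!is.null(core$full_ci)) {
    readr::write_csv(core$full_ci, file.path(dir, "full_model_ci.csv"),
                     progress = FALSE)
  }
  log_lines <- c(
    paste0("package: cureselect ",
           as.character(utils::packageVersion("cureselect"))),
    paste0("cause: ", core$cause),
    paste0("criterion: ", core$criterion),
    paste0("settings: ",
           jsonlite::toJSON(core$settings, auto_unbox = TRUE, digits = NA))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Render a cause-specific report as markdown
#'
#' Mirrors the conventional presentation of penalized cure-model analyses:
#' full-model coefficients (with bootstrap CIs when available), per-penalty
#' selected coefficients split into a cure (incidence) section and a
#' cause-specific hazard (latency) section, and the AIC/BIC model
#' comparison. Rendering is a pure function of the serializable core, so
#' regenerating from `report.json` is byte-identical.
#'
#' @param report A `cause_report` or a [report_core()] list.
#' @param decimals Decimals for coefficients and effect sizes (default 2).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report, decimals = 2L) {
  core <- if (inherits(report, "cause_report")) report_core(report) else report
  fmt <- function(x) formatC(round_half_up(x, decimals),
                             format = "f", digits = decimals)
  lines <- c(
    paste0("# Cause-specific mixture cure analysis: ", core$cause),
    "",
    paste0("Penalty selection criterion: ", toupper(core$criterion)),
    ""
  )

  ci_for <- function(component, term) {
    if (is.null(core$full_ci)) return(NULL)
    ci <- core$full_ci
    row <- ci[ci$component == component & ci$term == term, , drop = FALSE]
    if (nrow(row) != 1L) return(NULL)
    paste0(" (", fmt(row$conf.low), ", ", fmt(row$conf.high), ")")
  }

  coef_section <- function(fc, label) {
    co <- fc$coefficients
    out <- c(paste0("## ", label), "")
    for (comp in c("incidence", "latency")) {
      head_label <- if (comp == "incidence") "Cure (incidence)"
                    else paste0(core$cause, "-specific hazard (latency)")
      out <- c(out, paste0("### ", head_label), "",
               "| Term | Estimate | Effect |", "|---|---|---|")
      rows <- co[co$component == comp, , drop = FALSE]
      if (identical(label, "Full model")) {
        keep <- rep(TRUE, nrow(rows))
      } else {
        keep <- rows$estimate != 0 | rows$term == "(Intercept)"
      }
      rows <- rows[keep, , drop = FALSE]
      if (nrow(rows) == 0L) {
        out <- c(out, "| (none selected) | | |")
      } else {
        for (i in seq_len(nrow(rows))) {
          ci_txt <- if (identical(label, "Full model"))
            ci_for(comp, rows$term[i]) else NULL
          out <- c(out, paste0(
            "| ", rows$term[i], " | ", fmt(rows$estimate[i]),
            ci_txt %||% "", " | ",
            if (rows$term[i] == "(Intercept)") "-"
            else fmt(exp(rows$estimate[i])), " |"
          ))
        }
      }
      out <- c(out, "")
    }
    out
  }

  lines <- c(lines,
             coef_section(core$full, "Full model"),
             coef_section(core$scad, "SCAD penalty"),
             coef_section(core$lasso, "LASSO penalty"))

  cmp <- core$comparison
  lines <- c(lines, "## Model comparison", "",
             "| Method | df | log-likelihood | AIC | BIC |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(cmp))) {
    lines <- c(lines, paste0(
      "| ", cmp$method[i], " | ", cmp$df[i], " | ", fmt(cmp$loglik[i]),
      " | ", fmt(cmp$aic[i]), " | ", fmt(cmp$bic[i]), " |"
    ))
  }
  lines
}
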