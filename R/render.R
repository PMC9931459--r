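report_as_list <- function(report) {
  km <- lapply(report$km, function(s) {
    list(model = s$model, grouping = s$grouping, endpoint = s$endpoint,
         n_total = s$n_total, n = as.list(s$n),
         logrank = s$logrank, not_applicable = s$not_applicable,
         curves = lapply(s$curves, function(cv) {
           if (is.null(cv)) NULL else as.list(cv)
         }))
  })
  list(characteristics = report$characteristics,
       univariate = report$univariate,
       metrics = report$metrics,
       km = km,
       meta = report$meta)
}

write_tsv_stable <- function(df, path) {
  con <- file(path, open = "wb")  # binary mode: fixed "\n" line endings
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  path
}

km_long_table <- function(km) {
  rows <- list()
  for (nm in names(km)) {
    s <- km[[nm]]
    for (lv in names(s$curves)) {
      cv <- s$curves[[lv]]
      if (is.null(cv)) next
      rows[[length(rows) + 1L]] <- data.frame(
        model = s$model, grouping = s$grouping, endpoint = s$endpoint,
        group = lv, time = cv$time, surv = cv$surv,
        n_risk = cv$n_risk, n_event = cv$n_event,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(model = character(0), grouping = character(0),
                      endpoint = character(0), group = character(0),
                      time = numeric(0), surv = numeric(0),
                      n_risk = integer(0), n_event = integer(0)))
  }
  do.call(rbind, rows)
}

logrank_table <- function(km) {
  do.call(rbind, lapply(unname(km), function(s) {
    data.frame(model = s$model, grouping = s$grouping, endpoint = s$endpoint,
               statistic = if (is.null(s$logrank)) NA_real_ else s$logrank$statistic,
               df = if (is.null(s$logrank)) NA_integer_ else s$logrank$df,
               p_value = if (is.null(s$logrank)) NA_real_ else s$logrank$p_value,
               not_applicable = s$not_applicable,
               stringsAsFactors = FALSE)
  }))
}

#' Serialise an analysis report to files
#'
#' Writes the report as plot-ready tables. `format = "tsv"` produces
#' `characteristics.tsv`, `univariate.tsv`, `metrics.tsv`, `logrank.tsv`,
#' `km_curves.tsv` (survival curves as step-function tables: time,
#' survival, number at risk) and `metadata.json`; `format = "json"`
#' produces a single `report.json`. Output is byte-identical for identical
#' reports.
#'
#' @param report An `ildgapc_report` from [runAnalysis()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (default) or `"json"`.
#' @return Character vector of the files written, invisibly.
#' @export
renderReport <- function(report, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!inherits(report, "ildgapc_report")) {
    stop_validation("`report` must be an ildgapc_report")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  paths <- character(0)
  if (format == "json") {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(report_as_list(report), p, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    paths <- p
  } else {
    paths <- c(
      write_tsv_stable(report$characteristics,
                       file.path(dir, "characteristics.tsv")),
      write_tsv_stable(report$univariate, file.path(dir, "univariate.tsv")),
      write_tsv_stable(report$metrics, file.path(dir, "metrics.tsv")),
      write_tsv_stable(logrank_table(report$km),
                       file.path(dir, "logrank.tsv")),
      write_tsv_stable(km_long_table(report$km),
                       file.path(dir, "km_curves.tsv"))
    )
    meta_path <- file.path(dir, "metadata.json")
    jsonlite::write_json(report$meta, meta_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    paths <- c(paths, meta_path)
  }
  invisible(paths)
}
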