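## Group aggregation (mean +/- SEM, n), the study's hypothesis tests
## (Welch two-tailed t test; one-way ANOVA with post hoc Tukey), and
## pharmacology / time-course / open-probability summary tables.

#' Summarize per-cell estimates for one group
#'
#' @param values Per-cell estimates (finite).
#' @param label Group (composition) label.
#' @param parameter Parameter name.
#' @return A one-row data.frame: `composition`, `parameter`, `mean`, `sem`
#'   (`NA` when n = 1), `n`.
#' @export
summarize_group <- function(values, label, parameter) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to summarize")
  n <- length(values)
  data.frame(composition = label, parameter = parameter,
             mean = mean(values),
             sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
             n = n)
}

#' Format a summary row as "mean +/- sem (n)"
#'
#' @param s A one-row data.frame from [summarize_group()].
#' @param digits Significant digits for mean and sem.
#' @return Character scalar, e.g. `"3.7 ± 0.1 (7)"`.
#' @export
format_summary <- function(s, digits = 2) {
  if (is.na(s$sem)) sprintf("%s (%d)", signif(s$mean, digits), s$n)
  else sprintf("%s ± %s (%d)", signif(s$mean, digits),
               signif(s$sem, 2), s$n)
}

#' Two-group comparison (Welch two-tailed t test)
#'
#' @param a,b Per-cell values, each n >= 2.
#' @param var_equal Use the pooled-variance (Student) variant instead of
#'   Welch's unequal-variance test.
#' @param alpha Significance level.
#' @return A `comparison_result` list: `test`, `statistic`, `p_value`,
#'   `significant`, `df`.
#' @export
compare_two <- function(a, b, var_equal = FALSE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(test = "unpaired_t_two_tailed",
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 significant = tt$p.value < alpha,
                 df = unname(tt$parameter),
                 alpha = alpha), class = "comparison_result")
}

#' Multi-group comparison (one-way ANOVA with post hoc Tukey)
#'
#' @param groups Named list of >= 3 numeric vectors (each n >= 2).
#' @param alpha Significance level.
#' @return A `comparison_result` list with ANOVA `statistic` (F), `p_value`,
#'   `significant`, and `pairwise`: a data.frame of Tukey-adjusted pairwise
#'   p-values.
#' @export
compare_multi <- function(groups, alpha = 0.05) {
  if (length(groups) < 3)
    stop("fewer than 3 groups: use compare_two()")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(pair = rownames(tk), adj_p = tk[, "p adj"],
                         row.names = NULL)
  structure(list(test = "anova_tukey",
                 statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 significant = an[["Pr(>F)"]][1] < alpha,
                 pairwise = pairwise,
                 alpha = alpha), class = "comparison_result")
}

#' Build the study-style summary tables
#'
#' Aggregates per-cell fit outputs into three summary tables — pharmacology
#' (EC50/IC50 and scalar sensitivity statistics per composition), response
#' time course, and open probability — plus a provenance block. Each input
#' is a data.frame of per-cell rows with a `composition` column; missing
#' inputs produce a table with the compositions present.
#'
#' @param pharmacology Per-cell rows: `composition`, `parameter`, `value`.
#' @param time_course Per-cell rows: `composition` plus any of the
#'   `deactivation_fit` numeric fields.
#' @param open_probability Per-cell rows: `composition`, `method`, `value`,
#'   plus optionally `inv_tau_on_per_s`.
#' @param out_dir Output directory; tables are written as `table2.csv`,
#'   `table3.csv`, `table4.csv` with `provenance.json`.
#' @param seed,config_hash Provenance fields recorded alongside versions.
#' @return Invisibly, a list of the three tables (also written to disk).
#' @export
build_report <- function(pharmacology = NULL, time_course = NULL,
                         open_probability = NULL, out_dir = ".",
                         seed = NA_integer_, config_hash = "") {
  if (is.null(pharmacology) && is.null(time_course) &&
      is.null(open_probability))
    stop("no input fit tables supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  agg <- function(df, value_col = "value", by = c("composition", "parameter")) {
    need <- c(by, value_col)
    if (!all(need %in% names(df)))
      stop("input table missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    sp <- split(df, df[by], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d)
      summarize_group(d[[value_col]], d$composition[1],
                      if ("parameter" %in% by) d$parameter[1] else value_col)))
    rownames(out) <- NULL
    out[order(out$parameter, out$composition), ]
  }
  tables <- list()
  if (!is.null(pharmacology)) {
    tables$table2 <- agg(pharmacology)
    utils::write.csv(tables$table2, file.path(out_dir, "table2.csv"),
                     row.names = FALSE)
  }
  if (!is.null(time_course)) {
    num_cols <- setdiff(names(time_course)[vapply(time_course, is.numeric,
                                                  logical(1))], "composition")
    long <- do.call(rbind, lapply(num_cols, function(cn)
      data.frame(composition = time_course$composition, parameter = cn,
                 value = time_course[[cn]])))
    tables$table3 <- agg(long)
    utils::write.csv(tables$table3, file.path(out_dir, "table3.csv"),
                     row.names = FALSE)
  }
  if (!is.null(open_probability)) {
    op <- open_probability
    op$parameter <- paste0("popen_", op$method)
    tables$table4 <- agg(op[, c("composition", "parameter", "value")])
    utils::write.csv(tables$table4, file.path(out_dir, "table4.csv"),
                     row.names = FALSE)
  }
  prov <- list(package = "nmdarfx",
               version = as.character(utils::packageVersion("nmdarfx")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = seed, config_hash = config_hash,
               timestamp = "deterministic")
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tables)
}
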