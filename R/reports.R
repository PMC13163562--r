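#' Write analysis reports to a directory
#'
#' Renders the pipeline's aggregate results as CSV tables plus a plain-text
#' run report carrying the configuration echo, its content hash, the seed,
#' and library versions. The effective-diameter distribution is additionally
#' rendered as a two-bar chart (below vs at-or-above the reference
#' diameter). Sections whose input is `NULL` are skipped with a logged
#' notice; percent columns are written at full precision alongside their
#' rounded display columns.
#'
#' @param outdir Output directory (created if absent; unwritable is an
#'   error).
#' @param summary Cohort summary from [summarize_cohort()], or `NULL`.
#' @param comparison Protocol comparison from [compare_protocols()], or
#'   `NULL`.
#' @param projection Screening ledger from [cumulative_dose_ledger()], or
#'   `NULL`.
#' @param deff_dist Effective-diameter distribution from
#'   [deff_distribution()], or `NULL`.
#' @param config A [run_config()] echoed into the run report, or `NULL`.
#' @param seed Seed echoed into the run report.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_reports <- function(outdir, summary = NULL, comparison = NULL,
                          projection = NULL, deff_dist = NULL,
                          config = NULL, seed = NULL) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io(sprintf("Cannot create output directory '%s'.", outdir))
  }
  if (file.access(outdir, mode = 2) != 0) {
    abort_io(sprintf("Output directory '%s' is not writable.", outdir))
  }
  files <- character()
  emit <- function(tab, name) {
    path <- file.path(outdir, name)
    readr::write_csv(tab, path)
    path
  }
  if (!is.null(summary)) {
    files["summary"] <- emit(summary, "cohort_summary.csv")
  }
  if (!is.null(comparison)) {
    files["comparison"] <- emit(comparison, "protocol_comparison.csv")
  }
  if (!is.null(projection)) {
    files["projection"] <- emit(projection, "screening_ledger.csv")
  } else {
    message("No screening projection supplied; ledger output skipped.")
  }
  if (!is.null(deff_dist)) {
    files["deff_distribution"] <- emit(deff_dist, "deff_distribution.csv")
    chart <- file.path(outdir, "deff_distribution.png")
    plot_df <- tibble::tibble(
      group = factor(
        c(sprintf("Below %g cm", deff_dist$reference_cm[1]),
          sprintf("At or above %g cm", deff_dist$reference_cm[1])),
        levels = c(sprintf("Below %g cm", deff_dist$reference_cm[1]),
                   sprintf("At or above %g cm", deff_dist$reference_cm[1]))
      ),
      pct = c(deff_dist$pct_below[1], deff_dist$pct_at_or_above[1])
    )
    p <- ggplot2::ggplot(plot_df,
                         ggplot2::aes(x = .data$group, y = .data$pct)) +
      ggplot2::geom_col(fill = c("#2c7fb8", "#a6bddb"), width = 0.6) +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                         vjust = -0.4) +
      ggplot2::labs(x = NULL, y = "Patients (%)",
                    title = "Effective diameter vs reference phantom") +
      ggplot2::ylim(0, 105) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(chart, p, width = 5, height = 4, dpi = 120,
                    device = grDevices::png, type = "cairo")
    files["deff_chart"] <- chart
  }
  report <- file.path(outdir, "run_report.txt")
  lines <- c(
    "ctdose run report",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("ctdose version: %s", as.character(packageVersion("ctdose"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %s", if (is.null(seed)) "not set" else seed)
  )
  if (!is.null(config)) {
    lines <- c(lines, sprintf("config hash: %s", config_hash(config)),
               "configuration:",
               paste0("  ", strsplit(yaml::as.yaml(unclass(config)),
                                     "\n")[[1]]))
  }
  lines <- c(lines, "files:", paste0("  ", basename(files)))
  writeLines(lines, report)
  files["run_report"] <- report
  invisible(files)
}
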