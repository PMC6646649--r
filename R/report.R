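#' Run the full study analysis
#'
#' One call from a validated study matrix to every report table: the
#' lesion-type distribution, the per-reader CDR table (pre/post, delta and
#' percentage change), the false-positive recall table, the calc and mass
#' conversion-and-ignore tables, group mean/min/max summaries, the four ROC
#' curves (pooled pre, pooled post, theoretical-reader post, CAD
#' stand-alone) with AUCs and the percentage change in pooled AUC, and the
#' density-stratified per-reader deltas with their one-sample t tests.
#'
#' @param x A `study_matrix`.
#' @param localization Localization-aware scoring for the per-reader tables
#'   (default `TRUE`, the reader-study rule).
#' @param roc_localization Localization-aware recalls in the pooled
#'   aggregate scores (default `FALSE`: raw recall decisions are summed).
#' @return A `study_report` list.
#' @export
analyze_study <- function(x, localization = TRUE, roc_localization = FALSE) {
  metrics <- reader_metrics(x, localization)
  roc_pre <- pooled_roc(x, "pre", roc_localization)
  roc_post <- pooled_roc(x, "post", roc_localization)
  theo <- theoretical_transform(x)
  roc_theo <- pooled_roc(theo, "post", roc_localization)
  truth <- x$cases$truth_label
  roc_cad <- roc_from_scores(standalone_case_scores(x)[x$cases$case_id], truth)

  dens <- withCallingHandlers(
    density_stratified_deltas(x, localization),
    warning = function(w) invokeRestart("muffleWarning"))
  dens_tests <- purrr::map_dfr(split(dens, dens$density), function(s) {
    tt <- tryCatch(one_sample_t(s$delta), warning = function(w) NULL,
                   error = function(e) NULL)
    tibble::tibble(density = s$density[1], n_cases = s$n_cases[1],
                   mean_delta = mean(s$delta),
                   t_stat = tt$t_stat %g% NA_real_,
                   p_two_sided = tt$p_two_sided %g% NA_real_)
  })

  operating_points <- purrr::map_dfr(x$readers, function(r) {
    purrr::map_dfr(PHASES, function(ph) {
      op <- reader_operating_point(x, r, ph, localization)
      tibble::as_tibble(op)
    })
  })

  structure(list(
    lesions = lesion_distribution(x),
    reader_table = metrics,
    group = group_summary(metrics),
    operating_points = operating_points,
    roc = list(pre = roc_pre, post = roc_post, theoretical = roc_theo,
               cad_standalone = roc_cad),
    auc = list(pre = roc_pre$auc, post = roc_post$auc,
               theoretical = roc_theo$auc, cad_standalone = roc_cad$auc,
               pct_change = pct_change_auc(roc_pre$auc, roc_post$auc)),
    density = list(deltas = dens, tests = dens_tests),
    localization = localization, roc_localization = roc_localization
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  g <- x$group
  pick <- function(m) g$mean[g$metric == m]
  cat("Study report\n")
  cat(sprintf("  mean CDR: %.0f%% -> %.0f%% (+%.0f points, %.0f%% relative)\n",
              display_pct(pick("cdr_pre")), display_pct(pick("cdr_post")),
              round_half_away(pick("delta_cdr")), round_half_away(pick("pct_change_cdr"))))
  cat(sprintf("  mean FP recall-rate change: %.2f%%\n", pick("fp_rate_change")))
  cat(sprintf("  pooled AUC: %.4f -> %.4f (%.1f%% change); theoretical %.4f; CAD alone %.4f\n",
              x$auc$pre, x$auc$post, round_half_away(x$auc$pct_change, 1),
              x$auc$theoretical, x$auc$cad_standalone))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `metrics_report.json` plus CSVs mirroring the report tables:
#' lesion distribution, per-reader CDR / FP / conversion tables, ROC points
#' for all four curves, and the density-stratified tests.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p, progress = FALSE)
    p
  }
  paths <- c(
    w(report$lesions$by_combination, "lesion_distribution.csv"),
    w(report$reader_table, "reader_metrics.csv"),
    w(report$group, "group_summary.csv"),
    w(report$operating_points, "operating_points.csv"),
    w(dplyr::bind_rows(lapply(names(report$roc), function(nm) {
      dplyr::mutate(report$roc[[nm]]$points, curve_id = nm, .before = 1)
    })), "roc_points.csv"),
    w(report$density$tests, "density_tests.csv"))
  pj <- file.path(dir, "metrics_report.json")
  jsonlite::write_json(list(
    auc = report$auc,
    group = report$group,
    density_tests = report$density$tests,
    localization = report$localization,
    roc_localization = report$roc_localization),
    pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

#' Published seven-reader study summary tables
#'
#' The per-reader summary tables of the published retrospective AI-CAD
#' reader study that motivates this package (90 missed cancers, 32 normals,
#' 7 readers), transcribed from the printed report and bundled as plain CSV:
#' per-reader pre/post cancer detection rates (percent), false-positive
#' recall accounting, calc and mass conversion-and-ignore counts, the lesion
#' distribution of the cancer cases, and the printed pooled pre/post AUCs.
#' These are inputs for re-deriving the study's group-level summary
#' statistics; the underlying per-case decisions were not published.
#'
#' @return Named list of tibbles: `cdr`, `fp`, `conversion_calc`,
#'   `conversion_mass`, `lesions`, `pooled_auc`.
#' @export
published_summary_tables <- function() {
  p <- function(f) {
    path <- system.file("extdata", "tables", f, package = "cadreader")
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  list(cdr = p("reader_cdr.csv"),
       fp = p("reader_fp.csv"),
       conversion_calc = p("conversion_calc.csv"),
       conversion_mass = p("conversion_mass.csv"),
       lesions = p("lesion_distribution.csv"),
       pooled_auc = p("pooled_auc.csv"))
}
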