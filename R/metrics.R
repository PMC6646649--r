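#' Localization-aware true positive rule
#'
#' A recall on a cancer case counts as a true positive only when the reader
#' also claimed the correct laterality and the correct quadrant; a recall
#' pointing at the wrong side or wrong quadrant is scored as a false-negative
#' recall.
#'
#' @param case One cases-table row (`truth_label == "cancer"`).
#' @param decision One decisions-table row for that case.
#' @return `TRUE` iff the recall localizes the truth.
#' @export
is_true_positive <- function(case, decision) {
  decision$recall[[1]] == 1L &&
    decision$claimed_laterality[[1]] == case$truth_laterality[[1]] &&
    decision$claimed_quadrant[[1]] == case$truth_quadrant[[1]]
}

# Decisions joined with case truth; adds `tp` (localization-aware) and
# `hit` (case-level recall, location-agnostic).
joined_decisions <- function(x) {
  d <- dplyr::left_join(
    x$decisions,
    x$cases[, c("case_id", "truth_label", "truth_laterality", "truth_quadrant",
                "density", "lesion_components")],
    by = "case_id")
  d$hit <- d$recall == 1L
  d$tp <- d$hit & d$claimed_laterality == d$truth_laterality &
    d$claimed_quadrant == d$truth_quadrant
  d
}

# recall indicator for one reader/phase over a case subset, under either rule
recall_flags <- function(jd, reader_id, phase, localization) {
  sub <- jd[jd$reader_id == reader_id & jd$phase == phase, ]
  sub <- sub[order(sub$case_id), ]
  setNames(if (localization) sub$tp else sub$hit, sub$case_id)
}

#' Cancer detection rate of one reader in one phase
#'
#' The fraction of the study's cancer cases the reader correctly recalled —
#' a per-case sensitivity on the enriched reader-study set, not a
#' per-thousand screening rate. By default a recall only counts when its
#' claimed laterality and quadrant match the truth ([is_true_positive()]).
#'
#' @param x A `study_matrix`.
#' @param reader_id Reader identifier.
#' @param phase `"pre"` (unaided) or `"post"` (after viewing CAD marks).
#' @param localization Apply the localization-aware rule (default `TRUE`).
#' @return Proportion in `[0, 1]`.
#' @export
reader_cdr <- function(x, reader_id, phase, localization = TRUE) {
  jd <- joined_decisions(x)
  jd <- jd[jd$truth_label == "cancer", ]
  if (!nrow(jd)) stop_cadreader("CDR undefined: study has no cancer cases", "cadreader_undefined")
  mean(recall_flags(jd, reader_id, phase, localization))
}

#' Change and percentage change between two proportions
#'
#' @param pre,post Proportions in `[0, 1]`.
#' @return List with `delta` (percentage points, `100 * (post - pre)`) and
#'   `pct_change` (`100 * (post - pre) / pre`; `NA` with a warning when
#'   `pre == 0`).
#' @export
#' @examples
#' delta_and_pct_change(0.25, 0.41)  # delta 16, pct_change 64
delta_and_pct_change <- function(pre, post) {
  delta <- 100 * (post - pre)
  if (pre == 0) {
    warn("percentage change undefined for a zero baseline")
    pct <- NA_real_
  } else {
    pct <- 100 * (post - pre) / pre
  }
  list(delta = delta, pct_change = pct)
}

#' False-positive recall accounting for one reader
#'
#' Over the study's normal cases: recalls per phase, conversions
#' (`fp_increase`: not recalled unaided, recalled with CAD), reversals
#' (`fp_reduction`: recalled unaided, dropped with CAD), and the recall-rate
#' change in percentage points of the normal set. The conservation identity
#' `fp_post = fp_pre + fp_increase - fp_reduction` holds by construction.
#'
#' @inheritParams reader_cdr
#' @return List with `fp_pre`, `fp_increase`, `fp_reduction`, `fp_post`
#'   (integer counts) and `rate_change` (percent).
#' @export
fp_recall_metrics <- function(x, reader_id) {
  jd <- joined_decisions(x)
  jd <- jd[jd$truth_label == "normal", ]
  if (!nrow(jd)) stop_cadreader("FP metrics undefined: study has no normal cases", "cadreader_undefined")
  n_normal <- length(unique(jd$case_id))
  pre  <- recall_flags(jd, reader_id, "pre",  localization = FALSE)
  post <- recall_flags(jd, reader_id, "post", localization = FALSE)
  res <- list(
    fp_pre = sum(pre), fp_increase = sum(!pre & post),
    fp_reduction = sum(pre & !post), fp_post = sum(post))
  stopifnot(res$fp_post == res$fp_pre + res$fp_increase - res$fp_reduction)
  res$rate_change <- 100 * (res$fp_post - res$fp_pre) / n_normal
  res
}

#' Leading lesion class of a case
#'
#' Cases whose leading lesion type is microcalcifications are classed as
#' `"calc"`; every other case (mass, architectural distortion, asymmetry,
#' and mixed types led by one of those, e.g. mass with microcalcifications)
#' is classed as `"mass"`. The leading component is the first token of the
#' `lesion_components` field — a judgment recorded by the validating
#' radiologists and carried as data, never inferred.
#'
#' @param lesion_components Character vector of semicolon-joined component
#'   tokens, first token leading.
#' @return Character vector over `"calc"` / `"mass"`.
#' @export
#' @examples
#' leading_class("microcalcifications")       # "calc"
#' leading_class("mass;microcalcifications")  # "mass"
leading_class <- function(lesion_components) {
  comps <- split_components(lesion_components)
  if (any(lengths(comps) == 0)) {
    stop_cadreader("leading_class requires a non-empty lesion component set",
                   "cadreader_domain")
  }
  ifelse(vapply(comps, `[[`, "", 1) == "microcalcifications", "calc", "mass")
}

#' Conversion-and-ignore accounting for one reader and lesion class
#'
#' Over the cancer cases of one leading-lesion class: how many the reader
#' recalled unaided (`recalled_pre`), how many missed cases with a
#' truth-hitting CAD mark the reader converted to a recall after seeing the
#' marks (`additional_recalled`), and how many such flagged misses the
#' reader ignored (`ignored_flags`). A flag counts only when a mark actually
#' overlaps the validated truth, not merely when any mark is present.
#'
#' @inheritParams reader_cdr
#' @param class `"calc"` or `"mass"`.
#' @param localization Score recalls with the localization-aware rule
#'   (default `TRUE`); set `FALSE` for location-agnostic case-level recall.
#' @return List with `recalled_pre`, `additional_recalled`, `ignored_flags`.
#' @export
conversion_accounting <- function(x, reader_id, class, localization = TRUE) {
  stopifnot(class %in% c("calc", "mass"))
  jd <- joined_decisions(x)
  jd <- jd[jd$truth_label == "cancer", ]
  jd <- jd[leading_class(jd$lesion_components) == class, , drop = FALSE]
  if (!nrow(jd)) return(list(recalled_pre = 0L, additional_recalled = 0L, ignored_flags = 0L))
  pre  <- recall_flags(jd, reader_id, "pre",  localization)
  post <- recall_flags(jd, reader_id, "post", localization)
  hit <- case_truth_hit(x)[names(pre)]
  list(recalled_pre = sum(pre),
       additional_recalled = sum(!pre & post & hit),
       ignored_flags = sum(!pre & !post & hit))
}

#' Per-reader metrics table
#'
#' One row per reader: pre/post CDR with delta and percentage change,
#' false-positive recall accounting, and the calc/mass conversion columns.
#' All values unrounded; apply [display_pct()] for report formatting.
#'
#' @inheritParams reader_cdr
#' @return Tibble with one row per reader.
#' @export
reader_metrics <- function(x, localization = TRUE) {
  purrr::map_dfr(x$readers, function(r) {
    pre <- reader_cdr(x, r, "pre", localization)
    post <- reader_cdr(x, r, "post", localization)
    ch <- delta_and_pct_change(pre, post)
    fp <- fp_recall_metrics(x, r)
    cc <- conversion_accounting(x, r, "calc", localization)
    mm <- conversion_accounting(x, r, "mass", localization)
    tibble::tibble(
      reader_id = r, cdr_pre = pre, cdr_post = post,
      delta_cdr = ch$delta, pct_change_cdr = ch$pct_change,
      fp_pre = fp$fp_pre, fp_increase = fp$fp_increase,
      fp_reduction = fp$fp_reduction, fp_post = fp$fp_post,
      fp_rate_change = fp$rate_change,
      calc_recalled_pre = cc$recalled_pre, calc_additional = cc$additional_recalled,
      calc_ignored = cc$ignored_flags,
      mass_recalled_pre = mm$recalled_pre, mass_additional = mm$additional_recalled,
      mass_ignored = mm$ignored_flags)
  })
}

#' Mean / min / max summary across readers
#'
#' @param metrics Tibble of per-reader values (any numeric columns), e.g.
#'   from [reader_metrics()].
#' @return Tibble with one row per numeric column: `metric`, `mean`, `min`,
#'   `max`. Reader order never affects the result.
#' @export
group_summary <- function(metrics) {
  if (!nrow(metrics)) stop_cadreader("group_summary needs at least one reader", "cadreader_domain")
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  purrr::map_dfr(names(num), function(nm) {
    v <- num[[nm]]
    tibble::tibble(metric = nm, mean = mean(v, na.rm = TRUE),
                   min = suppressWarnings(min(v, na.rm = TRUE)),
                   max = suppressWarnings(max(v, na.rm = TRUE)))
  })
}

#' Per-reader CDR deltas stratified by breast density
#'
#' For each breast density category (1 fatty, 2 scattered, 3 heterogeneously
#' dense, 4 extremely dense) with at least one cancer case, the vector of
#' per-reader CDR changes (percentage points, post minus pre) restricted to
#' that stratum. These vectors feed [one_sample_t()] to test whether the CAD
#' benefit within a stratum differs from zero. Strata with no cancer cases
#' are omitted with a warning.
#'
#' @inheritParams reader_cdr
#' @return Tibble with columns `density`, `n_cases`, `reader_id`, `delta`.
#' @export
density_stratified_deltas <- function(x, localization = TRUE) {
  jd <- joined_decisions(x)
  jd <- jd[jd$truth_label == "cancer", ]
  out <- purrr::map_dfr(DENSITIES, function(d) {
    sub <- jd[jd$density == d, , drop = FALSE]
    n_cases <- length(unique(sub$case_id))
    if (n_cases == 0) {
      warn(sprintf("density stratum %d has no cancer cases; omitted", d))
      return(tibble::tibble())
    }
    purrr::map_dfr(unique(x$readers), function(r) {
      pre  <- mean(recall_flags(sub, r, "pre",  localization))
      post <- mean(recall_flags(sub, r, "post", localization))
      tibble::tibble(density = d, n_cases = n_cases, reader_id = r,
                     delta = 100 * (post - pre))
    })
  })
  out
}

#' Lesion-type distribution of the cancer cases
#'
#' Counts cancer cases by their full lesion-component combination and by
#' leading class (`calc` vs `mass`).
#'
#' @param x A `study_matrix`.
#' @return List with `by_combination` (tibble `lesion_components`, `n`) and
#'   `by_leading_class` (tibble `class`, `n`).
#' @export
lesion_distribution <- function(x) {
  cc <- x$cases[x$cases$truth_label == "cancer", ]
  comb <- dplyr::count(cc, .data$lesion_components, sort = TRUE, name = "n")
  lead <- dplyr::count(
    tibble::tibble(class = leading_class(cc$lesion_components)),
    .data$class, name = "n")
  list(by_combination = comb, by_leading_class = lead)
}
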