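#' Aggregate recall score per case
#'
#' The pooled-reader ordinal score for a case in one phase is the sum of the
#' binary recall decisions across readers, giving an integer in `[0, R]`
#' (0 to 7 for a seven-reader panel). By default the raw case-level recall
#' is summed; with `localization = TRUE` only correctly localized recalls
#' count.
#'
#' @param x A `study_matrix`.
#' @param phase `"pre"` or `"post"`.
#' @param localization Count only correctly localized recalls on cancers
#'   (default `FALSE`: the aggregate score sums raw recall decisions).
#' @return Named integer vector over all case ids.
#' @export
aggregate_scores <- function(x, phase, localization = FALSE) {
  jd <- joined_decisions(x)
  jd <- jd[jd$phase == phase, ]
  flag <- if (localization) {
    ifelse(jd$truth_label == "cancer", jd$tp, jd$hit)
  } else jd$hit
  agg <- tapply(as.integer(flag), jd$case_id, sum)
  out <- setNames(as.integer(agg[x$cases$case_id]), x$cases$case_id)
  if (anyNA(out)) stop_cadreader("aggregate score: missing decisions for some case", "cadreader_completeness")
  out
}

#' Empirical ROC curve from per-case scores
#'
#' Sweeps a recall threshold over the sorted unique scores (recall iff
#' `score >= t`), from a sentinel above the maximum (the (0, 0) corner) down
#' to the minimum (the (1, 1) corner), and integrates by the trapezoidal
#' rule. Ties produce diagonal chords; a single repeated score yields the
#' chance diagonal with AUC 0.5. The curve is invariant under any strictly
#' increasing transform of the scores, and the trapezoidal AUC equals the
#' tie-corrected Mann-Whitney rank statistic.
#'
#' @param scores Numeric vector of per-case scores.
#' @param truth Vector aligned with `scores`: `"cancer"`/`"normal"` (or
#'   logical, `TRUE` = cancer).
#' @return A `roc_curve`: list with `points` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_from_scores <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) truth <- as.character(truth) == "cancer"
  stopifnot(length(scores) == length(truth))
  if (!any(truth) || all(truth)) {
    stop_cadreader("ROC undefined: need at least one cancer and one normal case",
                   "cadreader_undefined")
  }
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- scores[truth]; neg <- scores[!truth]
  tpr <- vapply(ths, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(neg >= t), numeric(1))
  structure(list(
    points = tibble::tibble(threshold = ths, fpr = fpr, tpr = tpr),
    auc = trapezoid_auc(fpr, tpr)), class = "roc_curve")
}

trapezoid_auc <- function(fpr, tpr) {
  n <- length(fpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

# AUC only, without building the curve object: used in the bootstrap inner
# loop. Same threshold-sweep trapezoid as roc_from_scores.
auc_sweep <- function(pos, neg) {
  ths <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  tpr <- vapply(ths, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(neg >= t), numeric(1))
  trapezoid_auc(fpr, tpr)
}

#' Stand-alone CAD score per case
#'
#' The CAD's case-level suspicion score is the maximum mark score over the
#' case's marks, or 0 for an unmarked case. Feeding these scores to
#' [roc_from_scores()] yields the CAD's stand-alone ROC on the study set.
#'
#' @param x A `study_matrix`.
#' @return Named numeric vector over all case ids.
#' @export
standalone_case_scores <- function(x) {
  out <- setNames(rep(0, nrow(x$cases)), x$cases$case_id)
  if (nrow(x$marks)) {
    mx <- tapply(x$marks$neuscore, x$marks$case_id, max)
    out[names(mx)] <- as.numeric(mx)
  }
  out
}

#' Operating point of one reader in one phase
#'
#' @inheritParams reader_cdr
#' @return List with `reader_id`, `phase`, `fpr` (false-positive recall rate
#'   over normals) and `tpr` (localization-aware CDR over cancers).
#' @export
reader_operating_point <- function(x, reader_id, phase, localization = TRUE) {
  jd <- joined_decisions(x)
  nn <- jd[jd$truth_label == "normal", ]
  if (!nrow(nn) || !any(jd$truth_label == "cancer")) {
    stop_cadreader("operating point needs both truth classes", "cadreader_undefined")
  }
  list(reader_id = reader_id, phase = phase,
       fpr = mean(recall_flags(nn, reader_id, phase, localization = FALSE)),
       tpr = reader_cdr(x, reader_id, phase, localization))
}

#' Counterfactual "theoretical reader" transform
#'
#' Models readers who never ignore a CAD flag: the post-phase recall becomes
#' the unaided recall OR'ed with "the case carries at least one CAD mark",
#' applied to cancer and normal cases alike. A recall is never removed. For
#' a converted recall the claimed location is taken from the truth-hitting
#' mark when one exists (i.e. the validated truth location); otherwise the
#' laterality of the highest-scoring mark's view with an uncommitted
#' `central` quadrant.
#'
#' @param x A `study_matrix`.
#' @param score_threshold Minimum mark score for a case to count as flagged
#'   (default 0: every mark is shown).
#' @return A new `study_matrix` whose post-phase decisions are the
#'   theoretical ones; pre-phase decisions are untouched.
#' @export
theoretical_transform <- function(x, score_threshold = 0) {
  flagged <- case_flagged(x, score_threshold)
  hits <- case_truth_hit(x)
  top_lat <- top_mark_laterality(x)
  d <- x$decisions
  pre <- d[d$phase == "pre", ]
  post <- pre
  post$phase <- "post"
  convert <- pre$recall == 0L & flagged[pre$case_id]
  post$recall[convert] <- 1L
  for (i in which(convert)) {
    cid <- post$case_id[i]
    if (hits[[cid]]) {
      case <- x$cases[x$cases$case_id == cid, ]
      post$claimed_laterality[i] <- case$truth_laterality
      post$claimed_quadrant[i] <- case$truth_quadrant
    } else {
      post$claimed_laterality[i] <- top_lat[[cid]]
      post$claimed_quadrant[i] <- "central"
    }
  }
  study_matrix(x$cases, dplyr::bind_rows(pre, post), x$marks, readers = x$readers)
}

top_mark_laterality <- function(x) {
  out <- setNames(rep("L", nrow(x$cases)), x$cases$case_id)
  if (!nrow(x$marks)) return(out)
  mk <- x$marks[order(x$marks$case_id, -x$marks$neuscore), ]
  top <- mk[!duplicated(mk$case_id), ]
  out[top$case_id] <- ifelse(substr(top$view, 1, 1) == "L", "L", "R")
  out
}

#' Percentage change in AUC
#'
#' `100 * (auc_post - auc_pre) / auc_pre`: positive when CAD review improved
#' the pooled-reader AUC.
#'
#' @param auc_pre,auc_post AUCs in `(0, 1]`.
#' @return Percent change.
#' @export
#' @examples
#' pct_change_auc(0.7599, 0.8148)  # 7.22
pct_change_auc <- function(auc_pre, auc_post) {
  if (auc_pre == 0) stop_cadreader("percentage change undefined for zero baseline AUC",
                                   "cadreader_undefined")
  100 * (auc_post - auc_pre) / auc_pre
}

#' Pooled-reader ROC for one phase
#'
#' Convenience wrapper: builds the aggregate scores for the phase and the
#' resulting group ROC.
#'
#' @inheritParams aggregate_scores
#' @return A `roc_curve`.
#' @export
pooled_roc <- function(x, phase, localization = FALSE) {
  scores <- aggregate_scores(x, phase, localization)
  truth <- setNames(x$cases$truth_label, x$cases$case_id)[names(scores)]
  roc_from_scores(scores, truth)
}
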