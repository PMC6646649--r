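# Run `code` under a fixed RNG state, restoring the caller's state after.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Bootstrap the percentage change in pooled AUC
#'
#' Resamples either the cases or the readers with replacement (to the
#' original size), rebuilds the aggregate recall scores for both phases on
#' each replicate, computes the pooled pre- and post-CAD AUCs, and records
#' the percentage change in AUC. Summarized by the replicate mean and
#' standard deviation, a normal-approximation confidence interval
#' `[mu - z sigma, mu + z sigma]` (z = 2.58 at the default 99% level) and a
#' percentile interval. Case-axis replicates containing a single truth
#' class (or a degenerate zero baseline AUC) are redrawn and counted.
#'
#' Reader-axis resampling sums the recall decisions over the sampled reader
#' multiset — a reader drawn twice contributes twice — keeping the score
#' range `[0, R]`.
#'
#' @param x A `study_matrix`.
#' @param axis `"case"` or `"reader"`.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; the same seed reproduces the result bit for
#'   bit. Required.
#' @param ci_level Two-sided confidence level (default 0.99).
#' @param localization Use localization-aware recalls in the aggregate
#'   scores (default `FALSE`; the aggregate score sums raw recall
#'   decisions).
#' @return A `bootstrap_result` list: `axis`, `n_boot`, `seed`,
#'   `point_estimate`, `sample_mean`, `sample_sd`, `ci_normal`,
#'   `ci_percentile`, `ci_level`, `z`, `n_degenerate_redraws`,
#'   `significant` (is 0 outside the normal CI), and the `replicates`
#'   vector.
#' @export
bootstrap_auc_change <- function(x, axis = c("case", "reader"), n_boot = 10000,
                                 seed, ci_level = 0.99, localization = FALSE) {
  axis <- match.arg(axis)
  if (missing(seed)) stop_cadreader("a seed is required for the bootstrap", "cadreader_config")
  if (n_boot < 1) stop_cadreader("n_boot must be >= 1", "cadreader_config")
  if (axis == "reader" && length(x$readers) < 2) {
    stop_cadreader("reader-axis bootstrap needs at least 2 readers", "cadreader_config")
  }
  truth <- x$cases$truth_label == "cancer"
  if (!any(truth) || all(truth)) {
    stop_cadreader("bootstrap needs both truth classes", "cadreader_undefined")
  }

  rec <- recall_matrices(x, localization)
  agg_pre <- colSums(rec$pre); agg_post <- colSums(rec$post)
  point <- pct_change_auc(auc_sweep(agg_pre[truth], agg_pre[!truth]),
                          auc_sweep(agg_post[truth], agg_post[!truth]))

  n_case <- length(truth); n_reader <- length(x$readers)
  reps <- numeric(n_boot); n_redraw <- 0L
  local_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        if (axis == "case") {
          idx <- sample.int(n_case, n_case, replace = TRUE)
          tr <- truth[idx]
          if (all(tr) || !any(tr)) { n_redraw <- n_redraw + 1L; next }
          a_pre  <- auc_sweep(agg_pre[idx][tr],  agg_pre[idx][!tr])
          a_post <- auc_sweep(agg_post[idx][tr], agg_post[idx][!tr])
        } else {
          rs <- sample.int(n_reader, n_reader, replace = TRUE)
          sp <- colSums(rec$pre[rs, , drop = FALSE])
          ss <- colSums(rec$post[rs, , drop = FALSE])
          a_pre  <- auc_sweep(sp[truth], sp[!truth])
          a_post <- auc_sweep(ss[truth], ss[!truth])
        }
        if (a_pre == 0) { n_redraw <- n_redraw + 1L; next }
        reps[b] <- 100 * (a_post - a_pre) / a_pre
        break
      }
    }
  })

  mu <- mean(reps)
  sigma <- if (n_boot > 1) sd(reps) else 0
  z <- if (isTRUE(all.equal(ci_level, 0.99))) 2.58 else qnorm((1 + ci_level) / 2)
  ci_n <- c(mu - z * sigma, mu + z * sigma)
  alpha <- (1 - ci_level) / 2
  ci_p <- unname(quantile(reps, c(alpha, 1 - alpha)))
  structure(list(
    axis = axis, n_boot = as.integer(n_boot), seed = as.integer(seed),
    point_estimate = point, sample_mean = mu, sample_sd = sigma,
    ci_normal = ci_n, ci_percentile = ci_p, ci_level = ci_level, z = z,
    n_degenerate_redraws = n_redraw,
    significant = as.integer(ci_n[1] > 0 || ci_n[2] < 0),
    replicates = reps), class = "bootstrap_result")
}

# reader x case 0/1 recall matrices for both phases, rows in x$readers order
recall_matrices <- function(x, localization = FALSE) {
  jd <- joined_decisions(x)
  flag <- if (localization) {
    ifelse(jd$truth_label == "cancer", jd$tp, jd$hit)
  } else jd$hit
  build <- function(ph) {
    sub <- jd[jd$phase == ph, ]
    m <- matrix(0L, length(x$readers), nrow(x$cases),
                dimnames = list(x$readers, x$cases$case_id))
    m[cbind(match(sub$reader_id, x$readers), match(sub$case_id, x$cases$case_id))] <-
      as.integer(flag[jd$phase == ph])
    m
  }
  list(pre = build("pre"), post = build("post"))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> axis = %s, B = %d, seed = %d\n",
              x$axis, x$n_boot, x$seed))
  cat(sprintf("  pct change in AUC: point %.2f%%, mu %.2f%%, sigma %.2f%%\n",
              x$point_estimate, x$sample_mean, x$sample_sd))
  cat(sprintf("  %.0f%% normal CI [%.2f%%, %.2f%%]; percentile [%.2f%%, %.2f%%]; significant: %d\n",
              100 * x$ci_level, x$ci_normal[1], x$ci_normal[2],
              x$ci_percentile[1], x$ci_percentile[2], x$significant))
  if (x$n_degenerate_redraws > 0) {
    cat(sprintf("  degenerate replicates redrawn: %d\n", x$n_degenerate_redraws))
  }
  invisible(x)
}

#' @rdname bootstrap_auc_change
#' @param result A `bootstrap_result`.
#' @param path Output JSON path (replicates omitted; use
#'   `write.csv(result$replicates, ...)` for histogram data).
#' @export
write_bootstrap <- function(result, path) {
  out <- result[setdiff(names(result), "replicates")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Two-sided one-sample t test against a zero mean
#'
#' Tests whether per-reader deltas (e.g. CDR changes within a density
#' stratum) have mean zero: `t = mean / (sd / sqrt(n))` on `n - 1` degrees
#' of freedom, with the two-sided p obtained from the symmetric t tail
#' (evaluated through the regularized incomplete beta function underlying
#' the t distribution).
#'
#' @param deltas Numeric vector, `length >= 2`.
#' @return List with `t_stat`, `df`, `p_two_sided`. A zero-variance sample
#'   yields p = 0 (nonzero mean) or p = 1 (zero mean), each with a warning.
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3, 4, 5))  # t = 4.24, p = 0.013
one_sample_t <- function(deltas) {
  n <- length(deltas)
  if (n < 2) stop_cadreader("one_sample_t needs at least two observations", "cadreader_domain")
  m <- mean(deltas); s <- sd(deltas)
  if (s == 0) {
    if (m == 0) {
      warn("zero variance and zero mean: p = 1")
      return(list(t_stat = 0, df = n - 1L, p_two_sided = 1))
    }
    warn("zero variance with nonzero mean: p = 0")
    return(list(t_stat = sign(m) * Inf, df = n - 1L, p_two_sided = 0))
  }
  t <- m / (s / sqrt(n))
  list(t_stat = t, df = n - 1L, p_two_sided = 2 * pt(-abs(t), n - 1))
}
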