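#' Default lesion mix for simulated cancer cases
#'
#' Frequency table of lesion-component combinations observed in the
#' motivating seven-reader study (90 actionable missed cancers). The first
#' token of each combination is the leading lesion type as designated by the
#' validating radiologists, so the mix yields 17 calcification-led and 73
#' mass-led cases.
#'
#' @return Tibble with `lesion_components` and `count`.
#' @export
default_lesion_mix <- function() {
  tibble::tribble(
    ~lesion_components, ~count,
    "mass", 50L,
    "microcalcifications", 16L,
    "mass;microcalcifications", 9L,
    "architectural_distortion", 5L,
    "mass;architectural_distortion", 4L,
    "asymmetry", 3L,
    "architectural_distortion;microcalcifications", 1L,
    "microcalcifications;asymmetry", 1L,
    "focal_asymmetry", 1L)
}

#' Calibrate a CAD-compliance probability by bisection
#'
#' Finds the per-reader compliance probability `c` such that the expected
#' number of additional recalls, `c * n_cases * miss_rate * cad_sensitivity`
#' (misses that carry a truth-hitting mark, converted with probability `c`),
#' equals a target count. Solved by bisection on the (monotone) expectation.
#'
#' @param target_additional Target expected number of converted recalls.
#' @param n_cases Number of cancer cases of the relevant class.
#' @param miss_rate Reader's unaided miss rate (`1 - sens_pre`).
#' @param cad_sensitivity Case-level probability of a truth-hitting mark.
#' @param tol Bisection tolerance.
#' @return Compliance probability in `[0, 1]`.
#' @export
calibrate_compliance <- function(target_additional, n_cases, miss_rate,
                                 cad_sensitivity = 0.98, tol = 1e-10) {
  expected <- function(c) c * n_cases * miss_rate * cad_sensitivity
  if (target_additional <= 0) return(0)
  if (expected(1) < target_additional) {
    warn("target additional recalls exceeds the expected flagged misses; compliance capped at 1")
    return(1)
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (expected(mid) < target_additional) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Default per-reader behaviour parameters
#'
#' Seven readers whose unaided sensitivities, unaided false-positive recall
#' probabilities, CAD-compliance and reversal probabilities are calibrated
#' to the per-reader marginal counts of the motivating study (pre-CAD CDRs
#' 42-71%, 4-9 false-positive recalls of 32 normals, per-reader additional
#' recalls and reversals). Compliance with truth-hitting flags is fitted by
#' [calibrate_compliance()]; compliance with false flags and the reversal
#' probability are fitted the same way against the false-positive increase
#' and reduction counts.
#'
#' All probabilities are rates relative to the published study sizes (90
#' cancers, 32 normals), so they remain valid for any simulated study size.
#'
#' @param cad_sensitivity Case-level truth-hit probability of the CAD.
#' @param false_marks_per_normal Poisson mean of false marks on a normal
#'   case (determines how often an unflagged case allows a reversal).
#' @return Tibble with one row per reader.
#' @export
default_reader_params <- function(cad_sensitivity = 0.98,
                                  false_marks_per_normal = 0.7) {
  n_cancer <- 90; n_normal <- 32
  sens <- c(0.42, 0.54, 0.25, 0.46, 0.71, 0.56, 0.61)
  fp_n <- c(7, 6, 4, 8, 6, 9, 9)
  additional <- c(23, 13, 14, 6, 4, 4, 5)     # calc + mass conversions
  fp_inc <- c(4, 2, 2, 0, 0, 0, 0)
  fp_red <- c(3, 0, 1, 2, 0, 0, 0)
  p_any_false <- 1 - exp(-false_marks_per_normal)
  p_no_mark <- exp(-false_marks_per_normal)
  tibble::tibble(
    reader_id = paste0("R", 1:7),
    sens_pre = sens,
    fp_prob_pre = fp_n / n_normal,
    compliance_correct = vapply(1:7, function(i) {
      calibrate_compliance(additional[i], n_cancer, 1 - sens[i], cad_sensitivity)
    }, numeric(1)),
    compliance_false = pmin(1, fp_inc / (n_normal * (1 - fp_n / n_normal) * p_any_false)),
    reversal_prob = pmin(1, fp_red / pmax(fp_n * p_no_mark, 1e-12)),
    localization_accuracy = 1.0)
}

#' Simulation configuration
#'
#' Assembles and validates the generative model of a sequential CAD reader
#' study. Defaults emulate the motivating study's conditions: 90 cancer and
#' 32 normal cases, 7 readers with marginals calibrated to the published
#' per-reader tables, breast density mix 4/43/37/6, the lesion mix of
#' [default_lesion_mix()], and a CAD with 98% case-level sensitivity on the
#' cancers. Mark-score shapes (truncated normals) and false-mark rates
#' (Poisson) are modelling choices exposed here, never hard-coded.
#'
#' @param n_cancer,n_normal,n_readers Study sizes.
#' @param density_probs Probabilities over densities 1-4 (must sum to 1).
#'   When `n_cancer` times the probabilities gives whole numbers, the
#'   density counts are laid out exactly; otherwise sampled.
#' @param lesion_mix Tibble `lesion_components`/`count`; exact layout when
#'   `n_cancer` equals the total count, else sampled by weight.
#' @param reader_params Tibble as from [default_reader_params()]; must have
#'   `n_readers` rows.
#' @param cad_sensitivity Probability a cancer case gets a truth-hitting
#'   mark.
#' @param false_marks_per_cancer,false_marks_per_normal Poisson means of
#'   false marks per case.
#' @param score_true,score_false `c(mean, sd)` of the truncated-normal
#'   (clipped to `[0, 100]`) mark-score distributions for truth-hitting and
#'   false marks.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cancer = 90, n_normal = 32, n_readers = 7,
                       density_probs = c(4, 43, 37, 6) / 90,
                       lesion_mix = default_lesion_mix(),
                       reader_params = default_reader_params(
                         cad_sensitivity = cad_sensitivity,
                         false_marks_per_normal = false_marks_per_normal),
                       cad_sensitivity = 0.98,
                       false_marks_per_cancer = 0.3,
                       false_marks_per_normal = 0.7,
                       score_true = c(80, 12),
                       score_false = c(55, 15)) {
  cfg <- list(n_cancer = n_cancer, n_normal = n_normal, n_readers = n_readers,
              density_probs = density_probs, lesion_mix = lesion_mix,
              reader_params = reader_params, cad_sensitivity = cad_sensitivity,
              false_marks_per_cancer = false_marks_per_cancer,
              false_marks_per_normal = false_marks_per_normal,
              score_true = score_true, score_false = score_false)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field) stop_cadreader(paste0("invalid sim_config field: ", field),
                                        "cadreader_config")
  if (cfg$n_cancer < 1 || cfg$n_normal < 1 || cfg$n_readers < 1) bad("study sizes")
  if (length(cfg$density_probs) != 4 || any(cfg$density_probs < 0) ||
      abs(sum(cfg$density_probs) - 1) > 1e-8) bad("density_probs")
  rp <- cfg$reader_params
  if (nrow(rp) != cfg$n_readers) bad("reader_params (row count)")
  probs <- c(rp$sens_pre, rp$fp_prob_pre, rp$compliance_correct,
             rp$compliance_false, rp$reversal_prob, rp$localization_accuracy,
             cfg$cad_sensitivity)
  if (any(probs < 0 | probs > 1)) bad("probability outside [0, 1]")
  if (cfg$false_marks_per_cancer < 0 || cfg$false_marks_per_normal < 0) bad("false-mark rate")
  if (any(c(cfg$score_true[2], cfg$score_false[2]) < 0)) bad("score sd")
  invisible(cfg)
}

# deterministic quadrant -> pixel offset on a 2000 x 2800 view
QUADRANT_XY <- list(UO = c(1300, 500), UI = c(300, 500), LO = c(1300, 1900),
                    LI = c(300, 1900), central = c(800, 1200))

#' Generate a complete synthetic reader study
#'
#' Draws cases (density, lesion mix, truth location and box), CAD marks
#' (truth-hitting with the configured case sensitivity, Poisson false marks,
#' truncated-normal scores), and both phases of every reader's decisions.
#' Unaided recalls are Bernoulli in the reader's sensitivity (cancers) or
#' false-positive probability (normals). After CAD review, an unaided recall
#' on an unmarked case may be reversed (probability `reversal_prob`); an
#' unaided miss converts with probability `compliance_correct` when a
#' truth-hitting mark exists, else with `compliance_false` when any false
#' mark exists, else stays a miss. Readers are conditionally independent
#' given the case.
#'
#' Three RNG streams (cases, marks, readers) are sub-seeded from `seed`, so
#' changing reader parameters does not perturb case or mark sampling.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; identical seeds give identical studies.
#' @return A validated [study_matrix()] with the config and seed attached as
#'   attributes `sim_config` and `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed) {
  validate_sim_config(config)
  if (missing(seed)) stop_cadreader("a seed is required", "cadreader_config")
  cases <- local_seed(derive_seed(seed, "cases"), sim_cases(config))
  marks <- local_seed(derive_seed(seed, "marks"), sim_marks(config, cases))
  x0 <- list(cases = cases, marks = marks)
  decisions <- local_seed(derive_seed(seed, "readers"),
                          sim_decisions(config, cases, marks))
  x <- study_matrix(cases, decisions, marks,
                    readers = config$reader_params$reader_id)
  attr(x, "sim_config") <- config
  attr(x, "seed") <- as.integer(seed)
  x
}

sim_cases <- function(cfg) {
  n_c <- cfg$n_cancer; n_n <- cfg$n_normal
  ids <- sprintf("case%04d", seq_len(n_c + n_n))
  truth <- c(rep("cancer", n_c), rep("normal", n_n))

  dens_counts <- cfg$density_probs * n_c
  if (all(abs(dens_counts - round(dens_counts)) < 1e-9)) {
    dens_c <- sample(rep(DENSITIES, round(dens_counts)))
  } else {
    dens_c <- sample(DENSITIES, n_c, replace = TRUE, prob = cfg$density_probs)
  }
  dens_n <- sample(DENSITIES, n_n, replace = TRUE, prob = cfg$density_probs)

  mix <- cfg$lesion_mix
  if (sum(mix$count) == n_c) {
    combos <- sample(rep(mix$lesion_components, mix$count))
  } else {
    combos <- sample(mix$lesion_components, n_c, replace = TRUE, prob = mix$count)
  }

  lat <- sample(c("L", "R"), n_c, replace = TRUE)
  quad <- sample(setdiff(QUADRANTS, "none"), n_c, replace = TRUE)
  exam_date <- as.Date("2013-01-01") + sample.int(1000, n_c + n_n, replace = TRUE)
  gap <- sample(271:2117, n_c, replace = TRUE)

  boxes <- lapply(seq_len(n_c), function(i) {
    xy <- QUADRANT_XY[[quad[i]]] + round(runif(2, -100, 100))
    data.frame(view = paste0(lat[i], "CC"), x = xy[1], y = xy[2], w = 120, h = 120)
  })

  tibble::tibble(
    case_id = ids,
    patient_id = paste0("P", ids),
    truth_label = truth,
    lesion_components = c(combos, rep("", n_n)),
    density = c(dens_c, dens_n),
    truth_laterality = c(lat, rep("none", n_n)),
    truth_quadrant = c(quad, rep("none", n_n)),
    exam_date = exam_date,
    biopsy_date = c(exam_date[seq_len(n_c)] + gap, rep(as.Date(NA), n_n)),
    truth_boxes = c(boxes, rep(list(empty_boxes()), n_n)))
}

sim_marks <- function(cfg, cases) {
  rows <- list()
  for (i in seq_len(nrow(cases))) {
    cid <- cases$case_id[i]
    is_cancer <- cases$truth_label[i] == "cancer"
    if (is_cancer && runif(1) < cfg$cad_sensitivity) {
      tb <- cases$truth_boxes[[i]]
      jit <- round(runif(2, -40, 40))
      rows[[length(rows) + 1]] <- data.frame(
        case_id = cid, view = tb$view[1], x = max(0, tb$x[1] + jit[1]),
        y = max(0, tb$y[1] + jit[2]), w = tb$w[1], h = tb$h[1],
        neuscore = rtrunc_norm(1, cfg$score_true[1], cfg$score_true[2]))
    }
    lambda <- if (is_cancer) cfg$false_marks_per_cancer else cfg$false_marks_per_normal
    n_false <- rpois(1, lambda)
    for (k in seq_len(n_false)) {
      truth_lat <- cases$truth_laterality[i]
      # false marks go on the contralateral breast so they never hit truth
      side <- if (truth_lat == "L") "R" else if (truth_lat == "R") "L" else sample(c("L", "R"), 1)
      rows[[length(rows) + 1]] <- data.frame(
        case_id = cid, view = paste0(side, sample(c("CC", "MLO"), 1)),
        x = round(runif(1, 0, 1800)), y = round(runif(1, 0, 2600)),
        w = 100, h = 100,
        neuscore = rtrunc_norm(1, cfg$score_false[1], cfg$score_false[2]))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(case_id = character(), view = character(),
                          x = numeric(), y = numeric(), w = numeric(),
                          h = numeric(), neuscore = numeric()))
  }
  tibble::as_tibble(dplyr::bind_rows(rows))
}

sim_decisions <- function(cfg, cases, marks) {
  x_tmp <- structure(list(cases = cases, marks = marks,
                          readers = cfg$reader_params$reader_id,
                          decisions = NULL), class = "study_matrix")
  hit <- case_truth_hit(x_tmp)
  flagged <- case_flagged(x_tmp)
  top_lat <- top_mark_laterality(x_tmp)
  rp <- cfg$reader_params
  n_case <- nrow(cases)
  out <- vector("list", 2 * nrow(rp))

  wrong_location <- function(truth_lat, truth_quad) {
    repeat {
      lat <- sample(c("L", "R"), 1)
      quad <- sample(setdiff(QUADRANTS, "none"), 1)
      if (lat != truth_lat || quad != truth_quad) return(c(lat, quad))
    }
  }

  for (r in seq_len(nrow(rp))) {
    p <- rp[r, ]
    rec_pre <- integer(n_case); lat_pre <- rep("none", n_case); quad_pre <- rep("none", n_case)
    rec_post <- integer(n_case); lat_post <- rep("none", n_case); quad_post <- rep("none", n_case)
    for (i in seq_len(n_case)) {
      is_cancer <- cases$truth_label[i] == "cancer"
      cid <- cases$case_id[i]
      p_recall <- if (is_cancer) p$sens_pre else p$fp_prob_pre
      if (runif(1) < p_recall) {
        rec_pre[i] <- 1L
        if (is_cancer) {
          if (runif(1) < p$localization_accuracy) {
            lat_pre[i] <- cases$truth_laterality[i]; quad_pre[i] <- cases$truth_quadrant[i]
          } else {
            wl <- wrong_location(cases$truth_laterality[i], cases$truth_quadrant[i])
            lat_pre[i] <- wl[1]; quad_pre[i] <- wl[2]
          }
        } else {
          lat_pre[i] <- sample(c("L", "R"), 1)
          quad_pre[i] <- sample(setdiff(QUADRANTS, "none"), 1)
        }
      }
      if (rec_pre[i] == 1L) {
        if (!flagged[[cid]] && runif(1) < p$reversal_prob) {
          rec_post[i] <- 0L
        } else {
          rec_post[i] <- 1L; lat_post[i] <- lat_pre[i]; quad_post[i] <- quad_pre[i]
        }
      } else if (hit[[cid]] && runif(1) < p$compliance_correct) {
        rec_post[i] <- 1L
        lat_post[i] <- cases$truth_laterality[i]; quad_post[i] <- cases$truth_quadrant[i]
      } else if (!hit[[cid]] && flagged[[cid]] && runif(1) < p$compliance_false) {
        rec_post[i] <- 1L
        lat_post[i] <- top_lat[[cid]]
        quad_post[i] <- sample(setdiff(QUADRANTS, "none"), 1)
      }
    }
    out[[2 * r - 1]] <- tibble::tibble(
      reader_id = p$reader_id, case_id = cases$case_id, phase = "pre",
      recall = rec_pre, claimed_laterality = lat_pre, claimed_quadrant = quad_pre)
    out[[2 * r]] <- tibble::tibble(
      reader_id = p$reader_id, case_id = cases$case_id, phase = "post",
      recall = rec_post, claimed_laterality = lat_post, claimed_quadrant = quad_post)
  }
  dplyr::bind_rows(out)
}

#' Cohort simulation configuration
#'
#' Patient-flow counts for the retrospective cohort ladder, defaulting to
#' the motivating study's stages: 1393 biopsied patients of whom 499 had a
#' cancer biopsy, 973 a benign biopsy and 79 both; 317 cancer patients with
#' prior mammograms; 139 with retrospective findings vs 178 de novo; and a
#' 90 / 40 / 9 actionable / non-actionable / excluded split. Prior-exam
#' gaps are sampled uniformly over `prior_gap_days`.
#'
#' @param n_total,n_cancer,n_benign,n_both,n_with_priors,n_retrospective,n_de_novo,n_actionable,n_non_actionable,n_excluded
#'   Stage counts.
#' @param prior_gap_days Integer range (inclusive) of days between a prior
#'   exam and the biopsy.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_total = 1393, n_cancer = 499, n_benign = 973,
                          n_both = 79, n_with_priors = 317,
                          n_retrospective = 139, n_de_novo = 178,
                          n_actionable = 90, n_non_actionable = 40,
                          n_excluded = 9, prior_gap_days = c(271, 2117)) {
  cfg <- as.list(environment())
  bad <- function(msg) stop_cadreader(paste0("cohort_config: ", msg), "cadreader_config")
  if ((n_cancer - n_both) + (n_benign - n_both) + n_both != n_total) {
    bad("cancer-only + benign-only + both must equal total")
  }
  if (n_retrospective + n_de_novo != n_with_priors) {
    bad("retrospective + de_novo must equal with-priors")
  }
  if (n_actionable + n_non_actionable + n_excluded != n_retrospective) {
    bad("actionable + non_actionable + excluded must equal retrospective")
  }
  if (n_with_priors > n_cancer) bad("with-priors cannot exceed cancer patients")
  if (prior_gap_days[1] <= 270) bad("prior gap must be strictly greater than 270 days")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort table
#'
#' Emits one row per exam with exactly the configured stage counts, suitable
#' for [build_ledger()]. Every patient gets a current exam within 270 days
#' of biopsy; patients in the with-priors stage additionally get one or two
#' prior exams with gaps drawn from the configured range. Category and
#' retrospective-finding labels are attached to prior exam rows.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Cohort tibble in the [read_cohort()] schema.
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed)) stop_cadreader("a seed is required", "cadreader_config")
  cfg <- config
  local_seed(derive_seed(seed, "cohort"), {
    n_cancer_only <- cfg$n_cancer - cfg$n_both
    n_benign_only <- cfg$n_benign - cfg$n_both
    pid <- sprintf("pat%05d", seq_len(cfg$n_total))
    outcome <- c(rep("cancer", n_cancer_only), rep("cancer;benign", cfg$n_both),
                 rep("benign", n_benign_only))
    biopsy <- as.Date("2014-06-01") + sample.int(900, cfg$n_total, replace = TRUE)

    cancer_idx <- seq_len(cfg$n_cancer)      # cancer-only then both
    with_priors <- cancer_idx[seq_len(cfg$n_with_priors)]
    category <- rep(NA_character_, cfg$n_with_priors)
    category[seq_len(cfg$n_actionable)] <- "actionable"
    category[cfg$n_actionable + seq_len(cfg$n_non_actionable)] <- "non_actionable"
    category[cfg$n_actionable + cfg$n_non_actionable + seq_len(cfg$n_excluded)] <- "excluded"
    category[is.na(category)] <- "de_novo"

    rows <- vector("list", cfg$n_total + cfg$n_with_priors)
    k <- 0
    for (i in seq_len(cfg$n_total)) {
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        patient_id = pid[i], biopsy_outcomes = outcome[i], biopsy_date = biopsy[i],
        exam_id = paste0(pid[i], "_e1"),
        exam_date = biopsy[i] - sample.int(200, 1),
        retrospective_finding = NA_integer_, category = NA_character_,
        excluded_reason = NA_character_)
    }
    for (j in seq_along(with_priors)) {
      i <- with_priors[j]
      k <- k + 1
      cat_j <- category[j]
      n_pr <- if (cat_j == "actionable") sample(1:2, 1) else 1L
      gaps <- sample(cfg$prior_gap_days[1]:cfg$prior_gap_days[2], n_pr)
      rows[[k]] <- tibble::tibble(
        patient_id = pid[i], biopsy_outcomes = outcome[i], biopsy_date = biopsy[i],
        exam_id = paste0(pid[i], "_p", seq_len(n_pr)),
        exam_date = biopsy[i] - gaps,
        retrospective_finding = as.integer(cat_j != "de_novo"),
        category = cat_j,
        excluded_reason = if (cat_j == "excluded") {
          sample(EXCLUDED_REASONS, n_pr, replace = TRUE)
        } else NA_character_)
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a simulated study plus provenance to a directory
#'
#' Emits `cases.csv`, `decisions.csv`, `cad_marks.csv`, `cohort.csv` and a
#' `provenance.json` recording the full configuration, seed and package
#' version, sufficient to regenerate the study bit for bit.
#'
#' @param x A simulated `study_matrix` (from [simulate_study()]).
#' @param cohort Optional cohort tibble to write alongside.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(x, dir, cohort = NULL) {
  paths <- write_study(x, dir)
  if (!is.null(cohort)) {
    p <- file.path(dir, "cohort.csv")
    readr::write_csv(cohort, p, progress = FALSE)
    paths <- c(paths, p)
  }
  cfg <- attr(x, "sim_config")
  prov <- list(
    seed = attr(x, "seed"),
    package_version = as.character(utils::packageVersion("cadreader")),
    config = if (!is.null(cfg)) unclass(cfg) else NULL)
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(c(paths, pj))
}
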