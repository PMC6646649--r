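# In-code fixtures and independent oracles shared across the suite.

# One truth box on the CC view of the truth side.
truth_box_for <- function(lat) {
  data.frame(view = paste0(lat, "CC"), x = 400, y = 600, w = 120, h = 120)
}

# Build a study from explicit recall matrices (readers x cases, 0/1).
# Cancer recalls are correctly localized unless a case id appears in
# `wrong_location`; cases in `hit_cases` carry a truth-hitting mark, cases
# in `false_mark_cases` a contralateral false mark.
make_test_study <- function(pre, post, truth,
                            hit_cases = character(),
                            false_mark_cases = character(),
                            wrong_location = character(),
                            density = NULL,
                            lesion = NULL) {
  n_case <- ncol(pre)
  readers <- rownames(pre) %||% paste0("R", seq_len(nrow(pre)))
  case_ids <- colnames(pre) %||% sprintf("c%02d", seq_len(n_case))
  stopifnot(length(truth) == n_case, all(dim(pre) == dim(post)))
  is_cancer <- truth == "cancer"
  lat <- ifelse(is_cancer, "R", "none")
  quad <- ifelse(is_cancer, "UO", "none")
  density <- density %||% rep(2L, n_case)
  lesion <- lesion %||% ifelse(is_cancer, "mass", "")

  cases <- tibble::tibble(
    case_id = case_ids, patient_id = paste0("P", case_ids),
    truth_label = truth, lesion_components = lesion,
    density = as.integer(density),
    truth_laterality = lat, truth_quadrant = quad,
    exam_date = as.Date("2014-01-01"),
    biopsy_date = as.Date(ifelse(is_cancer, "2015-06-01", NA)),
    truth_boxes = lapply(seq_len(n_case), function(i) {
      if (is_cancer[i]) truth_box_for(lat[i]) else
        data.frame(view = character(), x = numeric(), y = numeric(),
                   w = numeric(), h = numeric())
    }))

  dec_one <- function(mat, phase) {
    do.call(rbind, lapply(seq_along(readers), function(r) {
      rec <- as.integer(mat[r, ])
      cl <- ifelse(rec == 1L, ifelse(is_cancer, lat, "L"), "none")
      cq <- ifelse(rec == 1L, ifelse(is_cancer, quad, "central"), "none")
      wrong <- case_ids %in% wrong_location & rec == 1L & is_cancer
      cq[wrong] <- "LI"
      tibble::tibble(reader_id = readers[r], case_id = case_ids, phase = phase,
                     recall = rec, claimed_laterality = cl, claimed_quadrant = cq)
    }))
  }
  decisions <- rbind(dec_one(pre, "pre"), dec_one(post, "post"))

  marks <- do.call(rbind, c(list(
    tibble::tibble(case_id = character(), view = character(), x = numeric(),
                   y = numeric(), w = numeric(), h = numeric(),
                   neuscore = numeric())),
    lapply(case_ids, function(cid) {
      i <- match(cid, case_ids)
      out <- NULL
      if (cid %in% hit_cases) {
        tb <- truth_box_for(lat[i])
        out <- rbind(out, tibble::tibble(
          case_id = cid, view = tb$view, x = tb$x + 30, y = tb$y + 30,
          w = tb$w, h = tb$h, neuscore = 80))
      }
      if (cid %in% false_mark_cases) {
        side <- if (is_cancer[i] && lat[i] == "R") "L" else "R"
        out <- rbind(out, tibble::tibble(
          case_id = cid, view = paste0(side, "MLO"), x = 100, y = 100,
          w = 100, h = 100, neuscore = 55))
      }
      out
    })))

  study_matrix(cases, decisions, marks, readers = readers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pixel-rasterization overlap oracle for integer boxes.
raster_overlap <- function(a, b) {
  ax <- seq(a[1], a[1] + a[3] - 1); ay <- seq(a[2], a[2] + a[4] - 1)
  bx <- seq(b[1], b[1] + b[3] - 1); by <- seq(b[2], b[2] + b[4] - 1)
  length(intersect(ax, bx)) > 0 && length(intersect(ay, by)) > 0
}

# Mann-Whitney pair-enumeration AUC oracle:
# (#concordant + 0.5 * #tied) / (n_pos * n_neg)
auc_pair_oracle <- function(scores, truth) {
  pos <- scores[truth == "cancer"]; neg <- scores[truth == "normal"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Small null-effect config: post identical to pre by construction.
null_effect_config <- function(n_cancer = 20, n_normal = 10) {
  rp <- default_reader_params()
  rp$compliance_correct <- 0
  rp$compliance_false <- 0
  rp$reversal_prob <- 0
  sim_config(n_cancer = n_cancer, n_normal = n_normal, reader_params = rp)
}
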