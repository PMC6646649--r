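#' Study data container for a sequential CAD reader study
#'
#' A `study_matrix` bundles the three tables of a sequential-design reader
#' study: the case roster with ground truth, the complete cube of reader
#' recall decisions (every reader reads every case twice, once unaided and
#' once with CAD marks visible), and the CAD marks with their 0-100
#' suspicion scores. Construction validates every schema invariant; all
#' downstream metrics assume a validated matrix.
#'
#' @param cases Tibble with columns `case_id`, `patient_id`, `truth_label`
#'   (`"cancer"`/`"normal"`), `lesion_components` (semicolon-joined tokens,
#'   first token is the leading lesion type; empty for normals), `density`
#'   (1-4), `truth_laterality` (`"L"`/`"R"`/`"none"`), `truth_quadrant`
#'   (`"UO"`,`"UI"`,`"LO"`,`"LI"`,`"central"`,`"none"`), `exam_date`,
#'   `biopsy_date` (`NA` allowed), and `truth_boxes` (list-column of data
#'   frames with `view`, `x`, `y`, `w`, `h`; empty for normals).
#' @param decisions Tibble with columns `reader_id`, `case_id`, `phase`
#'   (`"pre"`/`"post"`), `recall` (0/1), `claimed_laterality`,
#'   `claimed_quadrant`. Must contain exactly one row per
#'   (reader, case, phase) triple.
#' @param marks Tibble with columns `case_id`, `view`, `x`, `y`, `w`, `h`,
#'   `neuscore` (in `[0, 100]`). May have zero rows.
#' @param readers Optional character vector fixing reader order; defaults to
#'   the sorted unique readers in `decisions`.
#' @return An object of class `study_matrix`: a list with elements `cases`,
#'   `decisions`, `marks`, `readers`.
#' @seealso [read_study()], [validate_study()], [simulate_study()]
#' @export
study_matrix <- function(cases, decisions, marks, readers = NULL) {
  cases     <- tibble::as_tibble(cases)
  decisions <- tibble::as_tibble(decisions)
  marks     <- tibble::as_tibble(marks)
  if (!"truth_boxes" %in% names(cases)) cases$truth_boxes <- rep(list(empty_boxes()), nrow(cases))
  readers <- readers %g% sort(unique(decisions$reader_id))
  x <- structure(
    list(cases = cases, decisions = decisions, marks = marks,
         readers = as.character(readers)),
    class = "study_matrix")
  validate_study(x)
  x
}

empty_boxes <- function() {
  data.frame(view = character(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric())
}

#' @export
print.study_matrix <- function(x, ...) {
  nc <- sum(x$cases$truth_label == "cancer")
  nn <- sum(x$cases$truth_label == "normal")
  cat(sprintf(
    "<study_matrix> %d readers x %d cases (%d cancer, %d normal), %d decisions, %d CAD marks\n",
    length(x$readers), nrow(x$cases), nc, nn, nrow(x$decisions), nrow(x$marks)))
  invisible(x)
}

#' Validate a study matrix against the schema invariants
#'
#' Checks enum domains, truth-label consistency (normal cases carry no lesion
#' components, no truth location and no truth boxes; cancer cases carry at
#' least one component and a localization truth), completeness of the
#' decision cube (exactly one decision per reader x case x phase), recall /
#' claimed-location consistency, and mark score range.
#'
#' @param x A `study_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `cadreader_validation` (completeness failures additionally carry class
#'   `cadreader_completeness` and list the offending triples).
#' @export
validate_study <- function(x) {
  cs <- x$cases; dc <- x$decisions; mk <- x$marks
  fail <- function(msg, class = "cadreader_validation") stop_cadreader(msg, class)

  if (anyDuplicated(cs$case_id)) fail("duplicate case_id in cases table")
  if (!all(cs$truth_label %in% TRUTH)) fail("truth_label must be 'cancer' or 'normal'")
  if (!all(cs$density %in% DENSITIES)) fail("density must be in 1..4")
  if (!all(cs$truth_laterality %in% LATERALITY)) fail("bad truth_laterality token")
  if (!all(cs$truth_quadrant %in% QUADRANTS)) fail("bad truth_quadrant token")

  comp_list <- split_components(cs$lesion_components)
  bad_comp <- !vapply(comp_list, function(cc) all(cc %in% COMPONENTS), logical(1))
  if (any(bad_comp)) {
    fail(sprintf("unknown lesion component token in case(s): %s",
                 paste(cs$case_id[bad_comp], collapse = ", ")))
  }
  n_boxes <- vapply(cs$truth_boxes, nrow, integer(1))
  is_norm <- cs$truth_label == "normal"
  if (any(is_norm & (lengths(comp_list) > 0 | cs$truth_laterality != "none" |
                     cs$truth_quadrant != "none" | n_boxes > 0))) {
    fail("normal cases must have no lesion components, no truth location and no truth boxes")
  }
  if (any(!is_norm & (lengths(comp_list) == 0 | cs$truth_laterality == "none" |
                      cs$truth_quadrant == "none"))) {
    fail("cancer cases need at least one lesion component and a localization truth")
  }
  for (b in cs$truth_boxes) validate_boxes(b, fail)

  if (!all(dc$phase %in% PHASES)) fail("phase must be 'pre' or 'post'")
  if (!all(dc$recall %in% c(0L, 1L))) fail("recall must be 0 or 1")
  if (!all(dc$claimed_laterality %in% LATERALITY)) fail("bad claimed_laterality token")
  if (!all(dc$claimed_quadrant %in% QUADRANTS)) fail("bad claimed_quadrant token")
  if (!all(dc$case_id %in% cs$case_id)) {
    fail(sprintf("decision references unknown case_id: %s",
                 paste(unique(setdiff(dc$case_id, cs$case_id)), collapse = ", ")))
  }
  if (any(dc$recall == 1L & dc$claimed_laterality == "none")) {
    fail("recall = 1 requires a claimed laterality")
  }
  if (any(dc$recall == 0L & (dc$claimed_laterality != "none" | dc$claimed_quadrant != "none"))) {
    fail("recall = 0 requires claimed location fields set to 'none'")
  }

  want <- expand.grid(reader_id = x$readers, case_id = cs$case_id,
                      phase = PHASES, stringsAsFactors = FALSE)
  key <- function(d) paste(d$reader_id, d$case_id, d$phase, sep = "\r")
  kd <- key(dc); kw <- key(want)
  dup <- kd[duplicated(kd)]
  if (length(dup)) {
    fail(sprintf("duplicate decision triple(s): %s",
                 paste(head(gsub("\r", "/", unique(dup)), 5), collapse = "; ")),
         class = c("cadreader_completeness", "cadreader_validation"))
  }
  missing <- setdiff(kw, kd)
  extra <- setdiff(kd, kw)
  if (length(missing) || length(extra)) {
    fail(sprintf(
      "decision cube incomplete: %d missing, %d unexpected triple(s); first missing: %s",
      length(missing), length(extra),
      paste(head(gsub("\r", "/", missing), 5), collapse = "; ")),
      class = c("cadreader_completeness", "cadreader_validation"))
  }

  if (nrow(mk)) {
    if (!all(mk$view %in% VIEWS)) fail("bad CAD mark view token")
    if (!all(mk$case_id %in% cs$case_id)) fail("CAD mark references unknown case_id")
    if (!all(mk$neuscore >= 0 & mk$neuscore <= 100)) fail("neuscore must lie in [0, 100]")
    validate_boxes(mk[, c("x", "y", "w", "h")], fail)
  }
  invisible(x)
}

validate_boxes <- function(b, fail) {
  if (!nrow(b)) return(invisible())
  if (any(b$x < 0 | b$y < 0 | b$w <= 0 | b$h <= 0)) {
    fail("boxes need non-negative corner and strictly positive extent")
  }
}

split_components <- function(s) {
  s <- as.character(s)
  s[is.na(s)] <- ""
  strsplit(s, ";", fixed = TRUE)
}

#' Do two rectangular regions overlap?
#'
#' Boxes are axis-aligned pixel rectangles `c(x, y, w, h)` with a 0-based
#' corner, x rightward and y downward. Overlap requires strictly positive
#' intersection area, so edge-touching boxes do not overlap.
#'
#' @param a,b Numeric vectors `c(x, y, w, h)` with `w > 0`, `h > 0`.
#' @return `TRUE` iff the interiors intersect.
#' @export
#' @examples
#' boxes_overlap(c(0, 0, 10, 10), c(5, 5, 10, 10))  # TRUE
#' boxes_overlap(c(0, 0, 10, 10), c(10, 0, 5, 5))   # FALSE (edge-touching)
boxes_overlap <- function(a, b) {
  (a[[1]] < b[[1]] + b[[3]]) && (b[[1]] < a[[1]] + a[[3]]) &&
  (a[[2]] < b[[2]] + b[[4]]) && (b[[2]] < a[[2]] + a[[4]])
}

#' Does a CAD mark hit the validated truth of a cancer case?
#'
#' A mark hits when its view matches one of the case's truth boxes' views and
#' the two boxes overlap (positive intersection area). Calling this on a
#' normal case is an error: normal cases carry no truth boxes, and any mark
#' on them is by definition a false mark.
#'
#' @param case One row of a `study_matrix` cases table (a data frame row or
#'   one-row tibble) with `truth_label == "cancer"`.
#' @param mark One row of a marks table (`view`, `x`, `y`, `w`, `h`).
#' @return `TRUE` iff the mark overlaps a truth box on the same view.
#' @export
mark_hits_truth <- function(case, mark) {
  if (case$truth_label[[1]] != "cancer") {
    stop_cadreader("mark_hits_truth is defined only for cancer cases",
                   "cadreader_domain")
  }
  tb <- case$truth_boxes[[1]]
  if (!nrow(tb)) return(FALSE)
  m_box <- c(mark$x[[1]], mark$y[[1]], mark$w[[1]], mark$h[[1]])
  for (i in seq_len(nrow(tb))) {
    if (tb$view[i] == mark$view[[1]] &&
        boxes_overlap(c(tb$x[i], tb$y[i], tb$w[i], tb$h[i]), m_box)) {
      return(TRUE)
    }
  }
  FALSE
}

# Per-case logical: does the case carry at least one truth-hitting mark?
# Normal cases are FALSE by definition. Vectorized over a long truth-box
# table joined to the marks on (case, view).
case_truth_hit <- function(x) {
  hits <- setNames(rep(FALSE, nrow(x$cases)), x$cases$case_id)
  cancer <- x$cases[x$cases$truth_label == "cancer", ]
  if (!nrow(x$marks) || !nrow(cancer)) return(hits)
  tb <- dplyr::bind_rows(lapply(seq_len(nrow(cancer)), function(i) {
    b <- cancer$truth_boxes[[i]]
    if (!nrow(b)) return(NULL)
    cbind(case_id = cancer$case_id[i], b)
  }))
  if (is.null(tb) || !nrow(tb)) return(hits)
  j <- dplyr::inner_join(
    x$marks, tb, by = c("case_id", "view"), suffix = c("", ".t"),
    relationship = "many-to-many")
  if (!nrow(j)) return(hits)
  ov <- (j$x < j$x.t + j$w.t) & (j$x.t < j$x + j$w) &
        (j$y < j$y.t + j$h.t) & (j$y.t < j$y + j$h)
  hits[unique(j$case_id[ov])] <- TRUE
  hits
}

# Per-case logical: is the case flagged at all (any mark with neuscore >=
# display threshold)? The threshold defaults to 0, i.e. every mark is shown.
case_flagged <- function(x, score_threshold = 0) {
  mk <- x$marks[x$marks$neuscore >= score_threshold, , drop = FALSE]
  setNames(x$cases$case_id %in% mk$case_id, x$cases$case_id)
}

#' Read a study from its three CSV files
#'
#' Loads and validates the on-disk representation: `cases.csv`,
#' `decisions.csv` and `cad_marks.csv` (UTF-8, header row, comma delimiter).
#' `lesion_components` is a semicolon-joined token list whose first token is
#' the leading lesion type; `truth_boxes` is a semicolon-joined list of
#' `view:x:y:w:h` entries. Row order never affects downstream results.
#'
#' @param cases_path,decisions_path,marks_path Paths to the three CSVs.
#' @return A validated [study_matrix()].
#' @export
read_study <- function(cases_path, decisions_path, marks_path) {
  for (p in c(cases_path, decisions_path, marks_path)) {
    if (!file.exists(p)) stop_cadreader(paste0("file not found: ", p), "cadreader_io")
  }
  cases <- readr::read_csv(cases_path, col_types = readr::cols(
    case_id = "c", patient_id = "c", truth_label = "c", lesion_components = "c",
    density = "i", truth_laterality = "c", truth_quadrant = "c",
    exam_date = readr::col_date(), biopsy_date = readr::col_date(),
    truth_boxes = "c"), progress = FALSE)
  check_parse(cases, cases_path)
  cases$lesion_components <- cases$lesion_components %|NA|% ""
  cases$truth_boxes <- lapply(cases$truth_boxes %|NA|% "", parse_boxes)
  decisions <- readr::read_csv(decisions_path, col_types = readr::cols(
    reader_id = "c", case_id = "c", phase = "c", recall = "i",
    claimed_laterality = "c", claimed_quadrant = "c"), progress = FALSE)
  check_parse(decisions, decisions_path)
  marks <- readr::read_csv(marks_path, col_types = readr::cols(
    case_id = "c", view = "c", x = "d", y = "d", w = "d", h = "d",
    neuscore = "d"), progress = FALSE)
  check_parse(marks, marks_path)
  study_matrix(cases, decisions, marks)
}

`%|NA|%` <- function(x, v) { x[is.na(x)] <- v; x }

check_parse <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr)) {
    stop_cadreader(sprintf("parse error in %s at row %d: %s", path,
                           pr$row[1], pr$expected[1]), "cadreader_parse")
  }
}

parse_boxes <- function(s) {
  if (is.na(s) || s == "") return(empty_boxes())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 5
  if (any(bad)) stop_cadreader("truth_boxes entries must be view:x:y:w:h", "cadreader_parse")
  data.frame(
    view = vapply(parts, `[[`, "", 1),
    x = as.numeric(vapply(parts, `[[`, "", 2)),
    y = as.numeric(vapply(parts, `[[`, "", 3)),
    w = as.numeric(vapply(parts, `[[`, "", 4)),
    h = as.numeric(vapply(parts, `[[`, "", 5)))
}

#' Write a study matrix to its three CSV files
#'
#' Inverse of [read_study()]: a written study reloads to a matrix on which
#' every metric reproduces exactly.
#'
#' @param x A `study_matrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths written.
#' @export
write_study <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- x$cases
  cs$truth_boxes <- vapply(cs$truth_boxes, function(b) {
    if (!nrow(b)) return("")
    paste(sprintf("%s:%g:%g:%g:%g", b$view, b$x, b$y, b$w, b$h), collapse = ";")
  }, character(1))
  paths <- file.path(dir, c("cases.csv", "decisions.csv", "cad_marks.csv"))
  readr::write_csv(cs, paths[1], progress = FALSE)
  readr::write_csv(x$decisions, paths[2], progress = FALSE)
  readr::write_csv(x$marks, paths[3], progress = FALSE)
  invisible(paths)
}
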