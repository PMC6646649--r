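test_that("true positives require recall plus correct laterality and quadrant", {
  case <- tibble::tibble(truth_label = "cancer", truth_laterality = "R",
                         truth_quadrant = "UO")
  d <- function(recall, lat, quad) {
    tibble::tibble(recall = as.integer(recall), claimed_laterality = lat,
                   claimed_quadrant = quad)
  }
  expect_true(is_true_positive(case, d(1, "R", "UO")))
  expect_false(is_true_positive(case, d(1, "R", "LI")))   # wrong quadrant
  expect_false(is_true_positive(case, d(1, "L", "UO")))   # wrong side
  expect_false(is_true_positive(case, d(0, "none", "none")))
})

test_that("reader CDR counts correctly localized recalls over cancer cases", {
  # 90 cancers, reader recalls 38 correctly and 5 with the wrong quadrant
  n <- 90
  pre <- matrix(0, 1, n, dimnames = list("R1", sprintf("c%02d", 1:n)))
  pre[1, 1:43] <- 1
  x <- make_test_study(pre, pre, truth = rep("cancer", n),
                       wrong_location = sprintf("c%02d", 39:43))
  expect_equal(reader_cdr(x, "R1", "pre"), 38 / 90)
  expect_equal(round_half_away(100 * reader_cdr(x, "R1", "pre")), 42)
  expect_equal(reader_cdr(x, "R1", "pre", localization = FALSE), 43 / 90)

  all_in <- matrix(1, 1, 4, dimnames = list("R1", paste0("c", 1:4)))
  y <- make_test_study(all_in, all_in, truth = rep("cancer", 4))
  expect_identical(reader_cdr(y, "R1", "pre"), 1)
  none <- matrix(0, 1, 4, dimnames = list("R1", paste0("c", 1:4)))
  z <- make_test_study(none, none, truth = rep("cancer", 4))
  expect_identical(reader_cdr(z, "R1", "post"), 0)

  normals_only <- make_test_study(none, none, truth = rep("normal", 4))
  expect_error(reader_cdr(normals_only, "R1", "pre"), class = "cadreader_undefined")
})

test_that("delta and percentage change match the published per-reader arithmetic", {
  r3 <- delta_and_pct_change(0.25, 0.41)
  expect_equal(r3$delta, 16)
  expect_equal(r3$pct_change, 64)
  r1 <- delta_and_pct_change(0.42, 0.68)
  expect_equal(r1$delta, 26)
  expect_equal(r1$pct_change, 61.9, tolerance = 1e-3)
  expect_identical(display_pct(r1$pct_change / 100), 62)
  same <- delta_and_pct_change(0.37, 0.37)
  expect_identical(c(same$delta, same$pct_change), c(0, 0))
  expect_warning(zero <- delta_and_pct_change(0, 0.2), "zero baseline")
  expect_true(is.na(zero$pct_change))
})

test_that("false-positive accounting obeys conservation and the published example", {
  # 32 normals; 7 pre FPs, 4 conversions, 3 reversals -> 8 post, +3.1% rate
  n <- 32
  ids <- sprintf("n%02d", 1:n)
  pre <- matrix(0, 1, n, dimnames = list("R1", ids)); pre[1, 1:7] <- 1
  post <- matrix(0, 1, n, dimnames = list("R1", ids))
  post[1, c(1:4, 8:11)] <- 1                       # keeps 4, drops 3, adds 4
  x <- make_test_study(pre, post, truth = rep("normal", n))
  fp <- fp_recall_metrics(x, "R1")
  expect_identical(fp[c("fp_pre", "fp_increase", "fp_reduction", "fp_post")],
                   list(fp_pre = 7L, fp_increase = 4L, fp_reduction = 3L, fp_post = 8L))
  expect_equal(fp$rate_change, 100 / 32)
  expect_identical(display_pct(fp$rate_change / 100), 3)

  no_change <- make_test_study(pre, pre, truth = rep("normal", n))
  fp2 <- fp_recall_metrics(no_change, "R1")
  expect_identical(c(fp2$fp_increase, fp2$fp_reduction), c(0L, 0L))
  expect_identical(fp2$rate_change, 0)

  sat <- matrix(1, 1, n, dimnames = list("R1", ids))
  fp3 <- fp_recall_metrics(make_test_study(sat, sat, rep("normal", n)), "R1")
  expect_identical(fp3$fp_pre, 32L)
  expect_identical(fp3$fp_post, 32L)
})

test_that("conservation holds for every reader on random studies", {
  for (s in 1:3) {
    x <- simulate_study(sim_config(n_cancer = 12, n_normal = 9), seed = s)
    for (r in x$readers) {
      fp <- fp_recall_metrics(x, r)
      expect_identical(fp$fp_post, fp$fp_pre + fp$fp_increase - fp$fp_reduction)
    }
  }
})

test_that("leading class is the first-listed component; published mix gives 17/73", {
  expect_identical(leading_class("microcalcifications"), "calc")
  expect_identical(leading_class("mass;microcalcifications"), "mass")
  expect_identical(leading_class("microcalcifications;asymmetry"), "calc")
  expect_error(leading_class(""), class = "cadreader_domain")

  mix <- default_lesion_mix()
  classes <- leading_class(rep(mix$lesion_components, mix$count))
  expect_identical(sum(classes == "calc"), 17L)
  expect_identical(sum(classes == "mass"), 73L)
})

test_that("conversion accounting matches the published reader-1 calc row", {
  # 17 calc cancers: 8 recalled pre; of the 9 missed, 9 flagged: 6 converted,
  # 3 ignored
  n <- 17
  ids <- sprintf("k%02d", 1:n)
  pre <- matrix(0, 1, n, dimnames = list("R1", ids)); pre[1, 1:8] <- 1
  post <- pre; post[1, 9:14] <- 1
  x <- make_test_study(pre, post, truth = rep("cancer", n),
                       hit_cases = ids, lesion = rep("microcalcifications", n))
  cc <- conversion_accounting(x, "R1", "calc")
  expect_identical(cc, list(recalled_pre = 8L, additional_recalled = 6L,
                            ignored_flags = 3L))
  expect_identical(conversion_accounting(x, "R1", "mass"),
                   list(recalled_pre = 0L, additional_recalled = 0L,
                        ignored_flags = 0L))

  # reader who recalls everything pre has no conversion headroom
  all_in <- matrix(1, 1, n, dimnames = list("R1", ids))
  y <- make_test_study(all_in, all_in, truth = rep("cancer", n),
                       hit_cases = ids, lesion = rep("microcalcifications", n))
  cy <- conversion_accounting(y, "R1", "calc")
  expect_identical(c(cy$additional_recalled, cy$ignored_flags), c(0L, 0L))
})

test_that("conversion accounting equals brute-force triple enumeration", {
  x <- simulate_study(sim_config(n_cancer = 40, n_normal = 10), seed = 31)
  hit <- cadreader:::case_truth_hit(x)
  for (r in x$readers[c(1, 4)]) {
    for (cl in c("calc", "mass")) {
      got <- conversion_accounting(x, r, cl)
      cc <- x$cases[x$cases$truth_label == "cancer", ]
      cc <- cc[leading_class(cc$lesion_components) == cl, ]
      pre <- post <- logical(nrow(cc))
      for (i in seq_len(nrow(cc))) {
        dd <- x$decisions[x$decisions$reader_id == r &
                            x$decisions$case_id == cc$case_id[i], ]
        pre[i]  <- is_true_positive(cc[i, ], dd[dd$phase == "pre", ])
        post[i] <- is_true_positive(cc[i, ], dd[dd$phase == "post", ])
      }
      h <- hit[cc$case_id]
      expect_identical(got$recalled_pre, sum(pre))
      expect_identical(got$additional_recalled, sum(!pre & post & h))
      expect_identical(got$ignored_flags, sum(!pre & !post & h))
      # misses partition into converted, ignored-flag and never-flagged
      expect_identical(got$additional_recalled + got$ignored_flags +
                         sum(!pre & !h) + sum(!pre & post & !h), sum(!pre))
    }
  }
})

test_that("group summary reproduces the published averages and ignores order", {
  cdr_pre <- tibble::tibble(v = c(42, 54, 25, 46, 71, 56, 61))
  g <- group_summary(cdr_pre)
  expect_equal(g$mean, 50.714, tolerance = 1e-4)
  expect_identical(round_half_away(g$mean), 51)
  expect_identical(c(g$min, g$max), c(25, 71))

  mass_add <- tibble::tibble(v = c(17, 10, 6, 5, 3, 2, 2))
  expect_identical(round_half_away(group_summary(mass_add)$mean, 1), 6.4)

  shuffled <- tibble::tibble(v = rev(cdr_pre$v))
  expect_identical(group_summary(shuffled)$mean, g$mean)

  single <- group_summary(tibble::tibble(v = 0.3))
  expect_identical(c(single$mean, single$min, single$max), rep(0.3, 3))
  expect_error(group_summary(cdr_pre[0, ]), class = "cadreader_domain")
})

# brute-force per-stratum post-phase CDR used by the invariant below
reader_cdr_stratum <- function(x, r, d) {
  ids <- x$cases$case_id[x$cases$truth_label == "cancer" & x$cases$density == d]
  dd <- x$decisions[x$decisions$reader_id == r & x$decisions$phase == "post" &
                      x$decisions$case_id %in% ids, ]
  cc <- x$cases[match(dd$case_id, x$cases$case_id), ]
  mean(dd$recall == 1L & dd$claimed_laterality == cc$truth_laterality &
         dd$claimed_quadrant == cc$truth_quadrant)
}

test_that("density strata partition the cancer cases and deltas match subsets", {
  x <- simulate_study(sim_config(), seed = 17)
  dens <- density_stratified_deltas(x)
  counts <- unique(dens[, c("density", "n_cases")])
  expect_identical(sort(counts$n_cases), sort(c(4L, 43L, 37L, 6L)))
  expect_identical(sum(counts$n_cases), 90L)

  # subset oracle: recompute one stratum by brute force
  for (d in c(2, 3)) {
    sub_ids <- x$cases$case_id[x$cases$truth_label == "cancer" & x$cases$density == d]
    for (r in x$readers[c(2, 5)]) {
      cdr_of <- function(ph) {
        dd <- x$decisions[x$decisions$reader_id == r & x$decisions$phase == ph &
                            x$decisions$case_id %in% sub_ids, ]
        cc <- x$cases[match(dd$case_id, x$cases$case_id), ]
        mean(dd$recall == 1L & dd$claimed_laterality == cc$truth_laterality &
               dd$claimed_quadrant == cc$truth_quadrant)
      }
      want <- 100 * (cdr_of("post") - cdr_of("pre"))
      got <- dens$delta[dens$density == d & dens$reader_id == r]
      expect_equal(got, want)
    }
  }

  # per-reader TP counts summed over strata equal the overall TP count
  for (r in x$readers) {
    overall <- reader_cdr(x, r, "post") * 90
    by_stratum <- sum(vapply(unique(counts$density), function(d) {
      sub <- dens[dens$density == d & dens$reader_id == r, ]
      cdr_post_stratum <- reader_cdr_stratum(x, r, d)
      cdr_post_stratum * sub$n_cases
    }, numeric(1)))
    expect_equal(by_stratum, overall)
  }

  same <- simulate_study(null_effect_config(n_cancer = 30, n_normal = 10), seed = 3)
  dens0 <- suppressWarnings(density_stratified_deltas(same))
  expect_true(all(dens0$delta == 0))
})

test_that("reader_metrics table agrees with the individual metric functions", {
  x <- simulate_study(sim_config(n_cancer = 30, n_normal = 12), seed = 23)
  m <- reader_metrics(x)
  expect_identical(m$reader_id, x$readers)
  for (i in c(1, 6)) {
    r <- m$reader_id[i]
    expect_identical(m$cdr_pre[i], reader_cdr(x, r, "pre"))
    expect_identical(m$fp_post[i], fp_recall_metrics(x, r)$fp_post)
    expect_identical(m$mass_additional[i],
                     conversion_accounting(x, r, "mass")$additional_recalled)
  }
})
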