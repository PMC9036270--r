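# Small handmade cohort used across evaluation tests.
tiny_cohort <- function(kb) {
  diffs <- list(
    A = visiontriage:::fixture_differential(
      c("vitreous_hemorrhage", "peripheral_retinal", "floaters_pvd"), kb),
    B = visiontriage:::fixture_differential(
      c("migraine", "post_chiasmal", "lens_cornea"), kb),
    C = visiontriage:::fixture_differential(
      c("other_macular", "cvo", "migraine"), kb),
    D = visiontriage:::fixture_differential(
      c("crao", "naion_brao_bvo", "cvo"), kb)
  )
  records <- encounter_records(
    patient_id = c("A", "B", "C", "D"),
    gold_dx = c("peripheral_retinal;vitreous_hemorrhage", "migraine",
                "cvo", other_sentinel()),
    referrer_dx = c("peripheral_retinal", NA, "optic_neuritis", NA)
  )
  list(records = records, diffs = diffs)
}

test_that("top-k accuracy counts gold-set hits within the first k ranks", {
  kb <- builtin_kb()
  tc <- tiny_cohort(kb)
  # A: dual gold hit at rank 1; B: hit at 1; C: hit at 2; D: never (other)
  expect_identical(top_k_accuracy(tc$records, tc$diffs, 1)$correct, 2L)
  expect_identical(top_k_accuracy(tc$records, tc$diffs, 2)$correct, 3L)
  expect_identical(top_k_accuracy(tc$records, tc$diffs, 13)$correct, 3L)
  expect_equal(top_k_accuracy(tc$records, tc$diffs, 1)$percent, 50.0)

  prev <- 0L
  for (k in 1:13) {
    cur <- top_k_accuracy(tc$records, tc$diffs, k)$correct
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_error(top_k_accuracy(tc$records, tc$diffs[1:2], 1), "misaligned")
})

test_that("referrer accuracy treats missing referrals as incorrect", {
  kb <- builtin_kb()
  tc <- tiny_cohort(kb)
  ra <- referrer_accuracy(tc$records)
  expect_identical(ra$correct, 1L)  # only A matches its gold set
  expect_equal(ra$percent, 25.0)

  none <- encounter_records(c("x", "y"), c("migraine", "crao"),
                            c(NA, NA))
  expect_identical(referrer_accuracy(none)$correct, 0L)
  one <- encounter_records("x", "migraine", "migraine")
  expect_equal(referrer_accuracy(one)$percent, 100.0)
})

test_that("per-cluster counts sum to the overall counts", {
  kb <- builtin_kb()
  fx <- canonical_study_fixture(kb)
  for (k in list(1L, 2L, 3L, "referrer")) {
    tab <- per_cluster_accuracy(fx$records, fx$differentials, k, kb)
    overall <- if (identical(k, "referrer")) {
      referrer_accuracy(fx$records)
    } else {
      top_k_accuracy(fx$records, fx$differentials, k)
    }
    expect_identical(sum(tab$correct), overall$correct)
    expect_identical(sum(tab$total), overall$total)
  }
})

test_that("urgency confusion tabulates against gold urgency of any gold diagnosis", {
  kb <- builtin_kb()
  tc <- tiny_cohort(kb)
  # gold urgency: A URGENT, B NON_URGENT, C URGENT, D URGENT (sentinel)
  flags <- c("URGENT", "NON_URGENT", "NON_URGENT", "URGENT")
  cm <- urgency_confusion(tc$records, flags, kb)
  expect_identical(unlist(cm[c("tp", "fn", "tn", "fp")]),
                   c(tp = 2L, fn = 1L, tn = 1L, fp = 0L))

  all_urgent <- urgency_confusion(tc$records, rep("URGENT", 4), kb)
  expect_identical(all_urgent$fn, 0L)
  expect_identical(all_urgent$tn, 0L)

  expect_error(urgency_confusion(tc$records, flags[1:2], kb), "misaligned")

  # invariant to record order
  perm <- c(3, 1, 4, 2)
  rec_p <- tc$records[perm, ]
  class(rec_p) <- class(tc$records)
  cm_p <- urgency_confusion(rec_p, flags[perm], kb)
  expect_identical(cm_p[c("tp", "fn", "tn", "fp")],
                   cm[c("tp", "fn", "tn", "fp")])
})

test_that("exact binomial intervals match the tail-sum bisection oracle", {
  for (n in c(1, 5, 13, 20, 25, 30)) {
    for (x in 0:n) {
      ci <- clopper_pearson(x, n, 0.95)
      oc <- oracle_clopper_pearson(x, n, 0.95)
      expect_equal(ci$lo, unname(oc["lo"]), tolerance = 1e-9)
      expect_equal(ci$hi, unname(oc["hi"]), tolerance = 1e-9)
      expect_true(ci$lo <= 100 * x / n && 100 * x / n <= ci$hi)
    }
  }
  expect_identical(clopper_pearson(0, 10)$lo, 0)
  expect_identical(clopper_pearson(25, 25)$hi, 100)
  expect_error(clopper_pearson(5, 4), "out-of-range")
  expect_error(clopper_pearson(-1, 4), "out-of-range")
})

test_that("interval coverage is at least nominal (exhaustive at n = 25)", {
  n <- 25
  cis <- lapply(0:n, function(x) clopper_pearson(x, n, 0.95))
  for (p in seq(0.05, 0.95, by = 0.05)) {
    covered <- vapply(0:n, function(x) {
      ci <- cis[[x + 1]]
      ci$lo <= 100 * p && 100 * p <= ci$hi
    }, logical(1))
    coverage <- sum(stats::dbinom(0:n, n, p)[covered])
    expect_gte(coverage, 0.95)
  }
})

test_that("sensitivity and specificity come with exact intervals", {
  cm <- structure(list(tp = 51, fn = 3, tn = 19, fp = 6),
                  class = "urgency_confusion")
  ss <- sens_spec(cm, 0.95)
  expect_equal(ss$sensitivity$point, 94.4)
  expect_equal(ss$specificity$point, 76.0)

  zero <- structure(list(tp = 0, fn = 1, tn = 1, fp = 0),
                    class = "urgency_confusion")
  ss0 <- sens_spec(zero)
  expect_equal(ss0$sensitivity$point, 0)
  expect_identical(ss0$sensitivity$lo, 0)

  empty <- structure(list(tp = 0, fn = 0, tn = 1, fp = 0),
                     class = "urgency_confusion")
  expect_error(sens_spec(empty), "no positive")
})

test_that("encounter tables round-trip through delimited text", {
  kb <- builtin_kb()
  fx <- canonical_study_fixture(kb)
  tmp <- tempfile(fileext = ".tsv")
  write_encounters(fx$records, tmp)
  back <- read_encounters(tmp, kb)
  expect_identical(back$patient_id, fx$records$patient_id)
  expect_identical(back$gold_dx, fx$records$gold_dx)
  expect_identical(back$referrer_dx, fx$records$referrer_dx)
  expect_identical(back$q_red_reflex_absent, fx$records$q_red_reflex_absent)

  tmp2 <- tempfile(fileext = ".tsv")
  write_differentials(fx$differentials, tmp2)
  back2 <- read_differentials(tmp2, kb)
  expect_identical(names(back2), names(fx$differentials))
  expect_identical(back2[["P001"]]$dx, fx$differentials[["P001"]]$dx)
  expect_equal(back2[["P001"]]$posterior, fx$differentials[["P001"]]$posterior,
               tolerance = 1e-10)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgold_dx\treferrer_dx",
               "p1\tnot_a_diagnosis\t"), bad)
  expect_error(read_encounters(bad, kb), "row 1")
})
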