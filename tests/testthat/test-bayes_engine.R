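test_that("a single update follows Bayes' rule and don't-know is a no-op", {
  kb <- toy_kb(rbind(q1 = c(0.8, 0.2)), priors = c(0.5, 0.5))
  b <- new_belief(kb)

  yes <- update_belief(b, kb, "q1", "yes")
  expect_equal(unname(yes$probs), c(0.8, 0.2), tolerance = 1e-12)

  no <- update_belief(b, kb, "q1", "no")
  expect_equal(unname(no$probs), c(0.2, 0.8), tolerance = 1e-12)

  unk <- update_belief(b, kb, "q1", "unknown")
  expect_equal(unk$probs, b$probs, tolerance = 1e-15)
  expect_identical(unk$asked, "q1")

  expect_error(update_belief(yes, kb, "q1", "yes"), "already asked")
  expect_error(update_belief(b, kb, "nope", "yes"), "unknown question")
  expect_error(update_belief(b, kb, "q1", "maybe"), "invalid answer")
})

test_that("sequential updates equal the one-shot joint posterior", {
  for (seed in 1:20) {
    kb <- random_kb(nd = sample(2:8, 1), nq = sample(3:10, 1), seed = seed)
    answers <- random_answers(kb, seed + 1000)
    b <- new_belief(kb)
    for (qid in sample(names(answers))) {
      b <- update_belief(b, kb, qid, answers[[qid]])
    }
    expect_equal(b$probs, oracle_joint_posterior(kb, answers),
                 tolerance = 1e-12)
    expect_equal(sum(b$probs), 1, tolerance = 1e-9)
  }
})

test_that("answer order never changes the final posterior", {
  kb <- random_kb(nd = 5, nq = 8, seed = 99)
  answers <- random_answers(kb, 100, p_unknown = 0.3)
  ref <- NULL
  for (perm_seed in 1:8) {
    set.seed(perm_seed)
    b <- new_belief(kb)
    for (qid in sample(names(answers))) {
      b <- update_belief(b, kb, qid, answers[[qid]])
    }
    if (is.null(ref)) ref <- b$probs
    expect_equal(b$probs, ref, tolerance = 1e-12)
  }
})

test_that("predictive probability of YES matches direct summation", {
  kb <- toy_kb(rbind(q1 = c(0.8, 0.2)), priors = c(0.5, 0.5))
  expect_equal(predictive_yes(new_belief(kb), kb, "q1"), 0.5)

  degenerate <- new_belief(kb)
  degenerate$probs <- c(d1 = 1, d2 = 0)
  expect_equal(predictive_yes(degenerate, kb, "q1"), 0.8)

  for (seed in 1:10) {
    kb <- random_kb(nd = 6, nq = 6, seed = seed)
    b <- new_belief(kb)
    b <- update_belief(b, kb, "q1", "yes")
    for (q in c("q2", "q3")) {
      expect_equal(predictive_yes(b, kb, q), oracle_predictive(b, kb, q),
                   tolerance = 1e-12)
    }
  }
})

test_that("expected shift is zero for non-informative questions and 1/2 for perfect ones", {
  kb <- toy_kb(rbind(flat = c(0.4, 0.4, 0.4), sharp = c(0.4, 0.4, 0.4)),
               priors = c(1, 2, 3))
  expect_equal(expected_shift(new_belief(kb), kb, "flat"), 0,
               tolerance = 1e-12)

  kb2 <- toy_kb(rbind(q1 = c(1 - 1e-9, 1e-9)), priors = c(0.5, 0.5))
  expect_equal(expected_shift(new_belief(kb2), kb2, "q1"), 0.5,
               tolerance = 1e-6)

  for (seed in 1:10) {
    kb3 <- random_kb(nd = 5, nq = 5, seed = seed)
    b <- new_belief(kb3)
    for (q in kb3$questions$id) {
      expect_equal(expected_shift(b, kb3, q), oracle_shift(b, kb3, q),
                   tolerance = 1e-12)
    }
  }
})

test_that("a YES answer raises exactly the diagnoses more likely than the predictive mean", {
  for (seed in 1:10) {
    kb <- random_kb(nd = 6, nq = 4, seed = seed)
    b <- new_belief(kb)
    for (q in kb$questions$id) {
      pm <- predictive_yes(b, kb, q)
      post <- update_belief(b, kb, q, "yes")
      up <- post$probs > b$probs
      expect_identical(unname(up), unname(kb$likelihoods[q, ] > pm))
    }
  }
})

test_that("question selection asks seeds first then the exhaustive argmax", {
  kb <- random_kb(nd = 4, nq = 6, seed = 5, seeds = TRUE)
  b <- new_belief(kb)
  expect_identical(next_question(b, kb), "q1")

  for (seed in 1:15) {
    kb <- random_kb(nd = sample(2:6, 1), nq = sample(2:8, 1), seed = seed)
    b <- new_belief(kb)
    # advance past a random prefix of answers
    answers <- random_answers(kb, seed + 500)
    for (qid in utils::head(names(answers), 2)) {
      b <- update_belief(b, kb, qid, answers[[qid]])
    }
    expect_identical(next_question(b, kb), oracle_next_question(b, kb))
  }

  kb <- random_kb(nd = 3, nq = 3, seed = 1)
  b <- new_belief(kb)
  for (q in kb$questions$id) b <- update_belief(b, kb, q, "unknown")
  expect_null(next_question(b, kb))
})

test_that("the stopping rule fires on the posterior ratio boundary and budgets", {
  kb <- toy_kb(rbind(q1 = c(0.5, 0.5, 0.5)), priors = c(1, 1, 1),
               stop_ratio = 5)
  b <- new_belief(kb)
  expect_false(should_stop(b, kb))

  b$probs <- c(d1 = 0.90, d2 = 0.05, d3 = 0.05)
  expect_true(should_stop(b, kb))

  # ratio exactly at the threshold stops (>= convention); dyadic values keep
  # the ratio exact in floating point
  kb_r2 <- toy_kb(rbind(q1 = c(0.5, 0.5, 0.5)), priors = c(1, 1, 1),
                  stop_ratio = 2)
  b$probs <- c(d1 = 0.5, d2 = 0.25, d3 = 0.25)
  expect_true(should_stop(b, kb_r2))
  b$probs <- c(d1 = 0.45, d2 = 0.30, d3 = 0.25)
  expect_false(should_stop(b, kb_r2))

  # question budget
  kb2 <- toy_kb(rbind(q1 = c(0.5, 0.4), q2 = c(0.5, 0.4)),
                priors = c(1, 1), stop_ratio = 1e9, max_questions = 1)
  b2 <- update_belief(new_belief(kb2), kb2, "q1", "unknown")
  expect_true(should_stop(b2, kb2))

  # a further unknown answer never un-stops
  kb3 <- toy_kb(rbind(q1 = c(0.9, 0.1), q2 = c(0.5, 0.5)),
                priors = c(1, 1), stop_ratio = 5)
  b3 <- update_belief(new_belief(kb3), kb3, "q1", "yes")
  if (should_stop(b3, kb3)) {
    b4 <- update_belief(b3, kb3, "q2", "unknown")
    expect_true(should_stop(b4, kb3))
  }
})

test_that("the ranked differential is a deterministic permutation with canonical tie-break", {
  kb <- builtin_kb()
  b <- new_belief(kb)
  uniform <- b
  uniform$probs[] <- 1 / 13
  d <- rank_differential(uniform)
  expect_identical(d$dx, kb$diagnoses$id)

  b$probs <- stats::setNames(rep(1 / 13, 13), kb$diagnoses$id)
  b$probs[["migraine"]] <- b$probs[["migraine"]] + 0.5
  b$probs <- b$probs / sum(b$probs)
  expect_identical(rank_differential(b)$dx[1], "migraine")

  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(13)
    b$probs <- stats::setNames(p / sum(p), kb$diagnoses$id)
    d <- rank_differential(b)
    expect_identical(sort(d$dx), sort(kb$diagnoses$id))
    expect_true(all(diff(d$posterior) <= 0))
    ord <- order(-b$probs)
    expect_identical(d$dx, kb$diagnoses$id[ord])
    expect_equal(sum(d$posterior), 1, tolerance = 1e-9)
  }
})

test_that("a full session reproduces the joint posterior over the asked questions", {
  kb <- builtin_kb()
  tr <- run_session(kb, c())
  expect_identical(tr$differential$dx[1], rank_differential(new_belief(kb))$dx[1])
  expect_true(tr$terminated_by %in% c("MAX_QUESTIONS", "EXHAUSTED"))
  expect_identical(utils::head(tr$steps$question, 4),
                   c("sudden_onset", "monocular", "acuity_reduced",
                     "eye_pain"))
  expect_false(anyDuplicated(tr$steps$question) > 0)

  for (seed in 1:10) {
    kbr <- random_kb(nd = 5, nq = 7, seed = seed, seeds = TRUE)
    answers <- random_answers(kbr, seed + 2000)
    tr <- run_session(kbr, answers)
    asked <- answers[tr$steps$question]
    expect_equal(tr$belief$probs, oracle_joint_posterior(kbr, asked),
                 tolerance = 1e-12)
  }
})

test_that("evidence lists partition answered questions and sort by weight", {
  kb <- builtin_kb()
  ev <- evidence_for(kb, c(red_reflex_absent = "unknown"),
                     "vitreous_hemorrhage")
  expect_identical(nrow(ev$supports) + nrow(ev$refutes), 0L)

  answers <- c(red_reflex_absent = "yes", floaters = "yes", rapd = "no",
               eye_pain = "unknown")
  ev <- evidence_for(kb, answers, "vitreous_hemorrhage")
  expect_identical(nrow(ev$supports) + nrow(ev$refutes), 3L)
  expect_true(all(diff(ev$supports$weight) <= 0))
  expect_true(all(diff(ev$refutes$weight) <= 0))
  expect_true(all(ev$supports$weight >= 0))
  expect_error(evidence_for(kb, answers, "not_a_dx"), "unknown diagnosis")
})
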