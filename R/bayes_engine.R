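# Sequential Bayesian engine: belief updating, greedy question selection,
# stopping rule, ranked differential and per-diagnosis evidence.
#
# Model: answers are conditionally independent given the diagnosis
# (naive Bayes). A YES answer to question q multiplies the belief in
# diagnosis d by p_yes(q, d); NO multiplies by 1 - p_yes(q, d); UNKNOWN
# (don't know) carries likelihood 1 for every diagnosis and so never moves
# the differential.

#' Initial belief state from knowledge-base priors
#'
#' @param kb A `vision_kb`.
#' @return A `belief_state`: normalized probability vector over the 13
#'   diagnoses plus the set of already-asked question ids.
#' @export
new_belief <- function(kb) {
  probs <- kb_priors(kb)
  structure(list(probs = probs / sum(probs), asked = character()),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat("<belief_state> ", length(x$asked), " question(s) asked\n", sep = "")
  top <- sort(x$probs, decreasing = TRUE)[seq_len(min(3L, length(x$probs)))]
  cat("  top: ", paste0(names(top), " (", sprintf("%.3f", top), ")",
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_question <- function(kb, qid) {
  if (length(qid) != 1L || !qid %in% kb_question_ids(kb)) {
    stop("unknown question id: ", qid, call. = FALSE)
  }
}

answer_likelihood <- function(kb, qid, answer) {
  p <- kb_p_yes(kb, qid)
  switch(answer,
    yes = p,
    no = 1 - p,
    unknown = rep(1, length(p)),
    stop("invalid answer value: ", answer,
         " (must be yes, no or unknown)", call. = FALSE)
  )
}

#' Bayesian belief update for one answered question
#'
#' Applies Bayes' rule for a single Yes/No/Don't-know answer under the
#' conditional-independence model. A `"yes"` answer reweights each diagnosis
#' by its p_yes entry, `"no"` by its complement, and `"unknown"` leaves the
#' probabilities untouched; in every case the question is marked as asked and
#' the result is renormalized.
#'
#' @param belief A `belief_state`.
#' @param kb A `vision_kb`.
#' @param qid Question id (must not have been asked already).
#' @param answer One of `"yes"`, `"no"`, `"unknown"`.
#' @return The posterior `belief_state`.
#' @export
#' @examples
#' b <- new_belief(builtin_kb())
#' update_belief(b, builtin_kb(), "red_reflex_absent", "yes")
update_belief <- function(belief, kb, qid, answer) {
  check_question(kb, qid)
  if (qid %in% belief$asked) {
    stop("question already asked: ", qid, call. = FALSE)
  }
  lik <- answer_likelihood(kb, qid, answer)
  probs <- belief$probs * lik
  structure(list(probs = probs / sum(probs), asked = c(belief$asked, qid)),
            class = "belief_state")
}

#' Predictive probability of a YES answer
#'
#' Marginal probability that the next answer to `qid` is YES under the
#' current belief: the belief-weighted average of the per-diagnosis p_yes
#' values.
#'
#' @inheritParams update_belief
#' @return Probability in (0, 1).
#' @export
predictive_yes <- function(belief, kb, qid) {
  check_question(kb, qid)
  sum(belief$probs * kb_p_yes(kb, qid))
}

#' Expected pre-test to post-test probability shift of a question
#'
#' Scores a candidate question by how far, in expectation, its answer would
#' move the belief: the total-variation distance between the current belief
#' and the posterior, averaged over the YES and NO branches weighted by their
#' predictive probabilities. A question whose p_yes row is constant across
#' diagnoses scores exactly 0; a perfectly discriminating question between
#' two equiprobable diagnoses scores 1/2.
#'
#' @inheritParams update_belief
#' @return A score in `[0, 1)`.
#' @export
expected_shift <- function(belief, kb, qid) {
  check_question(kb, qid)
  if (qid %in% belief$asked) {
    stop("question already asked: ", qid, call. = FALSE)
  }
  p_yes_q <- predictive_yes(belief, kb, qid)
  pre <- belief$probs
  post_yes <- pre * kb_p_yes(kb, qid)
  post_yes <- post_yes / sum(post_yes)
  post_no <- pre * (1 - kb_p_yes(kb, qid))
  post_no <- post_no / sum(post_no)
  tv_yes <- sum(abs(post_yes - pre)) / 2
  tv_no <- sum(abs(post_no - pre)) / 2
  p_yes_q * tv_yes + (1 - p_yes_q) * tv_no
}

#' Select the next question to ask
#'
#' While unanswered seed questions remain they are asked first, in seed-rank
#' order (the fixed 3-4 question opening of the interview). Afterwards the
#' unasked question with the highest [expected_shift()] is chosen, ties
#' broken by lexicographic question id. Returns `NULL` when every question
#' has been asked.
#'
#' @inheritParams update_belief
#' @return A question id, or `NULL`.
#' @export
next_question <- function(belief, kb) {
  unasked <- setdiff(kb_question_ids(kb), belief$asked)
  if (!length(unasked)) return(NULL)
  seeds <- setdiff(kb_seed_questions(kb), belief$asked)
  if (length(seeds)) return(seeds[[1L]])
  scores <- vapply(unasked, function(q) expected_shift(belief, kb, q),
                   numeric(1))
  cand <- sort(unasked)
  cand[which.max(scores[match(cand, unasked)])]
}

# Reason the session should end, or NULL to continue.
stop_reason <- function(belief, kb) {
  unasked <- setdiff(kb_question_ids(kb), belief$asked)
  p <- sort(belief$probs, decreasing = TRUE)
  if (length(p) >= 2L && p[[1L]] / p[[2L]] >= kb$params$stop_ratio) {
    return("STOP_RULE")
  }
  if (length(belief$asked) >= kb$params$max_questions) return("MAX_QUESTIONS")
  if (!length(unasked)) return("EXHAUSTED")
  NULL
}

#' Stopping rule
#'
#' The interview stops once the level of suspicion for the top diagnosis
#' heavily outweighs the runner-up — operationalized as the ratio of the top
#' two posteriors reaching `stop_ratio` (boundary included) — or when the
#' question budget `max_questions` is spent, or when no unasked questions
#' remain.
#'
#' @inheritParams update_belief
#' @return `TRUE` or `FALSE`.
#' @export
should_stop <- function(belief, kb) {
  !is.null(stop_reason(belief, kb))
}

#' Ranked differential diagnosis
#'
#' Orders all diagnoses by posterior probability, descending; ties are broken
#' by the canonical diagnosis order, making the ranking fully deterministic.
#'
#' @param belief A `belief_state`.
#' @return A `vl_differential`: data.frame with columns `dx` and `posterior`,
#'   one row per diagnosis, posteriors non-increasing.
#' @export
rank_differential <- function(belief) {
  ord <- order(-belief$probs)  # stable: ties keep canonical order
  new_differential(names(belief$probs)[ord], unname(belief$probs[ord]))
}

new_differential <- function(dx, posterior) {
  structure(
    data.frame(dx = dx, posterior = posterior, stringsAsFactors = FALSE),
    class = c("vl_differential", "data.frame")
  )
}

#' @export
print.vl_differential <- function(x, ...) {
  cat("<differential> top:",
      paste0(utils::head(x$dx, 3), " (",
             sprintf("%.3f", utils::head(x$posterior, 3)), ")",
             collapse = ", "), "\n")
  invisible(as.data.frame(x))
}

resolve_answer <- function(answers, qid) {
  a <- if (is.function(answers)) {
    answers(qid)
  } else if (qid %in% names(answers)) {
    answers[[qid]]
  } else {
    NULL
  }
  if (is.null(a) || is.na(a) || !nzchar(a)) a <- "unknown"
  if (!a %in% ANSWER_VALUES) {
    stop("invalid answer for ", qid, ": ", a, call. = FALSE)
  }
  a
}

#' Run a full adaptive interview session
#'
#' Plays the whole dynamic loop against a source of answers: the seed
#' questions are asked first in seed-rank order, then questions are chosen
#' greedily by expected probability shift until the stopping rule fires, the
#' question budget is exhausted, or no questions remain. Any question absent
#' from `answers` is treated as "don't know".
#'
#' @param kb A `vision_kb`.
#' @param answers Named character vector (or function of a question id)
#'   mapping question ids to `"yes"`, `"no"` or `"unknown"`.
#' @return A `session_transcript`: `steps` (data.frame of `question`,
#'   `answer`), per-step differentials, `terminated_by` (one of
#'   `"STOP_RULE"`, `"MAX_QUESTIONS"`, `"EXHAUSTED"`), the final
#'   `belief` and final `differential`.
#' @export
#' @examples
#' tr <- run_session(builtin_kb(), c(binocular_field_defect = "yes"))
#' tr$differential$dx[1]
run_session <- function(kb, answers) {
  belief <- new_belief(kb)
  qids <- character()
  avals <- character()
  diffs <- list()

  ask <- function(qid) {
    a <- resolve_answer(answers, qid)
    belief <<- update_belief(belief, kb, qid, a)
    qids[[length(qids) + 1L]] <<- qid
    avals[[length(avals) + 1L]] <<- a
    diffs[[length(diffs) + 1L]] <<- rank_differential(belief)
  }

  for (qid in kb_seed_questions(kb)) ask(qid)

  repeat {
    reason <- stop_reason(belief, kb)
    if (!is.null(reason)) break
    ask(next_question(belief, kb))
  }

  structure(
    list(
      steps = data.frame(question = qids, answer = avals,
                         stringsAsFactors = FALSE),
      step_differentials = diffs,
      terminated_by = reason,
      belief = belief,
      differential = rank_differential(belief)
    ),
    class = "session_transcript"
  )
}

#' @export
print.session_transcript <- function(x, ...) {
  cat("<session_transcript> ", nrow(x$steps), " question(s), terminated by ",
      x$terminated_by, "\n", sep = "")
  top <- utils::head(x$differential, 3)
  cat("  top 3: ", paste0(top$dx, " (", sprintf("%.3f", top$posterior), ")",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Supporting and refuting evidence for a diagnosis
#'
#' For each answered (non-unknown) question, compares the likelihood of the
#' observed answer under `dx` with its prior-weighted average likelihood
#' under every other diagnosis. Answers more likely under `dx` support it;
#' answers less likely refute it. Weights are absolute natural-log
#' likelihood ratios, and each list is sorted by descending weight.
#'
#' @param kb A `vision_kb`.
#' @param answers Named character vector of answers.
#' @param dx Diagnosis id.
#' @return List with data.frames `supports` and `refutes`, each with columns
#'   `question`, `answer`, `weight`.
#' @export
#' @examples
#' ev <- evidence_for(builtin_kb(), c(red_reflex_absent = "yes"),
#'                    "vitreous_hemorrhage")
#' ev$supports
evidence_for <- function(kb, answers, dx) {
  if (!dx %in% kb_dx_ids(kb)) stop("unknown diagnosis id: ", dx, call. = FALSE)
  answers <- answers[!is.na(answers) & answers != "unknown"]
  items <- data.frame(question = character(), answer = character(),
                      weight = numeric(), supports = logical(),
                      stringsAsFactors = FALSE)
  priors <- kb_priors(kb)
  others <- setdiff(kb_dx_ids(kb), dx)
  w_other <- priors[others] / sum(priors[others])
  for (qid in names(answers)) {
    check_question(kb, qid)
    lik <- answer_likelihood(kb, qid, answers[[qid]])
    lik_dx <- lik[[dx]]
    lik_other <- sum(w_other * lik[others])
    items <- rbind(items, data.frame(
      question = qid, answer = answers[[qid]],
      weight = abs(log(lik_dx / lik_other)),
      supports = lik_dx > lik_other, stringsAsFactors = FALSE
    ))
  }
  sel <- function(keep) {
    out <- items[items$supports == keep,
                 c("question", "answer", "weight"), drop = FALSE]
    out <- out[order(-out$weight), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(supports = sel(TRUE), refutes = sel(FALSE))
}
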