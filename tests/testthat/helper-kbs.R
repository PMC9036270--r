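# Toy knowledge bases and independent oracles used across the suite.

# Minimal engine KB with arbitrary dimensions; bypasses vocabulary
# validation (the engine itself is vocabulary-agnostic).
toy_kb <- function(p_yes, priors, seed_ranks = NULL,
                   stop_ratio = 20, max_questions = nrow(p_yes),
                   epsilon = 1e-9) {
  nd <- ncol(p_yes)
  nq <- nrow(p_yes)
  dx_ids <- colnames(p_yes) %||% paste0("d", seq_len(nd))
  q_ids <- rownames(p_yes) %||% paste0("q", seq_len(nq))
  dimnames(p_yes) <- list(q_ids, dx_ids)
  if (is.null(seed_ranks)) seed_ranks <- rep(NA_integer_, nq)
  visiontriage:::new_kb(
    diagnoses = data.frame(
      id = dx_ids, display_name = dx_ids,
      cluster = rep("optic_nerve", nd),
      urgency = rep("URGENT", nd),
      prior = priors / sum(priors), stringsAsFactors = FALSE),
    questions = data.frame(id = q_ids, text = q_ids,
                           seed_rank = seed_ranks, stringsAsFactors = FALSE),
    likelihoods = p_yes,
    params = list(stop_ratio = stop_ratio,
                  max_questions = as.integer(max_questions),
                  epsilon = epsilon, ci_level = 0.95)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_kb <- function(nd, nq, seed, seeds = FALSE) {
  set.seed(seed)
  p <- matrix(runif(nq * nd, 0.05, 0.95), nq, nd)
  pri <- runif(nd, 0.2, 1)
  sr <- rep(NA_integer_, nq)
  if (seeds) sr[seq_len(min(3L, nq))] <- seq_len(min(3L, nq))
  toy_kb(p, pri, seed_ranks = sr)
}

random_answers <- function(kb, seed, p_unknown = 0.2) {
  set.seed(seed)
  qids <- kb$questions$id
  stats::setNames(
    sample(c("yes", "no", "unknown"), length(qids), replace = TRUE,
           prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2, p_unknown)),
    qids)
}

# Brute-force joint posterior: multiply all answer likelihoods per
# diagnosis, normalize once.
oracle_joint_posterior <- function(kb, answers) {
  lik <- rep(1, nrow(kb$diagnoses))
  names(lik) <- kb$diagnoses$id
  for (qid in names(answers)) {
    p <- kb$likelihoods[qid, ]
    lik <- lik * switch(answers[[qid]], yes = p, no = 1 - p,
                        unknown = rep(1, length(p)))
  }
  post <- kb$diagnoses$prior * lik
  stats::setNames(post / sum(post), kb$diagnoses$id)
}

# Direct-summation predictive oracle.
oracle_predictive <- function(belief, kb, qid) {
  s <- 0
  for (d in names(belief$probs)) {
    s <- s + belief$probs[[d]] * kb$likelihoods[qid, d]
  }
  s
}

# Explicit two-branch enumeration of the expected total-variation shift.
oracle_shift <- function(belief, kb, qid) {
  pre <- belief$probs
  out <- 0
  for (a in c("yes", "no")) {
    lik <- if (a == "yes") kb$likelihoods[qid, ] else 1 - kb$likelihoods[qid, ]
    w <- sum(pre * lik)
    post <- pre * lik / sum(pre * lik)
    out <- out + w * sum(abs(post - pre)) / 2
  }
  out
}

# Exhaustive argmax over unasked questions, lexicographic tie-break.
oracle_next_question <- function(belief, kb) {
  unasked <- setdiff(kb$questions$id, belief$asked)
  seeds <- setdiff(visiontriage:::kb_seed_questions(kb), belief$asked)
  if (length(seeds)) return(seeds[[1L]])
  if (!length(unasked)) return(NULL)
  best <- NULL
  best_score <- -Inf
  for (q in sort(unasked)) {
    s <- oracle_shift(belief, kb, q)
    if (s > best_score + 1e-15) {
      best <- q
      best_score <- s
    }
  }
  best
}

# Exact binomial interval by bisection on the binomial tail sums.
oracle_clopper_pearson <- function(x, n, level = 0.95, tol = 1e-12) {
  alpha <- (1 - level) / 2
  lo <- if (x == 0) 0 else {
    stats::uniroot(function(p) stats::pbinom(x - 1, n, p,
                                             lower.tail = FALSE) - alpha,
                   c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  hi <- if (x == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha,
                   c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  c(lo = 100 * lo, hi = 100 * hi)
}
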