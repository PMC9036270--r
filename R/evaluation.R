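# Diagnostic-accuracy evaluation: top-k accuracy, per-cluster accuracy,
# referrer accuracy, and urgency sensitivity/specificity with exact
# binomial confidence intervals.

#' Construct an encounter-record table
#'
#' One row per patient: answers to the questionnaire, the gold-standard
#' diagnosis label set (1 or 2 ids; the `"other"` sentinel is allowed for
#' out-of-vocabulary diagnoses), and the referrer's diagnosis if one was
#' attempted.
#'
#' @param patient_id Character vector of unique ids.
#' @param gold_dx Character vector; one or two diagnosis ids per record,
#'   separated by `";"`.
#' @param referrer_dx Character vector of diagnosis ids; `NA` or `""` when no
#'   referrer diagnosis was attempted.
#' @param answers Optional data.frame of `q_<question id>` columns with
#'   values `yes`/`no`/`unknown` (`NA` or empty treated as unknown).
#' @return An `encounter_records` data.frame.
#' @export
encounter_records <- function(patient_id, gold_dx, referrer_dx = NA_character_,
                              answers = NULL) {
  df <- data.frame(patient_id = as.character(patient_id),
                   gold_dx = as.character(gold_dx),
                   referrer_dx = as.character(referrer_dx),
                   stringsAsFactors = FALSE)
  if (!is.null(answers)) df <- cbind(df, answers)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicated patient_id values", call. = FALSE)
  }
  ngold <- lengths(gold_sets(df))
  if (any(ngold < 1L | ngold > 2L)) {
    stop("gold_dx must contain 1 or 2 diagnosis ids per record",
         call. = FALSE)
  }
  class(df) <- c("encounter_records", "data.frame")
  df
}

# List of gold diagnosis id vectors, one per record.
gold_sets <- function(records) {
  strsplit(records$gold_dx, ";", fixed = TRUE)
}

answer_columns <- function(records) {
  grep("^q_", names(records), value = TRUE)
}

# Named answer vector for one record row, unknowns included.
record_answers <- function(records, i) {
  cols <- answer_columns(records)
  a <- vapply(cols, function(cl) {
    v <- records[[cl]][[i]]
    if (is.na(v) || !nzchar(v)) "unknown" else v
  }, character(1))
  stats::setNames(a, sub("^q_", "", cols))
}

check_aligned <- function(records, diffs) {
  if (length(diffs) != nrow(records)) {
    stop("records and differentials are misaligned: ", nrow(records),
         " records vs ", length(diffs), " differentials", call. = FALSE)
  }
  nms <- names(diffs)
  if (!is.null(nms) && !identical(nms, records$patient_id)) {
    stop("records and differentials are misaligned: patient ids differ",
         call. = FALSE)
  }
  invisible(TRUE)
}

# A record is correct at depth k iff its gold set intersects the first k
# ranked diagnoses. The "other" sentinel never appears in a differential and
# so never matches.
correct_at_k <- function(records, diffs, k) {
  check_aligned(records, diffs)
  golds <- gold_sets(records)
  vapply(seq_len(nrow(records)), function(i) {
    topk <- utils::head(diffs[[i]]$dx, k)
    any(golds[[i]] %in% topk)
  }, logical(1))
}

#' Top-k diagnostic accuracy
#'
#' A case counts as correctly diagnosed at depth `k` when any of its
#' gold-standard diagnoses appears among the first `k` entries of its ranked
#' differential.
#'
#' @param records An `encounter_records` table.
#' @param diffs List of `vl_differential`s aligned with `records` (same
#'   length and order; names, if present, must match `patient_id`).
#' @param k Ranking depth (>= 1).
#' @return List with `correct`, `total` and `percent` (1 decimal place).
#' @export
top_k_accuracy <- function(records, diffs, k) {
  stopifnot(k >= 1)
  ok <- correct_at_k(records, diffs, k)
  list(correct = sum(ok), total = length(ok), percent = pct(sum(ok), length(ok)))
}

#' Referrer diagnostic accuracy
#'
#' A referral is correct when a diagnosis was attempted and it belongs to the
#' gold set; a referral without an attempted diagnosis is counted incorrect.
#'
#' @inheritParams top_k_accuracy
#' @return List with `correct`, `total` and `percent`.
#' @export
referrer_accuracy <- function(records) {
  ok <- referrer_correct(records)
  list(correct = sum(ok), total = length(ok), percent = pct(sum(ok), length(ok)))
}

referrer_correct <- function(records) {
  golds <- gold_sets(records)
  vapply(seq_len(nrow(records)), function(i) {
    r <- records$referrer_dx[[i]]
    !is.na(r) && nzchar(r) && r %in% golds[[i]]
  }, logical(1))
}

# Cluster used to group a record: the cluster of its first gold diagnosis
# (dual-gold records list the peripheral retinal issue first and therefore
# fall in the peripheral retinopathy/vitreous cluster).
record_cluster <- function(records, kb) {
  vapply(gold_sets(records), function(g) cluster_of(g[[1L]], kb), character(1))
}

#' Per-cluster diagnostic accuracy
#'
#' Groups records by the anatomical cluster of their gold diagnosis and
#' counts correct cases per cluster, either for the referrer
#' (`k = "referrer"`) or for the algorithm differential at depth `k`.
#' Clusters with no records are omitted.
#'
#' @inheritParams top_k_accuracy
#' @param k Ranking depth, or the string `"referrer"`.
#' @param kb A `vision_kb`.
#' @return data.frame with columns `cluster`, `correct`, `total`, `percent`,
#'   in fixed cluster order.
#' @export
per_cluster_accuracy <- function(records, diffs, k, kb) {
  ok <- if (identical(k, "referrer")) referrer_correct(records)
        else correct_at_k(records, diffs, k)
  cl <- record_cluster(records, kb)
  out <- do.call(rbind, lapply(cluster_labels(), function(lab) {
    n <- sum(cl == lab)
    if (!n) return(NULL)
    data.frame(cluster = lab, correct = sum(ok[cl == lab]), total = n,
               percent = pct(sum(ok[cl == lab]), n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Gold urgency of each record: URGENT if any gold diagnosis is urgent.
gold_urgency <- function(records, kb) {
  vapply(gold_sets(records), function(g) {
    if (any(vapply(g, urgency_of, character(1), kb = kb) == "URGENT")) {
      "URGENT"
    } else {
      "NON_URGENT"
    }
  }, character(1))
}

#' Urgency confusion matrix
#'
#' Cross-tabulates predicted against gold urgency (URGENT is the positive
#' class). A record's gold urgency is URGENT when any of its gold diagnoses
#' is urgent.
#'
#' @inheritParams top_k_accuracy
#' @param flags Character vector of predicted classes (`"URGENT"` /
#'   `"NON_URGENT"`) aligned with `records`.
#' @param kb A `vision_kb`.
#' @return List of counts `tp`, `fn`, `tn`, `fp` (class `urgency_confusion`).
#' @export
urgency_confusion <- function(records, flags, kb) {
  if (length(flags) != nrow(records)) {
    stop("records and flags are misaligned: ", nrow(records), " records vs ",
         length(flags), " flags", call. = FALSE)
  }
  gold <- gold_urgency(records, kb)
  structure(
    list(tp = sum(gold == "URGENT" & flags == "URGENT"),
         fn = sum(gold == "URGENT" & flags == "NON_URGENT"),
         tn = sum(gold == "NON_URGENT" & flags == "NON_URGENT"),
         fp = sum(gold == "NON_URGENT" & flags == "URGENT")),
    class = "urgency_confusion"
  )
}

#' @export
print.urgency_confusion <- function(x, ...) {
  cat("<urgency_confusion> tp=", x$tp, " fn=", x$fn, " tn=", x$tn,
      " fp=", x$fp, "\n", sep = "")
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion via the beta-quantile
#' characterization of the binomial tails. The lower bound is 0 when there
#' are no successes and the upper bound 100 when every trial succeeded.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (>= 1).
#' @param level Confidence level, e.g. 0.95.
#' @return A `proportion_ci`: `successes`, `trials`, `level`, `point`
#'   (percent, 1 decimal), `lo`, `hi` (exact percent bounds), and `lo_int`,
#'   `hi_int` (bounds rounded to integer percent, half up — the usual
#'   reporting style).
#' @export
#' @examples
#' clopper_pearson(19, 25, 0.95)
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    stop("out-of-range counts: successes=", successes, ", trials=", trials,
         call. = FALSE)
  }
  alpha <- (1 - level) / 2
  lo <- if (successes == 0) 0 else
    stats::qbeta(alpha, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha, successes + 1, trials - successes)
  structure(
    list(successes = successes, trials = trials, level = level,
         point = pct(successes, trials),
         lo = 100 * lo, hi = 100 * hi,
         lo_int = round_half_up(100 * lo), hi_int = round_half_up(100 * hi)),
    class = "proportion_ci"
  )
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(format_ci(x), "\n")
  invisible(x)
}

format_ci <- function(ci) {
  sprintf("%.1f%% (%d%% CI: %d-%d%%)", ci$point, round(100 * ci$level),
          ci$lo_int, ci$hi_int)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' @param cm An `urgency_confusion`.
#' @param level Confidence level.
#' @return List with `sensitivity` and `specificity`, each a
#'   `proportion_ci`.
#' @export
sens_spec <- function(cm, level = 0.95) {
  if (cm$tp + cm$fn == 0) stop("no positive cases", call. = FALSE)
  if (cm$tn + cm$fp == 0) stop("no negative cases", call. = FALSE)
  list(sensitivity = clopper_pearson(cm$tp, cm$tp + cm$fn, level),
       specificity = clopper_pearson(cm$tn, cm$tn + cm$fp, level))
}

#' Full accuracy report for a cohort
#'
#' Computes every diagnostic-accuracy statistic for a set of encounter
#' records with aligned differentials: overall and per-cluster referrer and
#' top-k accuracies, the same statistics restricted to urgent and non-urgent
#' cases, and urgency sensitivity/specificity (with exact CIs) for both the
#' algorithm's top-diagnosis flag and the referrer's diagnosis flag (a
#' referral without a diagnosis is flagged non-urgent).
#'
#' @inheritParams top_k_accuracy
#' @param kb A `vision_kb`.
#' @param ks Ranking depths to evaluate (default 1, 2, 3).
#' @return An `accuracy_report` list.
#' @export
evaluate_records <- function(records, diffs, kb, ks = c(1L, 2L, 3L)) {
  check_aligned(records, diffs)
  ks <- sort(unique(as.integer(ks)))
  topk <- lapply(ks, function(k) top_k_accuracy(records, diffs, k))
  names(topk) <- paste0("top", ks)

  clusters <- c(list(referrer = per_cluster_accuracy(records, diffs,
                                                     "referrer", kb)),
                stats::setNames(
                  lapply(ks, function(k)
                    per_cluster_accuracy(records, diffs, k, kb)),
                  paste0("top", ks)))

  gold_urg <- gold_urgency(records, kb)
  urgent <- records[gold_urg == "URGENT", , drop = FALSE]
  urgent_diffs <- diffs[gold_urg == "URGENT"]
  nonurgent <- records[gold_urg == "NON_URGENT", , drop = FALSE]
  nonurgent_diffs <- diffs[gold_urg == "NON_URGENT"]
  class(urgent) <- class(nonurgent) <- class(records)

  urgent_stats <- c(
    list(referrer = referrer_accuracy(urgent)),
    stats::setNames(lapply(ks, function(k)
      top_k_accuracy(urgent, urgent_diffs, k)), paste0("top", ks))
  )
  nonurgent_stats <- list(
    referrer = referrer_accuracy(nonurgent),
    top1 = top_k_accuracy(nonurgent, nonurgent_diffs, 1L)
  )

  algo_flags <- vapply(diffs, predicted_urgency, character(1), kb = kb)
  ref_flags <- vapply(records$referrer_dx, referrer_urgency, character(1),
                      kb = kb)
  algo_cm <- urgency_confusion(records, algo_flags, kb)
  ref_cm <- urgency_confusion(records, unname(ref_flags), kb)
  level <- kb$params$ci_level

  structure(
    list(
      n = nrow(records),
      ks = ks,
      referrer = referrer_accuracy(records),
      topk = topk,
      clusters = clusters,
      urgent = urgent_stats,
      nonurgent = nonurgent_stats,
      algorithm_confusion = algo_cm,
      referrer_confusion = ref_cm,
      algorithm_urgency = sens_spec(algo_cm, level),
      referrer_urgency = sens_spec(ref_cm, level)
    ),
    class = "accuracy_report"
  )
}

frac <- function(st) sprintf("%d/%d (%.1f%%)", st$correct, st$total, st$percent)

#' Format an accuracy report as text
#'
#' Mirrors the familiar cluster-by-cluster accuracy table layout plus the
#' urgency confusion statistics.
#'
#' @param report An `accuracy_report`.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  ks <- report$ks
  kcols <- paste0("top", ks)
  header <- paste(c("cluster", "referrer", paste0("top_", ks)),
                  collapse = "\t")
  cl_ref <- report$clusters$referrer
  rows <- vapply(seq_len(nrow(cl_ref)), function(i) {
    lab <- cl_ref$cluster[[i]]
    cells <- vapply(kcols, function(kc) {
      tab <- report$clusters[[kc]]
      j <- match(lab, tab$cluster)
      sprintf("%d/%d", tab$correct[[j]], tab$total[[j]])
    }, character(1))
    paste(c(lab, sprintf("%d/%d", cl_ref$correct[[i]], cl_ref$total[[i]]),
            cells), collapse = "\t")
  }, character(1))
  total_row <- paste(c(
    "total",
    sprintf("%d/%d", report$referrer$correct, report$referrer$total),
    vapply(kcols, function(kc)
      sprintf("%d/%d", report$topk[[kc]]$correct, report$topk[[kc]]$total),
      character(1))
  ), collapse = "\t")

  urgent_lines <- c(
    sprintf("urgent subset: referrer %s", frac(report$urgent$referrer)),
    vapply(kcols, function(kc)
      sprintf("urgent subset: %s %s", kc, frac(report$urgent[[kc]])),
      character(1)),
    sprintf("non-urgent subset: top1 %s", frac(report$nonurgent$top1))
  )

  cm_line <- function(tag, cm, ss) {
    c(sprintf("%s urgency confusion: tp=%d fn=%d tn=%d fp=%d",
              tag, cm$tp, cm$fn, cm$tn, cm$fp),
      sprintf("%s sensitivity: %s", tag, format_ci(ss$sensitivity)),
      sprintf("%s specificity: %s", tag, format_ci(ss$specificity)))
  }

  c(header, rows, total_row, "", urgent_lines, "",
    cm_line("algorithm", report$algorithm_confusion,
            report$algorithm_urgency),
    cm_line("referrer", report$referrer_confusion, report$referrer_urgency))
}

#' @export
print.accuracy_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
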