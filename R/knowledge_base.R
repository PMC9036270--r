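# Knowledge base: diagnosis vocabulary, question set, likelihood table,
# cluster/urgency maps and engine parameters.

KB_SCHEMA_VERSION <- 1L

KB_TOP_KEYS <- c("schema_version", "diagnoses", "questions", "likelihoods", "params")

ANSWER_VALUES <- c("yes", "no", "unknown")

#' Canonical diagnosis vocabulary for acute vision loss
#'
#' The engine reasons over a fixed vocabulary of 13 diagnoses of acute vision
#' loss, grouped so that every label is distinguishable from the others on
#' symptoms and bedside signs alone (no fundoscopy). NAION, BRAO and BVO form
#' a single label because they present alike with peripheral vision loss,
#' in contrast to the central ("other macular") causes. The row order of the
#' returned table is the canonical order used for deterministic tie-breaking
#' throughout the package.
#'
#' @return A data.frame with columns `id`, `display_name`, `cluster`,
#'   `urgency`, one row per diagnosis, in canonical order.
#' @seealso [cluster_labels()], [builtin_kb()]
#' @export
#' @examples
#' canonical_diagnoses()
canonical_diagnoses <- function() {
  data.frame(
    id = c(
      "optic_neuritis", "optic_nerve_compression", "naion_brao_bvo",
      "crao", "cvo", "temporal_arteritis", "other_macular",
      "peripheral_retinal", "floaters_pvd", "vitreous_hemorrhage",
      "lens_cornea", "migraine", "post_chiasmal"
    ),
    display_name = c(
      "Optic neuritis",
      "Optic nerve compression",
      "NAION/BRAO/BVO",
      "Central retinal artery occlusion (CRAO)",
      "Central vein occlusion (CVO)",
      "Temporal arteritis",
      "Other macular disease",
      "Peripheral retinal issue (retinal tear or detachment)",
      "Vitreous floaters/PVD",
      "Vitreous hemorrhage",
      "Lens/cornea issue (including acute angle glaucoma)",
      "Migraine",
      "Post-chiasmal disease"
    ),
    cluster = c(
      "optic_nerve", "optic_nerve", "optic_nerve", "optic_nerve",
      "optic_nerve", "optic_nerve", "macular", "peripheral_vitreous",
      "peripheral_vitreous", "peripheral_vitreous", "media", "migraine",
      "post_chiasmal"
    ),
    urgency = c(
      "URGENT", "URGENT", "URGENT", "URGENT", "URGENT", "URGENT",
      "NON_URGENT", "URGENT", "NON_URGENT", "URGENT", "NON_URGENT",
      "NON_URGENT", "URGENT"
    ),
    stringsAsFactors = FALSE
  )
}

#' Anatomical cluster labels
#'
#' Six anatomical clusters along the visual axis, plus an `other` sentinel for
#' gold-standard diagnoses outside the engine's vocabulary (e.g.
#' endophthalmitis).
#'
#' @return Character vector of the 7 cluster ids.
#' @export
cluster_labels <- function() {
  c("peripheral_vitreous", "optic_nerve", "macular", "media", "migraine",
    "post_chiasmal", "other")
}

#' Sentinel id for out-of-vocabulary gold diagnoses
#' @return The string `"other"`.
#' @export
other_sentinel <- function() "other"

default_params <- function() {
  list(stop_ratio = 20, max_questions = 15L, epsilon = 0.01, ci_level = 0.95)
}

# Low-level constructor; performs no validation (used for toy engine KBs in
# tests as well as the shipped KB).
new_kb <- function(diagnoses, questions, likelihoods, params = default_params(),
                   schema_version = KB_SCHEMA_VERSION) {
  structure(
    list(
      schema_version = as.integer(schema_version),
      diagnoses = diagnoses,
      questions = questions,
      likelihoods = likelihoods,
      params = params
    ),
    class = "vision_kb"
  )
}

kb_dx_ids <- function(kb) kb$diagnoses$id
kb_question_ids <- function(kb) kb$questions$id
kb_priors <- function(kb) stats::setNames(kb$diagnoses$prior, kb$diagnoses$id)
kb_seed_questions <- function(kb) {
  q <- kb$questions[!is.na(kb$questions$seed_rank), , drop = FALSE]
  q$id[order(q$seed_rank)]
}
kb_p_yes <- function(kb, qid) kb$likelihoods[qid, ]

#' @export
print.vision_kb <- function(x, ...) {
  seeds <- kb_seed_questions(x)
  cat("<vision_kb> schema v", x$schema_version, "\n", sep = "")
  cat("  diagnoses: ", nrow(x$diagnoses), " (",
      sum(x$diagnoses$urgency == "URGENT"), " urgent)\n", sep = "")
  cat("  questions: ", nrow(x$questions), " (seeds: ",
      paste(seeds, collapse = ", "), ")\n", sep = "")
  cat("  params: stop_ratio=", x$params$stop_ratio,
      ", max_questions=", x$params$max_questions,
      ", epsilon=", x$params$epsilon,
      ", ci_level=", x$params$ci_level, "\n", sep = "")
  invisible(x)
}

#' Validate a knowledge base
#'
#' Checks every structural invariant of a knowledge base and reports all
#' violations; it never throws. An empty return value means the knowledge base
#' is valid.
#'
#' @param kb A `vision_kb` object.
#' @return Character vector of human-readable issues (empty if valid), each
#'   naming the offending entry.
#' @export
#' @examples
#' validate_kb(builtin_kb())
validate_kb <- function(kb) {
  issues <- character()
  note <- function(...) issues[[length(issues) + 1L]] <<- paste0(...)

  canon <- canonical_diagnoses()
  dx <- kb$diagnoses

  if (!identical(kb$schema_version, KB_SCHEMA_VERSION)) {
    note("schema_version: expected ", KB_SCHEMA_VERSION, ", got ",
         kb$schema_version)
  }

  if (nrow(dx) != 13L) {
    note("diagnoses: expected exactly 13 labels, got ", nrow(dx))
  }
  if (!identical(dx$id, canon$id)) {
    missing <- setdiff(canon$id, dx$id)
    extra <- setdiff(dx$id, canon$id)
    if (length(missing)) note("diagnoses: missing ids: ",
                              paste(missing, collapse = ", "))
    if (length(extra)) note("diagnoses: unknown ids: ",
                            paste(extra, collapse = ", "))
    if (!length(missing) && !length(extra)) {
      note("diagnoses: ids not in canonical order")
    }
  }

  if (!all(dx$cluster %in% setdiff(cluster_labels(), "other"))) {
    bad <- dx$id[!dx$cluster %in% setdiff(cluster_labels(), "other")]
    note("cluster_map: invalid or missing cluster for: ",
         paste(bad, collapse = ", "))
  }
  if (anyNA(dx$cluster)) note("cluster_map: NA cluster present")
  if (!all(dx$urgency %in% c("URGENT", "NON_URGENT")) || anyNA(dx$urgency)) {
    bad <- dx$id[!dx$urgency %in% c("URGENT", "NON_URGENT")]
    note("urgency_map: invalid or missing urgency for: ",
         paste(bad, collapse = ", "))
  }

  if (anyNA(dx$prior) || any(dx$prior <= 0)) {
    note("priors: non-positive or missing prior for: ",
         paste(dx$id[is.na(dx$prior) | dx$prior <= 0], collapse = ", "))
  } else if (abs(sum(dx$prior) - 1) > 1e-9) {
    note("priors: must sum to 1 (sum = ", format(sum(dx$prior), digits = 15),
         ")")
  }

  qs <- kb$questions
  if (anyDuplicated(qs$id)) {
    note("questions: duplicated ids: ",
         paste(unique(qs$id[duplicated(qs$id)]), collapse = ", "))
  }
  seeds <- qs$seed_rank[!is.na(qs$seed_rank)]
  if (length(seeds)) {
    if (anyDuplicated(seeds) ||
        !identical(sort(as.integer(seeds)), seq_len(length(seeds)))) {
      note("questions: seed_rank values must be unique and contiguous from 1")
    }
    if (length(seeds) < 3L || length(seeds) > 4L) {
      note("questions: expected 3-4 seed questions, got ", length(seeds))
    }
  } else {
    note("questions: no seed questions defined (expected 3-4)")
  }

  lik <- kb$likelihoods
  if (!is.matrix(lik) ||
      !identical(rownames(lik), qs$id) ||
      !identical(colnames(lik), dx$id)) {
    note("likelihoods: table must be dense over questions x diagnoses, ",
         "rows/columns matching question and diagnosis ids")
  } else {
    eps <- kb$params$epsilon
    bad <- which(is.na(lik) | lik < eps | lik > 1 - eps, arr.ind = TRUE)
    if (nrow(bad)) {
      for (i in seq_len(min(nrow(bad), 20L))) {
        note("likelihoods: p_yes(", rownames(lik)[bad[i, 1]], ", ",
             colnames(lik)[bad[i, 2]], ") outside clipping floor [",
             eps, ", ", 1 - eps, "]")
      }
      if (nrow(bad) > 20L) note("likelihoods: ... and ", nrow(bad) - 20L,
                                " further out-of-range entries")
    }
  }

  p <- kb$params
  if (!is.numeric(p$stop_ratio) || p$stop_ratio <= 1) {
    note("params: stop_ratio must be > 1")
  }
  if (!is.numeric(p$max_questions) || p$max_questions < 1) {
    note("params: max_questions must be >= 1")
  }
  if (!is.numeric(p$epsilon) || p$epsilon <= 0 || p$epsilon >= 0.5) {
    note("params: epsilon must lie in (0, 0.5)")
  }
  if (!is.numeric(p$ci_level) || p$ci_level <= 0 || p$ci_level >= 1) {
    note("params: ci_level must lie in (0, 1)")
  }

  issues
}

#' Load a knowledge base from a YAML file
#'
#' Parses and validates a knowledge-base document. The schema has five
#' top-level keys: `schema_version`, `diagnoses` (list of `id`,
#' `display_name`, `cluster`, `urgency`, `prior`), `questions` (list of `id`,
#' `text`, optional `seed_rank`), `likelihoods` (question id -> diagnosis id
#' -> probability of a YES answer), and `params` (`stop_ratio`,
#' `max_questions`, `epsilon`, `ci_level`). Unknown top-level keys are
#' rejected.
#'
#' @param path Path to the YAML document.
#' @return A validated `vision_kb` object.
#' @seealso [write_kb()], [validate_kb()], [builtin_kb()]
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "vision_loss_kb.yaml",
#'                           package = "visiontriage"))
#' kb
load_kb <- function(path) {
  if (!file.exists(path)) {
    stop("knowledge base file not found: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)

  unknown <- setdiff(names(doc), KB_TOP_KEYS)
  if (length(unknown)) {
    stop("knowledge base schema violation: unknown top-level key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(KB_TOP_KEYS, names(doc))
  if (length(missing)) {
    stop("knowledge base schema violation: missing top-level key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  dx <- do.call(rbind, lapply(doc$diagnoses, function(d) {
    data.frame(
      id = as.character(d$id),
      display_name = as.character(d$display_name %||% d$id),
      cluster = as.character(d$cluster %||% NA_character_),
      urgency = as.character(d$urgency %||% NA_character_),
      prior = as.numeric(d$prior %||% NA_real_),
      stringsAsFactors = FALSE
    )
  }))

  qs <- do.call(rbind, lapply(doc$questions, function(q) {
    data.frame(
      id = as.character(q$id),
      text = as.character(q$text %||% q$id),
      seed_rank = if (is.null(q$seed_rank)) NA_integer_ else
        as.integer(q$seed_rank),
      stringsAsFactors = FALSE
    )
  }))

  lik <- matrix(NA_real_, nrow = nrow(qs), ncol = nrow(dx),
                dimnames = list(qs$id, dx$id))
  for (qid in names(doc$likelihoods)) {
    if (!qid %in% qs$id) {
      stop("knowledge base schema violation: likelihoods entry for unknown ",
           "question '", qid, "'", call. = FALSE)
    }
    row <- doc$likelihoods[[qid]]
    bad_dx <- setdiff(names(row), dx$id)
    if (length(bad_dx)) {
      stop("knowledge base schema violation: likelihoods[", qid,
           "] names unknown diagnosis: ", paste(bad_dx, collapse = ", "),
           call. = FALSE)
    }
    lik[qid, names(row)] <- as.numeric(unlist(row))
  }

  params <- utils::modifyList(default_params(), doc$params %||% list())
  params$max_questions <- as.integer(params$max_questions)

  kb <- new_kb(dx, qs, lik, params,
               schema_version = doc$schema_version %||% -1L)

  prior_sum <- sum(dx$prior)
  if (!anyNA(dx$prior) && abs(prior_sum - 1) > 1e-9) {
    stop("knowledge base normalization error: priors sum to ",
         format(prior_sum, digits = 15), ", expected 1", call. = FALSE)
  }
  issues <- validate_kb(kb)
  if (length(issues)) {
    stop("knowledge base validation failed:\n  - ",
         paste(issues, collapse = "\n  - "), call. = FALSE)
  }
  kb
}

#' Write a knowledge base to a YAML file
#'
#' Inverse of [load_kb()]: a load/write/load round-trip reproduces the same
#' structure.
#'
#' @param kb A `vision_kb` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  doc <- list(
    schema_version = kb$schema_version,
    params = kb$params,
    diagnoses = lapply(seq_len(nrow(kb$diagnoses)), function(i) {
      d <- kb$diagnoses[i, ]
      list(id = d$id, display_name = d$display_name, cluster = d$cluster,
           urgency = d$urgency, prior = d$prior)
    }),
    questions = lapply(seq_len(nrow(kb$questions)), function(i) {
      q <- kb$questions[i, ]
      out <- list(id = q$id, text = q$text)
      if (!is.na(q$seed_rank)) out$seed_rank <- as.integer(q$seed_rank)
      out
    }),
    likelihoods = stats::setNames(
      lapply(kb$questions$id, function(qid) {
        as.list(stats::setNames(kb$likelihoods[qid, ], kb$diagnoses$id))
      }),
      kb$questions$id
    )
  )
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

.builtin_kb_cache <- new.env(parent = emptyenv())

#' The shipped illustrative knowledge base
#'
#' Loads the knowledge base distributed with the package: the 13-diagnosis
#' vocabulary, 16 Yes/No/Don't-know questions covering history and bedside
#' findings (no fundoscopy required beyond the red reflex), a dense answer
#' likelihood table, and default engine parameters. The likelihood values are
#' illustrative and literature-plausible, not estimates from patient data;
#' they are constrained to behave correctly on key clinical anchors (an
#' absent red reflex points to vitreous hemorrhage and away from optic
#' nerve/circulation disease; a young patient without vascular risk factors
#' and an RAPD points to optic neuritis or nerve compression rather than
#' ischemia; a binocular field defect points behind the chiasm; an
#' uninformative interview in an older patient keeps urgent diagnoses in the
#' top of the differential).
#'
#' @return A validated `vision_kb`.
#' @export
#' @examples
#' kb <- builtin_kb()
#' kb
builtin_kb <- function() {
  if (is.null(.builtin_kb_cache$kb)) {
    path <- system.file("extdata", "vision_loss_kb.yaml",
                        package = "visiontriage")
    .builtin_kb_cache$kb <- load_kb(path)
  }
  .builtin_kb_cache$kb
}
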