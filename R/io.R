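# Delimited-text interchange for encounter records and differentials.
#
# Encounter tables are tab-separated with columns `patient_id`, `gold_dx`
# (semicolon-separated ids), `referrer_dx` (id or empty) and one `q_<id>`
# column per question (yes|no|unknown, empty meaning unknown). Differential
# tables are long-format: `patient_id`, `rank`, `dx`, `posterior`. Lines
# starting with `#` are provenance headers and are skipped on read.

provenance_header <- function(extra = character()) {
  c(sprintf("# visiontriage %s",
            as.character(utils::packageVersion("visiontriage"))),
    if (length(extra)) paste0("# ", extra))
}

write_tsv_atomic <- function(df, path, extra_header = character()) {
  lines <- c(
    provenance_header(extra_header),
    paste(names(df), collapse = "\t"),
    do.call(paste, c(lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    }), sep = "\t"))
  )
  write_atomic(lines, path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE)
}

#' Write an encounter table
#'
#' @param records An `encounter_records` table.
#' @param path Output path.
#' @param extra_header Optional provenance lines (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_encounters <- function(records, path, extra_header = character()) {
  write_tsv_atomic(as.data.frame(records), path, extra_header)
}

#' Read an encounter table
#'
#' @param path Path to a tab-separated encounter table.
#' @param kb A `vision_kb` used to validate diagnosis ids and answer columns.
#' @return An `encounter_records` table.
#' @export
read_encounters <- function(path, kb) {
  df <- read_tsv(path)
  required <- c("patient_id", "gold_dx", "referrer_dx")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("encounter table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  qcols <- grep("^q_", names(df), value = TRUE)
  unknown_q <- setdiff(sub("^q_", "", qcols), kb_question_ids(kb))
  if (length(unknown_q)) {
    stop("encounter table has answer columns for unknown question(s): ",
         paste(unknown_q, collapse = ", "), call. = FALSE)
  }
  valid_dx <- c(kb_dx_ids(kb), other_sentinel())
  for (i in seq_len(nrow(df))) {
    g <- strsplit(df$gold_dx[[i]], ";", fixed = TRUE)[[1]]
    if (!length(g) || !all(g %in% valid_dx)) {
      stop("encounter table row ", i, ": invalid gold_dx '", df$gold_dx[[i]],
           "'", call. = FALSE)
    }
    r <- df$referrer_dx[[i]]
    if (nzchar(r) && !r %in% valid_dx) {
      stop("encounter table row ", i, ": invalid referrer_dx '", r, "'",
           call. = FALSE)
    }
    for (cl in qcols) {
      v <- df[[cl]][[i]]
      if (nzchar(v) && !v %in% ANSWER_VALUES) {
        stop("encounter table row ", i, ": invalid answer '", v, "' in ",
             cl, call. = FALSE)
      }
    }
  }
  df$referrer_dx[!nzchar(df$referrer_dx)] <- NA_character_
  class(df) <- c("encounter_records", "data.frame")
  df
}

#' Write a differential table
#'
#' @param diffs Named list of `vl_differential`s (names are patient ids).
#' @param path Output path.
#' @param extra_header Optional provenance lines.
#' @return `path`, invisibly.
#' @export
write_differentials <- function(diffs, path, extra_header = character()) {
  long <- do.call(rbind, lapply(names(diffs), function(pid) {
    d <- diffs[[pid]]
    data.frame(patient_id = pid, rank = seq_len(nrow(d)), dx = d$dx,
               posterior = sprintf("%.12g", d$posterior),
               stringsAsFactors = FALSE)
  }))
  write_tsv_atomic(long, path, extra_header)
}

#' Read a differential table
#'
#' @param path Path to a long-format differential table.
#' @param kb A `vision_kb` used to validate diagnosis ids.
#' @return Named list of `vl_differential`s.
#' @export
read_differentials <- function(path, kb) {
  df <- read_tsv(path)
  required <- c("patient_id", "rank", "dx", "posterior")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("differential table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$dx), kb_dx_ids(kb))
  if (length(bad)) {
    stop("differential table names unknown diagnosis id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pids <- unique(df$patient_id)
  out <- lapply(pids, function(pid) {
    sub <- df[df$patient_id == pid, , drop = FALSE]
    sub <- sub[order(as.integer(sub$rank)), , drop = FALSE]
    new_differential(sub$dx, as.numeric(sub$posterior))
  })
  stats::setNames(out, pids)
}
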