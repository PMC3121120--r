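#' @title Local sequence similarity at desk scale
#' @name similarity
#' @description A small Smith-Waterman local aligner (linear gap penalty)
#'   plus an all-against-all search that emits hits in the 12-column tabular
#'   dialect, so the mapping pipeline runs without an external similarity
#'   search tool. Precomputed hit tables from such a tool can be ingested
#'   with [read_similarity_table()] instead and used interchangeably.
NULL

#' Alignment scoring scheme
#'
#' @param match score for a matching pair of residues (must be > 0).
#' @param mismatch score for a mismatching pair (must be <= 0).
#' @param gap per-position (linear) gap penalty (must be < 0).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2) {
  if (!(match > 0)) abort("scoring_scheme: match must be > 0")
  if (!(mismatch <= 0)) abort("scoring_scheme: mismatch must be <= 0")
  if (!(gap < 0)) abort("scoring_scheme: gap must be < 0")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

.seq_to_int <- function(s) utf8ToInt(s)

.align_one <- function(q_res, s_res, scheme) {
  sw_align_cpp(.seq_to_int(q_res), .seq_to_int(s_res),
               scheme$match, scheme$mismatch, scheme$gap)
}

#' Optimal local alignment of two sequences
#'
#' Computes the maximal Smith-Waterman local alignment score under a linear
#' gap penalty. Among equal-scoring alignments, the one with the smallest
#' (`q_start`, `s_start`), then the shortest, is reported. A best score of
#' zero corresponds to the empty alignment (spans `[0, 0)`).
#'
#' @param query,subject one-row sequence tables (or sequence tables from
#'   which the first row is taken); both must share an alphabet.
#' @param scheme a [scoring_scheme()].
#' @return A one-row tibble: `query_id`, `subject_id`, `score`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open),
#'   `identity_fraction`.
#' @examples
#' a <- sequence_table("a", "ACGT")
#' b <- sequence_table("b", "ACGT")
#' local_align(a, b)$score # 4
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  if (query$alphabet[1] != subject$alphabet[1]) {
    abort("local_align: query and subject alphabets differ")
  }
  if (!nzchar(query$residues[1]) || !nzchar(subject$residues[1])) {
    abort("local_align: empty sequence")
  }
  r <- .align_one(query$residues[1], subject$residues[1], scheme)
  tibble(query_id = query$id[1], subject_id = subject$id[1],
         score = r$score,
         q_start = r$q_start, q_end = r$q_end,
         s_start = r$s_start, s_end = r$s_end,
         identity_fraction = if (r$aln_len > 0) r$matches / r$aln_len else 0)
}

#' All-against-all similarity search
#'
#' Aligns every query against every subject and emits one hit per pair whose
#' local alignment score reaches `min_score`. The `evalue` column is the
#' monotone surrogate `exp(-score)`, valid only for ranking within one run;
#' the returned tibble carries attribute `evalue_surrogate = TRUE` to flag
#' this.
#'
#' @param queries,subjects sequence tables sharing an alphabet.
#' @param scheme a [scoring_scheme()].
#' @param min_score minimal local alignment score to report (> 0).
#' @return A hit tibble in the layout of [read_similarity_table()]
#'   (1-based inclusive coordinates), sorted by (`query_id`, `subject_id`).
#' @export
find_similar <- function(queries, subjects, scheme = scoring_scheme(),
                         min_score = 1) {
  if (!(min_score > 0)) abort("find_similar: min_score must be > 0")
  empty <- tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = numeric(),
                  mismatches = numeric(), gap_opens = numeric(),
                  q_start = numeric(), q_end = numeric(),
                  s_start = numeric(), s_end = numeric(),
                  evalue = numeric(), score = numeric())
  if (nrow(queries) == 0L || nrow(subjects) == 0L) {
    return(structure(empty, evalue_surrogate = TRUE))
  }
  if (queries$alphabet[1] != subjects$alphabet[1]) {
    abort("find_similar: query and subject alphabets differ")
  }
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(queries))) {
    qint <- .seq_to_int(queries$residues[i])
    for (j in seq_len(nrow(subjects))) {
      r <- sw_align_cpp(qint, .seq_to_int(subjects$residues[j]),
                        scheme$match, scheme$mismatch, scheme$gap)
      if (r$score < min_score) next
      k <- k + 1L
      rows[[k]] <- tibble(
        query_id = queries$id[i], subject_id = subjects$id[j],
        percent_identity = round(100 * r$matches / r$aln_len, 2),
        alignment_length = r$aln_len,
        mismatches = r$diag - r$matches,
        gap_opens = r$gap_opens,
        q_start = r$q_start + 1, q_end = r$q_end,
        s_start = r$s_start + 1, s_end = r$s_end,
        evalue = exp(-r$score), score = r$score)
    }
  }
  hits <- if (k == 0L) empty else bind_rows(rows)
  hits <- arrange(hits, .data$query_id, .data$subject_id)
  structure(hits, evalue_surrogate = TRUE)
}

#' Filter a hit table by e-value
#'
#' Keeps hits with `evalue <= max_evalue`; row order is preserved.
#'
#' @param hits a hit tibble.
#' @param max_evalue maximal e-value to keep (> 0).
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5) {
  if (!(max_evalue > 0)) abort("filter_hits: max_evalue must be > 0")
  filter(hits, .data$evalue <= max_evalue)
}
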