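#' @title Mapping-set container
#' @name mapping_sets
#' @description Mapped transcription factors and target genes are held as
#'   tibbles subclassed `reglink_mapping`, carrying a `label` attribute that
#'   names the construction (`TFbl`, `TFf`, `TFsf` for TFs; `TGbl`, `TGbs`,
#'   `TGblbs`, `TGpr`, `TGgalf` for TGs). Downstream stages check the label
#'   so sets cannot be integrated under the wrong provenance.
NULL

.TF_LABELS <- c("TFbl", "TFf", "TFsf")
.TG_LABELS <- c("TGbl", "TGbs", "TGblbs", "TGpr", "TGgalf")

.new_mapping <- function(pairs, label) {
  structure(pairs,
            label = label,
            class = c("reglink_mapping", class(tibble())))
}

#' Label of a mapping set
#' @param x a `reglink_mapping` object.
#' @return The label string (e.g. `"TFsf"`).
#' @export
mapping_label <- function(x) attr(x, "label", exact = TRUE)

.check_label <- function(x, expected, what) {
  lab <- mapping_label(x)
  if (is.null(lab) || !(lab %in% expected)) {
    abort(sprintf("%s: expected a mapping set labelled %s but got '%s'",
                  what, paste(expected, collapse = "/"),
                  if (is.null(lab)) "<none>" else lab))
  }
  invisible(lab)
}

#' @export
print.reglink_mapping <- function(x, ...) {
  cat("<regulatory mapping set ", mapping_label(x), ">\n", sep = "")
  NextMethod()
}

#' @rdname mapping_sets
#' @param x a `reglink_mapping` object.
#' @param ... unused.
#' @export
tidy.reglink_mapping <- function(x, ...) {
  mutate(as_tibble(x), label = mapping_label(x))
}

#' @rdname mapping_sets
#' @export
glance.reglink_mapping <- function(x, ...) {
  tibble(label = mapping_label(x),
         n_pairs = nrow(x),
         n_distinct_targets = dplyr::n_distinct(x$target_seq_id))
}

# TF mapping --------------------------------------------------------------

#' Map transcription factors by sequence similarity (set TFbl)
#'
#' Every (source TF, target sequence) pair among the similarity hits that
#' survives the e-value filter becomes a mapped pair; multiple hits for the
#' same pair collapse to one.
#'
#' @param source_tfs sequence table of source-genome TFs (defines the legal
#'   query ids).
#' @param hits a similarity-hit tibble whose queries are source TFs.
#' @param max_evalue e-value cutoff applied via [filter_hits()].
#' @return A `reglink_mapping` labelled `TFbl` with columns
#'   `source_tf_id`, `target_seq_id`.
#' @export
map_tf_bl <- function(source_tfs, hits, max_evalue = 1e-5) {
  stray <- setdiff(unique(hits$query_id), source_tfs$id)
  if (length(stray) > 0L) {
    abort(paste0("map_tf_bl: hit query id not among source TFs: ", stray[1]))
  }
  pairs <- filter_hits(hits, max_evalue)
  pairs <- distinct(tibble(source_tf_id = pairs$query_id,
                           target_seq_id = pairs$subject_id))
  pairs <- arrange(pairs, .data$source_tf_id, .data$target_seq_id)
  .new_mapping(pairs, "TFbl")
}

.annot_lookup <- function(annotations, ids, col) {
  annotations[[col]][match(ids, annotations$seq_id)]
}

#' Refine mapped TFs by protein family concordance (set TFf)
#'
#' Keeps a pair only when both the source TF and the target sequence carry a
#' family annotation and the family ids agree; pairs where either side is
#' unannotated are dropped (refinement is a positive concordance test).
#'
#' @param tfbl a `TFbl` mapping from [map_tf_bl()].
#' @param source_annot,target_annot annotation tibbles
#'   (see [read_annotations()]) for source TFs and target sequences.
#' @return A `reglink_mapping` labelled `TFf`.
#' @export
map_tf_family <- function(tfbl, source_annot, target_annot) {
  .check_label(tfbl, "TFbl", "map_tf_family")
  fam_s <- .annot_lookup(source_annot, tfbl$source_tf_id, "family_id")
  fam_t <- .annot_lookup(target_annot, tfbl$target_seq_id, "family_id")
  keep <- !is.na(fam_s) & !is.na(fam_t) & fam_s == fam_t
  .new_mapping(as_tibble(tfbl)[keep, , drop = FALSE], "TFf")
}

#' Refine mapped TFs by protein subfamily concordance (set TFsf)
#'
#' Like [map_tf_family()] but at subfamily resolution, applied to a `TFf`
#' set. Because subfamilies are nested within families, the result is always
#' a subset of the family-refined set.
#'
#' @param tff a `TFf` mapping from [map_tf_family()].
#' @inheritParams map_tf_family
#' @return A `reglink_mapping` labelled `TFsf`.
#' @export
map_tf_subfamily <- function(tff, source_annot, target_annot) {
  .check_label(tff, "TFf", "map_tf_subfamily")
  sub_s <- .annot_lookup(source_annot, tff$source_tf_id, "subfamily_id")
  sub_t <- .annot_lookup(target_annot, tff$target_seq_id, "subfamily_id")
  keep <- !is.na(sub_s) & !is.na(sub_t) & sub_s == sub_t
  .new_mapping(as_tibble(tff)[keep, , drop = FALSE], "TFsf")
}

# TG mapping --------------------------------------------------------------

#' Map target genes by sequence similarity (set TGbl)
#'
#' @param source_tgs sequence table of source-genome TGs (defines the legal
#'   query ids).
#' @param hits a similarity-hit tibble whose queries are source TGs.
#' @param max_evalue e-value cutoff applied via [filter_hits()].
#' @return A `reglink_mapping` labelled `TGbl` with columns `source_tg_id`,
#'   `target_seq_id`, `matched_motif_ids` (empty sets: similarity only).
#' @export
map_tg_bl <- function(source_tgs, hits, max_evalue = 1e-5) {
  stray <- setdiff(unique(hits$query_id), source_tgs$id)
  if (length(stray) > 0L) {
    abort(paste0("map_tg_bl: hit query id not among source TGs: ", stray[1]))
  }
  pairs <- filter_hits(hits, max_evalue)
  pairs <- distinct(tibble(source_tg_id = pairs$query_id,
                           target_seq_id = pairs$subject_id))
  pairs <- arrange(pairs, .data$source_tg_id, .data$target_seq_id)
  pairs$matched_motif_ids <- rep(list(character(0)), nrow(pairs))
  .new_mapping(pairs, "TGbl")
}

#' Map target genes by motif presence alone (sets TGbs, TGpr, TGgalf)
#'
#' Every target sequence containing at least one of the motifs is an entry;
#' no homology to a specific source TG is implied, so `source_tg_id` is
#' `NA`. The three labels are the same computation over different sequence
#' databases / motif provenances: gene sequences with curated motifs
#' (`TGbs`), promoter sequences with curated motifs (`TGpr`), promoter
#' sequences with externally discovered motifs (`TGgalf`).
#'
#' @param target_seqs nucleotide sequence table to scan.
#' @param motifs motif tibble to search for.
#' @param strands `"both"` (default) or `"forward"`.
#' @param label which motif-only set is being built.
#' @return A `reglink_mapping` with columns `source_tg_id` (all `NA`),
#'   `target_seq_id`, `matched_motif_ids` (list of motif ids found).
#' @export
map_tg_motif <- function(target_seqs, motifs,
                         strands = c("both", "forward"),
                         label = c("TGbs", "TGpr", "TGgalf")) {
  strands <- match.arg(strands)
  label <- match.arg(label)
  pres <- contains_any(target_seqs, motifs, strands = strands)
  entries <- summarise(group_by(pres, .data$seq_id),
                       matched_motif_ids = list(sort(unique(.data$motif_id))),
                       .groups = "drop")
  entries <- tibble(source_tg_id = rep(NA_character_, nrow(entries)),
                    target_seq_id = entries$seq_id,
                    matched_motif_ids = entries$matched_motif_ids)
  entries <- arrange(entries, .data$target_seq_id)
  .new_mapping(entries, label)
}

#' Refine similarity-mapped TGs by regulator motif presence (set TGblbs)
#'
#' Keeps a (source TG, target sequence) pair only when the target sequence
#' contains at least one binding-site motif of a TF that regulates that
#' source TG in the source network. Pairs whose source TG has no associated
#' motifs (no regulator with known motifs) are dropped with a warning:
#' such links cannot be carried by this route.
#'
#' @param tgbl a `TGbl` mapping from [map_tg_bl()].
#' @param target_seqs nucleotide sequence table the mapping points into.
#' @param network source-genome network tibble (`tf_id`, `tg_id`, `sign`).
#' @param motifs motif tibble (`tf_id`, `motif_id`, `consensus`).
#' @param strands `"both"` (default) or `"forward"`.
#' @return A `reglink_mapping` labelled `TGblbs`; entries carry the
#'   non-empty set of regulator motifs found in the target sequence.
#' @export
map_tg_bl_bs <- function(tgbl, target_seqs, network, motifs,
                         strands = c("both", "forward")) {
  strands <- match.arg(strands)
  .check_label(tgbl, "TGbl", "map_tg_bl_bs")
  # motifs of the regulators of each source TG
  reg <- inner_join(network, motifs, by = "tf_id",
                    relationship = "many-to-many")
  motifs_by_tg <- split(reg$motif_id, reg$tg_id)
  needed <- motifs[motifs$motif_id %in% unique(reg$motif_id), , drop = FALSE]
  scan_seqs <- target_seqs[target_seqs$id %in% unique(tgbl$target_seq_id), ,
                           drop = FALSE]
  pres <- contains_any(scan_seqs, distinct(needed, .data$motif_id,
                                           .keep_all = TRUE),
                       strands = strands)
  pres_by_seq <- split(pres$motif_id, pres$seq_id)
  n_orphans <- 0L
  keep <- logical(nrow(tgbl))
  matched <- vector("list", nrow(tgbl))
  for (i in seq_len(nrow(tgbl))) {
    want <- motifs_by_tg[[tgbl$source_tg_id[i]]]
    if (is.null(want) || length(want) == 0L) {
      n_orphans <- n_orphans + 1L
      next
    }
    found <- intersect(sort(unique(want)),
                       pres_by_seq[[tgbl$target_seq_id[i]]])
    if (length(found) > 0L) {
      keep[i] <- TRUE
      matched[[i]] <- found
    }
  }
  if (n_orphans > 0L) {
    warn(sprintf(
      "map_tg_bl_bs: dropped %d pair(s) whose source TG has no regulator motifs",
      n_orphans))
  }
  out <- as_tibble(tgbl)[keep, , drop = FALSE]
  out$matched_motif_ids <- matched[keep]
  .new_mapping(out, "TGblbs")
}
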