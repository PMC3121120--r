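#' @title Integration of mapped regulatory elements into predicted links
#' @name link_integration
#' @description For every signed link in the source network, the regulator's
#'   binding-site motifs are first searched in the source target gene; the
#'   motifs actually present there are then required in the candidate target
#'   genome gene. Candidate TFs come from a TF mapping set and candidate TGs
#'   from a TG mapping set; for similarity-based TG sets the candidate must
#'   be a homolog of the link's source TG, while motif-only TG sets pair the
#'   link with any entry (no homology constraint), which is what makes those
#'   routes explode combinatorially.
NULL

#' Motifs of a link's TF present in its source target gene
#'
#' @param link one row of a network tibble (`tf_id`, `tg_id`, `sign`).
#' @param motifs motif tibble; only rows for `link$tf_id` are used.
#' @param source_tg_seqs nucleotide sequence table containing the source TG.
#' @param strands `"both"` (default) or `"forward"`.
#' @return Character vector of motif ids (possibly empty: such a link
#'   cannot be mapped by this method).
#' @export
motifs_in_source_tg <- function(link, motifs, source_tg_seqs,
                                strands = c("both", "forward")) {
  strands <- match.arg(strands)
  tf_motifs <- motifs[motifs$tf_id == link$tf_id[1], , drop = FALSE]
  if (nrow(tf_motifs) == 0L) return(character(0))
  seq <- source_tg_seqs[source_tg_seqs$id == link$tg_id[1], , drop = FALSE]
  if (nrow(seq) == 0L) {
    warn(paste0("motifs_in_source_tg: no sequence for source TG ",
                link$tg_id[1], "; link skipped"))
    return(character(0))
  }
  pres <- contains_any(seq, tf_motifs, strands = strands)
  sort(unique(pres$motif_id))
}

#' Integrate mapped TFs and TGs into predicted regulatory links
#'
#' For each source link `(tf, tg, sign)`: let `M` be the TF's motifs found
#' in the source TG (links with empty `M` are dropped and counted). Every
#' mapped target TF of `tf` is combined with every candidate target gene
#' (homologs of `tg` for `TGbl`/`TGblbs` sets; all entries for motif-only
#' sets) that contains at least one motif of `M`. The predicted link
#' inherits the source sign and records the supporting motifs (the subset
#' of `M` present in the target gene). Predicted links that coincide on
#' `(target_tf, target_tg, sign)` are collapsed, with motif sets unioned.
#'
#' @param network source network tibble (`tf_id`, `tg_id`, `sign`).
#' @param tf_map a TF `reglink_mapping` (`TFbl`/`TFf`/`TFsf`).
#' @param tg_map a TG `reglink_mapping` (`TGbl`/`TGbs`/`TGblbs`/`TGpr`/`TGgalf`).
#' @param motifs motif tibble (`tf_id`, `motif_id`, `consensus`).
#' @param source_tg_seqs sequence table with the source TG sequences.
#' @param target_seqs sequence table the TG mapping points into (used to
#'   verify motif presence in candidate target genes).
#' @param strands `"both"` (default) or `"forward"`.
#' @param provenance optional expected provenance string (e.g.
#'   `"TFsf-TGblbs"`); a mismatch with the actual set labels is an error.
#' @return A tibble of predicted links: `source_tf_id`, `source_tg_id`,
#'   `target_tf_id`, `target_tg_id`, `sign`, `supporting_motif_ids`
#'   (list column, never empty), `provenance`; sorted by target pair.
#'   Attribute `n_links_no_source_motif` counts source links dropped
#'   because their source TG contained none of their TF's motifs.
#' @export
integrate_links <- function(network, tf_map, tg_map, motifs,
                            source_tg_seqs, target_seqs,
                            strands = c("both", "forward"),
                            provenance = NULL) {
  strands <- match.arg(strands)
  tf_label <- .check_label(tf_map, .TF_LABELS, "integrate_links")
  tg_label <- .check_label(tg_map, .TG_LABELS, "integrate_links")
  prov <- paste0(tf_label, "-", tg_label)
  if (!is.null(provenance) && !identical(provenance, prov)) {
    abort(sprintf(
      "integrate_links: requested provenance '%s' but mapping sets give '%s'",
      provenance, prov))
  }
  homology_based <- tg_label %in% c("TGbl", "TGblbs")

  # presence of every relevant motif in source TGs and target candidates,
  # computed once
  net_motifs <- motifs[motifs$tf_id %in% unique(network$tf_id), , drop = FALSE]
  src_seqs <- source_tg_seqs[source_tg_seqs$id %in% unique(network$tg_id), ,
                             drop = FALSE]
  src_pres <- contains_any(src_seqs, net_motifs, strands = strands)
  tgt_ids <- unique(tg_map$target_seq_id)
  tgt_scan <- target_seqs[target_seqs$id %in% tgt_ids, , drop = FALSE]
  tgt_pres <- contains_any(tgt_scan, net_motifs, strands = strands)
  src_by_seq <- split(src_pres$motif_id, src_pres$seq_id)
  tgt_by_seq <- split(tgt_pres$motif_id, tgt_pres$seq_id)
  motifs_by_tf <- split(net_motifs$motif_id, net_motifs$tf_id)
  tfmap_by_src <- split(tf_map$target_seq_id, tf_map$source_tf_id)
  tgmap_by_src <- if (homology_based) {
    split(tg_map$target_seq_id, tg_map$source_tg_id)
  } else NULL

  missing_tg <- setdiff(unique(network$tg_id), source_tg_seqs$id)
  if (length(missing_tg) > 0L) {
    warn(sprintf(
      "integrate_links: %d source TG(s) have no sequence; their links are skipped",
      length(missing_tg)))
  }

  n_no_motif <- 0L
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(network))) {
    tf <- network$tf_id[i]
    tg <- network$tg_id[i]
    sign <- network$sign[i]
    tf_motifs <- motifs_by_tf[[tf]]
    if (is.null(tf_motifs)) {
      n_no_motif <- n_no_motif + 1L
      next
    }
    if (!(tg %in% src_seqs$id)) next
    M <- intersect(sort(unique(tf_motifs)), src_by_seq[[tg]])
    if (length(M) == 0L) {
      n_no_motif <- n_no_motif + 1L
      next
    }
    target_tfs <- tfmap_by_src[[tf]]
    if (is.null(target_tfs) || length(target_tfs) == 0L) next
    cand <- if (homology_based) tgmap_by_src[[tg]] else tgt_ids
    if (is.null(cand) || length(cand) == 0L) next
    for (g in cand) {
      support <- intersect(M, tgt_by_seq[[g]])
      if (length(support) == 0L) next
      for (t in target_tfs) {
        k <- k + 1L
        rows[[k]] <- tibble(source_tf_id = tf, source_tg_id = tg,
                            target_tf_id = t, target_tg_id = g,
                            sign = sign,
                            supporting_motif_ids = list(support))
      }
    }
  }

  out <- if (k == 0L) {
    tibble(source_tf_id = character(), source_tg_id = character(),
           target_tf_id = character(), target_tg_id = character(),
           sign = character(), supporting_motif_ids = list())
  } else {
    links <- bind_rows(rows)
    links <- arrange(links, .data$target_tf_id, .data$target_tg_id,
                     .data$sign, .data$source_tf_id, .data$source_tg_id)
    links <- summarise(
      group_by(links, .data$target_tf_id, .data$target_tg_id, .data$sign),
      source_tf_id = .data$source_tf_id[1],
      source_tg_id = .data$source_tg_id[1],
      supporting_motif_ids = list(
        sort(unique(unlist(.data$supporting_motif_ids)))),
      .groups = "drop")
    select(links, "source_tf_id", "source_tg_id", "target_tf_id",
           "target_tg_id", "sign", "supporting_motif_ids")
  }
  out$provenance <- rep(prov, nrow(out))
  out <- arrange(out, .data$target_tf_id, .data$target_tg_id, .data$sign)
  structure(out, n_links_no_source_motif = n_no_motif)
}

#' Write predicted links to TSV
#'
#' @param links a predicted-link tibble from [integrate_links()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  links <- arrange(links, .data$target_tf_id, .data$target_tg_id, .data$sign)
  body <- vapply(seq_len(nrow(links)), function(i) {
    paste(links$source_tf_id[i], links$source_tg_id[i],
          links$target_tf_id[i], links$target_tg_id[i],
          ifelse(links$sign[i] == "positive", "+", "-"),
          paste(links$supporting_motif_ids[[i]], collapse = ","),
          links$provenance[i], sep = "\t")
  }, character(1))
  .write_lines(
    c("#source_tf\tsource_tg\ttarget_tf\ttarget_tg\tsign\tsupporting_motifs\tprovenance",
      body), path)
}

#' Read predicted links from TSV
#' @param path a file written by [write_links()].
#' @return A predicted-link tibble.
#' @export
read_links <- function(path) {
  parsed <- .read_tsv_rows(path, 7L, "links table")
  if (length(parsed$rows) == 0L) {
    return(tibble(source_tf_id = character(), source_tg_id = character(),
                  target_tf_id = character(), target_tg_id = character(),
                  sign = character(), supporting_motif_ids = list(),
                  provenance = character()))
  }
  m <- do.call(rbind, parsed$rows)
  bad <- which(!(m[, 5] %in% c("+", "-")))
  if (length(bad) > 0L) {
    abort(sprintf("links table: unknown sign token '%s' on line %d",
                  m[bad[1], 5], parsed$lineno[bad[1]]))
  }
  tibble(source_tf_id = m[, 1], source_tg_id = m[, 2],
         target_tf_id = m[, 3], target_tg_id = m[, 4],
         sign = ifelse(m[, 5] == "+", "positive", "negative"),
         supporting_motif_ids = strsplit(m[, 6], ",", fixed = TRUE),
         provenance = m[, 7])
}
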