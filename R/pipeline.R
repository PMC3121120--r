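#' @title End-to-end network mapping
#' @name pipeline
#' @description [run_mapping()] executes the three mapping steps (TF
#'   mapping, TG mapping, integration) plus expression confirmation on
#'   in-memory objects; [run_pipeline()] is the file-based wrapper that
#'   reads every input, delegates, and writes all artifacts plus a run
#'   manifest with the stage counts.
NULL

#' Map a regulatory network in memory
#'
#' @param source_tf_seqs,source_tg_seqs,target_seqs sequence tables.
#' @param motifs,network motif and network tibbles.
#' @param source_annotations,target_annotations annotation tibbles
#'   (required for TF modes `"f"`/`"sf"`).
#' @param promoters promoter sequence table (required for TG modes
#'   `"pr"`/`"galf"`).
#' @param galf_motifs externally discovered motif tibble (TG mode
#'   `"galf"`).
#' @param expression optional expression tibble; when given, predicted
#'   links are confirmed against it.
#' @param tf_mode `"bl"`, `"f"` or `"sf"`.
#' @param tg_mode `"bl"`, `"bs"`, `"blbs"`, `"pr"` or `"galf"`.
#' @param scheme a [scoring_scheme()] for the built-in aligner.
#' @param min_score minimal local-alignment score for a similarity hit.
#' @param max_evalue e-value cutoff for similarity-based mapping.
#' @param strands strand handling for motif scans.
#' @param tier a [tier_config()].
#' @param tf_hits,tg_hits optional precomputed hit tibbles (e.g. read from
#'   external similarity-search output); when given, the built-in aligner
#'   is skipped for that side.
#' @return A list with `tf_map`, `tg_map`, `links`, `confirmation` (or
#'   `NULL`), `provenance` and a `counts` tibble of stage totals.
#' @export
run_mapping <- function(source_tf_seqs, source_tg_seqs, target_seqs,
                        motifs, network,
                        source_annotations = NULL, target_annotations = NULL,
                        promoters = NULL, galf_motifs = NULL,
                        expression = NULL,
                        tf_mode = c("sf", "f", "bl"),
                        tg_mode = c("blbs", "bl", "bs", "pr", "galf"),
                        scheme = scoring_scheme(), min_score = 50,
                        max_evalue = 1e-5,
                        strands = c("both", "forward"),
                        tier = tier_config(),
                        tf_hits = NULL, tg_hits = NULL) {
  tf_mode <- match.arg(tf_mode)
  tg_mode <- match.arg(tg_mode)
  strands <- match.arg(strands)

  if (is.null(tf_hits)) {
    tf_hits <- find_similar(source_tf_seqs, target_seqs, scheme = scheme,
                            min_score = min_score)
  }
  tf_map <- map_tf_bl(source_tf_seqs, tf_hits, max_evalue = max_evalue)
  if (tf_mode %in% c("f", "sf")) {
    if (is.null(source_annotations) || is.null(target_annotations)) {
      abort("run_mapping: TF modes 'f'/'sf' need source and target annotations")
    }
    tf_map <- map_tf_family(tf_map, source_annotations, target_annotations)
    if (tf_mode == "sf") {
      tf_map <- map_tf_subfamily(tf_map, source_annotations,
                                 target_annotations)
    }
  }

  tg_db <- target_seqs
  if (tg_mode %in% c("bl", "blbs")) {
    if (is.null(tg_hits)) {
      tg_hits <- find_similar(source_tg_seqs, target_seqs, scheme = scheme,
                              min_score = min_score)
    }
    tg_map <- map_tg_bl(source_tg_seqs, tg_hits, max_evalue = max_evalue)
    if (tg_mode == "blbs") {
      tg_map <- map_tg_bl_bs(tg_map, target_seqs, network, motifs,
                             strands = strands)
    }
  } else {
    if (tg_mode %in% c("pr", "galf")) {
      if (is.null(promoters)) {
        abort("run_mapping: TG modes 'pr'/'galf' need promoter sequences")
      }
      tg_db <- promoters
    }
    scan_motifs_tbl <- if (tg_mode == "galf") {
      if (is.null(galf_motifs)) {
        abort("run_mapping: TG mode 'galf' needs a discovered-motif table")
      }
      galf_motifs
    } else motifs
    tg_map <- map_tg_motif(tg_db, scan_motifs_tbl, strands = strands,
                           label = c(bs = "TGbs", pr = "TGpr",
                                     galf = "TGgalf")[[tg_mode]])
  }

  links <- integrate_links(network, tf_map, tg_map, motifs,
                           source_tg_seqs = source_tg_seqs,
                           target_seqs = tg_db, strands = strands)
  confirmation <- if (!is.null(expression)) {
    confirm_links(links, expression, config = tier)
  } else NULL

  counts <- tibble(
    provenance = links$provenance[1] %||% paste0(mapping_label(tf_map), "-",
                                                 mapping_label(tg_map)),
    n_tf_pairs = nrow(tf_map),
    n_mapped_tfs = dplyr::n_distinct(tf_map$target_seq_id),
    n_tg_entries = nrow(tg_map),
    n_mapped_tgs = dplyr::n_distinct(tg_map$target_seq_id),
    n_links_mapped = nrow(links),
    n_links_no_source_motif =
      attr(links, "n_links_no_source_motif") %||% 0L,
    n_links_analyzed =
      if (!is.null(confirmation)) confirmation$summary$n_analyzed else NA_integer_,
    n_links_verified =
      if (!is.null(confirmation)) confirmation$summary$n_verified else NA_integer_)

  list(tf_map = tf_map, tg_map = tg_map, links = links,
       confirmation = confirmation,
       provenance = counts$provenance[1], counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score predicted links against a truth table
#'
#' Links are matched on the (`target_tf_id`, `target_tg_id`, `sign`)
#' triple.
#'
#' @param links a predicted-link tibble.
#' @param truth_links a tibble of true links with the same three columns.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `recall`, `precision`
#'   (undefined ratios as `NA`).
#' @export
evaluate_against_truth <- function(links, truth_links) {
  key <- function(x) paste(x$target_tf_id, x$target_tg_id, x$sign,
                           sep = "\r")
  pred <- unique(key(links))
  tru <- unique(key(truth_links))
  tp <- length(intersect(pred, tru))
  fp <- length(setdiff(pred, tru))
  fn <- length(setdiff(tru, pred))
  tibble(tp = tp, fp = fp, fn = fn,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Write a mapping set to TSV
#'
#' The set label is recorded in a `# label=` line so the file can be read
#' back with [read_mapping()] without losing provenance.
#'
#' @param x a `reglink_mapping`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(x, path) {
  lab <- mapping_label(x)
  is_tf <- lab %in% .TF_LABELS
  if (is_tf) {
    x <- arrange(x, .data$source_tf_id, .data$target_seq_id)
    body <- paste(x$source_tf_id, x$target_seq_id, "-", sep = "\t")
    header <- "#source_tf_id\ttarget_seq_id\tmatched_motif_ids"
  } else {
    x <- arrange(x, .data$source_tg_id, .data$target_seq_id)
    body <- vapply(seq_len(nrow(x)), function(i) {
      mm <- x$matched_motif_ids[[i]]
      paste(ifelse(is.na(x$source_tg_id[i]), "-", x$source_tg_id[i]),
            x$target_seq_id[i],
            if (length(mm) > 0) paste(mm, collapse = ",") else "-",
            sep = "\t")
    }, character(1))
    header <- "#source_tg_id\ttarget_seq_id\tmatched_motif_ids"
  }
  .write_lines(c(paste0("# label=", lab), header, body), path)
}

#' Read a mapping set written by [write_mapping()]
#' @param path input path.
#' @return A `reglink_mapping` with its original label.
#' @export
read_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  labline <- grep("^# label=", lines, value = TRUE)
  if (length(labline) == 0L) abort("read_mapping: missing '# label=' line")
  lab <- sub("^# label=", "", labline[1])
  if (!(lab %in% c(.TF_LABELS, .TG_LABELS))) {
    abort(paste0("read_mapping: unknown label ", lab))
  }
  parsed <- .read_tsv_rows(path, 3L, "mapping table")
  is_tf <- lab %in% .TF_LABELS
  if (length(parsed$rows) == 0L) {
    out <- if (is_tf) {
      tibble(source_tf_id = character(), target_seq_id = character())
    } else {
      tibble(source_tg_id = character(), target_seq_id = character(),
             matched_motif_ids = list())
    }
    return(.new_mapping(out, lab))
  }
  m <- do.call(rbind, parsed$rows)
  out <- if (is_tf) {
    tibble(source_tf_id = m[, 1], target_seq_id = m[, 2])
  } else {
    tibble(source_tg_id = ifelse(m[, 1] == "-", NA_character_, m[, 1]),
           target_seq_id = m[, 2],
           matched_motif_ids = lapply(m[, 3], function(s) {
             if (s == "-") character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
           }))
  }
  .new_mapping(out, lab)
}

#' Run the full pipeline from a configuration
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with input paths `source_tf_fasta`, `source_tg_fasta`,
#' `target_fasta`, `motif_table`, `network` and optionally
#' `promoter_fasta`, `galf_motif_table`, `source_annotations`,
#' `target_annotations`, `expression`, `tf_hits`, `tg_hits`,
#' `truth_links`; mode fields `tf_mode`, `tg_mode`; numeric fields
#' `min_score`, `max_evalue`; `strands`; tier fields
#' `contradictory_weight`, `neutral_weight`, `ratio_high`, `ratio_mid`;
#' and an output directory `out_dir`.
#'
#' Writes `tf_map.tsv`, `tg_map.tsv`, `links.tsv`, `confirmation.tsv`
#' (when expression is given) and `manifest.yaml` (stage counts, modes,
#' parameters, truth recall/precision when a truth table is given) under
#' `out_dir`. Identical inputs give byte-identical outputs.
#'
#' @param config a named list or YAML file path.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(field) {
    if (is.null(config[[field]])) {
      abort(paste0("run_pipeline: missing config field '", field, "'"))
    }
    config[[field]]
  }
  opt <- function(field, default = NULL) config[[field]] %||% default

  source_tf_seqs <- read_fasta(need("source_tf_fasta"))
  source_tg_seqs <- read_fasta(need("source_tg_fasta"))
  target_seqs <- read_fasta(need("target_fasta"))
  motifs <- read_motif_table(need("motif_table"))
  network <- read_network(need("network"))
  promoters <- if (!is.null(opt("promoter_fasta"))) {
    read_fasta(config$promoter_fasta)
  } else NULL
  galf_motifs <- if (!is.null(opt("galf_motif_table"))) {
    read_motif_table(config$galf_motif_table)
  } else NULL
  source_annotations <- if (!is.null(opt("source_annotations"))) {
    read_annotations(config$source_annotations)
  } else NULL
  target_annotations <- if (!is.null(opt("target_annotations"))) {
    read_annotations(config$target_annotations)
  } else NULL
  expression <- if (!is.null(opt("expression"))) {
    read_expression_matrix(config$expression)
  } else NULL
  tf_hits <- if (!is.null(opt("tf_hits"))) {
    read_similarity_table(config$tf_hits)
  } else NULL
  tg_hits <- if (!is.null(opt("tg_hits"))) {
    read_similarity_table(config$tg_hits)
  } else NULL

  tier <- tier_config(
    contradictory_weight = opt("contradictory_weight", 2),
    neutral_weight = opt("neutral_weight", 1),
    ratio_high = opt("ratio_high", 3),
    ratio_mid = opt("ratio_mid", 2))

  res <- run_mapping(
    source_tf_seqs, source_tg_seqs, target_seqs, motifs, network,
    source_annotations = source_annotations,
    target_annotations = target_annotations,
    promoters = promoters, galf_motifs = galf_motifs,
    expression = expression,
    tf_mode = opt("tf_mode", "sf"), tg_mode = opt("tg_mode", "blbs"),
    scheme = scoring_scheme(match = opt("match", 1),
                            mismatch = opt("mismatch", -1),
                            gap = opt("gap", -2)),
    min_score = opt("min_score", 50),
    max_evalue = opt("max_evalue", 1e-5),
    strands = opt("strands", "both"), tier = tier,
    tf_hits = tf_hits, tg_hits = tg_hits)

  manifest <- list(
    provenance = res$provenance,
    tf_mode = opt("tf_mode", "sf"), tg_mode = opt("tg_mode", "blbs"),
    min_score = opt("min_score", 50), max_evalue = opt("max_evalue", 1e-5),
    strands = opt("strands", "both"),
    counts = as.list(res$counts))

  if (!is.null(opt("truth_links"))) {
    tl <- read_links_truth(config$truth_links)
    ev <- evaluate_against_truth(res$links, tl)
    manifest$truth <- as.list(ev)
  }

  out_dir <- need("out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_mapping(res$tf_map, file.path(out_dir, "tf_map.tsv"))
  write_mapping(res$tg_map, file.path(out_dir, "tg_map.tsv"))
  write_links(res$links, file.path(out_dir, "links.tsv"))
  if (!is.null(res$confirmation)) {
    write_confirmation(res$confirmation, file.path(out_dir, "confirmation.tsv"))
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a truth-link table (as written by [write_scenario()])
#' @param path path to `truth_links.tsv`.
#' @return A tibble `source_tf_id`, `source_tg_id`, `target_tf_id`,
#'   `target_tg_id`, `sign`, `motif_id`.
#' @export
read_links_truth <- function(path) {
  parsed <- .read_tsv_rows(path, 6L, "truth links")
  if (length(parsed$rows) == 0L) {
    return(tibble(source_tf_id = character(), source_tg_id = character(),
                  target_tf_id = character(), target_tg_id = character(),
                  sign = character(), motif_id = character()))
  }
  m <- do.call(rbind, parsed$rows)
  tibble(source_tf_id = m[, 1], source_tg_id = m[, 2],
         target_tf_id = m[, 3], target_tg_id = m[, 4],
         sign = ifelse(m[, 5] == "+", "positive", "negative"),
         motif_id = m[, 6])
}
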