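#' @title File formats: sequences, hits, motifs, networks, annotations, expression
#' @name io_formats
#' @description Readers and writers for every external file the pipeline
#'   touches. All readers are deterministic and order-preserving and validate
#'   their input strictly (hard errors, never silent coercion); all writers
#'   sort output by primary id, emit UTF-8 with Unix newlines, and prefix the
#'   header line with `#` so files round-trip through the corresponding
#'   reader byte-identically.
NULL

# alphabets -------------------------------------------------------------

.NUC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
.PROT_CODES <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U")

.alphabet_codes <- function(alphabet) {
  switch(alphabet,
         nucleotide = .NUC_CODES,
         protein    = .PROT_CODES,
         abort(paste0("unknown alphabet: ", alphabet)))
}

.check_residues <- function(ids, residues, alphabet) {
  codes <- .alphabet_codes(alphabet)
  for (k in seq_along(residues)) {
    chars <- strsplit(residues[[k]], "")[[1]]
    bad <- which(!(chars %in% codes))
    if (length(bad) > 0L) {
      abort(sprintf(
        "illegal %s residue '%s' in record '%s' at position %d",
        alphabet, chars[bad[1]], ids[[k]], bad[1]))
    }
  }
  invisible(TRUE)
}

#' Construct a sequence table
#'
#' Sequences are kept as a tibble with one row per record, the container all
#' sequence-consuming functions in the package accept and return.
#'
#' @param id character vector of unique record ids.
#' @param residues character vector of sequences (upper-cased on input).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param description optional free-text descriptions (default empty).
#' @return A tibble with columns `id`, `description`, `residues`, `alphabet`.
#' @export
sequence_table <- function(id, residues, alphabet = c("nucleotide", "protein"),
                           description = "") {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id: ", id[duplicated(id)][1]))
  }
  .check_residues(id, residues, alphabet)
  tibble(id = id,
         description = rep_len(as.character(description), length(id)),
         residues = residues,
         alphabet = alphabet)
}

# FASTA -----------------------------------------------------------------

#' Read a FASTA file into a sequence table
#'
#' Record ids are the first whitespace-delimited token of each header;
#' residues are upper-cased and validated against the declared alphabet.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A sequence table (see [sequence_table()]), in file order.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) abort(paste0("empty sequence id in ", path))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]))
  }
  residues <- toupper(as.character(set))
  .check_residues(ids, residues, alphabet)
  tibble(id = ids, description = desc, residues = unname(residues),
         alphabet = alphabet)
}

#' Write a sequence table to FASTA
#'
#' Records are written sorted by id, one sequence line per record.
#'
#' @param seqs a sequence table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- arrange(seqs, .data$id)
  headers <- ifelse(nzchar(seqs$description),
                    paste(seqs$id, seqs$description), seqs$id)
  set <- Biostrings::BStringSet(setNames(seqs$residues, headers))
  Biostrings::writeXStringSet(set, path, width = 100000L)
  invisible(path)
}

# line-based TSV helpers -------------------------------------------------

.read_tsv_rows <- function(path, n_fields, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != n_fields)) {
    bad <- which(lens != n_fields)[1]
    abort(sprintf("%s: expected %d tab-separated fields but found %d on line %d",
                  what, n_fields, lens[bad], keep[bad]))
  }
  list(rows = rows, lineno = keep)
}

.parse_num <- function(x, lineno, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(sprintf("%s: unparseable number '%s' on line %d",
                  what, x[bad], lineno[bad]))
  }
  out
}

.write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# similarity hits (BLAST outfmt 6 dialect) --------------------------------

.HIT_COLS <- c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatches", "gap_opens",
               "q_start", "q_end", "s_start", "s_end", "evalue", "score")

#' Read a similarity-hit table (12-column BLAST tabular dialect)
#'
#' @param path path to a tab-delimited hit table (`#` lines are comments).
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `score`, one row per
#'   hit in file order. Coordinates are 1-based inclusive.
#' @export
read_similarity_table <- function(path) {
  parsed <- .read_tsv_rows(path, 12L, "similarity table")
  if (length(parsed$rows) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = numeric(),
                  mismatches = numeric(), gap_opens = numeric(),
                  q_start = numeric(), q_end = numeric(),
                  s_start = numeric(), s_end = numeric(),
                  evalue = numeric(), score = numeric()))
  }
  m <- do.call(rbind, parsed$rows)
  hits <- tibble(query_id = m[, 1], subject_id = m[, 2])
  for (k in 3:12) {
    hits[[.HIT_COLS[k]]] <- .parse_num(m[, k], parsed$lineno, "similarity table")
  }
  if (any(hits$q_start > hits$q_end)) {
    abort("similarity table: q_start > q_end")
  }
  if (any(hits$alignment_length < 1)) {
    abort("similarity table: alignment_length < 1")
  }
  if (any(hits$evalue < 0)) abort("similarity table: negative evalue")
  hits
}

#' Write a similarity-hit table
#'
#' @param hits a hit tibble as returned by [read_similarity_table()] or
#'   [find_similar()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  hits <- arrange(hits, .data$query_id, .data$subject_id)
  body <- vapply(seq_len(nrow(hits)), function(i) {
    paste(vapply(.HIT_COLS, function(cn) {
      v <- hits[[cn]][i]
      if (is.numeric(v)) as.character(v) else v
    }, character(1)), collapse = "\t")
  }, character(1))
  .write_lines(c(paste0("#", paste(.HIT_COLS, collapse = "\t")), body), path)
}

# motif tables ------------------------------------------------------------

#' Read a binding-site motif table
#'
#' Three tab-delimited columns: `tf_id`, `motif_id`, `consensus` (an IUPAC
#' nucleotide consensus string).
#'
#' @param path input path.
#' @return A tibble with columns `tf_id`, `motif_id`, `consensus`.
#' @export
read_motif_table <- function(path) {
  parsed <- .read_tsv_rows(path, 3L, "motif table")
  if (length(parsed$rows) == 0L) {
    return(tibble(tf_id = character(), motif_id = character(),
                  consensus = character()))
  }
  m <- do.call(rbind, parsed$rows)
  motifs <- tibble(tf_id = m[, 1], motif_id = m[, 2],
                   consensus = toupper(m[, 3]))
  for (i in seq_len(nrow(motifs))) {
    chars <- strsplit(motifs$consensus[i], "")[[1]]
    if (length(chars) == 0L) {
      abort(sprintf("motif '%s': empty consensus", motifs$motif_id[i]))
    }
    bad <- which(!(chars %in% .NUC_CODES))
    if (length(bad) > 0L) {
      abort(sprintf("motif '%s': illegal IUPAC character '%s'",
                    motifs$motif_id[i], chars[bad[1]]))
    }
  }
  if (anyDuplicated(motifs[c("tf_id", "motif_id")])) {
    abort("motif table: duplicate (tf_id, motif_id) pair")
  }
  motifs
}

#' Write a binding-site motif table
#' @param motifs a motif tibble (`tf_id`, `motif_id`, `consensus`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  motifs <- arrange(motifs, .data$tf_id, .data$motif_id)
  .write_lines(c("#tf_id\tmotif_id\tconsensus",
                 paste(motifs$tf_id, motifs$motif_id, motifs$consensus,
                       sep = "\t")),
               path)
}

# regulatory networks ----------------------------------------------------

#' Read a signed regulatory network edge list
#'
#' Three tab-delimited columns: `tf_id`, `tg_id` and a sign token `+` or `-`
#' (activation / repression).
#'
#' @param path input path.
#' @return A tibble with columns `tf_id`, `tg_id`, `sign` where `sign` is
#'   `"positive"` or `"negative"`.
#' @export
read_network <- function(path) {
  parsed <- .read_tsv_rows(path, 3L, "network")
  if (length(parsed$rows) == 0L) {
    return(tibble(tf_id = character(), tg_id = character(),
                  sign = character()))
  }
  m <- do.call(rbind, parsed$rows)
  bad <- which(!(m[, 3] %in% c("+", "-")))
  if (length(bad) > 0L) {
    abort(sprintf("network: unknown sign token '%s' on line %d",
                  m[bad[1], 3], parsed$lineno[bad[1]]))
  }
  net <- tibble(tf_id = m[, 1], tg_id = m[, 2],
                sign = ifelse(m[, 3] == "+", "positive", "negative"))
  if (anyDuplicated(net)) abort("network: duplicate (tf, tg, sign) triple")
  net
}

#' Write a signed regulatory network edge list
#' @param network a network tibble (`tf_id`, `tg_id`, `sign`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  network <- arrange(network, .data$tf_id, .data$tg_id, .data$sign)
  .write_lines(c("#tf_id\ttg_id\tsign",
                 paste(network$tf_id, network$tg_id,
                       ifelse(network$sign == "positive", "+", "-"),
                       sep = "\t")),
               path)
}

# family/subfamily annotations -------------------------------------------

#' Read protein family/subfamily annotations
#'
#' Three tab-delimited columns: `seq_id`, `family_id`, `subfamily_id`; `-`
#' denotes a missing annotation. Subfamilies are nested within families, so
#' a record with a subfamily but no family is rejected.
#'
#' @param path input path.
#' @return A tibble with columns `seq_id`, `family_id`, `subfamily_id`
#'   (missing values as `NA`).
#' @export
read_annotations <- function(path) {
  parsed <- .read_tsv_rows(path, 3L, "annotation table")
  if (length(parsed$rows) == 0L) {
    return(tibble(seq_id = character(), family_id = character(),
                  subfamily_id = character()))
  }
  m <- do.call(rbind, parsed$rows)
  ann <- tibble(seq_id = m[, 1],
                family_id = ifelse(m[, 2] == "-", NA_character_, m[, 2]),
                subfamily_id = ifelse(m[, 3] == "-", NA_character_, m[, 3]))
  bad <- which(!is.na(ann$subfamily_id) & is.na(ann$family_id))
  if (length(bad) > 0L) {
    abort(sprintf("annotation for '%s' has a subfamily but no family",
                  ann$seq_id[bad[1]]))
  }
  if (anyDuplicated(ann$seq_id)) abort("annotation table: duplicate seq_id")
  ann
}

#' Write protein family/subfamily annotations
#' @param annotations an annotation tibble (`seq_id`, `family_id`,
#'   `subfamily_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- arrange(annotations, .data$seq_id)
  na2dash <- function(x) ifelse(is.na(x), "-", x)
  .write_lines(c("#seq_id\tfamily_id\tsubfamily_id",
                 paste(annotations$seq_id, na2dash(annotations$family_id),
                       na2dash(annotations$subfamily_id), sep = "\t")),
               path)
}

# ternary expression matrices --------------------------------------------

.EXPR_LEVELS <- c("expressed", "not_expressed", "absent")

#' Read a ternary gene-expression call matrix
#'
#' The file has a header row (optionally prefixed `#`) whose first field
#' labels the gene-id column and whose remaining fields are experiment ids.
#' In ternary mode cells are `Y` (expressed), `N` (not expressed) or `ab`
#' (absent). If `numeric_threshold` is given, cells are numeric expression
#' values instead: values `>= numeric_threshold` are called expressed (the
#' boundary is inclusive), smaller values not expressed, and empty cells
#' absent.
#'
#' @param path input path.
#' @param numeric_threshold optional numeric expression cutoff.
#' @return A tibble with column `gene_id` plus one character column per
#'   experiment holding `"expressed"`, `"not_expressed"` or `"absent"`.
#' @export
read_expression_matrix <- function(path, numeric_threshold = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("expression matrix: empty file")
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    abort("expression matrix: header must name at least one experiment")
  }
  experiments <- header[-1]
  if (anyDuplicated(experiments)) {
    abort("expression matrix: duplicate experiment id")
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  # trailing empty cells are dropped by strsplit; pad so numeric mode can
  # treat them as absent, but a genuinely short row is still an error there
  nf <- length(header)
  lens <- lengths(rows)
  if (is.null(numeric_threshold) && any(lens != nf)) {
    bad <- which(lens != nf)[1]
    abort(sprintf("expression matrix: row on line %d has %d fields, expected %d",
                  bad + 1L, lens[bad], nf))
  }
  if (!is.null(numeric_threshold) && any(lens > nf)) {
    bad <- which(lens > nf)[1]
    abort(sprintf("expression matrix: row on line %d has %d fields, expected %d",
                  bad + 1L, lens[bad], nf))
  }
  rows <- lapply(rows, function(r) c(r, rep("", nf - length(r))))
  m <- do.call(rbind, rows)
  gene_ids <- m[, 1, drop = TRUE]
  if (anyDuplicated(gene_ids)) abort("expression matrix: duplicate gene id")
  cells <- m[, -1, drop = FALSE]
  if (is.null(numeric_threshold)) {
    known <- cells %in% c("Y", "N", "ab")
    if (!all(known)) {
      bad <- which(!known)[1]
      abort(sprintf("expression matrix: unknown call token '%s'", cells[bad]))
    }
    calls <- matrix(.EXPR_LEVELS[match(cells, c("Y", "N", "ab"))],
                    nrow = nrow(cells))
  } else {
    calls <- matrix("absent", nrow = nrow(cells), ncol = ncol(cells))
    filled <- nzchar(cells)
    vals <- suppressWarnings(as.numeric(cells[filled]))
    if (anyNA(vals)) abort("expression matrix: unparseable numeric cell")
    calls[filled] <- ifelse(vals >= numeric_threshold,
                            "expressed", "not_expressed")
  }
  out <- as_tibble(as.data.frame(calls, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(out) <- experiments
  dplyr::bind_cols(tibble(gene_id = gene_ids), out)
}

#' Write a ternary gene-expression call matrix
#' @param expr an expression tibble as returned by
#'   [read_expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  expr <- arrange(expr, .data$gene_id)
  experiments <- setdiff(names(expr), "gene_id")
  tok <- function(x) c("Y", "N", "ab")[match(x, .EXPR_LEVELS)]
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(expr$gene_id[i],
            vapply(experiments, function(e) tok(expr[[e]][i]), character(1))),
          collapse = "\t")
  }, character(1))
  .write_lines(c(paste0("#gene_id\t", paste(experiments, collapse = "\t")),
                 body),
               path)
}
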