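# Independent oracles and tiny fixture builders shared across tests.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# ---- brute-force local alignment oracle --------------------------------
# Best local alignment = max over all (query substring, subject substring)
# pairs of the global Needleman-Wunsch score with linear gap penalty,
# floored at zero (the empty alignment). Deliberately a different algorithm
# from the package's Smith-Waterman kernel.
bf_nw_score <- function(x, y, match, mismatch, gap) {
  m <- length(x); n <- length(y)
  D <- matrix(0, m + 1, n + 1)
  D[1, ] <- gap * (0:n)
  D[, 1] <- gap * (0:m)
  if (m > 0 && n > 0) {
    for (i in 1:m) {
      for (j in 1:n) {
        D[i + 1, j + 1] <- max(
          D[i, j] + if (x[i] == y[j]) match else mismatch,
          D[i, j + 1] + gap,
          D[i + 1, j] + gap)
      }
    }
  }
  D[m + 1, n + 1]
}

bf_local_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(A)) for (i2 in i1:length(A)) {
    for (j1 in seq_along(B)) for (j2 in j1:length(B)) {
      sc <- bf_nw_score(A[i1:i2], B[j1:j2], match, mismatch, gap)
      if (sc > best) best <- sc
    }
  }
  best
}

# ---- regex expansion oracle for motif scanning -------------------------
# Valid for subject sequences over concrete A/C/G/T: each IUPAC letter of
# the motif expands to a character class; overlapping matches found with a
# lookahead. Returns 0-based starts.
iupac_regex <- function(consensus) {
  cls <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
           M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
           V = "[ACG]", N = "[ACGT]")
  paste(cls[strsplit(consensus, "")[[1]]], collapse = "")
}

regex_scan_starts <- function(consensus, seq) {
  m <- gregexpr(paste0("(?=", iupac_regex(consensus), ")"), seq,
                perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

rc_dna <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}

regex_scan_oracle <- function(consensus, seq, strands = "both") {
  fwd <- regex_scan_starts(consensus, seq)
  out <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (strands == "both") {
    rev_ <- regex_scan_starts(rc_dna(consensus), seq)
    out <- rbind(out, data.frame(start = rev_,
                                 strand = rep("-", length(rev_))))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# ---- IUPAC subset oracle ----------------------------------------------
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# ---- small fixture builders -------------------------------------------
tiny_seqs <- function(ids, residues, alphabet = "nucleotide") {
  sequence_table(ids, residues, alphabet = alphabet)
}

# a hit tibble with given evalues and dummy coordinates
hit_fixture <- function(query_id, subject_id, evalue, score = 50) {
  n <- max(length(query_id), length(subject_id), length(evalue))
  tibble::tibble(
    query_id = rep_len(query_id, n), subject_id = rep_len(subject_id, n),
    percent_identity = 95, alignment_length = 100, mismatches = 5,
    gap_opens = 0, q_start = 1, q_end = 100, s_start = 1, s_end = 100,
    evalue = rep_len(evalue, n), score = rep_len(score, n))
}

# expression tibble from a call matrix (genes x experiments)
expr_fixture <- function(calls) {
  out <- tibble::as_tibble(as.data.frame(calls, stringsAsFactors = FALSE))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(calls)), out)
}
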