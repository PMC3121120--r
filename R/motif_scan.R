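#' @title IUPAC consensus motif scanning
#' @name motif_scan
#' @description Locates IUPAC consensus binding-site motifs on nucleotide
#'   sequences. Ambiguity codes in the scanned sequence use *subset*
#'   semantics: a sequence letter matches a motif letter only if every base
#'   it could denote is allowed by the motif letter (so an `N` run in a
#'   draft genome matches only a motif `N`, never `A`). Occurrence
#'   coordinates are 0-based half-open on the forward strand.
NULL

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# .IUPAC_SUBSET[code, base]: TRUE iff set(base) is a subset of set(code)
.IUPAC_SUBSET <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(.NUC_CODES, .NUC_CODES))
  for (code in .NUC_CODES) {
    for (base in .NUC_CODES) {
      m[code, base] <- all(.IUPAC_SETS[[base]] %in% .IUPAC_SETS[[code]])
    }
  }
  m
})

.IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", D = "H", H = "D", V = "B", N = "N")

#' Does one IUPAC code admit another?
#'
#' `TRUE` iff the base set denoted by `base` is a subset of the base set
#' denoted by `code`. Vectorised over both arguments.
#'
#' @param code IUPAC letter(s) from a motif consensus.
#' @param base IUPAC letter(s) from a scanned sequence.
#' @return Logical vector.
#' @examples
#' iupac_match("N", "A") # TRUE
#' iupac_match("R", "C") # FALSE
#' @export
iupac_match <- function(code, base) {
  code <- toupper(code)
  base <- toupper(base)
  bad <- setdiff(unique(c(code, base)), .NUC_CODES)
  if (length(bad) > 0L) {
    abort(paste0("illegal IUPAC letter: ", bad[1]))
  }
  .IUPAC_SUBSET[cbind(match(code, .NUC_CODES), match(base, .NUC_CODES))]
}

#' Reverse-complement an IUPAC nucleotide string
#'
#' Ambiguity codes complement to the code denoting the complemented base set
#' (e.g. `R` to `Y`, `B` to `V`).
#'
#' @param x character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(toupper(x), function(s) {
    chars <- rev(strsplit(s, "")[[1]])
    bad <- setdiff(chars, .NUC_CODES)
    if (length(bad) > 0L) abort(paste0("illegal IUPAC letter: ", bad[1]))
    paste(.IUPAC_COMPLEMENT[chars], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# scan one consensus (as integer codes) over one sequence (integer codes);
# returns 0-based start positions
.scan_codes <- function(motif_int, seq_int) {
  L <- length(motif_int)
  n <- length(seq_int)
  if (L > n) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    ok <- ok & .IUPAC_SUBSET[cbind(motif_int[k], seq_int[k:(k + n - L)])]
  }
  which(ok) - 1L
}

.to_codes <- function(s, what) {
  idx <- match(strsplit(s, "")[[1]], .NUC_CODES)
  if (anyNA(idx)) abort(paste0(what, ": illegal IUPAC letter"))
  idx
}

#' Locate motif occurrences on nucleotide sequences
#'
#' Every window of each sequence where all positions satisfy
#' [iupac_match()] is reported. With `strands = "both"` the reverse
#' complement of each motif is also scanned on the forward sequence and
#' reported with strand `-`; coordinates and `matched_text` always refer to
#' the forward strand. Overlapping occurrences are all reported.
#'
#' @param motifs a motif tibble (`tf_id`, `motif_id`, `consensus`), e.g.
#'   from [read_motif_table()].
#' @param seqs a nucleotide sequence table (see [sequence_table()]).
#' @param strands `"both"` (default) or `"forward"`.
#' @return A tibble with columns `motif_id`, `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, `matched_text`, sorted by
#'   (`motif_id`, `seq_id`, `start`, `strand`).
#' @export
scan_motifs <- function(motifs, seqs, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (any(seqs$alphabet != "nucleotide")) {
    abort("scan_motifs: sequences must be nucleotide")
  }
  seq_codes <- lapply(seqs$residues, .to_codes, what = "sequence")
  names(seq_codes) <- seqs$id
  out <- vector("list", nrow(motifs) * nrow(seqs))
  k <- 0L
  for (i in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[i]
    fwd <- .to_codes(cons, "motif consensus")
    rev_ <- if (strands == "both") .to_codes(reverse_complement(cons),
                                            "motif consensus") else NULL
    L <- length(fwd)
    for (j in seq_len(nrow(seqs))) {
      sc <- seq_codes[[j]]
      starts <- .scan_codes(fwd, sc)
      strand <- rep("+", length(starts))
      if (!is.null(rev_)) {
        rstarts <- .scan_codes(rev_, sc)
        starts <- c(starts, rstarts)
        strand <- c(strand, rep("-", length(rstarts)))
      }
      if (length(starts) == 0L) next
      k <- k + 1L
      out[[k]] <- tibble(
        motif_id = motifs$motif_id[i],
        seq_id = seqs$id[j],
        start = as.integer(starts),
        end = as.integer(starts + L),
        strand = strand,
        matched_text = substring(seqs$residues[j], starts + 1L, starts + L))
    }
  }
  occ <- if (k == 0L) {
    tibble(motif_id = character(), seq_id = character(),
           start = integer(), end = integer(), strand = character(),
           matched_text = character())
  } else {
    bind_rows(out[seq_len(k)])
  }
  arrange(occ, .data$motif_id, .data$seq_id, .data$start, .data$strand)
}

#' Which motifs occur at least once in each sequence?
#'
#' Presence/absence view of [scan_motifs()]: one row per (sequence, motif)
#' pair with at least one occurrence on the requested strand(s).
#'
#' @inheritParams scan_motifs
#' @return A tibble with columns `seq_id`, `motif_id` (distinct pairs).
#' @export
contains_any <- function(seqs, motifs, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (nrow(motifs) == 0L) {
    return(tibble(seq_id = character(), motif_id = character()))
  }
  occ <- scan_motifs(motifs, seqs, strands = strands)
  distinct(select(occ, "seq_id", "motif_id"))
}
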