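test_that("iupac_match implements subset semantics over base sets", {
  expect_true(iupac_match("N", "A"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("R", "R"))
  expect_false(iupac_match("A", "N"))
  expect_error(iupac_match("Q", "A"), "illegal IUPAC letter")

  # all 15 x 15 pairs against the expanded-set subset oracle
  codes <- names(iupac_sets_oracle)
  for (code in codes) {
    for (base in codes) {
      expect_identical(
        iupac_match(code, base),
        all(iupac_sets_oracle[[base]] %in% iupac_sets_oracle[[code]]),
        info = paste(code, base))
    }
  }
})

test_that("reverse_complement handles ambiguity codes", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("TGACTC"), "GAGTCA")
  expect_equal(reverse_complement("RYSWKMBDHVN"), "NBDHVKMWSRY")
})

test_that("scan_motifs finds windows with forward-strand coordinates", {
  motifs <- tibble::tibble(tf_id = "TF1", motif_id = "m1", consensus = "TGA")
  occ <- scan_motifs(motifs, tiny_seqs("s", "TTGAA"), strands = "forward")
  expect_equal(nrow(occ), 1)
  expect_equal(occ$start, 1L)
  expect_equal(occ$end, 4L)
  expect_equal(occ$matched_text, "TGA")

  long_motif <- tibble::tibble(tf_id = "TF1", motif_id = "m1",
                               consensus = "TGACTC")
  expect_equal(nrow(scan_motifs(long_motif, tiny_seqs("s", "ACGTA"))), 0)
})

test_that("scanner agrees with the regex-expansion oracle on random input", {
  set.seed(505)
  codes <- names(iupac_sets_oracle)
  for (k in 1:200) {
    seq <- rand_dna(sample(20:60, 1))
    L <- sample(4:10, 1)
    consensus <- paste(sample(codes, L, replace = TRUE,
                              prob = c(rep(4, 4), rep(1, 11))),
                       collapse = "")
    motifs <- tibble::tibble(tf_id = "t", motif_id = "m",
                             consensus = consensus)
    got <- scan_motifs(motifs, tiny_seqs("s", seq), strands = "both")
    want <- regex_scan_oracle(consensus, seq, strands = "both")
    expect_equal(got$start, want$start, info = paste(consensus, seq))
    expect_equal(got$strand, want$strand, info = paste(consensus, seq))
  }
})

test_that("both-strand scanning is closed under reverse complement", {
  set.seed(606)
  for (k in 1:25) {
    seq <- rand_dna(40)
    consensus <- paste(sample(c("A", "C", "G", "T", "R", "N"), 6,
                              replace = TRUE), collapse = "")
    motifs <- tibble::tibble(tf_id = "t", motif_id = "m",
                             consensus = consensus)
    fwd <- scan_motifs(motifs, tiny_seqs("s", seq), strands = "both")
    rev_ <- scan_motifs(motifs, tiny_seqs("s", rc_dna(seq)),
                        strands = "both")
    expect_equal(nrow(fwd), nrow(rev_))
    # coordinates mirror: start' = len - end
    expect_setequal(rev_$start, nchar(seq) - fwd$end)
  }
})

test_that("motif presence is monotone under embedding in a supersequence", {
  set.seed(707)
  motifs <- tibble::tibble(tf_id = "t", motif_id = "m", consensus = "TGACTC")
  for (k in 1:10) {
    core <- paste0(rand_dna(10), "TGACTC", rand_dna(10))
    sup <- paste0(rand_dna(15), core, rand_dna(15))
    expect_equal(contains_any(tiny_seqs("s", core), motifs)$motif_id, "m")
    expect_equal(contains_any(tiny_seqs("s", sup), motifs)$motif_id, "m")
  }
})

test_that("contains_any is the non-emptiness of scan_sequence", {
  set.seed(808)
  motifs <- tibble::tibble(
    tf_id = "t", motif_id = paste0("m", 1:5),
    consensus = vapply(1:5, function(i) rand_dna(5), character(1)))
  seqs <- tiny_seqs(paste0("s", 1:20),
                    vapply(1:20, function(i) rand_dna(80), character(1)))
  pres <- contains_any(seqs, motifs)
  occ <- scan_motifs(motifs, seqs)
  for (i in seq_len(nrow(motifs))) {
    for (j in seq_len(nrow(seqs))) {
      in_pres <- any(pres$motif_id == motifs$motif_id[i] &
                       pres$seq_id == seqs$id[j])
      in_occ <- any(occ$motif_id == motifs$motif_id[i] &
                      occ$seq_id == seqs$id[j])
      expect_identical(in_pres, in_occ)
    }
  }
  # no motif present / planted motif found
  expect_equal(nrow(contains_any(tiny_seqs("x", "AAAAAAAA"),
                                 tibble::tibble(tf_id = "t", motif_id = "m",
                                                consensus = "CCCC"))), 0)
  planted <- paste0(rand_dna(20), "CCCC")
  expect_equal(contains_any(tiny_seqs("x", planted),
                            tibble::tibble(tf_id = "t", motif_id = "m",
                                           consensus = "CCCC"))$motif_id,
               "m")
})
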