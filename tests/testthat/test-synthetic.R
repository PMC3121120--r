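test_that("mutate_sequence hits the requested substitution rate", {
  set.seed(81)
  s <- rand_dna(200)
  expect_equal(mutate_sequence(s, 0), s)

  m1 <- mutate_sequence(s, 1)
  expect_equal(sum(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]), 200)

  long <- rand_dna(10000)
  m <- mutate_sequence(long, 0.1)
  frac <- mean(strsplit(m, "")[[1]] != strsplit(long, "")[[1]])
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("plant_motif realizations are found by the scanner", {
  set.seed(82)
  s <- rand_dna(50)
  planted <- plant_motif(s, "TGACTC", 11)
  occ <- scan_motifs(tibble::tibble(tf_id = "t", motif_id = "m",
                                    consensus = "TGACTC"),
                     tiny_seqs("x", planted), strands = "forward")
  expect_true(10L %in% occ$start)  # 1-based position 11 = 0-based 10

  # an all-N motif accepts any realization
  sN <- plant_motif(s, "NNNN", 1)
  expect_equal(nchar(sN), nchar(s))
  occN <- scan_motifs(tibble::tibble(tf_id = "t", motif_id = "m",
                                     consensus = "NNNN"),
                      tiny_seqs("x", sN))
  expect_true(0L %in% occN$start)

  expect_error(plant_motif(s, "TGACTC", 46), "out of range")
})

test_that("degenerate positions are realized uniformly", {
  set.seed(83)
  draws <- vapply(1:1000, function(i) {
    substr(plant_motif("AAAA", "NNNN", 1), 1, 1)
  }, character(1))
  tab <- table(factor(draws, levels = c("A", "C", "G", "T")))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 1e-4)
})

test_that("scenario generation is reproducible and internally consistent", {
  p <- scenario_params(n_tf = 5, n_tg = 15, links_per_tf = 3, seed = 84)
  a <- generate_scenario(p)
  b <- generate_scenario(p)
  expect_identical(a, b)

  # changing the seed changes the bundle
  c_ <- generate_scenario(scenario_params(n_tf = 5, n_tg = 15,
                                          links_per_tf = 3, seed = 85))
  expect_false(identical(a$target_seqs, c_$target_seqs))

  # every conserved link's target TG contains a motif of its TF
  for (i in seq_len(nrow(a$truth$conserved_links))) {
    tl <- a$truth$conserved_links[i, ]
    tf_motifs <- a$motifs[a$motifs$tf_id == tl$source_tf_id, ]
    tgt <- a$target_seqs[a$target_seqs$id == tl$target_tg_id, ]
    expect_gt(nrow(contains_any(tgt, tf_motifs)), 0)
  }

  # conserved links only reference conserved elements
  expect_true(all(a$truth$conserved_links$source_tf_id %in%
                    a$truth$tf_homolog_pairs$source_id))
  expect_true(all(a$truth$conserved_links$source_tg_id %in%
                    a$truth$tg_homolog_pairs$source_id))
})

test_that("invalid scenario parameters are rejected", {
  expect_error(scenario_params(p_confirm_true = 0.8,
                               p_contradict_true = 0.3),
               "p_confirm_true")
  expect_error(scenario_params(motif_len = 600), "motif_len")
  expect_error(scenario_params(n_tf = 10, n_tg = 20, links_per_tf = 5),
               "one regulator per TG")
  expect_error(scenario_params(frac_positive = 1.2), "\\[0, 1\\]")
})

test_that("expression calibration converges to the planted confirm rate", {
  p <- scenario_params(n_tf = 4, n_tg = 12, links_per_tf = 3,
                       seq_len_tf = 100, seq_len_tg = 150,
                       frac_tf_conserved = 1, frac_tg_conserved = 1,
                       frac_link_conserved = 1, n_decoy_seqs = 0,
                       n_experiments = 2000, p_confirm_true = 0.8,
                       p_contradict_true = 0.1, p_absent = 0, seed = 86)
  sc <- generate_scenario(p)
  truth <- sc$truth$conserved_links
  links <- tibble::tibble(
    source_tf_id = truth$source_tf_id, source_tg_id = truth$source_tg_id,
    target_tf_id = truth$target_tf_id, target_tg_id = truth$target_tg_id,
    sign = truth$sign)
  counts <- count_links(links, sc$expression)
  n_total <- nrow(counts) * 2000
  conf_rate <- sum(counts$confirming) / n_total
  contra_rate <- sum(counts$contradictory) / n_total
  se_c <- sqrt(0.8 * 0.2 / n_total)
  se_x <- sqrt(0.1 * 0.9 / n_total)
  expect_lt(abs(conf_rate - 0.8), 3 * se_c)
  expect_lt(abs(contra_rate - 0.1), 3 * se_x)
})

test_that("written scenario bundles are byte-stable and re-readable", {
  p <- scenario_params(n_tf = 4, n_tg = 8, links_per_tf = 2,
                       seq_len_tf = 80, seq_len_tg = 120,
                       n_experiments = 6, seed = 87)
  sc <- generate_scenario(p)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_scenario(sc, d1)
  f2 <- write_scenario(generate_scenario(p), d2)
  for (nm in names(f1)) {
    expect_identical(readBin(f1[[nm]], "raw", file.size(f1[[nm]])),
                     readBin(f2[[nm]], "raw", file.size(f2[[nm]])),
                     info = nm)
  }
  expect_equal(nrow(read_fasta(f1[["target.fa"]])), nrow(sc$target_seqs))
  expect_equal(read_motif_table(f1[["motifs.tsv"]]),
               dplyr::arrange(sc$motifs, tf_id, motif_id))
  expect_equal(read_network(f1[["network.tsv"]]),
               dplyr::arrange(sc$network, tf_id, tg_id, sign))
})
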