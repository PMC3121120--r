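mk_map <- function(pairs, label) {
  reglinkmap:::.new_mapping(pairs, label)
}

simple_setup <- function(target_has_motif = TRUE) {
  motifs <- tibble::tibble(tf_id = "TF1", motif_id = c("m1", "m2"),
                           consensus = c("TGACTC", "CCCCCC"))
  network <- tibble::tibble(tf_id = "TF1", tg_id = "G1", sign = "negative")
  src_tg <- tiny_seqs("G1", paste0("AAAA", "TGACTC", "AAAA"))
  tgt_res <- if (target_has_motif) paste0("TT", "TGACTC", "TT") else
    "TTTTTTTTTT"
  targets <- tiny_seqs(c("tTF1", "tG1"), c("ACGTACGTAC", tgt_res))
  tf_map <- mk_map(tibble::tibble(source_tf_id = "TF1",
                                  target_seq_id = "tTF1"), "TFsf")
  tg_map <- mk_map(tibble::tibble(source_tg_id = "G1",
                                  target_seq_id = "tG1",
                                  matched_motif_ids = list("m1")), "TGblbs")
  list(motifs = motifs, network = network, src_tg = src_tg,
       targets = targets, tf_map = tf_map, tg_map = tg_map)
}

test_that("motifs_in_source_tg returns the TF motifs present in the TG", {
  s <- simple_setup()
  found <- motifs_in_source_tg(s$network[1, ], s$motifs, s$src_tg)
  expect_equal(found, "m1")   # m2 (CCCCCC) is not in the source TG

  none <- motifs_in_source_tg(
    s$network[1, ],
    tibble::tibble(tf_id = "TF1", motif_id = "mX", consensus = "GGGGGG"),
    s$src_tg)
  expect_equal(none, character(0))

  expect_warning(
    skipped <- motifs_in_source_tg(
      tibble::tibble(tf_id = "TF1", tg_id = "G9", sign = "positive"),
      s$motifs, s$src_tg),
    "no sequence")
  expect_equal(skipped, character(0))

  # definitional agreement with contains_any on random fixtures
  set.seed(51)
  for (k in 1:10) {
    mot <- tibble::tibble(tf_id = "T", motif_id = paste0("m", 1:3),
                          consensus = vapply(1:3, function(i) rand_dna(5),
                                             character(1)))
    seqt <- tiny_seqs("g", rand_dna(60))
    link <- tibble::tibble(tf_id = "T", tg_id = "g", sign = "positive")
    expect_equal(motifs_in_source_tg(link, mot, seqt),
                 sort(contains_any(seqt, mot)$motif_id))
  }
})

test_that("one conserved link integrates into one signed predicted link", {
  s <- simple_setup()
  links <- integrate_links(s$network, s$tf_map, s$tg_map, s$motifs,
                           s$src_tg, s$targets)
  expect_equal(nrow(links), 1)
  expect_equal(links$target_tf_id, "tTF1")
  expect_equal(links$target_tg_id, "tG1")
  expect_equal(links$sign, "negative")       # inherited from the source
  expect_equal(links$supporting_motif_ids[[1]], "m1")
  expect_equal(links$provenance, "TFsf-TGblbs")
  expect_equal(attr(links, "n_links_no_source_motif"), 0L)
})

test_that("a target gene lacking every source-TG motif yields no link", {
  s <- simple_setup(target_has_motif = FALSE)
  links <- integrate_links(s$network, s$tf_map, s$tg_map, s$motifs,
                           s$src_tg, s$targets)
  expect_equal(nrow(links), 0)
})

test_that("links whose source TG lacks its TF's motifs are dropped and counted", {
  s <- simple_setup()
  src_tg_clean <- tiny_seqs("G1", "AAAAAAAAAAAAAA")  # no motif
  links <- integrate_links(s$network, s$tf_map, s$tg_map, s$motifs,
                           src_tg_clean, s$targets)
  expect_equal(nrow(links), 0)
  expect_equal(attr(links, "n_links_no_source_motif"), 1L)
})

test_that("provenance mismatch is a hard error", {
  s <- simple_setup()
  expect_error(
    integrate_links(s$network, s$tf_map, s$tg_map, s$motifs, s$src_tg,
                    s$targets, provenance = "TFf-TGblbs"),
    "provenance")
  expect_error(
    integrate_links(s$network, s$tg_map, s$tg_map, s$motifs, s$src_tg,
                    s$targets),
    "expected a mapping set labelled")
})

test_that("supporting motifs occur in both source and target TG", {
  sc <- generate_scenario(scenario_params(n_tf = 5, n_tg = 15,
                                          links_per_tf = 3, seed = 52))
  res <- run_mapping(sc$source_tf_seqs, sc$source_tg_seqs, sc$target_seqs,
                     sc$motifs, sc$network,
                     source_annotations = sc$source_annotations,
                     target_annotations = sc$target_annotations,
                     tf_mode = "f", tg_mode = "blbs", min_score = 100)
  links <- res$links
  expect_gt(nrow(links), 0)
  for (i in seq_len(nrow(links))) {
    tf_motifs <- sc$motifs$motif_id[sc$motifs$tf_id == links$source_tf_id[i]]
    supp <- links$supporting_motif_ids[[i]]
    expect_true(all(supp %in% tf_motifs))
    mot <- sc$motifs[sc$motifs$motif_id %in% supp, ]
    src_seq <- sc$source_tg_seqs[sc$source_tg_seqs$id ==
                                   links$source_tg_id[i], ]
    tgt_seq <- sc$target_seqs[sc$target_seqs$id == links$target_tg_id[i], ]
    expect_setequal(
      intersect(supp, contains_any(src_seq, mot)$motif_id), supp)
    expect_setequal(
      intersect(supp, contains_any(tgt_seq, mot)$motif_id), supp)
  }
  # sign conservation: each predicted link carries its source link's sign
  net_key <- paste(sc$network$tf_id, sc$network$tg_id)
  expect_equal(links$sign,
               sc$network$sign[match(paste(links$source_tf_id,
                                           links$source_tg_id), net_key)])
})

test_that("integrating with TFsf never yields more links than with TFf", {
  sc <- generate_scenario(scenario_params(n_tf = 6, n_tg = 18,
                                          links_per_tf = 3,
                                          frac_tf_family_only = 0.4,
                                          seed = 53))
  base <- list(sc$source_tf_seqs, sc$source_tg_seqs, sc$target_seqs,
               sc$motifs, sc$network)
  run_mode <- function(mode) {
    run_mapping(sc$source_tf_seqs, sc$source_tg_seqs, sc$target_seqs,
                sc$motifs, sc$network,
                source_annotations = sc$source_annotations,
                target_annotations = sc$target_annotations,
                tf_mode = mode, tg_mode = "blbs", min_score = 100)
  }
  expect_lte(nrow(run_mode("sf")$links), nrow(run_mode("f")$links))
})
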