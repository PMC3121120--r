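# hand-enumerated rule table: sign, TF call, TG call -> class
RULE_TRUTH <- rbind(
  c("positive", "expressed",     "expressed",     "Confirming"),
  c("positive", "expressed",     "not_expressed", "Contradictory"),
  c("positive", "not_expressed", "expressed",     "Neutral"),
  c("positive", "not_expressed", "not_expressed", "Ignored"),
  c("positive", "absent",        "expressed",     "Ignored"),
  c("positive", "absent",        "not_expressed", "Ignored"),
  c("positive", "expressed",     "absent",        "Ignored"),
  c("positive", "not_expressed", "absent",        "Ignored"),
  c("positive", "absent",        "absent",        "Ignored"),
  c("negative", "expressed",     "expressed",     "Contradictory"),
  c("negative", "expressed",     "not_expressed", "Confirming"),
  c("negative", "not_expressed", "expressed",     "Confirming"),
  c("negative", "not_expressed", "not_expressed", "Contradictory"),
  c("negative", "absent",        "expressed",     "Ignored"),
  c("negative", "absent",        "not_expressed", "Ignored"),
  c("negative", "expressed",     "absent",        "Ignored"),
  c("negative", "not_expressed", "absent",        "Ignored"),
  c("negative", "absent",        "absent",        "Ignored"))

test_that("the rule engine matches the full 18-combination truth table", {
  got <- classify_experiment(RULE_TRUTH[, 1], RULE_TRUTH[, 2],
                             RULE_TRUTH[, 3])
  expect_equal(got, RULE_TRUTH[, 4])
  expect_error(classify_experiment("up", "expressed", "expressed"), "sign")
})

test_that("sign flips swap classes as the rules dictate", {
  # (expressed, expressed): Confirming <-> Contradictory under sign flip
  expect_equal(classify_experiment("positive", "expressed", "expressed"),
               "Confirming")
  expect_equal(classify_experiment("negative", "expressed", "expressed"),
               "Contradictory")
  # (expressed, not_expressed): Contradictory <-> Confirming
  expect_equal(classify_experiment("positive", "expressed", "not_expressed"),
               "Contradictory")
  expect_equal(classify_experiment("negative", "expressed", "not_expressed"),
               "Confirming")
})

link_row <- function(tf = "tf", tg = "tg", sign = "positive") {
  tibble::tibble(source_tf_id = "s", source_tg_id = "s",
                 target_tf_id = tf, target_tg_id = tg, sign = sign)
}

test_that("count_links counts per experiment and conserves the total", {
  # genes absent from the matrix: everything ignored
  calls <- matrix("expressed", nrow = 1, ncol = 43,
                  dimnames = list("other", sprintf("e%02d", 1:43)))
  counts <- count_links(link_row("nf", "ng"), expr_fixture(calls))
  expect_equal(counts$confirming, 0)
  expect_equal(counts$contradictory, 0)
  expect_equal(counts$neutral, 0)
  expect_equal(counts$ignored, 43)

  # positive link: both expressed in 5 of 8, TF-only expressed in 3
  tfrow <- rep("expressed", 8)
  tgrow <- c(rep("expressed", 5), rep("not_expressed", 3))
  calls <- rbind(tf = tfrow, tg = tgrow)
  colnames(calls) <- paste0("e", 1:8)
  counts <- count_links(link_row(), expr_fixture(calls))
  expect_equal(counts$confirming, 5)
  expect_equal(counts$contradictory, 3)
  expect_equal(counts$neutral, 0)
  expect_equal(counts$ignored, 0)

  # conservation on random matrices
  set.seed(61)
  for (k in 1:10) {
    n_exp <- sample(5:40, 1)
    calls <- matrix(sample(c("expressed", "not_expressed", "absent"),
                           2 * n_exp, replace = TRUE),
                    nrow = 2, dimnames = list(c("tf", "tg"),
                                              paste0("e", 1:n_exp)))
    counts <- count_links(link_row(sign = sample(c("positive", "negative"),
                                                 1)),
                          expr_fixture(calls))
    expect_equal(counts$confirming + counts$contradictory +
                   counts$neutral + counts$ignored, n_exp)
  }
})

test_that("count_links resolves ids through id_map", {
  calls <- matrix(c("expressed", "expressed"), nrow = 2,
                  dimnames = list(c("geneA", "geneB"), "e1"))
  counts <- count_links(link_row("tfX", "tgX"), expr_fixture(calls),
                        id_map = c(tfX = "geneA", tgX = "geneB"))
  expect_equal(counts$confirming, 1)
})

test_that("tier assignment follows the weighted and ratio rules", {
  tc <- function(confirming, contradictory, neutral) {
    assign_tier(tibble::tibble(confirming = confirming,
                               contradictory = contradictory,
                               neutral = neutral))
  }
  r <- tc(5, 1, 2)
  expect_true(r$verified)            # 5 > 2*1 + 1*2
  expect_equal(r$ratio_tier, "strong_3x")  # 5 >= 3*1

  r <- tc(0, 1, 0)
  expect_false(r$verified)
  expect_equal(r$ratio_tier, "unsupported")

  r <- tc(0, 0, 0)
  expect_false(r$verified)
  expect_equal(r$ratio_tier, "no_data")

  # brute-force case analysis over random triples: the four ratio tiers
  # partition analyzed links, at the stated boundaries
  set.seed(62)
  for (k in 1:200) {
    cc <- sample(0:12, 1); x <- sample(0:12, 1); nn <- sample(0:12, 1)
    if (cc == 0 && x == 0 && nn == 0) next
    conds <- c(strong_3x = cc >= 3 * x,
               strong_2x = cc >= 2 * x && cc < 3 * x,
               weak = cc >= x && cc < 2 * x,
               unsupported = cc < x)
    expect_equal(sum(conds), 1L)
    expect_equal(tc(cc, x, nn)$ratio_tier, names(which(conds)))
  }
})

test_that("raising the confirming count never demotes a link", {
  set.seed(63)
  rank <- c(no_data = 0, unsupported = 1, weak = 2, strong_2x = 3,
            strong_3x = 4)
  for (k in 1:50) {
    x <- sample(0:6, 1); nn <- sample(0:6, 1); cc <- sample(0:10, 1)
    a <- assign_tier(tibble::tibble(confirming = cc, contradictory = x,
                                    neutral = nn))
    b <- assign_tier(tibble::tibble(confirming = cc + 1, contradictory = x,
                                    neutral = nn))
    expect_gte(rank[[b$ratio_tier]], rank[[a$ratio_tier]])
    expect_gte(b$verified, a$verified)
  }
})

test_that("confirm_links summarises tiers as a partition of analyzed links", {
  # all links out of matrix: analyzed = 0
  calls <- matrix("expressed", nrow = 1, ncol = 5,
                  dimnames = list("z", paste0("e", 1:5)))
  rep0 <- confirm_links(link_row("nf", "ng"), expr_fixture(calls))
  expect_equal(rep0$summary$n_analyzed, 0)
  expect_equal(rep0$summary$no_data, 1)

  set.seed(64)
  n_links <- 40
  links <- dplyr::bind_rows(lapply(1:n_links, function(i) {
    link_row(paste0("tf", i), paste0("tg", i),
             sample(c("positive", "negative"), 1))
  }))
  genes <- c(paste0("tf", 1:n_links), paste0("tg", 1:n_links))
  calls <- matrix(sample(c("expressed", "not_expressed", "absent"),
                         length(genes) * 20, replace = TRUE),
                  nrow = length(genes),
                  dimnames = list(genes, paste0("e", 1:20)))
  rep_ <- confirm_links(links, expr_fixture(calls))
  s <- rep_$summary
  expect_equal(s$strong_3x + s$strong_2x + s$weak + s$unsupported,
               s$n_analyzed)
  expect_equal(s$n_analyzed + s$no_data, s$n_links)
  expect_equal(glance(rep_), s)
  expect_equal(nrow(tidy(rep_)), n_links)
})

test_that("true links verify more often than decoys at the planted rates", {
  sc <- generate_scenario(scenario_params(
    n_tf = 10, n_tg = 50, frac_tf_conserved = 1, frac_tg_conserved = 1,
    frac_link_conserved = 1, p_confirm_true = 0.8,
    p_contradict_true = 0.1, p_absent = 0.05, seed = 65))
  truth <- sc$truth$conserved_links
  true_links <- tibble::tibble(
    source_tf_id = truth$source_tf_id, source_tg_id = truth$source_tg_id,
    target_tf_id = truth$target_tf_id, target_tg_id = truth$target_tg_id,
    sign = truth$sign)
  # decoy links: the same TFs paired with unrelated decoy genes, whose
  # calls are independent 50/50 by construction
  set.seed(66)
  decoys <- true_links
  decoy_genes <- grep("^dec", sc$target_seqs$id, value = TRUE)
  decoys$target_tg_id <- sample(decoy_genes, nrow(decoys), replace = TRUE)
  rep_true <- confirm_links(true_links, sc$expression)
  rep_dec <- confirm_links(decoys, sc$expression)
  rate <- function(r) r$summary$n_verified / r$summary$n_analyzed
  expect_gt(rate(rep_true), rate(rep_dec))
})
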