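#' @title Synthetic paired-genome scenarios with a known truth table
#' @name synthetic_data
#' @description Generates a complete source/target fixture bundle —
#'   sequences, binding-site motifs, a signed network, family/subfamily
#'   annotations and a ternary expression matrix — together with the truth
#'   (which TFs/TGs are homologous, which links are conserved, where motifs
#'   were planted), so every pipeline stage can be exercised and scored
#'   without external data. Generation is fully deterministic given the
#'   seed in the parameters.
NULL

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Substitute bases at a fixed per-position rate
#'
#' Each position is replaced, independently with probability `rate`, by a
#' base drawn uniformly from the three alternatives (so a hit always
#' changes the base). Uses the current RNG state.
#'
#' @param seq a single A/C/G/T string.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, rate) {
  if (rate < 0 || rate > 1) abort("mutate_sequence: rate must be in [0, 1]")
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, bases)
  if (anyNA(idx)) abort("mutate_sequence: sequence must be over A/C/G/T")
  hit <- runif(length(idx)) < rate
  n_hit <- sum(hit)
  if (n_hit > 0L) {
    shift <- sample.int(3L, n_hit, replace = TRUE)
    idx[hit] <- ((idx[hit] - 1L + shift) %% 4L) + 1L
    chars <- bases[idx]
  }
  paste(chars, collapse = "")
}

#' Overwrite a window with a realization of an IUPAC consensus
#'
#' Each consensus letter is instantiated uniformly from its base set, and
#' the realization replaces the window starting at `position` (1-based).
#' A subsequent [scan_motifs()] is guaranteed to find the motif there.
#'
#' @param seq a single nucleotide string.
#' @param consensus an IUPAC consensus string.
#' @param position 1-based start of the window;
#'   `position + nchar(consensus) - 1` must not exceed `nchar(seq)`.
#' @return The modified string.
#' @export
plant_motif <- function(seq, consensus, position) {
  L <- nchar(consensus)
  if (position < 1 || position + L - 1 > nchar(seq)) {
    abort("plant_motif: window out of range")
  }
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters_, .NUC_CODES)
  if (length(bad) > 0L) abort(paste0("plant_motif: illegal IUPAC letter ",
                                     bad[1]))
  real <- vapply(letters_, function(ch) {
    s <- .IUPAC_SETS[[ch]]
    s[sample.int(length(s), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste0(substr(seq, 1, position - 1),
         paste(real, collapse = ""),
         substr(seq, position + L, nchar(seq)))
}

# remove every occurrence (both strands) of the given concrete motifs by
# flipping the middle base of each residual occurrence
.scrub_motifs <- function(seq, consensus_vec) {
  bases <- c("A", "C", "G", "T")
  mot <- tibble(tf_id = "x", motif_id = as.character(seq_along(consensus_vec)),
                consensus = consensus_vec)
  st <- sequence_table("s", seq)
  for (iter in 1:50) {
    occ <- scan_motifs(mot, st, strands = "both")
    if (nrow(occ) == 0L) return(st$residues[1])
    pos <- occ$start[1] + (occ$end[1] - occ$start[1]) %/% 2 + 1L
    cur <- substr(st$residues[1], pos, pos)
    alt <- sample(setdiff(bases, cur), 1L)
    substr(st$residues[1], pos, pos) <- alt
  }
  st$residues[1]
}

#' Parameters for a synthetic mapping scenario
#'
#' Defaults describe a desk-scale regime patterned on a genome-to-genome
#' mapping study: a source network of `n_tf` regulators wired to dedicated
#' target genes, a target genome containing mutated homologs of a fraction
#' of the source elements plus unrelated decoys, and a 43-experiment
#' ternary expression matrix whose per-experiment patterns confirm planted
#' links at a stated rate.
#'
#' @param n_tf,n_tg numbers of source TFs and TGs.
#' @param seq_len_tf,seq_len_tg source sequence lengths (bases).
#' @param motifs_per_tf binding-site motifs per TF.
#' @param motif_len motif length (bases).
#' @param links_per_tf regulated TGs per TF; each generated TG has at most
#'   one regulator, so `n_tf * links_per_tf <= n_tg` is required.
#' @param frac_positive fraction of links with positive sign.
#' @param frac_tf_conserved,frac_tg_conserved fractions of TFs/TGs with a
#'   homolog in the target genome.
#' @param frac_link_conserved probability that a link whose endpoints are
#'   both conserved is itself conserved (motif re-planted intact).
#' @param substitution_rate per-base substitution rate from source to
#'   target homolog.
#' @param n_decoy_seqs unrelated target sequences.
#' @param decoy_family_rate fraction of decoys annotated to a real TF
#'   family (but never the matching subfamily).
#' @param frac_tf_family_only fraction of conserved TFs whose target
#'   homolog shares the family but not the subfamily annotation.
#' @param n_experiments expression experiments.
#' @param p_confirm_true,p_contradict_true per-experiment probabilities
#'   that a conserved link draws a Confirming / Contradictory pattern
#'   (`p_confirm_true + p_contradict_true <= 1`; the remainder is
#'   Neutral/Ignored).
#' @param p_absent per-cell probability that a call is masked to absent.
#' @param promoter_len length of generated target promoter sequences.
#' @param seed integer RNG seed; identical parameters give a byte-identical
#'   bundle.
#' @return A validated list of class `scenario_params`.
#' @export
scenario_params <- function(n_tf = 10, n_tg = 50,
                            seq_len_tf = 300, seq_len_tg = 500,
                            motifs_per_tf = 2, motif_len = 8,
                            links_per_tf = 5, frac_positive = 0.7,
                            frac_tf_conserved = 0.8, frac_tg_conserved = 0.8,
                            frac_link_conserved = 0.6,
                            substitution_rate = 0.05,
                            n_decoy_seqs = 20, decoy_family_rate = 0.2,
                            frac_tf_family_only = 0.2,
                            n_experiments = 43,
                            p_confirm_true = 0.8, p_contradict_true = 0.1,
                            p_absent = 0.1,
                            promoter_len = 200, seed = 1) {
  p <- list(n_tf = n_tf, n_tg = n_tg, seq_len_tf = seq_len_tf,
            seq_len_tg = seq_len_tg, motifs_per_tf = motifs_per_tf,
            motif_len = motif_len, links_per_tf = links_per_tf,
            frac_positive = frac_positive,
            frac_tf_conserved = frac_tf_conserved,
            frac_tg_conserved = frac_tg_conserved,
            frac_link_conserved = frac_link_conserved,
            substitution_rate = substitution_rate,
            n_decoy_seqs = n_decoy_seqs,
            decoy_family_rate = decoy_family_rate,
            frac_tf_family_only = frac_tf_family_only,
            n_experiments = n_experiments,
            p_confirm_true = p_confirm_true,
            p_contradict_true = p_contradict_true,
            p_absent = p_absent, promoter_len = promoter_len, seed = seed)
  fracs <- c(frac_positive, frac_tf_conserved, frac_tg_conserved,
             frac_link_conserved, substitution_rate, decoy_family_rate,
             frac_tf_family_only, p_confirm_true, p_contradict_true,
             p_absent)
  if (any(fracs < 0 | fracs > 1)) {
    abort("scenario_params: fractions/probabilities must lie in [0, 1]")
  }
  if (p_confirm_true + p_contradict_true > 1) {
    abort("scenario_params: p_confirm_true + p_contradict_true must be <= 1")
  }
  counts <- c(n_tf, n_tg, seq_len_tf, seq_len_tg, motifs_per_tf, motif_len,
              links_per_tf, n_decoy_seqs, n_experiments, promoter_len)
  if (any(counts < 0)) abort("scenario_params: counts must be >= 0")
  if (motif_len > seq_len_tg || motif_len > promoter_len) {
    abort("scenario_params: motif_len exceeds a sequence length")
  }
  if (n_tf * links_per_tf > n_tg) {
    abort("scenario_params: need n_tf * links_per_tf <= n_tg (one regulator per TG)")
  }
  structure(p, class = "scenario_params")
}

#' Generate a full synthetic scenario
#'
#' @param params a [scenario_params()] object.
#' @return A list of class `reglink_scenario` with elements
#'   `source_tf_seqs`, `source_tg_seqs`, `target_seqs`,
#'   `target_promoters` (sequence tables), `motifs`, `network`,
#'   `source_annotations`, `target_annotations`, `expression` (tibbles),
#'   `truth` (list: `tf_homolog_pairs`, `tg_homolog_pairs`,
#'   `conserved_links`, `planted_occurrences`) and `params`.
#' @export
generate_scenario <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  withr::with_seed(params$seed, .generate_scenario_impl(params))
}

.generate_scenario_impl <- function(p) {
  tf_ids <- sprintf("sTF%02d", seq_len(p$n_tf))
  tg_ids <- sprintf("sTG%03d", seq_len(p$n_tg))

  # motifs: concrete (unambiguous) consensus strings, distinct per TF
  motifs <- bind_rows(lapply(tf_ids, function(tf) {
    tibble(tf_id = tf,
           motif_id = sprintf("%s_m%d", tf, seq_len(p$motifs_per_tf)),
           consensus = vapply(seq_len(p$motifs_per_tf),
                              function(k) .random_dna(p$motif_len),
                              character(1)))
  }))

  # network: TGs partitioned among TFs, one regulator per TG
  n_linked <- p$n_tf * p$links_per_tf
  linked_tgs <- sample(tg_ids, n_linked)
  network <- tibble(
    tf_id = rep(tf_ids, each = p$links_per_tf),
    tg_id = linked_tgs,
    sign = ifelse(runif(n_linked) < p$frac_positive,
                  "positive", "negative"))

  # source sequences; each linked TG carries one planted motif of its TF
  tf_res <- vapply(tf_ids, function(i) .random_dna(p$seq_len_tf),
                   character(1))
  tg_res <- vapply(tg_ids, function(i) .random_dna(p$seq_len_tg),
                   character(1))
  names(tg_res) <- tg_ids
  planted <- list()
  link_motif <- character(nrow(network))
  link_pos <- integer(nrow(network))
  for (i in seq_len(nrow(network))) {
    tfm <- motifs[motifs$tf_id == network$tf_id[i], , drop = FALSE]
    pick <- sample.int(nrow(tfm), 1L)
    pos <- sample.int(p$seq_len_tg - p$motif_len + 1L, 1L)
    tg_res[[network$tg_id[i]]] <-
      plant_motif(tg_res[[network$tg_id[i]]], tfm$consensus[pick], pos)
    link_motif[i] <- tfm$motif_id[pick]
    link_pos[i] <- pos
    planted[[length(planted) + 1L]] <-
      tibble(seq_id = network$tg_id[i], motif_id = tfm$motif_id[pick],
             start = pos - 1L, where = "source_tg")
  }

  source_tf_seqs <- sequence_table(tf_ids, unname(tf_res))
  source_tg_seqs <- sequence_table(tg_ids, unname(tg_res))

  # conserved elements and links
  cons_tfs <- sort(sample(tf_ids, round(p$frac_tf_conserved * p$n_tf)))
  cons_tgs <- sort(sample(tg_ids, round(p$frac_tg_conserved * p$n_tg)))
  eligible <- network$tf_id %in% cons_tfs & network$tg_id %in% cons_tgs
  conserved <- eligible & runif(nrow(network)) < p$frac_link_conserved

  t_id <- function(x) paste0("t", x)

  # target homologs: mutated copies; conserved-link motifs re-planted
  # intact, motifs of non-conserved (but eligible) links scrubbed
  tgt_ids <- character(0)
  tgt_res <- character(0)
  for (tf in cons_tfs) {
    tgt_ids <- c(tgt_ids, t_id(tf))
    tgt_res <- c(tgt_res, mutate_sequence(tf_res[[tf]], p$substitution_rate))
  }
  for (tg in cons_tgs) {
    res <- mutate_sequence(tg_res[[tg]], p$substitution_rate)
    li <- which(network$tg_id == tg)
    if (length(li) == 1L) {
      cons_here <- conserved[li]
      tf_cons <- motifs$consensus[motifs$tf_id == network$tf_id[li]]
      if (cons_here) {
        link_cons <- motifs$consensus[motifs$motif_id == link_motif[li]]
        res <- plant_motif(res, link_cons, link_pos[li])
        planted[[length(planted) + 1L]] <-
          tibble(seq_id = t_id(tg), motif_id = link_motif[li],
                 start = link_pos[li] - 1L, where = "target_tg")
      } else if (eligible[li]) {
        res <- .scrub_motifs(res, tf_cons)
      }
    }
    tgt_ids <- c(tgt_ids, t_id(tg))
    tgt_res <- c(tgt_res, res)
  }
  decoy_ids <- if (p$n_decoy_seqs > 0) {
    sprintf("dec%03d", seq_len(p$n_decoy_seqs))
  } else character(0)
  for (d in decoy_ids) {
    tgt_ids <- c(tgt_ids, d)
    tgt_res <- c(tgt_res, .random_dna(p$seq_len_tg))
  }
  target_seqs <- sequence_table(tgt_ids, tgt_res)

  # promoters for target genes (TG homologs and decoys); conserved-link
  # motifs planted in the promoter of the link's target gene as well
  prom_ids <- c(t_id(cons_tgs), decoy_ids)
  prom_res <- vapply(prom_ids, function(i) .random_dna(p$promoter_len),
                     character(1))
  names(prom_res) <- prom_ids
  for (li in which(conserved)) {
    pid <- t_id(network$tg_id[li])
    cons <- motifs$consensus[motifs$motif_id == link_motif[li]]
    pos <- sample.int(p$promoter_len - p$motif_len + 1L, 1L)
    prom_res[[pid]] <- plant_motif(prom_res[[pid]], cons, pos)
    planted[[length(planted) + 1L]] <-
      tibble(seq_id = pid, motif_id = link_motif[li],
             start = pos - 1L, where = "promoter")
  }
  target_promoters <- sequence_table(prom_ids, unname(prom_res))

  # annotations: conserved TF pairs share family (and usually subfamily)
  fam <- function(tf) paste0("FAM_", tf)
  subfam <- function(tf) paste0("SUB_", tf)
  source_annotations <- tibble(seq_id = tf_ids,
                               family_id = fam(tf_ids),
                               subfamily_id = subfam(tf_ids))
  fam_only <- sample(cons_tfs,
                     round(p$frac_tf_family_only * length(cons_tfs)))
  tgt_tf_ann <- tibble(
    seq_id = t_id(cons_tfs),
    family_id = fam(cons_tfs),
    subfamily_id = ifelse(cons_tfs %in% fam_only,
                          paste0(subfam(cons_tfs), "_alt"),
                          subfam(cons_tfs)))
  n_fam_decoy <- round(p$decoy_family_rate * length(decoy_ids))
  decoy_ann <- if (n_fam_decoy > 0) {
    picked <- sample(decoy_ids, n_fam_decoy)
    tibble(seq_id = picked,
           family_id = fam(sample(tf_ids, n_fam_decoy, replace = TRUE)),
           subfamily_id = paste0("SUB_", picked))
  } else {
    tibble(seq_id = character(), family_id = character(),
           subfamily_id = character())
  }
  target_annotations <- arrange(bind_rows(tgt_tf_ann, decoy_ann),
                                .data$seq_id)

  conserved_links <- tibble(
    source_tf_id = network$tf_id[conserved],
    source_tg_id = network$tg_id[conserved],
    target_tf_id = t_id(network$tf_id[conserved]),
    target_tg_id = t_id(network$tg_id[conserved]),
    sign = network$sign[conserved],
    motif_id = link_motif[conserved])

  expression <- .generate_expression(p, target_seqs$id, conserved_links)

  truth <- list(
    tf_homolog_pairs = tibble(source_id = cons_tfs,
                              target_id = t_id(cons_tfs)),
    tg_homolog_pairs = tibble(source_id = cons_tgs,
                              target_id = t_id(cons_tgs)),
    conserved_links = conserved_links,
    planted_occurrences = if (length(planted) > 0) bind_rows(planted) else
      tibble(seq_id = character(), motif_id = character(),
             start = integer(), where = character()))

  structure(list(source_tf_seqs = source_tf_seqs,
                 source_tg_seqs = source_tg_seqs,
                 target_seqs = target_seqs,
                 target_promoters = target_promoters,
                 motifs = motifs, network = network,
                 source_annotations = source_annotations,
                 target_annotations = target_annotations,
                 expression = expression,
                 truth = truth, params = p),
            class = "reglink_scenario")
}

# ternary expression calls: conserved-link genes follow the requested
# Confirming/Contradictory marginals, everything else is independent
# 50/50, then an absent mask is overlaid per cell
.generate_expression <- function(p, gene_ids, conserved_links) {
  n_exp <- p$n_experiments
  exp_ids <- sprintf("E%02d", seq_len(n_exp))
  calls <- matrix("not_expressed", nrow = length(gene_ids), ncol = n_exp,
                  dimnames = list(gene_ids, exp_ids))
  if (n_exp == 0L) {
    out <- as_tibble(as.data.frame(calls, stringsAsFactors = FALSE))
    return(dplyr::bind_cols(tibble(gene_id = gene_ids), out))
  }
  pc <- p$p_confirm_true
  px <- p$p_contradict_true
  q <- pc + px
  link_tfs <- unique(conserved_links$target_tf_id)
  background <- setdiff(gene_ids, unique(c(conserved_links$target_tg_id,
                                           link_tfs)))
  for (g in background) {
    calls[g, ] <- ifelse(runif(n_exp) < 0.5, "expressed", "not_expressed")
  }
  for (t in link_tfs) {
    calls[t, ] <- ifelse(runif(n_exp) < q, "expressed", "not_expressed")
  }
  for (i in seq_len(nrow(conserved_links))) {
    t <- conserved_links$target_tf_id[i]
    g <- conserved_links$target_tg_id[i]
    tf_on <- calls[t, ] == "expressed"
    if (conserved_links$sign[i] == "positive") {
      tg <- character(n_exp)
      u <- runif(n_exp)
      on_conf <- if (q > 0) pc / q else 0
      tg[tf_on] <- ifelse(u[tf_on] < on_conf, "expressed", "not_expressed")
      tg[!tf_on] <- ifelse(u[!tf_on] < 0.5, "expressed", "not_expressed")
      calls[g, ] <- tg
    } else {
      u <- runif(n_exp)
      tg <- rep("absent", n_exp)
      conf <- u < pc
      contra <- u >= pc & u < pc + px
      tg[conf] <- ifelse(tf_on[conf], "not_expressed", "expressed")
      tg[contra] <- ifelse(tf_on[contra], "expressed", "not_expressed")
      calls[g, ] <- tg
    }
  }
  if (p$p_absent > 0) {
    mask <- matrix(runif(length(calls)) < p$p_absent, nrow = nrow(calls))
    calls[mask] <- "absent"
  }
  out <- as_tibble(as.data.frame(calls, stringsAsFactors = FALSE))
  dplyr::bind_cols(tibble(gene_id = gene_ids), out)
}

#' Write a scenario bundle to a directory
#'
#' Emits `source_tf.fa`, `source_tg.fa`, `target.fa`, `promoters.fa`,
#' `motifs.tsv`, `network.tsv`, `annotations_source.tsv`,
#' `annotations_target.tsv`, `expression.tsv`, `truth_links.tsv` and a
#' `manifest.yaml` recording the generating parameters (including the
#' seed).
#'
#' @param scenario a `reglink_scenario` from [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "reglink_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(scenario$source_tf_seqs, fp("source_tf.fa"))
  write_fasta(scenario$source_tg_seqs, fp("source_tg.fa"))
  write_fasta(scenario$target_seqs, fp("target.fa"))
  write_fasta(scenario$target_promoters, fp("promoters.fa"))
  write_motif_table(scenario$motifs, fp("motifs.tsv"))
  write_network(scenario$network, fp("network.tsv"))
  write_annotations(scenario$source_annotations, fp("annotations_source.tsv"))
  write_annotations(scenario$target_annotations, fp("annotations_target.tsv"))
  write_expression_matrix(scenario$expression, fp("expression.tsv"))
  tl <- scenario$truth$conserved_links
  .write_lines(
    c("#source_tf\tsource_tg\ttarget_tf\ttarget_tg\tsign\tmotif_id",
      if (nrow(tl) > 0) {
        paste(tl$source_tf_id, tl$source_tg_id, tl$target_tf_id,
              tl$target_tg_id, ifelse(tl$sign == "positive", "+", "-"),
              tl$motif_id, sep = "\t")
      }), fp("truth_links.tsv"))
  yaml::write_yaml(unclass(scenario$params), fp("manifest.yaml"))
  files <- c("source_tf.fa", "source_tg.fa", "target.fa", "promoters.fa",
             "motifs.tsv", "network.tsv", "annotations_source.tsv",
             "annotations_target.tsv", "expression.tsv", "truth_links.tsv",
             "manifest.yaml")
  invisible(setNames(file.path(dir, files), files))
}
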