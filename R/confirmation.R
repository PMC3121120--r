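#' @title Expression-based confirmation of predicted links
#' @name expression_confirmation
#' @description Each predicted link is checked against every gene-expression
#'   experiment with a fixed rule table keyed on the regulation sign and the
#'   ternary calls of the TF and the TG. Experiments are counted as
#'   Confirming, Contradictory, Neutral or Ignored, and the counts are
#'   summarised into a weighted "verified" test and a Confirming-to-
#'   Contradictory ratio tier.
NULL

.CLASSES <- c("Confirming", "Contradictory", "Neutral", "Ignored")
.TIERS <- c("strong_3x", "strong_2x", "weak", "unsupported", "no_data")

# rule table: any absent call -> Ignored; otherwise keyed on
# (sign, TF call, TG call)
.RULES <- local({
  r <- c(
    "positive|expressed|expressed"         = "Confirming",
    "positive|expressed|not_expressed"     = "Contradictory",
    "positive|not_expressed|expressed"     = "Neutral",
    "positive|not_expressed|not_expressed" = "Ignored",
    "negative|expressed|expressed"         = "Contradictory",
    "negative|expressed|not_expressed"     = "Confirming",
    "negative|not_expressed|expressed"     = "Confirming",
    "negative|not_expressed|not_expressed" = "Contradictory")
  r
})

#' Classify one expression experiment against a signed link
#'
#' If either call is `absent` the experiment is `Ignored` (nothing can be
#' inferred). Otherwise, for positive regulation: both expressed is
#' `Confirming`; TF expressed without the TG is `Contradictory`; TG
#' expressed without the TF is `Neutral` (another regulator may act);
#' neither expressed is `Ignored`. For negative regulation: equal calls are
#' `Contradictory`, opposite calls `Confirming`. Vectorised; arguments are
#' recycled to a common length.
#'
#' @param sign `"positive"` or `"negative"` (vectorised).
#' @param tf_call,tg_call calls among `"expressed"`, `"not_expressed"`,
#'   `"absent"`.
#' @return Character vector over `Confirming`, `Contradictory`, `Neutral`,
#'   `Ignored`.
#' @examples
#' classify_experiment("positive", "expressed", "expressed") # Confirming
#' classify_experiment("negative", "not_expressed", "expressed") # Confirming
#' @export
classify_experiment <- function(sign, tf_call, tg_call) {
  n <- max(length(sign), length(tf_call), length(tg_call))
  sign <- rep_len(sign, n)
  tf_call <- rep_len(tf_call, n)
  tg_call <- rep_len(tg_call, n)
  if (!all(sign %in% c("positive", "negative"))) {
    abort("classify_experiment: sign must be 'positive' or 'negative'")
  }
  if (!all(tf_call %in% .EXPR_LEVELS) || !all(tg_call %in% .EXPR_LEVELS)) {
    abort("classify_experiment: calls must be expressed/not_expressed/absent")
  }
  out <- rep("Ignored", n)
  ok <- tf_call != "absent" & tg_call != "absent"
  out[ok] <- unname(.RULES[paste(sign[ok], tf_call[ok], tg_call[ok],
                                 sep = "|")])
  out
}

.expr_call_matrix <- function(expr) {
  experiments <- setdiff(names(expr), "gene_id")
  m <- as.matrix(expr[experiments])
  rownames(m) <- expr$gene_id
  m
}

.calls_for <- function(m, ids, n_exp) {
  idx <- match(ids, rownames(m))
  out <- matrix("absent", nrow = length(ids), ncol = n_exp)
  found <- !is.na(idx)
  out[found, ] <- m[idx[found], , drop = FALSE]
  out
}

#' Count Confirming/Contradictory/Neutral/Ignored experiments per link
#'
#' Target TF and TG ids are resolved to expression-matrix gene ids through
#' `id_map` (a named character vector, names = link ids, values = gene
#' ids); unmapped or unmeasured genes behave as absent in every experiment.
#' The four counts always sum to the number of experiments.
#'
#' @param links a predicted-link tibble (needs `target_tf_id`,
#'   `target_tg_id`, `sign`).
#' @param expr an expression tibble (see [read_expression_matrix()]).
#' @param id_map optional named character vector resolving link ids to
#'   expression gene ids (default: identity).
#' @return `links` with integer columns `confirming`, `contradictory`,
#'   `neutral`, `ignored` appended.
#' @export
count_links <- function(links, expr, id_map = NULL) {
  m <- .expr_call_matrix(expr)
  n_exp <- ncol(m)
  resolve <- function(ids) {
    if (is.null(id_map)) return(ids)
    mapped <- unname(id_map[ids])
    ifelse(is.na(mapped), ids, mapped)
  }
  tf_calls <- .calls_for(m, resolve(links$target_tf_id), n_exp)
  tg_calls <- .calls_for(m, resolve(links$target_tg_id), n_exp)
  cls <- matrix(
    classify_experiment(rep(links$sign, times = n_exp),
                        as.vector(tf_calls), as.vector(tg_calls)),
    nrow = nrow(links))
  links$confirming <- as.integer(rowSums(cls == "Confirming"))
  links$contradictory <- as.integer(rowSums(cls == "Contradictory"))
  links$neutral <- as.integer(rowSums(cls == "Neutral"))
  links$ignored <- as.integer(rowSums(cls == "Ignored"))
  links
}

#' Tier configuration for link confirmation
#'
#' The verified test asks whether the Confirming count strictly exceeds a
#' weighted sum of the Contradictory and Neutral counts
#' (`c > w_x * x + w_n * n`, defaults 2 and 1). Independently, links are
#' placed into ratio tiers by comparing the Confirming count with multiples
#' of the Contradictory count (defaults 3 and 2). Boundary conventions are
#' configurable because the published convention is not fully pinned down:
#' `verified_strict` toggles `>` vs `>=` in the verified test, and
#' `tier_lower_inclusive` toggles `>=` vs `>` at the lower bound of each
#' ratio tier.
#'
#' @param contradictory_weight,neutral_weight non-negative integer weights
#'   in the verified threshold.
#' @param ratio_high,ratio_mid Confirming-to-Contradictory multiples for the
#'   top two tiers; `ratio_high > ratio_mid >= 1`.
#' @param verified_strict use strict `>` in the verified test (default).
#' @param tier_lower_inclusive use `>=` at tier lower bounds (default).
#' @return A list of class `tier_config`.
#' @export
tier_config <- function(contradictory_weight = 2, neutral_weight = 1,
                        ratio_high = 3, ratio_mid = 2,
                        verified_strict = TRUE,
                        tier_lower_inclusive = TRUE) {
  if (contradictory_weight < 0 || neutral_weight < 0) {
    abort("tier_config: weights must be >= 0")
  }
  if (!(ratio_high > ratio_mid && ratio_mid >= 1)) {
    abort("tier_config: need ratio_high > ratio_mid >= 1")
  }
  structure(list(contradictory_weight = contradictory_weight,
                 neutral_weight = neutral_weight,
                 ratio_high = ratio_high, ratio_mid = ratio_mid,
                 verified_strict = verified_strict,
                 tier_lower_inclusive = tier_lower_inclusive),
            class = "tier_config")
}

#' Assign the verified flag and ratio tier from per-link counts
#'
#' `no_data` is assigned iff all three informative counts are zero. The
#' remaining links fall into exactly one of `strong_3x`
#' (`c >= ratio_high * x`), `strong_2x` (`ratio_high * x > c >= ratio_mid
#' * x`), `weak` (`ratio_mid * x > c >= x`) or `unsupported` (`x > c`),
#' under the default boundary conventions.
#'
#' @param counts a tibble with columns `confirming`, `contradictory`,
#'   `neutral` (e.g. from [count_links()]).
#' @param config a [tier_config()].
#' @return `counts` with logical `verified` and character `ratio_tier`
#'   columns appended.
#' @export
assign_tier <- function(counts, config = tier_config()) {
  cc <- counts$confirming
  x <- counts$contradictory
  nn <- counts$neutral
  thr <- config$contradictory_weight * x + config$neutral_weight * nn
  verified <- if (config$verified_strict) cc > thr else cc >= thr
  ge <- function(a, b) if (config$tier_lower_inclusive) a >= b else a > b
  tier <- rep("unsupported", length(cc))
  tier[ge(cc, x)] <- "weak"
  tier[ge(cc, config$ratio_mid * x)] <- "strong_2x"
  tier[ge(cc, config$ratio_high * x)] <- "strong_3x"
  tier[cc == 0 & x == 0 & nn == 0] <- "no_data"
  counts$verified <- verified & !(cc == 0 & x == 0 & nn == 0)
  counts$ratio_tier <- tier
  counts
}

#' Confirm predicted links against an expression matrix
#'
#' Runs [count_links()] and [assign_tier()] over a predicted-link table and
#' summarises the tier totals. "Links analyzed" are those with at least one
#' non-ignored experiment (`ratio_tier != "no_data"`); the four ratio tiers
#' partition the analyzed links.
#'
#' @inheritParams count_links
#' @param config a [tier_config()].
#' @return An object of class `link_confirmation`: a list with `links`
#'   (per-link counts, verified flag and tier), `summary` (one-row tibble of
#'   totals) and `config`.
#' @export
confirm_links <- function(links, expr, config = tier_config(),
                          id_map = NULL) {
  counted <- count_links(links, expr, id_map = id_map)
  counted <- assign_tier(counted, config = config)
  analyzed <- counted$ratio_tier != "no_data"
  summary <- tibble(
    n_links = nrow(counted),
    n_analyzed = sum(analyzed),
    n_verified = sum(counted$verified),
    strong_3x = sum(counted$ratio_tier == "strong_3x"),
    strong_2x = sum(counted$ratio_tier == "strong_2x"),
    weak = sum(counted$ratio_tier == "weak"),
    unsupported = sum(counted$ratio_tier == "unsupported"),
    no_data = sum(counted$ratio_tier == "no_data"))
  structure(list(links = counted, summary = summary, config = config),
            class = "link_confirmation")
}

#' @export
print.link_confirmation <- function(x, ...) {
  s <- x$summary
  cat("<link confirmation>\n")
  cat(sprintf("  links: %d, analyzed: %d, verified: %d\n",
              s$n_links, s$n_analyzed, s$n_verified))
  cat(sprintf("  tiers: strong_3x %d | strong_2x %d | weak %d | unsupported %d | no_data %d\n",
              s$strong_3x, s$strong_2x, s$weak, s$unsupported, s$no_data))
  invisible(x)
}

#' @rdname confirm_links
#' @param x a `link_confirmation` object.
#' @param ... unused.
#' @export
tidy.link_confirmation <- function(x, ...) as_tibble(x$links)

#' @rdname confirm_links
#' @export
glance.link_confirmation <- function(x, ...) x$summary

#' Write a link-confirmation report to TSV
#'
#' Per-link rows followed by a `#` summary block of tier totals.
#'
#' @param report a `link_confirmation` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confirmation <- function(report, path) {
  lk <- arrange(report$links, .data$target_tf_id, .data$target_tg_id,
                .data$sign)
  body <- vapply(seq_len(nrow(lk)), function(i) {
    paste(lk$source_tf_id[i], lk$source_tg_id[i], lk$target_tf_id[i],
          lk$target_tg_id[i], ifelse(lk$sign[i] == "positive", "+", "-"),
          lk$confirming[i], lk$contradictory[i], lk$neutral[i],
          lk$ignored[i], tolower(lk$verified[i]), lk$ratio_tier[i],
          sep = "\t")
  }, character(1))
  s <- report$summary
  .write_lines(c(
    "#source_tf\tsource_tg\ttarget_tf\ttarget_tg\tsign\tconfirming\tcontradictory\tneutral\tignored\tverified\tratio_tier",
    body,
    sprintf("# n_links=%d n_analyzed=%d n_verified=%d strong_3x=%d strong_2x=%d weak=%d unsupported=%d no_data=%d",
            s$n_links, s$n_analyzed, s$n_verified, s$strong_3x, s$strong_2x,
            s$weak, s$unsupported, s$no_data)), path)
}
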