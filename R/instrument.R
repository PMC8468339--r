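RESPONSE_LEVELS <- c("hit", "error", "dontknow")

item_cols <- function(n_items = 20L) paste0("Q", seq_len(n_items))

#' Questionnaire response table
#'
#' Tidy container for a pre/post two-group multiple-choice study: one row
#' per (participant, phase) with 20 item responses, each `"hit"`, `"error"`
#' or `"dontknow"` (the questionnaire offers an explicit "I do not know"
#' option to discourage guessing).
#'
#' @param participant character ids.
#' @param phase `"pre"` or `"post"`.
#' @param group `"control"` or `"experimental"`.
#' @param items data.frame or matrix of 20 response columns with values in
#'   `hit` / `error` / `dontknow`.
#' @return a `response_table` (also a data.frame with 23 columns).
#' @export
response_table <- function(participant, phase, group, items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (ncol(items) != 20L)
    abort_invalid(sprintf("expected 20 item columns, got %d", ncol(items)),
                  class = "mrisim_format_error")
  phase <- match_tokens(phase, c(pre = "pre", "pre-test" = "pre",
                                 post = "post", "post-test" = "post",
                                 "post-tets" = "post"), "phase")
  group <- match_tokens(group, c(control = "control", cg = "control",
                                 c = "control", experimental = "experimental",
                                 eg = "experimental", x = "experimental"),
                        "group")
  bad <- !unlist(items) %in% RESPONSE_LEVELS
  if (any(bad)) {
    w <- which(matrix(bad, nrow(items)), arr.ind = TRUE)[1, ]
    abort_invalid(sprintf("unknown response token '%s' at row %d, item %d",
                          items[w[1], w[2]], w[1], w[2]),
                  class = "mrisim_parse_error")
  }
  df <- data.frame(participant = as.character(participant), phase = phase,
                   group = group, items, stringsAsFactors = FALSE)
  names(df) <- c("participant", "phase", "group", item_cols())
  if (anyDuplicated(df[c("participant", "phase")]))
    abort_invalid("each (participant, phase) pair may appear at most once")
  class(df) <- c("response_table", "data.frame")
  df
}

match_tokens <- function(x, map, what) {
  key <- tolower(as.character(x))
  if (any(!key %in% names(map)))
    abort_invalid(sprintf("unknown %s value '%s'", what,
                          key[!key %in% names(map)][1]),
                  class = "mrisim_parse_error")
  unname(map[key])
}

#' Define an instrument part (item subset)
#'
#' The 20-item instrument splits into a theory part (items 1-10, first
#' lecture) and a practical part (items 11-20, second lecture); reliability
#' analysis may reduce each to a subset.
#'
#' @param name part label, conventionally `"T"` or `"P"`.
#' @param items 1-based item indices within 1..20.
#' @return a `part_def`.
#' @export
#' @examples
#' part_def("T", c(4, 5, 6, 8, 10))
part_def <- function(name, items) {
  items <- as.integer(items)
  if (!length(items) || any(items < 1L) || any(items > 20L) ||
      anyDuplicated(items))
    abort_invalid("items must be distinct indices in 1..20")
  structure(list(name = name, items = items), class = "part_def")
}

#' @export
print.part_def <- function(x, ...) {
  cat(sprintf("part_def '%s': items {%s}\n", x$name,
              paste(x$items, collapse = ", ")))
  invisible(x)
}

resp_matrix <- function(responses, part) {
  stopifnot(inherits(responses, "response_table"))
  as.matrix(responses[, item_cols()[part$items], drop = FALSE])
}

#' Hits rating: number of correct answers
#'
#' @param responses a `response_table`.
#' @param part a [part_def()]; defaults to all 20 items.
#' @return integer score per row, in `[0, length(part$items)]`.
#' @export
score_hits <- function(responses, part = part_def("all", 1:20)) {
  rowSums(resp_matrix(responses, part) == "hit")
}

#' Null-expectation rating: +1 hit, -1/3 error, 0 "I do not know"
#'
#' With four answer options per item, uniformly random guessing earns
#' `1/4 - 3/4 * 1/3 = 0` in expectation, so this rating removes the
#' incentive to guess.
#'
#' @inheritParams score_hits
#' @return numeric score per row.
#' @export
score_null_expectation <- function(responses, part = part_def("all", 1:20)) {
  m <- resp_matrix(responses, part)
  rowSums((m == "hit") - (m == "error") / 3)
}

#' Score a response table under either rating
#'
#' Convenience wrapper returning participant/phase/group plus the score.
#'
#' @inheritParams score_hits
#' @param rating `"hits"` or `"ne"` (null expectation).
#' @return data.frame with columns participant, phase, group, score.
#' @export
score_table <- function(responses, part = part_def("all", 1:20),
                        rating = c("hits", "ne")) {
  rating <- match.arg(rating)
  data.frame(responses[c("participant", "phase", "group")],
             score = if (rating == "hits") score_hits(responses, part)
                     else score_null_expectation(responses, part),
             stringsAsFactors = FALSE)
}

check_item_matrix <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (ncol(m) < 2L || nrow(m) < 2L)
    abort_invalid("need at least 2 items and 2 participants")
  m
}

#' Kuder-Richardson 20 reliability for binary item scores
#'
#' `KR-20 = k/(k-1) * (1 - sum(p_i * q_i) / var(X))`, with `p_i` the item
#' proportion correct (divisor `n`), `q_i = 1 - p_i`, and `var(X)` the
#' unbiased (`n - 1`) variance of the total scores.
#'
#' @param m participants x items matrix of 0/1 scores.
#' @return reliability coefficient (at most 1; may be negative).
#' @export
#' @examples
#' kr20(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0)))
kr20 <- function(m) {
  m <- check_item_matrix(m)
  if (!all(m %in% c(0, 1)))
    abort_invalid("KR-20 requires binary (0/1) item scores")
  k <- ncol(m)
  p <- colMeans(m)
  vtot <- stats::var(rowSums(m))
  if (vtot <= 0)
    abort_invalid("total-score variance is zero; reliability undefined",
                  class = "mrisim_reliability_error")
  (k / (k - 1)) * (1 - sum(p * (1 - p)) / vtot)
}

#' Cronbach's alpha for numeric item scores
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(X))` with unbiased variances
#' throughout. On a binary matrix, alpha and [kr20()] differ only through
#' the item-variance convention (`n - 1` here versus `n` in the classical
#' KR-20 `p*q` term).
#'
#' @param m participants x items numeric matrix.
#' @return reliability coefficient.
#' @export
cronbach_alpha <- function(m) {
  m <- check_item_matrix(m)
  k <- ncol(m)
  vtot <- stats::var(rowSums(m))
  if (vtot <= 0)
    abort_invalid("total-score variance is zero; reliability undefined",
                  class = "mrisim_reliability_error")
  (k / (k - 1)) * (1 - sum(apply(m, 2, stats::var)) / vtot)
}

corrected_item_total <- function(m, j) {
  total_rest <- rowSums(m[, -j, drop = FALSE])
  if (stats::sd(m[, j]) == 0 || stats::sd(total_rest) == 0) return(-Inf)
  stats::cor(m[, j], total_rest)
}

#' Greedy item-subset selection maximizing KR-20
#'
#' Backward elimination: repeatedly drop the item whose removal maximizes
#' the KR-20 of the remaining items until `target_size` remain. Ties are
#' broken by dropping the item with the lowest corrected item-total
#' correlation, then by the lowest item index, so the procedure is fully
#' deterministic.
#'
#' @param responses a `response_table` (typically filtered to the post-test
#'   phase) or a binary participants x items matrix whose columns are
#'   `part$items` in order.
#' @param part a [part_def()] naming the candidate items.
#' @param target_size number of items to retain.
#' @return a [part_def()] of the selected items (original item numbering).
#' @export
select_items <- function(responses, part, target_size) {
  if (inherits(responses, "response_table"))
    m <- (resp_matrix(responses, part) == "hit") * 1
  else m <- check_item_matrix(responses)
  if (ncol(m) != length(part$items))
    abort_invalid("matrix columns must match part$items")
  if (target_size > length(part$items))
    abort_invalid("target_size exceeds the part size")
  keep <- seq_along(part$items)
  while (length(keep) > target_size) {
    rel <- vapply(seq_along(keep), function(d)
      tryCatch(kr20(m[, keep[-d], drop = FALSE]), error = function(e) -Inf),
      0)
    best <- max(rel)
    cand <- which(rel >= best - 1e-12)
    if (length(cand) > 1L) {
      itc <- vapply(cand, function(d) corrected_item_total(
        m[, keep, drop = FALSE], d), 0)
      cand <- cand[itc <= min(itc) + 1e-12]
    }
    keep <- keep[-cand[1]]
  }
  part_def(part$name, part$items[keep])
}

#' Per-participant learning gain (post minus pre)
#'
#' @param post_scores,pre_scores numeric vectors named by participant id
#'   (e.g. built from [score_table()]).
#' @return named numeric vector of gains for the matched participants;
#'   unmatched participants are dropped with a message stating how many.
#' @export
gain <- function(post_scores, pre_scores) {
  common <- intersect(names(post_scores), names(pre_scores))
  if (!length(common))
    abort_invalid("no participants common to pre and post scores")
  dropped <- length(post_scores) + length(pre_scores) - 2 * length(common)
  if (dropped > 0)
    message(sprintf("gain: excluded %d unmatched participant record(s)", dropped))
  post_scores[common] - pre_scores[common]
}

#' Cohen's d from group summary statistics (pooled SD)
#'
#' `d = (m1 - m2) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' With equal group sizes the pooled SD reduces to
#' `sqrt((s1^2 + s2^2)/2)`.
#'
#' @param m1,s1,n1 mean, SD (unbiased) and size of the first group.
#' @param m2,s2,n2 same for the second group.
#' @return the standardized mean difference.
#' @export
#' @examples
#' cohen_d_from_stats(2.53, 1.36, 30, 1.63, 1.27, 30)
cohen_d_from_stats <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Cohen's d from two samples
#'
#' @param x,y numeric score vectors (first group minus second).
#' @return pooled-SD standardized mean difference.
#' @export
cohen_d <- function(x, y) {
  cohen_d_from_stats(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y))
}

shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0)  # degenerate sample: clearly non-normal
  stats::shapiro.test(x)$p.value
}

#' Two-group comparison with a normality-gated test
#'
#' Runs a Shapiro-Wilk normality test on each group; if both pass at
#' `alpha`, the groups are compared with a two-sided unpaired pooled-
#' variance t-test, otherwise with the two-sided unpaired rank-sum
#' (Mann-Whitney) test. Descriptives (median, mean, unbiased SD) and
#' Cohen's d with pooled SD are always reported.
#'
#' @param eg_scores,cg_scores numeric scores of the experimental / control
#'   group (each `n >= 3`).
#' @param alpha level used for the normality gate.
#' @return a `group_comparison`: `test_used` (`"t"` or `"rank"`), `p_value`,
#'   per-group `median`, `mean`, `sd`, `n`, `normality_p`, and
#'   `effect_size_d`.
#' @export
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(30, 1), rnorm(30, 0))
compare_groups <- function(eg_scores, cg_scores, alpha = 0.05) {
  if (length(eg_scores) < 3L || length(cg_scores) < 3L)
    abort_invalid("each group needs at least 3 observations")
  norm_p <- c(eg = shapiro_p(eg_scores), cg = shapiro_p(cg_scores))
  normal <- all(norm_p > alpha)
  test <- if (normal)
    stats::t.test(eg_scores, cg_scores, var.equal = TRUE)
  else suppressWarnings(stats::wilcox.test(eg_scores, cg_scores, exact = FALSE,
                                           correct = TRUE))
  structure(list(
    test_used = if (normal) "t" else "rank",
    p_value = unname(test$p.value),
    median = c(eg = stats::median(eg_scores), cg = stats::median(cg_scores)),
    mean = c(eg = mean(eg_scores), cg = mean(cg_scores)),
    sd = c(eg = stats::sd(eg_scores), cg = stats::sd(cg_scores)),
    n = c(eg = length(eg_scores), cg = length(cg_scores)),
    normality_p = norm_p,
    effect_size_d = cohen_d(eg_scores, cg_scores),
    alpha = alpha), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s test): p = %.3g\n", x$test_used, x$p_value))
  cat(sprintf("  EG: Med %.2f, Mean %.2f +/- %.2f (n = %d)\n",
              x$median["eg"], x$mean["eg"], x$sd["eg"], x$n["eg"]))
  cat(sprintf("  CG: Med %.2f, Mean %.2f +/- %.2f (n = %d)\n",
              x$median["cg"], x$mean["cg"], x$sd["cg"], x$n["cg"]))
  cat(sprintf("  Cohen's d = %.3f\n", x$effect_size_d))
  invisible(x)
}
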