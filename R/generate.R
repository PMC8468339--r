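# Gauss-grid moments of the hits score under the logistic response model:
# ability a ~ N(0,1) (optionally shifted by delta), item j answered with
# probability (1 - dontknow) and then correct with probability
# plogis(a - b_j). Returns mean and variance of the score over `items`.
score_moments <- function(delta, difficulties, items, dontknow) {
  a <- seq(-8, 8, length.out = 401)
  w <- stats::dnorm(a); w <- w / sum(w)
  q <- sapply(difficulties[items],
              function(b) (1 - dontknow) * stats::plogis(a + delta - b))
  qs <- rowSums(q)                       # E[S | a]
  m <- sum(w * qs)
  v_within <- sum(w * rowSums(q * (1 - q)))
  v_between <- sum(w * (qs - m)^2)
  list(mean = m, var = v_within + v_between)
}

# latent ability shift that produces a target Cohen's d on the hits score
# over `items` (shifted group vs unshifted group, pooled SD)
solve_ability_shift <- function(target_d, difficulties, items, dontknow) {
  if (target_d == 0) return(0)
  base <- score_moments(0, difficulties, items, dontknow)
  d_of <- function(delta) {
    m <- score_moments(delta, difficulties, items, dontknow)
    (m$mean - base$mean) / sqrt((m$var + base$var) / 2) - target_d
  }
  stats::uniroot(d_of, interval = sort(c(0, sign(target_d) * 8)),
                 tol = 1e-8)$root
}

#' Generate a synthetic questionnaire response table
#'
#' Emulates the deposited study layout: two groups (control/experimental),
#' two phases (pre/post), 20 items with responses in hit / error /
#' "I do not know". Each participant has a latent ability drawn from a
#' standard normal that persists across phases; each item is skipped
#' ("dontknow") with the configured propensity and otherwise answered
#' correctly with probability `plogis(ability - difficulty)`. In the
#' experimental group's post-test the ability is raised by a latent shift
#' calibrated (by quadrature on the response model) so that the Cohen's d
#' of the hits score over `effect_items` equals `effect_d` in expectation.
#'
#' @param n_per_group participants per group.
#' @param difficulties length-20 vector of item difficulties on the logit
#'   scale. The default, an increasing grid centred near +1 logit, keeps
#'   pre-test scores low (about 1 of 5 items correct), as expected of
#'   novices facing an expert-written instrument.
#' @param effect_d target Cohen's d of the experimental-vs-control post-test
#'   hits score over `effect_items` (0 = null).
#' @param effect_items items over which `effect_d` is calibrated.
#' @param dontknow propensity to answer "I do not know", in \[0, 1\].
#' @param seed integer seed; the table is deterministic given it.
#' @return a `response_table` with `4 * n_per_group` rows.
#' @export
generate_responses <- function(n_per_group = 30L,
                               difficulties = seq(0.6, 1.4, length.out = 20),
                               effect_d = 0, effect_items = 11:20,
                               dontknow = 0.35, seed = 1L) {
  if (length(difficulties) != 20L)
    abort_invalid("difficulties must have length 20")
  stopifnot_scalar(dontknow, "dontknow", 0, 1)
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) abort_invalid("n_per_group must be >= 1")
  delta <- solve_ability_shift(effect_d, difficulties, effect_items, dontknow)
  set.seed(derive_seed(seed, "responses"))
  groups <- rep(c("experimental", "control"), each = n_per_group)
  ids <- sprintf("%s%03d", rep(c("E", "C"), each = n_per_group),
                 c(seq_len(n_per_group), seq_len(n_per_group)))
  ability <- stats::rnorm(2 * n_per_group)
  rows <- list()
  for (phase in c("pre", "post")) {
    shift <- ifelse(groups == "experimental" & phase == "post", delta, 0)
    p_hit <- stats::plogis(outer(ability + shift, difficulties, `-`))
    u_dk <- matrix(stats::runif(2 * n_per_group * 20), ncol = 20)
    u_hit <- matrix(stats::runif(2 * n_per_group * 20), ncol = 20)
    resp <- ifelse(u_dk < dontknow, "dontknow",
                   ifelse(u_hit < p_hit, "hit", "error"))
    rows[[phase]] <- data.frame(participant = ids, phase = phase,
                                group = groups, resp,
                                stringsAsFactors = FALSE)
  }
  df <- rbind(rows$pre, rows$post)
  response_table(df$participant, df$phase, df$group, df[, -(1:3)])
}
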