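#' Planted association-rule specification
#'
#' A generative description of one antecedent-to-consequent dependency: the
#' antecedent block `lhs` is jointly true with probability `p_lhs`, and the
#' consequent `rhs` is drawn Bernoulli with probability `conf_true` when the
#' whole antecedent is true and `conf_false` otherwise. The mined support,
#' confidence and lift of the planted rule then have exact closed forms
#' ([expected_metrics()]), which is what makes recovery tests possible.
#'
#' @param lhs character vector of antecedent item names (nonempty).
#' @param rhs single consequent item name, not in `lhs`.
#' @param p_lhs probability in `[0, 1]` that all antecedent items co-occur.
#' @param conf_true `P(rhs | all lhs true)`.
#' @param conf_false `P(rhs | not all lhs true)`.
#' @return An object of class `planted_rule`.
#' @export
planted_rule <- function(lhs, rhs, p_lhs, conf_true, conf_false) {
  lhs <- as.character(lhs)
  rhs <- as.character(rhs)
  if (!length(lhs)) stop("planted rule needs a nonempty lhs")
  if (length(rhs) != 1) stop("planted rule rhs must be a single item")
  if (rhs %in% lhs) stop("rhs must not appear in lhs")
  if (anyDuplicated(lhs)) stop("duplicate lhs items")
  for (p in c(p_lhs, conf_true, conf_false)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop("probabilities must be single numbers in [0, 1]")
    }
  }
  structure(list(lhs = lhs, rhs = rhs, p_lhs = p_lhs,
                 conf_true = conf_true, conf_false = conf_false),
            class = "planted_rule")
}

#' Generator configuration for synthetic transaction tables
#'
#' @param n_records number of records to draw.
#' @param background_items named numeric vector: item name to Bernoulli
#'   probability, drawn independently per record. May also supply off-block
#'   marginals for planted antecedent items (when it does not, those default
#'   to the spec's `p_lhs`).
#' @param planted list of [planted_rule()] specs. Consequent items must be
#'   distinct across specs and must not appear in `background_items` or in any
#'   antecedent (so each planted conditional stays an exact closed form).
#' @param seed integer RNG seed; the same seed yields a bit-identical table.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_records, background_items = numeric(),
                             planted = list(), seed = 1L) {
  stopifnot(is.numeric(n_records), length(n_records) == 1, n_records >= 1)
  if (length(background_items)) {
    if (is.null(names(background_items)) || any(!nzchar(names(background_items)))) {
      stop("background_items must be a named probability vector")
    }
    if (anyDuplicated(names(background_items))) stop("duplicate background items")
    if (any(background_items < 0 | background_items > 1)) {
      stop("invalid probability in background_items")
    }
  }
  if (inherits(planted, "planted_rule")) planted <- list(planted)
  stopifnot(all(vapply(planted, inherits, TRUE, "planted_rule")))
  rhs_all <- vapply(planted, `[[`, "", "rhs")
  if (anyDuplicated(rhs_all)) {
    stop("planted specs sharing an RHS item are rejected")
  }
  lhs_all <- unlist(lapply(planted, `[[`, "lhs"))
  if (any(rhs_all %in% c(names(background_items), lhs_all))) {
    stop("planted RHS items must not appear in background items or any LHS")
  }
  structure(list(n_records = as.integer(n_records),
                 background_items = background_items,
                 planted = planted, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate independent Bernoulli transactions
#'
#' The null model for lift: every cell is an independent Bernoulli draw with
#' its item's probability, so every pair of itemsets is independent and all
#' population lifts equal 1.
#'
#' @param config a [generator_config()] with no planted rules.
#' @return A [transaction_table()].
#' @export
generate_independent <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (length(config$planted)) {
    stop("config has planted rules; use generate_with_planted_rules()")
  }
  p <- config$background_items
  if (!length(p)) stop("no background items to generate")
  set.seed(config$seed)
  n <- config$n_records
  m <- vapply(p, function(pi) stats::runif(n) < pi, logical(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(p)))
  transaction_table(m, provenance = sprintf("synthetic independent, seed %d",
                                            config$seed))
}

# Draw the antecedent block of one planted spec for n records.
# block: all-true with prob p_lhs; otherwise items are independent background
# draws rejection-sampled away from the all-true cell, so that
# P(all lhs true) = p_lhs exactly and the closed-form metrics are exact.
draw_lhs_block <- function(n, spec, background) {
  k <- length(spec$lhs)
  p_item <- vapply(spec$lhs, function(it) {
    if (it %in% names(background)) background[[it]] else spec$p_lhs
  }, 0)
  block <- stats::runif(n) < spec$p_lhs
  m <- matrix(TRUE, n, k, dimnames = list(NULL, spec$lhs))
  off <- which(!block)
  while (length(off)) {
    draw <- vapply(p_item, function(pi) stats::runif(length(off)) < pi,
                   logical(length(off)))
    if (length(off) == 1) draw <- matrix(draw, nrow = 1)
    m[off, ] <- draw
    off <- off[rowSums(draw) == k]  # redraw records that hit all-true by chance
    if (all(p_item == 1)) break     # degenerate: all-true is the only outcome
  }
  list(matrix = m, block = block)
}

#' Generate transactions with planted antecedent-consequent dependencies
#'
#' Background items are independent Bernoulli draws. For each planted spec the
#' antecedent block is jointly true with probability `p_lhs` (individual
#' antecedent items are otherwise drawn from their background marginals), and
#' the consequent is drawn with probability `conf_true` or `conf_false`
#' conditional on the block.
#'
#' @param config a [generator_config()].
#' @return A [transaction_table()].
#' @seealso [expected_metrics()] for the closed-form support/confidence/lift
#'   a planted spec induces.
#' @export
generate_with_planted_rules <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_records
  bg <- config$background_items
  planted_lhs <- unique(unlist(lapply(config$planted, `[[`, "lhs")))

  pure_bg <- bg[setdiff(names(bg), planted_lhs)]
  parts <- list()
  if (length(pure_bg)) {
    m <- vapply(pure_bg, function(pi) stats::runif(n) < pi, logical(n))
    if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(pure_bg)))
    parts$background <- m
  }
  for (spec in config$planted) {
    drawn <- draw_lhs_block(n, spec, bg)
    p_y <- ifelse(drawn$block, spec$conf_true, spec$conf_false)
    y <- stats::runif(n) < p_y
    block_m <- cbind(drawn$matrix, y)
    colnames(block_m) <- c(spec$lhs, spec$rhs)
    # an antecedent item may already exist (shared across specs): AND of roles
    # is not defined, so shared antecedents across specs are rejected upfront
    parts[[length(parts) + 1L]] <- block_m
  }
  all_names <- unlist(lapply(parts, colnames))
  if (anyDuplicated(all_names)) {
    stop("planted specs share antecedent items; use disjoint item sets")
  }
  transaction_table(do.call(cbind, parts),
                    provenance = sprintf("synthetic planted, seed %d",
                                         config$seed))
}

#' Closed-form metrics of a planted rule
#'
#' For a spec with antecedent-block probability `p`, `conf_true = c1` and
#' `conf_false = c0`:
#' support `= p * c1`, confidence `= c1`,
#' `P(Y) = c1 * p + c0 * (1 - p)`, lift `= c1 / P(Y)`.
#'
#' @param spec a [planted_rule()].
#' @return Named numeric vector `c(support, confidence, lift)`. The lift is
#'   `NaN` only in the degenerate case `P(Y) = 0`.
#' @examples
#' expected_metrics(planted_rule("A", "Y", 0.3, 0.8, 0.2))
#' # support 0.24, confidence 0.8, lift 0.8 / 0.38 = 2.105...
#' @export
expected_metrics <- function(spec) {
  stopifnot(inherits(spec, "planted_rule"))
  p_y <- spec$conf_true * spec$p_lhs + spec$conf_false * (1 - spec$p_lhs)
  c(support = spec$p_lhs * spec$conf_true,
    confidence = spec$conf_true,
    lift = spec$conf_true / p_y)
}
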