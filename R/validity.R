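# Internal-validity audits: dominated-warm-up failures, straight-lining,
# screen-position distribution, and attribute dominance.

#' Dominated warm-up task check
#'
#' A respondent fails the internal-validity check when they chose the
#' dominated alternative in at least one warm-up task; missing warm-up
#' answers make the respondent not assessable.
#'
#' @param warmups list of warm-up tasks from [make_warmups()] (each carries
#'   its `dominated` index).
#' @param responses n x n_warmups matrix of chosen alternatives (`NA` for
#'   missing), e.g. the `warmup` element of a `respondent_choices`.
#' @return data frame: respondent, n_failed, pass (`NA` when not assessable).
#' @export
check_dominated <- function(warmups, responses) {
  responses <- as.matrix(responses)
  if (length(warmups) != ncol(responses)) {
    stop("number of warm-up tasks and response columns disagree")
  }
  dom <- vapply(warmups, `[[`, integer(1L), "dominated")
  failed <- sweep(responses, 2L, dom, `==`)
  n_failed <- rowSums(failed, na.rm = TRUE)
  assessable <- rowSums(!is.na(responses)) == length(warmups)
  data.frame(
    respondent = seq_len(nrow(responses)),
    n_failed = n_failed,
    pass = ifelse(assessable, n_failed == 0L, NA)
  )
}

#' Screen-position profile and straight-lining flags
#'
#' Counts how often each respondent chose each screen position (leftmost,
#' middle, ..., rightmost) across main tasks and flags respondents whose
#' favourite position exceeds `threshold` of tasks ("straight-lining").
#'
#' @param choices a `respondent_choices` object.
#' @param threshold straight-line share threshold (default 9/13: more than 9
#'   of 13 tasks on one position).
#' @return list: `counts` (n x n_alts matrix), `flag` (logical),
#'   `position_shares` (cohort shares over positions, sums to 1),
#'   `n_flagged`.
#' @export
position_profile <- function(choices, threshold = 9 / 13) {
  stopifnot(inherits(choices, "respondent_choices"))
  nt <- ncol(choices$main)
  counts <- t(apply(choices$main, 1L, tabulate, nbins = choices$n_alts))
  flag <- apply(counts, 1L, max) / nt > threshold
  list(counts = counts, flag = flag,
       position_shares = colSums(counts) / sum(counts),
       n_flagged = sum(flag), threshold = threshold)
}

# Exact P(max position count >= k) for a uniform random chooser over
# n_tasks tasks and n_alts positions, by enumeration of count vectors.
straightline_probability <- function(n_tasks, n_alts = 3L, k) {
  counts <- expand.grid(rep(list(0:n_tasks), n_alts - 1L))
  tot <- rowSums(counts)
  counts <- counts[tot <= n_tasks, , drop = FALSE]
  last <- n_tasks - rowSums(counts)
  cc <- cbind(as.matrix(counts), last)
  keep <- apply(cc, 1L, max) >= k
  sum(apply(cc[keep, , drop = FALSE], 1L, function(v) {
    stats::dmultinom(v, prob = rep(1 / n_alts, n_alts))
  }))
}

#' Attribute-dominance detection
#'
#' A respondent is dominant on an ordered attribute when, in every main task,
#' the chosen alternative attains the best level of that attribute available
#' in the task (shared-best levels count as attaining it). Dominance is only
#' evaluated for ordered attributes: an attribute with no preference
#' direction has no "best" level.
#'
#' @param choices a `respondent_choices` object.
#' @param design the `choice_design` answered.
#' @param schema the [attribute_schema()].
#' @return list: `dominant` (n x n_ordered_attributes logical matrix),
#'   `per_attribute` (cohort counts), `n_dominant` (respondents dominant on
#'   at least one attribute).
#' @export
attribute_dominance <- function(choices, design, schema) {
  stopifnot(inherits(choices, "respondent_choices"))
  ord <- ordered_attributes(schema)
  if (length(ord) == 0L) stop("schema declares no ordered attributes")
  n <- nrow(choices$main); nt <- ncol(choices$main)
  attr_idx <- match(ord, names(schema$attributes))
  prefs <- lapply(schema$attributes[ord], level_preference)

  dominant <- matrix(TRUE, n, length(ord), dimnames = list(NULL, ord))
  for (i in seq_len(n)) {
    v <- choices$version[i]
    for (t in seq_len(nt)) {
      ch <- choices$main[i, t]
      for (m in seq_along(ord)) {
        if (!dominant[i, m]) next
        lv <- design$cells[v, t, , attr_idx[m]]
        r <- prefs[[m]][lv]
        if (r[ch] < max(r)) dominant[i, m] <- FALSE
      }
    }
  }
  list(dominant = dominant,
       per_attribute = colSums(dominant),
       n_dominant = sum(rowSums(dominant) > 0L))
}

#' Full internal-validity report
#'
#' Bundles the dominated-warm-up check, screen-position profile with
#' straight-lining flags, and attribute-dominance detection into one
#' cohort-level report.
#'
#' @param choices a `respondent_choices` object (warm-up answers, if any,
#'   are taken from it).
#' @param design the `choice_design` (its `warmups` are used).
#' @param schema the [attribute_schema()].
#' @param straightline_threshold passed to [position_profile()].
#' @return object of class `validity_report`.
#' @export
validity_report <- function(choices, design, schema,
                            straightline_threshold = 9 / 13) {
  pos <- position_profile(choices, straightline_threshold)
  dom <- attribute_dominance(choices, design, schema)
  warm <- NULL
  if (length(design$warmups) > 0L && !is.null(choices$warmup)) {
    warm <- check_dominated(design$warmups, choices$warmup)
  }
  structure(list(
    warmup = warm,
    warmup_failure_rate = if (!is.null(warm)) mean(!warm$pass, na.rm = TRUE),
    position = pos,
    dominance = dom
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Internal-validity report\n")
  if (!is.null(x$warmup)) {
    cat(sprintf("  dominated warm-up failure rate: %.1f%%\n",
                100 * x$warmup_failure_rate))
  }
  cat(sprintf("  position shares (left..right): %s\n",
              paste(sprintf("%.0f%%", 100 * x$position$position_shares),
                    collapse = " / ")))
  cat(sprintf("  straight-liners flagged: %d\n", x$position$n_flagged))
  cat(sprintf("  attribute-dominant respondents: %d (%s)\n",
              x$dominance$n_dominant,
              paste(names(x$dominance$per_attribute),
                    x$dominance$per_attribute, sep = "=", collapse = ", ")))
  invisible(x)
}
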