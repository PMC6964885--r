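# All cohort-level reporting quantities are computed on population-mean (mu)
# draws; per-respondent variants pool individual draws instead.

# Level-utility matrix for a set of mu draws: draws x total levels, plus the
# attribute/level labels. Linear attributes are evaluated at their design
# levels around the center.
level_utility_draws <- function(draws, schema, coding) {
  labs_attr <- character(0L); labs_lvl <- character(0L)
  cols <- list()
  for (a in schema$attributes) {
    L <- length(a$levels)
    labs_attr <- c(labs_attr, rep(a$name, L))
    labs_lvl <- c(labs_lvl, as.character(a$levels))
    idx <- coding$columns[[a$name]]$idx
    m <- switch(a$kind,
      linear = outer(drop(draws[, idx]), a$levels - a$center),
      binary = cbind(draws[, idx], -draws[, idx]),
      categorical = cbind(draws[, idx, drop = FALSE],
                          -rowSums(draws[, idx, drop = FALSE]))
    )
    cols[[a$name]] <- m
  }
  list(u = do.call(cbind, cols), attribute = labs_attr, level = labs_lvl)
}

#' Scale posterior utilities to the -10..+10 reporting range
#'
#' For every posterior draw of the population mean, the zero-centred level
#' utilities of all attributes are rescaled so the largest absolute level
#' utility in that draw equals 10 (+10 = strong preference, -10 = strong
#' aversion); medians and equal-tailed 95% credible intervals are then taken
#' across draws. Scaling per draw keeps the reported extreme at exactly 10
#' whenever one level dominates throughout the posterior, and is a monotone
#' transform, so the within-attribute level ordering is preserved.
#'
#' @param posterior an `hb_posterior`.
#' @param schema,coding schema and [coding_map()].
#' @return object of class `scaled_utilities`: data frame `table`
#'   (attribute, level, median, lo, hi), the per-draw scaling `factors`, and
#'   a `degenerate` flag for all-zero draws.
#' @export
scale_utilities <- function(posterior, schema, coding) {
  draws <- mu_draws(posterior)
  lu <- level_utility_draws(draws, schema, coding)
  maxabs <- apply(abs(lu$u), 1L, max)
  degenerate <- maxabs == 0
  factors <- ifelse(degenerate, NA_real_, 10 / maxabs)
  su <- lu$u * factors
  qs <- apply(su, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              na.rm = TRUE)
  out <- data.frame(attribute = lu$attribute, level = lu$level,
                    median = qs[1L, ], lo = qs[2L, ], hi = qs[3L, ],
                    row.names = NULL)
  if (any(degenerate)) {
    warning(sum(degenerate), " all-zero draws flagged as degenerate and dropped from scaling")
  }
  structure(list(table = out, factors = factors,
                 degenerate = any(degenerate), draws = su),
            class = "scaled_utilities")
}

#' @export
print.scaled_utilities <- function(x, ...) {
  cat("Scaled part-worth utilities (-10..+10), median [95% CrI]\n")
  print(transform(x$table, median = round(median, 2), lo = round(lo, 2),
                  hi = round(hi, 2)), row.names = FALSE)
  invisible(x)
}

#' Relative importance of attributes
#'
#' Per posterior draw of the population mean, each attribute's importance is
#' its level-utility range (best minus worst level); ranges are normalised to
#' sum to 100 within the draw. Point estimates are means across draws (so
#' they also sum to 100 exactly); credible intervals are equal-tailed 2.5/97.5
#' percentiles.
#'
#' @inheritParams scale_utilities
#' @return object of class `importance_table`: data frame `table`
#'   (attribute, importance, median, lo, hi) and the per-draw `draws` matrix.
#' @export
relative_importance <- function(posterior, schema, coding) {
  draws <- mu_draws(posterior)
  lu <- level_utility_draws(draws, schema, coding)
  attrs <- unique(lu$attribute)
  ranges <- vapply(attrs, function(a) {
    ui <- lu$u[, lu$attribute == a, drop = FALSE]
    apply(ui, 1L, max) - apply(ui, 1L, min)
  }, numeric(nrow(lu$u)))
  if (is.null(dim(ranges))) {   # single-draw posterior
    ranges <- matrix(ranges, nrow = 1L, dimnames = list(NULL, attrs))
  }
  ri <- 100 * ranges / rowSums(ranges)
  qs <- apply(ri, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975))
  out <- data.frame(attribute = attrs, importance = colMeans(ri),
                    median = qs[1L, ], lo = qs[2L, ], hi = qs[3L, ],
                    row.names = NULL)
  structure(list(table = out, draws = ri), class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Relative importance (%), mean [95% CrI]\n")
  print(transform(x$table, importance = round(importance, 1),
                  median = round(median, 1), lo = round(lo, 1),
                  hi = round(hi, 1)), row.names = FALSE)
  invisible(x)
}

#' Marginal rate of substitution against the benefit attribute
#'
#' The absolute increase in the chance of the benefit outcome (percentage
#' points of remission, for the bundled schema) a respondent at the
#' population mean would require to accept an undesirable attribute level:
#' per draw, `(utility of avoiding the level - utility of having it) /
#' benefit slope per percentage point`. For an effects-coded binary this is
#' `2|beta| / beta_benefit` when the level is disliked. Summarised as the
#' median and equal-tailed 95% CrI across draws. A warning is attached when
#' the benefit slope crosses zero in more than 1% of draws (the ratio is then
#' unstable).
#'
#' @inheritParams scale_utilities
#' @param attribute attribute name containing the undesirable level.
#' @param level the undesirable level (its value/label); defaults to the
#'   worst level for ordered attributes.
#' @param benefit_attribute the linear benefit attribute whose slope prices
#'   the trade-off (default `"remission"`).
#' @return one-row data frame: attribute, level, median, lo, hi,
#'   `unstable_share` (fraction of draws with a non-positive benefit slope).
#' @export
mrs <- function(posterior, schema, coding, attribute, level = NULL,
                benefit_attribute = "remission") {
  a <- schema$attributes[[attribute]]
  if (is.null(a)) stop("unknown attribute '", attribute, "'")
  ben <- schema$attributes[[benefit_attribute]]
  if (is.null(ben) || ben$kind != "linear") {
    stop("benefit attribute must be a linear attribute of the schema")
  }
  if (is.null(level)) {
    pref <- level_preference(a)
    if (is.null(pref)) stop("level must be given for unordered attributes")
    level <- a$levels[which.min(pref)]
  }
  li <- match(as.character(level), as.character(a$levels))
  if (is.na(li)) stop("unknown level '", level, "' for attribute '", attribute, "'")

  draws <- mu_draws(posterior)
  lu <- level_utility_draws(draws, schema, coding)
  ui <- lu$u[, lu$attribute == attribute, drop = FALSE]
  # utility of avoiding the level: the best alternative level of the attribute
  d <- apply(ui[, -li, drop = FALSE], 1L, max) - ui[, li]
  b <- draws[, coding$columns[[benefit_attribute]]$idx]
  unstable <- mean(b <= 0)
  if (unstable > 0.01) {
    warning(sprintf("benefit slope non-positive in %.1f%% of draws; MRS ratio is unstable",
                    100 * unstable))
  }
  val <- d / b
  qs <- stats::quantile(val, c(0.5, 0.025, 0.975))
  data.frame(attribute = attribute, level = as.character(level),
             median = qs[[1L]], lo = qs[[2L]], hi = qs[[3L]],
             unstable_share = unstable, row.names = NULL)
}

#' MRS table for every ordered non-benefit attribute's worst level
#'
#' @inheritParams mrs
#' @return data frame with one [mrs()] row per attribute.
#' @export
mrs_table <- function(posterior, schema, coding,
                      benefit_attribute = "remission") {
  targets <- setdiff(ordered_attributes(schema), benefit_attribute)
  do.call(rbind, lapply(targets, function(a) {
    mrs(posterior, schema, coding, a, benefit_attribute = benefit_attribute)
  }))
}
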