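#' Generate a balanced-overlap fractional-factorial choice design
#'
#' Builds `n_versions` independent versions of `n_tasks` choice tasks with
#' `n_alts` alternatives each. Within every version each attribute's levels
#' are dealt from a balanced multiset (every level appears equally often, up
#' to rounding), then a swap-based local search moves the fraction of tasks
#' in which at least two alternatives share a level toward `overlap_target`
#' while preserving the level counts exactly. Deliberate level overlap
#' sacrifices some statistical efficiency but simplifies each task for the
#' respondent. Attributes with fewer levels than alternatives overlap in
#' every task by pigeonhole; the achievable overlap range is reported in the
#' design audit.
#'
#' @param schema an [attribute_schema()].
#' @param n_versions,n_tasks,n_alts design dimensions (defaults 100, 13, 3).
#' @param overlap_target desired fraction of task-by-attribute cells in which
#'   two or more alternatives share a level, in `[0, 1)`. The default 0.7
#'   sits between the schema-forced minimum and the fully random rate for the
#'   bundled six-attribute schema.
#' @param seed integer seed; the design is deterministic given
#'   `(schema, dimensions, seed)`.
#' @return a `choice_design`: integer array `cells[version, task, alt, attr]`
#'   of level indices, an empty `warmups` list (see [make_warmups()]), and the
#'   [audit_design()] report in `$audit`.
#' @export
generate_design <- function(schema, n_versions = 100L, n_tasks = 13L,
                            n_alts = 3L, overlap_target = 0.7, seed = 1L) {
  stopifnot(inherits(schema, "attribute_schema"),
            n_versions >= 1L, n_tasks >= 1L, n_alts >= 2L,
            overlap_target >= 0, overlap_target < 1)
  lc <- level_counts(schema)
  if (n_alts > prod(lc)) {
    stop("infeasible dimensions: n_alts exceeds the number of distinct profiles")
  }
  A <- length(lc)
  # attributes with fewer levels than alternatives overlap in every task
  forced <- lc < n_alts
  n_free <- sum(!forced)
  t_attr <- rep(1, A)
  if (n_free > 0L) {
    t_attr[!forced] <- min(1, max(0, (overlap_target * A - sum(forced)) / n_free))
  }

  cells <- with_seed(as.integer(seed), {
    arr <- array(NA_integer_,
                 dim = c(n_versions, n_tasks, n_alts, A),
                 dimnames = list(NULL, NULL, NULL, names(schema$attributes)))
    for (v in seq_len(n_versions)) {
      for (k in seq_len(A)) {
        arr[v, , , k] <- fill_attribute(lc[k], n_tasks, n_alts,
                                        round(t_attr[k] * n_tasks))
      }
      arr[v, , , ] <- repair_duplicates(
        array(arr[v, , , ], dim = c(n_tasks, n_alts, A)),
        n_tasks, n_alts, lc)
    }
    arr
  })

  design <- structure(
    list(cells = cells, n_versions = n_versions, n_tasks = n_tasks,
         n_alts = n_alts, warmups = list(),
         overlap_target = overlap_target, seed = as.integer(seed)),
    class = "choice_design"
  )
  design$audit <- audit_design(design, schema)
  design
}

# Deal a balanced level multiset into an n_tasks x n_alts matrix, then use
# count-preserving swaps to hit the target number of overlap tasks.
fill_attribute <- function(L, n_tasks, n_alts, target_overlap_tasks) {
  n_cells <- n_tasks * n_alts
  counts <- rep(n_cells %/% L, L)
  extra <- n_cells - sum(counts)
  if (extra > 0L) {
    bump <- sample.int(L, extra)
    counts[bump] <- counts[bump] + 1L
  }
  pool <- sample(rep.int(seq_len(L), counts))
  m <- matrix(pool, nrow = n_tasks, ncol = n_alts)
  if (L < n_alts) return(m)  # overlap forced everywhere; nothing to steer

  n_ov <- function(mm) sum(apply(mm, 1L, anyDuplicated) > 0L)
  best <- m
  for (restart in seq_len(20L)) {
    cur <- n_ov(m)
    iter <- 0L
    while (cur != target_overlap_tasks && iter < 400L * n_tasks) {
      iter <- iter + 1L
      r1 <- sample.int(n_tasks, 1L); r2 <- sample.int(n_tasks, 1L)
      if (r1 == r2) next
      c1 <- sample.int(n_alts, 1L); c2 <- sample.int(n_alts, 1L)
      if (m[r1, c1] == m[r2, c2]) next
      prev <- (anyDuplicated(m[r1, ]) > 0L) + (anyDuplicated(m[r2, ]) > 0L)
      tmp <- m[r1, c1]; m[r1, c1] <- m[r2, c2]; m[r2, c2] <- tmp
      now <- (anyDuplicated(m[r1, ]) > 0L) + (anyDuplicated(m[r2, ]) > 0L)
      new_cur <- cur - prev + now
      if (abs(new_cur - target_overlap_tasks) < abs(cur - target_overlap_tasks)) {
        cur <- new_cur
      } else {
        tmp <- m[r1, c1]; m[r1, c1] <- m[r2, c2]; m[r2, c2] <- tmp
      }
    }
    if (cur == target_overlap_tasks) return(m)
    if (abs(cur - target_overlap_tasks) <
        abs(n_ov(best) - target_overlap_tasks)) best <- m
    m <- matrix(sample(pool), nrow = n_tasks, ncol = n_alts)
  }
  best
}

# Break up tasks whose alternatives are identical on every attribute by
# swapping one attribute cell with another task (level counts preserved).
repair_duplicates <- function(cells_v, n_tasks, n_alts, lc) {
  if (n_tasks < 2L) return(cells_v)
  free_attrs <- which(lc >= 2L)
  for (t in seq_len(n_tasks)) {
    guard <- 0L
    repeat {
      mat <- matrix(cells_v[t, , ], nrow = n_alts)
      dup <- anyDuplicated(as.data.frame(mat))
      if (!dup || guard > 100L) break
      guard <- guard + 1L
      k <- sample1(free_attrs)
      a <- dup  # duplicated alternative row
      t2 <- sample1(setdiff(seq_len(n_tasks), t))
      a2 <- sample.int(n_alts, 1L)
      tmp <- cells_v[t, a, k]
      cells_v[t, a, k] <- cells_v[t2, a2, k]
      cells_v[t2, a2, k] <- tmp
    }
  }
  cells_v
}

#' Audit a choice design
#'
#' Recounts, by exhaustive scan, the quantities the generator promises:
#' per-attribute level frequencies and their worst deviation from the uniform
#' expectation within any version, the overlap rate (fraction of
#' task-by-attribute cells where two or more alternatives share a level),
#' the number of tasks containing duplicate alternatives (must be zero), and
#' the number of accidentally dominated alternatives in main tasks (reported,
#' not forbidden).
#'
#' @param design a `choice_design`.
#' @param schema the matching [attribute_schema()].
#' @return a list of class `design_audit`.
#' @export
audit_design <- function(design, schema) {
  cells <- design$cells
  lc <- level_counts(schema)
  A <- length(lc)
  stopifnot(dim(cells)[4L] == A)
  nv <- design$n_versions; nt <- design$n_tasks; na <- design$n_alts

  freq <- vector("list", A); names(freq) <- names(schema$attributes)
  max_dev <- numeric(A); names(max_dev) <- names(schema$attributes)
  for (k in seq_len(A)) {
    expected <- nt * na / lc[k]
    dev_k <- 0
    tab_total <- integer(lc[k])
    for (v in seq_len(nv)) {
      tab <- tabulate(cells[v, , , k], nbins = lc[k])
      tab_total <- tab_total + tab
      dev_k <- max(dev_k, max(abs(tab - expected)))
    }
    freq[[k]] <- tab_total
    max_dev[k] <- dev_k
  }

  n_overlap <- 0L; n_dup <- 0L; n_dom <- 0L
  for (v in seq_len(nv)) for (t in seq_len(nt)) {
    mat <- matrix(cells[v, t, , ], nrow = na)
    n_overlap <- n_overlap + sum(apply(mat, 2L, anyDuplicated) > 0L)
    if (anyDuplicated(as.data.frame(mat))) n_dup <- n_dup + 1L
    n_dom <- n_dom + length(find_dominated(mat, schema))
  }

  structure(list(
    level_frequencies = freq,
    max_balance_deviation = max_dev,
    overlap_rate = n_overlap / (nv * nt * A),
    duplicate_task_count = n_dup,
    accidental_dominated_count = n_dom
  ), class = "design_audit")
}

#' @export
print.design_audit <- function(x, ...) {
  cat("Design audit\n")
  cat(sprintf("  overlap rate:            %.3f\n", x$overlap_rate))
  cat(sprintf("  max balance deviation:   %.1f (worst attribute)\n",
              max(x$max_balance_deviation)))
  cat(sprintf("  duplicate-alt tasks:     %d\n", x$duplicate_task_count))
  cat(sprintf("  dominated alts (main):   %d\n", x$accidental_dominated_count))
  invisible(x)
}

#' @export
print.choice_design <- function(x, ...) {
  cat(sprintf("Choice design: %d versions x %d tasks x %d alternatives, %d warm-ups\n",
              x$n_versions, x$n_tasks, x$n_alts, length(x$warmups)))
  if (!is.null(x$audit)) print(x$audit)
  invisible(x)
}

# Indices of dominated alternatives in a task (rows = alternatives, cols =
# attributes). Alternative j is dominated by k when k is weakly better on
# every ordered attribute, strictly better on at least one, and identical on
# unordered attributes (so the comparison is unambiguous).
find_dominated <- function(task_levels, schema) {
  na <- nrow(task_levels)
  attrs <- schema$attributes
  pref <- lapply(attrs, level_preference)
  dominated <- integer(0L)
  for (j in seq_len(na)) {
    for (k in seq_len(na)) {
      if (j == k) next
      weakly <- TRUE; strictly <- FALSE
      for (m in seq_along(attrs)) {
        pj <- task_levels[j, m]; pk <- task_levels[k, m]
        if (is.null(pref[[m]])) {
          if (pj != pk) { weakly <- FALSE; break }
        } else {
          rj <- pref[[m]][pj]; rk <- pref[[m]][pk]
          if (rk < rj) { weakly <- FALSE; break }
          if (rk > rj) strictly <- TRUE
        }
      }
      if (weakly && strictly) { dominated <- c(dominated, j); break }
    }
  }
  dominated
}

#' Generate warm-up tasks containing a dominated alternative
#'
#' Warm-up tasks introduce the choice format before the main tasks. Each one
#' contains exactly one alternative that is weakly worse than another on every
#' ordered attribute and strictly worse on at least one (unordered attributes
#' are held equal across that pair), so an attentive respondent should never
#' pick it. Warm-ups are flagged and excluded from estimation; choosing the
#' dominated alternative is the internal-validity failure tested by
#' [check_dominated()].
#'
#' @param schema an [attribute_schema()] with at least one ordered attribute.
#' @param n number of warm-up tasks (study default 2).
#' @param n_alts alternatives per task (default 3).
#' @param seed integer seed.
#' @return list of warm-up tasks, each a list with `levels` (alternatives by
#'   attributes matrix of level indices) and `dominated` (the flagged index).
#' @export
make_warmups <- function(schema, n = 2L, n_alts = 3L, seed = 1L) {
  stopifnot(inherits(schema, "attribute_schema"), n >= 0L, n_alts >= 2L)
  ord <- ordered_attributes(schema)
  if (length(ord) == 0L) stop("schema has no ordered attributes; cannot build a dominated alternative")
  if (n == 0L) return(list())
  attrs <- schema$attributes
  A <- length(attrs)
  lc <- level_counts(schema)
  ord_idx <- match(ord, names(attrs))

  with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      repeat {
        # dominator: random, but not at its worst level on every ordered attribute
        a_lv <- vapply(seq_len(A), function(k) sample.int(lc[k], 1L), integer(1L))
        pref <- lapply(attrs, level_preference)
        room <- vapply(ord_idx, function(k) pref[[k]][a_lv[k]] > 1L, logical(1L))
        if (!any(room)) next
        # dominated copy: weakly worse on ordered attributes, equal elsewhere
        b_lv <- a_lv
        for (k in ord_idx) {
          worse <- which(pref[[k]] <= pref[[k]][a_lv[k]])
          b_lv[k] <- sample1(worse)
        }
        if (all(b_lv == a_lv)) {
          k <- sample1(ord_idx[room])
          worse <- which(pref[[k]] < pref[[k]][a_lv[k]])
          b_lv[k] <- sample1(worse)
        }
        # remaining alternatives: random, must leave exactly one dominated
        for (tries in seq_len(200L)) {
          others <- if (n_alts > 2L) {
            t(replicate(n_alts - 2L,
              vapply(seq_len(A), function(k) sample.int(lc[k], 1L), integer(1L))))
          }
          mat <- rbind(a_lv, b_lv, others)
          rownames(mat) <- NULL
          perm <- sample.int(n_alts)
          mat <- mat[perm, , drop = FALSE]
          if (anyDuplicated(as.data.frame(mat))) next
          dom <- find_dominated(mat, schema)
          if (length(dom) == 1L && identical(mat[dom, ], b_lv)) {
            return(list(levels = mat, dominated = dom, is_warmup = TRUE))
          }
        }
      }
    })
  })
}
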