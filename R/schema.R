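#' Define a choice-experiment attribute
#'
#' @param name attribute name.
#' @param kind one of `"linear"`, `"categorical"`, `"binary"`. Linear
#'   attributes have numeric levels and enter the utility as a single slope
#'   per unit after centering; categorical and binary attributes are
#'   effects-coded (level utilities sum to zero within the attribute).
#' @param levels vector of level values: numeric for linear attributes,
#'   labels otherwise. Binary attributes have exactly 2 levels.
#' @param ordering `"increasing"` if later levels are better, `"decreasing"`
#'   if earlier levels are better, `"none"` if the attribute has no natural
#'   preference direction.
#' @param center centering constant (linear attributes only); slopes are then
#'   per unit of the level scale around this value.
#' @return an object of class `dce_attribute`.
#' @export
attribute <- function(name, kind = c("categorical", "linear", "binary"),
                      levels, ordering = c("none", "increasing", "decreasing"),
                      center = NULL) {
  kind <- match.arg(kind)
  ordering <- match.arg(ordering)
  if (length(levels) < 2L) stop("attribute '", name, "' needs >= 2 levels")
  if (kind == "linear") {
    if (!is.numeric(levels)) stop("linear attribute '", name, "' needs numeric levels")
    if (is.null(center)) center <- mean(range(levels))
    if (!is.finite(center)) stop("linear attribute '", name, "' needs a finite center")
  } else {
    center <- NULL
  }
  if (kind == "binary" && length(levels) != 2L) {
    stop("binary attribute '", name, "' must have exactly 2 levels")
  }
  structure(
    list(name = name, kind = kind, levels = levels,
         ordering = ordering, center = center),
    class = "dce_attribute"
  )
}

#' Assemble an attribute schema
#'
#' An ordered collection of [attribute()] definitions describing the design
#' space of a discrete-choice experiment.
#'
#' @param ... `dce_attribute` objects.
#' @return an object of class `attribute_schema`.
#' @seealso [crohn_schema()] for the bundled Crohn's disease maintenance
#'   therapy schema.
#' @export
attribute_schema <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && is.list(attrs[[1L]]) &&
      !inherits(attrs[[1L]], "dce_attribute")) {
    attrs <- attrs[[1L]]
  }
  ok <- vapply(attrs, inherits, logical(1L), what = "dce_attribute")
  if (!all(ok)) stop("all schema components must be built with attribute()")
  names(attrs) <- vapply(attrs, `[[`, character(1L), "name")
  if (anyDuplicated(names(attrs))) stop("duplicate attribute names")
  structure(list(attributes = attrs), class = "attribute_schema")
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat("Attribute schema with", length(x$attributes), "attributes:\n")
  for (a in x$attributes) {
    cat(sprintf("  %-18s %-11s %d levels (%s)%s\n", a$name, a$kind,
                length(a$levels), a$ordering,
                if (!is.null(a$center)) sprintf(", center %g", a$center) else ""))
  }
  invisible(x)
}

n_attributes <- function(schema) length(schema$attributes)
level_counts <- function(schema) {
  vapply(schema$attributes, function(a) length(a$levels), integer(1L))
}

#' Crohn's disease maintenance-therapy attribute schema
#'
#' The six attributes used in the Crohn's disease maintenance-therapy DCE:
#' chance of remission at one year (20/50/80 per 100, linear, centered at 50),
#' chance of withdrawal due to adverse events (1/15/30 per 100, linear,
#' centered at 15.5 so slopes are per percentage point), a six-level dosing
#' regimen with no preference ordering, and three Yes/No attributes (short
#' course of prednisone; possible low blood counts or liver reaction; small
#' risk of serious infection / possible cancer risk), "No" preferred for each.
#'
#' @return an `attribute_schema` with level counts (3, 3, 6, 2, 2, 2).
#' @export
crohn_schema <- function() {
  dosing <- c("daily tablets", "tablets twice a day",
              "weekly injection", "injection every 2 weeks",
              "IV infusion every 8 weeks",
              "daily tablets + IV infusion every 8 weeks")
  attribute_schema(
    attribute("remission", "linear", c(20, 50, 80),
              ordering = "increasing", center = 50),
    attribute("wdae", "linear", c(1, 15, 30),
              ordering = "decreasing", center = 15.5),
    attribute("dosing", "categorical", dosing, ordering = "none"),
    attribute("prednisone", "binary", c("Yes", "No"), ordering = "increasing"),
    attribute("blood_liver", "binary", c("Yes", "No"), ordering = "increasing"),
    attribute("infection_cancer", "binary", c("Yes", "No"), ordering = "increasing")
  )
}

#' Build the part-worth coding map for a schema
#'
#' Maps attribute levels to columns of the part-worth vector: linear
#' attributes get one column holding `level - center`; a categorical
#' attribute with L levels gets L-1 effects-coded columns (last level is -1
#' on all of them); binary attributes get one effects column (first level +1,
#' second level -1). Effects coding makes the implied level utilities sum to
#' zero within each attribute.
#'
#' @param schema an [attribute_schema()].
#' @return an object of class `coding_map` with per-attribute column indices
#'   and total column count `p`.
#' @export
coding_map <- function(schema) {
  stopifnot(inherits(schema, "attribute_schema"))
  cols <- list(); p <- 0L
  for (a in schema$attributes) {
    ncol_a <- switch(a$kind,
      linear = 1L,
      binary = 1L,
      categorical = length(a$levels) - 1L
    )
    cols[[a$name]] <- list(idx = seq.int(p + 1L, p + ncol_a), kind = a$kind)
    p <- p + ncol_a
  }
  names_out <- unlist(lapply(schema$attributes, function(a) {
    switch(a$kind,
      linear = a$name,
      binary = a$name,
      categorical = paste0(a$name, "_", seq_len(length(a$levels) - 1L))
    )
  }), use.names = FALSE)
  structure(list(columns = cols, p = p, colnames = names_out),
            class = "coding_map")
}

#' @export
print.coding_map <- function(x, ...) {
  cat("Coding map:", x$p, "part-worth columns\n")
  for (nm in names(x$columns)) {
    ci <- x$columns[[nm]]
    cat(sprintf("  %-18s %-11s cols %s\n", nm, ci$kind,
                paste(ci$idx, collapse = ",")))
  }
  invisible(x)
}

# Covariate row for one alternative: level index per attribute -> length-p x.
code_alternative <- function(levels_idx, schema, coding) {
  attrs <- schema$attributes
  if (length(levels_idx) != length(attrs)) stop("level index / attribute mismatch")
  x <- numeric(coding$p)
  for (k in seq_along(attrs)) {
    a <- attrs[[k]]
    idx <- coding$columns[[a$name]]$idx
    li <- levels_idx[[k]]
    if (li < 1L || li > length(a$levels)) {
      stop("level index out of range for attribute '", a$name, "'")
    }
    if (a$kind == "linear") {
      x[idx] <- a$levels[li] - a$center
    } else if (a$kind == "binary") {
      x[idx] <- if (li == 1L) 1 else -1
    } else {
      L <- length(a$levels)
      x[idx] <- if (li < L) {
        v <- numeric(L - 1L); v[li] <- 1; v
      } else rep(-1, L - 1L)
    }
  }
  x
}

#' Per-level utilities implied by a part-worth vector
#'
#' For each attribute, the zero-centred utility of each level under `beta`.
#' Linear attributes are evaluated at their design levels around the center,
#' so the returned values are centred at the attribute's center level.
#'
#' @param beta part-worth vector of length `coding$p`.
#' @param schema an [attribute_schema()].
#' @param coding the matching [coding_map()].
#' @return named list: one numeric vector of level utilities per attribute.
#' @export
level_utilities <- function(beta, schema, coding) {
  out <- list()
  for (a in schema$attributes) {
    idx <- coding$columns[[a$name]]$idx
    L <- length(a$levels)
    u <- vapply(seq_len(L), function(li) {
      if (a$kind == "linear") {
        (a$levels[li] - a$center) * beta[idx]
      } else if (a$kind == "binary") {
        if (li == 1L) beta[idx] else -beta[idx]
      } else {
        if (li < L) beta[idx][li] else -sum(beta[idx])
      }
    }, numeric(1L))
    out[[a$name]] <- u
  }
  out
}

# Preference rank of levels (higher = better); NULL for unordered attributes.
level_preference <- function(a) {
  L <- length(a$levels)
  switch(a$ordering,
    increasing = seq_len(L),
    decreasing = rev(seq_len(L)),
    none = NULL
  )
}

ordered_attributes <- function(schema) {
  names(Filter(function(a) a$ordering != "none", schema$attributes))
}
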