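#' Specify a synthetic respondent population
#'
#' Describes a finite mixture of multivariate-normal preference classes plus
#' optional pathological respondents ("injectors") used to exercise the
#' internal-validity detectors: straight-liners who always pick one screen
#' position, and attribute-dominant respondents who always pick the best
#' available level of one attribute.
#'
#' @param n_respondents number of respondents.
#' @param classes list of classes, each `list(share =, mu =, sigma =)` with
#'   `mu` a length-p part-worth mean and `sigma` a p x p covariance; shares
#'   must sum to 1 and each sigma must be symmetric positive semi-definite.
#' @param n_straightliners number of injected straight-liners.
#' @param n_attribute_dominant named integer vector, attribute name ->
#'   number of injected respondents dominant on that attribute.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_respondents, classes,
                            n_straightliners = 0L,
                            n_attribute_dominant = integer(0L)) {
  stopifnot(n_respondents >= 1L, length(classes) >= 1L)
  shares <- vapply(classes, `[[`, numeric(1L), "share")
  if (abs(sum(shares) - 1) > 1e-8) stop("class shares must sum to 1")
  p <- length(classes[[1L]]$mu)
  for (cl in classes) {
    if (length(cl$mu) != p) stop("all class means must share one length")
    s <- as.matrix(cl$sigma)
    if (!isTRUE(all.equal(s, t(s), tolerance = 1e-8))) {
      stop("class sigma must be symmetric")
    }
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("class sigma is not positive semi-definite")
    }
  }
  n_inject <- n_straightliners + sum(n_attribute_dominant)
  if (n_inject > n_respondents) stop("more injectors than respondents")
  structure(list(n_respondents = as.integer(n_respondents), classes = classes,
                 n_straightliners = as.integer(n_straightliners),
                 n_attribute_dominant = n_attribute_dominant, p = p),
            class = "population_spec")
}

#' Default synthetic population for the Crohn's maintenance-therapy schema
#'
#' A two-class mixture mirroring the qualitative preference structure the
#' package's downstream methods are meant to recover: a 55% "benefit-driven"
#' class whose utility is dominated by the chance of remission, and a 45%
#' "risk-averse" class with strong aversions to a course of prednisone and to
#' the rare infection/cancer risk. Magnitudes are package choices on the
#' per-percentage-point part-worth scale, not estimates.
#'
#' @param n_respondents cohort size (default 155).
#' @param n_straightliners,n_attribute_dominant injector counts passed to
#'   [population_spec()] (defaults 0).
#' @return a `population_spec` on the 10-column coding of [crohn_schema()].
#' @export
default_population_spec <- function(n_respondents = 155L,
                                    n_straightliners = 0L,
                                    n_attribute_dominant = integer(0L)) {
  mu_benefit <- c(0.045, -0.035, 0.10, -0.05, 0.05, 0.10, -0.05,
                  -0.15, -0.10, -0.15)
  mu_risk <- c(0.020, -0.030, 0.08, -0.08, 0.04, 0.06, -0.04,
               -0.42, -0.10, -0.40)
  sds <- c(0.015, 0.012, rep(0.10, 5L), 0.15, 0.12, 0.18)
  population_spec(
    n_respondents,
    classes = list(
      list(share = 0.55, mu = mu_benefit, sigma = diag(sds^2)),
      list(share = 0.45, mu = mu_risk, sigma = diag(sds^2))
    ),
    n_straightliners = n_straightliners,
    n_attribute_dominant = n_attribute_dominant
  )
}

#' Draw a respondent population with known preferences
#'
#' Class labels are drawn from the class shares, individual part-worth
#' vectors from the assigned class's multivariate normal, and injector
#' respondents are flagged with their behavioural type. The result is the
#' ground truth against which recovery of downstream estimators is tested.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @return object of class `true_preferences`: `beta` (n x p matrix),
#'   `class` (integer labels), `behavior` (`"logit"`, `"straightliner"`,
#'   `"dominant"`), `position` (fixed position of straight-liners),
#'   `dominant_attr` (attribute name for dominant respondents).
#' @export
simulate_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_respondents; p <- spec$p
  with_seed(as.integer(seed), {
    shares <- vapply(spec$classes, `[[`, numeric(1L), "share")
    lab <- sample.int(length(shares), n, replace = TRUE, prob = shares)
    beta <- matrix(NA_real_, n, p)
    for (k in seq_along(spec$classes)) {
      idx <- which(lab == k)
      if (length(idx)) {
        beta[idx, ] <- MASS::mvrnorm(length(idx), spec$classes[[k]]$mu,
                                     as.matrix(spec$classes[[k]]$sigma))
      }
    }
    behavior <- rep("logit", n)
    position <- rep(NA_integer_, n)
    dominant_attr <- rep(NA_character_, n)
    n_inject <- spec$n_straightliners + sum(spec$n_attribute_dominant)
    if (n_inject > 0L) {
      pool <- sample.int(n, n_inject)
      if (spec$n_straightliners > 0L) {
        sl <- pool[seq_len(spec$n_straightliners)]
        behavior[sl] <- "straightliner"
        position[sl] <- sample.int(3L, length(sl), replace = TRUE)
        pool <- pool[-seq_len(spec$n_straightliners)]
      }
      for (a in names(spec$n_attribute_dominant)) {
        cnt <- spec$n_attribute_dominant[[a]]
        if (cnt > 0L) {
          da <- pool[seq_len(cnt)]
          behavior[da] <- "dominant"
          dominant_attr[da] <- a
          pool <- pool[-seq_len(cnt)]
        }
      }
    }
    structure(list(beta = beta, class = lab, behavior = behavior,
                   position = position, dominant_attr = dominant_attr,
                   spec = spec),
              class = "true_preferences")
  })
}

#' @export
print.true_preferences <- function(x, ...) {
  cat(sprintf("True preferences for %d respondents (%d part-worth columns)\n",
              nrow(x$beta), ncol(x$beta)))
  cat("  class counts:", paste(tabulate(x$class), collapse = " / "), "\n")
  inj <- table(x$behavior)
  cat("  behaviours:  ", paste(names(inj), inj, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Coded covariate array for one design version: (n_tasks*n_alts) x p matrix,
# rows ordered task-major then alternative.
code_version <- function(design, v, schema, coding) {
  nt <- design$n_tasks; na <- design$n_alts
  X <- matrix(0, nt * na, coding$p)
  r <- 0L
  for (t in seq_len(nt)) for (j in seq_len(na)) {
    r <- r + 1L
    X[r, ] <- code_alternative(design$cells[v, t, j, ], schema, coding)
  }
  X
}

code_task <- function(levels_mat, schema, coding) {
  t(apply(levels_mat, 1L, code_alternative, schema = schema, coding = coding))
}

#' Simulate respondent choices from true preferences
#'
#' Logit respondents choose alternative j of a task with the multinomial
#' logit probability `exp(x_j' beta_i) / sum_k exp(x_k' beta_i)`;
#' straight-liners always pick their fixed screen position; attribute-
#' dominant respondents always pick an alternative attaining the task's best
#' available level of their attribute (uniform tie-break from the same RNG
#' stream). Warm-up responses are generated the same way and kept separate.
#'
#' @param design a `choice_design` (respondents are assigned versions
#'   cyclically in id order).
#' @param prefs a `true_preferences` object.
#' @param schema,coding the schema and [coding_map()] used to code the design.
#' @param seed integer seed.
#' @return object of class `respondent_choices`: `main` (n x n_tasks matrix
#'   of chosen alternative indices), `warmup` (n x n_warmups matrix or NULL),
#'   `version` (design version per respondent), `n_alts`.
#' @export
simulate_choices <- function(design, prefs, schema, coding, seed = 1L) {
  stopifnot(inherits(design, "choice_design"),
            inherits(prefs, "true_preferences"))
  if (ncol(prefs$beta) != coding$p) stop("beta / coding dimension mismatch")
  n <- nrow(prefs$beta)
  nt <- design$n_tasks; na <- design$n_alts
  version <- ((seq_len(n) - 1L) %% design$n_versions) + 1L
  nw <- length(design$warmups)

  with_seed(as.integer(seed), {
    Xv <- lapply(seq_len(design$n_versions), code_version,
                 design = design, schema = schema, coding = coding)
    Xw <- lapply(design$warmups, function(w) code_task(w$levels, schema, coding))

    pick_logit <- function(u) {
      pr <- exp(u - max(u))
      sample.int(length(u), 1L, prob = pr)
    }
    pick_dominant <- function(levels_mat, attr_name) {
      a <- schema$attributes[[attr_name]]
      pref <- level_preference(a)
      k <- match(attr_name, names(schema$attributes))
      r <- pref[levels_mat[, k]]
      best <- which(r == max(r))
      sample1(best)
    }

    main <- matrix(NA_integer_, n, nt)
    warm <- if (nw > 0L) matrix(NA_integer_, n, nw) else NULL
    for (i in seq_len(n)) {
      v <- version[i]
      b <- prefs$beta[i, ]
      bhv <- prefs$behavior[i]
      for (t in seq_len(nt)) {
        main[i, t] <- switch(bhv,
          logit = {
            u <- Xv[[v]][seq.int((t - 1L) * na + 1L, t * na), , drop = FALSE] %*% b
            pick_logit(drop(u))
          },
          straightliner = prefs$position[i],
          dominant = pick_dominant(
            matrix(design$cells[v, t, , ], nrow = na), prefs$dominant_attr[i])
        )
      }
      if (nw > 0L) for (w in seq_len(nw)) {
        warm[i, w] <- switch(bhv,
          logit = pick_logit(drop(Xw[[w]] %*% b)),
          straightliner = prefs$position[i],
          dominant = pick_dominant(design$warmups[[w]]$levels,
                                   prefs$dominant_attr[i])
        )
      }
    }
    respondent_choices(main = main, version = version, warmup = warm,
                       n_alts = na)
  })
}

#' Construct a respondent-choices object
#'
#' @param main n x n_tasks integer matrix of chosen alternative indices for
#'   the main (estimation) tasks.
#' @param version design version per respondent.
#' @param warmup optional n x n_warmups matrix of warm-up answers; warm-ups
#'   never enter the likelihood.
#' @param n_alts number of alternatives per task.
#' @param ids optional respondent identifiers (default `r1..rn`).
#' @return object of class `respondent_choices`.
#' @export
respondent_choices <- function(main, version, warmup = NULL, n_alts,
                               ids = NULL) {
  main <- as.matrix(main)
  n <- nrow(main)
  stopifnot(length(version) == n, n_alts >= 2L)
  if (any(main < 1L | main > n_alts)) stop("chosen alternative out of range")
  if (!is.null(warmup)) {
    warmup <- as.matrix(warmup)
    stopifnot(nrow(warmup) == n)
    if (any(warmup < 1L | warmup > n_alts, na.rm = TRUE)) {
      stop("warm-up choice out of range")
    }
  }
  ids <- ids %||% paste0("r", seq_len(n))
  structure(list(ids = ids, main = main, version = as.integer(version),
                 warmup = warmup, n_alts = as.integer(n_alts)),
            class = "respondent_choices")
}

#' @export
print.respondent_choices <- function(x, ...) {
  cat(sprintf("Respondent choices: %d respondents x %d tasks (%d alternatives)%s\n",
              nrow(x$main), ncol(x$main), x$n_alts,
              if (!is.null(x$warmup)) sprintf(", %d warm-ups", ncol(x$warmup)) else ""))
  invisible(x)
}
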