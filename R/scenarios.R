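# Treatment-scenario engine: fuse part-worth posteriors with network-meta-
# analysis (NMA) outcome distributions to rank treatments by preference-
# weighted benefit-risk.

#' Reconstruct an outcome posterior from its median and 95% CrI
#'
#' Published NMA outcome summaries (median and equal-tailed 95% credible
#' interval on the probability scale) are turned into a sampling
#' distribution that is normal on the log-odds scale: mean `logit(median)`,
#' sd `(logit(hi) - logit(lo)) / (2 * 1.959964)`. The logit-normal respects
#' the (0,1) support and the asymmetry of the printed intervals.
#'
#' @param median,lo,hi probabilities with `0 < lo <= median <= hi < 1`.
#' @return object of class `outcome_distribution`.
#' @export
fit_outcome_distribution <- function(median, lo, hi) {
  if (!(lo > 0 && hi < 1 && lo <= median && median <= hi)) {
    stop("need 0 < lo <= median <= hi < 1")
  }
  structure(list(median = median, lo = lo, hi = hi,
                 mean_logodds = logit(median),
                 sd_logodds = (logit(hi) - logit(lo)) / (2 * 1.959964)),
            class = "outcome_distribution")
}

#' Sample from a reconstructed outcome distribution
#'
#' @param od an [fit_outcome_distribution()] object.
#' @param n number of draws.
#' @return probabilities in (0, 1); a point mass at the median when the
#'   interval is degenerate.
#' @export
sample_outcome <- function(od, n) {
  stopifnot(inherits(od, "outcome_distribution"))
  if (od$sd_logodds == 0) return(rep(od$median, n))
  inv_logit(stats::rnorm(n, od$mean_logodds, od$sd_logodds))
}

#' Define a treatment profile
#'
#' A treatment as the respondents' utility model sees it: stochastic
#' remission and withdrawal-due-to-adverse-events (WDAE) outcomes plus fixed
#' categorical attribute assignments.
#'
#' @param name treatment name.
#' @param remission,wdae [fit_outcome_distribution()] objects (probability
#'   of maintaining remission at 1 year; probability of WDAE).
#' @param dosing dosing level: index or label in the schema's dosing levels.
#' @param prednisone,blood_liver,infection_cancer `"Yes"`/`"No"` flags.
#' @param schema schema used to validate the dosing level (default
#'   [crohn_schema()]).
#' @return object of class `treatment_profile`.
#' @export
treatment_profile <- function(name, remission, wdae, dosing,
                              prednisone, blood_liver, infection_cancer,
                              schema = crohn_schema()) {
  stopifnot(inherits(remission, "outcome_distribution"),
            inherits(wdae, "outcome_distribution"))
  dl <- schema$attributes$dosing$levels
  if (is.character(dosing)) dosing <- match(dosing, dl)
  if (is.na(dosing) || dosing < 1L || dosing > length(dl)) {
    stop("dosing level not in schema for treatment '", name, "'")
  }
  flags <- c(prednisone = prednisone, blood_liver = blood_liver,
             infection_cancer = infection_cancer)
  if (!all(flags %in% c("Yes", "No"))) stop("flags must be 'Yes' or 'No'")
  structure(list(name = name, remission = remission, wdae = wdae,
                 dosing = as.integer(dosing),
                 prednisone = prednisone, blood_liver = blood_liver,
                 infection_cancer = infection_cancer),
            class = "treatment_profile")
}

#' The six Crohn's maintenance-therapy treatment profiles
#'
#' Remission and WDAE outcome summaries from the source network
#' meta-analysis, plus the dosing and risk-attribute assignments, for
#' infliximab, infliximab + azathioprine, adalimumab, vedolizumab,
#' azathioprine and methotrexate. The base scenario assigns a short course
#' of prednisone to every treatment, so that attribute provably cancels out
#' of every comparison; [apply_sensitivity()] varies the footnoted flags.
#'
#' @return named list of [treatment_profile()] objects.
#' @export
crohn_treatment_profiles <- function() {
  sch <- crohn_schema()
  tp <- function(...) treatment_profile(..., schema = sch)
  od <- fit_outcome_distribution
  list(
    infliximab = tp("infliximab", od(0.48, 0.33, 0.64), od(0.12, 0.063, 0.25),
                    "IV infusion every 8 weeks", "Yes", "No", "Yes"),
    infliximab_azathioprine = tp("infliximab_azathioprine",
                    od(0.63, 0.44, 0.80), od(0.12, 0.045, 0.27),
                    "daily tablets + IV infusion every 8 weeks",
                    "Yes", "Yes", "Yes"),
    adalimumab = tp("adalimumab", od(0.61, 0.46, 0.75), od(0.023, 0.012, 0.042),
                    "injection every 2 weeks", "Yes", "No", "Yes"),
    vedolizumab = tp("vedolizumab", od(0.41, 0.27, 0.57), od(0.030, 0.014, 0.061),
                    "IV infusion every 8 weeks", "Yes", "No", "No"),
    azathioprine = tp("azathioprine", od(0.36, 0.24, 0.49), od(0.15, 0.079, 0.26),
                    "daily tablets", "Yes", "Yes", "Yes"),
    methotrexate = tp("methotrexate", od(0.42, 0.25, 0.61), od(0.38, 0.12, 0.83),
                    "weekly injection", "Yes", "Yes", "Yes")
  )
}

#' Vary treatment profiles for the sensitivity analyses
#'
#' `"base"` returns the profiles unchanged; `"no_prednisone_biologics"` sets
#' the prednisone flag to `"No"` for the four biologic-based treatments
#' (infliximab, infliximab + azathioprine, adalimumab, vedolizumab);
#' `"antitnf_blood_liver"` sets the blood-count/liver-reaction flag to
#' `"Yes"` for the two anti-TNF monotherapies (infliximab, adalimumab).
#'
#' @param profiles named list of [treatment_profile()]s.
#' @param scenario scenario name.
#' @return the adjusted profile list.
#' @export
apply_sensitivity <- function(profiles,
                              scenario = c("base", "no_prednisone_biologics",
                                           "antitnf_blood_liver")) {
  scenario <- match.arg(scenario)
  if (scenario == "no_prednisone_biologics") {
    for (nm in c("infliximab", "infliximab_azathioprine", "adalimumab",
                 "vedolizumab")) {
      if (!nm %in% names(profiles)) stop("profile '", nm, "' missing")
      profiles[[nm]]$prednisone <- "No"
    }
  } else if (scenario == "antitnf_blood_liver") {
    for (nm in c("infliximab", "adalimumab")) {
      if (!nm %in% names(profiles)) stop("profile '", nm, "' missing")
      profiles[[nm]]$blood_liver <- "Yes"
    }
  }
  profiles
}

# Fixed (non-outcome) covariate row of a profile; outcome columns left 0.
profile_fixed_x <- function(profile, schema, coding) {
  x <- numeric(coding$p)
  dos <- schema$attributes$dosing
  idx <- coding$columns$dosing$idx
  L <- length(dos$levels)
  x[idx] <- if (profile$dosing < L) {
    v <- numeric(L - 1L); v[profile$dosing] <- 1; v
  } else rep(-1, L - 1L)
  for (nm in c("prednisone", "blood_liver", "infection_cancer")) {
    x[coding$columns[[nm]]$idx] <- if (profile[[nm]] == "Yes") 1 else -1
  }
  x
}

#' Utility of a treatment profile for one part-worth vector
#'
#' The sum of the part-utilities of the profile's attributes:
#' `beta_rem * (remission% - center) + beta_wdae * (wdae% - center)` plus the
#' dosing-level part-worth and the effects-coded binary part-worths. Sampled
#' outcomes beyond the designed level range are linearly extrapolated, with a
#' warning, unless `clamp = TRUE`.
#'
#' @param profile a [treatment_profile()].
#' @param beta part-worth vector (length `coding$p`).
#' @param sampled_outcomes list with `remission` and `wdae` in percentage
#'   points (0-100 scale).
#' @param schema,coding schema and [coding_map()].
#' @param clamp clamp outcomes to the designed level range instead of
#'   extrapolating.
#' @return utility (scalar).
#' @export
profile_utility <- function(profile, beta, sampled_outcomes, schema, coding,
                            clamp = FALSE) {
  rem <- sampled_outcomes$remission
  wd <- sampled_outcomes$wdae
  ar <- schema$attributes$remission; aw <- schema$attributes$wdae
  out_of_range <- rem < min(ar$levels) || rem > max(ar$levels) ||
    wd < min(aw$levels) || wd > max(aw$levels)
  if (clamp) {
    rem <- min(max(rem, min(ar$levels)), max(ar$levels))
    wd <- min(max(wd, min(aw$levels)), max(aw$levels))
  } else if (out_of_range) {
    warning("sampled outcome outside the designed level range; extrapolating linearly")
  }
  x <- profile_fixed_x(profile, schema, coding)
  x[coding$columns$remission$idx] <- rem - ar$center
  x[coding$columns$wdae$idx] <- wd - aw$center
  drop(crossprod(x, beta))
}

# Core menu simulation shared by simulate_menu / simulate_pairs.
menu_sim_core <- function(profiles, posterior, schema, coding, n_draws,
                          seed, clamp) {
  K <- length(profiles)
  bd <- beta_draws(posterior)              # (total_draws, n, p)
  n <- dim(bd)[2L]; p <- dim(bd)[3L]; D_tot <- dim(bd)[1L]
  ar <- schema$attributes$remission; aw <- schema$attributes$wdae
  rem_col <- coding$columns$remission$idx
  wd_col <- coding$columns$wdae$idx
  Xfix <- t(vapply(profiles, profile_fixed_x, numeric(coding$p),
                   schema = schema, coding = coding))

  with_seed(as.integer(seed), {
    # shared-per-iteration outcome draws (percent scale), per profile
    rem_pct <- vapply(profiles, function(pr) 100 * sample_outcome(pr$remission, n_draws),
                      numeric(n_draws))
    wd_pct <- vapply(profiles, function(pr) 100 * sample_outcome(pr$wdae, n_draws),
                     numeric(n_draws))
    n_extrap <- sum(rem_pct < min(ar$levels) | rem_pct > max(ar$levels)) +
      sum(wd_pct < min(aw$levels) | wd_pct > max(aw$levels))
    if (clamp) {
      rem_pct <- pmin(pmax(rem_pct, min(ar$levels)), max(ar$levels))
      wd_pct <- pmin(pmax(wd_pct, min(aw$levels)), max(aw$levels))
    }
    rem_c <- rem_pct - ar$center
    wd_c <- wd_pct - aw$center
    # per-patient posterior draw indices, one per simulation draw
    idx <- matrix(sample.int(D_tot, n * n_draws, replace = TRUE), n, n_draws)
    prob <- matrix(0, n, K)
    for (i in seq_len(n)) {
      Bi <- matrix(bd[idx[i, ], i, ], n_draws, p)     # D x p
      U <- Bi %*% t(Xfix) + Bi[, rem_col] * rem_c + Bi[, wd_col] * wd_c
      pick <- max.col(U, ties.method = "random")
      prob[i, ] <- tabulate(pick, nbins = K) / n_draws
    }
    list(prob = prob, n_extrapolated = n_extrap)
  })
}

#' Simulate patient choice among a menu of treatments
#'
#' For each simulation draw, one joint posterior draw of each patient's
#' part-worth vector is combined with a fresh draw of every profile's
#' remission and WDAE outcomes (outcome draws are shared across patients
#' within an iteration); each patient picks the profile with the highest
#' utility (uniform random tie-break). Averaging over draws gives each
#' patient's choice-probability vector; the cohort is summarised both as the
#' share of patients whose modal treatment is each profile and as the mean
#' choice probability.
#'
#' @param profiles named list of [treatment_profile()]s (>= 2).
#' @param posterior an `hb_posterior`.
#' @param schema,coding schema and [coding_map()].
#' @param n_draws simulation draws (default 10000; fewer than 100 triggers a
#'   warning).
#' @param seed integer seed; the result is deterministic given it.
#' @param clamp clamp out-of-range sampled outcomes to the design range.
#' @return object of class `preference_sim`: per-patient `prob` matrix
#'   (rows sum to 1), `modal` treatment per patient, `modal_share` and
#'   `mean_prob` cohort summaries, `n_extrapolated` outcome draws beyond the
#'   design range, `n_draws`, `seed`.
#' @export
simulate_menu <- function(profiles, posterior, schema, coding,
                          n_draws = 10000L, seed = 1L, clamp = FALSE) {
  if (length(profiles) < 2L) stop("need >= 2 treatment profiles")
  if (n_draws < 100L) warning("fewer than 100 draws; preference estimates will be unstable")
  core <- menu_sim_core(profiles, posterior, schema, coding, n_draws, seed,
                        clamp)
  nm <- vapply(profiles, `[[`, character(1L), "name")
  colnames(core$prob) <- nm
  modal <- nm[max.col(core$prob, ties.method = "first")]
  structure(list(
    prob = core$prob,
    modal = modal,
    modal_share = vapply(nm, function(t) mean(modal == t), numeric(1L)),
    mean_prob = colMeans(core$prob),
    n_extrapolated = core$n_extrapolated,
    n_draws = as.integer(n_draws), seed = as.integer(seed)
  ), class = "preference_sim")
}

#' @export
print.preference_sim <- function(x, ...) {
  cat(sprintf("Preference simulation: %d patients x %d draws\n",
              nrow(x$prob), x$n_draws))
  tab <- data.frame(treatment = names(x$mean_prob),
                    modal_share = round(x$modal_share, 3),
                    mean_prob = round(x$mean_prob, 3))
  print(tab, row.names = FALSE)
  if (x$n_extrapolated > 0L) {
    cat(sprintf("  note: %d outcome draws beyond the designed level range (extrapolated)\n",
                x$n_extrapolated))
  }
  invisible(x)
}

#' Pairwise treatment-preference matrix
#'
#' Runs the menu simulation on every unordered pair of profiles and reports
#' the probability (averaged over patients and draws) that the row treatment
#' is preferred to the column treatment. `P[A,B] + P[B,A] = 1` holds by
#' construction; the diagonal is `NA`.
#'
#' @inheritParams simulate_menu
#' @return matrix of pairwise preference probabilities with an
#'   `n_extrapolated` attribute.
#' @export
simulate_pairs <- function(profiles, posterior, schema, coding,
                           n_draws = 10000L, seed = 1L, clamp = FALSE) {
  K <- length(profiles)
  nm <- vapply(profiles, `[[`, character(1L), "name")
  P <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  pair_seeds <- spawn_seeds(seed, K * (K - 1L) / 2L)
  s <- 0L
  n_ex <- 0L
  for (a in seq_len(K - 1L)) for (b in seq.int(a + 1L, K)) {
    s <- s + 1L
    core <- menu_sim_core(profiles[c(a, b)], posterior, schema, coding,
                          n_draws, pair_seeds[s], clamp)
    pab <- mean(core$prob[, 1L])
    P[a, b] <- pab
    P[b, a] <- 1 - pab
    n_ex <- n_ex + core$n_extrapolated
  }
  attr(P, "n_extrapolated") <- n_ex
  P
}
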