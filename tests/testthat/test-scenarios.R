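sch <- crohn_schema()
cm <- coding_map(sch)

test_that("outcome reconstruction does the right logit arithmetic", {
  od <- fit_outcome_distribution(0.5, 0.269, 0.731)
  expect_equal(od$mean_logodds, 0)
  expect_equal(od$sd_logodds, (log(0.731 / 0.269) - log(0.269 / 0.731)) / (2 * 1.959964))
  expect_equal(od$sd_logodds, 0.5102, tolerance = 1e-3)
  set.seed(1)
  s <- sample_outcome(od, 1e5)
  expect_lt(abs(median(s) - 0.5), 0.01)
  # degenerate interval is a point mass
  odp <- fit_outcome_distribution(0.4, 0.4, 0.4)
  expect_equal(sample_outcome(odp, 10L), rep(0.4, 10L))
  expect_error(fit_outcome_distribution(0.5, 0.6, 0.7), "lo <= median")
})

test_that("reconstructed NMA intervals have ~95% coverage of their own CrI", {
  # infliximab remission 48% (33 to 64)
  od <- crohn_treatment_profiles()$infliximab$remission
  set.seed(2)
  s <- sample_outcome(od, 1e5)
  cover <- mean(s > 0.33 & s < 0.64)
  expect_lt(abs(cover - 0.95), 0.01)
  expect_lt(abs(median(s) - 0.48), 0.01)
})

test_that("profile utility is the sum of its part-utilities", {
  profs <- crohn_treatment_profiles()
  beta0 <- rep(0, 10)
  expect_equal(profile_utility(profs$adalimumab, beta0,
                               list(remission = 61, wdae = 2.3), sch, cm), 0)
  # two profiles differing only in the infection/cancer flag differ by 2*beta
  beta <- c(0.04, -0.03, 0.1, -0.05, 0.05, 0.1, -0.05, -0.2, -0.1, -0.3)
  pA <- profs$infliximab; pB <- profs$infliximab
  pB$infection_cancer <- "No"
  out <- list(remission = 48, wdae = 12)
  expect_equal(profile_utility(pB, beta, out, sch, cm) -
                 profile_utility(pA, beta, out, sch, cm),
               -2 * beta[10L], tolerance = 1e-12)
  # hand-computed toy: adalimumab at remission 61%, wdae 2.3%
  # x = (11, -13.2, dosing level 4 -> e4, pred +1, blood -1, infection +1)
  manual <- 0.04 * 11 + (-0.03) * (2.3 - 15.5) + 0.1 + (-0.2) + (0.1) + (-0.3)
  expect_equal(profile_utility(profs$adalimumab, beta,
                               list(remission = 61, wdae = 2.3), sch, cm),
               manual, tolerance = 1e-12)
})

test_that("out-of-range sampled outcomes warn unless clamped", {
  profs <- crohn_treatment_profiles()
  beta <- rep(0.01, 10)
  expect_warning(profile_utility(profs$methotrexate, beta,
                                 list(remission = 42, wdae = 38), sch, cm),
                 "extrapolating")
  expect_silent(profile_utility(profs$methotrexate, beta,
                                list(remission = 42, wdae = 38), sch, cm,
                                clamp = TRUE))
})

test_that("pure infection/cancer aversion forces vedolizumab", {
  profs <- crohn_treatment_profiles()
  beta <- rep(0, 10); beta[10L] <- -1
  post <- fake_posterior(matrix(beta, 1, 10),
                         beta = array(rep(beta, each = 4), c(1, 4, 10)),
                         par_names = cm$colnames)
  res <- simulate_menu(profs, post, sch, cm, n_draws = 300L, seed = 5L)
  expect_true(all(res$prob[, "vedolizumab"] == 1))
  expect_equal(unname(res$modal_share["vedolizumab"]), 1)
})

test_that("pure remission preference with point-mass outcomes forces the best treatment", {
  profs <- list(
    a = treatment_profile("a", fit_outcome_distribution(0.63, 0.63, 0.63),
                          fit_outcome_distribution(0.1, 0.1, 0.1), 1L,
                          "Yes", "Yes", "Yes"),
    b = treatment_profile("b", fit_outcome_distribution(0.36, 0.36, 0.36),
                          fit_outcome_distribution(0.1, 0.1, 0.1), 1L,
                          "Yes", "Yes", "Yes")
  )
  beta <- rep(0, 10); beta[1L] <- 0.05
  post <- fake_posterior(matrix(beta, 1, 10),
                         beta = array(rep(beta, each = 3), c(1, 3, 10)))
  res <- simulate_menu(profs, post, sch, cm, n_draws = 200L, seed = 6L)
  expect_true(all(res$prob[, "a"] == 1))
})

test_that("identical profiles split 50/50 and the pairwise matrix is coherent", {
  profs <- crohn_treatment_profiles()
  twin <- list(x = profs$infliximab, y = profs$infliximab)
  twin$y$name <- "infliximab_copy"
  spec <- default_population_spec(20L)
  prefs <- simulate_population(spec, seed = 7L)
  post <- fake_posterior(matrix(rep(0, 10), 1, 10),
                         beta = array(aperm(array(prefs$beta, c(20, 10, 50)),
                                            c(3, 1, 2)), c(50, 20, 10)))
  res <- simulate_menu(twin, post, sch, cm, n_draws = 4000L, seed = 8L)
  expect_lt(abs(mean(res$prob[, 1L]) - 0.5), 0.05)
  P <- simulate_pairs(profs[1:3], post, sch, cm, n_draws = 500L, seed = 9L)
  off <- which(upper.tri(P), arr.ind = TRUE)
  for (r in seq_len(nrow(off))) {
    expect_equal(P[off[r, 1L], off[r, 2L]] + P[off[r, 2L], off[r, 1L]], 1)
  }
  expect_true(all(is.na(diag(P))))
})

test_that("pairwise preference equals an independent logit-normal comparison oracle", {
  # benefit-only preferences: P(adalimumab > azathioprine) is exactly the
  # probability one reconstructed remission posterior exceeds the other
  profs <- crohn_treatment_profiles()
  beta <- rep(0, 10); beta[1L] <- 0.06
  post <- fake_posterior(matrix(beta, 1, 10),
                         beta = array(rep(beta, each = 10), c(1, 10, 10)))
  P <- simulate_pairs(profs[c("adalimumab", "azathioprine")], post, sch, cm,
                      n_draws = 10000L, seed = 10L)
  odA <- profs$adalimumab$remission; odB <- profs$azathioprine$remission
  set.seed(11)
  oracle <- mean(rnorm(1e6, odA$mean_logodds, odA$sd_logodds) >
                   rnorm(1e6, odB$mean_logodds, odB$sd_logodds))
  expect_lt(abs(P["adalimumab", "azathioprine"] - oracle), 0.02)
})

test_that("stochastically better remission cannot hurt a treatment", {
  profs <- crohn_treatment_profiles()
  better <- profs$azathioprine
  better$name <- "azathioprine_boosted"
  better$remission <- fit_outcome_distribution(0.55, 0.42, 0.68)
  spec <- default_population_spec(15L)
  prefs <- simulate_population(spec, seed = 12L)
  post <- fake_posterior(matrix(rep(0, 10), 1, 10),
                         beta = array(aperm(array(prefs$beta, c(15, 10, 40)),
                                            c(3, 1, 2)), c(40, 15, 10)))
  p_base <- simulate_pairs(list(a = profs$azathioprine, b = profs$infliximab),
                           post, sch, cm, n_draws = 4000L, seed = 13L)[1L, 2L]
  p_boost <- simulate_pairs(list(a = better, b = profs$infliximab),
                            post, sch, cm, n_draws = 4000L, seed = 13L)[1L, 2L]
  expect_gte(p_boost, p_base - 0.02)
})

test_that("sensitivity scenarios change exactly the documented flags", {
  profs <- crohn_treatment_profiles()
  base <- apply_sensitivity(profs, "base")
  expect_identical(base, profs)
  nopred <- apply_sensitivity(profs, "no_prednisone_biologics")
  changed <- vapply(names(profs), function(nm) {
    !identical(nopred[[nm]], profs[[nm]])
  }, logical(1L))
  expect_equal(sum(changed), 4L)
  expect_true(all(vapply(nopred[c("infliximab", "adalimumab", "vedolizumab",
                                  "infliximab_azathioprine")],
                         function(p) p$prednisone == "No", logical(1L))))
  tnf <- apply_sensitivity(profs, "antitnf_blood_liver")
  expect_equal(sum(vapply(names(profs), function(nm) {
    !identical(tnf[[nm]], profs[[nm]])
  }, logical(1L))), 2L)
  expect_error(apply_sensitivity(profs, "unknown"), "arg")
})

test_that("in the base scenario prednisone is constant and cannot matter", {
  profs <- crohn_treatment_profiles()
  expect_true(all(vapply(profs, `[[`, character(1L), "prednisone") == "Yes"))
})
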