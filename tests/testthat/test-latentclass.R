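# Two well-separated preference classes with opposite-sign risk part-worths,
# used across the recovery checks.
lc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- crohn_schema(); cm <- coding_map(sch)
      design <- generate_design(sch, n_versions = 10L, n_tasks = 13L,
                                n_alts = 3L, overlap_target = 0.7, seed = 61L)
      mu1 <- c(0.05, -0.03, 0.1, -0.05, 0.05, 0.1, -0.05, 0.5, 0.3, 0.6)
      mu2 <- c(0.02, -0.03, 0.1, -0.05, 0.05, 0.1, -0.05, -0.5, -0.3, -0.6)
      spec <- population_spec(120L, list(
        list(share = 0.55, mu = mu1, sigma = diag(rep(1e-4, 10))),
        list(share = 0.45, mu = mu2, sigma = diag(rep(1e-4, 10)))
      ))
      prefs <- simulate_population(spec, seed = 62L)
      choices <- simulate_choices(design, prefs, sch, cm, seed = 63L)
      cache <<- list(schema = sch, coding = cm, design = design,
                     prefs = prefs, choices = choices)
    }
    cache
  }
})

test_that("a one-class solution reduces to the pooled MNL maximum likelihood", {
  fx <- lc_fixture()
  sol <- fit_lc(fx$choices, fx$design, fx$schema, fx$coding, n_classes = 1L,
                n_starts = 2L, seed = 64L)
  expect_equal(sol$pi, 1)
  # independent pooled-MNL optimiser over the summed per-respondent loglik
  Xv <- lapply(seq_len(fx$design$n_versions), dcepref:::code_version,
               design = fx$design, schema = fx$schema, coding = fx$coding)
  pooled_nll <- function(b) {
    -sum(vapply(seq_len(nrow(fx$choices$main)), function(i) {
      mnl_loglik(b, Xv[[fx$choices$version[i]]], fx$choices$main[i, ],
                 n_alts = 3L)
    }, numeric(1L)))
  }
  ind <- stats::optim(rep(0, 10), pooled_nll, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  expect_equal(sol$loglik, -ind$value, tolerance = 1e-5)
})

test_that("two latent classes are recovered from a separated mixture", {
  fx <- lc_fixture()
  sol <- fit_lc(fx$choices, fx$design, fx$schema, fx$coding, n_classes = 2L,
                n_starts = 5L, seed = 65L)
  # align labels to truth via the risk part-worth sign
  k_pos <- which.max(sol$beta[, 10L])
  truth_pos <- 1L  # class 1 has the positive risk coefficients
  share_hat <- sol$pi[k_pos]
  true_share <- mean(fx$prefs$class == truth_pos)
  expect_lt(abs(share_hat - true_share), 0.05)
  asg <- assign_classes(sol)
  map <- if (k_pos == 1L) c(1L, 2L) else c(2L, 1L)
  acc <- mean(map[asg$assignments$class] == fx$prefs$class)
  expect_gte(acc, 0.9)
  # certainty: well-separated classes leave few ambiguous respondents,
  # recounted directly from the membership matrix
  expect_lt(asg$frac_below, 0.2)
  expect_equal(asg$n_below, sum(apply(sol$membership, 1L, max) < 0.9))
})

test_that("BIC prefers two classes for two-class data and penalises parameters", {
  fx <- lc_fixture()
  s1 <- fit_lc(fx$choices, fx$design, fx$schema, fx$coding, 1L,
               n_starts = 2L, seed = 66L)
  s2 <- fit_lc(fx$choices, fx$design, fx$schema, fx$coding, 2L,
               n_starts = 4L, seed = 66L)
  expect_lt(s2$bic, s1$bic)
  expect_equal(s1$q, 10); expect_equal(s2$q, 21)
  expect_equal(s2$bic, -2 * s2$loglik + 21 * log(120), tolerance = 1e-10)
})

test_that("EM log-likelihood is monotone within a start", {
  fx <- lc_fixture()
  sol <- fit_lc(fx$choices, fx$design, fx$schema, fx$coding, 2L,
                n_starts = 1L, seed = 67L)
  expect_true(all(diff(sol$ll_trace) > -1e-8))
})

test_that("membership rows sum to one and labels can be permuted freely", {
  fx <- lc_fixture()
  sol <- fit_lc(fx$choices, fx$design, fx$schema, fx$coding, 2L,
                n_starts = 2L, seed = 68L)
  expect_true(all(abs(rowSums(sol$membership) - 1) < 1e-12))
  # label switching: recompute the mixture LL with permuted classes
  prep <- dcepref:::prepare_hb_data(fx$choices, fx$design, fx$schema, fx$coding)
  mix_ll <- function(pi_k, Bmat) {
    llk <- dcepref:::loglik_by_class(Bmat, prep)
    sum(apply(sweep(llk, 2L, log(pi_k), `+`), 1L, dcepref:::log_sum_exp))
  }
  ll_orig <- mix_ll(sol$pi, t(sol$beta))
  ll_perm <- mix_ll(sol$pi[2:1], t(sol$beta)[, 2:1])
  expect_equal(ll_orig, ll_perm, tolerance = 1e-12)
  expect_equal(ll_orig, sol$loglik, tolerance = 1e-6)
})

test_that("tied membership rows go to the lowest class index and are flagged", {
  sol <- structure(list(membership = rbind(c(0.95, 0.05), c(0.5, 0.5))),
                   class = "latent_class_solution")
  asg <- assign_classes(sol)
  expect_equal(asg$assignments$class, c(1L, 1L))
  expect_equal(asg$assignments$tie, c(FALSE, TRUE))
  expect_equal(asg$assignments$below_threshold, c(FALSE, TRUE))
})
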