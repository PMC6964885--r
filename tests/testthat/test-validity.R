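test_that("choosing a dominated warm-up alternative is a failure", {
  warmups <- list(list(dominated = 2L), list(dominated = 3L))
  resp <- rbind(c(2L, 1L),   # picked dominated once -> fail
                c(1L, 1L),   # never -> pass
                c(2L, 3L),   # both -> fail
                c(1L, NA))   # missing answer -> not assessable
  out <- check_dominated(warmups, resp)
  expect_equal(out$pass, c(FALSE, TRUE, FALSE, NA))
  expect_equal(out$n_failed, c(1, 0, 2, 0))
})

test_that("strong-preference cohorts essentially never fail the warm-ups", {
  fx <- crohn_fixture()
  spec <- population_spec(200L, list(list(
    share = 1, mu = 10 * dcepref:::default_population_spec(1)$classes[[1]]$mu,
    sigma = diag(rep(1e-6, 10))
  )))
  prefs <- simulate_population(spec, seed = 71L)
  ch <- simulate_choices(fx$design, prefs, fx$schema, fx$coding, seed = 72L)
  out <- check_dominated(fx$design$warmups, ch$warmup)
  expect_lt(mean(!out$pass), 0.02)
})

test_that("injected straight-liners are always flagged; counts recount", {
  fx <- crohn_fixture()
  spec <- default_population_spec(40L, n_straightliners = 6L)
  prefs <- simulate_population(spec, seed = 73L)
  ch <- simulate_choices(fx$design, prefs, fx$schema, fx$coding, seed = 74L)
  pos <- position_profile(ch)
  expect_true(all(pos$flag[prefs$behavior == "straightliner"]))
  # cohort aggregates recomputed independently
  expect_equal(pos$position_shares,
               as.vector(table(factor(ch$main, levels = 1:3))) / length(ch$main))
  expect_equal(sum(pos$position_shares), 1)
  expect_equal(rowSums(pos$counts), rep(13, 40))
})

test_that("random-chooser straight-lining rate matches the exact trinomial tail", {
  fx <- crohn_fixture()
  # flag rule: share > 9/13, i.e. max position count >= 10 of 13
  p_exact <- dcepref:::straightline_probability(13L, 3L, k = 10L)
  spec <- population_spec(4000L, list(list(share = 1, mu = rep(0, 10),
                                           sigma = matrix(0, 10, 10))))
  prefs <- simulate_population(spec, seed = 75L)
  ch <- simulate_choices(fx$design, prefs, fx$schema, fx$coding, seed = 76L)
  rate <- mean(position_profile(ch)$flag)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(rate - p_exact), 4 * se + 1e-12)
})

test_that("injected attribute-dominant respondents are always detected", {
  fx <- crohn_fixture()
  spec <- default_population_spec(
    40L, n_attribute_dominant = c(remission = 4L, prednisone = 3L))
  prefs <- simulate_population(spec, seed = 77L)
  ch <- simulate_choices(fx$design, prefs, fx$schema, fx$coding, seed = 78L)
  dom <- attribute_dominance(ch, fx$design, fx$schema)
  rem_injected <- which(prefs$dominant_attr == "remission")
  pred_injected <- which(prefs$dominant_attr == "prednisone")
  expect_true(all(dom$dominant[rem_injected, "remission"]))
  expect_true(all(dom$dominant[pred_injected, "prednisone"]))
  expect_false("dosing" %in% colnames(dom$dominant))
})

test_that("one violating task removes dominance", {
  fx <- crohn_fixture()
  spec <- default_population_spec(3L, n_attribute_dominant = c(remission = 3L))
  prefs <- simulate_population(spec, seed = 79L)
  ch <- simulate_choices(fx$design, prefs, fx$schema, fx$coding, seed = 80L)
  # force respondent 1 off the best remission level in task 1
  v <- ch$version[1L]
  rem <- fx$design$cells[v, 1L, , 1L]
  worst <- which.min(rem)
  if (rem[worst] == max(rem)) skip("task has constant remission; cannot violate")
  ch$main[1L, 1L] <- worst
  dom <- attribute_dominance(ch, fx$design, fx$schema)
  expect_false(dom$dominant[1L, "remission"])
})

test_that("uniform-chooser dominance rate matches per-task enumeration", {
  fx <- crohn_fixture()
  # exact: a uniform chooser is remission-dominant on version v with
  # probability prod_t (#alternatives attaining the task's best level / 3)
  n <- 3000L
  version <- ((seq_len(n) - 1L) %% fx$design$n_versions) + 1L
  p_dom_v <- vapply(seq_len(fx$design$n_versions), function(v) {
    prod(vapply(seq_len(13L), function(t) {
      rem <- fx$design$cells[v, t, , 1L]
      sum(rem == max(rem)) / 3
    }, numeric(1L)))
  }, numeric(1L))
  p_exact <- mean(p_dom_v[version])
  spec <- population_spec(n, list(list(share = 1, mu = rep(0, 10),
                                       sigma = matrix(0, 10, 10))))
  prefs <- simulate_population(spec, seed = 81L)
  ch <- simulate_choices(fx$design, prefs, fx$schema, fx$coding, seed = 82L)
  dom <- attribute_dominance(ch, fx$design, fx$schema)
  rate <- mean(dom$dominant[, "remission"])
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_lt(abs(rate - p_exact), 4 * se + 0.002)
})

test_that("the full validity report aggregates all three audits", {
  fx <- crohn_fixture()
  vr <- validity_report(fx$choices, fx$design, fx$schema)
  expect_s3_class(vr, "validity_report")
  expect_equal(sum(vr$position$position_shares), 1)
  expect_false(is.null(vr$warmup))
  expect_true(vr$warmup_failure_rate >= 0 && vr$warmup_failure_rate <= 1)
})
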