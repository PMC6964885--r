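sch <- crohn_schema()
cm <- coding_map(sch)

# mu draws with remission dominant, in the study's qualitative pattern
make_mu_draws <- function(D, seed = 1) {
  set.seed(seed)
  base <- c(0.04, -0.03, 0.12, -0.06, 0.04, 0.09, -0.02, -0.2, -0.1, -0.25)
  sweep(matrix(rnorm(D * 10, sd = 0.003), D, 10), 2L, base, `+`)
}

test_that("a known single draw scales exactly: max |u| = 4 maps to factor 2.5", {
  # one linear attribute with extreme utilities -4/+4 and one binary +-1
  sch2 <- attribute_schema(
    attribute("ben", "linear", c(0, 100), center = 50, ordering = "increasing"),
    attribute("risk", "binary", c("Yes", "No"), ordering = "increasing")
  )
  cm2 <- coding_map(sch2)
  post <- fake_posterior(matrix(c(0.08, -1), 1, 2))  # ben range +-4, risk +-1
  su <- scale_utilities(post, sch2, cm2)
  expect_equal(unname(su$factors), 2.5)
  tab <- su$table
  expect_equal(tab$median[tab$attribute == "ben"], c(-10, 10))
  expect_equal(tab$median[tab$attribute == "risk"], c(-2.5, 2.5))
  # single-draw posterior: medians equal that draw's scaled values, CrI is flat
  expect_equal(tab$lo, tab$median)
})

test_that("scaled utilities stay in [-10, 10] with the extreme at 10 and preserved ordering", {
  post <- fake_posterior(make_mu_draws(400), par_names = cm$colnames)
  su <- scale_utilities(post, sch, cm)
  expect_true(all(su$table$median >= -10 & su$table$median <= 10))
  expect_equal(max(abs(su$table$median)), 10)
  # monotone transform: scaled ordering within each attribute equals the
  # unscaled ordering of the posterior-median utilities
  mu_med <- apply(dcepref:::mu_draws(post), 2L, median)
  lu <- level_utilities(mu_med, sch, cm)
  for (a in names(lu)) {
    expect_equal(order(su$table$median[su$table$attribute == a]),
                 order(lu[[a]]))
  }
})

test_that("relative importance normalises ranges draw by draw", {
  # ranges 6, 3, 1 -> importance 60/30/10
  sch3 <- attribute_schema(
    attribute("a", "linear", c(0, 10), center = 5, ordering = "increasing"),
    attribute("b", "linear", c(0, 10), center = 5, ordering = "increasing"),
    attribute("c", "linear", c(0, 10), center = 5, ordering = "increasing")
  )
  cm3 <- coding_map(sch3)
  post <- fake_posterior(matrix(c(0.6, 0.3, 0.1), 1, 3))
  ri <- relative_importance(post, sch3, cm3)
  expect_equal(ri$table$importance, c(60, 30, 10))
  # zero-range attribute gets zero importance
  post0 <- fake_posterior(matrix(c(0.6, 0, 0.1), 1, 3))
  expect_equal(relative_importance(post0, sch3, cm3)$table$importance[2L], 0)
})

test_that("relative importance sums to 100 on every draw and is scale invariant", {
  post <- fake_posterior(make_mu_draws(300), par_names = cm$colnames)
  ri <- relative_importance(post, sch, cm)
  expect_true(all(abs(rowSums(ri$draws) - 100) < 1e-9))
  expect_equal(sum(ri$table$importance), 100, tolerance = 1e-9)
  # common positive rescaling of a draw's utilities leaves RI unchanged
  post2 <- fake_posterior(3.7 * make_mu_draws(300), par_names = cm$colnames)
  ri2 <- relative_importance(post2, sch, cm)
  expect_equal(ri$draws, ri2$draws, tolerance = 1e-9)
})

test_that("MRS closed form: slope 0.10 and level difference 1.44 give 14.4 points", {
  mu <- rep(0, 10); mu[1] <- 0.10; mu[10] <- -0.72  # 2|beta| = 1.44
  post <- fake_posterior(matrix(mu, 1, 10), par_names = cm$colnames)
  row <- mrs(post, sch, cm, "infection_cancer")
  expect_equal(row$median, 14.4, tolerance = 1e-10)
  # zero aversion -> zero MRS; doubling both leaves the ratio unchanged
  mu0 <- mu; mu0[10] <- 0
  expect_equal(mrs(fake_posterior(matrix(mu0, 1, 10)), sch, cm,
                   "infection_cancer")$median, 0)
  expect_equal(mrs(fake_posterior(matrix(2 * mu, 1, 10)), sch, cm,
                   "infection_cancer")$median, 14.4, tolerance = 1e-10)
})

test_that("MRS equals a grid-search utility-equating oracle", {
  # oracle: find the remission increase (to 0.01 points) equating the total
  # utility of two profiles that differ only in the target binary level
  draws <- make_mu_draws(25, seed = 9)
  post <- fake_posterior(draws, par_names = cm$colnames)
  for (attr in c("prednisone", "blood_liver", "infection_cancer")) {
    vals <- mrs(post, sch, cm, attr)
    idx <- cm$columns[[attr]]$idx
    oracle <- vapply(seq_len(nrow(draws)), function(d) {
      beta <- draws[d, ]
      grid <- seq(0, 40, by = 0.01)
      # utility gap between the bad-level profile with remission raised by
      # delta and the good-level profile at baseline remission:
      # (beta_idx + delta*b) - (-beta_idx) = 2*beta_idx + delta*b
      gap <- abs(2 * beta[idx] + grid * beta[1L])
      grid[which.min(gap)]
    }, numeric(1L))
    expect_lt(abs(vals$median - median(oracle)), 0.01 + 1e-9)
  }
})

test_that("an unstable benefit slope is flagged", {
  set.seed(11)
  draws <- cbind(rnorm(200, 0, 0.05), matrix(0, 200, 8), rnorm(200, -0.3, 0.05))
  post <- fake_posterior(draws, par_names = cm$colnames)
  expect_warning(mrs(post, sch, cm, "infection_cancer"), "unstable")
})
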