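# Shared fixtures, built in code. Heavier objects are created once per test
# run and memoised here.

toy_schema <- function() {
  attribute_schema(
    attribute("benefit", "linear", c(0, 50, 100), ordering = "increasing",
              center = 50),
    attribute("risk", "binary", c("Yes", "No"), ordering = "increasing")
  )
}

one_attr_schema <- function(L = 3L) {
  attribute_schema(
    attribute("a", "categorical", paste0("l", seq_len(L)), ordering = "none")
  )
}

# Build an hb_posterior-shaped object from explicit draws, for testing the
# summary and scenario layers in isolation from the sampler.
fake_posterior <- function(mu, beta = NULL, par_names = NULL) {
  mu <- as.matrix(mu)                       # draws x p
  D <- nrow(mu); p <- ncol(mu)
  mu_a <- array(NA_real_, c(1L, D, p)); mu_a[1L, , ] <- mu
  if (is.null(beta)) {
    n <- 1L
    beta_a <- array(NA_real_, c(1L, D, 1L, p)); beta_a[1L, , 1L, ] <- mu
  } else {
    n <- dim(beta)[2L]
    beta_a <- array(NA_real_, c(1L, dim(beta)))
    beta_a[1L, , , ] <- beta
  }
  sig_a <- array(0, c(1L, D, p, p))
  structure(list(mu = mu_a, sigma = sig_a, beta = beta_a,
                 loglik = matrix(0, 1L, D),
                 accept_rate = matrix(0.23, 1L, n),
                 settings = NULL, par_names = par_names %||% paste0("b", 1:p),
                 n_respondents = n),
            class = "hb_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small simulated cohort on the full Crohn schema, shared across tests.
crohn_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- crohn_schema()
      cm <- coding_map(sch)
      design <- generate_design(sch, n_versions = 10L, n_tasks = 13L,
                                n_alts = 3L, overlap_target = 0.7, seed = 11L)
      design$warmups <- make_warmups(sch, 2L, seed = 12L)
      spec <- default_population_spec(60L)
      prefs <- simulate_population(spec, seed = 13L)
      choices <- simulate_choices(design, prefs, sch, cm, seed = 14L)
      cache <<- list(schema = sch, coding = cm, design = design,
                     spec = spec, prefs = prefs, choices = choices)
    }
    cache
  }
})

# Brute-force MNL log-likelihood: direct probability enumeration, no
# log-sum-exp tricks; the independent oracle for mnl_loglik.
brute_mnl_loglik <- function(beta, tasks, choices) {
  ll <- 0
  for (t in seq_len(dim(tasks)[1L])) {
    u <- as.matrix(tasks[t, , ]) %*% beta
    pr <- exp(u) / sum(exp(u))
    ll <- ll + log(pr[choices[t]])
  }
  ll
}
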