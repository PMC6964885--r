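#' Multinomial-logit log-likelihood for one respondent
#'
#' `sum_t [ x_chosen' beta - log sum_j exp(x_j' beta) ]`, computed with the
#' log-sum-exp guard. The likelihood is invariant to adding a constant to all
#' alternatives' utilities within a task.
#'
#' @param beta part-worth vector (length p).
#' @param tasks coded task set: either a 3-d array `[task, alt, p]` or a
#'   `(n_tasks*n_alts) x p` matrix with rows ordered task-major.
#' @param choices integer vector of chosen alternative indices, one per task.
#' @param n_alts alternatives per task (required when `tasks` is a matrix).
#' @return the log-likelihood (scalar).
#' @export
mnl_loglik <- function(beta, tasks, choices, n_alts = NULL) {
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (is.array(tasks) && length(dim(tasks)) == 3L) {
    n_alts <- dim(tasks)[2L]
    X <- matrix(aperm(tasks, c(2L, 1L, 3L)), ncol = dim(tasks)[3L])
  } else {
    X <- as.matrix(tasks)
    if (is.null(n_alts)) stop("n_alts required for matrix input")
  }
  nt <- nrow(X) / n_alts
  stopifnot(nt == length(choices), nt == as.integer(nt))
  u <- matrix(X %*% beta, ncol = n_alts, byrow = TRUE)
  sum(u[cbind(seq_len(nt), choices)] - row_log_sum_exp(u))
}

#' MCMC settings for the hierarchical Bayesian sampler
#'
#' Defaults reproduce the full-scale analysis configuration (3 chains,
#' 150,000 burn-in and 350,000 monitoring iterations; draws thinned to 1,000
#' stored per chain). Interactive exploration and test suites should pass a
#' scaled-down profile.
#'
#' @param n_chains number of parallel chains (>= 2 so convergence can be
#'   diagnosed).
#' @param n_burnin,n_monitor burn-in and monitoring iterations per chain.
#' @param thin store every `thin`-th monitored draw.
#' @param adapt_window iterations between proposal-scale adaptations during
#'   burn-in.
#' @param adapt_target target Metropolis acceptance rate (0.234, the classic
#'   random-walk optimum).
#' @param mu_prior_var prior variance of the population mean,
#'   `mu ~ N(0, mu_prior_var * I)`.
#' @param wishart_df,wishart_scale inverse-Wishart prior on the population
#'   covariance, `Sigma ~ IW(wishart_df, wishart_scale)`; defaults (set at
#'   fit time when NULL) are `p + 3` and `0.01 * I`. The scale matrix enters
#'   the posterior as additive prior scatter, so it is kept small relative to
#'   any plausible part-worth variance on the per-percentage-point coding;
#'   an identity scale would dominate the data for realistic heterogeneity.
#' @param seed master seed; chain seeds are spawned from it.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_burnin = 150000L,
                          n_monitor = 350000L, thin = NULL,
                          adapt_window = 50L, adapt_target = 0.234,
                          mu_prior_var = 100, wishart_df = NULL,
                          wishart_scale = NULL, seed = 1L) {
  if (n_chains < 2L) stop("n_chains must be >= 2 (convergence diagnostics need parallel chains)")
  stopifnot(n_burnin >= 1L, n_monitor >= 1L)
  thin <- thin %||% max(1L, as.integer(n_monitor / 1000L))
  if (n_monitor %% thin != 0L) stop("n_monitor must be a multiple of thin")
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_monitor = as.integer(n_monitor), thin = as.integer(thin),
                 adapt_window = as.integer(adapt_window),
                 adapt_target = adapt_target, mu_prior_var = mu_prior_var,
                 wishart_df = wishart_df, wishart_scale = wishart_scale,
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Stack each respondent's coded version into one big covariate matrix plus
# the index vectors the vectorised likelihood needs.
prepare_hb_data <- function(data, design, schema, coding) {
  stopifnot(inherits(data, "respondent_choices"))
  n <- nrow(data$main)
  nt <- ncol(data$main); na <- data$n_alts
  if (nt != design$n_tasks || na != design$n_alts) {
    stop("choices and design dimensions disagree")
  }
  if (any(data$version < 1L | data$version > design$n_versions)) {
    stop("respondent mapped to a non-existent design version")
  }
  if (nt == 0L) stop("respondent with zero tasks")
  Xv <- lapply(seq_len(design$n_versions), code_version,
               design = design, schema = schema, coding = coding)
  X <- do.call(rbind, Xv[data$version])          # (n*nt*na) x p, resp-major
  chosen <- cbind(seq_len(n * nt), as.integer(t(data$main)))
  list(X = X, chosen = chosen, n = n, nt = nt, na = na, p = coding$p)
}

# Log-likelihood of every respondent under their own part-worth row of B.
loglik_all <- function(B, prep) {
  ridx <- rep(seq_len(prep$n), each = prep$nt * prep$na)
  u <- rowSums(prep$X * B[ridx, , drop = FALSE])
  um <- matrix(u, ncol = prep$na, byrow = TRUE)
  task_ll <- um[prep$chosen] - row_log_sum_exp(um)
  colSums(matrix(task_ll, nrow = prep$nt))
}

#' Fit the hierarchical Bayesian multinomial logit
#'
#' Individual part-worth vectors `beta_i` follow a population multivariate
#' normal `N(mu, Sigma)`; choices follow a multinomial logit given `beta_i`.
#' The sampler is Metropolis-within-Gibbs: a per-respondent random-walk
#' Metropolis step on `beta_i` (spherical normal proposal whose scale adapts
#' toward ~23% acceptance during burn-in), then conjugate Gibbs draws of `mu`
#' (normal) and `Sigma` (inverse-Wishart). Priors are weakly informative:
#' `mu ~ N(0, 100 I)`, `Sigma ~ IW(p + 3, I)` by default. Warm-up tasks never
#' enter the likelihood. The fit is deterministic given the settings seed.
#'
#' @param data a `respondent_choices` object (>= 2 respondents).
#' @param design the `choice_design` the respondents answered.
#' @param schema,coding schema and [coding_map()].
#' @param settings an [mcmc_settings()] profile.
#' @param verbose print per-chain progress.
#' @return object of class `hb_posterior` with draw arrays `mu[chain, draw,
#'   p]`, `sigma[chain, draw, p, p]`, `beta[chain, draw, n, p]`, per-chain
#'   acceptance rates, a total log-likelihood trace, and the settings.
#' @export
fit_hb <- function(data, design, schema, coding, settings = mcmc_settings(),
                   verbose = FALSE) {
  prep <- prepare_hb_data(data, design, schema, coding)
  if (prep$n < 2L) stop("need >= 2 respondents")
  p <- prep$p; n <- prep$n
  nu0 <- settings$wishart_df %||% (p + 3)
  S0 <- settings$wishart_scale %||% (0.01 * diag(p))
  v0 <- settings$mu_prior_var
  n_store <- settings$n_monitor %/% settings$thin
  chain_seeds <- spawn_seeds(settings$seed, settings$n_chains)

  mu_d <- array(NA_real_, c(settings$n_chains, n_store, p))
  sig_d <- array(NA_real_, c(settings$n_chains, n_store, p, p))
  beta_d <- array(NA_real_, c(settings$n_chains, n_store, n, p))
  ll_d <- matrix(NA_real_, settings$n_chains, n_store)
  acc_rate <- matrix(NA_real_, settings$n_chains, n)
  adapted <- rep(TRUE, settings$n_chains)

  for (ch in seq_len(settings$n_chains)) {
    res <- with_seed(chain_seeds[ch],
                     run_hb_chain(prep, settings, nu0, S0, v0, n_store,
                                  verbose = verbose, chain_id = ch))
    mu_d[ch, , ] <- res$mu
    sig_d[ch, , , ] <- res$sigma
    beta_d[ch, , , ] <- res$beta
    ll_d[ch, ] <- res$ll
    acc_rate[ch, ] <- res$acc_rate
    adapted[ch] <- res$adapted
  }
  if (!all(adapted)) {
    warning("proposal adaptation did not settle near the target acceptance rate in at least one chain")
  }
  structure(list(mu = mu_d, sigma = sig_d, beta = beta_d, loglik = ll_d,
                 accept_rate = acc_rate, settings = settings,
                 par_names = coding$colnames, n_respondents = n),
            class = "hb_posterior")
}

# Pooled (homogeneous) MNL maximum likelihood, used to warm-start chains.
pooled_mnl <- function(prep) {
  nll <- function(b) {
    um <- matrix(prep$X %*% b, ncol = prep$na, byrow = TRUE)
    -sum(um[prep$chosen] - row_log_sum_exp(um))
  }
  stats::optim(numeric(prep$p), nll, method = "BFGS",
               control = list(maxit = 200L))$par
}

# Average per-respondent Fisher information of the MNL likelihood at beta,
# used to shape the Metropolis proposal.
avg_fisher_info <- function(prep, beta) {
  um <- matrix(prep$X %*% beta, ncol = prep$na, byrow = TRUE)
  pr <- exp(um - row_log_sum_exp(um))          # (n*nt) tasks x na
  pvec <- as.vector(t(pr))                     # matches prep$X row order
  H <- crossprod(prep$X * sqrt(pvec))          # sum_j p_j x x'
  xbar <- rowsum(prep$X * pvec,
                 rep(seq_len(prep$n * prep$nt), each = prep$na))
  (H - crossprod(xbar)) / prep$n
}

run_hb_chain <- function(prep, settings, nu0, S0, v0, n_store,
                         verbose = FALSE, chain_id = 1L) {
  n <- prep$n; p <- prep$p
  # warm start: pooled MNL estimate plus chain-specific jitter, and a
  # moderate initial heterogeneity; burn-in then only has to adapt locally
  b0 <- pooled_mnl(prep)
  B <- matrix(rep(b0, each = n), n, p) + matrix(stats::rnorm(n * p, sd = 0.1), n, p)
  mu <- b0 + stats::rnorm(p, sd = 0.1)
  Sigma <- diag(p) / 10
  Hbar <- avg_fisher_info(prep, b0)
  # translation-move proposal: shaped by the pooled-likelihood information
  group_chol <- chol(chol2inv(chol(n * Hbar)))
  g_scale <- 1
  g_acc <- 0L; g_win <- 0L
  sc_step <- 0.3
  sc_acc <- 0L; sc_win <- 0L
  scales <- rep(2.38 / sqrt(p), n)
  ll <- loglik_all(B, prep)
  acc_count <- numeric(n)
  win_count <- numeric(n)
  last_win_rate <- rep(NA_real_, n)
  total <- settings$n_burnin + settings$n_monitor
  mu_out <- matrix(NA_real_, n_store, p)
  sig_out <- array(NA_real_, c(n_store, p, p))
  beta_out <- array(NA_real_, c(n_store, n, p))
  ll_out <- numeric(n_store)
  s <- 0L
  I0 <- diag(p) / v0

  for (iter in seq_len(total)) {
    Sig_inv <- chol2inv(chol(Sigma))
    # --- random-walk Metropolis on every beta_i (vectorised over
    # respondents); the proposal is shaped by the approximate conditional
    # posterior covariance (H + Sigma^-1)^-1 so likelihood-dominated and
    # prior-dominated directions mix at comparable rates
    prop_chol <- chol(chol2inv(chol(Hbar + Sig_inv)))
    Bp <- B + (matrix(stats::rnorm(n * p), n, p) %*% prop_chol) * scales
    llp <- loglik_all(Bp, prep)
    Bc <- sweep(B, 2L, mu); Bpc <- sweep(Bp, 2L, mu)
    lp <- -0.5 * rowSums((Bc %*% Sig_inv) * Bc)
    lpp <- -0.5 * rowSums((Bpc %*% Sig_inv) * Bpc)
    accept <- log(stats::runif(n)) < (llp + lpp - ll - lp)
    if (any(accept)) {
      B[accept, ] <- Bp[accept, , drop = FALSE]
      ll[accept] <- llp[accept]
    }
    acc_count <- acc_count + accept
    win_count <- win_count + accept
    if (iter <= settings$n_burnin && iter %% settings$adapt_window == 0L) {
      rate <- win_count / settings$adapt_window
      scales <- scales * exp(rate - settings$adapt_target)
      last_win_rate <- rate
      win_count[] <- 0
    }
    # --- joint translation move: shift mu and every beta_i together, so the
    # population location mixes at the pooled-likelihood rate even when the
    # heterogeneity Sigma is small (avoids the hierarchical "funnel")
    delta <- drop(stats::rnorm(p) %*% group_chol) * g_scale
    ll_g <- loglik_all(sweep(B, 2L, delta, `+`), prep)
    lp_mu <- -0.5 * sum(mu^2) / v0
    lp_mu_p <- -0.5 * sum((mu + delta)^2) / v0
    if (log(stats::runif(1L)) < sum(ll_g) - sum(ll) + lp_mu_p - lp_mu) {
      B <- sweep(B, 2L, delta, `+`)
      mu <- mu + delta
      ll <- ll_g
      g_acc <- g_acc + 1L
    }
    g_win <- g_win + 1L
    if (iter <= settings$n_burnin && g_win == settings$adapt_window) {
      g_scale <- g_scale * exp(g_acc / g_win - settings$adapt_target)
      g_acc <- 0L; g_win <- 0L
    }
    # --- conjugate Gibbs: mu | B, Sigma  then  Sigma | B, mu
    V <- chol2inv(chol(n * Sig_inv + I0))
    mu <- drop(MASS::mvrnorm(1L, V %*% (Sig_inv %*% colSums(B)), V))
    Bc <- sweep(B, 2L, mu)
    S_post <- S0 + crossprod(Bc)
    W <- stats::rWishart(1L, nu0 + n, chol2inv(chol(S_post)))[, , 1L]
    Sigma <- chol2inv(chol(W))
    Sigma <- (Sigma + t(Sigma)) / 2
    # --- interweaving-style scale move: rescale the deviations B - mu and
    # Sigma together (one coordinate or all), so the heterogeneity scale
    # mixes even when the likelihood only weakly identifies it. The normal
    # prior and the B-Jacobian cancel exactly; what remains is the
    # likelihood ratio, the IW prior ratio and the Sigma-Jacobian.
    j <- if (stats::runif(1L) < 0.5) 0L else sample.int(p, 1L)
    logc <- stats::rnorm(1L, 0, sc_step)
    Dv <- rep(1, p)
    if (j == 0L) Dv[] <- exp(logc / 2) else Dv[j] <- exp(logc / 2)
    Bs <- sweep(sweep(B, 2L, mu), 2L, Dv, `*`) + rep(mu, each = n)
    Sigma_s <- Sigma * outer(Dv, Dv)
    ll_s <- loglik_all(Bs, prep)
    Sig_inv_cur <- chol2inv(chol(Sigma))
    Sig_inv_s <- Sig_inv_cur / outer(Dv, Dv)
    sum_logD <- sum(log(Dv))
    log_iw <- -(nu0 + p + 1) * sum_logD -
      0.5 * (sum(S0 * Sig_inv_s) - sum(S0 * Sig_inv_cur))
    log_acc <- (sum(ll_s) - sum(ll)) + log_iw + (p + 1) * sum_logD
    if (log(stats::runif(1L)) < log_acc) {
      B <- Bs; Sigma <- Sigma_s; ll <- ll_s
      sc_acc <- sc_acc + 1L
    }
    sc_win <- sc_win + 1L
    if (iter <= settings$n_burnin && sc_win == settings$adapt_window) {
      sc_step <- sc_step * exp(sc_acc / sc_win - 0.44)
      sc_acc <- 0L; sc_win <- 0L
    }

    if (iter > settings$n_burnin &&
        (iter - settings$n_burnin) %% settings$thin == 0L) {
      s <- s + 1L
      mu_out[s, ] <- mu
      sig_out[s, , ] <- Sigma
      beta_out[s, , ] <- B
      ll_out[s] <- sum(ll)
    }
    if (verbose && iter %% 1000L == 0L) {
      message(sprintf("chain %d: iter %d/%d, mean acc %.2f",
                      chain_id, iter, total, mean(acc_count) / iter))
    }
  }
  list(mu = mu_out, sigma = sig_out, beta = beta_out, ll = ll_out,
       acc_rate = acc_count / total,
       adapted = all(is.na(last_win_rate)) ||
         mean(abs(last_win_rate - settings$adapt_target)) < 0.25)
}

#' @export
print.hb_posterior <- function(x, ...) {
  d <- dim(x$mu)
  cat(sprintf("HB-MNL posterior: %d chains x %d stored draws, %d respondents, %d part-worths\n",
              d[1L], d[2L], x$n_respondents, d[3L]))
  cat(sprintf("  mean Metropolis acceptance: %.2f\n", mean(x$accept_rate)))
  gr <- gelman_rubin(x)
  cat(sprintf("  max PSRF: %.3f (%s)\n", gr$max,
              if (gr$pass) "< 1.10, converged" else ">= 1.10"))
  invisible(x)
}

# Pool population-mean draws across chains into one (draws x p) matrix.
mu_draws <- function(posterior) {
  d <- dim(posterior$mu)
  m <- matrix(aperm(posterior$mu, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
  colnames(m) <- posterior$par_names
  m
}

# Pool respondent-level draws: list of (draws x p) per respondent is too
# large; return array (total_draws, n, p).
beta_draws <- function(posterior) {
  d <- dim(posterior$beta)
  array(aperm(posterior$beta, c(2L, 1L, 3L, 4L)),
        c(d[1L] * d[2L], d[3L], d[4L]))
}

#' Gelman-Rubin-Brooks potential scale reduction factor
#'
#' Classic multi-chain PSRF: with `W` the mean within-chain variance and
#' `B/n` the variance of the chain means, `var+ = ((n-1)/n) W + B/n` and
#' `Rhat = sqrt(var+/W)`, floored at 1 (with no between-chain spread the
#' unbiased `var+` slightly underestimates `W`). Values near 1 indicate the
#' chains have mixed; the conventional convergence threshold is 1.10.
#' Computed without chain-splitting; `split = TRUE` halves each chain first.
#'
#' @param x an `hb_posterior` (PSRF per population parameter) or a numeric
#'   matrix with one chain per column.
#' @param ... passed to methods.
#' @return for matrices, a single PSRF; for posteriors, a list with `psrf`
#'   (named vector over `mu` and the `Sigma` diagonal), `max`, `pass`
#'   (max < threshold), and `degenerate` (parameters with zero within-chain
#'   variance, whose PSRF is undefined and returned as `NA`).
#' @export
gelman_rubin <- function(x, ...) UseMethod("gelman_rubin")

#' @rdname gelman_rubin
#' @param split halve each chain before computing the statistic.
#' @export
gelman_rubin.matrix <- function(x, split = FALSE, ...) {
  if (split) {
    half <- floor(nrow(x) / 2L)
    x <- cbind(x[seq_len(half), , drop = FALSE],
               x[seq.int(nrow(x) - half + 1L, nrow(x)), , drop = FALSE])
  }
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("need >= 2 chains")
  if (n < 10L) stop("need >= 10 draws per chain")
  W <- mean(apply(x, 2L, stats::var))
  if (W == 0) return(NA_real_)  # degenerate: no within-chain variation
  B_over_n <- stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B_over_n
  max(1, sqrt(var_plus / W))
}

#' @rdname gelman_rubin
#' @param threshold convergence threshold for the pass flag (default 1.10).
#' @export
gelman_rubin.hb_posterior <- function(x, threshold = 1.10, split = FALSE, ...) {
  d <- dim(x$mu)
  p <- d[3L]
  chains_of <- function(v) matrix(v, d[2L], d[1L])  # draws x chains
  psrf <- c(
    vapply(seq_len(p), function(j) {
      gelman_rubin.matrix(t(x$mu[, , j, drop = TRUE]) , split = split)
    }, numeric(1L)),
    vapply(seq_len(p), function(j) {
      gelman_rubin.matrix(t(x$sigma[, , j, j]), split = split)
    }, numeric(1L))
  )
  names(psrf) <- c(paste0("mu_", x$par_names),
                   paste0("sigma_", x$par_names))
  list(psrf = psrf,
       max = if (all(is.na(psrf))) NA_real_ else max(psrf, na.rm = TRUE),
       pass = isTRUE(max(psrf, na.rm = TRUE) < threshold),
       degenerate = names(psrf)[is.na(psrf)])
}
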