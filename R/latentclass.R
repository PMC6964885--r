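# Latent-class multinomial logit: a finite mixture of within-class
# homogeneous MNL models over respondents, fitted by EM with multi-start.

# Log-likelihood of every respondent under every class part-worth vector:
# returns n x K matrix. Bmat is p x K.
loglik_by_class <- function(Bmat, prep) {
  u <- prep$X %*% Bmat                                # (n*nt*na) x K
  out <- matrix(NA_real_, prep$n, ncol(Bmat))
  for (k in seq_len(ncol(Bmat))) {
    um <- matrix(u[, k], ncol = prep$na, byrow = TRUE)
    task_ll <- um[prep$chosen] - row_log_sum_exp(um)
    out[, k] <- colSums(matrix(task_ll, nrow = prep$nt))
  }
  out
}

# Responsibility-weighted MNL maximum likelihood (one class's M-step),
# warm-started at beta0, by quasi-Newton with analytic gradient.
weighted_mnl_fit <- function(beta0, w, prep) {
  wt <- rep(w, each = prep$nt)                        # task-level weights
  negll <- function(b) {
    um <- matrix(prep$X %*% b, ncol = prep$na, byrow = TRUE)
    -sum(wt * (um[prep$chosen] - row_log_sum_exp(um)))
  }
  neggr <- function(b) {
    um <- matrix(prep$X %*% b, ncol = prep$na, byrow = TRUE)
    pr <- exp(um - row_log_sum_exp(um))               # (n*nt) x na
    # expand probabilities back to alternative-major row order
    pvec <- as.vector(t(pr))
    xbar <- colSums(prep$X * (pvec * rep(wt, each = prep$na)))
    chosen_rows <- (prep$chosen[, 1L] - 1L) * prep$na + prep$chosen[, 2L]
    xch <- colSums(prep$X[chosen_rows, , drop = FALSE] * wt)
    -(xch - xbar)
  }
  fit <- stats::optim(beta0, negll, neggr, method = "BFGS",
                      control = list(maxit = 200L, reltol = 1e-10))
  fit$par
}

#' Fit a latent-class multinomial logit by EM
#'
#' E-step: respondent responsibilities `r_ik` proportional to
#' `pi_k * prod_t P_MNL(choice_it | beta_k)`. M-step: `pi_k = mean(r_ik)` and
#' `beta_k` by responsibility-weighted MNL maximum likelihood (quasi-Newton,
#' warm-started). The best of `n_starts` random initialisations by final
#' log-likelihood is kept. Model fit is summarised by
#' `BIC = -2 LL + q log(N)` with `q = n_classes * p + (n_classes - 1)` free
#' parameters and `N` the number of respondents (the mixture is over
#' respondents, not choice observations).
#'
#' @param data a `respondent_choices` object.
#' @param design,schema,coding design and coding used by the respondents.
#' @param n_classes number of preference classes (1 reduces to a pooled MNL).
#' @param n_starts random restarts (default 20).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap per start.
#' @param seed integer seed.
#' @return object of class `latent_class_solution`: class shares `pi`,
#'   part-worth matrix `beta` (classes x p), membership probabilities
#'   (n x K), `loglik`, `ll_trace`, `bic`, `converged`, `n_starts`.
#' @export
fit_lc <- function(data, design, schema, coding, n_classes, n_starts = 20L,
                   tol = 1e-6, max_iter = 200L, seed = 1L) {
  stopifnot(n_classes >= 1L, n_starts >= 1L)
  prep <- prepare_hb_data(data, design, schema, coding)
  K <- as.integer(n_classes); p <- prep$p; n <- prep$n
  start_seeds <- spawn_seeds(seed, n_starts)

  best <- NULL
  for (st in seq_len(n_starts)) {
    sol <- with_seed(start_seeds[st],
                     run_em_once(prep, K, tol, max_iter))
    if (is.null(best) || sol$loglik > best$loglik) best <- sol
  }
  q <- K * p + (K - 1L)
  best$bic <- -2 * best$loglik + q * log(n)
  best$n_starts <- n_starts
  best$n_classes <- K
  best$q <- q
  best$par_names <- coding$colnames
  class(best) <- "latent_class_solution"
  best
}

run_em_once <- function(prep, K, tol, max_iter) {
  p <- prep$p; n <- prep$n
  Bmat <- matrix(stats::rnorm(p * K, sd = 0.25), p, K)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  trace <- numeric(0L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    llk <- loglik_by_class(Bmat, prep)                # n x K
    lw <- sweep(llk, 2L, log(pi_k), `+`)
    lse <- apply(lw, 1L, log_sum_exp)
    ll <- sum(lse)
    R <- exp(lw - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll < ll_old - 1e-8) {
      warning("EM log-likelihood decreased; keeping previous iterate")
      break
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi_new <- colMeans(R)
    # empty class: restart it with a perturbed copy of the largest class
    empty <- pi_new < 1 / (10 * n)
    if (any(empty)) {
      big <- which.max(pi_new)
      for (k in which(empty)) {
        Bmat[, k] <- Bmat[, big] + stats::rnorm(p, sd = 0.5)
        R[, k] <- 1 / K
      }
      R <- R / rowSums(R)
      pi_new <- colMeans(R)
    }
    pi_k <- pi_new
    for (k in seq_len(K)) {
      Bmat[, k] <- weighted_mnl_fit(Bmat[, k], R[, k], prep)
    }
  }
  list(pi = pi_k, beta = t(Bmat), membership = R, loglik = ll_old,
       ll_trace = trace, converged = converged)
}

#' @export
print.latent_class_solution <- function(x, ...) {
  cat(sprintf("Latent-class MNL: %d classes, LL = %.2f, BIC = %.2f (%d parameters)%s\n",
              x$n_classes, x$loglik, x$bic, x$q,
              if (x$converged) "" else " [not converged]"))
  cat("  shares:", paste(sprintf("%.3f", x$pi), collapse = " / "), "\n")
  invisible(x)
}

#' Assign respondents to latent classes
#'
#' Each respondent is assigned the class with the highest membership
#' probability (ties go to the lowest class index and are flagged), and the
#' share of respondents whose maximum probability falls below `threshold`
#' is reported as an assignment-certainty summary.
#'
#' @param solution a fitted [fit_lc()] solution.
#' @param threshold certainty threshold (default 0.90).
#' @return list: `assignments` data frame (respondent, class, max_prob, tie,
#'   below_threshold), `n_below`, `frac_below`.
#' @export
assign_classes <- function(solution, threshold = 0.90) {
  R <- solution$membership
  cls <- apply(R, 1L, which.max)  # which.max takes the lowest index on ties
  mx <- R[cbind(seq_len(nrow(R)), cls)]
  tie <- apply(R, 1L, function(r) sum(abs(r - max(r)) < 1e-12) > 1L)
  below <- mx < threshold
  list(
    assignments = data.frame(respondent = seq_len(nrow(R)), class = cls,
                             max_prob = mx, tie = tie,
                             below_threshold = below),
    n_below = sum(below),
    frac_below = mean(below)
  )
}
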