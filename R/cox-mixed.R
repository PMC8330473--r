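# Penalized partial-likelihood machinery for Cox models with normal
# log-frailties (random intercepts per grouping factor).
#
# For fixed variances theta, (beta, b) maximise the penalized Efron partial
# log-likelihood  l(beta, b) - sum_k |b_k|^2 / (2 theta_k)  by Newton
# iteration (score and information from compiled code). The variances are
# estimated by maximising the Laplace approximation to the integrated
# partial likelihood,
#   l_int(theta) = l(bhat) - bhat' D^-1 bhat / 2
#                  - log det(D) / 2 - log det(K_bb) / 2,
# where D = diag(theta) expanded over levels and K_bb is the frailty block
# of the penalized information at the optimum.

# Newton solver for fixed penalty. X: n x p (sorted rows), pen: penalty
# diagonal (0 for fixed effects, 1/theta for frailty columns).
.cox_pen_newton <- function(X, time, status, strata, pen, beta0 = NULL,
                            tol = 1e-8, max_iter = 30L) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  e <- cox_efron_cpp(X, time, status, strata, beta)
  ll_pen <- e$ll - 0.5 * sum(pen * beta^2)
  for (iter in seq_len(max_iter)) {
    g <- e$grad - pen * beta
    K <- e$info
    diag(K) <- diag(K) + pen
    step <- NULL
    for (ridge in c(0, 1e-8, 1e-4, 1e-2)) {
      step <- tryCatch(solve(K + diag(ridge, p), g), error = function(err) NULL)
      if (!is.null(step)) break
    }
    if (is.null(step)) stop("penalized information matrix is singular",
                            call. = FALSE)
    # halve steps that do not improve the penalized loglik
    repeat {
      beta_new <- beta + step
      e_new <- cox_efron_cpp(X, time, status, strata, beta_new)
      ll_new <- e_new$ll - 0.5 * sum(pen * beta_new^2)
      if (is.finite(ll_new) && ll_new >= ll_pen - 1e-12) break
      step <- step / 2
      if (max(abs(step)) < 1e-12) { beta_new <- beta; e_new <- e; ll_new <- ll_pen; break }
    }
    done <- abs(ll_new - ll_pen) < tol
    beta <- beta_new; e <- e_new; ll_pen <- ll_new
    if (done) break
  }
  K <- e$info
  diag(K) <- diag(K) + pen
  list(beta = beta, ll = e$ll, ll_pen = ll_pen,
       info = e$info, K = K, iter = iter)
}

# Laplace-approximate integrated partial log-likelihood for given theta.
.cox_laplace <- function(nt, fitted, pen_idx, q_k, theta) {
  bhat <- fitted$beta[pen_idx]
  Dinv <- rep(1 / theta, q_k)
  Kbb <- fitted$K[pen_idx, pen_idx, drop = FALSE]
  ld <- determinant(Kbb, logarithm = TRUE)
  fitted$ll - 0.5 * sum(Dinv * bhat^2) - 0.5 * sum(q_k * log(theta)) -
    0.5 * as.numeric(ld$modulus)
}

# Fit a mixed Cox model. Xf: fixed-effect design (may have 0 columns),
# groups: list of integer factor codes (one vector per random term).
# theta: fixed variances, or NULL to estimate.
.cox_mixed_fit <- function(Xf, groups, time, status, strata = NULL,
                           theta = NULL) {
  n <- length(time)
  if (is.null(strata)) strata <- rep(1L, n)
  Z <- lapply(groups, function(g) {
    f <- factor(g)
    m <- matrix(0, n, nlevels(f))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    colnames(m) <- levels(f)
    m
  })
  q_k <- vapply(Z, ncol, 0L)
  X <- do.call(cbind, c(list(Xf), Z))
  pf <- ncol(Xf)
  pen_idx <- pf + seq_len(sum(q_k))
  pen_group <- rep(seq_along(q_k), q_k)

  ord <- order(strata, time)
  Xo <- X[ord, , drop = FALSE]
  to <- time[ord]; so <- status[ord]
  sto <- as.integer(factor(strata[ord]))

  env <- new.env()
  env$beta <- rep(0, ncol(X))
  inner <- function(log_theta) {
    th <- exp(log_theta)
    pen <- c(rep(0, pf), rep(1 / th, q_k))
    ft <- .cox_pen_newton(Xo, to, so, sto, pen, beta0 = env$beta)
    env$beta <- ft$beta
    list(fit = ft, lint = .cox_laplace(n, ft, pen_idx, q_k, th))
  }

  if (is.null(theta)) {
    # keep the profile search inside the identifiable range: without the
    # penalty the frailty indicator blocks are exactly collinear
    obj <- function(lt) {
      if (any(lt < -12) || any(lt > 4)) return(1e10)
      -inner(lt)$lint
    }
    nth <- length(q_k)
    if (nth == 1L) {
      opt <- optim(log(0.05), obj, method = "Brent", lower = -12, upper = 4)
    } else {
      opt <- optim(rep(log(0.05), nth), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-6, maxit = 150))
    }
    theta <- exp(pmin(pmax(opt$par, -12), 4))
  }
  res <- inner(log(theta))
  ft <- res$fit
  Kinv <- solve(ft$K)
  # effective df: trace of Kinv %*% unpenalized information
  df_eff <- sum(Kinv * ft$info)  # = trace, both symmetric
  list(beta = ft$beta, fixed_idx = seq_len(pf), pen_idx = pen_idx,
       var = Kinv, theta = theta, loglik_penalized = ft$ll_pen,
       loglik_partial = ft$ll, loglik_integrated = res$lint,
       df_eff = df_eff, q_k = q_k)
}
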