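# Independent oracles used to cross-check the package implementations.
# These deliberately use naive loop-based algorithms, not the package's code
# paths.

# Efron-tie Cox negative partial log-likelihood, maximised with optim
oracle_efron_nll <- function(beta, X, time, status) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (t in unique(time[status == 1])) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    wD <- sum(exp(eta[D]))
    wR <- sum(exp(eta[R]))
    for (l in 0:(d - 1)) ll <- ll - log(wR - l / d * wD)
  }
  -ll
}

oracle_cox_beta <- function(X, time, status) {
  stats::optim(rep(0, ncol(X)), oracle_efron_nll, X = X, time = time,
               status = status, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))$par
}

# Brute-force paint matcher: box membership, exclusivity, the
# closer-to-another-median guard and delta-E ranking, all by explicit loops.
oracle_match_paints <- function(palette, groups, n_per_group = 2) {
  res <- list()
  elig_all <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    keep <- character(0)
    de_keep <- numeric(0)
    for (i in seq_len(nrow(palette))) {
      lab <- as.numeric(palette[i, c("L", "a", "b")])
      n_boxes <- 0
      for (h in groups) {
        if (all(lab >= h$min) && all(lab <= h$max)) n_boxes <- n_boxes + 1
      }
      in_g <- all(lab >= g$min) && all(lab <= g$max)
      if (!(in_g && n_boxes == 1)) next
      de_g <- delta_e_ciede2000(lab, g$median)
      guarded <- FALSE
      for (h in groups) {
        if (identical(h$name, g$name)) next
        if (delta_e_ciede2000(lab, h$median) <= de_g) guarded <- TRUE
      }
      if (guarded) next
      keep <- c(keep, palette$name[i])
      de_keep <- c(de_keep, de_g)
    }
    ord <- order(de_keep, keep)
    elig_all[[g$name]] <- data.frame(name = keep[ord], delta_e = de_keep[ord])
    res[[g$name]] <- head(keep[ord], n_per_group)
  }
  list(selected = res, eligible = elig_all)
}

# Brute-force Chebyshev-distance band: near zone as pixels whose Chebyshev
# distance to the nearest target pixel lies in (excl, excl + band]
oracle_near_zone <- function(target, band, excl) {
  h <- nrow(target); w <- ncol(target)
  tp <- which(target, arr.ind = TRUE)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (target[r, c]) next
    dmin <- min(pmax(abs(tp[, 1] - r), abs(tp[, 2] - c)))
    out[r, c] <- dmin > excl && dmin <= excl + band
  }
  out
}

# quick well-separated 4-habitat spec (pairwise Lab distance >= 5 channel SDs)
separated_spec <- function(side, seed, sd = 2, patch_scale = 8,
                           px_per_mm = 0.8) {
  mh <- list(
    microhabitat("h1", c(40, 0, 0), rep(sd, 3), 0.25, patch_scale),
    microhabitat("h2", c(60, 0, 0), rep(sd, 3), 0.25, patch_scale),
    microhabitat("h3", c(50, 14, 0), rep(sd, 3), 0.25, patch_scale),
    microhabitat("h4", c(50, 0, 14), rep(sd, 3), 0.25, patch_scale)
  )
  scene_spec(side, side, px_per_mm, mh, seed = seed)
}
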