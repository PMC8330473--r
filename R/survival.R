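# Detection-risk modelling: the relative-detection-distance transform,
# censoring conventions for field and online records, Cox proportional
# hazards with Gaussian frailties, likelihood-ratio / AIC model comparison
# and proportional-hazards diagnostics.

#' Field-trial survival response
#'
#' Detection distances are scaled as a proportion of the maximum possible
#' viewing distance at each position and inverted, so increasing response
#' means the observer walked further towards the target before detecting it.
#' Detected: `response = 1 - d_detect/d_max`, event 1. Missed: the response
#' records the closest possible approach, `1 - d_min/d_max`, censored.
#'
#' @param records data frame of detection records with columns `d_max`,
#'   `d_min`, `detected` (logical) and `d_detect` (`NA` when missed).
#' @return `records` with columns `response` (in `[0, 1]`) and `event`
#'   (1 detected / 0 censored) appended.
#' @export
field_response <- function(records) {
  stopifnot(all(c("d_max", "d_min", "detected", "d_detect") %in% names(records)))
  det <- records$detected
  if (any(det & (is.na(records$d_detect) | records$d_detect > records$d_max)))
    stop("detected records need d_detect <= d_max", call. = FALSE)
  if (any(records$d_min >= records$d_max))
    stop("records need d_min < d_max", call. = FALSE)
  records$response <- ifelse(det,
                             1 - records$d_detect / records$d_max,
                             1 - records$d_min / records$d_max)
  records$event <- as.integer(det)
  records
}

#' Online-trial survival response
#'
#' Search time in seconds, censored at the timeout. Also assigns the strata
#' key used in the analysis: crop size crossed with distance of the target
#' from the screen centre, discretised into quartiles over the analysed
#' dataset (inclusive empirical quantiles; boundary ties go to the lower
#' quartile).
#'
#' @param records data frame with columns `found` (logical), `time_s` (`NA`
#'   when not found), and for strata `crop_class` and `centre_distance_px`.
#' @param timeout_s censoring horizon (default 10 s).
#' @return `records` with `response`, `event`, `centre_quartile` and
#'   `strata_key` appended.
#' @export
online_response <- function(records, timeout_s = 10) {
  stopifnot(all(c("found", "time_s") %in% names(records)))
  if (any(records$found & (is.na(records$time_s) |
                           records$time_s > timeout_s | records$time_s <= 0)))
    stop("found records need 0 < time_s <= timeout_s", call. = FALSE)
  records$response <- ifelse(records$found, records$time_s, timeout_s)
  records$event <- as.integer(records$found)
  if (all(c("crop_class", "centre_distance_px") %in% names(records))) {
    records$centre_quartile <- centre_quartile(records$centre_distance_px)
    records$strata_key <- interaction(records$crop_class,
                                      records$centre_quartile, drop = FALSE)
  }
  records
}

#' Quartile assignment for centre distances
#'
#' Inclusive empirical quantile rule (type 7 quantiles of the analysed
#' dataset); values on a boundary are assigned to the lower quartile.
#'
#' @param x numeric distances.
#' @return integer quartile (1-4) per value.
#' @export
centre_quartile <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (x > q[1]) + (x > q[2]) + (x > q[3])
}

#' Fit a Cox proportional-hazards detection model
#'
#' Partial-likelihood maximisation with Efron tie handling (Breslow
#' available for fixed-effects fits). Normal random effects (log-frailties)
#' for e.g. subject and position enter as penalised Gaussian frailty terms;
#' their variances are estimated by maximising the Laplace-approximate
#' integrated partial likelihood (profile scheme). Fixed-effects-only fits
#' (`random = NULL`) are delegated to [survival::coxph()] and serve as the
#' reference implementation; mixed fits use the package's own penalised
#' Newton solver, which handles any number of frailty terms.
#'
#' For mixed fits `loglik` is the integrated partial log-likelihood and
#' `df = `(number of fixed coefficients) + (number of frailty variances), so
#' `aic` follows the integrated-likelihood convention; compare AICs only
#' between fits sharing the same random-effect structure. For fixed-effects
#' fits `loglik` is the partial log-likelihood and `df` the coefficient
#' count.
#'
#' @param data data frame containing the response and covariates (typically
#'   the output of [field_response()] or [online_response()]).
#' @param fixed one-sided formula of fixed effects, e.g.
#'   `~ strategy` or `~ delta_e_near`. Use `~ 1` for a null model.
#' @param random character vector of grouping column names to enter as
#'   Gaussian frailty terms (e.g. `c("subject", "position")`).
#' @param strata_col optional column name to stratify by.
#' @param response,event response/event column names.
#' @param ties `"efron"` (default) or `"breslow"`; mixed fits always use
#'   Efron.
#' @param theta optional fixed frailty variances (one per random term);
#'   skips variance estimation.
#' @return object of class `cox_detection_fit`: list with `coef`, `se`,
#'   `hr` (with Wald 95% CI columns), `loglik`, `df`, `aic`, `n`, `n_events`,
#'   `theta` (named frailty variances), `frail` (frailty modes), `fixed`,
#'   `random`, `strata_col`, `engine` (`"coxph"` or `"ppl"`), the model
#'   `data`, and for the coxph route the underlying fit (`fit`).
#' @export
fit_cox <- function(data, fixed = ~1, random = NULL, strata_col = NULL,
                    response = "response", event = "event", ties = "efron",
                    theta = NULL) {
  stopifnot(is.data.frame(data),
            all(c(response, event) %in% names(data)))
  if (sum(data[[event]]) < 1L) stop("no events in the data", call. = FALSE)
  fixed_terms <- attr(stats::terms(fixed), "term.labels")
  if (!is.null(strata_col)) stopifnot(strata_col %in% names(data))

  if (is.null(random)) {
    rhs <- fixed_terms
    if (!is.null(strata_col))
      rhs <- c(rhs, sprintf("survival::strata(%s)", strata_col))
    if (length(rhs) == 0L) rhs <- "1"
    fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                     response, event,
                                     paste(rhs, collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = ties, model = TRUE)
    beta <- stats::coef(fit)
    nf <- length(beta)
    se <- if (nf > 0) sqrt(diag(as.matrix(fit$var))[seq_len(nf)]) else numeric(0)
    ll <- fit$loglik[length(fit$loglik)]
    out <- list(coef = beta, se = se, loglik = ll, df = nf,
                aic = -2 * ll + 2 * nf, n = fit$n, n_events = fit$nevent,
                theta = numeric(0), frail = NULL, engine = "coxph", fit = fit)
  } else {
    stopifnot(all(random %in% names(data)))
    mm <- stats::model.matrix(fixed, data)
    Xf <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
    if (nrow(Xf) != nrow(data))
      stop("missing values in fixed-effect covariates", call. = FALSE)
    groups <- lapply(random, function(r) data[[r]])
    strat <- if (is.null(strata_col)) NULL else data[[strata_col]]
    mf <- .cox_mixed_fit(Xf, groups, time = data[[response]],
                         status = as.integer(data[[event]]),
                         strata = strat, theta = theta)
    beta <- mf$beta[mf$fixed_idx]
    names(beta) <- colnames(Xf)
    se <- sqrt(diag(mf$var)[mf$fixed_idx])
    names(mf$theta) <- random
    df <- length(beta) + length(mf$theta)
    out <- list(coef = beta, se = se, loglik = mf$loglik_integrated, df = df,
                aic = -2 * mf$loglik_integrated + 2 * df,
                n = nrow(data), n_events = sum(data[[event]]),
                theta = mf$theta,
                frail = split(mf$beta[mf$pen_idx], rep(random, mf$q_k)),
                loglik_penalized = mf$loglik_penalized,
                df_eff = mf$df_eff, engine = "ppl", fit = NULL)
  }

  nf <- length(out$coef)
  out$hr <- if (nf > 0) {
    data.frame(term = names(out$coef), coef = unname(out$coef),
               se = unname(out$se), hr = exp(unname(out$coef)),
               lower95 = exp(unname(out$coef) - 1.96 * unname(out$se)),
               upper95 = exp(unname(out$coef) + 1.96 * unname(out$se)),
               z = unname(out$coef) / unname(out$se), row.names = NULL)
  } else data.frame(term = character(), coef = numeric(), se = numeric(),
                    hr = numeric(), lower95 = numeric(), upper95 = numeric(),
                    z = numeric())
  out$fixed <- fixed_terms
  out$random <- random
  out$strata_col <- strata_col
  out$data <- data
  out$response <- response
  out$event <- event
  structure(out, class = "cox_detection_fit")
}

#' @export
print.cox_detection_fit <- function(x, ...) {
  cat(sprintf("Cox detection model: %d presentations, %d events\n",
              x$n, x$n_events))
  cat(sprintf("  fixed: %s%s%s\n",
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "(null)",
              if (length(x$random)) paste0("; frailty: ",
                                           paste(x$random, collapse = ", ")) else "",
              if (!is.null(x$strata_col)) paste0("; strata: ", x$strata_col) else ""))
  if (nrow(x$hr) > 0) {
    for (i in seq_len(nrow(x$hr)))
      cat(sprintf("  %s: HR = %.3f (95%% CI %.3f-%.3f), z = %.2f\n",
                  x$hr$term[i], x$hr$hr[i], x$hr$lower95[i], x$hr$upper95[i],
                  x$hr$z[i]))
  }
  if (length(x$theta))
    cat(sprintf("  frailty variance(s): %s\n",
                paste(sprintf("%s = %.4f", names(x$theta), x$theta),
                      collapse = ", ")))
  cat(sprintf("  %sloglik = %.3f, df = %.2f, AIC = %.3f\n",
              if (x$engine == "ppl") "integrated " else "",
              x$loglik, x$df, x$aic))
  invisible(x)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param full,reduced [fit_cox()] objects on the same data, `reduced`'s
#'   fixed terms a subset of `full`'s, identical random/strata structure.
#' @return list `(chisq, df, p)`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "cox_detection_fit"),
            inherits(reduced, "cox_detection_fit"))
  if (full$n != reduced$n || full$n_events != reduced$n_events)
    stop("models were fitted to different data", call. = FALSE)
  if (!all(reduced$fixed %in% full$fixed) ||
      !identical(reduced$random, full$random) ||
      !identical(reduced$strata_col, full$strata_col))
    stop("'reduced' is not nested in 'full'", call. = FALSE)
  df <- length(full$coef) - length(reduced$coef)
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' AIC model ladder
#'
#' Ranks competing fits of the same response data by AIC, with differences
#' from the best model and a flag for substantial differences (delta AIC
#' greater than 6). Only compare fits sharing the same random-effect
#' structure.
#'
#' @param fits list of [fit_cox()] objects.
#' @param labels model names (default from fixed terms).
#' @return data frame `(model, aic, delta_aic, substantial)` in ascending
#'   AIC order.
#' @export
aic_ladder <- function(fits, labels = NULL) {
  stopifnot(all(vapply(fits, inherits, TRUE, "cox_detection_fit")))
  n <- vapply(fits, `[[`, 0L, "n")
  ne <- vapply(fits, `[[`, 0L, "n_events")
  if (length(unique(n)) != 1L || length(unique(ne)) != 1L)
    stop("fits are not on identical response data", call. = FALSE)
  if (is.null(labels))
    labels <- vapply(fits, function(f)
      if (length(f$fixed)) paste(f$fixed, collapse = "+") else "null", "")
  aic <- vapply(fits, `[[`, 0.0, "aic")
  ord <- order(aic)
  out <- data.frame(model = labels[ord], aic = aic[ord],
                    delta_aic = aic[ord] - min(aic))
  out$substantial <- out$delta_aic > 6
  out
}

#' Proportional-hazards diagnostic
#'
#' Score test of association between scaled Schoenfeld residuals and a
#' transform of the response, per covariate (the `cox.zph` diagnostic), plus
#' the residual series for plotting.
#'
#' @param fit a [fit_cox()] object with at least one fixed covariate.
#' @param transform response transform passed to `survival::cox.zph`.
#' @return list with `table` (per-covariate chisq, df, p), `residuals`
#'   (scaled Schoenfeld residuals) and `x` (transformed response at events).
#' @export
ph_check <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cox_detection_fit"))
  if (fit$n_events < 2L) stop("need at least two events", call. = FALSE)
  if (length(fit$coef) == 0L)
    stop("no fixed covariates to check", call. = FALSE)
  base <- if (fit$engine == "coxph") fit else {
    # mixed fits: run the diagnostic on the equivalent fixed-effects model
    fit_cox(fit$data,
            stats::as.formula(paste("~", paste(fit$fixed, collapse = "+"))),
            random = NULL, strata_col = fit$strata_col,
            response = fit$response, event = fit$event)
  }
  z <- survival::cox.zph(base$fit, transform = transform)
  list(table = z$table, residuals = z$y, x = z$x)
}
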