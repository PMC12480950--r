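# Survey-scale driver analysis: Spearman screening, simple and stepwise
# multiple regression with validation, standardized coefficients, and the
# two nonlinear fits (exponential association, one-phase decay).

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations (midranks for ties) with two-sided
#' p-values; the screening step that identifies factors associated with
#' denitrification potential. Constant columns yield NA with a flag.
#'
#' @param table data.frame
#' @param columns columns to correlate (default: all numeric)
#' @return list with matrices `rho` and `p`, and `flagged` (constant columns)
#' @export
spearman_matrix <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  x <- as.data.frame(table[columns])
  m <- length(columns)
  rho <- p <- matrix(NA_real_, m, m, dimnames = list(columns, columns))
  flagged <- columns[vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0,
                            logical(1))]
  for (i in seq_len(m)) {
    for (j in seq_len(i)) {
      xi <- x[[i]]; xj <- x[[j]]
      ok <- is.finite(xi) & is.finite(xj)
      if (sum(ok) < 4 || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
        next
      }
      if (i == j) {
        rho[i, j] <- 1; p[i, j] <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(xi[ok], xj[ok], method = "spearman", exact = FALSE))
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  list(rho = rho, p = p, flagged = flagged)
}

#' Simple linear regression
#'
#' OLS of y on a single predictor with the two-sided slope test.
#'
#' @param x,y numeric vectors, n >= 3
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `se`,
#'   `conf_int` (95% for the slope), `n`
#' @export
simple_lr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # quiet on exact lines
  ci <- suppressWarnings(stats::confint(fit))["x", ]
  list(slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["x", "Pr(>|t|)"],
       se = sm$coefficients["x", "Std. Error"],
       conf_int = unname(ci), n = length(x), model = fit)
}

#' Cohen's d from a regression t statistic
#'
#' d = 2 t / sqrt(df), the conventional conversion from a t statistic with
#' df residual degrees of freedom.
#'
#' @param t t statistic
#' @param df residual degrees of freedom
#' @return Cohen's d
#' @export
cohens_d_from_t <- function(t, df) 2 * t / sqrt(df)

#' Standardized coefficients of a fitted linear model
#'
#' Slopes rescaled to z-scored response and predictors:
#' beta_std_j = beta_j sd(x_j)/sd(y), with 95% CI transformed identically,
#' the t statistic (invariant under rescaling) and Cohen's d = 2t/sqrt(df).
#' For a single-predictor model the standardized slope equals the Pearson
#' correlation.
#'
#' @param model a fitted `lm` with at least one non-intercept term
#' @return data.frame, one row per predictor: `term`, `beta`, `beta_std`,
#'   `ci_low`, `ci_high`, `t`, `p_value`, `cohens_d`
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "lm"))
  terms <- attr(stats::terms(model), "term.labels")
  if (length(terms) == 0) stop("model has no predictors", call. = FALSE)
  mf <- stats::model.frame(model)
  y <- stats::model.response(mf)
  sdy <- stats::sd(y)
  sm <- summary(model)$coefficients
  ci <- stats::confint(model)
  df <- stats::df.residual(model)
  rows <- lapply(terms, function(tm) {
    xj <- mf[[tm]]
    sdx <- stats::sd(xj)
    if (sdx == 0) stop("predictor '", tm, "' has zero variance",
                       call. = FALSE)
    sc <- sdx / sdy
    tval <- sm[tm, "t value"]
    data.frame(term = tm, beta = sm[tm, "Estimate"],
               beta_std = sm[tm, "Estimate"] * sc,
               ci_low = ci[tm, 1] * sc, ci_high = ci[tm, 2] * sc,
               t = tval, p_value = sm[tm, "Pr(>|t|)"],
               cohens_d = cohens_d_from_t(tval, df))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Residual diagnostics: Shapiro-Wilk normality and Breusch-Pagan
# homoscedasticity p-values.
.residual_checks <- function(model) {
  res <- stats::residuals(model)
  sw <- if (length(res) >= 3 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  bp <- tryCatch(lmtest::bptest(model)$p.value, error = function(e) NA_real_)
  c(shapiro_p = unname(sw), breusch_pagan_p = unname(bp))
}

#' Stepwise AIC multiple linear regression with validation
#'
#' The full driver-selection chain: (1) drop perfectly collinear or constant
#' candidates; (2) optionally screen candidates by Spearman association with
#' the response at `screen_alpha`; (3) bidirectional stepwise selection by
#' AIC from an intercept-only start ([MASS::stepAIC]); (4) drop predictors
#' until all variance inflation factors fall below `vif_max`; (5) optionally
#' prune predictors that are not individually significant at `prune_alpha`,
#' refitting after each drop; (6) report raw and standardized coefficients,
#' residual diagnostics, and nested-ANOVA comparisons against the
#' intercept-only and the all-candidate models.
#'
#' The procedure is deterministic given the table and options.
#'
#' @param table data.frame of sites
#' @param response response column name
#' @param candidates candidate predictor column names
#' @param screen apply the Spearman screen (step 2)
#' @param screen_alpha screening significance level
#' @param vif_max VIF threshold (predictors above it are dropped,
#'   highest first)
#' @param prune prune non-significant predictors (step 5)
#' @param prune_alpha pruning significance level
#' @return list of class `driver_regression`: `selected` (character),
#'   `model` (`lm`), `coefficients` (from [standardized_coefficients()], NULL
#'   for an intercept-only final model), `r_squared`, `aic`, `vif`,
#'   `residual_checks`, `anova_vs_null`, `anova_vs_full`, `screened_out`,
#'   `dropped_collinear`, `log` (character vector of actions taken)
#' @export
stepwise_aic_mlr <- function(table, response, candidates,
                             screen = TRUE, screen_alpha = 0.05,
                             vif_max = 5, prune = TRUE, prune_alpha = 0.05) {
  stopifnot(response %in% names(table), all(candidates %in% names(table)))
  log <- character(0)
  dat <- stats::na.omit(table[c(response, candidates)])
  y <- dat[[response]]

  # step 1: constant / perfectly collinear candidates
  keep <- candidates[vapply(candidates,
                            function(cn) stats::sd(dat[[cn]]) > 0, logical(1))]
  dropped_const <- setdiff(candidates, keep)
  if (length(keep) > 1) {
    qrX <- qr(scale(as.matrix(dat[keep])))
    if (qrX$rank < length(keep)) {
      indep <- keep[sort(qrX$pivot[seq_len(qrX$rank)])]
      log <- c(log, paste("dropped collinear candidate(s):",
                          paste(setdiff(keep, indep), collapse = ", ")))
      keep <- indep
    }
  }
  dropped_collinear <- union(dropped_const, setdiff(candidates, keep))
  if (length(dropped_const)) {
    log <- c(log, paste("dropped constant candidate(s):",
                        paste(dropped_const, collapse = ", ")))
  }

  # step 2: Spearman screen against the response
  screened_out <- character(0)
  if (screen && length(keep)) {
    pvals <- vapply(keep, function(cn) {
      suppressWarnings(stats::cor.test(dat[[cn]], y, method = "spearman",
                                       exact = FALSE)$p.value)
    }, numeric(1))
    screened_out <- keep[pvals >= screen_alpha]
    keep <- keep[pvals < screen_alpha]
    if (length(screened_out)) {
      log <- c(log, paste("Spearman screen removed:",
                          paste(screened_out, collapse = ", ")))
    }
  }

  null_fml <- stats::as.formula(paste(response, "~ 1"))
  null_model <- stats::lm(null_fml, data = dat)
  if (length(keep) == 0) {
    log <- c(log, "no candidates survived screening; intercept-only model")
    return(structure(list(selected = character(0), model = null_model,
                          coefficients = NULL,
                          r_squared = 0, aic = stats::AIC(null_model),
                          vif = NULL,
                          residual_checks = .residual_checks(null_model),
                          anova_vs_null = NULL, anova_vs_full = NULL,
                          screened_out = screened_out,
                          dropped_collinear = dropped_collinear, log = log),
                     class = "driver_regression"))
  }

  # step 3: bidirectional AIC stepping from intercept-only
  upper_fml <- stats::as.formula(
    paste(response, "~", paste(keep, collapse = " + ")))
  stepped <- MASS::stepAIC(null_model, direction = "both", trace = 0,
                           scope = list(lower = null_fml, upper = upper_fml))
  selected <- attr(stats::terms(stepped), "term.labels")
  log <- c(log, paste("stepwise AIC selected:",
                      if (length(selected)) paste(selected, collapse = ", ")
                      else "(intercept only)"))

  refit <- function(sel) {
    if (length(sel) == 0) return(null_model)
    stats::lm(stats::as.formula(
      paste(response, "~", paste(sel, collapse = " + "))), data = dat)
  }

  # step 4: VIF screen
  model <- refit(selected)
  while (length(selected) > 1) {
    v <- car::vif(model)
    if (max(v) < vif_max) break
    worst <- names(v)[which.max(v)]
    log <- c(log, paste0("VIF ", round(max(v), 1), " >= ", vif_max,
                         ": dropped ", worst))
    selected <- setdiff(selected, worst)
    model <- refit(selected)
  }

  # step 5: significance pruning
  if (prune) {
    repeat {
      if (length(selected) == 0) break
      sm <- summary(model)$coefficients
      pv <- sm[selected, "Pr(>|t|)", drop = TRUE]
      if (all(pv < prune_alpha)) break
      worst <- selected[which.max(pv)]
      log <- c(log, paste0("pruned non-significant predictor ", worst,
                           " (p = ", signif(max(pv), 3), ")"))
      selected <- setdiff(selected, worst)
      model <- refit(selected)
    }
  }

  vif <- if (length(selected) > 1) car::vif(model) else NULL
  coefs <- if (length(selected)) standardized_coefficients(model) else NULL
  full_model <- refit(keep)
  anova_null <- if (length(selected)) stats::anova(null_model, model) else NULL
  anova_full <- if (length(selected) < length(keep) && length(selected))
    stats::anova(model, full_model) else NULL

  structure(list(selected = selected, model = model, coefficients = coefs,
                 r_squared = summary(model)$r.squared,
                 aic = stats::AIC(model), vif = vif,
                 residual_checks = .residual_checks(model),
                 anova_vs_null = anova_null, anova_vs_full = anova_full,
                 screened_out = screened_out,
                 dropped_collinear = dropped_collinear, log = log),
            class = "driver_regression")
}

#' @export
print.driver_regression <- function(x, ...) {
  cat("Driver regression report\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
                     else "(intercept only)", "\n")
  cat("  R^2 =", round(x$r_squared, 4), " AIC =", round(x$aic, 2), "\n")
  if (!is.null(x$coefficients)) {
    cat("  standardized coefficients:\n")
    print(x$coefficients, row.names = FALSE)
  }
  invisible(x)
}

# Deterministic multi-start wrapper around nlsLM: tries the heuristic start
# and a fixed ladder of scaled starts, returns the converged fit with the
# lowest residual sum of squares.
.nls_multistart <- function(formula, data, starts, lower = NULL) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      if (is.null(lower)) minpack.lm::nlsLM(formula, data = data, start = st,
                                            control = minpack.lm::nls.lm.control(maxiter = 200))
      else minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                             control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Exponential association fit y = a exp(b x) + c
#'
#' Nonlinear least squares with endpoint-heuristic initialization (c from
#' the low end of y, b from the log-linearized slope) and a deterministic
#' ladder of scaled restarts. Reports the one-sided test of b > 0,
#' t = b/SE(b) with df = n - 3.
#'
#' @param x,y numeric, n >= 5
#' @return list with `a`, `b`, `c`, `se_b`, `t`, `df`, `p_one_sided`
#'   (for b > 0), `r_squared`, `converged`, `flags`
#' @export
exp_association_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stop("need n >= 5", call. = FALSE)
  dat <- data.frame(x = x, y = y)
  c0 <- min(y) - 0.05 * abs(min(y)) - 1e-8
  pos <- y - c0
  b0 <- tryCatch(unname(stats::coef(stats::lm(log(pos) ~ x))[2]),
                 error = function(e) 0.1)
  if (!is.finite(b0) || b0 == 0) b0 <- 0.1
  a0 <- exp(mean(log(pos) - b0 * x))
  starts <- list(list(a = a0, b = b0, c = c0))
  for (f in c(0.25, 0.5, 2, 4, -0.5, -1)) {
    starts <- c(starts, list(list(a = a0, b = b0 * f, c = c0)))
  }
  for (f in c(0.2, 5)) {
    starts <- c(starts, list(list(a = a0 * f, b = b0, c = c0)))
  }
  best <- .nls_multistart(y ~ a * exp(b * x) + c, dat, starts)
  if (is.null(best)) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, se_b = NA_real_,
                t = NA_real_, df = n - 3, p_one_sided = NA_real_,
                r_squared = NA_real_, converged = FALSE,
                flags = "non_convergence_after_restarts"))
  }
  fit <- best$fit
  est <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  df <- n - 3
  tval <- est["b"] / sm["b", "Std. Error"]
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  list(a = unname(est["a"]), b = unname(est["b"]), c = unname(est["c"]),
       se_b = unname(sm["b", "Std. Error"]), t = unname(tval), df = df,
       p_one_sided = unname(stats::pt(tval, df, lower.tail = FALSE)),
       r_squared = r2, converged = TRUE, flags = character(0))
}

#' One-phase decay fit Y = (Y0 - plateau) exp(-K x) + plateau
#'
#' Nonlinear least squares with the rate constant constrained nonnegative;
#' R^2 is reported on the original scale. Near-constant responses make K
#' unidentifiable and are flagged.
#'
#' @param x,y numeric, n >= 4, x >= 0
#' @return list with `y0`, `plateau`, `k`, `r_squared`, `converged`, `flags`
#' @export
one_phase_decay_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    return(list(y0 = y[1], plateau = y[1], k = NA_real_,
                r_squared = NA_real_, converged = FALSE,
                flags = "plateau_only_k_unidentifiable"))
  }
  dat <- data.frame(x = x, y = y)
  ord <- order(x)
  y0_0 <- y[ord][1]
  pl_0 <- y[ord][n]
  span <- max(x) - min(x)
  k0 <- log(2) / max(span / 3, 1e-6)
  starts <- list(list(y0 = y0_0, plateau = pl_0, k = k0))
  for (f in c(0.1, 0.3, 3, 10, 30)) {
    starts <- c(starts, list(list(y0 = y0_0, plateau = pl_0, k = k0 * f)))
  }
  best <- .nls_multistart(y ~ (y0 - plateau) * exp(-k * x) + plateau, dat,
                          starts,
                          lower = c(y0 = -Inf, plateau = -Inf, k = 0))
  if (is.null(best)) {
    return(list(y0 = NA_real_, plateau = NA_real_, k = NA_real_,
                r_squared = NA_real_, converged = FALSE,
                flags = "non_convergence_after_restarts"))
  }
  est <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  flags <- character(0)
  if (est["k"] <= 1e-10) flags <- "k_at_zero_boundary"
  list(y0 = unname(est["y0"]), plateau = unname(est["plateau"]),
       k = unname(est["k"]), se = se, r_squared = r2, converged = TRUE,
       flags = flags)
}
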