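# Baseline-category multinomial logit fitted by Newton-Raphson maximum
# likelihood, reporting relative risk ratios (RRR = exp(coef)) with Wald 95%
# CIs from the observed information, likelihood-ratio tests, predicted
# category probabilities and probability contrasts with delta-method CIs.

#' Fit a baseline-category multinomial logit (relative risk ratios)
#'
#' Maximum-likelihood fit of a multicategory logit in which each non-reference
#' outcome gets its own linear predictor against the reference (first factor
#' level, or `ref`). Estimation is exact Newton-Raphson on the full observed
#' information with step halving; convergence requires the gradient max-norm
#' below `tol`. Exponentiated coefficients are relative risk ratios: the
#' multiplicative change in the risk of an outcome relative to the reference
#' per unit of the predictor.
#'
#' @param formula Model formula; the response must be a factor (or coercible)
#'   with at least two levels.
#' @param data Data frame containing the model variables.
#' @param ref Reference outcome level; defaults to the first factor level.
#' @param tol Convergence tolerance on the gradient max-norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An object of class `multinom_rrr` with components `coefficients`
#'   (matrix, one row per non-reference outcome), `vcov`, `logLik`, `n`,
#'   `fitted.values` (n x K probability matrix), `levels`, `ref`,
#'   `iterations`, `converged` and the usual `terms`/`xlevels`/`model`
#'   bookkeeping. Reference-category coefficients are identically zero and
#'   are not stored.
#' @seealso [predicted_probabilities()], [probability_contrast()],
#'   [rrr_table()]
#' @examples
#' b <- rbind(STIB = c("(Intercept)" = 0.2, exposure = -0.4),
#'            RTIB = c("(Intercept)" = -0.4, exposure = -0.9))
#' d <- generate_from_logit(b, cohort_config(n_participants = 800, seed = 3))
#' fit <- fit_multinom_rrr(tib_category ~ exposure, d)
#' summary(fit)
#' @export
fit_multinom_rrr <- function(formula, data, ref = NULL, tol = 1e-8,
                             max_iter = 100L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, drop.unused.levels = FALSE,
                           na.action = stats::na.omit)
  trms <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  if (!is.null(ref)) {
    if (!ref %in% levels(y)) {
      abort("reference level '", ref, "' not among outcome levels",
            class = "actibed_model_error")
    }
    y <- stats::relevel(y, ref = ref)
  }
  lev <- levels(y)
  K <- length(lev)
  if (K < 2L) {
    abort("outcome needs at least two observed categories",
          class = "actibed_model_error")
  }
  tab <- table(y)
  if (any(tab == 0L)) {
    abort("empty outcome category: ",
          paste(names(tab)[tab == 0L], collapse = ", "),
          class = "actibed_model_error")
  }
  # unused predictor levels would break the contrasts; the response keeps all
  for (j in seq_along(mf)[-1L]) {
    if (is.factor(mf[[j]])) mf[[j]] <- droplevels(mf[[j]])
  }
  X <- stats::model.matrix(trms, mf)
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    abort("collinear design columns: ", paste(drop, collapse = ", "),
          class = "actibed_model_error")
  }
  Y <- matrix(0, n, K - 1L)
  for (k in 2:K) Y[, k - 1L] <- as.numeric(y == lev[k])

  prob_all <- function(B) {
    eta <- cbind(0, X %*% t(B))
    eta <- eta - apply(eta, 1L, max)
    E <- exp(eta)
    E / rowSums(E)
  }
  loglik <- function(P) sum(log(pmax(P[cbind(seq_len(n), as.integer(y))],
                                     1e-300)))

  B <- matrix(0, K - 1L, p, dimnames = list(lev[-1L], colnames(X)))
  P_all <- prob_all(B)
  ll <- loglik(P_all)
  converged <- FALSE
  grad_norm <- Inf
  it <- 0L
  H <- NULL
  while (it < max_iter) {
    it <- it + 1L
    P <- P_all[, -1L, drop = FALSE]
    g <- as.vector(vapply(seq_len(K - 1L),
                          function(k) crossprod(X, Y[, k] - P[, k])[, 1L],
                          numeric(p)))
    H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
    for (k in seq_len(K - 1L)) {
      for (l in seq_len(k)) {
        w <- P[, k] * ((k == l) - P[, l])
        blk <- -crossprod(X * w, X)
        ri <- (k - 1L) * p + seq_len(p)
        ci <- (l - 1L) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    grad_norm <- max(abs(g))
    if (grad_norm < tol) { converged <- TRUE; break }
    delta <- tryCatch(solve(-H, g), error = function(e) {
      abort("singular information matrix: possible perfect separation",
            class = "actibed_model_error")
    })
    step <- 1
    repeat {
      Bn <- B + step * matrix(delta, K - 1L, p, byrow = TRUE)
      Pn <- prob_all(Bn)
      lln <- loglik(Pn)
      if (lln >= ll - 1e-10 || step < 1 / 1024) break
      step <- step / 2
    }
    B <- Bn; P_all <- Pn; ll <- lln
    if (max(abs(B)) > 30) {
      worst <- which(abs(B) == max(abs(B)), arr.ind = TRUE)[1L, ]
      abort("non-convergence: coefficient for term '",
            colnames(B)[worst[2L]], "' (outcome ", rownames(B)[worst[1L]],
            ") diverged; possible perfect separation",
            class = "actibed_model_error")
    }
  }
  if (!converged) {
    abort("Newton iterations did not converge in ", max_iter,
          " steps (gradient max-norm ", signif(grad_norm, 3), ")",
          class = "actibed_model_error")
  }
  V <- solve(-H)
  pn <- as.vector(outer(colnames(X), lev[-1L],
                        function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- list(pn, pn)
  colnames(P_all) <- lev
  structure(list(
    coefficients = B, vcov = V, logLik = ll, n = n,
    fitted.values = P_all, levels = lev, ref = lev[1L],
    y = y, x = X, terms = trms,
    xlevels = stats::.getXlevels(trms, mf), model = mf,
    iterations = it, converged = converged, grad_norm = grad_norm,
    call = cl
  ), class = "multinom_rrr")
}

#' @export
print.multinom_rrr <- function(x, digits = 4, ...) {
  cat("Baseline-category multinomial logit (reference: ", x$ref, ")\n",
      sep = "")
  cat("Call: ", deparse(x$call), "\n\nCoefficients:\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("\nLog-likelihood: %.3f on %d parameters (n = %d)\n",
              x$logLik, length(x$coefficients), x$n))
  invisible(x)
}

#' @export
coef.multinom_rrr <- function(object, ...) object$coefficients

#' @export
vcov.multinom_rrr <- function(object, ...) object$vcov

#' @export
logLik.multinom_rrr <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.multinom_rrr <- function(object, ...) object$n

# stacked parameter vector in vcov order (outcome-major)
theta_vec <- function(object) {
  as.vector(t(object$coefficients)[, , drop = TRUE])
}

# standard errors aligned with the coefficient matrix
se_matrix <- function(object) {
  se <- sqrt(diag(object$vcov))
  matrix(se, nrow(object$coefficients), ncol(object$coefficients),
         byrow = TRUE, dimnames = dimnames(object$coefficients))
}

#' Relative risk ratio table
#'
#' @param object A fitted [fit_multinom_rrr()] model.
#' @param conf Confidence level for the Wald intervals (default 0.95).
#' @return Data frame with one row per non-reference outcome and term:
#'   coefficient, SE, RRR = exp(coef), Wald CI bounds on the RRR scale, z
#'   and two-sided p value.
#' @export
rrr_table <- function(object, conf = 0.95) {
  stopifnot(inherits(object, "multinom_rrr"))
  B <- object$coefficients
  SE <- se_matrix(object)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(
    outcome = rep(rownames(B), each = ncol(B)),
    term = rep(colnames(B), times = nrow(B)),
    estimate = as.vector(t(B)),
    se = as.vector(t(SE))
  )
  out$rrr <- exp(out$estimate)
  out$rrr_lower <- exp(out$estimate - zq * out$se)
  out$rrr_upper <- exp(out$estimate + zq * out$se)
  out$z <- out$estimate / out$se
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out
}

#' @export
summary.multinom_rrr <- function(object, conf = 0.95, ...) {
  structure(list(call = object$call, ref = object$ref, n = object$n,
                 logLik = object$logLik, iterations = object$iterations,
                 table = rrr_table(object, conf = conf)),
            class = "summary.multinom_rrr")
}

#' @export
print.summary.multinom_rrr <- function(x, digits = 3, ...) {
  cat("Baseline-category multinomial logit (reference: ", x$ref, ")\n",
      sep = "")
  cat(sprintf("n = %d, log-likelihood = %.3f (%d Newton iterations)\n\n",
              x$n, x$logLik, x$iterations))
  tab <- x$table
  tab$p_value <- format.pval(tab$p_value, digits = digits)
  num <- c("estimate", "se", "rrr", "rrr_lower", "rrr_upper", "z")
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
confint.multinom_rrr <- function(object, parm, level = 0.95, ...) {
  th <- theta_vec(object)
  se <- sqrt(diag(object$vcov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(th - zq * se, th + zq * se)
  dimnames(ci) <- list(rownames(object$vcov),
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.multinom_rrr <- function(object, newdata = NULL,
                                 type = c("probs", "class", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    P <- object$fitted.values
    X <- object$x
  } else {
    trms <- stats::delete.response(object$terms)
    mf <- stats::model.frame(trms, newdata, xlev = object$xlevels,
                             na.action = stats::na.pass)
    X <- stats::model.matrix(trms, mf, xlev = object$xlevels)
    eta <- cbind(0, X %*% t(object$coefficients))
    eta <- eta - apply(eta, 1L, max)
    E <- exp(eta)
    P <- E / rowSums(E)
    colnames(P) <- object$levels
  }
  switch(type,
         probs = P,
         class = factor(object$levels[max.col(P, ties.method = "first")],
                        levels = object$levels),
         link = X %*% t(object$coefficients))
}

#' @export
residuals.multinom_rrr <- function(object, ...) {
  Y <- matrix(0, object$n, length(object$levels),
              dimnames = list(NULL, object$levels))
  Y[cbind(seq_len(object$n), as.integer(object$y))] <- 1
  Y - object$fitted.values
}

#' @export
simulate.multinom_rrr <- function(object, nsim = 1, seed = NULL, ...) {
  P <- object$fitted.values
  cum <- t(apply(P, 1L, cumsum))
  draw <- function() {
    u <- stats::runif(object$n)
    idx <- rowSums(u > cum) + 1L
    factor(object$levels[idx], levels = object$levels)
  }
  out <- with_seed(seed, as.data.frame(
    stats::setNames(replicate(nsim, draw(), simplify = FALSE),
                    paste0("sim_", seq_len(nsim)))))
  out
}

#' @export
anova.multinom_rrr <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2L) {
    abort("anova() needs at least two nested multinom_rrr fits",
          class = "actibed_model_error")
  }
  df <- vapply(fits, function(f) length(f$coefficients), 1L)
  o <- order(df)
  fits <- fits[o]; df <- df[o]
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  chisq <- c(NA, 2 * diff(ll))
  ddf <- c(NA, diff(df))
  pv <- c(NA, stats::pchisq(chisq[-1L], ddf[-1L], lower.tail = FALSE))
  structure(data.frame(
    model = vapply(fits, function(f) deparse(stats::formula(f$terms)),
                   character(1)),
    df = df, logLik = ll, chisq = chisq, chisq_df = ddf, p_value = pv),
    heading = "Likelihood-ratio tests", class = c("anova", "data.frame"))
}

#' @export
plot.multinom_rrr <- function(x, exposure = NULL, ...) {
  exposure <- exposure %||% attr(x$terms, "term.labels")[1L]
  pp <- predicted_probabilities(x, exposure)
  levs <- unique(pp$level)
  M <- matrix(pp$prob, nrow = length(levs), byrow = FALSE,
              dimnames = list(levs, unique(pp$category)))
  graphics::matplot(seq_along(levs), M, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = exposure,
                    ylab = "predicted probability", ylim = c(0, 1), ...)
  graphics::axis(1, at = seq_along(levs), labels = levs)
  graphics::legend("topright", legend = colnames(M),
                   col = seq_len(ncol(M)), pch = 19, lty = 1, bty = "n")
  invisible(M)
}

## ---------------------------------------------------------------------------
## Predicted probabilities and contrasts at fixed covariates

# representative row: continuous covariates at means, factors at modes
baseline_row <- function(object) {
  mf <- object$model
  vars <- all.vars(stats::delete.response(object$terms))
  row <- list()
  for (v in vars) {
    col <- mf[[v]]
    row[[v]] <- if (is.numeric(col)) mean(col)
                else if (is.logical(col)) as.logical(stat_mode(col))
                else factor(stat_mode(col), levels = levels(factor(col)))
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

exposure_levels <- function(object, exposure) {
  col <- object$model[[exposure]]
  if (is.null(col)) {
    abort("'", exposure, "' is not a model variable",
          class = "actibed_domain_error")
  }
  if (is.factor(col)) levels(col)
  else if (is.logical(col)) c(FALSE, TRUE)
  else stats::quantile(col, c(1, 3, 5) / 6, names = FALSE)   # tertile mids
}

# probabilities and delta-method gradients at one design row x (length p)
prob_and_grad <- function(object, x) {
  B <- object$coefficients
  K1 <- nrow(B); p <- ncol(B)
  eta <- c(0, as.vector(B %*% x))
  eta <- eta - max(eta)
  pr <- exp(eta) / sum(exp(eta))
  # G[(k-1)p + j, c] = d p_c / d B[k, j] = p_c (1{c = k+1} - p_{k+1}) x_j
  G <- matrix(0, K1 * p, length(pr))
  for (k in seq_len(K1)) {
    for (cc in seq_along(pr)) {
      G[(k - 1L) * p + seq_len(p), cc] <-
        pr[cc] * ((cc == k + 1L) - pr[k + 1L]) * x
    }
  }
  list(prob = pr, grad = G)
}

design_row <- function(object, newdata) {
  trms <- stats::delete.response(object$terms)
  mf <- stats::model.frame(trms, newdata, xlev = object$xlevels)
  stats::model.matrix(trms, mf, xlev = object$xlevels)[1L, ]
}

#' Predicted category probabilities across exposure levels
#'
#' Evaluates the fitted category probabilities at each level of one exposure
#' with all other covariates fixed at their cohort means (continuous) or
#' modes (categorical), with delta-method confidence intervals.
#'
#' @param object A fitted [fit_multinom_rrr()] model.
#' @param exposure Name of a model variable (factor, logical or numeric; a
#'   numeric exposure is evaluated at its within-tertile midpoints).
#' @param levels Exposure levels to evaluate; defaults to all factor levels.
#' @param conf Confidence level (default 0.95).
#' @param at Optional one-row data frame overriding the covariate values.
#' @return Data frame with `level`, `category`, `prob`, `se`, `lower`,
#'   `upper`; probabilities at each level sum to 1.
#' @export
predicted_probabilities <- function(object, exposure, levels = NULL,
                                    conf = 0.95, at = NULL) {
  stopifnot(inherits(object, "multinom_rrr"))
  levs <- levels %||% exposure_levels(object, exposure)
  if (is.factor(object$model[[exposure]]) &&
      !all(as.character(levs) %in% base::levels(object$model[[exposure]]))) {
    abort("exposure level outside the fitted design",
          class = "actibed_domain_error")
  }
  base <- at %||% baseline_row(object)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  V <- object$vcov
  out <- lapply(levs, function(lv) {
    nd <- base
    nd[[exposure]] <- if (is.factor(object$model[[exposure]])) {
      factor(lv, levels = base::levels(object$model[[exposure]]))
    } else lv
    x <- design_row(object, nd)
    pg <- prob_and_grad(object, x)
    se <- sqrt(pmax(0, colSums(pg$grad * (V %*% pg$grad))))
    data.frame(level = as.character(lv), category = object$levels,
               prob = pg$prob, se = se,
               lower = pg$prob - zq * se, upper = pg$prob + zq * se)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Difference in category probabilities between two exposure levels
#'
#' Computes `P(category | level_a) - P(category | level_b)` for every
#' outcome category, other covariates fixed as in
#' [predicted_probabilities()], with delta-method CIs and Wald p values.
#' The contrasts across categories sum to zero.
#'
#' @inheritParams predicted_probabilities
#' @param level_a,level_b Exposure levels to contrast.
#' @return Data frame with `category`, `contrast`, `se`, `lower`, `upper`,
#'   `p_value`.
#' @export
probability_contrast <- function(object, exposure, level_a, level_b,
                                 conf = 0.95, at = NULL) {
  stopifnot(inherits(object, "multinom_rrr"))
  col <- object$model[[exposure]]
  if (is.factor(col) &&
      !all(c(level_a, level_b) %in% base::levels(col))) {
    abort("exposure level outside the fitted design",
          class = "actibed_domain_error")
  }
  base <- at %||% baseline_row(object)
  mk <- function(lv) {
    nd <- base
    nd[[exposure]] <- if (is.factor(col)) {
      factor(lv, levels = base::levels(col))
    } else lv
    prob_and_grad(object, design_row(object, nd))
  }
  a <- mk(level_a); b <- mk(level_b)
  d <- a$prob - b$prob
  G <- a$grad - b$grad
  se <- sqrt(pmax(0, colSums(G * (object$vcov %*% G))))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  z <- ifelse(se > 0, d / se, 0)
  data.frame(category = object$levels, contrast = d, se = se,
             lower = d - zq * se, upper = d + zq * se,
             p_value = ifelse(se > 0, 2 * stats::pnorm(-abs(z)), NA_real_))
}

## ---------------------------------------------------------------------------
## Study model wrappers (Model I / Model II covariate sets)

#' Fit a study model for a time-in-bed analysis table
#'
#' Wraps [fit_multinom_rrr()] with the two study covariate sets. Model I
#' adjusts for age, sex, average daily nap length and the physical-function
#' score and is used with the tertile exposures (`avg_cpm`, `pct_mid`,
#' `pct_high`); Model II additionally adjusts for the percentage of wear
#' time at >= 5000 cpm and is used only with the `highly_sedentary`
#' exposure. The overall exposure p value is a likelihood-ratio test of the
#' exposure block.
#'
#' @param table Analysis table with columns `tib_category`, the exposure
#'   columns (tertile factors are derived if absent), `age`, `sex`,
#'   `avg_nap_minutes`, `sppb_total`, `pct_high`.
#' @param exposure One of `"avg_cpm"`, `"pct_mid"`, `"pct_high"`,
#'   `"highly_sedentary"`.
#' @param model `"I"` or `"II"`; defaults to `"II"` for the
#'   `highly_sedentary` exposure and `"I"` otherwise.
#' @return A list of class `tib_model`: the `fit`, the exposure `rrr` rows,
#'   the full `rrr_table`, `overall_p` (LR test of the exposure block),
#'   `exposure`, `model` and `n`.
#' @export
fit_tib_model <- function(table,
                          exposure = c("avg_cpm", "pct_mid", "pct_high",
                                       "highly_sedentary"),
                          model = NULL) {
  exposure <- match.arg(exposure)
  model <- model %||% if (exposure == "highly_sedentary") "II" else "I"
  if (model == "II" && exposure != "highly_sedentary") {
    abort("Model II is used only with the highly_sedentary exposure",
          class = "actibed_model_error")
  }
  if (model == "I" && exposure == "highly_sedentary") {
    abort("the highly_sedentary exposure uses Model II",
          class = "actibed_model_error")
  }
  tab <- table
  if (exposure == "highly_sedentary") {
    tab$highly_sedentary <- factor(
      ifelse(tab$highly_sedentary, "highly_sedentary", "not_highly_sedentary"),
      levels = c("not_highly_sedentary", "highly_sedentary"))
    exp_col <- "highly_sedentary"
  } else {
    exp_col <- paste0(exposure, "_tertile")
    if (is.null(tab[[exp_col]])) tab[[exp_col]] <- tertile_assign(tab[[exposure]])
  }
  covars <- c("age", "sex", "avg_nap_minutes", "sppb_total")
  if (model == "II") covars <- c(covars, "pct_high")
  f_full <- stats::reformulate(c(exp_col, covars), response = "tib_category")
  f_red <- stats::reformulate(covars, response = "tib_category")
  fit <- fit_multinom_rrr(f_full, tab, ref = "UTIB")
  red <- fit_multinom_rrr(f_red, tab, ref = "UTIB")
  lr <- 2 * (fit$logLik - red$logLik)
  df <- length(fit$coefficients) - length(red$coefficients)
  full_tab <- rrr_table(fit)
  structure(list(
    fit = fit,
    rrr = full_tab[grepl(exp_col, full_tab$term, fixed = TRUE), ],
    rrr_table = full_tab,
    overall_p = stats::pchisq(lr, df, lower.tail = FALSE),
    exposure = exposure, exposure_column = exp_col,
    model = model, n = fit$n
  ), class = "tib_model")
}

#' @export
print.tib_model <- function(x, digits = 3, ...) {
  cat(sprintf("Study Model %s, exposure %s (n = %d)\n", x$model, x$exposure,
              x$n))
  tab <- x$rrr[c("outcome", "term", "rrr", "rrr_lower", "rrr_upper",
                 "p_value")]
  tab[-(1:2)] <- lapply(tab[-(1:2)], signif, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall exposure p (LR test): %.4g\n", x$overall_p))
  invisible(x)
}
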