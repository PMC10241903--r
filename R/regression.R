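# OLS with named columns; returns coefficients, t, p, and fit summaries.
# X is the candidate matrix WITHOUT intercept; an intercept is always added.
ols_terms <- function(x, y) {
  n <- length(y)
  X <- cbind("(Intercept)" = 1, x)
  qrx <- qr(X)
  aliased <- character(0)
  if (qrx$rank < ncol(X)) {
    drop_idx <- sort(qrx$pivot[(qrx$rank + 1L):ncol(X)])
    aliased <- colnames(X)[drop_idx]
  }
  if (length(aliased)) {
    return(list(aliased = setdiff(aliased, "(Intercept)")))
  }
  xtxi_piv <- chol2inv(qr.R(qrx))
  xtxi <- matrix(NA_real_, ncol(X), ncol(X))
  xtxi[qrx$pivot, qrx$pivot] <- xtxi_piv
  coefs <- qr.coef(qrx, y)
  res <- y - as.numeric(X %*% coefs)
  rss <- sum(res^2)
  df_res <- n - ncol(X)
  if (df_res < 1L) stopf("not enough observations for %d terms", ncol(X) - 1L)
  sigma2 <- rss / df_res
  se <- sqrt(diag(xtxi) * sigma2)
  tval <- coefs / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  keep <- setdiff(names(coefs), "(Intercept)")
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  k <- length(keep)
  list(coef = coefs[keep], t = tval[keep], p = pval[keep],
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
       f = if (k > 0) ((tss - rss) / k) / sigma2 else NA_real_,
       df = c(k, df_res), rss = rss, aliased = character(0))
}

#' Backward-elimination linear regression
#'
#' Iterative ordinary-least-squares pruning: starting from all candidate
#' columns, the least significant term is removed at each step until every
#' remaining term has `p < alpha` (or none remain). Used to predict
#' follow-up pegboard score from baseline imaging and demographic
#' candidates; all candidates - demographics included - are eliminable. The
#' procedure is deterministic given the data: ties on the maximum p-value
#' are broken by the smaller absolute t statistic, then lexicographic column
#' name; when columns are exactly collinear, one member of the set is
#' dropped first (deterministically: lexicographically among the aliased
#' columns flagged by the pivoted QR) and recorded in the trace.
#'
#' @param x numeric candidate matrix or data.frame with unique column names.
#' @param y numeric outcome (follow-up pegboard score).
#' @param alpha retention threshold (default 0.05).
#' @return an object of class `backward_lm`: `retained` (character),
#'   `model` (the [standardized_fit()] of the retained set, or `NULL` if
#'   none survive), `trace` (data.frame of removals: step, term, p and t at
#'   removal, reason), `alpha`, `n`.
#' @examples
#' sim <- generate_predictors(predictor_design(), seed = 1)
#' fit <- backward_eliminate(sim$x, sim$y)
#' fit$retained
#' @export
backward_eliminate <- function(x, y, alpha = 0.05) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stopf("`x` must have unique column names")
  }
  if (nrow(x) != length(y)) stopf("`x` and `y` sizes disagree")
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must lie in (0, 1)")
  active <- colnames(x)
  trace <- list()
  step <- 0L
  while (length(active)) {
    fit <- ols_terms(x[, active, drop = FALSE], y)
    if (length(fit$aliased)) {
      drop <- sort(fit$aliased)[1L]
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, term = drop, p = NA_real_,
                                  t = NA_real_, reason = "aliased",
                                  stringsAsFactors = FALSE)
      active <- setdiff(active, drop)
      next
    }
    pmax_ <- max(fit$p)
    if (pmax_ < alpha) break
    cand <- names(fit$p)[fit$p >= pmax_ - 1e-12]
    if (length(cand) > 1L) {
      cand <- cand[order(abs(fit$t[cand]), cand)]
    }
    drop <- cand[1L]
    step <- step + 1L
    trace[[step]] <- data.frame(step = step, term = drop,
                                p = unname(fit$p[drop]),
                                t = unname(fit$t[drop]), reason = "p >= alpha",
                                stringsAsFactors = FALSE)
    active <- setdiff(active, drop)
  }
  model <- if (length(active)) {
    standardized_fit(y, x[, active, drop = FALSE])
  } else NULL
  structure(
    list(retained = active, model = model,
         trace = if (length(trace)) do.call(rbind, trace) else
           data.frame(step = integer(0), term = character(0), p = numeric(0),
                      t = numeric(0), reason = character(0)),
         alpha = alpha, n = length(y)),
    class = "backward_lm")
}

#' @export
print.backward_lm <- function(x, ...) {
  cat(sprintf("Backward elimination (alpha = %g): %d of %d candidates retained\n",
              x$alpha, length(x$retained),
              length(x$retained) + nrow(x$trace)))
  if (is.null(x$model)) {
    cat("  no term reached significance; empty final model\n")
    return(invisible(x))
  }
  m <- x$model
  tab <- data.frame(term = names(m$beta), beta = signif(m$beta, 3),
                    t = signif(m$t, 4), p = signif(m$p, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("Adjusted R2 = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              m$adj_r2, m$df[1L], m$df[2L], m$f, m$p_model))
  invisible(x)
}

#' Standardized ordinary-least-squares fit
#'
#' Fits the outcome on the given predictor set with both sides z-scored, so
#' coefficients are standardized betas. Reports per-term t and p (identical
#' to the unstandardized fit), R-squared, adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - k - 1)`, and the overall model F.
#'
#' @param y numeric outcome.
#' @param x numeric predictor matrix (non-empty; `k < n - 1`).
#' @return a list: `beta` (named standardized coefficients), `t`, `p`,
#'   `r2`, `adj_r2`, `f`, `df` (c(k, n - k - 1)), `p_model`.
#' @export
standardized_fit <- function(y, x) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stopf("retained predictor set is empty")
  n <- length(y)
  if (ncol(x) >= n - 1L) stopf("k must be < n - 1")
  zx <- scale(x)
  if (any(attr(zx, "scaled:scale") == 0)) stopf("constant predictor column")
  zy <- as.numeric(scale(y))
  fit <- ols_terms(zx, zy)
  if (length(fit$aliased)) stopf("rank-deficient retained set")
  list(beta = fit$coef, t = fit$t, p = fit$p, r2 = fit$r2,
       adj_r2 = fit$adj_r2, f = fit$f, df = fit$df,
       p_model = pf(fit$f, fit$df[1L], fit$df[2L], lower.tail = FALSE))
}
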