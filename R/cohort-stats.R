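# ---- Type III sums of squares by block model comparison -------------------
#
# Factors are sum-to-zero coded and covariates centered, so dropping a
# term's columns from the full design reproduces the conventional Type III
# test (including the intercept / grand-mean test used for within-subject
# main effects). Designs here contain no factor interactions, for which this
# construction is exact.

# covariates: data.frame -> centered numeric design block
covariate_block <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    return(NULL)
  }
  covariates <- as.data.frame(covariates)
  blocks <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v - mean(v), ncol = 1L, dimnames = list(NULL, nm))
    } else {
      f <- droplevels(as.factor(v))
      if (nlevels(f) < 2L) stopf("covariate `%s` is constant", nm)
      m <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1L, drop = FALSE]
      colnames(m) <- paste0(nm, seq_len(ncol(m)))
      m <- sweep(m, 2L, colMeans(m))
    }
    m
  })
  do.call(cbind, blocks)
}

group_block <- function(group) {
  f <- droplevels(as.factor(group))
  m <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1L, drop = FALSE]
  colnames(m) <- paste0("group", seq_len(ncol(m)))
  m
}

# blocks: named list of design blocks (intercept included as its own block);
# returns per-term Type III SS / F / p plus the full-model residuals
type3_fit <- function(y, blocks) {
  X <- do.call(cbind, unname(blocks))
  n <- length(y)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stopf("design is rank deficient")
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df_res <- n - ncol(X)
  if (df_res < 1L) stopf("no residual degrees of freedom")
  widths <- vapply(blocks, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  tab <- data.frame(term = names(blocks), df = widths, ss = NA_real_,
                    f = NA_real_, p = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (i in seq_along(blocks)) {
    keep <- setdiff(seq_len(ncol(X)), starts[i]:ends[i])
    rss_red <- if (length(keep)) sum(lm.fit(X[, keep, drop = FALSE], y)$residuals^2)
               else sum(y^2)
    tab$ss[i] <- rss_red - rss
    tab$f[i] <- (tab$ss[i] / widths[i]) / (rss / df_res)
    tab$p[i] <- pf(tab$f[i], widths[i], df_res, lower.tail = FALSE)
  }
  list(table = tab, rss = rss, df_res = df_res, residuals = fit$residuals)
}

# ---- change scores --------------------------------------------------------

#' One-year change scores
#'
#' Per-subject one-year change, `score_visit2 - score_visit1`, for each
#' pegboard task, plus the motor-scale change. Subjects missing either visit
#' of a task are excluded from that task's change scores (listwise within
#' task), with a message.
#'
#' @param cohort a cohort data.frame as produced by [generate_cohort()]:
#'   columns `subject_id`, `diagnosis`, `ppt_<task>_v1/2`, `updrs_v1/2`.
#' @param tasks tasks to difference.
#' @return a long data.frame of class `change_scores`: `subject_id`,
#'   `diagnosis`, `task`, `change` (pegs/year), `updrs_change` (points/year).
#' @export
one_year_change <- function(cohort, tasks = TASK_LABELS) {
  stopifnot(is.data.frame(cohort))
  tasks <- match.arg(tasks, TASK_LABELS, several.ok = TRUE)
  out <- list()
  updrs_chg <- if (all(c("updrs_v1", "updrs_v2") %in% names(cohort))) {
    cohort$updrs_v2 - cohort$updrs_v1
  } else rep(NA_real_, nrow(cohort))
  for (task in tasks) {
    v1 <- cohort[[paste0("ppt_", task, "_v1")]]
    v2 <- cohort[[paste0("ppt_", task, "_v2")]]
    if (is.null(v1) || is.null(v2)) {
      stopf("cohort lacks both visits for task `%s`", task)
    }
    ok <- !is.na(v1) & !is.na(v2)
    if (any(!ok)) {
      message(sum(!ok), " subject(s) missing a visit excluded for task ", task)
    }
    out[[task]] <- data.frame(
      subject_id = cohort$subject_id[ok],
      diagnosis = cohort$diagnosis[ok], task = task,
      change = v2[ok] - v1[ok], updrs_change = updrs_chg[ok],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("change_scores", "data.frame")
  res
}

#' Summarize change scores by group and task
#'
#' @param changes a [one_year_change()] result.
#' @return a data.frame of group x task mean, SD, and n of the change.
#' @export
change_summary <- function(changes) {
  stopifnot(inherits(changes, "change_scores"))
  agg <- aggregate(change ~ diagnosis + task, data = changes,
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                       n = length(v)))
  out <- data.frame(diagnosis = agg$diagnosis, task = agg$task,
                    mean_change = agg$change[, "mean"],
                    sd_change = agg$change[, "sd"], n = agg$change[, "n"])
  out[order(out$task, out$diagnosis), ]
}

# ---- ANOVA / ANCOVA -------------------------------------------------------

#' One-way ANOVA, optionally covariate-adjusted
#'
#' Between-groups F test. With covariates the reported F is the group effect
#' from the linear model including the covariates (Type III sums of squares,
#' sum-to-zero factor coding).
#'
#' @param values numeric response.
#' @param group grouping factor (>= 2 levels, >= 2 observations each).
#' @param covariates optional data.frame of covariates (numeric or factor),
#'   same length as `values`.
#' @return a list of class `oneway_anova`: `f`, `df` (c(df1, df2)), `p`, and
#'   the full Type III `table`.
#' @export
oneway_anova <- function(values, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  if (any(table(group) < 2L)) stopf("every group needs at least 2 records")
  keep <- !is.na(values)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  if (any(!keep)) {
    message(sum(!keep), " record(s) with missing data excluded")
    values <- values[keep]; group <- droplevels(group[keep])
    if (!is.null(covariates)) covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  blocks <- list("(Intercept)" = matrix(1, length(values), 1L))
  cb <- covariate_block(covariates)
  if (!is.null(cb)) blocks$covariates <- cb
  blocks$group <- group_block(group)
  fit <- type3_fit(values, blocks)
  row <- fit$table[fit$table$term == "group", ]
  structure(list(f = row$f, df = c(row$df, fit$df_res), p = row$p,
                 table = fit$table, n = length(values)),
            class = "oneway_anova")
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (n = %d)\n",
              x$df[1L], x$df[2L], x$f, x$p, x$n))
  invisible(x)
}

#' Mixed-design repeated-measures ANCOVA
#'
#' Two-factor mixed analysis of covariance: one within-subject factor (e.g.
#' visit, or sensor), one between-subject factor (diagnosis), covariates as
#' between-subject regressors, Type III sums of squares with sum-to-zero
#' coding and covariates evaluated at their means. Computed by the standard
#' orthonormal-contrast decomposition: the between table comes from subject
#' means, the within main effect and interaction from orthonormal contrast
#' scores pooled across contrasts. With more than two within levels a
#' Greenhouse-Geisser epsilon is estimated from the contrast-score residual
#' covariance, a Mauchly sphericity test is run, and GG-corrected p-values
#' are reported alongside the uncorrected ones (flagged when sphericity is
#' violated).
#'
#' Subjects with incomplete within-factor cells are dropped with a message.
#'
#' @param data long-format data.frame.
#' @param dv,subject,within,between column names of the response, subject
#'   id, within factor, and between factor.
#' @param covariates character vector of covariate column names (constant
#'   within subject).
#' @return an object of class `mixed_ancova`: an effect `table` with F, df,
#'   p (and `p_gg` for within rows), `gg_epsilon`, `mauchly_p`,
#'   `sphericity_violated`, `n_subjects`, `n_dropped`.
#' @export
mixed_ancova <- function(data, dv, subject, within, between,
                         covariates = character()) {
  stopifnot(is.data.frame(data))
  for (col in c(dv, subject, within, between, covariates)) {
    if (!col %in% names(data)) stopf("column `%s` not found", col)
  }
  data <- data[, c(dv, subject, within, between, covariates)]
  data <- data[complete.cases(data), ]
  wlev <- unique(as.character(data[[within]]))
  k <- length(wlev)
  if (k < 2L) stopf("within factor needs >= 2 levels")
  # wide response matrix, subjects x within levels
  ids <- unique(as.character(data[[subject]]))
  Y <- matrix(NA_real_, length(ids), k, dimnames = list(ids, wlev))
  for (r in seq_len(nrow(data))) {
    Y[as.character(data[[subject]][r]), as.character(data[[within]][r])] <-
      data[[dv]][r]
  }
  complete <- rowSums(is.na(Y)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " subject(s) with incomplete within-factor cells dropped")
  }
  Y <- Y[complete, , drop = FALSE]
  ids <- rownames(Y)
  first <- data[!duplicated(as.character(data[[subject]])), ]
  rownames(first) <- as.character(first[[subject]])
  first <- first[ids, , drop = FALSE]
  grp <- droplevels(as.factor(first[[between]]))
  if (nlevels(grp) < 2L) stopf("between factor needs >= 2 levels")
  if (any(table(grp) < 2L)) stopf("every group needs at least 2 subjects")
  covs <- if (length(covariates)) first[, covariates, drop = FALSE] else NULL
  n <- nrow(Y)

  blocks <- list("(Intercept)" = matrix(1, n, 1L))
  cb <- covariate_block(covs)
  if (!is.null(cb)) blocks$covariates <- cb
  blocks$group <- group_block(grp)
  # between-subject stratum: subject means (x k so SS are on the usual scale)
  fit_b <- type3_fit(rowMeans(Y) * sqrt(k), blocks)
  # within stratum: orthonormal polynomial contrast scores
  C <- contr.poly(k)
  ss_time <- ss_ixn <- rss_w <- 0
  E <- matrix(NA_real_, n, k - 1L)
  for (cidx in seq_len(k - 1L)) {
    zc <- as.numeric(Y %*% C[, cidx])
    fz <- type3_fit(zc, blocks)
    ss_time <- ss_time + fz$table$ss[fz$table$term == "(Intercept)"]
    ss_ixn <- ss_ixn + fz$table$ss[fz$table$term == "group"]
    rss_w <- rss_w + fz$rss
    E[, cidx] <- fz$residuals
  }
  df_res <- fit_b$df_res
  df_time <- k - 1L
  df_ixn <- (k - 1L) * (nlevels(grp) - 1L)
  df_err_w <- (k - 1L) * df_res
  ms_err <- rss_w / df_err_w
  f_time <- (ss_time / df_time) / ms_err
  f_ixn <- (ss_ixn / df_ixn) / ms_err

  gg_eps <- 1
  mauchly_p <- NA_real_
  if (k > 2L) {
    S <- crossprod(E) / df_res
    gg_eps <- sum(diag(S))^2 / ((k - 1) * sum(S^2))
    W <- det(S) / (sum(diag(S)) / (k - 1))^(k - 1)
    dcorr <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * df_res)
    chi2 <- -df_res * dcorr * log(max(W, .Machine$double.xmin))
    df_m <- k * (k - 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi2, df_m, lower.tail = FALSE)
  }
  violated <- k > 2L && !is.na(mauchly_p) && mauchly_p < 0.05

  brow <- function(term) fit_b$table[fit_b$table$term == term, ]
  tab <- data.frame(
    effect = c(between, if (!is.null(cb)) "covariates", within,
               paste0(within, ":", between)),
    df1 = c(brow("group")$df, if (!is.null(cb)) brow("covariates")$df,
            df_time, df_ixn),
    df2 = c(df_res, if (!is.null(cb)) df_res, df_err_w, df_err_w),
    f = c(brow("group")$f, if (!is.null(cb)) brow("covariates")$f,
          f_time, f_ixn),
    p = c(brow("group")$p, if (!is.null(cb)) brow("covariates")$p,
          pf(f_time, df_time, df_err_w, lower.tail = FALSE),
          pf(f_ixn, df_ixn, df_err_w, lower.tail = FALSE)),
    stringsAsFactors = FALSE)
  tab$p_gg <- tab$p
  wrows <- tab$effect %in% c(within, paste0(within, ":", between))
  tab$p_gg[wrows] <- pf(tab$f[wrows], tab$df1[wrows] * gg_eps,
                        tab$df2[wrows] * gg_eps, lower.tail = FALSE)
  structure(list(table = tab, gg_epsilon = gg_eps, mauchly_p = mauchly_p,
                 sphericity_violated = violated, n_subjects = n,
                 n_dropped = n_dropped, within = within, between = between),
            class = "mixed_ancova")
}

#' @export
print.mixed_ancova <- function(x, ...) {
  cat(sprintf("Mixed ANCOVA (%d subjects, %d dropped)\n", x$n_subjects,
              x$n_dropped))
  tab <- x$table
  tab$f <- signif(tab$f, 4); tab$p <- signif(tab$p, 4)
  tab$p_gg <- signif(tab$p_gg, 4)
  print(tab, row.names = FALSE)
  if (!is.na(x$mauchly_p)) {
    cat(sprintf("Greenhouse-Geisser epsilon = %.3f; Mauchly p = %.3g%s\n",
                x$gg_epsilon, x$mauchly_p,
                if (x$sphericity_violated) " (sphericity violated: use p_gg)" else ""))
  }
  invisible(x)
}

# ---- post hoc families and FDR -------------------------------------------

#' Benjamini-Hochberg (or Benjamini-Yekutieli) adjusted p-values
#'
#' Step-up false-discovery-rate adjustment within one declared comparison
#' family. Thin validated interface over [stats::p.adjust()].
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(pvalues)) stopf("empty p-value family")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stopf("all p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = method)
}

#' Pairwise group comparisons of change scores with FDR correction
#'
#' Two-sample t tests (Welch by default) between diagnosis groups on the
#' one-year change of a single task, with Benjamini-Hochberg adjustment
#' within the declared family only.
#'
#' @param changes a [one_year_change()] result.
#' @param task the task whose change scores to compare.
#' @param comparisons list of length-2 character vectors naming group pairs;
#'   default all pairs present.
#' @param var_equal pooled-variance Student t instead of Welch.
#' @param fdr_method passed to [fdr_bh()].
#' @return a data.frame of class `posthoc_set`: comparison label, mean
#'   difference, t, df, raw `p`, adjusted `p_adj`.
#' @export
posthoc_group_changes <- function(changes, task, comparisons = NULL,
                                  var_equal = FALSE,
                                  fdr_method = c("BH", "BY")) {
  stopifnot(inherits(changes, "change_scores"))
  fdr_method <- match.arg(fdr_method)
  task <- match.arg(task, TASK_LABELS)
  d <- changes[changes$task == task, ]
  groups <- unique(as.character(d$diagnosis))
  if (is.null(comparisons)) {
    if (length(groups) < 2L) stopf("need at least two groups")
    comparisons <- combn(sort(groups), 2L, simplify = FALSE)
  }
  if (!length(comparisons)) stopf("empty comparison family")
  rows <- lapply(comparisons, function(pr) {
    stopifnot(length(pr) == 2L)
    a <- d$change[d$diagnosis == pr[1L]]
    b <- d$change[d$diagnosis == pr[2L]]
    tt <- t.test(a, b, var.equal = var_equal)
    data.frame(comparison = paste(pr, collapse = " vs "),
               estimate = mean(a) - mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_bh(out$p, method = fdr_method)
  class(out) <- c("posthoc_set", "data.frame")
  attr(out, "task") <- task
  out
}

#' Per-sensor group comparisons within one task
#'
#' For one task and one kinematic feature, compares the two diagnosis groups
#' sensor by sensor with two-sample t tests (Welch by default), adjusting
#' p-values with Benjamini-Hochberg within that task's sensor family only -
#' never across tasks. Sensors with fewer than 2 records in a group are
#' skipped with a message.
#'
#' @param features data.frame with columns `diagnosis`, `sensor`, `task`,
#'   and the feature column.
#' @param value feature column name (`"sd_accel"` or `"apen"`).
#' @param task task whose family of sensors is tested.
#' @param var_equal pooled-variance Student t instead of Welch.
#' @param fdr_method passed to [fdr_bh()].
#' @return a data.frame of class `posthoc_set`: sensor, per-group means,
#'   mean difference, t, df, `p`, `p_adj`.
#' @export
sensor_group_tests <- function(features, value = c("sd_accel", "apen"),
                               task, var_equal = FALSE,
                               fdr_method = c("BH", "BY")) {
  value <- match.arg(value)
  fdr_method <- match.arg(fdr_method)
  task <- match.arg(task, TASK_LABELS)
  d <- features[features$task == task, ]
  groups <- sort(unique(as.character(d$diagnosis)))
  if (length(groups) != 2L) stopf("need exactly two diagnosis groups")
  rows <- list()
  for (s in unique(as.character(d$sensor))) {
    a <- d[[value]][d$sensor == s & d$diagnosis == groups[1L]]
    b <- d[[value]][d$sensor == s & d$diagnosis == groups[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      message("sensor ", s, " skipped: a group has fewer than 2 records")
      next
    }
    tt <- t.test(a, b, var.equal = var_equal)
    rows[[s]] <- data.frame(
      sensor = s, mean_1 = mean(a), mean_2 = mean(b),
      estimate = mean(a) - mean(b), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no testable sensors")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1L])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2L])
  out$p_adj <- fdr_bh(out$p, method = fdr_method)
  class(out) <- c("posthoc_set", "data.frame")
  attr(out, "task") <- task
  attr(out, "value") <- value
  out
}

#' Correlate two change scores
#'
#' Spearman rank-order (average ranks for ties) or Pearson correlation with
#' a two-sided p-value, for change-change associations such as motor-scale
#' worsening versus pegboard decline.
#'
#' @param x,y paired numeric vectors (n >= 3 complete pairs).
#' @param method `"spearman"` or `"pearson"`.
#' @return a list: `estimate`, `p`, `n`, `method`.
#' @export
correlate_changes <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined: zero variance in an input")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}
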