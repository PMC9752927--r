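#' One-way ANOVA with Tukey post-hoc across groups
#'
#' Compares a network metric (or any numeric column) across subject groups:
#' overall F test plus Tukey HSD pairwise comparisons.
#'
#' @param table data.frame of subjects.
#' @param metric Name of the numeric column to compare.
#' @param group Name of the grouping column (default "group").
#' @return List with `f`, `p`, `group_means`, and `pairwise` (data.frame of
#'   Tukey comparisons: `comparison`, `diff`, `p_adj`).
#' @export
group_compare <- function(table, metric, group = "group") {
  d <- table[stats::complete.cases(table[, c(metric, group)]), c(metric, group)]
  names(d) <- c("value", "g")
  d$g <- factor(d$g)
  tab <- table(d$g)
  if (length(tab) < 2 || any(tab < 2)) {
    pg_stop("need >= 2 groups with >= 2 subjects each", "pg_stats_error")
  }
  if (all(tapply(d$value, d$g, stats::var) == 0)) {
    pg_stop("zero within-group variance: F undefined", "pg_stats_error")
  }
  fit <- stats::aov(value ~ g, data = d)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(
    f = sm[["F value"]][1],
    p = sm[["Pr(>F)"]][1],
    group_means = tapply(d$value, d$g, mean),
    pairwise = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE)
  )
}

#' Spearman correlation of a metric with seizure severity
#'
#' Rank correlation between a network metric and the severity score among
#' subjects with a recorded score (controls, whose score is undefined, drop
#' out automatically).
#'
#' @param table data.frame of subjects.
#' @param metric Name of the metric column.
#' @param severity Name of the severity column (default "va2").
#' @return List with `r` (Spearman rho), `p`, and `n` used.
#' @export
severity_correlation <- function(table, metric, severity = "va2") {
  d <- table[stats::complete.cases(table[, c(metric, severity)]),
             c(metric, severity)]
  if (nrow(d) < 5) pg_stop("need >= 5 paired observations", "pg_stats_error")
  ct <- suppressWarnings(
    stats::cor.test(d[[metric]], d[[severity]], method = "spearman",
                    exact = FALSE)
  )
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

#' Stepwise multiple linear regression of severity
#'
#' Forward stepwise selection with backward elimination at each step
#' (probability-of-F to enter 0.05, to remove 0.10 -- the classical
#' SPSS-style criteria). Response and candidates are z-scored, so the
#' reported coefficients are standardized betas. Complete cases only;
#' zero-variance and rank-deficient candidates are excluded with a warning.
#' Selection is fully deterministic given the table.
#'
#' @param table data.frame of subjects.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter Entry threshold on the coefficient p value (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return List with `terms` (data.frame `term`, `beta`, `p` for the
#'   selected model, zero rows if empty), `model` (the final `lm` or NULL),
#'   and `n` complete cases used.
#' @export
stepwise_regression <- function(table, response, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  cols <- c(response, candidates)
  d <- table[stats::complete.cases(table[, cols, drop = FALSE]), cols,
             drop = FALSE]
  n <- nrow(d)
  if (n < length(candidates) / 2 + 3) {
    if (n < 10) pg_stop("too few complete cases for stepwise selection",
                        "pg_stats_error")
  }
  keep <- vapply(cols, function(v) stats::sd(d[[v]]) > 0, logical(1))
  if (!keep[[response]]) pg_stop("response has zero variance", "pg_stats_error")
  dropped <- candidates[!keep[candidates]]
  if (length(dropped) > 0) {
    warning(sprintf("dropping zero-variance candidate(s): %s",
                    paste(dropped, collapse = ", ")))
    candidates <- setdiff(candidates, dropped)
  }
  z <- as.data.frame(lapply(d[, c(response, candidates), drop = FALSE], scale))
  names(z) <- c(response, candidates)

  selected <- character(0)
  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0) break
    # forward step: candidate with smallest coefficient p value
    ps <- vapply(pool, function(v) {
      X <- as.matrix(z[, c(selected, v), drop = FALSE])
      if (qr(cbind(1, X))$rank < ncol(X) + 1) return(NA_real_)  # collinear
      fit <- stats::lm(stats::reformulate(c(selected, v), response), data = z)
      stats::coef(summary(fit))[v, "Pr(>|t|)"]
    }, numeric(1))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= p_enter) break
    selected <- c(selected, pool[which.min(ps)])
    # backward pass: remove any term whose p rose above p_remove
    repeat {
      fit <- stats::lm(stats::reformulate(selected, response), data = z)
      cf <- stats::coef(summary(fit))
      pv <- cf[selected, "Pr(>|t|)"]
      if (max(pv) <= p_remove) break
      selected <- setdiff(selected, selected[which.max(pv)])
      if (length(selected) == 0) break
    }
  }
  if (length(selected) == 0) {
    return(list(terms = data.frame(term = character(0), beta = numeric(0),
                                   p = numeric(0), stringsAsFactors = FALSE),
                model = NULL, n = n))
  }
  fit <- stats::lm(stats::reformulate(selected, response), data = z)
  cf <- stats::coef(summary(fit))
  list(
    terms = data.frame(term = selected, beta = unname(cf[selected, "Estimate"]),
                       p = unname(cf[selected, "Pr(>|t|)"]),
                       stringsAsFactors = FALSE),
    model = fit, n = n
  )
}
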