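#' Proportion of inhibited cells with binomial standard error
#'
#' For k of n cells showing inhibition, the estimate is p = k/n with
#' standard error sqrt(p (1 - p) / n). Percentages print to one decimal.
#'
#' @param k Number of cells with inhibition (vectorized).
#' @param n Total number of cells.
#' @param group Optional group label(s).
#' @param n_individuals Optional number of individuals contributing.
#' @return A data.frame of class `"group_proportion"` with columns
#'   `group`, `k`, `n`, `p_hat`, `sem`, `pct`, `pct_sem`, `n_individuals`.
#' @examples
#' proportion_with_sem(34, 48)  # 70.8 +/- 6.6 %
#' @export
proportion_with_sem <- function(k, n, group = NA, n_individuals = NA) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  p <- k / n
  sem <- sqrt(p * (1 - p) / n)
  out <- data.frame(group = group, k = k, n = n, p_hat = p, sem = sem,
                    pct = round(100 * p, 1), pct_sem = round(100 * sem, 1),
                    n_individuals = n_individuals)
  class(out) <- c("group_proportion", "data.frame")
  out
}

#' @export
print.group_proportion <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("%s: %.1f +/- %.1f%% (%d of %d cells)\n",
                ifelse(is.na(x$group[i]), "all", as.character(x$group[i])),
                x$pct[i], x$pct_sem[i], x$k[i], x$n[i]))
  invisible(x)
}

#' @export
plot.group_proportion <- function(x, ...) {
  b <- graphics::barplot(x$p_hat, names.arg = x$group, ylim = c(0, 1),
                         ylab = "Proportion inhibited", las = 2, ...)
  graphics::arrows(b, pmax(x$p_hat - x$sem, 0), b,
                   pmin(x$p_hat + x$sem, 1),
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

# Tidy fixed-effect table from an lme4/lmerTest fit
fixef_table <- function(fit) {
  s <- stats::coef(summary(fit))
  stat_col <- intersect(c("z value", "t value"), colnames(s))[1]
  p_col <- grep("^Pr", colnames(s), value = TRUE)[1]
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"], statistic = s[, stat_col],
             p_value = if (!is.na(p_col)) s[, p_col]
               else 2 * stats::pnorm(-abs(s[, stat_col])),
             row.names = NULL)
}

#' Logistic mixed model for a binary cell property
#'
#' Fits a logit-link generalized linear mixed model of a per-cell binary
#' outcome (e.g. inhibition) on a group fixed effect with a random
#' intercept per individual, accounting for repeated measures within
#' single animals. Maximum likelihood with the Laplace approximation
#' (lme4::glmer); fixed-effect contrasts are reported with Wald
#' statistics. Non-convergence, or complete separation detected as
#' outsized estimates, flags the fit; a plain logistic fit is attached as
#' a diagnostic fallback.
#'
#' @param data Data.frame with the outcome, group and individual columns.
#' @param outcome,group,individual Column names (defaults `"inhibited"`,
#'   `"group"`, `"individual_id"`).
#' @return Object of class `"pr_mixed"`: `coefficients` (term, estimate,
#'   se, statistic, p_value), `ranef_var` (random-intercept variance),
#'   `link`, `converged`, `messages`, and the underlying `fit`.
#' @export
fit_logistic_mixed <- function(data, outcome = "inhibited",
                               group = "group",
                               individual = "individual_id") {
  stopifnot(all(c(outcome, group, individual) %in% names(data)))
  d <- data.frame(y = as.integer(data[[outcome]]),
                  g = factor(data[[group]]),
                  id = factor(data[[individual]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$g)) < 2L) stop("need at least 2 groups")
  msgs <- character(0)
  # singular (zero random-variance) fits arrive as messages and are
  # legitimate boundary solutions; real convergence failures are warnings.
  # The Wald table is computed inside the handler too: vcov() may warn
  # about Hessian fallbacks on boundary fits.
  cf <- NULL
  fit <- withCallingHandlers({
    m <- lme4::glmer(y ~ g + (1 | id), data = d,
                     family = stats::binomial())
    cf <- fixef_table(m)
    m
  },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  separation <- any(abs(cf$estimate) > 15)
  if (separation) {
    msgs <- c(msgs, "possible complete separation; estimates unstable")
    fallback <- stats::glm(y ~ g, data = d, family = stats::binomial())
    s <- stats::coef(summary(fallback))
    cf <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                     statistic = s[, 3], p_value = s[, 4],
                     row.names = NULL)
  }
  structure(list(coefficients = cf, ranef_var = vc$vcov[1],
                 link = "logit",
                 converged = length(msgs) == 0L && !separation,
                 messages = msgs, n_obs = nrow(d),
                 n_individuals = nlevels(droplevels(d$id)), fit = fit),
            class = "pr_mixed")
}

#' Linear mixed model for a continuous cell property
#'
#' Same design as [fit_logistic_mixed()] with an identity link and
#' Gaussian response (e.g. lambda_max compared across groups). REML fit
#' via lmerTest; fixed effects reported with Satterthwaite t-tests.
#'
#' @inheritParams fit_logistic_mixed
#' @param outcome Column name of the continuous response (default
#'   `"lambda_max"`).
#' @return Object of class `"pr_mixed"`.
#' @export
fit_linear_mixed <- function(data, outcome = "lambda_max",
                             group = "group",
                             individual = "individual_id") {
  stopifnot(all(c(outcome, group, individual) %in% names(data)))
  d <- data.frame(y = as.numeric(data[[outcome]]),
                  g = factor(data[[group]]),
                  id = factor(data[[individual]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$g)) < 2L) stop("need at least 2 groups")
  msgs <- character(0)
  # the Satterthwaite machinery can emit Hessian fallback warnings at
  # summary() time on small boundary fits; capture those too
  cf <- NULL
  fit <- withCallingHandlers({
    m <- lmerTest::lmer(y ~ g + (1 | id), data = d)
    cf <- fixef_table(m)
    m
  },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = cf,
                 ranef_var = vc$vcov[1], link = "identity",
                 converged = length(msgs) == 0L, messages = msgs,
                 n_obs = nrow(d),
                 n_individuals = nlevels(droplevels(d$id)), fit = fit),
            class = "pr_mixed")
}

#' @export
print.pr_mixed <- function(x, ...) {
  cat(sprintf("<%s-link mixed model: %d cells, %d individuals%s>\n",
              x$link, x$n_obs, x$n_individuals,
              if (x$converged) "" else " [flagged]"))
  print(x$coefficients, digits = 3)
  cat(sprintf("random intercept variance (individual): %.4g\n",
              x$ranef_var))
  invisible(x)
}

#' All pairwise group contrasts via two-group mixed models
#'
#' Refits the mixed model for every pair of groups, mirroring the pairwise
#' GLME comparisons reported alongside multi-group summaries. P-values are
#' per-pair (no multiplicity correction).
#'
#' @inheritParams fit_logistic_mixed
#' @param link `"logit"` for binary outcomes, `"identity"` for continuous.
#' @return Data.frame: `group1`, `group2`, `estimate`, `se`, `statistic`,
#'   `p_value`, `converged`.
#' @export
pairwise_group_tests <- function(data, outcome = "inhibited",
                                 group = "group",
                                 individual = "individual_id",
                                 link = c("logit", "identity")) {
  link <- match.arg(link)
  fitter <- if (link == "logit") fit_logistic_mixed else fit_linear_mixed
  gl <- unique(as.character(data[[group]]))
  pairs <- utils::combn(gl, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    d <- data[data[[group]] %in% pairs[, j], ]
    m <- fitter(d, outcome = outcome, group = group,
                individual = individual)
    cf <- m$coefficients[2, ]  # the group contrast
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               estimate = cf$estimate, se = cf$se,
               statistic = cf$statistic, p_value = cf$p_value,
               converged = m$converged)
  })
  do.call(rbind, out)
}

#' One-sample t-test of lambda_max against an expected opsin tuning
#'
#' Tests whether fitted lambda_max values differ from the expected peak of
#' a candidate opsin, with Bonferroni correction over the number of
#' comparisons made (`p_corr = min(1, p * n_comparisons)`).
#'
#' @param lambda_maxes Per-cell lambda_max values, nm (>= 3).
#' @param expected Expected tuning, nm.
#' @param n_comparisons Number of tests in the family (default 1).
#' @return List: `t`, `df`, `p_value`, `p_corrected`, `mean`, `expected`.
#' @export
ttest_vs_expected <- function(lambda_maxes, expected, n_comparisons = 1) {
  if (length(lambda_maxes) < 3L) stop("need at least 3 cells")
  if (stats::sd(lambda_maxes) == 0) {
    equal <- isTRUE(all.equal(mean(lambda_maxes), expected))
    return(list(t = if (equal) 0 else Inf,
                df = length(lambda_maxes) - 1,
                p_value = if (equal) 1 else 0,
                p_corrected = if (equal) 1 else 0,
                mean = mean(lambda_maxes), expected = expected))
  }
  tt <- stats::t.test(lambda_maxes, mu = expected)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       p_corrected = min(1, tt$p.value * n_comparisons),
       mean = mean(lambda_maxes), expected = expected)
}

# Compact letter display from a pairwise "significantly different" matrix.
# Groups sharing a letter are not significantly different: letters are the
# maximal cliques of the non-difference graph (groups here number <= ~10,
# so plain recursive Bron-Kerbosch enumeration is ample).
cld_letters <- function(levels, diff_mat) {
  n <- length(levels)
  adj <- !diff_mat
  diag(adj) <- FALSE  # no self-loops, or the recursion never shrinks p
  cliques <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0L && length(x) == 0L) {
      cliques[[length(cliques) + 1L]] <<- r
      return()
    }
    for (v in p) {
      nb <- which(adj[v, ])
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  out <- vapply(seq_len(n), function(i) {
    paste(letters[which(vapply(cliques, function(cl) i %in% cl,
                               logical(1)))], collapse = "")
  }, character(1))
  names(out) <- levels
  out
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Compares a per-cell duration (or any continuous feature) across groups:
#' one-way ANOVA F-test followed by Tukey's honest significant difference
#' for all pairs, summarized as a compact letter display (groups sharing a
#' letter do not differ at `alpha`).
#'
#' @param value Numeric response per cell.
#' @param group Group labels.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List: `F`, `df` (c(between, within)), `p_value`, `tukey`
#'   (data.frame of pairwise comparisons), `letters` (named character).
#' @export
anova_tukey <- function(value, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 cells")
  fit <- stats::aov(value ~ group)
  a <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  lv <- levels(group)
  diff_mat <- matrix(FALSE, length(lv), length(lv),
                     dimnames = list(lv, lv))
  # match comparison labels against level pairs rather than splitting on
  # "-", which may occur inside group names
  cmb <- utils::combn(lv, 2)
  for (i in seq_len(nrow(tukey))) {
    hit <- which(paste(cmb[2, ], cmb[1, ], sep = "-") ==
                   tukey$comparison[i] |
                 paste(cmb[1, ], cmb[2, ], sep = "-") ==
                   tukey$comparison[i])[1]
    sig <- tukey$p_adj[i] < alpha
    diff_mat[cmb[1, hit], cmb[2, hit]] <- sig
    diff_mat[cmb[2, hit], cmb[1, hit]] <- sig
  }
  list(F = a[["F value"]][1], df = a[["Df"]],
       p_value = a[["Pr(>F)"]][1], tukey = tukey,
       letters = cld_letters(lv, diff_mat))
}
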