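#' Multilevel regression of SAI change on session-specific recalibration
#'
#' Fits the reduced random-intercept model relating each participant's SAI
#' change to their recalibration, with four session-by-modality interaction
#' predictors (veridical/conflict x proprioceptive/visual recalibration) and
#' a participant-level random intercept estimated by restricted maximum
#' likelihood. Each participant contributes one observation per session.
#' Wald 95% confidence intervals and t statistics use residual degrees of
#' freedom `n_observations - 5` (five fixed-effect parameters). Variance
#' inflation factors are computed per predictor as `1 / (1 - R2_j)` from
#' regressing it on the other predictors.
#'
#' @param table Data frame with columns `participant`, `session` (values
#'   `"conflict"` and `"veridical"`), `delta_sai`, `recal_p`, `recal_v`.
#' @return An object of class `sai_recal_fit` with elements `terms` (data
#'   frame: term, beta, ci_low, ci_high, se, t, df, p), `vif`, `n_participants`,
#'   `n_observations`, `converged` (FALSE when the random-effect variance is
#'   estimated at the boundary and a fixed-effects-only fit is reported),
#'   and the underlying fitted model object.
#' @export
fit_sai_recalibration_model <- function(table) {
  req <- c("participant", "session", "delta_sai", "recal_p", "recal_v")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab <- table
  tab$session <- as.character(tab$session)
  if (!all(tab$session %in% c("conflict", "veridical")))
    stop("session must be 'conflict' or 'veridical'")
  # listwise exclusion of participants missing a session
  counts <- table(tab$participant, tab$session)
  keep <- rownames(counts)[rowSums(counts > 0) == 2]
  dropped <- setdiff(unique(as.character(tab$participant)), keep)
  if (length(dropped)) {
    warning("excluding participants missing a session: ",
            paste(dropped, collapse = ", "))
    tab <- tab[as.character(tab$participant) %in% keep, ]
  }
  if (!nrow(tab)) stop("no complete participants")
  conflict <- as.numeric(tab$session == "conflict")
  X <- data.frame(
    ver_recal_p  = (1 - conflict) * tab$recal_p,
    conf_recal_p = conflict * tab$recal_p,
    ver_recal_v  = (1 - conflict) * tab$recal_v,
    conf_recal_v = conflict * tab$recal_v)
  .check_collinearity(X)
  d <- cbind(delta_sai = tab$delta_sai, X,
             participant = factor(tab$participant))
  n_obs <- nrow(d)
  df_resid <- n_obs - 5L

  fit <- lme4::lmer(
    delta_sai ~ ver_recal_p + conf_recal_p + ver_recal_v + conf_recal_v +
      (1 | participant),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    lmfit <- stats::lm(delta_sai ~ ver_recal_p + conf_recal_p +
                         ver_recal_v + conf_recal_v, data = d)
    beta <- stats::coef(lmfit)
    se <- sqrt(diag(stats::vcov(lmfit)))
    model <- lmfit
  } else {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    model <- fit
  }
  tcrit <- stats::qt(0.975, df_resid)
  tval <- beta / se
  terms <- data.frame(
    term = names(beta),
    beta = as.numeric(beta),
    ci_low = as.numeric(beta - tcrit * se),
    ci_high = as.numeric(beta + tcrit * se),
    se = as.numeric(se),
    t = as.numeric(tval),
    df = df_resid,
    p = 2 * stats::pt(-abs(as.numeric(tval)), df_resid),
    stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms, vif = .vif(X),
                 n_participants = length(unique(d$participant)),
                 n_observations = n_obs,
                 converged = !singular, model = model),
            class = "sai_recal_fit")
}

# VIF_j = 1 / (1 - R2_j) from regressing predictor j on the others.
.vif <- function(X) {
  X <- as.data.frame(X)
  vapply(names(X), function(j) {
    others <- setdiff(names(X), j)
    if (stats::var(X[[j]]) == 0) return(NA_real_)
    r2 <- summary(stats::lm(
      stats::reformulate(others, response = j), data = X))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
}

.check_collinearity <- function(X) {
  m <- as.matrix(X)
  keep <- apply(m, 2, stats::var) > 0
  if (sum(keep) >= 2) {
    q <- qr(scale(m[, keep, drop = FALSE], scale = FALSE))
    if (q$rank < sum(keep))
      stop("collinear predictors: the design matrix is rank deficient")
  }
  invisible(TRUE)
}

#' @export
print.sai_recal_fit <- function(x, ...) {
  cat(sprintf(
    "<sai_recal_fit> %d participants, %d observations%s\n",
    x$n_participants, x$n_observations,
    if (!x$converged) " (singular random effect; fixed-effects fit)" else ""))
  print(x$terms, digits = 3)
  cat("VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.sai_recal_fit <- function(object, ...) {
  stats::setNames(object$terms$beta, object$terms$term)
}

#' @export
summary.sai_recal_fit <- function(object, ...) object

#' Predictor residuals for partial-relationship plots
#'
#' Residuals of the predictor of interest after regressing out the other
#' predictor by simple linear regression, used to visualise the unique
#' contribution of one recalibration modality to the SAI change. When the
#' other predictor has zero variance the residuals are the centred target
#' predictor.
#'
#' @param table Data frame.
#' @param target_predictor,other_predictor Column names.
#' @param outcome Optional outcome column name to carry alongside (default
#'   `"delta_sai"` if present).
#' @return Data frame with `residual` and, when available, the outcome
#'   column.
#' @export
predictor_residuals <- function(table, target_predictor, other_predictor,
                                outcome = "delta_sai") {
  stopifnot(nrow(table) >= 3,
            target_predictor %in% names(table),
            other_predictor %in% names(table))
  y <- table[[target_predictor]]
  x <- table[[other_predictor]]
  r <- if (stats::var(x) == 0) y - mean(y) else
    stats::resid(stats::lm(y ~ x))
  out <- data.frame(residual = as.numeric(r))
  if (outcome %in% names(table)) out[[outcome]] <- table[[outcome]]
  out
}

#' Two-by-two repeated-measures ANOVA
#'
#' Within-participant 2 x 2 ANOVA via the exact difference-score identity:
#' for each effect (two main effects and the interaction) the corresponding
#' contrast of a participant's four cell values is tested against zero with
#' a one-sample t test, and `F = t^2` with (1, n - 1) degrees of freedom.
#'
#' @param values Data frame with columns `participant`, `a`, `b` (each with
#'   exactly two levels), `value`; one value per cell per participant.
#' @return Named list of `test_result` objects: `a`, `b`, `a_x_b`.
#' @export
rm_anova_2x2 <- function(values) {
  stopifnot(all(c("participant", "a", "b", "value") %in% names(values)))
  la <- sort(unique(as.character(values$a)))
  lb <- sort(unique(as.character(values$b)))
  if (length(la) != 2 || length(lb) != 2)
    stop("both factors must have exactly two levels")
  cell <- function(ai, bi) {
    v <- values[values$a == la[ai] & values$b == lb[bi], ]
    v <- v[order(v$participant), ]
    v$value
  }
  ids <- sort(unique(values$participant))
  n <- length(ids)
  c11 <- cell(1, 1); c12 <- cell(1, 2); c21 <- cell(2, 1); c22 <- cell(2, 2)
  if (any(lengths(list(c11, c12, c21, c22)) != n))
    stop("incomplete 2x2 within-participant data")
  contrast_test <- function(d) {
    if (stats::sd(d) == 0) {
      f <- if (mean(d) == 0) 0 else Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      t <- mean(d) / (stats::sd(d) / sqrt(n))
      f <- t^2
      p <- 2 * stats::pt(-abs(t), n - 1)
    }
    structure(list(statistic = f, df = c(1, n - 1), p = p,
                   effect_size = NA_real_, method = "rm-ANOVA (F = t^2)"),
              class = "test_result")
  }
  list(
    a     = contrast_test((c11 + c12) / 2 - (c21 + c22) / 2),
    b     = contrast_test((c11 + c21) / 2 - (c12 + c22) / 2),
    a_x_b = contrast_test((c11 - c12) - (c21 - c22)))
}

#' @export
print.test_result <- function(x, ...) {
  df <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("<test_result> %s: statistic = %.4g, df = (%s), p = %.4g%s\n",
              x$method, x$statistic, df, x$p,
              if (is.finite(x$effect_size %||% NA))
                sprintf(", effect size = %.3f", x$effect_size) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three-group comparison
#'
#' One-way ANOVA with eta-squared and Tukey HSD pairwise comparisons (run
#' only after a significant omnibus test), or the Kruskal-Wallis rank test
#' (with tie correction) where distributional assumptions fail.
#'
#' @param values Numeric outcome vector.
#' @param groups Grouping factor/character vector (>= 3 levels).
#' @param method `"anova_tukey"` or `"kruskal_wallis"`.
#' @param alpha Omnibus significance level gating the post hoc table.
#' @return A `test_result`; for the ANOVA path with a significant omnibus, a
#'   `pairwise` data frame of Tukey-adjusted comparisons is attached.
#' @export
group_comparison <- function(values, groups,
                             method = c("anova_tukey", "kruskal_wallis"),
                             alpha = 0.05) {
  method <- match.arg(method)
  g <- factor(groups)
  if (nlevels(g) < 3) stop("need at least 3 groups")
  if (any(table(g) < 2)) stop("need >= 2 observations per group")
  stopifnot(length(values) == length(g))
  if (method == "kruskal_wallis") {
    k <- stats::kruskal.test(values, g)
    return(structure(list(statistic = unname(k$statistic),
                          df = unname(k$parameter), p = k$p.value,
                          effect_size = NA_real_,
                          method = "Kruskal-Wallis"),
                     class = "test_result"))
  }
  fit <- stats::aov(values ~ g)
  ss <- summary(fit)[[1]]
  f <- ss[["F value"]][1]
  p <- ss[["Pr(>F)"]][1]
  eta2 <- ss[["Sum Sq"]][1] / sum(ss[["Sum Sq"]])
  res <- structure(list(statistic = f,
                        df = c(ss[["Df"]][1], ss[["Df"]][2]),
                        p = p, effect_size = eta2,
                        method = "one-way ANOVA"),
                   class = "test_result")
  if (is.finite(p) && p < alpha) {
    tk <- stats::TukeyHSD(fit)$g
    res$pairwise <- data.frame(comparison = rownames(tk),
                               diff = tk[, "diff"],
                               p_adj = tk[, "p adj"],
                               row.names = NULL,
                               stringsAsFactors = FALSE)
  }
  res
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return A `test_result` with `statistic` = r, `df` = n - 2, two-tailed p.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(statistic = unname(ct$estimate),
                 df = unname(ct$parameter), p = ct$p.value,
                 effect_size = unname(ct$estimate),
                 method = "Pearson correlation"),
            class = "test_result")
}

#' One-sample t test with Cohen's d
#'
#' @param values Numeric vector (n >= 2, non-constant).
#' @param mu0 Null value.
#' @return A `test_result` with `effect_size` = Cohen's d.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation")
  tt <- stats::t.test(values, mu = mu0)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 effect_size = (mean(values) - mu0) / s,
                 method = "one-sample t"),
            class = "test_result")
}
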