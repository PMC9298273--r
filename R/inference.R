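# Statistics layer: one-sided Mann-Whitney AUC comparison, random-intercept
# linear mixed models with likelihood-ratio tests, Pearson correlation and
# Ward clustering of effect-size profiles.

#' One-sided Mann-Whitney rank test
#'
#' Compares two AUC (or any score) samples in a stated direction. For small
#' samples (combined n <= `exact_max_n`) the p-value is computed by complete
#' enumeration of all group assignments of the pooled midranks; larger
#' samples use the normal approximation with midrank tie correction and
#' continuity correction.
#'
#' @param auc_a,auc_b Non-empty numeric samples.
#' @param alternative `"b_greater"` tests whether sample b is
#'   stochastically larger than a; `"a_greater"` the reverse.
#' @param exact_max_n Largest combined sample size for the exact path.
#' @return Object of class `rank_test`: `U` (for the sample tested as
#'   larger), `p`, `direction`, `n_a`, `n_b`, `method`.
#' @export
#' @examples
#' mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6))$p  # exact 1/20
mann_whitney_one_sided <- function(auc_a, auc_b,
                                   alternative = c("b_greater", "a_greater"),
                                   exact_max_n = 12) {
  alternative <- match.arg(alternative)
  if (length(auc_a) == 0 || length(auc_b) == 0)
    stopf("both samples must be non-empty")
  if (alternative == "a_greater")
    return(structure(
      modifyList(unclass(mann_whitney_one_sided(auc_b, auc_a, "b_greater",
                                                exact_max_n)),
                 list(direction = "a_greater", n_a = length(auc_a),
                      n_b = length(auc_b))),
      class = "rank_test"))

  na <- length(auc_a); nb <- length(auc_b); n <- na + nb
  r <- rank(c(auc_a, auc_b))
  rb <- r[(na + 1):n]
  U <- sum(rb) - nb * (nb + 1) / 2
  if (n <= exact_max_n) {
    # permutation null: every assignment of nb pooled ranks to sample b
    sets <- combn(n, nb)
    Us <- colSums(matrix(r[sets], nrow = nb)) - nb * (nb + 1) / 2
    p <- mean(Us >= U - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    tie <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence in any direction
    } else {
      p <- pnorm((U - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    }
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "normal approximation, tie-corrected"
  }
  structure(list(U = U, p = p, direction = "b_greater",
                 n_a = na, n_b = nb, method = method),
            class = "rank_test")
}

#' @export
#' @method print rank_test
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> U = %.1f, one-sided p = %.4g (%s; n = %d, %d; %s)\n",
              x$U, x$p, x$direction, x$n_a, x$n_b, x$method))
  invisible(x)
}

#' Likelihood-ratio test of nested models
#'
#' @param full_loglik,reduced_loglik Maximised log-likelihoods (ML, not
#'   REML) of the nested pair fitted to the same data.
#' @param df Difference in number of parameters.
#' @param tol Numerical tolerance below which a reduced model may exceed the
#'   full model before an optimisation failure is declared.
#' @return List with `chi2` (clipped at 0) and `p`.
#' @export
likelihood_ratio_test <- function(full_loglik, reduced_loglik, df = 1,
                                  tol = 1e-6) {
  full_loglik <- as.numeric(full_loglik)
  reduced_loglik <- as.numeric(reduced_loglik)
  delta <- 2 * (full_loglik - reduced_loglik)
  if (delta < -tol * max(1, abs(full_loglik)))
    stopf("full model log-likelihood below reduced model: optimisation failure")
  chi2 <- max(delta, 0)
  list(chi2 = chi2, p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Random-intercept linear mixed model for condition effects
#'
#' Fits `prediction ~ condition + (1 | cell_line) + (1 | experiment)` by
#' maximum likelihood (ML rather than REML, so the likelihood-ratio test
#' against the random-effects-only reduced model is valid) and reports the
#' condition fixed effect on the probability scale of the classifier
#' predictions.
#'
#' @param table data.frame with columns `prediction`, `condition` and the
#'   random-effect grouping columns.
#' @param fixed Name of the fixed-effect column (2 or more levels; with two
#'   levels the effect of the second is reported).
#' @param response Name of the response column.
#' @param random Character vector of random-intercept grouping columns;
#'   groupings with a single level are dropped with a warning, and if none
#'   remain the model falls back to ordinary least squares with a warning.
#' @return Object of class `effect_estimate`: `beta_hat`, `se`, `chi2`, `p`,
#'   `varcomp` (named variances incl. residual), `n`, `random_terms`.
#' @export
fit_random_intercept_lmm <- function(table, fixed = "condition",
                                     response = "prediction",
                                     random = c("cell_line", "experiment")) {
  for (col in c(fixed, response, random))
    if (!col %in% names(table)) stopf("column '%s' missing from table", col)
  fx <- table[[fixed]]
  if (length(unique(fx)) < 2)
    stopf("fixed effect '%s' needs at least 2 levels", fixed)
  if (!is.numeric(fx)) table[[fixed]] <- factor(fx)

  keep <- random[vapply(random, function(g)
    length(unique(table[[g]])) > 1, logical(1))]
  dropped <- setdiff(random, keep)
  if (length(dropped) > 0)
    warnf("random grouping%s with a single level dropped: %s",
          if (length(dropped) > 1) "s" else "", paste(dropped, collapse = ", "))

  if (length(keep) == 0) {
    warnf("no random grouping with >1 level; falling back to a fixed-intercept linear model")
    full <- stats::lm(as.formula(paste(response, "~", fixed)), data = table)
    reduced <- stats::lm(as.formula(paste(response, "~ 1")), data = table)
    beta <- coef(full)[2]
    se <- sqrt(diag(vcov(full)))[2]
    vc <- c(residual = summary(full)$sigma^2)
  } else {
    rnd <- paste(sprintf("(1 | %s)", keep), collapse = " + ")
    f_full <- as.formula(paste(response, "~", fixed, "+", rnd))
    f_red <- as.formula(paste(response, "~ 1 +", rnd))
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    full <- suppressMessages(
      lme4::lmer(f_full, data = table, REML = FALSE, control = ctrl))
    reduced <- suppressMessages(
      lme4::lmer(f_red, data = table, REML = FALSE, control = ctrl))
    beta <- lme4::fixef(full)[2]
    se <- sqrt(diag(as.matrix(vcov(full))))[2]
    vcs <- lme4::VarCorr(full)
    vc <- setNames(vapply(keep, function(g) vcs[[g]][1, 1], numeric(1)), keep)
    vc <- c(vc, residual = attr(vcs, "sc")^2)
  }
  lrt <- likelihood_ratio_test(logLik(full), logLik(reduced), df = 1)
  structure(list(beta_hat = unname(beta), se = unname(se),
                 chi2 = lrt$chi2, p = lrt$p, varcomp = vc,
                 n = nrow(table), random_terms = if (length(keep)) keep else character(0),
                 full_fit = full, reduced_fit = reduced),
            class = "effect_estimate")
}

#' @export
#' @method print effect_estimate
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> beta = %.4f +/- %.4f, chi2(1) = %.2f, p = %.3g (n = %d)\n",
              x$beta_hat, x$se, x$chi2, x$p, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("'x' and 'y' must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance in input")
  stats::cor(x, y, method = "pearson")
}

#' Ward clustering of effect-size profiles
#'
#' Hierarchical clustering of condition effect-size profiles (rows =
#' conditions, columns = classifiers) by Ward's minimum-variance criterion
#' on Euclidean distances. Used to ask which stress condition's phenotype
#' profile sits closest to the disease profile.
#'
#' @param profiles Numeric matrix (>= 2 rows, no missing values) with row
#'   names identifying the conditions.
#' @return Object of class `effect_clustering`: `merge`, `height`, `order`,
#'   `labels` and the underlying `hclust` object.
#' @export
ward_cluster <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stopf("need at least 2 profiles to cluster")
  if (anyNA(profiles)) stopf("missing values in effect profiles")
  hc <- hclust(dist(profiles, method = "euclidean"), method = "ward.D2")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels %||% as.character(seq_len(nrow(profiles))),
                 hclust = hc),
            class = "effect_clustering")
}

#' @export
#' @method print effect_clustering
print.effect_clustering <- function(x, ...) {
  cat(sprintf("<effect_clustering> %d leaves, leaf order: %s\n",
              length(x$labels), paste(x$labels[x$order], collapse = ", ")))
  invisible(x)
}

# Leaves adjacent in the dendrogram leaf order?
leaves_adjacent <- function(clustering, a, b) {
  ord <- clustering$labels[clustering$order]
  abs(which(ord == a) - which(ord == b)) == 1
}
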