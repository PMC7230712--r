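# Statistical layer for day-type comparisons: chi-square goodness of fit
# with proportional expected weights, Welch's t from summary statistics,
# Benjamini-Hochberg step-up adjustment, and mixed-effects day-type models
# with pairwise contrasts.

# light-weight common container for test results
new_test_result <- function(statistic, df, p_raw, method,
                            effect_label = NA_character_,
                            family_id = NA_character_, extra = list()) {
  out <- c(list(statistic = statistic, df = df, p_raw = p_raw,
                p_adj = NA_real_, method = method,
                effect_label = effect_label, family_id = family_id),
           extra)
  class(out) <- "chrononutr_test"
  out
}

#' @export
print.chrononutr_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g%s\n",
              x$method, x$statistic, dfs, x$p_raw,
              if (!is.na(x$p_adj)) sprintf(" (adj %.4g)", x$p_adj) else ""))
  invisible(x)
}

#' Chi-square goodness of fit with proportional expected weights
#'
#' Tests whether observed counts are proportional to a vector of expected
#' weights (e.g. whether meal counts per day type are proportionate to the
#' number of contributing participants). Expected counts are
#' `sum(observed) * w_i / sum(w)`.
#'
#' @param observed integer counts, length >= 2.
#' @param expected_weights nonnegative weights, same length.
#' @return a `chrononutr_test` with `statistic`, `df = k - 1`, `p_raw`,
#'   and `expected` counts.
#' @examples
#' chi_square_gof(c(210, 133, 85, 141), c(28, 21, 17, 24))
#' @export
chi_square_gof <- function(observed, expected_weights) {
  if (length(observed) != length(expected_weights) || length(observed) < 2)
    stop("observed and expected_weights must have equal length >= 2")
  if (any(observed < 0) || any(expected_weights < 0))
    stop("counts and weights must be nonnegative")
  if (sum(observed) <= 0 || sum(expected_weights) <= 0)
    stop("totals must be positive")
  expected <- sum(observed) * expected_weights / sum(expected_weights)
  if (any(expected == 0)) stop("expected count of zero; drop empty cells")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  new_test_result(statistic = stat, df = df,
                  p_raw = stats::pchisq(stat, df, lower.tail = FALSE),
                  method = "Chi-square goodness of fit",
                  extra = list(expected = expected))
}

#' Welch's t-test from summary statistics
#'
#' Two-sided Welch (unequal variances) t-test computed from group means,
#' SDs and sizes, with Welch-Satterthwaite degrees of freedom. Used for
#' sex comparisons of demographic/anthropometric summaries.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return a `chrononutr_test` with `statistic` (t), fractional `df`, `p_raw`.
#' @examples
#' welch_t(1782, 121, 25, 1388, 109, 6) # t ~ 7.77
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  new_test_result(statistic = t, df = df,
                  p_raw = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
                  method = "Welch's t-test")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: order p-values increasingly, multiply by m/rank,
#' enforce monotonicity from the largest down, cap at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Mixed-effects day-type model with pairwise contrasts
#'
#' Fits `outcome ~ day_type + sex + age + (1 | subject)` by REML (lme4),
#' reports a Wald F for the day-type omnibus effect and all pairwise
#' day-type contrasts with BH-adjusted p-values. Denominator df use a
#' between-within (containment) approximation
#' `df2 = n_obs - n_subjects - q` where `q` is the number of day-type
#' parameters. Singular fits fall back to a fixed-effects linear model with
#' a warning.
#'
#' @param data data.frame with columns `subject_id`, `day_type` and the
#'   outcome; optional `sex`, `age_years` covariates (dropped from the
#'   formula if absent or constant).
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate columns to control for;
#'   default `c("sex", "age_years")`.
#' @return list with `omnibus` (a `chrononutr_test`), `contrasts`
#'   (data.frame: contrast, estimate, se, df, t, p_raw, p_adj), `fit`,
#'   `emmeans` (adjusted day-type means).
#' @export
fit_day_type_model <- function(data, outcome,
                               covariates = c("sex", "age_years")) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  data <- data[!is.na(data[[outcome]]) & !is.na(data$day_type), , drop = FALSE]
  data$day_type <- droplevels(factor(data$day_type))
  lv <- levels(data$day_type)
  if (length(lv) < 2) stop("need at least two day types")
  if (length(unique(data$subject_id)) < 2)
    stop("need at least two subjects with repeated measures")
  covariates <- covariates[covariates %in% names(data)]
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  rhs <- paste(c("day_type", covariates, "(1 | subject_id)"), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lme4::lmer(form, data = data, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("singular mixed-model fit; falling back to fixed-effects model")
    form2 <- stats::as.formula(paste(
      outcome, "~", paste(c("day_type", covariates), collapse = " + ")))
    fit <- stats::lm(form2, data = data)
  }
  beta <- if (singular) stats::coef(fit) else lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  q <- length(lv) - 1
  n_obs <- nrow(data)
  n_subj <- length(unique(data$subject_id))
  df2 <- if (singular) stats::df.residual(fit) else max(n_obs - n_subj - q, 2)

  idx <- grep("^day_type", names(beta))
  L <- matrix(0, q, length(beta))
  L[cbind(seq_len(q), idx)] <- 1
  Lb <- L %*% beta
  Fstat <- drop(t(Lb) %*% solve(L %*% V %*% t(L)) %*% Lb) / q
  omnibus <- new_test_result(
    statistic = Fstat, df = c(q, df2),
    p_raw = stats::pf(Fstat, q, df2, lower.tail = FALSE),
    method = "Mixed-model Wald F (day type)", effect_label = outcome)

  # estimated marginal means: reference level has coefficient 0
  lvl_coef <- c(0, beta[idx])
  names(lvl_coef) <- lv
  pairs <- utils::combn(lv, 2)
  cmat <- matrix(0, ncol(pairs), length(beta))
  for (j in seq_len(ncol(pairs))) {
    a <- match(pairs[1, j], lv); b <- match(pairs[2, j], lv)
    if (a > 1) cmat[j, idx[a - 1]] <- 1
    if (b > 1) cmat[j, idx[b - 1]] <- -1
  }
  est <- drop(cmat %*% beta)
  se <- sqrt(diag(cmat %*% V %*% t(cmat)))
  tstat <- est / se
  p_raw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  contrasts <- data.frame(
    contrast = paste(pairs[1, ], pairs[2, ], sep = " - "),
    estimate = est, se = se, df = df2, t = tstat,
    p_raw = p_raw, p_adj = bh_adjust(p_raw))
  list(omnibus = omnibus, contrasts = contrasts, fit = fit,
       emmeans = lvl_coef, singular = singular)
}
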