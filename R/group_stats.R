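# Factorial and pairwise comparisons across mycorrhizal type x sampling
# position, and the Spearman screen of CUE predictors.
#
# Designs with 8 AM vs 7 ECM species are unbalanced, so factorial sums of
# squares are type II throughout (each main effect adjusted for the other,
# the interaction last).

#' Two-way (or one-way) ANOVA with type-II sums of squares
#'
#' @param values numeric response vector.
#' @param factor_a first factor (e.g. mycorrhizal type AM/ECM).
#' @param factor_b optional second factor (e.g. rhizosphere position); when
#'   omitted a one-way ANOVA is returned.
#' @return data.frame with one row per term: `term`, `df`, `statistic` (F)
#'   and `p_value`.
#' @examples
#' two_way_anova(rnorm(40), gl(2, 20), rep(gl(2, 10), 2))
#' @export
two_way_anova <- function(values, factor_a, factor_b = NULL) {
  factor_a <- factor(factor_a)
  if (is.null(factor_b)) {
    fit <- stats::aov(values ~ factor_a)
    tab <- summary(fit)[[1]]
    return(data.frame(term = "factor_a", df = tab[1, "Df"],
                      statistic = tab[1, "F value"],
                      p_value = tab[1, "Pr(>F)"],
                      stringsAsFactors = FALSE))
  }
  factor_b <- factor(factor_b)
  if (nlevels(factor_a) < 2 || nlevels(factor_b) < 2 ||
      any(table(factor_a, factor_b) == 0))
    stop("empty or single-level design cell")
  fit <- stats::lm(values ~ factor_a * factor_b)
  tab <- car::Anova(fit, type = 2)
  terms <- c("factor_a", "factor_b", "factor_a:factor_b")
  data.frame(term = terms, df = tab[terms, "Df"],
             statistic = tab[terms, "F value"],
             p_value = tab[terms, "Pr(>F)"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scheirer–Ray–Hare nonparametric factorial test
#'
#' The rank analogue of two-way ANOVA: responses are replaced by mid-ranks,
#' a factorial ANOVA (type-II SS) is run on the ranks, and each effect's
#' `H = SS_effect / MS_total` is referred to a chi-square distribution with
#' the effect's df. Using the observed rank variance as `MS_total` applies
#' the tie correction automatically; with a single factor the statistic
#' reduces exactly to tie-corrected Kruskal–Wallis.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b as in [two_way_anova()]; `factor_b` optional.
#' @return data.frame with `term`, `df`, `statistic` (H) and `p_value`.
#' @examples
#' scheirer_ray_hare(rexp(40), gl(2, 20), rep(gl(2, 10), 2))
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b = NULL) {
  rk <- rank(values)
  n <- length(rk)
  ms_total <- stats::var(rk)
  if (ms_total == 0) {       # all observations tied
    terms <- if (is.null(factor_b)) "factor_a" else
      c("factor_a", "factor_b", "factor_a:factor_b")
    return(data.frame(term = terms, df = NA_integer_, statistic = 0,
                      p_value = 1, stringsAsFactors = FALSE))
  }
  factor_a <- factor(factor_a)
  if (is.null(factor_b)) {
    ss_a <- sum(tapply(rk, factor_a, function(g) length(g) * (mean(g) - mean(rk))^2))
    df_a <- nlevels(factor_a) - 1
    h <- ss_a / ms_total
    return(data.frame(term = "factor_a", df = df_a, statistic = h,
                      p_value = stats::pchisq(h, df_a, lower.tail = FALSE),
                      stringsAsFactors = FALSE))
  }
  factor_b <- factor(factor_b)
  if (nlevels(factor_a) < 2 || nlevels(factor_b) < 2 ||
      any(table(factor_a, factor_b) == 0))
    stop("empty or single-level design cell")
  fit <- stats::lm(rk ~ factor_a * factor_b)
  tab <- car::Anova(fit, type = 2)
  terms <- c("factor_a", "factor_b", "factor_a:factor_b")
  h <- tab[terms, "Sum Sq"] / ms_total
  df <- tab[terms, "Df"]
  data.frame(term = terms, df = df, statistic = h,
             p_value = stats::pchisq(h, df, lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wilcoxon two-group comparison
#'
#' Rank-sum (unpaired) or signed-rank (paired) test with mid-rank tie
#' handling; exact null distribution for small samples (n <= 25 per group,
#' no ties), otherwise the normal approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors (equal length when `paired`).
#' @param paired logical; pair observations by index.
#' @return List with `statistic` (W/U/V), `p_value`, `method`.
#' @examples
#' wilcoxon_pair(1:5, 6:10)$p_value  # fully separated, 5 vs 5
#' @export
wilcoxon_pair <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("need at least 3 observations per group")
  if (paired && length(group_a) != length(group_b))
    stop("paired groups must have equal length")
  use_exact <- length(group_a) <= 25 && length(group_b) <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, paired = paired,
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Spearman correlation screen
#'
#' Rank correlations (mid-ranks) of every predictor column against every
#' response column, with two-sided p-values from the t approximation.
#' Constant columns yield `NA` and a flag. No multiple-testing correction is
#' applied by default (raw significance is what co-occurrence studies
#' conventionally report); set `adjust = "BH"` for Benjamini–Hochberg across
#' the whole screen.
#'
#' @param predictors,responses data.frames of aligned numeric columns
#'   (same rows = samples).
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return List with matrices `rho` and `p` (predictors x responses) and a
#'   character vector `flags` naming constant columns.
#' @export
spearman_screen <- function(predictors, responses, adjust = "none") {
  if (nrow(predictors) != nrow(responses))
    stop("predictors and responses must have the same number of rows")
  if (nrow(predictors) < 4) stop("need at least 4 paired observations")
  np <- ncol(predictors); nr <- ncol(responses)
  rho <- p <- matrix(NA_real_, np, nr,
                     dimnames = list(names(predictors), names(responses)))
  flags <- character(0)
  for (i in seq_len(np)) {
    x <- predictors[[i]]
    if (length(unique(x[!is.na(x)])) < 2) {
      flags <- c(flags, names(predictors)[i]); next
    }
    for (j in seq_len(nr)) {
      y <- responses[[j]]
      if (length(unique(y[!is.na(y)])) < 2) {
        flags <- unique(c(flags, names(responses)[j])); next
      }
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  if (adjust != "none") {
    ok <- !is.na(p)
    p[ok] <- stats::p.adjust(p[ok], method = adjust)
  }
  list(rho = rho, p = p, flags = flags)
}

#' Route a response to a parametric or nonparametric factorial test
#'
#' Shapiro–Wilk on the residuals of the factorial fit; if normality is
#' rejected at `alpha`, a log transform is attempted (positive responses
#' only), and if residuals still fail the data are routed to
#' Scheirer–Ray–Hare.
#'
#' @param values response vector.
#' @param factor_a,factor_b design factors.
#' @param alpha rejection level for Shapiro–Wilk (default 0.05).
#' @return List with `route` (`"parametric"`/`"nonparametric"`),
#'   `transform` (`"identity"`/`"log"`), and the Shapiro p-values tried.
#' @export
normality_gate <- function(values, factor_a, factor_b = NULL, alpha = 0.05) {
  resid_of <- function(v) {
    if (is.null(factor_b)) stats::resid(stats::lm(v ~ factor(factor_a)))
    else stats::resid(stats::lm(v ~ factor(factor_a) * factor(factor_b)))
  }
  p_raw <- stats::shapiro.test(resid_of(values))$p.value
  if (p_raw >= alpha)
    return(list(route = "parametric", transform = "identity",
                shapiro_p = c(identity = p_raw)))
  if (all(values > 0)) {
    p_log <- stats::shapiro.test(resid_of(log(values)))$p.value
    if (p_log >= alpha)
      return(list(route = "parametric", transform = "log",
                  shapiro_p = c(identity = p_raw, log = p_log)))
    return(list(route = "nonparametric", transform = "identity",
                shapiro_p = c(identity = p_raw, log = p_log)))
  }
  list(route = "nonparametric", transform = "identity",
       shapiro_p = c(identity = p_raw))
}

#' Gated factorial comparison of one response
#'
#' Applies [normality_gate()] and runs the routed test, returning a tidy
#' table that records the route taken.
#'
#' @inheritParams normality_gate
#' @param response_name label used in the output.
#' @return data.frame: `response`, `term`, `df`, `statistic`, `p_value`,
#'   `method`, `transform`.
#' @export
factorial_compare <- function(values, factor_a, factor_b = NULL,
                              response_name = "response", alpha = 0.05) {
  ok <- !is.na(values)
  values <- values[ok]
  factor_a <- factor_a[ok]
  if (!is.null(factor_b)) factor_b <- factor_b[ok]
  gate <- normality_gate(values, factor_a, factor_b, alpha)
  if (gate$route == "parametric") {
    v <- if (gate$transform == "log") log(values) else values
    res <- two_way_anova(v, factor_a, factor_b)
    method <- "two_way_anova"
  } else {
    res <- scheirer_ray_hare(values, factor_a, factor_b)
    method <- "scheirer_ray_hare"
  }
  data.frame(response = response_name, res, method = method,
             transform = gate$transform, stringsAsFactors = FALSE)
}
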