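# Shared statistical primitives: Fisher's exact test with sample odds ratio,
# Mann-Whitney U with exact small-sample enumeration, multiple-testing
# adjustment, Storey q-values, and a thin linear/logistic fit contract.

#' Fisher's exact test with a sample odds ratio
#'
#' Exact hypergeometric test on a 2x2 contingency table. The p-value comes
#' from \code{\link[stats]{fisher.test}} (two-sided p is the sum of table
#' probabilities no larger than the observed one). Unlike \code{fisher.test},
#' the reported odds ratio is the sample cross-product ratio
#' \code{(a*d)/(b*c)}, with a Haldane-Anscombe correction of 0.5 added to
#' every cell when any cell is zero, so that enrichment statistics stay
#' finite and comparable across strata.
#'
#' @param table a 2x2 matrix of non-negative integer counts. Rows index the
#'   condition (e.g. longer/shorter), columns the outcome (e.g. eVariant or
#'   not).
#' @param sidedness "two" (default) or "one". One-sided tests the
#'   greater-association direction for cell \code{[1,1]}.
#' @return a list of class \code{stat_result} with elements \code{statistic}
#'   (the odds ratio), \code{odds_ratio}, \code{p}, \code{table},
#'   \code{sidedness}, \code{method}. If any table margin is zero the test is
#'   uninformative: \code{p = 1} and the odds ratio is \code{NA}.
#' @examples
#' fisher_exact(matrix(c(10, 5, 90, 895), nrow = 2))
#' @export
fisher_exact <- function(table, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("`table` must be a 2x2 matrix of counts")
  }
  if (any(table < 0) || any(table != round(table)) || any(!is.finite(table))) {
    stop("`table` must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    res <- list(statistic = NA_real_, odds_ratio = NA_real_, p = 1,
                table = table, sidedness = sidedness,
                method = "fisher_exact", note = "zero margin")
    class(res) <- "stat_result"
    return(res)
  }
  ft <- stats::fisher.test(table,
                           alternative = if (sidedness == "two") "two.sided" else "greater")
  or <- sample_odds_ratio(table)
  res <- list(statistic = or, odds_ratio = or, p = ft$p.value,
              table = table, sidedness = sidedness, method = "fisher_exact")
  class(res) <- "stat_result"
  res
}

# Cross-product OR; Haldane-Anscombe 0.5 on all cells when any cell is 0.
sample_odds_ratio <- function(table) {
  t2 <- table
  if (any(t2 == 0)) t2 <- t2 + 0.5
  (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location shift between two samples. The U statistic
#' counts, over all cross-pairs, the times an \code{x} value exceeds a
#' \code{y} value (ties count one half). For combined sample sizes up to
#' \code{exact_max} the p-value is computed by exhaustive enumeration of all
#' group assignments, which stays exact under ties; larger samples use the
#' normal approximation with the usual tie correction of the variance.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param sidedness "two" (default) or "one"; one-sided tests the
#'   alternative that \code{x} is stochastically smaller than \code{y}
#'   (small U).
#' @param exact_max largest \code{length(x) + length(y)} for which the exact
#'   enumeration is used (default 12).
#' @return a \code{stat_result} list with \code{statistic} (U for the first
#'   sample), \code{p}, \code{sidedness}, \code{exact} flag.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), sidedness = "one")
#' @export
mann_whitney_u <- function(x, y, sidedness = c("two", "one"), exact_max = 12L) {
  sidedness <- match.arg(sidedness)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  nx <- length(x); ny <- length(y)
  u <- u_statistic(x, y)
  all_tied <- length(unique(c(x, y))) == 1L
  if (all_tied) {
    res <- list(statistic = u, p = 1, sidedness = sidedness, exact = TRUE,
                method = "mann_whitney_u")
    class(res) <- "stat_result"
    return(res)
  }
  if (nx + ny <= exact_max) {
    p <- mwu_exact_p(x, y, u, sidedness)
    exact <- TRUE
  } else {
    p <- mwu_normal_p(c(x, y), nx, ny, u, sidedness)
    exact <- FALSE
  }
  res <- list(statistic = u, p = min(max(p, .Machine$double.xmin), 1),
              sidedness = sidedness, exact = exact, method = "mann_whitney_u")
  class(res) <- "stat_result"
  res
}

u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exhaustive null distribution of U over all C(nx+ny, nx) assignments of the
# pooled values to the first group; exact under ties.
mwu_exact_p <- function(x, y, u_obs, sidedness) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  idx <- utils::combn(n, nx)
  # U for each assignment from the pooled ranks (rank-sum identity)
  us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
  eps <- 1e-9
  if (sidedness == "one") {
    mean(us <= u_obs + eps)
  } else {
    mu <- nx * (n - nx) / 2
    # two-sided: arrangements at least as extreme in |U - E[U]|
    mean(abs(us - mu) >= abs(u_obs - mu) - eps)
  }
}

mwu_normal_p <- function(pooled, nx, ny, u_obs, sidedness) {
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu) / sqrt(sigma2)
  if (sidedness == "one") stats::pnorm(z) else 2 * stats::pnorm(-abs(z))
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with monotone enforcement, capped at 1) or
#' Bonferroni adjustment, delegating to \code{\link[stats]{p.adjust}}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method "bh" or "bonferroni".
#' @return adjusted p-values, same length and order as \code{p}.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Storey q-values
#'
#' False-discovery-rate q-values with an estimated null proportion
#' \eqn{\pi_0}. The smoother method evaluates
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))} over a
#' grid of \eqn{\lambda} values and extrapolates a cubic polynomial fit to the
#' largest \eqn{\lambda}; the fixed method uses a single \eqn{\lambda}. The
#' estimate is clipped to (0, 1]. On short lists (fewer than 100 p-values)
#' the smoother is unstable, so \eqn{\pi_0 = 1} is used there, making the
#' q-values coincide with Benjamini-Hochberg. Q-values are
#' \eqn{q_i = \min_{p_j \ge p_i} \hat\pi_0 m p_j / \mathrm{rank}(p_j)}, so
#' with \eqn{\hat\pi_0 = 1} they coincide with Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method "smoother" (default) or "fixed".
#' @param lambda grid of tuning values in (0, 1) (smoother) or a single value
#'   (fixed).
#' @return list with \code{q} (same order as \code{p}), \code{pi0},
#'   \code{lambda}, \code{method}.
#' @examples
#' storey_qvalues(runif(1000))$pi0
#' @export
storey_qvalues <- function(p, method = c("smoother", "fixed"),
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (anyNA(p) || any(p <= 0) || any(p > 1)) stop("p-values must be in (0, 1]")
  m <- length(p)
  if (m == 0) stop("empty p-value vector")
  if (method == "smoother" && m < 100) {
    # the cubic smoother is unstable on short lists; pi0 = 1 makes the
    # q-values coincide with Benjamini-Hochberg, which is conservative
    if (m < 10) warning("fewer than 10 p-values; falling back to pi0 = 1")
    pi0 <- 1
  } else if (method == "fixed") {
    lam <- lambda[1]
    pi0 <- sum(p > lam) / (m * (1 - lam))
  } else {
    pi0_lam <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
    fit <- stats::lm(pi0_lam ~ poly(lambda, 3))
    pi0 <- stats::predict(fit, newdata = data.frame(lambda = max(lambda)))[[1]]
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p)
  ranked <- p[o] * m * pi0 / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(ranked, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, pi0 = pi0, lambda = lambda, method = method)
}

#' Linear or logistic model fit with per-term tests
#'
#' Thin wrapper around \code{\link[stats]{lm}} / \code{\link[stats]{glm}}
#' exposing the coefficient table the enrichment analyses need: estimate,
#' standard error, and a t-test (linear) or Wald z-test (logistic) p-value per
#' term. Refuses rank-deficient designs and flags perfect separation in the
#' logistic case rather than reporting unstable p-values.
#'
#' @param response numeric response; for "logistic" either 0/1 or a fraction
#'   in [0, 1] (fractions are fit by quasi-binomial likelihood with t tests).
#' @param design numeric matrix or data.frame of predictors; an intercept is
#'   added automatically.
#' @param family "linear" or "logistic".
#' @return list with \code{coefficients} (data.frame: term, estimate, se,
#'   statistic, p), \code{family}, \code{converged}, \code{separation} flag.
#' @export
glm_fit <- function(response, design, family = c("linear", "logistic")) {
  family <- match.arg(family)
  design <- as.data.frame(design)
  if (nrow(design) != length(response)) stop("response/design length mismatch")
  X <- stats::model.matrix(~ ., data = design)
  if (qr(X)$rank < ncol(X)) {
    stop("design is rank deficient (collinear columns): ",
         paste(colnames(design), collapse = ", "))
  }
  dat <- cbind(.y = response, design)
  separation <- FALSE
  if (family == "linear") {
    fit <- stats::lm(.y ~ ., data = dat)
    tab <- summary(fit)$coefficients
  } else {
    fractional <- any(response > 0 & response < 1)
    fam <- if (fractional) stats::quasibinomial() else stats::binomial()
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = fam))
    mu <- stats::fitted(fit)
    if (!fractional && (any(mu > 1 - 1e-8) || any(mu < 1e-8))) {
      separation <- TRUE
    }
    tab <- summary(fit)$coefficients
  }
  coefs <- data.frame(term = rownames(tab), estimate = tab[, 1], se = tab[, 2],
                      statistic = tab[, 3],
                      p = if (separation) NA_real_ else tab[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = coefs, family = family,
       converged = if (inherits(fit, "glm")) fit$converged else TRUE,
       separation = separation, fit = fit)
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, " (", x$sidedness, "-sided)\n", sep = "")
  if (!is.null(x$odds_ratio)) cat("  odds ratio:", format(x$odds_ratio, digits = 4), "\n")
  if (!is.null(x$statistic) && is.null(x$odds_ratio)) {
    cat("  statistic:", format(x$statistic, digits = 4), "\n")
  }
  cat("  p:", format.pval(x$p, digits = 4), "\n")
  invisible(x)
}
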