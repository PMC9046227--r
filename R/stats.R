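#' Significance stars
#'
#' The figure-legend convention: `***` p < 0.001, `**` p < 0.01, `*`
#' p < 0.05, empty otherwise.
#'
#' @param p vector of p values.
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons.
#'
#' @param p raw p values.
#' @param m family size (default: `length(p)`).
#' @return adjusted p values (always >= raw).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

# t test that degrades gracefully on constant data (t = 0, p = 1 when the
# difference is exactly zero; |t| = Inf, p = 0 when constant but nonzero)
safe_t_test <- function(x, y, paired = FALSE) {
  res <- tryCatch(stats::t.test(x, y, paired = paired), error = function(e) NULL)
  if (!is.null(res) && is.finite(res$statistic)) return(res)
  d <- if (paired) mean(x - y) else mean(x) - mean(y)
  df <- if (paired) length(x) - 1 else length(x) + length(y) - 2
  list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
       parameter = c(df = df), p.value = if (d == 0) 1 else 0)
}

# Gauss-Legendre nodes/weights on (a, b) via the Golub-Welsch eigenvalue
# construction of the Jacobi matrix
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  o <- order(x)
  list(nodes = (b - a) / 2 * x[o] + (a + b) / 2, weights = (b - a) / 2 * w[o])
}

# P(max_j |T_j| <= q) for k equicorrelated (rho) multivariate-t components on
# df degrees of freedom: Dunnett's classical two-dimensional quadrature over
# the shared normal factor z and the scale s = sqrt(chi2_df / df), on fixed
# Gauss-Legendre grids. Deterministic; exact route for balanced designs.
dunnett_equicorr_prob <- function(q, k, df, rho) {
  sr <- sqrt(rho); cr <- sqrt(1 - rho)
  gz <- gauss_legendre(64, -8.5, 8.5)
  s_hi <- sqrt(stats::qchisq(1e-12, df, lower.tail = FALSE) / df)
  gs <- gauss_legendre(64, 1e-8, s_hi)
  dens_s <- exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
                  (df - 1) * log(gs$nodes) - df * gs$nodes^2 / 2)
  zz <- gz$nodes; wz <- gz$weights * stats::dnorm(zz)
  inner <- vapply(gs$nodes, function(si) {
    sum(wz * (stats::pnorm((q * si - sr * zz) / cr) -
                stats::pnorm((-q * si - sr * zz) / cr))^k)
  }, numeric(1))
  sum(gs$weights * dens_s * inner)
}

is_equicorrelated <- function(R, tol = 1e-8) {
  off <- R[upper.tri(R)]
  length(off) == 0L || max(off) - min(off) < tol
}

# family-wise Dunnett p for two-sided statistics t (vector) with contrast
# correlation matrix R and residual df: P(max_j |T_j| >= |t|). Balanced
# (equicorrelated) designs use the analytic quadrature; general designs fall
# back to seeded quasi-Monte-Carlo multivariate-t integration.
dunnett_p <- function(t, R, df) {
  k <- nrow(R)
  vapply(abs(t), function(q) {
    if (k == 1) return(2 * stats::pt(-q, df))
    if (q == 0) return(1)
    if (!is.finite(q)) return(0)
    if (is_equicorrelated(R)) {
      return(min(1, max(0, 1 - dunnett_equicorr_prob(q, k, df, mean(R[upper.tri(R)])))))
    }
    inner <- withr_preserve_seed(function() {
      set.seed(20260901L)
      mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k), df = as.integer(df),
                    corr = R,
                    algorithm = mvtnorm::GenzBretz(maxpts = 1e5, abseps = 1e-5))
    })
    max(0, 1 - as.numeric(inner))
  }, numeric(1))
}

# run fn() under a fixed RNG state without disturbing the caller's stream
withr_preserve_seed <- function(fn) {
  seed_exists <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (seed_exists) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  fn()
}

#' Dunnett critical value (two-sided) for a balanced many-to-one family
#'
#' Smallest q with `P(max_j |T_j| <= q) = 1 - alpha` for `k` contrasts on
#' `df` residual degrees of freedom with the balanced equicorrelation 0.5.
#'
#' @param k number of contrasts (non-reference groups).
#' @param df residual degrees of freedom.
#' @param alpha family-wise error rate.
#' @param rho common contrast correlation.
#' @return critical value q.
#' @export
dunnett_crit <- function(k, df, alpha = 0.05, rho = 0.5) {
  R <- matrix(rho, k, k); diag(R) <- 1
  stats::uniroot(function(q) dunnett_p(q, R, df) - alpha,
                 interval = c(1e-6, 20), tol = 1e-7)$root
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Tests each group against the reference group with family-wise control by
#' Dunnett's multivariate-t procedure. With `subject` given, the analysis is
#' paired: a randomized-block (repeated-measures) ANOVA removes the subject
#' effect before the contrasts; subjects missing any group are dropped with
#' a warning (complete blocks required). The contrast correlation matrix is
#' taken from the fitted model's contrast covariance, which reduces to the
#' classical equicorrelated form for balanced designs and remains exact for
#' unbalanced ones; the multivariate-t rectangle probability is evaluated
#' with a deterministic algorithm (3 or fewer contrasts) or seeded
#' quasi-Monte-Carlo integration.
#'
#' @param values numeric response.
#' @param group grouping factor; `reference_group` must be a level.
#' @param subject optional blocking factor (mouse/donor pairing).
#' @param reference_group reference level (default: first level).
#' @return A `group_comparison` with the overall F test and a per-contrast
#'   table (estimate, t, raw p, Dunnett-adjusted p, stars).
#' @export
anova_dunnett <- function(values, group, subject = NULL,
                          reference_group = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (is.null(reference_group)) reference_group <- levels(group)[1]
  if (!reference_group %in% levels(group)) {
    stop("reference group '", reference_group, "' not present")
  }
  group <- stats::relevel(group, ref = reference_group)
  df0 <- data.frame(y = values, group = group)
  blocked <- !is.null(subject)
  if (blocked) {
    df0$subject <- droplevels(as.factor(subject))
    complete <- rowSums(table(df0$subject, df0$group) > 0) == nlevels(df0$group)
    if (!all(complete)) {
      warning("dropping incomplete subject(s): ",
              paste(names(complete)[!complete], collapse = ", "))
      df0 <- droplevels(df0[df0$subject %in% names(complete)[complete], ])
    }
    if (nlevels(df0$subject) < 2) stop("fewer than 2 complete subjects")
    fit <- stats::lm(y ~ group + subject, data = df0)
  } else {
    fit <- stats::lm(y ~ group, data = df0)
  }
  if (fit$df.residual < 1) stop("zero residual degrees of freedom")
  # suppress the perfect-fit warning: the zero-variance case is flagged below
  a_tab <- suppressWarnings(stats::anova(fit))
  sigma2 <- a_tab["Residuals", "Mean Sq"]

  cn <- paste0("group", setdiff(levels(df0$group), reference_group))
  est <- stats::coef(fit)[cn]
  V <- suppressWarnings(stats::vcov(fit)[cn, cn, drop = FALSE])
  k <- length(cn)
  contrasts <- data.frame(
    contrast = paste(setdiff(levels(df0$group), reference_group), "-",
                     reference_group),
    estimate = unname(est), stringsAsFactors = FALSE)

  degenerate <- !is.finite(sigma2) || sigma2 <= .Machine$double.eps * mean(abs(df0$y) + 1)
  if (degenerate) {
    contrasts$t <- NA_real_
    contrasts$p <- 1
    contrasts$p_adj <- 1
    f_value <- NA_real_; f_p <- NA_real_
    flags <- "degenerate_zero_variance"
  } else {
    se <- sqrt(diag(V))
    contrasts$t <- contrasts$estimate / se
    contrasts$p <- 2 * stats::pt(-abs(contrasts$t), fit$df.residual)
    R <- stats::cov2cor(V)
    contrasts$p_adj <- dunnett_p(contrasts$t, R, fit$df.residual)
    f_value <- a_tab["group", "F value"]
    f_p <- a_tab["group", "Pr(>F)"]
    flags <- ""
  }
  contrasts$p_adj <- pmax(contrasts$p_adj, contrasts$p)
  contrasts$stars <- p_stars(contrasts$p_adj)
  structure(list(design = "one_way", blocked = blocked,
                 adjustment = "dunnett", reference = reference_group,
                 f_value = f_value, f_p = f_p, df_residual = fit$df.residual,
                 contrasts = contrasts, flags = flags),
            class = "group_comparison")
}

#' Two-way ANOVA with Sidak-adjusted cell contrasts
#'
#' Main-effect and interaction F tests for a complete crossed two-factor
#' design (optionally blocked on subject), followed by pairwise comparisons
#' of factor-A levels within each level of factor B, Sidak-adjusted across
#' the whole contrast family.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors (every cell must be non-empty).
#' @param subject optional blocking factor.
#' @return A `group_comparison` with `f_table` (A, B, interaction) and the
#'   Sidak-adjusted contrast table.
#' @export
anova_twoway_sidak <- function(values, factor_a, factor_b, subject = NULL) {
  A <- droplevels(as.factor(factor_a))
  B <- droplevels(as.factor(factor_b))
  if (nlevels(A) < 2 || nlevels(B) < 2) stop("both factors need >= 2 levels")
  if (any(table(A, B) == 0)) stop("design error: empty cell(s) in A x B")
  df0 <- data.frame(y = values, A = A, B = B)
  blocked <- !is.null(subject)
  if (blocked) df0$subject <- droplevels(as.factor(subject))
  fit <- stats::lm(if (blocked) y ~ subject + A * B else y ~ A * B, data = df0)
  if (fit$df.residual < 1) stop("zero residual degrees of freedom")
  a_tab <- stats::anova(fit)
  f_table <- data.frame(term = c("A", "B", "A:B"),
                        f = a_tab[c("A", "B", "A:B"), "F value"],
                        p = a_tab[c("A", "B", "A:B"), "Pr(>F)"],
                        stringsAsFactors = FALSE)

  # cell-mean parametrization for exact contrast SEs under any blocking
  df0$cell <- interaction(df0$A, df0$B, sep = "\r")
  fit_c <- stats::lm(if (blocked) y ~ 0 + cell + subject else y ~ 0 + cell,
                     data = df0)
  cn <- paste0("cell", levels(df0$cell))
  beta <- stats::coef(fit_c)
  Vc <- stats::vcov(fit_c)
  pairs_a <- utils::combn(levels(A), 2, simplify = FALSE)
  rows <- list()
  for (b in levels(B)) {
    for (pr in pairs_a) {
      c1 <- paste0("cell", paste(pr[1], b, sep = "\r"))
      c2 <- paste0("cell", paste(pr[2], b, sep = "\r"))
      L <- stats::setNames(numeric(length(beta)), names(beta))
      L[c1] <- 1; L[c2] <- -1
      est <- sum(L * beta)
      se <- sqrt(drop(t(L) %*% Vc %*% L))
      t_val <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste0(pr[1], " - ", pr[2], " | ", b),
        estimate = est, t = t_val,
        p = 2 * stats::pt(-abs(t_val), fit_c$df.residual),
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  contrasts$p_adj <- sidak_adjust(contrasts$p, nrow(contrasts))
  contrasts$stars <- p_stars(contrasts$p_adj)
  structure(list(design = "two_way", blocked = blocked, adjustment = "sidak",
                 f_table = f_table, df_residual = fit_c$df.residual,
                 contrasts = contrasts, flags = ""),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s ANOVA (%s)%s, %s correction\n",
              x$design, if (x$blocked) "paired/blocked" else "ordinary",
              if (nzchar(x$flags)) paste0(" [", x$flags, "]") else "",
              x$adjustment))
  if (!is.null(x$f_value)) {
    cat(sprintf("  overall F = %.4g, p = %.4g (df resid = %d)\n",
                x$f_value, x$f_p, x$df_residual))
  }
  if (!is.null(x$f_table)) print(x$f_table, row.names = FALSE, digits = 4)
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simple linear regression for cross-technique correlations
#'
#' Ordinary least squares of `y` on `x` with the t test on the slope, as
#' used for correlating readouts across techniques.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @return A `regression_fit`: slope, intercept, R^2, slope p value, n.
#' @export
linregress <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 observations")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  # exact fits trigger a "perfect fit" note from summary.lm; harmless here
  s <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = unname(s$coefficients[2, 4]),
                 stderr = unname(s$coefficients[2, 2]),
                 n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("linear fit: y = %.4g + %.4g x (R^2 = %.4f, p = %.3g, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}
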