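#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z into
#' the omnibus statistic K2 = z_skew^2 + z_kurt^2, referred to a chi-squared
#' distribution with 2 df. Requires n >= 8 (the transformation's validity
#' floor); below that the sample is flagged untested.
#'
#' @param x numeric vector.
#' @param alpha significance level for the normality decision.
#' @return list: `tested` (logical), `n`, `k2`, `p`, `normal` (decision at
#'   `alpha`; `NA` when untested), `z_skew`, `z_kurt`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8)
    return(list(tested = FALSE, n = n, k2 = NA_real_, p = NA_real_,
                normal = NA, z_skew = NA_real_, z_kurt = NA_real_))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # D'Agostino (1970) skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a)^2 + 1))

  # Anscombe-Glynn (1983) kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))

  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(tested = TRUE, n = n, k2 = k2, p = p, normal = p >= alpha,
       z_skew = z1, z_kurt = z2)
}

#' Significance stars at the 0.05 / 0.005 / 0.0005 thresholds
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"` for p < 0.0005, `"**"` for p < 0.005,
#'   `"*"` for p < 0.05, `"ns"` otherwise.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.0005, "***",
         ifelse(p < 0.005, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Group summary (mean +/- SEM, normality flag)
#'
#' @param values numeric vector.
#' @param group factor or character vector, same length.
#' @return data.frame `group`, `n`, `mean`, `sem`, `normal` (NA when n < 8).
#' @export
group_summary <- function(values, group) {
  group <- as.factor(group)
  do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    nc <- normality_check(v)
    data.frame(group = g, n = length(v), mean = mean(v), sem = sem(v),
               normal = nc$normal, stringsAsFactors = FALSE)
  }))
}

#' Compare experimental groups with report-grade conventions
#'
#' Two-group designs: Welch t-test when both groups pass the
#' D'Agostino-Pearson normality check (paired t-test for paired data),
#' otherwise Mann-Whitney (Wilcoxon rank-sum) or the Wilcoxon matched-pairs
#' signed-rank test. Many-group designs: one-way ANOVA plus Dunnett
#' contrasts against a designated control or Tukey all-pairs contrasts when
#' every group passes normality; otherwise Kruskal-Wallis plus
#' Holm-adjusted pairwise Wilcoxon tests. Significance stars at
#' 0.05 / 0.005 / 0.0005.
#'
#' @param values numeric response vector.
#' @param group grouping factor/character, same length.
#' @param design `"auto"` (by group count), `"two"`, or `"many"`.
#' @param paired paired observations (two-group only; requires equal n in
#'   input order).
#' @param posthoc `"dunnett"` or `"tukey"` (many-group parametric path).
#' @param control control group name for Dunnett (default first level).
#' @param alpha significance level used for the normality gate.
#' @return list of class `group_comparison`: `summary` (per-group),
#'   `parametric` (logical), `method`, `p` (omnibus or two-group p),
#'   `stars`, and for many groups `posthoc` (data.frame `comparison`,
#'   `estimate`, `p_adj`, `stars`).
#' @export
compare_groups <- function(values, group, design = c("auto", "two", "many"),
                           paired = FALSE, posthoc = c("dunnett", "tukey"),
                           control = NULL, alpha = 0.05) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  group <- as.factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  if (design == "auto") design <- if (k == 2) "two" else "many"
  if (design == "two" && k != 2) stop("design 'two' needs exactly 2 groups")
  summ <- group_summary(values, group)
  # untested small groups take the rank-based path only if any tested group
  # fails; an untested flag alone does not force non-parametric analysis
  checks <- lapply(levels(group), function(g) normality_check(values[group == g]))
  all_normal <- all(vapply(checks, function(cc) !isFALSE(cc$normal), TRUE))

  if (design == "two") {
    g1 <- values[group == levels(group)[1]]
    g2 <- values[group == levels(group)[2]]
    if (paired && length(g1) != length(g2))
      stop("paired comparison requires equal group sizes")
    if (all_normal) {
      tt <- stats::t.test(g1, g2, paired = paired, var.equal = FALSE)
      method <- if (paired) "paired t-test" else "Welch t-test"
      p <- tt$p.value
      est <- unname(if (paired) tt$estimate else diff(rev(tt$estimate)) * -1)
    } else {
      tt <- suppressWarnings(stats::wilcox.test(g1, g2, paired = paired))
      method <- if (paired) "Wilcoxon matched-pairs signed-rank"
                else "Mann-Whitney"
      p <- tt$p.value
      est <- mean(g1) - mean(g2)
    }
    out <- list(summary = summ, parametric = all_normal, method = method,
                p = p, estimate = est, stars = p_stars(p))
  } else {
    df <- data.frame(y = values, g = group)
    if (!is.null(control)) {
      if (!control %in% levels(group)) stop("unknown control group")
      df$g <- stats::relevel(df$g, ref = control)
    }
    if (all_normal) {
      fit <- stats::aov(y ~ g, data = df)
      p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
      lin <- multcomp::glht(fit, linfct = multcomp::mcp(
        g = if (posthoc == "dunnett") "Dunnett" else "Tukey"))
      ts <- summary(lin)$test
      ph <- data.frame(comparison = names(ts$coefficients),
                       estimate = as.numeric(ts$coefficients),
                       p_adj = as.numeric(ts$pvalues),
                       stringsAsFactors = FALSE)
      method <- paste0("one-way ANOVA + ",
                       if (posthoc == "dunnett") "Dunnett" else "Tukey")
    } else {
      kw <- stats::kruskal.test(y ~ g, data = df)
      p_omni <- kw$p.value
      pw <- stats::pairwise.wilcox.test(df$y, df$g, p.adjust.method = "holm",
                                        exact = FALSE)
      m <- pw$p.value
      idx <- which(!is.na(m), arr.ind = TRUE)
      ph <- data.frame(
        comparison = paste(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]],
                           sep = " - "),
        estimate = NA_real_,
        p_adj = m[idx],
        stringsAsFactors = FALSE)
      method <- "Kruskal-Wallis + pairwise Wilcoxon (Holm)"
    }
    ph$stars <- p_stars(ph$p_adj)
    out <- list(summary = summ, parametric = all_normal, method = method,
                p = p_omni, posthoc = ph, stars = p_stars(p_omni))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$method, "\n")
  print(x$summary, digits = 4, row.names = FALSE)
  cat(sprintf("p = %.4g %s\n", x$p, x$stars))
  if (!is.null(x$posthoc)) print(x$posthoc, digits = 4, row.names = FALSE)
  invisible(x)
}
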