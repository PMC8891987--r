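#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) skewness z-score and the Anscombe-Glynn
#' (1983) kurtosis z-score into the omnibus statistic K^2 = z_s^2 + z_k^2,
#' referred to a chi-squared distribution with 2 df. Requires n >= 8 (the
#' kurtosis transformation is undefined below that).
#'
#' @param x numeric sample, n >= 8, non-constant.
#' @return object of class `htest` with `statistic` (K^2), `p.value`, and
#'   the two component z-scores in `estimate`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  if (stats::var(x) == 0) stop("sample has zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970) transformation to normality
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  base <- (1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4)))
  zk <- ((1 - 2 / (9 * a)) - sign(base) * abs(base)^(1 / 3)) /
    sqrt(2 / (9 * a))                     # signed cube root: base can go
                                          # negative for very flat samples
  k2 <- zs^2 + zk^2
  structure(list(statistic = c(K2 = k2),
                 parameter = c(df = 2),
                 p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 estimate = c(z_skew = zs, z_kurtosis = zk),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z-tests on mean ranks with the tie-corrected pooled variance,
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with
#' tie term T = sum(t^3 - t) / (12 (N - 1)); two-sided p-values adjusted
#' over all pairs (Bonferroni by default, the convention of the common
#' GUI statistics packages; Holm or none available).
#'
#' @param values numeric observations.
#' @param groups factor/vector of group labels, same length.
#' @param p_adjust `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @return data.frame: group1, group2, z, p_value, p_adjusted.
#' @export
dunn_test <- function(values, groups,
                      p_adjust = c("bonferroni", "holm", "none")) {
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  rk <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ni <- tabulate(groups)
  lev <- levels(groups)
  pairs <- utils::combn(seq_along(lev), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[i1] + 1 / ni[i2]))
    z[j] <- (rbar[i1] - rbar[i2]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = lev[pairs[1, ]], group2 = lev[pairs[2, ]],
             z = z, p_value = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust))
}

#' Group comparison following the normality-gated decision tree
#'
#' Reproduces the conventional GUI-statistics workflow: each group is
#' tested for normality (D'Agostino-Pearson for n >= 8; Shapiro-Wilk
#' fallback for 3 <= n < 8, where K^2 is undefined). If the data follow or
#' partially follow a normal distribution — under the default
#' `"any-normal"` rule, at least one group looks normal — an ANOVA is run
#' (one-way with Tukey HSD pairwise follow-up, or two-way on
#' group x factor2); otherwise a Kruskal-Wallis test with Dunn's multiple
#' comparison. The stricter `"all-normal"` rule requires every group to
#' pass before using ANOVA.
#'
#' @param data data.frame with columns `group` and `value`, plus `factor2`
#'   for the two-way design.
#' @param design `"one-way"` or `"two-way"`.
#' @param normality_rule `"any-normal"` (permissive, default) or
#'   `"all-normal"`.
#' @param alpha significance cutoff (default 0.05) used both for the
#'   normality gate and the significance flags.
#' @param p_adjust adjustment for Dunn pairwise p-values.
#' @return list of class `comparison_report`: normality (per-group
#'   data.frame), branch, statistic, omnibus_p, pairwise (data.frame with
#'   significance flags), alpha.
#' @export
compare_groups <- function(data, design = c("one-way", "two-way"),
                           normality_rule = c("any-normal", "all-normal"),
                           alpha = 0.05,
                           p_adjust = c("bonferroni", "holm", "none")) {
  design <- match.arg(design)
  normality_rule <- match.arg(normality_rule)
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(data), all(c("group", "value") %in% names(data)))
  data$group <- factor(data$group)
  if (nlevels(data$group) < 2L) stop("need at least 2 groups")
  ni <- tabulate(data$group)
  if (any(ni < 3L)) stop("each group needs at least 3 observations")
  if (design == "two-way" && !"factor2" %in% names(data))
    stop("two-way design requires a factor2 column")

  norm <- do.call(rbind, lapply(levels(data$group), function(g) {
    x <- data$value[data$group == g]
    if (stats::var(x) == 0) {
      # degenerate group: no normality test is defined; treat as non-normal
      data.frame(group = g, n = length(x), test = "none (zero variance)",
                 p_value = NA_real_, normal = FALSE)
    } else if (length(x) >= 8L) {
      ht <- dagostino_pearson(x)
      data.frame(group = g, n = length(x), test = "dagostino-pearson",
                 p_value = ht$p.value, normal = ht$p.value > alpha)
    } else {
      ht <- stats::shapiro.test(x)
      data.frame(group = g, n = length(x), test = "shapiro-wilk",
                 p_value = ht$p.value, normal = ht$p.value > alpha)
    }
  }))
  parametric <- if (normality_rule == "any-normal") any(norm$normal)
    else all(norm$normal)

  if (!parametric) {
    kw <- stats::kruskal.test(value ~ group, data = data)
    pw <- dunn_test(data$value, data$group, p_adjust = p_adjust)
    branch <- "kruskal-dunn"
    statistic <- unname(kw$statistic)
    omnibus_p <- kw$p.value
  } else if (design == "one-way") {
    fit <- stats::aov(value ~ group, data = data)
    tk <- stats::TukeyHSD(fit)$group
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pw <- data.frame(group1 = cmp[, 1], group2 = cmp[, 2],
                     z = NA_real_, p_value = tk[, "p adj"],
                     p_adjusted = tk[, "p adj"], row.names = NULL)
    an <- summary(fit)[[1]]
    branch <- "anova-oneway"
    statistic <- an[["F value"]][1]
    omnibus_p <- an[["Pr(>F)"]][1]
  } else {
    data$factor2 <- factor(data$factor2)
    fit <- stats::aov(value ~ group * factor2, data = data)
    tk <- stats::TukeyHSD(fit, which = "group")$group
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pw <- data.frame(group1 = cmp[, 1], group2 = cmp[, 2],
                     z = NA_real_, p_value = tk[, "p adj"],
                     p_adjusted = tk[, "p adj"], row.names = NULL)
    an <- summary(fit)[[1]]
    branch <- "anova-twoway"
    statistic <- an[["F value"]][1]
    omnibus_p <- an[["Pr(>F)"]][1]
  }
  pw$significant <- pw$p_adjusted < alpha
  structure(list(normality = norm, branch = branch,
                 statistic = statistic, omnibus_p = omnibus_p,
                 pairwise = pw, alpha = alpha,
                 normality_rule = normality_rule, design = design),
            class = "comparison_report")
}

#' ROUT-style robust outlier flagging (univariate)
#'
#' The univariate special case of the robust-regression-and-outlier-test
#' procedure: the "model" is a robust constant (median), scale is the
#' normal-consistent MAD, residual p-values come from the t distribution
#' with n - 1 df, and flags are assigned by Benjamini-Hochberg FDR control
#' at rate Q. Flags are returned; data are never silently deleted. If the
#' MAD is zero while values differ, the scale falls back to the
#' normalized IQR (with a warning); if that is also zero the deviating
#' values are flagged directly.
#'
#' @param x numeric sample, n >= 10.
#' @param Q target false discovery rate among flagged points, in percent
#'   (default 1, the conventional setting).
#' @return logical vector: TRUE where the point is flagged as an outlier.
#' @export
rout_outliers <- function(x, Q = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("ROUT flagging requires n >= 10")
  stopifnot(Q > 0, Q < 100)
  med <- stats::median(x)
  resid <- x - med
  scale <- stats::mad(x)                       # 1.4826 * MAD
  if (scale == 0 && any(resid != 0)) {
    warning("zero MAD with distinct values; falling back to IQR scale")
    scale <- stats::IQR(x) / 1.349
  }
  if (scale == 0) return(resid != 0)
  tt <- resid / scale
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  ord <- order(p)
  thresh <- (seq_len(n) / n) * (Q / 100)
  pass <- p[ord] <= thresh
  kmax <- if (any(pass)) max(which(pass)) else 0L
  flags <- logical(n)
  if (kmax > 0L) flags[ord[seq_len(kmax)]] <- TRUE
  flags
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Group comparison (", x$design, ", rule: ", x$normality_rule,
      ")\n", sep = "")
  cat("Normality per group:\n")
  print(x$normality, row.names = FALSE)
  lab <- switch(x$branch,
                "kruskal-dunn" = "Kruskal-Wallis H",
                "anova-oneway" = "one-way ANOVA F",
                "anova-twoway" = "two-way ANOVA F (group)")
  cat(sprintf("\nBranch: %s; %s = %.4g, omnibus p = %.4g\n",
              x$branch, lab, x$statistic, x$omnibus_p))
  cat("Pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to CSV and text
#'
#' @param report a `comparison_report`.
#' @param csv_path path for the pairwise table CSV (optional).
#' @param txt_path path for a human-readable summary (optional).
#' @export
write_comparison_report <- function(report, csv_path = NULL,
                                    txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$pairwise, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); on.exit({ sink(); close(con) })
    print(report)
  }
  invisible(report)
}
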