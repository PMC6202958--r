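# Statistical layer: one-sided paired tests on evenness, Spearman
# correlations with Benjamini-Hochberg FDR, and the low-chlorophyll
# spectral-tuning trend model.

#' One-sided paired t-test
#'
#' t-test on the paired differences `x - y` against mu = 0, one-sided in
#' the stated direction. When the differences have zero variance the
#' result is flagged degenerate: p = 0.5 for identical vectors, 0 or 1 by
#' the sign convention otherwise.
#'
#' @param x,y Equal-length numeric vectors (n >= 2), no missing pairs.
#' @param direction `"greater"` (x tends to exceed y) or `"less"`.
#' @return A `paired_test` list: `statistic`, `p_value`, `direction`,
#'   `n_pairs`, `degenerate`.
#' @export
paired_t_one_sided <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed")
  d <- x - y
  if (sd(d) == 0) {
    s <- sign(mean(d))
    p <- if (s == 0) 0.5
    else if ((s > 0) == (direction == "greater")) 0 else 1
    return(structure(list(statistic = if (s == 0) 0 else s * Inf,
                          p_value = p, direction = direction,
                          n_pairs = length(x), degenerate = TRUE),
                     class = "paired_test"))
  }
  tt <- t.test(x, y, paired = TRUE, mu = 0, alternative = direction)
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 direction = direction, n_pairs = length(x),
                 degenerate = FALSE),
            class = "paired_test")
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the paired differences, zeros dropped by the
#' Wilcoxon convention. The exact null distribution is used for n <= 25
#' untied absolute differences; otherwise the normal approximation with
#' continuity correction.
#'
#' @inheritParams paired_t_one_sided
#' @return A `paired_test` list; `degenerate = TRUE` with `NA` p-value
#'   when every difference is zero.
#' @export
wilcoxon_signed_rank_paired <- function(x, y,
                                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed")
  d <- (x - y)[x != y]
  if (!length(d))
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          direction = direction, n_pairs = length(x),
                          degenerate = TRUE), class = "paired_test"))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(d, mu = 0, alternative = direction, exact = exact,
                correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 direction = direction, n_pairs = length(x),
                 degenerate = FALSE),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat("Paired one-sided test (", x$direction, "): statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4),
      ", n = ", x$n_pairs,
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Spearman correlations with Benjamini-Hochberg FDR
#'
#' Rank correlation (average ranks on ties) for each declared variable
#' pair, with BH q-values computed over the tested pair family. Pairs with
#' fewer than 4 complete observations or a constant variable yield `NA`
#' and are excluded from the correction family.
#'
#' @param data data.frame of observations.
#' @param pairs data.frame with columns `var1`, `var2` naming columns of
#'   `data`; this declared family defines the multiple-testing correction.
#' @return data.frame `var1`, `var2`, `n`, `rho`, `p`, `q`.
#' @export
spearman_fdr <- function(data, pairs) {
  stopifnot(is.data.frame(data), is.data.frame(pairs),
            all(c("var1", "var2") %in% names(pairs)))
  bad <- setdiff(unique(c(pairs$var1, pairs$var2)), names(data))
  if (length(bad)) stop("variables not in data: ", paste(bad, collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- data[[pairs$var1[i]]]
    y <- data[[pairs$var2[i]]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(var1 = pairs$var1[i], var2 = pairs$var2[i], n = n,
                        rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(var1 = pairs$var1[i], var2 = pairs$var2[i], n = n,
               rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out
}

#' Fit the low-chlorophyll spectral-tuning trend
#'
#' Ordinary least squares of the blue PR fraction on `ln(Chl-a)`,
#' restricted to samples with chlorophyll below the threshold `tau`
#' (default 0.25 ug/L, the pivot between blue- and green-dominated
#' regimes). Samples at or above `tau` form the unmodeled stratum and are
#' summarized by their mean blue fraction. The model is fitted on the
#' fraction scale; presenting percentages is formatting only.
#'
#' @param samples data.frame with columns `chl` (ug/L, > 0) and
#'   `blue_fraction`.
#' @param tau Chlorophyll threshold in ug/L.
#' @return A `tuning_trend` list: `fitted` flag, `slope`, `intercept`,
#'   `r_squared`, `n_points`, `tau`, `above_mean_blue`, `n_above`. With
#'   fewer than 3 low-chlorophyll samples no model is fitted and `fitted`
#'   is FALSE.
#' @export
fit_tuning_trend <- function(samples, tau = 0.25) {
  stopifnot(is.data.frame(samples),
            all(c("chl", "blue_fraction") %in% names(samples)))
  ok <- complete.cases(samples$chl, samples$blue_fraction) & samples$chl > 0
  s <- samples[ok, , drop = FALSE]
  low <- s[s$chl < tau, , drop = FALSE]
  above <- s[s$chl >= tau, , drop = FALSE]
  base <- list(tau = tau,
               above_mean_blue = if (nrow(above)) mean(above$blue_fraction)
                                 else NA_real_,
               n_above = nrow(above))
  if (nrow(low) < 3)
    return(structure(c(list(fitted = FALSE, slope = NA_real_,
                            intercept = NA_real_, r_squared = NA_real_,
                            n_points = nrow(low)), base),
                     class = "tuning_trend"))
  fit <- lm(blue_fraction ~ log(chl), data = low)
  # noiseless generated data is a legitimate input: silence the
  # "essentially perfect fit" note from summary.lm
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(c(list(fitted = TRUE,
                   slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]),
                   r_squared = r2,
                   n_points = nrow(low)), base),
            class = "tuning_trend")
}

#' @export
print.tuning_trend <- function(x, ...) {
  if (x$fitted)
    cat("Tuning trend (Chl-a < ", x$tau, "): blue = ", signif(x$slope, 4),
        " * ln(Chl) + ", signif(x$intercept, 4), ", R^2 = ",
        signif(x$r_squared, 4), ", n = ", x$n_points, "\n", sep = "")
  else
    cat("Tuning trend: not fitted (", x$n_points,
        " samples below threshold)\n", sep = "")
  if (x$n_above)
    cat("  above-threshold stratum: mean blue fraction ",
        signif(x$above_mean_blue, 4), " (n = ", x$n_above, ")\n", sep = "")
  invisible(x)
}
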