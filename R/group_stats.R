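#' Two-way ANOVA (genotype x stage) with type II sums of squares
#'
#' Classical two-factor ANOVA computed from sums of squares of nested
#' least-squares fits: for factors A and B with interaction,
#' SS(A) = RSS(B) - RSS(A + B), SS(B) = RSS(A) - RSS(A + B),
#' SS(A:B) = RSS(A + B) - RSS(A * B), with the residual from the full
#' model. Type II sums of squares coincide with the textbook decomposition
#' on balanced designs and remain well defined on unbalanced ones. F
#' p-values come from the F distribution (regularized incomplete beta).
#'
#' @param data data frame with the response and two factor columns.
#' @param response name of the numeric response column (default `"value"`).
#' @param factor_a,factor_b names of the factor columns (defaults
#'   `"genotype"`, `"stage"`).
#' @return Object of class `anova_result`: data frame with columns effect,
#'   ss, df, ms, F, p.
#' @export
two_way_anova <- function(data, response = "value", factor_a = "genotype",
                          factor_b = "stage") {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (any(!is.finite(y))) stop("response contains non-finite values")
  tab <- table(A, B)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)
    stop("design cells are empty, interaction inestimable: ",
         paste(sprintf("(%s, %s)", rownames(tab)[bad[, 1]],
                       colnames(tab)[bad[, 2]]), collapse = ", "))
  }
  if (sum(tab) <= nlevels(A) * nlevels(B))
    stop("at least one cell needs >= 2 replicates for the interaction model")

  rss <- function(X) {
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  X0 <- model.matrix(~1, data.frame(A, B))
  XA <- model.matrix(~A)
  XB <- model.matrix(~B)
  XAB <- model.matrix(~A + B)
  Xfull <- model.matrix(~A * B)

  rss_a <- rss(XA); rss_b <- rss(XB); rss_ab <- rss(XAB); rss_f <- rss(Xfull)
  ss_a <- rss_b - rss_ab
  ss_b <- rss_a - rss_ab
  ss_int <- rss_ab - rss_f
  df_a <- nlevels(A) - 1L
  df_b <- nlevels(B) - 1L
  df_int <- df_a * df_b
  df_res <- length(y) - ncol(Xfull)
  ms_res <- rss_f / df_res
  eff <- data.frame(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residual"),
    ss = c(ss_a, ss_b, ss_int, rss_f),
    df = c(df_a, df_b, df_int, df_res))
  eff$ms <- eff$ss / eff$df
  # guard the degenerate zero-variance case (all fitted residuals ~ 0)
  tol <- 1e-12 * (mean(y^2) + 1)
  eff$F <- if (ms_res > tol) c(eff$ms[1:3] / ms_res, NA) else
    c(ifelse(eff$ms[1:3] > tol, Inf, 0), NA)
  eff$p <- c(pf(eff$F[1:3], eff$df[1:3], df_res, lower.tail = FALSE), NA)
  structure(eff, class = c("anova_result", "data.frame"))
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m raw p-values ascending and sets
#' `adj p_(i) = max_{j <= i} min(1, 1 - (1 - p_(j))^(m - j + 1))`,
#' returning the adjusted values in the input order. Adjusted values are
#' never smaller than the raw ones and are monotone over the sorted
#' sequence.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_sidak <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  step <- pmin(1, 1 - (1 - ps)^(m - seq_len(m) + 1))
  adj <- cummax(step)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise genotype/stage comparisons with Holm-Sidak adjustment
#'
#' Emits both comparison families used in the figures — across stages
#' within each genotype, and between genotypes within each stage — as
#' Welch t-tests, adjusted within each family by [holm_sidak()].
#'
#' @inheritParams two_way_anova
#' @return Data frame: family, group, comparison, estimate (mean
#'   difference), p_raw, p_adj.
#' @export
pairwise_comparisons <- function(data, response = "value",
                                 factor_a = "genotype", factor_b = "stage") {
  y <- data[[response]]
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  rows <- list()
  tt <- function(y1, y2) {
    if (length(y1) < 2 || length(y2) < 2) return(c(NA_real_, NA_real_))
    ht <- tryCatch(stats::t.test(y1, y2), error = function(e) NULL)
    if (is.null(ht)) return(c(mean(y1) - mean(y2), NA_real_)) # constant data
    c(mean(y1) - mean(y2), ht$p.value)
  }
  for (a in levels(A)) {
    lv <- levels(B)
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
      r <- tt(y[A == a & B == lv[i]], y[A == a & B == lv[j]])
      rows[[length(rows) + 1]] <- data.frame(
        family = paste0("within_", factor_a), group = a,
        comparison = paste(lv[i], "vs", lv[j]),
        estimate = r[1], p_raw = r[2])
    }
  }
  for (b in levels(B)) {
    lv <- levels(A)
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
      r <- tt(y[B == b & A == lv[i]], y[B == b & A == lv[j]])
      rows[[length(rows) + 1]] <- data.frame(
        family = paste0("within_", factor_b), group = b,
        comparison = paste(lv[i], "vs", lv[j]),
        estimate = r[1], p_raw = r[2])
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam & !is.na(out$p_raw)
    out$p_adj[sel] <- holm_sidak(out$p_raw[sel])
  }
  out
}

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return Correlation coefficient in \[-1, 1\], with attribute `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  structure(stats::cor(x, y), n = length(x))
}
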