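effect_bands <- c("trivial", "small", "medium", "large")

#' Classify a mean difference into effect-size bands
#'
#' Bands follow the established QLQ-C30 mean-difference taxonomy on the
#' absolute difference: trivial 0-3 points, small 3-10, medium 10-15,
#' large > 15. Boundaries close on the lower category (a difference of
#' exactly 3 points is trivial).
#'
#' @param md Mean difference(s) on the 0-100 scale (sign ignored).
#' @return Factor with levels trivial/small/medium/large.
#' @export
#' @examples
#' classify_md(c(2.6096, 15.0773))
classify_md <- function(md) {
  a <- abs(md)
  band <- ifelse(a <= 3, "trivial",
          ifelse(a <= 10, "small",
          ifelse(a <= 15, "medium", "large")))
  factor(band, levels = effect_bands)
}

#' Classify an odds ratio into effect-size bands
#'
#' Odds-ratio bands are additive around 1: trivial within 1 +/- 0.05
#' (0.95-1.05 inclusive), small within 1 +/- 0.10, medium within 1 +/- 0.20,
#' large beyond 0.80/1.20 (strict). The additivity means reciprocal pairs do
#' not always share a band (0.855 and 1/0.855 = 1.17 both land in medium,
#' but this is not guaranteed at every boundary); the convention matches how
#' the bands are defined, not a log-symmetric one.
#'
#' @param or_value Odds ratio(s), strictly positive.
#' @return Factor with levels trivial/small/medium/large.
#' @export
#' @examples
#' classify_or(c(1.16848, 1.10396, 0.84858))
classify_or <- function(or_value) {
  if (any(or_value <= 0, na.rm = TRUE)) stop("odds ratios must be positive")
  o <- or_value
  band <- ifelse(o >= 0.95 & o <= 1.05, "trivial",
          ifelse(o >= 0.90 & o <= 1.10, "small",
          ifelse(o >= 0.80 & o <= 1.20, "medium", "large")))
  factor(band, levels = effect_bands)
}

#' Cross-tabulate effect-size bands against statistical significance
#'
#' Builds the band-by-significance summary for a table of per-domain effect
#' estimates: for the mean-difference column and the odds-ratio column
#' separately, the number of estimates in each band and the number of those
#' with `p < alpha`.
#'
#' @param estimates Data.frame with any of the column pairs (`md`, `md_p`)
#'   and (`or`, `or_p`).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Object of class `effect_size_table`: a list with `md` and/or `or`
#'   components, each a 4 x 2 matrix (`all`, `significant` by band), plus
#'   `alpha` and `n`.
#' @export
crosstab <- function(estimates, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  out <- list(alpha = alpha, n = nrow(estimates))
  tab1 <- function(band, p) {
    all_n <- table(band)
    sig_n <- table(band[!is.na(p) & p < alpha])
    cbind(all = as.integer(all_n), significant = as.integer(sig_n))
  }
  if (all(c("md", "md_p") %in% names(estimates)))
    out$md <- `rownames<-`(tab1(classify_md(estimates$md), estimates$md_p),
                           effect_bands)
  if (all(c("or", "or_p") %in% names(estimates)))
    out$or <- `rownames<-`(tab1(classify_or(estimates$or), estimates$or_p),
                           effect_bands)
  structure(out, class = "effect_size_table")
}

#' @export
print.effect_size_table <- function(x, ...) {
  cat(sprintf("Effect-size bands x significance (alpha = %g, n = %d)\n",
              x$alpha, x$n))
  for (m in intersect(c("md", "or"), names(x))) {
    cat(if (m == "md") "Mean differences:\n" else "Odds ratios:\n")
    tab <- x[[m]]
    pct <- function(k, tot) sprintf("%d (%d%%)", k, round(100 * k / max(tot, 1)))
    for (b in rownames(tab))
      cat(sprintf("  %-8s %-10s significant %s\n", b,
                  pct(tab[b, "all"], sum(tab[, "all"])),
                  pct(tab[b, "significant"], sum(tab[, "significant"]))))
  }
  invisible(x)
}

#' Odds of detecting a medium-or-large effect, one scale versus another
#'
#' Given band counts from two classifications of the same estimates (for
#' example odds-ratio versus mean-difference scales), computes the odds
#' ratio of falling in the medium-or-large bands:
#' `(p_a / (1 - p_a)) / (p_b / (1 - p_b))`.
#'
#' @param counts_a,counts_b Band counts (length-4 vectors in
#'   trivial/small/medium/large order, e.g. a column of [crosstab()]), or
#'   single proportions in `[0, 1]`.
#' @param digits Optionally round the two proportions to this many decimals
#'   before forming odds, reproducing arithmetic quoted from rounded
#'   proportions. Default `NULL` (exact).
#' @return The detection odds ratio; `Inf` when `p_a = 1`.
#' @export
#' @examples
#' detection_odds(0.24, 0.04)  # 7.58
detection_odds <- function(counts_a, counts_b, digits = NULL) {
  prop <- function(x) {
    if (length(x) == 1L) {
      if (x < 0 || x > 1) stop("a single value must be a proportion in [0, 1]")
      return(x)
    }
    if (length(x) != 4L) stop("band counts must have 4 entries")
    sum(x[3:4]) / sum(x)
  }
  pa <- prop(counts_a); pb <- prop(counts_b)
  if (!is.null(digits)) { pa <- round(pa, digits); pb <- round(pb, digits) }
  if (pb == 0) return(Inf)
  if (pa == 1 || pb == 1) return(if (pa == 1) Inf else 0)
  (pa / (1 - pa)) / (pb / (1 - pb))
}

#' Empirical equivalence between mean-difference and odds-ratio effect sizes
#'
#' Matches the two effect-size scales through their cumulative frequency
#' curves: for each grid value `m`, the empirical cumulative frequency of
#' `|MD|` at `m` is computed, and the odds-ratio magnitude
#' (`exp(|log OR|)`, i.e. the OR-above-1 equivalent) at the same cumulative
#' frequency is returned via the inverse empirical CDF with linear
#' interpolation. The mapping is monotone non-decreasing; grid values
#' outside the observed `|MD|` range are clamped to the range with a
#' warning.
#'
#' @param mds Mean differences (signs ignored).
#' @param ors Odds ratios (> 0).
#' @param md_grid Mean-difference grid values to map.
#' @return Data.frame with `md`, `cum_freq` and the matched `or`.
#' @export
md_or_equivalence <- function(mds, ors, md_grid) {
  if (!length(mds) || !length(ors)) stop("both effect lists must be non-empty")
  if (any(ors <= 0)) stop("odds ratios must be positive")
  am <- sort(abs(mds))
  ao <- sort(exp(abs(log(ors))))
  if (any(md_grid < min(am) | md_grid > max(am))) {
    warning("grid value(s) outside the observed |MD| range; clamped")
    md_grid <- pmin(pmax(md_grid, min(am)), max(am))
  }
  # piecewise-linear empirical CDF knots, duplicate values collapsed to their
  # largest plotting position so forward and inverse curves are consistent
  knots <- function(v) {
    n <- length(v)
    p <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
    keep <- !duplicated(v, fromLast = TRUE)
    list(x = v[keep], p = p[keep])
  }
  km <- knots(am); ko <- knots(ao)
  Fm <- approx(km$x, km$p, xout = md_grid, rule = 2)$y
  orq <- approx(ko$p, ko$x, xout = Fm, rule = 2)$y
  data.frame(md = md_grid, cum_freq = Fm, or = orq)
}
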