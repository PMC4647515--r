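#' QLQ-C30 domain definitions
#'
#' The 30 items of the EORTC QLQ-C30 (version 3) are scored into 15 domains:
#' five function scales (PF, RF, EF, CF, SF), nine symptom-oriented scales
#' (FA, NV, PA, DY, SL, AP, CO, DI, plus financial impact FI) and the global
#' health status / quality-of-life scale (QL). Items 1-28 are answered on a
#' 4-point scale (range 3); the two global items 29-30 on a 7-point scale
#' (range 6).
#'
#' Each domain also carries `n_levels`, the number of steps of its achievable
#' 0-100 score grid (`item_range * number of items`): a 2-item scale on
#' 4-point items can only take the 7 values 0, 16.7, ..., 100. This grid is
#' what the Beta-Binomial count representation is built on.
#'
#' @return A data.frame with one row per domain: `domain`, `kind`
#'   (`"function"`, `"symptom"` or `"global"`), `items` (comma-separated item
#'   numbers), `item_range` and `n_levels`.
#' @export
#' @examples
#' qlq_domains()
qlq_domains <- function() {
  def <- list(
    QL = list(kind = "global",   items = c(29L, 30L), range = 6L),
    PF = list(kind = "function", items = 1:5,         range = 3L),
    RF = list(kind = "function", items = c(6L, 7L),   range = 3L),
    EF = list(kind = "function", items = 21:24,       range = 3L),
    CF = list(kind = "function", items = c(20L, 25L), range = 3L),
    SF = list(kind = "function", items = c(26L, 27L), range = 3L),
    FA = list(kind = "symptom",  items = c(10L, 12L, 18L), range = 3L),
    NV = list(kind = "symptom",  items = c(14L, 15L), range = 3L),
    PA = list(kind = "symptom",  items = c(9L, 19L),  range = 3L),
    DY = list(kind = "symptom",  items = 8L,          range = 3L),
    SL = list(kind = "symptom",  items = 11L,         range = 3L),
    AP = list(kind = "symptom",  items = 13L,         range = 3L),
    CO = list(kind = "symptom",  items = 16L,         range = 3L),
    DI = list(kind = "symptom",  items = 17L,         range = 3L),
    FI = list(kind = "symptom",  items = 28L,         range = 3L)
  )
  data.frame(
    domain = names(def),
    kind = vapply(def, `[[`, "", "kind"),
    items = vapply(def, function(d) paste(d$items, collapse = ","), ""),
    item_range = vapply(def, function(d) d$range, 0L),
    n_levels = vapply(def, function(d) d$range * length(d$items), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

domain_def <- function(domain) {
  defs <- qlq_domains()
  i <- match(domain, defs$domain)
  if (is.na(i)) stop("unknown QLQ-C30 domain: ", domain)
  defs[i, ]
}

#' Score one QLQ-C30 domain from its item responses
#'
#' Computes the 0-100 domain score from raw item responses. The raw score is
#' the mean of the answered items; function scales are reverse-oriented so
#' that high scores mean better functioning, while symptom scales (and FI)
#' and the global scale increase with the raw score (high symptom scores mean
#' worse HRQoL, high QL better). Missing items are handled by the half rule:
#' the score is computed from the mean of the answered items provided at
#' least half the items were answered, otherwise the score is `NA`.
#'
#' @param items Integer responses, one per item of the domain, in
#'   `1:(item_range + 1)`; `NA` for unanswered items.
#' @param domain Domain code (see [qlq_domains()]).
#' @return Score in `[0, 100]`, or `NA_real_` when the half rule fails.
#' @export
#' @examples
#' score_domain(c(1, 2, 2, 1, 1), "PF")  # 86.67: mild impairment
#' score_domain(c(1, 1), "NV")           # 0: no nausea/vomiting
score_domain <- function(items, domain) {
  d <- domain_def(domain)
  n_items <- length(strsplit(d$items, ",")[[1]])
  if (length(items) != n_items)
    stop(sprintf("domain %s expects %d item responses, got %d",
                 domain, n_items, length(items)))
  ok <- !is.na(items)
  bad <- which(ok & (items < 1 | items > d$item_range + 1))
  if (length(bad))
    stop(sprintf("item %d response %s out of range [1, %d] for domain %s",
                 bad[1], format(items[bad[1]]), d$item_range + 1, domain))
  if (sum(ok) * 2 < n_items) return(NA_real_)
  rs <- mean(items[ok])
  if (d$kind == "function")
    (1 - (rs - 1) / d$item_range) * 100
  else
    ((rs - 1) / d$item_range) * 100
}

#' Score all 15 domains from a 30-item response vector
#'
#' @param responses Numeric vector of length 30 (items in questionnaire
#'   order), `NA` for unanswered items.
#' @return Named numeric vector of 15 domain scores.
#' @export
score_all_domains <- function(responses) {
  if (length(responses) != 30L)
    stop("expected 30 item responses, got ", length(responses))
  defs <- qlq_domains()
  out <- vapply(seq_len(nrow(defs)), function(i) {
    idx <- as.integer(strsplit(defs$items[i], ",")[[1]])
    score_domain(responses[idx], defs$domain[i])
  }, 0)
  names(out) <- defs$domain
  out
}

#' Map a bounded score to the unit interval
#'
#' The affine transform `u = (score - a) / (b - a)` mapping a score on
#' `[a, b]` to `[0, 1]`; for QLQ-C30 domain scores `a = 0`, `b = 100`, so a
#' score of 80 maps to 0.8.
#'
#' @param score Numeric score(s) in `[a, b]`.
#' @param a,b Scale minimum and maximum (default 0 and 100).
#' @return Value(s) in `[0, 1]`.
#' @export
#' @examples
#' unit_transform(80)  # 0.8
unit_transform <- function(score, a = 0, b = 100) {
  if (!(a < b)) stop("scale minimum must be below maximum")
  if (any(score < a - 1e-9 | score > b + 1e-9, na.rm = TRUE))
    stop(sprintf("score outside [%g, %g]", a, b))
  (score - a) / (b - a)
}

#' Count representation of a grid-valued score
#'
#' A domain whose achievable scores form the grid `0, 100/n, 200/n, ..., 100`
#' is represented as `k` of `n` achievable steps, the form consumed by the
#' Beta-Binomial likelihood. `k` is the nearest grid level; for any
#' achievable score the mapping is exact, and `k/n * 100` inverts it.
#'
#' @param score Score(s) in `[0, 100]`.
#' @param n_levels Number of grid steps `n` (per-domain, see [qlq_domains()]).
#' @return A data.frame with integer columns `k` and `n`.
#' @export
#' @examples
#' to_counts(66.7, 6)  # k = 4 of n = 6 (the CF grid)
to_counts <- function(score, n_levels) {
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (any(score < 0 | score > 100, na.rm = TRUE))
    stop("score outside [0, 100]")
  k <- as.integer(round(score / 100 * n_levels))
  data.frame(k = k, n = rep(as.integer(n_levels), length(k)))
}

#' Validate pre-computed scores against a domain's achievable grid
#'
#' Scores supplied directly (rather than computed from items) are checked
#' against the domain grid; off-grid values beyond `tol` raise a warning but
#' are kept, since rounding in source files is common.
#'
#' @param score Scores in `[0, 100]`.
#' @param domain Domain code.
#' @param tol Absolute tolerance for grid membership (default 0.05).
#' @return Invisibly, a logical vector flagging on-grid values.
#' @export
check_grid <- function(score, domain, tol = 0.05) {
  n <- domain_def(domain)$n_levels
  ok <- is.na(score) | abs(score - round(score / 100 * n) / n * 100) <= tol
  if (any(!ok))
    warning(sprintf("%d score(s) for %s are off the %d-step grid by more than %g",
                    sum(!ok), domain, n, tol))
  invisible(ok)
}
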