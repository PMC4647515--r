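#' Read a long-format trial dataset
#'
#' Reads the package's CSV dialect (comma-separated, UTF-8, header required,
#' column names case-insensitive). Two layouts are accepted:
#' \itemize{
#'   \item item layout: `patient_id, arm, visit_time, item_1 .. item_30` —
#'     items are scored into all 15 domains via [score_all_domains()];
#'   \item score layout: `patient_id, arm, visit_time, domain, score` —
#'     pre-computed 0-100 scores, validated against the domain grid
#'     (off-grid values warn, see [check_grid()]).
#' }
#' `arm` is coded 0 = control, 1 = experimental; `visit_time` in days from
#' randomization.
#'
#' @param path CSV file path.
#' @return A trial dataset: data.frame with columns `patient_id`, `arm`,
#'   `visit_time`, `domain`, `score`.
#' @export
read_trial_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(x) <- tolower(names(x))
  need <- c("patient_id", "arm", "visit_time")
  if (!all(need %in% names(x)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (!all(x$arm %in% c(0, 1)))
    stop("arm must be coded 0 (control) / 1 (experimental)")
  if (all(paste0("item_", 1:30) %in% names(x))) {
    items <- as.matrix(x[paste0("item_", 1:30)])
    scored <- t(apply(items, 1, score_all_domains))
    out <- data.frame(
      patient_id = rep(x$patient_id, each = 15L),
      arm = rep(as.integer(x$arm), each = 15L),
      visit_time = rep(x$visit_time, each = 15L),
      domain = rep(colnames(scored), times = nrow(x)),
      score = as.vector(t(scored)),
      stringsAsFactors = FALSE
    )
  } else if (all(c("domain", "score") %in% names(x))) {
    out <- x[c("patient_id", "arm", "visit_time", "domain", "score")]
    out$arm <- as.integer(out$arm)
    for (d in intersect(unique(out$domain), qlq_domains()$domain))
      check_grid(out$score[out$domain == d], d)
  } else {
    stop("expected either item_1..item_30 columns or (domain, score) columns")
  }
  validate_trial(out)
  out
}

#' Write a trial dataset in the package CSV dialect
#'
#' @param data Trial dataset (score layout).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  validate_trial(data)
  write.csv(data[c("patient_id", "arm", "visit_time", "domain", "score")],
            path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_trial <- function(data) {
  need <- c("patient_id", "arm", "visit_time", "domain", "score")
  if (!all(need %in% names(data)))
    stop("trial dataset needs columns: ", paste(need, collapse = ", "))
  if (nrow(data) == 0L) stop("trial dataset is empty")
  if (!all(data$arm %in% c(0L, 1L))) stop("arm must be 0/1")
  if (any(data$score < -1e-9 | data$score > 100 + 1e-9, na.rm = TRUE))
    stop("scores must lie in [0, 100]")
  invisible(TRUE)
}

#' Published effect estimates from six CRUK lung-cancer trials
#'
#' Loads the packaged transcription of the published per-domain treatment
#' effects from six CRUK-sponsored randomized lung-cancer trials (TOPICAL,
#' SOCCAR, Studies 10/11/12/14; 2909 patients): for each of the 90
#' trial-by-domain combinations, the Beta-Binomial odds ratio with 95% CI and
#' p-value and the repeated-measures mean difference with 95% CI and p-value,
#' exactly as printed in the source report. P-values printed as "<.0001" are
#' parsed to 1e-4 (only their position relative to 0.05 is ever used).
#'
#' @return A data.frame of 90 rows with columns `trial`, `domain`, `or`,
#'   `or_lcl`, `or_ucl`, `or_p`, `md`, `md_lcl`, `md_ucl`, `md_p`.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_effects.csv", package = "qlor",
                      mustWork = TRUE)
  x <- read.csv(path, stringsAsFactors = FALSE, colClasses = list(
    or_p = "character", md_p = "character"))
  parse_p <- function(p) ifelse(grepl("^<", p), 1e-4, suppressWarnings(as.numeric(p)))
  x$or_p <- parse_p(x$or_p)
  x$md_p <- parse_p(x$md_p)
  stopifnot(nrow(x) == 90L, all(x$or > 0), !anyNA(x$or_p), !anyNA(x$md_p))
  x
}
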