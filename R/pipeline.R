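#' End-to-end analysis pipeline for a trial dataset
#'
#' Runs the full per-domain analysis chain: Beta-Binomial odds ratio and
#' repeated-measures mean difference fits, effect-size classification and
#' the band-by-significance cross-tabulation, optional time-to-deterioration
#' analysis, and distributional screening. Failures in one domain are
#' recorded in the manifest and the remaining domains are processed. When
#' `estimates` is supplied instead of `data`, the pipeline runs in
#' classification-only mode: no models are fitted and the supplied effect
#' estimates (e.g. the packaged published table, [load_table2_fixture()])
#' are classified and cross-tabulated directly.
#'
#' @param data Trial dataset (score layout), or `NULL` in
#'   classification-only mode.
#' @param estimates Optional data.frame of pre-computed effect estimates
#'   with columns among `md`, `md_p`, `or`, `or_p`.
#' @param domains Domains to analyse (default: all present in `data`).
#' @param models Character subset of `c("BB", "MD", "TD")`.
#' @param alpha Significance level for the cross-tabulation.
#' @param td_threshold Deterioration threshold in points.
#' @param seed Seed recorded in the manifest and set before fitting (the
#'   jittered optimizer start draws from the RNG).
#' @param out_dir Optional directory; when given, the effect table, the
#'   cross-tabulation and the manifest are written as CSV/JSON.
#' @return List of class `qlor_pipeline`: `effects` (per-domain estimate
#'   rows), `table` (the [crosstab()]), `ttd`, `diagnostics`, `manifest`.
#' @export
run_pipeline <- function(data = NULL, estimates = NULL, domains = NULL,
                         models = c("BB", "MD", "TD"), alpha = 0.05,
                         td_threshold = 5, seed = 1L, out_dir = NULL) {
  if (is.null(data) && is.null(estimates))
    stop("supply a trial dataset or an effect-estimate table")
  if (!length(models)) stop("at least one model must be selected")
  manifest <- list(seed = as.integer(seed), alpha = alpha,
                   td_threshold = td_threshold,
                   models = models, package_version = as.character(
                     utils::packageVersion("qlor")),
                   r_version = as.character(getRversion()), failures = list())
  set.seed(seed)

  if (is.null(estimates)) {
    validate_trial(data)
    manifest$input_md5 <- dataset_md5(data)
    if (is.null(domains)) domains <- unique(data$domain)
    eff <- list(); ttd_res <- list()
    for (dm in domains) {
      dd <- data[data$domain == dm, , drop = FALSE]
      row <- data.frame(domain = dm, or = NA_real_, or_p = NA_real_,
                        md = NA_real_, md_p = NA_real_)
      if ("BB" %in% models) {
        f <- tryCatch(fit_bb(dd), error = function(e) e)
        if (inherits(f, "error")) {
          manifest$failures[[paste0("BB_", dm)]] <- conditionMessage(f)
        } else if (isTRUE(f$converged)) {
          row$or <- f$or$estimate; row$or_p <- f$or$p
        } else manifest$failures[[paste0("BB_", dm)]] <- "non-convergence"
      }
      if ("MD" %in% models) {
        f <- tryCatch(fit_md(dd), error = function(e) e)
        if (inherits(f, "error"))
          manifest$failures[[paste0("MD_", dm)]] <- conditionMessage(f)
        else if (isTRUE(f$converged)) { row$md <- f$md; row$md_p <- f$p }
      }
      if ("TD" %in% models) {
        t <- tryCatch(ttd_analysis(dd, threshold = td_threshold),
                      error = function(e) e)
        if (inherits(t, "error"))
          manifest$failures[[paste0("TD_", dm)]] <- conditionMessage(t)
        else ttd_res[[dm]] <- t
      }
      eff[[dm]] <- row
    }
    effects <- do.call(rbind, eff)
    diagnostics <- domain_distribution_report(data)
  } else {
    effects <- estimates
    ttd_res <- list()
    diagnostics <- NULL
    manifest$input_md5 <- dataset_md5(estimates)
    manifest$mode <- "classification-only"
  }
  have_md <- all(c("md", "md_p") %in% names(effects)) && any(!is.na(effects$md))
  have_or <- all(c("or", "or_p") %in% names(effects)) && any(!is.na(effects$or))
  keep <- rep(TRUE, nrow(effects))
  if (have_md && !have_or) keep <- !is.na(effects$md)
  if (have_or && !have_md) keep <- !is.na(effects$or)
  if (have_or && have_md) keep <- !is.na(effects$or) | !is.na(effects$md)
  tab <- crosstab(effects[keep, , drop = FALSE], alpha = alpha)

  res <- structure(list(effects = effects, table = tab, ttd = ttd_res,
                        diagnostics = diagnostics, manifest = manifest),
                   class = "qlor_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(effects, file.path(out_dir, "effects.csv"), row.names = FALSE)
    tab_df <- do.call(rbind, lapply(intersect(c("md", "or"), names(tab)),
      function(m) data.frame(measure = m, band = rownames(tab[[m]]),
                             all = tab[[m]][, "all"],
                             significant = tab[[m]][, "significant"])))
    write.csv(tab_df, file.path(out_dir, "effect_size_table.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  res
}

# md5 of a canonical serialization, for the manifest
dataset_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  write.csv(x, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.qlor_pipeline <- function(x, ...) {
  cat("qlor pipeline result:", nrow(x$effects), "effect row(s)\n")
  print(x$table)
  if (length(x$manifest$failures)) {
    cat("Stage failures:\n")
    for (nm in names(x$manifest$failures))
      cat("  ", nm, ": ", x$manifest$failures[[nm]], "\n", sep = "")
  }
  invisible(x)
}
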