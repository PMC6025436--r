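#' Run configuration
#'
#' Bundles every knob of a pipeline run; serialized verbatim into outputs
#' for provenance.
#'
#' @param stations a [station_set()], or `NULL` when `input` is given.
#' @param input path to a station CSV (read with [read_stations()]).
#' @param projection_label free text recording how coordinates were made
#'   planar.
#' @param diagonal kernel diagonal convention.
#' @param threshold eigenvalue-ratio screening threshold.
#' @param alpha_level covariate pruning level.
#' @param gmlr_only skip all eigenvector steps.
#' @param cv also run leave-one-out cross-validation for both models.
#' @param standard,multipliers level-classification settings.
#' @param seed integer seed recorded (and set) for any stochastic step.
#' @return list of class `run_config`.
#' @export
run_config <- function(stations = NULL, input = NULL,
                       projection_label = "planar (km)",
                       diagonal = "zero", threshold = 0.10,
                       alpha_level = 0.10, gmlr_only = FALSE, cv = FALSE,
                       standard = 35, multipliers = c(1, 1.5, 2),
                       seed = 1L) {
  structure(list(stations = stations, input = input,
                 projection_label = projection_label, diagonal = diagonal,
                 threshold = threshold, alpha_level = alpha_level,
                 gmlr_only = gmlr_only, cv = cv, standard = standard,
                 multipliers = multipliers, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full estimation procedure and build report tables
#'
#' Executes the five estimation steps in order (weights, eigenvectors,
#' stepwise selection, OLS, pruning + re-selection), fits the non-spatial
#' baseline, and assembles the report tables: a coefficient table with "/"
#' markers for pruned covariates, a metric-comparison table with percent
#' changes, and the residual Moran's I of both models.
#'
#' @param config a [run_config()] (or a [station_set()], wrapped with
#'   defaults).
#' @return list of class `esfr_report`: `config`, `model`, `gmlr`,
#'   `coef_table`, `metric_table`, `moran_table`, `cv` (when requested),
#'   `log` (per-stage r, n, selected eigenvector count).
#' @export
run_fit <- function(config) {
  if (inherits(config, "station_set")) config <- run_config(stations = config)
  stopifnot(inherits(config, "run_config"))
  stations <- config$stations
  if (is.null(stations)) {
    if (is.null(config$input)) stop("run_config needs stations or input path")
    stations <- read_stations(config$input)
  }
  set.seed(config$seed)
  y <- stations$value
  X <- stations$covariates
  gmlr <- fit_gmlr(y, X)
  attr(gmlr, "training") <- list(y = y, covariates = X,
                                 candidates = NULL, basis = NULL)
  gmlr <- prune_and_refit(gmlr, config$alpha_level)
  weights <- spatial_weights(stations, config$diagonal)
  if (config$gmlr_only) {
    model <- NULL
  } else {
    model <- fit_esfr(stations, weights = weights,
                      threshold = config$threshold,
                      alpha_level = config$alpha_level)
  }
  ref <- if (is.null(model)) gmlr else model
  fmt_num <- function(v) formatC(v, digits = 2, format = "f")
  coef_table <- data.frame(
    covariate = colnames(X),
    beta = vapply(colnames(X), function(nm)
      if (nm %in% ref$pruned) "/" else fmt_num(ref$beta[[nm]]), character(1)),
    p = vapply(colnames(X), function(nm)
      if (nm %in% ref$pruned) "/" else fmt_num(ref$pvalues[[nm]]), character(1)),
    row.names = NULL)
  moran_rows <- list(data.frame(model = "GMLR",
                                moran_i = residual_moran(gmlr, weights)$I,
                                p = residual_moran(gmlr, weights)$p))
  metric_table <- NULL
  if (!is.null(model)) {
    rm_ <- residual_moran(model, weights)
    moran_rows <- c(moran_rows, list(data.frame(model = "ESFR",
                                                moran_i = rm_$I, p = rm_$p)))
    metric_table <- data.frame(
      metric = c("r2_adj", "rse", "mape", "aicc"),
      gmlr = unlist(gmlr$fit[c("r2_adj", "rse", "mape", "aicc")]),
      esfr = unlist(model$fit[c("r2_adj", "rse", "mape", "aicc")]),
      row.names = NULL)
    metric_table$change_pct <- c(
      percent_change(metric_table$gmlr[1], metric_table$esfr[1], "increase"),
      percent_change(metric_table$gmlr[2], metric_table$esfr[2], "decrease"),
      if (is.na(metric_table$gmlr[3]) || is.na(metric_table$esfr[3])) NA_real_
      else percent_change(metric_table$gmlr[3], metric_table$esfr[3], "decrease"),
      percent_change(metric_table$gmlr[4], metric_table$esfr[4], "decrease"))
  }
  cv <- NULL
  if (config$cv) {
    cv <- list(gmlr = loocv(stations, "gmlr",
                            alpha_level = config$alpha_level))
    if (!config$gmlr_only)
      cv$esfr <- loocv(stations, "esfr", threshold = config$threshold,
                       alpha_level = config$alpha_level,
                       diagonal = config$diagonal)
  }
  structure(list(config = config, model = model, gmlr = gmlr,
                 coef_table = coef_table, metric_table = metric_table,
                 moran_table = do.call(rbind, moran_rows), cv = cv,
                 log = list(n = n_stations(stations), r = weights$r,
                            k_selected = if (is.null(model)) 0L
                                         else length(model$eigen_indices))),
            class = "esfr_report")
}

#' @export
print.esfr_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a report as Markdown
#'
#' @param report an `esfr_report` from [run_fit()].
#' @return character vector of Markdown lines.
#' @export
render_report <- function(report) {
  md_table <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1L, function(r) {
      vals <- vapply(r, function(v)
        if (is.na(suppressWarnings(as.numeric(v)))) as.character(v)
        else formatC(as.numeric(v), digits = 4, format = "g"), character(1))
      paste0("| ", paste(vals, collapse = " | "), " |")
    })
    c(hdr, sep, rows)
  }
  out <- c("# Spatially filtered regression report", "",
           sprintf("- stations: %d", report$log$n),
           sprintf("- kernel range r: %.4g", report$log$r),
           sprintf("- selected eigenvectors: %d", report$log$k_selected), "",
           "## Coefficients (standardized; '/' = pruned)", "",
           md_table(report$coef_table), "")
  if (!is.null(report$metric_table))
    out <- c(out, "## Fit metrics (GMLR vs ESFR)", "",
             md_table(report$metric_table), "")
  out <- c(out, "## Residual Moran's I", "", md_table(report$moran_table), "")
  if (!is.null(report$cv)) {
    cvdf <- do.call(rbind, lapply(report$cv, function(z)
      data.frame(model = toupper(z$method), mse = z$mse, rmse = z$rmse)))
    out <- c(out, "## Leave-one-out cross-validation", "", md_table(cvdf), "")
  }
  out
}

#' Write a report to disk
#'
#' Markdown plus a JSON document carrying the numbers and the verbatim run
#' configuration.
#'
#' @param report an `esfr_report`.
#' @param stem path stem; writes `<stem>.md` and `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_report <- function(report, stem) {
  writeLines(render_report(report), paste0(stem, ".md"))
  cfg <- report$config
  cfg$stations <- NULL  # data are not provenance; the input path is
  obj <- list(config = unclass(cfg),
              log = report$log,
              coefficients = report$coef_table,
              metrics = report$metric_table,
              residual_moran = report$moran_table,
              cv = if (!is.null(report$cv))
                lapply(report$cv, function(z)
                  list(mse = z$mse, rmse = z$rmse, n_failed = z$n_failed)))
  jsonlite::write_json(obj, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(stem)
}

#' Exceedance of a concentration standard
#'
#' `100 (mean(values) - standard) / standard`, rounded half-up to one
#' decimal: how far the average sits above (or below, negative) the
#' standard.
#'
#' @param values concentrations (non-empty).
#' @param standard the limit value (> 0), default 35.
#' @return percent, one decimal.
#' @export
exceedance_summary <- function(values, standard = 35) {
  if (!length(values)) stop("no values supplied")
  stopifnot(standard > 0)
  round_half_up(100 * (mean(values) - standard) / standard, 1L)
}
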