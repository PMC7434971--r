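#' Pipeline run configuration
#'
#' Exactly one input mode must be set: a corpus (directory of `.txt`
#' files or an id/text TSV), a precomputed binary document-by-lemma
#' matrix (TSV), or a precomputed charge series (two-column TSV or
#' numeric vector).  All analysis defaults restate the motivating
#' study's stated parameters: 10 retained factors, 5%/10% lemma
#' exclusion/selection, dynamic-complexity window 7 with step 1,
#' embedding dimension 3 with delay 1, and the changing-variance
#' change-point criterion.
#'
#' @param corpus Corpus input (path or `document_corpus`), or `NULL`.
#' @param matrix Matrix input (path or `lemma_matrix`), or `NULL`.
#' @param series Charge-series input (path or numeric), or `NULL`.
#' @param lemma_dict Optional lemma dictionary (path or named vector).
#' @param K Retained factors.
#' @param exclude_top_frac,select_frac Lemma frequency rule fractions.
#' @param dc_window Dynamic-complexity window width.
#' @param embed_m,embed_tau Recurrence embedding dimension and delay.
#' @param cost_kind Change-point cost, `"variance"` or `"mean"`.
#' @param threshold Change-point threshold (`NULL` = calibrated default).
#' @param lb_lags Ljung-Box lags (default 18, giving df = 16 after an
#'   ARMA(1,1) fit).
#' @param seed Seed echoed into the report (the analysis itself is
#'   deterministic; the seed matters when the corpus is simulated).
#' @param out_dir Output directory for serialized artifacts, or `NULL`.
#' @return A validated `run_config`.
#' @export
run_config <- function(corpus = NULL, matrix = NULL, series = NULL,
                       lemma_dict = NULL, K = 10L,
                       exclude_top_frac = 0.05, select_frac = 0.10,
                       dc_window = 7L, embed_m = 3L, embed_tau = 1L,
                       cost_kind = c("variance", "mean"),
                       threshold = NULL, lb_lags = 18L, seed = 1L,
                       out_dir = NULL) {
  cost_kind <- match.arg(cost_kind)
  modes <- c(corpus = !is.null(corpus), matrix = !is.null(matrix),
             series = !is.null(series))
  if (sum(modes) != 1L) {
    stop("exactly one of corpus, matrix, series must be given (got ",
         sum(modes), ")")
  }
  structure(list(
    corpus = corpus, matrix = matrix, series = series,
    lemma_dict = lemma_dict, K = as.integer(K),
    exclude_top_frac = exclude_top_frac, select_frac = select_frac,
    dc_window = as.integer(dc_window), embed_m = as.integer(embed_m),
    embed_tau = as.integer(embed_tau), cost_kind = cost_kind,
    threshold = threshold, lb_lags = as.integer(lb_lags),
    seed = as.integer(seed), out_dir = out_dir,
    input_mode = names(modes)[modes]
  ), class = "run_config")
}

#' Run the full phase-transition analysis pipeline
#'
#' Orchestrates corpus preparation, correspondence analysis, affective
#' charge, trend models, the three complexity representations, and
#' change-point detection into one reproducible report.  Stages that do
#' not apply to the chosen input mode are skipped and noted.  Re-running
#' with an identical config (and seed, for simulated corpora) reproduces
#' the report exactly.
#'
#' @param config A [run_config()].
#' @return A `transition_report`: nested list with the corpus summary,
#'   lemma-selection log, explained inertia, charge summary, logistic
#'   and ARIMA fits, per-representation change points and the ensemble
#'   transition, plus a config echo.  Written to
#'   `file.path(out_dir, "report.json")` when `out_dir` is set, along
#'   with TSV intermediates.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(software = paste0("dreamdyn ",
                                   as.character(utils::packageVersion("dreamdyn"))),
                 seed = config$seed, input_mode = config$input_mode,
                 config = config_echo(config))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ed <- NULL
  if (config$input_mode == "series") {
    ed <- read_series_input(config$series)
    report$notes <- "series mode: corpus and factor stages skipped"
  } else {
    if (config$input_mode == "corpus") {
      corpus <- if (inherits(config$corpus, "document_corpus"))
        config$corpus else segment_corpus(config$corpus)
      dict <- if (is.null(config$lemma_dict)) character(0)
        else if (is.character(config$lemma_dict) &&
                 length(config$lemma_dict) == 1L &&
                 file.exists(config$lemma_dict))
          read_lemma_dictionary(config$lemma_dict)
        else config$lemma_dict
      streams <- lemmatize(corpus, dict)
      selected <- rank_and_select_lemmas(streams,
                                         config$exclude_top_frac,
                                         config$select_frac)
      mat <- build_binary_matrix(streams, selected)
      report$corpus <- list(n_docs = nrow(corpus$docs),
                            excluded = corpus$excluded,
                            total_tokens = sum(lengths(corpus$tokens)))
      report$selection <- attr(selected, "selection_log")
      if (!is.null(out)) write_lemma_matrix(mat, file.path(out, "matrix.tsv"))
    } else {
      mat <- if (inherits(config$matrix, "lemma_matrix")) config$matrix
        else read_lemma_matrix(config$matrix)
      report$notes <- "matrix mode: corpus stages skipped"
    }
    space <- fit_correspondence(mat, K = config$K)
    vectors <- dream_vectors(space)
    ed <- euclidean_charge(vectors)
    report$factor_space <- list(
      K = space$K,
      eigenvalues = space$eigenvalues[seq_len(space$K)],
      explained_pct = space$explained_pct[seq_len(space$K)],
      explained_pct_K_total = sum(space$explained_pct[seq_len(space$K)]),
      excluded_rows = space$excluded_rows)
    if (!is.null(out)) write_factor_space(space, file.path(out, "factors"))
  }

  # an externally supplied series may take negative values, in which
  # case it is not a distance series: the centroid/logistic stages are
  # skipped and the dynamics layer runs on the raw values
  if (all(ed >= 0)) {
    charge <- centroid_classify(ed)
    report$charge <- list(centroid_radius = charge$centroid_radius,
                          n_inside = charge$n_inside,
                          n_outside = charge$n_outside,
                          pct_inside = charge$pct_inside,
                          pct_outside = charge$pct_outside)
    if (!is.null(out)) write_charge_series(charge, file.path(out, "charge"))
    labels <- charge$labels
  } else {
    report$charge <- list(
      skipped = "series contains negative values: not a distance series")
    labels <- NULL
  }
  report$trend <- run_trend_stage(ed, labels, config)
  dyn <- run_dynamics_stage(ed, config)
  report$change_points <- dyn$change_points
  report$ensemble <- dyn$ensemble
  if (!is.null(out)) {
    utils::write.table(
      data.frame(position = dyn$dc$positions,
                 fluctuation = dyn$dc$fluctuation,
                 distribution = dyn$dc$distribution,
                 complexity = dyn$dc$complexity),
      file.path(out, "dc_profile.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(dyn$rp$dist, file.path(out, "recurrence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(dyn$tfd$amplitude, file.path(out, "tfd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(strip_big(report),
                         file.path(out, "report.json"),
                         digits = NA, auto_unbox = TRUE, null = "null",
                         na = "null")
  }
  structure(report, class = "transition_report")
}

# Trend stage: logistic trend needs both classes; ARIMA needs length.
run_trend_stage <- function(ed, labels, config) {
  trend <- list()
  trend$logistic <- if (is.null(labels)) {
    list(skipped = "no centroid labels available")
  } else tryCatch({
    f <- fit_logistic_trend(labels)
    f[c("beta_const", "beta_time", "se_const", "se_time", "wald_const",
        "wald_time", "p_const", "p_time", "or_const", "or_time",
        "lr_chi2", "lr_df", "lr_p", "concordance_pct", "c_statistic")]
  }, error = function(e) list(error = conditionMessage(e)))
  trend$arima <- tryCatch({
    f <- fit_arima(ed, 1L, 1L, 1L)
    lb <- ljung_box(f$residuals, lags = config$lb_lags, fitdf = 2L)
    list(order = unname(f$order), constant = f$constant, ar1 = f$ar1,
         ma1 = f$ma1, se = unname(f$se), t_stats = unname(f$t_stats),
         p_values = unname(f$p_values), r_squared = f$r_squared,
         converged = f$converged, invertible = f$invertible,
         ma_sign_convention = f$ma_sign_convention,
         ljung_box = lb)
  }, error = function(e) list(error = conditionMessage(e)))
  trend$correlogram <- tryCatch({
    cg <- acf_pacf(ed, max_lag = min(20L, length(ed) - 2L))
    list(acf = cg$acf, pacf = cg$pacf, ci_bound = cg$ci_bound)
  }, error = function(e) list(error = conditionMessage(e)))
  trend
}

# Dynamics + change-point stage shared by all input modes.  Change
# indices found on derived representations are mapped back to
# original-series coordinates: the DC profile is end-aligned (profile
# index p <-> series index p + window - 1); recurrence and TFD axes are
# start-aligned (offset 0).
run_dynamics_stage <- function(ed, config) {
  dc <- dynamic_complexity(ed, window = config$dc_window)
  rp <- recurrence_matrix(ed, m = config$embed_m, tau = config$embed_tau)
  tfd <- stockwell_tfd(ed)

  cp_ed <- detect_change(ed, cost_kind = config$cost_kind,
                         threshold = config$threshold)
  cp_dc <- detect_change(dc$complexity, cost_kind = config$cost_kind,
                         threshold = config$threshold)
  cp_rp <- cpa_matrix(rp$dist, orientation = "both",
                      cost_kind = config$cost_kind,
                      threshold = config$threshold)
  # TFD: one change point from the instantaneous spectral energy (sum of
  # voice amplitudes at each time, zero-frequency voice excluded), which
  # localizes far more stably than a per-voice vote
  tfd_energy <- colSums(tfd$amplitude[-1, , drop = FALSE])
  cp_tfd <- detect_change(tfd_energy, cost_kind = config$cost_kind,
                          threshold = config$threshold)

  members <- c(
    ed = as.numeric(cp_ed$index),
    dc = if (is.na(cp_dc$index)) NA_real_
         else cp_dc$index + config$dc_window - 1L,
    rp = as.numeric(cp_rp$index),
    tfd = as.numeric(cp_tfd$index))
  ens <- tryCatch(ensemble_transition(members),
                  error = function(e) NULL)
  list(
    dc = dc, rp = rp, tfd = tfd,
    change_points = list(
      ed = cp_ed$index, dc_profile = cp_dc$index,
      dc_mapped = unname(members["dc"]), rp = cp_rp$index,
      tfd = cp_tfd$index,
      rp_lines_detected = cp_rp$n_detected,
      cost_kind = config$cost_kind, threshold = cp_ed$threshold),
    ensemble = if (is.null(ens)) list(detected = FALSE)
      else list(detected = TRUE, members = ens$members,
                mean_index = ens$mean_index,
                transition_index = ens$transition_index,
                excluded = ens$excluded))
}

config_echo <- function(config) {
  e <- unclass(config)
  for (f in c("corpus", "matrix", "series", "lemma_dict")) {
    if (!is.null(e[[f]]) && !is.character(e[[f]])) e[[f]] <- "<in-memory>"
  }
  e
}

strip_big <- function(report) {
  report           # matrices are written separately; report is scalar-safe
}

#' @export
print.transition_report <- function(x, ...) {
  cat("transition_report (", x$input_mode, " mode)\n", sep = "")
  if (!is.null(x$charge)) {
    cat(sprintf("  charge: radius %.4f, inside %d (%.1f%%), outside %d (%.1f%%)\n",
                x$charge$centroid_radius, x$charge$n_inside,
                x$charge$pct_inside, x$charge$n_outside,
                x$charge$pct_outside))
  }
  cp <- x$change_points
  cat(sprintf("  change points [%s cost]: ed=%s dc=%s rp=%s tfd=%s\n",
              cp$cost_kind, format(cp$ed), format(cp$dc_mapped),
              format(cp$rp), format(cp$tfd)))
  if (isTRUE(x$ensemble$detected)) {
    cat(sprintf("  ensemble transition: index %d (mean %.2f)\n",
                x$ensemble$transition_index, x$ensemble$mean_index))
  } else {
    cat("  ensemble transition: none detected\n")
  }
  invisible(x)
}

read_series_input <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  df <- utils::read.delim(series, header = TRUE)
  as.numeric(df[[ncol(df)]])
}
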