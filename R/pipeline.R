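#' Default pipeline configuration
#'
#' All tunable parameters of the extraction and classification pipeline, in
#' the units stated: envelope window/hop in seconds (10 ms / 5 ms), vowel
#' energy band in Hz, relative peak threshold and minimum peak gap; pitch
#' range and NCCF voicing threshold; pause threshold in seconds (0.3 s) and
#' F0 unit; SVM settings.
#'
#' @param ... named overrides, e.g. `pitch = list(f_min = 75)`; merged
#'   recursively over the defaults.
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    envelope = list(window_s = 0.010, hop_s = 0.005,
                    band_low = 300, band_high = 2500,
                    rel_threshold = 0.3, min_gap_s = 0.06),
    pitch = list(f_min = 60, f_max = 400, voicing_threshold = 0.3,
                 f_ref = 100, min_voiced_s = 0.02),
    features = list(pause_threshold_s = 0.3, f0_unit = "hz"),
    classifier = list(kernel = "linear", cost = 1, convention = "standard"),
    seed = 1L)
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults; anything omitted keeps its
#' default.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Extract prosodic features from WAV files into a feature table
#'
#' Runs the full per-recording pipeline on each file and writes/returns one
#' feature row per recording. Unreadable files are skipped with a logged
#' error; recordings with no detectable nuclei yield a row of `NA` features
#' with `flagged = TRUE`.
#'
#' @param paths character vector of WAV paths, or a single directory (all
#'   `.wav` files in it, sorted).
#' @param config a [default_config()].
#' @param output optional CSV path for the feature table.
#' @param channel channel selection for stereo input.
#' @param textgrid_dir optional directory for per-file nucleus TextGrids.
#' @param pitch_dir optional directory for per-file pitch dumps.
#' @param verbose log per-file progress to stderr.
#' @return data.frame: `subject_id`, `n_nuclei`, `flagged`, then the twelve
#'   feature columns.
#' @export
cmd_extract <- function(paths, config = default_config(), output = NULL,
                        channel = "left", textgrid_dir = NULL,
                        pitch_dir = NULL, verbose = FALSE) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, "\\.wav$", full.names = TRUE, ignore.case = TRUE))
  if (!length(paths)) stop("input error: no WAV files", call. = FALSE)
  rows <- vector("list", length(paths))
  n_fail <- 0L
  for (i in seq_along(paths)) {
    id <- tools::file_path_sans_ext(basename(paths[i]))
    row <- tryCatch({
      sig <- load_audio(paths[i], channel)
      fv <- extract_features(sig, config)
      nuc <- attr(fv, "nuclei")
      if (!is.null(textgrid_dir))
        write_textgrid(nuc, sig$duration,
                       file.path(textgrid_dir, paste0(id, ".TextGrid")))
      if (!is.null(pitch_dir))
        write_pitch_dump(attr(nuc, "pitch_track"),
                         file.path(pitch_dir, paste0(id, "_f0.tsv")))
      if (verbose)
        message(sprintf("[extract] %s: %d nuclei", id, nrow(nuc)))
      cbind(data.frame(subject_id = id, n_nuclei = nrow(nuc), flagged = FALSE),
            as.data.frame(fv))
    }, error = function(e) {
      message(sprintf("[extract] %s: ERROR %s", id, conditionMessage(e)))
      n_fail <<- n_fail + 1L
      na <- as.data.frame(as.list(stats::setNames(rep(NA_real_, 12), feature_names)))
      cbind(data.frame(subject_id = id, n_nuclei = 0L, flagged = TRUE), na)
    })
    rows[[i]] <- row
  }
  if (n_fail == length(paths)) stop("all input files failed", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(output))
    utils::write.csv(format(out, digits = 10, trim = TRUE, scientific = FALSE),
                     output, row.names = FALSE, quote = FALSE)
  out
}

## Attach labels to a feature table: `labels` is either the name of a column
## already present or a data.frame (subject_id, label) to join on subject_id.
join_labels <- function(table, labels) {
  if (is.data.frame(labels)) {
    if (is.null(labels$subject_id) || is.null(labels$label))
      stop("validation error: labels need subject_id and label columns", call. = FALSE)
    idx <- match(table$subject_id, labels$subject_id)
    if (any(is.na(idx)))
      stop("validation error: labels do not cover all subjects", call. = FALSE)
    table$label <- labels$label[idx]
  } else if (is.character(labels)) {
    if (!labels %in% colnames(table))
      stop("validation error: no label column '", labels, "'", call. = FALSE)
    table$label <- table[[labels]]
  }
  if (!length(table$label) || any(is.na(table$label) | table$label == ""))
    stop("validation error: empty or incomplete labels", call. = FALSE)
  table
}

#' Rank features between two labeled groups (KS report)
#'
#' @param table feature table (data.frame or CSV path) with feature columns.
#' @param labels either the name of a label column already in `table`
#'   (default `"label"`), or a data.frame `subject_id, label` to join.
#' @param alpha significance level.
#' @param output optional CSV path for the report.
#' @return a `ks_ranking` (see [rank_features()]).
#' @export
cmd_rank <- function(table, labels = "label", alpha = 0.05, output = NULL) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.csv(table)
  table <- join_labels(table, labels)
  ranked <- rank_features(table, alpha = alpha)
  if (!is.null(output)) write_ranking(ranked, output)
  ranked
}

#' Classify a labeled feature table with LOOCV SVMs
#'
#' Modes: `"groups"` ranks features, partitions them into SIG/PSIG/NSIG
#' significance tiers and evaluates the seven non-empty tier unions
#' (SIG, PSIG, NSIG, SIG-PSIG, SIG-NSIG, PSIG-NSIG, SIG-PSIG-NSIG);
#' `"search_all"` runs the exhaustive subset search; `"subset"` evaluates one
#' named subset. Results always carry both metric conventions.
#'
#' @param table feature table (data.frame or CSV path) with a label column
#'   (see [cmd_rank()] for `labels`).
#' @param labels label column name or `subject_id`/`label` data.frame.
#' @param mode `"groups"`, `"search_all"` or `"subset"`.
#' @param subset feature names (for `mode = "subset"`), e.g.
#'   `c("ARR","MSD","SDF","MFF")` or a single dash/comma-separated string.
#' @param config a [default_config()] (its `classifier` entry is used).
#' @param output optional JSON results path; the full configuration and seed
#'   are embedded in the file.
#' @return list with `mode`, `results`, `config`.
#' @export
cmd_classify <- function(table, labels = "label",
                         mode = c("groups", "search_all", "subset"),
                         subset = NULL, config = default_config(),
                         output = NULL) {
  mode <- match.arg(mode)
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.csv(table)
  table <- join_labels(table, labels)
  cc <- classifier_config(kernel = config$classifier$kernel,
                          cost = config$classifier$cost,
                          convention = config$classifier$convention)
  res <- switch(mode,
    groups = {
      ranked <- rank_features(table)
      tiers <- group_significance(ranked)
      combos <- list(SIG = "SIG", PSIG = "PSIG", NSIG = "NSIG",
                     `SIG-PSIG` = c("SIG", "PSIG"),
                     `SIG-NSIG` = c("SIG", "NSIG"),
                     `PSIG-NSIG` = c("PSIG", "NSIG"),
                     `SIG-PSIG-NSIG` = c("SIG", "PSIG", "NSIG"))
      out <- lapply(names(combos), function(nm) {
        feats <- unlist(tiers[combos[[nm]]], use.names = FALSE)
        if (!length(feats)) return(list(group = nm, features = character(0),
                                        accuracy = NA, note = "empty tier"))
        ev <- loocv_evaluate(table, feats, cc)
        list(group = nm, features = feats,
             accuracy = ev$accuracy,
             sensitivity = ev$metrics_standard$sensitivity,
             specificity = ev$metrics_standard$specificity,
             sens_pv = ev$metrics_predictive$sensitivity,
             spec_pv = ev$metrics_predictive$specificity)
      })
      names(out) <- names(combos)
      out
    },
    search_all = exhaustive_subset_search(table, cc),
    subset = {
      if (is.null(subset)) stop("validation error: subset required", call. = FALSE)
      if (length(subset) == 1L) subset <- strsplit(subset, "[-,]")[[1]]
      ev <- loocv_evaluate(table, subset, cc)
      list(subset = subset, accuracy = ev$accuracy,
           sensitivity = ev$metrics_standard$sensitivity,
           specificity = ev$metrics_standard$specificity,
           sens_pv = ev$metrics_predictive$sensitivity,
           spec_pv = ev$metrics_predictive$specificity)
    })
  out <- list(mode = mode, results = res,
              config = unclass(config), seed = config$seed)
  if (!is.null(output))
    jsonlite::write_json(out, output, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(out)
}

#' Synthesize a cohort of WAV recordings with ground-truth sidecars
#'
#' Writes one 16-bit PCM WAV per recording, a `labels.csv`, and a JSON
#' ground-truth sidecar per WAV (true nucleus timeline and features).
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_group recordings per group.
#' @param seed integer seed.
#' @param ... passed to [synth_audio_cohort()].
#' @return invisibly, the labels data.frame.
#' @export
cmd_synth <- function(out_dir, n_per_group = 10L, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- synth_audio_cohort(n_per_group, seed = seed, ...)
  labs <- data.frame(subject_id = character(0), label = character(0))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    id <- sprintf("%s_%02d", gsub("-", "", rec$label), ((i - 1L) %% n_per_group) + 1L)
    write_wav(rec$signal, path = file.path(out_dir, paste0(id, ".wav")))
    tr <- rec$truth
    jsonlite::write_json(
      list(subject_id = id, label = rec$label,
           nuclei = tr$nuclei[, c("onset", "offset", "mean_f0_hz")],
           features = tr$features[feature_names]),
      file.path(out_dir, paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    labs <- rbind(labs, data.frame(subject_id = id, label = rec$label))
  }
  utils::write.csv(labs, file.path(out_dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(labs)
}
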