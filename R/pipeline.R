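#' Simulate, preprocess and featurize a cohort in one pass
#'
#' Streams participant by participant (synthesize -> preprocess -> extract
#' features) so a full cohort never has to be held in memory as raw
#' recordings. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param blocks Feature banks to extract.
#' @return List: `features` (participants x features matrix), `block`
#'   (character vector labeling feature columns), `labels`, `participants`,
#'   `segment_durations` (s), `cycle_durations` (s, detected).
#' @export
cohort_features <- function(config = cohort_config(),
                            blocks = c("spatiotemporal", "time", "frequency")) {
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  labels <- c(rep(1L, config$n_case), rep(0L, config$n_control))
  feats <- NULL
  ids <- character(n)
  durs <- numeric(n)
  cyc <- numeric(n)
  for (i in seq_len(n)) {
    grp <- if (labels[i] == 1L) "case" else "control"
    id <- sprintf("%s_%03d", grp, if (grp == "case") i else i - config$n_case)
    p <- sample_gait_params(grp, config)
    rec <- synthesize_recording(p, config, participant_id = id,
                                group_label = labels[i])
    seg <- preprocess_recording(rec)
    v <- extract_features(seg, blocks)
    if (is.null(feats)) {
      feats <- matrix(NA_real_, n, length(v),
                      dimnames = list(NULL, names(v)))
      block_lab <- attr(v, "block")
    }
    feats[i, ] <- v
    ids[i] <- id
    durs[i] <- seg$duration_s
    cyc[i] <- seg$duration_s / 2
  }
  list(features = feats, block = block_labels(blocks),
       labels = labels, participants = ids,
       segment_durations = durs, cycle_durations = cyc)
}

# internal: block labels without recomputing features
block_labels <- function(blocks) {
  sizes <- c(spatiotemporal = 10L, time = 300L, frequency = 825L)
  unlist(lapply(blocks, function(b) rep(b, sizes[[b]])), use.names = FALSE)
}

#' Run configuration for the end-to-end analysis
#'
#' @param cohort A [cohort_config()] (the synthetic cohort source).
#' @param pca_threshold Cumulative explained variance for the time/frequency
#'   PCA reduction (default 0.95).
#' @param alpha Stepwise entry threshold (default 0.05).
#' @param k Cross-validation folds (default 10).
#' @param C Linear-SVM penalty (default 1).
#' @param sbs Run sequential backward selection before classification
#'   (default FALSE; see the methods vignette).
#' @param reduce Classification input for the time/frequency banks: "pca"
#'   (default; the retained 95%-variance PC scores) or "none" (raw
#'   features).
#' @param stages Which stages to run, a prefix of
#'   c("features", "inference", "classification").
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), pca_threshold = 0.95,
                       alpha = 0.05, k = 10, C = 1, sbs = FALSE,
                       reduce = c("pca", "none"),
                       stages = c("features", "inference", "classification")) {
  reduce <- match.arg(reduce)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(cohort = cohort, pca_threshold = pca_threshold,
                 alpha = alpha, k = k, C = C, sbs = sbs, reduce = reduce,
                 stages = stages),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()]; the `cohort` key mirrors
#' [cohort_config()] (the kinematic parameter table keeps its coded
#' default).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  yml <- yaml::read_yaml(path)
  cc <- do.call(cohort_config, yml$cohort %||% list())
  args <- yml[setdiff(names(yml), "cohort")]
  do.call(run_config, c(list(cohort = cc), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Simulates a cohort, preprocesses every participant to a two-cycle gait
#' segment, extracts the three feature banks, and then (per `stages`) runs
#' the inferential analysis (case/control summary table of the
#' spatiotemporal features; PCA at the configured cumulative variance plus
#' stepwise forward logistic regression with odds ratios and Nagelkerke R2
#' for each bank; PC-feature correlation tables) and the classification
#' stage (cross-validated linear SVM over all seven feature-bank
#' combinations with identical folds).
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; if given, all tables are written as
#'   CSV/JSON and a machine-readable run log is emitted. Outputs are
#'   deterministic given the seed, so re-running overwrites files with
#'   identical content.
#' @return A result bundle (list); see elements `cohort`, `group_table`,
#'   `logistic`, `pca`, `pc_correlations`, `classification`,
#'   `classification_table`.
#' @export
run_analysis <- function(config = run_config(), out_dir = NULL) {
  bundle <- list(config = config)
  ch <- cohort_features(config$cohort)
  bundle$cohort <- ch
  y <- ch$labels
  st <- ch$features[, ch$block == "spatiotemporal", drop = FALSE]
  tm <- ch$features[, ch$block == "time", drop = FALSE]
  fq <- ch$features[, ch$block == "frequency", drop = FALSE]

  if ("inference" %in% config$stages) {
    bundle$group_table <- group_summary(st, y)
    pca_tm <- pca_reduce(tm, config$pca_threshold)
    pca_fq <- pca_reduce(fq, config$pca_threshold)
    bundle$pca <- list(time = pca_tm, frequency = pca_fq)
    bundle$logistic <- list(
      spatiotemporal = stepwise_logistic(st, y, alpha = config$alpha),
      time = stepwise_logistic(retained_scores(pca_tm), y,
                               alpha = config$alpha),
      frequency = stepwise_logistic(retained_scores(pca_fq), y,
                                    alpha = config$alpha)
    )
    bundle$pc_correlations <- list(
      time = pc_feature_correlations(pca_tm, tm),
      frequency = pc_feature_correlations(pca_fq, fq)
    )
  }

  if ("classification" %in% config$stages) {
    if (config$reduce == "pca") {
      if (is.null(bundle$pca)) {
        bundle$pca <- list(time = pca_reduce(tm, config$pca_threshold),
                           frequency = pca_reduce(fq, config$pca_threshold))
      }
      # PC scores keep their natural within-block scale; the small
      # spatiotemporal block is z-scored onto a comparable footing
      blocks <- list(spatiotemporal = scale(st),
                     time = retained_scores(bundle$pca$time),
                     frequency = retained_scores(bundle$pca$frequency))
      standardize <- FALSE
    } else {
      blocks <- list(spatiotemporal = st, time = tm, frequency = fq)
      standardize <- TRUE
    }
    bundle$classification <- run_block_combinations(
      blocks, y, k = config$k, C = config$C, sbs = config$sbs,
      seed = config$cohort$seed + 1L, standardize = standardize)
    bundle$classification_table <- combination_table(bundle$classification)
  }

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

logistic_table <- function(fit) {
  k <- nrow(fit$terms)
  cbind(fit$terms,
        nagelkerke_r2 = rep(fit$nagelkerke_r2, k),
        n = rep(fit$n, k))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  ch <- bundle$cohort
  w(data.frame(participant_id = ch$participants, group = ch$labels,
               segment_duration_s = ch$segment_durations), "cohort_manifest.csv")
  feat <- data.frame(participant_id = ch$participants, ch$features,
                     check.names = FALSE)
  w(feat, "features.csv")
  if (!is.null(bundle$group_table)) {
    w(bundle$group_table, "spatiotemporal_group_table.csv")
    for (b in names(bundle$logistic)) {
      w(logistic_table(bundle$logistic[[b]]),
        sprintf("logistic_%s.csv", b))
    }
    for (b in names(bundle$pc_correlations)) {
      cm <- bundle$pc_correlations[[b]]
      w(data.frame(component = rownames(cm) %||% paste0("PC", seq_len(nrow(cm))),
                   cm, check.names = FALSE),
        sprintf("pc_feature_correlations_%s.csv", b))
    }
  }
  if (!is.null(bundle$classification)) {
    w(bundle$classification_table, "classification_table.csv")
    roc <- do.call(rbind, lapply(names(bundle$classification), function(nm) {
      cbind(combination = nm, bundle$classification[[nm]]$roc)
    }))
    w(roc, "roc_points.csv")
    per_fold <- lapply(bundle$classification, function(r) r$per_fold)
    jsonlite::write_json(per_fold, file.path(out_dir, "per_fold.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  log <- list(
    seed = bundle$config$cohort$seed,
    n_case = bundle$config$cohort$n_case,
    n_control = bundle$config$cohort$n_control,
    stages = bundle$config$stages,
    pca_threshold = bundle$config$pca_threshold,
    alpha = bundle$config$alpha, k = bundle$config$k, C = bundle$config$C,
    reduce = bundle$config$reduce, sbs = bundle$config$sbs,
    package_version = as.character(utils::packageVersion("gaitdep")),
    r_version = R.version.string
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
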