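# End-to-end orchestration: simulate/ingest -> preprocess -> train ->
# embed -> classify -> evaluate, with a reproducibility manifest.

# Derive a per-stage seed from the single pipeline seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 7919) %% 2147483647
}

#' Pipeline configuration
#'
#' One object holding everything a run needs. The single `seed` fans out
#' deterministically to every stochastic stage (synthetic records, weight
#' init, shuffling), so one integer reproduces a run bit for bit.
#'
#' @param source `"synthetic"` or `"wfdb"`.
#' @param synthetic for the synthetic source: list with `n_train`,
#'   `n_test` beat counts and optional `pattern`, `pvc_fraction`,
#'   `base_rr`, `prematurity`, plus noise amplitudes (see [noise_spec()]).
#' @param data_dir for the wfdb source: directory of `<id>.hea/.dat`
#'   records with `<id>.csv` beat annotation tables.
#' @param train_records,test_records,excluded_records record-id lists for
#'   the wfdb source; default the published MIT-BIH split.
#' @param denoise a [denoise_config()]; default applies no denoising.
#' @param embedder an [embedder_config()].
#' @param train a [train_config()].
#' @param K classifier votes (default 1).
#' @param seed master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = c("synthetic", "wfdb"),
                            synthetic = list(n_train = 400, n_test = 200),
                            data_dir = NULL,
                            train_records = MITDB_TRAIN,
                            test_records = MITDB_TEST,
                            excluded_records = MITDB_EXCLUDED,
                            denoise = denoise_config(),
                            embedder = embedder_config(),
                            train = train_config(),
                            K = 1, seed = 1) {
  source <- match.arg(source)
  if (source == "wfdb" && is.null(data_dir))
    stop("config error: data_dir is required for source = 'wfdb'")
  defaults <- list(n_train = 400, n_test = 200, pattern = "random",
                   pvc_fraction = 0.3, base_rr = 0.8, prematurity = 0.25,
                   gaussian_sd = 0.02, powerline_amp = 0.01,
                   fluorescent_amp = 0.01, baseline_amp = 0.05,
                   baseline_freq = 0.3)
  synthetic <- utils::modifyList(defaults, synthetic)
  structure(list(source = source, synthetic = synthetic,
                 data_dir = data_dir, train_records = train_records,
                 test_records = test_records,
                 excluded_records = excluded_records, denoise = denoise,
                 embedder = embedder, train = train, K = K, seed = seed),
            class = "pipeline_config")
}

synth_split <- function(cfg, n_beats, stage_seed) {
  s <- cfg$synthetic
  generate_record(
    n_beats,
    rhythm = rhythm_spec(s$pattern, s$pvc_fraction, s$base_rr,
                         s$prematurity),
    noise = noise_spec(s$gaussian_sd, s$powerline_amp, s$fluorescent_amp,
                       s$baseline_amp, s$baseline_freq, seed = stage_seed),
    record_id = paste0("synth", stage_seed))
}

load_wfdb_split <- function(dir, ids, window, dcfg, mapping) {
  sets <- lapply(ids, function(id) {
    rec <- read_wfdb_record(file.path(dir, paste0(id, ".hea")))
    ann <- read_beat_annotations(file.path(dir, paste0(id, ".csv")))
    rec <- apply_denoise(rec, dcfg)
    extract_beats(rec, ann, window = window, mapping = mapping)
  })
  do.call(c, sets)
}

#' Run the full detection pipeline
#'
#' Generates (or loads) training and test data, optionally denoises,
#' extracts and tanh-normalizes R-centred beats, trains the metric
#' embedder, embeds both splits, classifies test beats by KNN over the
#' training embeddings, and computes the five evaluation metrics. With
#' `out_dir` set, writes embeddings, predictions and metrics as CSV plus a
#' YAML manifest that [run_pipeline_from_manifest()] can replay.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @return List with `report` (a `metrics_report`), `model`, embeddings,
#'   predictions, and the per-epoch training `history`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  window <- cfg$embedder$input_length
  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cfg$seed, 3)
  if (cfg$source == "synthetic") {
    tr <- synth_split(cfg, cfg$synthetic$n_train, derive_seed(cfg$seed, 1))
    te <- synth_split(cfg, cfg$synthetic$n_test, derive_seed(cfg$seed, 2))
    train_beats <- extract_beats(apply_denoise(tr$record, cfg$denoise),
                                 tr$annotations, window = window)
    test_beats <- extract_beats(apply_denoise(te$record, cfg$denoise),
                                te$annotations, window = window)
  } else {
    if (!dir.exists(cfg$data_dir))
      stop("data error: directory not found: ", cfg$data_dir)
    ids <- sub("\\.hea$", "", basename(list.files(cfg$data_dir,
                                                  pattern = "\\.hea$")))
    if (length(ids) == 0)
      stop("data error: no .hea records in ", cfg$data_dir)
    part <- partition_records(ids, cfg$train_records, cfg$test_records,
                              cfg$excluded_records)
    if (length(part$train) == 0 || length(part$test) == 0)
      stop("data error: empty train or test partition")
    train_beats <- load_wfdb_split(cfg$data_dir, part$train, window,
                                   cfg$denoise, default_label_map())
    test_beats <- load_wfdb_split(cfg$data_dir, part$test, window,
                                  cfg$denoise, default_label_map())
  }
  if (any(train_beats$label == "pvc") == FALSE)
    stop("data error: training split contains no PVC beats")
  train_beats <- normalize_beats(train_beats)
  test_beats <- normalize_beats(test_beats)
  res <- train_and_eval(train_beats, test_beats, tcfg, cfg$embedder,
                        K = cfg$K)
  out <- list(report = res$report, model = res$model,
              train_emb = res$train_emb, test_emb = res$test_emb,
              pred = res$pred, truth = as.character(test_beats$label),
              history = res$model$history, config = cfg)
  if (!is.null(out_dir)) write_artifacts(out, cfg, out_dir)
  out
}

config_to_list <- function(cfg) {
  list(source = cfg$source, synthetic = cfg$synthetic,
       data_dir = cfg$data_dir,
       train_records = cfg$train_records, test_records = cfg$test_records,
       excluded_records = cfg$excluded_records,
       denoise = unclass(cfg$denoise),
       embedder = list(
         channels = vapply(cfg$embedder$groups, `[[`, numeric(1),
                           "channels"),
         kernel_sizes = vapply(cfg$embedder$groups, `[[`, numeric(1),
                               "kernel_size"),
         pool = cfg$embedder$groups[[1]]$pool,
         input_length = cfg$embedder$input_length),
       train = unclass(cfg$train), K = cfg$K, seed = cfg$seed)
}

list_to_config <- function(l) {
  pipeline_config(
    source = l$source, synthetic = l$synthetic, data_dir = l$data_dir,
    train_records = unlist(l$train_records),
    test_records = unlist(l$test_records),
    excluded_records = unlist(l$excluded_records),
    denoise = do.call(denoise_config, lapply(l$denoise, unlist)),
    embedder = embedder_config(unlist(l$embedder$channels),
                               unlist(l$embedder$kernel_sizes),
                               l$embedder$pool, l$embedder$input_length),
    train = do.call(train_config,
                    l$train[setdiff(names(l$train), "optimizer")]),
    K = l$K, seed = l$seed)
}

write_artifacts <- function(out, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(out$train_emb),
                   file.path(out_dir, "train_embeddings.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(out$test_emb),
                   file.path(out_dir, "test_embeddings.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(truth = out$truth, pred = out$pred),
                   file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics_row(out$report),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(out$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config_to_list(cfg), file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Replay a pipeline run from its manifest
#'
#' @param manifest_path path to a `manifest.yaml` written by
#'   [run_pipeline()].
#' @param out_dir optional artifact directory for the replay.
#' @return The [run_pipeline()] result.
#' @export
run_pipeline_from_manifest <- function(manifest_path, out_dir = NULL) {
  run_pipeline(list_to_config(yaml::read_yaml(manifest_path)), out_dir)
}
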