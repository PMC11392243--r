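# End-to-end orchestration: segment -> flow -> features -> fuse -> detect
# -> evaluate, with manifests and deterministic reruns. Subjects are
# processed one at a time so a full-resolution cohort never has to sit in
# memory at once.

#' Pipeline configuration
#'
#' @param cohort A `phantom_cohort`, or a manifest data.frame with columns
#'   `subject_id`, `view`, `label`, `path` (both views per subject).
#' @param out_dir Run directory for all artifacts.
#' @param train_cohort Optional `phantom_cohort` used to train the
#'   segmenter and the per-view backbones (kept disjoint from `cohort` so
#'   feature learning never sees the evaluation subjects).
#' @param segmenter Optional pre-trained `ef_unet`; required when `cohort`
#'   is a manifest (no ground-truth masks to train from).
#' @param backbones Optional named list `list(A2C =, A4C =)` of trained
#'   `ef_backbone`s.
#' @param image_size Frame side length every stage operates at.
#' @param seg Segmenter settings: `depth`, `base_channels`, `epochs`,
#'   `lr`, `frames_per_subject` (training frames sampled per subject).
#' @param tsn Temporal-network settings: `k` (snippets), `epochs`, `lr`.
#' @param flow [flow_params()].
#' @param clip Flow encoding clip (pixels/frame).
#' @param classifiers,grids Classifier bank selection and grids.
#' @param n_folds Outer cross-validation folds.
#' @param seed Master seed; per-stage seeds (segmenter, backbone, snippets,
#'   folds, classifiers) are derived from it.
#' @param verbose Log stage progress to stderr.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(cohort, out_dir, train_cohort = NULL,
                            segmenter = NULL, backbones = NULL,
                            image_size = 224L,
                            seg = list(), tsn = list(), flow = flow_params(),
                            clip = 20, classifiers = classifier_names(),
                            grids = default_grids(), n_folds = 5L, seed = 17L,
                            verbose = TRUE) {
  seg_def <- list(depth = 3L, base_channels = 4L, epochs = 8L, lr = 1e-3,
                  frames_per_subject = 3L)
  seg <- utils::modifyList(seg_def, seg)
  tsn_def <- list(k = 7L, epochs = 15L, lr = 1e-3)
  tsn <- utils::modifyList(tsn_def, tsn)
  cfg <- structure(list(
    cohort = cohort, out_dir = out_dir, train_cohort = train_cohort,
    segmenter = segmenter, backbones = backbones,
    image_size = as.integer(image_size), seg = seg, tsn = tsn, flow = flow,
    clip = clip, classifiers = classifiers, grids = grids,
    n_folds = as.integer(n_folds), seed = as.integer(seed), verbose = verbose
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (inherits(cfg$cohort, "phantom_cohort")) {
    if (cfg$cohort$template$image_size != cfg$image_size) {
      stop_config("image_size", "does not match the cohort's phantom image size")
    }
  } else if (is.data.frame(cfg$cohort)) {
    need <- c("subject_id", "view", "label", "path")
    if (!all(need %in% names(cfg$cohort))) {
      stop_config("cohort", "manifest must have subject_id, view, label, path columns")
    }
    for (sid in unique(cfg$cohort$subject_id)) {
      vv <- cfg$cohort$view[cfg$cohort$subject_id == sid]
      for (v in c("A2C", "A4C")) {
        if (!v %in% vv) {
          stop_config("cohort", sprintf("subject %s is missing its %s view", sid, v))
        }
      }
    }
    miss <- !file.exists(cfg$cohort$path) & !dir.exists(cfg$cohort$path)
    if (any(miss)) {
      stop_config("cohort", sprintf("path does not exist: %s", cfg$cohort$path[which(miss)[1]]))
    }
    if (is.null(cfg$segmenter)) {
      stop_config("segmenter", "is required for manifest input (no masks to train on)")
    }
  } else {
    stop_config("cohort", "must be a phantom_cohort or a manifest data.frame")
  }
  if (is.null(cfg$segmenter) && is.null(cfg$train_cohort)) {
    stop_config("train_cohort", "is required when no trained segmenter is supplied")
  }
  if (is.null(cfg$backbones) && is.null(cfg$train_cohort)) {
    stop_config("train_cohort", "is required when no trained backbones are supplied")
  }
  invisible(cfg)
}

pipe_log <- function(cfg, stage, msg, t0 = NULL) {
  if (!isTRUE(cfg$verbose)) return(invisible())
  el <- if (is.null(t0)) "" else sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0)
  message(sprintf("[echoflow] %-10s %s%s", stage, msg, el))
}

# realize one subject of either cohort flavour into per-view sequences
pipeline_subject_views <- function(cfg, subj) {
  if (inherits(subj, "list") && !is.null(subj$configs)) {
    return(phantom_realize(subj))
  }
  rows <- cfg$cohort[cfg$cohort$subject_id == subj, ]
  out <- list()
  for (v in c("A2C", "A4C")) {
    r <- rows[rows$view == v, ][1, ]
    out[[v]] <- list(sequence = read_echo(r$path, input_size = cfg$image_size,
                                          view = v, subject_id = r$subject_id,
                                          label = r$label),
                     truth = NULL)
  }
  out
}

# sequence -> masked frames -> flow -> 8-bit encodings
pipeline_encode_view <- function(cfg, segmenter, seq_obj) {
  seg <- segment_sequence(segmenter, seq_obj)
  fields <- flow_sequence(seg$masked, cfg$flow)
  encode_flow_sequence(fields, clip = cfg$clip)
}

train_pipeline_segmenter <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  frames <- list()
  masks <- list()
  for (subj in cfg$train_cohort$subjects) {
    views <- phantom_realize(subj)
    for (v in names(views)) {
      n <- length(views[[v]]$sequence$frames)
      fpc <- subj$configs[[v]]$frames_per_cycle
      # sample frames across one cycle so systole and diastole both appear
      pick <- unique(round(seq(1, min(fpc, n), length.out = cfg$seg$frames_per_subject)))
      for (t in pick) {
        frames[[length(frames) + 1L]] <- views[[v]]$sequence$frames[[t]]
        masks[[length(masks) + 1L]] <- views[[v]]$truth$wall_masks[[t]]
      }
    }
  }
  ucfg <- unet_config(depth = cfg$seg$depth, base_channels = cfg$seg$base_channels,
                      input_size = cfg$image_size)
  seg <- build_segmenter(ucfg, seed = derive_seed(cfg$seed, "seg-init"))
  seg <- train_segmenter(seg, frames, masks, epochs = cfg$seg$epochs,
                         lr = cfg$seg$lr, seed = derive_seed(cfg$seed, "seg-train"))
  pipe_log(cfg, "segment", sprintf("trained U-Net on %d frames, %d epochs",
                                   length(frames), cfg$seg$epochs), t0)
  seg
}

train_pipeline_backbones <- function(cfg, segmenter) {
  t0 <- as.numeric(Sys.time())
  items <- list(A2C = list(), A4C = list())
  for (subj in cfg$train_cohort$subjects) {
    views <- phantom_realize(subj)
    for (v in names(views)) {
      enc <- pipeline_encode_view(cfg, segmenter, views[[v]]$sequence)
      items[[v]][[length(items[[v]]) + 1L]] <- list(encodings = enc, label = subj$label)
    }
  }
  backbones <- list()
  train_labels <- vapply(items$A2C, function(it) it$label, character(1))
  for (v in c("A2C", "A4C")) {
    bb <- build_backbone(seed = derive_seed(cfg$seed, paste0("bb-init-", v)))
    backbones[[v]] <- train_backbone(
      bb, items[[v]],
      config = consensus_config(k = cfg$tsn$k, sampling_mode = "random"),
      epochs = cfg$tsn$epochs, lr = cfg$tsn$lr,
      seed = derive_seed(cfg$seed, paste0("bb-train-", v)),
      class_levels = class_level_order(train_labels, "RWMA")
    )
  }
  pipe_log(cfg, "features", sprintf("trained %d-snippet backbones on %d subjects/view",
                                    cfg$tsn$k, length(items$A2C)), t0)
  backbones
}

#' Run the full RWMA detection pipeline
#'
#' Stages, in order: (train and) apply the U-Net segmenter; dense optical
#' flow on the masked frames; 8-bit flow encoding; per-view temporal
#' ConvNet features (k centered snippets, consensus average); A2C+A4C
#' fusion to 2048-d; stratified k-fold classifier bank with grid search;
#' metric reports. All artifacts (features, predictions, reports, manifest
#' with parameters and seeds) are written under `config$out_dir`; rerunning
#' with an identical config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with the detection `report`, the fused `features` matrix,
#'   `labels`, the trained `segmenter` and `backbones`, and output `paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  segmenter <- cfg$segmenter
  if (is.null(segmenter)) segmenter <- train_pipeline_segmenter(cfg)
  backbones <- cfg$backbones
  if (is.null(backbones)) backbones <- train_pipeline_backbones(cfg, segmenter)

  subjects <- if (inherits(cfg$cohort, "phantom_cohort")) {
    cfg$cohort$subjects
  } else {
    as.list(unique(cfg$cohort$subject_id))
  }
  n <- length(subjects)
  feats <- matrix(0, n, 2048L)
  labels <- character(n)
  ids <- character(n)
  t0 <- as.numeric(Sys.time())
  for (i in seq_len(n)) {
    views <- pipeline_subject_views(cfg, subjects[[i]])
    fv <- list()
    for (v in c("A2C", "A4C")) {
      enc <- pipeline_encode_view(cfg, segmenter, views[[v]]$sequence)
      fv[[v]] <- extract_features(backbones[[v]], enc,
                                  consensus_config(k = cfg$tsn$k), view = v)
    }
    fused <- fuse_views(fv$A2C, fv$A4C)
    feats[i, ] <- fused$values
    labels[i] <- views$A2C$sequence$label
    ids[i] <- views$A2C$sequence$subject_id
    if (i %% 10 == 0) pipe_log(cfg, "features", sprintf("%d/%d subjects", i, n), t0)
  }
  pipe_log(cfg, "features", sprintf("extracted fused features for %d subjects", n), t0)

  plan <- make_cv_plan(labels, n_folds = cfg$n_folds,
                       seed = derive_seed(cfg$seed, "folds"))
  t0 <- as.numeric(Sys.time())
  report <- run_detection(feats, labels, plan, classifiers = cfg$classifiers,
                          spaces = cfg$grids,
                          seed = derive_seed(cfg$seed, "classifiers"))
  pipe_log(cfg, "detect", sprintf("%d classifiers under %d-fold CV",
                                  length(cfg$classifiers), cfg$n_folds), t0)

  # artifacts
  fdf <- data.frame(subject_id = ids, label = labels, feats,
                    stringsAsFactors = FALSE)
  names(fdf) <- c("subject_id", "label", sprintf("f%04d", seq_len(2048L)))
  write.csv(fdf, file.path(cfg$out_dir, "features.csv"), row.names = FALSE)
  pred <- report$predictions
  pred$subject_id <- ids[pred$subject]
  write.csv(pred, file.path(cfg$out_dir, "predictions.csv"), row.names = FALSE)
  rep_json <- list(
    overall = lapply(report$overall, function(o) {
      list(confusion = o$confusion[c("TP", "TN", "FP", "FN")],
           metrics = as.list(o$metrics), auc = o$auc)
    }),
    summary = lapply(report$summary, function(s) s)
  )
  jsonlite::write_json(rep_json, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  manifest <- list(
    package_version = as.character(utils::packageVersion("echoflow")),
    n_subjects = n, image_size = cfg$image_size, seed = cfg$seed,
    seg = cfg$seg, tsn = cfg$tsn,
    flow = unclass(cfg$flow), clip = cfg$clip, n_folds = cfg$n_folds,
    classifiers = cfg$classifiers
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)

  list(report = report, features = feats, labels = labels, subject_ids = ids,
       segmenter = segmenter, backbones = backbones,
       paths = list(
         features = file.path(cfg$out_dir, "features.csv"),
         predictions = file.path(cfg$out_dir, "predictions.csv"),
         report = file.path(cfg$out_dir, "report.json"),
         manifest = file.path(cfg$out_dir, "manifest.json")
       ))
}
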