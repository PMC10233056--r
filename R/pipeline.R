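# End-to-end orchestration: segment (delayed phase) -> representative
# slice/crop -> characterize -> size measurement -> rule inference ->
# evaluation, with file-based stage interfaces so each stage is
# independently inspectable and cached runs are resumable.

#' Pipeline configuration
#'
#' Desk-scale defaults: a reduced segmentation net (2 stages, base width 8,
#' attention on) and a reduced characterizer, suitable for the 64 x 64
#' phantom presets; scale `n_down`/`base_width`/`steps` up for larger data.
#'
#' @param n_folds Patient folds; fold `test_fold` is held out for testing,
#'   the rest train the models.
#' @param test_fold Which fold to hold out.
#' @param seg_n_down,seg_base_width,seg_attention,seg_steps,seg_batch,seg_lr
#'   Segmentation net architecture and training settings.
#' @param threshold Binarization threshold for predicted probability maps;
#'   `NULL` (default) selects the threshold maximizing the median
#'   training-patient DICE over a 0.2-0.8 sweep, mirroring how an
#'   appropriate operating threshold is chosen from the DICE-vs-threshold
#'   curve.
#' @param min_component Minimum predicted component size (voxels).
#' @param char Characterizer architecture ([char_config()]).
#' @param char_steps,char_batch,char_lr Characterizer training settings.
#' @param adaptive Use the phase-routed adaptive loss.
#' @param call_threshold Feature-call probability threshold.
#' @param margin Crop margin fraction.
#' @param policy LI-RADS ambiguity policy.
#' @param loss Segmentation [loss_config()]. The pipeline's training default
#'   lowers the Lovasz trigger to 0.1 so the fine-tuning stage starts only
#'   once the main loss is well down.
#' @param seed Global pipeline seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_folds = 3L, test_fold = 1L,
                            seg_n_down = 2L, seg_base_width = 8L,
                            seg_attention = TRUE, seg_steps = 300L,
                            seg_batch = 8L, seg_lr = 1e-3,
                            threshold = NULL, min_component = 5L,
                            char = char_config(), char_steps = 250L,
                            char_batch = 8L, char_lr = 2e-3,
                            adaptive = TRUE, call_threshold = 0.5,
                            margin = 0.25, policy = "prefer_washout_rule",
                            loss = loss_config(lovasz_trigger = 0.1),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

.read_manifest <- function(data_dir) {
  f <- file.path(data_dir, "lesions_detail.csv")
  if (!file.exists(f)) stop("missing lesion table: ", f)
  utils::read.csv(f)
}

.dataset_patients <- function(data_dir) {
  fs <- list.files(data_dir, pattern = "^patient[0-9]+_mask\\.nii\\.gz$")
  sort(as.integer(sub("^patient([0-9]+)_.*$", "\\1", fs)))
}

# Ground-truth lesion crops of one study; one crop per phase per lesion,
# labels routed per phase. Returns list(crops, labels, x, lesion_key).
.gt_lesion_crops <- function(study, lesion_rows, margin = 0.25,
                             out_size = 64L) {
  comps <- extract_components(study$mask, min_voxels = 1L)
  pre <- lapply(study$phases, preprocess_volume)
  crops <- list(); labs <- list(); xs <- integer(0); keys <- character(0)
  for (i in seq_len(nrow(lesion_rows))) {
    r <- lesion_rows[i, ]
    lab_id <- comps$labels[r$center_y, r$center_x, r$center_z]
    if (lab_id == 0) next
    cmask <- comps$labels == lab_id
    for (ph in c("arterial", "portal_venous", "delayed")) {
      s <- select_representative_slice(cmask)
      crop <- crop_resize(pre[[ph]][, , s], cmask[, , s] + 0,
                          margin = margin, out_size = out_size)
      crops[[length(crops) + 1]] <- crop
      if (ph == "arterial") {
        labs[[length(labs) + 1]] <- data.frame(aphe = r$B1, washout = NA,
                                               capsule = NA)
        xs <- c(xs, 0L)
      } else {
        labs[[length(labs) + 1]] <- data.frame(aphe = NA, washout = r$B2,
                                               capsule = r$B3)
        xs <- c(xs, 1L)
      }
      keys <- c(keys, sprintf("%d_%d", r$patient_id, r$lesion_id))
    }
  }
  list(crops = crops, labels = if (length(labs)) do.call(rbind, labs) else
         data.frame(aphe = logical(0), washout = logical(0),
                    capsule = logical(0)),
       x = xs, lesion_key = keys)
}

#' Run the full scoring pipeline on a phantom dataset
#'
#' Trains the reduced segmentation network on the delayed-phase 2.5D windows
#' of the training folds, trains the characterizer on ground-truth lesion
#' crops of the same patients, then scores every held-out patient fully
#' automatically: segment, extract components, pick the representative slice
#' per phase, crop, characterize, measure size, infer the LI-RADS category.
#' Writes `scores.csv`, per-patient predicted masks, and `eval.json` under
#' `out_dir`; reruns with an unchanged configuration reuse cached stage
#' outputs.
#'
#' @param data_dir Dataset directory from [generate_dataset()].
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, `list(scores, eval, seg_model, char_model)`.
#' @export
run_pipeline <- function(data_dir, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- digest_config(config)
  hash_file <- file.path(out_dir, "config_hash.json")
  cached_ok <- file.exists(hash_file) &&
    identical(jsonlite::read_json(hash_file)$hash, cfg_hash)
  jsonlite::write_json(list(hash = cfg_hash, seed = config$seed),
                       hash_file, auto_unbox = TRUE)

  detail <- .read_manifest(data_dir)
  patients <- .dataset_patients(data_dir)
  split <- split_folds(patients, n_folds = config$n_folds,
                       seed = derive_seed(config$seed, 1L))
  fp <- fold_patients(split, config$test_fold)
  studies <- lapply(patients, function(p) {
    st <- read_study(data_dir, p)
    st$lesions <- detail[detail$patient_id == p, , drop = FALSE]
    st
  })
  names(studies) <- as.character(patients)

  # ---- stage 1: segmentation training --------------------------------------
  seg_cache <- file.path(out_dir, "seg_model.rds")
  if (cached_ok && file.exists(seg_cache)) {
    seg_model <- readRDS(seg_cache)
  } else {
    tr_windows <- build_window_dataset(studies[as.character(fp$train)])
    d <- dim(studies[[1]]$phases$delayed)
    sc <- seg_config(n_down = config$seg_n_down,
                     base_width = config$seg_base_width,
                     attention = config$seg_attention,
                     input_size = d[1:2])
    seg_model <- fit_segmentation(tr_windows$windows, tr_windows$labels, sc,
                                  config$loss, steps = config$seg_steps,
                                  batch_size = config$seg_batch,
                                  lr = config$seg_lr,
                                  seed = derive_seed(config$seed, 2L))
    saveRDS(seg_model, seg_cache)
  }

  # ---- stage 1b: operating-threshold selection on training patients --------
  threshold <- config$threshold
  thr_file <- file.path(out_dir, "threshold.json")
  if (is.null(threshold)) {
    if (cached_ok && file.exists(thr_file)) {
      threshold <- jsonlite::read_json(thr_file)$threshold
    } else {
      cal <- utils::head(fp$train, 8)
      grid <- seq(0.2, 0.8, by = 0.1)
      cal_probs <- lapply(cal, function(p) {
        st <- studies[[as.character(p)]]
        list(pr = predict_volume(seg_model,
                                 preprocess_volume(st$phases$delayed)),
             mask = st$mask)
      })
      med <- vapply(grid, function(thr) {
        stats::median(vapply(cal_probs, function(cp)
          patient_dice(binarize(cp$pr, thr), cp$mask), 0))
      }, 0)
      threshold <- grid[which.max(med)]
    }
  }
  jsonlite::write_json(list(threshold = threshold), thr_file,
                       auto_unbox = TRUE)

  # ---- stage 2: characterizer training -------------------------------------
  char_cache <- file.path(out_dir, "char_model.rds")
  if (cached_ok && file.exists(char_cache)) {
    char_model <- readRDS(char_cache)
  } else {
    tr <- list(crops = list(),
               labels = NULL, x = integer(0))
    for (p in fp$train) {
      st <- studies[[as.character(p)]]
      if (nrow(st$lesions) == 0) next
      g <- .gt_lesion_crops(st, st$lesions, margin = config$margin)
      tr$crops <- c(tr$crops, g$crops)
      tr$labels <- rbind(tr$labels, g$labels)
      tr$x <- c(tr$x, g$x)
    }
    if (length(tr$crops) == 0) stop("no training lesions for characterization")
    char_model <- fit_characterizer(tr$crops, tr$labels, tr$x,
                                    config$char, adaptive = config$adaptive,
                                    steps = config$char_steps,
                                    batch_size = config$char_batch,
                                    lr = config$char_lr,
                                    seed = derive_seed(config$seed, 3L))
    saveRDS(char_model, char_cache)
  }

  # ---- stage 3: automatic scoring of held-out patients ---------------------
  scores_file <- file.path(out_dir, "scores.csv")
  rows <- list()
  patient_rows <- list()
  dice_rows <- list()
  cat_pairs <- list()
  for (p in fp$test) {
    st <- studies[[as.character(p)]]
    pre <- lapply(st$phases, preprocess_volume)
    probs <- predict_volume(seg_model, pre$delayed)
    mask <- binarize(probs, threshold)
    RNifti::writeNifti(RNifti::asNifti(mask + 0),
                       file.path(out_dir,
                                 sprintf("patient%03d_predmask.nii.gz", p)))
    comps <- extract_components(mask, min_voxels = config$min_component)
    truth_comps <- extract_components(st$mask, min_voxels = 1L)
    ll <- lesion_level_metrics(comps$labels, truth_comps$labels)
    cts <- .pixel_counts(mask, st$mask)
    dice_rows[[length(dice_rows) + 1]] <-
      data.frame(patient_id = p, TP = cts[["TP"]], FP = cts[["FP"]],
                 FN = cts[["FN"]], dice = patient_dice(mask, st$mask))
    patient_rows[[length(patient_rows) + 1]] <-
      data.frame(patient_id = p, n_true = length(truth_comps$ids),
                 n_detected = ll$TP, n_pred = length(comps$ids))
    for (id in comps$ids) {
      cmask <- comps$labels == id
      crops <- list()
      for (ph in c("arterial", "portal_venous", "delayed")) {
        s <- select_representative_slice(cmask)
        crops[[length(crops) + 1]] <- crop_resize(pre[[ph]][, , s],
                                                  cmask[, , s] + 0,
                                                  margin = config$margin,
                                                  out_size = 64L)
        names(crops)[length(crops)] <- ph
      }
      feat <- predict_features(char_model, crops,
                               call_threshold = config$call_threshold)
      size_mm <- measure_lesion_size(cmask, st$spacing_mm)
      inf <- infer_lirads(feat$B1, feat$B2, feat$B3, size_mm,
                          policy = config$policy)
      # ground-truth lesion this component overlaps (if any)
      ov <- truth_comps$labels[cmask]
      gt_label <- NA_character_; gt_lesion <- NA_integer_
      if (any(ov > 0)) {
        gt_id <- as.integer(names(which.max(table(ov[ov > 0]))))
        gt_vox <- which(truth_comps$labels == gt_id, arr.ind = TRUE)[1, ]
        le <- st$lesions
        hit <- which(le$center_y == gt_vox[1] & le$center_x == gt_vox[2] &
                       le$center_z == gt_vox[3])
        if (length(hit) == 0 && nrow(le) > 0) {
          dd <- (le$center_y - gt_vox[1])^2 + (le$center_x - gt_vox[2])^2 +
            (le$center_z - gt_vox[3])^2
          hit <- which.min(dd)
        }
        if (length(hit) >= 1) {
          gt_label <- le$resolved[hit[1]]
          gt_lesion <- le$lesion_id[hit[1]]
        }
      }
      rows[[length(rows) + 1]] <-
        data.frame(patient_id = p, component = id,
                   p_aphe = feat$p_aphe, p_washout = feat$p_washout,
                   p_capsule = feat$p_capsule,
                   B1 = feat$B1, B2 = feat$B2, B3 = feat$B3,
                   size_mm = size_mm, category = inf$value,
                   resolved = inf$resolved, gt_lesion = gt_lesion,
                   gt_label = gt_label)
      if (!is.na(gt_label))
        cat_pairs[[length(cat_pairs) + 1]] <- c(inf$resolved, gt_label)
    }
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = integer(0), component = integer(0),
               p_aphe = numeric(0), p_washout = numeric(0),
               p_capsule = numeric(0), B1 = logical(0), B2 = logical(0),
               B3 = logical(0), size_mm = numeric(0),
               category = character(0), resolved = character(0),
               gt_lesion = integer(0), gt_label = character(0))
  utils::write.csv(scores, scores_file, row.names = FALSE)

  dice_df <- do.call(rbind, dice_rows)
  pat_df <- do.call(rbind, patient_rows)
  lesion_tot <- list(TP = sum(pat_df$n_detected),
                     FN = sum(pat_df$n_true) - sum(pat_df$n_detected))
  cat_mat <- NULL; cat_acc <- NA_real_
  if (length(cat_pairs)) {
    cp <- do.call(rbind, cat_pairs)
    keep <- cp[, 1] %in% c("LR3", "LR4", "LR5") &
      cp[, 2] %in% c("LR3", "LR4", "LR5")
    if (any(keep)) {
      cm <- confusion_and_accuracy(cp[keep, 1], cp[keep, 2])
      cat_mat <- cm$matrix; cat_acc <- cm$accuracy
    }
  }
  eval_rep <- list(
    per_patient_dice = dice_df,
    median_dice = stats::median(dice_df$dice),
    local_dice_mean = local_dice_mean(dice_df),
    global_dice = global_dice(dice_df),
    patient_level = patient_level_metrics(pat_df),
    lesion_recall = if (sum(pat_df$n_true) > 0)
      lesion_tot$TP / sum(pat_df$n_true) else NA_real_,
    category_accuracy = cat_acc,
    threshold_used = threshold,
    n_scored = nrow(scores))
  jsonlite::write_json(
    list(median_dice = eval_rep$median_dice,
         threshold_used = threshold,
         local_dice_mean = eval_rep$local_dice_mean,
         global_dice = eval_rep$global_dice,
         lesion_recall = eval_rep$lesion_recall,
         category_accuracy = eval_rep$category_accuracy,
         n_scored = eval_rep$n_scored),
    file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(scores = scores, eval = eval_rep, seg_model = seg_model,
                 char_model = char_model, confusion = cat_mat,
                 test_patients = fp$test))
}

#' Adaptive-learning ablation harness
#'
#' Trains the characterizer under each requested variant (adaptive loss
#' on/off x vgg/resnet backbone) on the same ground-truth crops, split and
#' seed, and reports each variant's per-feature and LI-RADS accuracy on the
#' held-out lesions (ground-truth sizes isolate characterization error).
#'
#' @param data_dir Dataset directory from [generate_dataset()].
#' @param variants Data frame with columns `adaptive` (logical) and
#'   `backbone` (`"vgg"`/`"resnet"`); defaults to adaptive on/off on the vgg
#'   backbone.
#' @param config A [pipeline_config()] (characterizer settings are used).
#' @return Data frame: one row per variant with feature and category
#'   accuracies.
#' @export
run_ablation <- function(data_dir,
                         variants = data.frame(adaptive = c(TRUE, FALSE),
                                               backbone = "vgg"),
                         config = pipeline_config()) {
  detail <- .read_manifest(data_dir)
  patients <- .dataset_patients(data_dir)
  split <- split_folds(patients, n_folds = config$n_folds,
                       seed = derive_seed(config$seed, 1L))
  fp <- fold_patients(split, config$test_fold)
  collect <- function(pats) {
    out <- list(crops = list(), labels = NULL, x = integer(0),
                full = NULL)
    for (p in pats) {
      st <- read_study(data_dir, p)
      rows <- detail[detail$patient_id == p, , drop = FALSE]
      if (nrow(rows) == 0) next
      g <- .gt_lesion_crops(st, rows, margin = config$margin)
      out$crops <- c(out$crops, g$crops)
      out$labels <- rbind(out$labels, g$labels)
      out$x <- c(out$x, g$x)
      out$full <- rbind(out$full,
                        rows[match(g$lesion_key,
                                   sprintf("%d_%d", rows$patient_id,
                                           rows$lesion_id)), ])
    }
    out
  }
  tr <- collect(fp$train)
  te <- collect(fp$test)
  res <- list()
  for (v in seq_len(nrow(variants))) {
    adap <- variants$adaptive[v]
    bb <- as.character(variants$backbone[v])
    cc <- config$char; cc$backbone <- bb
    labels <- tr$labels
    if (!adap) {
      # non-adaptive baseline: every head trained on every crop, with the
      # lesion's labels attached regardless of phase
      labels <- data.frame(aphe = tr$full$B1, washout = tr$full$B2,
                           capsule = tr$full$B3)
    }
    mdl <- fit_characterizer(tr$crops, labels, tr$x, cc, adaptive = adap,
                             steps = config$char_steps,
                             batch_size = config$char_batch,
                             lr = config$char_lr,
                             seed = derive_seed(config$seed, 4L))
    # per-lesion fused predictions on held-out lesions
    keys <- unique(te$full$lesion_id + 1000 * te$full$patient_id)
    ok_feat <- c(aphe = 0, washout = 0, capsule = 0); n_les <- 0
    cat_ok <- 0
    for (k in keys) {
      sel <- which(te$full$lesion_id + 1000 * te$full$patient_id == k)
      # reconstruct the named per-phase crop list for this lesion
      crops <- te$crops[sel]
      names(crops) <- rep(c("arterial", "portal_venous", "delayed"),
                          length.out = length(sel))
      feat <- predict_features(mdl, crops,
                               call_threshold = config$call_threshold)
      row <- te$full[sel[1], ]
      n_les <- n_les + 1
      ok_feat <- ok_feat + c(feat$B1 == row$B1, feat$B2 == row$B2,
                             feat$B3 == row$B3)
      inf <- infer_lirads(feat$B1, feat$B2, feat$B3, row$diameter_mm,
                          policy = config$policy)
      cat_ok <- cat_ok + (inf$resolved == row$resolved)
    }
    res[[v]] <- data.frame(adaptive = adap, backbone = bb,
                           n_lesions = n_les,
                           acc_aphe = ok_feat[["aphe"]] / n_les,
                           acc_washout = ok_feat[["washout"]] / n_les,
                           acc_capsule = ok_feat[["capsule"]] / n_les,
                           macro_feature_acc = mean(ok_feat) / n_les,
                           category_accuracy = cat_ok / n_les)
  }
  do.call(rbind, res)
}

# Stable hash of a configuration for cache validation.
digest_config <- function(config) {
  s <- as.character(jsonlite::toJSON(config[order(names(config))],
                                     auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  u <- utf8ToInt(s)
  sprintf("%d-%.0f", nchar(s), sum(u * (seq_along(u) %% 9973)))
}
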