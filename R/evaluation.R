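## End-to-end pipeline: spike encoding of a chunked dataset, model fitting
## per architecture, session-wise cross-validation, accuracy vs. stimulus
## duration, and JSON run records.

#' Encode a list of gesture samples into spike form
#'
#' EMG chunks are delta-modulated and rasterized to 16 channels
#' (8 x UP/DOWN) on the 1 ms tick grid; DVS chunks are cropped to 40x40,
#' parity-subsampled into four 20x20 streams (merged polarity, as on the
#' crossbar MLP cores) and kept as event streams — per-tick rasters are
#' materialized lazily in batches to bound memory. Per-chunk spike-count
#' features for both modalities are precomputed.
#'
#' @param samples list of [gesture_sample()].
#' @param dm_cfg a [delta_mod_config()].
#' @param tick raster tick in ms.
#' @param crop_size DVS crop window (default 40).
#' @return an `encoded_dataset` list.
#' @export
encode_samples <- function(samples, dm_cfg = delta_mod_config(), tick = 1,
                           crop_size = 40L) {
  N <- length(samples)
  dur <- samples[[1]]$duration_ms
  emg_rasters <- vector("list", N)
  quads <- vector("list", N)
  emg_counts <- matrix(0, N, 16L)
  dvs_counts <- lapply(1:4, function(k) matrix(0, N, (crop_size %/% 2L)^2))
  for (i in seq_len(N)) {
    s <- samples[[i]]
    tr <- delta_modulate(s$emg, dm_cfg)
    emg_rasters[[i]] <- rasterize(tr, tick = tick, duration_ms = dur)
    emg_counts[i, ] <- spike_counts(emg_rasters[[i]])
    q <- subsample_quad(crop_events(s$dvs, crop_size))
    quads[[i]] <- q
    for (k in 1:4)
      dvs_counts[[k]][i, ] <- tabulate(q[[k]]$y * q[[k]]$width + q[[k]]$x + 1L,
                                       nbins = (crop_size %/% 2L)^2)
  }
  structure(list(emg_rasters = emg_rasters, emg_counts = emg_counts,
                 dvs_quads = quads, dvs_counts = dvs_counts,
                 labels = match(vapply(samples, `[[`, "", "label"), GESTURES),
                 sessions = vapply(samples, `[[`, 0L, "session"),
                 subjects = vapply(samples, `[[`, 0L, "subject"),
                 duration_ms = dur, tick = tick, dm_cfg = dm_cfg,
                 crop_size = as.integer(crop_size), n = N),
            class = "encoded_dataset")
}

enc_emg_array <- function(enc, idx) stack_rasters(enc$emg_rasters[idx])

enc_branch_arrays <- function(enc, idx) {
  T_ <- as.integer(ceiling(enc$duration_ms / enc$tick))
  lapply(1:4, function(k)
    stack_rasters(lapply(enc$dvs_quads[idx], function(q)
      rasterize(q[[k]], tick = enc$tick, duration_ms = enc$duration_ms,
                merge_polarity = TRUE))))
}

# chunked spiking evaluation over an encoded dataset; modality "emg"/"dvs"
eval_spec_encoded <- function(spec, enc, idx, modality, extra_ticks = 2L,
                              chunk = 100L) {
  pred <- integer(length(idx))
  hidden <- NULL
  counts <- NULL
  hid_spikes <- 0
  for (part in split(seq_along(idx), ceiling(seq_along(idx) / chunk))) {
    ii <- idx[part]
    fb <- if (modality == "emg")
      snn_forward_batch(spec, enc_emg_array(enc, ii), extra_ticks)
    else snn_forward_batch(spec, enc_branch_arrays(enc, ii), extra_ticks)
    pred[part] <- fb$decisions
    if (is.null(hidden)) {
      hidden <- matrix(0, length(idx), ncol(fb$hidden_counts))
      counts <- matrix(0, length(idx), ncol(fb$counts))
    }
    hidden[part, ] <- fb$hidden_counts
    counts[part, ] <- fb$counts
    st <- fb$spike_totals
    hid_spikes <- hid_spikes +
      if (is.list(st)) sum(vapply(st, function(s) sum(s[-c(1L, length(s))]), 0))
      else sum(st[-c(1L, length(st))])
  }
  list(pred = pred, hidden_counts = hidden, counts = counts,
       hidden_rate = hid_spikes / (length(idx) * penultimate_width(spec)))
}

# threshold grid search on encoded data (validation accuracy, rate-balance
# tie-break); mirrors ann_to_snn() on the pipeline's lazy rasters
search_thresholds_encoded <- function(ann, thresholds, enc, idx_cal, idx_val,
                                      modality, target_rate = NULL,
                                      extra_ticks = 2L) {
  x_cal <- if (modality == "emg") enc$emg_counts[idx_cal, , drop = FALSE]
           else lapply(enc$dvs_counts, function(m) m[idx_cal, , drop = FALSE])
  bases <- ann_bases(ann, x_cal) / thresholds$spikes_target
  y_val <- enc$labels[idx_val]
  res <- data.frame(multiplier = thresholds$multipliers, accuracy = NA_real_,
                    hidden_rate = NA_real_)
  cands <- vector("list", length(thresholds$multipliers))
  for (ci in seq_along(thresholds$multipliers)) {
    th <- bases * thresholds$multipliers[ci]
    if (inherits(ann, "submlp_ensemble") ||
        ann$layers[[1]]$quant$kind == "binary")
      th <- pmax(round(th), 1)
    cand <- set_thresholds(ann, th)
    ev <- eval_spec_encoded(cand, enc, idx_val, modality, extra_ticks)
    res$accuracy[ci] <- mean(ev$pred == y_val)
    res$hidden_rate[ci] <- ev$hidden_rate
    cands[[ci]] <- cand
  }
  best_acc <- max(res$accuracy)
  ok <- which(res$accuracy >= best_acc - thresholds$tie_tol)
  pick <- if (!is.null(target_rate) && length(ok) > 1L)
    ok[which.min(abs(res$hidden_rate[ok] - target_rate))]
  else ok[which.max(res$accuracy[ok])]
  out <- cands[[pick]]
  attr(out, "hidden_rate") <- res$hidden_rate[pick]
  attr(out, "search") <- res
  out
}

#' Fit a gesture classification model on encoded data
#'
#' Architectures: `"odin-emg"` (int3 16-230-5 quantization-aware ANN on
#' EMG spike counts, mapped to a spiking net with threshold search),
#' `"morphic-dvs"` (four binary 400-210-5 subMLPs on the subsampled DVS
#' streams, mapped likewise), `"fusion-odin"` (both of the above frozen,
#' penultimate layers concatenated into a 1,070-wide layer feeding a
#' retrained int3 5-unit head), `"loihi-emg"` (surrogate-gradient trained
#' 16-128d-128d-5 spiking MLP — small datasets only), and `"constant"`
#' (always predicts class 1; chance-level reference).
#'
#' @param enc an `encoded_dataset`.
#' @param idx_train training sample indices.
#' @param arch architecture string.
#' @param cfg a [train_config()].
#' @param thresholds a [threshold_search_spec()].
#' @param val_frac fraction of training data held out for threshold
#'   search / head validation.
#' @param max_val cap on validation subset size (simulation cost control).
#' @return a `gesture_model`.
#' @export
fit_gesture_model <- function(enc, idx_train, arch, cfg = train_config(),
                              thresholds = threshold_search_spec(),
                              val_frac = 0.2, max_val = 150L) {
  model <- structure(list(arch = arch, dm_cfg = enc$dm_cfg,
                          tick = enc$tick, duration_ms = enc$duration_ms,
                          crop_size = enc$crop_size,
                          frame_period_ms = NULL),
                     class = "gesture_model")
  if (arch == "constant") return(model)
  set.seed(cfg$seed)
  n_val <- min(max(1L, round(val_frac * length(idx_train))), max_val)
  vi <- sample(idx_train, n_val)
  fi <- setdiff(idx_train, vi)
  y <- enc$labels

  fit_emg_snn <- function(target_rate = NULL) {
    ann <- train_quantized_ann(
      spec_odin_emg(), list(x = enc$emg_counts[fi, , drop = FALSE],
                            y = y[fi]), cfg)
    search_thresholds_encoded(ann, thresholds, enc, fi, vi, "emg",
                              target_rate)
  }
  fit_dvs_snn <- function(target_rate = NULL) {
    ann <- train_quantized_ann(
      spec_morphic_dvs(),
      list(x = lapply(enc$dvs_counts, function(m) m[fi, , drop = FALSE]),
           y = y[fi]), cfg)
    search_thresholds_encoded(ann, thresholds, enc, fi, vi, "dvs",
                              target_rate)
  }

  if (arch == "odin-emg") {
    model$spec <- fit_emg_snn()
  } else if (arch == "morphic-dvs") {
    model$spec <- fit_dvs_snn()
  } else if (arch == "fusion-odin") {
    emg_snn <- fit_emg_snn()
    # balance the DVS hidden activity toward the EMG hidden rate
    dvs_snn <- fit_dvs_snn(target_rate = attr(emg_snn, "hidden_rate"))
    dvs_ens <- dvs_snn
    dvs_ens$mode <- "concat_hidden"
    fused <- build_fusion(emg_snn, dvs_ens, output_quant = quant_spec("int3"))
    ha <- eval_spec_encoded(emg_snn, enc, idx_train, "emg")$hidden_counts
    hb <- eval_spec_encoded(dvs_snn, enc, idx_train, "dvs")$hidden_counts
    model$spec <- retrain_fusion_head(
      fused, list(hidden = cbind(ha, hb), y = y[idx_train]), cfg, thresholds)
    model$single_modality <- list(emg = emg_snn, dvs = dvs_snn)
  } else if (arch == "loihi-emg") {
    spec <- spec_loihi_emg_mlp()
    cfg$train_delays <- TRUE
    model$spec <- train_surrogate(
      spec, list(rasters = enc$emg_rasters[idx_train],
                 labels = y[idx_train]), cfg)
  } else stop("unknown architecture: ", arch)
  model
}

#' Predict gesture classes for encoded samples
#' @param model a `gesture_model`; @param enc an `encoded_dataset`;
#' @param idx sample indices (default all).
#' @export
predict_encoded <- function(model, enc, idx = seq_len(enc$n)) {
  switch(model$arch,
         constant = rep(1L, length(idx)),
         `odin-emg` = eval_spec_encoded(model$spec, enc, idx, "emg")$pred,
         `morphic-dvs` = eval_spec_encoded(model$spec, enc, idx, "dvs")$pred,
         `fusion-odin` = {
           pred <- integer(length(idx))
           for (part in split(seq_along(idx),
                              ceiling(seq_along(idx) / 100L))) {
             ii <- idx[part]
             fb <- fusion_forward_batch(model$spec,
                                        enc_emg_array(enc, ii),
                                        enc_branch_arrays(enc, ii))
             pred[part] <- fb$decisions
           }
           pred
         },
         `loihi-emg` = vapply(idx, function(i)
           run_network(model$spec, enc$emg_rasters[[i]],
                       extra_ticks = 3L)$decision, 0L),
         stop("unknown architecture: ", model$arch))
}

#' Predict gesture classes for raw samples
#' @param model a `gesture_model`; @param samples list of
#'   [gesture_sample()].
#' @export
predict_gestures <- function(model, samples) {
  if (!is.null(model$predict_fun)) return(model$predict_fun(samples))
  enc <- encode_samples(samples, model$dm_cfg, model$tick, model$crop_size)
  predict_encoded(model, enc)
}

#' Session-wise k-fold cross-validation
#'
#' Folds are split by recording session: the sessions are deterministically
#' shuffled (given `seed`) and assigned round-robin to k folds, so with
#' three sessions and k = 3 each fold holds out exactly one session across
#' all subjects. Reports per-fold, mean and standard deviation of accuracy.
#'
#' @param samples list of [gesture_sample()] (chunked dataset).
#' @param arch architecture, see [fit_gesture_model()].
#' @param k number of folds; requires at least k distinct sessions.
#' @param seed RNG seed for fold assignment and training.
#' @param cfg a [train_config()]; its seed is set from `seed`.
#' @param thresholds a [threshold_search_spec()].
#' @param enc optional pre-encoded dataset (skips encoding).
#' @return object of class `cv_result`: `folds` data frame, `mean`, `sd`.
#' @export
crossvalidate <- function(samples, arch, k = 3L, seed = 1L,
                          cfg = train_config(),
                          thresholds = threshold_search_spec(),
                          enc = NULL) {
  if (is.null(enc)) enc <- encode_samples(samples)
  sess <- sort(unique(enc$sessions))
  if (length(sess) < k)
    stop("only ", length(sess), " sessions; need at least k = ", k)
  set.seed(seed)
  fold_of_session <- setNames(rep(seq_len(k), length.out = length(sess)),
                              sample(sess))
  folds <- data.frame(fold = integer(0), accuracy = numeric(0),
                      n_test = integer(0))
  predictions <- integer(enc$n)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of_session[as.character(enc$sessions)] == f)
    train_idx <- setdiff(seq_len(enc$n), test_idx)
    cfg_f <- cfg
    cfg_f$seed <- seed + f
    model <- fit_gesture_model(enc, train_idx, arch, cfg_f, thresholds)
    pred <- predict_encoded(model, enc, test_idx)
    predictions[test_idx] <- pred
    row <- data.frame(fold = f,
                      accuracy = mean(pred == enc$labels[test_idx]),
                      n_test = length(test_idx))
    if (!is.null(model$single_modality)) {
      # single-modality test accuracy of the frozen upstream networks
      y_te <- enc$labels[test_idx]
      row$accuracy_emg <- mean(eval_spec_encoded(
        model$single_modality$emg, enc, test_idx, "emg")$pred == y_te)
      row$accuracy_dvs <- mean(eval_spec_encoded(
        model$single_modality$dvs, enc, test_idx, "dvs")$pred == y_te)
    }
    folds <- rbind(folds, row)
  }
  structure(list(folds = folds, mean = mean(folds$accuracy),
                 sd = sd(folds$accuracy), arch = arch, k = k, seed = seed,
                 predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %.1f%% +/- %.1f%% over %d session folds\n",
              x$arch, 100 * x$mean, 100 * x$sd, x$k))
  invisible(x)
}

truncate_sample <- function(s, dur_ms) {
  n_keep <- max(1L, floor(dur_ms * s$emg$rate / 1000))
  emg <- emg_recording(s$emg$samples[, seq_len(n_keep), drop = FALSE],
                       s$emg$rate)
  keep <- s$dvs$t < dur_ms * 1000
  dvs <- event_stream(s$dvs$t[keep], s$dvs$x[keep], s$dvs$y[keep],
                      s$dvs$p[keep], s$dvs$width, s$dvs$height)
  gesture_sample(emg, dvs, s$label, duration_ms = max(dur_ms, 1),
                 subject = s$subject, session = s$session,
                 repetition = s$repetition, chunk_index = s$chunk_index)
}

#' Classification accuracy as a function of stimulus duration
#'
#' Each sample's events and EMG samples are truncated to the stated
#' duration before inference. A frame-based model (non-NULL
#' `frame_period_ms`, e.g. 50 ms at the 20 fps frame rate) returns no
#' prediction (NA accuracy) for durations shorter than one frame period,
#' since no frame has arrived yet.
#'
#' @param model a `gesture_model` (optionally carrying `frame_period_ms`).
#' @param samples list of [gesture_sample()].
#' @param durations vector of stimulus durations in ms; must not exceed
#'   the sample duration.
#' @return data frame `(duration_ms, accuracy)`.
#' @export
accuracy_vs_duration <- function(model, samples,
                                 durations = c(10, 25, 50, 100, 150, 200)) {
  full <- samples[[1]]$duration_ms
  if (any(durations > full))
    stop("duration exceeds sample length (", full, " ms)")
  labels <- match(vapply(samples, `[[`, "", "label"), GESTURES)
  acc <- vapply(durations, function(d) {
    if (!is.null(model$frame_period_ms) && d < model$frame_period_ms)
      return(NA_real_)
    trunc <- lapply(samples, truncate_sample, dur_ms = d)
    mean(predict_gestures(model, trunc) == labels)
  }, 0)
  data.frame(duration_ms = durations, accuracy = acc)
}

#' Write a JSON run record
#'
#' One self-describing record per experiment: configuration hash, seed,
#' per-fold metrics and any cost reports.
#'
#' @param path output JSON path.
#' @param seed the run seed.
#' @param cfg the [train_config()] (hashed into `config_hash`).
#' @param cv a `cv_result` (optional).
#' @param cost a list of `cost_report`s (optional).
#' @export
write_run_record <- function(path, seed, cfg, cv = NULL, cost = NULL) {
  rec <- list(config_hash = rlang::hash(cfg), seed = seed,
              timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(cv))
    rec$cv <- list(arch = cv$arch, k = cv$k, mean_accuracy = cv$mean,
                   sd_accuracy = cv$sd, folds = cv$folds)
  if (!is.null(cost)) rec$cost <- lapply(cost, unclass)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
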