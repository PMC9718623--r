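#' Pipeline configuration
#'
#' One configuration object for the whole pipeline: synthesis, segmentation,
#' the two feature extractors, fusion, selection and evaluation. A single
#' global seed fans out to fixed per-stage seeds, so every stage is
#' independently reproducible. Serialises to/from YAML; unknown keys are
#' rejected.
#'
#' @param seed Global seed; default 1.
#' @param n_per_class,n_classes,hw Synthetic image counts and frame size.
#' @param segment Run the segmentation stage and extract features from the
#'   colour-mapped segmented images; default TRUE.
#' @param n_segments,alpha,sigma_c,sigma_s Segmentation parameters.
#' @param extractor_a,extractor_b Descriptors of the two feature views;
#'   `"mock"` extractors with independent projection seeds.
#' @param dim_a,dim_b Feature dimensions of the two views; default 128 each.
#' @param tau_high,tau_low Fusion thresholds.
#' @param pop_size,n_iters,lam Selection (butterfly optimization) settings.
#' @param split,cv_folds,use_cv Evaluation protocol (50:50 holdout by
#'   default; 10-fold cross-validation under `use_cv`).
#' @param out_dir Output directory for intermediate CSVs; default a fresh
#'   temporary directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_per_class = 40L, n_classes = 5L,
                            hw = 128L, segment = TRUE, n_segments = 200L,
                            alpha = 0.99, sigma_c = 10, sigma_s = 0.1,
                            extractor_a = "darknet_mock",
                            extractor_b = "squeezenet_mock",
                            dim_a = 128L, dim_b = 128L,
                            tau_high = 0.9, tau_low = 0.05,
                            pop_size = 30L, n_iters = 200L, lam = 0.01,
                            split = 0.5, cv_folds = 10L, use_cv = FALSE,
                            out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
              n_classes = as.integer(n_classes), hw = as.integer(hw),
              segment = isTRUE(segment), n_segments = as.integer(n_segments),
              alpha = alpha, sigma_c = sigma_c, sigma_s = sigma_s,
              extractor_a = extractor_a, extractor_b = extractor_b,
              dim_a = as.integer(dim_a), dim_b = as.integer(dim_b),
              tau_high = tau_high, tau_low = tau_low,
              pop_size = as.integer(pop_size), n_iters = as.integer(n_iters),
              lam = lam, split = split, cv_folds = as.integer(cv_folds),
              use_cv = isTRUE(use_cv), out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stage order synth -> segment -> extract (two views) ->
#' fuse -> select -> classify, writing intermediate CSVs under
#' `cfg$out_dir` and recording a manifest row per stage (dimensions,
#' outputs, timestamps). A stage failure aborts with the stage name after
#' persisting the manifest so far.
#'
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_run`: list with `manifest` (tibble), `metrics`
#'   (panel metrics tibble), `selection` (`boa_selection`), `fusion_report`,
#'   and `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir %||% tempfile("grainsight_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, dims, output) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, dims = dims, output = output,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
    )
    utils::write.csv(dplyr::bind_rows(manifest),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. synthesis
  samples <- run_stage("synth", gen_grain_images(
    cfg$n_per_class, cfg$n_classes, cfg$hw,
    seed = derive_seed(cfg$seed, "synth")
  ))
  note("synth", sprintf("%d images %dx%d, %d classes", length(samples),
                        cfg$hw, cfg$hw, cfg$n_classes), "")

  # 2. segmentation -> colour-mapped images feed the extractors
  if (cfg$segment) {
    segd <- run_stage("segment", purrr::map(samples, function(s) {
      res <- segment_image(s$image, cfg$n_segments, cfg$alpha,
                           cfg$sigma_c, cfg$sigma_s)
      list(image = res$colormapped, label = s$label,
           mask_area = sum(res$mask), threshold = res$threshold)
    }))
    seg_log <- tibble::tibble(
      sample_id = sprintf("s_%04d", seq_along(segd)),
      label = purrr::map_int(segd, "label"),
      threshold = purrr::map_dbl(segd, "threshold"),
      mask_area_px = purrr::map_dbl(segd, "mask_area")
    )
    utils::write.csv(seg_log, file.path(out_dir, "segmentation_log.csv"),
                     row.names = FALSE)
    note("segment", sprintf("%d masks", length(segd)), "segmentation_log.csv")
    inputs <- segd
  } else {
    inputs <- samples
  }

  # 3. two feature views
  ext_a <- mock_extractor(cfg$dim_a, seed = derive_seed(cfg$seed, "extract_a"),
                          name = cfg$extractor_a)
  ext_b <- mock_extractor(cfg$dim_b, seed = derive_seed(cfg$seed, "extract_b"),
                          name = cfg$extractor_b)
  f_a <- run_stage("extract_a", extract_features(ext_a, inputs))
  f_b <- run_stage("extract_b", extract_features(ext_b, inputs))
  write_features_csv(f_a, file.path(out_dir, "features_a.csv"))
  write_features_csv(f_b, file.path(out_dir, "features_b.csv"))
  note("extract_a", sprintf("%d x %d", nrow(f_a), cfg$dim_a), "features_a.csv")
  note("extract_b", sprintf("%d x %d", nrow(f_b), cfg$dim_b), "features_b.csv")

  # 4. fusion
  fused <- run_stage("fuse", fuse_features(
    f_a, f_b, fusion_config(cfg$tau_high, cfg$tau_low)
  ))
  write_features_csv(fused$features, file.path(out_dir, "fused.csv"))
  note("fuse", sprintf("%d x %d", nrow(fused$features),
                       fused$report$fused_dim), "fused.csv")

  # 5. selection
  sel <- run_stage("select", run_improved_boa(
    fused$features,
    boa_config(pop_size = cfg$pop_size, n_iters = cfg$n_iters,
               seed = derive_seed(cfg$seed, "select")),
    lam = cfg$lam
  ))
  selected <- dplyr::select(fused$features, "sample_id", "label",
                            dplyr::all_of(sel$selected_ids))
  write_features_csv(selected, file.path(out_dir, "selected.csv"))
  note("select", sprintf("%d x %d", nrow(selected), sel$n_selected),
       "selected.csv")

  # 6. classification
  ev <- run_stage("classify", evaluate_panel(
    selected, classifier_panel(),
    eval_config(split = cfg$split, cv_folds = cfg$cv_folds,
                use_cv = cfg$use_cv,
                seed = derive_seed(cfg$seed, "classify"))
  ))
  utils::write.csv(ev$metrics, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  note("classify", sprintf("%d classifiers", nrow(ev$metrics)), "results.csv")

  structure(
    list(manifest = dplyr::bind_rows(manifest), metrics = ev$metrics,
         selection = sel, fusion_report = fused$report,
         evaluation = ev, out_dir = out_dir),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", nrow(x$manifest), " stages -> ", x$out_dir, "\n",
      sep = "")
  print(x$manifest[, c("stage", "dims", "output")])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
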