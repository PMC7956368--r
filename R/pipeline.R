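#' End-to-end dissimilarity-space classification pipeline
#'
#' Runs the full method on a labeled image dataset: stratified train/test
#' split, then for every (architecture, kc, representation) member: train the
#' Siamese scorer on the training images, select `kc` prototypes per class by
#' supervised k-means, project both folds into the dissimilarity space, train
#' one-vs-all linear SVMs on the training projections and score the test
#' fold. Member score matrices are fused by sum rule (optionally z-normalized
#' with training-fold statistics first) and the fusion is evaluated by
#' accuracy and one-vs-all AUC.
#'
#' One Siamese network is trained per (architecture, representation); the
#' prototype grid reuses it. All randomness derives from `seed`.
#'
#' @param data Dataset tibble, or a path to an image folder tree readable by
#'   [read_image_folder()].
#' @param architectures List of `snn_architecture` objects (or a vector of
#'   backbone ids in 1..8, taken at their 224 input size).
#' @param kc_grid Per-class prototype counts to ensemble over.
#' @param representations Subset of `c("original", "hasc")`.
#' @param options [train_options()]; its seed is overridden by `seed`.
#' @param train_fraction Stratified split fraction.
#' @param cost,kernel One-vs-all SVM options.
#' @param znorm_members Z-normalize member scores (training-fold statistics)
#'   before the sum; off by default for the plain sum rule.
#' @param cluster_side Clustering representation side.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory: writes per-member score CSVs, prototype
#'   CSVs, model checkpoints, the fused scores, the report and a JSON log of
#'   all seeds and options.
#' @return A `dissim_pipeline` object: `report` (accuracy, AUC, n), `fused`
#'   score matrix, `members` tibble (one row per member with its test
#'   accuracy and scores), and the resolved configuration.
#' @export
run_pipeline <- function(data,
                         architectures = list(reduced_network3()),
                         kc_grid = 3,
                         representations = "original",
                         options = train_options(learning_rate = 1e-3, iterations = 500),
                         train_fraction = 0.75,
                         cost = 1, kernel = "linear",
                         znorm_members = FALSE,
                         cluster_side = 32,
                         seed = 1,
                         out_dir = NULL) {
  if (is.character(data)) data <- read_image_folder(data)
  check_dataset(data)
  if (!all(representations %in% c("original", "hasc"))) {
    abort('`representations` must be a subset of c("original", "hasc").')
  }
  if (length(kc_grid) == 0) abort("`kc_grid` must be nonempty.")
  if (is.numeric(architectures)) {
    architectures <- lapply(architectures, snn_architecture)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  folds <- split_images(data, train_fraction, seed = derive_seed(seed, "fold"))
  truth <- folds$test$class

  members <- list()
  mi <- 0L
  for (rep_name in representations) {
    for (ai in seq_along(architectures)) {
      arch <- architectures[[ai]]
      side <- arch$input_size
      tr <- folds$train; te <- folds$test
      if (rep_name == "hasc") {
        tr <- hasc_images(tr, out_size = side)
        te <- hasc_images(te, out_size = side)
      }
      opts <- options
      opts$seed <- derive_seed(seed, sprintf("snn_%s_%d", rep_name, ai))
      fit <- train_snn(tr, arch, opts)
      if (!is.null(out_dir)) {
        saveRDS(fit, file.path(out_dir, sprintf("snn_%s_arch%d.rds", rep_name, ai)))
        jsonlite::write_json(
          fit$trace, file.path(out_dir, sprintf("snn_%s_arch%d_log.json", rep_name, ai)),
          dataframe = "rows", digits = NA
        )
      }
      for (kc in kc_grid) {
        mi <- mi + 1L
        protos <- select_prototypes(tr, kc, side = cluster_side,
                                    seed = derive_seed(seed, paste0("proto", kc)))
        dtr <- build_design_matrix(tr, protos, fit)
        dte <- build_design_matrix(te, protos, fit)
        svm_fit <- fit_ova_svm(dtr, cost = cost, kernel = kernel)
        s_te <- stats::predict(svm_fit, dte)
        if (znorm_members) {
          s_tr <- stats::predict(svm_fit, dtr)
          s_te <- znorm(s_te, reference = s_tr)
        }
        attr(s_te, "source_id") <- sprintf("%s_arch%d_kc%d", rep_name, arch$id, kc)
        if (!is.null(out_dir)) {
          write_prototypes(protos, file.path(out_dir, sprintf("prototypes_%s_kc%d.csv", rep_name, kc)))
          write_scores(s_te, file.path(out_dir, sprintf("scores_%s.csv", attr(s_te, "source_id"))))
        }
        members[[mi]] <- list(
          representation = rep_name, architecture = arch$id,
          architecture_name = arch$name, kc = kc,
          scores = s_te, accuracy = accuracy(s_te$.pred, truth)
        )
      }
    }
  }

  fused <- sum_rule(lapply(members, `[[`, "scores"))
  report <- evaluate_scores(fused, truth)
  member_tbl <- dplyr::bind_rows(lapply(members, function(m) {
    tibble(representation = m$representation, architecture = m$architecture,
           architecture_name = m$architecture_name, kc = m$kc,
           accuracy = m$accuracy, scores = list(m$scores))
  }))

  out <- structure(list(
    report = report, fused = fused, members = member_tbl, truth = truth,
    config = list(
      architectures = vapply(architectures, function(a) a$name, ""),
      kc_grid = kc_grid, representations = representations,
      train_fraction = train_fraction, cost = cost, kernel = kernel,
      znorm_members = znorm_members, cluster_side = cluster_side,
      seed = seed, options = unclass(options)
    )
  ), class = "dissim_pipeline")

  if (!is.null(out_dir)) {
    write_scores(fused, file.path(out_dir, "scores_fused.csv"))
    jsonlite::write_json(
      list(report = as.list(report), config = out$config),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}

#' @export
print.dissim_pipeline <- function(x, ...) {
  cat(sprintf("<dissim_pipeline> %d member(s), fused accuracy %.2f%%, AUC %.3f (n = %d)\n",
              nrow(x$members), x$report$accuracy, x$report$auc, x$report$n))
  invisible(x)
}

#' Load a pipeline run configuration from YAML
#'
#' Field names mirror the arguments of [run_pipeline()]; `architectures` may
#' be a vector of backbone ids or `"reduced3"` entries, and `train_options`
#' fields are passed to [train_options()].
#'
#' @param path YAML file.
#' @return A named list of [run_pipeline()] arguments.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$dataset)) args$data <- cfg$dataset
  if (!is.null(cfg$architectures)) {
    args$architectures <- lapply(cfg$architectures, function(a) {
      if (identical(a, "reduced3")) reduced_network3() else snn_architecture(as.integer(a))
    })
  }
  for (nm in c("kc_grid", "representations", "train_fraction", "cost",
               "kernel", "znorm_members", "cluster_side", "seed", "out_dir")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  if (!is.null(cfg$train_options)) {
    args$options <- do.call(train_options, cfg$train_options)
  }
  args
}
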