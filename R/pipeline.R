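# End-to-end pipeline wiring: train -> probability maps -> LU segments ->
# ROC, on a cohort of patients with a patient-level train/test split, plus a
# manifest that records every parameter and seed so any stage can be re-run
# bit-identically.

#' Pipeline configuration
#'
#' Collects every tunable of the probability-mapping pipeline, with the
#' defaults used throughout the package (3x3 patches, 9x90 dictionaries,
#' sparsity 2, forgetting factor 0.995, 9x9 / sigma 5 smoothing, LU grid step
#' 0.025 with minimum width 0.1, alpha 0.05).
#'
#' @param feature `"dc"` or `"texture"`.
#' @param train_ids,test_ids patient ids of the split; must be disjoint (the
#'   model is always evaluated on patients it never saw).
#' @param patch,atoms,sparsity,lambda0,epochs,remove_dc see [scar_model()].
#' @param smooth_window,smooth_sigma test-time residual smoothing.
#' @param step,min_width,alpha LU-segment grid and significance level.
#' @param seed master integer seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(feature = c("texture", "dc"),
                            train_ids, test_ids,
                            patch = 3L, atoms = 90L, sparsity = 2L,
                            lambda0 = 0.995, epochs = 40L, remove_dc = FALSE,
                            smooth_window = 9L, smooth_sigma = 5,
                            step = 0.025, min_width = 0.1, alpha = 0.05,
                            seed = 1L) {
  feature <- match.arg(feature)
  if (length(intersect(train_ids, test_ids)))
    stop("training and test patient sets must be disjoint")
  structure(list(feature = feature, train_ids = train_ids, test_ids = test_ids,
                 patch = patch, atoms = atoms, sparsity = sparsity,
                 lambda0 = lambda0, epochs = epochs, remove_dc = remove_dc,
                 smooth_window = smooth_window, smooth_sigma = smooth_sigma,
                 step = step, min_width = min_width, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full probability-mapping pipeline on a cohort
#'
#' Stages: collect the training slices of the training patients, fit a
#' [scar_model()] (dictionary learning included for the texture feature),
#' predict probability maps for every test patient, sigmoid-extend them,
#' build the LU segment size table and (when both groups are present among
#' the test patients) the Mann-Whitney significance map, and compute
#' per-patient ROC curves with a vertical average.  A stage failure is
#' rethrown with the stage name; completed artifacts are kept in the error
#' condition.
#'
#' @param cohort list of patients as produced by [generate_cohort()] (each a
#'   list with `id`, `group`, `slices`).
#' @param config a [pipeline_config()].
#' @param roc_reference `"annotation"` scores ROC against the scar masks;
#'   `"core"` against `truth_core` with the border band excluded (phantoms
#'   only).
#' @return An object of class `"scar_pipeline"`: list with `model`, `maps`
#'   (per test patient), `size_table`, `lu_test` (or NULL), `roc`
#'   (per-patient + averaged), and `manifest`.
#' @export
run_pipeline <- function(cohort, config,
                         roc_reference = c("annotation", "core")) {
  stopifnot(inherits(config, "pipeline_config"))
  roc_reference <- match.arg(roc_reference)
  ids <- vapply(cohort, `[[`, "", "id")
  missing_ids <- setdiff(c(config$train_ids, config$test_ids), ids)
  if (length(missing_ids))
    stop("unknown patient ids: ", paste(missing_ids, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  train_slices <- stage("training-data", {
    unlist(lapply(cohort[ids %in% config$train_ids], `[[`, "slices"),
           recursive = FALSE)
  })
  model <- stage("fit", {
    scar_model(train_slices, feature = config$feature, patch = config$patch,
               atoms = config$atoms, sparsity = config$sparsity,
               lambda0 = config$lambda0, epochs = config$epochs,
               remove_dc = config$remove_dc,
               smooth_window = config$smooth_window,
               smooth_sigma = config$smooth_sigma,
               seed = derive_seed(config$seed, 17L))
  })

  test_pat <- cohort[ids %in% config$test_ids]
  maps <- stage("probability-maps", {
    out <- lapply(test_pat, function(p) predict(model, p$slices, type = "map"))
    names(out) <- vapply(test_pat, `[[`, "", "id")
    out
  })
  ext_maps <- stage("sigmoid-extension",
                    lapply(maps, function(pm) lapply(pm, sigmoid_extend)))

  grid <- lu_grid(config$step, config$min_width)
  groups <- vapply(test_pat, `[[`, "", "group")
  size_table <- stage("segment-sizes",
                      segment_size_table(ext_maps, groups, grid))
  lu_test <- if (length(unique(groups)) == 2 && all(table(groups) >= 2)) {
    stage("group-test", lu_significance_map(size_table, alpha = config$alpha))
  } else NULL

  roc <- stage("roc", {
    per_patient <- lapply(seq_along(test_pat), function(i) {
      p <- test_pat[[i]]
      ann <- lapply(p$slices, `[[`, "annotation")
      if (roc_reference == "core") {
        ann <- lapply(p$slices, function(s)
          region_annotation(s$annotation$myocardium, s$truth_core))
        excl <- lapply(p$slices, `[[`, "truth_border")
        map_roc(maps[[i]], ann, exclude = excl)
      } else {
        map_roc(maps[[i]], ann)
      }
    })
    list(per_patient = per_patient, averaged = average_roc(per_patient))
  })

  manifest <- c(unclass(config),
                list(package_version = as.character(utils::packageVersion("scarmap")),
                     n_patients = length(cohort),
                     roc_reference = roc_reference,
                     model_seed = derive_seed(config$seed, 17L)))
  structure(list(model = model, maps = maps, extended_maps = ext_maps,
                 size_table = size_table, lu_test = lu_test, roc = roc,
                 manifest = manifest),
            class = "scar_pipeline")
}

#' @export
print.scar_pipeline <- function(x, ...) {
  cat("scar probability-mapping pipeline run\n")
  print(x$model)
  cat(sprintf("  %d test patients; mean AUC = %.4f\n",
              length(x$maps), mean(x$roc$averaged$per_patient_aucs)))
  if (!is.null(x$lu_test))
    cat(sprintf("  LU segments significant at alpha = %.3g: %d of %d\n",
                attr(x$lu_test, "alpha"), sum(x$lu_test$significant),
                nrow(x$lu_test)))
  invisible(x)
}

#' Write pipeline artifacts to a run directory
#'
#' Writes the manifest (JSON), class model (JSON), dictionaries (JSON), the
#' size and p-value tables (CSV), probability maps (32-bit TIFF) and
#' rendered maps (PNG).
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_class_model(result$model$model, file.path(dir, "class_model.json"))
  if (!is.null(result$model$dictionaries)) {
    write_dictionary(result$model$dictionaries$scar,
                     file.path(dir, "dictionary_scar.json"))
    write_dictionary(result$model$dictionaries$myo,
                     file.path(dir, "dictionary_myo.json"))
  }
  utils::write.csv(result$size_table, file.path(dir, "segment_sizes.csv"),
                   row.names = FALSE)
  if (!is.null(result$lu_test))
    utils::write.csv(result$lu_test, file.path(dir, "lu_pvalues.csv"),
                     row.names = FALSE)
  for (pid in names(result$maps)) {
    for (k in seq_along(result$maps[[pid]])) {
      m <- result$maps[[pid]][[k]]
      v <- unclass(m)
      v[is.na(v)] <- 0                         # exact 0 marks non-myocardium
      write_gray_image(v, file.path(dir, sprintf("map_%s_s%02d.tiff", pid, k)))
      png::writePNG(render_map(m), file.path(dir, sprintf("map_%s_s%02d.png", pid, k)))
    }
  }
  invisible(dir)
}
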