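# Orchestration and strict CSV interchange: schema-validated tables and a
# seeded, manifest-producing end-to-end run over the analysis stages.

#' Strict CSV table I/O
#'
#' `write_table` writes an RFC-4180 CSV (UTF-8, row order preserved);
#' `read_table` reads one and validates it against a declared schema of
#' column names to types (`"numeric"`, `"integer"`, `"character"`,
#' `"logical"`). Violations name the offending column.
#'
#' @param table data.frame to write.
#' @param path file path.
#' @param schema named character vector, column name -> type; `NULL` skips
#'   validation.
#' @return `read_table` returns the validated data.frame; `write_table`
#'   returns `path` invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing) > 0) {
      stop("missing column(s): ", paste(missing, collapse = ", "))
    }
    for (col in names(schema)) {
      ok <- switch(schema[[col]],
                   numeric = is.numeric(df[[col]]),
                   integer = is.numeric(df[[col]]) &&
                     all(df[[col]] == round(df[[col]]), na.rm = TRUE),
                   character = is.character(df[[col]]),
                   logical = is.logical(df[[col]]),
                   stop("unknown schema type for column ", col))
      if (!ok) stop("column '", col, "' violates schema type ", schema[[col]])
    }
  }
  df
}

#' Run the co-development analysis pipeline end to end
#'
#' Executes, in dependency order: cohort simulation (or loading), change
#' description (summary, stability, change scores), cross-sectional and
#' longitudinal prediction with Haufe features, and network-block
#' convergence classification, writing every artifact as CSV plus a JSON
#' manifest recording seeds, stage status and output file hashes. A rerun
#' with the same configuration reproduces every artifact byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort a [cohort_config()] (simulation stage) or a
#'   `synthetic_cohort` produced earlier.
#' @param stages character subset of
#'   `c("simulate", "describe", "predict", "blocks")`.
#' @param clustering_args list passed to [make_site_clusters()] (`n_clusters`,
#'   `min_size`).
#' @param prediction a [prediction_config()].
#' @param seed integer seed recorded in the manifest and used for all
#'   stage-level randomness.
#' @return the manifest, invisibly; artifacts and `manifest.json` are in
#'   `out_dir`.
#' @export
run_pipeline <- function(out_dir, cohort,
                         stages = c("simulate", "describe", "predict",
                                    "blocks"),
                         clustering_args = list(n_clusters = 5, min_size = 10),
                         prediction = prediction_config(inner_folds = 5,
                                                        n_test_clusters = 2),
                         seed = 1) {
  stages <- match.arg(stages, c("simulate", "describe", "predict", "blocks"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("codevelop")),
                   seed = seed, stages = stages, outputs = list())
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    write_table(df, path)
    manifest$outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  if ("simulate" %in% stages) {
    stopifnot(inherits(cohort, "cohort_config"))
    cohort <- generate_cohort(cohort)
  }
  stopifnot(inherits(cohort, "synthetic_cohort"))
  emit("demographics.csv", cohort$demographics)
  emit("cognition_y0.csv", as.data.frame(cohort$cognition_y0))
  emit("cognition_y2.csv", as.data.frame(cohort$cognition_y2))
  write_parcel_scheme(cohort$scheme, file.path(out_dir, "parcels.csv"))
  manifest$outputs[["parcels.csv"]] <-
    unname(tools::md5sum(file.path(out_dir, "parcels.csv")))

  dem <- cohort$demographics
  covars <- data.frame(sex = dem$sex, age_y0 = dem$age_y0,
                       interval = dem$age_y2 - dem$age_y0)

  if ("describe" %in% stages) {
    emit("cohort_summary.csv",
         cohort_summary(cohort$cognition_y0, cohort$cognition_y2))
    stab <- spearman_stability(cohort$cognition_y0, cohort$cognition_y2,
                               data.frame(sex = dem$sex, age = dem$age_y0),
                               data.frame(sex = dem$sex, age = dem$age_y2))
    emit("cognition_stability.csv", stab)
    ch <- change_scores(cohort$cognition_y0, cohort$cognition_y2, covars)
    emit("cognition_change_sd.csv",
         data.frame(measure = colnames(cohort$cognition_y0), sd = ch$sd))
  }

  result_cross <- result_long <- NULL
  if ("predict" %in% stages) {
    sizes <- table(dem$site)
    clustering <- do.call(make_site_clusters,
                          c(list(site_sizes = c(sizes)), clustering_args))
    pc1 <- derive_pc1(cohort$cognition_y0)
    y0 <- apply_pc1(pc1, cohort$cognition_y0)
    y2 <- apply_pc1(pc1, cohort$cognition_y2)
    cov_cross <- data.frame(sex = dem$sex, age = dem$age_y0, fd = dem$fd_y0)
    result_cross <- nested_cv_krr(cohort$fc_y0, y0, cov_cross, dem$site,
                                  clustering, prediction)
    cov_long <- data.frame(sex = dem$sex, age = dem$age_y0,
                           interval = dem$age_y2 - dem$age_y0,
                           fd0 = dem$fd_y0, fd2 = dem$fd_y2)
    dy <- y2 - y0
    result_long <- nested_cv_krr(cohort$fc_y2 - cohort$fc_y0, dy, cov_long,
                                 dem$site, clustering, prediction)
    emit("prediction_cross.csv", result_cross$folds)
    emit("prediction_long.csv", result_long$folds)
    manifest$mean_r_cross <- result_cross$mean_r
    manifest$mean_r_long <- result_long$mean_r
  }

  if ("blocks" %in% stages) {
    if (is.null(result_cross)) {
      stop("missing upstream artifact: blocks stage needs prediction outputs")
    }
    pnf_cross <- haufe_pnf(result_cross)
    pnf_long <- haufe_pnf(result_long)
    summ <- classify_convergence(block_average(pnf_cross, cohort$scheme),
                                 block_average(pnf_long, cohort$scheme))
    chord_export(summ, file.path(out_dir, "blocks.csv"))
    manifest$outputs[["blocks.csv"]] <-
      unname(tools::md5sum(file.path(out_dir, "blocks.csv")))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
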