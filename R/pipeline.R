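#' Pipeline configuration
#'
#' @param min_alters Minimum eligible alters per retained network.
#' @param scale Standardize numeric model-frame predictors.
#' @param sd_denominator `"sample"` or `"population"` SD for z-scoring.
#' @param seed Integer seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters only when the input study is generated).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_alters = 15L, scale = TRUE,
                            sd_denominator = "sample", seed = 1L) {
  structure(list(min_alters = min_alters, scale = scale,
                 sd_denominator = sd_denominator, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # stable short hash of the resolved configuration
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  substr(paste(format(sum(utf8ToInt(json) * seq_along(utf8ToInt(json)) %%
                            1000003)), nchar(json), sep = "-"), 1, 24)
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  writeLines(readr::format_csv(df, na = ""), con, sep = "")
  close(con)
  path
}

#' Run the full analysis pipeline on a study
#'
#' Executes derive, structure, assortativity, filter, models and reporting in
#' order, persisting each stage's output as CSV (with the resolved config
#' hash in a header comment) plus a JSON manifest of row counts and file
#' hashes. Re-running on identical input and configuration reproduces
#' identical hashes.
#'
#' @param study A [study_data] object.
#' @param out_dir Artifact directory (created).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`validation`,
#'   `filter_report`, `frame`, `suite`, `glm_cluster`, `bivariate`,
#'   `descriptives`, `forest`, `manifest`).
#' @export
run_pipeline <- function(study, out_dir, config = pipeline_config()) {
  stopifnot(inherits(study, "study_data"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  validation <- validate_study(study)
  derived <- derive_study(study)
  struct <- structural_summary(derived)
  assort <- study_assortativity(derived)
  filt <- filter_networks(derived, min_alters = config$min_alters)
  frame <- model_frame(filt$study, scale = config$scale,
                       sd_denominator = config$sd_denominator)
  suite <- model_suite(frame)
  glm_fit <- fit_cluster_robust_logit(frame)
  bivar <- bivariate_suite(frame)
  desc <- descriptives_table(filt$study)
  forest <- forest_table(suite)

  files <- list(
    validation = validation,
    structure_networks = struct$networks,
    structure_alters = struct$alters,
    assortativity = assort,
    filter_report = filt$report$per_ego,
    model_frame = frame,
    models_comparison = suite$comparison,
    model_indices = suite$indices,
    glm_cluster = glm_fit$coefficients,
    bivariate_tests = bivar,
    descriptives = desc,
    forest = forest)
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_stamped_csv(files[[nm]], p, hash)
    paths[nm] <- p
  }
  jsonlite::write_json(suite$indices, file.path(out_dir, "model_indices.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    config = unclass(config), config_hash = hash,
    n_networks_in = n_networks(study),
    n_networks_analyzed = filt$report$study$n_networks_out,
    n_model_rows = nrow(frame),
    row_counts = lapply(files, nrow),
    file_md5 = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(validation = validation, filter_report = filt$report,
                 frame = frame, suite = suite, glm_cluster = glm_fit,
                 bivariate = bivar, descriptives = desc, forest = forest,
                 manifest = manifest))
}

summarise_numeric <- function(x, group, characteristic) {
  ok <- !is.na(x)
  tibble::tibble(group = group, characteristic = characteristic,
                 level = NA_character_, n = NA_integer_, pct = NA_real_,
                 n_missing = sum(!ok),
                 mean = mean(x[ok]), sd = sd(x[ok]),
                 median = median(x[ok]),
                 iqr = unname(quantile(x[ok], 0.75) - quantile(x[ok], 0.25)))
}

summarise_categorical <- function(x, levels, group, characteristic) {
  x <- as.character(x)
  counts <- c(vapply(levels, function(l) sum(x == l, na.rm = TRUE),
                     integer(1)),
              missing = sum(is.na(x)))
  tibble::tibble(group = group, characteristic = characteristic,
                 level = names(counts), n = as.integer(counts),
                 pct = 100 * as.integer(counts) / length(x),
                 n_missing = NA_integer_, mean = NA_real_, sd = NA_real_,
                 median = NA_real_, iqr = NA_real_)
}

#' Descriptive summary of egos, networks and alters
#'
#' A tidy long version of the classic descriptive table: means (SD) and
#' medians (IQR) for numeric characteristics, counts (%) with explicit
#' missing-data rows for categorical ones, grouped into `ego`, `network` and
#' `alter` blocks.
#'
#' @param study A [study_data] (typically filtered); derived and structural
#'   columns are computed on the fly.
#' @return Tibble: `group`, `characteristic`, `level`, `n`, `pct`,
#'   `n_missing`, `mean`, `sd`, `median`, `iqr`.
#' @export
descriptives_table <- function(study) {
  if (!inherits(study, "derived_study")) study <- derive_study(study)
  struct <- structural_summary(study)
  assort <- study_assortativity(study)
  e <- study$egos
  a <- study$alters
  bw <- struct$alters$betweenness
  yn <- function(v) ifelse(is.na(v), NA_character_, ifelse(v == 1, "yes", "no"))
  dplyr::bind_rows(
    summarise_numeric(e$age, "ego", "age"),
    summarise_numeric(e$education, "ego", "education"),
    summarise_categorical(yn(e$vaccinated), c("no", "yes"), "ego", "vaccinated"),
    summarise_categorical(ifelse(e$sex == 1, "female", "male"),
                          c("male", "female"), "ego", "sex"),
    summarise_categorical(yn(e$single), c("no", "yes"), "ego", "single"),
    summarise_categorical(yn(e$employed), c("no", "yes"), "ego", "employed"),
    summarise_categorical(e$media_category, MEDIA_CATEGORIES, "ego", "media"),
    summarise_numeric(struct$networks$size, "network", "size"),
    summarise_numeric(struct$networks$density, "network", "density"),
    summarise_numeric(struct$networks$components, "network", "components"),
    summarise_numeric(a$age, "alter", "age"),
    summarise_numeric(a$education, "alter", "education"),
    summarise_categorical(yn(a$vaccinated), c("no", "yes"), "alter",
                          "vaccinated"),
    summarise_categorical(ifelse(a$sex == 1, "female", "male"),
                          c("male", "female"), "alter", "sex"),
    summarise_categorical(yn(a$single), c("no", "yes"), "alter", "single"),
    summarise_numeric(a$intensity, "alter", "intensity"),
    summarise_numeric(bw, "alter", "betweenness"),
    summarise_numeric(assort$score, "alter", "assortativity"))
}

#' Forest-plot-ready odds-ratio table for a model suite
#'
#' One row per (model, term) with the OR and its 95% CI; factor reference
#' levels are included with OR 1 and flagged, so plotting code can show them.
#'
#' @param suite A [model_suite()] result (or a single `mixed_fit`).
#' @return Tibble: `model_id`, `term`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `reference` (logical).
#' @export
forest_table <- function(suite) {
  fits <- if (inherits(suite, "model_suite")) suite$fits
  else list(model = suite)
  dplyr::bind_rows(lapply(names(fits), function(id) {
    f <- fits[[id]]
    rows <- f$coefficients |>
      dplyr::transmute(model_id = id, term = .data$term, or = .data$or,
                       ci_low = .data$or_low, ci_high = .data$or_high,
                       p_value = .data$p_value, reference = FALSE)
    if ("media" %in% f$predictors) {
      rows <- dplyr::bind_rows(
        rows,
        tibble::tibble(model_id = id, term = "mediatraditional", or = 1,
                       ci_low = 1, ci_high = 1, p_value = NA_real_,
                       reference = TRUE))
    }
    rows
  }))
}
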