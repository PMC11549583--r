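#' Alters eligible for analysis within one personal network
#'
#' An alter is eligible when its vaccination status is known and it is not an
#' isolate (degree >= 1 in the binarized alter graph) — isolates have no
#' network neighbours, so their assortativity score is undefined. Degrees are
#' evaluated once, on the original binarized graph; they are not recomputed
#' after removing ineligible alters.
#'
#' @param network A `personal_network` object.
#' @return The `alters` tibble restricted to eligible alters.
#' @export
eligible_alters <- function(network) {
  deg <- alter_degrees(network)
  keep <- !is.na(network$alters$vaccinated) & deg >= 1L
  network$alters[keep, , drop = FALSE]
}

#' Restrict a study to analyzable personal networks
#'
#' Retains personal networks with at least `min_alters` eligible alters
#' (vaccination status known and not an isolate); the boundary is inclusive.
#' Retained networks keep all their alters — per-alter eligibility is applied
#' later, when the model frame is built — so structural measures can still be
#' computed on the full nominated network.
#'
#' @param study A [study_data] object.
#' @param min_alters Minimum eligible-alter count for a network to be kept
#'   (default 15).
#' @return List with `study` (the retained subset, a [study_data]) and
#'   `report`: `per_ego` tibble (`ego_id`, `n_alters_raw`,
#'   `n_alters_eligible`, `included`, `exclusion_reason`) and `study` list
#'   (`n_networks_in`, `n_networks_out`, `n_alter_rows_out`).
#' @export
filter_networks <- function(study, min_alters = 15L) {
  stopifnot(inherits(study, "study_data"))
  if (min_alters < 1) {
    abort("config error: min_alters must be at least 1")
  }
  per_ego <- dplyr::bind_rows(lapply(networks(study), function(net) {
    n_elig <- nrow(eligible_alters(net))
    tibble::tibble(ego_id = net$ego$ego_id,
                   n_alters_raw = nrow(net$alters),
                   n_alters_eligible = n_elig,
                   included = n_elig >= min_alters,
                   exclusion_reason = if (n_elig >= min_alters) NA_character_
                   else "fewer_than_min_eligible_alters")
  }))
  keep <- per_ego$ego_id[per_ego$included]
  out <- study
  out$egos <- study$egos[study$egos$ego_id %in% keep, , drop = FALSE]
  out$alters <- study$alters[study$alters$ego_id %in% keep, , drop = FALSE]
  out$ties <- study$ties[study$ties$ego_id %in% keep, , drop = FALSE]
  list(study = out,
       report = list(
         per_ego = per_ego,
         study = list(n_networks_in = nrow(study$egos),
                      n_networks_out = length(keep),
                      n_alter_rows_out =
                        sum(per_ego$n_alters_eligible[per_ego$included]))))
}

# level-1 / level-2 numeric variables that get z-scored in the model frame
LEVEL1_NUMERIC <- c("alter_education", "alter_age", "betweenness",
                    "assortativity")
LEVEL2_NUMERIC <- c("ego_education", "ego_age", "size", "density",
                    "components")

#' Build the standardized two-level analysis table
#'
#' One row per eligible alter of a (filtered) study with complete data on all
#' model variables, ego-level columns repeated per row. Egos with missing
#' media category are dropped (in the field data the only ego-level
#' missingness). Numeric predictors are mean-centred and scaled: alter-level
#' ones over the retained alter rows, ego/network-level ones over the retained
#' egos (so each ego contributes once to its own scaling). Binary indicators
#' and the outcome are left on their original 0/1 scale. `loo_prop` — the
#' leave-one-out proportion of vaccinated alters of the same ego — is
#' computed over the rows of the frame itself.
#'
#' @param study A [study_data] (typically the output of [filter_networks()]);
#'   derived columns are added on the fly if absent.
#' @param scale Logical: standardize numeric predictors (default `TRUE`).
#' @param sd_denominator `"sample"` (n-1) or `"population"` (n).
#' @return Tibble with columns `ego_id`, `alter_id`, `vaccinated` (outcome),
#'   `alter_sex`, `alter_education`, `alter_single`, `alter_age`, `intensity`,
#'   `betweenness`, `assortativity`, `ego_sex`, `ego_education`, `ego_age`,
#'   `ego_employed`, `ego_vaccinated`, `media` (factor, reference
#'   `traditional`), `size`, `density`, `components`, `loo_prop`. Attributes:
#'   `scalers` (center/scale per standardized column), `drop_log` (per-reason
#'   dropped-row counts).
#' @export
model_frame <- function(study, scale = TRUE,
                        sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!inherits(study, "derived_study")) study <- derive_study(study)
  struct <- structural_summary(study)
  assort <- study_assortativity(study)

  elig <- dplyr::bind_rows(lapply(networks(study), eligible_alters))
  drop_log <- c(ineligible_alter = nrow(study$alters) - nrow(elig))

  egos <- study$egos
  missing_media <- is.na(egos$media_category)
  if (any(missing_media)) {
    inform(sprintf("%d ego(s) dropped from model frame: missing media use",
                   sum(missing_media)))
  }
  egos <- egos[!missing_media, , drop = FALSE]
  drop_log["ego_missing_media"] <- sum(elig$ego_id %in%
                                         study$egos$ego_id[missing_media])
  elig <- elig[elig$ego_id %in% egos$ego_id, , drop = FALSE]

  frame <- elig |>
    dplyr::transmute(ego_id = .data$ego_id, alter_id = .data$alter_id,
                     vaccinated = .data$vaccinated,
                     alter_sex = .data$sex, alter_education = .data$education,
                     alter_single = .data$single, alter_age = .data$age,
                     intensity = .data$intensity) |>
    dplyr::left_join(assort[c("ego_id", "alter_id", "score")],
                     by = c("ego_id", "alter_id")) |>
    dplyr::rename(assortativity = "score") |>
    dplyr::left_join(struct$alters, by = c("ego_id", "alter_id")) |>
    dplyr::left_join(
      egos |>
        dplyr::transmute(ego_id = .data$ego_id, ego_sex = .data$sex,
                         ego_education = .data$education, ego_age = .data$age,
                         ego_employed = .data$employed,
                         ego_vaccinated = .data$vaccinated,
                         media = .data$media_category),
      by = "ego_id") |>
    dplyr::left_join(struct$networks, by = "ego_id")

  # complete-case rule over every model variable
  model_vars <- c("vaccinated", "alter_sex", "alter_education", "alter_single",
                  "alter_age", "intensity", "betweenness", "assortativity",
                  "ego_sex", "ego_education", "ego_age", "ego_employed",
                  "ego_vaccinated", "media", "size", "density", "components")
  incomplete <- !stats::complete.cases(frame[model_vars])
  if (any(incomplete)) {
    reasons <- vapply(which(incomplete), function(i) {
      model_vars[which(is.na(frame[i, model_vars]))[1]]
    }, character(1))
    for (r in unique(reasons)) {
      drop_log[paste0("missing_", r)] <- sum(reasons == r)
    }
    inform(sprintf("%d incomplete alter row(s) dropped from model frame",
                   sum(incomplete)))
    frame <- frame[!incomplete, , drop = FALSE]
  }
  if (nrow(frame) == 0) {
    abort("empty model frame after filtering", class = "pnavax_empty_frame")
  }

  # leave-one-out vaccinated proportion, over the frame's own rows
  frame <- frame |>
    dplyr::group_by(.data$ego_id) |>
    dplyr::mutate(loo_prop = if (dplyr::n() > 1) {
      (sum(.data$vaccinated) - .data$vaccinated) / (dplyr::n() - 1)
    } else {
      NA_real_
    }) |>
    dplyr::ungroup()

  frame$media <- factor(frame$media, levels = MEDIA_CATEGORIES)

  # a constant numeric (possible in small or homogeneous studies, e.g. every
  # network one component) is centred to 0 rather than aborting the frame
  safe_scale <- function(values, reference, v) {
    z <- tryCatch(standardize(reference, denominator = sd_denominator),
                  error = function(e) {
                    warn(sprintf("'%s' has zero spread; centred to 0", v))
                    structure(reference - mean(reference),
                              center = mean(reference), scale = 1)
                  })
    list(values = (values - attr(z, "center")) / attr(z, "scale"),
         scaler = c(center = attr(z, "center"), scale = attr(z, "scale")))
  }
  scalers <- list()
  if (scale) {
    for (v in LEVEL1_NUMERIC) {
      s <- safe_scale(frame[[v]], frame[[v]], v)
      scalers[[v]] <- s$scaler
      frame[[v]] <- s$values
    }
    ego_rows <- !duplicated(frame$ego_id)
    if (sum(ego_rows) < 2) {
      abort("degenerate input: need at least 2 egos to standardize level-2 variables")
    }
    for (v in LEVEL2_NUMERIC) {
      s <- safe_scale(frame[[v]], frame[[v]][ego_rows], v)
      scalers[[v]] <- s$scaler
      frame[[v]] <- s$values
    }
  }
  attr(frame, "scalers") <- scalers
  attr(frame, "drop_log") <- drop_log
  frame
}
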