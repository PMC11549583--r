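#' Construct a personal-network study object
#'
#' Bundles the three linked tables of an egocentric study — ego attributes,
#' alter attributes with ego-alter tie attributes, and alter-alter ties — plus
#' an optional referral-chain edge list, into a validated `study_data` object.
#' Alters are ego-scoped: `alter_id` is unique within an ego, and the ego is
#' never a node of its own alter graph.
#'
#' Ordinal items (closeness, meeting frequency, tie strength) are coerced to
#' canonical lowercase tokens; 1-based numeric codes are accepted. Unparseable
#' labels are recorded as missing with a warning, never dropped. Duplicate
#' undirected ties (including both orientations of the same pair) are collapsed
#' to a single row with a warning.
#'
#' @param egos Data frame with columns `ego_id`, `sex`, `age`, `education`,
#'   `single`, `employed`, `vaccinated` and the five media indicators
#'   `media_central_tv`, `media_local_press`, `media_search`, `media_social`,
#'   `media_influencers` (0/1).
#' @param alters Data frame with columns `ego_id`, `alter_id`, `sex`, `age`,
#'   `education`, `single`, `vaccinated`, `closeness`, `meet_frequency`.
#' @param ties Data frame with columns `ego_id`, `a`, `b`, `strength`.
#' @param referrals Optional data frame with columns `referrer`, `referred`.
#'
#' @return An object of class `study_data`: a list with tibbles `egos`,
#'   `alters`, `ties` and (possibly `NULL`) `referrals`.
#' @export
#' @examples
#' s <- generate_study(generator_config(n_egos = 3, seed = 1))$study
#' s
study_data <- function(egos, alters, ties, referrals = NULL) {
  egos <- coerce_egos(tibble::as_tibble(egos))
  alters <- coerce_alters(tibble::as_tibble(alters))
  ties <- coerce_ties(tibble::as_tibble(ties))

  if (anyDuplicated(egos$ego_id)) {
    abort(sprintf("integrity error: duplicate ego_id(s): %s",
                  paste(unique(egos$ego_id[duplicated(egos$ego_id)]),
                        collapse = ", ")),
          class = "pnavax_integrity_error")
  }
  if (any(!alters$ego_id %in% egos$ego_id)) {
    abort("integrity error: alters reference unknown ego_id",
          class = "pnavax_integrity_error")
  }
  dup_alt <- duplicated(alters[c("ego_id", "alter_id")])
  if (any(dup_alt)) {
    abort(sprintf("integrity error: duplicate alter_id within ego: %s",
                  paste(unique(paste(alters$ego_id[dup_alt],
                                     alters$alter_id[dup_alt], sep = "/")),
                        collapse = ", ")),
          class = "pnavax_integrity_error")
  }

  # tie endpoints must resolve within the ego's alter list
  key <- paste(alters$ego_id, alters$alter_id)
  bad_a <- !(paste(ties$ego_id, ties$a) %in% key)
  bad_b <- !(paste(ties$ego_id, ties$b) %in% key)
  if (any(bad_a | bad_b)) {
    i <- which(bad_a | bad_b)[1]
    abort(sprintf(
      "integrity error: tie (%s, %s) of ego %s references an unknown alter",
      ties$a[i], ties$b[i], ties$ego_id[i]),
      class = "pnavax_integrity_error")
  }
  if (any(ties$a == ties$b)) {
    abort("integrity error: self-tie (a == b) in ties table",
          class = "pnavax_integrity_error")
  }

  # store undirected pairs once, endpoints in sorted order
  lo <- pmin(ties$a, ties$b)
  hi <- pmax(ties$a, ties$b)
  ties$a <- lo
  ties$b <- hi
  dup <- duplicated(ties[c("ego_id", "a", "b")])
  n_dup <- sum(dup)
  dup_by_ego <- if (n_dup > 0) table(ties$ego_id[dup]) else table(character())
  if (n_dup > 0) {
    warn(sprintf("collapsed %d duplicate undirected tie(s)", n_dup))
    ties <- ties[!dup, , drop = FALSE]
  }

  too_many <- table(alters$ego_id)
  if (any(too_many > 25)) {
    abort("integrity error: more than 25 alters nominated by an ego",
          class = "pnavax_integrity_error")
  }

  if (!is.null(referrals)) {
    referrals <- tibble::as_tibble(referrals)
    require_columns(referrals, c("referrer", "referred"), "referrals")
    referrals$referrer <- as.character(referrals$referrer)
    referrals$referred <- as.character(referrals$referred)
    if (any(!referrals$referred %in% egos$ego_id)) {
      abort("integrity error: referral edge refers to unknown referred ego",
            class = "pnavax_integrity_error")
    }
    # unknown referrers are permitted as explicit external seeds
  }

  structure(list(egos = egos, alters = alters, ties = ties,
                 referrals = referrals),
            collapsed_ties = as.list(dup_by_ego),
            class = "study_data")
}

EGO_COLUMNS <- c("ego_id", "sex", "age", "education", "single", "employed",
                 "vaccinated", "media_central_tv", "media_local_press",
                 "media_search", "media_social", "media_influencers")
ALTER_COLUMNS <- c("ego_id", "alter_id", "sex", "age", "education", "single",
                   "vaccinated", "closeness", "meet_frequency")
TIE_COLUMNS <- c("ego_id", "a", "b", "strength")

require_columns <- function(df, cols, table_name) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("format error: %s table is missing column(s): %s",
                  table_name, paste(missing_cols, collapse = ", ")),
          class = "pnavax_format_error")
  }
  invisible(df)
}

coerce_egos <- function(egos) {
  require_columns(egos, EGO_COLUMNS, "egos")
  egos$ego_id <- as.character(egos$ego_id)
  for (col in c("sex", "single", "employed", "vaccinated",
                grep("^media_", EGO_COLUMNS, value = TRUE))) {
    egos[[col]] <- coerce_binary(egos[[col]], paste0("egos$", col))
  }
  egos$age <- suppressWarnings(as.integer(egos$age))
  egos$education <- suppressWarnings(as.integer(egos$education))
  if (any(egos$age < 18, na.rm = TRUE)) {
    abort("integrity error: ego age below 18", class = "pnavax_integrity_error")
  }
  if (any(egos$education < 1 | egos$education > 13, na.rm = TRUE)) {
    abort("integrity error: ego education outside 1..13",
          class = "pnavax_integrity_error")
  }
  egos[EGO_COLUMNS]
}

coerce_alters <- function(alters) {
  require_columns(alters, ALTER_COLUMNS, "alters")
  alters$ego_id <- as.character(alters$ego_id)
  alters$alter_id <- as.character(alters$alter_id)
  for (col in c("sex", "single", "vaccinated")) {
    alters[[col]] <- coerce_binary(alters[[col]], paste0("alters$", col))
  }
  alters$age <- suppressWarnings(as.integer(alters$age))
  alters$education <- suppressWarnings(as.integer(alters$education))
  if (any(alters$education < 1 | alters$education > 13, na.rm = TRUE)) {
    abort("integrity error: alter education outside 1..13",
          class = "pnavax_integrity_error")
  }
  alters$closeness <- coerce_level(alters$closeness, CLOSENESS_LEVELS,
                                   "closeness")
  alters$meet_frequency <- coerce_level(alters$meet_frequency, MEET_LEVELS,
                                        "meet_frequency")
  alters[ALTER_COLUMNS]
}

coerce_ties <- function(ties) {
  require_columns(ties, TIE_COLUMNS, "ties")
  ties$ego_id <- as.character(ties$ego_id)
  ties$a <- as.character(ties$a)
  ties$b <- as.character(ties$b)
  ties$strength <- coerce_level(ties$strength, STRENGTH_LEVELS, "tie strength")
  ties[TIE_COLUMNS]
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data> %d personal networks, %d alters, %d ties%s\n",
              nrow(x$egos), nrow(x$alters), nrow(x$ties),
              if (is.null(x$referrals)) ""
              else sprintf(", %d referral edges", nrow(x$referrals))))
  invisible(x)
}

#' Number of personal networks in a study
#' @param study A `study_data` object.
#' @return Integer count of egos.
#' @export
n_networks <- function(study) nrow(study$egos)

#' Extract one personal network from a study
#'
#' @param study A `study_data` object.
#' @param ego_id Identifier of the ego whose network to extract.
#' @return A `personal_network` object: list with `ego` (one-row tibble),
#'   `alters` and `ties` tibbles restricted to that ego.
#' @export
get_network <- function(study, ego_id) {
  if (!ego_id %in% study$egos$ego_id) {
    abort(sprintf("unknown ego_id: %s", ego_id),
          class = "pnavax_integrity_error")
  }
  structure(
    list(ego = study$egos[study$egos$ego_id == ego_id, , drop = FALSE],
         alters = study$alters[study$alters$ego_id == ego_id, , drop = FALSE],
         ties = study$ties[study$ties$ego_id == ego_id, , drop = FALSE]),
    class = "personal_network")
}

#' @export
print.personal_network <- function(x, ...) {
  cat(sprintf("<personal_network> ego %s: %d alters, %d ties\n",
              x$ego$ego_id, nrow(x$alters), nrow(x$ties)))
  invisible(x)
}

#' List all personal networks of a study
#' @param study A `study_data` object.
#' @return Named list of `personal_network` objects, one per ego.
#' @export
networks <- function(study) {
  setNames(lapply(study$egos$ego_id, function(e) get_network(study, e)),
           study$egos$ego_id)
}

#' Media sources reported by each ego
#'
#' @param egos The `egos` tibble of a study.
#' @return A list, one entry per ego, each a character vector of source
#'   tokens (subset of the five questionnaire options); zero-length when the
#'   ego recorded no source, `NA` when the indicators themselves are missing.
#' @export
media_sources_of <- function(egos) {
  cols <- c(media_central_tv = "central_tv", media_local_press = "local_press",
            media_search = "search_engines", media_social = "social_media",
            media_influencers = "influencers")
  lapply(seq_len(nrow(egos)), function(i) {
    v <- unlist(egos[i, names(cols)])
    if (all(is.na(v))) return(NA_character_)
    unname(cols[which(v == 1)])
  })
}
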