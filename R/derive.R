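#' Categorize an ego's health-information media sources
#'
#' Maps the set of sources an ego reported for health and prevention
#' information to a three-level factor: `traditional` (only central TV and/or
#' local press), `online` (only search engines, social media and/or
#' influencers), or `both`. An empty or missing set yields `NA`. The reference
#' level for modelling is `traditional`.
#'
#' @param sources Character vector of source tokens, a subset of
#'   `pn_levels()$media_sources`; may be empty or `NA`.
#' @return One of `"traditional"`, `"online"`, `"both"`, or `NA_character_`.
#' @export
#' @examples
#' categorize_media(c("central_tv"))                   # "traditional"
#' categorize_media(c("search_engines", "social_media")) # "online"
#' categorize_media(c("local_press", "social_media"))  # "both"
categorize_media <- function(sources) {
  if (length(sources) == 0 || all(is.na(sources))) return(NA_character_)
  sources <- sources[!is.na(sources)]
  unknown <- setdiff(sources, MEDIA_SOURCES)
  if (length(unknown) > 0) {
    abort(sprintf("unknown media source token(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  trad <- any(sources %in% TRADITIONAL_SOURCES)
  onl <- any(sources %in% ONLINE_SOURCES)
  if (trad && onl) "both" else if (trad) "traditional" else "online"
}

check_level <- function(level, levels, what) {
  if (length(level) != 1 || is.na(level) || !(level %in% levels)) {
    abort(sprintf("unknown %s level: %s", what, paste(level, collapse = ", ")))
  }
  level
}

#' Binarize emotional closeness
#'
#' 1 iff the ego reported a *very close* relation with the alter; every other
#' level (not at all / not very / close) codes 0.
#'
#' @param level Closeness token or vector thereof (`pn_levels()$closeness`);
#'   `NA` propagates.
#' @return Integer 0/1 (or `NA`).
#' @export
binarize_closeness <- function(level) {
  vapply(level, function(l) {
    if (is.na(l)) return(NA_integer_)
    check_level(l, CLOSENESS_LEVELS, "closeness")
    as.integer(l == "very_close")
  }, integer(1), USE.NAMES = FALSE)
}

#' Binarize face-to-face meeting frequency
#'
#' 1 iff ego and alter meet at least twice a month (`every_2_weeks`, `weekly`
#' or `daily`); monthly or rarer codes 0.
#'
#' @param level Meeting-frequency token or vector
#'   (`pn_levels()$meet_frequency`); `NA` propagates.
#' @return Integer 0/1 (or `NA`).
#' @export
binarize_meet_frequency <- function(level) {
  vapply(level, function(l) {
    if (is.na(l)) return(NA_integer_)
    check_level(l, MEET_LEVELS, "meet_frequency")
    as.integer(l %in% c("every_2_weeks", "weekly", "daily"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Binarize an alter-alter tie label
#'
#' Any reported relation (acquaintance, casual friend, close friend) codes 1;
#' an absent label (`NA`, alters do not know each other) codes 0.
#'
#' @param strength Tie-strength token or vector (`pn_levels()$tie_strength`),
#'   possibly `NA`.
#' @return Integer 0/1.
#' @export
binarize_tie <- function(strength) {
  vapply(strength, function(s) {
    if (is.na(s)) return(0L)
    check_level(s, STRENGTH_LEVELS, "tie strength")
    1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Mean-centre and standardize a numeric vector
#'
#' Z-scores the non-missing entries (sample SD, denominator n-1 by default);
#' missing entries stay missing. The centring mean and scaling SD are attached
#' so the transform is invertible with [unstandardize()].
#'
#' @param values Numeric vector, possibly with `NA`.
#' @param denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return Numeric vector with attributes `center` and `scale`.
#' @export
#' @examples
#' standardize(c(1, 2, 3))       # -1 0 1
#' standardize(c(2, NA, 4))      # -0.707 NA 0.707
standardize <- function(values, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  ok <- !is.na(values)
  if (sum(ok) < 2) {
    abort("degenerate input: need at least 2 non-missing values to standardize")
  }
  m <- mean(values[ok])
  s <- sd(values[ok])
  if (denominator == "population") {
    s <- s * sqrt((sum(ok) - 1) / sum(ok))
  }
  if (!is.finite(s) || s == 0) {
    abort("degenerate input: zero spread, cannot standardize")
  }
  out <- (values - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Invert a standardization
#' @param z Output of [standardize()] (or any numeric vector).
#' @param center,scale Mean and SD used; default to `z`'s attributes.
#' @return Vector on the original scale.
#' @export
unstandardize <- function(z, center = attr(z, "center"),
                          scale = attr(z, "scale")) {
  as.numeric(z) * scale + center
}

#' Derive modelling variables from raw attributes and tie labels
#'
#' Augments a study with every deterministic derived variable: per alter,
#' `very_close`, `meets_2x_month` and their product `intensity` (1 iff the ego
#' feels very close to the alter *and* they meet at least twice a month); per
#' tie, `present` (binarized); per ego, `media_category`
#' (traditional/online/both, `NA` when no source recorded).
#'
#' @param study A [study_data] object.
#' @return The same `study_data` with added columns; class gains
#'   `"derived_study"`.
#' @export
derive_study <- function(study) {
  stopifnot(inherits(study, "study_data"))
  a <- study$alters
  a$very_close <- binarize_closeness(a$closeness)
  a$meets_2x_month <- binarize_meet_frequency(a$meet_frequency)
  a$intensity <- a$very_close * a$meets_2x_month
  study$alters <- a
  study$ties$present <- binarize_tie(study$ties$strength)
  study$egos$media_category <- vapply(media_sources_of(study$egos),
                                      categorize_media, character(1))
  class(study) <- unique(c("derived_study", class(study)))
  study
}
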