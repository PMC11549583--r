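#' Read a study from the three-table CSV interchange format
#'
#' Loads `egos`, `alters` and `ties` CSV tables (plus an optional `referrals`
#' table) and assembles a validated [study_data] object. Empty cells are read
#' as missing; ordinal items may be given as canonical tokens or 1-based
#' numeric codes.
#'
#' @param egos_path,alters_path,ties_path Paths to the three CSV tables.
#' @param referrals_path Optional path to a referral-chain edge list
#'   (`referrer`, `referred`).
#' @return A [study_data] object.
#' @seealso [save_study()] for the inverse; round-tripping is the identity on
#'   all typed fields.
#' @export
load_study <- function(egos_path, alters_path, ties_path,
                       referrals_path = NULL) {
  read_tbl <- function(path) {
    if (!file.exists(path)) {
      abort(sprintf("format error: file not found: %s", path),
            class = "pnavax_format_error")
    }
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, na = c("", "NA"))
  }
  referrals <- if (!is.null(referrals_path)) read_tbl(referrals_path) else NULL
  study_data(read_tbl(egos_path), read_tbl(alters_path), read_tbl(ties_path),
             referrals = referrals)
}

#' Write a study to the three-table CSV interchange format
#'
#' Writes `egos.csv`, `alters.csv`, `ties.csv` and, when referral edges are
#' present, `referrals.csv` into `out_dir`. [load_study()] applied to the
#' written files reproduces every typed field.
#'
#' @param study A [study_data] object.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named character vector of written paths.
#' @export
save_study <- function(study, out_dir) {
  stopifnot(inherits(study, "study_data"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("I/O error: cannot create directory %s", out_dir))
  }
  paths <- c(egos = file.path(out_dir, "egos.csv"),
             alters = file.path(out_dir, "alters.csv"),
             ties = file.path(out_dir, "ties.csv"))
  readr::write_csv(study$egos, paths["egos"], na = "")
  readr::write_csv(study$alters, paths["alters"], na = "")
  readr::write_csv(study$ties, paths["ties"], na = "")
  if (!is.null(study$referrals)) {
    paths["referrals"] <- file.path(out_dir, "referrals.csv")
    readr::write_csv(study$referrals, paths["referrals"], na = "")
  }
  invisible(paths)
}

#' Validate a study and summarise data-quality issues per network
#'
#' Pure reporting: never mutates or drops anything. For each personal network
#' it counts alters, alters with missing vaccination status, isolates in the
#' binarized alter graph, and duplicate tie rows that were collapsed when the
#' object was built.
#'
#' @param study A [study_data] object.
#' @return A tibble with one row per ego: `ego_id`, `n_alters`,
#'   `n_missing_vaccination`, `n_isolates`, `n_duplicate_ties_collapsed`,
#'   `all_clear` (logical).
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "study_data"))
  collapsed <- attr(study, "collapsed_ties") %||% list()
  rows <- lapply(study$egos$ego_id, function(e) {
    net <- get_network(study, e)
    deg <- alter_degrees(net)
    n_dup <- as.integer(collapsed[[e]] %||% 0L)
    tibble::tibble(
      ego_id = e,
      n_alters = nrow(net$alters),
      n_missing_vaccination = sum(is.na(net$alters$vaccinated)),
      n_isolates = sum(deg == 0L),
      n_duplicate_ties_collapsed = n_dup)
  })
  out <- dplyr::bind_rows(rows)
  out$all_clear <- out$n_missing_vaccination == 0L & out$n_isolates == 0L &
    out$n_duplicate_ties_collapsed == 0L
  out
}

#' Export a binarized alter graph as GraphML
#'
#' Writes the ego-excluded, binarized alter-alter graph of one personal
#' network for external network viewers. Node attributes carry the alter's
#' vaccination status where known.
#'
#' @param network A `personal_network` object.
#' @param path Output `.graphml` path.
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(network, path) {
  g <- build_alter_graph(network)
  vacc <- setNames(network$alters$vaccinated, network$alters$alter_id)
  igraph::V(g)$vaccinated <- ifelse(is.na(vacc[igraph::V(g)$name]), -1L,
                                    vacc[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
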