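#' Per-alter vaccination assortativity scores for one personal network
#'
#' For each alter i of an ego's network, the score is the difference between
#' the proportion of i's network neighbours that are vaccinated and the
#' proportion of all the ego's alters that are vaccinated, with i itself
#' excluded from both proportions. Alters with missing vaccination status are
#' excluded from the numerator and denominator of both proportions. A positive
#' score means i's direct neighbours are vaccinated above the network's
#' (leave-i-out) base rate — assortative mixing on the trait.
#'
#' The score is missing for isolates (no neighbour with known status) and in
#' networks with fewer than 2 known-status alters; it is never silently 0.
#'
#' @param network A `personal_network` object.
#' @return Tibble with one row per alter: `alter_id`, `n_known_neighbors`,
#'   `neighbor_prop`, `overall_prop`, `score` (all proportions in `[0, 1]`,
#'   score in `[-1, 1]` or `NA`).
#' @export
network_assortativity <- function(network) {
  g <- build_alter_graph(network)
  ids <- igraph::V(g)$name
  n <- length(ids)
  v <- setNames(network$alters$vaccinated, network$alters$alter_id)[ids]
  known <- as.numeric(!is.na(v))
  vacc <- ifelse(is.na(v), 0, v)
  if (n == 0) {
    return(tibble::tibble(alter_id = character(0),
                          n_known_neighbors = integer(0),
                          neighbor_prop = numeric(0),
                          overall_prop = numeric(0), score = numeric(0)))
  }
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nb_known <- as.numeric(A %*% known)
  nb_vacc <- as.numeric(A %*% (vacc * known))
  tot_known <- sum(known)
  oo_known <- tot_known - known          # leave-one-out known count
  oo_vacc <- sum(vacc * known) - vacc * known
  neighbor_prop <- ifelse(nb_known > 0, nb_vacc / nb_known, NA_real_)
  overall_prop <- ifelse(oo_known > 0, oo_vacc / oo_known, NA_real_)
  score <- neighbor_prop - overall_prop
  score[tot_known < 2] <- NA_real_
  tibble::tibble(alter_id = ids, n_known_neighbors = as.integer(nb_known),
                 neighbor_prop = neighbor_prop, overall_prop = overall_prop,
                 score = score)
}

#' Vaccination assortativity score of a single alter
#'
#' @param network A `personal_network` object.
#' @param focal `alter_id` of the focal alter.
#' @return One-row tibble as in [network_assortativity()]; `score` is `NA`
#'   when the focal alter has no neighbour with known vaccination status or
#'   the network has fewer than 2 known-status alters.
#' @export
#' @examples
#' # a vaccinated focal with 6 of 9 known-status neighbours vaccinated, in a
#' # 25-alter network with 14 vaccinated: 6/9 - 13/24 = 0.125
alter_assortativity <- function(network, focal) {
  res <- network_assortativity(network)
  if (!focal %in% res$alter_id) {
    abort(sprintf("unknown alter_id: %s", focal),
          class = "pnavax_integrity_error")
  }
  res[res$alter_id == focal, , drop = FALSE]
}

#' Mean assortativity score of a personal network
#'
#' Arithmetic mean over alters with a defined score; reports how many alters
#' contributed and how many were missing (isolates or degenerate networks).
#'
#' @param network A `personal_network` object.
#' @return List with `mean` (`NA` if no score is defined), `n_contributing`,
#'   `n_missing`.
#' @export
network_mean_assortativity <- function(network) {
  s <- network_assortativity(network)$score
  ok <- !is.na(s)
  list(mean = if (any(ok)) mean(s[ok]) else NA_real_,
       n_contributing = sum(ok), n_missing = sum(!ok))
}

#' Referral-chain dyad concordance on vaccination status
#'
#' Tabulates directed referrer-to-referred dyads of a link-tracing recruitment
#' chain by the vaccination status of both parties. Dyads with either status
#' unknown are excluded from the denominator (and logged). The headline
#' percentage is the share of dyads in which a vaccinated participant referred
#' another vaccinated participant.
#'
#' @param referral_edges Data frame with columns `referrer`, `referred`.
#' @param status Named 0/1 vector: vaccination status by `ego_id`.
#' @return List: `n_dyads`, `n_vv`, `n_vu`, `n_uv`, `n_uu`,
#'   `concordant_vacc_pct` (`NA` when `n_dyads` is 0), `n_excluded`.
#' @export
#' @examples
#' referral_concordance(
#'   data.frame(referrer = c("e1", "e1"), referred = c("e2", "e3")),
#'   c(e1 = 1, e2 = 1, e3 = 0))
referral_concordance <- function(referral_edges, status) {
  if (is.null(referral_edges) || nrow(referral_edges) == 0) {
    return(list(n_dyads = 0L, n_vv = 0L, n_vu = 0L, n_uv = 0L, n_uu = 0L,
                concordant_vacc_pct = NA_real_, n_excluded = 0L))
  }
  s_from <- unname(status[referral_edges$referrer])
  s_to <- unname(status[referral_edges$referred])
  keep <- !is.na(s_from) & !is.na(s_to)
  if (any(!keep)) {
    inform(sprintf(
      "%d referral dyad(s) excluded: vaccination status unknown for one side",
      sum(!keep)))
  }
  s_from <- s_from[keep]
  s_to <- s_to[keep]
  n_vv <- sum(s_from == 1 & s_to == 1)
  n_vu <- sum(s_from == 1 & s_to == 0)
  n_uv <- sum(s_from == 0 & s_to == 1)
  n_uu <- sum(s_from == 0 & s_to == 0)
  n <- length(s_from)
  list(n_dyads = n, n_vv = n_vv, n_vu = n_vu, n_uv = n_uv, n_uu = n_uu,
       concordant_vacc_pct = if (n > 0) 100 * n_vv / n else NA_real_,
       n_excluded = sum(!keep))
}

#' Recruitment response rate
#'
#' Share of invited persons who became respondents, as a percentage.
#'
#' @param n_respondents,n_invited Counts; `n_invited` must be positive and at
#'   least `n_respondents`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' response_rate(83, 153)  # 54.2 (to 1 dp)
response_rate <- function(n_respondents, n_invited) {
  stopifnot(n_invited > 0, n_respondents >= 0, n_respondents <= n_invited)
  100 * n_respondents / n_invited
}

#' Per-alter assortativity for every network of a study
#'
#' @param study A [study_data] object.
#' @return Tibble: `ego_id`, `alter_id`, `n_known_neighbors`, `neighbor_prop`,
#'   `overall_prop`, `score`.
#' @export
study_assortativity <- function(study) {
  dplyr::bind_rows(lapply(networks(study), function(net) {
    res <- network_assortativity(net)
    res$ego_id <- net$ego$ego_id
    res[c("ego_id", setdiff(names(res), "ego_id"))]
  }))
}
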