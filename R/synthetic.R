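#' Configuration for the synthetic personal-network generator
#'
#' Defaults emulate the field study the package is designed around: ~83 egos
#' nominating 15-25 alters each (sizes skewed towards 24-25), dense alter
#' graphs (mean density 0.65, between-network SD 0.21), attribute marginals
#' matching the study's descriptive table, vaccination assigned by a
#' two-level logistic model with a random ego intercept, a contagion
#' mechanism inducing small positive vaccination assortativity, ~11% missing
#' alter vaccination status and ~5% missing ego media use, and link-tracing
#' referral parameters (6 seeds, 76% status-concordant referrals).
#'
#' Generating coefficients apply to covariates centred at their configured
#' marginals (numerics z-scored by the configured mean/SD, binaries and media
#' dummies centred at their configured prevalence), so `intercept` is the
#' log-odds of alter vaccination for an average alter of an average ego.
#'
#' @param n_egos Number of egos.
#' @param alters_range,alters_weights Support and sampling weights of the
#'   per-ego alter count.
#' @param target_density Mean edge probability of the alter graphs.
#' @param density_sd Between-network SD of the edge probability (0 = fixed);
#'   drawn from a Beta distribution matched by moments.
#' @param graph_model `"bernoulli"` (independent edges, the default) or
#'   `"planted"` (two-block planted partition at the same expected density,
#'   mimicking the fragmented, subgroup-structured networks reported for
#'   unvaccinated egos).
#' @param block_ratio For `"planted"`: ratio of between-block to within-block
#'   edge probability (0 = disconnected blocks, 1 = Bernoulli).
#' @param ego,alter Named lists of attribute marginals (see defaults).
#' @param media_probs Probabilities of traditional/online/both media use.
#' @param p_media_missing Probability an ego's media use is missing.
#' @param coefficients Named list of generating fixed-effect log-odds.
#' @param intercept Log-odds of vaccination at covariate means.
#' @param sigma_ego SD of the ego random intercept.
#' @param contagion_rounds,contagion_strength Number of synchronous
#'   neighbour-influence rounds and their strength: each round adds
#'   `strength * (neighbour vaccinated fraction - 0.5)` to an alter's
#'   log-odds before a fresh Bernoulli draw, inducing positive assortativity.
#' @param p_isolate Per-alter probability of being isolated (all its ties
#'   removed); reintroduces the fragmentation and isolate-driven missing
#'   assortativity scores seen in field networks, which dense Bernoulli
#'   graphs alone would essentially never produce.
#' @param p_missing_alter_vacc Missing-completely-at-random rate for alter
#'   vaccination status.
#' @param referral Named list: `n_seeds`, `p_concordant`, `refusal_rate`,
#'   `mean_referrals`.
#' @param seed Integer seed; mandatory, every stochastic call is derived
#'   from it.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(
    n_egos = 83,
    alters_range = 15:25,
    alters_weights = c(1, 1, 1, 1, 1, 3, 3, 5, 5, 20, 60),
    target_density = 0.65,
    density_sd = 0.21,
    graph_model = c("bernoulli", "planted"),
    block_ratio = 0.15,
    ego = list(age_mean = 53.33, age_sd = 15.86, p_female = 0.52,
               educ_mean = 9.70, educ_sd = 1.78, p_single = 0.125,
               p_employed = 0.5625, p_vaccinated = 0.78),
    alter = list(age_mean = 52.64, age_sd = 16.06, p_female = 0.525,
                 educ_mean = 9.35, educ_sd = 1.93, p_single = 0.204,
                 closeness_probs = c(not_at_all = 0.05, not_very = 0.15,
                                     close = 0.40, very_close = 0.40),
                 meet_probs = c(lt_once_year = 0.02, once_year = 0.05,
                                few_times_year = 0.18, once_month = 0.20,
                                every_2_weeks = 0.20, weekly = 0.20,
                                daily = 0.15)),
    media_probs = c(traditional = 0.17, online = 0.33, both = 0.45) / 0.95,
    p_media_missing = 0.05,
    coefficients = list(
      alter_sex = log(1.13), alter_education = log(1.87),
      alter_single = log(0.67), alter_age = log(0.98),
      intensity = log(0.92),
      ego_sex = log(1.04), ego_education = log(1.24), ego_age = log(1.02),
      ego_employed = log(0.63), ego_vaccinated = log(3.75),
      media_online = log(0.37), media_both = log(0.75),
      size = log(0.96), density = log(1.23), components = log(1.04)),
    intercept = qlogis(0.64),
    sigma_ego = 0.913,
    contagion_rounds = 1,
    contagion_strength = 1.0,
    p_isolate = 0.01,
    p_missing_alter_vacc = 0.113,
    referral = list(n_seeds = 6, p_concordant = 0.76, refusal_rate = 0.458,
                    mean_referrals = 2),
    seed = NULL) {
  graph_model <- match.arg(graph_model)
  cfg <- list(n_egos = n_egos, alters_range = alters_range,
              alters_weights = alters_weights,
              target_density = target_density, density_sd = density_sd,
              graph_model = graph_model, block_ratio = block_ratio,
              ego = ego, alter = alter,
              media_probs = media_probs / sum(media_probs),
              p_media_missing = p_media_missing,
              coefficients = coefficients, intercept = intercept,
              sigma_ego = sigma_ego,
              contagion_rounds = contagion_rounds,
              contagion_strength = contagion_strength,
              p_isolate = p_isolate,
              p_missing_alter_vacc = p_missing_alter_vacc,
              referral = referral, seed = seed)
  probs <- c(cfg$target_density, cfg$p_media_missing, cfg$media_probs,
             cfg$p_missing_alter_vacc, cfg$p_isolate,
             ego$p_female, ego$p_single,
             ego$p_employed, ego$p_vaccinated, alter$p_female, alter$p_single,
             referral$p_concordant, referral$refusal_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("config error: probabilities must lie in [0, 1]")
  }
  if (length(alters_range) == 0 || length(alters_weights) != length(alters_range)) {
    abort("config error: alters_range empty or weights mismatched")
  }
  if (max(alters_range) > 25 || min(alters_range) < 1) {
    abort("config error: alters_range must lie in 1..25")
  }
  if (sigma_ego < 0 || contagion_rounds < 0) {
    abort("config error: sigma_ego and contagion_rounds must be non-negative")
  }
  structure(cfg, class = "generator_config")
}

#' Load a named generator profile
#'
#' Profiles are YAML files under `inst/extdata/profiles/`; the shipped
#' `lerestilike` profile is the package default configuration (synthetic —
#' it mirrors published marginals, not any individual-level data).
#'
#' @param name Profile name (currently `"lerestilike"`).
#' @param seed Integer seed to attach.
#' @return A `generator_config`.
#' @export
load_profile <- function(name = "lerestilike", seed = NULL) {
  path <- system.file("extdata", "profiles", paste0(name, ".yaml"),
                      package = "pnavax")
  if (path == "") abort(sprintf("unknown profile: %s", name))
  y <- yaml::read_yaml(path)
  y$media_probs <- unlist(y$media_probs)
  y$alter$closeness_probs <- unlist(y$alter$closeness_probs)
  y$alter$meet_probs <- unlist(y$alter$meet_probs)
  y$seed <- seed
  do.call(generator_config, y)
}

# discretized normal on the 1..13 education grid
sample_education <- function(n, mean, sd) {
  pmin(pmax(round(rnorm(n, mean, sd)), 1L), 13L)
}

sample_age <- function(n, mean, sd) {
  pmax(round(rnorm(n, mean, sd)), 18L)
}

#' Generate a random binarized alter graph
#'
#' Independent-edge (Bernoulli) simple undirected graph: each of the
#' `choose(n, 2)` possible alter-alter ties is present independently with
#' probability `target_density`, so the expected density equals the target.
#'
#' @param n Number of alters (>= 2).
#' @param target_density Edge probability in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An undirected `igraph` with vertex names `a01`, `a02`, ...
#' @export
generate_alter_graph <- function(n, target_density, seed = NULL) {
  if (n < 2 || target_density < 0 || target_density > 1) {
    abort("config error: need n >= 2 and target_density in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("a%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  present <- runif(nrow(pairs)) < target_density
  g <- igraph::graph_from_edgelist(pairs[present, , drop = FALSE],
                                   directed = FALSE)
  missing_ids <- setdiff(ids, igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(missing_ids), name = missing_ids)
  igraph::permute(g, match(igraph::V(g)$name, ids))
}

# two-block planted partition at the same expected density: within-block
# edge probability p_in, between-block p_out = block_ratio * p_in, with
# the mixture matching target_density
planted_alter_graph <- function(n, target_density, block_ratio) {
  ids <- sprintf("a%02d", seq_len(n))
  block <- rep(1:2, length.out = n)[order(runif(n))]
  pairs <- t(combn(seq_len(n), 2))
  within <- block[pairs[, 1]] == block[pairs[, 2]]
  w <- mean(within)
  p_in <- min(target_density / (w + (1 - w) * block_ratio), 1)
  # if within-block probability saturates, raise p_out so the expected
  # density still matches the target
  p_out <- if (p_in >= 1) min(max((target_density - w) / (1 - w), 0), 1)
  else block_ratio * p_in
  present <- runif(nrow(pairs)) < ifelse(within, p_in, p_out)
  el <- cbind(ids[pairs[present, 1]], ids[pairs[present, 2]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  missing_ids <- setdiff(ids, igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(missing_ids), name = missing_ids)
  g <- igraph::permute(g, match(igraph::V(g)$name, ids))
  igraph::set_vertex_attr(g, "block", value = block)
}

# one of {tv}, {press}, {tv,press} etc. consistent with a media category
sources_for_category <- function(category) {
  trad <- sample(c("central_tv", "local_press"),
                 size = sample(1:2, 1), replace = FALSE)
  onl <- sample(ONLINE_SOURCES, size = sample(1:3, 1), replace = FALSE)
  switch(category, traditional = trad, online = onl, both = c(trad, onl))
}

#' Generate a synthetic egocentric study with known ground truth
#'
#' Draws ego and alter attributes from the configured marginals (attributes
#' mutually independent), Bernoulli alter graphs at the configured density,
#' assigns alter vaccination from the two-level logistic model (ego intercept
#' ~ Normal(0, sigma_ego^2)), optionally applies contagion rounds that induce
#' positive assortativity, applies missingness last, and simulates the
#' link-tracing referral chain. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()] with a non-`NULL` `seed`.
#' @return List with `study` (a [study_data]) and `truth`: generating
#'   `coefficients`, `intercept`, `sigma_ego`, per-ego random intercepts
#'   `b_ego`, per-alter tibble `alters` (`ego_id`, `alter_id`, `eta_model`
#'   — the pre-contagion linear predictor — `vaccinated_true`, `eligible`),
#'   and `recruitment` (the link-tracing bookkeeping).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$seed)) abort("config error: seed is mandatory")
  set.seed(config$seed)
  cf <- config$coefficients
  eg <- config$ego
  al <- config$alter

  n_egos <- config$n_egos
  ego_ids <- sprintf("e%03d", seq_len(n_egos))
  media_cat <- sample(MEDIA_CATEGORIES, n_egos, replace = TRUE,
                      prob = config$media_probs)
  media_missing <- runif(n_egos) < config$p_media_missing
  egos <- tibble::tibble(
    ego_id = ego_ids,
    sex = rbinom(n_egos, 1, eg$p_female),
    age = sample_age(n_egos, eg$age_mean, eg$age_sd),
    education = sample_education(n_egos, eg$educ_mean, eg$educ_sd),
    single = rbinom(n_egos, 1, eg$p_single),
    employed = rbinom(n_egos, 1, eg$p_employed),
    vaccinated = rbinom(n_egos, 1, eg$p_vaccinated))
  media_ind <- matrix(0L, n_egos, 5,
                      dimnames = list(NULL, c("media_central_tv",
                                              "media_local_press",
                                              "media_search", "media_social",
                                              "media_influencers")))
  src_col <- c(central_tv = "media_central_tv", local_press = "media_local_press",
               search_engines = "media_search", social_media = "media_social",
               influencers = "media_influencers")
  for (i in seq_len(n_egos)) {
    if (media_missing[i]) {
      media_ind[i, ] <- NA_integer_
    } else {
      media_ind[i, src_col[sources_for_category(media_cat[i])]] <- 1L
    }
  }
  egos <- dplyr::bind_cols(egos, tibble::as_tibble(media_ind))

  b_ego <- rnorm(n_egos, 0, config$sigma_ego)

  # Beta draw for per-network edge probability, moment-matched to
  # (target_density, density_sd); degenerate SD means a fixed probability
  draw_density <- function() {
    m <- config$target_density
    s <- config$density_sd
    if (s <= 0 || m <= 0 || m >= 1) return(m)
    v <- min(s^2, m * (1 - m) * 0.98)
    k <- m * (1 - m) / v - 1
    stats::rbeta(1, m * k, (1 - m) * k)
  }

  alters_list <- list()
  ties_list <- list()
  truth_list <- list()
  for (i in seq_len(n_egos)) {
    n_alt <- if (length(config$alters_range) == 1) config$alters_range
    else sample(config$alters_range, 1, prob = config$alters_weights)
    aid <- sprintf("%s_a%02d", ego_ids[i], seq_len(n_alt))
    p_edge <- draw_density()
    g <- if (config$graph_model == "planted") {
      planted_alter_graph(n_alt, p_edge, config$block_ratio)
    } else {
      generate_alter_graph(n_alt, p_edge)
    }
    g <- igraph::set_vertex_attr(g, "name", value = aid)
    # dense Bernoulli graphs essentially never fragment, but field networks
    # do: a small per-alter isolation probability reintroduces isolates
    iso <- which(runif(n_alt) < config$p_isolate)
    if (length(iso) > 0) {
      g <- igraph::delete_edges(g, unique(unlist(igraph::incident_edges(g, iso))))
    }
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    deg <- rowSums(A)

    closeness <- sample(CLOSENESS_LEVELS, n_alt, replace = TRUE,
                        prob = al$closeness_probs[CLOSENESS_LEVELS])
    meet <- sample(MEET_LEVELS, n_alt, replace = TRUE,
                   prob = al$meet_probs[MEET_LEVELS])
    alt <- tibble::tibble(
      ego_id = ego_ids[i], alter_id = aid,
      sex = rbinom(n_alt, 1, al$p_female),
      age = sample_age(n_alt, al$age_mean, al$age_sd),
      education = sample_education(n_alt, al$educ_mean, al$educ_sd),
      single = rbinom(n_alt, 1, al$p_single),
      closeness = closeness, meet_frequency = meet)
    intensity <- binarize_closeness(closeness) * binarize_meet_frequency(meet)

    # generating linear predictor: covariates centred at configured marginals
    p_int <- sum(al$closeness_probs[c("very_close")]) *
      sum(al$meet_probs[c("every_2_weeks", "weekly", "daily")])
    med <- if (media_missing[i]) "traditional" else media_cat[i]
    comp0 <- component_count(g)
    eta <- config$intercept +
      cf$alter_sex * (alt$sex - al$p_female) +
      cf$alter_education * (alt$education - al$educ_mean) / al$educ_sd +
      cf$alter_single * (alt$single - al$p_single) +
      cf$alter_age * (alt$age - al$age_mean) / al$age_sd +
      cf$intensity * (intensity - p_int) +
      cf$ego_sex * (egos$sex[i] - eg$p_female) +
      cf$ego_education * (egos$education[i] - eg$educ_mean) / eg$educ_sd +
      cf$ego_age * (egos$age[i] - eg$age_mean) / eg$age_sd +
      cf$ego_employed * (egos$employed[i] - eg$p_employed) +
      cf$ego_vaccinated * (egos$vaccinated[i] - eg$p_vaccinated) +
      cf$media_online * ((med == "online") - config$media_probs[["online"]]) +
      cf$media_both * ((med == "both") - config$media_probs[["both"]]) +
      cf$size * (n_alt - 24) / 1.7 +
      cf$density * (p_edge - config$target_density) /
        max(config$density_sd, 1e-9) +
      cf$components * (comp0 - 1.16) / 0.51 +
      b_ego[i]

    vacc <- rbinom(n_alt, 1, plogis(eta))
    if (config$contagion_rounds > 0 && config$contagion_strength != 0) {
      for (r in seq_len(config$contagion_rounds)) {
        nb_frac <- ifelse(deg > 0, as.numeric(A %*% vacc) / deg, 0.5)
        vacc <- rbinom(n_alt, 1,
                       plogis(eta + config$contagion_strength * (nb_frac - 0.5)))
      }
    }
    vacc_obs <- vacc
    vacc_obs[runif(n_alt) < config$p_missing_alter_vacc] <- NA_integer_
    alt$vaccinated <- vacc_obs
    alt <- alt[c("ego_id", "alter_id", "sex", "age", "education", "single",
                 "vaccinated", "closeness", "meet_frequency")]
    alters_list[[i]] <- alt

    el <- igraph::as_edgelist(g)
    if (nrow(el) > 0) {
      ties_list[[i]] <- tibble::tibble(
        ego_id = ego_ids[i], a = pmin(el[, 1], el[, 2]),
        b = pmax(el[, 1], el[, 2]),
        strength = sample(STRENGTH_LEVELS, nrow(el), replace = TRUE))
    }
    truth_list[[i]] <- tibble::tibble(
      ego_id = ego_ids[i], alter_id = aid, eta_model = eta,
      vaccinated_true = vacc,
      eligible = !is.na(vacc_obs) & deg >= 1)
  }

  study <- study_data(egos, dplyr::bind_rows(alters_list),
                      if (length(ties_list) > 0) dplyr::bind_rows(ties_list)
                      else tibble::tibble(ego_id = character(0),
                                          a = character(0), b = character(0),
                                          strength = character(0)))
  referral_params <- config$referral
  referral_params$n_seeds <- min(referral_params$n_seeds, n_egos)
  recruitment <- simulate_link_tracing(study, referral_params)
  study$referrals <- recruitment$referral_edges
  list(study = study,
       truth = list(coefficients = cf, intercept = config$intercept,
                    sigma_ego = config$sigma_ego,
                    b_ego = setNames(b_ego, ego_ids),
                    alters = dplyr::bind_rows(truth_list),
                    recruitment = recruitment[setdiff(names(recruitment),
                                                      "referral_edges")]))
}

#' Simulate respondent-driven link-tracing recruitment over a study's egos
#'
#' Starting from `n_seeds` randomly chosen seed egos, each participant refers
#' a Poisson-distributed number of not-yet-contacted egos; with probability
#' `p_concordant` a referral targets an ego whose vaccination status matches
#' the referrer's (when one is available). Invitees refuse with probability
#' `refusal_rate` (refusals are counted as invited but join no edge). When
#' every chain dies out with egos still uncontacted, the chain is truncated
#' and a note logged.
#'
#' @param study A [study_data] object.
#' @param params List: `n_seeds`, `p_concordant`, `refusal_rate`,
#'   `mean_referrals`, and optionally `max_respondents` — recruitment stops
#'   once that many egos have responded (field studies stop at a target
#'   sample size long before the population is exhausted; without a cap a
#'   saturated chain is forced into discordant referrals as the
#'   minority-status pool drains).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return List: `referral_edges` (tibble `referrer`, `referred`), `seeds`,
#'   `n_invited`, `n_refused`, `n_respondents`, `response_rate_pct`.
#' @export
simulate_link_tracing <- function(study,
                                  params = list(n_seeds = 6,
                                                p_concordant = 0.76,
                                                refusal_rate = 0.458,
                                                mean_referrals = 2),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  egos <- study$egos
  if (nrow(egos) < params$n_seeds) {
    abort("config error: fewer egos than requested seeds")
  }
  max_resp <- params$max_respondents %||% Inf
  status <- setNames(egos$vaccinated, egos$ego_id)
  seeds <- sample(egos$ego_id, params$n_seeds)
  contacted <- seeds
  frontier <- seeds
  edges <- list()
  n_invited <- length(seeds)
  n_refused <- 0L
  participants <- seeds
  while (length(frontier) > 0 && length(participants) < max_resp) {
    nxt <- character(0)
    for (ref in frontier) {
      if (length(participants) >= max_resp) break
      remaining <- setdiff(egos$ego_id, contacted)
      if (length(remaining) == 0) break
      k <- min(stats::rpois(1, params$mean_referrals), length(remaining))
      for (j in seq_len(k)) {
        if (length(participants) >= max_resp) break
        remaining <- setdiff(egos$ego_id, contacted)
        if (length(remaining) == 0) break
        same <- remaining[!is.na(status[remaining]) & !is.na(status[ref]) &
                            status[remaining] == status[ref]]
        pool <- if (runif(1) < params$p_concordant && length(same) > 0) {
          same
        } else {
          diff_pool <- setdiff(remaining, same)
          if (length(diff_pool) > 0) diff_pool else remaining
        }
        target <- if (length(pool) == 1) pool else sample(pool, 1)
        contacted <- c(contacted, target)
        n_invited <- n_invited + 1L
        if (runif(1) < params$refusal_rate) {
          n_refused <- n_refused + 1L
        } else {
          participants <- c(participants, target)
          edges[[length(edges) + 1]] <- c(ref, target)
          nxt <- c(nxt, target)
        }
      }
    }
    frontier <- nxt
  }
  if (length(setdiff(egos$ego_id, contacted)) > 0 &&
      length(participants) < max_resp) {
    inform(sprintf("link-tracing chains died out with %d ego(s) uncontacted",
                   length(setdiff(egos$ego_id, contacted))))
  }
  referral_edges <- if (length(edges) > 0) {
    m <- do.call(rbind, edges)
    tibble::tibble(referrer = m[, 1], referred = m[, 2])
  } else {
    tibble::tibble(referrer = character(0), referred = character(0))
  }
  list(referral_edges = referral_edges, seeds = seeds,
       n_invited = n_invited, n_refused = n_refused,
       n_respondents = length(participants),
       response_rate_pct = response_rate(length(participants), n_invited))
}
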