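test_that("identical config and seed reproduce the study exactly", {
  cfg <- generator_config(n_egos = 10, seed = 123)
  g1 <- generate_study(cfg)
  g2 <- generate_study(cfg)
  expect_identical(g1$study$egos, g2$study$egos)
  expect_identical(g1$study$alters, g2$study$alters)
  expect_identical(g1$study$ties, g2$study$ties)
  expect_identical(g1$study$referrals, g2$study$referrals)
  expect_identical(g1$truth$b_ego, g2$truth$b_ego)

  g3 <- generate_study(generator_config(n_egos = 10, seed = 124))
  expect_false(identical(g1$study$alters, g3$study$alters))
  expect_error(generate_study(generator_config(n_egos = 10)),
               "seed is mandatory")
})

test_that("config validation rejects impossible settings", {
  expect_error(generator_config(target_density = 1.3, seed = 1),
               "config error")
  expect_error(generator_config(alters_range = 10:30, seed = 1),
               "config error")
  expect_error(generator_config(sigma_ego = -1, seed = 1), "config error")
  expect_error(generate_alter_graph(1, 0.5), "config error")
  expect_error(generate_alter_graph(10, -0.2), "config error")
})

test_that("generated attribute marginals track the configured ones", {
  cfg <- generator_config(n_egos = 400, seed = 2024)
  study <- generate_study(cfg)$study
  e <- study$egos
  n <- nrow(e)
  # 3*SE bands around each configured marginal
  band <- function(x, p) expect_lt(abs(mean(x) - p),
                                   3 * sqrt(p * (1 - p) / length(x)) + 1e-9)
  band(e$sex, 0.52)
  band(e$vaccinated, 0.78)
  band(e$employed, 0.5625)
  expect_lt(abs(mean(e$age) - 53.33), 3 * 15.86 / sqrt(n) + 1)  # +1: truncation
  expect_lt(abs(mean(e$education) - 9.7), 3 * 1.78 / sqrt(n) + 0.1)

  d <- derive_study(study)
  med <- d$egos$media_category
  expect_lt(abs(mean(is.na(med)) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  p_online <- 0.33 / 0.95
  expect_lt(abs(mean(med == "online", na.rm = TRUE) - p_online),
            3 * sqrt(p_online * (1 - p_online) / sum(!is.na(med))))

  a <- study$alters
  band(a$sex, 0.525)
  expect_lt(abs(mean(is.na(a$vaccinated)) - 0.113),
            3 * sqrt(0.113 * 0.887 / nrow(a)))
  expect_lt(abs(mean(d$alters$intensity) - 0.22),
            3 * sqrt(0.22 * 0.78 / nrow(a)) + 0.02)

  sizes <- table(a$ego_id)
  expect_true(all(sizes >= 15 & sizes <= 25))
  expect_gt(mean(sizes), 23)   # distribution skewed to 24-25 alters

  dens <- structural_summary(study)$networks$density
  expect_lt(abs(mean(dens) - 0.65), 0.05)
  expect_gt(sd(dens), 0.1)     # between-network density dispersion
})

test_that("vaccination base rate is honoured when all effects are off", {
  props <- vapply(1:8, function(s) {
    cfg <- generator_config(n_egos = 60, coefficients = zero_coefficients(),
                            sigma_ego = 0, contagion_rounds = 0,
                            p_missing_alter_vacc = 0, seed = 500 + s)
    mean(generate_study(cfg)$study$alters$vaccinated)
  }, numeric(1))
  n_total <- 8 * 60 * 24   # approximate alter count across replicates
  expect_lt(abs(mean(props) - 0.64), 3 * sqrt(0.64 * 0.36 / n_total) + 0.005)
  # and the mean assortativity is ~0 without contagion
  cfg <- generator_config(n_egos = 60, coefficients = zero_coefficients(),
                          sigma_ego = 0, contagion_rounds = 0, seed = 42)
  a <- study_assortativity(generate_study(cfg)$study)
  expect_lt(abs(mean(a$score, na.rm = TRUE)), 0.01)
})

test_that("contagion induces positive mean assortativity versus control", {
  # sparse graphs so neighbourhoods actually differ from the network mean;
  # in dense graphs every alter sees nearly the whole network and the score
  # is pinned near zero whatever the mechanism does
  mc <- function(strength, n_rep, seed0) {
    vapply(seq_len(n_rep), function(s) {
      cfg <- generator_config(
        n_egos = 40, target_density = 0.12, density_sd = 0,
        contagion_strength = strength, contagion_rounds = 5, sigma_ego = 0,
        coefficients = zero_coefficients(), p_missing_alter_vacc = 0,
        p_isolate = 0, seed = seed0 + s)
      mean(study_assortativity(generate_study(cfg)$study)$score, na.rm = TRUE)
    }, numeric(1))
  }
  with_contagion <- mc(6, 25, 6000)
  control <- mc(0, 25, 7000)
  se_diff <- sqrt(var(with_contagion) / 25 + var(control) / 25)
  expect_gt(mean(with_contagion) - mean(control), 3 * se_diff)
  expect_gt(mean(with_contagion), 0)
  expect_lt(abs(mean(control)), 3 * sd(control) / sqrt(25))
})

test_that("Bernoulli alter graphs hit the target density on average", {
  expect_equal(igraph::ecount(generate_alter_graph(25, 1.0, seed = 3)), 300)
  expect_equal(igraph::ecount(generate_alter_graph(25, 0.0, seed = 3)), 0)
  set.seed(8)
  dens <- replicate(400, graph_density(generate_alter_graph(25, 0.65)))
  se <- sqrt(0.65 * 0.35 / (400 * 300))
  expect_lt(abs(mean(dens) - 0.65), 3 * se)
})

test_that("planted-partition graphs keep the expected density but gain structure", {
  set.seed(9)
  cfg <- generator_config(n_egos = 30, graph_model = "planted",
                          block_ratio = 0.1, seed = 77)
  study <- generate_study(cfg)$study
  dens <- structural_summary(study)$networks$density
  expect_lt(abs(mean(dens) - 0.65), 0.08)
})

test_that("link tracing produces seeds, concordant referrals and bookkeeping", {
  # large population, recruitment stopped at a target sample size — an
  # uncapped chain would exhaust the minority-status pool and force
  # discordant referrals
  study <- generate_study(generator_config(n_egos = 600, seed = 900))$study
  lt <- simulate_link_tracing(
    study, params = list(n_seeds = 6, p_concordant = 0.76, refusal_rate = 0,
                         mean_referrals = 3, max_respondents = 120),
    seed = 901)
  expect_equal(length(lt$seeds), 6L)
  # chain roots: every referred ego appears once; seeds are never referred
  expect_false(any(lt$seeds %in% lt$referral_edges$referred))
  expect_equal(anyDuplicated(lt$referral_edges$referred), 0L)

  status <- setNames(study$egos$vaccinated, study$egos$ego_id)
  dy <- referral_concordance(lt$referral_edges, status)
  conc <- (dy$n_vv + dy$n_uu) / dy$n_dyads
  expect_lt(abs(conc - 0.76), 3 * sqrt(0.76 * 0.24 / dy$n_dyads) + 0.05)

  # refusals reduce the response rate
  lt2 <- simulate_link_tracing(
    study, params = list(n_seeds = 6, p_concordant = 0.76,
                         refusal_rate = 0.458, mean_referrals = 2),
    seed = 902)
  expect_lt(lt2$response_rate_pct, 100)
  expect_equal(lt2$n_respondents + lt2$n_refused, lt2$n_invited)

  # all-vaccinated, fully concordant chain
  all_v <- study
  all_v$egos$vaccinated <- 1L
  lt3 <- simulate_link_tracing(
    all_v, params = list(n_seeds = 6, p_concordant = 1, refusal_rate = 0,
                         mean_referrals = 3), seed = 903)
  dy3 <- referral_concordance(lt3$referral_edges,
                              setNames(all_v$egos$vaccinated,
                                       all_v$egos$ego_id))
  expect_equal(dy3$concordant_vacc_pct, 100)
})

test_that("generated studies flow through the whole pipeline unassisted", {
  g <- generate_study(generator_config(n_egos = 20, seed = 1234))
  rep <- validate_study(g$study)
  expect_equal(nrow(rep), 20L)
  d <- derive_study(g$study)
  f <- filter_networks(d)
  fr <- suppressMessages(suppressWarnings(model_frame(f$study)))
  expect_gt(nrow(fr), 0)
  m <- suppressWarnings(
    fit_random_intercept_logit(fr, c("alter_education", "ego_vaccinated",
                                     "media")))
  expect_true(is.finite(m$logLik))
})

test_that("the shipped lerestilike profile round-trips into a valid config", {
  cfg <- load_profile("lerestilike", seed = 7)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_egos, 83)
  expect_equal(cfg$target_density, 0.65)
  expect_equal(cfg$referral$n_seeds, 6)
  expect_equal(cfg$coefficients$media_online, log(0.37), tolerance = 1e-5)
  g <- generate_study(cfg)
  expect_equal(n_networks(g$study), 83)
  expect_error(load_profile("nope"), "unknown profile")
})
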