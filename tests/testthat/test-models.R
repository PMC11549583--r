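# shared fixture: moderately sized synthetic frame with real clustering
fixture_frame <- local({
  frame <- NULL
  function() {
    if (is.null(frame)) {
      g <- generate_study(generator_config(n_egos = 35, seed = 101))
      frame <<- suppressMessages(suppressWarnings(
        model_frame(filter_networks(derive_study(g$study))$study)))
    }
    frame
  }
})

test_that("latent-scale ICC follows sigma2 / (sigma2 + pi^2/3)", {
  expect_equal(icc_latent(0.83), 0.83 / (0.83 + pi^2 / 3), tolerance = 1e-15)
  expect_equal(round(icc_latent(0.83), 1), 0.2)
  expect_equal(icc_latent(pi^2 / 3), 0.5)
  expect_equal(icc_latent(0), 0)
  expect_error(icc_latent(-0.1), "non-negative")
  # strictly increasing and bounded in [0, 1)
  s <- seq(0, 50, by = 0.5)
  v <- icc_latent(s)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 1))
})

test_that("mixed fit reports coherent Wald tables and variance shares", {
  fr <- fixture_frame()
  m <- suppressWarnings(fit_random_intercept_logit(fr, pn_predictors("full")))
  co <- m$coefficients
  expect_equal(co$or, exp(co$estimate), tolerance = 1e-12)
  expect_true(all(co$or_low <= co$or & co$or <= co$or_high))
  expect_equal(co$p_value, 2 * pnorm(-abs(co$estimate / co$se)),
               tolerance = 1e-12)
  expect_equal(m$n_obs, nrow(fr))
  expect_equal(m$n_groups, length(unique(fr$ego_id)))
  expect_gte(m$icc, 0)
  expect_lt(m$icc, 1)
  expect_gte(m$r2_conditional, m$r2_marginal)
  expect_true(all(c(m$r2_marginal, m$r2_conditional) >= 0 &
                    c(m$r2_marginal, m$r2_conditional) < 1))
})

test_that("null-model R2 reduces to 0 and the ICC identity", {
  fr <- fixture_frame()
  m0 <- fit_random_intercept_logit(fr, pn_predictors("null"))
  expect_equal(nrow(m0$coefficients), 1L)   # intercept only
  expect_equal(m0$r2_marginal, 0, tolerance = 1e-10)
  expect_equal(m0$r2_conditional, m0$icc, tolerance = 1e-10)
})

test_that("mixed fit degenerates to plain logistic when sigma_ego = 0", {
  cf <- zero_coefficients()
  cf$alter_education <- log(1.87)
  cf$alter_single <- log(0.67)
  cf$ego_vaccinated <- log(3.75)
  cf$media_online <- log(0.37)
  g <- generate_study(generator_config(
    n_egos = 120, coefficients = cf, sigma_ego = 0, contagion_rounds = 0,
    p_missing_alter_vacc = 0, p_isolate = 0, p_media_missing = 0,
    seed = 211))
  fr <- suppressMessages(suppressWarnings(
    model_frame(filter_networks(derive_study(g$study))$study)))
  preds <- c("alter_education", "alter_single", "ego_vaccinated", "media")
  m <- suppressWarnings(fit_random_intercept_logit(fr, preds))
  g0 <- glm(vaccinated ~ alter_education + alter_single + ego_vaccinated +
              media, data = fr, family = binomial())
  expect_lt(m$sigma2_ego, 0.02)
  expect_equal(m$coefficients$estimate, unname(coef(g0)), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("constant outcomes and perfectly separating predictors are diagnosed", {
  fr <- fixture_frame()
  fr_const <- fr
  fr_const$vaccinated <- 1L
  expect_error(fit_random_intercept_logit(fr_const, "alter_sex"),
               class = "pnavax_separation_error")
  fr_sep <- fr
  fr_sep$alter_sex <- fr_sep$vaccinated     # perfect predictor
  expect_error(fit_random_intercept_logit(fr_sep, "alter_sex"),
               "alter_sex", class = "pnavax_separation_error")
})

test_that("leave-one-out vaccinated proportion is computed over frame rows", {
  fr <- fixture_frame()
  by_ego <- split(fr, fr$ego_id)
  for (chunk in by_ego[1:5]) {
    n <- nrow(chunk)
    expect_equal(chunk$loo_prop,
                 (sum(chunk$vaccinated) - chunk$vaccinated) / (n - 1))
  }
  # an ego whose frame alters are all vaccinated has loo_prop 1 everywhere
  all_v <- by_ego[vapply(by_ego, function(x) all(x$vaccinated == 1),
                         logical(1))]
  if (length(all_v) > 0) {
    expect_true(all(unlist(lapply(all_v, `[[`, "loo_prop")) == 1))
  }
})

test_that("cluster-robust fit returns robust and classical SEs", {
  fr <- fixture_frame()
  cl <- fit_cluster_robust_logit(fr)
  expect_equal(cl$n_clusters, length(unique(fr$ego_id)))
  expect_true(all(cl$coefficients$or_low <= cl$coefficients$or))
  expect_equal(length(cl$classical_se), nrow(cl$coefficients))
  one_ego <- fr[fr$ego_id == fr$ego_id[1], ]
  expect_error(fit_cluster_robust_logit(one_ego, "alter_sex"),
               "single ego")
})

test_that("robust SEs exceed classical SEs for ego-level predictors on average", {
  set.seed(311)
  ratios <- replicate(25, {
    g <- generate_study(generator_config(n_egos = 25, sigma_ego = 1.2,
                                         seed = sample.int(1e6, 1)))
    fr <- suppressMessages(suppressWarnings(
      model_frame(filter_networks(derive_study(g$study))$study)))
    cl <- fit_cluster_robust_logit(fr, c("alter_education", "ego_vaccinated",
                                         "media", "ego_education"))
    idx <- match(c("ego_vaccinated", "mediaonline", "mediaboth",
                   "ego_education"), cl$coefficients$term)
    idx <- idx[!is.na(idx)]
    mean(cl$coefficients$se[idx] / cl$classical_se[idx])
  })
  expect_gt(mean(ratios), 1)
})

test_that("the model suite spans null to full with consistent structure", {
  fr <- fixture_frame()
  suite <- suppressWarnings(model_suite(fr))
  expect_named(suite$fits, c("model1_null", "model2_attributes",
                             "model3_network", "model4_full"))
  expect_equal(suite$fits$model1_null$coefficients$term, "(Intercept)")
  expect_setequal(suite$fits$model4_full$predictors,
                  union(suite$fits$model2_attributes$predictors,
                        suite$fits$model3_network$predictors))
  expect_setequal(unique(suite$comparison$model_id), names(suite$fits))
  expect_equal(nrow(suite$indices), 4L)
})

test_that("generating only network effects leaves attribute ORs near 1", {
  cf <- zero_coefficients()
  cf$intensity <- 0.8
  g <- generate_study(generator_config(
    n_egos = 120, coefficients = cf, sigma_ego = 0.3, contagion_rounds = 0,
    p_missing_alter_vacc = 0, p_isolate = 0, p_media_missing = 0, seed = 401))
  fr <- suppressMessages(suppressWarnings(
    model_frame(filter_networks(derive_study(g$study))$study)))
  m2 <- suppressWarnings(
    fit_random_intercept_logit(fr, pn_predictors("attributes")))
  attr_or <- m2$coefficients$or[m2$coefficients$term != "(Intercept)"]
  expect_true(all(abs(log(attr_or)) < 0.5))
  m3 <- suppressWarnings(
    fit_random_intercept_logit(fr, pn_predictors("network")))
  est <- m3$coefficients[m3$coefficients$term == "intensity", ]
  expect_gt(est$estimate, 0)
  expect_lt(est$p_value, 0.05)
})

test_that("bivariate suite detects dependence and respects margins", {
  # strong ego-alter concordance by construction
  set.seed(17)
  n_ego <- 40
  mk_frame <- function(concordant) {
    ego_vacc <- rbinom(n_ego, 1, 0.6)
    rows <- lapply(seq_len(n_ego), function(i) {
      n_alt <- 20
      p <- if (concordant) ifelse(ego_vacc[i] == 1, 0.8, 0.25) else 0.55
      tibble::tibble(ego_id = sprintf("e%02d", i),
                     vaccinated = rbinom(n_alt, 1, p),
                     ego_vaccinated = ego_vacc[i],
                     media = factor(sample(c("traditional", "online", "both"),
                                           n_alt, replace = TRUE),
                                    levels = c("traditional", "online", "both")),
                     assortativity = rnorm(n_alt))
    })
    dplyr::bind_rows(rows)
  }
  dep <- suppressMessages(bivariate_suite(mk_frame(TRUE)))
  p_dep <- dep$p_value[dep$test == "alter_vacc_x_ego_vacc" &
                         dep$method == "chi-square"]
  expect_lt(p_dep, 1e-6)

  # independence: p should not be systematically extreme
  ps <- replicate(20, {
    b <- suppressMessages(bivariate_suite(mk_frame(FALSE)))
    b$p_value[b$test == "alter_vacc_x_ego_vacc" & b$method == "chi-square"]
  })
  expect_gt(mean(ps), 0.2)          # uniform p-values average ~0.5
  expect_lt(mean(ps < 0.05), 0.3)   # type-I rate not inflated wildly

  # quartile margins conserve group sizes
  fr <- mk_frame(TRUE)
  q <- cut(fr$assortativity,
           breaks = unique(quantile(fr$assortativity,
                                    probs = c(0, .25, .5, .75, 1))),
           include.lowest = TRUE, labels = FALSE)
  tab <- table(q, interaction(fr$media, fr$ego_vaccinated, drop = TRUE))
  expect_equal(unname(colSums(tab)),
               as.vector(table(interaction(fr$media, fr$ego_vaccinated,
                                           drop = TRUE))))
})
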