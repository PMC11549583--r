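ATTRIBUTE_PREDICTORS <- c("alter_sex", "alter_education", "alter_single",
                          "alter_age", "ego_sex", "ego_education", "ego_age",
                          "ego_employed", "ego_vaccinated", "media")
NETWORK_PREDICTORS <- c("intensity", "betweenness", "assortativity",
                        "size", "density", "components")

#' Predictor sets of the model suite
#'
#' @param which `"null"` (none), `"attributes"` (ego and alter attributes),
#'   `"network"` (relational and structural variables), or `"full"` (union).
#' @return Character vector of model-frame column names.
#' @export
pn_predictors <- function(which = c("full", "null", "attributes", "network")) {
  which <- match.arg(which)
  switch(which,
         null = character(0),
         attributes = ATTRIBUTE_PREDICTORS,
         network = NETWORK_PREDICTORS,
         full = c(ATTRIBUTE_PREDICTORS[1:4], NETWORK_PREDICTORS[1:3],
                  ATTRIBUTE_PREDICTORS[5:10], NETWORK_PREDICTORS[4:6]))
}

# error if a categorical predictor perfectly predicts the outcome
check_separation <- function(frame, predictors) {
  y <- frame$vaccinated
  if (length(unique(y)) < 2) {
    abort("separation diagnostic: outcome is constant",
          class = "pnavax_separation_error")
  }
  for (p in predictors) {
    x <- frame[[p]]
    if (is.factor(x) || length(unique(x)) <= 3) {
      by_cell <- tapply(y, x, function(v) length(unique(v)))
      if (all(by_cell == 1)) {
        abort(sprintf(
          "separation diagnostic: outcome constant within every cell of '%s'",
          p), class = "pnavax_separation_error")
      }
    }
  }
  invisible(TRUE)
}

wald_table <- function(est, vc, level = 0.95) {
  est <- est[!is.na(est)]          # aliased (rank-deficient) terms dropped
  est <- est[names(est) %in% rownames(vc)]
  vc <- vc[names(est), names(est), drop = FALSE]
  se <- sqrt(diag(vc))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  q <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(term = names(est), estimate = unname(est), se = unname(se),
                 z = unname(z), p_value = unname(p),
                 or = exp(unname(est)),
                 or_low = exp(unname(est - q * se)),
                 or_high = exp(unname(est + q * se)))
}

#' Fit a two-level random-intercept logistic regression
#'
#' Maximum-likelihood (Laplace) fit of alter vaccination status on the chosen
#' predictors with a random intercept per ego, via [lme4::glmer()]. Reports
#' Wald 95% CIs on the log-odds scale exponentiated to odds ratios, the
#' random-intercept variance, the latent-scale ICC, and Nakagawa
#' marginal/conditional R2. Deterministic given the frame and optimizer
#' settings. Non-convergence is flagged on the result, not raised; complete
#' separation by a categorical predictor raises a diagnostic error naming it.
#'
#' @param frame A [model_frame()] tibble.
#' @param predictors Character vector of frame columns (see
#'   [pn_predictors()]); empty for the null model.
#' @return Object of class `mixed_fit`: list with `coefficients` (tibble:
#'   term, estimate, se, z, p_value, or, or_low, or_high), `sigma2_ego`,
#'   `icc`, `r2_marginal`, `r2_conditional`, `n_obs`, `n_groups`, `logLik`,
#'   `aic`, `converged`, `predictors`, and the underlying `fit`.
#' @export
fit_random_intercept_logit <- function(frame, predictors = pn_predictors()) {
  stopifnot(all(predictors %in% names(frame)))
  if (length(unique(frame$ego_id)) < 2) {
    abort("need at least 2 ego groups for a random-intercept model")
  }
  check_separation(frame, predictors)
  rhs <- if (length(predictors) == 0) "1" else paste(predictors, collapse = " + ")
  fml <- as.formula(paste0("vaccinated ~ ", rhs, " + (1 | ego_id)"))
  fit <- lme4::glmer(fml, data = frame, family = binomial(),
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged) warn(paste("mixed fit convergence:", paste(msgs, collapse = "; ")))
  beta <- lme4::fixef(fit)
  vc <- as.matrix(vcov(fit))
  sigma2 <- as.numeric(lme4::VarCorr(fit)$ego_id[1, 1])
  r2 <- r2_nakagawa(fit)
  structure(list(coefficients = wald_table(beta, vc),
                 sigma2_ego = sigma2,
                 icc = icc_latent(sigma2),
                 r2_marginal = r2[["marginal"]],
                 r2_conditional = r2[["conditional"]],
                 n_obs = stats::nobs(fit),
                 n_groups = lme4::ngrps(fit)[["ego_id"]],
                 logLik = as.numeric(logLik(fit)),
                 aic = stats::AIC(fit),
                 converged = converged,
                 predictors = predictors,
                 fit = fit),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %d obs in %d ego groups; sigma2_ego=%.3f, ICC=%.3f\n",
              x$n_obs, x$n_groups, x$sigma2_ego, x$icc))
  cat(sprintf("  R2 marginal=%.3f conditional=%.3f  logLik=%.1f%s\n",
              x$r2_marginal, x$r2_conditional, x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Latent-scale intraclass correlation for a logistic mixed model
#'
#' Under the latent-threshold convention the level-1 residual of a logistic
#' model has variance pi^2/3, so the share of variance attributable to the
#' grouping is `sigma2 / (sigma2 + pi^2/3)`.
#'
#' @param sigma2_ego Random-intercept variance (>= 0).
#' @return ICC in `[0, 1)`.
#' @export
#' @examples
#' icc_latent(0.83)  # ~0.2015, i.e. 0.2 at one decimal
icc_latent <- function(sigma2_ego) {
  if (any(sigma2_ego < 0)) abort("sigma2_ego must be non-negative")
  sigma2_ego / (sigma2_ego + pi^2 / 3)
}

#' Nakagawa marginal and conditional R2 for a logistic mixed model
#'
#' Marginal R2 is the variance of the fixed-effect linear predictor over the
#' total latent variance (fixed + random intercept + logit residual pi^2/3);
#' conditional R2 adds the random-intercept variance to the numerator.
#'
#' @param fit A `mixed_fit` or `glmerMod` object.
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "mixed_fit")) fit <- fit$fit
  eta_fixed <- as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit))
  var_f <- if (length(eta_fixed) > 1) var(eta_fixed) else 0
  sigma2 <- as.numeric(lme4::VarCorr(fit)$ego_id[1, 1])
  total <- var_f + sigma2 + pi^2 / 3
  c(marginal = var_f / total, conditional = (var_f + sigma2) / total)
}

#' Logistic GLM with ego-clustered robust standard errors
#'
#' Single-level logistic fit of the same outcome with cluster-robust (CR)
#' covariance clustered by ego, via [sandwich::vcovCL()]. To compensate for
#' the absent random intercept the default predictor set adds `loo_prop`, the
#' leave-one-out proportion of vaccinated alters of the same ego. CR1
#' small-sample scaling is applied by default (`cadjust = TRUE`); set
#' `cadjust = FALSE` for CR0.
#'
#' @param frame A [model_frame()] tibble (must contain `loo_prop` when it is
#'   among the predictors).
#' @param predictors Frame columns; default full set plus `loo_prop`.
#' @param cadjust Logical, CR1 cluster-count correction.
#' @return Object of class `glm_cluster_fit`: list with `coefficients`
#'   (robust-SE Wald table as in [fit_random_intercept_logit()]),
#'   `classical_se`, `n_obs`, `n_clusters`, and the underlying `fit`.
#' @export
fit_cluster_robust_logit <- function(frame,
                                     predictors = c(pn_predictors(), "loo_prop"),
                                     cadjust = TRUE) {
  stopifnot(all(predictors %in% names(frame)))
  n_cl <- length(unique(frame$ego_id))
  if (n_cl < 2) {
    abort("cluster-robust SEs undefined with a single ego cluster")
  }
  if ("loo_prop" %in% predictors && any(is.na(frame$loo_prop))) {
    abort("loo_prop missing for some rows (single-alter egos); drop them first")
  }
  check_separation(frame, predictors)
  rhs <- if (length(predictors) == 0) "1" else paste(predictors, collapse = " + ")
  fit <- glm(as.formula(paste0("vaccinated ~ ", rhs)), data = frame,
             family = binomial())
  vc <- sandwich::vcovCL(fit, cluster = frame$ego_id, cadjust = cadjust)
  structure(list(coefficients = wald_table(coef(fit), vc),
                 classical_se = sqrt(diag(vcov(fit))),
                 n_obs = stats::nobs(fit),
                 n_clusters = n_cl,
                 fit = fit),
            class = "glm_cluster_fit")
}

#' Fit the four-model comparison suite
#'
#' Fits, on one model frame: model 1 — null (intercept and random intercept
#' only); model 2 — ego and alter attributes only; model 3 — network
#' variables only (intensity, betweenness, assortativity, size, density,
#' components); model 4 — full. Returns the fits, a tidy long comparison
#' table, and per-model indices.
#'
#' @param frame A [model_frame()] tibble.
#' @return Object of class `model_suite`: list with `fits` (named list of
#'   `mixed_fit`), `comparison` (long tibble: model_id, term, estimate, se,
#'   p_value, or, or_low, or_high), `indices` (tibble: model_id, sigma2_ego,
#'   icc, r2_marginal, r2_conditional, logLik, aic, n_obs, n_groups).
#' @export
model_suite <- function(frame) {
  specs <- list(model1_null = "null", model2_attributes = "attributes",
                model3_network = "network", model4_full = "full")
  fits <- lapply(specs, function(w)
    fit_random_intercept_logit(frame, pn_predictors(w)))
  comparison <- dplyr::bind_rows(lapply(names(fits), function(id) {
    dplyr::mutate(fits[[id]]$coefficients, model_id = id, .before = 1)
  }))
  indices <- dplyr::bind_rows(lapply(names(fits), function(id) {
    f <- fits[[id]]
    tibble::tibble(model_id = id, sigma2_ego = f$sigma2_ego, icc = f$icc,
                   r2_marginal = f$r2_marginal,
                   r2_conditional = f$r2_conditional, logLik = f$logLik,
                   aic = f$aic, n_obs = f$n_obs, n_groups = f$n_groups)
  }))
  structure(list(fits = fits, comparison = comparison, indices = indices),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite> 4 random-intercept logistic models\n")
  print(as.data.frame(x$indices), digits = 3)
  invisible(x)
}

# chi-square with Fisher fallback when expected counts are sparse
chisq_or_fisher <- function(tab, label) {
  ch <- suppressWarnings(chisq.test(tab, correct = FALSE))
  out <- tibble::tibble(test = label, method = "chi-square",
                        statistic = unname(ch$statistic),
                        df = unname(ch$parameter),
                        p_value = unname(ch$p.value))
  if (any(ch$expected < 5)) {
    inform(sprintf("sparse cells in '%s': adding Fisher exact p", label))
    fp <- tryCatch(fisher.test(tab)$p.value,
                   error = function(e)
                     fisher.test(tab, simulate.p.value = TRUE,
                                 B = 10000)$p.value)
    out <- dplyr::bind_rows(out, tibble::tibble(
      test = label, method = "fisher", statistic = NA_real_, df = NA_real_,
      p_value = fp))
  }
  out
}

#' Routine bivariate companions to the model suite
#'
#' Runs the descriptive hypothesis tests that accompany the multilevel
#' models: chi-square tests of alter vaccination against ego vaccination and
#' against ego media category; a chi-square (with Fisher fallback on sparse
#' cells) of ego vaccination against media category at the ego level;
#' two-sided pooled-variance t tests of the assortativity score grouped by
#' alter and by ego vaccination status; and a chi-square of assortativity
#' quartiles against the six media-by-ego-vaccination groups.
#'
#' @param frame A [model_frame()] tibble.
#' @return Tibble: `test`, `method`, `statistic`, `df`, `p_value`.
#' @export
bivariate_suite <- function(frame) {
  out <- list()
  out$a <- chisq_or_fisher(table(frame$vaccinated, frame$ego_vaccinated),
                           "alter_vacc_x_ego_vacc")
  out$b <- chisq_or_fisher(table(frame$vaccinated, frame$media),
                           "alter_vacc_x_ego_media")
  ego_rows <- frame[!duplicated(frame$ego_id), ]
  out$c <- chisq_or_fisher(table(ego_rows$ego_vaccinated, ego_rows$media),
                           "ego_vacc_x_ego_media")
  tt <- function(score, group, label) {
    t_res <- t.test(score[group == 0], score[group == 1], var.equal = TRUE)
    tibble::tibble(test = label, method = "t-test",
                   statistic = unname(t_res$statistic),
                   df = unname(t_res$parameter),
                   p_value = unname(t_res$p.value))
  }
  out$d <- tt(frame$assortativity, frame$vaccinated,
              "assortativity_by_alter_vacc")
  out$e <- tt(frame$assortativity, frame$ego_vaccinated,
              "assortativity_by_ego_vacc")
  q <- cut(frame$assortativity,
           breaks = unique(quantile(frame$assortativity,
                                    probs = c(0, .25, .5, .75, 1))),
           include.lowest = TRUE, labels = FALSE)
  grp <- interaction(frame$media, frame$ego_vaccinated, drop = TRUE)
  out$f <- chisq_or_fisher(table(q, grp), "assortativity_quartiles_x_media_vacc")
  dplyr::bind_rows(out)
}
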