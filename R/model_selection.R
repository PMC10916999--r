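# Count-family GLMs with fixed covariates, exhaustive additive enumeration
# of motor-feature subsets, AICc ranking and delta-AIC equivalence sets.
# Because the motor features are transformations of the same key-press data
# they are strongly dependent, so models are compared by information
# criterion rather than by per-coefficient p-values.

#' The five fixed covariates
#'
#' Age, sex, education level, and the HADS depression and anxiety scores are
#' forced into every candidate model.
#'
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("age_years", "sex", "education_level", "hads_depression", "hads_anxiety")
}

#' Small-sample corrected AIC
#'
#' `AIC = -2 loglik + 2k`; `AICc = AIC + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (intercept, slopes, factor
#'   contrasts, and any dispersion/scale parameter).
#' @param n Number of observations; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")",
      call. = FALSE
    )
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Build the per-participant analysis table
#'
#' Joins the filtered participant records with their motor feature row.
#'
#' @param participants Participant tibble (typically
#'   `apply_exclusions(...)$included`).
#' @param features Feature tibble from [build_feature_table()].
#' @return Tibble with one row per participant.
#' @export
analysis_table <- function(participants, features) {
  dplyr::inner_join(participants, features, by = "participant_id")
}

.fit_family <- function(formula, data, family, init_theta = NULL) {
  warn <- character(0)
  fit <- withCallingHandlers(
    switch(family,
      poisson = stats::glm(formula, data = data, family = stats::poisson()),
      negative_binomial = if (is.null(init_theta)) {
        MASS::glm.nb(formula, data = data)
      } else {
        MASS::glm.nb(formula, data = data, init.theta = init_theta)
      },
      gaussian = stats::glm(formula, data = data, family = stats::gaussian()),
      stop("unknown family: ", family, call. = FALSE)
    ),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  glm_converged <- isTRUE(fit$converged)
  # strict flag: the mean model converged AND the dispersion estimate is
  # stable (no iteration/alternation limit); used for equivalence reasoning
  converged <- glm_converged &&
    !any(grepl("iteration limit|alternation limit", warn)) &&
    is.null(fit$th.warn)
  list(
    fit = fit, converged = converged, glm_converged = glm_converged,
    warnings = warn
  )
}

#' Fit one candidate GLM
#'
#' Fits `outcome ~ covariates + features` by maximum likelihood with a log
#' link for the count families (Poisson, negative binomial) and the identity
#' link for the Gaussian fallback. Convergence problems are reported through
#' the `converged` flag, never silently.
#'
#' @param outcome Name of the count outcome column.
#' @param features Character vector of motor-feature columns (may be empty:
#'   the covariates-only null model).
#' @param data Analysis table ([analysis_table()]); used columns must be
#'   complete.
#' @param family `"poisson"`, `"negative_binomial"` or `"gaussian"`.
#' @param covariates Fixed covariates, included in every model.
#' @param init_theta Optional starting value for the negative-binomial
#'   dispersion (speeds up repeated fits on the same data).
#' @param keep_model Keep the underlying `glm` object (default `TRUE`; the
#'   enumeration drops it to bound memory).
#' @return A `tapcog_fit` list: coefficient table with standard errors,
#'   log-likelihood, parameter count `k` (counting every estimated parameter
#'   once, including the NB dispersion and Gaussian scale), `n`, `aic`,
#'   `aicc`, residual and null deviances, and the `converged` flag.
#' @export
fit_glm <- function(outcome, features = character(0), data,
                    family = c("negative_binomial", "poisson", "gaussian"),
                    covariates = default_covariates(),
                    init_theta = NULL, keep_model = TRUE) {
  family <- match.arg(family)
  used <- c(outcome, covariates, features)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  nas <- vapply(data[used], anyNA, logical(1))
  if (any(nas)) {
    stop(
      "missing values in used column(s): ",
      paste(used[nas], collapse = ", "),
      call. = FALSE
    )
  }
  rhs <- paste(c(covariates, features), collapse = " + ")
  if (rhs == "") rhs <- "1"
  formula <- as.formula(paste(outcome, "~", rhs))
  res <- .fit_family(formula, data, family, init_theta)
  fit <- res$fit
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop(
      "rank-deficient design; collinear column(s): ",
      paste(names(cf)[is.na(cf)], collapse = ", "),
      call. = FALSE
    )
  }
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- nobs(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- list(
    outcome = outcome,
    features = features,
    covariates = covariates,
    family = family,
    coefficients = tibble::tibble(
      term = names(cf), estimate = unname(cf), se = unname(se[names(cf)])
    ),
    loglik = as.numeric(ll),
    k = k,
    n = n,
    aic = -2 * as.numeric(ll) + 2 * k,
    aicc = aicc(as.numeric(ll), k, n),
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    theta = if (family == "negative_binomial") fit$theta else NA_real_,
    converged = res$converged,
    glm_converged = res$glm_converged,
    warnings = res$warnings,
    model = if (keep_model) fit else NULL
  )
  class(out) <- "tapcog_fit"
  out
}

#' @export
print.tapcog_fit <- function(x, ...) {
  cat(sprintf(
    "<tapcog_fit> %s ~ %s [%s]%s\n  n = %d, k = %d, logLik = %.2f, AICc = %.2f\n",
    x$outcome,
    if (length(x$features)) paste(x$features, collapse = " + ") else "(null)",
    x$family,
    if (x$converged) "" else "  ** NOT CONVERGED **",
    x$n, x$k, x$loglik, x$aicc
  ))
  invisible(x)
}

#' Adjusted pseudo-R-squared
#'
#' A deviance-based convention:
#' `1 - (residual deviance / null deviance) * (n - 1)/(n - k)`, clamped
#' below at 0, where `k` counts the mean-model coefficients and the null
#' deviance is taken from `null_fitted`. For a Gaussian model compared
#' against the intercept-only model this reduces exactly to the classical
#' adjusted R-squared. It is a package convention for GLMs (reported as
#' such), not a likelihood-theoretic quantity.
#'
#' @param fitted A `tapcog_fit`.
#' @param null_fitted The reference fit on the same data (its *residual*
#'   deviance is used as the null deviance); defaults to the intercept-only
#'   deviance stored with `fitted`.
#' @return Proportion in \[0, 1\].
#' @export
adjusted_pseudo_r2 <- function(fitted, null_fitted = NULL) {
  null_dev <- if (is.null(null_fitted)) {
    fitted$null_deviance
  } else {
    null_fitted$deviance
  }
  k_mean <- nrow(fitted$coefficients)
  r2 <- 1 - (fitted$deviance / null_dev) * (fitted$n - 1) / (fitted$n - k_mean)
  max(r2, 0)
}

#' Incident rate ratios of a count-model fit
#'
#' Exponentiated coefficients with Wald confidence bounds. An IRR above 1
#' means a higher expected error count per unit increase of the predictor;
#' below 1, a lower count. Only defined for log-link count families.
#'
#' @param fitted A `tapcog_fit` with family poisson or negative binomial.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `term`, `irr`, `conf_low`, `conf_high`.
#' @export
incident_rate_ratios <- function(fitted, level = 0.95) {
  if (fitted$family == "gaussian") {
    stop("incident rate ratios are undefined for a gaussian (identity link) fit",
      call. = FALSE
    )
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  cf <- fitted$coefficients
  tibble::tibble(
    term = cf$term,
    irr = exp(cf$estimate),
    conf_low = exp(cf$estimate - z * cf$se),
    conf_high = exp(cf$estimate + z * cf$se)
  )
}

#' Exhaustive all-subsets model comparison
#'
#' Fits every additive combination of the candidate motor features (2^m
#' models, never with interactions), each including the fixed covariates,
#' and ranks the models by AICc. The covariates-only null model is the empty
#' subset. Models within 2 AICc units of the best converged model form the
#' statistical-equivalence set. Non-converged fits stay visible in the table
#' but are flagged, ranked last, and never define the equivalence set.
#'
#' Ties in AICc are broken by smaller `k`, then by feature names, so the
#' table is deterministic.
#'
#' @param data Analysis table with no missing values in used columns.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate feature columns (m <= 16
#'   enforced by default; enumeration is 2^m).
#' @param family Model family for every fit.
#' @param covariates Fixed covariates.
#' @param cap Hard limit on m (default 16); raise explicitly for larger
#'   enumerations.
#' @param warn_above Emit a runtime warning when m exceeds this (default 12).
#' @return A `model_table`: tibble with columns `rank`, `features`, `k`,
#'   `loglik`, `aic`, `aicc`, `delta_aicc`, `equivalent`, `converged`,
#'   `is_null`, `pseudo_r2_adj`, carrying the slim fits and metadata as
#'   attributes.
#' @export
dredge_subsets <- function(data, outcome, candidates,
                           family = c("negative_binomial", "poisson", "gaussian"),
                           covariates = default_covariates(),
                           cap = 16, warn_above = 12) {
  family <- match.arg(family)
  m <- length(candidates)
  if (m > cap) {
    stop(
      "candidate set of ", m, " features implies 2^", m,
      " model fits, above the cap (", cap, "); raise `cap` explicitly ",
      "if this is intended",
      call. = FALSE
    )
  }
  if (m > warn_above) {
    warning("enumerating 2^", m, " = ", 2^m, " models; this may be slow",
      call. = FALSE
    )
  }
  null_fit <- fit_glm(outcome, character(0), data,
    family = family,
    covariates = covariates, keep_model = FALSE
  )
  init_theta <- if (family == "negative_binomial") null_fit$theta else NULL
  n_models <- 2^m
  fits <- vector("list", n_models)
  fits[[1]] <- null_fit
  if (n_models > 1) {
    for (idx in 2:n_models) {
      bits <- bitwAnd(idx - 1, 2^(seq_len(m) - 1)) > 0
      feats <- candidates[bits]
      fits[[idx]] <- tryCatch(
        fit_glm(outcome, feats, data,
          family = family,
          covariates = covariates, init_theta = init_theta,
          keep_model = FALSE
        ),
        error = function(e) {
          # a failed fit stays in the table as a non-converged placeholder
          list(
            outcome = outcome, features = feats, family = family,
            coefficients = tibble::tibble(
              term = character(0), estimate = numeric(0), se = numeric(0)
            ),
            loglik = NA_real_, k = NA_integer_, n = nrow(data),
            aic = NA_real_, aicc = NA_real_,
            deviance = NA_real_, null_deviance = null_fit$null_deviance,
            theta = NA_real_, converged = FALSE,
            warnings = conditionMessage(e), model = NULL
          )
        }
      )
    }
  }
  tab <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      features = paste(sort(f$features), collapse = "+"),
      n_features = length(f$features),
      k = f$k,
      loglik = f$loglik,
      aic = f$aic,
      aicc = f$aicc,
      converged = f$converged,
      is_null = length(f$features) == 0,
      pseudo_r2_adj = if (f$converged) {
        adjusted_pseudo_r2(f)
      } else {
        NA_real_
      }
    )
  }))
  ord <- order(!tab$converged, tab$aicc, tab$k, tab$features)
  tab <- tab[ord, ]
  fits <- fits[ord]
  best_aicc <- tab$aicc[tab$converged][1]
  if (is.na(best_aicc)) {
    stop("no candidate model converged for outcome ", outcome, call. = FALSE)
  }
  tab$delta_aicc <- tab$aicc - best_aicc
  tab$equivalent <- tab$converged & tab$delta_aicc < 2
  tab$rank <- seq_len(nrow(tab))
  tab <- tab[, c(
    "rank", "features", "n_features", "k", "loglik", "aic", "aicc",
    "delta_aicc", "equivalent", "converged", "is_null", "pseudo_r2_adj"
  )]
  structure(tab,
    outcome = outcome, family = family, candidates = candidates,
    covariates = covariates, n = nrow(data), fits = fits,
    null_in_equivalence_set = tab$equivalent[tab$is_null],
    class = c("model_table", class(tab))
  )
}

#' Best fit of a model table
#'
#' @param table A `model_table`.
#' @return The `tapcog_fit` of the top-ranked converged model.
#' @export
best_fit <- function(table) {
  attr(table, "fits")[[1]]
}

#' Decide whether motor features improve prediction
#'
#' Computes the AICc distance of the covariates-only null model from the
#' best model. Motor features are declared to improve prediction of the
#' outcome only when the null model falls *outside* the delta-AICc < 2
#' equivalence set.
#'
#' @param table A `model_table` from [dredge_subsets()].
#' @return List: `outcome`, `family`, `null_delta_aicc`, `improvement`
#'   (logical), `null_in_equivalence_set`, `best_features`,
#'   `best_pseudo_r2_adj`, `n_models`, `n_equivalent`.
#' @export
evaluate_hypothesis <- function(table) {
  null_row <- which(table$is_null)
  if (length(null_row) != 1) {
    stop("model table must contain exactly one null-model row", call. = FALSE)
  }
  null_delta <- table$delta_aicc[null_row]
  list(
    outcome = attr(table, "outcome"),
    family = attr(table, "family"),
    null_delta_aicc = null_delta,
    improvement = null_delta > 2,
    null_in_equivalence_set = table$equivalent[null_row],
    best_features = table$features[1],
    best_pseudo_r2_adj = table$pseudo_r2_adj[1],
    n_models = nrow(table),
    n_equivalent = sum(table$equivalent)
  )
}

#' Choose the residual family for an outcome
#'
#' Fits the covariates-only null model under Poisson and negative-binomial
#' families. The negative binomial is preferred when it beats Poisson by
#' more than 2 AICc units; if the negative-binomial null fails to converge,
#' the Gaussian (identity link) family is used instead and the fallback is
#' recorded.
#'
#' @param data Analysis table.
#' @param outcome Outcome column name.
#' @param covariates Fixed covariates.
#' @return List: `family`, `aicc_poisson`, `aicc_negative_binomial`,
#'   `fallback` (logical), `reason`.
#' @export
select_family <- function(data, outcome, covariates = default_covariates()) {
  pois <- tryCatch(
    fit_glm(outcome, character(0), data,
      family = "poisson",
      covariates = covariates, keep_model = FALSE
    ),
    error = function(e) NULL
  )
  nb <- tryCatch(
    fit_glm(outcome, character(0), data,
      family = "negative_binomial",
      covariates = covariates, keep_model = FALSE
    ),
    error = function(e) NULL
  )
  # For family choice the NB fit is usable whenever the mean model
  # converged: on equidispersed data the dispersion drifts to the Poisson
  # boundary (theta -> Inf, flagged unstable) but its AICc is still the
  # right comparison, and the Poisson family is then retained.
  nb_ok <- !is.null(nb) && isTRUE(nb$glm_converged)
  pois_ok <- !is.null(pois) && pois$converged
  if (!nb_ok) {
    gauss <- tryCatch(
      fit_glm(outcome, character(0), data,
        family = "gaussian",
        covariates = covariates, keep_model = FALSE
      ),
      error = function(e) NULL
    )
    if (is.null(gauss) && !pois_ok) {
      stop("no residual family could be fitted for outcome ", outcome,
        call. = FALSE
      )
    }
    return(list(
      family = "gaussian",
      aicc_poisson = if (pois_ok) pois$aicc else NA_real_,
      aicc_negative_binomial = NA_real_,
      fallback = TRUE,
      reason = "negative-binomial null model did not converge; gaussian residuals assumed"
    ))
  }
  if (pois_ok && pois$aicc - nb$aicc <= 2) {
    return(list(
      family = "poisson",
      aicc_poisson = pois$aicc,
      aicc_negative_binomial = nb$aicc,
      fallback = FALSE,
      reason = "negative binomial not better than Poisson by more than 2 AICc"
    ))
  }
  list(
    family = "negative_binomial",
    aicc_poisson = if (pois_ok) pois$aicc else NA_real_,
    aicc_negative_binomial = nb$aicc,
    fallback = FALSE,
    reason = "negative binomial beats Poisson by more than 2 AICc"
  )
}
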