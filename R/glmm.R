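## ---------------------------------------------------------------------------
## Mixed-model engine: binomial-logit and gaussian-identity models with
## subject-level random effects and a fixed per-observation offset, the
## machinery behind the two-step procedure. Estimation is delegated to lme4
## (Laplace approximation for binomial models, REML for linear models); this
## module owns the model grammar, the offset plumbing, Wald inference and the
## AIC bookkeeping, and provides an independent Gauss-Hermite quadrature
## evaluator of the marginal likelihood for cross-checks.
## ---------------------------------------------------------------------------

#' Specify a mixed model
#'
#' A small structured grammar mirroring the analysis pseudo-code: a response
#' column, fixed-effect columns (with or without an intercept), a
#' subject-level random structure (a random intercept, or correlated random
#' slopes without an intercept), an optional per-observation offset column
#' (entering the linear predictor with coefficient fixed at 1), and the
#' family.
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names.
#' @param random `"intercept"` for `(1 | id)`, or a character vector of
#'   column names for `(0 + ... | id)` correlated slopes, or `"none"`.
#' @param offset optional offset column name.
#' @param family `"binomial"` (logit) or `"gaussian"` (identity).
#' @param intercept include a fixed intercept? (default `FALSE` for binomial
#'   choice models, which are conventionally written `~ 0 + ...`).
#' @param id grouping column (default `"subject"`).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, fixed, random = "intercept", offset = NULL,
                       family = c("binomial", "gaussian"),
                       intercept = FALSE, id = "subject") {
  family <- match.arg(family)
  structure(list(response = response, fixed = fixed, random = random,
                 offset = offset, family = family, intercept = intercept,
                 id = id),
            class = "model_spec")
}

#' lme4 formula for a model specification
#' @param spec a `model_spec`.
#' @return a formula.
#' @export
spec_formula <- function(spec) {
  fe <- paste(c(if (spec$intercept) "1" else "0", spec$fixed), collapse = " + ")
  re <- if (identical(spec$random, "intercept")) {
    sprintf("(1 | %s)", spec$id)
  } else if (identical(spec$random, "none")) {
    NULL
  } else {
    sprintf("(0 + %s | %s)", paste(spec$random, collapse = " + "), spec$id)
  }
  stats::as.formula(paste(spec$response, "~",
                          paste(c(fe, re), collapse = " + ")),
                    env = globalenv())
}

#' @export
format.model_spec <- function(x, term_names = NULL, ...) {
  nm <- function(v) if (!is.null(term_names)) {
    vapply(v, function(t) term_names[[t]] %||% t, character(1))
  } else v
  fe <- paste(c(if (x$intercept) "1" else "0", nm(x$fixed)), collapse = " + ")
  re <- if (identical(x$random, "intercept")) "(1 | Subject ID)"
        else if (identical(x$random, "none")) NULL
        else sprintf("(0 + %s | Subject ID)", paste(nm(x$random), collapse = " + "))
  head <- if (x$family == "binomial") "glmer" else "lmer"
  tail <- c(if (x$family == "binomial") 'family = "binomial"',
            if (!is.null(x$offset)) sprintf("offset = %s", nm(x$offset)))
  sprintf("%s(%s ~ %s%s)", head, nm(x$response),
          paste(c(fe, re), collapse = " + "),
          if (length(tail)) paste0(", ", paste(tail, collapse = ", ")) else "")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## wrap an lme4 fit into the engine's result container
as_fit_result <- function(fit, spec, model_id = NULL) {
  sm <- summary(fit)$coefficients
  stat <- sm[, 3]  # z for glmer, t for lmer
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      stat = stat, p = 2 * stats::pnorm(-abs(stat)),
                      row.names = NULL)
  ll <- logLik(fit)
  k <- attr(ll, "df")
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(model_id = model_id, spec = spec, coefficients = coefs,
                 ranef_vcov = lme4::VarCorr(fit),
                 subject_modes = lme4::ranef(fit),
                 log_likelihood = as.numeric(ll), df = k,
                 aic = -2 * as.numeric(ll) + 2 * k,
                 n_obs = stats::nobs(fit),
                 converged = is.null(msgs),
                 messages = msgs,
                 fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 3, ...) {
  if (!is.null(x$model_id)) cat("model", x$model_id, "\n")
  cat(format(x$spec), "\n")
  tab <- cbind(round(x$coefficients[, c("estimate", "se", "stat")], digits),
               p = signif(x$coefficients$p, 2))
  rownames(tab) <- x$coefficients$term
  print(tab)
  cat(sprintf("logLik %.1f, AIC %.1f, n = %d%s\n", x$log_likelihood, x$aic,
              x$n_obs, if (x$converged) "" else "  [convergence warning]"))
  invisible(x)
}

#' Fit a binomial mixed logistic model
#'
#' Maximizes the Laplace-approximated marginal likelihood (adaptive
#' quadrature with `nAGQ > 1` is available for scalar random effects;
#' `nAGQ = 0` performs only the cheaper penalized-least-squares step, useful
#' inside large simulation studies). Standard errors come from the observed
#' information at the optimum and p-values from a two-sided Wald normal
#' reference.
#'
#' @param data a data.frame (usually a `feature_table`).
#' @param spec a binomial `model_spec`.
#' @param nAGQ integration setting passed to [lme4::glmer()].
#' @param model_id optional label carried into the result.
#' @return a `fit_result`.
#' @export
fit_binomial_glmm <- function(data, spec, nAGQ = 1L, model_id = NULL) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "binomial")
  yv <- data[[spec$response]]
  if (!all(yv %in% c(0, 1))) config_stop("response must be binary 0/1")
  if (length(unique(data[[spec$id]])) < 2L && !identical(spec$random, "none"))
    config_stop("at least 2 subjects are required for subject-level random effects")
  X <- as.matrix(data[, spec$fixed, drop = FALSE])
  if (qr(X)$rank < ncol(X))
    config_stop("fixed-effect design is rank deficient (collinear columns among: %s)",
                paste(spec$fixed, collapse = ", "))
  off <- if (!is.null(spec$offset)) data[[spec$offset]] else NULL
  if (identical(spec$random, "none")) {
    ## degenerate limit: no random effects, ordinary logistic ML
    fit <- do.call(stats::glm,
                    list(formula = spec_formula(spec), data = data,
                         family = stats::binomial(), offset = off))
    return(as_glm_result(fit, spec, model_id))
  }
  ## do.call embeds the offset VALUE in the call, avoiding lme4's lazy
  ## re-evaluation of the offset symbol in the formula environment
  fit <- do.call(lme4::glmer,
                 list(formula = spec_formula(spec), data = data,
                      family = stats::binomial(), offset = off, nAGQ = nAGQ,
                      control = lme4::glmerControl(calc.derivs = FALSE)))
  as_fit_result(fit, spec, model_id)
}

## wrap a glm/lm fit (the no-random-effects degenerate limit)
as_glm_result <- function(fit, spec, model_id = NULL) {
  sm <- summary(fit)$coefficients
  stat <- sm[, 3]
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      stat = stat, p = 2 * stats::pnorm(-abs(stat)),
                      row.names = NULL)
  ll <- logLik(fit)
  k <- attr(ll, "df")
  structure(list(model_id = model_id, spec = spec, coefficients = coefs,
                 ranef_vcov = NULL, subject_modes = NULL,
                 log_likelihood = as.numeric(ll), df = k,
                 aic = -2 * as.numeric(ll) + 2 * k,
                 n_obs = stats::nobs(fit), converged = TRUE,
                 messages = NULL, fit = fit),
            class = "fit_result")
}

#' Fit a gaussian linear mixed model
#'
#' Restricted maximum likelihood via [lme4::lmer()]; fixed-effect tests use a
#' two-sided Wald normal reference, consistent with the reporting convention
#' of the binomial models.
#'
#' @inheritParams fit_binomial_glmm
#' @param REML use REML (default) or ML.
#' @return a `fit_result`.
#' @export
fit_linear_mixed <- function(data, spec, REML = TRUE, model_id = NULL) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "gaussian")
  off <- if (!is.null(spec$offset)) data[[spec$offset]] else NULL
  if (identical(spec$random, "none")) {
    fit <- do.call(stats::glm,
                    list(formula = spec_formula(spec), data = data,
                         family = stats::gaussian(), offset = off))
    return(as_glm_result(fit, spec, model_id))
  }
  fit <- do.call(lme4::lmer,
                 list(formula = spec_formula(spec), data = data, offset = off,
                      REML = REML))
  as_fit_result(fit, spec, model_id)
}

#' Fit a model specification with the appropriate engine
#' @inheritParams fit_binomial_glmm
#' @param ... passed to the family-specific fitter.
#' @return a `fit_result`.
#' @export
fit_model <- function(data, spec, model_id = NULL, ...) {
  if (spec$family == "binomial") fit_binomial_glmm(data, spec, model_id = model_id, ...)
  else fit_linear_mixed(data, spec, model_id = model_id, ...)
}

#' Linear predictor of a fitted model
#'
#' Returns `eta = X beta` plus, when `include_random`, the subject-specific
#' random-effect contribution `Z b`, on the link scale and before any link
#' transformation. These values feed the `offset` of downstream models in the
#' two-step procedure. Predicting for a subject unseen at fit time with
#' `include_random = TRUE` is an error.
#'
#' @param fit a `fit_result`.
#' @param data data to predict for (default: the fitting data).
#' @param include_random include subject random effects (default `TRUE`).
#' @return numeric linear predictor, one value per row.
#' @export
linear_predictions <- function(fit, data = NULL, include_random = TRUE) {
  stopifnot(inherits(fit, "fit_result"))
  mixed <- inherits(fit$fit, "merMod")
  if (is.null(data)) {
    eta <- if (mixed) {
      predict(fit$fit, type = "link", re.form = if (include_random) NULL else NA)
    } else {
      predict(fit$fit, type = "link")
    }
  } else {
    if (mixed && include_random) {
      seen <- rownames(lme4::ranef(fit$fit)[[fit$spec$id]])
      new_ids <- setdiff(as.character(unique(data[[fit$spec$id]])), seen)
      if (length(new_ids))
        config_stop("subjects unseen at fit time (%s) have no random-effect modes",
                    paste(new_ids, collapse = ", "))
      eta <- predict(fit$fit, newdata = data, type = "link", re.form = NULL)
    } else if (mixed) {
      eta <- predict(fit$fit, newdata = data, type = "link", re.form = NA)
    } else {
      eta <- predict(fit$fit, newdata = data, type = "link")
    }
  }
  ## predict() folds the fitting offset into the prediction; remove it so the
  ## returned value is the model's own linear-predictor contribution
  if (!is.null(fit$spec$offset)) {
    off <- if (is.null(data)) {
      fr <- if (mixed) fit$fit@frame else fit$fit$model
      fr[["(offset)"]]
    } else data[[fit$spec$offset]]
    eta <- eta - off
  }
  as.numeric(eta)
}

#' Marginal log-likelihood by Gauss-Hermite quadrature
#'
#' Independent brute-force evaluator of the random-intercept binomial
#' marginal log-likelihood: for each subject the Bernoulli likelihood is
#' integrated over the intercept distribution `N(0, sd_intercept^2)` with an
#' `n_nodes`-point Gauss-Hermite rule (nodes and weights from the
#' Golub-Welsch eigendecomposition of the Jacobi matrix, computed here from
#' first principles). Used as the oracle against which the Laplace
#' approximation is checked.
#'
#' @param y binary response vector.
#' @param X fixed-effect design matrix.
#' @param id subject factor.
#' @param beta fixed-effect coefficients.
#' @param sd_intercept random-intercept SD.
#' @param offset optional per-observation offset.
#' @param n_nodes number of quadrature nodes (default 201).
#' @return the marginal log-likelihood.
#' @export
gh_marginal_loglik <- function(y, X, id, beta, sd_intercept, offset = NULL,
                               n_nodes = 201L) {
  i <- seq_len(n_nodes - 1L)
  a <- sqrt(i / 2)
  J <- matrix(0, n_nodes, n_nodes)
  J[cbind(i, i + 1L)] <- a
  J[cbind(i + 1L, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  w <- e$vectors[1L, ]^2  # physicists' weights / sqrt(pi): sum to 1
  if (is.null(offset)) offset <- rep(0, length(y))
  eta0 <- drop(X %*% beta) + offset
  ll <- 0
  for (s in unique(id)) {
    k <- id == s
    per_node <- vapply(nodes, function(z) {
      eta <- eta0[k] + sqrt(2) * sd_intercept * z
      sum(dbinom(y[k], 1L, logistic(eta), log = TRUE))
    }, numeric(1))
    m <- max(per_node)
    ll <- ll + m + log(sum(w * exp(per_node - m)))
  }
  ll
}
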