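# Firth-penalized logistic regression. Maximizes the penalized
# log-likelihood l(beta) + 0.5 * log det I(beta) (Jeffreys-prior penalty),
# which removes the leading term of the small-sample bias of the MLE and
# yields finite estimates even under complete separation — the regime
# spontaneous-report triples with sparse co-exposure cells live in.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 30
  out[big] <- x[big] + log1p(exp(-x[big]))
  out[!big] <- log1p(exp(x[!big]))
  out
}

#' Penalized log-likelihood of a logistic model
#'
#' The binomial log-likelihood plus half the log-determinant of the
#' Fisher information at `beta`.
#'
#' @param beta coefficient vector.
#' @param x design matrix (including intercept column).
#' @param y 0/1 outcome vector.
#' @return scalar penalized log-likelihood (`-Inf` if the information
#'   matrix is singular at `beta`).
#' @export
firth_penalized_loglik <- function(beta, x, y) {
  eta <- drop(x %*% beta)
  ll <- sum(y * eta - log1pexp(eta))
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  info <- crossprod(x * sqrt(w))
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  ll + 0.5 * as.numeric(ld$modulus)
}

#' Fit a logistic regression with Firth's penalty
#'
#' Newton–Raphson (Fisher scoring) on the modified score
#' \eqn{U^*(\beta) = X'(y - \pi + h(1/2 - \pi))}, where \eqn{h} holds the
#' diagonal of the weighted hat matrix, with step-halving on the
#' penalized log-likelihood. The reported covariance is the inverse
#' Fisher information at the optimum (Wald-type).
#'
#' @param x design matrix, intercept column included, with column names.
#' @param y 0/1 outcome vector.
#' @param tol convergence tolerance on both the modified score and the
#'   coefficient step (default 1e-6).
#' @param max_iter maximum Newton iterations (default 50).
#' @param max_halving maximum step-halvings per iteration (default 10).
#' @return a `firth_fit`: `beta` (named), `cov` (inverse information),
#'   `converged`, `n_iter`, `penalized_loglik`, `max_score`, `n`,
#'   `n_events`, `dropped` (names of columns removed before fitting, set
#'   by higher-level callers).
#' @export
firth_logistic <- function(x, y, tol = 1e-6, max_iter = 50, max_halving = 10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop_faersddi("estimation requires at least one event and one non-event")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop_faersddi("design matrix is rank-deficient; aliased column(s): ",
      paste(aliased, collapse = ", "))
  }

  beta <- numeric(ncol(x))
  pll <- firth_penalized_loglik(beta, x, y)
  converged <- FALSE
  max_score <- Inf
  iter <- 0
  inv_info <- NULL

  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    inv_info <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(inv_info)) {
      stop_faersddi("Fisher information singular at iteration ", iter)
    }
    h <- rowSums((xw %*% inv_info) * xw)
    score <- drop(crossprod(x, y - p + h * (0.5 - p)))
    max_score <- max(abs(score))
    delta <- drop(inv_info %*% score)

    # step-halving: do not accept a step that lowers the penalized loglik
    step <- 1
    for (half in 0:max_halving) {
      cand <- beta + step * delta
      pll_new <- firth_penalized_loglik(cand, x, y)
      if (pll_new >= pll - 1e-12) break
      step <- step / 2
    }
    moved <- max(abs(step * delta))
    beta <- beta + step * delta
    pll <- firth_penalized_loglik(beta, x, y)
    if (max_score < tol && moved < tol) {
      converged <- TRUE
      break
    }
  }

  # covariance at the accepted optimum
  eta <- drop(x %*% beta)
  p <- stats::plogis(eta)
  xw <- x * sqrt(p * (1 - p))
  cov <- chol2inv(chol(crossprod(xw)))
  dimnames(cov) <- list(colnames(x), colnames(x))

  structure(
    list(
      beta = stats::setNames(beta, colnames(x)),
      cov = cov,
      converged = converged,
      n_iter = iter,
      penalized_loglik = pll,
      max_score = max_score,
      n = nrow(x),
      n_events = sum(y),
      dropped = character(0)
    ),
    class = "firth_fit"
  )
}

#' @export
print.firth_fit <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  tab <- data.frame(estimate = x$beta, se = se,
    z = x$beta / se, row.names = names(x$beta))
  cat("Firth logistic fit (n = ", x$n, ", events = ", x$n_events,
    ", converged = ", x$converged, ", iterations = ", x$n_iter, ")\n",
    sep = "")
  print(round(tab, 4))
  invisible(x)
}

# Design matrix for the interaction model: intercept, the two drug
# indicators, their product, and the covariates (binary age group, gender,
# two drug-count dummies).
triple_design <- function(rows) {
  cbind(
    intercept = 1,
    drug_a = rows$exposed_a,
    drug_b = rows$exposed_b,
    interaction = rows$exposed_a * rows$exposed_b,
    age65 = rows$age65,
    male = rows$male,
    bin3_4 = rows$bin3_4,
    bin_ge5 = rows$bin_ge5
  )
}

#' Fit the Firth interaction model for one triple
#'
#' Builds the design matrix (drug A, drug B, their interaction, and the
#' covariates) from the triple's analysis rows and fits it by
#' [firth_logistic()]. Constant covariate columns are dropped with a
#' warning and recorded in `$dropped`; a constant interaction column
#' aborts the fit, since the interaction effect is then unidentifiable.
#'
#' @param triple a `triple_dataset`.
#' @param ... passed to [firth_logistic()] (`tol`, `max_iter`, ...).
#' @return a `firth_fit`.
#' @export
fit_triple <- function(triple, ...) {
  stopifnot(inherits(triple, "triple_dataset"))
  x <- triple_design(triple$rows)
  constant <- apply(x[, -1, drop = FALSE], 2, function(col) {
    length(unique(col)) == 1
  })
  constant_cols <- names(constant)[constant]
  if ("interaction" %in% constant_cols) {
    stop_faersddi("triple '", triple$id,
      "': interaction column is constant; effect unidentifiable")
  }
  if (length(constant_cols)) {
    warning("triple '", triple$id, "': dropping constant column(s) ",
      paste(constant_cols, collapse = ", "), call. = FALSE)
    x <- x[, setdiff(colnames(x), constant_cols), drop = FALSE]
  }
  fit <- firth_logistic(x, triple$rows$outcome, ...)
  fit$dropped <- constant_cols
  fit
}

#' Relative excess risk due to interaction (additive scale)
#'
#' From the fitted interaction model, RERI(OR) =
#' \eqn{e^{\beta_1+\beta_2+\beta_3} - e^{\beta_1} - e^{\beta_2} + 1},
#' with odds ratios standing in for relative risks under the
#' rare-outcome approximation. The standard error comes from the delta
#' method with gradient \eqn{(e^s - e^{\beta_1},\ e^s - e^{\beta_2},\
#' e^s)}, \eqn{s = \beta_1+\beta_2+\beta_3}, applied to the 3x3
#' coefficient covariance block. A positive additive interaction is
#' declared when both the estimate and the lower confidence bound exceed
#' zero.
#'
#' @param fit a `firth_fit` containing coefficients `drug_a`, `drug_b`
#'   and `interaction`.
#' @param alpha two-sided confidence level complement (default 0.05).
#' @return a `reri_result`: `reri`, `se`, `ci_low`, `ci_high`,
#'   `significant`, plus the implied odds ratios `or11`, `or10`, `or01`.
#' @export
compute_reri <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "firth_fit"))
  need <- c("drug_a", "drug_b", "interaction")
  if (!all(need %in% names(fit$beta))) {
    stop_faersddi("fit lacks coefficient(s) ",
      paste(setdiff(need, names(fit$beta)), collapse = ", "))
  }
  b <- fit$beta[need]
  if (any(!is.finite(b))) {
    stop_faersddi("non-finite coefficients; cannot propagate RERI")
  }
  v <- fit$cov[need, need]
  s <- sum(b)
  reri <- exp(s) - exp(b[["drug_a"]]) - exp(b[["drug_b"]]) + 1
  grad <- c(exp(s) - exp(b[["drug_a"]]), exp(s) - exp(b[["drug_b"]]), exp(s))
  se <- sqrt(drop(t(grad) %*% v %*% grad))
  z <- stats::qnorm(1 - alpha / 2)
  ci_low <- reri - z * se
  ci_high <- reri + z * se
  structure(
    list(
      reri = reri, se = se, ci_low = ci_low, ci_high = ci_high,
      or11 = exp(s), or10 = exp(b[["drug_a"]]), or01 = exp(b[["drug_b"]]),
      significant = (reri > 0) && (ci_low > 0)
    ),
    class = "reri_result"
  )
}

#' Multiplicative interaction measure
#'
#' The ratio of odds ratios OR11 / (OR10 * OR01) = \eqn{e^{\beta_3}},
#' with a two-sided Wald p-value for \eqn{\beta_3 = 0}. A positive
#' multiplicative interaction is declared when the ratio exceeds 1 and
#' the p-value is below `alpha`.
#'
#' @param fit a `firth_fit` containing an `interaction` coefficient.
#' @param alpha significance level (default 0.05).
#' @return a `multiplicative_result`: `ratio`, `p_value`, `se_log`,
#'   `significant`.
#' @export
compute_multiplicative <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "firth_fit"))
  if (!("interaction" %in% names(fit$beta))) {
    stop_faersddi("fit lacks an interaction coefficient")
  }
  b3 <- fit$beta[["interaction"]]
  v3 <- fit$cov["interaction", "interaction"]
  if (!is.finite(v3) || v3 <= 0) {
    stop_faersddi("degenerate fit: interaction variance is not positive")
  }
  se <- sqrt(v3)
  p <- 2 * stats::pnorm(-abs(b3 / se))
  structure(
    list(ratio = exp(b3), p_value = p, se_log = se,
      significant = (exp(b3) > 1) && (p < alpha)),
    class = "multiplicative_result"
  )
}

#' Combine the per-scale verdicts into a signal flag
#'
#' A drug-drug interaction signal is declared when there is evidence of
#' interaction on at least one scale.
#'
#' @param additive a `reri_result`.
#' @param multiplicative a `multiplicative_result`.
#' @return list with logical `signal` and the two verdicts.
#' @export
classify_signal <- function(additive, multiplicative) {
  list(
    signal = isTRUE(additive$significant) || isTRUE(multiplicative$significant),
    additive_significant = isTRUE(additive$significant),
    multiplicative_significant = isTRUE(multiplicative$significant)
  )
}

#' Fit and score one triple on both interaction scales
#'
#' @param triple a `triple_dataset`.
#' @param alpha significance level for both scales (default 0.05).
#' @param ... passed to [fit_triple()].
#' @return an `interaction_result`: `id`, `triple` metadata, `fit`,
#'   `additive`, `multiplicative`, `signal`, or — when the triple cannot
#'   be fit (e.g. constant interaction column) — an object with `error`
#'   set and `signal = FALSE`.
#' @export
analyze_triple <- function(triple, alpha = 0.05, ...) {
  res <- tryCatch({
    fit <- suppressWarnings(fit_triple(triple, ...))
    additive <- compute_reri(fit, alpha)
    multiplicative <- compute_multiplicative(fit, alpha)
    cls <- classify_signal(additive, multiplicative)
    list(fit = fit, additive = additive, multiplicative = multiplicative,
      signal = cls$signal, error = NULL)
  }, error = function(e) {
    list(fit = NULL, additive = NULL, multiplicative = NULL,
      signal = FALSE, error = conditionMessage(e))
  })
  structure(
    c(list(id = triple$id, covid_drug = triple$covid_drug,
      comed = triple$comed, ae_hlt = triple$ae_hlt,
      counts = triple$counts), res),
    class = "interaction_result"
  )
}

#' Analyze a list of triples
#'
#' @param triples list of `triple_dataset` objects.
#' @param alpha significance level (default 0.05).
#' @param ... passed to [fit_triple()].
#' @return list of `interaction_result` objects, named by triple id.
#' @export
analyze_triples <- function(triples, alpha = 0.05, ...) {
  stats::setNames(
    lapply(triples, analyze_triple, alpha = alpha, ...),
    vapply(triples, `[[`, "", "id")
  )
}

#' Flatten interaction results to a table
#'
#' One row per triple: cell counts, coefficient estimates with standard
#' errors, RERI with its confidence interval, the multiplicative ratio
#' with its p-value, per-scale verdicts and the signal flag. Failed
#' triples appear with their failure reason and `NA` statistics.
#'
#' @param results list of `interaction_result` objects.
#' @param adjust_p optional multiple-testing adjustment for the
#'   multiplicative p-values, e.g. `"BH"`; default `"none"` (per-test
#'   alpha, no correction).
#' @return data frame.
#' @export
results_table <- function(results, adjust_p = "none") {
  if (length(results) == 0) {
    out <- data.frame(
      triple_id = character(0), covid_drug = character(0),
      comed = character(0), ae_hlt = character(0), n11 = integer(0),
      n10 = integer(0), n01 = integer(0), n00 = integer(0),
      beta_drug_a = numeric(0), se_drug_a = numeric(0),
      beta_drug_b = numeric(0), se_drug_b = numeric(0),
      beta_interaction = numeric(0), se_interaction = numeric(0),
      converged = logical(0), reri = numeric(0), reri_ci_low = numeric(0),
      reri_ci_high = numeric(0), additive_significant = logical(0),
      mult_ratio = numeric(0), mult_p = numeric(0),
      multiplicative_significant = logical(0), signal = logical(0),
      error = character(0), stringsAsFactors = FALSE
    )
    if (!identical(adjust_p, "none")) out$mult_p_adjusted <- numeric(0)
    return(out)
  }
  rows <- lapply(results, function(r) {
    base <- data.frame(
      triple_id = r$id, covid_drug = r$covid_drug, comed = r$comed,
      ae_hlt = r$ae_hlt,
      n11 = r$counts[["n11"]], n10 = r$counts[["n10"]],
      n01 = r$counts[["n01"]], n00 = r$counts[["n00"]],
      stringsAsFactors = FALSE
    )
    if (is.null(r$error)) {
      b <- r$fit$beta
      se <- sqrt(diag(r$fit$cov))
      cbind(base, data.frame(
        beta_drug_a = b[["drug_a"]], se_drug_a = se[["drug_a"]],
        beta_drug_b = b[["drug_b"]], se_drug_b = se[["drug_b"]],
        beta_interaction = b[["interaction"]],
        se_interaction = se[["interaction"]],
        converged = r$fit$converged,
        reri = r$additive$reri, reri_ci_low = r$additive$ci_low,
        reri_ci_high = r$additive$ci_high,
        additive_significant = r$additive$significant,
        mult_ratio = r$multiplicative$ratio,
        mult_p = r$multiplicative$p_value,
        multiplicative_significant = r$multiplicative$significant,
        signal = r$signal, error = NA_character_,
        stringsAsFactors = FALSE
      ))
    } else {
      cbind(base, data.frame(
        beta_drug_a = NA_real_, se_drug_a = NA_real_,
        beta_drug_b = NA_real_, se_drug_b = NA_real_,
        beta_interaction = NA_real_, se_interaction = NA_real_,
        converged = NA, reri = NA_real_, reri_ci_low = NA_real_,
        reri_ci_high = NA_real_, additive_significant = NA,
        mult_ratio = NA_real_, mult_p = NA_real_,
        multiplicative_significant = NA, signal = FALSE, error = r$error,
        stringsAsFactors = FALSE
      ))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!identical(adjust_p, "none")) {
    out$mult_p_adjusted <- stats::p.adjust(out$mult_p, method = adjust_p)
  }
  out
}

#' Age or gender disparity of a detected interaction
#'
#' Fits a Firth logistic model of the outcome on the stratum indicator
#' (over-65 vs under-65, or male vs female) over the triple's full
#' analysis rows, adjusted for the other demographic variable, the
#' drug-count dummies and both drug indicators. Reports the Wald odds
#' ratio for the stratum indicator and per-stratum counts of co-exposed
#' outcome-positive reports. A p-value below `alpha` marks the signal as
#' age- or gender-specific.
#'
#' @param triple a `triple_dataset` (typically one retained by the EPV
#'   filter).
#' @param stratum_variable `"age"` (indicator = over-65) or `"gender"`
#'   (indicator = male).
#' @param alpha significance level (default 0.05).
#' @param ... passed to [firth_logistic()].
#' @return a `stratum_result`: `triple_id`, `stratum_variable`,
#'   `counts` (co-exposed outcome-positive reports per stratum),
#'   `or`, `ci_low`, `ci_high`, `p_value`, `specific`.
#' @export
stratified_disparity <- function(triple, stratum_variable = c("age", "gender"),
                                 alpha = 0.05, ...) {
  stopifnot(inherits(triple, "triple_dataset"))
  stratum_variable <- match.arg(stratum_variable)
  rows <- triple$rows
  stratum <- if (stratum_variable == "age") rows$age65 else rows$male
  other <- if (stratum_variable == "age") rows$male else rows$age65
  if (length(unique(stratum)) == 1) {
    stop_faersddi("stratum variable '", stratum_variable,
      "' is constant over the analysis rows")
  }
  x <- cbind(
    intercept = 1, stratum = stratum, other_demo = other,
    bin3_4 = rows$bin3_4, bin_ge5 = rows$bin_ge5,
    drug_a = rows$exposed_a, drug_b = rows$exposed_b
  )
  constant <- apply(x[, -1, drop = FALSE], 2, function(col) {
    length(unique(col)) == 1
  })
  x <- x[, c(TRUE, !constant), drop = FALSE]
  fit <- firth_logistic(x, rows$outcome, ...)
  b <- fit$beta[["stratum"]]
  se <- sqrt(fit$cov["stratum", "stratum"])
  z <- stats::qnorm(1 - alpha / 2)
  p <- 2 * stats::pnorm(-abs(b / se))

  co <- rows$exposed_a == 1 & rows$exposed_b == 1 & rows$outcome == 1
  counts <- if (stratum_variable == "age") {
    c(under65 = sum(co & rows$age65 == 0), over65 = sum(co & rows$age65 == 1))
  } else {
    c(female = sum(co & rows$male == 0), male = sum(co & rows$male == 1))
  }

  structure(
    list(
      triple_id = triple$id, stratum_variable = stratum_variable,
      counts = counts, or = exp(b), ci_low = exp(b - z * se),
      ci_high = exp(b + z * se), p_value = p, specific = p < alpha,
      fit = fit
    ),
    class = "stratum_result"
  )
}

#' Flatten stratified disparity results to a table
#'
#' @param strata list of `stratum_result` objects.
#' @return data frame keyed by triple id and stratum variable.
#' @export
strata_table <- function(strata) {
  out <- do.call(rbind, lapply(strata, function(s) {
    data.frame(
      triple_id = s$triple_id, stratum_variable = s$stratum_variable,
      count_stratum0 = s$counts[[1]], count_stratum1 = s$counts[[2]],
      or = s$or, ci_low = s$ci_low, ci_high = s$ci_high,
      p_value = s$p_value, specific = s$specific, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
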