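#' Psychometric model specification
#'
#' @param fixed Character vector of fixed-effect terms (column names of the
#'   trial table, plus `:`-interactions), always including the continuous
#'   fricative term `x`.
#' @param response Response column name (default `response_s`).
#' @param random_intercept Include a per-subject random intercept?
#' @param subject Grouping column for the random intercept.
#' @return A `model_spec` object.
#' @export
model_spec <- function(fixed = "x", response = "response_s",
                       random_intercept = TRUE, subject = "subject") {
  structure(list(fixed = unique(fixed), response = response,
                 random_intercept = isTRUE(random_intercept),
                 subject = subject),
            class = "model_spec")
}

spec_formula <- function(spec, mixed = spec$random_intercept) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  if (mixed) rhs <- paste0(rhs, " + (1 | ", spec$subject, ")")
  stats::as.formula(paste(spec$response, "~", rhs))
}

# treatment-coded factors with the documented reference levels
prepare_trials <- function(trials) {
  d <- as.data.frame(trials)
  for (f in names(.context_reference)) {
    if (f %in% names(d)) {
      d[[f]] <- factor(d[[f]])
      # constant columns (e.g. a single transition type) keep their level
      if (.context_reference[[f]] %in% levels(d[[f]]))
        d[[f]] <- stats::relevel(d[[f]], ref = .context_reference[[f]])
    }
  }
  if ("subject" %in% names(d)) d$subject <- factor(d$subject)
  d
}

trials_f_med <- function(trials, f_med = NULL) {
  if (!is.null(f_med)) return(f_med)
  fm <- attr(trials, "f_med")
  if (is.null(fm)) {
    if (!all(c("sp1_hz", "x") %in% names(trials)))
      stop("`f_med` not supplied and not recoverable from the trial table",
           call. = FALSE)
    fm <- exp(stats::median(log(trials$sp1_hz) - trials$x))
  }
  fm
}

new_fit_result <- function(model, spec, f_med, mixed, sigma_u = NA_real_,
                           n_obs, aggregated = FALSE) {
  if (mixed) {
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    npar <- length(est) + 1L # + random-intercept variance
    conv <- length(model@optinfo$conv$lme4$messages) == 0
  } else {
    cf <- summary(model)$coefficients
    est <- cf[, "Estimate"]
    se <- cf[, "Std. Error"]
    npar <- length(est)
    conv <- model$converged
  }
  z <- est / se
  terms_tab <- data.frame(term = names(est), estimate = unname(est),
                          se = unname(se), z = unname(z),
                          p = 2 * stats::pnorm(-abs(unname(z))),
                          row.names = NULL)
  ll <- as.numeric(stats::logLik(model))
  separated <- any(abs(est) > 15)
  structure(list(terms = terms_tab, logLik = ll, n_params = npar,
                 aic = 2 * npar - 2 * ll, converged = conv && !separated,
                 separation = separated, mixed = mixed, sigma_u = sigma_u,
                 coding = "treatment", reference_levels = .context_reference,
                 f_med = f_med, spec = spec, n_obs = n_obs,
                 aggregated = aggregated, model = model),
            class = "psychofit")
}

#' @export
print.psychofit <- function(x, ...) {
  cat(sprintf("Psychometric %s logistic fit (%d obs%s)\n",
              if (x$mixed) "mixed" else "fixed-effects", x$n_obs,
              if (x$aggregated) ", binomial-aggregated" else ""))
  print(x$terms, digits = 4)
  cat(sprintf("logLik %.3f  AIC %.2f  params %d%s\n", x$logLik, x$aic,
              x$n_params,
              if (x$mixed) sprintf("  sigma_u %.3f", x$sigma_u) else ""))
  if (!x$converged)
    cat("WARNING: fit flagged non-converged",
        if (x$separation) "(possible complete separation: |estimate| > 15)",
        "\n")
  invisible(x)
}

#' Fit a fixed-effects logistic psychometric model
#'
#' Bernoulli maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, binomial family) at the trial level. Complete separation
#' is flagged (diverging estimates, |beta| > 15) rather than silently
#' accepted.
#'
#' @param trials A trial table (see [simulate_trials()]).
#' @param spec A [model_spec()] (its `random_intercept` flag is ignored
#'   here).
#' @param f_med Centering frequency in Hz; taken from the trial table when
#'   omitted.
#' @return A `psychofit` object: per-term estimate/SE/Wald z/p, logLik,
#'   parameter count, AIC, convergence flag, coding metadata and `f_med`.
#' @export
fit_logistic <- function(trials, spec = model_spec(), f_med = NULL) {
  d <- prepare_trials(trials)
  f_med <- trials_f_med(trials, f_med)
  if (length(unique(d[[spec$response]])) < 2)
    stop("response must take at least two distinct values", call. = FALSE)
  fml <- spec_formula(spec, mixed = FALSE)
  mm <- stats::model.matrix(stats::as.formula(
    paste("~", if (length(spec$fixed)) paste(spec$fixed, collapse = "+") else "1")), d)
  if (qr(mm)$rank < ncol(mm)) {
    alias <- colnames(mm)[-seq_len(qr(mm)$rank)]
    stop("design matrix is rank deficient (aliased: ",
         paste(alias, collapse = ", "), ")", call. = FALSE)
  }
  fit <- stats::glm(fml, family = stats::binomial(), data = d)
  res <- new_fit_result(fit, spec, f_med, mixed = FALSE, n_obs = nrow(d))
  if (res$separation)
    warning("possible complete separation: estimates diverged (|beta| > 15)",
            call. = FALSE)
  res
}

# collapse Bernoulli trials to binomial counts over unique covariate cells;
# coefficients and SEs are unchanged. The grouping uses every covariate
# column of the table (not just the model terms) so the binomial constant
# is identical across candidate models and AIC comparisons stay valid.
aggregate_trials <- function(d, spec) {
  vars <- unique(c(spec$subject, "x", names(.context_reference),
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE))))
  vars <- intersect(vars, names(d))
  key <- do.call(paste, c(d[vars], sep = "\r"))
  succ <- tapply(d[[spec$response]], key, sum)
  tot <- tapply(d[[spec$response]], key, length)
  first <- !duplicated(key)
  agg <- d[first, vars, drop = FALSE]
  ord <- key[first]
  agg$.succ <- as.vector(succ[ord])
  agg$.fail <- as.vector(tot[ord]) - agg$.succ
  rownames(agg) <- NULL
  agg
}

#' Fit a random-intercept logistic psychometric model
#'
#' Maximum likelihood via `lme4::glmer` with a per-subject random
#' intercept; the marginal likelihood integrates the intercept by Laplace
#' approximation (`n_agq = 1`) or adaptive Gauss-Hermite quadrature
#' (`n_agq >= 7` recommended when checking quadrature convergence). Trials
#' are aggregated to binomial counts over unique subject-by-covariate cells
#' before fitting, which leaves coefficients and their SEs unchanged.
#'
#' @param trials A trial table.
#' @param spec A [model_spec()].
#' @param f_med Centering frequency in Hz (from the table when omitted).
#' @param n_agq Number of adaptive quadrature nodes (1 = Laplace).
#' @param aggregate Aggregate to binomial counts first? (default TRUE).
#' @return A `psychofit` object (with `sigma_u`, the estimated
#'   random-intercept SD). With a single subject the model degenerates and
#'   the fixed-effects fit is returned with a warning.
#' @export
fit_mixed_logistic <- function(trials, spec = model_spec(), f_med = NULL,
                               n_agq = 1L, aggregate = TRUE) {
  d <- prepare_trials(trials)
  f_med <- trials_f_med(trials, f_med)
  if (length(unique(d[[spec$subject]])) < 2) {
    warning("fewer than 2 subjects: falling back to the fixed-effects fit",
            call. = FALSE)
    return(fit_logistic(trials, spec, f_med))
  }
  if (aggregate) {
    d <- aggregate_trials(d, spec)
    lhs <- "cbind(.succ, .fail)"
  } else {
    lhs <- spec$response
  }
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(paste0(lhs, " ~ ", rhs, " + (1 | ", spec$subject, ")"))
  fit <- suppressMessages(lme4::glmer(fml, data = d,
                                      family = stats::binomial(),
                                      nAGQ = n_agq))
  sigma_u <- sqrt(as.numeric(lme4::VarCorr(fit)[[spec$subject]]))
  new_fit_result(fit, spec, f_med, mixed = TRUE, sigma_u = sigma_u,
                 n_obs = nrow(d), aggregated = aggregate)
}

#' Forward stepwise AIC model selection
#'
#' Starting from the intercept-only (plus nothing) model, greedily adds the
#' candidate term giving the largest AIC decrease; stops when no candidate
#' improves AIC by more than `delta_threshold`. Interaction terms become
#' eligible only once both parent main effects are in the model.
#'
#' @param trials A trial table.
#' @param candidates Character vector of candidate terms (mains and
#'   `a:b` interactions).
#' @param random_intercept Use the mixed fitter throughout?
#' @param delta_threshold Minimum AIC improvement to accept a term
#'   (default 2).
#' @param f_med Centering frequency in Hz.
#' @param n_agq Quadrature nodes for the mixed fitter.
#' @return A list: `fit` (the selected `psychofit`) and `trace` (a data
#'   frame of candidate evaluations: step, term, AIC, accepted).
#' @export
forward_select <- function(trials, candidates,
                           random_intercept = TRUE, delta_threshold = 2,
                           f_med = NULL, n_agq = 1L) {
  stopifnot(length(candidates) > 0)
  f_med <- trials_f_med(trials, f_med)
  fit_one <- function(terms) {
    sp <- model_spec(fixed = terms, random_intercept = random_intercept)
    if (random_intercept) fit_mixed_logistic(trials, sp, f_med, n_agq = n_agq)
    else fit_logistic(trials, sp, f_med)
  }
  parents_in <- function(term, included) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    length(parts) == 1L || all(parts %in% included)
  }
  included <- character(0)
  current <- fit_one(included)
  trace <- data.frame(step = integer(0), term = character(0),
                      aic = numeric(0), accepted = logical(0))
  step <- 0L
  repeat {
    step <- step + 1L
    pool <- setdiff(candidates, included)
    pool <- pool[vapply(pool, parents_in, logical(1), included = included)]
    if (!length(pool)) break
    fits <- lapply(pool, function(tm) fit_one(c(included, tm)))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    accepted <- current$aic - aics[best] > delta_threshold
    trace <- rbind(trace, data.frame(step = step, term = pool,
                                     aic = aics,
                                     accepted = accepted &
                                       seq_along(pool) == best))
    if (!accepted) break
    included <- c(included, pool[best])
    current <- fits[[best]]
  }
  list(fit = current, trace = trace, included = included)
}

# fixed-effects linear predictor at given factor levels as a function of x;
# returns c(intercept, slope)
predictor_line <- function(fit, context) {
  spec <- fit$spec
  vars <- setdiff(unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE))), "x")
  nd <- data.frame(x = c(0, 1))
  for (v in vars) {
    lev <- if (v %in% names(context)) context[[v]]
           else .context_reference[[v]]
    if (is.null(lev) || is.na(lev))
      stop("no level supplied or known for factor `", v, "`", call. = FALSE)
    ref <- .context_reference[[v]]
    nd[[v]] <- factor(rep(lev, 2), levels = unique(c(ref, lev,
                                                     .context_alternative[[v]])))
  }
  eta <- if (fit$mixed) {
    stats::predict(fit$model, newdata = nd, re.form = NA, type = "link")
  } else {
    stats::predict(fit$model, newdata = nd, type = "link")
  }
  c(intercept = unname(eta[1]), slope = unname(eta[2] - eta[1]))
}

#' 50% category boundary implied by a fitted model
#'
#' Solves the fixed-effects (population-average) linear predictor for the
#' centered log-Hz value at which P(/s/) = 0.5, with the random intercept
#' at its mean, and maps it back to Hz: `f_med * exp(x50)`.
#'
#' @param fit A `psychofit` object whose model includes the fricative term
#'   `x` with a positive slope at the requested context.
#' @param context Named character vector (or list) of factor levels;
#'   omitted factors sit at their reference level.
#' @return Boundary frequency in Hz.
#' @export
crossover <- function(fit, context = character(0)) {
  stopifnot(inherits(fit, "psychofit"))
  if (!"x" %in% unlist(strsplit(fit$spec$fixed, ":", fixed = TRUE)))
    stop("fitted model does not include the fricative term `x`",
         call. = FALSE)
  line <- predictor_line(fit, context)
  if (line[["slope"]] <= 0)
    stop("non-positive fricative slope: no monotone /s/ boundary exists",
         call. = FALSE)
  unname(fit$f_med * exp(-line[["intercept"]] / line[["slope"]]))
}

#' Context effects as boundary shifts in Hz
#'
#' For each factor, the difference between the 50% boundary at its
#' reference level and at its alternative level, all other factors held at
#' reference ("common currency" for context effects). Factors absent from
#' the fitted model report exactly 0.
#'
#' @param fit A `psychofit` object.
#' @param factors Character vector of context factor columns (default: the
#'   audio-only factors).
#' @return A `shift_table` data frame: `factor`, `reference`,
#'   `alternative`, `shift_hz` (positive when the alternative level moves
#'   the boundary toward lower frequencies, i.e. biases responses toward
#'   /s/).
#' @export
shift_table <- function(fit, factors = c("voice_gender", "vowel",
                                         "transition")) {
  stopifnot(inherits(fit, "psychofit"))
  in_model <- unique(unlist(strsplit(fit$spec$fixed, ":", fixed = TRUE)))
  shifts <- vapply(factors, function(f) {
    if (!f %in% in_model) return(0)
    ref_ctx <- stats::setNames(.context_reference[f], f)
    alt_ctx <- stats::setNames(.context_alternative[f], f)
    crossover(fit, ref_ctx) - crossover(fit, alt_ctx)
  }, numeric(1))
  structure(data.frame(factor = factors,
                       reference = unname(.context_reference[factors]),
                       alternative = unname(.context_alternative[factors]),
                       shift_hz = unname(shifts), row.names = NULL),
            class = c("shift_table", "data.frame"))
}
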