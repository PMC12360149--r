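# Mixed-model comparison of movement responses. Models are fitted with
# mgcv::gam: random intercepts as penalized ridge smooths (bs = "re"),
# families poisson (log), beta (logit), Tweedie (log, power estimated in
# (1, 2)) and lognormal (Gaussian on the log response). Fixed-effect
# structure is chosen by all-subsets AIC with a fewest-parameters-within-2
# parsimony rule; inference uses marginal means with Tukey-adjusted pairwise
# contrasts.

FAMILIES <- c("poisson", "beta", "tweedie", "lognormal")

#' Model specification
#'
#' @param response response column name.
#' @param family one of "poisson" (log link), "beta" (logit), "tweedie"
#'   (log, power profiled in (1, 2)), "lognormal" (Gaussian on log response).
#' @param fixed character vector of candidate fixed effects; interactions as
#'   `"a:b"` and only retained when both main effects are present.
#' @param random character vector of random-intercept variables; numeric
#'   columns are binned into quintile factors before fitting.
#' @return a `model_spec`.
#' @export
model_spec <- function(response, family = FAMILIES, fixed,
                       random = character()) {
  family <- match.arg(family)
  inter <- grepl(":", fixed, fixed = TRUE)
  for (tm in fixed[inter]) {
    mains <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(mains %in% fixed))
      stop("interaction ", tm, " requires both main effects", call. = FALSE)
  }
  structure(list(response = response, family = family, fixed = fixed,
                 random = random), class = "model_spec")
}

prepare_model_data <- function(spec, data) {
  vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  for (v in vars)
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  for (v in spec$random) {
    if (is.numeric(data[[v]])) {
      br <- unique(quantile(data[[v]], probs = seq(0, 1, 0.2), na.rm = TRUE))
      data[[v]] <- if (length(br) > 2L)
        cut(data[[v]], breaks = br, include.lowest = TRUE)
      else factor(data[[v]])
    } else data[[v]] <- factor(data[[v]])
  }
  if (spec$family == "lognormal") {
    if (any(data[[spec$response]] <= 0))
      stop("lognormal response must be positive", call. = FALSE)
    data$.log_response <- log(data[[spec$response]])
  }
  data
}

model_formula <- function(spec, fixed = spec$fixed) {
  lhs <- if (spec$family == "lognormal") ".log_response" else spec$response
  rhs <- c(if (length(fixed)) fixed else "1",
           sprintf('s(%s, bs = "re")', spec$random))
  as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

model_family <- function(spec) {
  switch(spec$family,
         poisson = stats::poisson(link = "log"),
         beta = patch_family_env(mgcv::betar(link = "logit")),
         tweedie = patch_family_env(mgcv::tw(link = "log")),
         lognormal = stats::gaussian())
}

# mgcv's extended families resolve unexported mgcv internals (e.g.
# ldTweedie) through their enclosing environment, which breaks when the
# family is built outside an attached mgcv; re-root the closure chain in the
# mgcv namespace
patch_family_env <- function(fam) {
  ns <- asNamespace("mgcv")
  for (nm in names(fam)) {
    if (!is.function(fam[[nm]])) next
    e <- environment(fam[[nm]])
    if (is.null(e) || identical(e, ns)) next
    if (!identical(environmentName(parent.env(e)), "mgcv"))
      try(parent.env(e) <- ns, silent = TRUE)
  }
  fam
}

#' Fit one mixed model
#'
#' Maximum-likelihood fit (`method = "ML"`, comparable AICs across
#' fixed-effect structures). Non-convergence is reported via the `converged`
#' flag rather than an error so selection can skip the candidate.
#'
#' @param spec a [model_spec()].
#' @param data model data (one row per analysis unit, e.g. fish-season).
#' @param fixed fixed-effect subset to fit (defaults to the full candidate
#'   set).
#' @return a `model_fit`: list with `spec`, `fixed`, `fit` (gam object),
#'   `coefficients` (fixed effects with SEs), `aic`, `n_fixed`, `converged`.
#' @export
fit_behaviour_model <- function(spec, data, fixed = spec$fixed) {
  data <- prepare_model_data(spec, data)
  fml <- model_formula(spec, fixed)
  fit <- try(mgcv::gam(fml, family = model_family(spec), data = data,
                       method = "ML"), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(spec = spec, fixed = fixed, fit = NULL,
                          coefficients = NULL, aic = Inf, n_fixed = NA,
                          converged = FALSE, data = data),
                     class = "model_fit"))
  npar <- fit$nsdf
  b <- coef(fit)[seq_len(npar)]
  se <- sqrt(diag(vcov(fit))[seq_len(npar)])
  structure(list(spec = spec, fixed = fixed, fit = fit,
                 coefficients = data.frame(term = names(b), estimate = b,
                                           se = se, row.names = NULL),
                 aic = AIC(fit), n_fixed = npar,
                 converged = isTRUE(fit$converged), data = data),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s ~ %s | family %s | AIC %.2f | %d fixed par\n",
              x$spec$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$spec$family, x$aic, x$n_fixed))
  invisible(x)
}

#' Admissible fixed-effect subsets
#'
#' All subsets of the candidate fixed effects, keeping an interaction only
#' when both of its main effects are present.
#'
#' @param fixed candidate fixed-effect terms.
#' @return list of character vectors (including the empty, intercept-only
#'   subset).
#' @export
all_fixed_subsets <- function(fixed) {
  n <- length(fixed)
  subsets <- list()
  for (m in 0:(2^n - 1)) {
    sel <- fixed[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (tm in sel[grepl(":", sel, fixed = TRUE)]) {
      mains <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(mains %in% sel)) { ok <- FALSE; break }
    }
    if (ok) subsets[[length(subsets) + 1L]] <- sel
  }
  subsets
}

#' Parsimony-within-window selection rule
#'
#' Among candidates with AIC within `window` of the minimum, return the index
#' of the one with the fewest parameters; ties on parameter count go to the
#' lower AIC.
#'
#' @param aic numeric AIC per candidate (non-finite = non-convergent,
#'   excluded).
#' @param n_params parameter count per candidate.
#' @param window AIC window (default 2).
#' @return integer index of the selected candidate.
#' @export
select_by_parsimony <- function(aic, n_params, window = 2) {
  ok <- is.finite(aic)
  if (!any(ok)) stop("no convergent candidate model", call. = FALSE)
  eligible <- which(ok & aic <= min(aic[ok]) + window)
  eligible[order(n_params[eligible], aic[eligible])][1]
}

#' All-subsets AIC selection with the parsimony rule
#'
#' Fits every admissible fixed-effect subset of the spec (random structure
#' held fixed), ranks by AIC, and returns the most parsimonious fit within
#' `window` AIC units of the best.
#'
#' @param spec a [model_spec()] (its `fixed` is the global candidate set).
#' @param data model data.
#' @param window AIC parsimony window (default 2).
#' @return list `best` (the selected `model_fit`), `table` (data.frame of
#'   all candidates: terms, AIC, parameters, converged, selected).
#' @export
select_behaviour_model <- function(spec, data, window = 2) {
  subsets <- all_fixed_subsets(spec$fixed)
  fits <- lapply(subsets, function(fx) fit_behaviour_model(spec, data, fx))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, function(f) {
    if (is.na(f$n_fixed)) Inf else f$n_fixed
  }, numeric(1))
  pick <- select_by_parsimony(aic, npar, window)
  tab <- data.frame(
    terms = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(intercept)", ""),
    aic = aic, n_fixed = npar,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    selected = seq_along(fits) == pick)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  list(best = fits[[pick]], table = tab)
}

# lpmatrix with random-effect columns zeroed (random effects at their mean)
fixed_lpmatrix <- function(fit, grid) {
  g <- fit$fit
  mf <- fit$data
  for (v in fit$spec$random)
    if (is.null(grid[[v]])) grid[[v]] <- factor(levels(mf[[v]])[1],
                                                levels = levels(mf[[v]]))
  X <- predict(g, newdata = grid, type = "lpmatrix")
  for (sm in g$smooth) X[, sm$first.para:sm$last.para] <- 0
  X
}

#' Marginal means and Tukey-adjusted pairwise contrasts
#'
#' Link-scale marginal means of `factor`, averaging over a full factorial
#' grid of the other fixed factors (equal reference weights) with numeric
#' covariates at their mean and random effects at zero. Pairwise differences
#' are tested with the studentized-range (Tukey) family adjustment using
#' normal large-sample degrees of freedom; with two levels this reduces to
#' the unadjusted z-test.
#'
#' @param fit a converged `model_fit`.
#' @param factor name of the factor to compare (must be in the fitted fixed
#'   effects).
#' @param alpha significance level (default 0.05).
#' @return list `means` (level, link-scale estimate, SE, response-scale
#'   mean) and `contrasts` (pair, estimate, SE, z, p_adjusted, significant).
#' @export
marginal_contrasts <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "model_fit"), isTRUE(fit$converged))
  vars <- unique(unlist(strsplit(fit$fixed, ":", fixed = TRUE)))
  if (!factor %in% vars)
    stop("factor ", factor, " not in fitted fixed effects", call. = FALSE)
  mf <- fit$data
  if (nlevels(mf[[factor]]) < 2L)
    stop("factor has a single level", call. = FALSE)
  levs <- lapply(vars, function(v) {
    if (is.factor(mf[[v]])) levels(mf[[v]]) else mean(mf[[v]], na.rm = TRUE)
  })
  names(levs) <- vars
  grid <- expand.grid(levs, stringsAsFactors = FALSE)
  for (v in vars)
    if (is.factor(mf[[v]]))
      grid[[v]] <- factor(grid[[v]], levels = levels(mf[[v]]))
  X <- fixed_lpmatrix(fit, grid)
  lv <- levels(mf[[factor]])
  L <- t(vapply(lv, function(l) colMeans(X[grid[[factor]] == l, ,
                                           drop = FALSE]),
                numeric(ncol(X))))
  b <- coef(fit$fit); V <- vcov(fit$fit)
  est <- drop(L %*% b)
  se <- sqrt(diag(L %*% V %*% t(L)))
  linkinv <- if (fit$spec$family == "lognormal") exp
             else family(fit$fit)$linkinv
  means <- data.frame(level = lv, emmean = est, se = se,
                      response = linkinv(est), row.names = NULL)
  k <- length(lv)
  pr <- t(combn(k, 2))
  Lc <- L[pr[, 1], , drop = FALSE] - L[pr[, 2], , drop = FALSE]
  cest <- drop(Lc %*% b)
  cse <- sqrt(diag(Lc %*% V %*% t(Lc)))
  z <- cest / cse
  p <- ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf, lower.tail = FALSE)
  contrasts <- data.frame(
    pair = paste(lv[pr[, 1]], lv[pr[, 2]], sep = " - "),
    estimate = cest, se = cse, z = z, p_adjusted = p,
    significant = p < alpha, row.names = NULL)
  list(means = means, contrasts = contrasts)
}

#' Predict responses on a covariate grid
#'
#' Response-scale predictions from the fixed effects only (random effects at
#' zero); deterministic. For lognormal fits the prediction is
#' `exp(mu)` (the conditional median).
#'
#' @param fit a converged `model_fit`.
#' @param grid data.frame with one column per fitted fixed effect; factor
#'   levels must have been seen in fitting.
#' @return numeric vector of predictions, one per grid row.
#' @export
predict_effects <- function(fit, grid) {
  stopifnot(inherits(fit, "model_fit"), isTRUE(fit$converged))
  vars <- unique(unlist(strsplit(fit$fixed, ":", fixed = TRUE)))
  mf <- fit$data
  for (v in vars) {
    if (is.factor(mf[[v]])) {
      bad <- setdiff(unique(as.character(grid[[v]])), levels(mf[[v]]))
      if (length(bad))
        stop("unseen factor level(s) for ", v, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      grid[[v]] <- factor(grid[[v]], levels = levels(mf[[v]]))
    }
  }
  X <- fixed_lpmatrix(fit, grid)
  eta <- drop(X %*% coef(fit$fit))
  linkinv <- if (fit$spec$family == "lognormal") exp
             else family(fit$fit)$linkinv
  unname(linkinv(eta))
}
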