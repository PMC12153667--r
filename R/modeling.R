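# Hierarchical weather-response models of hourly ODBA and activity:
# cyclic circadian spline + standardized weather/trait terms + random
# individual intercepts + AR-1 residuals; all-subsets AIC selection,
# repeatability (ICC), plasticity and classification quality.

# term registry: base covariates each fixed term involves (marginality and
# collinearity checks key off this map)
TERM_BASES <- list(
  temp = "temp", rain = "rain", wind = "wind", rh = "rh", soilm = "soilm",
  soilt10 = "soilt10", soilt30 = "soilt30", age = "age", bci = "bci",
  sex = "sex",
  temp_sq = "temp", rain_sq = "rain",
  bci_temp = c("bci", "temp"), bci_rain = c("bci", "rain"),
  bci_sex = c("bci", "sex"))

# lower-order terms each term requires (marginality)
TERM_REQUIRES <- list(
  temp_sq = "temp", rain_sq = "rain",
  bci_temp = c("bci", "temp"), bci_rain = c("bci", "rain"),
  bci_sex = c("bci", "sex"))

#' Specify a hierarchical hourly model
#'
#' @param response `"log2_odba"` (Gaussian, log2 hourly ODBA) or `"active"`
#'   (binomial hourly activity).
#' @param fixed_terms character vector of fixed terms; valid names are the
#'   standardized covariates `temp`, `rain`, `wind`, `rh`, `soilm`,
#'   `soilt10`, `soilt30`, the traits `age`, `sex`, `bci`, the quadratics
#'   `temp_sq`, `rain_sq`, and the interactions `bci_temp`, `bci_rain`,
#'   `bci_sex`. Quadratics/interactions require their lower-order terms.
#' @param knots basis dimension of the cyclic cubic regression spline of
#'   hour of day (default 10).
#' @param ar1 include an AR-1 residual correlation within each
#'   individual-deployment series (Gaussian response only).
#' @param random_slope optional single covariate name given an individual
#'   random slope (uncorrelated with the intercept).
#' @return a `model_spec` list.
#' @export
model_spec <- function(response = c("log2_odba", "active"),
                       fixed_terms = character(), knots = 10, ar1 = TRUE,
                       random_slope = NULL) {
  response <- match.arg(response)
  unknown <- setdiff(fixed_terms, names(TERM_BASES))
  if (length(unknown) > 0) {
    stop("unknown fixed terms: ", paste(unknown, collapse = ", "))
  }
  for (tm in fixed_terms) {
    req <- TERM_REQUIRES[[tm]]
    if (!is.null(req) && !all(req %in% fixed_terms)) {
      stop("term '", tm, "' requires ", paste(req, collapse = " and "))
    }
  }
  if (knots < 4) stop("need at least 4 knots for a cyclic cubic basis")
  structure(list(response = response, fixed_terms = fixed_terms,
                 knots = knots, ar1 = ar1, random_slope = random_slope),
            class = "model_spec")
}

# cyclic cubic regression-spline basis on hour of day, periodic over 24 h
cyclic_basis <- function(hour, knots = 10) {
  kn <- seq(0, 24, length.out = knots + 1)
  mgcv::cSplineDes(hour %% 24, kn)
}

#' Build the fixed-effect design for a model spec
#'
#' Constructs the cyclic cubic spline basis of hour of day (value and
#' curvature continuous across the 0/24 wrap; the basis is a partition of
#' unity, so its first column is dropped when an intercept is present) and
#' the standardized covariate, quadratic and interaction columns.
#' Continuous covariates must already be standardized: a column with
#' |mean| > 0.01 or |SD - 1| > 0.01 is rejected.
#'
#' @param data data frame with `hour` (in `[0, 24)`), the standardized
#'   covariates named by the spec's terms, and `sex` if used.
#' @param spec a [model_spec()].
#' @param check_standardized enforce the standardization gate; disable
#'   only for subsets of an already-standardized table (e.g.
#'   cross-validation folds), whose subset moments drift legitimately.
#' @return list: `X` (design matrix with intercept), `columns` (term of
#'   each column), `basis` (full spline basis, for diagnostics).
#' @export
build_design <- function(data, spec, check_standardized = TRUE) {
  if (any(data$hour < 0 | data$hour >= 24)) stop("hour must lie in [0, 24)")
  cont <- unique(unlist(TERM_BASES[spec$fixed_terms]))
  cont <- setdiff(cont, "sex")
  for (v in cont) {
    if (!v %in% names(data)) stop("missing covariate '", v, "'")
    if (check_standardized &&
        (abs(mean(data[[v]])) > 0.01 || abs(sd(data[[v]]) - 1) > 0.01)) {
      stop("covariate '", v, "' is not standardized (mean 0, SD 1)")
    }
  }
  basis <- cyclic_basis(data$hour, spec$knots)
  nb <- ncol(basis)
  X <- cbind(`(Intercept)` = 1, basis[, -1, drop = FALSE])
  colnames(X) <- c("(Intercept)", paste0("circ", seq_len(nb - 1)))
  cols <- c("(Intercept)", rep("circadian", nb - 1))
  for (tm in spec$fixed_terms) {
    val <- switch(tm,
      temp_sq = data$temp^2,
      rain_sq = data$rain^2,
      sex = as.numeric(data$sex == "M"),
      bci_temp = data$bci * data$temp,
      bci_rain = data$bci * data$rain,
      bci_sex = data$bci * as.numeric(data$sex == "M"),
      data[[tm]])
    X <- cbind(X, val)
    colnames(X)[ncol(X)] <- tm
    cols <- c(cols, tm)
  }
  list(X = X, columns = cols, basis = basis)
}

# shared: assemble a fitting frame (design columns + response + grouping +
# AR-1 time index) from a modeling table
make_fit_frame <- function(data, spec, check_standardized = TRUE) {
  need <- c("individual_id", "hour")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("data missing columns: ",
                             paste(miss, collapse = ", "))
  resp <- spec$response
  if (!resp %in% names(data)) {
    if (resp == "log2_odba" && "hourly_odba" %in% names(data)) {
      data$log2_odba <- log2(data$hourly_odba)
    } else {
      stop("data missing response '", resp, "'")
    }
  }
  keep <- is.finite(as.numeric(data[[resp]]))
  data <- data[keep, , drop = FALSE]
  des <- build_design(data, spec, check_standardized = check_standardized)
  dd <- as.data.frame(des$X[, -1, drop = FALSE]) # intercept via formula
  names(dd) <- make.names(colnames(des$X)[-1])
  dd$.response <- as.numeric(data[[resp]])
  dd$individual_id <- factor(data$individual_id)
  if ("hour_start" %in% names(data)) {
    hrs <- as.numeric(data$hour_start) / 3600
    dd$.tindex <- as.integer(round(hrs - min(hrs)))
    if ("deployment" %in% names(data)) {
      # separate deployments by a gap long enough to decorrelate
      dd$.tindex <- dd$.tindex +
        as.integer(factor(data$deployment)) * 100000L
    }
  } else {
    dd$.tindex <- stats::ave(seq_len(nrow(dd)),
                             dd$individual_id, FUN = seq_along)
  }
  rs <- spec$random_slope
  if (!is.null(rs)) {
    dd$.slope <- if (rs %in% colnames(des$X)) des$X[, rs] else data[[rs]]
  }
  list(frame = dd, design = des, data = data,
       xcols = make.names(colnames(des$X)[-1]))
}

cov_ranges_of <- function(data, terms) {
  cont <- setdiff(unique(unlist(TERM_BASES[terms])), "sex")
  cont <- intersect(cont, names(data))
  if (length(cont) == 0) return(NULL)
  tibble::tibble(covariate = cont,
                 min = vapply(cont, function(v) min(data[[v]]), numeric(1)),
                 max = vapply(cont, function(v) max(data[[v]]), numeric(1)))
}

#' Fit the hourly ODBA linear mixed model with AR-1 residuals
#'
#' REML/ML fit of log2 hourly ODBA on the spec's design with random
#' individual intercepts (optionally an uncorrelated random slope) and an
#' AR-1 residual correlation evaluated on the hourly time index within each
#' individual series, so a gap of g hours contributes correlation rho^g
#' (deployment breaks, offset by a large index jump, decorrelate).
#'
#' Hours with zero or missing ODBA cannot be log-transformed and are
#' excluded here (they remain inactive hours for the binomial model).
#'
#' @param data modeling table: `individual_id`, `hour`, `hour_start` (or a
#'   per-individual order is assumed), response `log2_odba` (or
#'   `hourly_odba`), standardized covariates, optionally `deployment`.
#' @param spec a [model_spec()] with `response = "log2_odba"`.
#' @param method `"REML"` (default) or `"ML"` (required for AIC comparison
#'   of fixed structures).
#' @return an `ns_fit` list: `coefficients` (tibble with SEs),
#'   `sigma_individual2`, `sigma_resid2`, `sigma_slope2`, `rho`, `logLik`,
#'   `n_params`, `aic`, `r2`, `icc`, `converged`, `boundary` (near-zero
#'   intercept variance flag), plus the underlying `nlme::lme` object.
#' @export
fit_lmm_ar1 <- function(data, spec, method = "REML") {
  stopifnot(inherits(spec, "model_spec"), spec$response == "log2_odba")
  mf <- make_fit_frame(data, spec)
  dd <- mf$frame
  form <- as.formula(paste(".response ~", paste(mf$xcols, collapse = " + ")))
  random <- if (is.null(spec$random_slope)) {
    list(individual_id = nlme::pdIdent(~1))
  } else {
    list(individual_id = nlme::pdDiag(~ 1 + .slope))
  }
  corr <- if (spec$ar1) {
    nlme::corAR1(form = ~ .tindex | individual_id)
  } else {
    NULL
  }
  fit <- try(nlme::lme(fixed = form, random = random, data = dd,
                       correlation = corr, method = method,
                       control = nlme::lmeControl(maxIter = 100,
                                                  msMaxIter = 100,
                                                  opt = "optim",
                                                  returnObject = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(converged = FALSE,
                          message = attr(fit, "condition")$message,
                          spec = spec),
                     class = "ns_fit"))
  }
  tt <- summary(fit)$tTable
  coefs <- tibble::tibble(term = rownames(tt), estimate = tt[, "Value"],
                          se = tt[, "Std.Error"], p = tt[, "p-value"])
  vc <- nlme::VarCorr(fit)
  sig_ind2 <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  slope2 <- if (!is.null(spec$random_slope)) {
    suppressWarnings(as.numeric(vc[".slope", "Variance"]))
  } else {
    NA_real_
  }
  sig_res2 <- fit$sigma^2
  rho <- if (spec$ar1) {
    as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else {
    0
  }
  ll <- logLik(fit)
  obs <- dd$.response
  fitted_c <- as.numeric(fitted(fit, level = 1))
  structure(list(
    fit = fit, spec = spec, coefficients = coefs,
    sigma_individual2 = sig_ind2, sigma_resid2 = sig_res2,
    sigma_slope2 = slope2, rho = rho,
    logLik = as.numeric(ll), n_params = attr(ll, "df"),
    aic = stats::AIC(fit), r2 = cor(fitted_c, obs)^2,
    icc = compute_icc(sig_ind2, sig_res2),
    n = nrow(dd), method = method,
    converged = TRUE,
    boundary = sig_ind2 < 1e-8 * sig_res2,
    cov_ranges = cov_ranges_of(mf$data, spec$fixed_terms)),
    class = "ns_fit")
}

#' @export
print.ns_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<ns_fit: non-converged>", x$message, "\n")
    return(invisible(x))
  }
  cat("Hierarchical fit (", x$spec$response, "), n =", x$n, "\n")
  cat(sprintf("  AIC %.1f | logLik %.1f | k %d\n", x$aic, x$logLik,
              x$n_params))
  if (!is.null(x$r2)) cat(sprintf("  R2 %.3f\n", x$r2))
  cat(sprintf("  var(ind) %.4f | var(resid) %.4f | ICC %.3f | rho %.3f\n",
              x$sigma_individual2, x$sigma_resid2, x$icc, x$rho))
  invisible(x)
}

#' Fit the binomial hourly-activity model
#'
#' Logistic mixed model of hourly activity with random individual
#' intercepts (lme4, adaptive approximation). With `include_ar1 = TRUE` the
#' selected specification is refit by penalized quasi-likelihood with an
#' AR-1 working correlation (MASS::glmmPQL), mirroring the staged design in
#' which selection runs without residual autocorrelation and AR-1 is added
#' to the selected model only.
#'
#' Classification quality (accuracy at a 0.5 cut and Matthews correlation)
#' is computed from conditional predictions (individual effects included).
#'
#' @param data modeling table with logical/0-1 `active`.
#' @param spec a [model_spec()] with `response = "active"`.
#' @param include_ar1 refit with AR-1 working correlation.
#' @param nAGQ adaptive Gauss-Hermite points for the lme4 fit (0 = fast
#'   PIRLS approximation, used in large selection scans).
#' @param check_standardized see [build_design()].
#' @return an `ns_fit` list with `coefficients`, `sigma_individual2`,
#'   `rho` (working AR-1, 0 unless `include_ar1`), `aic`/`logLik` (lme4
#'   fit), `accuracy`, `mcc`, `separation` flag.
#' @export
fit_glmm_binomial <- function(data, spec, include_ar1 = FALSE, nAGQ = 1,
                              check_standardized = TRUE) {
  stopifnot(inherits(spec, "model_spec"), spec$response == "active")
  mf <- make_fit_frame(data, spec, check_standardized = check_standardized)
  dd <- mf$frame
  dd$.response <- as.numeric(dd$.response)
  if (length(unique(dd$.response)) < 2) {
    stop("both activity classes must be present")
  }
  rhs <- if (length(mf$xcols) > 0) paste(mf$xcols, collapse = " + ") else "1"
  form <- as.formula(paste(".response ~", rhs, "+ (1 | individual_id)"))
  fit <- tryCatch(suppressMessages(lme4::glmer(
    form, data = dd, family = stats::binomial(), nAGQ = nAGQ,
    control = lme4::glmerControl(calc.derivs = FALSE,
                                 check.conv.singular = "ignore"))),
    error = function(e) e)
  separation <- FALSE
  if (inherits(fit, "error")) {
    # (quasi-)separable data break the PIRLS iterations; report the
    # separation and fall back to a fixed-effects logistic fit
    separation <- TRUE
    fit <- suppressWarnings(stats::glm(
      as.formula(paste(".response ~", rhs)), data = dd,
      family = stats::binomial()))
    fe <- coef(fit)
    sig_ind2 <- NA_real_
  } else {
    fe <- lme4::fixef(fit)
    sig_ind2 <- as.numeric(lme4::VarCorr(fit)$individual_id[1, 1])
  }
  se <- sqrt(diag(as.matrix(vcov(fit))))
  separation <- separation || any(abs(fe) > 15)
  rho <- 0
  pql <- NULL
  if (include_ar1) {
    fform <- as.formula(paste(".response ~", rhs))
    pql <- suppressMessages(suppressWarnings(MASS::glmmPQL(
      fixed = fform, random = ~ 1 | individual_id, family = stats::binomial(),
      data = dd, correlation = nlme::corAR1(form = ~ .tindex | individual_id),
      verbose = FALSE)))
    rho <- as.numeric(coef(pql$modelStruct$corStruct, unconstrained = FALSE))
    fe <- nlme::fixef(pql)
    se <- summary(pql)$tTable[, "Std.Error"]
    p <- as.numeric(predict(pql, type = "response", level = 1))
  } else {
    p <- as.numeric(predict(fit, type = "response"))
  }
  pred <- p > 0.5
  truth <- dd$.response == 1
  conf <- confusion_counts(truth, pred)
  ll <- logLik(fit)
  structure(list(
    fit = fit, pql_fit = pql, spec = spec,
    coefficients = tibble::tibble(term = names(fe),
                                  estimate = as.numeric(fe),
                                  se = as.numeric(se)),
    sigma_individual2 = sig_ind2,
    rho = rho, logLik = as.numeric(ll), n_params = attr(ll, "df"),
    aic = stats::AIC(fit),
    accuracy = (conf["tp"] + conf["tn"]) / sum(conf),
    mcc = compute_mcc(conf["tp"], conf["tn"], conf["fp"], conf["fn"]),
    confusion = conf, separation = separation, n = nrow(dd),
    converged = TRUE,
    cov_ranges = cov_ranges_of(mf$data, spec$fixed_terms)),
    class = "ns_fit")
}

confusion_counts <- function(truth, pred) {
  c(tp = sum(truth & pred), tn = sum(!truth & !pred),
    fp = sum(!truth & pred), fn = sum(truth & !pred))
}

# marginality- and collinearity-respecting subsets of a term set
enumerate_subsets <- function(terms, forbidden_pairs = NULL,
                              max_candidates = 4096) {
  n <- length(terms)
  if (n > 12) stop("term set too large for all-subsets enumeration")
  subsets <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- terms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (tm in sel) {
      req <- TERM_REQUIRES[[tm]]
      if (!is.null(req) && !all(req %in% sel)) { ok <- FALSE; break }
    }
    if (ok && !is.null(forbidden_pairs) && nrow(forbidden_pairs) > 0) {
      bases <- unique(unlist(TERM_BASES[sel]))
      for (i in seq_len(nrow(forbidden_pairs))) {
        if (forbidden_pairs$var1[i] %in% bases &&
            forbidden_pairs$var2[i] %in% bases) { ok <- FALSE; break }
      }
    }
    if (ok) subsets[[length(subsets) + 1]] <- sel
  }
  if (length(subsets) > max_candidates) {
    stop("candidate set too large: ", length(subsets), " models")
  }
  subsets
}

#' All-subsets AIC model selection
#'
#' Enumerates every marginality-respecting subset of the full spec's fixed
#' terms (quadratics only with their linear term, interactions only with
#' both main effects), skips any candidate containing both members of a
#' forbidden collinear pair, fits each candidate, and ranks by AIC (ties
#' broken toward fewer parameters). Gaussian candidates are fit by ML (AIC
#' comparison across fixed structures); binomial candidates by lme4 without
#' AR-1.
#'
#' @param data modeling table.
#' @param full_spec a [model_spec()] carrying the full term set.
#' @param forbidden_pairs tibble (`var1`, `var2`) from
#'   [collinearity_screen()], or `NULL`.
#' @param max_candidates guard on the enumeration size.
#' @param nAGQ passed to [fit_glmm_binomial()] for binomial candidates.
#' @return a `selection_table` list: `table` (one row per candidate:
#'   `model_id`, `terms`, `k`, `aic`, `delta_aic`, per-term presence
#'   flags), `term_support` (percentage of candidates within 2 AIC of the
#'   best containing each term), `best_spec`, `best_fit`.
#' @export
all_subsets_selection <- function(data, full_spec, forbidden_pairs = NULL,
                                  max_candidates = 4096, nAGQ = 0) {
  terms <- full_spec$fixed_terms
  subsets <- enumerate_subsets(terms, forbidden_pairs, max_candidates)
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sp <- model_spec(full_spec$response, subsets[[i]],
                     knots = full_spec$knots, ar1 = full_spec$ar1)
    f <- if (full_spec$response == "log2_odba") {
      fit_lmm_ar1(data, sp, method = "ML")
    } else {
      sp$ar1 <- FALSE
      fit_glmm_binomial(data, sp, nAGQ = nAGQ)
    }
    fits[[i]] <- f
    flags <- as.list(terms %in% subsets[[i]])
    names(flags) <- terms
    rows[[i]] <- tibble::tibble(
      model_id = i,
      terms = paste(subsets[[i]], collapse = "+"),
      k = if (isTRUE(f$converged)) f$n_params else NA_integer_,
      aic = if (isTRUE(f$converged)) f$aic else NA_real_,
      !!!flags)
  }
  tab <- dplyr::bind_rows(rows)
  ord <- order(tab$aic, tab$k)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - tab$aic[1]
  near <- tab[!is.na(tab$delta_aic) & tab$delta_aic < 2, , drop = FALSE]
  support <- tibble::tibble(
    term = terms,
    pct_delta2 = vapply(terms,
                        function(tm) 100 * mean(near[[tm]]), numeric(1)))
  best_terms <- strsplit(tab$terms[1], "+", fixed = TRUE)[[1]]
  if (length(best_terms) == 1 && best_terms == "") best_terms <- character(0)
  structure(list(table = tab, term_support = support,
                 best_spec = model_spec(full_spec$response, best_terms,
                                        knots = full_spec$knots,
                                        ar1 = full_spec$ar1),
                 best_fit = fits[[1]]),
            class = "selection_table")
}

#' Intra-class correlation (repeatability)
#'
#' `ICC = var_individual / (var_individual + var_residual)`: the fraction
#' of variance (conditional on the fixed effects) attributable to stable
#' individual differences.
#'
#' @param var_individual,var_residual non-negative variance components, not
#'   both zero.
#' @return numeric in `[0, 1]`.
#' @examples
#' compute_icc(2, 6) # 0.25
#' @export
compute_icc <- function(var_individual, var_residual) {
  if (var_individual < 0 || var_residual < 0) {
    stop("variance components must be non-negative")
  }
  if (var_individual + var_residual == 0) {
    stop("variance components must not both be zero")
  }
  var_individual / (var_individual + var_residual)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`:
#' +1 for perfect classification, -1 for perfectly inverted predictions, 0
#' for no association. When any marginal total is zero the coefficient is
#' undefined and 0 is returned with attribute `undefined = TRUE`.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (total > 0).
#' @return numeric MCC.
#' @export
compute_mcc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("empty confusion table")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) {
    return(structure(0, undefined = TRUE))
  }
  (tp * tn - fp * fn) / denom
}

#' MCC and accuracy from label vectors
#' @param truth,pred logical (or 0/1) vectors of equal length.
#' @return list with `mcc`, `accuracy`, and the confusion counts.
#' @export
classification_quality <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  stopifnot(length(truth) == length(pred))
  conf <- confusion_counts(truth, pred)
  list(mcc = compute_mcc(conf["tp"], conf["tn"], conf["fp"], conf["fn"]),
       accuracy = (conf["tp"] + conf["tn"]) / sum(conf),
       confusion = conf)
}

#' Predict total daily ODBA under a covariate scenario
#'
#' Evaluates the fitted model's population-level linear predictor for each
#' of the 24 scenario hours, back-transforms (`2^`) to the natural ODBA
#' scale, and sums. Uncertainty is by the delta method on the linear
#' predictor (gradient `ln 2 * 2^eta_h * x_h`).
#'
#' @param fit an `ns_fit` from [fit_lmm_ar1()].
#' @param scenario data frame of 24 rows (`hour` = 0..23) supplying every
#'   covariate the model uses, on the standardized scale.
#' @param level confidence level for the interval.
#' @return list: `daily_odba`, `se`, `lower`, `upper`, `hourly`
#'   (per-hour predictions on the natural scale).
#' @export
predict_daily_odba <- function(fit, scenario, level = 0.95) {
  stopifnot(inherits(fit, "ns_fit"), isTRUE(fit$converged))
  spec <- fit$spec
  if (nrow(scenario) != 24) stop("scenario must have 24 hourly rows")
  needed <- setdiff(unique(unlist(TERM_BASES[spec$fixed_terms])), NULL)
  miss <- setdiff(needed, names(scenario))
  if (length(miss) > 0) {
    stop("scenario missing covariates: ", paste(miss, collapse = ", "))
  }
  des <- build_design_unchecked(scenario, spec)
  beta <- nlme::fixef(fit$fit)
  X <- des$X
  stopifnot(ncol(X) == length(beta))
  eta <- as.numeric(X %*% beta)
  hourly <- 2^eta
  total <- sum(hourly)
  V <- as.matrix(vcov(fit$fit))
  grad <- as.numeric(log(2) * crossprod(X, hourly))
  se <- sqrt(as.numeric(t(grad) %*% V %*% grad))
  zq <- qnorm(1 - (1 - level) / 2)
  list(daily_odba = total, se = se,
       lower = total - zq * se, upper = total + zq * se,
       hourly = hourly)
}

# design without the standardization gate (scenarios legitimately sit at
# fixed off-zero covariate values)
build_design_unchecked <- function(data, spec) {
  basis <- cyclic_basis(data$hour, spec$knots)
  nb <- ncol(basis)
  X <- cbind(1, basis[, -1, drop = FALSE])
  colnames(X) <- c("(Intercept)", paste0("circ", seq_len(nb - 1)))
  for (tm in spec$fixed_terms) {
    val <- switch(tm,
      temp_sq = data$temp^2,
      rain_sq = data$rain^2,
      sex = as.numeric(data$sex == "M"),
      bci_temp = data$bci * data$temp,
      bci_rain = data$bci * data$rain,
      bci_sex = data$bci * as.numeric(data$sex == "M"),
      data[[tm]])
    X <- cbind(X, val)
    colnames(X)[ncol(X)] <- tm
  }
  list(X = X)
}

#' Nightly-scale mixed model and repeatability
#'
#' Linear mixed model of a nightly response (total ODBA or active minutes)
#' on night-averaged covariates with random individual intercepts; the
#' variance decomposition gives the repeatability (ICC) of nightly energy
#' expenditure.
#'
#' @param night_data tibble: `individual_id`, `night_id`, the response
#'   column, and the covariate columns.
#' @param covariates character vector of covariate columns (may be empty).
#' @param response response column name (default `"total_odba"`).
#' @param min_individuals,min_nights replication floor (defaults 5 and 3).
#' @return list: `fit` (nlme::lme), `coefficients`,
#'   `decomposition` (list `var_individual`, `var_residual`, `icc`), `n`.
#' @export
fit_nightly_model <- function(night_data, covariates = character(),
                              response = "total_odba",
                              min_individuals = 5, min_nights = 3) {
  stopifnot(response %in% names(night_data),
            all(covariates %in% names(night_data)))
  counts <- table(night_data$individual_id)
  if (length(counts) < min_individuals || min(counts) < min_nights) {
    stop("insufficient replication: need >= ", min_individuals,
         " individuals with >= ", min_nights, " nights each")
  }
  dd <- as.data.frame(night_data)
  dd$.response <- dd[[response]]
  rhs <- if (length(covariates) > 0) {
    paste(covariates, collapse = " + ")
  } else {
    "1"
  }
  fit <- nlme::lme(as.formula(paste(".response ~", rhs)),
                   random = ~ 1 | individual_id, data = dd,
                   method = "REML",
                   control = nlme::lmeControl(returnObject = TRUE))
  vc <- nlme::VarCorr(fit)
  vi <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  vr <- fit$sigma^2
  tt <- summary(fit)$tTable
  list(fit = fit,
       coefficients = tibble::tibble(term = rownames(tt),
                                     estimate = tt[, "Value"],
                                     se = tt[, "Std.Error"]),
       decomposition = list(var_individual = vi, var_residual = vr,
                            icc = compute_icc(vi, vr)),
       n = nrow(dd))
}

#' Grouped k-fold cross-validation of the activity classifier
#'
#' Individual-nights are assigned whole to folds (no hour of a night is
#' split across folds, avoiding leakage); each fold is predicted from a
#' model trained on the others, using conditional predictions for
#' individuals present in training.
#'
#' @param data modeling table with `active`, `hour_start` (night grouping
#'   is derived noon-to-noon) or an explicit `night_id` column.
#' @param spec binomial [model_spec()].
#' @param k number of folds (>= 2).
#' @param seed RNG seed for fold assignment.
#' @param nAGQ passed to the lme4 fits.
#' @return list: `folds` (tibble per fold: accuracy, mcc, n), `accuracy`,
#'   `accuracy_sd`, `mcc`, `mcc_sd`, `notes` (e.g. single-class training
#'   folds).
#' @export
k_fold_cv <- function(data, spec, k = 5, seed = 1, nAGQ = 0) {
  if (k < 2) stop("k must be >= 2")
  if (!"night_id" %in% names(data)) {
    if (!"hour_start" %in% names(data)) {
      stop("need night_id or hour_start to form leakage-safe folds")
    }
    data$night_id <- night_id_of(data$hour_start)
  }
  grp <- interaction(data$individual_id, data$night_id, drop = TRUE)
  ug <- levels(grp)
  if (k > length(ug)) stop("more folds than individual-nights")
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = length(ug)))
  names(fold_of) <- ug
  folds <- fold_of[as.character(grp)]
  notes <- character(0)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    if (length(unique(as.numeric(train$active))) < 2) {
      notes <- c(notes, paste("fold", f, "training data single-class"))
      next
    }
    ft <- fit_glmm_binomial(train, spec, nAGQ = nAGQ,
                            check_standardized = FALSE)
    mf_test <- make_fit_frame(test, spec, check_standardized = FALSE)
    nd <- mf_test$frame
    p <- as.numeric(predict(ft$fit, newdata = nd, type = "response",
                            allow.new.levels = TRUE))
    q <- classification_quality(nd$.response == 1, p > 0.5)
    rows[[f]] <- tibble::tibble(fold = f, accuracy = as.numeric(q$accuracy),
                                mcc = as.numeric(q$mcc), n = nrow(nd))
  }
  tab <- dplyr::bind_rows(rows)
  list(folds = tab,
       accuracy = mean(tab$accuracy), accuracy_sd = sd(tab$accuracy),
       mcc = mean(tab$mcc), mcc_sd = sd(tab$mcc),
       notes = notes)
}

#' Compare random-slope against random-intercept models
#'
#' Refits the base model once per candidate weather covariate with an added
#' individual random slope (uncorrelated with the intercept, one extra
#' variance parameter), comparing by AIC and by a likelihood-ratio test
#' with the 50:50 chi-square(0)/chi-square(1) boundary mixture (the slope
#' variance is tested on the boundary of its parameter space). A statistic
#' of exactly 0 returns p = 1 by convention.
#'
#' @param data modeling table.
#' @param base_spec Gaussian [model_spec()] without a random slope.
#' @param slope_covariates covariate names to try as random slopes.
#' @param method likelihood used for both fits (default `"ML"`).
#' @return tibble: `covariate`, `aic_base`, `aic_slope`, `delta_aic`
#'   (slope - base; negative favours the slope model), `lrt`, `p`,
#'   `slope_var`, `converged`.
#' @export
compare_random_slopes <- function(data, base_spec, slope_covariates,
                                  method = "ML") {
  base <- fit_lmm_ar1(data, base_spec, method = method)
  if (!isTRUE(base$converged)) stop("base fit did not converge")
  rows <- lapply(slope_covariates, function(cv) {
    sp <- base_spec
    sp$random_slope <- cv
    f <- fit_lmm_ar1(data, sp, method = method)
    if (!isTRUE(f$converged)) {
      return(tibble::tibble(covariate = cv, aic_base = base$aic,
                            aic_slope = NA_real_, delta_aic = NA_real_,
                            lrt = NA_real_, p = NA_real_,
                            slope_var = NA_real_, converged = FALSE))
    }
    stat <- max(0, 2 * (f$logLik - base$logLik))
    p <- if (stat == 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
    tibble::tibble(covariate = cv, aic_base = base$aic, aic_slope = f$aic,
                   delta_aic = f$aic - base$aic, lrt = stat, p = p,
                   slope_var = f$sigma_slope2, converged = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Predicted daily-ODBA plasticity surface over temperature by BCI
#'
#' For each BCI level, predicts total daily ODBA across a standardized
#' temperature grid (all other covariates held at 0, their standardized
#' mean), with delta-method confidence intervals. Requires the fit to
#' contain the `bci_temp` interaction. Grid points outside the covariate
#' range observed during fitting are flagged as extrapolation.
#'
#' @param fit an `ns_fit` containing `bci_temp`.
#' @param bci_levels named numeric vector of standardized BCI values (e.g.
#'   quantiles of the cohort).
#' @param temp_grid standardized temperature values.
#' @param sex,age values for any trait terms in the model (defaults `"F"`,
#'   0).
#' @return tibble: `bci_level`, `bci`, `temp`, `daily_odba`, `lower`,
#'   `upper`, `extrapolated`.
#' @export
plasticity_surface <- function(fit, bci_levels, temp_grid, sex = "F",
                               age = 0) {
  stopifnot(inherits(fit, "ns_fit"))
  if (!"bci_temp" %in% fit$spec$fixed_terms) {
    stop("fit does not contain the bci_temp interaction")
  }
  rng <- fit$cov_ranges
  trange <- if (!is.null(rng) && "temp" %in% rng$covariate) {
    unlist(rng[rng$covariate == "temp", c("min", "max")])
  } else {
    c(-Inf, Inf)
  }
  rows <- list()
  for (j in seq_along(bci_levels)) {
    for (tv in temp_grid) {
      scen <- tibble::tibble(hour = 0:23, temp = tv, rain = 0, wind = 0,
                             rh = 0, soilm = 0, soilt10 = 0, soilt30 = 0,
                             bci = bci_levels[[j]], age = age, sex = sex)
      pr <- predict_daily_odba(fit, scen)
      rows[[length(rows) + 1]] <- tibble::tibble(
        bci_level = names(bci_levels)[j] %||% as.character(j),
        bci = bci_levels[[j]], temp = tv,
        daily_odba = pr$daily_odba, lower = pr$lower, upper = pr$upper,
        extrapolated = tv < trange[1] | tv > trange[2])
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Cross-season consistency of individual intercepts
#'
#' Extracts the conditional-mode individual intercepts from each seasonal
#' fit and computes the Spearman rank correlation between seasons over the
#' individuals shared by both (omitted, with a note, when fewer than 3 are
#' shared).
#'
#' @param fits named list, one element per season: either an `ns_fit` or a
#'   data frame with columns `individual_id` and `intercept`.
#' @return list: `intercepts` (tibble `season`, `individual_id`,
#'   `intercept`), `correlations` (tibble `season1`, `season2`, `n_shared`,
#'   `spearman`, `note`).
#' @export
intercept_consistency <- function(fits) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  ints <- lapply(names(fits), function(s) {
    f <- fits[[s]]
    if (inherits(f, "ns_fit")) {
      re <- nlme::ranef(f$fit)
      tibble::tibble(season = s, individual_id = rownames(re),
                     intercept = re[["(Intercept)"]])
    } else {
      tibble::tibble(season = s, individual_id = f$individual_id,
                     intercept = f$intercept)
    }
  })
  ints <- dplyr::bind_rows(ints)
  seasons <- names(fits)
  rows <- list()
  for (i in seq_along(seasons)) {
    for (j in seq_along(seasons)) {
      if (j <= i) next
      a <- ints[ints$season == seasons[i], ]
      b <- ints[ints$season == seasons[j], ]
      shared <- intersect(a$individual_id, b$individual_id)
      if (length(shared) < 3) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          season1 = seasons[i], season2 = seasons[j],
          n_shared = length(shared), spearman = NA_real_,
          note = "fewer than 3 shared individuals")
        next
      }
      r <- cor(a$intercept[match(shared, a$individual_id)],
               b$intercept[match(shared, b$individual_id)],
               method = "spearman")
      rows[[length(rows) + 1]] <- tibble::tibble(
        season1 = seasons[i], season2 = seasons[j],
        n_shared = length(shared), spearman = r, note = NA_character_)
    }
  }
  list(intercepts = ints, correlations = dplyr::bind_rows(rows))
}

#' Per-night disparity in total ODBA across individuals
#'
#' Ratio of the most to the least ODBA-expending individual on each night
#' (nights with fewer than 2 individuals are skipped; nights whose minimum
#' is zero are excluded and flagged).
#'
#' @param night_records tibble with `individual_id`, `night_id`,
#'   `total_odba`.
#' @return list: `per_night` (tibble `night_id`, `n_individuals`, `ratio`),
#'   `mean_ratio`, `range`, `n_excluded_zero`.
#' @export
nightly_disparity <- function(night_records) {
  per <- night_records |>
    dplyr::group_by(.data$night_id) |>
    dplyr::summarise(n_individuals = dplyr::n(),
                     max_odba = max(.data$total_odba),
                     min_odba = min(.data$total_odba), .groups = "drop") |>
    dplyr::filter(.data$n_individuals >= 2)
  zero <- per$min_odba == 0
  kept <- per[!zero, , drop = FALSE]
  kept$ratio <- kept$max_odba / kept$min_odba
  list(per_night = kept[, c("night_id", "n_individuals", "ratio")],
       mean_ratio = mean(kept$ratio),
       range = range(kept$ratio),
       n_excluded_zero = sum(zero))
}
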