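# Full-subset additive-model selection of clonal-richness drivers.
#
# Gaussian additive models (penalized regression splines via mgcv) are fit
# for every admissible combination of at most two predictors, ranked by
# AICc, and summarized with Akaike weights; per-predictor importance is the
# sum of weights over models containing the predictor. A parsimony rule
# picks the candidate (delta AICc <= 2) model with the fewest predictors.

#' Default driver-analysis configuration
#'
#' Bundles the tunable knobs of the driver analysis: the predictor transform
#' map, display labels, collinearity thresholds, spline basis size, and the
#' candidate-set cutoff.
#'
#' @param transforms Named character vector mapping predictor to transform
#'   (`"sqrt"`, `"log"` or `"identity"`). Defaults: square root for the
#'   cyclone exposure probability, turbidity (KD490) and distance from
#'   shore; log for SST.
#' @param labels Named character vector of display names used in model
#'   labels.
#' @param predictors Candidate predictors, in priority order for the
#'   collinearity prefilter (earlier wins on conflict).
#' @param factors Which predictors are categorical factors.
#' @param r_max Collinearity prefilter threshold on \|Pearson r\| (default
#'   0.8).
#' @param pair_r_max Maximum \|r\| between the two predictors of one model
#'   (default 0.28).
#' @param max_vars Maximum predictors per model (default 2).
#' @param basis_dim Spline basis dimension per smooth (default 4; site-level
#'   samples of 14-16 forbid more).
#' @param delta_cutoff Candidate-set cutoff on delta AICc (default 2).
#' @param include_interactions Add factor + smooth-by-factor specs for
#'   admissible factor/continuous pairs (default `TRUE`).
#' @return A list of class `driver_config`.
#' @export
driver_config <- function(
    transforms = c(cyclone_pr = "sqrt", sst = "log", kd490 = "sqrt",
                   dist_shore = "sqrt"),
    labels = c(cyclone_pr = "cyclone", sst = "SST", kd490 = "KD490",
               dist_shore = "Dist.shore", dugong = "dugong",
               latitude = "latitude"),
    predictors = c("cyclone_pr", "dugong", "sst", "kd490", "dist_shore",
                   "latitude"),
    factors = "dugong",
    r_max = 0.8, pair_r_max = 0.28, max_vars = 2L, basis_dim = 4L,
    delta_cutoff = 2, include_interactions = TRUE) {
  structure(list(transforms = transforms, labels = labels,
                 predictors = predictors, factors = factors,
                 r_max = r_max, pair_r_max = pair_r_max,
                 max_vars = as.integer(max_vars),
                 basis_dim = as.integer(basis_dim),
                 delta_cutoff = delta_cutoff,
                 include_interactions = include_interactions),
            class = "driver_config")
}

#' Apply the declared predictor transforms
#'
#' Adds a `<var>_t` column per transformed predictor; untransformed
#' predictors are copied. Each transform is applied exactly once and the
#' map is recorded as an attribute.
#'
#' @param covariates Site covariate data frame.
#' @param config A [driver_config()].
#' @return The data frame with `<var>_t` columns and attribute
#'   `transforms_applied`.
#' @export
apply_transforms <- function(covariates, config = driver_config()) {
  for (v in intersect(config$predictors, names(covariates))) {
    if (v %in% config$factors) next
    tr <- config$transforms[v]
    tr <- if (is.na(tr)) "identity" else tr
    covariates[[paste0(v, "_t")]] <- switch(
      tr,
      sqrt = sqrt(covariates[[v]]),
      log = log(covariates[[v]]),
      identity = covariates[[v]],
      stop("unknown transform '", tr, "' for ", v))
  }
  attr(covariates, "transforms_applied") <- config$transforms
  covariates
}

# display label for a predictor, with transform suffix for continuous ones
predictor_label <- function(v, config) {
  lab <- config$labels[v]
  if (is.na(lab)) lab <- v
  if (!(v %in% config$factors)) {
    tr <- config$transforms[v]
    if (!is.na(tr) && tr != "identity") lab <- paste0(lab, ".", tr)
  }
  unname(lab)
}

# transformed column used in formulas
predictor_column <- function(v, config) {
  if (v %in% config$factors) v else paste0(v, "_t")
}

#' Collinearity prefilter on candidate predictors
#'
#' Walks the predictors in priority order; a predictor is dropped when its
#' absolute Pearson correlation (point-biserial for binary factors, on the
#' transformed scale for continuous ones) with any already-retained
#' predictor exceeds `r_max`. Constant predictors are dropped with a
#' warning since their correlation is undefined.
#'
#' @param covariates Transformed covariate table (see [apply_transforms()]).
#' @param config A [driver_config()]; `config$predictors` is the priority
#'   order and `config$r_max` the threshold.
#' @return List with `retained` (character vector) and `drops` (data frame
#'   of dropped predictor, conflicting predictor, correlation).
#' @export
prefilter_predictors <- function(covariates, config = driver_config()) {
  cand <- intersect(config$predictors, names(covariates))
  if (length(cand) < 2L) stop("need at least two candidate predictors")
  num <- lapply(cand, function(v) {
    x <- covariates[[predictor_column(v, config)]]
    if (is.factor(x)) x <- as.numeric(x)
    if (is.logical(x) || is.character(x)) x <- as.numeric(as.factor(x))
    x
  })
  names(num) <- cand
  retained <- character(0)
  drops <- data.frame(dropped = character(0), against = character(0),
                      r = numeric(0), stringsAsFactors = FALSE)
  for (v in cand) {
    if (stats::sd(num[[v]]) == 0) {
      warning("predictor '", v, "' is constant; dropped")
      drops <- rbind(drops, data.frame(dropped = v, against = NA_character_,
                                       r = NA_real_))
      next
    }
    conflict <- NA_character_; rconf <- NA_real_
    for (u in retained) {
      r <- stats::cor(num[[v]], num[[u]])
      if (abs(r) > config$r_max) { conflict <- u; rconf <- r; break }
    }
    if (is.na(conflict)) retained <- c(retained, v)
    else drops <- rbind(drops, data.frame(dropped = v, against = conflict,
                                          r = rconf))
  }
  list(retained = retained, drops = drops)
}

#' Enumerate candidate model specifications
#'
#' Emits the null model, every single-predictor model, every two-predictor
#' model whose predictors' absolute pairwise correlation does not exceed
#' `pair_r_max`, and — when interactions are enabled — a factor plus
#' smooth-by-factor spec for each admissible factor/continuous pair (the
#' continuous smooth varying by factor level).
#'
#' @param retained Character vector of retained predictors.
#' @param covariates Transformed covariate table (for pairwise
#'   correlations).
#' @param config A [driver_config()].
#' @return A list of `model_spec` objects: each a list with `predictors`,
#'   `terms` (per-term `var`, `kind` in smooth/factor/smooth_by_factor,
#'   optional `by`), and `label`.
#' @export
build_candidate_models <- function(retained, covariates,
                                   config = driver_config()) {
  if (length(retained) == 0L) stop("no retained predictors")
  mk <- function(predictors, terms, label)
    structure(list(predictors = predictors, terms = terms, label = label),
              class = "model_spec")
  term_for <- function(v) {
    if (v %in% config$factors) list(var = v, kind = "factor")
    else list(var = v, kind = "smooth")
  }
  specs <- list(mk(character(0), list(), "null"))
  for (v in retained) {
    specs[[length(specs) + 1L]] <-
      mk(v, list(term_for(v)), predictor_label(v, config))
  }
  if (length(retained) >= 2L && config$max_vars >= 2L) {
    pairs <- utils::combn(retained, 2L, simplify = FALSE)
    for (pr in pairs) {
      x <- covariates[[predictor_column(pr[1L], config)]]
      y <- covariates[[predictor_column(pr[2L], config)]]
      if (is.factor(x) || is.character(x)) x <- as.numeric(as.factor(x))
      if (is.factor(y) || is.character(y)) y <- as.numeric(as.factor(y))
      r <- stats::cor(x, y)
      if (abs(r) > config$pair_r_max) next
      lab <- paste(vapply(pr, predictor_label, character(1),
                          config = config), collapse = "+")
      specs[[length(specs) + 1L]] <-
        mk(pr, lapply(pr, term_for), lab)
      if (config$include_interactions) {
        fac <- pr[pr %in% config$factors]
        con <- pr[!(pr %in% config$factors)]
        if (length(fac) == 1L && length(con) == 1L) {
          lab_i <- paste0(predictor_label(fac, config), "+",
                          predictor_label(con, config), ".by.",
                          predictor_label(fac, config))
          specs[[length(specs) + 1L]] <- mk(
            pr,
            list(list(var = fac, kind = "factor"),
                 list(var = con, kind = "smooth_by_factor", by = fac)),
            lab_i)
        }
      }
    }
  }
  specs
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`; finite only when `n > k + 1`.
#' Converges to AIC as `n` grows.
#'
#' @param logL Maximized log-likelihood.
#' @param k Effective parameter count (including the scale parameter).
#' @param n Sample size.
#' @return AICc value (Inf when `n <= k + 1`).
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one Gaussian additive model
#'
#' Fits the model described by a spec from [build_candidate_models()]:
#' continuous predictors enter as penalized regression splines (thin-plate,
#' basis dimension `config$basis_dim`), factors as dummy-coded effects, and
#' smooth-by-factor terms as one smooth per factor level. Fitting is by
#' maximum likelihood (mgcv) so that likelihoods are comparable across
#' specs; `k` is the model's effective degrees of freedom including the
#' scale parameter, and r-squared is the fraction of response variance
#' explained.
#'
#' @param data Transformed covariate table with response column `R`.
#' @param spec A `model_spec`.
#' @param config A [driver_config()].
#' @param response Response column name (default `"R"`).
#' @return A list of class `model_fit`: `spec`, `label`, `n`, `k`, `logLik`,
#'   `AICc`, `r2`, and the underlying `gam` object.
#' @export
fit_additive_model <- function(data, spec, config = driver_config(),
                               response = "R") {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(data)
  if (!all(is.finite(data[[response]])))
    stop("non-finite response values")
  # worst-case parameter count for this spec (unpenalized)
  kb <- config$basis_dim
  k_max <- 1L
  for (tm in spec$terms) {
    k_max <- k_max + switch(tm$kind,
      smooth = kb - 1L,
      factor = length(unique(data[[tm$var]])) - 1L,
      smooth_by_factor = (kb - 1L) * length(unique(data[[tm$by]])))
  }
  if (n < k_max + 2L)
    stop("refusing to fit '", spec$label, "': n = ", n,
         " is too small for ", k_max, " coefficients plus scale",
         " (need n >= k + 2); reduce basis_dim or the predictor set")
  rhs <- "1"
  for (tm in spec$terms) {
    col <- predictor_column(tm$var, config)
    rhs <- c(rhs, switch(
      tm$kind,
      smooth = sprintf("s(%s, k = %d)", col, kb),
      factor = col,
      smooth_by_factor = sprintf("s(%s, k = %d, by = %s)", col, kb,
                                 tm$by)))
  }
  for (f in intersect(config$factors, vapply(spec$terms, `[[`, "",
                                             "var"))) {
    data[[f]] <- factor(data[[f]])
  }
  fm <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(fm, data = data, method = "ML")
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design for model '", spec$label, "'")
  ll <- stats::logLik(fit)
  k <- as.numeric(attr(ll, "df"))  # effective df including scale
  y <- data[[response]]
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(spec = spec, label = spec$label, n = n, k = k,
                 logLik = as.numeric(ll), AICc = aicc(as.numeric(ll), k, n),
                 r2 = max(0, min(1, r2)), gam = fit),
            class = "model_fit")
}

#' Rank fitted models by AICc
#'
#' Computes delta AICc relative to the best model and Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`; flags the candidate set
#' (delta AICc within `delta_cutoff`) and selects the parsimonious model:
#' fewest predictors within the candidate set, ties broken by lower AICc,
#' then lexicographic label.
#'
#' @param fits List of `model_fit` objects. Fits with non-finite AICc are
#'   excluded with a warning.
#' @param delta_cutoff Candidate-set cutoff (default 2).
#' @return A data frame of class `model_table`, sorted ascending by AICc,
#'   with columns `label`, `n_predictors`, `k`, `logLik`, `AICc`,
#'   `delta_AICc`, `wi`, `r2`, `candidate`; attributes `parsimonious`
#'   (label) and `specs` (list of specs in table order).
#' @export
rank_models <- function(fits, delta_cutoff = 2) {
  stopifnot(length(fits) >= 1L)
  finite <- vapply(fits, function(f) is.finite(f$AICc), logical(1))
  if (!all(finite)) {
    warning(sum(!finite), " fit(s) with non-finite AICc excluded")
    fits <- fits[finite]
  }
  if (length(fits) == 0L) stop("no fits with finite AICc")
  tab <- data.frame(
    label = vapply(fits, `[[`, "", "label"),
    n_predictors = vapply(fits, function(f) length(f$spec$predictors),
                          integer(1)),
    k = vapply(fits, `[[`, 0, "k"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    AICc = vapply(fits, `[[`, 0, "AICc"),
    stringsAsFactors = FALSE)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta_AICc / 2)
  tab$wi <- w / sum(w)
  tab$r2 <- vapply(fits, `[[`, 0, "r2")
  tab$candidate <- tab$delta_AICc <= delta_cutoff
  ord <- order(tab$AICc, tab$label)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  specs <- lapply(fits, `[[`, "spec")[ord]
  cand <- which(tab$candidate)
  pars <- cand[order(tab$n_predictors[cand], tab$AICc[cand],
                     tab$label[cand])][1L]
  class(tab) <- c("model_table", "data.frame")
  attr(tab, "specs") <- specs
  attr(tab, "parsimonious") <- tab$label[pars]
  tab
}

#' Akaike-weight variable importance
#'
#' The importance of a predictor is the sum of Akaike weights over all
#' models whose specification contains it; a smooth-by-factor term counts
#' for both participating predictors. Values lie in \[0, 1\]; a predictor in
#' no model scores 0.
#'
#' @param table A `model_table` from [rank_models()], or any data frame with
#'   a `wi` column and a `predictors` list-column (or an attached `specs`
#'   attribute).
#' @param predictors Optional character vector of predictors to report
#'   (defaults to every predictor appearing in any model).
#' @return A data frame of class `importance_table` with columns `predictor`
#'   and `importance`, sorted by descending importance.
#' @export
variable_importance <- function(table, predictors = NULL) {
  stopifnot(is.data.frame(table), "wi" %in% names(table))
  plist <- if (!is.null(table$predictors)) {
    lapply(table$predictors, as.character)
  } else {
    specs <- attr(table, "specs")
    if (is.null(specs)) stop("need a predictors column or specs attribute")
    lapply(specs, `[[`, "predictors")
  }
  all_p <- unique(unlist(plist))
  if (is.null(predictors)) predictors <- all_p
  imp <- vapply(predictors, function(p) {
    sum(table$wi[vapply(plist, function(ps) p %in% ps, logical(1))])
  }, numeric(1))
  out <- data.frame(predictor = predictors, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Full driver analysis for one or more species
#'
#' Runs the complete chain per species: predictor transforms, collinearity
#' prefilter (threshold 0.8), candidate-model enumeration (at most two
#' predictors, pairwise \|r\| <= 0.28, optional smooth-by-factor
#' interactions), Gaussian additive-model fits, AICc ranking with Akaike
#' weights and the parsimony rule, and per-predictor importance.
#'
#' @param covariates Data frame with columns `species`, `R`, and the
#'   candidate predictors of `config`.
#' @param config A [driver_config()].
#' @return A named list (one element per species) of lists with
#'   `model_table`, `importance`, `retained`, `drops`, `parsimonious`.
#' @export
run_driver_analysis <- function(covariates, config = driver_config()) {
  stopifnot("R" %in% names(covariates))
  if (!"species" %in% names(covariates)) covariates$species <- "all"
  out <- lapply(split(covariates, covariates$species), function(d) {
    d <- apply_transforms(d, config)
    pf <- prefilter_predictors(d, config)
    specs <- build_candidate_models(pf$retained, d, config)
    fits <- lapply(specs, fit_additive_model, data = d, config = config)
    tab <- rank_models(fits, config$delta_cutoff)
    list(model_table = tab,
         importance = variable_importance(tab, predictors = pf$retained),
         retained = pf$retained, drops = pf$drops,
         parsimonious = attr(tab, "parsimonious"))
  })
  out
}
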