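#' Shannon diversity index
#'
#' H = -sum p_i log p_i over taxa with positive counts, natural log.
#'
#' @param counts Non-negative integer vector with at least one positive
#'   entry.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (all(counts == 0)) stop("all-zero count vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Simpson diversity index (Gini-Simpson form)
#'
#' D = 1 - sum p_i^2: the probability that two reads drawn at random
#' belong to different taxa.
#'
#' @param counts Non-negative integer vector with at least one positive
#'   entry.
#' @return Simpson index in [0, 1).
#' @export
simpson <- function(counts) {
  if (all(counts == 0)) stop("all-zero count vector")
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Rank-based inverse normal transform
#'
#' Maps average ranks through the standard normal quantile of
#' (rank - 0.5)/n, so downstream models reflect relative ordering rather
#' than absolute differences. Ties receive identical outputs.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector of normal scores.
#' @export
rank_normalize <- function(values) {
  n <- length(values)
  if (n < 2) stop("rank normalization needs at least 2 values")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / n)
}

#' Per-sample alpha diversity table
#'
#' @param table A `feature_table`.
#' @return data.frame with `sample_id`, `shannon`, `simpson`, and
#'   `simpson_rank_normal` (the inverse-normal scores of Simpson).
#' @export
alpha_diversity <- function(table) {
  sh <- apply(table$counts, 2, shannon)
  si <- apply(table$counts, 2, simpson)
  data.frame(sample_id = colnames(table$counts), shannon = sh, simpson = si,
             simpson_rank_normal = if (length(si) >= 2) rank_normalize(si) else NA_real_,
             row.names = NULL)
}

.lmm_predictors <- c("segment", "continent", "doa", "bird_type", "housing",
                     "hv_region")

build_lmm_data <- function(response, meta, predictors) {
  stopifnot(length(response) == nrow(meta))
  bad <- setdiff(predictors, names(meta))
  if (length(bad) > 0) stop("unknown predictors: ", paste(bad, collapse = ", "))
  d <- data.frame(.y = response, bioproject = factor(meta$bioproject_id))
  for (p in predictors) {
    v <- meta[[p]]
    d[[p]] <- if (is.factor(v)) droplevels(v) else if (p == "doa") as.numeric(v)
              else droplevels(factor(v))
  }
  # constant predictors are aliased with the intercept
  const <- predictors[vapply(predictors, function(p)
    length(unique(d[[p]])) < 2, logical(1))]
  if (length(const) > 0)
    stop("aliased (constant) predictors: ", paste(const, collapse = ", "))
  d
}

#' Select an estimable fixed-effect predictor subset
#'
#' Greedily drops predictors until the fixed-effect design is full rank:
#' constant predictors go first, then terms owning aliased design columns.
#' With few datasets, design factors assigned at the dataset level are
#' often mutually confounded and cannot all be estimated.
#'
#' @param response Numeric response vector.
#' @param meta A `sample_metadata`.
#' @param predictors Candidate predictor names.
#' @return Character vector of retained predictors (possibly empty).
#' @export
select_estimable_predictors <- function(response, meta, predictors) {
  preds <- predictors[vapply(predictors, function(p)
    length(unique(meta[[p]])) >= 2, logical(1))]
  while (length(preds) > 0) {
    d <- build_lmm_data(response, meta, preds)
    X <- stats::model.matrix(stats::reformulate(preds, response = ".y"), d)
    qrX <- qr(X)
    if (qrX$rank == ncol(X)) return(preds)
    aliased_col <- qrX$pivot[ncol(X)]  # drop the term owning the last pivot
    term <- c("(Intercept)", preds)[attr(X, "assign")[aliased_col] + 1]
    preds <- setdiff(preds, term)
  }
  character(0)
}

#' Random-intercept mixed model for alpha diversity
#'
#' Fits `response ~ predictors + (1 | bioproject)` by REML. BioProject is
#' the random effect: samples from one study share a technical and
#' husbandry context, and the model's inference targets the fixed design
#' factors across studies. Adjusted GVIFs (GVIF^(1/(2 df))) quantify
#' collinearity between the fixed terms.
#'
#' @param response Numeric response vector, one value per metadata row
#'   (e.g. Shannon, or rank-normalized Simpson).
#' @param meta A `sample_metadata` with >= 2 distinct BioProjects.
#' @param predictors Fixed-effect names among segment, continent, doa,
#'   bird_type, housing, hv_region. `doa` enters as a continuous
#'   covariate; factors use their canonical level order (segments in
#'   anatomical order, duodenum first).
#' @return An object of class `lmm_fit`: list with the `lme4` model,
#'   `coefficients` (term, estimate, se, t), `varcomp` (bioproject and
#'   residual variances), `aic` (REML and ML), `agvif` per predictor, and
#'   the fitted predictor names.
#' @export
fit_lmm <- function(response, meta, predictors = .lmm_predictors) {
  if (length(unique(meta$bioproject_id)) < 2)
    stop("need >= 2 BioProjects for a random-intercept model")
  d <- build_lmm_data(response, meta, predictors)
  fix_form <- stats::reformulate(predictors, response = ".y")
  X <- stats::model.matrix(fix_form, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  form <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + "),
                                  "+ (1 | bioproject)"))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  new_lmm_fit(fit, d, predictors)
}

new_lmm_fit <- function(fit, data, predictors) {
  ct <- as.data.frame(stats::coef(summary(fit)))
  names(ct) <- c("estimate", "se", "t")
  ct <- cbind(term = rownames(ct), ct)
  rownames(ct) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(bioproject = vc$vcov[vc$grp == "bioproject"],
               residual = vc$vcov[vc$grp == "Residual"])
  ml_fit <- stats::update(fit, REML = FALSE)
  agvif <- rep(NA_real_, length(predictors))
  names(agvif) <- predictors
  if (length(predictors) >= 2) {
    v <- tryCatch(car::vif(fit), error = function(e) NULL)
    if (!is.null(v)) {
      if (is.matrix(v)) agvif[rownames(v)] <- v[, "GVIF^(1/(2*Df))"]
      else agvif[names(v)] <- sqrt(v)  # single-df terms: GVIF^(1/2)
    }
  } else if (length(predictors) == 1) {
    agvif[] <- 1
  }
  structure(list(model = fit, data = data, predictors = predictors,
                 coefficients = ct, varcomp = varcomp,
                 aic = c(REML = stats::AIC(fit), ML = stats::AIC(ml_fit)),
                 logLik_ml = as.numeric(stats::logLik(ml_fit)),
                 agvif = agvif),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept mixed model (REML)\n")
  cat("Fixed terms:", paste(x$predictors, collapse = ", "), "\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("Variance components: bioproject %.4g, residual %.4g\n",
              x$varcomp["bioproject"], x$varcomp["residual"]))
  cat(sprintf("AIC: %.2f (REML), %.2f (ML)\n", x$aic["REML"], x$aic["ML"]))
  invisible(x)
}

term_of_coefficient <- function(fit) {
  # maps each fixed-effect coefficient (minus intercept) to its model term
  X <- stats::model.matrix(stats::reformulate(fit$predictors, response = ".y"),
                           fit$data)
  assign <- attr(X, "assign")
  terms <- c("(Intercept)", fit$predictors)[assign + 1]
  stats::setNames(terms, colnames(X))
}

#' Drop non-significant predictors and refit
#'
#' A fixed term is dropped when every one of its coefficients has
#' |t| below `t_threshold`; a factor is retained if any level reaches the
#' threshold. The reduced model is refitted and AICs (ML criterion, the
#' comparable one across fixed-effect structures) are reported for both
#' models. A warning is raised when any adjusted GVIF of the full model
#' reaches `gvif_threshold`, since collinearity can mask a predictor's t
#' values.
#'
#' @param fit An `lmm_fit`.
#' @param t_threshold Absolute t value below which a term is deemed
#'   non-significant (default 2).
#' @param gvif_threshold Adjusted-GVIF warning level (default 1.2).
#' @return The reduced `lmm_fit`, with attributes `dropped` (character),
#'   `aic_full` and `aic_reduced` (ML-criterion AICs).
#' @export
reduce_model <- function(fit, t_threshold = 2, gvif_threshold = 1.2) {
  stopifnot(inherits(fit, "lmm_fit"))
  high <- fit$agvif[!is.na(fit$agvif) & fit$agvif >= gvif_threshold]
  if (length(high) > 0)
    warning("adjusted GVIF >= ", gvif_threshold, " for: ",
            paste(names(high), collapse = ", "))
  tm <- term_of_coefficient(fit)
  keep <- character(0)
  for (p in fit$predictors) {
    tv <- fit$coefficients$t[tm[fit$coefficients$term] == p]
    if (any(abs(tv) >= t_threshold)) keep <- c(keep, p)
  }
  dropped <- setdiff(fit$predictors, keep)
  if (length(keep) == 0) {
    warning("all predictors dropped; returning intercept-only fit")
    form <- stats::as.formula(".y ~ 1 + (1 | bioproject)")
    red <- lme4::lmer(form, data = fit$data, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    out <- new_lmm_fit(red, fit$data, character(0))
  } else if (length(dropped) == 0) {
    out <- fit
  } else {
    form <- stats::as.formula(paste(".y ~", paste(keep, collapse = " + "),
                                    "+ (1 | bioproject)"))
    red <- lme4::lmer(form, data = fit$data, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    out <- new_lmm_fit(red, fit$data, keep)
  }
  attr(out, "dropped") <- dropped
  attr(out, "aic_full") <- fit$aic["ML"]
  attr(out, "aic_reduced") <- out$aic["ML"]
  out
}
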