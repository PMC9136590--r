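#' Automated-versus-manual agreement regression
#'
#' Ordinary least squares of the automated CI on the manually counted CI
#' for the same plates, the standard check that area-based scoring
#' agrees with hand counts. `r_squared = 1 - SSE/SST`, which on a simple
#' regression equals the squared Pearson correlation of the two columns.
#'
#' @param records `data.frame` with numeric columns `manual_ci` and
#'   `automated_ci` (CIs in \[-1, 1\]); extra columns such as `strain`
#'   and `compound` are allowed and ignored here.
#' @return object of class `agreement_fit` with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `lm` fit in `$fit`.
#' @export
fit_agreement <- function(records) {
  records <- validate_agreement(records, need_strain = FALSE)
  if (nrow(records) < 3L) stop("need at least 3 records to fit agreement")
  if (var(records$manual_ci) == 0)
    stop("degenerate fit: manual_ci has zero variance")
  fit <- lm(automated_ci ~ manual_ci, data = records)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((records$automated_ci - mean(records$automated_ci))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = if (sst == 0) 0 else 1 - sse / sst,
         n = nrow(records), fit = fit),
    class = "agreement_fit")
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf(
    "Agreement: automated = %.4f + %.4f * manual,  R^2 = %.4f  (n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Test for a strain-dependent systematic error
#'
#' Fits `automated_ci ~ manual_ci + strain` with strain as a categorical
#' term and compares it against the manual-CI-only model by
#' extra-sum-of-squares ANOVA. A significant F would indicate that the
#' automated method disagrees with manual counts differently for some
#' genetic backgrounds, i.e. a strain-dependent systematic error.
#' Per-strain coefficients are reported normalized to the reference
#' strain (whose estimate is exactly 0) with 95% confidence intervals.
#'
#' @param records `data.frame` with `strain`, `manual_ci`,
#'   `automated_ci`; at least 2 strains with 2 records each.
#' @param reference reference strain; default the lexicographically
#'   first.
#' @return object of class `strain_effect_result`: `f_statistic`,
#'   `df1`, `df2`, `p_value`, and `estimates`, a `data.frame` of
#'   per-strain normalized estimates with `lwr`/`upr` 95% CI bounds.
#' @export
strain_effect_anova <- function(records, reference = NULL) {
  records <- validate_agreement(records, need_strain = TRUE)
  records$strain <- as.character(records$strain)
  tab <- table(records$strain)
  if (length(tab) < 2L) stop("need at least 2 strains")
  if (any(tab < 2L))
    stop("every strain needs at least 2 records; too few for: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (is.null(reference)) reference <- sort(names(tab))[1]
  if (!reference %in% names(tab)) stop("unknown reference strain: ", reference)
  records$strain <- stats::relevel(factor(records$strain), ref = reference)

  reduced <- lm(automated_ci ~ manual_ci, data = records)
  full <- lm(automated_ci ~ manual_ci + strain, data = records)
  if (anyNA(coef(full))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop("rank-deficient strain model; aliased terms: ",
         paste(bad, collapse = ", "))
  }
  an <- anova(reduced, full)

  strains <- levels(records$strain)
  cf <- coef(full)
  ci <- confint(full, level = 0.95)
  idx <- paste0("strain", strains[-1])
  estimates <- data.frame(
    strain = strains,
    estimate = c(0, unname(cf[idx])),
    lwr = c(NA_real_, unname(ci[idx, 1])),
    upr = c(NA_real_, unname(ci[idx, 2])),
    stringsAsFactors = FALSE)

  structure(
    list(f_statistic = an$F[2], df1 = as.integer(an$Df[2]),
         df2 = as.integer(an$Res.Df[2]),
         p_value = an$`Pr(>F)`[2], reference = reference,
         estimates = estimates, fit = full),
    class = "strain_effect_result")
}

#' @export
print.strain_effect_result <- function(x, ...) {
  cat(sprintf(
    "Strain effect on method agreement: F(%d, %d) = %.3f, p = %.4g (reference %s)\n",
    x$df1, x$df2, x$f_statistic, x$p_value, x$reference))
  invisible(x)
}

#' Broad-sense heritability from a one-way random-effects model
#'
#' Models a phenotype (here, the plate CI) with strain as a random
#' effect, `phenotype ~ 1 + (1|strain)`, and reports
#' \deqn{H^2 = \sigma^2_{strain} / (\sigma^2_{strain} + \sigma^2_{res}),}
#' the fraction of total phenotypic variance explained by strain. The
#' default `"anova"` backend is the method-of-moments one-way
#' random-effects estimator: `var_strain = (MSB - MSW) / n0` with
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`, which coincides with the
#' likelihood fit in expectation on balanced designs. The `"reml"`
#' backend fits the mixed model with `lme4::lmer`. Negative
#' method-of-moments strain components are truncated at 0 so that
#' `h2` stays in \[0, 1\].
#'
#' @param phenotypes `data.frame` with columns `strain` and `value` (or
#'   `phenotype`).
#' @param method `"anova"` (method of moments, default) or `"reml"`
#'   (requires lme4).
#' @return object of class `heritability_estimate`: `h2`, `var_strain`,
#'   `var_residual`, `n_strains`, `n_total`, `method`.
#' @export
broad_sense_heritability <- function(phenotypes,
                                     method = c("anova", "reml")) {
  method <- match.arg(method)
  if (!is.data.frame(phenotypes) || !"strain" %in% names(phenotypes))
    stop("`phenotypes` must be a data.frame with a `strain` column")
  vcol <- intersect(c("value", "phenotype"), names(phenotypes))[1]
  if (is.na(vcol)) stop("`phenotypes` needs a `value` (or `phenotype`) column")
  d <- data.frame(strain = as.character(phenotypes$strain),
                  value = as.numeric(phenotypes[[vcol]]))
  d <- d[stats::complete.cases(d), ]
  tab <- table(d$strain)
  if (length(tab) < 2L)
    stop("heritability is undefined for a single strain")
  if (any(tab < 2L))
    stop("every strain needs at least 2 replicates; too few for: ",
         paste(names(tab)[tab < 2L], collapse = ", "))

  if (method == "anova") {
    fit <- aov(value ~ strain, data = d)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    msb <- ms[1]; msw <- ms[2]
    N <- nrow(d); k <- length(tab)
    n0 <- (N - sum(tab^2) / N) / (k - 1)
    var_strain <- max(0, (msb - msw) / n0)
    var_res <- msw
  } else {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method = \"reml\" requires the lme4 package")
    fit <- lme4::lmer(value ~ 1 + (1 | strain), data = d)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_strain <- vc$vcov[vc$grp == "strain"]
    var_res <- vc$vcov[vc$grp == "Residual"]
  }
  total <- var_strain + var_res
  h2 <- if (total == 0) 0 else var_strain / total
  structure(
    list(h2 = h2, var_strain = var_strain, var_residual = var_res,
         n_strains = length(tab), n_total = nrow(d), method = method),
    class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf(
    "H^2 = %.3f  (var_strain = %.4g, var_residual = %.4g; %d strains, %d observations; %s estimator)\n",
    x$h2, x$var_strain, x$var_residual, x$n_strains, x$n_total, x$method))
  invisible(x)
}

# internal: validate the paired-CI record table
validate_agreement <- function(records, need_strain) {
  if (!is.data.frame(records))
    stop("`records` must be a data.frame")
  need <- c("manual_ci", "automated_ci", if (need_strain) "strain")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("manual_ci", "automated_ci")) {
    v <- records[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop("`", col, "` must be numeric with no missing values")
    if (any(v < -1 | v > 1))
      stop("`", col, "` contains values outside [-1, 1]")
  }
  if (need_strain && any(!nzchar(as.character(records$strain))))
    stop("`strain` contains empty identifiers")
  records
}
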