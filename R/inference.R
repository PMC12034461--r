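# Mixed-effects comparison of neuronal network participation.

#' Mixed-effects test of network participation by fate and group
#'
#' Fits a restricted-maximum-likelihood random-intercept model of
#' participation with neurons nested within animals (one random intercept
#' per animal) and reports Type III F tests of the fixed effects with the
#' configured denominator-df method (Satterthwaite by default). When the
#' random-intercept variance is singular the model is refit as a
#' fixed-effects-only linear model, with a message recording the downgrade.
#'
#' Participation is analysed untransformed on [0, 1]; records with missing
#' participation (zero detected events at that timepoint) are excluded
#' listwise.
#'
#' @param records data.frame with columns `participation`, `animal_id` and
#'   the fixed-effect columns.
#' @param fixed character vector of fixed-effect terms built from the
#'   record columns, e.g. `c("fate", "timepoint")` or `"fate * group"`.
#' @param dfMethod `"Satterthwaite"` (default) or `"Kenward-Roger"`.
#' @param forceFixedOnly fit the unclustered linear model regardless
#'   (equivalent to forcing the random-intercept variance to zero).
#' @return A list of class `"participationLme"`: `tests` (data.frame with
#'   `effect`, `F`, `df_num`, `df_den`, `p`), `fit` (the model object),
#'   `coefficients`, `method` (`"lmm"` or `"lm"`), `formula`.
#' @examples
#' rec <- simulateParticipationTable(nAnimalsPerGroup = 4L,
#'                                   neuronsRange = c(10L, 15L), seed = 1)
#' fitParticipationLme(rec, fixed = "fate")$tests
#' @export
fitParticipationLme <- function(records, fixed = c("fate", "group"),
                                dfMethod = c("Satterthwaite",
                                             "Kenward-Roger"),
                                forceFixedOnly = FALSE) {
  dfMethod <- match.arg(dfMethod)
  if (!"participation" %in% names(records) ||
      !"animal_id" %in% names(records))
    nq_stop("records need columns participation and animal_id")
  keep <- !is.na(records$participation)
  records <- records[keep, , drop = FALSE]
  if (any(records$participation < 0 | records$participation > 1))
    nq_stop("participation must lie in [0, 1]")
  if (length(unique(records$animal_id)) < 2L)
    nq_stop("at least 2 animals required")
  rhs <- paste(fixed, collapse = " + ")
  form_fix <- as.formula(paste("participation ~", rhs))
  form_lmm <- as.formula(paste("participation ~", rhs, "+ (1 | animal_id)"))

  fit_lm <- function() {
    fit <- lm(form_fix, data = records)
    a <- car::Anova(fit, type = 3)
    rows <- !rownames(a) %in% c("(Intercept)", "Residuals")
    tests <- data.frame(effect = rownames(a)[rows],
                        F = a[rows, "F value"],
                        df_num = a[rows, "Df"],
                        df_den = fit$df.residual,
                        p = a[rows, "Pr(>F)"],
                        stringsAsFactors = FALSE)
    list(tests = tests, fit = fit, coefficients = coef(fit), method = "lm",
         formula = form_fix)
  }

  out <- if (forceFixedOnly) {
    fit_lm()
  } else {
    fit <- lmerTest::lmer(form_lmm, data = records, REML = TRUE)
    if (lme4::isSingular(fit, tol = 1e-5)) {
      message("fitParticipationLme: singular random-intercept variance; ",
              "downgraded to a fixed-effects-only linear model")
      fit_lm()
    } else {
      a <- anova(fit, type = "III", ddf = dfMethod)
      tests <- data.frame(effect = rownames(a),
                          F = a[["F value"]],
                          df_num = a[["NumDF"]],
                          df_den = a[["DenDF"]],
                          p = a[["Pr(>F)"]],
                          stringsAsFactors = FALSE)
      list(tests = tests, fit = fit, coefficients = lme4::fixef(fit),
           method = "lmm", formula = form_lmm)
    }
  }
  rownames(out$tests) <- NULL
  out$df_method <- dfMethod
  class(out) <- "participationLme"
  out
}

#' @export
print.participationLme <- function(x, ...) {
  cat(sprintf("Participation mixed model (%s, %s df): %s\n", x$method,
              x$df_method, deparse(x$formula)))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Does baseline participation predict the day of death?
#'
#' Random-intercept regression of the observed death day on baseline
#' network participation, restricted to neurons with an observed death.
#' Reports the slope estimate, its Type III F test and a 95% Wald
#' confidence interval.
#'
#' @param records data.frame with columns `participation` (baseline),
#'   `death_day`, `animal_id`; only rows with an observed death are used
#'   (rows with `NA` death day are dropped).
#' @param minDeaths minimum number of observed deaths; below this the fit
#'   is refused with a diagnostic (default 3).
#' @return A list: `slope`, `ci95`, `F`, `df`, `p`, `fit`, `method`.
#' @examples
#' rec <- data.frame(participation = runif(30), death_day = sample(1:11, 30,
#'   replace = TRUE), animal_id = rep(c("a", "b", "c"), 10))
#' baselineVsDeathdayRegression(rec)$slope
#' @export
baselineVsDeathdayRegression <- function(records, minDeaths = 3L) {
  req <- c("participation", "death_day", "animal_id")
  if (!all(req %in% names(records)))
    nq_stop("records need columns %s", paste(req, collapse = ", "))
  records <- records[!is.na(records$death_day) &
                       !is.na(records$participation), , drop = FALSE]
  if (nrow(records) < minDeaths)
    nq_stop("only %d neurons with an observed death day (< %d); refusing to fit",
            nrow(records), minDeaths)
  fit <- suppressMessages(
    lmerTest::lmer(death_day ~ participation + (1 | animal_id),
                   data = records, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    fitl <- lm(death_day ~ participation, data = records)
    sm <- summary(fitl)
    slope <- coef(fitl)[["participation"]]
    se <- sm$coefficients["participation", "Std. Error"]
    Fv <- sm$coefficients["participation", "t value"]^2
    df <- c(1, fitl$df.residual)
    p <- sm$coefficients["participation", "Pr(>|t|)"]
    ci <- slope + c(-1, 1) * qnorm(0.975) * se
    return(list(slope = slope, ci95 = ci, F = Fv, df = df, p = p,
                fit = fitl, method = "lm"))
  }
  a <- anova(fit, type = "III", ddf = "Satterthwaite")
  slope <- lme4::fixef(fit)[["participation"]]
  se <- sqrt(vcov(fit)["participation", "participation"])
  list(slope = slope,
       ci95 = slope + c(-1, 1) * qnorm(0.975) * se,
       F = a["participation", "F value"],
       df = c(a["participation", "NumDF"], a["participation", "DenDF"]),
       p = a["participation", "Pr(>F)"],
       fit = fit, method = "lmm")
}
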