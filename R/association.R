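#' Classify general and abdominal obesity
#'
#' General adiposity: BMI >= 30 kg/m2 (inclusive). Central adiposity by waist
#' circumference: > 102 cm for men, > 88 cm for women (strict). Central
#' adiposity by waist-to-hip ratio: > 0.90 for men, > 0.85 for women
#' (strict).
#'
#' @param covariates data.frame with `sex` ("man"/"woman"), `bmi`, `waist`,
#'   `whr`.
#' @return data.frame: subject_id (if present), `general`, `central_wc`,
#'   `central_whr`, each 0/1.
#' @export
classify_obesity <- function(covariates) {
  need <- c("sex", "bmi", "waist", "whr")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols)) {
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sex <- covariates$sex
  bad <- setdiff(unique(sex), c("man", "woman"))
  if (length(bad)) stop("unknown sex code(s): ", paste(bad, collapse = ", "))
  man <- sex == "man"
  out <- data.frame(
    general = as.integer(covariates$bmi >= 30),
    central_wc = as.integer(ifelse(man, covariates$waist > 102,
                                   covariates$waist > 88)),
    central_whr = as.integer(ifelse(man, covariates$whr > 0.90,
                                    covariates$whr > 0.85)))
  if ("subject_id" %in% names(covariates)) {
    out <- cbind(data.frame(subject_id = covariates$subject_id,
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' Default adjustment covariate set
#'
#' Age, sex, occupation, smoking status, education, marital status,
#' menopausal status, physical activity and energy intake — the maximally
#' adjusted model used for tertile odds ratios.
#' @return character vector of covariate column names.
#' @export
default_adjustment <- function() {
  c("age", "sex", "occupation", "smoking", "education", "marital",
    "menopause", "physical_activity", "energy")
}

build_model_frame <- function(outcome, tertiles, covariates, adjusted,
                              covariate_set, trend = FALSE) {
  df <- data.frame(.y = outcome)
  if (trend) {
    df$.tert <- as.numeric(factor(tertiles, levels = c("T1", "T2", "T3")))
  } else {
    df$.tert <- factor(tertiles, levels = c("T1", "T2", "T3"))
  }
  if (adjusted) {
    missing_cols <- setdiff(covariate_set, names(covariates))
    if (length(missing_cols)) {
      stop("covariate table lacks adjustment column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    for (cv in covariate_set) {
      v <- covariates[[cv]]
      df[[cv]] <- if (is.character(v)) factor(v) else v
    }
  }
  df
}

# Returns the estimate/SE table. Aliased *covariate* terms (e.g. the
# structurally collinear menopause-for-men level when sex is also in the
# model) are dropped with a message; aliased exposure (tertile) terms are a
# hard error, as is separation.
check_glm_fit <- function(fit) {
  cf <- coef(fit)
  alias <- names(cf)[is.na(cf)]
  if (length(alias)) {
    if (any(startsWith(alias, ".tert"))) {
      stop("singular design: collinear column(s) ",
           paste(alias, collapse = ", "))
    }
    message("dropping aliased covariate term(s): ",
            paste(alias, collapse = ", "))
  }
  tab <- summary(fit)$coefficients
  if (any(!is.finite(tab[, "Estimate"])) ||
      any(!is.finite(tab[, "Std. Error"])) ||
      any(tab[, "Std. Error"] > 1e3)) {
    stop("logistic fit shows separation (non-finite or exploding ",
         "estimates); consider a penalized model or pooled categories")
  }
  tab
}

#' Tertile logistic regression for a binary obesity outcome
#'
#' Fits a maximum-likelihood logistic model with tertile indicators (T1 as
#' the reference), crude or adjusted for the configured covariate set.
#' Odds ratios are `exp(coef)` with Wald confidence intervals
#' `exp(coef +/- z * SE)`.
#'
#' @param outcome 0/1 vector (both classes present).
#' @param tertiles factor/character of T1/T2/T3 labels (each nonempty).
#' @param covariates covariate data.frame (needed when `adjusted = TRUE`).
#' @param adjusted include the adjustment covariates.
#' @param covariate_set columns to adjust for (default [default_adjustment()]).
#' @param alpha two-sided CI level parameter (default 0.05 for 95% CIs).
#' @param network,outcome_name optional labels carried into the result.
#' @return Object of class `association_result`: data.frame `estimates`
#'   (tertile, n, cases, or, ci_low, ci_high), `p_trend`, `model`
#'   ("crude"/"adjusted"), `covariates`, labels.
#' @export
fit_tertile_logistic <- function(outcome, tertiles, covariates = NULL,
                                 adjusted = FALSE,
                                 covariate_set = default_adjustment(),
                                 alpha = 0.05,
                                 network = NA_character_,
                                 outcome_name = NA_character_) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2) stop("outcome must have both classes")
  tert <- factor(tertiles, levels = c("T1", "T2", "T3"))
  if (any(table(tert) == 0)) stop("every tertile must be nonempty")
  df <- build_model_frame(outcome, tert, covariates, adjusted, covariate_set)
  fit <- glm(.y ~ ., data = df, family = binomial())
  tab <- check_glm_fit(fit)
  z <- qnorm(1 - alpha / 2)
  cf <- tab[, "Estimate"]; se <- tab[, "Std. Error"]
  rows <- lapply(c("T1", "T2", "T3"), function(tl) {
    n_t <- sum(tert == tl); cases <- sum(outcome[tert == tl])
    if (tl == "T1") {
      data.frame(tertile = tl, n = n_t, cases = cases, or = 1,
                 ci_low = NA_real_, ci_high = NA_real_)
    } else {
      nm <- paste0(".tert", tl)
      data.frame(tertile = tl, n = n_t, cases = cases,
                 or = exp(cf[[nm]]),
                 ci_low = exp(cf[[nm]] - z * se[[nm]]),
                 ci_high = exp(cf[[nm]] + z * se[[nm]]))
    }
  })
  est <- do.call(rbind, rows)
  p_tr <- p_for_trend(outcome, tert, covariates, adjusted, covariate_set)
  structure(
    list(estimates = est, p_trend = p_tr,
         model = if (adjusted) "adjusted" else "crude",
         covariates = if (adjusted) covariate_set else character(0),
         network = network, outcome = outcome_name, alpha = alpha),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Tertile logistic regression (", x$model, ")",
      if (!is.na(x$network)) paste0(" | network: ", x$network),
      if (!is.na(x$outcome)) paste0(" | outcome: ", x$outcome), "\n", sep = "")
  print(x$estimates, row.names = FALSE)
  cat("P for trend:", format.pval(x$p_trend, digits = 3), "\n")
  invisible(x)
}

#' Wald test for trend across tertiles
#'
#' Re-fits the logistic model with the ordinal tertile index (1, 2, 3)
#' entered as a single continuous covariate (or the per-tertile median score
#' when `coding = "median"` and `scores` are supplied) and returns the Wald
#' p-value of that term.
#'
#' @inheritParams fit_tertile_logistic
#' @param coding `"ordinal"` (default) or `"median"`.
#' @param scores raw network scores, required for median coding.
#' @return p-value.
#' @export
p_for_trend <- function(outcome, tertiles, covariates = NULL,
                        adjusted = FALSE,
                        covariate_set = default_adjustment(),
                        coding = c("ordinal", "median"), scores = NULL) {
  coding <- match.arg(coding)
  outcome <- as.integer(outcome)
  tert <- factor(tertiles, levels = c("T1", "T2", "T3"))
  df <- build_model_frame(outcome, tert, covariates, adjusted, covariate_set,
                          trend = TRUE)
  if (coding == "median") {
    if (is.null(scores)) stop("median coding needs the raw scores")
    med <- tapply(scores, tert, stats::median)
    df$.tert <- as.numeric(med[as.character(tert)])
  }
  fit <- glm(.y ~ ., data = df, family = binomial())
  tab <- check_glm_fit(fit)
  2 * pnorm(-abs(tab[".tert", "Estimate"] / tab[".tert", "Std. Error"]))
}

#' Descriptive statistics of covariates across tertiles
#'
#' Continuous variables: mean and SD per tertile with a one-way ANOVA
#' p-value. Categorical variables: percentage per tertile with a Pearson
#' chi-squared p-value (no continuity correction). Categoricals with a
#' single observed level are flagged and their test skipped.
#'
#' @param covariates covariate data.frame.
#' @param tertiles T1/T2/T3 labels.
#' @param variables columns to describe (default: all but subject_id).
#' @return data.frame: variable, level (for categoricals), T1/T2/T3 summary,
#'   test, p_value, flag.
#' @export
tertile_descriptives <- function(covariates, tertiles,
                                 variables = setdiff(names(covariates),
                                                     "subject_id")) {
  tert <- factor(tertiles, levels = c("T1", "T2", "T3"))
  if (any(table(tert) == 0)) stop("every tertile must be nonempty")
  rows <- list()
  for (v in variables) {
    x <- covariates[[v]]
    if (is.numeric(x)) {
      mns <- tapply(x, tert, mean); sds <- tapply(x, tert, sd)
      p <- summary(aov(x ~ tert))[[1]][["Pr(>F)"]][1]
      if (is.na(p)) p <- 1  # zero between-group variance
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_,
        T1 = sprintf("%.2f ± %.2f", mns[["T1"]], sds[["T1"]]),
        T2 = sprintf("%.2f ± %.2f", mns[["T2"]], sds[["T2"]]),
        T3 = sprintf("%.2f ± %.2f", mns[["T3"]], sds[["T3"]]),
        test = "anova", p_value = p, flag = "")
    } else {
      x <- factor(x)
      if (nlevels(droplevels(x)) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = levels(droplevels(x))[1],
          T1 = "100%", T2 = "100%", T3 = "100%",
          test = "chisq", p_value = NA_real_, flag = "single_level")
        next
      }
      tab <- table(x, tert)
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      pct <- prop.table(tab, margin = 2) * 100
      for (lv in rownames(tab)) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lv,
          T1 = sprintf("%.1f%%", pct[lv, "T1"]),
          T2 = sprintf("%.1f%%", pct[lv, "T2"]),
          T3 = sprintf("%.1f%%", pct[lv, "T3"]),
          test = "chisq", p_value = p, flag = "")
      }
    }
  }
  do.call(rbind, rows)
}

#' Sample size for estimating a prevalence
#'
#' `n = p (1 - p) z^2 / E^2`, with `z` the standard-normal `1 - alpha/2`
#' quantile and `E` the absolute error margin, optionally multiplied by a
#' design effect, rounded to the nearest integer. With an expected
#' overweight/obesity prevalence of 0.65, a margin of 0.04 and alpha 0.05
#' this gives 546 participants.
#'
#' @param p expected prevalence in `[0, 1]`.
#' @param E absolute error margin (> 0).
#' @param alpha significance level in `(0, 1)` (default 0.05).
#' @param design_effect optional multiplier (default 1).
#' @return required sample size (integer-valued numeric).
#' @export
compute_sample_size <- function(p, E, alpha = 0.05, design_effect = 1) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (E <= 0) stop("error margin E must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- qnorm(1 - alpha / 2)
  round(p * (1 - p) * z^2 / E^2 * design_effect)
}

#' Association table across networks and outcomes
#'
#' Runs crude and adjusted tertile logistic models for every network-outcome
#' pair and returns a flat table (one row per network, outcome, model and
#' tertile).
#'
#' @param score_table data.frame from [score_networks()] with
#'   `<network>_tertile` columns.
#' @param outcomes data.frame of 0/1 outcome columns (plus subject_id).
#' @param covariates covariate data.frame.
#' @param covariate_set adjustment set (default [default_adjustment()]).
#' @return data.frame with columns network, outcome, model, tertile, n,
#'   cases, or, ci_low, ci_high, p_trend.
#' @export
association_table <- function(score_table, outcomes, covariates,
                              covariate_set = default_adjustment()) {
  networks <- sub("_tertile$", "",
                  grep("_tertile$", names(score_table), value = TRUE))
  outcome_cols <- setdiff(names(outcomes), "subject_id")
  rows <- list()
  for (nw in networks) {
    tert <- score_table[[paste0(nw, "_tertile")]]
    for (oc in outcome_cols) {
      for (adj in c(FALSE, TRUE)) {
        res <- fit_tertile_logistic(outcomes[[oc]], tert, covariates,
                                    adjusted = adj,
                                    covariate_set = covariate_set,
                                    network = nw, outcome_name = oc)
        est <- res$estimates
        est$network <- nw; est$outcome <- oc; est$model <- res$model
        est$p_trend <- res$p_trend
        rows[[length(rows) + 1]] <-
          est[c("network", "outcome", "model", "tertile", "n", "cases",
                "or", "ci_low", "ci_high", "p_trend")]
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
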