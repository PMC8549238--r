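#' Planted conditional-dependence structure for a synthetic cohort
#'
#' Describes a block-structured precision matrix over food-group variables:
#' disjoint blocks of nodes (planted communities) share a common within-block
#' partial correlation, optional bridge pairs connect blocks into larger
#' networks, and all remaining pairs carry a background partial correlation
#' (zero by default, i.e. conditional independence).
#'
#' @param n_groups number of food-group variables.
#' @param blocks list of disjoint integer vectors (1-based node indices).
#' @param within_partial numeric vector, one signed partial correlation per
#'   block, each strictly inside (-1, 1).
#' @param bridges optional two-column matrix (or list of length-2 vectors) of
#'   node pairs joining blocks, with `bridge_partial` giving the partial
#'   correlation per bridge (recycled if scalar).
#' @param bridge_partial partial correlation value(s) for bridge pairs.
#' @param background_partial partial correlation for all remaining pairs
#'   (default 0).
#' @return An object of class `planted_structure`.
#' @export
planted_structure <- function(n_groups, blocks, within_partial,
                              bridges = NULL, bridge_partial = 0.15,
                              background_partial = 0) {
  stopifnot(n_groups >= 1)
  blocks <- lapply(blocks, as.integer)
  if (length(within_partial) == 1L) {
    within_partial <- rep(within_partial, length(blocks))
  }
  if (length(within_partial) != length(blocks)) {
    stop("need one within-block partial correlation per block")
  }
  all_nodes <- unlist(blocks)
  if (anyDuplicated(all_nodes)) stop("blocks must be disjoint")
  if (length(all_nodes) && (min(all_nodes) < 1L || max(all_nodes) > n_groups)) {
    stop("block node indices must lie in 1..n_groups")
  }
  if (any(abs(within_partial) >= 1) || abs(background_partial) >= 1) {
    stop("partial correlations must be strictly inside (-1, 1)")
  }
  if (!is.null(bridges)) {
    if (is.list(bridges)) bridges <- do.call(rbind, bridges)
    bridges <- matrix(as.integer(bridges), ncol = 2)
    if (length(bridge_partial) == 1L) {
      bridge_partial <- rep(bridge_partial, nrow(bridges))
    }
    if (length(bridge_partial) != nrow(bridges)) {
      stop("need one bridge partial per bridge pair")
    }
    if (any(abs(bridge_partial) >= 1)) {
      stop("partial correlations must be strictly inside (-1, 1)")
    }
  }
  structure(
    list(n_groups = as.integer(n_groups), blocks = blocks,
         within_partial = within_partial, bridges = bridges,
         bridge_partial = if (is.null(bridges)) numeric(0) else bridge_partial,
         background_partial = background_partial),
    class = "planted_structure")
}

#' Build a positive-definite precision matrix from a planted structure
#'
#' Sets unit diagonal and off-diagonal entries `omega_ij = -rho` for every
#' planted pair (so that with unit diagonal the implied partial correlation
#' equals `rho`), then adds diagonal loading in steps of `delta_step` until the
#' minimum eigenvalue reaches `min_eig`. Loading shrinks the achieved partial
#' correlations below the planted values, so the achieved matrix of partial
#' correlations is recomputed and returned alongside the precision matrix
#' rather than assumed equal to the request.
#'
#' @param structure a [planted_structure()].
#' @param min_eig minimum eigenvalue required after loading (default 0.05).
#' @param delta_step diagonal loading increment (default 0.05).
#' @param max_delta loading bound; structures still indefinite after this much
#'   loading are rejected as infeasible (default 10).
#' @return A list of class `planted_precision` with elements `omega` (the
#'   precision matrix), `achieved_partial` (matrix of implied partial
#'   correlations), `delta` (total diagonal loading applied) and `structure`.
#' @export
build_planted_precision <- function(structure, min_eig = 0.05,
                                    delta_step = 0.05, max_delta = 10) {
  stopifnot(inherits(structure, "planted_structure"))
  p <- structure$n_groups
  omega <- diag(p)
  for (b in seq_along(structure$blocks)) {
    nodes <- structure$blocks[[b]]
    rho <- structure$within_partial[b]
    for (i in nodes) for (j in nodes) if (i != j) omega[i, j] <- -rho
  }
  if (!is.null(structure$bridges)) {
    for (k in seq_len(nrow(structure$bridges))) {
      i <- structure$bridges[k, 1]; j <- structure$bridges[k, 2]
      omega[i, j] <- omega[j, i] <- -structure$bridge_partial[k]
    }
  }
  bg <- structure$background_partial
  if (bg != 0) {
    planted <- omega != 0 | diag(p) == 1
    omega[!planted] <- -bg
  }
  delta <- 0
  while (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) < min_eig) {
    delta <- delta + delta_step
    if (delta > max_delta) {
      stop("planted structure infeasible: not positive definite after ",
           "diagonal loading of ", max_delta)
    }
    diag(omega) <- diag(omega) + delta_step
  }
  # Cholesky as the definiteness certificate
  chol(omega)
  d <- sqrt(diag(omega))
  achieved <- -omega / outer(d, d)
  diag(achieved) <- 1
  structure(
    list(omega = omega, achieved_partial = achieved, delta = delta,
         structure = structure),
    class = "planted_precision")
}

#' Simulate a subjects-by-food-groups intake table
#'
#' Draws rows from the multivariate normal distribution whose covariance is the
#' inverse of the supplied precision matrix (the Gaussian graphical model the
#' downstream estimator assumes). Latent z-scores can be returned as-is
#' (`identity`) or mapped monotonically to non-negative gram-per-day intakes by
#' an exponential shift (`expshift`): `intake = median_gd * exp(0.4 * z)`, so
#' the marginal median sits near a typical intake.
#'
#' @param precision positive-definite precision matrix (or a
#'   `planted_precision`).
#' @param n_subjects number of rows to draw (>= 2).
#' @param marginal_transform `"identity"` or `"expshift"`.
#' @param seed integer seed; the same seed yields an identical table.
#' @param group_names optional column labels (default `group01`...).
#' @param median_gd typical intake in g/d used by the expshift transform.
#' @return A data.frame with `subject_id` then one column per food group.
#' @export
simulate_intake_table <- function(precision, n_subjects,
                                  marginal_transform = c("identity", "expshift"),
                                  seed = 1L, group_names = NULL,
                                  median_gd = 50) {
  if (inherits(precision, "planted_precision")) precision <- precision$omega
  marginal_transform <- match.arg(marginal_transform)
  stopifnot(n_subjects >= 2)
  p <- ncol(precision)
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix is not positive definite")
  sigma <- solve(precision)
  cl <- chol(sigma)
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n_subjects * p), n_subjects, p) %*% cl
  if (marginal_transform == "expshift") z <- median_gd * exp(0.4 * z)
  if (is.null(group_names)) group_names <- sprintf("group%02d", seq_len(p))
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n_subjects)), z,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("subject_id", group_names)
  out
}

#' Default covariate distributions for the synthetic cohort
#'
#' Marginal distributions emulating a community-based FFQ cohort of Tehranian
#' adults: mean age ~45 y, 69% women, 63% with low physical activity
#' (< 3000 MET-min/week), ~5% current smokers, ~81% married, mean energy
#' intake ~2586 kcal/d, mean BMI ~27.8 kg/m2. Anthropometry (BMI, waist
#' circumference, waist-to-hip ratio) is included so obesity outcomes can be
#' classified from measured values.
#'
#' @return A named list usable as `covariate_spec`.
#' @export
default_covariate_spec <- function() {
  list(
    age = list(mean = 44.7, sd = 10.8, min = 20, max = 59),
    sex = list(p_woman = 0.69),
    physical_activity = list(p_low = 0.63),
    smoking = list(p = c(never = 0.91, former = 0.038, current = 0.052)),
    marital = list(p_married = 0.809),
    education = list(p = c(educated = 0.343, diploma = 0.40, under_diploma = 0.257)),
    occupation = list(p = c(employed = 0.26, housekeeper = 0.50, retired = 0.12,
                            unemployed = 0.12)),
    energy = list(mean = 2586, sd = 1140, min = 500),
    menopause = list(p_post_in_women = 0.278),
    bmi = list(mean = 27.8, sd = 5.6, min = 15),
    waist = list(mean = 92.0, sd = 12.4, min = 55),
    whr = list(mean = 0.88, sd = 0.11, min = 0.6)
  )
}

rtrunc_norm <- function(n, mean, sd, min = -Inf, max = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < min | x > max)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < min | x[bad] > max]
  }
  x
}

#' Simulate a covariate/anthropometry table
#'
#' @param n_subjects number of subjects (0 gives an empty table with the full
#'   header).
#' @param covariate_spec distributions, as from [default_covariate_spec()];
#'   every field of that list must be present.
#' @param seed integer seed.
#' @return A data.frame with subject_id, age, sex, physical_activity, smoking,
#'   marital, education, occupation, energy, menopause, bmi, waist, whr.
#'   Menopause for men is the explicit level `"not_applicable"`, never missing.
#' @export
simulate_covariates <- function(n_subjects, covariate_spec = default_covariate_spec(),
                                seed = 1L) {
  required <- names(default_covariate_spec())
  missing_fields <- setdiff(required, names(covariate_spec))
  if (length(missing_fields)) {
    stop("covariate_spec is missing field(s): ",
         paste(missing_fields, collapse = ", "))
  }
  # tolerate YAML-roundtripped specs where named vectors became lists
  cs <- lapply(covariate_spec, function(f)
    lapply(f, function(x) if (is.list(x)) unlist(x) else x))
  empty <- data.frame(subject_id = character(0), age = numeric(0),
                      sex = character(0), physical_activity = character(0),
                      smoking = character(0), marital = character(0),
                      education = character(0), occupation = character(0),
                      energy = numeric(0), menopause = character(0),
                      bmi = numeric(0), waist = numeric(0), whr = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_subjects == 0) return(empty)
  set.seed(as.integer(seed))
  n <- n_subjects
  sample_p <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  sex <- ifelse(runif(n) < cs$sex$p_woman, "woman", "man")
  menopause <- ifelse(
    sex == "woman",
    ifelse(runif(n) < cs$menopause$p_post_in_women, "post", "pre"),
    "not_applicable")
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = rtrunc_norm(n, cs$age$mean, cs$age$sd, cs$age$min, cs$age$max),
    sex = sex,
    physical_activity = ifelse(runif(n) < cs$physical_activity$p_low,
                               "low", "moderate_high"),
    smoking = sample_p(cs$smoking$p),
    marital = ifelse(runif(n) < cs$marital$p_married, "married", "other"),
    education = sample_p(cs$education$p),
    occupation = sample_p(cs$occupation$p),
    energy = rtrunc_norm(n, cs$energy$mean, cs$energy$sd, cs$energy$min),
    menopause = menopause,
    bmi = rtrunc_norm(n, cs$bmi$mean, cs$bmi$sd, cs$bmi$min),
    waist = rtrunc_norm(n, cs$waist$mean, cs$waist$sd, cs$waist$min),
    whr = rtrunc_norm(n, cs$whr$mean, cs$whr$sd, cs$whr$min),
    stringsAsFactors = FALSE)
}

#' Simulate binary obesity outcomes from network-score tertiles
#'
#' For each configured outcome, draws Bernoulli responses with
#' `logit(p) = intercept + sum over networks of log-OR x tertile indicator`.
#' This is the generative inverse of the tertile logistic model the
#' association stage fits, so planted odds ratios are recoverable.
#'
#' @param score_table a network score table containing `<network>_tertile`
#'   columns (see [score_networks()]); scores must already be tertiled.
#' @param outcome_model named list: one entry per outcome, each a list with
#'   `intercept` (log-odds in tertile 1 of every network) and `effects`, a
#'   named list mapping network name to a vector `c(T2 = logOR, T3 = logOR)`.
#' @param seed integer seed.
#' @return data.frame with subject_id and one 0/1 column per outcome.
#' @export
simulate_outcomes <- function(score_table, outcome_model, seed = 1L) {
  tert_cols <- grep("_tertile$", names(score_table), value = TRUE)
  if (!length(tert_cols)) {
    stop("scores have not been tertiled yet: no *_tertile columns found")
  }
  set.seed(as.integer(seed))
  n <- nrow(score_table)
  out <- data.frame(subject_id = score_table$subject_id,
                    stringsAsFactors = FALSE)
  for (oc in names(outcome_model)) {
    om <- outcome_model[[oc]]
    eta <- rep(om$intercept, n)
    for (nw in names(om$effects)) {
      col <- paste0(nw, "_tertile")
      if (!col %in% names(score_table)) {
        stop("no tertile column for network '", nw, "'")
      }
      tert <- as.character(score_table[[col]])
      eff <- om$effects[[nw]]
      eta <- eta + ifelse(tert == "T2", eff[["T2"]],
                          ifelse(tert == "T3", eff[["T3"]], 0))
    }
    p <- 1 / (1 + exp(-eta))
    out[[oc]] <- rbinom(n, 1L, p)
  }
  out
}

#' Default planted structure: six communities forming three networks
#'
#' Thirty-five food groups, six planted communities (blocks) of sizes
#' 5, 8, 5, 6, 3 and 3, bridged pairwise so they assemble into three dietary
#' networks (30 food groups in total) while five background groups stay
#' conditionally independent. Block indices follow the packaged registry so
#' the planted networks read as a healthy network (cooked-vegetable and
#' fruit/raw-vegetable communities), an unhealthy network (processed-meat,
#' snack/high-fat-dairy and fruit-juice/canned-fruit communities) and a
#' saturated-fats network (butter, margarine, animal fat).
#'
#' @param within_partial within-block partial correlations, one per block.
#' @return A [planted_structure()].
#' @export
default_structure <- function(within_partial = c(0.20, 0.12, 0.20, 0.16, 0.25, 0.30)) {
  planted_structure(
    n_groups = 35,
    blocks = list(
      c(12L, 15L, 17L, 19L, 21L),            # cooked veg, mushroom, potato, grains, legumes
      c(5L, 7L, 8L, 11L, 13L, 14L, 16L, 20L),# fruit / raw veg / nuts / low-fat dairy
      c(2L, 4L, 27L, 32L, 35L),              # processed meat, fish, SSB, veg oils, coffee
      c(6L, 22L, 23L, 24L, 26L, 28L),        # high-fat dairy, snacks, cookies, chips, sauces
      c(9L, 10L, 18L),                       # canned fruit, fruit juices, side dish
      c(29L, 30L, 31L)),                     # butter, margarine, animal fat
    within_partial = within_partial,
    bridges = rbind(c(12L, 7L),   # joins the two healthy communities
                    c(2L, 6L),    # joins processed-meat and snack communities
                    c(24L, 9L)),  # joins the juice community into unhealthy
    bridge_partial = 0.20)
}
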