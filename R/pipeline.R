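#' Default pipeline configuration
#'
#' A configuration running the full pipeline on the default synthetic cohort:
#' 850 subjects, 35 food groups with six planted communities bridged into
#' three dietary networks, exponential-shift marginals, EBIC-selected
#' graphical-lasso penalty, unweighted link communities over all nonzero
#' edges, per-network PCA scoring, and crude + adjusted tertile odds ratios
#' for the three obesity outcomes.
#'
#' @param seed integer seed driving every random draw.
#' @param output_dir optional directory for artifacts (NULL: nothing written).
#' @return a config list for [run_pipeline()].
#' @export
default_config <- function(seed = 1L, output_dir = NULL) {
  list(
    synthetic = list(
      n_subjects = 850L,
      structure = default_structure(),
      marginal_transform = "expshift",
      outcome_model = list(
        general = list(intercept = -1.2, effects = list()),
        central_wc = list(
          intercept = -1.0,
          effects = list(network2 = c(T2 = log(1.35), T3 = log(1.4)))),
        central_whr = list(
          intercept = -0.8,
          effects = list(network3 = c(T2 = log(1.1), T3 = log(1.55))))),
      covariate_spec = default_covariate_spec()),
    input = NULL,                      # list(intake=, mapping=, covariates=)
    preprocess = list(log_transform = FALSE),
    ggm = list(lambda = NULL, gamma = 0.5, n_lambda = 30),
    communities = list(edges = "all", weighted = FALSE),
    scoring = list(),
    association = list(covariate_set = default_adjustment()),
    output_dir = output_dir,
    seed = as.integer(seed))
}

#' Write / read a pipeline configuration as YAML
#'
#' Serializes a config list (see [default_config()]) to a YAML file and back.
#' The planted structure is stored as plain fields (`n_groups`, `blocks`,
#' `within_partial`, `bridges`, `bridge_partial`, `background_partial`) and
#' revalidated through [planted_structure()] on read.
#'
#' @param config a config list.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   config list ready for [run_pipeline()].
#' @export
write_config <- function(config, path) {
  cfg <- config
  if (!is.null(cfg$synthetic$structure)) {
    st <- cfg$synthetic$structure
    cfg$synthetic$structure <- list(
      n_groups = st$n_groups,
      blocks = lapply(st$blocks, as.integer),
      within_partial = st$within_partial,
      bridges = if (is.null(st$bridges)) NULL else
        apply(st$bridges, 1, as.integer, simplify = FALSE),
      bridge_partial = st$bridge_partial,
      background_partial = st$background_partial)
  }
  if (!is.null(cfg$synthetic$outcome_model)) {
    cfg$synthetic$outcome_model <- lapply(cfg$synthetic$outcome_model,
      function(om) list(intercept = om$intercept,
                        effects = lapply(om$effects, as.list)))
  }
  if (!is.null(cfg$synthetic$covariate_spec)) {
    # yaml drops names from named atomic vectors; store them as maps
    cfg$synthetic$covariate_spec <- lapply(cfg$synthetic$covariate_spec,
      function(f) lapply(f, function(x) {
        if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
      }))
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic$structure)) {
    st <- cfg$synthetic$structure
    cfg$synthetic$structure <- planted_structure(
      n_groups = st$n_groups,
      blocks = st$blocks,
      within_partial = unlist(st$within_partial),
      bridges = if (is.null(st$bridges)) NULL else
        do.call(rbind, lapply(st$bridges, as.integer)),
      bridge_partial = if (is.null(st$bridges)) 0.15 else
        unlist(st$bridge_partial),
      background_partial = if (is.null(st$background_partial)) 0 else
        st$background_partial)
  }
  if (!is.null(cfg$synthetic$outcome_model)) {
    cfg$synthetic$outcome_model <- lapply(cfg$synthetic$outcome_model,
      function(om) list(intercept = om$intercept,
                        effects = lapply(om$effects, unlist)))
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

validate_config <- function(config) {
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp) {
    stop("config must have exactly one of 'synthetic' or 'input'")
  }
  if (!config$communities$edges %in% c("all", "strong")) {
    stop("communities$edges must be 'all' or 'strong'")
  }
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  slim <- config
  slim$output_dir <- NULL
  writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the dietary-network pipeline end to end
#'
#' Generates (or loads) the intake and covariate tables, standardizes
#' intakes, estimates the sparse precision matrix, converts it to a
#' partial-correlation network, detects link communities, assembles dietary
#' networks, scores subjects with tertiles, classifies or simulates obesity
#' outcomes, and fits crude and adjusted tertile odds ratios. When
#' `output_dir` is set, every intermediate artifact is written as CSV/JSON
#' plus a run manifest (seed, config hash, stage counts).
#'
#' @param config list, see [default_config()]. When loading real data,
#'   `config$input` holds paths `intake` (item- or group-level CSV),
#'   `mapping` (item,group CSV; NULL if already grouped) and `covariates`.
#' @return list of class `pipeline_result`: intake, covariates, standardized,
#'   correlation, penalty (selection or fixed), precision fit, network
#'   (`pcor_network`), communities, dietary networks (with loadings), scores,
#'   outcomes, associations (flat table), descriptives, manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  seed <- config$seed
  log_stage <- function(...) message("[dietggm] ", ...)

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    planted <- build_planted_precision(syn$structure)
    registry <- food_group_registry()
    gnames <- registry$group[seq_len(syn$structure$n_groups)]
    intake <- simulate_intake_table(planted, syn$n_subjects,
                                    syn$marginal_transform,
                                    seed = seed, group_names = gnames)
    covariates <- simulate_covariates(syn$n_subjects, syn$covariate_spec,
                                      seed = seed + 1L)
    log_stage("simulated ", syn$n_subjects, " subjects x ",
              length(gnames), " food groups")
  } else {
    intake <- read.csv(config$input$intake, check.names = FALSE,
                       stringsAsFactors = FALSE)
    if (!is.null(config$input$mapping)) {
      map <- read.csv(config$input$mapping, stringsAsFactors = FALSE)
      intake <- aggregate_to_groups(intake, map)
    }
    covariates <- read.csv(config$input$covariates, stringsAsFactors = FALSE)
    planted <- NULL
    log_stage("loaded ", nrow(intake), " subjects x ",
              ncol(intake) - 1, " food groups")
  }

  standardized <- standardize_intakes(intake,
                                      log_transform = isTRUE(config$preprocess$log_transform))
  S <- sample_correlation(standardized)

  if (is.null(config$ggm$lambda)) {
    sel <- select_penalty(standardized, gamma = config$ggm$gamma,
                          n_lambda = config$ggm$n_lambda)
    # report partial correlations from the support-restricted MLE so the
    # edge weights are not lasso-shrunk; the support is the selected one
    fit <- sel$refit
    log_stage("EBIC-selected lambda = ", format(sel$lambda, digits = 4))
  } else {
    sel <- NULL
    fit <- graphical_lasso(S, config$ggm$lambda)
  }
  network <- precision_to_partial(fit)
  log_stage(nrow(network$edges), " edges kept (",
            sum(network$edges$strong), " strong)")

  communities <- detect_link_communities(network,
                                         edges = config$communities$edges,
                                         weighted = isTRUE(config$communities$weighted))
  log_stage(length(communities$communities), " link communities, D = ",
            format(communities$partition_density, digits = 4))
  networks <- assemble_networks(communities)
  log_stage(length(networks), " dietary networks (>= 3 food groups)")

  scores <- NULL; outcomes <- NULL; associations <- NULL
  descriptives <- NULL
  if (length(networks)) {
    scored <- score_networks(standardized, networks)
    scores <- scored$scores
    networks <- scored$networks
    if (!is.null(config$synthetic) &&
        length(config$synthetic$outcome_model)) {
      om <- config$synthetic$outcome_model
      for (oc in names(om)) {
        known <- names(om[[oc]]$effects) %in% names(networks)
        if (!all(known)) {
          log_stage("outcome '", oc, "': dropping effect(s) for ",
                    "unassembled network(s) ",
                    paste(names(om[[oc]]$effects)[!known], collapse = ", "))
          om[[oc]]$effects <- om[[oc]]$effects[known]
        }
      }
      outcomes <- simulate_outcomes(scores, om, seed = seed + 2L)
    } else {
      outcomes <- classify_obesity(covariates)
    }
    associations <- association_table(scores, outcomes, covariates,
                                      config$association$covariate_set)
    first_tert <- scores[[grep("_tertile$", names(scores), value = TRUE)[1]]]
    descriptives <- tertile_descriptives(
      covariates, first_tert,
      variables = intersect(c("age", "sex", "bmi", "waist", "whr",
                              "physical_activity", "smoking", "marital",
                              "energy"), names(covariates)))
    log_stage("associations fitted for ", length(networks), " network(s) x ",
              ncol(outcomes) - 1, " outcome(s)")
  } else {
    warning("no dietary networks assembled; scoring and association skipped")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dietggm")),
    seed = seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_subjects = nrow(intake),
    n_groups = ncol(intake) - 1L,
    lambda = if (!is.null(sel)) sel$lambda else fit$lambda,
    n_edges = nrow(network$edges),
    n_strong_edges = sum(network$edges$strong),
    n_communities = length(communities$communities),
    partition_density = communities$partition_density,
    n_networks = length(networks),
    subjects_per_tertile = if (!is.null(scores)) {
      as.list(table(scores[[grep("_tertile$", names(scores))[1]]]))
    } else NULL)

  result <- structure(
    list(intake = intake, covariates = covariates,
         standardized = standardized, correlation = S,
         planted = planted, penalty = sel, fit = fit, network = network,
         communities = communities, networks = networks, scores = scores,
         outcomes = outcomes, associations = associations,
         descriptives = descriptives, manifest = manifest,
         config = config),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) write_pipeline_artifacts(result)
  result
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(result$intake, "intake.csv")
  wcsv(result$covariates, "covariates.csv")
  wcsv(result$standardized, "standardized.csv")
  write.csv(result$correlation, file.path(dir, "correlation.csv"))
  write.csv(result$network$rho, file.path(dir, "partial_correlations.csv"))
  write_edge_list(result$network, file.path(dir, "edges.csv"))
  if (!is.null(result$scores)) wcsv(result$scores, "network_scores.csv")
  if (!is.null(result$outcomes)) wcsv(result$outcomes, "outcomes.csv")
  if (!is.null(result$associations)) {
    wcsv(result$associations, "associations.csv")
    jsonlite::write_json(result$associations,
                         file.path(dir, "associations.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(result$descriptives)) wcsv(result$descriptives,
                                          "tertile_descriptives.csv")
  if (length(result$networks)) {
    export_network_graphml(result$networks, result$network,
                           file.path(dir, "networks.graphml"))
    loadings <- lapply(result$networks, function(nw)
      as.list(unclass(nw$loadings)))
    jsonlite::write_json(loadings, file.path(dir, "loadings.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("dietggm pipeline result\n",
      "  subjects: ", m$n_subjects, ", food groups: ", m$n_groups, "\n",
      "  lambda: ", format(m$lambda, digits = 4),
      ", edges: ", m$n_edges, " (", m$n_strong_edges, " strong)\n",
      "  communities: ", m$n_communities,
      " (D = ", format(m$partition_density, digits = 4), ")",
      ", dietary networks: ", m$n_networks, "\n", sep = "")
  invisible(x)
}

#' Export dietary networks as GraphML
#'
#' Writes one GraphML file containing every assembled network, with node
#' attributes (food group, network name, community ids, centrality, PCA
#' loading) and edge attributes (partial correlation, sign, strong flag,
#' width proportional to `|rho|`). Node ordering is deterministic
#' (alphabetical within network size rank).
#'
#' @param networks a `dietary_network_set`.
#' @param partials the `pcor_network` the networks came from.
#' @param file output path.
#' @return the igraph object, invisibly.
#' @export
export_network_graphml <- function(networks, partials, file) {
  if (!length(networks)) {
    warning("empty network list: writing an empty graph")
    g <- igraph::make_empty_graph(directed = FALSE)
    igraph::write_graph(g, file, format = "graphml")
    return(invisible(g))
  }
  nodes <- list(); edges <- list()
  for (nw in networks) {
    ord <- order(nw$nodes)
    nodes[[length(nodes) + 1]] <- data.frame(
      name = nw$nodes[ord],
      network = nw$name,
      communities = vapply(nw$nodes[ord], function(v) {
        paste(nw$node_communities[[v]], collapse = ";")
      }, character(1)),
      centrality = as.integer(nw$centrality[nw$nodes[ord]]),
      central = nw$nodes[ord] == nw$central,
      loading = if (!is.null(nw$loadings)) {
        as.numeric(nw$loadings[nw$nodes[ord]])
      } else NA_real_,
      stringsAsFactors = FALSE)
    ed <- nw$edges
    edges[[length(edges) + 1]] <- data.frame(
      from = partials$nodes[ed$i], to = partials$nodes[ed$j],
      weight = ed$partial_correlation,
      sign = ed$sign,
      style = ifelse(ed$sign == "positive", "solid", "dashed"),
      strong = ed$strong,
      width = abs(ed$partial_correlation),
      stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, nodes)
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, file, format = "graphml")
  invisible(g)
}
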