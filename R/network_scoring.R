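#' First-principal-component factor loadings for a dietary network
#'
#' Loadings are the leading eigenvector of the correlation matrix of the
#' network's standardized intake columns, scaled by the square root of its
#' eigenvalue (the factor-loading convention). The eigenvector sign is fixed
#' so the central food's loading is non-negative, which keeps scores
#' orientation-stable across runs.
#'
#' @param standardized data.frame from [standardize_intakes()].
#' @param network a `dietary_network` (or a list with `nodes` and `central`).
#' @param min_nodes minimum network size (default 3; lower only for testing).
#' @return Named numeric vector of loadings (class `loading_vector`, with the
#'   network name and explained-variance share as attributes).
#' @export
pca_loadings <- function(standardized, network, min_nodes = 3) {
  nodes <- network$nodes
  if (length(nodes) < min_nodes) {
    stop("network has fewer than ", min_nodes, " food groups")
  }
  missing_cols <- setdiff(nodes, names(standardized))
  if (length(missing_cols)) {
    stop("standardized table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(standardized) <= length(nodes)) {
    stop("need more subjects than network food groups")
  }
  R <- cor(as.matrix(standardized[nodes]))
  eg <- eigen(R, symmetric = TRUE)
  if (length(nodes) > 1 && abs(eg$values[1] - eg$values[2]) <= 1e-8) {
    stop("degenerate loadings: leading eigenvalue is (near-)tied; the ",
         "network's intake columns have no dominant principal component")
  }
  v <- eg$vectors[, 1]
  loadings <- v * sqrt(eg$values[1])
  names(loadings) <- nodes
  central <- network$central
  if (!is.null(central) && loadings[[central]] < 0) loadings <- -loadings
  structure(loadings, class = "loading_vector",
            network = network$name,
            explained = eg$values[1] / length(nodes))
}

#' Per-subject network score
#'
#' `score_s = sum_j loading_j * z_sj` over the network's food groups: each
#' standardized intake multiplied by its (signed) factor loading, then summed.
#'
#' @param standardized data.frame from [standardize_intakes()].
#' @param loadings named loading vector from [pca_loadings()].
#' @return numeric vector of scores, one per subject.
#' @export
network_score <- function(standardized, loadings) {
  cols <- names(loadings)
  missing_cols <- setdiff(cols, names(standardized))
  if (length(missing_cols)) {
    stop("no standardized intake for: ", paste(missing_cols, collapse = ", "))
  }
  as.vector(as.matrix(standardized[cols]) %*% as.numeric(loadings))
}

#' Assign rank-based tertiles
#'
#' Subjects are sorted by score (stable: ties keep input order, and the
#' earlier subject goes to the lower tertile). Group sizes differ by at most
#' one, with any remainder assigned to the lower tertiles; T1 holds the
#' lowest scores.
#'
#' @param scores numeric vector (length >= 3, not all equal).
#' @return factor with levels T1, T2, T3 in input order.
#' @export
assign_tertiles <- function(scores) {
  n <- length(scores)
  if (n < 3) stop("need at least 3 subjects for tertiles")
  if (diff(range(scores)) == 0) stop("all scores identical: tertiles undefined")
  base <- n %/% 3
  rem <- n %% 3
  sizes <- base + c(rem >= 1, rem >= 2, 0)
  ord <- order(scores)  # stable for ties (radix)
  lab <- rep(c("T1", "T2", "T3"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = c("T1", "T2", "T3"))
}

#' Score subjects on every dietary network
#'
#' Computes PCA loadings, scores and tertiles per network and stores the
#' loadings back on the returned network set.
#'
#' @param standardized data.frame from [standardize_intakes()].
#' @param networks a `dietary_network_set`.
#' @return list with `scores` (data.frame: subject_id, `<network>_score`,
#'   `<network>_tertile`, ...) and `networks` (the input set with `loadings`
#'   filled in).
#' @export
score_networks <- function(standardized, networks) {
  out <- data.frame(subject_id = standardized$subject_id,
                    stringsAsFactors = FALSE)
  for (nw in names(networks)) {
    ld <- pca_loadings(standardized, networks[[nw]])
    networks[[nw]]$loadings <- ld
    sc <- network_score(standardized, ld)
    out[[paste0(nw, "_score")]] <- sc
    out[[paste0(nw, "_tertile")]] <- assign_tertiles(sc)
  }
  list(scores = out, networks = networks)
}
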