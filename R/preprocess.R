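#' The packaged 35-food-group registry
#'
#' Returns the default registry of food-group labels over which dietary
#' networks are estimated (meat, dairy, fruit, vegetable, grain, snack, fat
#' and beverage groups; whole grains are intentionally absent). Users can
#' extend or replace it when their FFQ uses a different grouping.
#'
#' @return data.frame with columns `index` and `group`.
#' @export
food_group_registry <- function() {
  read.csv(system.file("extdata", "food_groups.csv", package = "dietggm"),
           stringsAsFactors = FALSE)
}

#' Aggregate item-level intakes to food groups
#'
#' Sums gram-per-day intakes of member items within each food group. Output
#' columns follow registry order for groups present in the registry, then any
#' user-defined groups in first-appearance order; groups with no mapped item
#' are simply absent.
#'
#' @param items data.frame: `subject_id` plus one numeric g/d column per item.
#' @param map data.frame with columns `item` and `group`; every item column of
#'   `items` must appear.
#' @param registry group registry used for ordering; defaults to the packaged
#'   35-group registry.
#' @return data.frame: `subject_id` plus one column per food group (g/d).
#' @export
aggregate_to_groups <- function(items, map, registry = food_group_registry()) {
  stopifnot(is.data.frame(items), "subject_id" %in% names(items))
  if (anyDuplicated(items$subject_id)) {
    stop("duplicate subject_id values: ",
         paste(unique(items$subject_id[duplicated(items$subject_id)]),
               collapse = ", "))
  }
  item_cols <- setdiff(names(items), "subject_id")
  unmapped <- setdiff(item_cols, map$item)
  if (length(unmapped)) {
    stop("unmapped item column(s): ", paste(unmapped, collapse = ", "))
  }
  grp <- setNames(map$group, map$item)[item_cols]
  groups_present <- unique(grp)
  ordered_groups <- c(intersect(registry$group, groups_present),
                      setdiff(groups_present, registry$group))
  x <- as.matrix(items[item_cols])
  if (any(x < 0, na.rm = TRUE)) stop("negative intakes are not allowed")
  out <- vapply(ordered_groups,
                function(g) rowSums(x[, grp == g, drop = FALSE]),
                numeric(nrow(items)))
  out <- as.data.frame(out, optional = TRUE)
  names(out) <- ordered_groups
  cbind(data.frame(subject_id = items$subject_id, stringsAsFactors = FALSE), out)
}

#' Standardize food-group intakes to z-scores
#'
#' Column-wise `(x - mean) / sd` with the sample standard deviation (n - 1
#' denominator). An optional `log1p`-style transform (`log(x + 1)` on the g/d
#' scale) can be applied first for heavily skewed intakes; it is off by
#' default.
#'
#' @param grouped data.frame: `subject_id` plus numeric food-group columns.
#' @param log_transform apply `log(x + 1)` before standardizing.
#' @param na_action `"error"` (default) or `"drop_subjects"` (complete-case,
#'   logged via message).
#' @return data.frame of the same shape with z-score columns.
#' @export
standardize_intakes <- function(grouped, log_transform = FALSE,
                                na_action = c("error", "drop_subjects")) {
  na_action <- match.arg(na_action)
  stopifnot("subject_id" %in% names(grouped))
  cols <- setdiff(names(grouped), "subject_id")
  x <- as.matrix(grouped[cols])
  if (anyNA(x)) {
    if (na_action == "error") stop("missing intake values present")
    keep <- stats::complete.cases(x)
    message("dropping ", sum(!keep), " subject(s) with missing intakes")
    grouped <- grouped[keep, , drop = FALSE]
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need at least 2 subjects")
  if (log_transform) x <- log(x + 1)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant food-group column(s): ",
         paste(cols[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  out <- as.data.frame(z, optional = TRUE)
  names(out) <- cols
  cbind(data.frame(subject_id = grouped$subject_id, stringsAsFactors = FALSE),
        out)
}
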