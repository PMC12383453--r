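#' Spearman correlation matrix of a feature table
#'
#' Rank-based correlations (average ranks on ties) between all feature
#' columns, used to diagnose multicollinearity before model training.
#'
#' @param table data.frame containing the feature columns (e.g. from
#'   [extract_features()]).
#' @param features character vector of feature columns; defaults to the 18
#'   canonical metrics present in `table`.
#' @return symmetric correlation matrix with unit diagonal, class
#'   `correlation_matrix`.
#' @export
spearman_matrix <- function(table, features = intersect(feature_names(),
                                                        names(table))) {
  x <- as.matrix(table[, features, drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 rows for correlations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature column(s): ",
         paste(features[sds == 0], collapse = ", "))
  r <- stats::cor(x, method = "spearman")
  class(r) <- c("correlation_matrix", class(r))
  r
}

#' Cluster features by Ward linkage on 1 - |r_s|
#'
#' Agglomerative clustering of features using the distance `1 - |r_s|`
#' (absolute Spearman correlation) and Ward's linkage, with flat clusters
#' cut at a linkage-height threshold. With the default stringent threshold
#' of 0.1, features with `|r_s| >= 0.9` merge (two singletons merge at a
#' height equal to their distance). Note that Ward linkage on a
#' non-Euclidean precomputed distance matrix is a heuristic use of the Ward
#' update rule; it is applied here as standard Ward-on-distances
#' agglomeration (see the methods vignette).
#'
#' @param corr a [spearman_matrix()].
#' @param threshold dendrogram cut height.
#' @return object of class `feature_clusters`: list with `membership`
#'   (named integer), `tree` (the `hclust`), `threshold`.
#' @export
ward_clusters <- function(corr, threshold = 0.1) {
  d <- stats::as.dist(1 - abs(unclass(corr)))
  tree <- stats::hclust(d, method = "ward.D2")
  membership <- stats::cutree(tree, h = threshold)
  structure(list(membership = membership, tree = tree,
                 threshold = threshold),
            class = "feature_clusters")
}

#' Pick one representative feature per cluster
#'
#' The default `"medoid"` rule keeps, per cluster, the feature with the
#' largest mean `|r_s|` to the other members (ties broken by the order of
#' `priority`). The `"preset"` rule returns the fixed published selection of
#' fifteen features, dropping `Q1 MLCGap`, `SAS10` and `MCS` from the
#' eighteen (the choice within each correlated pair is not recoverable from
#' the medoid rule alone).
#'
#' @param clusters a [ward_clusters()] result.
#' @param corr the matching [spearman_matrix()].
#' @param rule `"medoid"` or `"preset"`.
#' @param priority character vector used for tie-breaking; defaults to
#'   [feature_names()] order.
#' @return character vector of selected feature names.
#' @export
select_representatives <- function(clusters, corr,
                                   rule = c("medoid", "preset"),
                                   priority = feature_names()) {
  rule <- match.arg(rule)
  feats <- names(clusters$membership)
  if (rule == "preset") {
    sel <- setdiff(feature_names(), c("Q1 MLCGap", "SAS10", "MCS"))
    return(intersect(feats, sel))
  }
  r <- abs(unclass(corr))
  ord <- order(match(feats, priority, nomatch = length(priority) + 1L))
  reps <- character(0)
  for (cl in unique(clusters$membership)) {
    members <- feats[clusters$membership == cl]
    if (length(members) == 1) { reps <- c(reps, members); next }
    score <- vapply(members, function(f)
      mean(r[f, setdiff(members, f)]), 0)
    members_by_priority <- members[order(match(members, feats[ord]))]
    score <- score[members_by_priority]
    reps <- c(reps, members_by_priority[which.max(score)])
  }
  feats[feats %in% reps]
}
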