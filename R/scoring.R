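# Corpus-level aggregation: per-query total scores over the best-matching
# fraction of references, per-reference contribution scores, and
# group-specificity scores adjusted by the global geometric mean.

#' Total distance score for one query document
#'
#' A query's total reference distance is the arithmetic mean of its
#' `k = ceiling(fraction * n_references)` smallest document distances
#' (minimum 1), reflecting that only a minority of references (guidelines)
#' are applicable to any one query (assessment report). The default fraction
#' of 5% is the operating point used for both matching methods.
#'
#' @param query_id Query document identifier.
#' @param distances Named numeric vector: reference_id -> distance.
#' @param fraction Fraction of best-matching references to average over, in
#'   `(0, 1]`.
#' @param method Optional method label carried through to the output.
#' @return One-row data.frame: `query_id`, `method`, `fraction`, `k`,
#'   `total_distance`, plus a list column `contributing_reference_ids`
#'   holding the `k` contributing references in ascending-distance order
#'   (ties broken by reference id).
#' @export
score_query <- function(query_id, distances, fraction = 0.05, method = NA_character_) {
  if (length(distances) == 0L) stopf("score_query('%s'): empty distance map", query_id)
  if (is.null(names(distances)) || any(!nzchar(names(distances)))) {
    stopf("score_query('%s'): distances must be named by reference_id", query_id)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    stopf("score_query('%s'): fraction must be in (0, 1]", query_id)
  }
  k <- max(1L, as.integer(ceiling(fraction * length(distances))))
  ord <- order(distances, names(distances))
  sel <- ord[seq_len(k)]
  out <- data.frame(query_id = query_id, method = method, fraction = fraction,
                    k = k, total_distance = mean(distances[sel]),
                    stringsAsFactors = FALSE)
  out$contributing_reference_ids <- I(list(names(distances)[sel]))
  out
}

check_complete_grid <- function(pair_distances) {
  qs <- sort(unique(pair_distances$query_id))
  rs <- sort(unique(pair_distances$reference_id))
  key <- paste(pair_distances$query_id, pair_distances$reference_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    stopf("duplicate pair in distance grid: (%s, %s)", dup[1], dup[2])
  }
  want <- as.vector(outer(qs, rs, paste, sep = "\r"))
  missing <- setdiff(want, key)
  if (length(missing)) {
    shown <- vapply(utils::head(missing, 5L), function(k) {
      paste0("(", sub("\r", ", ", k, fixed = TRUE), ")")
    }, character(1))
    stopf("incomplete distance grid: missing %d pair(s), e.g. %s",
          length(missing), paste(shown, collapse = " "))
  }
  list(queries = qs, references = rs)
}

#' Score every query against the reference corpus
#'
#' @param pair_distances Data.frame of pair distances (one method/aggregator;
#'   a complete query x reference grid).
#' @param fraction Best-matching fraction, as in [score_query()].
#' @return Data.frame of per-query scores, ordered by `query_id`.
#' @export
score_all_queries <- function(pair_distances, fraction = 0.05) {
  meth <- unique(paste(pair_distances$method, pair_distances$aggregator))
  if (length(meth) != 1L) {
    stopf("score_all_queries: pair_distances mixes methods/aggregators (%s)",
          paste(meth, collapse = "; "))
  }
  grid <- check_complete_grid(pair_distances)
  out <- do.call(rbind, lapply(grid$queries, function(q) {
    rows <- pair_distances[pair_distances$query_id == q, ]
    d <- stats::setNames(rows$distance, rows$reference_id)
    score_query(q, d, fraction = fraction, method = rows$method[1])
  }))
  rownames(out) <- NULL
  out
}

#' Per-reference contribution scores
#'
#' Ranks references (guidelines) by how close they are to the query corpus:
#' for each reference, collect its distances to every query in whose
#' contributing set it appears and average them. References that never
#' contribute get a missing score and sort last. Setting `mode = "all"`
#' averages over all queries instead, ignoring the contributing cut.
#'
#' @param query_scores Data.frame from [score_all_queries()].
#' @param pair_distances The pair-distance grid the scores were computed from.
#' @param mode `"contributing"` (default) or `"all"`.
#' @return Data.frame `reference_id`, `n_contributions`, `mean_distance`,
#'   sorted ascending by `mean_distance` with missings last.
#' @export
reference_contribution_scores <- function(query_scores, pair_distances,
                                          mode = c("contributing", "all")) {
  mode <- match.arg(mode)
  if (length(unique(query_scores$fraction)) > 1L ||
      length(unique(query_scores$method)) > 1L) {
    stopf("reference_contribution_scores: query_scores mixes methods or fractions")
  }
  grid <- check_complete_grid(pair_distances)
  dist_of <- stats::setNames(
    pair_distances$distance,
    paste(pair_distances$query_id, pair_distances$reference_id, sep = "\r"))
  contrib <- stats::setNames(rep(0L, length(grid$references)), grid$references)
  sums <- stats::setNames(rep(0, length(grid$references)), grid$references)
  for (i in seq_len(nrow(query_scores))) {
    q <- query_scores$query_id[i]
    refs <- query_scores$contributing_reference_ids[[i]]
    contrib[refs] <- contrib[refs] + 1L
    sums[refs] <- sums[refs] + dist_of[paste(q, refs, sep = "\r")]
  }
  if (mode == "contributing") {
    mean_d <- ifelse(contrib > 0L, sums / pmax(contrib, 1L), NA_real_)
  } else {
    mean_d <- vapply(grid$references, function(r) {
      mean(dist_of[paste(grid$queries, r, sep = "\r")])
    }, numeric(1))
  }
  out <- data.frame(reference_id = grid$references,
                    n_contributions = as.integer(contrib),
                    mean_distance = as.numeric(mean_d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_distance, out$reference_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Group-specificity scores
#'
#' Measures how specifically a reference matches a group of queries (for
#' example, all products in one therapeutic-area category): for each
#' (reference, group), the difference between the geometric mean of the
#' reference's distances to all queries and the geometric mean over the
#' group's queries. A positive difference means the reference is closer to
#' the group than it is globally, i.e. semantically specific to it. Zero
#' distances are floored at `1e-12` before taking logs. All queries enter
#' both means, independent of any best-fraction cut.
#'
#' @param pair_distances Complete pair-distance grid (one method).
#' @param groups Named character vector `query_id -> group_label`, or a
#'   data.frame with columns `query_id` and `group_label`. Queries may be
#'   left out of all groups; each belongs to at most one.
#' @return Data.frame `group_label`, `reference_id`, `global_geo_mean`,
#'   `group_geo_mean`, `difference`, sorted within group by descending
#'   difference.
#' @export
group_specificity <- function(pair_distances, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group_label),
                              as.character(groups$query_id))
  }
  if (anyDuplicated(names(groups))) {
    stopf("group_specificity: query '%s' assigned to more than one group",
          names(groups)[duplicated(names(groups))][1])
  }
  grid <- check_complete_grid(pair_distances)
  unknown <- setdiff(names(groups), grid$queries)
  if (length(unknown)) {
    stopf("group_specificity: grouped query '%s' absent from the distance grid",
          unknown[1])
  }
  dist_of <- stats::setNames(
    pair_distances$distance,
    paste(pair_distances$query_id, pair_distances$reference_id, sep = "\r"))
  labels <- unique(unname(groups))
  out <- do.call(rbind, lapply(labels, function(g) {
    members <- names(groups)[groups == g]
    if (length(members) == 0L) stopf("group_specificity: group '%s' has no queries", g)
    rows <- do.call(rbind, lapply(grid$references, function(r) {
      all_d <- dist_of[paste(grid$queries, r, sep = "\r")]
      grp_d <- dist_of[paste(members, r, sep = "\r")]
      data.frame(group_label = g, reference_id = r,
                 global_geo_mean = geometric_mean(all_d),
                 group_geo_mean = geometric_mean(grp_d),
                 stringsAsFactors = FALSE)
    }))
    rows$difference <- rows$global_geo_mean - rows$group_geo_mean
    rows[order(-rows$difference, rows$reference_id), ]
  }))
  rownames(out) <- NULL
  out
}
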