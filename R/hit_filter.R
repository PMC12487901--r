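#' Threshold policies for defense/antidefense structure-search hits
#'
#' Builds a named filter policy. The two bundled presets reproduce the
#' thresholds used when screening viral structure catalogues against
#' defense and antidefense model libraries:
#'
#' * `"defensefinder"` — TM-score > 0.65, E-value < 1e-3, average alignment
#'   coverage > 0.6, cluster average TM-score > 0.5.
#' * `"antidefense"` — TM-score > 0.65, E-value < 1e-3 (applied per hit
#'   only when the hit's source provides E-values; see `evalue_sources`),
#'   average alignment coverage > 0.5, cluster average TM-score > 0.5,
#'   intracluster alignment length > 100.
#'
#' All bounds are strict inequalities.
#'
#' @param name `"defensefinder"`, `"antidefense"`, or `"custom"`.
#' @param tm_min,evalue_max,avg_cov_min,cluster_tm_min,intracluster_alnlen_min
#'   Policy bounds; `NA` disables a bound. Only used with `name = "custom"`.
#' @param evalue_sources For hit tables carrying a `source` column: the
#'   sources to which the E-value bound applies (`NULL` = all). The
#'   antidefense preset exempts `"dbapis"`, whose models carry no E-values.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(name = c("defensefinder", "antidefense", "custom"),
                          tm_min = NA, evalue_max = NA, avg_cov_min = NA,
                          cluster_tm_min = NA,
                          intracluster_alnlen_min = NA,
                          evalue_sources = NULL) {
  name <- match.arg(name)
  pol <- switch(name,
    defensefinder = list(tm_min = 0.65, evalue_max = 1e-3,
                         avg_cov_min = 0.6, cluster_tm_min = 0.5,
                         intracluster_alnlen_min = NA_real_,
                         evalue_sources = NULL),
    antidefense = list(tm_min = 0.65, evalue_max = 1e-3,
                       avg_cov_min = 0.5, cluster_tm_min = 0.5,
                       intracluster_alnlen_min = 100,
                       evalue_sources = "antidefensefinder"),
    custom = list(tm_min = tm_min, evalue_max = evalue_max,
                  avg_cov_min = avg_cov_min,
                  cluster_tm_min = cluster_tm_min,
                  intracluster_alnlen_min = intracluster_alnlen_min,
                  evalue_sources = evalue_sources))
  structure(c(list(name = name), pol), class = "filter_policy")
}

#' Read named filter policies from a YAML file
#'
#' The file maps policy names to blocks of bounds
#' (`tm_min`, `evalue_max`, `avg_cov_min`, `cluster_tm_min`,
#' `intracluster_alnlen_min`, `evalue_sources`); missing bounds are
#' disabled.
#'
#' @param path Path to a YAML file.
#' @return A named list of `filter_policy` objects.
#' @export
read_policies <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(p, nm) {
    pol <- filter_policy("custom",
                         tm_min = p$tm_min %||% NA,
                         evalue_max = p$evalue_max %||% NA,
                         avg_cov_min = p$avg_cov_min %||% NA,
                         cluster_tm_min = p$cluster_tm_min %||% NA,
                         intracluster_alnlen_min =
                           p$intracluster_alnlen_min %||% NA,
                         evalue_sources = p$evalue_sources)
    pol$name <- nm
    pol
  })
}

#' Keep the best hit per query
#'
#' For every query, keeps the hit maximizing identity fraction times query
#' coverage. Ties are broken by the higher TM-score, then by the
#' lexicographically smaller target id, so the result is deterministic.
#'
#' @param hits Hit tibble with columns `query`, `target`, `fident`, `qcov`
#'   and (for tie-breaking) `alntmscore`.
#' @return One row per query with an added `best_score` column
#'   (`fident * qcov`).
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(dplyr::mutate(hits, best_score = numeric(0)))
  tm <- if ("alntmscore" %in% names(hits)) hits$alntmscore else 0
  scored <- dplyr::mutate(hits, best_score = .data$fident * .data$qcov,
                          .tm_tie = tm)
  scored <- dplyr::arrange(scored, .data$query,
                           dplyr::desc(.data$best_score),
                           dplyr::desc(.data$.tm_tie), .data$target)
  out <- dplyr::slice_head(dplyr::group_by(scored, .data$query), n = 1)
  dplyr::select(dplyr::ungroup(out), -".tm_tie")
}

#' Per-cluster hit statistics against each target
#'
#' For every (structural cluster of the query, target) combination,
#' computes the mean TM-score and mean alignment length over all hits from
#' members of that cluster to that target. These feed the cluster-level
#' criteria of [apply_policy()].
#'
#' @param hits Hit tibble with `query`, `target`, `alntmscore`, `alnlen`.
#' @param members Membership tibble (`cluster_id`, `protein_id`); queries
#'   without a cluster are treated as singleton clusters of themselves.
#' @return A tibble with `cluster_id`, `target`, `cluster_mean_tm`,
#'   `cluster_mean_alnlen`, `n_hits`.
#' @export
cluster_hit_stats <- function(hits, members = NULL) {
  cl <- query_cluster(hits$query, members)
  stats <- dplyr::summarise(
    dplyr::group_by(tibble(cluster_id = cl, target = hits$target,
                           alntmscore = hits$alntmscore,
                           alnlen = hits$alnlen),
                    .data$cluster_id, .data$target),
    cluster_mean_tm = mean(.data$alntmscore),
    cluster_mean_alnlen = mean(.data$alnlen),
    n_hits = dplyr::n(), .groups = "drop")
  stats
}

query_cluster <- function(query, members) {
  if (is.null(members)) return(query)
  lookup <- setNames(members$cluster_id, members$protein_id)
  out <- unname(lookup[query])
  out[is.na(out)] <- query[is.na(out)]
  out
}

#' Filter hits under a threshold policy
#'
#' A hit survives iff all bounds of the policy hold as strict inequalities:
#' TM-score above `tm_min`, E-value below `evalue_max` (skipped when the
#' bound is disabled, or when the hit's `source` is exempt), average
#' alignment coverage `(qcov + tcov) / 2` above `avg_cov_min`, and — at the
#' cluster level — mean TM-score and mean alignment length of all hits from
#' the query's structural cluster to the same target above
#' `cluster_tm_min` / `intracluster_alnlen_min`. Hits without a
#' cluster-statistics entry fail the cluster-level criteria, with a
#' warning.
#'
#' @param hits Hit tibble with `query`, `target`, `alntmscore`, `evalue`,
#'   `qcov`, `tcov`, `alnlen`, optionally `source`.
#' @param policy A [filter_policy()].
#' @param members Optional membership tibble used to compute cluster
#'   statistics from `hits` when `cluster_stats` is not supplied.
#' @param cluster_stats Optional precomputed tibble from
#'   [cluster_hit_stats()].
#' @return The surviving subset of `hits` (same columns).
#' @export
apply_policy <- function(hits, policy, members = NULL,
                         cluster_stats = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(hits) == 0) return(hits)
  if (is.null(cluster_stats)) {
    cluster_stats <- cluster_hit_stats(hits, members)
  }
  cl <- query_cluster(hits$query, members)
  key <- paste(cl, hits$target, sep = "\r")
  skey <- paste(cluster_stats$cluster_id, cluster_stats$target, sep = "\r")
  idx <- match(key, skey)
  if (anyNA(idx)) {
    warning(sprintf(
      "%d hits lack cluster statistics and fail cluster-level criteria",
      sum(is.na(idx))), call. = FALSE)
  }
  mean_tm <- cluster_stats$cluster_mean_tm[idx]
  mean_alnlen <- cluster_stats$cluster_mean_alnlen[idx]

  ok <- rep(TRUE, nrow(hits))
  if (!is.na(policy$tm_min)) ok <- ok & hits$alntmscore > policy$tm_min
  if (!is.na(policy$evalue_max)) {
    e_ok <- hits$evalue < policy$evalue_max
    if (!is.null(policy$evalue_sources) && "source" %in% names(hits)) {
      e_ok <- e_ok | !(hits$source %in% policy$evalue_sources)
    }
    ok <- ok & e_ok
  }
  if (!is.na(policy$avg_cov_min)) {
    ok <- ok & (hits$qcov + hits$tcov) / 2 > policy$avg_cov_min
  }
  if (!is.na(policy$cluster_tm_min)) {
    ok <- ok & !is.na(mean_tm) & mean_tm > policy$cluster_tm_min
  }
  if (!is.na(policy$intracluster_alnlen_min)) {
    ok <- ok & !is.na(mean_alnlen) &
      mean_alnlen > policy$intracluster_alnlen_min
  }
  hits[ok, , drop = FALSE]
}

#' Merge antidefense hit sets, keeping the best TM-score per query
#'
#' Combines two policy-filtered antidefense hit tables (e.g. from an
#' antidefense model library and from a phage anti-prokaryotic-immunity
#' database) and keeps, per query, the single hit with the maximal
#' TM-score. Ties prefer the first table, then the lexicographically
#' smaller target id.
#'
#' @param hits_adf,hits_dbapis Filtered hit tibbles; a `source` column is
#'   added (`"antidefensefinder"` / `"dbapis"`) if absent.
#' @return One hit per query.
#' @export
merge_antidefense <- function(hits_adf, hits_dbapis) {
  if (!"source" %in% names(hits_adf) && nrow(hits_adf) > 0) {
    hits_adf$source <- "antidefensefinder"
  }
  if (!"source" %in% names(hits_dbapis) && nrow(hits_dbapis) > 0) {
    hits_dbapis$source <- "dbapis"
  }
  combined <- dplyr::bind_rows(hits_adf, hits_dbapis)
  if (nrow(combined) == 0) return(combined)
  src_rank <- match(combined$source, c("antidefensefinder", "dbapis"))
  combined <- dplyr::arrange(
    dplyr::mutate(combined, .src = src_rank),
    .data$query, dplyr::desc(.data$alntmscore), .data$.src, .data$target)
  out <- dplyr::slice_head(dplyr::group_by(combined, .data$query), n = 1)
  dplyr::select(dplyr::ungroup(out), -".src")
}
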