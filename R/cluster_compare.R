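#' Count unique cluster-to-cluster relationships from a hit table
#'
#' Maps every hit's query and target protein to its cluster and collects
#' the unordered pairs of distinct clusters linked by at least one hit.
#' Self-hits and within-cluster hits contribute nothing; hits are treated
#' as undirected, so the result is invariant to swapping query and target.
#'
#' @param hits Hit tibble with columns `query`, `target` (other columns
#'   ignored; no score thresholds are applied here).
#' @param members Membership tibble (`cluster_id`, `protein_id`); every
#'   protein in `hits` must be resolvable.
#' @return A tibble with columns `cluster_a`, `cluster_b` (canonical order,
#'   `cluster_a < cluster_b`) and `evidence_count` (number of supporting
#'   hits), sorted by the pair.
#' @export
count_cluster_pairs <- function(hits, members) {
  lookup <- setNames(members$cluster_id, members$protein_id)
  unresolved <- setdiff(unique(c(hits$query, hits$target)), names(lookup))
  if (length(unresolved) > 0) {
    stop("protein ids not found in any cluster: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  qc <- unname(lookup[hits$query])
  tc <- unname(lookup[hits$target])
  keep <- qc != tc  # drops self-hits and within-cluster hits alike
  a <- pmin(qc[keep], tc[keep])
  b <- pmax(qc[keep], tc[keep])
  pairs <- dplyr::count(tibble(cluster_a = a, cluster_b = b),
                        .data$cluster_a, .data$cluster_b,
                        name = "evidence_count")
  dplyr::arrange(pairs, .data$cluster_a, .data$cluster_b)
}

#' Ratio of structure- to sequence-level cluster relationships
#'
#' @param pairs_struct,pairs_seq Pair tibbles from [count_cluster_pairs()]
#'   computed on the same cluster universe.
#' @return A list with `ratio` (`|pairs_struct| / |pairs_seq|`; `Inf` when
#'   no sequence-level pairs exist but structure-level pairs do) and
#'   `infinite` (logical flag for that degenerate case).
#' @export
relationship_gain <- function(pairs_struct, pairs_seq) {
  n_s <- nrow(pairs_struct)
  n_q <- nrow(pairs_seq)
  if (n_q == 0) {
    list(ratio = if (n_s > 0) Inf else NaN, infinite = n_s > 0)
  } else {
    list(ratio = n_s / n_q, infinite = FALSE)
  }
}

#' Cross-tabulate host-type labels between two clustering levels
#'
#' For every protein, looks up the host type of its sequence-level cluster
#' and of its structure-level cluster and tabulates the transitions. A
#' protein present at only one level is counted in an `"unpaired"` margin
#' and a warning is logged.
#'
#' @param labels_seq,labels_struct Label tibbles from [classify_clusters()]
#'   for the sequence and structure clusterings.
#' @param members_seq,members_struct The corresponding membership tibbles;
#'   each protein appears in exactly one cluster per level.
#' @return A tibble with columns `kind_seq`, `kind_struct`, `n` and
#'   `fraction` (of all proteins in the table). Unpaired proteins appear
#'   with `"unpaired"` in the missing level's column.
#' @export
transition_table <- function(labels_seq, labels_struct,
                             members_seq, members_struct) {
  seq_kind <- dplyr::left_join(members_seq, labels_seq, by = "cluster_id")
  struct_kind <- dplyr::left_join(members_struct, labels_struct,
                                  by = "cluster_id")
  stopifnot(!anyDuplicated(seq_kind$protein_id),
            !anyDuplicated(struct_kind$protein_id))
  merged <- dplyr::full_join(
    tibble(protein_id = seq_kind$protein_id, kind_seq = seq_kind$kind),
    tibble(protein_id = struct_kind$protein_id,
           kind_struct = struct_kind$kind),
    by = "protein_id")
  n_unpaired <- sum(is.na(merged$kind_seq)) + sum(is.na(merged$kind_struct))
  if (n_unpaired > 0) {
    warning(sprintf("%d proteins present at one clustering level only",
                    n_unpaired), call. = FALSE)
  }
  merged$kind_seq[is.na(merged$kind_seq)] <- "unpaired"
  merged$kind_struct[is.na(merged$kind_struct)] <- "unpaired"
  out <- dplyr::count(merged, .data$kind_seq, .data$kind_struct, name = "n")
  out$fraction <- if (nrow(out) > 0) out$n / sum(out$n) else numeric(0)
  out
}
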