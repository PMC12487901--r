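#' Oligomeric-state label from assembly chain counts
#'
#' Derives a state label from the number of copies of a chain in its
#' biological assembly and the number of distinct chain types in that
#' assembly: `"monomer"` when both are 1, a homo-oligomer name
#' (`"homodimer"`, `"homotrimer"`, ..., `"homoN-mer"` beyond octamer) when
#' the chain is repeated in an otherwise single-type assembly, and
#' `"hetero-N-mer"` (N = distinct chain types) when other chain types are
#' present.
#'
#' @param copies Integer vector: copies of the chain in the assembly.
#' @param distinct_chains Integer vector: distinct chain types in the
#'   assembly.
#' @return Character vector of state labels.
#' @export
oligo_state_label <- function(copies, distinct_chains) {
  stopifnot(all(copies >= 1), all(distinct_chains >= 1),
            length(copies) == length(distinct_chains))
  greek <- c("2" = "homodimer", "3" = "homotrimer", "4" = "homotetramer",
             "5" = "homopentamer", "6" = "homohexamer",
             "7" = "homoheptamer", "8" = "homooctamer")
  out <- character(length(copies))
  hetero <- distinct_chains > 1
  out[hetero] <- sprintf("hetero-%d-mer", distinct_chains[hetero])
  mono <- !hetero & copies == 1
  out[mono] <- "monomer"
  homo <- !hetero & copies > 1
  named <- homo & copies <= 8
  out[named] <- greek[as.character(copies[named])]
  big <- homo & copies > 8
  out[big] <- sprintf("homo%d-mer", copies[big])
  out
}

#' Homo-/hetero-oligomer flags from PDB chain hits
#'
#' A query is flagged homo-oligomeric if any of its hits is to a chain
#' found more than once in its biological assembly, and hetero-oligomeric
#' if any hit chain shares its assembly with other chain types. The flags
#' are independent: both can hold when different hits give different
#' evidence.
#'
#' @param hit_targets Character vector of PDB chain ids hit by one query
#'   (already thresholded on TM-score upstream, see [infer_state()]).
#' @param annotations Annotation tibble (`pdb_chain_id`, `copies`,
#'   `distinct_chains`), see [read_oligo_annotations()].
#' @return A list with logical `homo` and `hetero`. Hit chains missing
#'   from the annotations are skipped with a warning.
#' @export
classify_homo_hetero <- function(hit_targets, annotations) {
  idx <- match(hit_targets, annotations$pdb_chain_id)
  if (anyNA(idx)) {
    warning("skipping hit chains without oligomeric annotation: ",
            paste(unique(hit_targets[is.na(idx)]), collapse = ", "),
            call. = FALSE)
    idx <- idx[!is.na(idx)]
  }
  list(homo = any(annotations$copies[idx] > 1),
       hetero = any(annotations$distinct_chains[idx] > 1))
}

#' Infer the oligomeric state of a query by TM-score-weighted voting
#'
#' Hits below the TM-score threshold are discarded; the remaining hits vote
#' for the oligomeric state of their annotated PDB chain, each with weight
#' equal to its TM-score, and the state with the largest summed weight is
#' returned. Weight ties are broken by the number of supporting hits, then
#' by the lexicographically smaller label. Queries with no surviving hits
#' get state `NA`.
#'
#' @param hits Hit tibble for one query with columns `target` and
#'   `alntmscore` (TM-score in \[0, 1\]).
#' @param annotations Annotation tibble (`pdb_chain_id`, `copies`,
#'   `distinct_chains`).
#' @param tm_min TM-score threshold; hits with `alntmscore < tm_min` are
#'   discarded.
#' @return A list with `state` (label or `NA`), `weights` (named numeric:
#'   summed TM-score per state), and the `homo`/`hetero` flags of
#'   [classify_homo_hetero()] computed on the surviving hits.
#' @export
infer_state <- function(hits, annotations, tm_min = 0.5) {
  stopifnot(all(c("target", "alntmscore") %in% names(hits)))
  kept <- hits[!is.na(hits$alntmscore) & hits$alntmscore >= tm_min, ,
               drop = FALSE]
  idx <- match(kept$target, annotations$pdb_chain_id)
  if (anyNA(idx)) {
    warning("skipping hit chains without oligomeric annotation: ",
            paste(unique(kept$target[is.na(idx)]), collapse = ", "),
            call. = FALSE)
    kept <- kept[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(kept) == 0) {
    return(list(state = NA_character_, weights = numeric(0),
                homo = FALSE, hetero = FALSE))
  }
  state <- oligo_state_label(annotations$copies[idx],
                             annotations$distinct_chains[idx])
  weights <- tapply(kept$alntmscore, state, sum)
  counts <- tapply(rep(1L, nrow(kept)), state, sum)
  ord <- order(-weights, -counts, names(weights))
  flags <- classify_homo_hetero(kept$target, annotations)
  list(state = names(weights)[ord[1]],
       weights = setNames(as.numeric(weights), names(weights)),
       homo = flags$homo, hetero = flags$hetero)
}

#' Infer oligomeric states for every query in a hit table
#'
#' Applies [infer_state()] per query, or per cluster when a membership
#' table is supplied — the votes of all hits of all cluster members are
#' then pooled, matching the practice of assigning a state to a cluster's
#' proteins jointly.
#'
#' @param hits Hit tibble with columns `query`, `target`, `alntmscore`.
#' @param annotations Annotation tibble (`pdb_chain_id`, `copies`,
#'   `distinct_chains`).
#' @param tm_min TM-score threshold, see [infer_state()].
#' @param members Optional membership tibble (`cluster_id`, `protein_id`);
#'   when given, states are inferred per cluster.
#' @return A tibble with columns `query` (protein or cluster id), `state`,
#'   `homo`, `hetero` and `top_weight`.
#' @export
infer_states <- function(hits, annotations, tm_min = 0.5, members = NULL) {
  if (!is.null(members)) {
    lookup <- setNames(members$cluster_id, members$protein_id)
    unresolved <- setdiff(unique(hits$query), names(lookup))
    if (length(unresolved) > 0) {
      stop("query proteins not found in any cluster: ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    }
    group <- unname(lookup[hits$query])
  } else {
    group <- hits$query
  }
  calls <- purrr::map(split(hits, group), infer_state,
                      annotations = annotations, tm_min = tm_min)
  tibble(
    query = names(calls),
    state = unname(vapply(calls, `[[`, character(1), "state")),
    homo = unname(vapply(calls, `[[`, logical(1), "homo")),
    hetero = unname(vapply(calls, `[[`, logical(1), "hetero")),
    top_weight = unname(vapply(calls, function(cl) {
      if (length(cl$weights) == 0) NA_real_ else max(cl$weights)
    }, numeric(1))))
}
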