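#' Parse the superkingdom from a host lineage string
#'
#' Host lineages are semicolon-delimited rank strings with the superkingdom
#' first (e.g. `"Bacteria; Pseudomonadota; Gammaproteobacteria"`). Lineages
#' rooted at `Viruses` denote a virus-infecting virus and map to
#' `"undefined"`. Unrecognized or empty superkingdoms return `NA` so the
#' caller can report the offending row and continue.
#'
#' @param lineage Character vector of lineage strings.
#' @return Character vector of host domains, `NA` where malformed.
#' @export
parse_superkingdom <- function(lineage) {
  first <- stringr::str_trim(stringr::str_split_i(lineage, ";", 1))
  out <- rep(NA_character_, length(lineage))
  key <- tolower(first)
  out[key == "bacteria"] <- "bacteria"
  out[key == "archaea"] <- "archaea"
  out[key %in% c("eukaryota", "eukarya", "eukaryotes")] <- "eukaryota"
  out[key == "viruses"] <- "undefined"
  out[is.na(lineage) | key == ""] <- NA_character_
  out
}

#' Resolve the host domain set of one virus
#'
#' Looks a virus taxid up in a virus-host mapping table and returns the set
#' of host domains parsed from the superkingdom rank of each recorded host
#' lineage. A taxid absent from the map (or `NA`), or a host lineage rooted
#' at `Viruses`, yields `"undefined"`. Curation overrides, matched on the
#' exact virus lineage name (case-insensitive), take precedence over the
#' mapping.
#'
#' @param virus_taxid A single integer taxid (may be `NA`).
#' @param host_map Tibble with columns `virus_taxid`, `host_lineage`
#'   (see [read_host_map()]).
#' @param overrides Optional tibble with columns `lineage`, `domain`
#'   (see [read_overrides()]).
#' @param virus_lineage Optional virus lineage name used for override
#'   matching.
#' @return Character vector: the set of host domains. If it contains
#'   `"undefined"` it contains nothing else.
#' @export
assign_host <- function(virus_taxid, host_map, overrides = NULL,
                        virus_lineage = NULL) {
  if (!is.null(overrides) && !is.null(virus_lineage) &&
      !is.na(virus_lineage)) {
    hit <- tolower(overrides$lineage) == tolower(virus_lineage)
    if (any(hit)) return(unique(overrides$domain[hit]))
  }
  if (is.na(virus_taxid)) return("undefined")
  rows <- host_map$host_lineage[host_map$virus_taxid == virus_taxid]
  if (length(rows) == 0) return("undefined")
  domains <- parse_superkingdom(rows)
  if (anyNA(domains)) {
    warning(sprintf("malformed host lineage for taxid %s: %s",
                    virus_taxid,
                    paste(rows[is.na(domains)], collapse = " | ")),
            call. = FALSE)
    domains <- domains[!is.na(domains)]
  }
  domains <- unique(domains)
  defined <- setdiff(domains, "undefined")
  if (length(defined) == 0) "undefined" else defined
}

#' Resolve host domains for a table of proteins
#'
#' Vectorized host assignment: each protein carries the taxid of its source
#' virus (and optionally the virus lineage name, used for curation
#' overrides). A protein whose virus has recorded hosts in several domains
#' contributes one row per domain.
#'
#' @param proteins Tibble with columns `protein_id`, `virus_taxid` and
#'   optionally `virus_lineage`.
#' @param host_map,overrides See [assign_host()].
#' @return A long tibble with columns `protein_id`, `host_domain`; every
#'   protein appears at least once, and a protein with `"undefined"` has no
#'   other rows.
#' @export
assign_protein_hosts <- function(proteins, host_map, overrides = NULL) {
  stopifnot(all(c("protein_id", "virus_taxid") %in% names(proteins)))
  lineages <- if ("virus_lineage" %in% names(proteins)) {
    proteins$virus_lineage
  } else rep(NA_character_, nrow(proteins))

  # resolve each distinct (taxid, lineage) once, then join back
  keys <- tibble(virus_taxid = proteins$virus_taxid, virus_lineage = lineages)
  uniq <- dplyr::distinct(keys)
  resolved <- purrr::map2(uniq$virus_taxid, uniq$virus_lineage,
                          function(t, l) {
                            assign_host(t, host_map, overrides, l)
                          })
  uniq$host_domain <- resolved
  out <- dplyr::left_join(
    dplyr::mutate(keys, protein_id = proteins$protein_id),
    uniq, by = c("virus_taxid", "virus_lineage"))
  out <- tidyr::unnest(out[, c("protein_id", "host_domain")],
                       "host_domain")
  out
}

#' Classify a cluster as monohost, heterohost or host-undefined
#'
#' A cluster is assigned a host type from the host domains of its member
#' proteins. To limit the effect of isolated virus-host misannotations, a
#' minority host domain only counts toward a heterohost label when it is
#' supported by at least `min_count` proteins or `min_fraction` of the
#' total cluster size, whichever is bigger (the fraction is rounded up, so
#' the threshold is a whole-protein count). The modal defined domain always
#' qualifies; ties for the mode qualify jointly and thus yield a heterohost
#' label. Clusters composed solely of proteins without a defined host are
#' host-undefined.
#'
#' @param member_ids Character vector of member protein ids (non-empty).
#' @param protein_hosts Long tibble (`protein_id`, `host_domain`) as from
#'   [assign_protein_hosts()].
#' @param min_count Minimum member count for a minority domain to qualify.
#' @param min_fraction Minimum fraction of the total cluster size
#'   (including undefined-host members) for a minority domain to qualify.
#' @return A list with elements `kind` (`"mono"`, `"hetero"` or
#'   `"undefined"`) and `domains` (sorted character vector: singleton if
#'   mono, length >= 2 if hetero, empty if undefined).
#' @export
classify_cluster_host_type <- function(member_ids, protein_hosts,
                                       min_count = 3, min_fraction = 0.01) {
  if (length(member_ids) == 0) stop("empty cluster", call. = FALSE)
  if (anyDuplicated(member_ids)) stop("duplicate member ids", call. = FALSE)
  missing <- setdiff(member_ids, protein_hosts$protein_id)
  if (length(missing) > 0) {
    stop("unresolvable member ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- protein_hosts[protein_hosts$protein_id %in% member_ids, ]
  counts <- table(rows$host_domain[rows$host_domain %in% DEFINED_DOMAINS])
  host_type_from_counts(
    counts = setNames(as.integer(counts), names(counts)),
    n_total = length(member_ids),
    min_count = min_count, min_fraction = min_fraction)
}

#' Host-type label from per-domain counts
#'
#' The counting core of [classify_cluster_host_type()], exposed for direct
#' use on composition vectors.
#'
#' @param counts Named integer vector of member counts per *defined* host
#'   domain (zero entries allowed).
#' @param n_total Total cluster size, including undefined-host members.
#' @param min_count,min_fraction See [classify_cluster_host_type()].
#' @return A list with `kind` and `domains` (see
#'   [classify_cluster_host_type()]).
#' @export
host_type_from_counts <- function(counts, n_total, min_count = 3,
                                  min_fraction = 0.01) {
  stopifnot(n_total >= 1, all(names(counts) %in% DEFINED_DOMAINS))
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return(list(kind = "undefined", domains = character(0)))
  }
  threshold <- max(min_count, ceiling(min_fraction * n_total))
  modal <- names(counts)[counts == max(counts)]
  qualifying <- union(modal, names(counts)[counts >= threshold])
  if (length(qualifying) >= 2) {
    list(kind = "hetero", domains = sort(qualifying))
  } else {
    list(kind = "mono", domains = qualifying)
  }
}

#' Classify every cluster in a membership table
#'
#' @param members Membership tibble (`cluster_id`, `protein_id`,
#'   `is_representative`), see [read_cluster_members()].
#' @param protein_hosts Long tibble (`protein_id`, `host_domain`).
#' @param min_count,min_fraction See [classify_cluster_host_type()].
#' @return A tibble with columns `cluster_id`, `kind` and `domains`
#'   (qualifying domains joined with `"+"` in sorted order, `""` for
#'   host-undefined clusters).
#' @export
classify_clusters <- function(members, protein_hosts, min_count = 3,
                              min_fraction = 0.01) {
  labels <- purrr::map(split(members$protein_id, members$cluster_id),
                       classify_cluster_host_type,
                       protein_hosts = protein_hosts,
                       min_count = min_count, min_fraction = min_fraction)
  tibble(
    cluster_id = names(labels),
    kind = unname(vapply(labels, `[[`, character(1), "kind")),
    domains = unname(vapply(labels, function(l) {
      paste(l$domains, collapse = "+")
    }, character(1))))
}

#' Host-type distribution over clusters and proteins
#'
#' Summarizes a labelled clustering: cluster counts per host-type label,
#' the per-protein cross-tabulation of protein host domain against cluster
#' host type (the inner/outer ring view), and the fraction of proteins that
#' fall in heterohost clusters.
#'
#' @param labels Label tibble from [classify_clusters()].
#' @param members Membership tibble used to produce `labels`.
#' @param protein_hosts Long tibble (`protein_id`, `host_domain`).
#' @return A list with `cluster_counts` (kind, domains, n),
#'   `protein_table` (host_domain, cluster_kind, n; a multi-domain protein
#'   counts once per domain) and `hetero_protein_fraction` (distinct
#'   proteins in heterohost clusters over all distinct proteins).
#' @export
host_distribution <- function(labels, members, protein_hosts) {
  cluster_counts <- dplyr::count(labels, .data$kind, .data$domains,
                                 name = "n")
  joined <- dplyr::left_join(members, labels, by = "cluster_id")
  per_protein <- dplyr::inner_join(
    joined[, c("protein_id", "kind")], protein_hosts, by = "protein_id")
  protein_table <- dplyr::count(per_protein, .data$host_domain,
                                cluster_kind = .data$kind, name = "n")
  hetero_ids <- unique(joined$protein_id[joined$kind == "hetero"])
  frac <- length(hetero_ids) / length(unique(joined$protein_id))
  list(cluster_counts = cluster_counts,
       protein_table = protein_table,
       hetero_protein_fraction = frac)
}
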