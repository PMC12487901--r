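#' Read a tabular structure-search hit file (m8 format)
#'
#' Reads the conventional twelve-column tabular output of sequence/structure
#' search tools (query, target, fident, alnlen, mismatch, gapopen, qstart,
#' qend, tstart, tend, evalue, bits), optionally extended with further
#' columns such as `alntmscore`, `lddt`, `qcov` and `tcov`.
#'
#' @param path Path to a headerless tab-separated hit file.
#' @param extra_cols Character vector naming columns appended after the
#'   twelve standard ones, in file order. Use `NULL` for a plain m8 file.
#' @return A tibble with one row per hit. `fident`, `qcov`, `tcov`,
#'   `alntmscore` and `lddt` are fractions in \[0, 1\].
#' @export
read_hits <- function(path, extra_cols = c("alntmscore", "qcov", "tcov")) {
  cols <- c(M8_COLS, extra_cols)
  hits <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                          progress = FALSE)
  validate_hits(hits)
  hits
}

M8_COLS <- c("query", "target", "fident", "alnlen", "mismatch", "gapopen",
             "qstart", "qend", "tstart", "tend", "evalue", "bits")

#' Write a hit table in m8 format
#'
#' @param hits A hit tibble as returned by [read_hits()].
#' @param path Output path; written headerless and tab-separated, standard
#'   columns first, any extra columns after, in table order.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  extra <- setdiff(names(hits), M8_COLS)
  readr::write_tsv(hits[, c(M8_COLS, extra)], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

validate_hits <- function(hits) {
  stopifnot(all(c("query", "target") %in% names(hits)))
  for (col in intersect(c("fident", "qcov", "tcov", "alntmscore", "lddt"),
                        names(hits))) {
    bad <- !is.na(hits[[col]]) & (hits[[col]] < 0 | hits[[col]] > 1)
    if (any(bad)) {
      stop(sprintf("column '%s' must lie in [0, 1]; %d rows violate this",
                   col, sum(bad)), call. = FALSE)
    }
  }
  if ("evalue" %in% names(hits) && any(hits$evalue < 0, na.rm = TRUE)) {
    stop("column 'evalue' must be non-negative", call. = FALSE)
  }
  invisible(hits)
}

#' Read and write cluster membership tables
#'
#' Cluster membership files have columns `cluster_id`, `protein_id` and
#' `is_representative` (logical), one row per member. The same dialect is
#' used for sequence-level and structure-level clusterings.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with columns `cluster_id`, `protein_id`,
#'   `is_representative`.
#' @export
read_cluster_members <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         cluster_id = readr::col_character(),
                         protein_id = readr::col_character(),
                         is_representative = readr::col_logical()))
  validate_cluster_members(m)
  m
}

#' @rdname read_cluster_members
#' @param members A membership tibble.
#' @export
write_cluster_members <- function(members, path) {
  validate_cluster_members(members)
  readr::write_tsv(members, path, progress = FALSE)
  invisible(path)
}

validate_cluster_members <- function(members) {
  stopifnot(all(c("cluster_id", "protein_id", "is_representative") %in%
                  names(members)))
  dup <- duplicated(members[, c("cluster_id", "protein_id")])
  if (any(dup)) stop("duplicate cluster members found", call. = FALSE)
  reps <- tapply(members$is_representative, members$cluster_id, sum)
  if (any(reps != 1)) {
    stop("every cluster must have exactly one representative", call. = FALSE)
  }
  invisible(members)
}

#' Read and write virus-host mapping tables
#'
#' The mapping table has columns `virus_taxid` (integer) and `host_lineage`
#' (a semicolon-delimited rank string, superkingdom first, e.g.
#' `"Bacteria; Pseudomonadota; ..."`). Multiple rows per taxid are allowed;
#' a virus then has several recorded hosts.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with columns `virus_taxid`, `host_lineage`.
#' @export
read_host_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    virus_taxid = readr::col_integer(),
                    host_lineage = readr::col_character()))
}

#' @rdname read_host_map
#' @param host_map A host-map tibble.
#' @export
write_host_map <- function(host_map, path) {
  readr::write_tsv(host_map, path, progress = FALSE)
  invisible(path)
}

#' Read host overrides from TSV or YAML
#'
#' Overrides force a host domain for named viral lineages regardless of the
#' mapping table (manual curation of known misannotations). TSV files need
#' columns `lineage` and `domain`; YAML files are a list of
#' `{lineage: ..., domain: ...}` entries.
#'
#' @param path Path to a `.tsv`/`.txt` or `.yml`/`.yaml` file.
#' @return A tibble with columns `lineage`, `domain`.
#' @export
read_overrides <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    out <- tibble(
      lineage = vapply(entries, function(e) e$lineage, character(1)),
      domain = vapply(entries, function(e) e$domain, character(1)))
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             lineage = readr::col_character(),
                             domain = readr::col_character()))
  }
  stopifnot(all(out$domain %in% HOST_DOMAINS))
  out
}

#' Read and write genomic-context (neighborhood) tables
#'
#' One row per gene in a genomic window: `context_id`, `species_id`,
#' `order_index` (0-based position within the window, increasing with
#' `start`), `start`/`end` (1-based inclusive nucleotide coordinates),
#' `strand` (`+`/`-`), `family` (protein family label) and `is_target`
#' (whether the gene encodes a screening target protein).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with the columns above.
#' @export
read_neighborhoods <- function(path) {
  nbh <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           context_id = readr::col_character(),
                           species_id = readr::col_character(),
                           order_index = readr::col_integer(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           strand = readr::col_character(),
                           family = readr::col_character(),
                           is_target = readr::col_logical()))
  validate_neighborhoods(nbh)
  nbh
}

#' @rdname read_neighborhoods
#' @param neighborhoods A neighborhood tibble.
#' @export
write_neighborhoods <- function(neighborhoods, path) {
  validate_neighborhoods(neighborhoods)
  readr::write_tsv(neighborhoods, path, progress = FALSE)
  invisible(path)
}

validate_neighborhoods <- function(nbh) {
  stopifnot(all(c("context_id", "species_id", "order_index", "start", "end",
                  "strand", "family", "is_target") %in% names(nbh)))
  stopifnot(all(nbh$start <= nbh$end), all(nbh$start >= 1),
            all(nbh$strand %in% c("+", "-")))
  ord_ok <- vapply(split(nbh, nbh$context_id), function(ctx) {
    ctx <- ctx[order(ctx$order_index), ]
    !is.unsorted(ctx$start, strictly = FALSE) &&
      !anyDuplicated(ctx$order_index)
  }, logical(1))
  if (!all(ord_ok)) {
    stop("order_index must increase with start within each context",
         call. = FALSE)
  }
  invisible(nbh)
}

#' Read genomic contexts from a GFF3 file
#'
#' Gene-level records are converted to the neighborhood table dialect used
#' by the pattern miner. The family label and target flag are taken from
#' named GFF attributes; the context and species identifiers from the
#' seqid and a named attribute (falling back to the seqid).
#'
#' @param path Path to an (uncompressed) GFF3 file.
#' @param family_attr,target_attr,species_attr Attribute names holding the
#'   protein family label, the target flag (`"true"`/`"1"` counts as TRUE)
#'   and the species identifier.
#' @return A neighborhood tibble as from [read_neighborhoods()].
#' @export
read_neighborhoods_gff <- function(path, family_attr = "family",
                                   target_attr = "is_target",
                                   species_attr = "species") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the 'rtracklayer' package", call. = FALSE)
  }
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (!family_attr %in% names(g)) {
    stop(sprintf("GFF attribute '%s' not found", family_attr), call. = FALSE)
  }
  tgt <- if (target_attr %in% names(g)) {
    tolower(as.character(g[[target_attr]])) %in% c("true", "1", "yes")
  } else rep(FALSE, nrow(g))
  spc <- if (species_attr %in% names(g)) {
    as.character(g[[species_attr]])
  } else as.character(g$seqid)
  nbh <- tibble(
    context_id = as.character(g$seqid),
    species_id = spc,
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    family = as.character(g[[family_attr]]),
    is_target = tgt)
  nbh <- dplyr::arrange(nbh, .data$context_id, .data$start)
  nbh <- dplyr::mutate(dplyr::group_by(nbh, .data$context_id),
                       order_index = seq_len(dplyr::n()) - 1L)
  nbh <- dplyr::ungroup(nbh)
  nbh <- nbh[, c("context_id", "species_id", "order_index", "start", "end",
                 "strand", "family", "is_target")]
  validate_neighborhoods(nbh)
  nbh
}

#' Read and write oligomeric-state annotation tables
#'
#' One row per PDB chain: `pdb_chain_id`, `copies` (number of copies of
#' that chain in the biological assembly) and `distinct_chains` (number of
#' distinct chain types in the assembly).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with the columns above plus a derived `state_label`.
#' @export
read_oligo_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           pdb_chain_id = readr::col_character(),
                           copies = readr::col_integer(),
                           distinct_chains = readr::col_integer()))
  stopifnot(all(ann$copies >= 1), all(ann$distinct_chains >= 1))
  ann$state_label <- oligo_state_label(ann$copies, ann$distinct_chains)
  ann
}

#' @rdname read_oligo_annotations
#' @param annotations An annotation tibble.
#' @export
write_oligo_annotations <- function(annotations, path) {
  cols <- c("pdb_chain_id", "copies", "distinct_chains")
  readr::write_tsv(annotations[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read and write per-model confidence score tables
#'
#' Score tables carry one row per predicted model: `model_id`, `kind`
#' (`"monomer"` or `"homodimer"`), `mean_plddt` (0-100), and optionally
#' `ptm`, `iptm` and `pdockq` (all 0-1; `iptm` only for homodimers).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with the columns above.
#' @export
read_score_table <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("model_id", "kind", "mean_plddt") %in% names(s)))
  stopifnot(all(s$kind %in% c("monomer", "homodimer")))
  stopifnot(all(s$mean_plddt >= 0 & s$mean_plddt <= 100, na.rm = TRUE))
  for (col in intersect(c("ptm", "iptm", "pdockq"), names(s))) {
    stopifnot(all(s[[col]] >= 0 & s[[col]] <= 1, na.rm = TRUE))
  }
  s
}

#' @rdname read_score_table
#' @param scores A score tibble.
#' @export
write_score_table <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}

#' Write a minimal PDB model stub with per-residue pLDDT in the B-factor
#'
#' Writes one C-alpha ATOM record per residue, with the supplied pLDDT
#' value in the B-factor column — the convention used by structure
#' prediction pipelines. Coordinates are placeholders on a line; the files
#' are intended for confidence parsing, not geometry.
#'
#' @param path Output path.
#' @param chains A named list mapping chain identifier (single letter) to a
#'   numeric vector of per-residue pLDDT values in \[0, 100\].
#' @return `path`, invisibly.
#' @export
write_model_stub <- function(path, chains) {
  stopifnot(length(chains) >= 1, !is.null(names(chains)))
  lines <- character(0)
  serial <- 0L
  for (ch in names(chains)) {
    plddt <- chains[[ch]]
    stopifnot(all(plddt >= 0 & plddt <= 100))
    for (i in seq_along(plddt)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, ch, i, i * 3.8, 0, 0, 1, plddt[i]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
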