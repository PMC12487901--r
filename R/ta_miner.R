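#' Prefilter protein communities for genomic-context screening
#'
#' Keeps "dark" communities — groups of structurally related proteins with
#' little functional annotation — that are large enough to screen: median
#' functional brightness strictly below `brightness_max` percent and at
#' least `min_members` protein members.
#'
#' @param communities Tibble with columns `community_id`,
#'   `median_brightness` (percent, 0-100) and `member_count`.
#' @param brightness_max Strict upper bound on median brightness (percent).
#' @param min_members Inclusive lower bound on member count.
#' @return The surviving subset of `communities`.
#' @export
prefilter_communities <- function(communities, brightness_max = 5,
                                  min_members = 5) {
  stopifnot(all(c("community_id", "median_brightness", "member_count") %in%
                  names(communities)))
  communities[communities$median_brightness < brightness_max &
                communities$member_count >= min_members, , drop = FALSE]
}

#' Species-support gate for a set of genomic contexts
#'
#' A community's genomic contexts are only screened when the target
#' protein occurs in at least `min_species` different species; otherwise
#' apparent conservation could reflect a handful of closely related
#' genomes. Species are counted once regardless of how many contexts they
#' contribute.
#'
#' @param neighborhoods Neighborhood tibble, see [read_neighborhoods()].
#' @param min_species Minimum number of distinct `species_id` values.
#' @return `neighborhoods` unchanged if the gate passes, else a zero-row
#'   tibble with the same columns.
#' @export
species_gate <- function(neighborhoods, min_species = 6) {
  if (length(unique(neighborhoods$species_id)) >= min_species) {
    neighborhoods
  } else {
    neighborhoods[0, , drop = FALSE]
  }
}

#' Occurrences of a family pattern in one genomic context
#'
#' An occurrence is a run of consecutive genes whose family labels equal
#' `families` in order, with every internal intergenic distance
#' (`start(next) - end(prev) - 1` under 1-based inclusive coordinates) at
#' most `gap_max` nucleotides, and — by default — all genes on the same
#' strand, reflecting operonic co-transcription.
#'
#' @param context_genes Tibble of the genes of one context (columns
#'   `order_index`, `start`, `end`, `strand`, `family`).
#' @param families Character vector of family labels, length >= 2.
#' @param gap_max Maximum internal intergenic distance in nucleotides.
#' @param same_strand Require all pattern genes on one strand.
#' @return A tibble with one row per occurrence: `first_idx`, `last_idx`
#'   (row positions in gene order), `start`, `end` (nucleotide span).
#' @export
pattern_occurrences <- function(context_genes, families, gap_max = 100,
                                same_strand = TRUE) {
  stopifnot(length(families) >= 2)
  g <- context_genes[order(context_genes$order_index), , drop = FALSE]
  m <- occ_runs(g$family, g$start, g$end, g$strand, families, gap_max,
                same_strand)
  tibble(first_idx = m[, 1], last_idx = m[, 2],
         start = g$start[m[, 1]], end = g$end[m[, 2]])
}

# Occurrence runs of `pattern` over parallel gene vectors (already in
# positional order); returns an integer matrix of (first, last) indices.
occ_runs <- function(fams, starts, ends, strands, pattern, gap_max,
                     same_strand) {
  len <- length(pattern)
  n <- length(fams)
  out <- integer(0)
  if (n >= len) {
    gap_ok <- if (n > 1) {
      starts[-1] - ends[-n] - 1L <= gap_max
    } else logical(0)
    for (i in seq_len(n - len + 1)) {
      j <- i + len - 1L
      if (any(fams[i:j] != pattern)) next
      if (len > 1 && !all(gap_ok[i:(j - 1)])) next
      if (same_strand && any(strands[i:j] != strands[i])) next
      out <- c(out, i, j)
    }
  }
  matrix(out, ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("first", "last")))
}

#' Families conserved across a set of genomic contexts
#'
#' A family is "conserved" when it is present (at least once) in at least
#' `presence_min` of the contexts, boundary inclusive.
#'
#' @param neighborhoods Neighborhood tibble.
#' @param presence_min Minimum presence fraction in \[0, 1\].
#' @return Sorted character vector of conserved family labels.
#' @export
conservation_profile <- function(neighborhoods, presence_min = 0.5) {
  n_ctx <- length(unique(neighborhoods$context_id))
  if (n_ctx == 0) return(character(0))
  pres <- dplyr::distinct(neighborhoods[, c("context_id", "family")])
  counts <- table(pres$family)
  sort(names(counts)[counts / n_ctx >= presence_min])
}

#' Fraction of contexts containing a valid pattern occurrence
#'
#' The support measure of the miner: the fraction of contexts with at
#' least one occurrence of `families` satisfying the order, intergenic-gap
#' and strand criteria (see [pattern_occurrences()]). Support is
#' anti-monotone in pattern length: every occurrence of an extended
#' pattern contains an occurrence of the pattern itself.
#'
#' @param neighborhoods Neighborhood tibble.
#' @param families Character vector of family labels, length >= 2.
#' @param gap_max,same_strand See [pattern_occurrences()].
#' @return A single frequency in \[0, 1\].
#' @export
pattern_freq <- function(neighborhoods, families, gap_max = 100,
                         same_strand = TRUE) {
  ctxs <- split(neighborhoods, neighborhoods$context_id)
  if (length(ctxs) == 0) return(0)
  hit <- vapply(ctxs, function(g) {
    g <- g[order(g$order_index), , drop = FALSE]
    nrow(occ_runs(g$family, g$start, g$end, g$strand, families, gap_max,
                  same_strand)) > 0
  }, logical(1))
  mean(hit)
}

# Does one context support the pattern with clean flanks: at least one
# valid occurrence such that every gene outside it whose family is
# conserved (and not part of the pattern) lies > flank_gap_min nt away.
context_supports <- function(context_genes, families, conserved,
                             gap_max, flank_gap_min, same_strand) {
  g <- context_genes[order(context_genes$order_index), , drop = FALSE]
  runs <- occ_runs(g$family, g$start, g$end, g$strand, families, gap_max,
                   same_strand)
  outside <- which(g$family %in% setdiff(conserved, families))
  any_clean_run(runs, g$start, g$end, outside, flank_gap_min)
}

any_clean_run <- function(runs, starts, ends, outside_pos, flank_gap_min) {
  for (k in seq_len(nrow(runs))) {
    i <- runs[k, 1]; j <- runs[k, 2]
    bad <- FALSE
    for (o in outside_pos) {
      d <- if (o < i) starts[i] - ends[o] - 1L
           else starts[o] - ends[j] - 1L
      if (d <= flank_gap_min) { bad <- TRUE; break }
    }
    if (!bad) return(TRUE)
  }
  FALSE
}

#' Mine conserved bicistronic gene patterns from genomic contexts
#'
#' Screens the conserved genomic windows around target proteins for gene
#' patterns with toxin-antitoxin characteristics. Candidate patterns are
#' contiguous runs of 2 to `max_len` gene families, in fixed order, that
#' include the family of a target gene. For each candidate:
#'
#' * `freq` — the fraction of contexts with a valid occurrence (order
#'   preserved, internal intergenic gaps at most `gap_max` nt, one strand);
#' * `best_extension_freq` — the largest such frequency over all
#'   one-gene left/right extensions of the pattern;
#' * `score = freq - best_extension_freq` — a pattern scores highly when
#'   it is frequent *as is* and no longer variant is comparably frequent;
#' * `supporting_contexts` / `species_support` — the contexts (and their
#'   distinct species) where a valid occurrence additionally has clean
#'   flanks: every conserved family outside the pattern lies more than
#'   `flank_gap_min` nt away, restricting neighborhood conservation to the
#'   pattern itself.
#'
#' Candidates must have at least one clean-flank supporting context and at
#' least `min_species` distinct supporting species. Results are ranked by
#' score, then frequency, then shorter length, then label order. An empty
#' result means no pattern satisfied the criteria — not an error.
#'
#' @param neighborhoods Neighborhood tibble; passed through
#'   [species_gate()] first, so fewer than `min_species` species yields an
#'   empty result.
#' @param gap_max Maximum internal intergenic distance (nt).
#' @param flank_gap_min Conserved genes outside the pattern must lie
#'   strictly more than this many nt away.
#' @param presence_min Presence fraction defining "conserved" families,
#'   see [conservation_profile()].
#' @param min_species Minimum distinct supporting species.
#' @param max_len Maximum pattern length in genes.
#' @param same_strand Require pattern genes on one strand.
#' @return A tibble ranked best-first with columns `families`
#'   (comma-joined), `length`, `freq`, `best_extension_freq`, `score`,
#'   `n_support`, `species_support` and `supporting_contexts`
#'   (list-column of context ids).
#' @export
mine_patterns <- function(neighborhoods, gap_max = 100, flank_gap_min = 100,
                          presence_min = 0.5, min_species = 6,
                          max_len = 4, same_strand = TRUE) {
  empty <- tibble(families = character(0), length = integer(0),
                  freq = numeric(0), best_extension_freq = numeric(0),
                  score = numeric(0), n_support = integer(0),
                  species_support = integer(0),
                  supporting_contexts = list())
  gated <- species_gate(neighborhoods, min_species)
  if (nrow(gated) == 0) return(empty)
  ctxs <- lapply(split(gated, gated$context_id), function(g) {
    g[order(g$order_index), , drop = FALSE]
  })
  n_ctx <- length(ctxs)
  conserved <- conservation_profile(gated, presence_min)
  target_families <- unique(gated$family[gated$is_target])

  # one enumeration pass per context: every *valid* run (internal gaps and
  # strand criteria already satisfied) of length 2..max_len+1; tuples that
  # never occur validly have frequency 0 and need no further handling
  wins <- lapply(ctxs, function(g) {
    n <- nrow(g)
    key <- character(0); first <- integer(0); last <- integer(0)
    if (n >= 2) {
      gap_ok <- g$start[-1] - g$end[-n] - 1L <= gap_max
      for (len in 2:min(max_len + 1L, n)) {
        for (i in seq_len(n - len + 1)) {
          j <- i + len - 1L
          if (!all(gap_ok[i:(j - 1)])) next
          if (same_strand && any(g$strand[i:j] != g$strand[i])) next
          key <- c(key, paste(g$family[i:j], collapse = "\r"))
          first <- c(first, i); last <- c(last, j)
        }
      }
    }
    list(key = key, first = first, last = last)
  })
  occ_counts <- table(unlist(lapply(wins, function(w) unique(w$key))))
  if (length(occ_counts) == 0) return(empty)
  freq_of <- setNames(as.numeric(occ_counts) / n_ctx, names(occ_counts))
  tuples <- strsplit(names(freq_of), "\r", fixed = TRUE)

  is_candidate <- vapply(tuples, function(fam) {
    length(fam) <= max_len && any(fam %in% target_families)
  }, logical(1))

  rows <- purrr::map(tuples[is_candidate], function(fam) {
    key <- paste(fam, collapse = "\r")
    # supporting contexts: valid occurrence with clean conserved flanks
    supp <- vapply(seq_len(n_ctx), function(ci) {
      w <- wins[[ci]]
      hit <- which(w$key == key)
      if (length(hit) == 0) return(FALSE)
      g <- ctxs[[ci]]
      runs <- cbind(w$first[hit], w$last[hit])
      outside <- which(g$family %in% setdiff(conserved, fam))
      any_clean_run(runs, g$start, g$end, outside, flank_gap_min)
    }, logical(1))
    if (!any(supp)) return(NULL)
    supp_ctx <- names(ctxs)[supp]
    n_species <- length(unique(
      gated$species_id[gated$context_id %in% supp_ctx]))
    if (n_species < min_species) return(NULL)
    ext_keys <- names(freq_of)[vapply(tuples, function(other) {
      length(other) == length(fam) + 1 &&
        (identical(other[-1], fam) ||
           identical(other[-length(other)], fam))
    }, logical(1))]
    best_ext <- if (length(ext_keys) == 0) 0 else max(freq_of[ext_keys])
    tibble(families = paste(fam, collapse = ","),
           length = length(fam), freq = freq_of[[key]],
           best_extension_freq = best_ext,
           score = freq_of[[key]] - best_ext,
           n_support = sum(supp), species_support = n_species,
           supporting_contexts = list(supp_ctx))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, dplyr::desc(.data$score), dplyr::desc(.data$freq),
                 .data$length, .data$families)
}
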