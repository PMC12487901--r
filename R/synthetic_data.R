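#' Configuration for the synthetic-data generators
#'
#' One configuration object drives every generator. Each generator derives
#' its own random substream from `seed`, so changing the parameters of one
#' table never perturbs another, and identical configurations always yield
#' identical tables.
#'
#' Defaults emulate a RefSeq-scale viral protein catalogue at desk scale: the host mixture follows the observed domain
#' shares of viral protein hosts (79.9% bacteria, 15.4% eukaryota, 1.1%
#' archaea, remainder undefined), planted bicistrons have internal gaps
#' within the 100-nt operonic limit and decoy flanks beyond it, and 20
#' contexts over 8 species clear the 6-species screening gate.
#'
#' @param seed Integer master seed (keep below 2^31 - 16).
#' @param n_clusters,cluster_size_mean Number of protein clusters and their
#'   mean size (sizes are 1 + Poisson).
#' @param host_mixture Named probabilities over
#'   bacteria/archaea/eukaryota/undefined; must sum to 1.
#' @param minority_inject_rate Fraction of defined-host clusters that
#'   receive an injected minority domain sized just above or below the
#'   heterohost threshold.
#' @param n_queries Number of queries for the oligomeric-state hit tables.
#' @param hit_noise_sd Standard deviation of the TM-score noise.
#' @param n_contexts,n_species Genomic contexts and distinct species.
#' @param planted_pattern Family labels of the planted bicistron (length
#'   >= 2).
#' @param internal_gap_range,flank_gap_range Integer nucleotide ranges for
#'   intergenic gaps inside the planted pattern and between the pattern
#'   and its decoy flanks.
#' @param decoy_family_pool Size of the decoy family vocabulary; large
#'   enough that no decoy becomes conserved across contexts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 40, cluster_size_mean = 25,
                       host_mixture = c(bacteria = 0.799,
                                        eukaryota = 0.154,
                                        archaea = 0.011,
                                        undefined = 0.036),
                       minority_inject_rate = 0.3,
                       n_queries = 500, hit_noise_sd = 0.05,
                       n_contexts = 20, n_species = 8,
                       planted_pattern = c("fam_tox", "fam_antitox"),
                       internal_gap_range = c(0L, 100L),
                       flank_gap_range = c(101L, 400L),
                       decoy_family_pool = 30) {
  stopifnot(abs(sum(host_mixture) - 1) < 1e-9,
            all(names(host_mixture) %in% HOST_DOMAINS),
            minority_inject_rate >= 0, minority_inject_rate <= 1,
            length(planted_pattern) >= 2,
            internal_gap_range[1] <= internal_gap_range[2],
            flank_gap_range[1] <= flank_gap_range[2],
            hit_noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_clusters = n_clusters,
                 cluster_size_mean = cluster_size_mean,
                 host_mixture = host_mixture,
                 minority_inject_rate = minority_inject_rate,
                 n_queries = n_queries, hit_noise_sd = hit_noise_sd,
                 n_contexts = n_contexts, n_species = n_species,
                 planted_pattern = planted_pattern,
                 internal_gap_range = as.integer(internal_gap_range),
                 flank_gap_range = as.integer(flank_gap_range),
                 decoy_family_pool = decoy_family_pool),
            class = "sim_config")
}

# substream offsets: one per generator
SIM_STREAMS <- c(clusters = 3L, oligo = 7L, neighborhoods = 11L)

lineage_for <- function(domain, i) {
  switch(domain,
    bacteria = sprintf("Bacteria; SynthPhylum%02d; SynthClass", i %% 7),
    archaea = sprintf("Archaea; SynthPhylum%02d; SynthClass", i %% 7),
    eukaryota = sprintf("Eukaryota; SynthPhylum%02d; SynthClass", i %% 7),
    undefined = "Viruses; SynthViralFamily; Synthvirus")
}

#' Generate protein, host-map and cluster tables with known host labels
#'
#' Draws clusters whose dominant host domain follows the configured
#' mixture. A configured fraction of defined-host clusters receives an
#' injected minority domain sized exactly at the heterohost threshold
#' `max(3, ceiling(0.01 N))` (true heterohost) or one below it (true
#' monohost), so that the threshold rule is exercised on both sides.
#' Clusters whose dominant domain is undefined are realized half as taxids
#' absent from the host map and half as virus-infecting viruses.
#'
#' @param cfg A [sim_config()].
#' @return A list of tibbles: `proteins` (`protein_id`, `virus_taxid`),
#'   `host_map`, `members` (cluster membership) and `truth` (`cluster_id`,
#'   `kind`, `domains`).
#' @export
gen_cluster_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + SIM_STREAMS[["clusters"]], {
    proteins <- list(); host_map <- list(); members <- list(); truth <- list()
    taxid_next <- 100000L
    pid_next <- 1L
    domains <- names(cfg$host_mixture)
    for (ci in seq_len(cfg$n_clusters)) {
      cid <- sprintf("SC%04d", ci)
      n <- 1L + rpois(1, cfg$cluster_size_mean - 1)
      dominant <- sample(domains, 1, prob = cfg$host_mixture)
      threshold <- max(3L, as.integer(ceiling(0.01 * n)))
      member_domains <- rep(dominant, n)
      if (dominant == "undefined") {
        kind <- "undefined"; label_domains <- character(0)
      } else if (runif(1) < cfg$minority_inject_rate && n >= 2L) {
        minority <- sample(setdiff(DEFINED_DOMAINS, dominant), 1)
        go_hetero <- runif(1) < 0.5
        # minority must stay below the dominant count to keep the mode
        m_hi <- min(threshold, floor((n - 1) / 2))
        m <- if (go_hetero) m_hi else min(threshold - 1L, floor((n - 1) / 2))
        if (m >= 1L) member_domains[seq_len(m)] <- minority
        if (m >= threshold) {
          kind <- "hetero"; label_domains <- sort(c(dominant, minority))
        } else {
          kind <- "mono"; label_domains <- dominant
        }
      } else {
        kind <- "mono"; label_domains <- dominant
      }
      member_domains <- sample(member_domains)  # shuffle positions
      pids <- sprintf("VP%06d", pid_next:(pid_next + n - 1L))
      pid_next <- pid_next + n
      taxids <- taxid_next:(taxid_next + n - 1L)
      taxid_next <- taxid_next + n
      absent <- member_domains == "undefined" & (seq_len(n) %% 2 == 0)
      proteins[[ci]] <- tibble(protein_id = pids, virus_taxid = taxids)
      host_map[[ci]] <- tibble(
        virus_taxid = taxids[!absent],
        host_lineage = vapply(which(!absent), function(k) {
          lineage_for(member_domains[k], k)
        }, character(1)))
      members[[ci]] <- tibble(cluster_id = cid, protein_id = pids,
                              is_representative = seq_len(n) == 1L)
      truth[[ci]] <- tibble(cluster_id = cid, kind = kind,
                            domains = paste(label_domains, collapse = "+"))
    }
    list(proteins = dplyr::bind_rows(proteins),
         host_map = dplyr::bind_rows(host_map),
         members = dplyr::bind_rows(members),
         truth = dplyr::bind_rows(truth))
  })
}

OLIGO_STATE_POOL <- tibble::tibble(
  copies = c(1L, 2L, 3L, 4L, 1L, 1L),
  distinct_chains = c(1L, 1L, 1L, 1L, 2L, 3L))

#' Generate oligomeric-state hit tables with known true states
#'
#' Each query receives a true oligomeric state; hits to chains of that
#' state get TM-scores around 0.78 and decoy hits around 0.58 (both with
#' configured Gaussian noise, clamped to the valid range), plus a few
#' sub-threshold hits around 0.3, so the true state stochastically
#' dominates the TM-score-weighted vote.
#'
#' @param cfg A [sim_config()].
#' @return A list of tibbles: `hits` (m8 columns plus `alntmscore`,
#'   `qcov`, `tcov`), `annotations` (`pdb_chain_id`, `copies`,
#'   `distinct_chains`) and `truth` (`query`, `state`).
#' @export
gen_oligo_hits <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + SIM_STREAMS[["oligo"]], {
    pool <- OLIGO_STATE_POOL
    pool$state <- oligo_state_label(pool$copies, pool$distinct_chains)
    chains_per_state <- 8L
    annotations <- tibble(
      pdb_chain_id = sprintf("%s_%d",
                             rep(sprintf("pdb%02d", seq_len(nrow(pool))),
                                 each = chains_per_state),
                             rep(seq_len(chains_per_state), nrow(pool))),
      copies = rep(pool$copies, each = chains_per_state),
      distinct_chains = rep(pool$distinct_chains, each = chains_per_state))
    ann_state <- rep(pool$state, each = chains_per_state)

    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    rows <- purrr::map(seq_len(cfg$n_queries), function(qi) {
      qid <- sprintf("Q%05d", qi)
      true_state <- sample(pool$state, 1)
      t_idx <- sample(which(ann_state == true_state), 4, replace = TRUE)
      d_idx <- sample(which(ann_state != true_state), 3, replace = TRUE)
      n_low <- 2L
      l_idx <- sample(nrow(annotations), n_low, replace = TRUE)
      tm <- c(clamp(rnorm(4, 0.78, cfg$hit_noise_sd), 0.51, 1),
              clamp(rnorm(3, 0.58, cfg$hit_noise_sd), 0.50, 1),
              clamp(rnorm(n_low, 0.30, cfg$hit_noise_sd), 0, 0.49))
      idx <- c(t_idx, d_idx, l_idx)
      n <- length(idx)
      alnlen <- as.integer(round(runif(n, 80, 300)))
      tibble(query = qid, target = annotations$pdb_chain_id[idx],
             fident = round(clamp(rnorm(n, 0.35, 0.1), 0.05, 1), 3),
             alnlen = alnlen, mismatch = as.integer(round(alnlen * 0.5)),
             gapopen = as.integer(round(runif(n, 0, 10))),
             qstart = 1L, qend = alnlen, tstart = 1L, tend = alnlen,
             evalue = signif(10^runif(n, -20, -3), 3),
             bits = as.integer(round(runif(n, 50, 500))),
             alntmscore = round(tm, 4),
             qcov = round(clamp(rnorm(n, 0.8, 0.1), 0.1, 1), 3),
             tcov = round(clamp(rnorm(n, 0.8, 0.1), 0.1, 1), 3),
             true_state = true_state)
    })
    hits <- dplyr::bind_rows(rows)
    truth <- dplyr::distinct(tibble(query = hits$query,
                                    state = hits$true_state))
    hits$true_state <- NULL
    list(hits = hits, annotations = annotations, truth = truth)
  })
}

#' Generate genomic contexts with a planted bicistron
#'
#' Builds `n_contexts` genomic windows across `n_species` species. Every
#' context carries the planted pattern in order on the plus strand, with
#' internal gaps drawn from `internal_gap_range`, flanked on both sides by
#' decoy genes whose families are drawn per context from a large pool
#' (hence never conserved) at gaps drawn from `flank_gap_range`. The first
#' planted gene is the screening target.
#'
#' @param cfg A [sim_config()].
#' @param assert_recoverable When `TRUE`, error if the configured gap
#'   ranges are inconsistent with recovering the planted pattern under the
#'   default mining criteria (internal gaps above 100 nt or flank gaps not
#'   above 100 nt). Leave `FALSE` to generate adversarial variants.
#' @return A list with `neighborhoods` (tibble, see
#'   [read_neighborhoods()]) and `truth_pattern` (the planted family
#'   labels).
#' @export
gen_neighborhoods <- function(cfg, assert_recoverable = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (assert_recoverable &&
      (cfg$internal_gap_range[2] > 100 || cfg$flank_gap_range[1] <= 100)) {
    stop("gap ranges inconsistent with planted-pattern recovery: need ",
         "internal gaps <= 100 nt and flank gaps > 100 nt", call. = FALSE)
  }
  withr::with_seed(cfg$seed + SIM_STREAMS[["neighborhoods"]], {
    rgap <- function(range) {
      as.integer(round(runif(1, range[1], range[2])))
    }
    decoys <- sprintf("dcy_%03d", seq_len(cfg$decoy_family_pool))
    species <- sprintf("sp_%02d", ((seq_len(cfg$n_contexts) - 1) %%
                                     cfg$n_species) + 1L)
    rows <- purrr::map(seq_len(cfg$n_contexts), function(ci) {
      n_left <- sample(1:3, 1); n_right <- sample(1:3, 1)
      fams <- c(sample(decoys, n_left), cfg$planted_pattern,
                sample(decoys, n_right))
      n <- length(fams)
      in_pattern <- seq_len(n) > n_left &
        seq_len(n) <= n_left + length(cfg$planted_pattern)
      # pattern genes on +; decoys on random strands
      strand <- ifelse(in_pattern, "+", sample(c("+", "-"), n,
                                               replace = TRUE))
      lens <- as.integer(round(runif(n, 300, 900)))
      start <- integer(n); end <- integer(n)
      pos <- 1L
      for (k in seq_len(n)) {
        if (k > 1) {
          internal <- in_pattern[k] && in_pattern[k - 1]
          gap <- rgap(if (internal) cfg$internal_gap_range
                      else cfg$flank_gap_range)
          pos <- end[k - 1] + gap + 1L
        }
        start[k] <- pos; end[k] <- pos + lens[k] - 1L
      }
      tibble(context_id = sprintf("ctx_%03d", ci),
             species_id = species[ci],
             order_index = seq_len(n) - 1L,
             start = start, end = end, strand = strand, family = fams,
             is_target = seq_len(n) == n_left + 1L)
    })
    list(neighborhoods = dplyr::bind_rows(rows),
         truth_pattern = cfg$planted_pattern)
  })
}
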