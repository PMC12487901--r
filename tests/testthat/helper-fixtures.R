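# Small in-code fixture builders shared across test files.

# Long (protein_id, host_domain) table plus member ids realizing a
# composition vector of per-domain counts.
make_composition <- function(bacteria = 0, archaea = 0, eukaryota = 0,
                             undefined = 0) {
  domains <- rep(c("bacteria", "archaea", "eukaryota", "undefined"),
                 times = c(bacteria, archaea, eukaryota, undefined))
  ids <- sprintf("p%03d", seq_along(domains))
  list(member_ids = ids,
       protein_hosts = tibble::tibble(protein_id = ids,
                                      host_domain = domains))
}

# One genomic context from parallel vectors; coordinates laid out from
# gene lengths and intergenic gaps (gap[i] precedes gene i+1).
make_context <- function(context_id, species_id, families, lengths, gaps,
                         strands = NULL, targets = NULL) {
  n <- length(families)
  strands <- strands %||% rep("+", n)
  targets <- targets %||% c(TRUE, rep(FALSE, n - 1))
  start <- integer(n); end <- integer(n); pos <- 1L
  for (k in seq_len(n)) {
    if (k > 1) pos <- end[k - 1] + gaps[k - 1] + 1L
    start[k] <- pos; end[k] <- pos + lengths[k] - 1L
  }
  tibble::tibble(context_id = context_id, species_id = species_id,
                 order_index = seq_len(n) - 1L, start = start, end = end,
                 strand = strands, family = families, is_target = targets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small neighborhood instance for miner cross-checks.
random_neighborhoods <- function(n_ctx, max_genes = 8, n_fams = 5,
                                 n_species = 4) {
  fams_pool <- sprintf("f%d", seq_len(n_fams))
  target_fam <- sample(fams_pool, 1)
  rows <- lapply(seq_len(n_ctx), function(ci) {
    n <- sample(2:max_genes, 1)
    families <- sample(fams_pool, n, replace = TRUE)
    make_context(sprintf("c%02d", ci),
                 sprintf("s%d", sample(n_species, 1)),
                 families,
                 lengths = sample(200:600, n, replace = TRUE),
                 gaps = sample(0:200, max(n - 1, 0), replace = TRUE),
                 strands = sample(c("+", "-"), n, replace = TRUE),
                 targets = families == target_fam)
  })
  dplyr::bind_rows(rows)
}

# Random hit table against a random annotation set for oligostate checks.
random_oligo_instance <- function(n_hits = 12, n_chains = 10) {
  ann <- tibble::tibble(
    pdb_chain_id = sprintf("ch%02d", seq_len(n_chains)),
    copies = sample(1:4, n_chains, replace = TRUE),
    distinct_chains = sample(1:3, n_chains, replace = TRUE))
  hits <- tibble::tibble(
    query = "q1",
    target = sample(ann$pdb_chain_id, n_hits, replace = TRUE),
    alntmscore = round(runif(n_hits, 0, 1), 3))
  list(hits = hits, annotations = ann)
}
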