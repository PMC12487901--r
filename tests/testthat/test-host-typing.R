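test_that("assign_host parses superkingdoms and handles unresolvable viruses", {
  host_map <- tibble::tibble(
    virus_taxid = c(10L, 20L, 20L, 30L, 40L),
    host_lineage = c("Bacteria; Pseudomonadota; Gammaproteobacteria",
                     "Eukaryota; Chordata; Mammalia",
                     "Bacteria; Bacillota; Bacilli",
                     "Viruses; Mimiviridae; Mimivirus",
                     "Archaea; Euryarchaeota; Methanococci"))
  expect_setequal(assign_host(10L, host_map), "bacteria")
  expect_setequal(assign_host(40L, host_map), "archaea")
  # multiple recorded hosts contribute one domain each
  expect_setequal(assign_host(20L, host_map), c("bacteria", "eukaryota"))
  # absent taxid, missing taxid, virus-infecting virus
  expect_identical(assign_host(999L, host_map), "undefined")
  expect_identical(assign_host(NA_integer_, host_map), "undefined")
  expect_identical(assign_host(30L, host_map), "undefined")
})

test_that("curation overrides take precedence, case-insensitively", {
  host_map <- tibble::tibble(virus_taxid = 7L,
                             host_lineage = "Eukaryota; Chordata")
  overrides <- tibble::tibble(lineage = "Leviviridae sp.",
                              domain = "bacteria")
  expect_identical(
    assign_host(7L, host_map, overrides, virus_lineage = "leviviridae SP."),
    "bacteria")
  # no lineage match: mapping rules apply
  expect_identical(
    assign_host(7L, host_map, overrides, virus_lineage = "Other virus"),
    "eukaryota")
})

test_that("malformed lineages warn but do not abort the record", {
  host_map <- tibble::tibble(
    virus_taxid = c(1L, 1L),
    host_lineage = c("???unknown rank", "Bacteria; Bacillota"))
  expect_warning(res <- assign_host(1L, host_map), "malformed")
  expect_identical(res, "bacteria")
})

test_that("cluster host typing applies the minority-count threshold", {
  cases <- list(
    list(counts = c(100, 0, 0, 0), kind = "mono", domains = "bacteria"),
    # minority below max(3, ceiling(0.01 * 200)) = 3
    list(counts = c(198, 0, 2, 0), kind = "mono", domains = "bacteria"),
    # minority at max(3, ceiling(0.01 * 400)) = 4
    list(counts = c(396, 0, 4, 0), kind = "hetero",
         domains = c("bacteria", "eukaryota")),
    list(counts = c(0, 0, 0, 5), kind = "undefined", domains = character(0)),
    list(counts = c(5, 3, 3, 0), kind = "hetero",
         domains = c("archaea", "bacteria", "eukaryota")))
  for (cs in cases) {
    comp <- make_composition(cs$counts[1], cs$counts[2], cs$counts[3],
                             cs$counts[4])
    lab <- classify_cluster_host_type(comp$member_ids, comp$protein_hosts)
    expect_identical(lab$kind, cs$kind)
    expect_identical(lab$domains, cs$domains)
  }
})

test_that("classification errors on empty clusters and unresolvable members", {
  comp <- make_composition(bacteria = 2)
  expect_error(classify_cluster_host_type(character(0), comp$protein_hosts),
               "empty")
  expect_error(classify_cluster_host_type(c("p001", "ghost"),
                                          comp$protein_hosts),
               "ghost")
})

test_that("classification is invariant to member order", {
  comp <- make_composition(bacteria = 10, eukaryota = 4, undefined = 2)
  set.seed(42)
  base <- classify_cluster_host_type(comp$member_ids, comp$protein_hosts)
  for (i in 1:5) {
    perm <- classify_cluster_host_type(sample(comp$member_ids),
                                       comp$protein_hosts)
    expect_identical(perm, base)
  }
})

test_that("adding members of a qualifying domain never removes it", {
  set.seed(7)
  for (i in 1:50) {
    counts <- c(bacteria = sample(0:20, 1), archaea = sample(0:20, 1),
                eukaryota = sample(0:20, 1))
    n <- sum(counts) + sample(0:5, 1)
    if (sum(counts) == 0) next
    lab <- host_type_from_counts(counts, n)
    for (d in lab$domains) {
      grown <- counts
      grown[d] <- grown[d] + sample(1:10, 1)
      lab2 <- host_type_from_counts(grown, n + grown[d] - counts[d])
      expect_true(d %in% lab2$domains)
    }
  }
})

test_that("host_type_from_counts matches the brute-force rule evaluator", {
  # spot-check here; the exhaustive sweep runs in the acceptance suite
  set.seed(11)
  for (i in 1:200) {
    v <- sample(0:15, 4, replace = TRUE)
    if (sum(v) == 0) next
    got <- host_type_from_counts(
      c(bacteria = v[1], archaea = v[2], eukaryota = v[3]), sum(v))
    want <- oracle_host_type(v[1], v[2], v[3], v[4])
    expect_identical(got$kind, want$kind)
    expect_identical(got$domains, unname(want$domains))
  }
})

test_that("host_distribution counts clusters and protein fractions", {
  members <- tibble::tibble(
    cluster_id = rep(c("C1", "C2", "C3"), times = c(4, 3, 3)),
    protein_id = sprintf("p%03d", 1:10),
    is_representative = rep(c(TRUE, FALSE), times = c(1, 3)) |>
      c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE) |> head(10))
  hosts <- tibble::tibble(
    protein_id = sprintf("p%03d", 1:10),
    host_domain = c(rep("bacteria", 4), rep("bacteria", 3),
                    c("bacteria", "eukaryota", "eukaryota")))
  labels <- classify_clusters(members, hosts, min_count = 1)
  dist <- host_distribution(labels, members, hosts)
  counts <- dist$cluster_counts
  expect_equal(counts$n[counts$kind == "mono"], c(2))
  expect_equal(counts$n[counts$kind == "hetero"], c(1))
  expect_equal(dist$hetero_protein_fraction, 0.3)
  # all-mono case has zero heterohost protein fraction
  labels2 <- classify_clusters(members, hosts)  # default min_count=3: mono
  dist2 <- host_distribution(labels2, members, hosts)
  expect_equal(dist2$hetero_protein_fraction, 0)
  # protein-level table rows sum to protein-domain pairs
  expect_equal(sum(dist$protein_table$n), nrow(hosts))
})

test_that("multi-domain proteins count toward each of their domains", {
  members <- tibble::tibble(cluster_id = "C1",
                            protein_id = c("p1", "p2", "p3", "p4"),
                            is_representative = c(TRUE, FALSE, FALSE, FALSE))
  hosts <- tibble::tibble(
    protein_id = c("p1", "p1", "p2", "p3", "p4"),
    host_domain = c("bacteria", "eukaryota", "bacteria", "bacteria",
                    "eukaryota"))
  lab <- classify_cluster_host_type(members$protein_id, hosts,
                                    min_count = 2)
  expect_identical(lab$kind, "hetero")
  expect_identical(lab$domains, c("bacteria", "eukaryota"))
})
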