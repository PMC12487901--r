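# Independent brute-force evaluators used to cross-check the package
# implementations. Deliberately written in plain base R, separate from the
# package code paths.

# Host-type label directly from the minority-count rule, for a composition
# vector of (bacteria, archaea, eukaryota, undefined) member counts.
oracle_host_type <- function(b, a, e, u, min_count = 3, min_fraction = 0.01) {
  n_total <- b + a + e + u
  counts <- c(bacteria = b, archaea = a, eukaryota = e)
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(list(kind = "undefined",
                                       domains = character(0)))
  threshold <- max(min_count, ceiling(min_fraction * n_total))
  qualifying <- character(0)
  for (d in names(counts)) {
    if (counts[[d]] == max(counts) || counts[[d]] >= threshold) {
      qualifying <- c(qualifying, d)
    }
  }
  if (length(qualifying) >= 2) {
    list(kind = "hetero", domains = sort(qualifying))
  } else {
    list(kind = "mono", domains = qualifying)
  }
}

# Weighted-vote oligomeric state by a plain groupby-sum-argmax.
oracle_infer_state <- function(hits, annotations, tm_min = 0.5) {
  kept <- hits[hits$alntmscore >= tm_min, , drop = FALSE]
  i <- match(kept$target, annotations$pdb_chain_id)
  kept <- kept[!is.na(i), , drop = FALSE]
  i <- i[!is.na(i)]
  if (nrow(kept) == 0) return(NA_character_)
  state <- oligo_state_label(annotations$copies[i],
                             annotations$distinct_chains[i])
  agg <- aggregate(list(w = kept$alntmscore, n = rep(1, nrow(kept))),
                   by = list(state = state), FUN = sum)
  agg <- agg[order(-agg$w, -agg$n, agg$state), ]
  agg$state[1]
}

# Direct-rule pattern miner: plain nested loops over tuples and contexts.
oracle_mine_patterns <- function(nbh, gap_max = 100, flank_gap_min = 100,
                                 presence_min = 0.5, min_species = 6,
                                 max_len = 4, same_strand = TRUE) {
  empty <- data.frame(families = character(0), freq = numeric(0),
                      best_extension_freq = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(unique(nbh$species_id)) < min_species) return(empty)
  ctxs <- lapply(split(nbh, nbh$context_id),
                 function(g) g[order(g$order_index), ])
  n_ctx <- length(ctxs)

  fam_presence <- sapply(unique(nbh$family), function(f) {
    sum(sapply(ctxs, function(g) f %in% g$family))
  })
  conserved <- names(fam_presence)[fam_presence / n_ctx >= presence_min]
  targets <- unique(nbh$family[nbh$is_target])

  occs <- function(g, fam) {
    res <- list()
    len <- length(fam)
    if (nrow(g) < len) return(res)
    for (i in 1:(nrow(g) - len + 1)) {
      j <- i + len - 1
      ok <- all(g$family[i:j] == fam)
      if (ok && len > 1) {
        for (k in i:(j - 1)) {
          if (g$start[k + 1] - g$end[k] - 1 > gap_max) ok <- FALSE
        }
      }
      if (ok && same_strand && length(unique(g$strand[i:j])) > 1) ok <- FALSE
      if (ok) res[[length(res) + 1]] <- c(i, j)
    }
    res
  }

  all_tuples <- list()
  for (g in ctxs) {
    if (nrow(g) < 2) next
    for (len in 2:min(max_len + 1, nrow(g))) {
      for (i in 1:(nrow(g) - len + 1)) {
        all_tuples[[paste(g$family[i:(i + len - 1)], collapse = "\r")]] <- TRUE
      }
    }
  }
  tuples <- lapply(names(all_tuples), function(k) strsplit(k, "\r")[[1]])
  freq <- sapply(tuples, function(fam) {
    mean(sapply(ctxs, function(g) length(occs(g, fam)) > 0))
  })
  keys <- sapply(tuples, paste, collapse = "\r")
  names(freq) <- keys

  rows <- list()
  for (fam in tuples) {
    if (length(fam) > max_len || !any(fam %in% targets)) next
    key <- paste(fam, collapse = "\r")
    if (freq[[key]] == 0) next
    supp <- sapply(ctxs, function(g) {
      for (oc in occs(g, fam)) {
        clean <- TRUE
        for (o in seq_len(nrow(g))) {
          if (o >= oc[1] && o <= oc[2]) next
          if (!(g$family[o] %in% conserved)) next
          if (g$family[o] %in% fam) next
          d <- if (o < oc[1]) g$start[oc[1]] - g$end[o] - 1
               else g$start[o] - g$end[oc[2]] - 1
          if (d <= flank_gap_min) clean <- FALSE
        }
        if (clean) return(TRUE)
      }
      FALSE
    })
    if (!any(supp)) next
    sp <- unique(nbh$species_id[nbh$context_id %in% names(ctxs)[supp]])
    if (length(sp) < min_species) next
    ext <- 0
    for (other in tuples) {
      if (length(other) != length(fam) + 1) next
      if (all(other[-1] == fam) || all(other[-length(other)] == fam)) {
        ext <- max(ext, freq[[paste(other, collapse = "\r")]])
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      families = paste(fam, collapse = ","), freq = freq[[key]],
      best_extension_freq = ext, score = freq[[key]] - ext,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  len <- lengths(strsplit(out$families, ","))
  out[order(-out$score, -out$freq, len, out$families), , drop = FALSE]
}
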