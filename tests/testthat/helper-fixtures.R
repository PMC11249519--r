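# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# -- tiny hand-built samples --------------------------------------------------

make_sample <- function(sample_id, label, material, rows,
                        total_fragments = 1e6) {
  # rows: list of c(region, n_cpgs, n_methylated) triples
  df <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(region_id = r[[1L]], n_cpgs = as.integer(r[[2L]]),
                 n_methylated = as.integer(r[[3L]]), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(region_id = character(), n_cpgs = integer(),
               n_methylated = integer(), stringsAsFactors = FALSE)
  }
  sample_fragments(sample_id, label, material, total_fragments, df)
}

# fragments at given alpha values using 20 CpGs (alpha on a 0.05 grid)
alpha_frags <- function(region, alphas) {
  lapply(alphas, function(a) list(region, 20L, as.integer(round(a * 20))))
}

# small cached synthetic worlds (built once per test run)
.world_cache <- new.env(parent = emptyenv())
cached_world <- function(key, builder) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- builder()
  .world_cache[[key]]
}

small_world <- function() {
  cached_world("small", function() {
    w <- synthetic_discovery_world(seed = 42, n_regions = 1500,
                                   n_per_cell = 15, n_tissue = 12,
                                   n_background = 12)
    w$markers <- discover_markers(w$luad, w$lusc, w$background, k = 15)
    w
  })
}

# -- independent oracles ------------------------------------------------------

# textbook Benjamini-Hochberg step-up: adj p_(i) = min_{j >= i} m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj_sorted, 1)[order(o)]
}

# brute-force pairwise Mann-Whitney AUC
auc_oracle <- function(scores, positive) {
  xs <- scores[positive]; ys <- scores[!positive]
  tot <- 0
  for (x in xs) for (y in ys) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(xs) * length(ys))
}

# grid brute force for the threshold scan (101-point grid).
# samples: list of numeric alpha vectors; returns NULL or
# list(threshold, n_target, n_other)
scan_oracle <- function(target_alphas, other_alphas, direction,
                        grid = seq(0, 1, by = 0.01)) {
  # epsilon absorbs binary-representation noise between grid values
  # (k * 0.01) and fragment alphas (k / n_cpgs)
  eps <- 1e-9
  qualify <- function(alphas, t) {
    if (direction == "hypo") any(alphas <= t + eps) else any(alphas >= t - eps)
  }
  best <- NULL
  for (t in grid) {
    nt <- sum(vapply(target_alphas, qualify, logical(1L), t))
    no <- sum(vapply(other_alphas, qualify, logical(1L), t))
    if (no < 2L && nt >= 1L) {
      better <- is.null(best) || nt > best$n_target ||
        (nt == best$n_target &&
           ((direction == "hypo" && t < best$threshold) ||
            (direction == "hyper" && t > best$threshold)))
      if (better) best <- list(threshold = t, n_target = nt, n_other = no)
    }
  }
  best
}

# write a FASTA with CCGG planted at given 1-based positions
write_toy_fasta <- function(chrom_cuts, chrom_lens, path = tempfile(fileext = ".fa")) {
  lines <- character()
  for (i in seq_along(chrom_cuts)) {
    s <- rep("A", chrom_lens[[i]])
    for (p in chrom_cuts[[i]]) s[p:(p + 3L)] <- c("C", "C", "G", "G")
    lines <- c(lines, paste0(">chr", i), paste(s, collapse = ""))
  }
  writeLines(lines, path)
  path
}
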