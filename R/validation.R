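# Marker validation: fold-change reproducibility in an independent
# fragment cohort, 450K probe-to-region differential testing with BH
# correction, and promoter-overlap gene association with an empirical
# differential-expression p value against random gene sets.
#
# Note on the expression test: differential expression is assessed with
# a plain two-sample t test on ln(TPM + 1) followed by BH, not with a
# moderated (empirical-Bayes) statistic.

#' Fold-change reproducibility of markers in an independent cohort
#'
#' Per marker, the mean depth-normalized qualifying-read count in the
#' target class is compared with the other class (both plus a
#' pseudocount); the marker reproduces when the ratio exceeds
#' `fc_threshold` in its direction of enrichment.
#'
#' @param markers marker data.frame from [discover_markers()].
#' @param cohort independent tissue cohort (list of [sample_fragments()])
#'   containing both LUAD and LUSC samples.
#' @param fc_threshold fold-change cutoff (default 1.5, strict `>`).
#' @param pseudocount added to both means (default 0.5).
#' @param min_cpgs per-fragment CpG minimum (default 3).
#' @return list `per_marker` (data.frame with `fold_change`,
#'   `consistent`) and `fraction_reproduced`.
#' @export
fold_change_reproducibility <- function(markers, cohort, fc_threshold = 1.5,
                                        pseudocount = 0.5, min_cpgs = 3L) {
  labs <- cohort_labels(cohort)
  if (!all(c("LUAD", "LUSC") %in% labs)) stop("cohort must contain both classes")
  totals <- vapply(cohort, `[[`, numeric(1L), "total_fragments")
  counts <- marker_count_matrix(cohort, markers, min_cpgs = min_cpgs)
  norm <- sweep(counts, 2L, totals, function(c, t) 1e9 * c / t)
  labs <- unname(labs)
  mean_by <- function(cls) rowMeans(norm[, labs == cls, drop = FALSE])
  m_luad <- mean_by("LUAD"); m_lusc <- mean_by("LUSC")
  tgt <- ifelse(markers$target_class == "LUAD", m_luad, m_lusc)
  oth <- ifelse(markers$target_class == "LUAD", m_lusc, m_luad)
  fc <- (tgt + pseudocount) / (oth + pseudocount)
  consistent <- fc > fc_threshold
  list(per_marker = data.frame(region_id = markers$region_id,
                               target_class = markers$target_class,
                               direction = markers$direction,
                               fold_change = fc, consistent = consistent,
                               stringsAsFactors = FALSE),
       fraction_reproduced = mean(consistent))
}

#' Assign 450K probes to enriched regions
#'
#' A probe is assigned to the region whose half-open interval contains
#' its CpG coordinate; probes outside all regions stay unassigned.
#'
#' @param probes data.frame `probe_id`, `chrom`, `pos` (0-based).
#' @param regions a [region_catalog()].
#' @return data.frame `probe_id`, `region_id` (NA when unassigned).
#' @export
map_probes_to_regions <- function(probes, regions) {
  out <- data.frame(probe_id = probes$probe_id,
                    region_id = NA_character_, stringsAsFactors = FALSE)
  if (!nrow(probes) || !nrow(regions)) return(out)
  pg <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$pos + 1L, width = 1L))
  rg <- catalog_granges(regions)
  hits <- GenomicRanges::findOverlaps(pg, rg, select = "first")
  out$region_id <- regions$region_id[hits]
  out
}

#' Average probe betas per region
#'
#' The methylation level of a region is approximated by the unweighted
#' mean beta of its assigned probes; regions without probes are omitted.
#'
#' @param beta a [beta_matrix()].
#' @param assignment data.frame from [map_probes_to_regions()].
#' @return region x sample numeric matrix.
#' @export
region_beta <- function(beta, assignment) {
  keep <- !is.na(assignment$region_id) &
    assignment$probe_id %in% rownames(beta$values)
  a <- assignment[keep, , drop = FALSE]
  if (!nrow(a)) return(matrix(numeric(), 0L, ncol(beta$values)))
  v <- beta$values[a$probe_id, , drop = FALSE]
  g <- factor(a$region_id, levels = unique(a$region_id))
  out <- rowsum(v, g) / as.vector(table(g))
  out[order(rownames(out)), , drop = FALSE]
}

# vectorised two-sided equal-variance two-sample t test per row;
# rows with zero variance in both groups get p = 1 by convention
row_t_test <- function(m, group1, group2) {
  x <- m[, group1, drop = FALSE]; y <- m[, group2, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per class")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  t[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(t = t, p = p, mean_diff = m1 - m2)
}

#' Differential 450K test of markers on region-averaged betas
#'
#' Two-sided equal-variance Student t test per marker region (LUAD vs
#' LUSC), Benjamini-Hochberg correction across tested markers; a marker
#' is consistent when its adjusted p is below `alpha` and the sign of
#' the LUAD-LUSC beta difference matches the marker's class and
#' direction (e.g. a LUAD-hypo marker expects lower beta in LUAD).
#'
#' @param rb region x sample beta matrix from [region_beta()].
#' @param labels named character vector (sample -> `"LUAD"`/`"LUSC"`)
#'   covering the columns of `rb`.
#' @param markers marker data.frame; only markers present in `rb` are
#'   tested.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return list `per_marker` (data.frame `region_id`, `t`, `p`,
#'   `p_adj`, `consistent`) and `fraction_significant`.
#' @export
differential_test_450k <- function(rb, labels, markers, alpha = 0.05) {
  labels <- labels[colnames(rb)]
  tested <- markers[markers$region_id %in% rownames(rb), , drop = FALSE]
  if (!nrow(tested)) {
    return(list(per_marker = data.frame(), fraction_significant = NA_real_))
  }
  m <- rb[tested$region_id, , drop = FALSE]
  tt <- row_t_test(m, which(labels == "LUAD"), which(labels == "LUSC"))
  p_adj <- stats::p.adjust(tt$p, method = "BH")
  expected_sign <- ifelse(tested$direction == "hypo", -1, 1) *
    ifelse(tested$target_class == "LUAD", 1, -1)
  consistent <- p_adj < alpha & sign(tt$mean_diff) == expected_sign
  list(per_marker = data.frame(region_id = tested$region_id, t = tt$t,
                               p = tt$p, p_adj = p_adj,
                               direction = tested$direction,
                               target_class = tested$target_class,
                               consistent = consistent,
                               stringsAsFactors = FALSE),
       fraction_significant = mean(consistent))
}

#' Associate genes with markers via promoter overlap
#'
#' A gene is marker-associated when the overlap between its promoter and
#' the marker exceeds `min_overlap` of the marker's length (strict `>`;
#' the marker is the denominator because promoters are typically much
#' longer than the ~117 bp regions). Many-to-many associations are
#' allowed.
#'
#' @param markers marker data.frame with `region_id`.
#' @param regions a [region_catalog()] supplying marker coordinates.
#' @param promoters data.frame `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_overlap overlap fraction bound (default 0.5).
#' @return data.frame `region_id`, `gene_id`, `overlap_fraction`.
#' @export
associate_genes <- function(markers, regions, promoters, min_overlap = 0.5) {
  mk <- regions[regions$region_id %in% markers$region_id, , drop = FALSE]
  empty <- data.frame(region_id = character(), gene_id = character(),
                      overlap_fraction = double(), stringsAsFactors = FALSE)
  if (!nrow(mk) || !nrow(promoters)) return(empty)
  mg <- GenomicRanges::GRanges(mk$chrom, IRanges::IRanges(mk$start + 1L, mk$end))
  pg <- GenomicRanges::GRanges(promoters$chrom,
                               IRanges::IRanges(promoters$start + 1L,
                                                promoters$end))
  hits <- GenomicRanges::findOverlaps(mg, pg)
  if (!length(hits)) return(empty)
  ov <- GenomicRanges::pintersect(mg[S4Vectors::queryHits(hits)],
                                  pg[S4Vectors::subjectHits(hits)])
  frac <- GenomicRanges::width(ov) / GenomicRanges::width(mg[S4Vectors::queryHits(hits)])
  keep <- frac > min_overlap
  data.frame(region_id = mk$region_id[S4Vectors::queryHits(hits)][keep],
             gene_id = promoters$gene_id[S4Vectors::subjectHits(hits)][keep],
             overlap_fraction = frac[keep], stringsAsFactors = FALSE)
}

#' Empirical p value for marker-associated differential expression
#'
#' Differential expression per gene is a two-sided t test on
#' `ln(TPM + 1)` with BH correction across all matrix genes (adjusted
#' p < 0.05). The observed fraction of DE genes within `gene_set` is
#' ranked against `n_random` equally sized gene sets drawn uniformly
#' without replacement; the empirical p is the fraction of random sets
#' with a DE fraction at least as large (no +1 correction by default, so
#' an observed fraction beating every random set yields exactly 0).
#'
#' @param tpm a [tpm_matrix()] with labels.
#' @param labels named character vector (sample -> class) covering the
#'   matrix columns; defaults to `tpm$labels`.
#' @param gene_set non-empty character vector of genes in the matrix.
#' @param n_random number of random sets (default 500, must be > 0).
#' @param seed integer seed.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param plus_one use the conservative (+1)/(+1) estimator (default
#'   FALSE).
#' @return list `fraction_de`, `empirical_p`, `de_genes`.
#' @export
de_empirical_p <- function(tpm, labels = tpm$labels, gene_set, n_random = 500L,
                           seed = 1L, alpha = 0.05, plus_one = FALSE) {
  if (!length(gene_set)) stop("empty gene set")
  if (n_random < 1L) stop("n_random must be > 0")
  if (!all(gene_set %in% rownames(tpm$values))) {
    stop("gene_set contains genes absent from the matrix")
  }
  labels <- labels[colnames(tpm$values)]
  classes <- sort(unique(as.character(labels)))
  stopifnot(length(classes) == 2L)
  lv <- log(tpm$values + 1)
  tt <- row_t_test(lv, which(labels == classes[1L]),
                   which(labels == classes[2L]))
  p_adj <- stats::p.adjust(tt$p, method = "BH")
  de <- stats::setNames(p_adj < alpha, rownames(tpm$values))
  frac_obs <- mean(de[gene_set])
  all_genes <- rownames(tpm$values)
  set.seed(seed)
  frac_rand <- vapply(seq_len(n_random), function(i) {
    mean(de[sample(all_genes, length(gene_set))])
  }, numeric(1L))
  hits <- sum(frac_rand >= frac_obs)
  emp <- if (plus_one) (hits + 1) / (n_random + 1) else hits / n_random
  list(fraction_de = frac_obs, empirical_p = emp,
       de_genes = names(de)[de & names(de) %in% gene_set])
}
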