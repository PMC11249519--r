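# Fragment-based subtype marker discovery.
#
# For each region and direction the scan chooses an alpha threshold from
# the finite set of observed fragment alpha values: fragments with
# alpha <= alpha_hypo (resp. >= alpha_hyper) are hypo-(hyper-)methylated,
# a sample qualifies if it contains at least `min_fragments` such
# fragments, and a threshold is admissible when fewer than two
# other-class samples qualify (n_other < 2). Among admissible thresholds
# the scan maximises the number of qualifying target-class samples and
# breaks ties toward the more extreme threshold. Candidates are then
# filtered against noncancer plasma (dropped when more than 20% of
# background samples qualify) and the top-k per (class, direction) cell
# are kept, ties included, ranked by n_target.

#' Alpha value of a fragment
#'
#' The fraction of methylated CpGs among all CpGs on one sequenced DNA
#' fragment.
#'
#' @param n_cpgs CpG count on the fragment (>= 1).
#' @param n_methylated methylated-CpG count, in `[0, n_cpgs]`.
#' @return numeric in `[0,1]`, vectorised.
#' @export
alpha_value <- function(n_cpgs, n_methylated) {
  if (any(n_cpgs <= 0)) stop("n_cpgs must be >= 1")
  if (any(n_methylated < 0 | n_methylated > n_cpgs)) {
    stop("n_methylated outside [0, n_cpgs]")
  }
  n_methylated / n_cpgs
}

#' Does a sample qualify at a threshold?
#'
#' @param sample a [sample_fragments()].
#' @param region_id region to inspect.
#' @param threshold alpha threshold in `[0,1]`.
#' @param direction `"hypo"` (qualify on `alpha <= threshold`) or
#'   `"hyper"` (`alpha >= threshold`); comparisons are inclusive.
#' @param min_fragments minimum qualifying fragments (default 1).
#' @param min_cpgs fragments with fewer CpGs are ignored (default 3).
#' @return logical.
#' @export
sample_qualifies <- function(sample, region_id, threshold,
                             direction = c("hypo", "hyper"),
                             min_fragments = 1L, min_cpgs = 3L) {
  direction <- match.arg(direction)
  stopifnot(threshold >= 0, threshold <= 1)
  fr <- sample$fragments
  keep <- which(fr$region_id == region_id & fr$n_cpgs >= min_cpgs)
  if (!length(keep)) return(FALSE)
  a <- fr$n_methylated[keep] / fr$n_cpgs[keep]
  n_q <- if (direction == "hypo") sum(a <= threshold) else sum(a >= threshold)
  n_q >= min_fragments
}

# per-sample qualifying statistic: the alpha at which a sample starts to
# qualify. hypo: k-th smallest alpha (qualifies iff stat <= t);
# hyper: k-th largest (qualifies iff stat >= t).
sample_stat <- function(alphas, direction, min_fragments) {
  k <- min_fragments
  if (length(alphas) < k) return(NA_real_)
  if (direction == "hypo") sort(alphas, partial = k)[k]
  else -sort(-alphas, partial = k)[k]
}

#' Scan alpha thresholds for one region
#'
#' Evaluates every distinct observed fragment alpha in the region as a
#' candidate threshold and returns the admissible one (n_other < 2,
#' n_target >= 1) maximising n_target; ties break toward the more
#' extreme threshold (smaller for hypo, larger for hyper).
#'
#' @param region_id region identifier.
#' @param target_samples,other_samples lists of [sample_fragments()].
#' @param direction `"hypo"` or `"hyper"`.
#' @param min_fragments qualifying-fragment minimum per sample.
#' @param min_cpgs per-fragment CpG minimum.
#' @param max_other admissibility bound, `n_other < max_other` (default 2).
#' @return `NULL` if no admissible threshold, else a list
#'   `threshold`, `n_target`, `n_other`.
#' @export
scan_thresholds <- function(region_id, target_samples, other_samples,
                            direction = c("hypo", "hyper"),
                            min_fragments = 1L, min_cpgs = 3L,
                            max_other = 2L) {
  direction <- match.arg(direction)
  if (!length(target_samples) || !length(other_samples)) {
    stop("need at least one target and one other sample")
  }
  region_alphas <- function(s) {
    fr <- s$fragments
    keep <- which(fr$region_id == region_id & fr$n_cpgs >= min_cpgs)
    fr$n_methylated[keep] / fr$n_cpgs[keep]
  }
  t_alpha <- lapply(target_samples, region_alphas)
  o_alpha <- lapply(other_samples, region_alphas)
  cand <- sort(unique(unlist(c(t_alpha, o_alpha))))
  if (!length(cand)) return(NULL)
  t_stat <- vapply(t_alpha, sample_stat, numeric(1L), direction, min_fragments)
  o_stat <- vapply(o_alpha, sample_stat, numeric(1L), direction, min_fragments)
  nt <- no <- integer(length(cand))
  for (i in seq_along(cand)) {
    if (direction == "hypo") {
      nt[i] <- sum(t_stat <= cand[i], na.rm = TRUE)
      no[i] <- sum(o_stat <= cand[i], na.rm = TRUE)
    } else {
      nt[i] <- sum(t_stat >= cand[i], na.rm = TRUE)
      no[i] <- sum(o_stat >= cand[i], na.rm = TRUE)
    }
  }
  ok <- no < max_other & nt >= 1L
  if (!any(ok)) return(NULL)
  best_nt <- max(nt[ok])
  at_best <- which(ok & nt == best_nt)
  pick <- if (direction == "hypo") at_best[1L] else at_best[length(at_best)]
  list(threshold = cand[pick], n_target = nt[pick], n_other = no[pick])
}

#' Background-filter candidate markers against noncancer plasma
#'
#' For each candidate, `bg_fraction` is the fraction of noncancer plasma
#' samples containing qualifying fragments at the candidate's threshold
#' and direction; candidates with `bg_fraction > max_fraction` (strict)
#' are removed.
#'
#' @param candidates data.frame with columns `region_id`, `direction`,
#'   `threshold` (plus any others, preserved).
#' @param noncancer_plasma non-empty list of [sample_fragments()].
#' @param max_fraction removal bound (default 0.2).
#' @param min_fragments,min_cpgs as in [sample_qualifies()].
#' @return the retained rows with a `bg_fraction` column.
#' @export
apply_background_filter <- function(candidates, noncancer_plasma,
                                    max_fraction = 0.2, min_fragments = 1L,
                                    min_cpgs = 3L) {
  if (!length(noncancer_plasma)) stop("noncancer cohort is empty")
  if (!nrow(candidates)) {
    candidates$bg_fraction <- numeric(0)
    return(candidates)
  }
  at <- cohort_alpha_table(noncancer_plasma, min_cpgs = min_cpgs)
  n_bg <- length(noncancer_plasma)
  bg_fraction <- numeric(nrow(candidates))
  for (d in c("hypo", "hyper")) {
    rows <- which(candidates$direction == d)
    if (!length(rows)) next
    stats_dt <- cohort_stat_table(at[region_id %in% candidates$region_id[rows]],
                                  d, min_fragments)
    by_region <- split(stats_dt$stat, stats_dt$region_id)
    sgn <- if (d == "hypo") 1 else -1
    for (r in rows) {
      s <- by_region[[candidates$region_id[r]]]
      q <- if (is.null(s)) 0L
           else sum(s <= sgn * candidates$threshold[r], na.rm = TRUE)
      bg_fraction[r] <- q / n_bg
    }
  }
  candidates$bg_fraction <- bg_fraction
  candidates[candidates$bg_fraction <= max_fraction, , drop = FALSE]
}

#' Rank candidates and select the top k with ties
#'
#' Sorts one (class, direction) cell descending by `n_target` (secondary
#' key `region_id` for determinism) and keeps every candidate whose
#' `n_target` ties with the k-th value.
#'
#' @param candidates data.frame with `n_target` and `region_id`.
#' @param k selection size (default 2500).
#' @return the selected rows with a `rank` column.
#' @export
rank_and_select <- function(candidates, k = 2500L) {
  if (!nrow(candidates)) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  ord <- order(-candidates$n_target, candidates$region_id)
  candidates <- candidates[ord, , drop = FALSE]
  if (nrow(candidates) > k) {
    cutoff <- candidates$n_target[k]
    keep <- candidates$n_target >= cutoff
    candidates <- candidates[keep, , drop = FALSE]
  }
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

# per-sample qualifying statistics for every (region, sample) of a
# cohort alpha table, signed so that "qualifies at threshold t" is
# always "stat <= signed t" (sgn = +1 hypo, -1 hyper). min/max go
# through data.table's optimised grouped aggregation.
cohort_stat_table <- function(at, direction, min_fragments = 1L) {
  sgn <- if (direction == "hypo") 1 else -1
  if (!nrow(at)) {
    return(data.table::data.table(region_id = character(),
                                  sample_id = character(), stat = double()))
  }
  if (min_fragments == 1L) {
    if (direction == "hypo") {
      at[, .(stat = min(alpha)), by = .(region_id, sample_id)]
    } else {
      at[, .(stat = -max(alpha)), by = .(region_id, sample_id)]
    }
  } else {
    at[, .(stat = sgn * sample_stat(alpha, direction, min_fragments)),
       by = .(region_id, sample_id)][!is.na(stat)]
  }
}

# vectorised scan over all regions of one (target, other) cohort pair.
# Equivalent to calling scan_thresholds() per region with
# min_fragments = 1 semantics generalised to k-th order statistics.
scan_all_regions <- function(target_at, other_at, direction,
                             min_fragments = 1L, max_other = 2L,
                             target_stats = NULL, other_stats = NULL) {
  sgn <- if (direction == "hypo") 1 else -1
  ts <- if (is.null(target_stats)) {
    cohort_stat_table(target_at, direction, min_fragments)
  } else target_stats
  os <- if (is.null(other_stats)) {
    cohort_stat_table(other_at, direction, min_fragments)
  } else other_stats
  if (!nrow(ts)) return(NULL)
  # per region: o2 = max_other-th smallest signed other stat (Inf if fewer)
  o2 <- os[, .(o2 = if (.N >= max_other) sort(stat, partial = max_other)[max_other]
               else Inf), by = region_id]
  res <- merge(ts, o2, by = "region_id", all.x = TRUE)
  res[is.na(o2), o2 := Inf]
  # best signed threshold = largest target stat strictly below o2;
  # n_target = count of target stats <= it
  res <- res[stat < o2,
             .(stat_star = max(stat), n_target = .N, o2 = o2[1L]),
             by = region_id]
  if (!nrow(res)) return(NULL)
  no <- os[res, on = "region_id",
           .(n_other = sum(stat <= i.stat_star, na.rm = TRUE)),
           by = .EACHI][, n_other]
  data.frame(region_id = res$region_id,
             direction = direction,
             threshold = sgn * res$stat_star,
             n_target = res$n_target,
             n_other = no,
             stringsAsFactors = FALSE)
}

#' Discover subtype-specific methylation markers
#'
#' Runs the threshold scan per region for each of the four
#' (class, direction) cells — LUAD-hypo, LUAD-hyper, LUSC-hypo,
#' LUSC-hyper — background-filters against noncancer plasma and
#' rank-selects the top `k` per cell (ties included).
#'
#' @param luad_tissue,lusc_tissue,noncancer_plasma non-empty lists of
#'   [sample_fragments()].
#' @param k top-k per cell (default 2500).
#' @param min_fragments qualifying-fragment minimum per sample (default 1:
#'   a sample "contains" qualifying fragments).
#' @param min_cpgs per-fragment CpG minimum for alpha (default 3).
#' @param max_bg_fraction background-filter bound (default 0.2).
#' @return data.frame of markers: `region_id`, `target_class`,
#'   `direction`, `threshold`, `n_target`, `n_other`, `bg_fraction`,
#'   `rank`.
#' @export
discover_markers <- function(luad_tissue, lusc_tissue, noncancer_plasma,
                             k = 2500L, min_fragments = 1L, min_cpgs = 3L,
                             max_bg_fraction = 0.2) {
  if (!length(luad_tissue) || !length(lusc_tissue) || !length(noncancer_plasma)) {
    stop("all three cohorts must be non-empty")
  }
  luad_at <- cohort_alpha_table(luad_tissue, min_cpgs = min_cpgs)
  lusc_at <- cohort_alpha_table(lusc_tissue, min_cpgs = min_cpgs)
  stats <- list(
    LUAD = lapply(c(hypo = "hypo", hyper = "hyper"), function(d)
      cohort_stat_table(luad_at, d, min_fragments)),
    LUSC = lapply(c(hypo = "hypo", hyper = "hyper"), function(d)
      cohort_stat_table(lusc_at, d, min_fragments))
  )
  cells <- list(
    list(class = "LUAD", other = "LUSC", dir = "hypo"),
    list(class = "LUAD", other = "LUSC", dir = "hyper"),
    list(class = "LUSC", other = "LUAD", dir = "hypo"),
    list(class = "LUSC", other = "LUAD", dir = "hyper")
  )
  out <- lapply(cells, function(cell) {
    cand <- scan_all_regions(NULL, NULL, cell$dir,
                             min_fragments = min_fragments,
                             target_stats = stats[[cell$class]][[cell$dir]],
                             other_stats = stats[[cell$other]][[cell$dir]])
    if (is.null(cand) || !nrow(cand)) return(NULL)
    cand$target_class <- cell$class
    cand <- apply_background_filter(cand, noncancer_plasma,
                                    max_fraction = max_bg_fraction,
                                    min_fragments = min_fragments,
                                    min_cpgs = min_cpgs)
    if (!nrow(cand)) return(NULL)
    rank_and_select(cand, k = k)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(region_id = character(), direction = character(),
                      threshold = double(), n_target = integer(),
                      n_other = integer(), target_class = character(),
                      bg_fraction = double(), rank = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[, c("region_id", "target_class", "direction", "threshold",
          "n_target", "n_other", "bg_fraction", "rank")]
}

#' Write / read a marker table
#'
#' @param markers marker data.frame from [discover_markers()].
#' @param path TSV path.
#' @return `path` (write) or the marker data.frame (read).
#' @export
write_markers <- function(markers, path) {
  data.table::fwrite(markers, path, sep = "\t")
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"), stringsAsFactors = FALSE)
}
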