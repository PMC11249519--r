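# cfDNA feature construction: depth-normalized subtype-specific read
# counts per marker, size-constrained K-means merging of markers
# (45-55 per cluster, within each class+direction cell), and
# ln(mean normalized count + 1) features per merged marker.

#' Depth-normalize a qualifying-fragment count
#'
#' `10^9 * count / total_fragments`, where `total_fragments` is the
#' sample's genome-wide deduplicated mapped fragment count.
#'
#' @param count qualifying-fragment count at a marker (vectorised).
#' @param total_fragments genome-wide fragment count, > 0.
#' @return normalized count(s).
#' @export
normalize_count <- function(count, total_fragments) {
  if (any(total_fragments <= 0)) stop("total_fragments must be > 0")
  1e9 * count / total_fragments
}

#' Count a sample's subtype-specific reads at a marker
#'
#' Fragments in the marker's region with alpha at or beyond the marker
#' threshold in the marker direction (inclusive comparisons), among
#' fragments with at least `min_cpgs` CpGs.
#'
#' @param sample a [sample_fragments()].
#' @param marker one-row data.frame (or list) with `region_id`,
#'   `direction`, `threshold`.
#' @param min_cpgs per-fragment CpG minimum (default 3).
#' @return integer count.
#' @export
marker_read_count <- function(sample, marker, min_cpgs = 3L) {
  fr <- sample$fragments
  keep <- which(fr$region_id == marker$region_id & fr$n_cpgs >= min_cpgs)
  if (!length(keep)) return(0L)
  a <- fr$n_methylated[keep] / fr$n_cpgs[keep]
  if (marker$direction == "hypo") sum(a <= marker$threshold)
  else sum(a >= marker$threshold)
}

cohort_ids <- function(cohort) {
  unname(vapply(cohort, `[[`, character(1L), "sample_id"))
}

# counts for all markers x all samples of a cohort, as a markers x
# samples matrix (row order = marker rows)
marker_count_matrix <- function(cohort, markers, min_cpgs = 3L) {
  at <- cohort_alpha_table(cohort, min_cpgs = min_cpgs)
  samples <- cohort_ids(cohort)
  m <- matrix(0, nrow(markers), length(samples),
              dimnames = list(NULL, samples))
  if (!nrow(at)) return(m)
  at <- at[region_id %in% unique(markers$region_id)]
  by_region <- split(seq_len(nrow(at)), at$region_id)
  sidx <- match(at$sample_id, samples)
  for (i in seq_len(nrow(markers))) {
    rows <- by_region[[markers$region_id[i]]]
    if (is.null(rows)) next
    a <- at$alpha[rows]
    hit <- if (markers$direction[i] == "hypo") a <= markers$threshold[i]
           else a >= markers$threshold[i]
    if (any(hit)) {
      tab <- tabulate(sidx[rows][hit], nbins = length(samples))
      m[i, ] <- tab
    }
  }
  m
}

#' Size-constrained K-means clustering
#'
#' Partitions `n` items into `K = round(n / ((min_size + max_size) / 2))`
#' clusters (clipped to the feasible range
#' `[ceiling(n / max_size), floor(n / min_size)]`) with every cluster
#' size in `[min_size, max_size]`. The assignment step is a
#' capacity-limited greedy (items ordered by distance) followed by a
#' repair pass that fills under-sized clusters with the cheapest moves;
#' centers and assignments iterate until convergence or `max_iter`.
#'
#' @param x numeric matrix, one row per item.
#' @param min_size,max_size cluster size bounds (defaults 45, 55).
#' @param seed integer seed for center initialisation.
#' @param max_iter iteration cap (default 100).
#' @param strict error when no K satisfies the bounds (default TRUE);
#'   with `strict = FALSE` the nearest feasible K is used and a warning
#'   notes out-of-band sizes.
#' @return integer vector of cluster assignments in `1..K`.
#' @export
constrained_kmeans <- function(x, min_size = 45L, max_size = 55L, seed = 1L,
                               max_iter = 100L, strict = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < min_size) {
    if (strict) stop(sprintf("infeasible: %d items < min_size %d", n, min_size))
    warning("cluster of ", n, " items below min_size")
    return(rep(1L, n))
  }
  k_lo <- ceiling(n / max_size)
  k_hi <- floor(n / min_size)
  if (k_lo > k_hi) {
    if (strict) stop(sprintf("infeasible: no K gives sizes in [%d, %d] for n = %d",
                             min_size, max_size, n))
    warning("no feasible K for n = ", n, "; sizes will leave [min, max]")
    k_hi <- k_lo
  }
  K <- min(max(round(n / ((min_size + max_size) / 2)), k_lo), k_hi)
  if (K == 1L) return(rep(1L, n))
  set.seed(seed)
  centers <- x[sample.int(n, K), , drop = FALSE]
  cap <- min(max_size, ceiling(n / K) + (max_size - min_size))
  assign_bounded <- function(d) {
    # d: n x K distances. Greedy by best-distance order with capacity cap,
    # then repair clusters under min_size.
    sizes <- integer(K)
    asg <- integer(n)
    ord <- order(apply(d, 1L, min))
    for (i in ord) {
      pref <- order(d[i, ])
      j <- pref[which(sizes[pref] < cap)[1L]]
      asg[i] <- j
      sizes[j] <- sizes[j] + 1L
    }
    # repair: fill clusters below the per-cluster minimum
    floor_size <- min(min_size, floor(n / K))
    repeat {
      under <- which(sizes < floor_size)
      if (!length(under)) break
      j <- under[1L]
      movable <- which(asg != j & sizes[asg] > floor_size)
      cost <- d[cbind(movable, j)] - d[cbind(movable, asg[movable])]
      mv <- movable[which.min(cost)]
      sizes[asg[mv]] <- sizes[asg[mv]] - 1L
      asg[mv] <- j
      sizes[j] <- sizes[j] + 1L
    }
    asg
  }
  asg_prev <- NULL
  for (iter in seq_len(max_iter)) {
    d <- outer(rowSums(x^2), rep(1, K)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    asg <- assign_bounded(d)
    if (identical(asg, asg_prev)) break
    asg_prev <- asg
    for (j in seq_len(K)) {
      centers[j, ] <- colMeans(x[asg == j, , drop = FALSE])
    }
  }
  sizes <- tabulate(asg, K)
  if (strict && (any(sizes < min_size) || any(sizes > max_size))) {
    # cap/floor arithmetic guarantees feasibility; this is a safety net
    stop("constrained_kmeans produced out-of-bound cluster sizes")
  }
  asg
}

#' Build merged markers from individual markers
#'
#' Clusters each (class, direction) cell's markers by their profile of
#' ln(normalized qualifying-read count + 1) across the reference
#' (discovery tissue) samples, with cluster sizes constrained to
#' `[min_size, max_size]`.
#'
#' @param markers marker data.frame from [discover_markers()].
#' @param reference_cohort list of [sample_fragments()] used as the
#'   clustering feature space (typically the discovery tissue samples).
#' @param min_size,max_size cluster-size bounds (defaults 45, 55).
#' @param seed integer seed.
#' @param min_cpgs per-fragment CpG minimum (default 3).
#' @param strict passed to [constrained_kmeans()]; with `strict = FALSE`
#'   cells too small or gap-infeasible fall back to the nearest feasible
#'   partition with a warning.
#' @return a `merged_markers` object: data.frame `merged_id`,
#'   `target_class`, `direction`, `n_members` with attribute `members`
#'   (named list of marker row indices into `markers`) and `markers`.
#' @export
build_merged_markers <- function(markers, reference_cohort, min_size = 45L,
                                 max_size = 55L, seed = 1L, min_cpgs = 3L,
                                 strict = TRUE) {
  stopifnot(nrow(markers) > 0L, length(reference_cohort) > 0L)
  totals <- vapply(reference_cohort, `[[`, numeric(1L), "total_fragments")
  counts <- marker_count_matrix(reference_cohort, markers, min_cpgs = min_cpgs)
  prof <- log(sweep(counts, 2L, totals, function(c, t) 1e9 * c / t) + 1)
  cell_key <- paste(markers$target_class, markers$direction, sep = ":")
  members <- list()
  rows <- list()
  for (cell in sort(unique(cell_key))) {
    idx <- which(cell_key == cell)
    asg <- constrained_kmeans(prof[idx, , drop = FALSE], min_size = min_size,
                              max_size = max_size,
                              seed = derive_seed(seed, cell), strict = strict)
    for (j in sort(unique(asg))) {
      mid <- sprintf("%s:m%02d", cell, j)
      members[[mid]] <- idx[asg == j]
      rows[[mid]] <- data.frame(
        merged_id = mid,
        target_class = markers$target_class[idx[1L]],
        direction = markers$direction[idx[1L]],
        n_members = sum(asg == j), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, members = members, markers = markers,
            class = c("merged_markers", "data.frame"))
}

#' Write / read a merged-marker catalog as JSON
#'
#' Records member marker lists for exact reuse at validation time.
#'
#' @param merged a `merged_markers` object.
#' @param path JSON path.
#' @return `path` (write) or a `merged_markers` object (read).
#' @export
write_merged_markers <- function(merged, path) {
  members <- attr(merged, "members")
  markers <- attr(merged, "markers")
  payload <- list(
    clusters = lapply(seq_len(nrow(merged)), function(i) {
      list(merged_id = merged$merged_id[i],
           target_class = merged$target_class[i],
           direction = merged$direction[i],
           member_rows = members[[merged$merged_id[i]]])
    }),
    markers = markers
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_merged_markers
#' @export
read_merged_markers <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  markers <- as.data.frame(payload$markers, stringsAsFactors = FALSE)
  cl <- payload$clusters  # simplified to a data.frame with a list column
  out <- data.frame(merged_id = cl$merged_id,
                    target_class = cl$target_class,
                    direction = cl$direction,
                    n_members = vapply(cl$member_rows, length, integer(1L)),
                    stringsAsFactors = FALSE)
  members <- lapply(cl$member_rows, as.integer)
  names(members) <- out$merged_id
  structure(out, members = members, markers = markers,
            class = c("merged_markers", "data.frame"))
}

#' Build a sample's feature vector over merged markers
#'
#' Per merged marker: the mean over member markers of the normalized
#' qualifying-read count, transformed as `ln(mean + 1)`, in catalog
#' order.
#'
#' @param sample a [sample_fragments()].
#' @param merged a `merged_markers` object.
#' @param min_cpgs per-fragment CpG minimum (default 3).
#' @return named numeric vector, one value per merged marker.
#' @export
build_feature_vector <- function(sample, merged, min_cpgs = 3L) {
  if (is.null(sample$total_fragments) || !isTRUE(sample$total_fragments > 0)) {
    stop("sample lacks a positive total_fragments")
  }
  fm <- build_feature_matrix(stats::setNames(list(sample), sample$sample_id),
                             merged, min_cpgs = min_cpgs)
  stats::setNames(fm[1L, ], colnames(fm))
}

#' Build the feature matrix for a cohort
#'
#' @param cohort named list of [sample_fragments()].
#' @param merged a `merged_markers` object.
#' @param min_cpgs per-fragment CpG minimum (default 3).
#' @return numeric samples x merged-markers matrix.
#' @export
build_feature_matrix <- function(cohort, merged, min_cpgs = 3L) {
  markers <- attr(merged, "markers")
  members <- attr(merged, "members")
  totals <- vapply(cohort, `[[`, numeric(1L), "total_fragments")
  if (any(!is.finite(totals) | totals <= 0)) {
    stop("every sample needs a positive total_fragments")
  }
  counts <- marker_count_matrix(cohort, markers, min_cpgs = min_cpgs)
  norm <- sweep(counts, 2L, totals, function(c, t) 1e9 * c / t)
  f <- vapply(merged$merged_id, function(mid) {
    log(colMeans(norm[members[[mid]], , drop = FALSE]) + 1)
  }, numeric(length(cohort)))
  f <- matrix(f, nrow = length(cohort),
              dimnames = list(cohort_ids(cohort), merged$merged_id))
  f
}
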