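# Region catalogs: the unit intervals of all methylation analysis.
# Coordinates are 0-based half-open internally (BED convention on disk).

#' Construct a validated region catalog
#'
#' A region catalog is a `data.frame` (class `region_catalog`) with columns
#' `chrom`, `start`, `end` (0-based half-open), `region_id` and optionally
#' `n_cpgs`. Regions are the MspI-delimited intervals that RRBS and
#' cfMethyl-Seq enrich; every fragment-level statistic is computed per
#' region.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `end > start`.
#' @param region_id unique identifiers; defaults to `"chrom:start-end"`.
#' @param n_cpgs optional non-negative CpG counts per region.
#' @return a `region_catalog` data.frame.
#' @export
region_catalog <- function(chrom, start, end, region_id = NULL, n_cpgs = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) stop("non-integer region coordinates")
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop(sprintf("region %d has end <= start (%d <= %d)", bad, end[bad], start[bad]))
  }
  if (is.null(region_id)) region_id <- sprintf("%s:%d-%d", chrom, start, end)
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id)) stop("duplicated region_id in catalog")
  out <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    region_id = region_id, stringsAsFactors = FALSE
  )
  if (!is.null(n_cpgs)) {
    n_cpgs <- as.integer(n_cpgs)
    if (any(n_cpgs < 0, na.rm = TRUE)) stop("n_cpgs must be >= 0")
    out$n_cpgs <- n_cpgs
  }
  class(out) <- c("region_catalog", "data.frame")
  out
}

#' Read a region catalog from a BED-like file
#'
#' Accepts 3-5 tab-separated columns: chrom, start, end, optional
#' region_id, optional n_cpgs. Missing ids are auto-generated as
#' `chrom:start-end`.
#'
#' @param path path to a BED-like file (no header).
#' @return a [region_catalog()].
#' @export
read_region_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    return(region_catalog(character(), integer(), integer()))
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("cannot parse BED file: ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) {
    return(region_catalog(character(), integer(), integer()))
  }
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns")
  start <- suppressWarnings(as.integer(dt[[2L]]))
  end <- suppressWarnings(as.integer(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    stop(sprintf("malformed region at line %d of %s", bad[1L], path))
  }
  region_catalog(
    chrom = as.character(dt[[1L]]),
    start = start, end = end,
    region_id = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NULL,
    n_cpgs = if (ncol(dt) >= 5L) dt[[5L]] else NULL
  )
}

#' Write a region catalog as BED
#'
#' @param catalog a [region_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "region_catalog"))
  cols <- c("chrom", "start", "end", "region_id",
            if ("n_cpgs" %in% names(catalog)) "n_cpgs")
  data.table::fwrite(as.data.frame(catalog)[, cols, drop = FALSE], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

region_length <- function(catalog) catalog$end - catalog$start

# 1-based inclusive GRanges view of a 0-based half-open catalog
catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start + 1L, end = catalog$end),
    region_id = catalog$region_id
  )
}
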