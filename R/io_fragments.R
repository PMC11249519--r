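# Per-sample fragment collections and their on-disk TSV encoding.
#
# One row = one sequenced fragment (optionally with a multiplicity
# column): the alpha value is a per-fragment statistic, so fragments, not
# CpG calls, are the stored unit. The genome-wide deduplicated mapped
# fragment count (`total_fragments`) is the normalization denominator and
# generally exceeds the number of stored (region-mapped) fragments, so it
# is carried explicitly in sidecar header lines.

SAMPLE_LABELS <- c("LUAD", "LUSC", "noncancer")
SAMPLE_MATERIALS <- c("tissue", "plasma")

#' Construct a single sample's fragment collection
#'
#' @param sample_id sample identifier.
#' @param label one of `"LUAD"`, `"LUSC"`, `"noncancer"`.
#' @param material `"tissue"` or `"plasma"`.
#' @param total_fragments genome-wide deduplicated mapped fragment count
#'   (normalization denominator); must be at least the number of stored
#'   fragments.
#' @param fragments data.frame with columns `region_id`, `n_cpgs`,
#'   `n_methylated` (one row per fragment).
#' @return a `sample_fragments` object.
#' @export
sample_fragments <- function(sample_id, label, material, total_fragments,
                             fragments) {
  label <- match.arg(label, SAMPLE_LABELS)
  material <- match.arg(material, SAMPLE_MATERIALS)
  if (label == "noncancer" && material == "tissue") {
    stop("noncancer samples are plasma in this design")
  }
  fragments <- data.table::as.data.table(fragments)[
    , .(region_id = as.character(region_id),
        n_cpgs = as.integer(n_cpgs),
        n_methylated = as.integer(n_methylated))]
  if (nrow(fragments)) {
    if (any(fragments$n_cpgs < 1L)) stop("fragment with n_cpgs < 1")
    if (any(fragments$n_methylated < 0L |
            fragments$n_methylated > fragments$n_cpgs)) {
      stop("fragment with n_methylated outside [0, n_cpgs]")
    }
  }
  total_fragments <- as.double(total_fragments)
  if (!isTRUE(total_fragments > 0)) stop("total_fragments must be > 0")
  if (total_fragments < nrow(fragments)) {
    stop("total_fragments smaller than number of stored fragments")
  }
  structure(
    list(sample_id = as.character(sample_id), label = label,
         material = material, total_fragments = total_fragments,
         fragments = fragments),
    class = "sample_fragments"
  )
}

#' @export
print.sample_fragments <- function(x, ...) {
  cat(sprintf("<sample_fragments> %s [%s, %s]: %d fragments in %d regions, total %g\n",
              x$sample_id, x$label, x$material, nrow(x$fragments),
              data.table::uniqueN(x$fragments$region_id), x$total_fragments))
  invisible(x)
}

#' Read a cohort of fragment tables from TSV
#'
#' The file has a header `sample_id  region_id  n_cpgs  n_methylated
#' [count]` preceded by one sidecar comment line per sample:
#' `#sample<TAB>id<TAB>label<TAB>material<TAB>total_fragments`.
#' An optional `count` column expands to repeated fragments.
#'
#' @param path TSV path.
#' @return named list of [sample_fragments()] (a "cohort").
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  side <- grep("^#sample\t", lines, value = TRUE)
  if (!length(side)) stop("fragment table lacks '#sample' sidecar lines")
  meta <- do.call(rbind, strsplit(side, "\t", fixed = TRUE))
  meta <- data.frame(sample_id = meta[, 2L], label = meta[, 3L],
                     material = meta[, 4L],
                     total_fragments = as.double(meta[, 5L]),
                     stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) <= 1L) {
    dt <- data.table::data.table(sample_id = character(),
                                 region_id = character(),
                                 n_cpgs = integer(), n_methylated = integer())
  } else {
    dt <- data.table::fread(text = body, header = TRUE, sep = "\t")
  }
  need <- c("sample_id", "region_id", "n_cpgs", "n_methylated")
  if (!all(need %in% names(dt))) stop("fragment table missing columns")
  if (nrow(dt) && any(dt$n_methylated > dt$n_cpgs)) {
    stop("fragment with n_methylated > n_cpgs")
  }
  if (nrow(dt) && !all(dt$sample_id %in% meta$sample_id)) {
    stop("fragment rows for samples absent from sidecar")
  }
  if ("count" %in% names(dt) && nrow(dt)) {
    dt <- dt[rep(seq_len(nrow(dt)), dt$count)]
    dt[, count := NULL]
  }
  cohort <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    sample_fragments(
      m$sample_id, m$label, m$material, m$total_fragments,
      dt[sample_id == m$sample_id,
         .(region_id, n_cpgs, n_methylated)]
    )
  })
  names(cohort) <- meta$sample_id
  cohort
}

#' Write a cohort of fragment tables as TSV
#'
#' @param cohort named list of [sample_fragments()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(cohort, path) {
  stopifnot(length(cohort) > 0L)
  side <- vapply(cohort, function(s) {
    sprintf("#sample\t%s\t%s\t%s\t%.0f", s$sample_id, s$label, s$material,
            s$total_fragments)
  }, character(1L))
  body <- data.table::rbindlist(lapply(cohort, function(s) {
    if (!nrow(s$fragments)) return(NULL)
    data.table::data.table(sample_id = s$sample_id, s$fragments)
  }))
  writeLines(c(side, "sample_id\tregion_id\tn_cpgs\tn_methylated"), path)
  if (!is.null(body) && nrow(body)) {
    data.table::fwrite(body, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Cohort labels
#' @param cohort list of [sample_fragments()].
#' @return named character vector of labels.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, `[[`, character(1L), "label")
}

# One flat data.table for a cohort: sample_id, label, region_id, alpha,
# n_cpgs. Fragments below min_cpgs are dropped (alpha on 1-2 CpGs is too
# coarse to resolve methylation components).
cohort_alpha_table <- function(cohort, min_cpgs = 3L) {
  dt <- data.table::rbindlist(lapply(cohort, function(s) {
    f <- s$fragments
    if (!nrow(f)) return(NULL)
    data.table::data.table(
      sample_id = s$sample_id, label = s$label,
      region_id = f$region_id, n_cpgs = f$n_cpgs,
      alpha = f$n_methylated / f$n_cpgs
    )
  }))
  if (is.null(dt) || !nrow(dt)) {
    return(data.table::data.table(sample_id = character(), label = character(),
                                  region_id = character(), n_cpgs = integer(),
                                  alpha = double()))
  }
  dt[n_cpgs >= min_cpgs]
}
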