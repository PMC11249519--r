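# Beta (450K-style) and TPM matrices with attached sample labels and
# feature coordinates, plus their CSV encodings.

#' Construct a beta matrix
#'
#' @param values numeric probe x sample matrix of beta values in `[0,1]`,
#'   with probe ids as rownames and sample ids as colnames.
#' @param probes data.frame `probe_id`, `chrom`, `pos` (0-based CpG
#'   coordinate) covering all rows of `values`.
#' @param labels named character vector of sample labels (names = sample
#'   ids), or `NULL`.
#' @return a `beta_matrix` object.
#' @export
beta_matrix <- function(values, probes, labels = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix needs probe rownames and sample colnames")
  }
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  if (!all(rownames(values) %in% probes$probe_id)) {
    stop("probes table does not cover all matrix rows")
  }
  probes <- probes[match(rownames(values), probes$probe_id), , drop = FALSE]
  if (!is.null(labels)) labels <- labels[colnames(values)]
  structure(list(values = values, probes = probes, labels = labels),
            class = "beta_matrix")
}

#' Construct a TPM matrix
#'
#' @param values numeric gene x sample matrix of TPM values (>= 0).
#' @param promoters optional data.frame `gene_id`, `chrom`, `start`,
#'   `end` of promoter intervals (0-based half-open).
#' @param labels named character vector of sample labels, or `NULL`.
#' @return a `tpm_matrix` object.
#' @export
tpm_matrix <- function(values, promoters = NULL, labels = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(values < 0)) stop("TPM values must be >= 0")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("TPM matrix needs gene rownames and sample colnames")
  }
  if (!is.null(labels)) labels <- labels[colnames(values)]
  structure(list(values = values, promoters = promoters, labels = labels),
            class = "tpm_matrix")
}

#' Read a beta or TPM matrix from CSV
#'
#' The CSV holds the numeric matrix with row and column headers.
#' Companion files supply feature coordinates and sample labels.
#'
#' @param path CSV path (first column = feature id).
#' @param kind `"beta"` or `"tpm"`.
#' @param features optional companion CSV: `probe_id,chrom,pos` for beta,
#'   `gene_id,chrom,start,end` for tpm.
#' @param labels optional companion CSV `sample_id,label`.
#' @return a [beta_matrix()] or [tpm_matrix()].
#' @export
read_matrix <- function(path, kind = c("beta", "tpm"), features = NULL,
                        labels = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  lab <- NULL
  if (!is.null(labels)) {
    ldf <- utils::read.csv(labels, stringsAsFactors = FALSE)
    lab <- stats::setNames(as.character(ldf$label), ldf$sample_id)
  }
  if (kind == "beta") {
    probes <- if (!is.null(features)) {
      utils::read.csv(features, stringsAsFactors = FALSE)
    } else {
      data.frame(probe_id = rownames(m), chrom = NA_character_,
                 pos = NA_integer_, stringsAsFactors = FALSE)
    }
    beta_matrix(m, probes, lab)
  } else {
    tpm_matrix(m, promoters = if (!is.null(features)) {
      utils::read.csv(features, stringsAsFactors = FALSE)
    }, labels = lab)
  }
}

#' Write a beta/TPM matrix to CSV
#'
#' @param x a [beta_matrix()] or [tpm_matrix()].
#' @param path CSV output path for the values.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, c("beta_matrix", "tpm_matrix")))
  df <- data.frame(id = rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read promoter intervals from a BED-like file
#'
#' Columns: chrom, start, end, gene_id (tab-separated, 0-based half-open).
#'
#' @param path BED path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
read_promoters <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4L) stop("promoter BED needs 4 columns")
  out <- data.frame(gene_id = as.character(dt[[4L]]),
                    chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]), end = as.integer(dt[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("promoter with end <= start")
  out
}
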