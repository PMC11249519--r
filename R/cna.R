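# Downstream thresholding of externally supplied copy-number output
# (per-bin purity-adjusted log2 ratios and tumor fractions, ichorCNA
# style). No HMM inference happens here.

#' Call per-bin copy-number state
#'
#' Strict thresholds: log2 ratio `> gain_threshold` is a gain,
#' `< loss_threshold` a loss, everything else neutral.
#'
#' @param log2_ratio numeric vector of per-bin log2 copy-number ratios.
#' @param gain_threshold default 0.3.
#' @param loss_threshold default -0.3.
#' @return character vector in `{"gain", "loss", "neutral"}`.
#' @export
call_cna <- function(log2_ratio, gain_threshold = 0.3, loss_threshold = -0.3) {
  stopifnot(is.finite(gain_threshold), is.finite(loss_threshold),
            gain_threshold > loss_threshold)
  if (any(!is.finite(log2_ratio))) stop("non-finite log2 ratio")
  out <- rep("neutral", length(log2_ratio))
  out[log2_ratio > gain_threshold] <- "gain"
  out[log2_ratio < loss_threshold] <- "loss"
  out
}

#' Detect chromosome 9p21.3 loss
#'
#' 9p21.3 loss is loss of CDKN2A/B and/or MTAP: true iff any of the
#' three genes' bins is called loss.
#'
#' @param calls named character vector of per-bin calls (names = bin
#'   ids), as from [call_cna()].
#' @param gene_bins named character vector mapping `CDKN2A`, `CDKN2B`,
#'   `MTAP` to bin ids; all three must be present.
#' @return logical.
#' @export
detect_9p21_loss <- function(calls, gene_bins) {
  need <- c("CDKN2A", "CDKN2B", "MTAP")
  if (!all(need %in% names(gene_bins))) {
    stop("gene_bins must map CDKN2A, CDKN2B and MTAP")
  }
  bins <- gene_bins[need]
  if (!all(bins %in% names(calls))) stop("gene mapped to unknown bin")
  any(calls[bins] == "loss")
}

#' Tumor-fraction-stratified classification accuracy
#'
#' Splits samples into detectable (`fraction >= limit`, inclusive) and
#' undetectable groups and reports accuracy per group; an empty group's
#' accuracy is `NA` (undefined), not 0.
#'
#' @param predictions named vector of predicted labels.
#' @param truth named vector of true labels, same sample ids.
#' @param fractions named numeric vector of tumor fractions in `[0,1]`.
#' @param limit detectability limit (default 0.03).
#' @return data.frame `group`, `n`, `accuracy`.
#' @export
stratify_accuracy <- function(predictions, truth, fractions, limit = 0.03) {
  ids <- names(truth)
  if (is.null(ids) || !setequal(ids, names(predictions)) ||
      !setequal(ids, names(fractions))) {
    stop("sample ids of predictions, truth and fractions must match")
  }
  predictions <- predictions[ids]
  fractions <- fractions[ids]
  stopifnot(all(fractions >= 0 & fractions <= 1))
  detectable <- fractions >= limit
  acc <- function(mask) {
    if (!any(mask)) return(NA_real_)
    mean(predictions[mask] == truth[mask])
  }
  data.frame(group = c("detectable", "undetectable"),
             n = c(sum(detectable), sum(!detectable)),
             accuracy = c(acc(detectable), acc(!detectable)),
             stringsAsFactors = FALSE)
}

#' Read a CNA bin table
#'
#' BED+score TSV: chrom, start, end, log2_ratio.
#'
#' @param path TSV path.
#' @return data.frame with a `bin_id` (`chrom:start-end`) column.
#' @export
read_cna_bins <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4L) stop("CNA bin table needs 4 columns")
  out <- data.frame(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]), end = as.integer(dt[[3L]]),
                    log2_ratio = as.double(dt[[4L]]), stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("CNA bin with end <= start")
  out$bin_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}
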