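# In-silico MspI digestion. MspI cuts C^CGG; the enriched regions of
# RRBS / cfMethyl-Seq libraries are the intervals between two adjacent
# cut sites shorter than 350 bp. CCGG is its own reverse complement, so
# scanning one strand is strand-complete.

#' Find MspI cut sites in a nucleotide sequence
#'
#' MspI recognises CCGG and cuts between the first C and the CGG, so each
#' occurrence starting at 0-based position `p` yields a cut point at
#' `p + 1`. Matching is case-insensitive; N never matches.
#'
#' @param sequence nucleotide string (or a `Biostrings::DNAString`).
#' @param chrom chromosome name attached to the result.
#' @return data.frame `chrom`, `pos` (0-based cut coordinates, sorted).
#' @export
find_cut_sites <- function(sequence, chrom = "chr") {
  if (inherits(sequence, "DNAString")) {
    starts <- Biostrings::start(Biostrings::matchPattern("CCGG", sequence))
  } else {
    seq <- toupper(as.character(sequence))
    # lookahead keeps overlapping occurrences (CCGG cannot self-overlap,
    # but the scan should not depend on that)
    m <- gregexpr("(?=CCGG)", seq, perl = TRUE)[[1L]]
    starts <- if (m[1L] == -1L) integer() else as.integer(m)
  }
  data.frame(chrom = rep(chrom, length(starts)),
             pos = as.integer(starts),  # 1-based start == 0-based start + 1
             stringsAsFactors = FALSE)
}

#' Build enriched regions from ordered cut sites
#'
#' One candidate region per adjacent cut-site pair on the same
#' chromosome; retained iff its length (`end - start`) is strictly below
#' `max_len`.
#'
#' @param cut_sites data.frame `chrom`, `pos` as from [find_cut_sites()],
#'   sorted by `pos` within chromosome.
#' @param max_len retain regions with length `< max_len` (default 350).
#' @return a [region_catalog()].
#' @export
build_regions <- function(cut_sites, max_len = 350L) {
  stopifnot(is.data.frame(cut_sites), all(c("chrom", "pos") %in% names(cut_sites)))
  pieces <- lapply(split(cut_sites$pos, cut_sites$chrom), function(pos) {
    if (is.unsorted(pos, strictly = FALSE)) stop("cut sites must be sorted")
    if (length(pos) < 2L) return(NULL)
    data.frame(start = pos[-length(pos)], end = pos[-1L])
  })
  chroms <- rep(names(pieces), vapply(pieces, function(p) if (is.null(p)) 0L else nrow(p), integer(1L)))
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || !nrow(pieces)) {
    return(region_catalog(character(), integer(), integer()))
  }
  keep <- (pieces$end - pieces$start) < max_len
  region_catalog(chroms[keep], pieces$start[keep], pieces$end[keep])
}

#' Digest a genome FASTA into the enriched-region catalog
#'
#' Scans every sequence for CCGG, forms inter-cut regions and applies the
#' length filter. Optionally annotates each region with its CpG count and
#' flags regions containing N (which `drop_n` removes).
#'
#' @param fasta path to a (possibly soft-masked) genome FASTA.
#' @param max_len strict region length cutoff in bp (default 350).
#' @param annotate_cpgs count CG dinucleotides per region (default TRUE).
#' @param drop_n drop regions containing N (default FALSE; they are
#'   flagged in column `has_n` either way).
#' @return a [region_catalog()] with attribute `summary` = list
#'   `n_regions`, `mean_length`.
#' @export
digest_genome <- function(fasta, max_len = 350L, annotate_cpgs = TRUE,
                          drop_n = FALSE) {
  if (!file.exists(fasta)) stop("cannot read FASTA: ", fasta)
  genome <- Biostrings::readDNAStringSet(fasta)
  if (!length(genome)) stop("empty FASTA: ", fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  per_chrom <- lapply(seq_along(genome), function(i) {
    cuts <- find_cut_sites(genome[[i]], chrom = names(genome)[i])
    cat_i <- build_regions(cuts, max_len = max_len)
    if (!nrow(cat_i)) return(cat_i)
    views <- Biostrings::Views(genome[[i]], start = cat_i$start + 1L,
                               end = cat_i$end)
    if (annotate_cpgs) {
      cat_i$n_cpgs <- Biostrings::vcountPattern(
        "CG", Biostrings::DNAStringSet(views))
    }
    cat_i$has_n <- Biostrings::vcountPattern(
      "N", Biostrings::DNAStringSet(views)) > 0L
    cat_i
  })
  out <- data.table::rbindlist(per_chrom, fill = TRUE)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (nrow(out) && drop_n) out <- out[!out$has_n, , drop = FALSE]
  if (nrow(out)) {
    class(out) <- c("region_catalog", "data.frame")
  } else {
    out <- region_catalog(character(), integer(), integer())
  }
  attr(out, "summary") <- list(
    n_regions = nrow(out),
    mean_length = if (nrow(out)) mean(out$end - out$start) else NA_real_
  )
  out
}
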