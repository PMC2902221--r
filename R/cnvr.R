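# Merging per-animal CNV calls into copy-number-variable regions (CNVRs)
# and computing catalogue summary statistics.

calls_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge per-animal CNV calls into CNVRs
#'
#' Calls of the same type (gain/loss) overlapping by at least 1 bp are
#' united, single-linkage, into one copy-number-variable region; gains and
#' losses are merged independently and never combined. Merging is idempotent
#' and order-independent. Bookended (adjacent, non-overlapping) calls are
#' *not* merged: overlap means a shared base pair.
#'
#' @param calls `cgh_calls` data.frame (animal_id, chrom, start, end, state)
#' @return data.frame of class `cgh_cnvr`: chrom, start, end, type,
#'   n_animals, animals (comma-separated), sorted by (type, chrom, start)
#' @export
merge_calls <- function(calls) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), n_animals = integer(),
                      animals = character(), stringsAsFactors = FALSE)
  class(empty) <- c("cgh_cnvr", "data.frame")
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  if (any(calls$end <= calls$start)) stop_invalid("calls must have end > start")

  out <- lapply(c("loss", "gain"), function(type) {
    sub <- calls[calls$state == type, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    gr <- calls_to_granges(sub)
    # min.gapwidth = 0 merges only truly overlapping ranges, not bookended
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hits <- GenomicRanges::findOverlaps(gr, red)
    an <- split(sub$animal_id[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits))
    df <- granges_to_df(red)
    df$type <- type
    df$n_animals <- vapply(seq_len(nrow(df)),
                           function(i) length(unique(an[[as.character(i)]])),
                           integer(1))
    df$animals <- vapply(seq_len(nrow(df)), function(i)
      paste(sort(unique(an[[as.character(i)]])), collapse = ","), character(1))
    df
  })
  out <- do.call(rbind, out)
  out <- out[order(out$type, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cgh_cnvr", "data.frame")
  out
}

#' Summarise a CNVR catalogue
#'
#' Per type (loss/gain) and overall: region count, mean size (total content
#' divided by count, rounded to the nearest bp), median size (middle order
#' statistic; mean of the two middles for even counts, rounded), size range,
#' total content in bp, and percent of the genome (rounded to 3 decimals).
#' Also returns the size-class histogram used for catalogue size-spectrum
#' plots.
#'
#' @param cnvrs `cgh_cnvr` data.frame
#' @param genome_length total genome length in bp (> 0)
#' @param bins upper size-class edges in bp for the histogram; the last class
#'   is open-ended
#' @return list of class `cgh_cnvr_summary`: `table` (data.frame with rows
#'   loss/gain/all) and `size_hist` (data.frame: bin, count)
#' @export
cnvr_summary <- function(cnvrs, genome_length,
                         bins = c(5, 10, 20, 50, 100, 500, 2000) * 1e3) {
  if (genome_length <= 0) stop_invalid("genome_length must be > 0")
  sizes <- cnvrs$end - cnvrs$start
  one <- function(sz, label) {
    if (length(sz) == 0)
      return(data.frame(type = label, count = 0L, mean_size = NA_real_,
                        median_size = NA_real_, min_size = NA_real_,
                        max_size = NA_real_, content_bp = 0,
                        percent_genome = 0, stringsAsFactors = FALSE))
    data.frame(type = label, count = length(sz),
               mean_size = round(sum(sz) / length(sz)),
               median_size = round(stats::median(sz)),
               min_size = min(sz), max_size = max(sz),
               content_bp = sum(sz),
               percent_genome = round(100 * sum(sz) / genome_length, 3),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(one(sizes[cnvrs$type == "loss"], "loss"),
               one(sizes[cnvrs$type == "gain"], "gain"),
               one(sizes, "all"))
  edges <- c(0, sort(bins), Inf)
  cnt <- if (length(sizes)) as.vector(table(cut(sizes, edges, right = TRUE)))
         else rep(0L, length(edges) - 1)
  hist <- data.frame(
    bin = paste0(c("<=", rep("<=", length(bins) - 1), ">")[seq_len(length(bins) + 1)],
                 c(bins / 1e3, bins[length(bins)] / 1e3), "kb"),
    count = cnt)
  structure(list(table = tab, size_hist = hist), class = "cgh_cnvr_summary")
}

#' @export
print.cgh_cnvr_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mean number of CNV calls per animal
#'
#' @param calls `cgh_calls` data.frame
#' @param n_animals number of animals assayed (calls may cover fewer)
#' @return mean calls per animal
#' @export
calls_per_animal <- function(calls, n_animals) {
  if (n_animals <= 0) stop_invalid("n_animals must be > 0")
  nrow(calls) / n_animals
}
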