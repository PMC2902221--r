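# Readers/writers for the package's file dialects. All genomic output is
# 0-based half-open (BED dialect); 1-based closed input can be declared and
# is converted at the boundary. Every writer stamps the dialect in a header
# comment.

DIALECT_COMMENT <- "# coords: 0-based half-open"

convert_coords <- function(df, coords) {
  if (coords == "1-closed") df$start <- df$start - 1
  df
}

#' Read a probe table
#'
#' Tab-separated with header: probe_id, chrom, start, end, x, y and either
#' both channel intensities (intensity_cy3, intensity_cy5) or a log2ratio
#' column. Rows are sorted by (chrom, start) (with a warning if the input was
#' not); coordinates are converted to the internal 0-based half-open dialect.
#'
#' @param path file path
#' @param coords input coordinate dialect: "0-half-open" (default) or
#'   "1-closed"
#' @return `cgh_ratio` data.frame; `array_id`/`cy3`/`cy5` attributes are
#'   restored from `#ARRAY`/`#CY3`/`#CY5` header comments when present
#' @export
read_probe_table <- function(path, coords = c("0-half-open", "1-closed")) {
  coords <- match.arg(coords)
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_invalid("missing column: %s", paste(miss, collapse = ", "))
  if (is.null(tab$log2ratio) &&
      (is.null(tab$intensity_cy3) || is.null(tab$intensity_cy5)))
    stop_invalid("missing column: log2ratio (or intensity_cy3 + intensity_cy5)")
  tab <- convert_coords(tab, coords)
  o <- order(tab$chrom, tab$start)
  if (!identical(o, seq_len(nrow(tab)))) {
    warning("probe table was not sorted by (chrom, start); sorting",
            call. = FALSE)
    tab <- tab[o, , drop = FALSE]
    rownames(tab) <- NULL
  }
  meta <- function(tag) {
    line <- hdr[startsWith(hdr, paste0("#", tag, "\t"))]
    if (length(line)) sub(paste0("^#", tag, "\t"), "", line[1]) else NULL
  }
  attr(tab, "array_id") <- meta("ARRAY")
  attr(tab, "cy3") <- meta("CY3")
  attr(tab, "cy5") <- meta("CY5")
  class(tab) <- c("cgh_ratio", "data.frame")
  tab
}

#' @rdname read_probe_table
#' @param tab table to write
#' @export
write_probe_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(DIALECT_COMMENT, con)
  for (tag in c("array_id", "cy3", "cy5")) {
    v <- attr(tab, tag)
    if (!is.null(v))
      writeLines(sprintf("#%s\t%s", toupper(sub("array_id", "ARRAY", tag)), v), con)
  }
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED file into a feature data.frame
#'
#' Standard BED (0-based half-open, no header, tab-separated). Columns 4-6
#' are taken as name, identity (numeric, e.g. percent identity of a
#' segmental duplication) and evidence ("WGAC"/"WSSD"/"both") when present.
#'
#' @param path file path
#' @return data.frame: chrom, start, end (+ name, identity, evidence)
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  get <- function(i) vapply(parts, `[[`, character(1), i)
  df <- data.frame(chrom = get(1),
                   start = suppressWarnings(as.numeric(get(2))),
                   end = suppressWarnings(as.numeric(get(3))),
                   stringsAsFactors = FALSE)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop_invalid("malformed BED interval at line %d of %s", bad[1], path)
  if (ncol >= 4) df$name <- get(4)
  if (ncol >= 5) df$identity <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6) df$evidence <- get(6)
  df
}

#' @rdname read_bed
#' @param df data.frame with chrom, start, end and optional name, identity,
#'   evidence columns
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  for (extra in c("name", "identity", "evidence"))
    if (!is.null(df[[extra]])) cols <- c(cols, list(as.character(df[[extra]])))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(DIALECT_COMMENT, lines), path)
  invisible(path)
}

#' Read / write a hybridization design sheet
#'
#' Tab-separated with header: array_id, cy3, cy5, design_id, swap_of.
#'
#' @param path file path
#' @return `cgh_design` data.frame
#' @export
read_design_sheet <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("array_id", "cy3", "cy5", "swap_of")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_invalid("design sheet missing column: %s", paste(miss, collapse = ", "))
  class(d) <- c("cgh_design", "data.frame")
  validate_design(d)
  d
}

#' @rdname read_design_sheet
#' @param design design to write
#' @export
write_design_sheet <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a hybridization design
#'
#' Checks that every array's dye-swap mate exists, is reciprocal, and has
#' the same animals with roles exchanged (self-self pairs, where both roles
#' are one animal, are allowed).
#'
#' @param design `cgh_design` data.frame
#' @return the design, invisibly; errors on inconsistency
#' @export
validate_design <- function(design) {
  if (anyDuplicated(design$array_id))
    stop_invalid("duplicate array_id in design")
  for (i in seq_len(nrow(design))) {
    mate <- design[design$array_id == design$swap_of[i], , drop = FALSE]
    if (nrow(mate) != 1)
      stop_invalid("array %s: dye-swap mate %s missing from design",
                   design$array_id[i], design$swap_of[i])
    if (mate$swap_of != design$array_id[i] ||
        mate$cy3 != design$cy5[i] || mate$cy5 != design$cy3[i])
      stop_invalid("array %s and %s are not a consistent dye-swap pair",
                   design$array_id[i], mate$array_id)
  }
  invisible(design)
}

#' Write a genome model as FASTA plus a chromosome-size table
#'
#' Random sequence at the requested GC content, with assembly gaps written
#' as N runs; a `<prefix>.sizes.tsv` companion lists chromosome lengths.
#'
#' @param genome `cgh_genome`
#' @param path FASTA output path
#' @param gc genome GC fraction
#' @param seed integer seed
#' @return path, invisibly
#' @export
write_genome_fasta <- function(genome, path, gc = 0.418, seed = NULL) {
  seqs <- sim_genome_sequence(genome, gc = gc, seed = seed)
  Biostrings::writeXStringSet(seqs, path)
  sizes <- genome$chrom
  utils::write.table(sizes, paste0(tools::file_path_sans_ext(path), ".sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate genome sequence for a genome model
#'
#' I.i.d. bases at the given GC fraction; optional GC islands override the
#' composition locally; assembly gaps become N runs.
#'
#' @param genome `cgh_genome`
#' @param gc background GC fraction
#' @param islands optional data.frame (chrom, start, end, gc) of regions
#'   with their own GC composition
#' @param seed integer seed
#' @return [Biostrings::DNAStringSet] named by chromosome
#' @export
sim_genome_sequence <- function(genome, gc = 0.418, islands = NULL, seed = NULL) {
  stopifnot(inherits(genome, "cgh_genome"))
  if (gc < 0 || gc > 1) stop_invalid("gc must be in [0, 1]")
  draw <- function(n, g) sample(c("G", "C", "A", "T"), n, replace = TRUE,
                                prob = c(g / 2, g / 2, (1 - g) / 2, (1 - g) / 2))
  with_seed(seed, {
    seqs <- lapply(seq_len(nrow(genome$chrom)), function(i) {
      chrom <- genome$chrom$chrom[i]
      L <- genome$chrom$length[i]
      s <- draw(L, gc)
      if (!is.null(islands)) {
        isl <- islands[islands$chrom == chrom, , drop = FALSE]
        for (k in seq_len(nrow(isl)))
          s[(isl$start[k] + 1):isl$end[k]] <-
            draw(isl$end[k] - isl$start[k], isl$gc[k])
      }
      g <- genome$gaps[genome$gaps$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(g))) s[(g$start[k] + 1):g$end[k]] <- "N"
      paste(s, collapse = "")
    })
    names(seqs) <- genome$chrom$chrom
    Biostrings::DNAStringSet(unlist(seqs))
  })
}
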