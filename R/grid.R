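#' Genome grid at 1-kb resolution
#'
#' The model discretises the genome into 1-based, inclusive bins of exactly
#' 1000 bp. A `genome_grid` records, per chromosome, how many such bins it
#' spans; every simulator and analysis structure is laid out on this grid.
#'
#' @param chrom character vector of unique chromosome identifiers.
#' @param length_bins integer vector of chromosome lengths in 1-kb bins.
#' @return A `genome_grid`: a data frame with columns `chrom` and
#'   `length_bins`, ordered as given.
#' @examples
#' genome_grid(c("chrI", "chrII"), c(230, 813))
#' @export
genome_grid <- function(chrom, length_bins) {
  chrom <- as.character(chrom)
  length_bins <- as.integer(length_bins)
  if (length(chrom) != length(length_bins) || length(chrom) == 0)
    stop("chrom and length_bins must be non-empty vectors of equal length")
  if (anyDuplicated(chrom)) stop("chromosome ids must be unique")
  if (any(is.na(length_bins)) || any(length_bins < 1L))
    stop("every chromosome must span at least one 1-kb bin")
  structure(data.frame(chrom = chrom, length_bins = length_bins,
                       stringsAsFactors = FALSE),
            class = c("genome_grid", "data.frame"))
}

#' Read a genome grid definition
#'
#' Accepts either a two-column TSV (`chromosome`, `length_bp`) or a FASTA
#' index (`.fai`, as written by `samtools faidx`), from which chromosome
#' lengths in bp are converted to 1-kb bins by `ceiling(length_bp / 1000)`.
#'
#' @param path path to a grid TSV or a `.fai` file.
#' @return A [genome_grid()].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (nrow(tab) == 0) stop("empty grid file: ", path)
  # tolerate a header row on the 2-column TSV form
  if (!is.na(suppressWarnings(as.numeric(tab[1, 2])))) {
    first <- 1L
  } else {
    first <- 2L
    if (nrow(tab) < 2) stop("no data rows in grid file: ", path)
  }
  tab <- tab[first:nrow(tab), , drop = FALSE]
  len_bp <- suppressWarnings(as.numeric(tab[[2]]))
  if (any(is.na(len_bp)) || any(len_bp <= 0))
    stop("chromosome lengths must be positive numbers (bp)")
  genome_grid(tab[[1]], ceiling(len_bp / 1000))
}

#' @export
print.genome_grid <- function(x, ...) {
  cat("genome_grid:", nrow(x), "chromosome(s),",
      sum(x$length_bins), "kb total\n")
  NextMethod()
}

n_bins <- function(grid) sum(grid$length_bins)

grid_chrom_length <- function(grid, chrom) {
  i <- match(chrom, grid$chrom)
  if (anyNA(i)) stop("chromosome(s) not in grid: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  grid$length_bins[i]
}

# map a bp position (1-based) to its 1-kb bin
bp_to_bin <- function(pos_bp) floor((pos_bp - 1) / 1000) + 1
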