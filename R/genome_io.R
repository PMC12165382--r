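#' Read an origin catalog
#'
#' Reads replication-origin records in OriDB-style tab-separated form with a
#' header (`chromosome`, `start`, `end`, `status`, `name`) or as 4-column BED
#' (`chrom`, `start`, `end`, `name`) where the name field carries the status.
#' BED starts (0-based, half-open) are converted to 1-based inclusive
#' coordinates. Records are filtered to the requested status classes;
#' OriDB distinguishes `Confirmed`, `Likely` and `Dubious` origins and the
#' model conventionally keeps the first two.
#'
#' @param path path to the catalog file.
#' @param statuses character vector of status classes to retain.
#' @return A data frame (`origin_catalog`) with columns `chrom`, `start`,
#'   `end`, `status`, `name` in input order, filtered to `statuses`.
#' @export
read_origin_catalog <- function(path, statuses = c("Confirmed", "Likely")) {
  if (length(statuses) == 0)
    stop("statuses must name at least one origin class")
  bad_status <- setdiff(statuses, ORIGIN_STATUSES)
  if (length(bad_status) > 0)
    stop("unknown origin status requested: ", paste(bad_status, collapse = ", "))
  if (!file.exists(path)) stop("origin catalog not found: ", path)

  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", tolower(first))
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 4)
    stop("origin catalog needs at least 4 tab-separated columns")

  if (has_header) {
    names(tab) <- tolower(names(tab))
    cols <- c("chromosome", "start", "end", "status")
    if (!all(cols %in% names(tab)))
      stop("catalog header must contain: ", paste(cols, collapse = ", "))
    cat_df <- data.frame(chrom = as.character(tab$chromosome),
                         start = as.numeric(tab$start),
                         end = as.numeric(tab$end),
                         status = as.character(tab$status),
                         name = if ("name" %in% names(tab))
                           as.character(tab$name)
                         else paste0("origin_", seq_len(nrow(tab))),
                         stringsAsFactors = FALSE)
  } else {
    # BED: 0-based half-open, status in the name column
    cat_df <- data.frame(chrom = as.character(tab[[1]]),
                         start = as.numeric(tab[[2]]) + 1,
                         end = as.numeric(tab[[3]]),
                         status = as.character(tab[[4]]),
                         name = paste0("origin_", seq_len(nrow(tab))),
                         stringsAsFactors = FALSE)
  }
  if (any(is.na(cat_df$start)) || any(is.na(cat_df$end)))
    stop("non-numeric origin coordinates in ", path)
  if (any(cat_df$start < 1) || any(cat_df$start > cat_df$end))
    stop("origin coordinates must satisfy 1 <= start <= end")
  unknown <- which(!(cat_df$status %in% ORIGIN_STATUSES))
  if (length(unknown) > 0)
    stop("unknown origin status '", cat_df$status[unknown[1]],
         "' at row ", unknown[1])

  keep <- cat_df$status %in% statuses
  n_parsed <- nrow(cat_df)
  cat_df <- cat_df[keep, , drop = FALSE]
  rownames(cat_df) <- NULL
  if (nrow(cat_df) == 0)
    stop("no origins retained after filtering to {",
         paste(statuses, collapse = ", "), "}")
  message(sprintf("origin catalog: parsed %d records, retained %d with status {%s}",
                  n_parsed, nrow(cat_df), paste(statuses, collapse = ", ")))
  class(cat_df) <- c("origin_catalog", "data.frame")
  cat_df
}

ORIGIN_STATUSES <- c("Confirmed", "Likely", "Dubious")

#' Map catalog origins onto the 1-kb grid
#'
#' Each origin is assigned the bin containing the midpoint of its
#' (`start`, `end`) interval. Origins that land on the same bin are resolved
#' per `collision_rule`: keep the first record, keep the record with the
#' largest firing rate (requires `rates`), or raise an error.
#'
#' @param catalog an origin catalog data frame (`chrom`, `start`, `end`,
#'   `name`, ...).
#' @param grid a [genome_grid()].
#' @param collision_rule one of `"keep_first"`, `"merge_max_rate"`, `"error"`.
#' @param rates named numeric vector of firing rates (per origin name);
#'   required for `merge_max_rate`.
#' @return Data frame with columns `origin_id`, `chrom`, `bin`; at most one
#'   row per (chromosome, bin).
#' @export
map_origins_to_bins <- function(catalog, grid,
                                collision_rule = c("keep_first",
                                                   "merge_max_rate", "error"),
                                rates = NULL) {
  collision_rule <- match.arg(collision_rule)
  len <- grid_chrom_length(grid, catalog$chrom)
  mid <- (catalog$start + catalog$end) / 2
  bin <- bp_to_bin(mid)
  if (any(bin < 1) || any(bin > len))
    stop("origin midpoint falls outside its chromosome: ",
         paste(catalog$name[bin < 1 | bin > len], collapse = ", "))
  out <- data.frame(origin_id = catalog$name, chrom = catalog$chrom, bin = bin,
                    stringsAsFactors = FALSE)

  key <- paste(out$chrom, out$bin)
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    if (collision_rule == "error") {
      clash <- out$origin_id[key %in% dup_keys[1]]
      stop("origins share bin ", dup_keys[1], ": ",
           paste(clash, collapse = ", "))
    }
    keep <- !logical(nrow(out))
    for (k in dup_keys) {
      idx <- which(key == k)
      if (collision_rule == "merge_max_rate") {
        if (is.null(rates))
          stop("collision_rule = 'merge_max_rate' requires a rates vector")
        ri <- rates[out$origin_id[idx]]
        if (anyNA(ri)) stop("rates missing for colliding origins at bin ", k)
        winner <- idx[which.max(ri)]
      } else {
        winner <- idx[1]
      }
      keep[setdiff(idx, winner)] <- FALSE
      warning(sprintf("bin collision at %s: kept %s, dropped %s", k,
                      out$origin_id[winner],
                      paste(out$origin_id[setdiff(idx, winner)], collapse = ", ")),
              call. = FALSE)
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Timing profile on the 1-kb grid
#'
#' A replication-timing profile stores, for every bin of every chromosome,
#' the (population-mean) time in minutes at which that locus replicates,
#' plus a per-bin flag recording whether the value was measured or filled by
#' interpolation/extension.
#'
#' @param grid a [genome_grid()].
#' @param time named list (per chromosome) of numeric minute vectors, one
#'   value per bin.
#' @param measured named list of logical vectors matching `time`; defaults
#'   to all-measured.
#' @return A `timing_profile` object.
#' @export
timing_profile <- function(grid, time, measured = NULL) {
  stopifnot(inherits(grid, "genome_grid"))
  if (is.null(measured))
    measured <- lapply(time, function(v) rep(TRUE, length(v)))
  for (ch in grid$chrom) {
    v <- time[[ch]]
    if (is.null(v) || length(v) != grid_chrom_length(grid, ch))
      stop("timing vector for ", ch, " missing or wrong length")
    if (any(!is.finite(v)) || any(v < 0))
      stop("replication times must be finite and >= 0 (", ch, ")")
  }
  structure(list(grid = grid, time = time[grid$chrom],
                 measured = measured[grid$chrom]),
            class = "timing_profile")
}

#' @export
print.timing_profile <- function(x, ...) {
  v <- timing_values(x)
  cat(sprintf("timing_profile: %d chromosome(s), %d kb, range %.2f-%.2f min\n",
              nrow(x$grid), length(v), min(v), max(v)))
  invisible(x)
}

#' Flatten a timing profile to one numeric vector
#'
#' @param tp a [timing_profile()].
#' @return Numeric vector of per-bin times, chromosomes concatenated in grid
#'   order.
#' @export
timing_values <- function(tp) unlist(tp$time, use.names = FALSE)

#' Look up profile values at origin bins
#'
#' @param tp a [timing_profile()].
#' @param origins data frame with `chrom` and `bin` columns.
#' @return Numeric vector of times, one per origin row.
#' @export
timing_at_origins <- function(tp, origins) {
  mapply(function(ch, b) {
    v <- tp$time[[ch]]
    if (is.null(v)) stop("chromosome not in profile: ", ch)
    if (b < 1 || b > length(v)) stop("origin bin outside profile: ", ch, ":", b)
    v[b]
  }, origins$chrom, origins$bin, USE.NAMES = FALSE)
}

#' Read an experimental replication-timing profile
#'
#' Reads per-position replication times (minutes from S-phase onset) from
#' bedGraph (`chrom start end minutes`, 0-based half-open), 3-column TSV
#' (`chrom bin minutes`, 1-based bins), or fixed-step wig, and resamples
#' them onto the 1-kb grid. Bins between measured positions are filled by
#' linear interpolation; bins outside the measured span take the nearest
#' measured value. Both kinds of filled bin are flagged as interpolated.
#'
#' @param path input file; format chosen by extension (`.bedgraph`/`.bg`,
#'   `.wig`, else TSV).
#' @param grid a [genome_grid()].
#' @param origin_shift minutes subtracted from every value, to re-zero
#'   datasets whose clock does not start at S-phase onset (default 0).
#' @return A [timing_profile()].
#' @export
read_timing_profile <- function(path, grid, origin_shift = 0) {
  if (!file.exists(path)) stop("timing file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bedgraph", "bg")) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    tab <- tab[!grepl("^track", tab[[1]]), , drop = FALSE]
    pts <- data.frame(chrom = as.character(tab[[1]]),
                      bin = bp_to_bin((as.numeric(tab[[2]]) +
                                         as.numeric(tab[[3]])) / 2 + 1),
                      minutes = as.numeric(tab[[4]]),
                      stringsAsFactors = FALSE)
  } else if (ext == "wig") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading wig requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "wig")
    pts <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      bin = bp_to_bin((GenomicRanges::start(gr) +
                                         GenomicRanges::end(gr)) / 2),
                      minutes = gr$score, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (is.character(tab[[2]][1]) &&
        is.na(suppressWarnings(as.numeric(tab[[2]][1]))))
      tab <- tab[-1, , drop = FALSE]
    pts <- data.frame(chrom = as.character(tab[[1]]),
                      bin = as.integer(tab[[2]]),
                      minutes = as.numeric(tab[[3]]),
                      stringsAsFactors = FALSE)
  }
  if (any(is.na(pts$minutes)) || any(pts$minutes < 0))
    stop("replication times must be numeric and >= 0")
  pts$minutes <- pts$minutes - origin_shift
  if (any(pts$minutes < 0))
    stop("origin_shift produces negative replication times")

  time <- list(); measured <- list()
  for (ch in grid$chrom) {
    p <- pts[pts$chrom == ch, , drop = FALSE]
    if (nrow(p) == 0)
      stop("no measured timing points for chromosome ", ch)
    if (is.unsorted(p$bin, strictly = TRUE))
      stop("timing positions must be sorted and unique within ", ch)
    len <- grid_chrom_length(grid, ch)
    if (any(p$bin < 1) || any(p$bin > len))
      stop("timing position outside chromosome ", ch)
    if (nrow(p) == 1) {
      v <- rep(p$minutes, len)
    } else {
      v <- stats::approx(p$bin, p$minutes, xout = seq_len(len),
                         method = "linear", rule = 2)$y
    }
    m <- logical(len); m[p$bin] <- TRUE
    time[[ch]] <- v
    measured[[ch]] <- m
  }
  timing_profile(grid, time, measured)
}

#' Write a timing profile as bedGraph
#'
#' Each 1-kb bin becomes one 0-based half-open interval; values are written
#' at full precision so that a write/read round trip is exact.
#'
#' @param tp a [timing_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timing_bedgraph <- function(tp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in tp$grid$chrom) {
    v <- tp$time[[ch]]
    b <- seq_along(v)
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, (b - 1L) * 1000L, b * 1000L, v),
               con)
  }
  invisible(path)
}

#' Read/write per-origin firing-rate tables
#'
#' Rate tables are TSV with header `origin_id  chrom  bin  rate`; rates are
#' per minute per free firing factor.
#'
#' @param path file path.
#' @return `read_rate_table`: data frame with those four columns.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("rate table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("origin_id", "chrom", "bin", "rate")
  if (!all(need %in% names(tab)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(tab$rate)) || any(tab$rate <= 0))
    stop("firing rates must be finite and > 0")
  tab[need]
}

#' @rdname read_rate_table
#' @param rates data frame with columns `origin_id`, `chrom`, `bin`, `rate`.
#' @export
write_rate_table <- function(rates, path) {
  df <- rates[c("origin_id", "chrom", "bin", "rate")]
  df$rate <- sprintf("%.17g", df$rate)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
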