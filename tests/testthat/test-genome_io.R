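test_that("origin catalog reading filters by status and validates input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_origin_tsv(path, data.frame(
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(1000, 5000, 2000), end = c(2000, 6000, 3000),
    status = c("Confirmed", "Dubious", "Likely"),
    name = c("ARS101", "ARS102", "ARS201")))

  cat1 <- suppressMessages(read_origin_catalog(path,
                                               c("Confirmed", "Likely")))
  expect_equal(nrow(cat1), 2)
  expect_equal(cat1$name, c("ARS101", "ARS201"))

  # filtering is idempotent: re-filtering the retained records changes nothing
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_origin_tsv(path2, data.frame(chromosome = cat1$chrom,
                                     start = cat1$start, end = cat1$end,
                                     status = cat1$status, name = cat1$name))
  cat2 <- suppressMessages(read_origin_catalog(path2,
                                               c("Confirmed", "Likely")))
  expect_equal(cat2$name, cat1$name)
  expect_equal(cat2$start, cat1$start)

  expect_error(read_origin_catalog(path, character(0)), "at least one")
  expect_error(suppressMessages(read_origin_catalog(path, "Weird")),
               "unknown origin status")
  expect_error(suppressMessages(read_origin_catalog(path, "Dubious")),
               NA) # Dubious alone is a valid (if unusual) selection

  bad <- withr::local_tempfile(fileext = ".tsv")
  write_origin_tsv(bad, data.frame(chromosome = "chr1", start = 1, end = 999,
                                   status = "Sorta", name = "x"))
  expect_error(suppressMessages(read_origin_catalog(bad)), "row 1")
  expect_error(read_origin_catalog(tempfile(), "Confirmed"), "not found")
})

test_that("BED-style catalogs carry status in the name field", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1999\tConfirmed", "chr1\t4999\t5999\tDubious"),
             path)
  bed <- suppressMessages(read_origin_catalog(path, "Confirmed"))
  expect_equal(nrow(bed), 1)
  expect_equal(bed$start, 1000)  # 0-based half-open converted to 1-based
  expect_equal(bed$end, 1999)
})

test_that("origins map to the midpoint 1-kb bin with collision resolution", {
  grid <- genome_grid("chr1", 5)
  cat1 <- data.frame(chrom = "chr1", start = 1500, end = 2500,
                     name = "a", stringsAsFactors = FALSE)
  expect_equal(map_origins_to_bins(cat1, grid)$bin, 2)

  # midpoints 1200 and 1800 share bin 2
  cat2 <- data.frame(chrom = "chr1", start = c(1100, 1700),
                     end = c(1300, 1900), name = c("a", "b"),
                     stringsAsFactors = FALSE)
  kept <- suppressWarnings(map_origins_to_bins(cat2, grid, "keep_first"))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$origin_id, "a")
  expect_equal(kept$bin, 2)
  expect_error(map_origins_to_bins(cat2, grid, "error"), "a, b")
  by_rate <- suppressWarnings(
    map_origins_to_bins(cat2, grid, "merge_max_rate",
                        rates = c(a = 0.1, b = 0.5)))
  expect_equal(by_rate$origin_id, "b")

  beyond <- data.frame(chrom = "chr1", start = 5500, end = 6500, name = "z",
                       stringsAsFactors = FALSE)
  expect_error(map_origins_to_bins(beyond, grid), "outside")
  off_grid <- data.frame(chrom = "chrX", start = 1, end = 10, name = "z",
                         stringsAsFactors = FALSE)
  expect_error(map_origins_to_bins(off_grid, grid), "not in grid")
})

test_that("timing profiles interpolate gaps and extend edges", {
  grid <- genome_grid("c1", 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t1\t10", "c1\t3\t20"), path)
  tp <- read_timing_profile(path, grid)
  expect_equal(tp$time$c1, c(10, 15, 20))
  expect_equal(tp$measured$c1, c(TRUE, FALSE, TRUE))

  # bins outside the measured span take the nearest measured value
  grid4 <- genome_grid("c1", 4)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t2\t12", "c1\t4\t12"), path2)
  tp2 <- read_timing_profile(path2, grid4)
  expect_equal(tp2$time$c1, rep(12, 4))
  expect_false(tp2$measured$c1[1])

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t3\t20", "c1\t1\t10"), path3)
  expect_error(read_timing_profile(path3, grid), "sorted")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c1\t1\t-5", path4)
  expect_error(read_timing_profile(path4, grid), ">= 0")
  path5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c2\t1\t5", path5)
  expect_error(read_timing_profile(path5, grid), "no measured timing")
})

test_that("interpolated values never leave the measured range", {
  set.seed(7)
  for (rep in 1:5) {
    len <- sample(20:60, 1)
    grid <- genome_grid("c1", len)
    bins <- sort(sample.int(len, sample(3:8, 1)))
    vals <- round(runif(length(bins), 5, 60), 3)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(sprintf("c1\t%d\t%g", bins, vals), path)
    tp <- read_timing_profile(path, grid)
    expect_true(all(tp$time$c1 >= min(vals) - 1e-12))
    expect_true(all(tp$time$c1 <= max(vals) + 1e-12))
    expect_equal(tp$time$c1[bins], vals)
  }
})

test_that("bedGraph write/read round trip reproduces bin values exactly", {
  grid <- genome_grid(c("c1", "c2"), c(7, 4))
  set.seed(11)
  tp <- timing_profile(grid, list(c1 = runif(7, 1, 50), c2 = runif(4, 1, 50)))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_timing_bedgraph(tp, path)
  tp2 <- read_timing_profile(path, grid)
  expect_identical(tp2$time$c1, tp$time$c1)
  expect_identical(tp2$time$c2, tp$time$c2)
})

test_that("grid definitions load from TSV and FASTA index", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t230218", "chr2\t813184"), path)
  g <- read_grid(path)
  expect_equal(g$length_bins, c(231, 814))

  fai <- withr::local_tempfile(fileext = ".fai")
  writeLines(c("chr1\t230218\t6\t60\t61", "chr2\t813184\t234067\t60\t61"), fai)
  expect_equal(read_grid(fai)$length_bins, c(231, 814))

  expect_error(genome_grid(c("a", "a"), c(2, 3)), "unique")
  expect_error(genome_grid("a", 0), "at least one")
})

test_that("rate tables round-trip through TSV", {
  rates <- data.frame(origin_id = c("o1", "o2"), chrom = "c1",
                      bin = c(3L, 9L), rate = c(1.234e-4, 0.05),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rates, path)
  back <- read_rate_table(path)
  expect_equal(back$rate, rates$rate)
  expect_equal(back$bin, rates$bin)
})
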