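test_that("pairs TSV round-trips byte-identically", {
  pairs <- tibble::tibble(
    id = c("r1", "r2", "r3"),
    chr1 = c("A", "A", "B"), pos1 = c(100, 250, 7),
    chr2 = c("B", "A", "B"), pos2 = c(900, 301, 44),
    strand1 = c("+", "-", "+"), strand2 = c("-", "-", "+"),
    mapq1 = c(60, 20, 60), mapq2 = c(60, 60, 10), dup = FALSE
  )
  path <- withr::local_tempfile(fileext = ".pairs")
  write_pairs(pairs, path)
  back <- read_pairs(path)
  expect_equal(as.data.frame(back), as.data.frame(pairs))
  path2 <- withr::local_tempfile(fileext = ".pairs")
  write_pairs(back, path2)
  expect_identical(readr::read_lines(path), readr::read_lines(path2))
  # malformed line is reported with its number
  bad <- withr::local_tempfile()
  readr::write_lines(c("# header", "r1\tA\t1\tB", "x"), bad)
  expect_error(read_pairs(bad, format = "pairs"), "line")
})

test_that("SAM input yields 0-based mate-paired records", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ctgA\tLN:10000",
    "@SQ\tSN:ctgB\tLN:8000",
    # proper pair ctgA:101 (fwd) / ctgB:201 (rev), 1-based SAM
    paste("p1", 65, "ctgA", 101, 60, "10M", "=", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("p1", 145, "ctgB", 201, 55, "10M", "=", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    # duplicate-flagged pair
    paste("p2", 1089, "ctgA", 301, 60, "10M", "=", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("p2", 1153, "ctgA", 401, 60, "10M", "=", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    # unpaired read: skipped and tallied
    paste("p3", 0, "ctgB", 11, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t")
  ), sam)
  pp <- read_pairs(sam, format = "sam")
  expect_equal(nrow(pp), 2)
  p1 <- pp[pp$id == "p1", ]
  expect_equal(p1$pos1, 100)            # 1-based -> 0-based
  expect_equal(p1$pos2, 200)
  expect_equal(p1$chr2, "ctgB")
  expect_equal(p1$strand2, "-")
  expect_equal(p1$mapq2, 55)
  expect_false(p1$dup)
  expect_true(pp$dup[pp$id == "p2"])
  expect_equal(attr(pp, "n_unpaired"), 1)
})

test_that("simulator output survives a pairs-file round trip", {
  cfg <- sim_config(genome_length = 1e6, n_pairs = 500, seed = 44,
                    contig_law = law_constant(50000))
  fr <- fragment_into_contigs(cfg)
  sim <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
  path <- withr::local_tempfile(fileext = ".pairs.gz")
  write_pairs(sim$pairs, path)
  back <- read_pairs(path)
  cols <- c("id", "chr1", "pos1", "chr2", "pos2", "strand1", "strand2",
            "mapq1", "mapq2")
  expect_equal(as.data.frame(back[cols]), as.data.frame(sim$pairs[cols]))
})

test_that("AGP writing round-trips and FASTA honours orientation and gaps", {
  skip_if_not_installed("Biostrings")
  layout <- tibble::tibble(
    scaffold = c("sc1", "sc1", "sc2"),
    idx = c(1L, 2L, 1L),
    contig = c("A", "B", "C"),
    orientation = c("+", "-", "+"),
    gap_before = c(0, 120, 0)
  )
  contigs <- tibble::tibble(contig = c("A", "B", "C"),
                            length = c(30, 20, 10))
  agp <- withr::local_tempfile(fileext = ".agp")
  write_agp(layout, contigs, agp)
  back <- read_agp(agp)
  expect_equal(as.data.frame(back), as.data.frame(layout))

  seqs <- Biostrings::DNAStringSet(c(
    A = paste(rep("ACGTA", 6), collapse = ""),
    B = paste(rep("GGCC", 5), collapse = ""),
    C = "ACGTACGTAC"
  ))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_scaffold_fasta(layout, seqs, fa)
  out <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(out[["sc2"]]), "ACGTACGTAC")
  sc1 <- as.character(out[["sc1"]])
  expect_equal(nchar(sc1), 30 + 120 + 20)
  expect_equal(substr(sc1, 1, 30), as.character(seqs[["A"]]))
  expect_equal(substr(sc1, 31, 150), strrep("N", 120))
  expect_equal(substr(sc1, 151, 170),
               as.character(Biostrings::reverseComplement(seqs[["B"]])))
  # gaps below the AGP minimum are written as 10 bp
  tiny <- layout
  tiny$gap_before[2] <- 3
  agp2 <- withr::local_tempfile(fileext = ".agp")
  write_agp(tiny, contigs, agp2)
  expect_equal(read_agp(agp2)$gap_before[2], 10)
})

test_that("bed/bedGraph/truth-map writers produce parseable text", {
  iv <- tibble::tibble(chrom = c("c1", "c2"), start = c(0, 50),
                       end = c(10, 99))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, bed)
  expect_equal(readr::read_lines(bed), c("c1\t0\t10", "c2\t50\t99"))
  prof <- tibble::tibble(pos = c(500, 1000), n_span = c(3L, 4L),
                         llr = c(1.5, -2.25))
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(prof, "ctg1", bg)
  expect_match(readr::read_lines(bg)[2], "ctg1\t750\t1250\t-2.25")
  tm <- tibble::tibble(contig = "A", part = 1L, c_start = 0, c_end = 10,
                       chrom = "chr1", start = 5, end = 15, strand = "+")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_truth_map(tm, tf)
  expect_equal(as.data.frame(read_truth_map(tf)), as.data.frame(tm))
})

test_that("N50 definition and QC on a perfect reconstruction", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(n50(numeric(0)), 0)

  cfg <- sim_config(genome_length = 2e6, n_chromosomes = 2, seed = 50,
                    contig_law = law_constant(50000), n_pairs = 10)
  fr <- fragment_into_contigs(cfg)
  truth <- fr$truth
  # rebuild the true layout: contigs in genomic order, orientation matching
  # the placement strand, gaps as simulated
  perfect <- truth %>%
    dplyr::group_by(chrom) %>%
    dplyr::arrange(start, .by_group = TRUE) %>%
    dplyr::mutate(scaffold = chrom, idx = dplyr::row_number(),
                  orientation = strand,
                  gap_before = ifelse(idx == 1, 0,
                                      start - dplyr::lag(end))) %>%
    dplyr::ungroup() %>%
    dplyr::select(scaffold, idx, contig, orientation, gap_before)
  qc <- qc_metrics(perfect, fr$contigs, truth, spacing = 1000)
  expect_equal(qc$misjoin_frac_5k, 0)
  expect_equal(qc$misjoin_frac_10k, 0)
  expect_equal(qc$misjoin_frac_50k, 0)
  expect_equal(qc$strand_switches, 0)
  expect_equal(qc$gap_discrepancy_p95, 0)
  expect_equal(qc$n50, n50(2e6 / 2 + numeric(2)))
})

test_that("a planted cross-chromosome fusion is flagged at every threshold", {
  cfg <- sim_config(genome_length = 2e6, n_chromosomes = 2, seed = 51,
                    contig_law = law_constant(50000), n_pairs = 10)
  fr <- fragment_into_contigs(cfg)
  truth <- fr$truth
  ord <- truth %>% dplyr::arrange(chrom, start)
  chr1 <- ord$contig[ord$chrom == "chr1"]
  chr2 <- ord$contig[ord$chrom == "chr2"]
  fused <- dplyr::bind_rows(
    tibble::tibble(scaffold = "fused", idx = seq_along(c(chr1[1:3], chr2[1:3])),
                   contig = c(chr1[1:3], chr2[1:3])),
    tibble::tibble(scaffold = "rest1", idx = seq_along(chr1[-(1:3)]),
                   contig = chr1[-(1:3)]),
    tibble::tibble(scaffold = "rest2", idx = seq_along(chr2[-(1:3)]),
                   contig = chr2[-(1:3)])
  ) %>%
    dplyr::mutate(orientation = truth$strand[match(contig, truth$contig)],
                  gap_before = ifelse(idx == 1, 0, 100))
  qc <- qc_metrics(fused, fr$contigs, truth, spacing = 1000)
  spans <- fused %>%
    dplyr::left_join(fr$contigs, by = "contig") %>%
    dplyr::group_by(scaffold) %>%
    dplyr::summarise(span = sum(length) + sum(gap_before))
  expected_frac <- spans$span[spans$scaffold == "fused"] / sum(spans$span)
  expect_equal(qc$misjoin_frac_5k, expected_frac, tolerance = 1e-9)
  expect_equal(qc$misjoin_frac_50k, expected_frac, tolerance = 1e-9)
  expect_equal(qc$n_misjoined_scaffolds, 1)
})

test_that("QC is invariant under scaffold relabeling and global flips", {
  cfg <- sim_config(genome_length = 2e6, n_chromosomes = 2, seed = 52,
                    contig_law = law_constant(40000), n_pairs = 10)
  fr <- fragment_into_contigs(cfg)
  truth <- fr$truth
  base <- truth %>%
    dplyr::group_by(chrom) %>%
    dplyr::arrange(start, .by_group = TRUE) %>%
    dplyr::mutate(scaffold = chrom, idx = dplyr::row_number(),
                  orientation = strand,
                  gap_before = ifelse(idx == 1, 0, start - dplyr::lag(end))) %>%
    dplyr::ungroup() %>%
    dplyr::select(scaffold, idx, contig, orientation, gap_before)
  q0 <- qc_metrics(base, fr$contigs, truth, spacing = 1000)
  # relabel scaffolds
  relab <- base %>% dplyr::mutate(scaffold = paste0("x_", scaffold))
  q1 <- qc_metrics(relab, fr$contigs, truth, spacing = 1000)
  expect_equal(q1$n50, q0$n50)
  expect_equal(q1$strand_switches, q0$strand_switches)
  expect_equal(q1$misjoin_frac_5k, q0$misjoin_frac_5k)
  # globally flip one scaffold (reverse order, flip orientations)
  flip1 <- base %>%
    dplyr::group_by(scaffold) %>%
    dplyr::arrange(dplyr::desc(idx), .by_group = TRUE) %>%
    dplyr::mutate(
      orientation = ifelse(scaffold == "chr1",
                           ifelse(orientation == "+", "-", "+"), orientation),
      gb = gap_before
    ) %>%
    dplyr::mutate(idx2 = dplyr::row_number()) %>%
    dplyr::ungroup()
  flip1 <- flip1 %>%
    dplyr::group_by(scaffold) %>%
    dplyr::mutate(gap_before = ifelse(scaffold == "chr1",
                                      c(0, rev(gb[-1])), gb),
                  idx = ifelse(scaffold == "chr1", idx2, idx)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(scaffold, idx) %>%
    dplyr::select(scaffold, idx, contig, orientation, gap_before)
  flip1 <- flip1[!(flip1$scaffold == "chr2"), ]
  flip1 <- dplyr::bind_rows(flip1, base[base$scaffold == "chr2", ])
  q2 <- qc_metrics(flip1, fr$contigs, truth, spacing = 1000)
  expect_equal(q2$strand_switches, q0$strand_switches)
  expect_equal(q2$misjoin_frac_5k, q0$misjoin_frac_5k)
})
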