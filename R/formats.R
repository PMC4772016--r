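#' Read mapped pairs from a pairs TSV or SAM/BAM file
#'
#' The pairs format is a 4DN-style TSV with `#`-prefixed header lines and
#' columns `readID chr1 pos1 chr2 pos2 strand1 strand2` plus two optional
#' extension columns `mapq1 mapq2` (assumed 60 when absent); positions are
#' 0-based. SAM/BAM input is parsed with Rsamtools: primary alignments are
#' mate-paired by read name, 1-based positions are converted to 0-based,
#' strands come from the reverse flag and the duplicate flag from the SAM
#' duplicate bit; reads without a mapped mate are skipped and tallied.
#'
#' @param path input file (pairs TSVs may be gzipped).
#' @param format `"auto"` (by extension), `"pairs"`, `"sam"` or `"bam"`.
#' @return a pair tibble (`id`, `chr1`, `pos1`, `chr2`, `pos2`, `strand1`,
#'   `strand2`, `mapq1`, `mapq2`, `dup`), with attribute `n_unpaired` for
#'   SAM/BAM input.
#' @export
read_pairs <- function(path, format = c("auto", "pairs", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path)) "bam"
    else if (grepl("\\.sam$", path)) "sam"
    else "pairs"
  }
  if (format == "pairs") return(read_pairs_tsv(path))
  read_pairs_bam(path, sam = format == "sam")
}

read_pairs_tsv <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble(id = character(0), chr1 = character(0), pos1 = numeric(0),
                  chr2 = character(0), pos2 = numeric(0),
                  strand1 = character(0), strand2 = character(0),
                  mapq1 = numeric(0), mapq2 = numeric(0), dup = logical(0)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 7 & nf != 9)
  if (length(bad) > 0) {
    abort(sprintf("malformed pairs line %d: expected 7 or 9 columns, got %d",
                  which(!startsWith(lines, "#"))[bad[1]], nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  tibble(
    id = m[, 1], chr1 = m[, 2], pos1 = as.numeric(m[, 3]),
    chr2 = m[, 4], pos2 = as.numeric(m[, 5]),
    strand1 = m[, 6], strand2 = m[, 7],
    mapq1 = if (ncol(m) >= 9) as.numeric(m[, 8]) else 60,
    mapq2 = if (ncol(m) >= 9) as.numeric(m[, 9]) else 60,
    dup = FALSE
  )
}

read_pairs_bam <- function(path, sam = FALSE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("SAM/BAM input needs the Rsamtools package")
  }
  if (sam) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "mapq", "strand"))
  b <- Rsamtools::scanBam(path, param = prm)[[1]]
  df <- tibble(qname = b$qname, flag = b$flag,
               chrom = as.character(b$rname), pos = b$pos - 1,
               mapq = b$mapq,
               strand = as.character(b$strand),
               dup = bitwAnd(b$flag, 1024L) > 0,
               first = bitwAnd(b$flag, 64L) > 0)
  tallies <- df %>% dplyr::count(.data$qname)
  paired <- tallies$qname[tallies$n == 2]
  n_unpaired <- sum(tallies$n != 2)
  df <- df[df$qname %in% paired, , drop = FALSE] %>%
    arrange(.data$qname, desc(.data$first))
  a <- df[seq(1, nrow(df), by = 2), ]
  b2 <- df[seq(2, nrow(df), by = 2), ]
  out <- tibble(
    id = a$qname, chr1 = a$chrom, pos1 = a$pos, chr2 = b2$chrom,
    pos2 = b2$pos, strand1 = a$strand, strand2 = b2$strand,
    mapq1 = a$mapq, mapq2 = b2$mapq, dup = a$dup | b2$dup
  )
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' Write pairs as a 4DN-style pairs TSV
#'
#' Columns `readID chr1 pos1 chr2 pos2 strand1 strand2 mapq1 mapq2`;
#' gzip-compressed when `path` ends in `.gz`. Round-trips byte-identically
#' through [read_pairs()].
#'
#' @param pairs pair tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  hdr <- c("## pairs format v1.0",
           "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2 mapq1 mapq2")
  body <- sprintf("%s\t%s\t%d\t%s\t%d\t%s\t%s\t%d\t%d",
                  pairs$id %||% sprintf("pair%07d", seq_len(nrow(pairs))),
                  pairs$chr1, as.integer(pairs$pos1), pairs$chr2,
                  as.integer(pairs$pos2), pairs$strand1, pairs$strand2,
                  as.integer(pairs$mapq1), as.integer(pairs$mapq2))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Write a scaffold layout as AGP v2.1 (and read it back)
#'
#' Emits one `W` component line per contig (orientation in column 9) and one
#' `N` gap line per inter-contig gap (gap sizes floored at 10 bp, type
#' `scaffold`, linkage `yes`, evidence `proximity_ligation`). AGP
#' coordinates are 1-based inclusive; the conversion from the package's
#' 0-based half-open layout happens here and in [read_agp()], which inverts
#' it exactly.
#'
#' @param layout layout tibble.
#' @param contigs tibble `contig`, `length`.
#' @param path output path.
#' @return `path` invisibly (`write_agp`); a layout tibble (`read_agp`).
#' @export
write_agp <- function(layout, contigs, path) {
  lines <- c("##agp-version 2.1")
  for (s in unique(layout$scaffold)) {
    sub <- layout[layout$scaffold == s, , drop = FALSE]
    sub <- sub[order(sub$idx), ]
    pos <- 0
    part <- 0
    for (i in seq_len(nrow(sub))) {
      gap <- if (i == 1) 0 else max(round(sub$gap_before[i]), 10)
      if (i > 1) {
        part <- part + 1
        lines <- c(lines, sprintf(
          "%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\tproximity_ligation",
          s, pos + 1, pos + gap, part, gap))
        pos <- pos + gap
      }
      len <- contigs$length[match(sub$contig[i], contigs$contig)]
      part <- part + 1
      lines <- c(lines, sprintf(
        "%s\t%d\t%d\t%d\tW\t%s\t1\t%d\t%s",
        s, pos + 1, pos + len, part, sub$contig[i], len,
        sub$orientation[i]))
      pos <- pos + len
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map_dfr(f, function(x) {
    tibble(scaffold = x[1], type = x[5],
           contig = if (x[5] == "W") x[6] else NA_character_,
           orientation = if (x[5] == "W") x[9] else NA_character_,
           size = as.numeric(if (x[5] == "W") x[8] else x[6]))
  })
  out <- list()
  for (s in unique(rows$scaffold)) {
    sub <- rows[rows$scaffold == s, ]
    gap <- 0
    idx <- 0
    for (i in seq_len(nrow(sub))) {
      if (sub$type[i] == "N" || sub$type[i] == "U") {
        gap <- sub$size[i]
      } else {
        idx <- idx + 1
        out[[length(out) + 1]] <- tibble(
          scaffold = s, idx = idx, contig = sub$contig[i],
          orientation = sub$orientation[i],
          gap_before = if (idx == 1) 0 else gap)
        gap <- 0
      }
    }
  }
  bind_rows(out)
}

#' Write scaffold sequences as FASTA
#'
#' Assembles each scaffold sequence from its contig sequences (reverse
#' complementing minus-orientation contigs) with `N` runs of the estimated
#' gap lengths (minimum 10) between them.
#'
#' @param layout layout tibble.
#' @param sequences a named `Biostrings::DNAStringSet` of contig sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_scaffold_fasta <- function(layout, sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTA output needs the Biostrings package")
  }
  missing <- setdiff(layout$contig, names(sequences))
  if (length(missing) > 0) {
    abort(paste("missing sequence for contig(s):",
                paste(head(missing, 3), collapse = ", ")))
  }
  seqs <- character(0)
  for (s in unique(layout$scaffold)) {
    sub <- layout[layout$scaffold == s, , drop = FALSE]
    sub <- sub[order(sub$idx), ]
    parts <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      seg <- as.character(sequences[[sub$contig[i]]])
      if (sub$orientation[i] == "-") {
        seg <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(seg)))
      }
      gap <- if (i == 1) "" else
        strrep("N", max(round(sub$gap_before[i]), 10))
      parts[i] <- paste0(gap, seg)
    }
    seqs[s] <- paste(parts, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Write intervals as BED / a profile as bedGraph
#'
#' Plain 0-based half-open BED3 (`write_bed`) and 4-column bedGraph of a
#' support profile (`write_bedgraph`; each grid position covers one stride).
#'
#' @param intervals tibble `chrom`, `start`, `end`.
#' @param profile a [support_profile()] tibble plus a `contig` name.
#' @param contig contig name for the bedGraph.
#' @param stride grid stride of the profile (bp).
#' @param value which profile column to write (default `llr`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  readr::write_lines(sprintf("%s\t%d\t%d", intervals$chrom,
                             as.integer(intervals$start),
                             as.integer(intervals$end)), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_bedgraph <- function(profile, contig, path, stride = 500,
                           value = "llr") {
  readr::write_lines(sprintf("%s\t%d\t%d\t%.6g", contig,
                             as.integer(profile$pos - stride / 2),
                             as.integer(profile$pos + stride / 2),
                             profile[[value]]), path)
  invisible(path)
}

#' Read a bedGraph depth track
#'
#' @param path bedGraph file (`chrom start end depth`, 0-based half-open).
#' @return tibble `chrom`, `start`, `end`, `depth`.
#' @export
read_depth <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                  col_types = "ciid", comment = "#")
}

#' Write / read a truth map as TSV
#'
#' Documented columns: `contig part c_start c_end chrom start end strand`;
#' all coordinates 0-based half-open.
#'
#' @param truth truth-map tibble.
#' @param path file path (gzip by extension).
#' @return `path` invisibly / a truth tibble.
#' @export
write_truth_map <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_map
#' @export
read_truth_map <- function(path) {
  readr::read_tsv(path, col_types = "ciddcddc")
}
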