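#' Build a CpG coordinate index from a reference FASTA
#'
#' Scans a reference genome for CpG dinucleotides and numbers them
#' CpG_1 .. CpG_N genome-wide, in chromosome appearance order. All other
#' modules address the genome through this index: a fragment's position is
#' the global index of its first covered CpG, and per-CpG count vectors have
#' length N. Detection is case-insensitive (soft-masked lowercase repeats are
#' included); dinucleotides containing N or any other ambiguity code are
#' excluded.
#'
#' @param fasta Path to a FASTA file (plain or gzip-compressed).
#' @return A `GenomeIndex` object: a list with elements
#'   \describe{
#'     \item{chrom_order}{chromosome names in FASTA appearance order}
#'     \item{cpg_positions}{named list of sorted 1-based genomic positions of
#'       the C of each CpG}
#'     \item{chrom_offsets}{named integer vector; number of CpGs on earlier
#'       chromosomes, so chromosome `c`'s first global index is
#'       `chrom_offsets[c] + 1`}
#'     \item{chrom_sizes}{named integer vector of sequence lengths}
#'     \item{total_cpgs}{N, the genome-wide CpG count}
#'   }
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTCGG"), fa)
#' idx <- build_index(fa)
#' idx$total_cpgs            # 2
#' idx$cpg_positions$chr1    # 2 5
#' @export
build_index <- function(fasta) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) stop("unreadable FASTA '", fasta, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(seqs) <- nm
  # DNAStringSet uppercases on read, so soft-masked CpGs are found; fixed
  # matching keeps IUPAC ambiguity codes (incl. N) from matching C or G.
  hits <- Biostrings::vmatchPattern("CG", seqs, fixed = TRUE)
  positions <- lapply(hits, function(h) BiocGenerics::start(h))
  positions <- lapply(positions, as.integer)
  names(positions) <- nm
  counts <- vapply(positions, length, integer(1))
  offsets <- c(0L, cumsum(counts))[seq_along(nm)]
  names(offsets) <- nm
  structure(list(
    chrom_order   = nm,
    cpg_positions = positions,
    chrom_offsets = offsets,
    chrom_sizes   = stats::setNames(Biostrings::width(seqs), nm),
    total_cpgs    = sum(counts)
  ), class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex:", length(x$chrom_order), "sequence(s),",
      x$total_cpgs, "CpG sites\n")
  n <- min(5L, length(x$chrom_order))
  for (ch in x$chrom_order[seq_len(n)]) {
    cat(sprintf("  %s: %d CpGs (offset %d)\n", ch,
                length(x$cpg_positions[[ch]]), x$chrom_offsets[[ch]]))
  }
  if (length(x$chrom_order) > n) cat("  ...\n")
  invisible(x)
}

#' Save / load a genome index
#'
#' The index is persisted as a two-column TSV (chromosome, 1-based position
#' of the CpG's C) preceded by header lines carrying the format version and
#' chromosome sizes, so downstream commands can reload it by path instead of
#' re-scanning the FASTA.
#'
#' @param index A `GenomeIndex`.
#' @param path Output (input) file path.
#' @return `write_index` returns `path` invisibly; `read_index` returns a
#'   `GenomeIndex`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "GenomeIndex"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#fragmeth_index\tv1", con)
  writeLines(sprintf("#size\t%s\t%d", index$chrom_order,
                     index$chrom_sizes[index$chrom_order]), con)
  dt <- data.table::data.table(
    chrom = rep(index$chrom_order,
                vapply(index$cpg_positions[index$chrom_order], length,
                       integer(1))),
    pos = unlist(index$cpg_positions[index$chrom_order], use.names = FALSE))
  if (nrow(dt)) {
    writeLines(paste(dt$chrom, dt$pos, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1]], "#fragmeth_index")) {
    stop("not a fragmeth index file: ", path)
  }
  hdr <- lines[startsWith(lines, "#size\t")]
  body <- lines[!startsWith(lines, "#")]
  sz <- do.call(rbind, strsplit(hdr, "\t", fixed = TRUE))
  chroms <- sz[, 2]
  sizes <- stats::setNames(as.integer(sz[, 3]), chroms)
  positions <- stats::setNames(
    rep(list(integer(0)), length(chroms)), chroms)
  if (length(body)) {
    parts <- data.table::fread(text = body, header = FALSE,
                               col.names = c("chrom", "pos"))
    by_ch <- split(as.integer(parts$pos), parts$chrom)
    positions[names(by_ch)] <- by_ch
  }
  counts <- vapply(positions, length, integer(1))
  offsets <- stats::setNames(c(0L, cumsum(counts))[seq_along(chroms)], chroms)
  structure(list(chrom_order = chroms, cpg_positions = positions,
                 chrom_offsets = offsets, chrom_sizes = sizes,
                 total_cpgs = sum(counts)),
            class = "GenomeIndex")
}

#' Translate between genomic loci and global CpG indices
#'
#' `locus_to_cpg` is exact-match: `pos` must be the 1-based position of a
#' CpG's C. `cpg_to_locus` is its inverse. `region_to_cpg_range` maps a
#' 0-based half-open genomic interval to the half-open global CpG index range
#' `[start_cpg, end_cpg)` of the CpGs whose C lies inside it; intervals
#' covering no CpG return an empty range at the insertion point.
#'
#' @param index A `GenomeIndex`.
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position of a CpG's C.
#' @return `locus_to_cpg`: the global CpG index (integer).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTCGG"), fa)
#' idx <- build_index(fa)
#' locus_to_cpg(idx, "chr1", 5)        # 2
#' cpg_to_locus(idx, 2)                # chr1:5
#' region_to_cpg_range(idx, "chr1", 0, 7)  # [1, 3)
#' @export
locus_to_cpg <- function(index, chrom, pos) {
  p <- index$cpg_positions[[chrom]]
  if (is.null(p)) stop("unknown chromosome: ", chrom)
  i <- findInterval(pos, p)
  if (i == 0L || p[i] != pos) {
    stop("position ", chrom, ":", pos, " is not a CpG site")
  }
  unname(index$chrom_offsets[[chrom]] + i)
}

#' @rdname locus_to_cpg
#' @param cpg Global CpG index in `1..N`.
#' @return `cpg_to_locus`: list with `chrom` and 1-based `pos`.
#' @export
cpg_to_locus <- function(index, cpg) {
  if (!is_count(cpg) || cpg < 1L || cpg > index$total_cpgs) {
    stop("CpG index out of range [1, ", index$total_cpgs, "]: ", cpg)
  }
  off <- index$chrom_offsets
  k <- findInterval(cpg - 1L, off)   # last chromosome with offset < cpg
  chrom <- index$chrom_order[[k]]
  list(chrom = chrom,
       pos = index$cpg_positions[[chrom]][[cpg - off[[k]]]])
}

#' @rdname locus_to_cpg
#' @param start,end 0-based half-open genomic interval bounds.
#' @return `region_to_cpg_range`: list with global `start_cpg`, `end_cpg`
#'   (half-open).
#' @export
region_to_cpg_range <- function(index, chrom, start, end) {
  p <- index$cpg_positions[[chrom]]
  if (is.null(p)) stop("unknown chromosome: ", chrom)
  stopifnot(start >= 0, end >= start)
  off <- index$chrom_offsets[[chrom]]
  # 0-based start: a CpG at 1-based position q is inside iff q > start, q <= end
  s <- findInterval(start, p) + 1L
  e <- findInterval(end, p) + 1L
  list(start_cpg = unname(off + s), end_cpg = unname(off + e))
}

#' Append CpG index columns to a BED table
#'
#' For each interval of a BED-style table (0-based half-open), appends
#' `startCpG` and `endCpG`: the half-open global CpG index range covered.
#' Rows covering no CpG keep their (empty) insertion-point range. Row order
#' is preserved.
#'
#' @param index A `GenomeIndex`.
#' @param bed A data.frame whose first three columns are chrom, start, end
#'   (additional payload columns are carried through), or a path to a BED
#'   file.
#' @param strict If `TRUE`, a malformed row or unknown chromosome aborts;
#'   otherwise the row is dropped with a warning naming its line number.
#' @return The input table with integer `startCpG` and `endCpG` columns
#'   appended.
#' @export
convert_bed <- function(index, bed, strict = FALSE) {
  if (is.character(bed) && length(bed) == 1L) {
    bed <- utils::read.delim(bed, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
  }
  bed <- as.data.frame(bed)
  if (nrow(bed) == 0L) {
    bed$startCpG <- integer(0); bed$endCpG <- integer(0)
    return(bed)
  }
  if (ncol(bed) < 3L) stop("BED input needs at least 3 columns")
  chrom <- as.character(bed[[1]])
  start <- suppressWarnings(as.numeric(bed[[2]]))
  end <- suppressWarnings(as.numeric(bed[[3]]))
  bad <- is.na(start) | is.na(end) | start < 0 | end < start |
    !(chrom %in% index$chrom_order)
  if (any(bad)) {
    msg <- paste0("malformed or unmappable BED row(s) at line(s): ",
                  paste(which(bad), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; dropped")
    bed <- bed[!bad, , drop = FALSE]
    chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
  }
  rng <- mapply(function(ch, s, e) {
    r <- region_to_cpg_range(index, ch, s, e)
    c(r$start_cpg, r$end_cpg)
  }, chrom, start, end, SIMPLIFY = TRUE)
  if (length(rng) == 0L) rng <- matrix(integer(0), nrow = 2)
  bed$startCpG <- as.integer(rng[1, ])
  bed$endCpG <- as.integer(rng[2, ])
  bed
}

#' URL of a UCSC reference genome FASTA
#'
#' Convenience for fetching a named assembly before [build_index()]; the
#' download itself is left to the caller (e.g. `curl`), keeping the package
#' network-free.
#'
#' @param genome Assembly name, e.g. `"hg19"`, `"hg38"`, `"mm10"`.
#' @return The URL string of the gzip-compressed assembly FASTA.
#' @export
ucsc_genome_url <- function(genome) {
  sprintf("https://hgdownload.soe.ucsc.edu/goldenPath/%s/bigZips/%s.fa.gz",
          genome, genome)
}
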