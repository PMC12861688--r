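#' Conversion parameters for aligned-read methylation calling
#'
#' Defaults follow common bisulfite practice: require properly-paired reads
#' (`-f 3`, applied only when the file contains paired-end reads), exclude
#' unmapped/secondary/duplicate/QC-fail reads (`-F 1796`), and require
#' mapping quality at least 10. `long_read = TRUE` switches to
#' base-modification (MM/ML tag) calling with no mate merging.
#'
#' @param require_flags SAM flag bits that must all be set (paired-end files
#'   only).
#' @param exclude_flags SAM flag bits none of which may be set.
#' @param min_mapq Minimum mapping quality.
#' @param long_read Call methylation from MM/ML base-modification tags.
#' @return A `ConversionParams` list.
#' @export
conversion_params <- function(require_flags = 3L, exclude_flags = 1796L,
                              min_mapq = 10L, long_read = FALSE) {
  stopifnot(require_flags >= 0L, require_flags < 65536L,
            exclude_flags >= 0L, exclude_flags < 65536L, min_mapq >= 0L)
  structure(list(require_flags = as.integer(require_flags),
                 exclude_flags = as.integer(exclude_flags),
                 min_mapq = as.integer(min_mapq),
                 long_read = isTRUE(long_read)),
            class = "ConversionParams")
}

# Map 1-based reference positions onto 1-based query (read) indices through
# a cigar. Returns NA for positions under D/N ops or outside the alignment.
ref_to_query <- function(cigar, pos, ref_positions) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  out <- rep(NA_integer_, length(ref_positions))
  refc <- pos
  qryc <- 1L
  for (k in seq_along(ops)) {
    op <- ops[[k]]; len <- lens[[k]]
    if (op %in% c("M", "=", "X")) {
      sel <- ref_positions >= refc & ref_positions < refc + len
      out[sel] <- qryc + (ref_positions[sel] - refc)
      refc <- refc + len; qryc <- qryc + len
    } else if (op %in% c("I", "S")) {
      qryc <- qryc + len
    } else if (op %in% c("D", "N")) {
      refc <- refc + len
    }                                    # H, P consume nothing
  }
  out
}

cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# Bisulfite strand of a read: top ('CT') if the original fragment came from
# the top strand. Inferred from FLAG: read1 forward = top, and mate
# orientation flips for read2; an explicit XG tag ("CT"/"GA") overrides.
read_is_top_strand <- function(flag, xg = NA_character_) {
  if (!is.na(xg)) return(xg == "CT")
  is_rev <- bitwAnd(flag, 16L) > 0L
  is_r2 <- bitwAnd(flag, 128L) > 0L
  is_rev == is_r2
}

#' Call the methylation pattern of one aligned read
#'
#' Projects the read onto the reference CpG grid through its cigar and reads
#' off the converted base at each overlapped CpG: top-strand reads are
#' inspected at the C position (C = methylated, T = unmethylated), bottom
#' strand at the G position (G = methylated, A = unmethylated); anything
#' else, or a deletion/clip over the site, yields `.`. Reads overlapping no
#' CpG return `NULL`.
#'
#' @param chrom,pos Mapped chromosome and 1-based leftmost position.
#' @param cigar Cigar string.
#' @param seq Read bases as aligned (forward reference orientation).
#' @param top_strand Logical; see [read_is_top_strand()].
#' @param index A `GenomeIndex`.
#' @return `list(start_cpg, pattern)` or `NULL`.
#' @export
call_read <- function(chrom, pos, cigar, seq, top_strand, index) {
  p <- index$cpg_positions[[chrom]]
  if (is.null(p)) stop("chromosome '", chrom, "' absent from genome index")
  span_end <- pos + cigar_ref_width(cigar) - 1L
  # site to inspect: the C itself (top) or the G one base right (bottom)
  qpos_of <- if (top_strand) p else p + 1L
  lo <- findInterval(pos - 1L, qpos_of) + 1L
  hi <- findInterval(span_end, qpos_of)
  if (hi < lo) return(NULL)
  cps <- lo:hi
  qidx <- ref_to_query(cigar, pos, qpos_of[cps])
  bases <- rep(NA_character_, length(qidx))
  ok <- !is.na(qidx)
  if (any(ok)) {
    bases[ok] <- substring(seq, qidx[ok], qidx[ok])
  }
  calls <- if (top_strand) {
    ifelse(is.na(bases), ".", ifelse(bases == "C", "C",
                                     ifelse(bases == "T", "T", ".")))
  } else {
    ifelse(is.na(bases), ".", ifelse(bases == "G", "C",
                                     ifelse(bases == "A", "T", ".")))
  }
  list(start_cpg = unname(index$chrom_offsets[[chrom]] + lo),
       pattern = paste(calls, collapse = ""))
}

#' Merge the methylation calls of two mates
#'
#' The merged pattern spans the union of both mates' CpGs; the unsequenced
#' gap between non-overlapping mates is filled with `.`, and where mates
#' overlap, agreement keeps the call while disagreement becomes `.`.
#'
#' @param call1,call2 `list(start_cpg, pattern)` as from [call_read()].
#' @return `list(start_cpg, pattern)`.
#' @export
merge_mates <- function(call1, call2) {
  if (is.null(call1)) return(call2)
  if (is.null(call2)) return(call1)
  s <- min(call1$start_cpg, call2$start_cpg)
  e <- max(call1$start_cpg + nchar(call1$pattern),
           call2$start_cpg + nchar(call2$pattern))
  merged <- rep(".", e - s)
  for (cl in list(call1, call2)) {
    chars <- strsplit(cl$pattern, "", fixed = TRUE)[[1]]
    at <- cl$start_cpg - s + seq_along(chars)
    cur <- merged[at]
    take <- chars != "."
    conflict <- take & cur != "." & cur != chars
    merged[at[take]] <- chars[take]
    merged[at[conflict]] <- "."
  }
  list(start_cpg = s, pattern = paste(merged, collapse = ""))
}

# Parse MM/ML base-modification tags of one read into a map from reference
# position (of the inspected base) to modification probability. Handles the
# 'C+m' (5mC) sub-tag; positions refer to the read as sequenced, so
# reverse-strand reads are walked on the reverse complement of the stored
# sequence.
modification_probs <- function(mm, ml, flag, pos, cigar, seq) {
  if (is.na(mm) || is.null(ml) || length(ml) == 0L) return(NULL)
  entries <- strsplit(mm, ";", fixed = TRUE)[[1]]
  sel <- grep("^C\\+m", entries)
  if (length(sel) == 0L) return(NULL)
  fields <- strsplit(entries[[sel[1]]], ",", fixed = TRUE)[[1]]
  deltas <- as.integer(fields[-1])
  if (length(deltas) == 0L) return(NULL)
  is_rev <- bitwAnd(flag, 16L) > 0L
  stored <- strsplit(seq, "", fixed = TRUE)[[1]]
  orig <- if (is_rev) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rev(unname(comp[stored]))
  } else stored
  c_at <- which(orig == "C")
  picks <- integer(length(deltas))
  ptr <- 0L
  for (k in seq_along(deltas)) {
    ptr <- ptr + deltas[[k]] + 1L
    if (ptr > length(c_at)) return(NULL)   # malformed tag
    picks[[k]] <- c_at[[ptr]]
  }
  probs <- (as.numeric(ml[seq_along(picks)]) + 0.5) / 256
  stored_idx <- if (is_rev) length(stored) + 1L - picks else picks
  # stored read index -> reference position via the cigar
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  refpos <- rep(NA_integer_, length(stored))
  refc <- pos; qryc <- 1L
  for (k in seq_along(ops)) {
    op <- ops[[k]]; len <- lens[[k]]
    if (op %in% c("M", "=", "X")) {
      refpos[qryc:(qryc + len - 1L)] <- refc:(refc + len - 1L)
      refc <- refc + len; qryc <- qryc + len
    } else if (op %in% c("I", "S")) {
      qryc <- qryc + len
    } else if (op %in% c("D", "N")) {
      refc <- refc + len
    }
  }
  rp <- refpos[stored_idx]
  keep <- !is.na(rp)
  if (!any(keep)) return(NULL)
  stats::setNames(probs[keep], rp[keep])
}

#' Call a long read's methylation pattern from base-modification tags
#'
#' Each overlapped CpG is called methylated (`C`) when its modification
#' probability is at least 0.5, unmethylated (`T`) below, and unknown (`.`)
#' when the site carries no modification call. Probabilities decode ML bytes
#' as `(ML + 0.5) / 256`, so a tag value of 128 (probability 0.5) calls
#' methylated.
#'
#' @inheritParams call_read
#' @param flag SAM flag (for strand).
#' @param mm,ml MM tag string and ML byte vector.
#' @return `list(start_cpg, pattern)` or `NULL`.
#' @export
call_longread <- function(chrom, pos, cigar, seq, flag, mm, ml, index) {
  p <- index$cpg_positions[[chrom]]
  if (is.null(p)) stop("chromosome '", chrom, "' absent from genome index")
  probs <- modification_probs(mm, ml, flag, pos, cigar, seq)
  if (is.null(probs)) return(NULL)
  is_rev <- bitwAnd(flag, 16L) > 0L
  span_end <- pos + cigar_ref_width(cigar) - 1L
  # native reads carry Cs on their own strand: top-strand reads report the
  # CpG's C, reverse reads the complementary C at the G position
  qpos_of <- if (is_rev) p + 1L else p
  lo <- findInterval(pos - 1L, qpos_of) + 1L
  hi <- findInterval(span_end, qpos_of)
  if (hi < lo) return(NULL)
  cps <- lo:hi
  key <- as.character(qpos_of[cps])
  pr <- unname(probs[key])
  calls <- ifelse(is.na(pr), ".", ifelse(pr >= 0.5, "C", "T"))
  list(start_cpg = unname(index$chrom_offsets[[chrom]] + lo),
       pattern = paste(calls, collapse = ""))
}

#' Convert aligned reads to collapsed PAT records
#'
#' Applies SAM flag and mapping-quality filters, pairs mates by read name,
#' calls each read against the CpG index, merges mates, and collapses
#' identical fragment patterns. Accepts BAM or plain SAM (converted on the
#' fly). Each fragment contributes exactly one pattern.
#'
#' @param path BAM or SAM file of mapped reads.
#' @param index A `GenomeIndex` built from the same reference.
#' @param params A [conversion_params()] object.
#' @return Collapsed PAT records (data.frame).
#' @export
bam_to_pat <- function(path, index, params = conversion_params()) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
      tag = c("MM", "ML", "XG")))[[1]]
  n <- length(b$qname)
  if (n == 0L) {
    return(pat_records(character(0), integer(0), character(0), integer(0)))
  }
  chroms <- as.character(b$rname)
  missing_ref <- setdiff(unique(chroms[!is.na(b$pos)]), index$chrom_order)
  if (length(missing_ref)) {
    stop("reference sequence(s) absent from genome index: ",
         paste(missing_ref, collapse = ", "))
  }
  flags <- b$flag
  keep <- bitwAnd(flags, 4L) == 0L & !is.na(b$pos) &
    bitwAnd(flags, params$exclude_flags) == 0L &
    (is.na(b$mapq) | b$mapq >= params$min_mapq)
  paired_file <- any(bitwAnd(flags, 1L) > 0L)
  if (paired_file && !params$long_read) {
    keep <- keep & bitwAnd(flags, params$require_flags) == params$require_flags
  }
  idxs <- which(keep)
  seqs <- as.character(b$seq)
  calls <- vector("list", length(idxs))
  names(calls) <- b$qname[idxs]
  for (j in seq_along(idxs)) {
    i <- idxs[[j]]
    cl <- if (params$long_read) {
      call_longread(chroms[[i]], b$pos[[i]], b$cigar[[i]], seqs[[i]],
                    flags[[i]],
                    mm = b$tag$MM[[i]] %||% NA_character_,
                    ml = b$tag$ML[[i]], index = index)
    } else {
      xgi <- if (!is.null(b$tag$XG)) b$tag$XG[[i]] else NA_character_
      call_read(chroms[[i]], b$pos[[i]], b$cigar[[i]], seqs[[i]],
                read_is_top_strand(flags[[i]], xgi), index)
    }
    if (!is.null(cl)) cl$chrom <- chroms[[i]]
    calls[j] <- list(cl)   # keeps NULL placeholders without shrinking
  }
  ok <- !vapply(calls, is.null, logical(1))
  calls <- calls[ok]
  if (length(calls) == 0L) {
    return(pat_records(character(0), integer(0), character(0), integer(0)))
  }
  by_name <- split(seq_along(calls), names(calls))
  frags <- lapply(by_name, function(ii) {
    if (length(ii) == 1L) return(calls[[ii]])
    grp <- calls[ii]
    chs <- unique(vapply(grp, `[[`, character(1), "chrom"))
    if (length(chs) > 1L) {
      warning("mates of '", names(calls)[ii[1]],
              "' map to different chromosomes; pair dropped")
      return(NULL)
    }
    merged <- Reduce(merge_mates, grp)
    merged$chrom <- chs
    merged
  })
  frags <- frags[!vapply(frags, is.null, logical(1))]
  rec <- data.frame(
    chrom = vapply(frags, `[[`, character(1), "chrom"),
    start_cpg = vapply(frags, `[[`, numeric(1), "start_cpg"),
    pattern = vapply(frags, `[[`, character(1), "pattern"),
    count = 1L, stringsAsFactors = FALSE)
  rec$start_cpg <- as.integer(rec$start_cpg)
  rec <- canonicalize_pat(rec)
  rec <- rec[grepl("[CT]", rec$pattern), , drop = FALSE]
  collapse_pat(rec, chrom_order = index$chrom_order)
}
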