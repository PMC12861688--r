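#' Construct a table of fragment methylation patterns (PAT records)
#'
#' A PAT record is one sequenced fragment reduced to its CpG methylation
#' pattern: chromosome, global index of the first covered CpG, a string over
#' `C` (methylated), `T` (unmethylated) and `.` (unknown), and a multiplicity
#' count. Identical patterns over identical CpGs are stored once with an
#' increased count.
#'
#' @param chrom Character vector of chromosome names.
#' @param start_cpg Integer vector of global 1-based CpG indices of the first
#'   pattern character.
#' @param pattern Character vector of pattern strings over `{C, T, .}`.
#' @param count Positive integer multiplicities (recycled).
#' @return A data.frame with columns `chrom`, `start_cpg`, `pattern`,
#'   `count`.
#' @examples
#' pat_records("chr1", 5, c("CTTT", "CTTT"))
#' @export
pat_records <- function(chrom, start_cpg, pattern, count = 1L) {
  df <- data.frame(chrom = as.character(chrom),
                   start_cpg = as.integer(start_cpg),
                   pattern = as.character(pattern),
                   count = as.integer(count),
                   stringsAsFactors = FALSE)
  validate_pat(df)
  df
}

validate_pat <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "start_cpg", "pattern", "count") %in%
                  names(records)))
  if (nrow(records) == 0L) return(invisible(records))
  if (any(is.na(records$start_cpg)) || any(records$start_cpg < 1L)) {
    stop("start_cpg must be a positive CpG index")
  }
  if (any(records$count < 1L)) stop("count must be >= 1")
  if (any(grepl("[^CT.]", records$pattern))) {
    stop("pattern may only contain C, T and .")
  }
  if (any(!grepl("[CT]", records$pattern))) {
    stop("pattern must contain at least one observed (non-'.') site")
  }
  invisible(records)
}

# Trim leading/trailing '.' (advancing start_cpg) and drop records left with
# no observed site; the canonical form under which collapse() can merge.
canonicalize_pat <- function(records) {
  if (nrow(records) == 0L) return(records)
  lead <- nchar(records$pattern) - nchar(sub("^\\.+", "", records$pattern))
  records$start_cpg <- records$start_cpg + lead
  records$pattern <- gsub("^\\.+|\\.+$", "", records$pattern)
  records[nchar(records$pattern) > 0L, , drop = FALSE]
}

#' Merge identical fragment patterns
#'
#' Records equal in (chrom, start_cpg, pattern) are merged with summed
#' counts; output is sorted by chromosome (in `chrom_order` if given,
#' otherwise appearance order), then start CpG, then pattern in C-locale
#' byte order (`.` < `C` < `T`). Total count is conserved and the operation
#' is idempotent.
#'
#' @param records PAT records (see [pat_records()]).
#' @param chrom_order Optional character vector fixing chromosome sort order.
#' @return Collapsed, sorted PAT records.
#' @examples
#' collapse_pat(pat_records("chr1", 5, c("CTTT", "CTTT")))  # count 2
#' @export
collapse_pat <- function(records, chrom_order = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) return(records)
  ord <- chrom_order %||% unique(records$chrom)
  dt <- data.table::as.data.table(records)
  out <- dt[, list(count = sum(count)), by = c("chrom", "start_cpg", "pattern")]
  out[, `:=`(.chidx = match(chrom, ord))]
  if (anyNA(out$.chidx)) stop("record chromosome not in chrom_order")
  data.table::setorder(out, .chidx, start_cpg, pattern)  # C-locale string sort
  out[, `:=`(.chidx = NULL)]
  data.table::setDF(out)
  rownames(out) <- NULL
  out
}

#' Write / read a PAT file
#'
#' PAT files are 4-column tab-separated text (chrom, start CpG index,
#' pattern, count), sorted. With `index = TRUE` the file is block-gzip
#' compressed and tabix-indexed on the CpG index column for direct regional
#' access.
#'
#' @param records Collapsed PAT records.
#' @param path Output path; `.gz` is appended when indexing if absent.
#' @param index Compress with bgzip and build a tabix index.
#' @return The final file path, invisibly.
#' @export
write_pat <- function(records, path, index = TRUE) {
  validate_pat(records)
  plain <- sub("\\.gz$", "", path)
  data.table::fwrite(records[, c("chrom", "start_cpg", "pattern", "count")],
                     plain, sep = "\t", col.names = FALSE, quote = FALSE)
  if (!index) return(invisible(plain))
  gz <- Rsamtools::bgzip(plain, dest = paste0(plain, ".gz"), overwrite = TRUE)
  file.remove(plain)
  Rsamtools::indexTabix(gz, seq = 1, start = 2, end = 2, zeroBased = FALSE)
  invisible(gz)
}

#' @rdname write_pat
#' @return `read_pat`: the full PAT table as a data.frame.
#' @export
read_pat <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  df <- tryCatch(
    utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = c("character", "integer", "character",
                                     "integer")),
    error = function(e) {
      data.frame(chrom = character(0), start_cpg = integer(0),
                 pattern = character(0), count = integer(0),
                 stringsAsFactors = FALSE)
    })
  names(df) <- c("chrom", "start_cpg", "pattern", "count")
  df
}

# Global CpG indices of the observed (non-'.') sites of each record.
observed_sites <- function(records) {
  mapply(function(s, p) {
    s + which(strsplit(p, "", fixed = TRUE)[[1]] != ".") - 1L
  }, records$start_cpg, records$pattern, SIMPLIFY = FALSE)
}

#' Clip PAT records to a CpG index range
#'
#' Pattern characters outside the half-open global range
#' `[start_cpg, end_cpg)` are removed, record start indices advanced, and the
#' result canonicalized (leading/trailing `.` trimmed; records left without
#' an observed site dropped).
#'
#' @param records PAT records.
#' @param start_cpg,end_cpg Half-open global CpG index range.
#' @return Clipped PAT records.
#' @examples
#' clip_pat(pat_records("chr1", 3, "CCCT"), 4, 6)  # chr1 4 "CC"
#' @export
clip_pat <- function(records, start_cpg, end_cpg) {
  if (nrow(records) == 0L) return(records)
  len <- nchar(records$pattern)
  from <- pmax(start_cpg - records$start_cpg + 1L, 1L)
  to <- pmin(end_cpg - records$start_cpg, len)
  keep <- from <= to
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) return(records)
  from <- from[keep]; to <- to[keep]
  records$pattern <- substr(records$pattern, from, to)
  records$start_cpg <- records$start_cpg + from - 1L
  canonicalize_pat(records)
}

#' Query a PAT source for fragments in a CpG index region
#'
#' Returns every record with an observed CpG inside `[start_cpg, end_cpg)`,
#' optionally clipped to a range, filtered by a minimum number of observed
#' CpGs, and randomly thinned. `min_sites` counts observed (non-`.`) sites
#' after clipping; thinning treats a count-k record as k independent
#' Bernoulli keeps.
#'
#' @param pat PAT records (data.frame) or path to a PAT file; a
#'   tabix-indexed file is accessed regionally.
#' @param chrom Chromosome of the query (required with a file source; with
#'   an in-memory source `NULL` means all chromosomes).
#' @param start_cpg,end_cpg Half-open global CpG index range; defaults span
#'   everything.
#' @param clip_to Optional length-2 vector: clip patterns to this half-open
#'   CpG range.
#' @param min_sites Minimum observed CpGs per fragment (after clipping).
#' @param subsample_rate Probability of keeping each fragment.
#' @param seed RNG seed for subsampling (`NULL`: use current stream).
#' @param max_span With an indexed file, how far upstream of `start_cpg` to
#'   scan for fragments that start before but reach into the region.
#' @return PAT records.
#' @export
query_pat <- function(pat, chrom = NULL, start_cpg = 1L, end_cpg = .Machine$integer.max,
                      clip_to = NULL, min_sites = 1L, subsample_rate = 1,
                      seed = NULL, max_span = 1000L) {
  stopifnot(min_sites >= 1L, subsample_rate >= 0, subsample_rate <= 1)
  if (is.character(pat)) {
    tbi <- paste0(pat, ".tbi")
    if (!is.null(chrom) && file.exists(tbi)) {
      tbx_end <- min(max(1L, end_cpg - 1L), 536870912L)  # htslib bin limit
      lines <- Rsamtools::scanTabix(
        pat, param = GenomicRanges::GRanges(
          chrom, IRanges::IRanges(max(1L, start_cpg - max_span),
                                  tbx_end)))[[1]]
      records <- if (length(lines)) {
        df <- data.table::fread(text = lines, header = FALSE,
                                colClasses = list(character = c(1, 3)),
                                col.names = c("chrom", "start_cpg", "pattern",
                                              "count"))
        data.table::setDF(df)
        df
      } else {
        pat_records(character(0), integer(0), character(0), integer(0))
      }
    } else {
      records <- read_pat(pat)
    }
  } else {
    records <- as.data.frame(pat)
  }
  if (!is.null(chrom)) records <- records[records$chrom == chrom, , drop = FALSE]
  if (nrow(records)) {
    obs <- observed_sites(records)
    hit <- vapply(obs, function(o) any(o >= start_cpg & o < end_cpg),
                  logical(1))
    records <- records[hit, , drop = FALSE]
  }
  if (!is.null(clip_to)) {
    records <- clip_pat(records, clip_to[[1]], clip_to[[2]])
  }
  if (nrow(records) && min_sites > 1L) {
    nobs <- nchar(gsub(".", "", records$pattern, fixed = TRUE))
    records <- records[nobs >= min_sites, , drop = FALSE]
  }
  if (subsample_rate < 1) {
    records <- with_rng_seed(seed, {
      if (nrow(records)) {
        records$count <- stats::rbinom(nrow(records), records$count,
                                       subsample_rate)
      }
      records[records$count > 0L, , drop = FALSE]
    })
  }
  rownames(records) <- NULL
  records
}

#' Mask CpG sites out of PAT records
#'
#' Every pattern character whose global CpG index falls inside any of the
#' mask ranges becomes `.` (e.g. to blind polymorphic CpGs or blacklist
#' regions); records left with no observed site are removed, and the result
#' is re-collapsed.
#'
#' @param records PAT records.
#' @param mask Data.frame with columns `chrom`, `start_cpg`, `end_cpg`
#'   (half-open global CpG ranges).
#' @param chrom_order Optional chromosome sort order for the re-collapse.
#' @return Masked, collapsed PAT records.
#' @export
mask_pat <- function(records, mask, chrom_order = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L || nrow(mask) == 0L) {
    return(collapse_pat(records, chrom_order))
  }
  for (r in seq_len(nrow(records))) {
    m <- mask[mask$chrom == records$chrom[r], , drop = FALSE]
    if (nrow(m) == 0L) next
    s <- records$start_cpg[r]
    chars <- strsplit(records$pattern[r], "", fixed = TRUE)[[1]]
    idx <- s + seq_along(chars) - 1L
    hit <- rep(FALSE, length(idx))
    for (k in seq_len(nrow(m))) {
      hit <- hit | (idx >= m$start_cpg[k] & idx < m$end_cpg[k])
    }
    chars[hit] <- "."
    records$pattern[r] <- paste(chars, collapse = "")
  }
  records <- records[grepl("[CT]", records$pattern), , drop = FALSE]
  records <- canonicalize_pat(records)
  collapse_pat(records, chrom_order)
}

#' Mix PAT sources at given concentrations
#'
#' Simulates an in-silico admixture: each fragment of source `i` is kept
#' independently with probability `rates[i]`; survivors are pooled, sorted
#' and collapsed. The same seed reproduces the same mixture.
#'
#' @param pats List of PAT record tables or file paths.
#' @param rates Numeric vector of keep probabilities, one per source.
#' @param seed RNG seed.
#' @param chrom_order Optional chromosome sort order.
#' @return Collapsed PAT records of the mixture.
#' @export
mix_pat <- function(pats, rates, seed = NULL, chrom_order = NULL) {
  if (length(pats) != length(rates)) {
    stop("need one rate per PAT source (got ", length(pats), " sources, ",
         length(rates), " rates)")
  }
  stopifnot(all(rates >= 0), all(rates <= 1))
  with_rng_seed(seed, {
    parts <- lapply(seq_along(pats), function(i) {
      rec <- if (is.character(pats[[i]])) read_pat(pats[[i]]) else
        as.data.frame(pats[[i]])
      if (nrow(rec) == 0L) return(rec)
      rec$count <- stats::rbinom(nrow(rec), rec$count, rates[[i]])
      rec[rec$count > 0L, , drop = FALSE]
    })
    collapse_pat(do.call(rbind, parts), chrom_order)
  })
}
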