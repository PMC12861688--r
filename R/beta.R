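#' Per-CpG methylation count vector (BETA)
#'
#' A BETA vector stores, for every CpG of the genome, the number of
#' methylated observations and the total number of observations, as
#' fixed-width unsigned integers (8 or 16 bits). Its on-disk form is raw
#' little-endian interleaved (meth, total) pairs with no header, so the file
#' size is exactly `2 * N * width/8` bytes and any CpG can be read by
#' offset.
#'
#' @param meth,total Integer vectors of equal length N.
#' @param width Bits per stored value: 8 or 16. Values are clamped
#'   (saturated) at `2^width - 1`.
#' @return A `BetaVector` list with elements `meth`, `total`, `width`.
#' @export
beta_vector <- function(meth, total, width = 8L) {
  stopifnot(length(meth) == length(total), width %in% c(8L, 16L))
  meth <- as.integer(meth); total <- as.integer(total)
  if (any(meth < 0L) || any(total < 0L) || any(meth > total)) {
    stop("need 0 <= meth <= total at every CpG")
  }
  cap <- bitwShiftL(1L, width) - 1L
  structure(list(meth = pmin(meth, cap), total = pmin(total, cap),
                 width = as.integer(width)),
            class = "BetaVector")
}

#' @export
print.BetaVector <- function(x, ...) {
  cov <- x$total > 0L
  cat(sprintf("BetaVector: %d CpGs, %d covered, mean methylation %.3f (%d-bit)\n",
              length(x$meth), sum(cov),
              if (any(cov)) sum(x$meth) / sum(x$total) else NA_real_,
              x$width))
  invisible(x)
}

#' Reduce PAT records to per-CpG counts
#'
#' Each `C` in a count-k record adds k to both the methylated and total
#' count of its CpG, each `T` adds k to the total only, and `.` adds
#' nothing. Counts saturate at the width maximum rather than overflowing.
#'
#' @param records PAT records.
#' @param n_cpgs Genome-wide CpG count N (e.g. `index$total_cpgs`).
#' @param width Stored value width in bits (8 or 16).
#' @return A [beta_vector()].
#' @examples
#' b <- pat_to_beta(pat_records("chr1", 5, "CT", 2), n_cpgs = 10)
#' b$meth[5:6]   # 2 0
#' b$total[5:6]  # 2 2
#' @export
pat_to_beta <- function(records, n_cpgs, width = 8L) {
  meth <- integer(n_cpgs); total <- integer(n_cpgs)
  if (nrow(records)) {
    validate_pat(records)
    chars <- strsplit(records$pattern, "", fixed = TRUE)
    lens <- lengths(chars)
    if (any(records$start_cpg + lens - 1L > n_cpgs)) {
      stop("pattern extends past CpG_", n_cpgs)
    }
    pos <- unlist(mapply(function(s, l) s + seq_len(l) - 1L,
                         records$start_cpg, lens, SIMPLIFY = FALSE))
    ch <- unlist(chars)
    k <- rep(records$count, lens)
    obs <- ch != "."
    total_tab <- tapply(k[obs], pos[obs], sum)
    total[as.integer(names(total_tab))] <- as.integer(total_tab)
    m <- ch == "C"
    meth_tab <- tapply(k[m], pos[m], sum)
    meth[as.integer(names(meth_tab))] <- as.integer(meth_tab)
  }
  beta_vector(pmin(meth, total), total, width)
}

#' Write / read a BETA file
#'
#' @param beta A `BetaVector`.
#' @param path File path.
#' @return `write_beta` returns `path` invisibly; `read_beta` returns a
#'   `BetaVector`.
#' @export
write_beta <- function(beta, path) {
  stopifnot(inherits(beta, "BetaVector"))
  n <- length(beta$meth)
  inter <- integer(2L * n)
  inter[seq(1L, by = 2L, length.out = n)] <- beta$meth
  inter[seq(2L, by = 2L, length.out = n)] <- beta$total
  bytes <- if (beta$width == 8L) {
    as.raw(inter)
  } else {
    lo <- as.raw(inter %% 256L)
    hi <- as.raw(inter %/% 256L)
    out <- raw(4L * n)
    out[seq(1L, by = 2L, length.out = 2L * n)] <- lo
    out[seq(2L, by = 2L, length.out = 2L * n)] <- hi
    out
  }
  writeBin(bytes, path)
  invisible(path)
}

#' @rdname write_beta
#' @param width Bits per stored value the file was written with.
#' @export
read_beta <- function(path, width = 8L) {
  stopifnot(width %in% c(8L, 16L))
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  vals <- if (width == 8L) {
    as.integer(bytes)
  } else {
    u <- as.integer(bytes)
    u[seq(1L, length(u), by = 2L)] + 256L * u[seq(2L, length(u), by = 2L)]
  }
  n <- length(vals) %/% 2L
  beta_vector(vals[seq(1L, by = 2L, length.out = n)],
              vals[seq(2L, by = 2L, length.out = n)], width)
}

# Pooled (meth, total) sums over each block's CpG range, one beta at a time.
beta_block_counts <- function(beta, blocks) {
  n <- length(beta$meth)
  cm <- c(0, cumsum(as.numeric(beta$meth)))
  ct <- c(0, cumsum(as.numeric(beta$total)))
  s <- blocks$startCpG; e <- blocks$endCpG
  if (any(s < 1L | e > n + 1L | e < s)) {
    stop("block CpG range outside [1, ", n + 1L, ")")
  }
  list(meth = cm[e] - cm[s], total = ct[e] - ct[s])
}

#' Average methylation of blocks across samples
#'
#' For each sample and block, the pooled ratio
#' `sum(meth) / sum(total)` over the block's CpGs; blocks whose total
#' coverage in a sample is below `min_cov` are reported `NA`. With a groups
#' table, one extra column per group holds the unweighted mean of its
#' member samples' non-missing values.
#'
#' @param betas Named list of `BetaVector`s (or BETA file paths), one per
#'   sample.
#' @param blocks Data.frame with `startCpG` / `endCpG` columns (e.g. from
#'   [convert_bed()] or [segment_genome()]); other columns are carried
#'   through.
#' @param groups Optional data.frame with columns `sample` and `group`.
#' @param min_cov Minimum pooled coverage for a non-missing value.
#' @param width Bit width used when reading BETA paths.
#' @return `blocks` with one numeric column per sample (and per group).
#' @export
beta_to_table <- function(betas, blocks, groups = NULL, min_cov = 1L,
                          width = 8L) {
  stopifnot(all(c("startCpG", "endCpG") %in% names(blocks)))
  if (is.null(names(betas)) || any(names(betas) == "")) {
    stop("'betas' must be a named list (sample names)")
  }
  out <- as.data.frame(blocks)
  for (s in names(betas)) {
    b <- betas[[s]]
    if (is.character(b)) b <- read_beta(b, width)
    cnt <- beta_block_counts(b, blocks)
    v <- ifelse(cnt$total >= min_cov, cnt$meth / cnt$total, NA_real_)
    out[[s]] <- v
  }
  if (!is.null(groups)) {
    stopifnot(all(c("sample", "group") %in% names(groups)))
    missing_s <- setdiff(names(betas), groups$sample)
    if (length(missing_s)) {
      stop("samples absent from groups table: ",
           paste(missing_s, collapse = ", "))
    }
    for (g in unique(groups$group)) {
      members <- intersect(groups$sample[groups$group == g], names(betas))
      vals <- as.matrix(out[, members, drop = FALSE])
      out[[g]] <- rowMeans(vals, na.rm = TRUE)
      out[[g]][is.nan(out[[g]])] <- NA_real_
    }
  }
  out
}
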