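#' Log marginal likelihood of a methylation block
#'
#' Score of a block of pooled counts under a Bernoulli model with a
#' symmetric Beta(alpha, alpha) prior on the methylation probability:
#' `log B(meth + alpha, unmeth + alpha) - log B(alpha, alpha)`. Larger
#' pseudocounts favour longer, less homogeneous blocks. Vectorized over
#' counts.
#'
#' @param meth,unmeth Non-negative observation counts.
#' @param alpha Beta prior pseudocount, > 0.
#' @return Log score (0 for an empty block).
#' @examples
#' block_score(10, 0, alpha = 1)  # log(1/11)
#' @export
block_score <- function(meth, unmeth, alpha) {
  if (alpha <= 0) stop("pseudocount alpha must be > 0")
  stopifnot(all(meth >= 0), all(unmeth >= 0))
  lbeta(meth + alpha, unmeth + alpha) - lbeta(alpha, alpha)
}

# DP over one chromosome's CpG run. channels: list of list(meth, total)
# vectors restricted to the run; positions: genomic positions of the run's
# CpGs. Returns integer boundaries (local, half-open blocks j..i).
segment_run <- function(channels, positions, alpha, max_cpg, min_cpg,
                        max_bp) {
  n <- length(positions)
  cms <- lapply(channels, function(ch) c(0, cumsum(as.numeric(ch$meth))))
  cts <- lapply(channels, function(ch) c(0, cumsum(as.numeric(ch$total))))
  best <- c(0, rep(-Inf, n))
  back <- integer(n + 1L)
  for (i in seq_len(n)) {
    j_lo <- max(0L, i - max_cpg)
    j_hi <- i - min_cpg
    if (j_hi < j_lo) next
    js <- j_lo:j_hi
    if (is.finite(max_bp)) {
      # genomic extent: from the C of CpG j+1 to one past the G of CpG i
      ext <- (positions[i] + 2L) - positions[js + 1L]
      js <- js[ext <= max_bp]
      if (length(js) == 0L) next
    }
    sc <- 0
    for (k in seq_along(channels)) {
      m <- cms[[k]][i + 1L] - cms[[k]][js + 1L]
      u <- (cts[[k]][i + 1L] - cts[[k]][js + 1L]) - m
      sc <- sc + block_score(m, u, alpha)
    }
    tot <- best[js + 1L] + sc
    w <- which.max(tot)          # first max: smallest j, longest last block
    if (tot[w] > -Inf) {
      best[i + 1L] <- tot[w]
      back[i + 1L] <- js[w]
    }
  }
  if (!is.finite(best[n + 1L])) {
    stop("no feasible segmentation under the size constraints")
  }
  bounds <- integer(0)
  i <- n
  while (i > 0L) {
    bounds <- c(back[i + 1L], bounds)
    i <- back[i + 1L]
  }
  list(starts = bounds + 1L, ends = c(bounds[-1L], n),
       score = best[n + 1L])
}

#' Segment the CpG axis into homogeneous methylation blocks
#'
#' Finds, per chromosome, the partition of consecutive CpGs that maximizes
#' the summed [block_score()] over all channels (samples or sample groups),
#' by dynamic programming — the exact optimum under the block-size
#' constraints, with per-CpG independence inside a block and counts pooled
#' across a block's CpGs. Ties prefer the longer final block. Blocks tile
#' the requested range exactly.
#'
#' @param channels List of `BetaVector`s (or `list(meth, total)` pairs),
#'   all of genome length N.
#' @param index A `GenomeIndex`.
#' @param alpha Beta prior pseudocount (trade-off between block length and
#'   homogeneity).
#' @param max_cpg,min_cpg Maximal/minimal block size in CpGs.
#' @param max_bp Maximal genomic block extent in bases.
#' @param cpg_range Optional half-open global CpG range to segment
#'   (default: whole genome).
#' @return Data.frame of blocks: `chrom`, 0-based half-open `start`/`end`
#'   (from the first C to one past the last G), `startCpG`, `endCpG`
#'   (half-open global CpG indices), and the block `score`.
#' @export
segment_genome <- function(channels, index, alpha = 1, max_cpg = 5000L,
                           min_cpg = 1L, max_bp = Inf, cpg_range = NULL) {
  if (alpha <= 0) stop("pseudocount alpha must be > 0")
  stopifnot(max_cpg >= min_cpg, min_cpg >= 1L)
  if (inherits(channels, "BetaVector")) channels <- list(channels)
  n <- index$total_cpgs
  for (ch in channels) {
    if (length(ch$meth) != n) {
      stop("channel length ", length(ch$meth), " != genome CpG count ", n)
    }
  }
  rng <- cpg_range %||% c(1L, n + 1L)
  stopifnot(rng[1] >= 1L, rng[2] <= n + 1L, rng[1] <= rng[2])
  if (rng[1] == rng[2]) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), startCpG = integer(0),
                      endCpG = integer(0), score = numeric(0)))
  }
  out <- list()
  for (chrom in index$chrom_order) {
    off <- index$chrom_offsets[[chrom]]
    pos <- index$cpg_positions[[chrom]]
    lo <- max(rng[1], off + 1L)
    hi <- min(rng[2], off + length(pos) + 1L)
    if (hi <= lo) next
    loc <- (lo - off):(hi - 1L - off)
    sub <- lapply(channels, function(ch) {
      list(meth = ch$meth[loc + off], total = ch$total[loc + off])
    })
    seg <- segment_run(sub, pos[loc], alpha, max_cpg, min_cpg, max_bp)
    s_cpg <- off + loc[seg$starts]
    e_cpg <- off + loc[seg$ends] + 1L
    sc <- numeric(length(seg$starts))
    for (k in seq_along(channels)) {
      cnt <- beta_block_counts(channels[[k]],
                               data.frame(startCpG = s_cpg, endCpG = e_cpg))
      sc <- sc + block_score(cnt$meth, cnt$total - cnt$meth, alpha)
    }
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = pos[loc[seg$starts]] - 1L,
      end = pos[loc[seg$ends]] + 1L,
      startCpG = s_cpg, endCpG = e_cpg, score = sc,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               startCpG = integer(0), endCpG = integer(0),
               score = numeric(0))
  rownames(res) <- NULL
  res
}
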