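#' Parameters for differential-methylation marker finding
#'
#' `tg_quant` and `bg_quant` are outlier-trimming fractions: for a
#' hypomethylated marker the target group is summarized by its
#' `1 - tg_quant` quantile (defaults to the 75th percentile) and the
#' background by its `bg_quant` quantile (the 2.5th percentile), so a few
#' aberrant replicates cannot veto a block. The robust delta is the
#' difference of those two quantiles; the strict delta is
#' `min(background) - max(target)`.
#'
#' @param tg_quant,bg_quant Trimming fractions in `[0, 1]`.
#' @param min_delta Required robust delta.
#' @param direction `"hypo"` (target unmethylated), `"hyper"`, or `"both"`.
#' @param p_threshold Maximum p-value (of the test chosen by `test`).
#' @param test Which p-value filters/ranks: `"t"`, `"mann_whitney"` or
#'   `"welch_mvalue"`.
#' @param min_cpgs,min_bp,max_bp Block size limits.
#' @param max_na_frac Maximum fraction of missing samples per group.
#' @param mval_offset Count offset in the M-value transform
#'   `log2((meth + offset) / (unmeth + offset))`.
#' @return A `MarkerParams` list.
#' @export
marker_params <- function(tg_quant = 0.25, bg_quant = 0.025,
                          min_delta = 0.2, direction = c("hypo", "hyper",
                                                         "both"),
                          p_threshold = 0.05, test = c("t", "mann_whitney",
                                                       "welch_mvalue"),
                          min_cpgs = 1L, min_bp = 0L, max_bp = Inf,
                          max_na_frac = 0.5, mval_offset = 1) {
  stopifnot(tg_quant >= 0, tg_quant <= 1, bg_quant >= 0, bg_quant <= 1,
            p_threshold >= 0, p_threshold <= 1)
  structure(list(tg_quant = tg_quant, bg_quant = bg_quant,
                 min_delta = min_delta, direction = match.arg(direction),
                 p_threshold = p_threshold, test = match.arg(test),
                 min_cpgs = min_cpgs, min_bp = min_bp, max_bp = max_bp,
                 max_na_frac = max_na_frac, mval_offset = mval_offset),
            class = "MarkerParams")
}

#' Per-group summary statistics of a block table
#'
#' For every block and group: the mean of member-sample means, a requested
#' percentile (linear interpolation), minimum, maximum, and the fraction of
#' missing member values. All statistics ignore NA values.
#'
#' @param table Block-by-sample numeric matrix or the data.frame from
#'   [beta_to_table()] (sample columns selected via `groups$sample`).
#' @param groups Data.frame with columns `sample`, `group`.
#' @param quantiles Named numeric vector: percentile to compute per group
#'   (a single value is recycled).
#' @return Named list (one per group) of data.frames with columns `mean`,
#'   `quantile`, `min`, `max`, `na_frac`.
#' @export
compute_group_stats <- function(table, groups, quantiles = 0.5) {
  tab <- as.data.frame(table)
  gnames <- unique(groups$group)
  if (length(quantiles) == 1L) {
    quantiles <- stats::setNames(rep(quantiles, length(gnames)), gnames)
  }
  out <- list()
  for (g in gnames) {
    samples <- groups$sample[groups$group == g]
    v <- as.matrix(tab[, samples, drop = FALSE])
    qs <- apply(v, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) NA_real_ else
        unname(stats::quantile(x, quantiles[[g]], type = 7))
    })
    out[[g]] <- data.frame(
      mean = rowMeans(v, na.rm = TRUE),
      quantile = qs,
      min = suppressWarnings(apply(v, 1, min, na.rm = TRUE)),
      max = suppressWarnings(apply(v, 1, max, na.rm = TRUE)),
      na_frac = rowMeans(is.na(v)))
    out[[g]]$mean[is.nan(out[[g]]$mean)] <- NA_real_
    out[[g]]$min[is.infinite(out[[g]]$min)] <- NA_real_
    out[[g]]$max[is.infinite(out[[g]]$max)] <- NA_real_
  }
  out
}

# two-sided Welch t-test p-value, NA when variance is degenerate
welch_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

mann_whitney_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  exact <- max(length(a), length(b)) <= 8L && !any(duplicated(c(a, b)))
  suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                      correct = TRUE)$p.value)
}

#' Score one block: deltas and group-difference p-values
#'
#' Computes the robust (quantile-trimmed) and strict (min/max) methylation
#' difference between background and target samples, two-sided p-values for
#' Welch's t-test and the Mann-Whitney U test on the raw block values, and
#' Welch's t-test on per-sample M-values
#' `log2((sum meth + offset) / (sum unmeth + offset))` when block counts
#' are supplied.
#'
#' @param target,background Numeric vectors of per-sample block methylation.
#' @param params A [marker_params()] object.
#' @param target_counts,background_counts Optional lists with `meth` and
#'   `total` per sample for the M-value test.
#' @param direction `"hypo"` or `"hyper"` (a `"both"` caller scores twice).
#' @return List with `delta_robust`, `delta_strict`, `p_t`, `p_mw`,
#'   `p_mvalue`.
#' @export
score_block <- function(target, background, params = marker_params(),
                        target_counts = NULL, background_counts = NULL,
                        direction = "hypo") {
  tg <- target[!is.na(target)]; bg <- background[!is.na(background)]
  if (length(tg) == 0L || length(bg) == 0L) {
    return(list(delta_robust = NA_real_, delta_strict = NA_real_,
                p_t = NA_real_, p_mw = NA_real_, p_mvalue = NA_real_))
  }
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  if (direction == "hypo") {
    delta_robust <- q(bg, params$bg_quant) - q(tg, 1 - params$tg_quant)
    delta_strict <- min(bg) - max(tg)
  } else {
    delta_robust <- q(tg, params$tg_quant) - q(bg, 1 - params$bg_quant)
    delta_strict <- min(tg) - max(bg)
  }
  p_mv <- NA_real_
  if (!is.null(target_counts) && !is.null(background_counts)) {
    mv <- function(cn) log2((cn$meth + params$mval_offset) /
                              (cn$total - cn$meth + params$mval_offset))
    p_mv <- welch_p(mv(target_counts), mv(background_counts))
  }
  list(delta_robust = delta_robust, delta_strict = delta_strict,
       p_t = welch_p(tg, bg), p_mw = mann_whitney_p(tg, bg),
       p_mvalue = p_mv)
}

#' Find group-specific differentially methylated blocks
#'
#' One-versus-all over the groups: each group in turn is the target and all
#' remaining samples the background. Blocks pass if the robust delta (in
#' the requested direction) reaches `min_delta`, the chosen test's p-value
#' is at most `p_threshold`, block size lies within the CpG/bp limits, and
#' neither group exceeds `max_na_frac` missing samples. Passing blocks are
#' ranked by robust delta (descending), ties broken by smaller p-value.
#'
#' @param betas Named list of `BetaVector`s or BETA paths, one per sample.
#' @param blocks Data.frame with `chrom`, `start`, `end`, `startCpG`,
#'   `endCpG`.
#' @param groups Data.frame with columns `sample`, `group`.
#' @param params A [marker_params()] object.
#' @param min_cov Minimum block coverage per sample (else NA).
#' @param width BETA bit width for file input.
#' @return Data.frame of markers: block columns, `target`, group means,
#'   `delta_robust`, `delta_strict`, `p_t`, `p_mw`, `p_mvalue`,
#'   `direction`, ordered best-first within each target group.
#' @export
find_markers <- function(betas, blocks, groups, params = marker_params(),
                         min_cov = 1L, width = 8L) {
  if (length(unique(groups$group)) < 2L) stop("need at least 2 groups")
  stopifnot(all(c("startCpG", "endCpG") %in% names(blocks)))
  betas <- lapply(betas, function(b) {
    if (is.character(b)) read_beta(b, width) else b
  })
  samples <- names(betas)
  counts <- lapply(betas, beta_block_counts, blocks = blocks)
  vals <- vapply(samples, function(s) {
    cn <- counts[[s]]
    ifelse(cn$total >= min_cov, cn$meth / cn$total, NA_real_)
  }, numeric(nrow(blocks)))
  vals <- matrix(vals, nrow = nrow(blocks),
                 dimnames = list(NULL, samples))
  n_cpgs <- blocks$endCpG - blocks$startCpG
  bp <- if (all(c("start", "end") %in% names(blocks))) {
    blocks$end - blocks$start
  } else rep(NA_integer_, nrow(blocks))
  size_ok <- n_cpgs >= params$min_cpgs &
    (is.na(bp) | (bp >= params$min_bp & bp <= params$max_bp))
  dirs <- if (params$direction == "both") c("hypo", "hyper") else
    params$direction
  res <- list()
  for (g in unique(groups$group)) {
    tg_s <- intersect(groups$sample[groups$group == g], samples)
    bg_s <- setdiff(samples, tg_s)
    for (dir in dirs) {
      for (i in seq_len(nrow(blocks))) {
        if (!size_ok[i]) next
        tg <- vals[i, tg_s]; bg <- vals[i, bg_s]
        if (mean(is.na(tg)) > params$max_na_frac ||
            mean(is.na(bg)) > params$max_na_frac) next
        tc <- list(meth = vapply(counts[tg_s], function(cn) cn$meth[i],
                                 numeric(1)),
                   total = vapply(counts[tg_s], function(cn) cn$total[i],
                                  numeric(1)))
        bc <- list(meth = vapply(counts[bg_s], function(cn) cn$meth[i],
                                 numeric(1)),
                   total = vapply(counts[bg_s], function(cn) cn$total[i],
                                  numeric(1)))
        sc <- score_block(tg, bg, params, tc, bc, direction = dir)
        if (is.na(sc$delta_robust) || sc$delta_robust < params$min_delta) next
        p_rank <- switch(params$test, t = sc$p_t, mann_whitney = sc$p_mw,
                         welch_mvalue = sc$p_mvalue)
        if (is.na(p_rank) || p_rank > params$p_threshold) next
        row <- blocks[i, , drop = FALSE]
        row$target <- g
        row$direction <- dir
        row$target_mean <- mean(tg, na.rm = TRUE)
        row$background_mean <- mean(bg, na.rm = TRUE)
        row$delta_robust <- sc$delta_robust
        row$delta_strict <- sc$delta_strict
        row$p_t <- sc$p_t; row$p_mw <- sc$p_mw; row$p_mvalue <- sc$p_mvalue
        row$p_rank <- p_rank
        res[[length(res) + 1L]] <- row
      }
    }
  }
  if (length(res) == 0L) {
    out <- blocks[0, , drop = FALSE]
    for (cl in c("target", "direction")) out[[cl]] <- character(0)
    for (cl in c("target_mean", "background_mean", "delta_robust",
                 "delta_strict", "p_t", "p_mw", "p_mvalue", "p_rank")) {
      out[[cl]] <- numeric(0)
    }
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$target, -out$delta_robust, out$p_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
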