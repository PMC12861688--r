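#' Parameters for fragment homogeneity classification
#'
#' Defaults follow the convention that a fragment is mostly unmethylated
#' (U) when at most 25% of its observed CpGs are methylated, mostly
#' methylated (M) at 75% or more, mixed (X) in between, and only fragments
#' observing at least 3 CpGs are classified at all.
#'
#' @param u_threshold Upper methylated fraction (inclusive) for class U.
#' @param m_threshold Lower methylated fraction (inclusive) for class M.
#' @param min_sites Minimum observed (non-`.`) CpGs per fragment.
#' @return A `HomogParams` list.
#' @export
homog_params <- function(u_threshold = 0.25, m_threshold = 0.75,
                         min_sites = 3L) {
  stopifnot(u_threshold >= 0, u_threshold <= m_threshold, m_threshold <= 1,
            min_sites >= 1L)
  structure(list(u_threshold = u_threshold, m_threshold = m_threshold,
                 min_sites = as.integer(min_sites)),
            class = "HomogParams")
}

#' Classify fragments as U / X / M
#'
#' For each pattern, with k observed (non-`.`) sites and methylated fraction
#' `f = #C / k`: fragments with `k < min_sites` are `"filtered"`, `"U"` if
#' `f <= u_threshold`, `"M"` if `f >= m_threshold`, else `"X"`. Unknown
#' sites never dilute the fraction.
#'
#' @param pattern Character vector of patterns over `{C, T, .}`.
#' @param params A [homog_params()] object.
#' @return Character vector over `{"U", "X", "M", "filtered"}`.
#' @examples
#' classify_fragment(c("CCCT", "CTTT", "CCTT", "CT."))
#' @export
classify_fragment <- function(pattern, params = homog_params()) {
  n_c <- nchar(gsub("[^C]", "", pattern))
  k <- n_c + nchar(gsub("[^T]", "", pattern))
  f <- ifelse(k > 0L, n_c / k, NA_real_)
  ifelse(k < params$min_sites, "filtered",
         ifelse(f <= params$u_threshold, "U",
                ifelse(f >= params$m_threshold, "M", "X")))
}

#' Count U/X/M fragments per region
#'
#' Fragments are clipped to each block's CpG range before classification
#' (so a fragment spanning two blocks contributes its in-block portion to
#' each), unless `clip = FALSE`, in which case whole intersecting fragments
#' are classified. A count-k record contributes k.
#'
#' @param pat PAT records or file path (see [query_pat()]).
#' @param blocks Data.frame with `chrom`, `startCpG`, `endCpG` columns (run
#'   [convert_bed()] first for plain BED input).
#' @param params A [homog_params()] object.
#' @param clip Clip fragments to block boundaries before classifying.
#' @return `blocks` with integer columns `U`, `X`, `M` appended.
#' @export
count_homog <- function(pat, blocks, params = homog_params(), clip = TRUE) {
  if (!all(c("startCpG", "endCpG") %in% names(blocks))) {
    stop("blocks lack startCpG/endCpG columns; run convert_bed() first")
  }
  out <- as.data.frame(blocks)
  out$U <- 0L; out$X <- 0L; out$M <- 0L
  for (i in seq_len(nrow(out))) {
    rec <- query_pat(pat, chrom = out$chrom[i],
                     start_cpg = out$startCpG[i], end_cpg = out$endCpG[i],
                     clip_to = if (clip) c(out$startCpG[i], out$endCpG[i]))
    if (nrow(rec) == 0L) next
    cls <- classify_fragment(rec$pattern, params)
    for (lab in c("U", "X", "M")) {
      out[[lab]][i] <- sum(rec$count[cls == lab])
    }
  }
  out
}

#' Write homogeneity counts
#'
#' Binary mode stores, per block in order, three saturating unsigned 8-bit
#' counts (U, X, M); text mode writes the full TSV.
#'
#' @param counts Output of [count_homog()].
#' @param path File path.
#' @param text Write tab-separated text instead of binary.
#' @return `path`, invisibly.
#' @export
write_homog <- function(counts, path, text = FALSE) {
  if (text) {
    utils::write.table(counts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    v <- as.integer(t(as.matrix(counts[, c("U", "X", "M")])))
    writeBin(as.raw(pmin(v, 255L)), path)
  }
  invisible(path)
}
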