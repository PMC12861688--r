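ANSI_RED <- "\033[31m"
ANSI_GREEN <- "\033[32m"
ANSI_YELLOW <- "\033[33m"
ANSI_RESET <- "\033[0m"

#' Strip ANSI escape sequences from text
#'
#' @param x Character vector.
#' @return `x` without terminal color codes.
#' @export
strip_ansi <- function(x) gsub("\033\\[[0-9;]*m", "", x)

#' Render a fragment stack for a CpG region as text lines
#'
#' Each fragment becomes a run of glyphs aligned to CpG columns: `C`
#' (methylated, red when colored), `T` (unmethylated, green), `.`
#' (unknown). Fragments are packed greedily: a fragment joins the first row
#' whose occupied span it does not overlap; a count-k record is drawn k
#' times. With `classify = TRUE` whole fragments are colored by their U/X/M
#' class (green/yellow/red) instead of per-site.
#'
#' @param records PAT records.
#' @param start_cpg,end_cpg Half-open global CpG range to draw.
#' @param color Emit ANSI colors.
#' @param classify Color whole fragments by [classify_fragment()] class.
#' @param homog A [homog_params()] for `classify` mode.
#' @param header Prepend a locus header line.
#' @return Character vector of lines.
#' @export
render_pat_lines <- function(records, start_cpg, end_cpg, color = FALSE,
                             classify = FALSE, homog = homog_params(),
                             header = TRUE) {
  k <- end_cpg - start_cpg
  stopifnot(k >= 1L)
  records <- clip_pat(as.data.frame(records), start_cpg, end_cpg)
  lines <- if (header) {
    sprintf("CpG %d-%d (%d sites)", start_cpg, end_cpg - 1L, k)
  } else character(0)
  if (nrow(records) == 0L) return(lines)
  # expand counts, sort by start then longer first for tight packing
  idx <- rep(seq_len(nrow(records)), records$count)
  frags <- records[idx, , drop = FALSE]
  frags <- frags[order(frags$start_cpg, -nchar(frags$pattern)), ,
                 drop = FALSE]
  row_end <- integer(0)              # last occupied column per row
  rows <- list()
  for (i in seq_len(nrow(frags))) {
    s <- frags$start_cpg[i] - start_cpg + 1L
    e <- s + nchar(frags$pattern[i]) - 1L
    slot <- which(row_end < s)
    if (length(slot) == 0L) {
      slot <- length(row_end) + 1L
      rows[[slot]] <- rep(" ", k)
      row_end <- c(row_end, 0L)
    } else slot <- slot[[1]]
    chars <- strsplit(frags$pattern[i], "", fixed = TRUE)[[1]]
    if (color) {
      chars <- if (classify) {
        cls <- classify_fragment(frags$pattern[i], homog)
        col <- switch(cls, U = ANSI_GREEN, M = ANSI_RED, X = ANSI_YELLOW,
                      filtered = "")
        if (nzchar(col)) paste0(col, chars, ANSI_RESET) else chars
      } else {
        ifelse(chars == "C", paste0(ANSI_RED, "C", ANSI_RESET),
               ifelse(chars == "T", paste0(ANSI_GREEN, "T", ANSI_RESET),
                      "."))
      }
    }
    rows[[slot]][s:e] <- chars
    row_end[slot] <- e
  }
  c(lines, vapply(rows, function(r) sub("\\s+$", "", paste(r, collapse = "")),
                  character(1)))
}

#' Render per-CpG average methylation as digit lines
#'
#' One line per sample; each CpG's average methylation is discretized to a
#' single digit `min(floor(10 * meth / total), 9)`, uncovered CpGs render
#' `-`. Optional vertical bars mark block boundaries, and `heatmap = TRUE`
#' adds a background color ramp.
#'
#' @param betas Named list of `BetaVector`s.
#' @param start_cpg,end_cpg Half-open global CpG range.
#' @param boundaries Optional global CpG indices at which to insert a `|`
#'   (a bar goes between CpG `b - 1` and `b`).
#' @param color,heatmap Emit ANSI colors / background ramp.
#' @param header Prepend a locus header line.
#' @return Character vector of lines, one per sample (plus header).
#' @export
render_beta_lines <- function(betas, start_cpg, end_cpg, boundaries = NULL,
                              color = FALSE, heatmap = FALSE,
                              header = TRUE) {
  k <- end_cpg - start_cpg
  stopifnot(k >= 1L)
  at <- start_cpg:(end_cpg - 1L)
  lines <- if (header) {
    sprintf("CpG %d-%d (%d sites)", start_cpg, end_cpg - 1L, k)
  } else character(0)
  bar_after <- intersect(boundaries %||% integer(0), at[-1])
  ramp <- c(rep(ANSI_GREEN, 3), rep(ANSI_YELLOW, 4), rep(ANSI_RED, 3))
  for (s in names(betas)) {
    b <- betas[[s]]
    m <- b$meth[at]; t_ <- b$total[at]
    d <- ifelse(t_ > 0L, pmin(floor(10 * m / t_), 9), NA_real_)
    glyph <- ifelse(is.na(d), "-", as.character(d))
    if (color || heatmap) {
      cg <- glyph
      ok <- !is.na(d)
      cg[ok] <- paste0(ramp[d[ok] + 1L], glyph[ok], ANSI_RESET)
      glyph <- cg
    }
    if (length(bar_after)) {
      pos <- match(bar_after, at)
      for (p in rev(sort(pos))) {
        glyph <- append(glyph, "|", after = p - 1L)
      }
    }
    lines <- c(lines, paste0(s, "  ", paste(glyph, collapse = "")))
  }
  lines
}
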