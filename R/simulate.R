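#' Simulate a CpG-bearing reference genome
#'
#' Builds a single-chromosome genome with exactly `n_cpgs` CG dinucleotides
#' planted at known positions, separated by CG-free A/T filler, so that
#' [build_index()] ground truth is known by construction.
#'
#' @param n_cpgs Number of CpG sites to plant.
#' @param spacing Distance in bases between consecutive CpG C positions
#'   (`spacing = 2` produces adjacent CGCG runs).
#' @param chrom Chromosome name.
#' @param pad CG-free padding at both ends.
#' @param seed RNG seed for the filler.
#' @return List with `chrom`, `seq` (the sequence string), `positions`
#'   (1-based C positions), `length`.
#' @export
simulate_genome <- function(n_cpgs, spacing = 10L, chrom = "chrS",
                            pad = 50L, seed = NULL) {
  stopifnot(n_cpgs >= 1L, spacing >= 2L, pad >= 0L)
  with_rng_seed(seed, {
    positions <- pad + 1L + (seq_len(n_cpgs) - 1L) * spacing
    len <- positions[n_cpgs] + 1L + pad
    chars <- sample(c("A", "T"), len, replace = TRUE)
    chars[positions] <- "C"
    chars[positions + 1L] <- "G"
    list(chrom = chrom, seq = paste(chars, collapse = ""),
         positions = positions, length = len)
  })
}

#' Write a simulated genome as FASTA
#'
#' @param genome Output of [simulate_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sim_fasta <- function(genome, path) {
  chunks <- substring(genome$seq,
                      seq(1L, nchar(genome$seq), by = 60L),
                      pmin(seq(60L, nchar(genome$seq) + 59L, by = 60L),
                           nchar(genome$seq)))
  writeLines(c(paste0(">", genome$chrom), chunks), path)
  invisible(path)
}

# callable CpG local indices for a read span [a, b]: top-strand reads are
# inspected at the C, bottom-strand at the G (C position + 1)
callable_cpgs <- function(positions, a, b, top) {
  q <- if (top) positions else positions + 1L
  which(q >= a & q <= b)
}

random_errors <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1L)
    }, character(1))
  }
  chars
}

#' Simulate converted (or modification-tagged) reads from a genome
#'
#' Fragments are placed uniformly; per fragment an allele is drawn by fair
#' coin when `theta2` is given (imprinting-like two-allele mixture), then
#' each covered CpG's methylation is Bernoulli with that allele's per-site
#' probability, shared across the fragment. Bisulfite-style conversion is
#' applied per strand (unmethylated C reads as T on the top strand, G as A
#' on the bottom); `long_read = TRUE` instead writes the native sequence
#' with MM/ML base-modification tags. The SAM output carries proper flags
#' (paired mode emits mates, leaving an unsequenced `.` gap when
#' `insert_len > 2 * read_len`), and a truth table of per-fragment patterns
#' is returned.
#'
#' @param genome Output of [simulate_genome()].
#' @param theta Per-CpG methylation probability (scalar recycled to all
#'   sites), allele 1.
#' @param theta2 Optional allele-2 probabilities for a 50/50 two-allele
#'   mixture.
#' @param depth Target mean per-base coverage.
#' @param read_len Read length in bases.
#' @param paired Emit read pairs.
#' @param insert_len Fragment length in paired mode.
#' @param long_read Emit native long reads with MM/ML tags.
#' @param error_rate Per-base substitution error probability.
#' @param seed RNG seed.
#' @param sam_path Output SAM path (default: tempfile).
#' @return List with `sam` (path), `truth` (collapsed PAT records of the
#'   true patterns), `truth_fragments` (one row per fragment), `n_fragments`.
#' @export
simulate_reads <- function(genome, theta, theta2 = NULL, depth = 30L,
                           read_len = 80L, paired = FALSE,
                           insert_len = 2L * read_len, long_read = FALSE,
                           error_rate = 0, seed = NULL,
                           sam_path = tempfile(fileext = ".sam")) {
  n_cpg <- length(genome$positions)
  theta <- rep_len(theta, n_cpg)
  if (!is.null(theta2)) theta2 <- rep_len(theta2, n_cpg)
  span <- if (paired) insert_len else read_len
  if (span > genome$length) stop("fragment span exceeds chromosome length")
  if (paired && insert_len < read_len) stop("insert_len < read_len")
  n_frag <- ceiling(depth * genome$length / span)
  pos <- genome$positions
  off <- 0L  # single-chromosome genome: global CpG index == local
  with_rng_seed(seed, {
    sam <- character(0)
    truth <- vector("list", n_frag)
    ref_chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    for (f in seq_len(n_frag)) {
      s <- sample.int(genome$length - span + 1L, 1L)
      top <- stats::runif(1) < 0.5
      th <- if (!is.null(theta2) && stats::runif(1) < 0.5) theta2 else theta
      # methylation state of every CpG the fragment could touch
      touch <- which(pos >= s - 1L & pos <= s + span - 1L)
      meth <- stats::setNames(stats::rbinom(length(touch), 1L, th[touch]) ==
                                1L, touch)
      spans <- if (paired) {
        list(c(s, s + read_len - 1L),
             c(s + insert_len - read_len, s + insert_len - 1L))
      } else list(c(s, s + span - 1L))
      callable <- sort(unique(unlist(lapply(spans, function(sp) {
        callable_cpgs(pos, sp[1], sp[2], top)
      }))))
      qname <- sprintf("frag%06d", f)
      for (ri in seq_along(spans)) {
        a <- spans[[ri]][1]; b <- spans[[ri]][2]
        chars <- ref_chars[a:b]
        if (long_read) {
          # native bases; methylation carried by MM/ML tags
          cc <- callable_cpgs(pos, a, b, top)
          tagpos <- if (top) pos[cc] else pos[cc] + 1L
          mstate <- meth[as.character(cc)]
          ord <- if (top) order(tagpos) else order(-tagpos)
          ml <- ifelse(mstate[ord], 230L, 20L)
          mm <- paste0("C+m?,", paste(rep(0L, length(ord)), collapse = ","),
                       ";")
          tags <- sprintf("MM:Z:%s\tML:B:C,%s", mm,
                          paste(ml, collapse = ","))
          flag <- if (top) 0L else 16L
          chars <- random_errors(chars, error_rate)
          sam <- c(sam, paste(qname, flag, genome$chrom, a, 60L,
                              paste0(length(chars), "M"), "*", 0L, 0L,
                              paste(chars, collapse = ""), "*", tags,
                              sep = "\t"))
        } else {
          conv <- which(pos >= a - 1L & pos <= b)
          for (ci in conv) {
            mm <- isTRUE(meth[as.character(ci)])
            p <- pos[ci]
            if (top) {
              if (p >= a && p <= b && !mm) chars[p - a + 1L] <- "T"
            } else {
              if (p + 1L >= a && p + 1L <= b && !mm) chars[p + 2L - a] <- "A"
            }
          }
          chars <- random_errors(chars, error_rate)
          # top-strand fragments: read1 forward at the left span (99/147);
          # bottom-strand: read1 reverse at the right span (83), mate 163
          fl <- if (!paired) {
            if (top) 0L else 16L
          } else if (top) {
            if (ri == 1L) 99L else 147L
          } else {
            if (ri == 2L) 83L else 163L
          }
          mate <- if (paired) {
            other <- spans[[3L - ri]][1]
            tl <- if (a <= other) insert_len else -insert_len
            c("=", other, tl)
          } else c("*", 0L, 0L)
          sam <- c(sam, paste(qname, fl, genome$chrom, a, 60L,
                              paste0(length(chars), "M"), mate[1], mate[2],
                              mate[3],
                              paste(chars, collapse = ""), "*",
                              sep = "\t"))
        }
      }
      if (length(callable)) {
        cset <- callable
        patt <- rep(".", max(cset) - min(cset) + 1L)
        patt[cset - min(cset) + 1L] <-
          ifelse(meth[as.character(cset)], "C", "T")
        truth[[f]] <- data.frame(chrom = genome$chrom,
                                 start_cpg = off + min(cset),
                                 pattern = paste(patt, collapse = ""),
                                 count = 1L, stringsAsFactors = FALSE)
      }
    }
    body <- sam[order(as.integer(vapply(strsplit(sam, "\t", fixed = TRUE),
                                        `[[`, character(1), 4)))]
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, genome$length),
                 body), sam_path)
    truth_df <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    if (is.null(truth_df)) {
      truth_df <- pat_records(character(0), integer(0), character(0),
                              integer(0))
    }
    list(sam = sam_path,
         truth = collapse_pat(truth_df, chrom_order = genome$chrom),
         truth_fragments = truth_df,
         n_fragments = n_frag)
  })
}

#' Simulate a fragment matrix directly from the generative model
#'
#' Draws reads from the per-site Bernoulli model used by the bimodality
#' test: optionally a 50/50 two-allele mixture, each read's sites
#' independent given its allele, with optional missingness.
#'
#' @param theta1 Per-site methylation probabilities, allele 1.
#' @param theta2 Optional allele-2 probabilities (NULL: single allele).
#' @param n_reads Number of reads.
#' @param missing_rate Probability an entry is unobserved.
#' @param seed RNG seed.
#' @return Integer matrix (reads x sites) with NA for missing entries.
#' @export
simulate_fragment_matrix <- function(theta1, theta2 = NULL, n_reads = 30L,
                                     missing_rate = 0, seed = NULL) {
  k <- length(theta1)
  with_rng_seed(seed, {
    m <- matrix(NA_integer_, n_reads, k)
    for (j in seq_len(n_reads)) {
      th <- if (!is.null(theta2) && stats::runif(1) < 0.5) theta2 else theta1
      m[j, ] <- stats::rbinom(k, 1L, th)
    }
    if (missing_rate > 0) {
      m[matrix(stats::runif(length(m)) < missing_rate, n_reads, k)] <-
        NA_integer_
    }
    # every read must keep at least one observation
    allna <- rowSums(!is.na(m)) == 0L
    m[allna, 1L] <- stats::rbinom(sum(allna), 1L, theta1[[1]])
    m
  })
}
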