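# Shared fixtures, built in code.

# index over a tiny hand-written genome
make_index <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), fa)
  build_index(fa)
}

tiny_index <- function() make_index(c(chr1 = "ACGTCGG"))

# random valid PAT records on one chromosome
random_pat <- function(n, max_cpg = 50L, max_len = 6L, seed = 1L) {
  with_seed(seed, {
    pat <- vapply(seq_len(n), function(i) {
      len <- sample(max_len, 1)
      repeat {
        p <- paste(sample(c("C", "T", "."), len, replace = TRUE,
                          prob = c(0.4, 0.4, 0.2)), collapse = "")
        if (grepl("[CT]", p) && !grepl("^\\.|\\.$", p)) return(p)
      }
    }, character(1))
    pat_records("chr1", sample(max_cpg, n, replace = TRUE), pat,
                sample(3L, n, replace = TRUE))
  })
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# exhaustive-search segmentation oracle: best total block score over all
# 2^(n-1) partitions of n CpGs, subject to block size limits; block scores
# are pretabulated so full enumeration stays cheap
brute_force_segment <- function(channels, alpha, max_cpg = Inf,
                                min_cpg = 1L) {
  n <- length(channels[[1]]$meth)
  S <- matrix(-Inf, n, n)   # S[lo, hi]: summed-channel score of block lo..hi
  for (lo in 1:n) {
    for (hi in lo:n) {
      len <- hi - lo + 1L
      if (len > max_cpg || len < min_cpg) next
      s <- 0
      for (ch in channels) {
        m <- sum(ch$meth[lo:hi])
        u <- sum(ch$total[lo:hi]) - m
        s <- s + block_score(m, u, alpha)
      }
      S[lo, hi] <- s
    }
  }
  best <- -Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    if (n > 1L) {
      bounds <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2L))) > 0L)
    } else bounds <- integer(0)
    edges <- c(0L, bounds, n)
    s <- sum(S[cbind(edges[-length(edges)] + 1L, edges[-1L])])
    best <- max(best, s)
  }
  best
}

# per-channel random coverage fixture for segmentation tests
random_channels <- function(n_cpgs, n_channels, seed) {
  with_seed(seed, {
    lapply(seq_len(n_channels), function(i) {
      total <- rpois(n_cpgs, 8)
      list(meth = rbinom(n_cpgs, total, runif(1)), total = total)
    })
  })
}

# one-chromosome index whose CpG spacing is known
seg_index <- function(n, spacing = 10L, seed = 1L) {
  g <- simulate_genome(n, spacing = spacing, seed = seed)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  on.exit(unlink(fa))
  build_index(fa)
}

as_channels <- function(chs) {
  lapply(chs, function(ch) beta_vector(ch$meth, ch$total, width = 16L))
}

# synthetic block-by-sample setting with one planted marker (block 7 is
# unmethylated in group G, methylated everywhere else)
planted_markers <- function(seed = 1, n_blocks = 30, depth = 50L) {
  with_seed(seed, {
    n_cpgs <- n_blocks * 3L
    blocks <- data.frame(chrom = "sim",
                         start = (seq_len(n_blocks) - 1L) * 30L,
                         end = seq_len(n_blocks) * 30L,
                         startCpG = seq(1L, n_cpgs, by = 3L),
                         endCpG = seq(4L, n_cpgs + 1L, by = 3L))
    samples <- c(paste0("g", 1:3), paste0("o", 1:6))
    groups <- data.frame(sample = samples,
                         group = c(rep("G", 3), rep("O", 6)))
    betas <- lapply(samples, function(s) {
      base <- runif(n_blocks, 0.75, 0.95)
      if (startsWith(s, "g")) base[7] <- runif(1, 0.03, 0.07) else
        base[7] <- runif(1, 0.85, 0.95)
      p <- rep(base, each = 3L)
      total <- rep(depth, n_cpgs)
      beta_vector(rbinom(n_cpgs, total, p), total, width = 16L)
    })
    names(betas) <- samples
    list(blocks = blocks, groups = groups, betas = betas)
  })
}
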