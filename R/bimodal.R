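#' Build a read-by-site fragment matrix for a region
#'
#' Expands PAT records intersecting a CpG range into a matrix with one row
#' per sequenced fragment (a count-k record becomes k rows) and one column
#' per CpG of the range: 1 = methylated, 0 = unmethylated, NA = unobserved.
#' Columns with no observation are kept (they are simply uninformative).
#'
#' @param records PAT records.
#' @param start_cpg,end_cpg Half-open global CpG index range.
#' @return Integer matrix with column names set to global CpG indices.
#' @export
fragment_matrix <- function(records, start_cpg, end_cpg) {
  k <- end_cpg - start_cpg
  stopifnot(k >= 1L)
  records <- clip_pat(as.data.frame(records), start_cpg, end_cpg)
  n <- sum(records$count)
  m <- matrix(NA_integer_, nrow = n, ncol = k,
              dimnames = list(NULL, start_cpg + seq_len(k) - 1L))
  if (n == 0L) return(m)
  row <- 1L
  for (r in seq_len(nrow(records))) {
    chars <- strsplit(records$pattern[r], "", fixed = TRUE)[[1]]
    vals <- ifelse(chars == "C", 1L, ifelse(chars == "T", 0L, NA_integer_))
    at <- records$start_cpg[r] - start_cpg + seq_along(vals)
    for (dup in seq_len(records$count[r])) {
      m[row, at] <- vals
      row <- row + 1L
    }
  }
  m
}

# Bernoulli log-likelihood of matrix m under per-site probabilities theta,
# with 0*log(0) := 0 and NA entries skipped.
bernoulli_loglik <- function(m, theta) {
  ll <- 0
  for (i in seq_len(ncol(m))) {
    r <- m[, i]
    r <- r[!is.na(r)]
    if (length(r) == 0L) next
    th <- theta[[i]]
    n1 <- sum(r); n0 <- length(r) - n1
    if (n1 > 0L) ll <- ll + n1 * log(th)
    if (n0 > 0L) ll <- ll + n0 * log(1 - th)
  }
  ll
}

#' Fit the single-allele model
#'
#' Maximum-likelihood per-site methylation probabilities: at each CpG the
#' methylated fraction of its observations. Sites without observations are
#' excluded from the likelihood.
#'
#' @param m Fragment matrix from [fragment_matrix()].
#' @return List with `theta` (per-site MLE, NA where unobserved) and
#'   `loglik`.
#' @export
fit_single_allele <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L) stop("empty fragment matrix")
  theta <- colMeans(m, na.rm = TRUE)
  theta[is.nan(theta)] <- NA_real_
  obs <- !is.na(theta)
  ll <- if (any(obs)) bernoulli_loglik(m[, obs, drop = FALSE], theta[obs])
        else 0
  list(theta = theta, loglik = ll)
}

# per-read log density under theta for observed entries (vector over reads)
read_loglik <- function(m, theta) {
  k <- ncol(m)
  ll <- numeric(nrow(m))
  for (i in seq_len(k)) {
    r <- m[, i]
    ok <- !is.na(r)
    if (!any(ok)) next
    ll[ok] <- ll[ok] + r[ok] * log(theta[[i]]) +
      (1L - r[ok]) * log(1 - theta[[i]])
  }
  ll
}

#' Fit the two-allele mixture by expectation-maximization
#'
#' The two-component model assigns each fragment to one of two alleles with
#' fixed 50/50 prior and per-site methylation probabilities per allele. The
#' E-step computes per-read allele responsibilities; the M-step re-estimates
#' each allele's per-site probability as the responsibility-weighted
#' methylated fraction (non-missing entries only). Iterates until the
#' log-likelihood gain falls below `tol` or `max_iter` is hit; the
#' likelihood is non-decreasing across iterations. `hard = TRUE` switches
#' to winner-takes-all assignment. Probabilities are kept in
#' `[1e-6, 1 - 1e-6]` during iteration; on return, estimates within that
#' clamp of 0/1 are snapped to the boundary when that does not lower the
#' likelihood.
#'
#' @param m Fragment matrix from [fragment_matrix()].
#' @param init Length-2 numeric: initial methylation probability of allele 1
#'   and allele 2 at every site.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param hard Use hard allele assignment instead of soft responsibilities.
#' @return List with `theta1`, `theta2`, `responsibilities`, `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`.
#' @export
fit_two_allele_em <- function(m, init = c(0.9, 0.1), tol = 1e-6,
                              max_iter = 300L, hard = FALSE) {
  if (!is.matrix(m) || nrow(m) < 2L) {
    stop("need at least 2 reads for the two-allele model")
  }
  eps <- 1e-6
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  k <- ncol(m)
  th1 <- rep(clamp(init[[1]]), k)
  th2 <- rep(clamp(init[[2]]), k)
  mix_loglik <- function(l1, l2) {
    hi <- pmax(l1, l2)
    sum(hi + log(0.5 * exp(l1 - hi) + 0.5 * exp(l2 - hi)))
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  w <- NULL
  repeat {
    it <- it + 1L
    l1 <- read_loglik(m, th1)
    l2 <- read_loglik(m, th2)
    ll <- mix_loglik(l1, l2)
    trace <- c(trace, ll)
    w <- 1 / (1 + exp(l2 - l1))          # P(allele 1 | read)
    if (hard) w <- as.numeric(w >= 0.5)
    if (ll - ll_old < tol) { converged <- TRUE; break }
    if (it > max_iter) break
    ll_old <- ll
    for (i in seq_len(k)) {
      r <- m[, i]
      ok <- !is.na(r)
      if (!any(ok)) next
      w1 <- sum(w[ok]); w2 <- sum(1 - w[ok])
      if (w1 > 0) th1[[i]] <- clamp(sum(w[ok] * r[ok]) / w1)
      if (w2 > 0) th2[[i]] <- clamp(sum((1 - w[ok]) * r[ok]) / w2)
    }
  }
  # snap near-boundary estimates and keep the snap only if it helps
  snap <- function(x) ifelse(x <= 2 * eps, 0, ifelse(x >= 1 - 2 * eps, 1, x))
  s1 <- snap(th1); s2 <- snap(th2)
  if (!identical(s1, th1) || !identical(s2, th2)) {
    ll_snap <- mix_loglik(read_loglik_safe(m, s1), read_loglik_safe(m, s2))
    if (ll_snap >= trace[length(trace)]) {
      th1 <- s1; th2 <- s2
      trace[length(trace)] <- ll_snap
    }
  }
  list(theta1 = th1, theta2 = th2,
       responsibilities = w,
       loglik = trace[length(trace)], loglik_trace = trace,
       converged = converged, n_iter = it)
}

# read_loglik tolerating exact 0/1 probabilities (impossible observations
# give -Inf for that read, handled by the log-sum-exp mixture).
read_loglik_safe <- function(m, theta) {
  k <- ncol(m)
  ll <- numeric(nrow(m))
  for (i in seq_len(k)) {
    r <- m[, i]
    ok <- !is.na(r)
    if (!any(ok)) next
    lth <- ifelse(r[ok] == 1L, log(theta[[i]]), log(1 - theta[[i]]))
    lth[ifelse(r[ok] == 1L, theta[[i]] == 1, theta[[i]] == 0)] <- 0
    ll[ok] <- ll[ok] + lth
  }
  ll
}

#' Likelihood-ratio test for bimodal (allele-specific) methylation
#'
#' Tests whether a two-allele mixture (each allele with its own per-site
#' methylation probabilities, 50/50 prior) explains a region's fragments
#' significantly better than a single set of per-site probabilities. The
#' statistic is `2 * (loglik_two - loglik_single)`, clamped at 0, referred
#' to a chi-squared distribution with df = number of informative sites (the
#' parameter-count difference between the 2k- and k-parameter models).
#' Small p-values indicate bimodal, e.g. imprinted, methylation.
#'
#' @param m Fragment matrix from [fragment_matrix()].
#' @param init,tol,max_iter,hard Passed to [fit_two_allele_em()].
#' @return List with `statistic`, `p_value`, `df`, `n_reads`, `n_sites`,
#'   and the two fits (`single`, `two`).
#' @examples
#' m <- rbind(matrix(1L, 3, 2), matrix(0L, 3, 2))  # 3 "CC" + 3 "TT" reads
#' test_bimodal(m)$statistic                        # 12 * log(2)
#' @export
test_bimodal <- function(m, init = c(0.9, 0.1), tol = 1e-6,
                         max_iter = 300L, hard = FALSE) {
  if (!is.matrix(m) || ncol(m) == 0L) stop("no CpG sites in region")
  informative <- colSums(!is.na(m)) > 0L
  if (!any(informative)) stop("no informative CpG sites in region")
  m <- m[, informative, drop = FALSE]
  single <- fit_single_allele(m)
  two <- fit_two_allele_em(m, init = init, tol = tol, max_iter = max_iter,
                           hard = hard)
  lambda <- max(0, 2 * (two$loglik - single$loglik))
  df <- ncol(m)
  list(statistic = lambda,
       p_value = stats::pchisq(lambda, df = df, lower.tail = FALSE),
       df = df, n_reads = nrow(m), n_sites = ncol(m),
       single = single, two = two)
}

#' Test many regions for bimodal methylation
#'
#' Runs [test_bimodal()] on the fragments of each block and reports a
#' Benjamini-Hochberg adjusted p-value across the tested blocks.
#'
#' @param pat PAT records or file path.
#' @param blocks Data.frame with `chrom`, `startCpG`, `endCpG`.
#' @param min_reads Minimum fragments required to test a block (untested
#'   blocks report NA).
#' @param ... Passed to [test_bimodal()].
#' @return `blocks` with `n_reads`, `n_sites`, `statistic`, `p_value`,
#'   `p_adj` columns.
#' @export
test_bimodal_regions <- function(pat, blocks, min_reads = 10L, ...) {
  out <- as.data.frame(blocks)
  out$n_reads <- NA_integer_; out$n_sites <- NA_integer_
  out$statistic <- NA_real_; out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    rec <- query_pat(pat, chrom = out$chrom[i],
                     start_cpg = out$startCpG[i], end_cpg = out$endCpG[i])
    if (nrow(rec) == 0L || sum(rec$count) < min_reads) next
    m <- fragment_matrix(rec, out$startCpG[i], out$endCpG[i])
    res <- tryCatch(test_bimodal(m, ...), error = function(e) NULL)
    if (is.null(res)) next
    out$n_reads[i] <- res$n_reads; out$n_sites[i] <- res$n_sites
    out$statistic[i] <- res$statistic; out$p_value[i] <- res$p_value
  }
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
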