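#' Mann-Whitney U test with exact two-sided p values
#'
#' Computes the U statistic of the first sample from rank sums with midrank
#' tie handling. For `n1 * n2 <= 400` (or `mode = "exact"`) the two-sided
#' p value is exact: the full permutation distribution of the rank sum over
#' all `choose(n1 + n2, n1)` labelings is computed (by the count-generating
#' dynamic programme over the observed midranks, which enumerates the same
#' distribution), and
#' \eqn{p = \min(1,\; 2\min(P(U \le u), P(U \ge u)))}.
#' Larger problems use the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param sampleA,sampleB numeric vectors (non-empty).
#' @param mode "auto" (exact when n1*n2 <= 400), "exact" or "normal".
#' @return a [RankTestResult-class].
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(sampleA, sampleB,
                        mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(sampleA) || !length(sampleB))
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(sampleA); n2 <- length(sampleB)
  r <- rank(c(sampleA, sampleB))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- switch(mode, exact = TRUE, normal = FALSE,
                  auto = n1 * n2 <= 400)
  if (exact) {
    p <- exactRankP(u, r, n1)
    method <- "exact"
  } else {
    p <- normalRankP(u, r, n1, n2)
    method <- "normal-approximation"
  }
  new("RankTestResult", uStatistic = u, pValue = p, method = method,
      sampleSizes = c(as.integer(n1), as.integer(n2)))
}

# Exact permutation distribution of the size-n1 rank sum over the observed
# midranks. Midranks are doubled to integers; counts[k, s] = number of
# subsets of size k-1 with doubled rank sum s (offset by 1). Counts stay
# exact in doubles up to choose(40, 20) ~ 1.4e11 << 2^53.
exactRankP <- function(u, r, n1) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- matrix(0, n1 + 1L, total + 1L)
  counts[1L, 1L] <- 1
  for (ri in r2) {
    kmax <- n1
    # update in decreasing k so each rank is used at most once
    for (k in kmax:1) {
      nz <- which(counts[k, ] > 0)
      if (length(nz))
        counts[k + 1L, nz + ri] <- counts[k + 1L, nz + ri] + counts[k, nz]
    }
  }
  dist <- counts[n1 + 1L, ]
  tot <- sum(dist)
  s2 <- seq_along(dist) - 1L                       # doubled rank sums
  u2 <- s2 - n1 * (n1 + 1L)                        # doubled U values
  uObs2 <- round(2 * u)
  pLe <- sum(dist[u2 <= uObs2 + 1e-9]) / tot
  pGe <- sum(dist[u2 >= uObs2 - 1e-9]) / tot
  min(1, 2 * min(pLe, pGe))
}

# Normal approximation with tie-corrected variance and continuity
# correction.
normalRankP <- function(u, r, n1, n2) {
  n <- n1 + n2
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieCorr)
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @rdname RankTestResult-class
#' @export
setMethod("uStatistic", "RankTestResult", function(x) x@uStatistic)

#' @rdname RankTestResult-class
#' @export
setMethod("pValue", "RankTestResult", function(x) x@pValue)

setMethod("show", "RankTestResult", function(object) {
  cat("Mann-Whitney rank test (", object@method, ")\n", sep = "")
  cat("  n1 =", object@sampleSizes[1], ", n2 =", object@sampleSizes[2],
      ":  U =", object@uStatistic, ",  two-sided p =",
      format(object@pValue, digits = 4), "\n")
})
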