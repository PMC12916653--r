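# Rank-based primitives shared by the evaluation and downstream modules.
# AUROC and the Mann-Whitney U test are implemented together because they are
# the same statistic: AUROC = U / (n1 * n0).

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with ties counted
#' one half, i.e. the probability that a randomly chosen case outscores a
#' randomly chosen control.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary outcome (0/1, logical, or control/case).
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auroc <- function(scores, labels) {
  y <- as_binary_outcome(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC requires both classes present", call. = FALSE)
  }
  r <- rank(scores)                      # midranks handle ties as 1/2
  u <- sum(r[y == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

# U statistic of x (cases) versus y (controls), ties counted half.
mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-sided Mann-Whitney U test p-value
#'
#' Exact permutation enumeration of the U distribution for combined
#' n1 + n2 <= `exact_limit` (enumeration is a permutation test, so ties are
#' handled exactly too); otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit combined-size cutoff for exact enumeration (default 20).
#' @return two-sided p-value in (0, 1\].
#' @export
#' @examples
#' mann_whitney_p(c(1, 2, 3), c(4, 5, 6))   # 2 / choose(6, 3) = 0.1
mann_whitney_p <- function(x, y, exact_limit = 20L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("mann_whitney_p requires non-empty samples", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- mann_whitney_u(x, y)
  if (n <= exact_limit) {
    r <- rank(c(x, y))
    offset <- n1 * (n1 + 1) / 2
    sets <- utils::combn(n, n1)
    us <- colSums(matrix(r[sets], nrow = n1)) - offset
    lo <- mean(us <= u + 1e-9)
    hi <- mean(us >= u - 1e-9)
    return(min(1, 2 * min(lo, hi)))
  }
  r <- rank(c(x, y))
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)             # all observations tied
  z <- (u - n1 * n2 / 2)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}
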