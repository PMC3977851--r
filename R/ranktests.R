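#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent groups.
#' For small samples (combined n at most `exact_limit`) the p-value is
#' exact by permutation: every assignment of the pooled values to the two
#' groups is enumerated, ties handled by mid-ranks, and the p-value is the
#' proportion of assignments with a U statistic at least as extreme as the
#' observed one. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b numeric vectors, non-empty.
#' @param tail `"two_sided"` or `"one_sided_greater"` (alternative: values
#'   in `group_a` tend to be greater than in `group_b`).
#' @param exact_limit combined-size switchover from exact enumeration to
#'   the normal approximation (default 12).
#' @return List with `U` (number of (a, b) pairs with a > b, ties counted
#'   1/2), `p`, `method` (`"exact"` or `"normal"`), `tail`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.10
#' @export
mann_whitney <- function(group_a, group_b, tail = c("two_sided", "one_sided_greater"),
                         exact_limit = 12) {
  tail <- match.arg(tail)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  eps <- 1e-9

  if (n <= exact_limit) {
    sets <- combn(n, na)
    rank_sums <- colSums(matrix(r[sets], nrow = na))
    us <- rank_sums - na * (na + 1) / 2
    p <- switch(tail,
      two_sided = mean(abs(us - mu) >= abs(u_obs - mu) - eps),
      one_sided_greater = mean(us >= u_obs - eps))
    method <- "exact"
  } else {
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else if (tail == "two_sided") {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sigma
      p <- min(1, 2 * pnorm(-abs(z)))
    } else {
      z <- (u_obs - mu - 0.5) / sigma
      p <- pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  list(U = u_obs, p = p, method = method, tail = tail)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests for a systematic within-pair change. Zero differences are
#' dropped; ties among |differences| are mid-ranked. For n (non-zero
#' pairs) at most `exact_limit` the null distribution is exact: all 2^n
#' sign patterns are enumerated. Larger n uses the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param pre,post numeric vectors of equal length (>= 5 pairs).
#' @param tail `"two_sided"` or `"one_sided_greater"` (alternative:
#'   `post` tends to exceed `pre`).
#' @param exact_limit switchover from exact enumeration (default 15).
#' @return List with `V` (sum of positive-difference ranks), `p`,
#'   `method`, `n_used`, `tail`.
#' @examples
#' wilcoxon_paired(rep(0, 5), 1:5, tail = "one_sided_greater")$p  # 1/32
#' @export
wilcoxon_paired <- function(pre, post, tail = c("two_sided", "one_sided_greater"),
                            exact_limit = 15) {
  tail <- match.arg(tail)
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 5) stop("need at least 5 pairs")
  d <- post - pre
  d <- d[d != 0]
  if (!length(d)) {
    warning("all differences are zero; p = 1")
    return(list(V = 0, p = 1, method = "degenerate", n_used = 0L, tail = tail))
  }
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  eps <- 1e-9

  if (n <= exact_limit) {
    # exact: V under random signs; enumerate all 2^n patterns
    vs <- 0
    for (i in seq_len(n)) vs <- c(vs, vs + r[i])
    p <- switch(tail,
      two_sided = mean(abs(vs - mu) >= abs(v_obs - mu) - eps),
      one_sided_greater = mean(vs >= v_obs - eps))
    method <- "exact"
  } else {
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    if (tail == "two_sided") {
      z <- (v_obs - mu - sign(v_obs - mu) * 0.5) / sigma
      p <- min(1, 2 * pnorm(-abs(z)))
    } else {
      z <- (v_obs - mu - 0.5) / sigma
      p <- pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  list(V = v_obs, p = p, method = method, n_used = n, tail = tail)
}
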