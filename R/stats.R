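#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' The U statistic counts pairs where a value from `a` exceeds one from `b`
#' (ties count one half). The p value is computed by exact permutation
#' enumeration when `min(length(a), length(b)) <= 8` and there are no ties,
#' and by the normal approximation with midrank tie correction and
#' continuity correction otherwise.
#'
#' @param a,b numeric vectors (both non-empty)
#' @param tail `"two"`, `"one_greater"` (alternative: values of `a` tend to
#'   exceed `b`), or `"one_less"`
#' @return list with `u` (U statistic of group `a`), `p`, `method`
#'   (`exact` / `normal`), `tail`, `n_a`, `n_b`
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), tail = "one_less")$p  # 1/20
#' @export
mann_whitney_u <- function(a, b, tail = c("two", "one_greater", "one_less")) {
  tail <- match.arg(tail)
  if (length(a) == 0 || length(b) == 0)
    stop(errorCondition("both groups must be non-empty",
                        class = c("apomut_empty_group", "error")))
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && min(n, m) <= 8) {
    ## exact permutation null: U of every n-subset of the pooled ranks
    combs <- combn(n + m, n)
    ranks <- rank(pooled)
    us <- colSums(matrix(ranks[combs], nrow = n)) - n * (n + 1) / 2
    p <- switch(tail,
      one_greater = mean(us >= u_a),
      one_less = mean(us <= u_a),
      two = mean(abs(us - n * m / 2) >= abs(u_a - n * m / 2)))
    method <- "exact"
  } else {
    p <- mw_normal_p(a, b, tail)
    method <- "normal"
  }
  list(u = u_a, p = min(p, 1), method = method, tail = tail,
       n_a = n, n_b = m)
}

## tie- and continuity-corrected normal approximation of the U test
mw_normal_p <- function(a, b, tail) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  t_tab <- table(pooled)
  tie_term <- sum(t_tab^3 - t_tab)
  N <- n + m
  sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  if (sigma == 0) return(1)
  z_gr <- (u_a - mu - 0.5) / sigma
  z_ls <- (u_a - mu + 0.5) / sigma
  switch(tail,
    one_greater = stats::pnorm(z_gr, lower.tail = FALSE),
    one_less = stats::pnorm(z_ls),
    two = min(1, 2 * min(stats::pnorm(z_gr, lower.tail = FALSE),
                         stats::pnorm(z_ls))))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up rule: `q_i = min over j >= i of (m * p_(j) / j)` over the sorted
#' p values, mapped back to input order and capped at 1.
#'
#' @param p_values numeric vector of p values in \[0, 1\]
#' @return q values, same order as input
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop(errorCondition("p values must lie in [0, 1]",
                        class = c("apomut_bad_p", "error")))
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(m * p_values[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Compare groups with Mann-Whitney U tests under one FDR family
#'
#' Runs one test per comparison and corrects the resulting p values jointly
#' with [bh_fdr()]. The FDR family is exactly the set of comparisons passed
#' in one call — declare it explicitly rather than correcting across
#' unrelated analyses.
#'
#' @param comparisons list of lists, each with `label`, `a`, `b` and
#'   optionally `tail` (default `"two"`)
#' @param path optional path; when given, the report is written as TSV
#' @return data.frame `label`, `n_a`, `n_b`, `u`, `p`, `q`, `tail`, `method`
#' @export
comparison_report <- function(comparisons, path = NULL) {
  rows <- lapply(comparisons, function(cmp) {
    tail <- if (is.null(cmp$tail)) "two" else cmp$tail
    r <- mann_whitney_u(cmp$a, cmp$b, tail)
    data.frame(label = cmp$label, n_a = r$n_a, n_b = r$n_b, u = r$u,
               p = r$p, tail = tail, method = r$method)
  })
  df <- do.call(rbind, rows)
  df$q <- bh_fdr(df$p)
  df <- df[, c("label", "n_a", "n_b", "u", "p", "q", "tail", "method")]
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
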