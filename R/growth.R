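#' Population doubling time
#'
#' `PDT = TExpan * log(2) / log(Q2 / Q1)` — the expansion time divided
#' by the number of doublings achieved. Base-invariant; vectorized over
#' records.
#'
#' @param q1 Cells seeded (> 0).
#' @param q2 Cells harvested (must exceed `q1`: positive growth).
#' @param texpan Expansion time in hours (> 0).
#' @return Doubling time(s) in hours.
#' @export
doubling_time <- function(q1, q2, texpan) {
  if (any(q1 <= 0) || any(texpan <= 0))
    stop("q1 and texpan must be positive")
  if (any(q2 <= q1)) stop("non-positive growth: q2 must exceed q1")
  texpan * log(2) / log(q2 / q1)
}

#' Wilcoxon rank-sum comparison of doubling times
#'
#' Two-sided rank-sum test between two groups of doubling times (or any
#' continuous measurements). For small problems (`nA + nB <=
#' exact_max_n`, default 12) the p-value is exact, by enumeration of all
#' group assignments with tied observations mid-ranked; larger problems
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Numeric vectors (>= 3 values each).
#' @param exact_max_n Enumeration threshold on `nA + nB`.
#' @return List with `statistic` (rank sum W of group `a`), `u`
#'   (Mann-Whitney U), `p.value`, `method`.
#' @export
compare_growth <- function(a, b, exact_max_n = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty group")
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs >= 3 values")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))  # mid-ranks for ties
  w_obs <- sum(r[seq_len(na)])
  u_obs <- w_obs - na * (na + 1) / 2
  mu_w <- na * (n + 1) / 2
  if (n <= exact_max_n) {
    sets <- combn(n, na)
    w_all <- colSums(matrix(r[sets], nrow = na))
    p <- mean(abs(w_all - mu_w) >= abs(w_obs - mu_w) - 1e-12)
    method <- "exact enumeration (mid-ranked ties)"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- w_obs - mu_w
    cc <- if (dev == 0) 0 else sign(dev) * 0.5
    z <- if (sigma2 > 0) (dev - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie and continuity corrected)"
  }
  list(statistic = c(W = w_obs), u = u_obs, p.value = p, method = method)
}

#' Doubling times for a table of growth records
#'
#' @param records `data.frame` with columns `q1`, `q2`, `texpan` (as
#'   from [simulate_growth_records()]).
#' @return The records with an added `pdt` column (hours).
#' @export
growth_pdt <- function(records) {
  stopifnot(all(c("q1", "q2", "texpan") %in% colnames(records)))
  records$pdt <- doubling_time(records$q1, records$q2, records$texpan)
  records
}
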