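# Cohort statistics: Mann-Whitney comparisons, Spearman correlation,
# size-normalized profile averaging.

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' U is the rank-sum statistic for group `a` with midrank ties. The
#' two-tailed p-value is exact (full enumeration of the rank-sum null) for
#' combined n <= 12 without ties, and the normal approximation with tie
#' correction otherwise. If every value in both groups is identical the
#' comparison is degenerate: U = n1 n2 / 2, p = 1, `degenerate = TRUE`.
#'
#' @param a,b Numeric value vectors (each n >= 3).
#' @return One-row tibble: `n_a`, `n_b`, `u_statistic`, `p_value`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `method`, `degenerate`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 3 || n2 < 3)
    stop_sf("mann_whitney: need >= 3 values per group (got %d, %d)", n1, n2)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (sd(c(a, b)) == 0) {
    p <- 1; method <- "degenerate"; degen <- TRUE
  } else {
    degen <- FALSE
    exact <- (n1 + n2) <= 12 && !ties
    method <- if (exact) "exact" else "normal approximation"
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = FALSE)$p.value)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  tibble(n_a = n1, n_b = n2, u_statistic = u, p_value = p,
         mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
         method = method, degenerate = degen)
}

#' Spearman rank correlation with two-tailed p-value
#'
#' rho is the Pearson correlation of midranks; the two-tailed p-value uses
#' the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop_sf("spearman_cor: need >= 4 complete pairs, got %d", n)
  if (sd(x) == 0 || sd(y) == 0)
    stop_sf("spearman_cor: constant input")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), n - 2)
  }
  tibble(rho = rho, p_value = p, n = n)
}

#' Average pole-to-pole profiles across cells of different spindle sizes
#'
#' Each cell's profile is rescaled to the \[0, 1\] pole-to-pole fraction,
#' linearly interpolated onto a common grid, and max-normalized; the mean
#' and a per-grid-point t-distribution 95% CI are returned. Profiles with
#' fewer than 4 samples are rejected with a warning naming them.
#'
#' @param profiles Long tibble with columns `cell`, `position_um`,
#'   `intensity`.
#' @param grid_n Number of grid points on \[0, 1\].
#' @param conf Confidence level for the band.
#' @return Tibble `position_frac`, `mean`, `ci_lo`, `ci_hi`, `n_cells`;
#'   the per-cell interpolated matrix (cells x grid) is attached as
#'   attribute `"per_cell"`.
#' @export
average_profiles <- function(profiles, grid_n = 100, conf = 0.95) {
  need <- c("cell", "position_um", "intensity")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop_sf("average_profiles: missing columns: %s", paste(miss, collapse = ", "))
  split_p <- split(profiles, profiles$cell)
  short <- names(split_p)[vapply(split_p, nrow, integer(1)) < 4L]
  if (length(short)) {
    warning(sprintf("average_profiles: rejecting profiles with < 4 samples: %s",
                    paste(short, collapse = ", ")), call. = FALSE)
    split_p <- split_p[setdiff(names(split_p), short)]
  }
  if (length(split_p) < 2L)
    stop_sf("average_profiles: need >= 2 usable profiles")
  grid <- seq(0, 1, length.out = grid_n)
  per_cell <- t(vapply(split_p, function(df) {
    pos <- df$position_um
    frac <- (pos - min(pos)) / (max(pos) - min(pos))
    v <- approx(frac, df$intensity, xout = grid, rule = 2)$y
    v / max(v)
  }, numeric(grid_n)))
  nc <- nrow(per_cell)
  m <- colMeans(per_cell)
  se <- apply(per_cell, 2, sd) / sqrt(nc)
  tq <- qt(1 - (1 - conf) / 2, nc - 1)
  out <- tibble(position_frac = grid, mean = m,
                ci_lo = m - tq * se, ci_hi = m + tq * se, n_cells = nc)
  attr(out, "per_cell") <- per_cell
  out
}

#' Significance star codes
#'
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001,
#' `ns` otherwise.
#'
#' @param p Numeric p-values.
#' @return Character vector of star codes.
#' @export
star_code <- function(p) {
  dplyr::case_when(p <= 1e-4 ~ "****", p <= 1e-3 ~ "***",
                   p <= 1e-2 ~ "**", p <= 0.05 ~ "*", TRUE ~ "ns")
}
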