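#' Adjusted Rand index between two partitions of the same samples
#'
#' Chance-corrected agreement between two label vectors; 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return The adjusted Rand index, a number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)  # degenerate: both partitions trivial
  (sij - expected) / (mx - expected)
}

# round half up to `digits` decimals (printed-style percentages)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

# z-score rows of a features x samples matrix; constant rows -> 0
standardize_rows <- function(values) {
  mu <- rowMeans(values)
  sd <- apply(values, 1, stats::sd)
  z <- (values - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
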