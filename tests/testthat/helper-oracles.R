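# Independent oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Brute-force CIGAR interpreter: expands the alignment base by base
# along the reference and derives gaps/overhangs from the per-base
# operation sequence.
oracle_gaps <- function(pos, cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  refops <- character(0)
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("M", "D", "N", "=", "X"))
      refops <- c(refops, rep(ops[k], lens[k]))
  }
  is_n <- refops == "N"
  if (!any(is_n))
    return(data.frame(gap_start = integer(), gap_end = integer(),
                      left_overhang = integer(),
                      right_overhang = integer()))
  r <- rle(is_n)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_runs <- which(r$values)
  aligned_in <- function(a, b) {
    if (b < a) 0L else sum(refops[a:b] %in% c("M", "=", "X"))
  }
  out <- lapply(seq_along(n_runs), function(j) {
    i <- n_runs[j]
    prev_end <- if (j == 1L) 0L else ends[n_runs[j - 1L]]
    next_start <- if (j == length(n_runs)) length(refops) + 1L
    else starts[n_runs[j + 1L]]
    data.frame(
      gap_start = pos + starts[i] - 1L,
      gap_end = pos + ends[i],
      left_overhang = aligned_in(prev_end + 1L, starts[i] - 1L),
      right_overhang = aligned_in(ends[i] + 1L, next_start - 1L))
  })
  do.call(rbind, out)
}

# Rank-and-sum Spearman: explicit average ranks, explicit
# product-moment formula on the ranks.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i)
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, 0)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx^2) - n * mean(rx)^2
  syy <- sum(ry^2) - n * mean(ry)^2
  sxy / sqrt(sxx * syy)
}

# Closed-form least squares via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Random (syntactically valid, mapped) CIGAR strings for fuzzing.
random_cigar <- function(max_blocks = 4L) {
  blocks <- sample.int(max_blocks, 1L)
  parts <- sprintf("%dM", sample(1:60, 1L))
  for (b in seq_len(blocks - 1L)) {
    mid <- sample(c("N", "D", "I"), 1L,
                  prob = c(0.6, 0.2, 0.2))
    parts <- c(parts, sprintf("%d%s", sample(1:80, 1L), mid),
               sprintf("%dM", sample(1:60, 1L)))
  }
  if (stats::runif(1) < 0.3) parts <- c(sprintf("%dS", sample(1:10, 1L)), parts)
  if (stats::runif(1) < 0.3) parts <- c(parts, sprintf("%dS", sample(1:10, 1L)))
  paste(parts, collapse = "")
}
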