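# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# multiset helpers: live FG sets are kept as sorted integer vectors
ms_add <- function(ms, ids) sort(c(ms, as.integer(ids)))

ms_remove_one <- function(ms, id) {
  i <- match(id, ms)
  if (is.na(i)) stop("fg_not_available: FG ", id, " not present", call. = FALSE)
  ms[-i]
}

# deterministic sub-seed derivation; keeps results reproducible when one
# run seed drives several independent generators
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + k * 12345) %% 2147483647L)
}

# integer histogram as named numeric vector (names = heavy-atom value)
hist_from_values <- function(values) {
  if (length(values) == 0L) return(numeric(0))
  tab <- table(values)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

hist_values <- function(h) as.integer(names(h))

hist_total <- function(h) sum(h)

# discrete convolution of two integer histograms
hist_convolve <- function(h1, h2) {
  if (length(h1) == 0L || length(h2) == 0L) return(numeric(0))
  v1 <- hist_values(h1); v2 <- hist_values(h2)
  sums <- outer(v1, v2, `+`)
  counts <- outer(as.numeric(h1), as.numeric(h2))
  agg <- tapply(as.numeric(counts), as.vector(sums), sum)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out[order(as.integer(names(out)))]
}

hist_shift <- function(h, by) {
  if (length(h) == 0L) return(h)
  names(h) <- as.character(hist_values(h) + as.integer(by))
  h
}

# lower median of an integer histogram: smallest value whose cumulative
# count reaches half the total
hist_median <- function(h) {
  if (length(h) == 0L) return(NA_integer_)
  h <- h[order(hist_values(h))]
  cum <- cumsum(as.numeric(h))
  hist_values(h)[which(cum >= hist_total(h) / 2)[1L]]
}

hist_mean <- function(h) {
  if (length(h) == 0L) return(NA_real_)
  sum(hist_values(h) * as.numeric(h)) / hist_total(h)
}

# truncated-normal integer draws used by the synthetic-data generators
rtrunc_norm_int <- function(n, mean, sd, lower, upper) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(2L * (n - length(out)) + 8L, mean, sd))
    x <- x[x >= lower & x <= upper]
    out <- c(out, as.integer(x))
  }
  out[seq_len(n)]
}

path_pkg_file <- function(...) {
  system.file(..., package = "deldesign", mustWork = TRUE)
}
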