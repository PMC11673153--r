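#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic base generator (linear congruential); independent of R's RNG
# so package constants never disturb user-visible random streams.
.lcg_bases <- function(n, seed) {
  a <- 1103515245; cc <- 12345; m <- 2^31
  state <- seed %% m
  out <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    state <- (a * state + cc) %% m
    out[i] <- bases[(state %/% 65536) %% 4 + 1]
  }
  out
}

.is_interval <- function(x) {
  is.numeric(x) && length(x) == 2L && !anyNA(x) && x[1] <= x[2]
}

.interval_seq <- function(iv) seq.int(iv[1], iv[2])

.complement_base <- function(b) {
  c(A = "C", C = "A", G = "T", T = "G")[b]
}

# round to 1 decimal; R's round() is round-half-to-even
.pct1 <- function(x) round(x, 1)
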