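#' Reference coordinate frame for the mitochondrial control region
#'
#' A `reference_map` fixes the coordinate system every variant call is
#' expressed in: a reference sequence, the D-loop interval, its upstream (UP)
#' and downstream (DOWN) hypervariable subintervals, and the interval of the
#' 8-bp repeat array that is excluded from variant calling. All coordinates
#' are 1-based inclusive nucleotide positions ("np") on the reference; no
#' 0-based representation is ever exposed.
#'
#' The default intervals follow the horse control-region layout used for
#' matriline typing: D-loop np 15445-16660, UP np 15445-16153, DOWN np
#' 16154-16660, with the repeat array at np 16129-16153. The UP and DOWN
#' intervals must be disjoint, adjacent, and together cover the D-loop.
#'
#' @param sequence Character scalar, the reference DNA sequence (A/C/G/T).
#' @param reference_id Identifier for the coordinate frame.
#' @param dloop_interval,up_interval,down_interval 1-based inclusive
#'   intervals `c(start, end)`.
#' @param repeat_interval Optional interval of the tandem-repeat array,
#'   excluded from variant calling and haplotype identity (length
#'   heteroplasmy makes repeat counts non-reproducible). `NULL` disables the
#'   exclusion.
#' @return An object of class `reference_map`.
#' @export
reference_map <- function(sequence,
                          reference_id = "reference",
                          dloop_interval = c(15445L, 16660L),
                          up_interval = c(15445L, 16153L),
                          down_interval = c(16154L, 16660L),
                          repeat_interval = c(16129L, 16153L)) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence must contain only A/C/G/T")
  }
  for (iv in list(dloop_interval, up_interval, down_interval)) {
    if (!.is_interval(iv)) stop("intervals must be numeric c(start, end) with start <= end")
  }
  n <- nchar(sequence)
  if (dloop_interval[2] > n) stop("dloop_interval exceeds reference length")
  if (up_interval[1] != dloop_interval[1] ||
      down_interval[2] != dloop_interval[2] ||
      down_interval[1] != up_interval[2] + 1L) {
    stop("up and down intervals must be disjoint, adjacent, and cover the dloop_interval")
  }
  if (!is.null(repeat_interval)) {
    if (!.is_interval(repeat_interval)) stop("bad repeat_interval")
    if (repeat_interval[1] < dloop_interval[1] || repeat_interval[2] > dloop_interval[2]) {
      stop("repeat_interval must lie within the dloop_interval")
    }
  }
  structure(
    list(
      reference_id = reference_id,
      sequence = sequence,
      dloop_interval = as.integer(dloop_interval),
      up_interval = as.integer(up_interval),
      down_interval = as.integer(down_interval),
      repeat_interval = if (is.null(repeat_interval)) NULL else as.integer(repeat_interval)
    ),
    class = "reference_map"
  )
}

#' @export
print.reference_map <- function(x, ...) {
  cat("Reference coordinate frame:", x$reference_id, "\n")
  cat("  length:", nchar(x$sequence), "bp\n")
  cat(sprintf("  D-loop: np %d-%d (UP %d-%d, DOWN %d-%d)\n",
              x$dloop_interval[1], x$dloop_interval[2],
              x$up_interval[1], x$up_interval[2],
              x$down_interval[1], x$down_interval[2]))
  if (!is.null(x$repeat_interval)) {
    cat(sprintf("  repeat array (excluded): np %d-%d\n",
                x$repeat_interval[1], x$repeat_interval[2]))
  }
  invisible(x)
}

#' Reference base at given positions
#'
#' @param ref A `reference_map`.
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(ref, positions) {
  stopifnot(inherits(ref, "reference_map"))
  vapply(positions, function(p) substr(ref$sequence, p, p), character(1))
}

.ref_cache <- new.env(parent = emptyenv())

#' Synthetic mitochondrial reference (stand-in coordinate frame)
#'
#' Builds a deterministic synthetic 16,660-bp sequence that serves as the
#' coordinate frame for all worked examples and simulations in this package.
#' It is *not* a real mitogenome: it is a reproducible stand-in carrying the
#' control-region layout used throughout (D-loop np 15445-16660, UP/DOWN
#' split at np 16153/16154) and a synthetic 8-bp tandem-repeat array at np
#' 16129-16153. Analyses of real data should construct a [reference_map()]
#' from the genuine reference sequence instead.
#'
#' @return A `reference_map`.
#' @export
synthetic_mt_reference <- function() {
  if (!is.null(.ref_cache$ref)) return(.ref_cache$ref)
  n <- 16660L
  bases <- .lcg_bases(n, seed = 987654321)
  # synthetic 8-bp repeat array filling np 16129-16153
  unit <- c("G", "T", "G", "C", "A", "C", "C", "T")
  idx <- 16129:16153
  bases[idx] <- rep_len(unit, length(idx))
  ref <- reference_map(paste(bases, collapse = ""),
                       reference_id = "synthetic_mt_ref_v1")
  .ref_cache$ref <- ref
  ref
}
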