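#' Synthetic MSY locus references (stand-ins)
#'
#' Deterministic synthetic reference sequences for the three male-specific
#' Y-chromosome loci (YE3, YE17, YXX) used for stallion haplotyping, with
#' their configured diagnostic positions. These are reproducible stand-ins
#' carrying the locus layout only; analyses of real data should supply the
#' genuine locus references and diagnostic positions.
#'
#' The YE17 diagnostic position defaults to np 1277 (the site whose variant
#' state defines haplotype HT02). The YE3 and YXX diagnostic positions are
#' configuration with arbitrary defaults.
#'
#' @param length Locus reference length in bp.
#' @param diagnostic Named integer vector of diagnostic positions per locus.
#' @return Named list (YE3, YE17, YXX) of lists with `locus`, `sequence`,
#'   `diagnostic_position`, `ref_base`, `variant_base`.
#' @export
synthetic_msy_references <- function(length = 1500L,
                                     diagnostic = c(YE3 = 600L, YE17 = 1277L,
                                                    YXX = 700L)) {
  loci <- c("YE3", "YE17", "YXX")
  stopifnot(all(loci %in% names(diagnostic)), all(diagnostic <= length))
  out <- lapply(seq_along(loci), function(k) {
    seqc <- .lcg_bases(length, seed = 1234500 + k)
    pos <- as.integer(diagnostic[[loci[k]]])
    rb <- seqc[pos]
    list(locus = loci[k], sequence = paste(seqc, collapse = ""),
         diagnostic_position = pos, ref_base = rb,
         variant_base = unname(.complement_base(rb)))
  })
  setNames(out, loci)
}

#' Type one MSY locus from sequence
#'
#' Aligns a stallion's locus sequence semi-globally to the locus reference
#' and reads the state at the configured diagnostic position. Variants at
#' other positions are logged but do not change the state.
#'
#' @param seq Character scalar, the query sequence.
#' @param locus_ref One element of [synthetic_msy_references()] (or a list
#'   with the same fields).
#' @param min_score Minimum alignment score (default half the query length).
#' @return List with `state` (`"reference"`, `"variant"`, or `"missing"`
#'   when the diagnostic position is uncovered) and `other_variants`
#'   (a [variant_table()] of non-diagnostic calls).
#' @export
type_locus <- function(seq, locus_ref, min_score = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  res <- .align_query(seq, locus_ref$sequence)
  if (is.null(min_score)) min_score <- 0.5 * nchar(seq)
  if (res$score < min_score) stop("unalignable sequence")
  pos <- locus_ref$diagnostic_position
  v <- res$variants
  at_diag <- v$position == pos
  state <- if (!pos %in% res$coverage) {
    "missing"
  } else if (any(at_diag & v$kind == "substitution")) {
    "variant"
  } else {
    "reference"
  }
  list(state = state, other_variants = v[!at_diag, , drop = FALSE])
}

#' MSY haplotype rule table
#'
#' Three-locus rule table for stallion haplotypes: all-reference is HT01;
#' a variant at the YE17 diagnostic site defines HT02; a variant at the
#' configured third-locus diagnostic site defines HT3. Which of YE3/YXX
#' defines HT3 is configuration (`ht3_locus`); callers should set it
#' explicitly.
#'
#' @param ht3_locus `"YXX"` (default) or `"YE3"`.
#' @return An object of class `msy_rules`.
#' @export
msy_rules <- function(ht3_locus = c("YXX", "YE3")) {
  ht3_locus <- match.arg(ht3_locus)
  structure(list(ht2_locus = "YE17", ht3_locus = ht3_locus), class = "msy_rules")
}

#' Call an MSY haplotype from per-locus states
#'
#' @param genotype Named character vector or list with states for `YE3`,
#'   `YE17`, `YXX`: `"reference"`, `"variant"`, or `"missing"`.
#' @param rules An [msy_rules()] table.
#' @return `"HT01"`, `"HT02"`, `"HT3"`, `"unclassified"` (an unexpected
#'   variant combination), or `"uncallable"` (all loci missing).
#' @export
call_msy <- function(genotype, rules) {
  stopifnot(inherits(rules, "msy_rules"))
  loci <- c("YE3", "YE17", "YXX")
  st <- vapply(loci, function(l) as.character(genotype[[l]]), character(1))
  if (!all(st %in% c("reference", "variant", "missing"))) {
    stop("locus states must be reference/variant/missing")
  }
  if (all(st == "missing")) return("uncallable")
  variant_at <- loci[st == "variant"]
  if (!length(variant_at)) return("HT01")
  if (identical(variant_at, rules$ht2_locus)) return("HT02")
  if (identical(variant_at, rules$ht3_locus)) return("HT3")
  "unclassified"
}

#' MSY haplotype frequencies
#'
#' Counts and percentages over callable samples; `"uncallable"` calls are
#' excluded from the denominator and reported separately.
#'
#' @param calls Character vector of [call_msy()] results.
#' @return List with `table` (data.frame `haplotype`, `count`, `percent`)
#'   and `uncallable` count.
#' @export
msy_frequencies <- function(calls) {
  stopifnot(length(calls) >= 1L)
  unc <- sum(calls == "uncallable")
  ok <- calls[calls != "uncallable"]
  if (!length(ok)) stop("no callable samples")
  cnt <- table(ok)
  df <- data.frame(haplotype = names(cnt), count = as.integer(cnt),
                   percent = .pct1(100 * as.integer(cnt) / length(ok)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$count, df$haplotype), , drop = FALSE]
  rownames(df) <- NULL
  list(table = df, uncallable = unc)
}
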