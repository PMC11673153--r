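#' Construct a variant table
#'
#' Variants are recorded against the reference coordinate frame: 1-based
#' `position`, `ref` and `alt` alleles, and `kind` (`substitution`,
#' `insertion`, `deletion`). Substitutions have equal-length alleles; an
#' insertion is anchored to the reference base it follows (`ref` empty); a
#' deletion records the removed reference bases (`alt` empty).
#'
#' @param position Integer vector of 1-based reference positions.
#' @param ref,alt Character vectors of alleles.
#' @param kind Character vector, one of `"substitution"`, `"insertion"`,
#'   `"deletion"`.
#' @return A `data.frame` with columns `position`, `ref`, `alt`, `kind`.
#' @export
variant_table <- function(position = integer(), ref = character(),
                          alt = character(), kind = character()) {
  df <- data.frame(position = as.integer(position), ref = as.character(ref),
                   alt = as.character(alt), kind = as.character(kind),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% c("substitution", "insertion", "deletion")
  if (any(bad)) stop("unknown variant kind: ", paste(unique(df$kind[bad]), collapse = ", "))
  sub <- df$kind == "substitution"
  if (any(nchar(df$ref[sub]) != nchar(df$alt[sub]))) {
    stop("substitutions must have equal-length ref and alt alleles")
  }
  df[order(df$position), , drop = FALSE]
}

.validate_variants_against_ref <- function(variants, ref) {
  chk <- variants$kind != "insertion"
  if (any(chk)) {
    obs <- vapply(which(chk), function(i) {
      substr(ref$sequence, variants$position[i],
             variants$position[i] + nchar(variants$ref[i]) - 1L)
    }, character(1))
    if (any(obs != variants$ref[chk])) {
      stop("variant ref alleles do not match the reference sequence")
    }
  }
  invisible(TRUE)
}

# Left-align an indel against the reference: shift the event left while the
# base preceding it equals the last base of the inserted/deleted segment.
# `base_at` maps an absolute reference position to its base ("" off the end).
.left_align_indel <- function(position, allele, kind, base_at) {
  k <- nchar(allele)
  if (k == 0L) return(list(position = position, allele = allele))
  repeat {
    prev <- if (kind == "deletion") position - 1L else position
    if (prev < 1L) break
    prev_base <- base_at(prev)
    last_base <- substr(allele, k, k)
    if (!nzchar(prev_base) || prev_base != last_base) break
    allele <- paste0(prev_base, substr(allele, 1L, k - 1L))
    position <- position - 1L
  }
  list(position = position, allele = allele)
}

# Semi-global alignment of one query against an arbitrary reference string.
# Returns ref-coordinate variants and the covered position set.
.align_query <- function(query, refseq, offset = 0L,
                         match = 1, mismatch = -1,
                         gap_opening = 4, gap_extension = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE,
                                                  type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(refseq),
    type = "global-local",
    substitutionMatrix = mat,
    gapOpening = gap_opening,
    gapExtension = gap_extension
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  start_ref <- Biostrings::start(Biostrings::subject(aln)) + offset
  acgt <- c("A", "C", "G", "T")

  refpos <- start_ref - 1L
  cov <- logical(nchar(refseq) + offset)  # indexed by absolute position
  subs_pos <- integer(); subs_ref <- character(); subs_alt <- character()
  indels <- list()
  i <- 1L; L <- length(p)
  while (i <= L) {
    qc <- p[i]; rc <- s[i]
    if (qc != "-" && rc != "-") {
      refpos <- refpos + 1L
      if (qc %in% acgt) {
        cov[refpos] <- TRUE
        if (qc != rc) {
          subs_pos <- c(subs_pos, refpos)
          subs_ref <- c(subs_ref, rc)
          subs_alt <- c(subs_alt, qc)
        }
      }
      i <- i + 1L
    } else if (rc == "-") {        # insertion in query
      j <- i
      while (j <= L && s[j] == "-") j <- j + 1L
      ins <- paste(p[i:(j - 1L)], collapse = "")
      if (!grepl("[^ACGT]", ins)) {
        indels[[length(indels) + 1L]] <- list(pos = refpos, allele = ins,
                                              kind = "insertion")
      }
      i <- j
    } else {                        # deletion from reference
      j <- i
      while (j <= L && p[j] == "-") j <- j + 1L
      k <- j - i
      del <- paste(s[i:(j - 1L)], collapse = "")
      indels[[length(indels) + 1L]] <- list(pos = refpos + 1L, allele = del,
                                            kind = "deletion")
      cov[(refpos + 1L):(refpos + k)] <- TRUE
      refpos <- refpos + k
      i <- j
    }
  }

  base_at <- function(pos) substr(refseq, pos - offset, pos - offset)
  variants <- variant_table(subs_pos, subs_ref, subs_alt,
                            rep("substitution", length(subs_pos)))
  if (length(indels)) {
    rows <- lapply(indels, function(e) {
      la <- .left_align_indel(e$pos, e$allele, e$kind, base_at)
      if (e$kind == "deletion") {
        data.frame(position = la$position, ref = la$allele, alt = "",
                   kind = "deletion", stringsAsFactors = FALSE)
      } else {
        data.frame(position = la$position, ref = "", alt = la$allele,
                   kind = "insertion", stringsAsFactors = FALSE)
      }
    })
    variants <- rbind(variants, do.call(rbind, rows))
    variants <- variants[order(variants$position), , drop = FALSE]
  }
  list(variants = variants, coverage = which(cov),
       score = Biostrings::score(aln), start = start_ref)
}

#' Anchor a control-region sequence to the reference and call variants
#'
#' Aligns a query sequence semi-globally against the reference (free end
#' gaps on the reference side: the whole query must align within the
#' reference), maps every covered reference position, and reports variants
#' in reference coordinates. Indels are left-aligned. IUPAC ambiguity codes
#' (including `N`) are treated as non-calls: the position is dropped from
#' the coverage set. Positions inside the repeat interval are excluded from
#' both variant output and coverage.
#'
#' @param seq Character scalar (the query DNA sequence, IUPAC alphabet) or a
#'   list with elements `sample_id` and `sequence`.
#' @param ref A [reference_map()].
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring
#'   parameters.
#' @param min_score Minimum alignment score; below it the sequence is
#'   rejected as unalignable. Default: half the query length under the
#'   default unit match score.
#' @param min_overlap Minimum number of covered positions inside the D-loop
#'   interval; below it the call is rejected for insufficient coverage.
#' @param window Optional interval `c(start, end)` restricting the reference
#'   region searched (a speed-up when the query is known to come from the
#'   D-loop); `NULL` searches the whole reference.
#' @return An object of class `dloop_alignment`: list with `sample_id`,
#'   `variants` (a [variant_table()]), `coverage` (sorted integer positions),
#'   and `score`.
#' @export
anchor_align <- function(seq, ref,
                         match = 1, mismatch = -1,
                         gap_opening = 4, gap_extension = 1,
                         min_score = NULL, min_overlap = 50L,
                         window = NULL) {
  stopifnot(inherits(ref, "reference_map"))
  sample_id <- "query"
  if (is.list(seq)) {
    sample_id <- seq$sample_id %||% "query"
    seq <- seq$sequence
  }
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGTRYSWKMBDHVN]", seq)) stop("sequence contains non-IUPAC characters")

  if (is.null(window)) {
    subject <- ref$sequence; offset <- 0L
  } else {
    stopifnot(.is_interval(window))
    window <- as.integer(window)
    subject <- substr(ref$sequence, window[1], window[2])
    offset <- window[1] - 1L
  }
  res <- .align_query(seq, subject, offset = offset, match = match,
                      mismatch = mismatch, gap_opening = gap_opening,
                      gap_extension = gap_extension)
  if (is.null(min_score)) min_score <- 0.5 * match * nchar(seq)
  if (res$score < min_score) stop("unalignable sequence")

  # drop the repeat array from variants and coverage
  if (!is.null(ref$repeat_interval)) {
    rep_pos <- .interval_seq(ref$repeat_interval)
    res$coverage <- setdiff(res$coverage, rep_pos)
    res$variants <- res$variants[!res$variants$position %in% rep_pos, , drop = FALSE]
  }
  dl <- .interval_seq(ref$dloop_interval)
  if (length(intersect(res$coverage, dl)) < min_overlap) {
    stop("insufficient coverage")
  }
  structure(list(sample_id = sample_id, variants = res$variants,
                 coverage = sort(res$coverage), score = res$score),
            class = "dloop_alignment")
}

#' @export
print.dloop_alignment <- function(x, ...) {
  cat("D-loop alignment for sample", x$sample_id, "\n")
  cat("  covered positions:", length(x$coverage),
      sprintf("(np %d-%d)", min(x$coverage), max(x$coverage)), "\n")
  cat("  variants:", nrow(x$variants), "\n")
  if (nrow(x$variants)) print(head(x$variants, 20))
  invisible(x)
}
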