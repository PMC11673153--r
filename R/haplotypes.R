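#' Construct a named mitochondrial haplotype
#'
#' A haplotype is a named set of variants relative to the reference together
#' with a coverage mask: the set of reference positions the haplotype's
#' defining sequences actually cover. Uncovered ("nd") positions are unknown
#' and never contribute to identity comparisons.
#'
#' @param name Haplotype name (e.g. `"Capriola_ASCAL_ITA"`).
#' @param variants A [variant_table()]; all positions must be unique.
#' @param coverage Integer vector of covered reference positions.
#' @param ref Optional [reference_map()]; when supplied, variants are checked
#'   to lie inside the D-loop interval and ref alleles to match the
#'   reference.
#' @return An object of class `mt_haplotype`.
#' @export
mt_haplotype <- function(name, variants, coverage, ref = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (anyDuplicated(variants$position)) {
    stop("no two variants of a haplotype may share a position")
  }
  coverage <- sort(unique(as.integer(coverage)))
  if (!all(variants$position %in% coverage)) {
    stop("every variant position must be covered")
  }
  if (!is.null(ref)) {
    dl <- ref$dloop_interval
    if (any(variants$position < dl[1] | variants$position > dl[2])) {
      stop("variants must fall inside the dloop_interval")
    }
    .validate_variants_against_ref(variants, ref)
  }
  structure(list(name = name, variants = variants, coverage = coverage),
            class = "mt_haplotype")
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat("mtDNA haplotype", x$name, "-", nrow(x$variants), "variants,",
      length(x$coverage), "covered positions\n")
  invisible(x)
}

# state of a haplotype at a position: NA if uncovered, "ref" if covered and
# non-variant, otherwise "<kind>:<alt>"
.hap_state <- function(hap, positions) {
  st <- ifelse(positions %in% hap$coverage, "ref", NA_character_)
  idx <- match(positions, hap$variants$position)
  hit <- !is.na(idx) & !is.na(st)
  st[hit] <- paste0(hap$variants$kind[idx[hit]], ":", hap$variants$alt[idx[hit]])
  st
}

.variant_keys <- function(variants) {
  paste(variants$position, variants$kind, variants$alt, sep = "|")
}

#' Call a sample against a haplotype catalogue
#'
#' A sample matches a catalogued haplotype iff, over the intersection of
#' their coverages, the two variant sets are identical. Coverage gaps never
#' create new haplotypes: a gapped sample consistent with exactly one
#' catalogued haplotype is merged into it. If the gaps leave several
#' catalogued haplotypes indistinguishable, the ambiguity set is returned.
#' A sample matching no catalogued haplotype mints a new name using the
#' configured prefix/suffix convention.
#'
#' @param variants A [variant_table()] for the sample.
#' @param coverage Integer vector of covered positions.
#' @param catalogue Named list of [mt_haplotype()] objects (may be empty).
#' @param suffix,new_prefix Naming convention for newly minted haplotypes:
#'   `"<prefix><nn>_<suffix>"`.
#' @return A list with `status` (`"known"`, `"ambiguous"`, or `"new"`),
#'   `names` (matched name(s) or the minted name), and for new haplotypes
#'   `haplotype`, the minted [mt_haplotype()].
#' @export
call_haplotype <- function(variants, coverage, catalogue,
                           suffix = "ASCAL_ITA", new_prefix = "HT") {
  coverage <- sort(unique(as.integer(coverage)))
  if (length(catalogue)) {
    informative <- FALSE
    matches <- character()
    for (hap in catalogue) {
      common <- intersect(coverage, hap$coverage)
      if (!length(common)) next
      informative <- TRUE
      sv <- variants[variants$position %in% common, , drop = FALSE]
      hv <- hap$variants[hap$variants$position %in% common, , drop = FALSE]
      if (setequal(.variant_keys(sv), .variant_keys(hv))) {
        matches <- c(matches, hap$name)
      }
    }
    if (!informative) stop("uninformative sample")
    if (length(matches) == 1L) return(list(status = "known", names = matches))
    if (length(matches) > 1L) return(list(status = "ambiguous", names = matches))
  }
  name <- sprintf("%s%02d_%s", new_prefix, length(catalogue) + 1L, suffix)
  list(status = "new", names = name,
       haplotype = mt_haplotype(name, variants, coverage))
}

#' Cluster many aligned samples into haplotypes
#'
#' Processes samples in order, calling each against the (growing) catalogue
#' with [call_haplotype()]. Ambiguous samples are reported but do not grow
#' the catalogue.
#'
#' @param alignments List of `dloop_alignment` objects (or lists with
#'   `sample_id`, `variants`, `coverage`).
#' @param catalogue Starting catalogue (named list of [mt_haplotype()]);
#'   empty by default so haplotypes are discovered de novo.
#' @inheritParams call_haplotype
#' @return List with `calls` (data.frame: `sample_id`, `haplotype`,
#'   `status`; ambiguous calls collapse the candidate set with `|`) and the
#'   final `catalogue`.
#' @export
cluster_haplotypes <- function(alignments, catalogue = list(),
                               suffix = "ASCAL_ITA", new_prefix = "HT") {
  ids <- character(); haps <- character(); status <- character()
  for (a in alignments) {
    res <- call_haplotype(a$variants, a$coverage, catalogue,
                          suffix = suffix, new_prefix = new_prefix)
    if (res$status == "new") {
      catalogue[[res$names]] <- res$haplotype
    }
    ids <- c(ids, a$sample_id %||% "sample")
    haps <- c(haps, paste(res$names, collapse = "|"))
    status <- c(status, res$status)
  }
  list(calls = data.frame(sample_id = ids, haplotype = haps, status = status,
                          stringsAsFactors = FALSE),
       catalogue = catalogue)
}

.resolve_region <- function(region, ref) {
  if (is.character(region)) {
    region <- match.arg(region, c("dloop", "up", "down"))
    return(switch(region, dloop = ref$dloop_interval,
                  up = ref$up_interval, down = ref$down_interval))
  }
  stopifnot(.is_interval(region))
  region <- as.integer(region)
  if (region[1] < ref$dloop_interval[1] || region[2] > ref$dloop_interval[2]) {
    stop("bad region")
  }
  region
}

#' Count polymorphic sites among haplotypes
#'
#' In `among` mode a position counts iff at least two distinct states are
#' observed among the haplotypes covering it (positions covered by fewer
#' than two haplotypes are skipped). In `reference` mode a position counts
#' iff any covering haplotype differs from the reference.
#'
#' @param haps List of [mt_haplotype()] (at least two).
#' @param ref A [reference_map()].
#' @param region `"dloop"`, `"up"`, `"down"`, or an interval inside the
#'   D-loop.
#' @param mode `"among"` (default) or `"reference"`.
#' @return Integer count of polymorphic sites.
#' @export
count_polymorphic_sites <- function(haps, ref, region = "dloop",
                                    mode = c("among", "reference")) {
  mode <- match.arg(mode)
  stopifnot(length(haps) >= 2L)
  iv <- .resolve_region(region, ref)
  pos <- sort(unique(unlist(lapply(haps, function(h) h$variants$position))))
  pos <- pos[pos >= iv[1] & pos <= iv[2]]
  if (!length(pos)) return(0L)
  states <- vapply(haps, .hap_state, character(length(pos)), positions = pos)
  if (length(pos) == 1L) states <- matrix(states, nrow = 1L)
  count <- 0L
  for (i in seq_along(pos)) {
    st <- states[i, ]
    st <- st[!is.na(st)]
    if (mode == "among") {
      if (length(st) >= 2L && length(unique(st)) >= 2L) count <- count + 1L
    } else {
      if (any(st != "ref")) count <- count + 1L
    }
  }
  count
}

#' Define a haplogroup diagnostic rule
#'
#' @param haplogroup Haplogroup letter (e.g. `"G"`).
#' @param motif A [variant_table()] of diagnostic variants; all must be
#'   present (and covered) for the rule to match.
#' @param priority Unique integer; lower values are tried first.
#' @return An object of class `haplogroup_rule`.
#' @export
haplogroup_rule <- function(haplogroup, motif, priority) {
  stopifnot(is.character(haplogroup), length(haplogroup) == 1L)
  if (!nrow(motif)) stop("diagnostic motifs must be non-empty")
  structure(list(haplogroup = haplogroup, motif = motif,
                 priority = as.integer(priority)),
            class = "haplogroup_rule")
}

#' Assign a haplotype to a haplogroup
#'
#' The highest-priority rule whose full diagnostic motif is contained in
#' (and covered by) the haplotype wins. A motif position outside the
#' haplotype's coverage makes that rule a non-match and is flagged in the
#' output. No matching rule yields `"unclassified"`.
#'
#' @param hap A [mt_haplotype()].
#' @param rules List of [haplogroup_rule()] with unique priorities.
#' @return List with `haplogroup` (letter or `"unclassified"`) and
#'   `uncovered_rules` (haplogroups whose motif hit an uncovered position).
#' @export
assign_haplogroup <- function(hap, rules) {
  prios <- vapply(rules, function(r) r$priority, integer(1))
  if (anyDuplicated(prios)) stop("rule priorities must be unique")
  rules <- rules[order(prios)]
  uncovered <- character()
  hap_keys <- .variant_keys(hap$variants)
  for (r in rules) {
    if (!all(r$motif$position %in% hap$coverage)) {
      uncovered <- c(uncovered, r$haplogroup)
      next
    }
    if (all(.variant_keys(r$motif) %in% hap_keys)) {
      return(list(haplogroup = r$haplogroup, uncovered_rules = uncovered))
    }
  }
  list(haplogroup = "unclassified", uncovered_rules = uncovered)
}

#' Pairwise difference matrix among haplotypes
#'
#' The distance between two haplotypes is the number of positions, covered
#' in both, at which their states differ. It replaces tree/network building
#' as the package's summary of between-haplotype divergence.
#'
#' @param haps List of at least two [mt_haplotype()].
#' @return A symmetric integer matrix with zero diagonal, dimnames taken
#'   from haplotype names.
#' @export
pairwise_differences <- function(haps) {
  stopifnot(length(haps) >= 2L)
  n <- length(haps)
  nm <- vapply(haps, function(h) h$name, character(1))
  d <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- intersect(haps[[i]]$coverage, haps[[j]]$coverage)
      pos <- sort(unique(c(haps[[i]]$variants$position,
                           haps[[j]]$variants$position)))
      pos <- pos[pos %in% common]
      if (length(pos)) {
        si <- .hap_state(haps[[i]], pos)
        sj <- .hap_state(haps[[j]], pos)
        d[i, j] <- d[j, i] <- sum(si != sj)
      }
    }
  }
  d
}
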