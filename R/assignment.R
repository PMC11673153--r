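#' Build the family-by-haplotype contingency table
#'
#' Counts mares by (pedigree family, observed haplotype). The result is a
#' non-negative integer matrix (families in rows, haplotypes in columns)
#' with class `contingency_table`; the input order of rows does not matter.
#'
#' @param mares Data frame with columns `sample_id`, `family`, `haplotype`.
#' @param families,haplotypes Optional character vectors fixing the row and
#'   column order (and carrying families/haplotypes with zero counts, which
#'   are never dropped silently). Defaults to sorted unique labels.
#' @return An integer matrix of class `contingency_table`.
#' @export
build_contingency <- function(mares, families = NULL, haplotypes = NULL) {
  if (is.null(mares) || nrow(mares) == 0L) stop("no data")
  stopifnot(all(c("sample_id", "family", "haplotype") %in% names(mares)))
  if (any(!nzchar(mares$family)) || any(!nzchar(mares$haplotype)) ||
      anyNA(mares$family) || anyNA(mares$haplotype)) {
    stop("every mare needs family and haplotype labels")
  }
  families <- families %||% sort(unique(mares$family))
  haplotypes <- haplotypes %||% sort(unique(mares$haplotype))
  if (!all(mares$family %in% families)) stop("mare family outside supplied families")
  if (!all(mares$haplotype %in% haplotypes)) stop("mare haplotype outside supplied haplotypes")
  m <- table(factor(mares$family, levels = families),
             factor(mares$haplotype, levels = haplotypes))
  m <- matrix(as.integer(m), nrow = length(families),
              dimnames = list(family = families, haplotype = haplotypes))
  class(m) <- c("contingency_table", class(m))
  m
}

#' @export
print.contingency_table <- function(x, ...) {
  y <- unclass(x)
  y <- rbind(y, `N females` = colSums(y))
  y <- cbind(y, Total = rowSums(y))
  print(y)
  invisible(x)
}

.support <- function(tab, h, taken, soft_taken) {
  fams <- rownames(tab)[tab[, h] > 0L]
  fams <- setdiff(fams, taken)
  hard <- setdiff(fams, soft_taken)
  if (length(hard)) hard else fams
}

#' Iterative haplotype-to-family assignment
#'
#' Implements the empirical stepwise procedure used to associate each
#' detected haplotype uniquely with a pedigree maternal family. A
#' haplotype's *support* is the set of families in which it was observed
#' that are not yet claimed by another haplotype. The procedure iterates:
#'
#' * Rule A (uniqueness / exclusion): any haplotype whose support is a
#'   singleton is assigned to that family; repeated to a fixed point. The
#'   rule is recorded as `unique-support` when the haplotype was only ever
#'   observed in that family, `exclusion` when competitors' assignments
#'   shrank the support to one.
#' * Rule B (majority): open haplotypes are ranked by largest support count,
#'   then largest margin over the second-best family, then haplotype name;
#'   the first with a unique most-frequent family is assigned to it.
#' * Rule tie: when no open haplotype has a unique most-frequent family,
#'   the top-ranked one is assigned its tied family set jointly; tied
#'   families are withheld from other supports only when the other
#'   haplotype retains an alternative.
#'
#' The procedure terminates when all haplotypes are resolved or no rule
#' applies. It is deterministic and invariant to row/column permutations of
#' the table.
#'
#' @param table A [build_contingency()] matrix.
#' @return An object of class `family_assignment`: list with `map` (named
#'   list haplotype -> family set), `steps` (data.frame of haplotype,
#'   families, rule, step), `families_without_haplotype`, and `unassigned`.
#' @export
assign_families <- function(table) {
  stopifnot(inherits(table, "contingency_table") || is.matrix(table))
  tab <- unclass(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("no data")
  open <- sort(colnames(tab)[colSums(tab) > 0L])
  original_support <- lapply(setNames(open, open),
                             function(h) rownames(tab)[tab[, h] > 0L])
  assigned <- list(); rules <- character(); steps <- integer()
  taken <- character()       # families fixed by singleton assignments
  soft_taken <- character()  # families held by a tie assignment
  step <- 0L

  repeat {
    # Rule A to a fixed point
    repeat {
      changed <- FALSE
      for (h in open) {
        sup <- .support(tab, h, taken, soft_taken)
        if (length(sup) == 1L) {
          step <- step + 1L
          rule <- if (length(original_support[[h]]) == 1L) "unique-support" else "exclusion"
          assigned[[h]] <- sort(sup); rules[h] <- rule; steps[h] <- step
          taken <- c(taken, sup)
          open <- setdiff(open, h)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!length(open)) break

    # Rule B: rank open haplotypes
    cand <- lapply(setNames(open, open), function(h) {
      sup <- .support(tab, h, taken, soft_taken)
      if (!length(sup)) return(NULL)
      cnt <- tab[sup, h]
      names(cnt) <- sup
      cnt <- sort(cnt, decreasing = TRUE)
      margin <- if (length(cnt) > 1L) cnt[1] - cnt[2] else cnt[1]
      list(h = h, counts = cnt, max = cnt[1], margin = margin,
           argmax = names(cnt)[cnt == cnt[1]])
    })
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) {
      # open haplotypes with empty support are unassignable
      break
    }
    ord <- order(-vapply(cand, `[[`, numeric(1), "max"),
                 -vapply(cand, `[[`, numeric(1), "margin"),
                 vapply(cand, `[[`, character(1), "h"))
    cand <- cand[ord]
    uniq <- Filter(function(c) length(c$argmax) == 1L, cand)
    if (length(uniq)) {
      c1 <- uniq[[1]]
      step <- step + 1L
      assigned[[c1$h]] <- c1$argmax; rules[c1$h] <- "majority"; steps[c1$h] <- step
      taken <- c(taken, c1$argmax)
      open <- setdiff(open, c1$h)
    } else {
      c1 <- cand[[1]]
      step <- step + 1L
      assigned[[c1$h]] <- sort(c1$argmax); rules[c1$h] <- "tie"; steps[c1$h] <- step
      soft_taken <- c(soft_taken, c1$argmax)
      open <- setdiff(open, c1$h)
    }
  }

  unassigned <- open
  covered <- unlist(assigned, use.names = FALSE)
  fams_nonzero <- rownames(tab)[rowSums(tab) > 0L]
  without <- setdiff(fams_nonzero, covered)
  hs <- sort(names(assigned))
  steps_df <- data.frame(
    haplotype = hs,
    families = vapply(hs, function(h) paste(assigned[[h]], collapse = "|"), character(1)),
    rule = rules[hs],
    step = steps[hs],
    stringsAsFactors = FALSE, row.names = NULL
  )
  steps_df <- steps_df[order(steps_df$step), , drop = FALSE]
  structure(list(map = assigned, steps = steps_df,
                 families_without_haplotype = without,
                 unassigned = unassigned, table = tab),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("Haplotype-to-family assignment (", nrow(x$steps), " haplotypes)\n", sep = "")
  print(x$steps, row.names = FALSE)
  if (length(x$families_without_haplotype)) {
    cat("families without haplotype:",
        paste(x$families_without_haplotype, collapse = ", "), "\n")
  }
  if (length(x$unassigned)) {
    cat("unassignable haplotypes:", paste(x$unassigned, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.family_assignment <- function(object, ...) {
  tab <- object$table
  retained <- sum(vapply(names(object$map), function(h) {
    sum(tab[object$map[[h]], h])
  }, numeric(1)))
  out <- list(n_haplotypes = length(object$map),
              retained_mares = as.integer(retained),
              total_mares = as.integer(sum(tab)),
              rules = table(object$steps$rule))
  class(out) <- "summary.family_assignment"
  out
}

#' @export
print.summary.family_assignment <- function(x, ...) {
  cat("haplotypes assigned:", x$n_haplotypes, "\n")
  cat("mares matching their family's haplotype:", x$retained_mares,
      "of", x$total_mares, "\n")
  print(x$rules)
  invisible(x)
}

#' Exhaustive matching oracle for the assignment problem
#'
#' Independent check of the stepwise procedure: enumerates every feasible
#' family-to-haplotype matching and maximizes the number of mares whose
#' observed haplotype is the one matched to their family. Feasibility:
#' every family with mares is matched to a haplotype observed in it; every
#' haplotype with mares receives at least one family; a haplotype may cover
#' several families only when each of those families carries no alternative
#' haplotype.
#'
#' @param table A [build_contingency()] matrix (at most ~12x12; the search
#'   is exact enumeration).
#' @param max_combinations Guard on the enumeration size.
#' @return List with `retained` (the optimum), `map` (named list haplotype
#'   -> family set achieving it), and `uncoverable` (families with mares
#'   but no haplotype).
#' @export
matching_oracle <- function(table, max_combinations = 5e6) {
  tab <- unclass(table)
  fams <- rownames(tab)[rowSums(tab) > 0L]
  haps <- colnames(tab)[colSums(tab) > 0L]
  cand <- lapply(setNames(fams, fams), function(f) haps[tab[f, ] > 0L])
  uncoverable <- fams[vapply(cand, length, integer(1)) == 0L]
  fams <- setdiff(fams, uncoverable)
  sizes <- vapply(cand[fams], length, integer(1))
  if (prod(sizes) > max_combinations) stop("table too large for exact enumeration")
  single <- fams[sizes == 1L]  # families with no alternative haplotype

  best <- -1L; best_map <- NULL
  choice <- integer(length(fams))
  recurse <- function(i, score) {
    if (i > length(fams)) {
      # validity: every haplotype covered; multi-family haplotypes only
      # bundle no-alternative families
      sel <- vapply(seq_along(fams), function(k) cand[[fams[k]]][choice[k]], character(1))
      if (!all(haps %in% sel)) return(invisible(NULL))
      by_h <- split(fams, sel)
      for (h in names(by_h)) {
        fs <- by_h[[h]]
        if (length(fs) > 1L && !all(fs %in% single)) return(invisible(NULL))
      }
      if (score > best) {
        best <<- score
        best_map <<- by_h
      }
      return(invisible(NULL))
    }
    f <- fams[i]
    for (k in seq_along(cand[[f]])) {
      choice[i] <<- k
      recurse(i + 1L, score + tab[f, cand[[f]][k]])
    }
  }
  if (length(fams)) recurse(1L, 0L)
  if (is.null(best_map)) {
    return(list(retained = NA_integer_, map = NULL, uncoverable = uncoverable))
  }
  list(retained = as.integer(best), map = best_map[sort(names(best_map))],
       uncoverable = uncoverable)
}

#' Retention report: which mares match their family's assigned haplotype
#'
#' A mare is retained iff her observed haplotype's assigned family set
#' contains her pedigree family; otherwise she is culled. Mares whose
#' haplotype is absent from the assignment map are counted separately as
#' unassessable.
#'
#' @param mares Data frame with `sample_id`, `family`, `haplotype`.
#' @param assignment A [assign_families()] result (or a named list
#'   haplotype -> family set).
#' @return An object of class `retention_report`: list with `per_mare`
#'   (data.frame adding `status`), and counts `retained`, `culled`,
#'   `unassessable`.
#' @export
retention <- function(mares, assignment) {
  map <- if (inherits(assignment, "family_assignment")) assignment$map else assignment
  status <- vapply(seq_len(nrow(mares)), function(i) {
    h <- mares$haplotype[i]
    if (!h %in% names(map)) return("unassessable")
    if (mares$family[i] %in% map[[h]]) "retained" else "culled"
  }, character(1))
  per <- cbind(mares, status = status, stringsAsFactors = FALSE)
  structure(list(per_mare = per,
                 retained = sum(status == "retained"),
                 culled = sum(status == "culled"),
                 unassessable = sum(status == "unassessable")),
            class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat("Retention:", x$retained, "retained,", x$culled, "culled")
  if (x$unassessable) cat(",", x$unassessable, "unassessable")
  cat(" (of", nrow(x$per_mare), "mares)\n")
  invisible(x)
}

#' Haplotype counts and percentage frequencies
#'
#' Percentages are 100 x column total / grand total, rounded
#' half-to-even to one decimal.
#'
#' @param table A [build_contingency()] matrix.
#' @return Data frame with `haplotype`, `count`, `percent`.
#' @export
haplotype_frequencies <- function(table) {
  tab <- unclass(table)
  counts <- colSums(tab)
  data.frame(haplotype = colnames(tab),
             count = as.integer(counts),
             percent = .pct1(100 * counts / sum(counts)),
             stringsAsFactors = FALSE, row.names = NULL)
}
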