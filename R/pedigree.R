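#' Validate raw pedigree records
#'
#' Checks a pedigree table for structural defects: duplicate ids, dangling
#' parent ids, sex conflicts (an id used both as sire and dam, or a sire
#' recorded as female), impossible birth-year ordering, and cycles
#' (an individual being its own ancestor). Founders are individuals with
#' both parents unknown.
#'
#' @param records Data frame with columns `id`, `sire`, `dam`, and
#'   optionally `sex` (`"M"`/`"F"`), `birth_year`, `family`. Empty strings
#'   or `NA` mean unknown.
#' @return List with `ok` (logical), `errors` (character vector), and, when
#'   valid, `pedigree` (the [pedigree()] object).
#' @export
validate_pedigree <- function(records) {
  errors <- character()
  req <- c("id", "sire", "dam")
  if (!all(req %in% names(records))) {
    return(list(ok = FALSE, errors = "records need columns id, sire, dam"))
  }
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- NA_character_
    x
  }
  id <- norm(records$id); sire <- norm(records$sire); dam <- norm(records$dam)
  if (anyNA(id)) errors <- c(errors, "missing individual ids")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) errors <- c(errors, paste("duplicate ids:", paste(dup, collapse = ", ")))
  dangling <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(dangling)) {
    errors <- c(errors, paste("dangling parent ids:", paste(dangling, collapse = ", ")))
  }
  sex <- if ("sex" %in% names(records)) norm(records$sex) else rep(NA_character_, length(id))
  both <- intersect(sire[!is.na(sire)], dam[!is.na(dam)])
  if (length(both)) {
    errors <- c(errors, paste("ids used both as sire and dam:", paste(both, collapse = ", ")))
  }
  sx <- setNames(sex, id)
  bad_sire <- unique(sire[!is.na(sire)][sx[sire[!is.na(sire)]] %in% "F"])
  bad_dam <- unique(dam[!is.na(dam)][sx[dam[!is.na(dam)]] %in% "M"])
  if (length(bad_sire)) errors <- c(errors, paste("female recorded as sire:", paste(bad_sire, collapse = ", ")))
  if (length(bad_dam)) errors <- c(errors, paste("male recorded as dam:", paste(bad_dam, collapse = ", ")))
  if ("birth_year" %in% names(records)) {
    by <- setNames(suppressWarnings(as.numeric(records$birth_year)), id)
    for (p in c("sire", "dam")) {
      pp <- get(p)
      known <- !is.na(pp) & !is.na(by[id]) & !is.na(by[pp]) & pp %in% id
      viol <- id[known][by[pp[known]] >= by[id[known]]]
      if (length(viol)) {
        errors <- c(errors, paste0(p, " born after (or with) offspring: ",
                                   paste(viol, collapse = ", ")))
      }
    }
  }
  if (length(errors)) return(list(ok = FALSE, errors = errors))

  # cycle detection via Kahn's algorithm
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), NA_integer_, idx[sire])
  di <- ifelse(is.na(dam), NA_integer_, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order_out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (c in children[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order_out) < n) {
    cyc <- id[setdiff(seq_len(n), order_out)]
    return(list(ok = FALSE,
                errors = paste("pedigree cycle involving:", paste(cyc, collapse = ", "))))
  }
  ped <- structure(
    list(id = id, sire = si, dam = di, sex = sex,
         birth_year = if ("birth_year" %in% names(records))
           suppressWarnings(as.numeric(records$birth_year)) else rep(NA_real_, n),
         family = if ("family" %in% names(records)) norm(records$family)
           else rep(NA_character_, n),
         order = order_out,
         children = children),
    class = "pedigree")
  list(ok = TRUE, errors = character(), pedigree = ped)
}

#' Construct a validated pedigree
#'
#' @inheritParams validate_pedigree
#' @return An object of class `pedigree`. Errors (including cycles) abort
#'   with the full error list.
#' @export
pedigree <- function(records) {
  v <- validate_pedigree(records)
  if (!v$ok) stop(paste(v$errors, collapse = "\n"))
  v$pedigree
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", length(x$id), "individuals;",
      length(founders(x)), "founders;",
      "completeness", sprintf("%.1f%%", 100 * completeness(x)), "\n")
  invisible(x)
}

#' Founders of a pedigree
#'
#' @param ped A [pedigree()].
#' @return Character ids of individuals with both parents unknown.
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$sire) & is.na(ped$dam)]
}

#' Reference population
#'
#' The individuals the diversity statistics describe. The default is the
#' individuals with no recorded progeny (the usual "living animals with no
#' progeny" convention for an active studbook); it can be overridden with
#' an explicit id list.
#'
#' @param ped A [pedigree()].
#' @param ids Optional character ids overriding the default.
#' @return Character vector of reference ids.
#' @export
reference_population <- function(ped, ids = NULL) {
  if (!is.null(ids)) {
    if (!all(ids %in% ped$id)) stop("reference ids absent from pedigree")
    return(ids)
  }
  has_child <- vapply(ped$children, length, integer(1)) > 0L
  ped$id[!has_child]
}

#' Pedigree completeness
#'
#' Fraction of recorded individuals with both parents known.
#'
#' @param ped A [pedigree()].
#' @return A fraction in `[0, 1]`.
#' @export
completeness <- function(ped) {
  mean(!is.na(ped$sire) & !is.na(ped$dam))
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient of every individual as half the
#' additive relationship between its parents, by the recursive tabular
#' kinship method. An unknown parent contributes no identity by descent.
#'
#' @param ped A [pedigree()].
#' @param reference Optional id vector; the returned `average` is taken
#'   over it (default: [reference_population()]).
#' @return List with `F` (named per-individual coefficients) and `average`.
#' @export
inbreeding <- function(ped, reference = NULL) {
  n <- length(ped$id)
  if (n > 6000L) stop("pedigree too large for the dense kinship table; subset first")
  ord <- ped$order
  K <- matrix(0, n, n)
  for (i in ord) {
    s <- ped$sire[i]; d <- ped$dam[i]
    ks <- if (!is.na(s)) K[s, ] else numeric(n)
    kd <- if (!is.na(d)) K[d, ] else numeric(n)
    row <- 0.5 * (ks + kd)
    fij <- if (!is.na(s) && !is.na(d)) K[s, d] else 0
    K[i, ] <- row
    K[, i] <- row
    K[i, i] <- 0.5 * (1 + fij)
  }
  Fv <- setNames(2 * diag(K) - 1, ped$id)
  refids <- reference %||% reference_population(ped)
  list(F = Fv, average = mean(Fv[refids]))
}

# Origins = real founders plus one phantom per unknown parent side of a
# non-founder; returns, for each individual, its expected genome proportion
# from each origin. Rows: individuals (pedigree order); cols: origins.
.origin_contributions <- function(ped) {
  n <- length(ped$id)
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  origins <- ped$id[is_founder]
  phantoms <- character()
  for (i in seq_len(n)) {
    if (is_founder[i]) next
    if (is.na(ped$sire[i])) phantoms <- c(phantoms, paste0(ped$id[i], "/S"))
    if (is.na(ped$dam[i])) phantoms <- c(phantoms, paste0(ped$id[i], "/D"))
  }
  origins <- c(origins, phantoms)
  m <- length(origins)
  oidx <- setNames(seq_len(m), origins)
  C <- matrix(0, n, m, dimnames = list(ped$id, origins))
  for (i in ped$order) {
    if (is_founder[i]) {
      C[i, oidx[ped$id[i]]] <- 1
      next
    }
    s <- ped$sire[i]; d <- ped$dam[i]
    row <- numeric(m)
    row <- row + if (!is.na(s)) 0.5 * C[s, ] else {
      tmp <- numeric(m); tmp[oidx[paste0(ped$id[i], "/S")]] <- 0.5; tmp
    }
    row <- row + if (!is.na(d)) 0.5 * C[d, ] else {
      tmp <- numeric(m); tmp[oidx[paste0(ped$id[i], "/D")]] <- 0.5; tmp
    }
    C[i, ] <- row
  }
  C
}

#' Founder contributions and equivalent founders
#'
#' For each founder (with one phantom founder per unknown parent side of a
#' non-founder, so contributions always sum to one), computes the expected
#' genome proportion `q_k` contributed to the reference population, and the
#' equivalent number of founders `f_e = 1 / sum(q_k^2)`.
#'
#' @param ped A [pedigree()].
#' @param reference Optional id vector (default [reference_population()]).
#' @return List with `q` (named vector over founders and phantoms, summing
#'   to 1), `f_e`, and `n_founders` (real founders only).
#' @export
founder_contributions <- function(ped, reference = NULL) {
  refids <- reference %||% reference_population(ped)
  if (!length(refids)) stop("empty reference population")
  C <- .origin_contributions(ped)
  q <- colMeans(C[refids, , drop = FALSE])
  list(q = q, f_e = 1 / sum(q^2), n_founders = length(founders(ped)))
}

#' Effective number of ancestors
#'
#' Iterative marginal-contribution analysis of pedigree bottlenecks. At
#' each round the candidate ancestor with the largest marginal contribution
#' is selected; a candidate's marginal contribution is the expected fraction
#' of the reference gene pool that originates in it and did not pass through
#' (and was not already present in) a previously selected ancestor. The
#' effective number of ancestors is `f_a = 1 / sum(p_j^2)` over the selected
#' marginal contributions.
#'
#' Candidates are the strict ancestors of the reference population.
#' Selection stops when the residual unexplained fraction, or the largest
#' remaining marginal contribution, falls below `eps`.
#'
#' @param ped A [pedigree()].
#' @param reference Optional id vector (default [reference_population()]).
#' @param eps Stopping threshold on the residual contribution.
#' @param max_rounds Safety bound on the number of selections.
#' @return List with `p` (named marginal contributions, selection order),
#'   `f_a`, `n_ancestors` (number selected), and `explained = sum(p)`.
#' @export
effective_ancestors <- function(ped, reference = NULL, eps = 1e-6,
                                max_rounds = 10000L) {
  refids <- reference %||% reference_population(ped)
  if (!length(refids)) stop("empty reference population")
  n <- length(ped$id)
  ref_ind <- ped$id %in% refids
  N <- sum(ref_ind)
  rev_ord <- rev(ped$order)

  # upward pass: u[i] = P(a random reference gene descends from i without
  # passing through a blocked individual strictly below i)
  upward <- function(blocked) {
    u <- numeric(n)
    for (i in rev_ord) {
      val <- if (ref_ind[i]) 1 / N else 0
      for (c in ped$children[[i]]) {
        if (!blocked[c]) val <- val + 0.5 * u[c]
      }
      u[i] <- val
    }
    u
  }
  # downward pass: g[i] = P(a gene of i originates from or through a
  # blocked individual)
  downward <- function(blocked) {
    g <- numeric(n)
    for (i in ped$order) {
      if (blocked[i]) { g[i] <- 1; next }
      s <- ped$sire[i]; d <- ped$dam[i]
      g[i] <- 0.5 * (if (!is.na(s)) g[s] else 0) +
              0.5 * (if (!is.na(d)) g[d] else 0)
    }
    g
  }

  blocked <- rep(FALSE, n)
  u0 <- upward(blocked)
  self_term <- ifelse(ref_ind, 1 / N, 0)
  candidate <- (u0 - self_term) > 1e-15   # strict ancestors of the reference

  p <- numeric(0)
  for (round in seq_len(max_rounds)) {
    if (sum(p) >= 1 - eps) break
    u <- upward(blocked)
    g <- downward(blocked)
    marg <- u * (1 - g)
    marg[!candidate | blocked] <- -Inf
    best <- which.max(marg)
    if (!is.finite(marg[best]) || marg[best] < eps) break
    p <- c(p, setNames(marg[best], ped$id[best]))
    blocked[best] <- TRUE
  }
  if (!length(p)) stop("no ancestors found for the reference population")
  list(p = p, f_a = 1 / sum(p^2), n_ancestors = length(p), explained = sum(p))
}

#' Total ascendants of the reference population
#'
#' @param ped A [pedigree()].
#' @param reference Optional id vector.
#' @return Integer count of strict ancestors of the reference population.
#' @export
total_ascendants <- function(ped, reference = NULL) {
  refids <- reference %||% reference_population(ped)
  n <- length(ped$id)
  anc <- rep(FALSE, n)
  stack <- match(refids, ped$id)
  seen_parent_of <- function(i) c(ped$sire[i], ped$dam[i])
  while (length(stack)) {
    i <- stack[[1L]]; stack <- stack[-1L]
    for (p in seen_parent_of(i)) {
      if (!is.na(p) && !anc[p]) {
        anc[p] <- TRUE
        stack <- c(stack, p)
      }
    }
  }
  sum(anc)
}

#' Founder genome equivalents by gene dropping
#'
#' Monte-Carlo gene dropping: every founder (and phantom parent) carries
#' two uniquely labelled alleles which are transmitted Mendelian-randomly
#' down the pedigree. Per replicate, allele frequencies `p_a` are computed
#' over the reference population's gene pool and the founder genome
#' equivalent is `N_g = 1 / (2 * mean(sum(p_a^2)))` over replicates. The
#' Monte-Carlo standard error of `N_g` is reported (delta method on the
#' replicate mean of `sum(p_a^2)`).
#'
#' @param ped A [pedigree()].
#' @param reference Optional id vector (default [reference_population()]).
#' @param replicates Number of gene-dropping replicates (>= 1).
#' @param seed Mandatory integer seed; results are bit-for-bit reproducible
#'   for a given seed and replicate count.
#' @return List with `N_g`, `se`, `mean_sq` (mean of `sum(p_a^2)`), and
#'   `replicates`.
#' @export
founder_genomes <- function(ped, reference = NULL, replicates = 10000L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(replicates >= 1L)
  refids <- reference %||% reference_population(ped)
  if (!length(refids)) stop("empty reference population")
  n <- length(ped$id)
  R <- as.integer(replicates)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  A1 <- matrix(0L, n, R)
  A2 <- matrix(0L, n, R)
  next_allele <- 0L
  new_pair <- function() {
    next_allele <<- next_allele + 2L
    c(next_allele - 1L, next_allele)
  }
  for (i in ped$order) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) {
      pr <- new_pair()
      pick <- runif(R) < 0.5
      A1[i, ] <- ifelse(pick, pr[1], pr[2])
    } else {
      pick <- runif(R) < 0.5
      A1[i, ] <- ifelse(pick, A1[s, ], A2[s, ])
    }
    if (is.na(d)) {
      pr <- new_pair()
      pick <- runif(R) < 0.5
      A2[i, ] <- ifelse(pick, pr[1], pr[2])
    } else {
      pick <- runif(R) < 0.5
      A2[i, ] <- ifelse(pick, A1[d, ], A2[d, ])
    }
  }
  ridx <- match(refids, ped$id)
  G <- rbind(A1[ridx, , drop = FALSE], A2[ridx, , drop = FALSE])
  ngenes <- nrow(G)
  ssq <- numeric(R)
  for (r in seq_len(R)) {
    tab <- tabulate(G[, r], nbins = next_allele)
    ssq[r] <- sum((tab / ngenes)^2)
  }
  m <- mean(ssq)
  se_m <- if (R > 1L) sd(ssq) / sqrt(R) else NA_real_
  list(N_g = 1 / (2 * m), se = se_m / (2 * m^2), mean_sq = m, replicates = R)
}

#' Expected mtDNA haplotype from strict matriline descent
#'
#' Propagates haplotypes strictly through dam links: every individual is
#' expected to carry the haplotype of its matriline founder. Individuals
#' whose dam line is interrupted by an unknown dam before reaching a
#' pedigree founder are `"untraceable"`; matrilines ending in a founder
#' absent from the map are `"unmapped matriline"`.
#'
#' @param ped A [pedigree()].
#' @param founder_map Named character vector: matriline founder id ->
#'   haplotype name.
#' @return Named character vector of expected haplotypes per individual.
#' @export
matriline_expected_haplotype <- function(ped, founder_map) {
  n <- length(ped$id)
  out <- rep(NA_character_, n)
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  for (i in ped$order) {
    d <- ped$dam[i]
    if (is.na(d)) {
      idl <- ped$id[i]
      out[i] <- if (idl %in% names(founder_map)) {
        founder_map[[idl]]
      } else if (is_founder[i]) {
        "unmapped matriline"
      } else {
        "untraceable"
      }
    } else {
      out[i] <- out[d]
    }
  }
  setNames(out, ped$id)
}

#' Probability-of-gene-origin summary of a pedigree
#'
#' One-stop computation of the diversity statistics of a closed studbook:
#' founder and ascendant counts, equivalent founders `f_e`, effective
#' ancestors `f_a`, founder genome equivalents `N_g` (gene dropping, with
#' Monte-Carlo standard error), the bottleneck ratio `f_e/f_a`, the drift
#' ratio `N_g/f_e`, average inbreeding over the reference population, and
#' pedigree completeness.
#'
#' @param ped A [pedigree()].
#' @param reference Optional id vector (default [reference_population()]).
#' @param replicates Gene-dropping replicates.
#' @param seed Mandatory seed for gene dropping.
#' @param eps Stopping threshold for the ancestor analysis.
#' @return An object of class `gene_origin`.
#' @export
gene_origin <- function(ped, reference = NULL, replicates = 10000L, seed,
                        eps = 1e-6) {
  refids <- reference %||% reference_population(ped)
  fc <- founder_contributions(ped, refids)
  ea <- effective_ancestors(ped, refids, eps = eps)
  ng <- founder_genomes(ped, refids, replicates = replicates, seed = seed)
  inb <- inbreeding(ped, refids)
  structure(list(
    n_reference = length(refids),
    total_founders = length(fc$q),
    n_real_founders = fc$n_founders,
    total_ascendants = total_ascendants(ped, refids),
    q = fc$q, f_e = fc$f_e,
    p = ea$p, f_a = ea$f_a, n_ancestors = ea$n_ancestors,
    N_g = ng$N_g, N_g_se = ng$se,
    ratio_fe_fa = fc$f_e / ea$f_a,
    ratio_ng_fe = ng$N_g / fc$f_e,
    average_inbreeding = inb$average,
    completeness = completeness(ped),
    replicates = ng$replicates
  ), class = "gene_origin")
}

#' @export
print.gene_origin <- function(x, ...) {
  cat("Probability-of-gene-origin summary\n")
  fmt <- function(lab, val) cat(sprintf("  %-28s %s\n", lab, val))
  fmt("Reference animals", x$n_reference)
  fmt("Total founders", x$total_founders)
  fmt("Total ascendants", x$total_ascendants)
  fmt("Equivalent founders (f_e)", sprintf("%.2f", x$f_e))
  fmt("Effective ascendants (f_a)", sprintf("%.2f", x$f_a))
  fmt("f_e/f_a (bottlenecks)", sprintf("%.2f", x$ratio_fe_fa))
  fmt("Founder genomes (N_g)", sprintf("%.2f (MC se %.3g)", x$N_g, x$N_g_se))
  fmt("N_g/f_e (genetic drift)", sprintf("%.4f", x$ratio_ng_fe))
  fmt("Average inbreeding", sprintf("%.2f%%", 100 * x$average_inbreeding))
  fmt("Pedigree completeness", sprintf("%.1f%%", 100 * x$completeness))
  invisible(x)
}
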