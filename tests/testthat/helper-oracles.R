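# Independent oracles and tiny fixture builders shared across test files.

ref0 <- synthetic_mt_reference()

make_ped <- function(id, sire = NA, dam = NA, sex = NA, birth_year = NA,
                     family = NA) {
  pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                      birth_year = birth_year, family = family,
                      stringsAsFactors = FALSE))
}

# state matrix scan: brute-force polymorphic-site count from full per-position
# state matrices (independent of the package's variant-position shortcut)
brute_polymorphic <- function(haps, iv, mode) {
  positions <- seq.int(iv[1], iv[2])
  states <- sapply(haps, function(h) {
    st <- ifelse(positions %in% h$coverage, "ref", NA)
    for (k in seq_len(nrow(h$variants))) {
      p <- h$variants$position[k]
      if (p %in% positions && p %in% h$coverage) {
        st[positions == p] <- paste0(h$variants$kind[k], ":", h$variants$alt[k])
      }
    }
    st
  })
  count <- 0L
  for (i in seq_along(positions)) {
    st <- states[i, ]
    st <- st[!is.na(st)]
    if (mode == "among") {
      if (length(st) >= 2 && length(unique(st)) >= 2) count <- count + 1L
    } else {
      if (any(st != "ref")) count <- count + 1L
    }
  }
  count
}

# random haplotype set with planted substitutions and random coverage gaps
random_hap_set <- function(n_hap, ref, n_pos = 30, gap_prob = 0.3) {
  dl <- ref$dloop_interval
  usable <- setdiff(seq.int(dl[1], dl[2]),
                    seq.int(ref$repeat_interval[1], ref$repeat_interval[2]))
  pool <- sort(sample(usable, n_pos))
  lapply(seq_len(n_hap), function(i) {
    k <- sample(0:6, 1)
    pos <- sort(sample(pool, k))
    rb <- ref_base(ref, pos)
    alt <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    cov <- usable
    if (runif(1) < gap_prob) {
      gap_start <- sample(usable[usable < dl[2] - 120], 1)
      cov <- setdiff(cov, seq.int(gap_start, gap_start + 99))
    }
    cov <- union(cov, pos)  # planted variants always covered
    mt_haplotype(paste0("R", i),
                 variant_table(pos, rb, unname(alt),
                               rep("substitution", length(pos))),
                 cov)
  })
}

# per-position state lookup used by brute-force distance checks
.hap_state_test <- function(hap, positions) {
  st <- ifelse(positions %in% hap$coverage, "ref", NA_character_)
  idx <- match(positions, hap$variants$position)
  hit <- !is.na(idx) & !is.na(st)
  st[hit] <- paste0(hap$variants$kind[idx[hit]], ":", hap$variants$alt[idx[hit]])
  st
}

# Wright path-counting inbreeding oracle: F_X = sum over common ancestors A
# and node-disjoint path pairs of (1/2)^(n + n' + 1) (1 + F_A)
wright_inbreeding <- function(ped_df) {
  ids <- ped_df$id
  sire <- setNames(ped_df$sire, ids)
  dam <- setNames(ped_df$dam, ids)
  paths_memo <- new.env(parent = emptyenv())
  paths_up <- function(x) {
    if (!is.null(paths_memo[[x]])) return(paths_memo[[x]])
    out <- list(x)
    for (p in c(sire[[x]], dam[[x]])) {
      if (!is.na(p)) {
        for (pp in paths_up(p)) out[[length(out) + 1L]] <- c(x, pp)
      }
    }
    paths_memo[[x]] <- out
    out
  }
  f_memo <- new.env(parent = emptyenv())
  F_of <- function(x) {
    if (!is.null(f_memo[[x]])) return(f_memo[[x]])
    s <- sire[[x]]; d <- dam[[x]]
    if (is.na(s) || is.na(d)) { f_memo[[x]] <- 0; return(0) }
    tot <- 0
    ps <- paths_up(s); pd <- paths_up(d)
    for (p1 in ps) {
      a <- p1[length(p1)]
      for (p2 in pd) {
        if (p2[length(p2)] != a) next
        if (length(intersect(p1[-length(p1)], p2[-length(p2)]))) next
        n1 <- length(p1) - 1L; n2 <- length(p2) - 1L
        tot <- tot + 0.5^(n1 + n2 + 1) * (1 + F_of(a))
      }
    }
    f_memo[[x]] <- tot
    tot
  }
  setNames(vapply(ids, F_of, numeric(1)), ids)
}

# random generation-structured pedigree (parents only from the previous
# generation), returned as a raw data frame
random_pedigree_df <- function(n_gen = 5, per_gen = 8, p_parents = 0.7) {
  id <- character(); sire <- character(); dam <- character()
  sex <- character(); gen_ids <- list()
  counter <- 0
  for (g in seq_len(n_gen)) {
    prev <- if (g > 1) gen_ids[[g - 1]] else list(M = character(), F = character())
    cur_m <- character(); cur_f <- character()
    for (k in seq_len(per_gen)) {
      counter <- counter + 1
      this <- sprintf("P%03d", counter)
      sx <- if (runif(1) < 0.5) "M" else "F"
      if (g > 1 && length(prev$M) && length(prev$F) && runif(1) < p_parents) {
        s <- prev$M[sample.int(length(prev$M), 1)]
        d <- prev$F[sample.int(length(prev$F), 1)]
      } else {
        s <- NA_character_; d <- NA_character_
      }
      id <- c(id, this); sire <- c(sire, s); dam <- c(dam, d)
      sex <- c(sex, sx)
      if (sx == "M") cur_m <- c(cur_m, this) else cur_f <- c(cur_f, this)
    }
    gen_ids[[g]] <- list(M = cur_m, F = cur_f)
  }
  data.frame(id = id, sire = sire, dam = dam, sex = sex,
             stringsAsFactors = FALSE)
}

# from-scratch marginal-ancestor selection: per candidate, a forward pass
# computing P(gene of i is from the not-yet-explained part of j's genome,
# without passing through an already-selected ancestor)
naive_effective_ancestors <- function(ped_df, ref_ids, eps = 1e-6) {
  ids <- ped_df$id
  n <- length(ids)
  sire <- match(ped_df$sire, ids)
  dam <- match(ped_df$dam, ids)
  # topological order: repeatedly emit individuals whose parents are emitted
  done <- logical(n); ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!done &
                   (is.na(sire) | done[ifelse(is.na(sire), 1L, sire)]) &
                   (is.na(dam) | done[ifelse(is.na(dam), 1L, dam)]))
    ord <- c(ord, ready); done[ready] <- TRUE
  }
  ref <- match(ref_ids, ids)
  g_of <- function(S) {
    g <- numeric(n)
    for (i in ord) {
      if (i %in% S) { g[i] <- 1; next }
      g[i] <- 0.5 * (if (!is.na(sire[i])) g[sire[i]] else 0) +
              0.5 * (if (!is.na(dam[i])) g[dam[i]] else 0)
    }
    g
  }
  contrib <- function(j, S, gS) {
    w <- numeric(n)
    for (i in ord) {
      if (i == j) { w[i] <- 1 - gS[j]; next }
      if (i %in% S) { w[i] <- 0; next }
      w[i] <- 0.5 * (if (!is.na(sire[i])) w[sire[i]] else 0) +
              0.5 * (if (!is.na(dam[i])) w[dam[i]] else 0)
    }
    mean(w[ref])
  }
  # candidates: strict ancestors of the reference population
  anc <- logical(n); stack <- ref
  while (length(stack)) {
    i <- stack[1]; stack <- stack[-1]
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p) && !anc[p]) { anc[p] <- TRUE; stack <- c(stack, p) }
    }
  }
  cand <- which(anc)
  S <- integer(0); p <- numeric(0)
  repeat {
    if (sum(p) >= 1 - eps || !length(setdiff(cand, S))) break
    gS <- g_of(S)
    vals <- vapply(setdiff(cand, S), contrib, numeric(1), S = S, gS = gS)
    names(vals) <- ids[setdiff(cand, S)]
    best <- which.max(vals)
    if (vals[best] < eps) break
    p <- c(p, vals[best])
    S <- c(S, match(names(vals)[best], ids))
  }
  list(p = p, f_a = 1 / sum(p^2))
}
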