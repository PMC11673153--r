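#' Read a mare metadata table
#'
#' @param path CSV with header `sample_id,family[,haplotype][,year]`.
#' @return Data frame.
#' @export
read_mares <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "family") %in% names(df))) {
    stop("mare table needs columns sample_id, family")
  }
  df
}

#' Read a pedigree table
#'
#' @param path CSV with header `id,sire,dam,sex,birth_year,family`; empty
#'   string means unknown.
#' @return A validated [pedigree()].
#' @export
read_pedigree <- function(path) {
  pedigree(read.csv(path, stringsAsFactors = FALSE))
}

.write_stage <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full uniparental-marker analysis pipeline
#'
#' Orchestrates the stages in dependency order: (1) haplotype calling from a
#' FASTA of control-region sequences (skipped when the mare table already
#' carries a `haplotype` column), (2) contingency table, family assignment,
#' and retention, (3) pedigree gene-origin statistics when a pedigree is
#' supplied, (4) MSY typing when a stallion genotype table is supplied.
#' Every stage writes its outputs as CSV into `out_dir` and the run is
#' summarised in a machine-readable `summary.json` with md5 checksums of
#' all written files. A stage failure aborts with the failing stage named;
#' outputs of completed stages are retained.
#'
#' @param config A list: `mares` (data frame or CSV path; required),
#'   `fasta` (optional path to sample sequences), `catalogue` (optional
#'   starting haplotype catalogue; default [ascal_motif_catalogue()] when
#'   calling from FASTA with `use_catalogue = TRUE`, empty for de novo),
#'   `use_catalogue` (logical, default TRUE), `pedigree` (data frame, path,
#'   or NULL), `msy` (data frame, path, or NULL), `msy_rules` (default
#'   [msy_rules()]), `reference` (default [synthetic_mt_reference()]),
#'   `replicates` (gene dropping, default 10000), `seed` (required when any
#'   stochastic stage runs), `out_dir` (required), `oracle` (logical, run
#'   [matching_oracle()], default TRUE).
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  summary <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ref <- config$reference %||% synthetic_mt_reference()

  mares <- config$mares
  if (is.character(mares)) mares <- stage("read_mares", read_mares(mares))
  if (is.null(mares) || nrow(mares) == 0L) stop("pipeline stage 'build_contingency' failed: no data")

  # stage 1: haplotype calling
  if (!is.null(config$fasta)) {
    stage("haplotype", {
      seqs <- Biostrings::readDNAStringSet(config$fasta)
      use_cat <- config$use_catalogue %||% TRUE
      catalogue <- config$catalogue %||%
        (if (use_cat) ascal_motif_catalogue(ref) else list())
      pad <- 60L
      win <- c(max(1L, ref$dloop_interval[1] - pad),
               min(nchar(ref$sequence), ref$dloop_interval[2] + pad))
      alns <- lapply(seq_along(seqs), function(i) {
        anchor_align(list(sample_id = names(seqs)[i],
                          sequence = as.character(seqs[[i]])),
                     ref, window = win)
      })
      cl <- cluster_haplotypes(alns, catalogue = catalogue)
      vt <- do.call(rbind, lapply(alns, function(a) {
        if (!nrow(a$variants)) return(NULL)
        cbind(sample_id = a$sample_id, a$variants)
      }))
      if (!is.null(vt)) written <- c(written, .write_stage(vt, out_dir, "variants.csv"))
      written <- c(written, .write_stage(cl$calls, out_dir, "haplotype_calls.csv"))
      cat_df <- do.call(rbind, lapply(cl$catalogue, function(h) {
        data.frame(haplotype = h$name, n_variants = nrow(h$variants),
                   n_covered = length(h$coverage), stringsAsFactors = FALSE)
      }))
      written <- c(written, .write_stage(cat_df, out_dir, "haplotype_catalogue.csv"))
      mares <- merge(mares[setdiff(names(mares), "haplotype")],
                      cl$calls[c("sample_id", "haplotype")], by = "sample_id")
      summary$haplotypes <- list(n_distinct = length(unique(cl$calls$haplotype[cl$calls$status != "ambiguous"])),
                                  n_samples = nrow(cl$calls),
                                  n_ambiguous = sum(cl$calls$status == "ambiguous"))
    })
  }
  if (!"haplotype" %in% names(mares)) {
    stop("pipeline stage 'build_contingency' failed: mares carry no haplotype calls")
  }

  # stage 2: contingency, assignment, retention
  stage("assignment", {
    tab <- build_contingency(mares)
    asg <- assign_families(tab)
    ret <- retention(mares, asg)
    freq <- haplotype_frequencies(tab)
    written <- c(written,
                  .write_stage(as.data.frame(unclass(tab)), out_dir, "contingency.csv"),
                  .write_stage(asg$steps, out_dir, "assignment.csv"),
                  .write_stage(ret$per_mare, out_dir, "retention.csv"),
                  .write_stage(freq, out_dir, "haplotype_frequencies.csv"))
    summary$assignment <- list(
      map = lapply(asg$map, identity),
      retained = ret$retained, culled = ret$culled,
      unassessable = ret$unassessable)
    if (isTRUE(config$oracle %||% TRUE)) {
      orc <- matching_oracle(tab)
      summary$assignment$oracle_retained <- orc$retained
    }
  })

  # stage 3: pedigree statistics
  if (!is.null(config$pedigree)) {
    stage("pedstats", {
      ped <- config$pedigree
      if (is.character(ped)) ped <- read_pedigree(ped)
      if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
      seed <- config$seed %||% stop("seed required for gene dropping")
      go <- gene_origin(ped, reference = config$reference_ids,
                        replicates = config$replicates %||% 10000L,
                        seed = seed)
      stats_df <- data.frame(
        statistic = c("Reference animals", "Total founders", "Total ascendants",
                      "Equivalent founders (f_e)", "Effective ascendants (f_a)",
                      "f_e/f_a (bottlenecks)", "Founder genomes (N_g)",
                      "N_g/f_e (genetic drift)", "Average inbreeding",
                      "Pedigree completeness"),
        value = c(go$n_reference, go$total_founders, go$total_ascendants,
                  go$f_e, go$f_a, go$ratio_fe_fa, go$N_g, go$ratio_ng_fe,
                  go$average_inbreeding, go$completeness),
        stringsAsFactors = FALSE)
      written <- c(written, .write_stage(stats_df, out_dir, "pedigree_stats.csv"))
      summary$pedigree <- as.list(stats_df$value)
      names(summary$pedigree) <- stats_df$statistic
    })
  }

  # stage 4: MSY typing
  if (!is.null(config$msy)) {
    stage("msy", {
      msy <- config$msy
      if (is.character(msy)) msy <- read.csv(msy, stringsAsFactors = FALSE)
      rules <- config$msy_rules %||% msy_rules()
      calls <- vapply(seq_len(nrow(msy)), function(i) {
        call_msy(as.list(msy[i, c("YE3", "YE17", "YXX")]), rules)
      }, character(1))
      calls_df <- data.frame(sample_id = msy$sample_id, haplotype = calls,
                             stringsAsFactors = FALSE)
      fr <- msy_frequencies(calls)
      written <- c(written,
                    .write_stage(calls_df, out_dir, "msy_calls.csv"),
                    .write_stage(fr$table, out_dir, "msy_frequencies.csv"))
      summary$msy <- list(frequencies = fr$table, uncallable = fr$uncallable)
    })
  }

  summary$checksums <- as.list(tools::md5sum(written))
  names(summary$checksums) <- basename(written)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
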