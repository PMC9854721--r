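# One-call orchestration of the full analysis with reproducible reports.

#' Run configuration for the analysis pipeline
#'
#' Collects inputs, stage toggles, iteration counts and seeds. Every
#' stochastic stage draws its seed deterministically from the single
#' `seed` field, and all values are echoed in the run manifest.
#'
#' @param table2 path to a variable-site haplotype table (TSV dialect).
#' @param genepop optional path to a GENEPOP genotype file.
#' @param groups optional named character vector mapping population codes
#'   to groups (for the AMOVA stage).
#' @param total_length optional analyzed sequence length L.
#' @param stages character vector among `"coi"`, `"divergence"`,
#'   `"recombination"`, `"network"`, `"msat"`, `"amova"`, `"trees"`,
#'   `"power"`.
#' @param rate,rate_bounds molecular-clock settings (substitutions/site/Myr).
#' @param hwe_batches,hwe_iters Hardy-Weinberg Markov-chain schedule.
#' @param dest_boot Jost D bootstrap replicates.
#' @param amova_perm AMOVA permutations.
#' @param tree_boot tree bootstrap replicates.
#' @param power_reps power-simulation replicates.
#' @param power_fst power-simulation target Fst.
#' @param seed master seed.
#' @param out_dir output directory for reports.
#' @return A `"run_config"` list.
#' @export
run_config <- function(table2 = NULL, genepop = NULL, groups = NULL,
                       total_length = NULL,
                       stages = c("coi", "divergence", "recombination",
                                  "network"),
                       rate = 0.02, rate_bounds = c(0.0069, 0.03),
                       hwe_batches = 20, hwe_iters = 5000,
                       dest_boot = 1000, amova_perm = 1023,
                       tree_boot = 10000, power_reps = 200,
                       power_fst = 0.117, seed = 1, out_dir = tempdir()) {
  structure(list(table2 = table2, genepop = genepop, groups = groups,
                 total_length = total_length, stages = stages, rate = rate,
                 rate_bounds = rate_bounds, hwe_batches = hwe_batches,
                 hwe_iters = hwe_iters, dest_boot = dest_boot,
                 amova_perm = amova_perm, tree_boot = tree_boot,
                 power_reps = power_reps, power_fst = power_fst,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (COI diversity, divergence and
#' dating, recombination, haplotype network, microsatellite statistics,
#' AMOVA, trees, power), writing TSV reports, Newick trees, GraphML
#' networks and a JSON manifest (package version, config, per-stage seeds)
#' into `config$out_dir`. Identical configs produce byte-identical
#' reports. A stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return Invisible list of results per stage, with `files` listing the
#'   written report paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(files = character(0))
  add_file <- function(p) res$files <<- c(res$files, p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_wreckpop("stage '", name, "' failed: ", conditionMessage(e)))
  }
  needs_coi <- intersect(config$stages,
                         c("coi", "divergence", "recombination", "network"))
  sset <- NULL
  if (length(needs_coi)) {
    if (is.null(config$table2))
      stop_wreckpop("stages ", paste(needs_coi, collapse = ","),
                    " need a table2 input")
    vsm <- stage("read", read_variable_site_table(
      config$table2, total_length = config$total_length))
    sset <- expand_haplotypes(vsm)
  }
  gtab <- NULL
  needs_msat <- intersect(config$stages, c("msat", "amova", "trees"))
  if (!is.null(config$genepop)) gtab <- stage("read", read_genepop(config$genepop))
  else if (length(needs_msat))
    stop_wreckpop("stages ", paste(needs_msat, collapse = ","),
                  " need a genepop input")

  if ("coi" %in% config$stages) {
    res$coi <- stage("coi", {
      all <- coi_diversity(sset, seed = derive_seed(config$seed, 1))
      by_lin <- lapply(unique(sset$records$lineage), function(li) {
        n <- sum(sset$records$lineage == li)
        if (n >= 2) coi_diversity(sset, lineage = li,
                                  seed = derive_seed(config$seed, 2))
        else NULL
      })
      names(by_lin) <- unique(sset$records$lineage)
      df <- do.call(rbind, lapply(c(list(all = all),
                                    Filter(Negate(is.null), by_lin)),
        function(x) data.frame(n = x$n, h = x$h, S = x$S,
                               Hd = round(x$Hd, 4), k = round(x$k, 4),
                               Pi = round(x$Pi, 5), Fs = round(x$Fs, 4),
                               Fs_p = x$Fs_p)))
      df <- cbind(set = rownames(df), df)
      add_file(write_tsv_report(df, file.path(config$out_dir,
                                              "coi_diversity.tsv")))
      df
    })
  }
  if ("divergence" %in% config$stages) {
    res$divergence <- stage("divergence", {
      L <- config$total_length
      if (is.null(L))
        stop_wreckpop("divergence stage needs total_length")
      dv <- pairwise_dxy(sset, L)
      lin <- dv$lineages
      pairs <- combn(lin, 2)
      df <- data.frame(lineage1 = pairs[1, ], lineage2 = pairs[2, ])
      df$Dxy <- apply(pairs, 2, function(pr) dv$Dxy[pr[1], pr[2]])
      df$Da <- apply(pairs, 2, function(pr) dv$Da[pr[1], pr[2]])
      add_file(write_tsv_report(df, file.path(config$out_dir,
                                              "divergence.tsv")))
      dv
    })
  }
  if ("recombination" %in% config$stages) {
    res$recombination <- stage("recombination", {
      rep_ <- hudson_kaplan_rm(sset)
      df <- as.data.frame(rep_$intervals)
      names(df) <- c("left", "right")
      add_file(write_tsv_report(df, file.path(config$out_dir,
                                              "recombination_intervals.tsv")))
      rep_
    })
  }
  if ("network" %in% config$stages) {
    res$network <- stage("network", {
      net <- median_joining_network(sset)
      write_network(net,
                    graphml = file.path(config$out_dir, "network.graphml"),
                    edges_tsv = file.path(config$out_dir,
                                          "network_edges.tsv"))
      add_file(file.path(config$out_dir, "network_edges.tsv"))
      add_file(file.path(config$out_dir, "network.graphml"))
      net
    })
  }
  if ("msat" %in% config$stages) {
    res$msat <- stage("msat", {
      sums <- locus_summaries(gtab, hwe = TRUE, null_alleles = TRUE,
                              seed = derive_seed(config$seed, 3))
      sums$q_hwe <- fdr_adjust(sums$p_hwe)
      add_file(write_tsv_report(sums, file.path(config$out_dir,
                                                "locus_summaries.tsv")))
      fst <- wc_fstats(gtab, n_perm = 199,
                       seed = derive_seed(config$seed, 4))
      dest <- jost_dest(gtab, n_boot = config$dest_boot,
                        seed = derive_seed(config$seed, 5))
      glob <- data.frame(Fst = fst$Fst, p_fst = fst$p_fst, Dest = dest$D,
                         p_dest = dest$p)
      add_file(write_tsv_report(glob, file.path(config$out_dir,
                                                "global_differentiation.tsv")))
      list(summaries = sums, fst = fst, dest = dest)
    })
  }
  if ("amova" %in% config$stages) {
    res$amova <- stage("amova", {
      am <- hierarchical_amova(gtab, groups = config$groups,
                               n_perm = config$amova_perm,
                               seed = derive_seed(config$seed, 6))
      f <- am$fit
      df <- data.frame(
        level = c("among_groups", "among_pops_within_groups",
                  "within_pops"),
        SS = unname(f$ss), sigma = unname(f$sigma),
        pct = unname(100 * f$sigma / sum(f$sigma)))
      add_file(write_tsv_report(df, file.path(config$out_dir, "amova.tsv")))
      am
    })
  }
  if ("trees" %in% config$stages) {
    res$trees <- stage("trees", {
      tr <- bootstrap_support(gtab, n_reps = config$tree_boot,
                              seed = derive_seed(config$seed, 7))
      p <- file.path(config$out_dir, "msat_nj.nwk")
      write_tree_newick(tr, p); add_file(p)
      tr
    })
  }
  if ("power" %in% config$stages) {
    res$power <- stage("power", {
      sizes <- if (!is.null(gtab)) as.numeric(table(gtab$individuals$pop))
               else fixture_dataset("table1_design")$n_mic
      base <- draw_base_frequencies(seed = derive_seed(config$seed, 8))
      pw <- structure_power(base, sizes, config$power_fst,
                            reps = config$power_reps,
                            seed = derive_seed(config$seed, 9))
      df <- data.frame(target_fst = pw$target_fst, power = pw$power_chi2,
                       reps = pw$reps, Ne = pw$Ne, t = pw$t)
      add_file(write_tsv_report(df, file.path(config$out_dir, "power.tsv")))
      pw
    })
  }
  manifest <- list(
    package = "wreckpop",
    version = as.character(packageVersion("wreckpop")),
    config = config[setdiff(names(config), "out_dir")],
    files = basename(res$files))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  res$manifest <- mpath
  invisible(res)
}
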