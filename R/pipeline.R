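#' Build and validate a pipeline configuration
#'
#' A configuration is a plain named list (serializable to YAML) describing
#' one end-to-end run. In `demo` mode all inputs are simulated with
#' planted ground truth; in `files` mode the `paths` entries name existing
#' inputs. Unknown keys are rejected so typos fail before any stage runs.
#'
#' @param mode "demo" (simulate inputs) or "files".
#' @param seed RNG seed for every stochastic stage.
#' @param n_genes Demo-mode cohort size (default 200).
#' @param extend Read-extension target length (default 150).
#' @param bin_size Coverage bin size (default 20).
#' @param flank Metagene/average-signal flank (default 4000).
#' @param windows A [pausing_windows()] object or NULL for defaults.
#' @param body_bins Metagene body bins (default 100).
#' @param tier_boundaries Tier cut fractions (default `c(0.30, 0.50)`).
#' @param de_preset DE threshold preset name (default "results_v1").
#' @param promoter_dist Promoter annotation distance (default 1000).
#' @param depletion Named list of depletion multipliers
#'   (promoter_mult/body_mult/terminal_mult/background_mult).
#' @param paths Files-mode named list: genes, reads_control,
#'   reads_depleted, chrom_sizes; optional peaks, blacklist, k4, k79, k27,
#'   de_table.
#' @return Validated config list (class `polpause_config`).
#' @export
pipeline_config <- function(mode = c("demo", "files"), seed = 1,
                            n_genes = 200, extend = 150, bin_size = 20,
                            flank = 4000, windows = NULL, body_bins = 100,
                            tier_boundaries = c(0.30, 0.50),
                            de_preset = "results_v1",
                            promoter_dist = 1000,
                            depletion = list(promoter_mult = 2,
                                             body_mult = 0.5),
                            paths = list()) {
  cfg <- list(mode = match.arg(mode), seed = seed, n_genes = n_genes,
              extend = extend, bin_size = bin_size, flank = flank,
              windows = windows, body_bins = body_bins,
              tier_boundaries = tier_boundaries, de_preset = de_preset,
              promoter_dist = promoter_dist, depletion = depletion,
              paths = paths)
  validate_config(cfg)
  class(cfg) <- "polpause_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A config list (e.g. parsed from YAML).
#' @export
validate_config <- function(config) {
  known <- c("mode", "seed", "n_genes", "extend", "bin_size", "flank",
             "windows", "body_bins", "tier_boundaries", "de_preset",
             "promoter_dist", "depletion", "paths")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!config$mode %in% c("demo", "files"))
    stop("mode must be 'demo' or 'files'")
  for (k in c("seed", "n_genes", "extend", "bin_size", "flank",
              "body_bins", "promoter_dist"))
    if (!is.numeric(config[[k]]) || length(config[[k]]) != 1L ||
        config[[k]] <= 0)
      stop("config key '", k, "' must be a positive number")
  if (!config$de_preset %in% names(de_presets()))
    stop("unknown de_preset: ", config$de_preset)
  if (config$mode == "files") {
    need <- c("genes", "reads_control", "reads_depleted", "chrom_sizes")
    miss <- setdiff(need, names(config$paths))
    if (length(miss))
      stop("files mode requires path(s): ", paste(miss, collapse = ", "))
    for (p in unlist(config$paths))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  invisible(TRUE)
}

# 32-bit polynomial rolling hash of the deparsed config, for output
# provenance headers.
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", h)
}

.write_stage <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# polpause config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pausing-analysis pipeline
#'
#' Executes simulate (demo mode) or load (files mode), then coverage,
#' metagene, pausing, chromatin classification and peak/DE integration,
#' writing one TSV per stage plus a run log and a config echo into
#' `out_dir`. Every output carries the config hash in a header comment;
#' re-running with the same config and inputs reproduces the files
#' byte-identically.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML file
#'   holding one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the per-stage result objects.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  logf <- file.path(out_dir, "run.log")
  cat("polpause run, config_hash=", hash, "\n", sep = "", file = logf)
  note <- function(...) cat(..., "\n", sep = "", file = logf,
                            append = TRUE)
  run_stage <- function(name, expr) {
    note("stage ", name, " started")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    note("stage ", name, " done")
    res
  }
  yaml::write_yaml(config[setdiff(names(config), "windows")],
                   file.path(out_dir, "config.yaml"))
  windows <- config$windows %||% pausing_windows()

  inputs <- run_stage("inputs", {
    if (config$mode == "demo") {
      genome <- simulate_genome(n_genes = config$n_genes,
                                seed = config$seed)
      truth_ctrl <- sim_truth(genome$genes)
      truth_depl <- do.call(apply_depletion,
                            c(list(truth_ctrl), config$depletion))
      reads_ctrl <- simulate_reads(truth_ctrl, genome$genes, genome$sizes,
                                   seed = config$seed + 1L)
      reads_depl <- simulate_reads(truth_depl, genome$genes, genome$sizes,
                                   seed = config$seed + 2L)
      n <- length(genome$genes)
      states <- sample(c("active", "bivalent", "silent"), n,
                       replace = TRUE, prob = c(0.6, 0.25, 0.15))
      marks <- simulate_marks(genome$genes, states,
                              seed = config$seed + 3L)
      ids <- genome$genes$gene_id
      set.seed(config$seed + 4L)
      dn <- sample(ids, max(1L, round(0.15 * n)))
      up <- sample(setdiff(ids, dn), max(1L, round(0.05 * n)))
      de <- simulate_de(genome$genes, down_genes = dn, up_genes = up,
                        seed = config$seed + 5L)
      .write_stage(truth_ctrl, file.path(out_dir, "truth_control.tsv"),
                   hash)
      .write_stage(truth_depl, file.path(out_dir, "truth_depleted.tsv"),
                   hash)
      list(genes = genome$genes, sizes = genome$sizes,
           reads_ctrl = reads_ctrl, reads_depl = reads_depl,
           marks = marks, de = de, states = states)
    } else {
      sizes <- read_chrom_sizes(config$paths$chrom_sizes)
      genes <- read_genes(config$paths$genes, sizes = sizes)
      rd <- function(p) read_bed6(p, sizes = sizes, strand_required = TRUE)
      marks <- if (all(c("k4", "k79", "k27") %in% names(config$paths)))
        list(k4 = read_peaks(config$paths$k4),
             k79 = read_peaks(config$paths$k79),
             k27 = read_peaks(config$paths$k27)) else NULL
      de <- if (!is.null(config$paths$de_table))
        read_de_table(config$paths$de_table) else NULL
      list(genes = genes, sizes = sizes,
           reads_ctrl = rd(config$paths$reads_control),
           reads_depl = rd(config$paths$reads_depleted),
           marks = marks, de = de, states = NULL)
    }
  })

  tracks <- run_stage("coverage", {
    mk <- function(reads) {
      frags <- extend_reads(reads, config$extend, inputs$sizes)
      compute_coverage(frags, inputs$sizes, bin_size = config$bin_size,
                       total_reads = length(reads))
    }
    tr <- list(control = mk(inputs$reads_ctrl),
               depleted = mk(inputs$reads_depl))
    write_bedgraph(tr$control, file.path(out_dir, "coverage_control.bedgraph"))
    write_bedgraph(tr$depleted,
                   file.path(out_dir, "coverage_depleted.bedgraph"))
    tr
  })

  genes_iso <- run_stage("gene_selection", {
    g <- select_isolated_genes(inputs$genes, min_distance = 4000)
    g[width(g) >= max(301, config$body_bins)]
  })

  profiles <- run_stage("metagene", {
    pc <- metagene_profile(tracks$control, genes_iso, flank = config$flank,
                           body_bins = config$body_bins)
    pd <- metagene_profile(tracks$depleted, genes_iso,
                           flank = config$flank,
                           body_bins = config$body_bins)
    out <- data.frame(bin = pc$bin, region = pc$region,
                      position = pc$position, control = pc$value,
                      depleted = pd$value)
    .write_stage(out, file.path(out_dir, "metagene_profiles.tsv"), hash)
    out
  })

  pausing <- run_stage("pausing", {
    mc <- pausing_metrics(tracks$control, genes_iso, windows,
                          flank = config$flank,
                          boundaries = config$tier_boundaries)
    md <- pausing_metrics(tracks$depleted, genes_iso, windows,
                          flank = config$flank,
                          boundaries = config$tier_boundaries)
    .write_stage(mc, file.path(out_dir, "pausing_control.tsv"), hash)
    .write_stage(md, file.path(out_dir, "pausing_depleted.tsv"), hash)
    cmp_tr <- compare_conditions(md$tr, mc$tr)
    cmp_pi <- compare_conditions(md$pi3, mc$pi3)
    cmp <- data.frame(metric = c("tr", "pi3"),
                      statistic = c(cmp_tr$statistic, cmp_pi$statistic),
                      p_value = c(cmp_tr$p_value, cmp_pi$p_value),
                      median_depleted = c(cmp_tr$median_a, cmp_pi$median_a),
                      median_control = c(cmp_tr$median_b, cmp_pi$median_b),
                      direction = c(cmp_tr$direction, cmp_pi$direction))
    .write_stage(cmp, file.path(out_dir, "condition_comparison.tsv"), hash)
    list(control = mc, depleted = md, comparison = cmp)
  })

  classification <- run_stage("chromatin_state", {
    if (is.null(inputs$marks)) return(NULL)
    calls <- classify_genes(inputs$genes, inputs$marks$k4,
                            inputs$marks$k79, inputs$marks$k27)
    .write_stage(calls, file.path(out_dir, "chromatin_calls.tsv"), hash)
    calls
  })

  integration <- run_stage("integration", {
    if (is.null(inputs$de)) return(NULL)
    sets <- filter_de(inputs$de, preset = config$de_preset)
    # promoter-bound genes approximated by promoter-proximal peaks built
    # from the depleted-vs-control comparison is out of scope here; in
    # demo mode the bound set is derived from simulated promoter reads
    peaks <- GRanges(seqnames(inputs$genes),
                     IRanges(gene_tss(inputs$genes) - 50,
                             gene_tss(inputs$genes) + 50),
                     name = paste0("pk", seq_along(inputs$genes)),
                     score = 100)
    keep <- pausing$control$avg_signal >
      stats::median(pausing$control$avg_signal)
    bound <- bound_genes(peaks[inputs$genes$gene_id %in%
                                 pausing$control$gene_id[keep]],
                         inputs$genes,
                         promoter_dist = config$promoter_dist)
    bd <- bound_vs_de(bound, sets$up, sets$down)
    comp <- if (!is.null(classification))
      state_composition(sets$down$gene_id, classification) else NULL
    if (!is.null(comp))
      .write_stage(comp, file.path(out_dir, "down_state_composition.tsv"),
                   hash)
    .write_stage(data.frame(n_bound = bd$n_bound,
                            fraction_down = bd$fraction_down,
                            fraction_up = bd$fraction_up,
                            fraction_neither = bd$fraction_neither),
                 file.path(out_dir, "bound_vs_de.tsv"), hash)
    list(de_sets = sets, bound = bound, bound_vs_de = bd,
         composition = comp)
  })

  note("run complete")
  invisible(list(inputs = inputs, tracks = tracks, genes = genes_iso,
                 profiles = profiles, pausing = pausing,
                 classification = classification,
                 integration = integration))
}
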