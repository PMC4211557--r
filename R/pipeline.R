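PIPELINE_DEFAULTS <- list(
  mode = "synthetic",
  input = list(fasta = NULL, germline_fasta = NULL),
  synthesis = list(n_germlines = 8, n_families = 4, length = 130,
                   n_clonotypes = 200, base_rate = 0.07, decay_length = 50),
  registers = c("TCEM_I", "TCEM_IIA", "TCEM_IIB"),
  alleles = NULL,           # default: the DR roster
  threshold_sd = 1,
  fc_mode = "molecule",
  max_length = 130,
  seed = 1,
  out_dir = "tcemrep_out")

#' Build and validate a pipeline configuration
#'
#' Configuration is a JSON file (or an R list) with the same keys as the
#' defaults: `mode` ("synthetic" or "fasta"), `input$fasta` /
#' `input$germline_fasta`, `synthesis` parameters, `registers`, `alleles`,
#' `threshold_sd`, `fc_mode` ("molecule" or "instance"), `max_length`,
#' `seed`, `out_dir`. Unset keys take their defaults; every default actually
#' used is echoed into the run manifest, so no silent defaults exist.
#'
#' @param config Path to a JSON config file, or a named list of overrides.
#' @param ... Individual key overrides (applied after `config`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_contract("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  merge_in <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_in(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- merge_in(PIPELINE_DEFAULTS, config)
  cfg <- merge_in(cfg, list(...))
  problems <- character()
  if (!cfg$mode %in% c("synthetic", "fasta"))
    problems <- c(problems, "mode must be 'synthetic' or 'fasta'")
  if (cfg$mode == "fasta") {
    if (is.null(cfg$input$fasta))
      problems <- c(problems, "fasta mode requires input$fasta")
    else if (!file.exists(cfg$input$fasta))
      problems <- c(problems, paste0("input$fasta not found: ",
                                     cfg$input$fasta))
    if (!is.null(cfg$input$germline_fasta) &&
        !file.exists(cfg$input$germline_fasta))
      problems <- c(problems, paste0("input$germline_fasta not found: ",
                                     cfg$input$germline_fasta))
  }
  bad_reg <- setdiff(cfg$registers, register_names())
  if (length(bad_reg))
    problems <- c(problems, paste0("unknown register(s): ",
                                   paste(bad_reg, collapse = ", ")))
  if (!cfg$fc_mode %in% c("molecule", "instance"))
    problems <- c(problems, "fc_mode must be 'molecule' or 'instance'")
  if (!is.numeric(cfg$threshold_sd) || cfg$threshold_sd <= 0)
    problems <- c(problems, "threshold_sd must be a positive number")
  if (!is.null(cfg$alleles)) {
    bad <- setdiff(cfg$alleles, hla_allele_roster()$allele)
    if (length(bad))
      problems <- c(problems, paste0("unknown allele(s): ",
                                     paste(bad, collapse = ", ")))
  }
  if (length(problems))
    stop_contract("invalid pipeline config:\n  - ",
                  paste(problems, collapse = "\n  - "))
  if (is.null(cfg$alleles)) cfg$alleles <- hla_allele_roster("DR")$allele
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(...) message("[tcemrep] ", sprintf(...))

load_input_dataset <- function(cfg) {
  if (cfg$mode == "synthetic") {
    syn <- cfg$synthesis
    lib <- make_germline_library(n_germlines = syn$n_germlines,
                                 length = syn$length,
                                 n_families = syn$n_families,
                                 seed = derive_seed(cfg$seed, "library"))
    params <- shm_parameters(base_rate = syn$base_rate,
                             decay_length = syn$decay_length,
                             seed = derive_seed(cfg$seed, "shm"))
    ds <- simulate_repertoire(lib, syn$n_clonotypes, params)
    pipeline_log("simulated %d clonotypes from %d germlines",
                 syn$n_clonotypes, syn$n_germlines)
    ds
  } else {
    recs <- read_fasta(cfg$input$fasta)
    ds <- curate(recs, max_length = cfg$max_length)
    pipeline_log("read %d records from %s; %s", nrow(recs),
                 cfg$input$fasta, ds$provenance[1])
    if (!is.null(cfg$input$germline_fasta))
      ds$germline_reference <- read_fasta(cfg$input$germline_fasta)
    ds
  }
}

# Stage implementations. Each writes its outputs under out_dir and returns
# the relative paths of files written.

stage_simulate <- function(cfg) {
  ds <- load_input_dataset(cfg)
  fa <- file.path(cfg$out_dir, "repertoire.fasta")
  write_fasta(ds$records, fa)
  files <- "repertoire.fasta"
  if (!is.null(ds$germline_reference)) {
    write_fasta(ds$germline_reference,
                file.path(cfg$out_dir, "germlines.fasta"))
    files <- c(files, "germlines.fasta")
  }
  if (!is.null(ds$ground_truth)) {
    write_ground_truth(ds, file.path(cfg$out_dir, "ground_truth.tsv"))
    files <- c(files, "ground_truth.tsv")
  }
  list(dataset = ds, files = files)
}

stage_extract <- function(cfg, dataset) {
  files <- character()
  for (reg in cfg$registers) {
    tab <- build_frequency_table(dataset, reg)
    origin <- NULL
    if (!is.null(dataset$germline_reference))
      origin <- attribute_origin(tab, dataset$germline_reference)
    f <- sprintf("motifs_%s.tsv", reg)
    write_motif_table(tab, file.path(cfg$out_dir, f), origin = origin)
    pipeline_log("extract %s: %d unique motifs, %d instances", reg,
                 nrow(tab$entries), tab$total_instances)
    files <- c(files, f)
  }
  files
}

stage_classify <- function(cfg, motif_files) {
  files <- character()
  for (f in motif_files) {
    tab <- read_motif_table(file.path(cfg$out_dir, f))
    if (cfg$fc_mode == "instance") {
      tab$entries$molecule_count <- tab$entries$instance_count
      tab$total_molecules <- tab$total_instances
    }
    h <- fc_histogram(tab)
    out <- sprintf("fc_histogram_%s.tsv", tab$register)
    df <- data.frame(fc = h$fc, unique_count = h$unique_count,
                     weighted_count = h$weighted_count,
                     cumulative = h$cumulative_fraction)
    write.table(df, file.path(cfg$out_dir, out), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pipeline_log("classify %s: midpoint FC %d", tab$register,
                 attr(h, "midpoint_fc"))
    files <- c(files, out)
  }
  files
}

stage_present <- function(cfg, dataset) {
  predictors <- lapply(cfg$alleles, make_surrogate_affinity_predictor,
                       seed = derive_seed(cfg$seed, "affinity_surrogate"))
  prof <- repertoire_binding_profile(dataset, predictors,
                                     threshold_sd = cfg$threshold_sd)
  write.table(prof, file.path(cfg$out_dir, "binding_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cleave <- lapply(CATHEPSINS, function(enz) {
    pred <- make_surrogate_cleavage_predictor(
      enz, seed = derive_seed(cfg$seed, "cleavage_surrogate"))
    profs <- data.table::rbindlist(lapply(seq_len(nrow(dataset$records)),
      function(i) cleavage_profile(pred, dataset$records[i, ])))
    profs[, .(probability = mean(probability)), by = .(bond_after, enzyme)]
  })
  cleave <- as.data.frame(data.table::rbindlist(cleave))
  write.table(cleave, file.path(cfg$out_dir, "cleavage_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log("present: %d alleles, threshold %g SD", length(cfg$alleles),
               cfg$threshold_sd)
  c("binding_profile.tsv", "cleavage_profile.tsv")
}

stage_compare <- function(cfg, table_a, table_b) {
  ta <- read_motif_table(table_a)
  tb <- read_motif_table(table_b)
  ov <- motif_set_overlap(ta, tb)
  fcmap <- map_fc_from_reference(ta, tb)
  out <- file.path(cfg$out_dir, "overlap_report.tsv")
  df <- data.frame(register = ta$register,
                   motifs_a = nrow(ta$entries), motifs_b = nrow(tb$entries),
                   shared_count = ov$shared_count,
                   shared_fraction_of_A = ov$shared_fraction_of_A,
                   shared_fraction_of_B = ov$shared_fraction_of_B,
                   unclassified_fraction_of_A =
                     attr(fcmap, "unclassified_fraction"))
  write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  "overlap_report.tsv"
}

write_manifest <- function(cfg, files) {
  paths <- file.path(cfg$out_dir, files)
  manifest <- list(
    package = "tcemrep",
    version = as.character(utils::packageVersion("tcemrep")),
    config = unclass(cfg),
    seed = cfg$seed,
    outputs = data.frame(file = files,
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full analysis pipeline
#'
#' Synthetic or FASTA input -> per-register motif tables (with origin
#' attribution when a germline reference is present) -> frequency-class
#' histograms -> binding and cleavage presentation profiles, plus a JSON run
#' manifest recording the fully resolved configuration, the seed, and an md5
#' digest of every output file. Outputs are deterministic given identical
#' config and seed.
#'
#' @param config A `pipeline_config`, config-file path, or named list.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- stage_simulate(cfg)
  files <- sim$files
  files <- c(files, stage_extract(cfg, sim$dataset))
  files <- c(files, stage_classify(cfg, grep("^motifs_", files,
                                             value = TRUE)))
  files <- c(files, stage_present(cfg, sim$dataset))
  write_manifest(cfg, files)
}

#' Command-line entry point
#'
#' Dispatcher behind the `tcemrep` executable script
#' (`system.file("exec", "tcemrep", package = "tcemrep")`):
#' `tcemrep simulate|extract|classify|present|compare|run --config <file>
#' [--seed N] [--out DIR]`. Each subcommand is runnable standalone on the
#' outputs of the previous stage; `run` chains all stages.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the files written.
#' @export
tcemrep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tcemrep <simulate|extract|classify|present|compare|run>",
    "[--config FILE] [--seed N] [--out DIR]")
  if (length(args) == 0L) stop_contract(usage)
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    if (i[1] == length(args)) stop_contract("missing value for ", flag)
    args[i[1] + 1L]
  }
  overrides <- list()
  seed <- opt("--seed"); if (!is.null(seed))
    overrides$seed <- as.integer(seed)
  out <- opt("--out"); if (!is.null(out)) overrides$out_dir <- out
  cfg <- do.call(pipeline_config,
                 c(list(config = opt("--config", list())), overrides))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- switch(cmd,
    run = return(invisible(run_pipeline(cfg))),
    simulate = stage_simulate(cfg)$files,
    extract = stage_extract(cfg, load_input_dataset(cfg)),
    classify = {
      tabs <- list.files(cfg$out_dir, pattern = "^motifs_.*\\.tsv$")
      if (length(tabs) == 0L)
        stop_contract("classify: no motifs_*.tsv found in ", cfg$out_dir,
                      " (run 'extract' first)")
      stage_classify(cfg, tabs)
    },
    present = stage_present(cfg, load_input_dataset(cfg)),
    compare = {
      a <- opt("--table-a"); b <- opt("--table-b")
      if (is.null(a) || is.null(b))
        stop_contract("compare: need --table-a and --table-b motif TSVs")
      for (p in c(a, b)) if (!file.exists(p))
        stop_contract("compare: missing upstream output: ", p)
      stage_compare(cfg, a, b)
    },
    stop_contract("unknown subcommand '", cmd, "'\n", usage))
  write_manifest(cfg, files)
  invisible(files)
}
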