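#' Pipeline configuration
#'
#' Collects the analysis thresholds and the simulation settings for an
#' end-to-end synthetic run. Threshold defaults: PACCE call cutoff
#' SR >= 2, base-competition cutoff SR >= 5, enrichment q-cutoff 0.01,
#' structure resolution cutoff 3 angstroms.
#'
#' @param simulation A [simulation_config()].
#' @param orientation SR channel orientation (see [compute_sr()]).
#' @param sr_pacce PACCE RS-call threshold.
#' @param sr_base Base-competition call threshold.
#' @param q_cutoff Enrichment q-value cutoff.
#' @param resolution_max Structure resolution cutoff (angstroms).
#' @param score_threshold PSM score cutoff.
#' @param cap SR cap for singleton-channel records.
#' @param seed Run seed (overrides the simulation seed when given).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            orientation = "light_probe",
                            sr_pacce = 2, sr_base = 5, q_cutoff = 0.01,
                            resolution_max = 3.0, score_threshold = 600,
                            cap = 20, seed = NULL) {
  stopifnot(sr_pacce > 0, sr_base > 0, q_cutoff > 0, resolution_max > 0)
  if (!is.null(seed)) {
    simulation$seed <- as.integer(seed)
  }
  structure(list(simulation = simulation, orientation = orientation,
                 sr_pacce = sr_pacce, sr_base = sr_base,
                 q_cutoff = q_cutoff, resolution_max = resolution_max,
                 score_threshold = score_threshold, cap = cap),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key-value (TOML dialect) file
#'
#' Accepts flat `key = value` lines; `#` comments and `[section]` headers
#' are ignored (sections only group keys visually). Values may be numbers,
#' `true`/`false`, or quoted strings. Recognized keys are the arguments of
#' [pipeline_config()] and [simulation_config()].
#'
#' @param path Config file path.
#' @param seed Optional seed overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl('^".*"$', val) || grepl("^'.*'$", val)) {
      val <- substr(val, 2, nchar(val) - 1)
    } else if (val %in% c("true", "false")) {
      val <- identical(val, "true")
    } else if (grepl("^\\[", val)) {
      val <- as.numeric(strsplit(gsub("[][]", "", val), ",")[[1]])
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    kv[[key]] <- val
  }
  sim_args <- kv[names(kv) %in% names(formals(simulation_config))]
  pc_args <- kv[names(kv) %in% setdiff(names(formals(pipeline_config)),
                                       c("simulation", "seed"))]
  sim <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, c(list(simulation = sim, seed = seed), pc_args))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.provenance <- function(config) {
  list(config_hash = rlang::hash(unclass(config)),
       seed = config$simulation$seed,
       package = "paccer",
       version = as.character(utils::packageVersion("paccer")))
}

#' Run the full synthetic pipeline
#'
#' Stages: simulate -> quantify -> call -> enrich -> distance -> report.
#' Each stage writes TSV outputs into `outdir`; the run is summarized in
#' `summary.json` together with a provenance block (config hash, seed,
#' package version). Deterministic stages are byte-identical across reruns
#' with the same configuration.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory stage results and `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[paccer] ", ...)
  simc <- config$simulation

  # -- simulate ------------------------------------------------------------
  say("simulate: ", simc$n_proteins, " proteins, seed ", simc$seed)
  proteome <- generate_proteome(simc)
  psm <- generate_psm_table(proteome, simc)
  write_proteome_fasta(proteome, file.path(outdir, "proteome.fasta"))
  write_truth_table(proteome, file.path(outdir, "truth_sites.tsv"))
  .write_tsv(proteome$domains, file.path(outdir, "truth_domains.tsv"))
  .write_tsv(psm, file.path(outdir, "psm.tsv"))

  # -- quantify ------------------------------------------------------------
  psm_in <- read_psm_table(file.path(outdir, "psm.tsv"),
                           score_threshold = config$score_threshold)
  sq <- quantify_sites(psm_in, proteome, orientation = config$orientation,
                       cap = config$cap)
  write_site_quant(sq, file.path(outdir, "site_quant.tsv"))
  sel <- residue_selectivity(sq)
  .write_tsv(sel, file.path(outdir, "residue_selectivity.tsv"))
  say("quantify: ", nrow(sq$summary), " site x condition summaries")

  # -- call ----------------------------------------------------------------
  calls <- call_rs_cys(sq, sr_threshold = config$sr_pacce)
  .write_tsv(calls, file.path(outdir, "rs_calls.tsv"))
  say("call: ", sum(calls$rs_flag), " RS-Cys of ", nrow(calls), " sites")

  # -- enrich --------------------------------------------------------------
  site_bg <- unique(sq$summary[, c("protein_id", "site_key", "residue",
                                   "position")])
  rs_sites <- calls[calls$rs_flag, c("protein_id", "position"), drop = FALSE]
  enr <- if (nrow(rs_sites) > 0) {
    binomial_domain_enrichment(rs_sites,
                               site_bg[, c("protein_id", "position")],
                               proteome$domains, q_cutoff = config$q_cutoff)
  } else {
    NULL
  }
  if (!is.null(enr)) .write_tsv(enr, file.path(outdir, "enrichment.tsv"))
  rbp_ref <- proteome$proteins$protein_id[proteome$proteins$rbp_flag]
  detected <- unique(site_bg$protein_id)
  rs_prot <- unique(calls$protein_id[calls$rs_flag])
  overlap <- length(intersect(rs_prot, intersect(rbp_ref, detected)))
  overlap_p <- if (length(rs_prot) > 0) {
    hypergeometric_overlap(length(detected),
                           length(intersect(rbp_ref, detected)),
                           length(rs_prot), overlap)
  } else {
    NA_real_
  }
  say("enrich: ", if (is.null(enr)) 0 else sum(enr$enriched),
      " enriched domains; RBP overlap p = ", format(overlap_p))

  # -- distance ------------------------------------------------------------
  # plant a toy structure: RS sites near the RNA (~10 A), insensitive far
  # (~30 A); up to 6 proteins so chain ids stay single characters
  set.seed(simc$seed + 2L)
  calls_cys <- calls[calls$residue == "C", , drop = FALSE]
  prots <- utils::head(unique(calls_cys$protein_id), 6)
  chain_ids <- LETTERS[seq_along(prots)]
  planted <- do.call(rbind, lapply(seq_along(prots), function(i) {
    ci <- calls_cys[calls_cys$protein_id == prots[i], , drop = FALSE]
    ci <- utils::head(ci, 3)
    data.frame(chain = chain_ids[i], resnum = ci$position,
               target_distance = round(ifelse(ci$rs_flag,
                                              stats::runif(nrow(ci), 6, 14),
                                              stats::runif(nrow(ci), 25, 40)),
                                       3),
               stringsAsFactors = FALSE)
  }))
  dist_summary <- NULL
  annotated <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    pdb_text <- generate_toy_structure(planted,
                                       structure_id = "SYNTHETIC_RNP")
    writeLines(pdb_text, file.path(outdir, "structure_synthetic.pdb"))
    chain_map <- data.frame(structure_id = "SYNTHETIC_RNP",
                            chain_id = chain_ids, protein_id = prots,
                            stringsAsFactors = FALSE)
    .write_tsv(chain_map, file.path(outdir, "structure_chain_map.tsv"))
    model <- parse_structure(file.path(outdir, "structure_synthetic.pdb"),
                             structure_id = "SYNTHETIC_RNP")
    model <- renumber_to_reference(model, identity = TRUE)
    dists <- cys_rna_distances(model)
    annotated <- join_sites_to_structures(dists, calls, chain_map)
    .write_tsv(annotated, file.path(outdir, "distances.tsv"))
    dist_summary <- summarize_distance_by_class(annotated, proteome$domains)
    .write_tsv(dist_summary, file.path(outdir, "distance_summary.tsv"))
    say("distance: ", nrow(annotated), " site instances measured")
  }

  # -- report --------------------------------------------------------------
  summary <- list(
    provenance = .provenance(config),
    counts = list(
      n_proteins = nrow(proteome$proteins),
      n_psm = nrow(psm),
      n_sites = length(unique(paste(sq$summary$protein_id,
                                    sq$summary$site_key))),
      n_rs_cys = sum(calls$rs_flag),
      n_rs_proteins = length(rs_prot)),
    rbp_overlap = list(universe = length(detected),
                       rbp_in_universe = length(intersect(rbp_ref, detected)),
                       rs_proteins = length(rs_prot),
                       overlap = overlap, p_value = overlap_p),
    residue_selectivity = stats::setNames(as.list(sel$fraction),
                                          sel$residue),
    n_enriched_domains = if (is.null(enr)) 0L else sum(enr$enriched),
    distance_by_class = if (is.null(dist_summary)) NULL else
      stats::setNames(as.list(dist_summary$mean_distance),
                      dist_summary$class))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(outdir = outdir, proteome = proteome, psm = psm,
                 site_quant = sq, calls = calls, enrichment = enr,
                 distances = annotated, distance_summary = dist_summary,
                 summary = summary))
}

#' Render a human-readable report from a completed run directory
#'
#' Reads the stage TSVs and summary JSON written by [run_pipeline()] and
#' produces `report.txt` with RS-Cys counts, the fraction of RS proteins in
#' the RBP reference, the residue-selectivity table, and distance-by-class
#' means. Regeneration is idempotent. Missing stage outputs produce a
#' partial report with warnings.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @return The report text, invisibly; writes `report.txt` in `run_dir`.
#' @export
render_report <- function(run_dir) {
  p <- function(...) file.path(run_dir, ...)
  lines <- c("PACCE synthetic pipeline report",
             strrep("=", 31))
  if (file.exists(p("summary.json"))) {
    s <- jsonlite::read_json(p("summary.json"))
    lines <- c(lines,
               sprintf("config hash : %s", s$provenance$config_hash),
               sprintf("seed        : %s", s$provenance$seed),
               "",
               sprintf("proteins       : %d", s$counts$n_proteins),
               sprintf("PSM records    : %d", s$counts$n_psm),
               sprintf("quantified sites: %d", s$counts$n_sites),
               sprintf("RS-Cys sites   : %d", s$counts$n_rs_cys),
               sprintf("RS proteins    : %d", s$counts$n_rs_proteins),
               sprintf("RS/RBP overlap : %d of %d RBPs in universe (p = %s)",
                       s$rbp_overlap$overlap, s$rbp_overlap$rbp_in_universe,
                       format(s$rbp_overlap$p_value)))
  } else {
    warning("summary.json missing; partial report", call. = FALSE)
  }
  if (file.exists(p("residue_selectivity.tsv"))) {
    sel <- utils::read.delim(p("residue_selectivity.tsv"))
    lines <- c(lines, "", "residue selectivity:",
               sprintf("  %s  %5d  %.3f", sel$residue, sel$n_sites,
                       sel$fraction))
  }
  if (file.exists(p("distance_summary.tsv"))) {
    ds <- utils::read.delim(p("distance_summary.tsv"))
    lines <- c(lines, "", "mean Cys-RNA distance by class (angstroms):",
               sprintf("  %-12s n=%3d  %s", ds$class, ds$n,
                       ifelse(is.na(ds$mean_distance), "absent",
                              sprintf("%.1f", ds$mean_distance))))
  }
  writeLines(lines, p("report.txt"))
  invisible(paste(lines, collapse = "\n"))
}

#' Command-line entry point
#'
#' Subcommands: `run` (full synthetic pipeline), `simulate`, `report`.
#' `run`/`simulate` accept `--config` (key-value TOML-dialect file),
#' `--seed` and `--outdir`; `report` takes `--outdir`.
#'
#' @param args Character vector of CLI arguments (defaults to the command
#'   line).
#' @return Exit status 0, invisibly.
#' @export
pacce_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: pacce <run|simulate|report> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--outdir", type = "character",
                            default = "pacce_run"))),
    args = rest)
  config <- if (!is.null(opts$config)) {
    read_pipeline_config(opts$config, seed = opts$seed)
  } else {
    pipeline_config(seed = opts$seed)
  }
  switch(cmd,
    run = {
      run_pipeline(config, opts$outdir)
      render_report(opts$outdir)
    },
    simulate = {
      dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
      proteome <- generate_proteome(config$simulation)
      psm <- generate_psm_table(proteome, config$simulation)
      write_proteome_fasta(proteome, file.path(opts$outdir,
                                               "proteome.fasta"))
      write_truth_table(proteome, file.path(opts$outdir, "truth_sites.tsv"))
      .write_tsv(psm, file.path(opts$outdir, "psm.tsv"))
    },
    report = render_report(opts$outdir),
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
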