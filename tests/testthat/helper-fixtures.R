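# small in-code fixtures shared across test files

# a two-protein toy proteome as a named character vector
toy_proteome <- c(
  P1 = "MKCARLLCKDEK",
  P2 = "MAAKCARWWK"
)

# write a PSM TSV from a data.frame of partial columns, filling defaults
write_psm_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  defaults <- data.frame(
    peptide = "CAR", mod_index = 1L, mod_mass = 604.2637,
    protein_ids = "P1", intensity_light = 1000, intensity_heavy = 1000,
    replicate_id = "r1", condition = "pacce", score = 700,
    cleavage_class = "fully_tryptic", stringsAsFactors = FALSE)
  full <- defaults[rep(1, nrow(rows)), , drop = FALSE]
  for (nm in names(rows)) full[[nm]] <- rows[[nm]]
  write.table(full, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# build a site_quant object directly from per-replicate site SRs
site_quant_fixture <- function(pacce_srs, mixing_srs,
                               protein_id = "P1", site_key = "C3",
                               residue = NULL, position = NULL) {
  residue <- residue %||% substr(site_key, 1, 1)
  position <- position %||% as.integer(sub("^[A-Za-z]+", "", site_key))
  mk <- function(srs, cond, prefix) {
    if (length(srs) == 0) return(NULL)
    data.frame(protein_id = protein_id, site_key = site_key,
               residue = residue, position = position, condition = cond,
               replicate_id = sprintf("%s_%d", prefix, seq_along(srs)),
               sr = srs, n_forms = 1L, ambiguous = FALSE, capped = FALSE,
               stringsAsFactors = FALSE)
  }
  reps <- rbind(mk(pacce_srs, "pacce", "p"), mk(mixing_srs, "mixing", "m"))
  summ <- do.call(rbind, lapply(split(reps, reps$condition), function(g) {
    data.frame(protein_id = protein_id, site_key = site_key,
               residue = residue, position = position,
               condition = g$condition[1], mean_sr = mean(g$sr),
               n_replicates = nrow(g), ambiguous = FALSE, capped = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ), class = "site_quant")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: tail probability of U by brute-force enumeration of
# every assignment of pooled slots to the control group
oracle_mw_p <- function(treatment, control) {
  pooled <- c(treatment, control)
  n <- length(pooled)
  n_ctl <- length(control)
  u_obs <- sum(outer(treatment, control, ">"))
  sel <- combn(n, n_ctl)
  u_all <- apply(sel, 2, function(ctl_idx) {
    sum(outer(pooled[-ctl_idx], pooled[ctl_idx], ">"))
  })
  mean(u_all >= u_obs)
}

# brute-force minimum SG-to-RNA distance, independent of the engine
brute_force_min_distance <- function(model, chain, resnum) {
  a <- model$atoms
  rna_chains <- model$chains$chain_id[model$chains$molecule_type == "rna"]
  sg <- a[a$chain_id == chain & a$resnum == resnum & a$atom_name == "SG", ]
  rna <- a[a$chain_id %in% rna_chains, ]
  best <- Inf
  for (i in seq_len(nrow(rna))) {
    d <- sqrt(sum((c(sg$x[1], sg$y[1], sg$z[1]) -
                     c(rna$x[i], rna$y[i], rna$z[i]))^2))
    best <- min(best, d)
  }
  best
}
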