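.psm_required_cols <- c("peptide", "mod_index", "mod_mass", "protein_ids",
                        "intensity_light", "intensity_heavy", "replicate_id",
                        "condition", "score", "cleavage_class")

#' Read a PSM-level table of probe-modified peptides
#'
#' Reads the TSV schema (peptide, mod_index, mod_mass, protein_ids
#' [semicolon-separated], intensity_light, intensity_heavy, replicate_id,
#' condition, score, cleavage_class), applies the score cutoff (default
#' 600, a strict search-engine score threshold that reduces false-positive
#' identifications), rejects malformed rows with their line numbers, and
#' labels each modification mass against the known adduct constants within
#' 0.01 Da.
#'
#' @param path TSV file path.
#' @param score_threshold Keep rows with score at or above this value.
#' @param mass_tol Adduct-mass matching tolerance in Da.
#' @return data.frame of retained rows, with an added `adduct_label` column
#'   (cep_cys / ia_alkyne / d1..d4 / other). Rejected row numbers are
#'   reported via a message.
#' @export
read_psm_table <- function(path, score_threshold = 600, mass_tol = 0.01) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(.psm_required_cols, names(df))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    df$adduct_label <- character(0)
    return(df)
  }
  bad <- (!is.na(df$intensity_light) & df$intensity_light < 0) |
    (!is.na(df$intensity_heavy) & df$intensity_heavy < 0) |
    is.na(df$mod_index) | df$mod_index < 1 |
    df$mod_index > nchar(df$peptide) |
    (is.na(df$intensity_light) & is.na(df$intensity_heavy))
  if (any(bad)) {
    message(sum(bad), " malformed PSM row(s) rejected (data lines ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[df$score >= score_threshold, , drop = FALSE]
  df$adduct_label <- label_adduct(df$mod_mass, mass_tol)
  rownames(df) <- NULL
  df
}

#' Label a modification mass against the known adduct constants
#' @param mod_mass Numeric vector of modification masses (Da).
#' @param mass_tol Matching tolerance (Da).
#' @return Character vector of adduct labels, "other" when unmatched.
#' @export
label_adduct <- function(mod_mass, mass_tol = 0.01) {
  vapply(mod_mass, function(m) {
    if (is.na(m)) return("other")
    hit <- which(abs(adduct_masses - m) <= mass_tol)
    if (length(hit)) names(adduct_masses)[hit[1]] else "other"
  }, character(1))
}

#' Compute the SILAC ratio (SR) of a probe-modified peptide record
#'
#' SR = probe-only channel / competition channel under the configured
#' orientation. The default orientation `"light_probe"` treats the light
#' channel as probe-only and the heavy channel as competition (matching a
#' setup in which light cells receive probe alone and heavy cells are
#' co-treated with competitor). If the competition channel is absent or
#' zero while the probe channel is present, SR is set to `cap` and the
#' `capped` flag is raised; records lacking the probe channel are dropped
#' (SR = NA) with a logged reason.
#'
#' @param intensity_light,intensity_heavy Channel intensities (>= 0 or NA).
#' @param orientation "light_probe" or "heavy_probe".
#' @param cap Ratio assigned to singleton-channel records (default 20).
#' @return data.frame with columns `sr` and `capped`.
#' @export
compute_sr <- function(intensity_light, intensity_heavy,
                       orientation = c("light_probe", "heavy_probe"),
                       cap = 20) {
  orientation <- match.arg(orientation)
  if (all(is.na(intensity_light) & is.na(intensity_heavy))) {
    stop("undefined ratio: both channels absent", call. = FALSE)
  }
  probe <- if (orientation == "light_probe") intensity_light else
    intensity_heavy
  comp <- if (orientation == "light_probe") intensity_heavy else
    intensity_light
  probe_ok <- !is.na(probe) & probe > 0
  comp_ok <- !is.na(comp) & comp > 0
  sr <- rep(NA_real_, length(probe))
  capped <- rep(FALSE, length(probe))
  sr[probe_ok & comp_ok] <- probe[probe_ok & comp_ok] /
    comp[probe_ok & comp_ok]
  sr[probe_ok & !comp_ok] <- cap
  capped[probe_ok & !comp_ok] <- TRUE
  n_drop <- sum(!probe_ok)
  if (n_drop > 0) {
    message(n_drop, " record(s) dropped: probe-only channel absent")
  }
  data.frame(sr = sr, capped = capped)
}

#' Map a probe-modified peptide to protein-coordinate sites
#'
#' Locates the peptide by substring search in each listed protein and
#' converts the within-peptide modification index to a 1-based protein
#' coordinate. Peptides occurring at several offsets or shared between
#' several accessions yield one site per mapping, each flagged ambiguous.
#'
#' @param peptide Amino-acid string.
#' @param mod_index 1-based index of the modified residue in the peptide.
#' @param protein_ids Character vector of accessions (or one
#'   semicolon-separated string).
#' @param proteome Named character vector of protein sequences or a
#'   [Biostrings::AAStringSet].
#' @return data.frame (protein_id, residue, position, site_key, ambiguous).
#' @export
map_peptide_to_site <- function(peptide, mod_index, protein_ids, proteome) {
  if (inherits(proteome, "AAStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  ids <- unlist(strsplit(protein_ids, ";", fixed = TRUE))
  residue <- substr(peptide, mod_index, mod_index)
  rows <- list()
  for (id in ids) {
    seq <- proteome[[id]]
    if (is.null(seq)) next
    offs <- gregexpr(peptide, seq, fixed = TRUE)[[1]]
    if (offs[1] == -1) next
    for (o in offs) {
      pos <- (o - 1L) + mod_index
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, residue = residue, position = as.integer(pos),
        site_key = paste0(residue, pos), ambiguous = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    stop("unmapped peptide: '", peptide, "' not found in listed protein(s) ",
         paste(ids, collapse = ";"), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$ambiguous <- nrow(out) > 1
  out
}

# vectorized site mapping over a PSM table; returns psm rows replicated per
# mapping with site columns appended
.map_psms <- function(psm, proteome) {
  if (inherits(proteome, "AAStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  key <- paste(psm$peptide, psm$mod_index, psm$protein_ids, sep = "\r")
  uk <- !duplicated(key)
  maps <- lapply(which(uk), function(i) {
    m <- map_peptide_to_site(psm$peptide[i], psm$mod_index[i],
                             psm$protein_ids[i], proteome)
    m$.key <- key[i]
    m
  })
  maps <- do.call(rbind, maps)
  maps_by_key <- split(maps, maps$.key)
  counts <- vapply(maps_by_key, nrow, integer(1))[key]
  idx <- rep(seq_len(nrow(psm)), times = counts)
  site_rows <- do.call(rbind, maps_by_key[key])
  out <- cbind(psm[idx, , drop = FALSE],
               site_rows[, c("protein_id", "residue", "position",
                             "site_key", "ambiguous")])
  rownames(out) <- NULL
  out
}

#' Aggregate peptide-form ratios to site-level SILAC ratios
#'
#' Site-basis aggregation: within a replicate, the site SR is the median of
#' the SRs of all peptide forms covering the site (fully tryptic,
#' half-tryptic and missed cleavages combined; even-sized medians use the
#' midpoint of the two central values). Across replicates the summary
#' `mean_sr` is the arithmetic mean of the per-replicate medians.
#'
#' @param x data.frame with columns protein_id, site_key, residue, position,
#'   condition, replicate_id, sr (and optionally ambiguous, capped), i.e. a
#'   mapped PSM table with ratios attached.
#' @return Object of class `site_quant`: list with `replicates` (one row
#'   per site x condition x replicate: sr = median over forms, n_forms) and
#'   `summary` (one row per site x condition: mean_sr, n_replicates,
#'   ambiguous, capped).
#' @export
aggregate_site_sr <- function(x) {
  stopifnot(all(c("protein_id", "site_key", "condition", "replicate_id",
                  "sr") %in% names(x)))
  x <- x[!is.na(x$sr), , drop = FALSE]
  gkey <- interaction(x$protein_id, x$site_key, x$condition, x$replicate_id,
                      drop = TRUE, sep = "\r")
  reps <- do.call(rbind, lapply(split(x, gkey), function(g) {
    data.frame(protein_id = g$protein_id[1],
               site_key = g$site_key[1],
               residue = if ("residue" %in% names(g)) g$residue[1] else
                 substr(g$site_key[1], 1, 1),
               position = if ("position" %in% names(g)) g$position[1] else
                 as.integer(sub("^[A-Za-z]+", "", g$site_key[1])),
               condition = g$condition[1],
               replicate_id = g$replicate_id[1],
               sr = stats::median(g$sr),
               n_forms = nrow(g),
               ambiguous = if ("ambiguous" %in% names(g)) any(g$ambiguous)
                 else FALSE,
               capped = if ("capped" %in% names(g)) any(g$capped) else FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(reps) <- NULL
  skey <- interaction(reps$protein_id, reps$site_key, reps$condition,
                      drop = TRUE, sep = "\r")
  summ <- do.call(rbind, lapply(split(reps, skey), function(g) {
    data.frame(protein_id = g$protein_id[1], site_key = g$site_key[1],
               residue = g$residue[1], position = g$position[1],
               condition = g$condition[1],
               mean_sr = mean(g$sr), n_replicates = nrow(g),
               ambiguous = any(g$ambiguous), capped = any(g$capped),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ), class = "site_quant")
}

#' @export
print.site_quant <- function(x, ...) {
  cat(sprintf("site_quant: %d site x condition summaries (%d sites), %d replicate rows\n",
              nrow(x$summary),
              length(unique(paste(x$summary$protein_id, x$summary$site_key))),
              nrow(x$replicates)))
  invisible(x)
}

#' Quantify sites from a PSM table and a proteome
#'
#' Convenience chain: compute per-record SRs ([compute_sr()]), map peptides
#' to protein coordinates ([map_peptide_to_site()]), and aggregate to
#' site-level ratios ([aggregate_site_sr()]).
#'
#' @param psm PSM data.frame (as from [read_psm_table()] or
#'   [generate_psm_table()]).
#' @param proteome Named character vector, `AAStringSet`, or
#'   `synthetic_proteome`.
#' @inheritParams compute_sr
#' @return A `site_quant` object.
#' @export
quantify_sites <- function(psm, proteome,
                           orientation = c("light_probe", "heavy_probe"),
                           cap = 20) {
  orientation <- match.arg(orientation)
  if (inherits(proteome, "synthetic_proteome")) {
    proteome <- stats::setNames(proteome$proteins$sequence,
                                proteome$proteins$protein_id)
  }
  ratios <- compute_sr(psm$intensity_light, psm$intensity_heavy,
                       orientation, cap)
  psm$sr <- ratios$sr
  psm$capped <- ratios$capped
  psm <- psm[!is.na(psm$sr), , drop = FALSE]
  mapped <- .map_psms(psm, proteome)
  aggregate_site_sr(mapped)
}

#' Residue selectivity of probe modification
#'
#' Fraction of probe-modified sites assigned to each nucleophilic residue;
#' fractions sum to 1 over the observed residues. Useful to confirm the
#' probe's cysteine chemoselectivity (a cysteine-directed electrophile
#' should put the bulk of its sites on C).
#'
#' @param sites data.frame with a `residue` column (e.g. a `site_quant`
#'   summary, deduplicated by site), or a `site_quant` object.
#' @return data.frame (residue, n_sites, fraction), sorted by fraction.
#' @export
residue_selectivity <- function(sites) {
  if (inherits(sites, "site_quant")) sites <- sites$summary
  if (nrow(sites) == 0) {
    return(data.frame(residue = character(0), n_sites = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  u <- unique(sites[, c("protein_id", "site_key", "residue")])
  tab <- table(factor(u$residue, levels = nucleophilic_residues))
  tab <- tab[tab > 0]
  out <- data.frame(residue = names(tab), n_sites = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$fraction), , drop = FALSE]
}

#' Write a site-quant object as TSV
#'
#' The summary table is written with the per-replicate SRs serialized into
#' a JSON column.
#'
#' @param sq A `site_quant`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_quant <- function(sq, path) {
  summ <- sq$summary
  rep_json <- vapply(seq_len(nrow(summ)), function(i) {
    r <- sq$replicates[sq$replicates$protein_id == summ$protein_id[i] &
                         sq$replicates$site_key == summ$site_key[i] &
                         sq$replicates$condition == summ$condition[i], ,
                       drop = FALSE]
    as.character(jsonlite::toJSON(stats::setNames(
      round(r$sr, 6), r$replicate_id), auto_unbox = FALSE))
  }, character(1))
  summ$replicate_srs <- rep_json
  utils::write.table(summ, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
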