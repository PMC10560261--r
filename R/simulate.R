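#' Simulation configuration for the synthetic PACCE world
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' reproduce the study design of a PACCE experiment: n = 3 biologically
#' independent replicates for the 1:1 mixing control and n = 6 independent
#' replicates for the competition (PACCE) condition, with planted
#' competition factors spanning the SR >= 2 call threshold.
#'
#' @param n_proteins Number of synthetic proteins to generate.
#' @param n_mix_replicates Replicates of the 1:1 mixing control (default 3).
#' @param n_pacce_replicates Replicates of the PACCE condition (default 6).
#' @param noise_cv Coefficient of variation of the lognormal MS1 intensity
#'   noise (0 = noise free).
#' @param half_tryptic_rate Probability that a cysteine-covering fully
#'   tryptic peptide also yields a half-tryptic form.
#' @param max_missed_cleavages Maximum missed cleavages in the digest
#'   (default 2, matching a standard search configuration).
#' @param rs_fraction Fraction of cysteines planted as RNA-sensitive.
#' @param noncys_rate Fraction of *planted* modified sites assigned to
#'   non-cysteine nucleophilic residues (exercises residue-selectivity
#'   reporting; default 0.28, i.e. ~72% of planted sites are cysteines —
#'   ambiguous mappings of short peptides can shift the observed fraction).
#' @param competition_range Range (min, max) of the uniform distribution the
#'   planted competition factors are drawn from (default c(2, 20)).
#' @param rnase_mode If TRUE, emulate the RNase pre-treatment control:
#'   every competition factor is forced to 1 (no RNA crosslinking left to
#'   compete with the probe).
#' @param rbp_fraction Fraction of proteins flagged as reference RBPs.
#' @param seed Integer seed; all generator output is deterministic given it.
#'
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_proteins = 50,
                              n_mix_replicates = 3,
                              n_pacce_replicates = 6,
                              noise_cv = 0.2,
                              half_tryptic_rate = 0.25,
                              max_missed_cleavages = 2,
                              rs_fraction = 0.4,
                              noncys_rate = 0.28,
                              competition_range = c(2, 20),
                              rnase_mode = FALSE,
                              rbp_fraction = 0.37,
                              seed = 1L) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1 ||
      is.na(n_proteins) || n_proteins < 1) {
    stop("invalid config: `n_proteins` must be a positive count",
         call. = FALSE)
  }
  stopifnot(n_mix_replicates >= 1, n_pacce_replicates >= 1,
            noise_cv >= 0, half_tryptic_rate >= 0, half_tryptic_rate <= 1,
            max_missed_cleavages >= 0,
            rs_fraction >= 0, rs_fraction <= 1,
            noncys_rate >= 0, noncys_rate < 1,
            length(competition_range) == 2,
            competition_range[1] >= 1,
            competition_range[2] >= competition_range[1])
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_mix_replicates = as.integer(n_mix_replicates),
    n_pacce_replicates = as.integer(n_pacce_replicates),
    noise_cv = noise_cv,
    half_tryptic_rate = half_tryptic_rate,
    max_missed_cleavages = as.integer(max_missed_cleavages),
    rs_fraction = rs_fraction,
    noncys_rate = noncys_rate,
    competition_range = as.numeric(competition_range),
    rnase_mode = isTRUE(rnase_mode),
    rbp_fraction = rbp_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# background amino-acid frequencies, roughly human proteome-like
.aa_freq <- local({
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 1.0, E = 7.1, Q = 4.8,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
         P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)
  f / sum(f)
})

#' Generate a ground-truth synthetic proteome
#'
#' Draws `n_proteins` random amino-acid sequences, guarantees each carries
#' at least one cysteine, plants a configurable fraction of cysteines as
#' RNA-sensitive (RS) with competition factors drawn uniformly from
#' `competition_range`, and attaches domain annotations (RBD names on
#' RBP-flagged proteins). Output is byte-identical for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_proteome`: a list with data frames
#'   `proteins` (protein_id, sequence, length, rbp_flag), `cys_sites`
#'   (protein_id, position, rs_flag, competition_factor) and `domains`
#'   (protein_id, domain_name, category, start, end), plus the `config`.
#' @export
generate_proteome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("SYN%04d", seq_len(n))
  lens <- sample(80:400, n, replace = TRUE)
  sequences <- vapply(lens, function(L) {
    paste(sample(names(.aa_freq), L, replace = TRUE, prob = .aa_freq),
          collapse = "")
  }, character(1))

  # guarantee >= 1 Cys per protein by planting extra cysteines
  cys_rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- strsplit(sequences[i], "")[[1]]
    n_extra <- max(1L, stats::rpois(1, lens[i] / 100))
    pool <- setdiff(seq_along(s), which(s == "C"))
    plant <- sample(pool, min(n_extra, length(pool)))
    s[plant] <- "C"
    sequences[i] <- paste(s, collapse = "")
    pos <- which(s == "C")
    cys_rows[[i]] <- data.frame(protein_id = ids[i], position = pos,
                                stringsAsFactors = FALSE)
  }
  cys <- do.call(rbind, cys_rows)
  cys$rs_flag <- stats::runif(nrow(cys)) < config$rs_fraction
  cys$competition_factor <- ifelse(
    cys$rs_flag,
    stats::runif(nrow(cys), config$competition_range[1],
                 config$competition_range[2]),
    1.0)
  if (config$rnase_mode) {
    # RNase control: RNA is degraded before crosslinking, nothing competes
    cys$competition_factor <- 1.0
  }

  rbp_flag <- stats::runif(n) < config$rbp_fraction
  other_domains <- c("Pkinase", "WD40", "Ank", "zf-C2H2", "SH3", "PDZ")
  dom_rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(1:3, 1)
    pool <- if (rbp_flag[i]) c(rbd_domain_names, other_domains) else
      other_domains
    names_i <- sample(pool, k)
    # carve k non-overlapping spans
    cuts <- sort(sample(seq_len(lens[i] - 1), 2 * k))
    dom_rows[[i]] <- data.frame(
      protein_id = ids[i],
      domain_name = names_i,
      category = ifelse(names_i %in% rbd_domain_names, "RBD", "other"),
      start = cuts[seq(1, 2 * k, by = 2)],
      end = cuts[seq(2, 2 * k, by = 2)],
      stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, dom_rows)

  structure(list(
    proteins = data.frame(protein_id = ids, sequence = sequences,
                          length = nchar(sequences), rbp_flag = rbp_flag,
                          stringsAsFactors = FALSE),
    cys_sites = cys,
    domains = domains,
    config = config
  ), class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf(
    "synthetic_proteome: %d proteins, %d Cys sites (%d RS), %d domains\n",
    nrow(x$proteins), nrow(x$cys_sites), sum(x$cys_sites$rs_flag),
    nrow(x$domains)))
  invisible(x)
}

# positions after which trypsin cuts: K/R not followed by P
.cleavage_points <- function(seq_chars) {
  L <- length(seq_chars)
  kr <- which(seq_chars %in% c("K", "R"))
  kr[kr == L | seq_chars[pmin(kr + 1L, L)] != "P"]
}

#' In-silico tryptic digest of one protein
#'
#' Cuts after K/R (never before P), emits all fully tryptic peptides, all
#' missed-cleavage forms up to `max_missed_cleavages`, and, for each
#' cysteine-covering fully tryptic peptide, a half-tryptic form with one
#' non-tryptic terminus at probability `half_tryptic_rate` (uses the
#' current RNG stream). Every cysteine is covered by at least one form.
#'
#' @param truth A `synthetic_proteome` protein entry (any list with a
#'   `sequence` field) or a plain amino-acid string.
#' @param config A [simulation_config()].
#' @return data.frame with columns peptide, start, end, cleavage_class
#'   (fully_tryptic / missed_cleavage / half_tryptic) and n_missed.
#' @export
digest_protein <- function(truth, config = simulation_config()) {
  sequence <- if (is.character(truth)) truth else truth$sequence
  stopifnot(is.character(sequence), length(sequence) == 1,
            nchar(sequence) > 0)
  s <- strsplit(sequence, "")[[1]]
  cuts <- c(0L, .cleavage_points(s), length(s))
  cuts <- unique(cuts)
  nseg <- length(cuts) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (mc in 0:min(config$max_missed_cleavages, nseg - i)) {
      st <- cuts[i] + 1L
      en <- cuts[i + 1L + mc]
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, st, en), start = st, end = en,
        cleavage_class = if (mc == 0) "fully_tryptic" else "missed_cleavage",
        n_missed = mc, stringsAsFactors = FALSE)
    }
  }
  forms <- do.call(rbind, out)

  # stochastic half-tryptic forms at Cys-covering fully tryptic peptides
  if (config$half_tryptic_rate > 0) {
    cys_pos <- which(s == "C")
    ft <- forms[forms$cleavage_class == "fully_tryptic", , drop = FALSE]
    ht <- list()
    for (j in seq_len(nrow(ft))) {
      covered <- cys_pos[cys_pos >= ft$start[j] & cys_pos <= ft$end[j]]
      if (length(covered) == 0 || ft$end[j] - ft$start[j] < 2) next
      if (stats::runif(1) >= config$half_tryptic_rate) next
      cpos <- covered[1]
      # trim residues off one terminus, keeping the Cys inside
      can_n <- cpos > ft$start[j]
      can_c <- cpos < ft$end[j]
      from_n <- if (can_n && can_c) stats::runif(1) < 0.5 else can_n
      if (from_n) {
        st <- ft$start[j] + sample.int(cpos - ft$start[j], 1)
        en <- ft$end[j]
      } else {
        st <- ft$start[j]
        en <- ft$end[j] - sample.int(ft$end[j] - cpos, 1)
      }
      ht[[length(ht) + 1L]] <- data.frame(
        peptide = substr(sequence, st, en), start = st, end = en,
        cleavage_class = "half_tryptic", n_missed = NA_integer_,
        stringsAsFactors = FALSE)
    }
    if (length(ht)) forms <- rbind(forms, do.call(rbind, ht))
  }
  rownames(forms) <- NULL
  forms
}

# lognormal multiplier with coefficient of variation cv (mean on log scale 0)
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))
}

#' Generate a synthetic PSM table with planted competition effects
#'
#' For every cysteine of the proteome, each covering peptide form receives
#' one record per replicate and condition. Channel intensities are drawn
#' lognormally around a per-form base intensity; in the PACCE condition the
#' competition (heavy) channel is divided by the site's planted competition
#' factor, while in the 1:1 mixing condition both channels share the same
#' mean. A configurable minority of additional records carries non-cysteine
#' residue assignments so residue-selectivity reporting can be exercised.
#'
#' @param proteome A [generate_proteome()] result.
#' @param config A [simulation_config()]; defaults to the proteome's own.
#' @return data.frame in the PSM table schema: peptide, mod_index, mod_mass,
#'   protein_ids, intensity_light, intensity_heavy, replicate_id, condition,
#'   score, cleavage_class.
#' @export
generate_psm_table <- function(proteome, config = proteome$config) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  set.seed(config$seed + 1L)
  reps <- c(sprintf("mix_%d", seq_len(config$n_mix_replicates)),
            sprintf("pacce_%d", seq_len(config$n_pacce_replicates)))
  conds <- c(rep("mixing", config$n_mix_replicates),
             rep("pacce", config$n_pacce_replicates))

  recs <- list()
  emit_site <- function(protein_id, forms, pos, factor_, residue) {
    cover <- forms[forms$start <= pos & forms$end >= pos, , drop = FALSE]
    if (nrow(cover) > 4) cover <- cover[seq_len(4), , drop = FALSE]
    base <- 10^stats::runif(nrow(cover), 5, 7)
    for (j in seq_len(nrow(cover))) {
      nl <- .ln_noise(length(reps), config$noise_cv)
      nh <- .ln_noise(length(reps), config$noise_cv)
      light <- base[j] * nl
      heavy <- base[j] * nh
      heavy[conds == "pacce"] <- heavy[conds == "pacce"] / factor_
      recs[[length(recs) + 1L]] <<- data.frame(
        peptide = cover$peptide[j],
        mod_index = pos - cover$start[j] + 1L,
        mod_mass = adduct_masses[["cep_cys"]],
        protein_ids = protein_id,
        intensity_light = light,
        intensity_heavy = heavy,
        replicate_id = reps,
        condition = conds,
        score = stats::runif(length(reps), 600, 1000),
        cleavage_class = cover$cleavage_class[j],
        stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(nrow(proteome$proteins))) {
    p <- proteome$proteins[i, ]
    forms <- digest_protein(p$sequence, config)
    cys_i <- proteome$cys_sites[proteome$cys_sites$protein_id ==
                                  p$protein_id, , drop = FALSE]
    for (k in seq_len(nrow(cys_i))) {
      emit_site(p$protein_id, forms, cys_i$position[k],
                cys_i$competition_factor[k], "C")
    }
    # planted non-Cys assignments: insensitive sites on other nucleophiles
    n_noncys <- stats::rbinom(1, nrow(cys_i),
                              config$noncys_rate / (1 - config$noncys_rate))
    if (n_noncys > 0) {
      s <- strsplit(p$sequence, "")[[1]]
      cand <- which(s %in% setdiff(nucleophilic_residues, "C"))
      cand <- setdiff(cand, cys_i$position)
      if (length(cand)) {
        for (pos in sample(cand, min(n_noncys, length(cand)))) {
          emit_site(p$protein_id, forms, pos, 1.0, s[pos])
        }
      }
    }
  }
  psm <- do.call(rbind, recs)
  rownames(psm) <- NULL
  psm
}

#' Write the proteome as FASTA
#' @param proteome A `synthetic_proteome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$proteins$sequence)
  names(aa) <- proteome$proteins$protein_id
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Write the per-cysteine ground-truth table as TSV
#' @inheritParams write_proteome_fasta
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(proteome, path) {
  utils::write.table(proteome$cys_sites, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
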