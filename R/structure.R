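#' Generate a toy protein-RNA structure with planted minimum distances
#'
#' Emits PDB-format text containing one or more protein chains whose
#' cysteine residues carry SG atoms, plus one RNA chain (residue names
#' A/U/G/C with O2' atoms). For each planted site the nearest RNA atom is
#' an O2' placed exactly `target_distance` angstroms from the SG along the
#' x axis; every other atom is farther, so the planted minimum is
#' unambiguous. Sites are spaced 200 A apart, which keeps coordinates
#' inside the fixed-width PDB field; target distances above 99 A are
#' rejected (they could collide with a neighboring site's RNA). Coordinates are written at the format's 0.001 A precision, so
#' plant distances with at most three decimals for exact round-trips.
#'
#' @param planted data.frame with columns `chain`, `resnum`,
#'   `target_distance` (angstroms, > 0). May have zero rows, producing a
#'   valid file with no cysteine sites.
#' @param structure_id Identifier written to the HEADER line.
#' @param resolution Nominal resolution written to the REMARK 2 record.
#' @return A single character scalar of PDB-format text.
#' @export
generate_toy_structure <- function(planted,
                                   structure_id = "TOYS",
                                   resolution = 2.0) {
  planted <- as.data.frame(planted)
  if (nrow(planted) > 0) {
    stopifnot(all(c("chain", "resnum", "target_distance") %in%
                    names(planted)))
    if (anyDuplicated(planted[, c("chain", "resnum")])) {
      stop("invalid plant: duplicate (chain, resnum) entries", call. = FALSE)
    }
    if (any(planted$target_distance <= 0)) {
      stop("invalid plant: target_distance must be > 0", call. = FALSE)
    }
    if (any(planted$target_distance > 99)) {
      stop("invalid plant: target_distance above 99 A exceeds the toy layout",
           call. = FALSE)
    }
  }
  lines <- c(
    sprintf("HEADER    SYNTHETIC RNP FIXTURE                   01-JAN-26   %s",
            substr(paste0(structure_id, "    "), 1, 4)),
    sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", resolution))
  serial <- 0L
  atom_line <- function(name, resname, chain, resnum, x, y, z,
                        occ = 1, b = 0, element = substr(name, 1, 1)) {
    serial <<- serial + 1L
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, nm, resname, chain, resnum, x, y, z, occ, b, element)
  }
  rna_chain <- "X"
  if (nrow(planted) > 0 && rna_chain %in% planted$chain) rna_chain <- "Z"
  prot <- character(0)
  rna <- character(0)
  for (i in seq_len(nrow(planted))) {
    off <- (i - 1) * 200
    d <- round(planted$target_distance[i], 3)
    ch <- as.character(planted$chain[i])
    rn <- as.integer(planted$resnum[i])
    prot <- c(prot,
              atom_line("N",  "CYS", ch, rn, off - 2.5, 1.2, 0.0),
              atom_line("CA", "CYS", ch, rn, off - 1.8, 0.4, 0.0, element = "C"),
              atom_line("CB", "CYS", ch, rn, off - 1.0, 0.8, 1.0, element = "C"),
              atom_line("SG", "CYS", ch, rn, off, 0.0, 0.0, element = "S"))
    base <- .rna_resnames[((i - 1) %% 4) + 1]
    rna <- c(rna,
             atom_line("O2'", base, rna_chain, i, off + d, 0.0, 0.0),
             atom_line("C1'", base, rna_chain, i, off + d + 7, 3.0, 0.0,
                       element = "C"),
             atom_line("P",   base, rna_chain, i, off + d + 9, -4.0, 2.0))
  }
  if (nrow(planted) == 0) {
    # still a valid coordinate file: a lone RNA residue, zero Cys sites
    rna <- c(atom_line("O2'", "A", rna_chain, 1, 0, 0, 0),
             atom_line("C1'", "A", rna_chain, 1, 1.5, 0, 0, element = "C"))
  }
  paste(c(lines, prot, "TER", rna, "TER", "END", ""), collapse = "\n")
}

.parse_pdb_atoms <- function(pdb_lines) {
  rec <- substr(pdb_lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  # multi-model files: keep the first model only
  model_starts <- grep("^MODEL ", pdb_lines)
  if (length(model_starts) > 1) {
    end1 <- grep("^ENDMDL", pdb_lines)[1]
    if (!is.na(end1)) is_atom[seq_along(pdb_lines) > end1] <- FALSE
  }
  ln <- pdb_lines[is_atom]
  if (length(ln) == 0) stop("parse error: no coordinate records", call. = FALSE)
  f <- function(a, b) trimws(substr(ln, a, b))
  data.frame(
    line = which(is_atom),
    record = trimws(rec[is_atom]),
    serial = as.integer(f(7, 11)),
    atom_name = f(13, 16),
    altloc = substr(ln, 17, 17),
    resname = f(18, 20),
    chain_id = substr(ln, 22, 22),
    resnum = as.integer(f(23, 26)),
    icode = substr(ln, 27, 27),
    x = as.numeric(f(31, 38)),
    y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    element = toupper(f(77, 78)),
    stringsAsFactors = FALSE)
}

#' Classify a chain as protein, RNA, DNA or other
#'
#' Composition rule: RNA if at least half of the residue names are
#' A/U/G/C *and* the chain has at least one O2' atom (robust to modified
#' nucleotides and to DNA mimics); DNA if at least half are DA/DT/DG/DC;
#' protein if at least half are standard amino acids; otherwise other.
#'
#' @param chain_atoms data.frame of the chain's atoms (as in a
#'   `structure_model`'s `atoms` slot).
#' @return One of "protein", "rna", "dna", "other".
#' @export
classify_chain <- function(chain_atoms) {
  res <- unique(chain_atoms[, c("resnum", "icode", "resname")])
  nm <- res$resname
  frac <- function(set) mean(nm %in% set)
  if (frac(.rna_resnames) >= 0.5 &&
      any(chain_atoms$atom_name %in% c("O2'", "O2*"))) return("rna")
  if (frac(.dna_resnames) >= 0.5) return("dna")
  if (frac(.aa3) >= 0.5) return("protein")
  "other"
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records. Only the first model of a multi-model file is
#' kept; alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by file order). Resolution is taken from the
#' REMARK 2 header when present, else from the `resolution` argument.
#'
#' @param pdb Path to a PDB file, or PDB-format text (single string or
#'   character vector of lines).
#' @param structure_id Identifier to attach; defaults to the file base name
#'   or the HEADER id.
#' @param resolution Resolution (angstroms) if not present in the header.
#' @return Object of class `structure_model`: list with `structure_id`,
#'   `resolution`, `atoms` (one row per retained atom, with a `ref_resnum`
#'   column initialized to the author numbering only after
#'   [renumber_to_reference()]) and `chains` (chain_id, molecule_type,
#'   n_residues).
#' @export
parse_structure <- function(pdb, structure_id = NULL, resolution = NA_real_) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    if (is.null(structure_id)) {
      structure_id <- tools::file_path_sans_ext(basename(pdb))
    }
    pdb_lines <- readLines(pdb)
  } else {
    pdb_lines <- if (length(pdb) == 1) strsplit(pdb, "\n")[[1]] else pdb
  }
  atoms <- .parse_pdb_atoms(pdb_lines)

  hdr <- pdb_lines[startsWith(pdb_lines, "HEADER")]
  if (is.null(structure_id)) {
    structure_id <- if (length(hdr)) trimws(substr(hdr[1], 63, 66)) else
      "structure"
    if (!nzchar(structure_id)) structure_id <- "structure"
  }
  rem2 <- grep("^REMARK   2 RESOLUTION", pdb_lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1],
                    regexpr("RESOLUTION\\.\\s*[0-9.]+", rem2[1]))
    if (length(m)) {
      resolution <- as.numeric(sub("RESOLUTION\\.\\s*", "", m))
    }
  }

  # resolve altlocs: within (chain, resnum, icode, atom_name) keep the
  # highest-occupancy record, first on ties
  key <- paste(atoms$chain_id, atoms$resnum, atoms$icode, atoms$atom_name,
               sep = "\r")
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(atoms$occupancy), 1, atoms$occupancy)
    keep <- !duplicated(key[order(-occ, atoms$line)])
    keep_idx <- sort(order(-occ, atoms$line)[keep])
    atoms <- atoms[keep_idx, , drop = FALSE]
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("parse error: non-finite atom coordinates", call. = FALSE)
  }
  atoms$ref_resnum <- NA_integer_
  rownames(atoms) <- NULL

  chains <- do.call(rbind, lapply(split(atoms, atoms$chain_id), function(a) {
    data.frame(chain_id = a$chain_id[1],
               molecule_type = classify_chain(a),
               n_residues = nrow(unique(a[, c("resnum", "icode")])),
               stringsAsFactors = FALSE)
  }))
  rownames(chains) <- NULL
  structure(list(structure_id = structure_id, resolution = resolution,
                 atoms = atoms, chains = chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model %s: %d atoms, %d chains (%s), resolution %s\n",
              x$structure_id, nrow(x$atoms), nrow(x$chains),
              paste(sprintf("%s:%s", x$chains$chain_id,
                            x$chains$molecule_type), collapse = ", "),
              ifelse(is.na(x$resolution), "NA", format(x$resolution))))
  invisible(x)
}

#' Filter structures by resolution and an exclusion list
#'
#' @param models List of `structure_model` objects.
#' @param resolution_max Keep structures with resolution at or below this
#'   threshold (default 3 angstroms); structures with unknown resolution
#'   are kept.
#' @param exclude Character vector of structure_ids to drop (manual
#'   removals, e.g. structures with unnatural RNA).
#' @return Filtered list.
#' @export
filter_structures <- function(models, resolution_max = 3.0,
                              exclude = character(0)) {
  keep <- vapply(models, function(m) {
    !(m$structure_id %in% exclude) &&
      (is.na(m$resolution) || m$resolution <= resolution_max)
  }, logical(1))
  models[keep]
}

#' Renumber author residue numbers to reference (UniProt) coordinates
#'
#' Applies a mapping table of (structure_id, chain_id, author_number,
#' reference_number) rows, filling the model's `ref_resnum` column.
#' Residues without a mapping keep `ref_resnum = NA` and are excluded from
#' site joins downstream. `identity = TRUE` copies author numbers through,
#' which is the right fallback for synthetic fixtures.
#'
#' @param model A `structure_model`.
#' @param mapping data.frame with columns structure_id (optional), chain_id,
#'   author_number, reference_number. Ignored when `identity = TRUE`.
#' @param identity Use the identity mapping.
#' @return The model with `ref_resnum` filled where mapped.
#' @export
renumber_to_reference <- function(model, mapping = NULL, identity = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (identity) {
    model$atoms$ref_resnum <- model$atoms$resnum
    return(model)
  }
  stopifnot(is.data.frame(mapping),
            all(c("chain_id", "author_number", "reference_number") %in%
                  names(mapping)))
  if ("structure_id" %in% names(mapping)) {
    mapping <- mapping[mapping$structure_id == model$structure_id, ,
                       drop = FALSE]
  }
  key <- paste(mapping$chain_id, mapping$author_number, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    conflicting <- vapply(dup, function(k) {
      length(unique(mapping$reference_number[key == k])) > 1
    }, logical(1))
    if (any(conflicting)) {
      stop("conflicting duplicate renumbering mappings", call. = FALSE)
    }
    mapping <- mapping[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  akey <- paste(model$atoms$chain_id, model$atoms$resnum, sep = "\r")
  idx <- match(akey, key)
  model$atoms$ref_resnum <- as.integer(mapping$reference_number[idx])
  model
}

.rna_atoms <- function(model, include_hydrogens = TRUE) {
  rna_chains <- model$chains$chain_id[model$chains$molecule_type == "rna"]
  a <- model$atoms[model$atoms$chain_id %in% rna_chains, , drop = FALSE]
  if (!include_hydrogens) a <- a[a$element != "H", , drop = FALSE]
  a
}

#' Minimum cysteine-SG-to-RNA distance for one site
#'
#' For each instance (copy across chains) of the cysteine identified by its
#' reference residue number, computes the minimum Euclidean distance
#' sqrt(dx^2 + dy^2 + dz^2) from the SG atom to any atom of any RNA chain.
#' All instances are emitted as separate rows.
#'
#' @param model A renumbered `structure_model`.
#' @param chain_id Restrict to one protein chain; NULL = all protein chains.
#' @param ref_resnum Reference residue number of the cysteine; NULL = every
#'   cysteine with an SG atom.
#' @param include_hydrogens Include RNA hydrogens if present in the file.
#' @return data.frame with columns structure_id, chain_id, ref_resnum,
#'   site_key, instance_index, distance. Cysteines lacking an SG atom are
#'   skipped; the skipped table is attached as attribute "skipped".
#' @export
min_cys_rna_distance <- function(model, chain_id = NULL, ref_resnum = NULL,
                                 include_hydrogens = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  rna <- .rna_atoms(model, include_hydrogens)
  if (nrow(rna) == 0) stop("no RNA chain in structure", call. = FALSE)
  prot_chains <- model$chains$chain_id[model$chains$molecule_type == "protein"]
  a <- model$atoms
  cys <- a[a$chain_id %in% prot_chains & a$resname == "CYS" &
             !is.na(a$ref_resnum), , drop = FALSE]
  if (!is.null(chain_id)) cys <- cys[cys$chain_id %in% chain_id, , drop = FALSE]
  if (!is.null(ref_resnum)) {
    cys <- cys[cys$ref_resnum %in% ref_resnum, , drop = FALSE]
  }
  inst <- unique(cys[, c("chain_id", "resnum", "ref_resnum")])
  inst <- inst[order(inst$ref_resnum, inst$chain_id, inst$resnum), ,
               drop = FALSE]
  rows <- list()
  skipped <- list()
  counter <- list()
  for (i in seq_len(nrow(inst))) {
    sg <- cys[cys$chain_id == inst$chain_id[i] &
                cys$resnum == inst$resnum[i] & cys$atom_name == "SG", ,
              drop = FALSE]
    key <- as.character(inst$ref_resnum[i])
    if (nrow(sg) == 0) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        chain_id = inst$chain_id[i], ref_resnum = inst$ref_resnum[i],
        reason = "no SG atom (unresolved side chain)",
        stringsAsFactors = FALSE)
      next
    }
    counter[[key]] <- (counter[[key]] %||% 0L) + 1L
    d <- sqrt((rna$x - sg$x[1])^2 + (rna$y - sg$y[1])^2 +
                (rna$z - sg$z[1])^2)
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = model$structure_id,
      chain_id = inst$chain_id[i],
      ref_resnum = inst$ref_resnum[i],
      site_key = paste0("C", inst$ref_resnum[i]),
      instance_index = counter[[key]],
      distance = min(d),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    structure_id = character(0), chain_id = character(0),
    ref_resnum = integer(0), site_key = character(0),
    instance_index = integer(0), distance = numeric(0),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All cysteine-RNA distances in a structure
#'
#' Convenience wrapper over [min_cys_rna_distance()] covering every
#' cysteine (with an SG atom and a reference number) in every protein
#' chain.
#'
#' @inheritParams min_cys_rna_distance
#' @return See [min_cys_rna_distance()].
#' @export
cys_rna_distances <- function(model, include_hydrogens = TRUE) {
  min_cys_rna_distance(model, include_hydrogens = include_hydrogens)
}

#' Attach RS-Cys status to distance records
#'
#' Matches distance records to RS-Cys calls via a chain-to-protein map and
#' the site key. Sites quantified and flagged RS become "rs", quantified
#' but unflagged become "insensitive", and structure cysteines never
#' quantified become "not_quantified".
#'
#' @param distance_records Output of [min_cys_rna_distance()].
#' @param rs_calls Output of [call_rs_cys()] (needs protein_id, site_key,
#'   rs_flag).
#' @param chain_map data.frame (structure_id, chain_id, protein_id) mapping
#'   structure chains to protein accessions; NULL matches on site_key only.
#' @return The distance records with `protein_id` and `rs_status` columns.
#' @export
join_sites_to_structures <- function(distance_records, rs_calls,
                                     chain_map = NULL) {
  d <- distance_records
  if (!is.null(chain_map)) {
    idx <- match(paste(d$structure_id, d$chain_id),
                 paste(chain_map$structure_id, chain_map$chain_id))
    d$protein_id <- chain_map$protein_id[idx]
    call_key <- paste(rs_calls$protein_id, rs_calls$site_key)
    hit <- match(paste(d$protein_id, d$site_key), call_key)
  } else {
    d$protein_id <- NA_character_
    hit <- match(d$site_key, rs_calls$site_key)
  }
  d$rs_status <- ifelse(is.na(hit), "not_quantified",
                        ifelse(rs_calls$rs_flag[hit], "rs", "insensitive"))
  d
}

#' Mean cysteine-RNA distance by RS class
#'
#' Collapses multi-instance records to one headline distance per site (the
#' minimum across instances) and reports arithmetic mean distances with
#' counts for the classes: all sites, RS sites, RS sites inside annotated
#' RNA-binding domains, and RNA-insensitive sites. Empty classes are
#' reported with `n = 0` and `mean_distance = NA` (absent, not zero).
#'
#' @param annotated Output of [join_sites_to_structures()].
#' @param rbd_annotations Optional domain annotation data.frame
#'   (protein_id, domain_name, category, start, end); rows with
#'   category "RBD" or a domain name in `rbd_names` define RBD spans.
#' @param rbd_names Domain names counted as RBDs.
#' @return data.frame (class, n, mean_distance).
#' @export
summarize_distance_by_class <- function(annotated, rbd_annotations = NULL,
                                        rbd_names = rbd_domain_names) {
  stopifnot(nrow(annotated) > 0)
  key <- paste(annotated$structure_id, annotated$protein_id,
               annotated$site_key)
  head_d <- tapply(annotated$distance, key, min)
  first <- annotated[!duplicated(key), , drop = FALSE]
  first <- first[order(paste(first$structure_id, first$protein_id,
                             first$site_key)), , drop = FALSE]
  first$headline <- as.numeric(head_d[sort(names(head_d))])

  in_rbd <- rep(FALSE, nrow(first))
  if (!is.null(rbd_annotations) && nrow(rbd_annotations) > 0) {
    spans <- rbd_annotations
    if ("category" %in% names(spans)) {
      spans <- spans[spans$category == "RBD" |
                       spans$domain_name %in% rbd_names, , drop = FALSE]
    } else {
      spans <- spans[spans$domain_name %in% rbd_names, , drop = FALSE]
    }
    pos <- as.integer(sub("^[A-Za-z]+", "", first$site_key))
    for (i in seq_len(nrow(first))) {
      s <- spans[spans$protein_id %in% first$protein_id[i], , drop = FALSE]
      in_rbd[i] <- any(s$start <= pos[i] & pos[i] <= s$end)
    }
  }
  classes <- list(
    all = rep(TRUE, nrow(first)),
    rs = first$rs_status == "rs",
    rs_in_rbd = first$rs_status == "rs" & in_rbd,
    insensitive = first$rs_status == "insensitive")
  do.call(rbind, lapply(names(classes), function(cl) {
    sel <- classes[[cl]]
    data.frame(class = cl, n = sum(sel),
               mean_distance = if (any(sel)) mean(first$headline[sel]) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
}
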