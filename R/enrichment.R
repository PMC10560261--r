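#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q_i = min over j with p_j >= p_i of (m * p_j / rank_j), capped at 1.
#' Order-preserving in p.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("invalid input: p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(m * p_values[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sided binomial p by the minimum-likelihood convention:
# sum of all point masses not exceeding the observed mass
.binom_two_sided <- function(x, n, p0) {
  d_obs <- stats::dbinom(x, n, p0)
  d_all <- stats::dbinom(0:n, n, p0)
  min(1, sum(d_all[d_all <= d_obs * (1 + 1e-7)]))
}

#' Binomial domain enrichment of modified sites
#'
#' For each domain, counts the sites of `site_set` falling inside any of
#' the domain's annotated spans (1-based, inclusive on both ends), compares
#' against the background proportion p0 (the fraction of
#' `background_site_set` inside the domain) with an exact two-sided
#' binomial test (minimum-likelihood convention), and corrects across
#' domains by Benjamini-Hochberg. Enrichment requires q below the cutoff
#' *and* an observed proportion above background. Domains never hit in the
#' background receive a conservative pseudo-background
#' p0 = 0.5 / |background|.
#'
#' @param site_set data.frame of sites (protein_id, position).
#' @param background_site_set data.frame of background sites (same
#'   columns); typically all quantified probe-modified sites.
#' @param annotations data.frame (protein_id, domain_name, start, end).
#' @param q_cutoff BH q-value cutoff for declaring enrichment (default
#'   0.01).
#' @return data.frame (domain_name, x, n, p0, observed_prop, p_value,
#'   q_value, enriched), sorted by p_value.
#' @export
binomial_domain_enrichment <- function(site_set, background_site_set,
                                       annotations, q_cutoff = 0.01) {
  if (nrow(site_set) == 0) {
    stop("empty site set", call. = FALSE)
  }
  stopifnot(all(c("protein_id", "position") %in% names(site_set)),
            all(c("protein_id", "domain_name", "start", "end") %in%
                  names(annotations)))
  in_domain <- function(sites, spans) {
    hit <- logical(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      s <- spans[spans$protein_id == sites$protein_id[i], , drop = FALSE]
      hit[i] <- any(s$start <= sites$position[i] &
                      sites$position[i] <= s$end)
    }
    hit
  }
  n <- nrow(site_set)
  n_bg <- nrow(background_site_set)
  doms <- unique(annotations$domain_name)
  rows <- lapply(doms, function(dm) {
    spans <- annotations[annotations$domain_name == dm, , drop = FALSE]
    x <- sum(in_domain(site_set, spans))
    bg_hits <- sum(in_domain(background_site_set, spans))
    p0 <- if (bg_hits == 0) 0.5 / n_bg else bg_hits / n_bg
    data.frame(domain_name = dm, x = x, n = n, p0 = p0,
               observed_prop = x / n,
               p_value = .binom_two_sided(x, n, p0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$enriched <- out$q_value < q_cutoff & out$observed_prop > out$p0
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric upper-tail overlap test
#'
#' P(X >= overlap) when drawing `set_b_size` elements without replacement
#' from a universe of `universe_size` containing `set_a_size` successes.
#' The standard significance test for the overlap of two gene/protein sets
#' within a detection universe.
#'
#' @param universe_size,set_a_size,set_b_size,overlap Non-negative counts.
#' @return The upper-tail p-value.
#' @export
hypergeometric_overlap <- function(universe_size, set_a_size, set_b_size,
                                   overlap) {
  if (set_a_size > universe_size || set_b_size > universe_size ||
      overlap > min(set_a_size, set_b_size) || overlap < 0) {
    stop("invalid input: inconsistent counts", call. = FALSE)
  }
  k_max <- min(set_a_size, set_b_size)
  ks <- overlap:k_max
  sum(exp(lchoose(set_a_size, ks) +
            lchoose(universe_size - set_a_size, set_b_size - ks) -
            lchoose(universe_size, set_b_size)))
}

#' Approximate a site position from a peptide span ("average down")
#'
#' Harmonizes peptide-resolution datasets with site-resolution ones: the
#' site is the floor of the mean of the peptide start and end positions.
#'
#' @param peptide_start,peptide_end 1-based inclusive peptide coordinates
#'   on the protein (vectors allowed).
#' @return Integer vector of approximate site positions.
#' @export
average_down_site <- function(peptide_start, peptide_end) {
  stopifnot(all(peptide_start <= peptide_end), all(peptide_start >= 1))
  as.integer(floor((peptide_start + peptide_end) / 2))
}

#' Join sites against intrinsically disordered region annotations
#'
#' Membership is inclusive on both span ends. IDR spans are consumed as an
#' external annotation table (e.g. disorder predictions), not recomputed.
#'
#' @param sites data.frame (protein_id, position, and optionally rs_flag).
#' @param idr_spans data.frame (protein_id, start, end).
#' @return `sites` with a logical `in_idr` column; a summary of counts by
#'   RS status (when `rs_flag` is present) is attached as attribute
#'   "summary".
#' @export
idr_annotation_join <- function(sites, idr_spans) {
  in_idr <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- idr_spans[idr_spans$protein_id == sites$protein_id[i], ,
                   drop = FALSE]
    in_idr[i] <- nrow(s) > 0 && any(s$start <= sites$position[i] &
                                      sites$position[i] <= s$end)
  }
  sites$in_idr <- in_idr
  if ("rs_flag" %in% names(sites) && nrow(sites) > 0) {
    attr(sites, "summary") <- as.data.frame(
      table(rs_flag = sites$rs_flag, in_idr = sites$in_idr))
  }
  sites
}
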