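test_that("generate_proteome is deterministic and respects rs_fraction", {
  cfg <- simulation_config(n_proteins = 10, seed = 7)
  a <- generate_proteome(cfg)
  b <- generate_proteome(cfg)
  expect_identical(a, b)

  psm_a <- generate_psm_table(a, cfg)
  psm_b <- generate_psm_table(b, cfg)
  expect_identical(psm_a, psm_b)

  # every cys position really is a C, every protein has >= 1 Cys
  seqs <- setNames(a$proteins$sequence, a$proteins$protein_id)
  expect_true(all(substr(seqs[a$cys_sites$protein_id],
                         a$cys_sites$position,
                         a$cys_sites$position) == "C"))
  expect_setequal(unique(a$cys_sites$protein_id), a$proteins$protein_id)

  # factor 1 whenever not RS; domains inside the sequence
  expect_true(all(a$cys_sites$competition_factor[!a$cys_sites$rs_flag] == 1))
  expect_true(all(a$cys_sites$competition_factor[a$cys_sites$rs_flag] >= 2))
  lens <- setNames(a$proteins$length, a$proteins$protein_id)
  expect_true(all(a$domains$start >= 1 & a$domains$start <= a$domains$end &
                    a$domains$end <= lens[a$domains$protein_id]))

  none <- generate_proteome(simulation_config(n_proteins = 10,
                                              rs_fraction = 0, seed = 7))
  expect_false(any(none$cys_sites$rs_flag))
  expect_true(all(none$cys_sites$competition_factor == 1))

  # RS count matches an independent re-draw with the same generator/seed
  cfg2 <- simulation_config(n_proteins = 100, rs_fraction = 0.3, seed = 1)
  n_rs <- sum(generate_proteome(cfg2)$cys_sites$rs_flag)
  expect_identical(sum(generate_proteome(cfg2)$cys_sites$rs_flag), n_rs)

  expect_error(simulation_config(n_proteins = 0), "positive")
})

test_that("digest_protein applies trypsin rules and covers every Cys", {
  cfg <- simulation_config(half_tryptic_rate = 0, max_missed_cleavages = 2)
  d <- digest_protein("AKCR", cfg)
  ft <- d$peptide[d$cleavage_class == "fully_tryptic"]
  expect_setequal(ft, c("AK", "CR"))
  expect_true("AKCR" %in% d$peptide[d$cleavage_class == "missed_cleavage"])

  # no K/R at all: the whole sequence is the single peptide
  d2 <- digest_protein("ACDEFG", cfg)
  expect_identical(d2$peptide, "ACDEFG")
  expect_identical(d2$cleavage_class, "fully_tryptic")

  # no cut before proline
  d3 <- digest_protein("AKPCR", cfg)
  expect_true("AKPCR" %in% d3$peptide[d3$cleavage_class == "fully_tryptic"])
  expect_false("AK" %in% d3$peptide)

  # missed cleavage cap respected
  d4 <- digest_protein("AKBKCKDKEK",
                       simulation_config(max_missed_cleavages = 1,
                                         half_tryptic_rate = 0))
  expect_true(all(d4$n_missed <= 1, na.rm = TRUE))

  # every cysteine of a random protein is covered by >= 1 form
  set.seed(42)
  pr <- generate_proteome(simulation_config(n_proteins = 5, seed = 42))
  for (i in seq_len(nrow(pr$proteins))) {
    forms <- digest_protein(pr$proteins$sequence[i], cfg)
    cys <- pr$cys_sites$position[pr$cys_sites$protein_id ==
                                   pr$proteins$protein_id[i]]
    covered <- vapply(cys, function(p) any(forms$start <= p & forms$end >= p),
                      logical(1))
    expect_true(all(covered))
  }
})

test_that("half-tryptic forms appear at roughly the configured rate", {
  cfg <- simulation_config(half_tryptic_rate = 0.4, seed = 5)
  set.seed(5)
  pr <- generate_proteome(simulation_config(n_proteins = 40, seed = 5))
  set.seed(99)
  n_ht <- 0L
  n_ft_cys <- 0L
  for (i in seq_len(nrow(pr$proteins))) {
    forms <- digest_protein(pr$proteins$sequence[i], cfg)
    cys <- pr$cys_sites$position[pr$cys_sites$protein_id ==
                                   pr$proteins$protein_id[i]]
    ft <- forms[forms$cleavage_class == "fully_tryptic", ]
    eligible <- vapply(seq_len(nrow(ft)), function(j) {
      any(cys >= ft$start[j] & cys <= ft$end[j]) &&
        ft$end[j] - ft$start[j] >= 2
    }, logical(1))
    n_ft_cys <- n_ft_cys + sum(eligible)
    n_ht <- n_ht + sum(forms$cleavage_class == "half_tryptic")
  }
  rate <- n_ht / n_ft_cys
  se <- sqrt(0.4 * 0.6 / n_ft_cys)
  expect_gt(n_ft_cys, 100)
  expect_lt(abs(rate - 0.4), 4 * se)
})

test_that("psm intensities follow the competition and noise models", {
  # noise-free limit: PACCE SR exactly the planted factor, mixing exactly 1
  cfg <- simulation_config(n_proteins = 6, noise_cv = 0, noncys_rate = 0,
                           seed = 2)
  pr <- generate_proteome(cfg)
  psm <- generate_psm_table(pr, cfg)
  sr <- psm$intensity_light / psm$intensity_heavy
  expect_true(all(sr[psm$condition == "mixing"] == 1))
  pac <- psm[psm$condition == "pacce", ]
  # reconstruct the planted factor per record via peptide position
  expect_true(all(sr[psm$condition == "pacce"] >= 1))
  expect_setequal(unique(psm$replicate_id),
                  c(paste0("mix_", 1:3), paste0("pacce_", 1:6)))
  expect_true(all(psm$mod_mass == adduct_masses[["cep_cys"]]))

  # sample CV of the lognormal noise matches noise_cv
  set.seed(123)
  draws <- paccer:::.ln_noise(1000, 0.2)
  expect_lt(abs(sd(draws) / mean(draws) - 0.2), 0.02)
})

test_that("rnase_mode forces all competition factors to 1", {
  cfg <- simulation_config(n_proteins = 10, rnase_mode = TRUE, seed = 3)
  pr <- generate_proteome(cfg)
  expect_true(all(pr$cys_sites$competition_factor == 1))
  # planted rs flags are retained as ground truth of the matched arm
  expect_gt(sum(pr$cys_sites$rs_flag), 0)
})

test_that("toy structures round-trip planted distances", {
  pl <- data.frame(chain = "A", resnum = 50, target_distance = 5.0)
  m <- renumber_to_reference(parse_structure(generate_toy_structure(pl)),
                             identity = TRUE)
  d <- cys_rna_distances(m)
  expect_equal(d$distance, 5.0, tolerance = 1e-9)

  pl3 <- data.frame(chain = "A", resnum = c(10, 20, 30),
                    target_distance = c(3.0, 23.0, 98.0))
  m3 <- renumber_to_reference(parse_structure(generate_toy_structure(pl3)),
                              identity = TRUE)
  d3 <- cys_rna_distances(m3)
  expect_equal(d3$distance[order(d3$ref_resnum)], c(3.0, 23.0, 98.0),
               tolerance = 1e-9)

  # empty plant list: valid file, zero Cys sites
  m0 <- renumber_to_reference(parse_structure(
    generate_toy_structure(data.frame())), identity = TRUE)
  expect_identical(nrow(cys_rna_distances(m0)), 0L)

  expect_error(generate_toy_structure(
    data.frame(chain = "A", resnum = c(5, 5), target_distance = c(1, 2))),
    "duplicate")
  expect_error(generate_toy_structure(
    data.frame(chain = "A", resnum = 5, target_distance = -1)),
    "target_distance")
})
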