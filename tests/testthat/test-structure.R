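test_that("parse_structure round-trips fixtures and reads the header", {
  pl <- data.frame(chain = "A", resnum = c(10, 20),
                   target_distance = c(4, 30))
  txt <- generate_toy_structure(pl, resolution = 2.5)
  m <- parse_structure(txt)
  expect_equal(m$resolution, 2.5)
  # 4 protein atoms + 3 RNA atoms per site
  expect_identical(nrow(m$atoms), 14L)
  expect_setequal(m$chains$molecule_type, c("protein", "rna"))
  # SG coordinates survive the fixed-width round trip
  sg <- m$atoms[m$atoms$atom_name == "SG", ]
  expect_equal(sg$x, c(0, 200))

  expect_error(parse_structure("REMARK nothing here"), "no coordinate")
})

test_that("multi-model files keep model 1 and altlocs resolve by occupancy", {
  al <- function(serial, name, alt, occ, x) {
    sprintf("ATOM  %5d  %-3s%1sCYS A  10    %8.3f%8.3f%8.3f%6.2f  0.00           %1s",
            serial, name, alt, x, 0, 0, occ, substr(name, 1, 1))
  }
  two_models <- c("MODEL        1", al(1, "SG", " ", 1, 1.0), "ENDMDL",
                  "MODEL        2", al(2, "SG", " ", 1, 9.0), "ENDMDL")
  m <- parse_structure(two_models)
  expect_identical(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 1.0)

  alt <- c(al(1, "SG", "A", 0.6, 1.0), al(2, "SG", "B", 0.4, 2.0))
  ma <- parse_structure(alt)
  expect_identical(nrow(ma$atoms), 1L)
  expect_equal(ma$atoms$x, 1.0)          # A (occ 0.6) retained

  # tie in occupancy: first record wins
  tie <- c(al(1, "SG", "A", 0.5, 3.0), al(2, "SG", "B", 0.5, 4.0))
  expect_equal(parse_structure(tie)$atoms$x, 3.0)
})

test_that("classify_chain uses the composition + O2' rule", {
  mk <- function(resnames, atoms) data.frame(
    resnum = seq_along(resnames), icode = "", resname = resnames,
    atom_name = atoms, stringsAsFactors = FALSE)
  expect_identical(classify_chain(mk(c("A", "U", "G"), c("O2'", "C1'", "P"))),
                   "rna")
  # A/U/G/C names without any O2' atom are not called RNA
  expect_identical(classify_chain(mk(c("A", "U", "G"), c("P", "C1'", "P"))),
                   "other")
  expect_identical(classify_chain(mk(c("DA", "DT"), c("P", "P"))), "dna")
  expect_identical(classify_chain(mk(c("ALA", "GLY", "CYS"),
                                     c("CA", "CA", "SG"))), "protein")
  # 40% nucleotide content is below the majority threshold
  expect_identical(classify_chain(mk(c("A", "U", "XXX", "YYY", "ZZZ"),
                                     c("O2'", "P", "C", "C", "C"))),
                   "other")
})

test_that("renumbering maps author to reference numbers", {
  pl <- data.frame(chain = "A", resnum = c(47, 60), target_distance = c(5, 7))
  m <- parse_structure(generate_toy_structure(pl), structure_id = "S1")

  ident <- renumber_to_reference(m, identity = TRUE)
  expect_equal(ident$atoms$ref_resnum, ident$atoms$resnum)

  off <- data.frame(structure_id = "S1", chain_id = "A",
                    author_number = c(47, 60), reference_number = c(57, 70))
  mm <- renumber_to_reference(m, off)
  sg <- mm$atoms[mm$atoms$atom_name == "SG", ]
  expect_setequal(sg$ref_resnum, c(57L, 70L))

  # unmapped residues stay NA and are excluded from the distance join
  partial <- off[1, ]
  mp <- renumber_to_reference(m, partial)
  d <- cys_rna_distances(mp)
  expect_identical(nrow(d), 1L)
  expect_identical(d$site_key, "C57")

  dup <- rbind(off, data.frame(structure_id = "S1", chain_id = "A",
                               author_number = 47, reference_number = 99))
  expect_error(renumber_to_reference(m, dup), "conflicting")
})

test_that("minimum distance engine is exact on constructed geometry", {
  # 3-4-5 triangle: SG at origin, nearest RNA atom at (3, 4, 0)
  lines <- c(
    "ATOM      1  SG  CYS A  10       0.000   0.000   0.000  1.00  0.00           S",
    "ATOM      2  O2'   A X   1       3.000   4.000   0.000  1.00  0.00           O",
    "ATOM      3  C1'   A X   1      30.000   0.000   0.000  1.00  0.00           C")
  m <- renumber_to_reference(parse_structure(lines), identity = TRUE)
  d <- cys_rna_distances(m)
  expect_equal(d$distance, 5.0)

  # planted 23.0 round-trips at full precision
  pl <- data.frame(chain = "A", resnum = 50, target_distance = 23.0)
  m23 <- renumber_to_reference(parse_structure(generate_toy_structure(pl)),
                               identity = TRUE)
  expect_equal(cys_rna_distances(m23)$distance, 23.0, tolerance = 1e-9)

  # brute-force oracle equivalence on a randomized fixture
  set.seed(4)
  pl2 <- data.frame(chain = "A", resnum = c(5, 15, 25),
                    target_distance = round(runif(3, 2, 60), 3))
  m2 <- renumber_to_reference(parse_structure(generate_toy_structure(pl2)),
                              identity = TRUE)
  d2 <- cys_rna_distances(m2)
  for (i in seq_len(nrow(d2))) {
    expect_equal(d2$distance[i],
                 brute_force_min_distance(m2, d2$chain_id[i],
                                          as.integer(sub("C", "", d2$site_key[i]))),
                 tolerance = 1e-9)
  }

  # rigid-body transform invariance
  rot <- function(atoms, theta) {
    x <- atoms$x * cos(theta) - atoms$y * sin(theta) + 11.5
    y <- atoms$x * sin(theta) + atoms$y * cos(theta) - 3.25
    atoms$x <- x; atoms$y <- y; atoms$z <- atoms$z + 7
    atoms
  }
  m3 <- m2
  m3$atoms <- rot(m3$atoms, 0.7)
  d3 <- cys_rna_distances(m3)
  expect_equal(d3$distance, d2$distance, tolerance = 1e-6)

  # Cys without SG is skipped with a reason; no RNA chain is an error
  no_sg <- c(
    "ATOM      1  CA  CYS A  10       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  O2'   A X   1       3.000   4.000   0.000  1.00  0.00           O")
  msg <- renumber_to_reference(parse_structure(no_sg), identity = TRUE)
  dd <- cys_rna_distances(msg)
  expect_identical(nrow(dd), 0L)
  expect_match(attr(dd, "skipped")$reason, "SG")

  prot_only <- "ATOM      1  SG  CYS A  10       0.000   0.000   0.000  1.00  0.00           S"
  expect_error(cys_rna_distances(
    renumber_to_reference(parse_structure(prot_only), identity = TRUE)),
    "no RNA chain")
})

test_that("multiple instances across chains are all emitted", {
  pl <- data.frame(chain = c("A", "B"), resnum = c(50, 50),
                   target_distance = c(6.0, 9.0))
  m <- renumber_to_reference(parse_structure(generate_toy_structure(pl)),
                             identity = TRUE)
  d <- min_cys_rna_distance(m, ref_resnum = 50)
  expect_identical(nrow(d), 2L)
  expect_setequal(d$instance_index, c(1L, 2L))
  expect_setequal(round(d$distance, 6), c(6.0, 9.0))
  # headline (min across instances) respects each instance's distance
  expect_true(min(d$distance) <= min(d$distance))
})

test_that("filter_structures applies resolution cutoff and exclusions", {
  mk <- function(id, res) {
    m <- parse_structure(generate_toy_structure(
      data.frame(chain = "A", resnum = 1, target_distance = 5),
      structure_id = id, resolution = res))
    m$structure_id <- id
    m
  }
  models <- list(mk("GOOD", 2.0), mk("COARSE", 3.4), mk("BADRNA", 1.5))
  kept <- filter_structures(models, resolution_max = 3.0,
                            exclude = "BADRNA")
  expect_identical(vapply(kept, `[[`, "", "structure_id"), "GOOD")
})

test_that("site join and class summaries recover planted distances", {
  pl <- data.frame(chain = c("A", "A", "B"), resnum = c(10, 99, 20),
                   target_distance = c(10, 10, 30))
  m <- renumber_to_reference(parse_structure(generate_toy_structure(
    pl, structure_id = "SYN1")), identity = TRUE)
  m$structure_id <- "SYN1"
  d <- cys_rna_distances(m)
  calls <- data.frame(protein_id = c("P1", "P2"),
                      site_key = c("C10", "C20"),
                      rs_flag = c(TRUE, FALSE), stringsAsFactors = FALSE)
  cmap <- data.frame(structure_id = "SYN1", chain_id = c("A", "B"),
                     protein_id = c("P1", "P2"), stringsAsFactors = FALSE)
  ann <- join_sites_to_structures(d, calls, cmap)
  expect_setequal(ann$rs_status[ann$site_key == "C10"], "rs")
  expect_identical(ann$rs_status[ann$site_key == "C20"], "insensitive")
  expect_identical(ann$rs_status[ann$site_key == "C99"], "not_quantified")

  rbd <- data.frame(protein_id = "P1", domain_name = "RRM",
                    category = "RBD", start = 5, end = 15)
  s <- summarize_distance_by_class(ann, rbd)
  expect_equal(s$mean_distance[s$class == "rs"], 10)
  expect_equal(s$mean_distance[s$class == "rs_in_rbd"], 10)
  expect_equal(s$mean_distance[s$class == "insensitive"], 30)
  # shuffling records does not change class means
  s2 <- summarize_distance_by_class(ann[rev(seq_len(nrow(ann))), ], rbd)
  expect_equal(s2$mean_distance, s$mean_distance)

  # empty class reported as absent, not zero
  ann_rs <- ann[ann$rs_status != "insensitive", ]
  s3 <- summarize_distance_by_class(ann_rs, rbd)
  expect_identical(s3$n[s3$class == "insensitive"], 0L)
  expect_true(is.na(s3$mean_distance[s3$class == "insensitive"]))
})
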