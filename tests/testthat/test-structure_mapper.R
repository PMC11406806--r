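# Structure loading, protein-shielding profiles, fragment mapping,
# visualization output and in-silico fragment prediction.

toy_mmcif <- function(path) {
  lines <- c(
    "data_toy", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.B_iso_or_equiv",
    sprintf("ATOM %d P P %s A %d %.3f 0.000 0.000 0.00",
            1:100, rep(c("A", "U", "G", "C"), 25), 1:100, (1:100) * 7),
    sprintf("ATOM %d C CA %s B %d %.3f 30.000 0.000 0.00",
            101:150, rep(c("GLY", "ALA"), 25), 1:50, (1:50) * 7),
    "#")
  writeLines(lines, path)
  path
}

test_that("mmCIF chains classify by residue alphabet", {
  path <- withr::local_tempfile(fileext = ".cif")
  m <- read_structure(toy_mmcif(path))
  ch <- m$chains[order(m$chains$chain_id), ]
  expect_equal(ch$kind, c("rRNA", "protein"))
  expect_equal(ch$n_residues, c(100L, 50L))
  # representative atom of nucleotides is the phosphorus
  expect_true(all(m$residues$rep_atom[m$residues$chain == "A"] == "P"))
})

test_that("a 95%-nucleotide chain still counts as rRNA", {
  m <- build_toy_structure(100)
  atoms <- m$atoms
  atoms$res_name[atoms$res_seq %in% 1:5 & atoms$chain == "R"] <- "GLY"
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(tibble::tibble(region_id = character(),
                                   chain = character(),
                                   residues = list(), n_selected = integer(),
                                   n_dropped = integer(), weight = numeric()),
                    structure(list(atoms = atoms), class = "structure_model"),
                    path)
  m2 <- read_structure(path)
  expect_equal(m2$chains$kind[m2$chains$chain_id == "R"], "rRNA")
})

test_that("structures without nucleotide chains are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:10, 1:10, (1:10) * 4, 0, 0), "END"), path)
  expect_error(read_structure(path), "no nucleotide")
})

test_that("shielding follows the proximity rule on hand-placed atoms", {
  # residue 5 has a protein atom 3 A away; residue 20 nothing within 20 A
  m <- build_toy_structure(30, tibble::tibble(start = 4L, end = 5L))
  prof <- exposure_profile(m, radius = 5)
  expect_false(prof$exposed[prof$res_seq == 5])
  expect_equal(prof$nearest_protein_distance[prof$res_seq == 5], 3)
  expect_true(prof$exposed[prof$res_seq == 20])
  expect_gt(prof$nearest_protein_distance[prof$res_seq == 20], 5)
})

test_that("grid-based shield counts equal the all-pairs brute force", {
  withr::with_seed(29, {
    n_res <- 300L; n_prot <- 1500L
    rna <- tibble::tibble(chain = "R", res_seq = seq_len(n_res),
                          res_name = "A", atom_name = "P", element = "P",
                          x = runif(n_res, 0, 60), y = runif(n_res, 0, 60),
                          z = runif(n_res, 0, 60), b = 0)
    prot <- tibble::tibble(chain = "Q", res_seq = seq_len(n_prot),
                           res_name = "GLY", atom_name = "CA", element = "C",
                           x = runif(n_prot, 0, 60), y = runif(n_prot, 0, 60),
                           z = runif(n_prot, 0, 60), b = 0)
  })
  atoms <- dplyr::bind_rows(rna, prot)
  model <- structure(list(
    atoms = atoms,
    residues = dplyr::rename(rna, rep_atom = "atom_name"),
    chains = tibble::tibble(chain_id = c("R", "Q"),
                            n_residues = c(n_res, n_prot),
                            frac_nuc = c(1, 0), frac_aa = c(0, 1),
                            kind = c("rRNA", "protein"))),
    class = "structure_model")
  prof <- exposure_profile(model, radius = 5)
  brute <- vapply(seq_len(n_res), function(i) {
    sum((prot$x - rna$x[i])^2 + (prot$y - rna$y[i])^2 +
          (prot$z - rna$z[i])^2 <= 25)
  }, integer(1))
  expect_equal(prof$shield_count, brute)
  nearest_brute <- vapply(seq_len(n_res), function(i) {
    sqrt(min((prot$x - rna$x[i])^2 + (prot$y - rna$y[i])^2 +
               (prot$z - rna$z[i])^2))
  }, numeric(1))
  hit <- prof$shield_count > 0
  expect_equal(prof$nearest_protein_distance[hit], nearest_brute[hit])
})

test_that("fragment mapping selects modeled residues and reports gaps", {
  m <- build_toy_structure(100)
  regs <- tibble::tibble(region_id = c("C1", "C2"), species_id = "R",
                         start = c(10L, 60L), end = c(40L, 90L),
                         length = 30L, mean_abundance = c(0.4, 0.1),
                         support = 1L)
  sel <- map_fragments(regs, m)
  expect_equal(sel$n_selected, c(30L, 30L))
  expect_equal(sel$weight, c(1, 0.25))

  # drop residues 16..20 from the model: 5-residue gap
  m2 <- m
  m2$residues <- m2$residues[!(m2$residues$chain == "R" &
                                 m2$residues$res_seq %in% 16:20), ]
  sel2 <- map_fragments(regs[1, ], m2)
  expect_equal(sel2$n_selected, 25L)
  expect_equal(sel2$n_dropped, 5L)

  m3 <- m
  m3$residues <- m3$residues[!(m3$residues$chain == "R" &
                                 m3$residues$res_seq %in% 11:40), ]
  expect_warning(sel3 <- map_fragments(regs[1, ], m3), "unmodeled")
  expect_equal(sel3$n_selected, 0L)
})

test_that("visualization scripts are deterministic with one block per selection", {
  m <- build_toy_structure(100, tibble::tibble(start = 30L, end = 70L))
  regs <- tibble::tibble(region_id = "C1", species_id = "R",
                         start = 10L, end = 40L, length = 30L,
                         mean_abundance = 0.4, support = 1L)
  sel <- map_fragments(regs, m)
  f1 <- withr::local_tempfile(fileext = ".pml")
  f2 <- withr::local_tempfile(fileext = ".pml")
  write_visualization(sel, m, f1)
  write_visualization(sel, m, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_length(grep("^select contam_", lines), 1)
  expect_length(grep("^color col_", lines), 1)
  expect_true(any(grepl("color gray80", lines)))
  expect_true(any(grepl("hide everything, chain Q", lines)))

  empty <- sel[0, ]
  f3 <- withr::local_tempfile(fileext = ".pml")
  write_visualization(empty, m, f3)
  expect_length(grep("^select", readLines(f3)), 0)
})

test_that("B-factor PDB round-trips abundance weights within 0.01", {
  m <- build_toy_structure(100)
  regs <- tibble::tibble(region_id = c("C1", "C2"), species_id = "R",
                         start = c(10L, 60L), end = c(40L, 90L),
                         length = 30L, mean_abundance = c(0.4, 0.1),
                         support = 1L)
  sel <- map_fragments(regs, m)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_visualization(sel, m, withr::local_tempfile(fileext = ".pml"),
                      bfactor_pdb = path)
  m2 <- read_structure(path)
  r <- m2$residues[m2$residues$chain == "R", ]
  expect_true(all(abs(r$b[r$res_seq %in% 11:40] / 100 - 1.0) <= 0.01))
  expect_true(all(abs(r$b[r$res_seq %in% 61:90] / 100 - 0.25) <= 0.01))
  expect_true(all(r$b[r$res_seq %in% c(1:10, 41:60, 91:100)] == 0))
})

test_that("a single shielded run of length 40 is the single predicted fragment", {
  m <- build_toy_structure(100, tibble::tibble(start = 30L, end = 70L))
  pred <- predict_fragments(exposure_profile(m))
  expect_equal(nrow(pred), 1L)
  expect_equal(c(pred$start, pred$end, pred$length), c(30L, 70L, 40L))

  # fully exposed chain: every inter-nick interval is < len_min
  pred0 <- predict_fragments(exposure_profile(build_toy_structure(100)))
  expect_equal(nrow(pred0), 0L)
})

test_that("predictions recover constructed shielded runs at the fragment loci", {
  runs <- tibble::tibble(start = c(30L, 120L), end = c(70L, 155L))
  m <- build_toy_structure(200, runs)
  pred <- predict_fragments(exposure_profile(m))
  expect_equal(nrow(pred), 2L)
  for (i in seq_len(nrow(runs))) {
    j <- max(riboclean:::interval_jaccard(pred$start, pred$end,
                                          runs$start[i], runs$end[i]))
    expect_gte(j, 0.8)
  }
  # better-protected interiors rank higher
  expect_true(all(diff(pred$mean_shield) <= 0))
})

test_that("predicted fragments are disjoint, in bounds and length-bounded", {
  withr::with_seed(37, {
    for (rep in 1:5) {
      k <- sample(2:4, 1)
      starts <- sort(sample(seq(10L, 160L, by = 50L), k))
      runs <- tibble::tibble(start = starts,
                             end = starts + sample(18:48, k, replace = TRUE))
      m <- build_toy_structure(220, runs)
      pred <- predict_fragments(exposure_profile(m), len_min = 20L,
                                len_max = 50L)
      if (nrow(pred) == 0) next
      expect_true(all(pred$length >= 20L & pred$length <= 50L))
      expect_true(all(pred$start >= 0L & pred$end <= 220L))
      p <- pred[order(pred$start), ]
      if (nrow(p) > 1) expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
    }
  })
})
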