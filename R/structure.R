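# Mapping contaminant rRNA fragments onto a ribosome structure: chain
# classification, protein-shielding profiles, visualization scripts and
# in-silico prediction of nuclease-accessible fragments.
#
# No installed R package parses mmCIF/PDB coordinate files, so a minimal
# atom-record reader (ATOM/HETATM fixed columns for PDB; the _atom_site loop
# for mmCIF) is implemented here.

NUCLEOTIDE_RESIDUES <- c("A", "U", "G", "C", "T", "I", "N",
                         "DA", "DT", "DG", "DC", "DU", "DI",
                         "PSU", "1MA", "5MC", "7MG", "OMG", "OMC", "2MG",
                         "M2G", "H2U", "5MU", "4SU")
AMINO_ACID_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                         "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                         "PRO", "SER", "THR", "TRP", "TYR", "VAL", "SEC",
                         "PYL", "MSE", "UNK")

#' Read a ribosome structure from mmCIF or PDB
#'
#' Chains are classified as rRNA, protein or other by their residue
#' alphabet (a chain must be at least 90% nucleotide or amino-acid residues
#' to get the corresponding kind). Each residue's representative atom is its
#' phosphorus (nucleotides), falling back to the first atom. Unmodeled
#' residues appear as gaps in the residue numbering and are tolerated by the
#' fragment mapping.
#'
#' @param file Path to a `.cif`/`.mmcif` or `.pdb`/`.ent` file.
#' @return A `structure_model` list: `atoms` (tibble chain/res_seq/res_name/
#'   atom_name/element/x/y/z/b), `residues` (one row per residue with
#'   representative-atom coordinates), `chains` (chain_id, kind,
#'   n_residues).
#' @export
read_structure <- function(file) {
  ext <- tolower(tools::file_ext(file))
  atoms <- if (ext %in% c("cif", "mmcif")) {
    parse_mmcif_atoms(file)
  } else {
    parse_pdb_atoms(file)
  }
  if (nrow(atoms) == 0) stopf("no atom records in %s", file)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stopf("non-finite atom coordinates in %s", file)
  }

  residues <- atoms |>
    group_by(.data$chain, .data$res_seq) |>
    summarise(
      res_name = first(.data$res_name),
      rep_atom = dplyr::if_else(any(.data$atom_name == "P"), "P",
                                first(.data$atom_name)),
      x = .data$x[match(.data$rep_atom[1], .data$atom_name)],
      y = .data$y[match(.data$rep_atom[1], .data$atom_name)],
      z = .data$z[match(.data$rep_atom[1], .data$atom_name)],
      b = .data$b[match(.data$rep_atom[1], .data$atom_name)],
      .groups = "drop") |>
    arrange(.data$chain, .data$res_seq)

  chains <- residues |>
    group_by(chain_id = .data$chain) |>
    summarise(
      n_residues = n(),
      frac_nuc = mean(.data$res_name %in% NUCLEOTIDE_RESIDUES),
      frac_aa = mean(.data$res_name %in% AMINO_ACID_RESIDUES),
      .groups = "drop") |>
    mutate(kind = dplyr::case_when(
      .data$frac_nuc >= 0.9 ~ "rRNA",
      .data$frac_aa >= 0.9 ~ "protein",
      TRUE ~ "other"))
  if (!any(chains$kind == "rRNA")) {
    stopf("no nucleotide (rRNA) chains in %s", file)
  }
  structure(list(atoms = atoms, residues = residues, chains = chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chains\n",
              nrow(x$atoms), nrow(x$chains)))
  print(count(x$chains, .data$kind))
  invisible(x)
}

parse_pdb_atoms <- function(file) {
  lines <- readLines(file)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(lines) == 0) return(tibble())
  fld <- function(a, b) trimws(substring(lines, a, b))
  elem <- fld(77, 78)
  name <- fld(13, 16)
  elem[elem == ""] <- substring(gsub("[0-9']", "", name[elem == ""]), 1, 1)
  tibble(
    chain = fld(22, 22),
    res_seq = as.integer(fld(23, 26)),
    res_name = fld(18, 20),
    atom_name = name,
    element = toupper(elem),
    x = as.numeric(fld(31, 38)),
    y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    b = as.numeric(fld(61, 66))
  )
}

parse_mmcif_atoms <- function(file) {
  lines <- readLines(file)
  loop_starts <- which(trimws(lines) == "loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(tags, "_atom_site."))) next
    rows <- character(0)
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (l == "" || startsWith(l, "#") || startsWith(l, "_") || l == "loop_") break
      rows <- c(rows, l)
      i <- i + 1L
    }
    mat <- do.call(rbind, strsplit(rows, "\\s+"))
    colnames(mat) <- sub("^_atom_site\\.", "", tags)
    get <- function(...) {
      for (nm in c(...)) if (nm %in% colnames(mat)) return(mat[, nm])
      rep(NA_character_, nrow(mat))
    }
    return(tibble(
      chain = get("auth_asym_id", "label_asym_id"),
      res_seq = as.integer(get("auth_seq_id", "label_seq_id")),
      res_name = get("label_comp_id", "auth_comp_id"),
      atom_name = gsub('"', "", get("label_atom_id", "auth_atom_id")),
      element = toupper(get("type_symbol")),
      x = as.numeric(get("Cartn_x")),
      y = as.numeric(get("Cartn_y")),
      z = as.numeric(get("Cartn_z")),
      b = as.numeric(get("B_iso_or_equiv"))
    ))
  }
  tibble()
}

#' Protein-shielding profile of rRNA residues
#'
#' For every rRNA residue, counts protein heavy atoms within `radius`
#' angstrom of its representative atom (a proximity proxy for "shielded by
#' ribosomal proteins"); a residue is exposed when the count is below
#' `shield_min`. Neighbour search uses a uniform spatial grid with cell size
#' `radius`; the exact nearest protein distance is also reported.
#'
#' @param model A `structure_model`.
#' @param radius Shielding radius in angstrom (default 5).
#' @param shield_min Minimum shielding atom count (default 1: any protein
#'   heavy atom within the radius shields).
#' @return An `exposure_profile` tibble: `chain`, `res_seq`, `res_name`,
#'   `shield_count`, `nearest_protein_distance`, `exposed`.
#' @export
exposure_profile <- function(model, radius = 5, shield_min = 1L) {
  rna_chains <- model$chains$chain_id[model$chains$kind == "rRNA"]
  prot_chains <- model$chains$chain_id[model$chains$kind == "protein"]
  res <- model$residues |> filter(.data$chain %in% rna_chains)
  atoms <- model$atoms |>
    filter(.data$chain %in% prot_chains, .data$element != "H")

  n <- nrow(res)
  counts <- integer(n)
  nearest <- rep(Inf, n)
  if (nrow(atoms) > 0 && n > 0) {
    cell <- function(v) as.integer(floor(v / radius))
    akey <- paste(cell(atoms$x), cell(atoms$y), cell(atoms$z))
    aidx <- split(seq_len(nrow(atoms)), akey)
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (i in seq_len(n)) {
      cx <- cell(res$x[i]); cy <- cell(res$y[i]); cz <- cell(res$z[i])
      keys <- paste(cx + shifts[, 1], cy + shifts[, 2], cz + shifts[, 3])
      cand <- unlist(aidx[keys], use.names = FALSE)
      if (length(cand) > 0) {
        d2 <- (atoms$x[cand] - res$x[i])^2 + (atoms$y[cand] - res$y[i])^2 +
          (atoms$z[cand] - res$z[i])^2
        counts[i] <- sum(d2 <= radius^2)
        nearest[i] <- sqrt(min(d2))
      }
      if (counts[i] == 0) {
        # grid neighbourhood empty or nearest beyond it: exact fallback
        d2 <- (atoms$x - res$x[i])^2 + (atoms$y - res$y[i])^2 +
          (atoms$z - res$z[i])^2
        nearest[i] <- sqrt(min(d2))
      }
    }
  }
  out <- tibble(chain = res$chain, res_seq = res$res_seq,
                res_name = res$res_name, shield_count = counts,
                nearest_protein_distance = nearest,
                exposed = counts < shield_min)
  out <- new_riboclean_tbl(out, "exposure_profile")
  attr(out, "params") <- list(radius = radius, shield_min = shield_min)
  out
}

#' Map contaminant regions onto structure residues
#'
#' Converts each region's rRNA-gene interval (0-based nt) into a set of
#' modeled residues on the matching rRNA chain and attaches a
#' max-normalized abundance weight in `[0, 1]`. By default nucleotide `i`
#' (0-based) maps to residue `i + 1` on the chain whose id equals the
#' species id (identity map); supply `chain_map` (tibble `species_id`,
#' `chain`, `offset`) for anything else, e.g. mature-rRNA numbering shifts.
#' Residues missing from the model (gaps) are dropped and counted.
#'
#' @param regions A `contaminant_regions` tibble.
#' @param model A `structure_model`.
#' @param chain_map Optional tibble `species_id`, `chain`, `offset` (residue
#'   number = nt position + 1 + offset).
#' @return A `fragment_selection` tibble: `region_id`, `chain`, `residues`
#'   (list-column of residue numbers), `n_selected`, `n_dropped`, `weight`.
#' @export
map_fragments <- function(regions, model, chain_map = NULL) {
  rna_chains <- model$chains$chain_id[model$chains$kind == "rRNA"]
  if (is.null(chain_map)) {
    chain_map <- tibble(species_id = unique(regions$species_id)) |>
      mutate(chain = if (length(rna_chains) == 1) rna_chains else
        if_else(.data$species_id %in% rna_chains, .data$species_id,
                NA_character_),
        offset = 0L)
    if (any(is.na(chain_map$chain))) {
      stopf("no rRNA chain matches species %s; supply chain_map",
            paste(chain_map$species_id[is.na(chain_map$chain)], collapse = ", "))
    }
  }
  wmax <- max(regions$mean_abundance)
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    cm <- chain_map[chain_map$species_id == regions$species_id[i], ]
    if (nrow(cm) == 0) {
      stopf("species %s missing from chain_map", regions$species_id[i])
    }
    wanted <- seq(regions$start[i] + 1L, regions$end[i]) + cm$offset[1]
    modeled <- model$residues$res_seq[model$residues$chain == cm$chain[1]]
    sel <- intersect(wanted, modeled)
    if (length(sel) == 0) {
      warnf("region %s is entirely unmodeled on chain %s",
            regions$region_id[i], cm$chain[1])
    }
    tibble(region_id = regions$region_id[i], chain = cm$chain[1],
           residues = list(sel), n_selected = length(sel),
           n_dropped = length(wanted) - length(sel),
           weight = regions$mean_abundance[i] / wmax)
  })
  new_riboclean_tbl(out, "fragment_selection")
}

#' Write a PyMOL script (and optional B-factor PDB) for fragment selections
#'
#' The script colors rRNA chains gray, paints each contaminant selection in
#' a red ramp scaled by its abundance weight and hides protein chains for
#' clarity. The optional PDB variant writes `weight * 100` into the
#' temperature-factor column of the selected residues (0 elsewhere) for use
#' in any structure viewer.
#'
#' @param selections A `fragment_selection` from [map_fragments()].
#' @param model A `structure_model`.
#' @param file Output `.pml` path.
#' @param bfactor_pdb Optional output PDB path.
#' @return `file`, invisibly.
#' @export
write_visualization <- function(selections, model, file, bfactor_pdb = NULL) {
  rna_chains <- model$chains$chain_id[model$chains$kind == "rRNA"]
  prot_chains <- model$chains$chain_id[model$chains$kind == "protein"]
  lines <- c(
    "bg_color white",
    "hide everything",
    sprintf("show cartoon, chain %s", paste(rna_chains, collapse = "+")),
    sprintf("color gray80, chain %s", paste(rna_chains, collapse = "+"))
  )
  if (length(prot_chains) > 0) {
    lines <- c(lines, sprintf("hide everything, chain %s",
                              paste(prot_chains, collapse = "+")))
  }
  for (i in seq_len(nrow(selections))) {
    resi <- selections$residues[[i]]
    if (length(resi) == 0) next
    w <- selections$weight[i]
    rgb <- c(1, 0.85 * (1 - w), 0.85 * (1 - w))  # light pink -> red
    cname <- sprintf("contam_%s", selections$region_id[i])
    lines <- c(lines,
               sprintf("select %s, chain %s and resi %s", cname,
                       selections$chain[i], compress_resi(resi)),
               sprintf("set_color col_%s, [%.3f, %.3f, %.3f]", cname,
                       rgb[1], rgb[2], rgb[3]),
               sprintf("color col_%s, %s", cname, cname))
  }
  writeLines(lines, file)
  if (!is.null(bfactor_pdb)) write_bfactor_pdb(selections, model, bfactor_pdb)
  invisible(file)
}

# PyMOL resi syntax: runs of consecutive residues as a-b, joined by '+'.
compress_resi <- function(resi) {
  resi <- sort(unique(resi))
  brk <- c(0L, which(diff(resi) != 1L), length(resi))
  paste(vapply(seq_len(length(brk) - 1L), function(j) {
    run <- resi[(brk[j] + 1L):brk[j + 1L]]
    if (length(run) == 1) as.character(run) else
      sprintf("%d-%d", run[1], run[length(run)])
  }, character(1)), collapse = "+")
}

#' Write a PDB with abundance weights in the B-factor column
#'
#' @param selections A `fragment_selection`.
#' @param model A `structure_model`.
#' @param file Output PDB path.
#' @return `file`, invisibly.
#' @export
write_bfactor_pdb <- function(selections, model, file) {
  atoms <- model$atoms
  bf <- numeric(nrow(atoms))
  for (i in seq_len(nrow(selections))) {
    hit <- atoms$chain == selections$chain[i] &
      atoms$res_seq %in% selections$residues[[i]]
    bf[hit] <- selections$weight[i] * 100
  }
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000L,
    substr(atoms$atom_name, 1, 4), substr(atoms$res_name, 1, 3),
    substr(atoms$chain, 1, 1), atoms$res_seq %% 10000L,
    atoms$x, atoms$y, atoms$z, 1.0, bf, substr(atoms$element, 1, 2))
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Predict major rRNA contaminant fragments from structure alone
#'
#' Operationalizes in-silico contaminant prediction without pilot
#' sequencing: exposed residues (not shielded by ribosomal proteins) are
#' treated as nuclease-accessible nick sites, and every maximal protected
#' run between two consecutive accessible positions whose length falls in
#' `[len_min, len_max]` is a candidate fragment (runs longer than
#' `len_max` — e.g. the subunit interface — would be removed by footprint
#' size selection). Candidates are ranked by mean interior shield count,
#' best-protected first.
#'
#' @param profile An `exposure_profile`.
#' @param len_min,len_max Fragment length bounds in nt (defaults 20 / 50,
#'   the footprint size-selection window).
#' @return Tibble: `chain`, `start`, `end` (0-based half-open nt on the
#'   chain), `length`, `mean_shield`, ranked by `mean_shield` descending.
#' @export
predict_fragments <- function(profile, len_min = 20L, len_max = 50L) {
  out <- profile |>
    group_by(.data$chain) |>
    group_modify(function(d, key) {
      acc <- sort(d$res_seq[d$exposed])
      if (length(acc) < 2) {
        return(tibble(start = integer(), end = integer(),
                      length = integer(), mean_shield = numeric()))
      }
      runs <- tibble(start = acc[-length(acc)], end = acc[-1] - 1L) |>
        mutate(length = .data$end - .data$start) |>
        filter(.data$length >= len_min, .data$length <= len_max)
      runs$mean_shield <- vapply(seq_len(nrow(runs)), function(j) {
        interior <- d$shield_count[d$res_seq > runs$start[j] &
                                     d$res_seq <= runs$end[j]]
        mean(interior)
      }, numeric(1))
      runs
    }) |>
    ungroup() |>
    arrange(desc(.data$mean_shield), .data$chain, .data$start)
  select(out, "chain", "start", "end", "length", "mean_shield")
}

#' Build a synthetic toy ribosome structure
#'
#' Constructs a linear single-chain rRNA model (P atoms spaced so that
#' neighbouring residues never shield each other) with protein atoms placed
#' 3 angstrom from the residues listed in `shielded_runs` — a fully
#' controlled stand-in for a real ribosome model, used to validate the
#' exposure and prediction machinery.
#'
#' @param n_res Number of rRNA residues.
#' @param shielded_runs Tibble/list with `start`, `end` (0-based half-open
#'   residue intervals to shield with protein).
#' @param spacing Distance between consecutive P atoms (angstrom).
#' @return A `structure_model`.
#' @export
build_toy_structure <- function(n_res, shielded_runs = tibble(start = integer(),
                                                              end = integer()),
                                spacing = 7) {
  shielded_runs <- as_tibble(shielded_runs)
  x <- (seq_len(n_res) - 1L) * spacing
  rna <- tibble(chain = "R", res_seq = seq_len(n_res),
                res_name = rep(c("A", "U", "G", "C"), length.out = n_res),
                atom_name = "P", element = "P",
                x = x, y = 0, z = 0, b = 0)
  shielded <- unique(unlist(purrr::map2(shielded_runs$start, shielded_runs$end,
                                        ~ seq(.x + 1L, .y))))
  prot <- if (length(shielded) > 0) {
    tibble(chain = "Q", res_seq = seq_along(shielded), res_name = "GLY",
           atom_name = "CA", element = "C",
           x = (shielded - 1L) * spacing, y = 3, z = 0, b = 0)
  } else tibble()
  atoms <- bind_rows(rna, prot)
  residues <- atoms |> rename(rep_atom = "atom_name") |>
    select("chain", "res_seq", "res_name", "rep_atom", "x", "y", "z", "b")
  chains <- tibble(chain_id = c("R", if (nrow(prot) > 0) "Q"),
                   n_residues = c(n_res, if (nrow(prot) > 0) nrow(prot)),
                   frac_nuc = c(1, if (nrow(prot) > 0) 0),
                   frac_aa = c(0, if (nrow(prot) > 0) 1),
                   kind = c("rRNA", if (nrow(prot) > 0) "protein"))
  structure(list(atoms = atoms, residues = residues, chains = chains),
            class = "structure_model")
}
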