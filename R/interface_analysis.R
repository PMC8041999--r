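# Interface analysis: residue-residue contacts, footprint classification
# into receptor loops and HLA elements, Shrake-Rupley solvent-accessible
# surface area, and buried surface area of the receptor-ligand interface.

#' Van der Waals radii used for surface calculations
#'
#' A fixed, documented radii set: C 1.70, N 1.55, O 1.52, S 1.80 Angstrom.
#' @return Named numeric vector of radii (Angstrom).
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

#' Find residue-residue contacts across the receptor-ligand interface
#'
#' A contact is any (receptor residue, partner residue) pair with at least
#' one heavy-atom pair within the cutoff. The partner side comprises the
#' HLA heavy chain, the peptide and beta-2 microglobulin, each labelled by
#' element. One record per residue pair, carrying the minimum distance and
#' the atom names achieving it, ordered by receptor residue then partner.
#'
#' @param model A `complex_model`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0, the
#'   conventional crystallographic contact criterion).
#' @return A data frame of class `contact_table` with columns `kir_resno`,
#'   `kir_resid`, `partner_chain`, `partner_resno`, `partner_resid`,
#'   `element` (`hla`, `peptide` or `b2m`), `min_distance`, `kir_atom`,
#'   `partner_atom`. Zero rows if no contacts.
#' @export
find_contacts <- function(model, cutoff = 4.0) {
  stopifnot(inherits(model, "complex_model"), cutoff > 0)
  kir <- model_part(model, "kir", filter = "heavy")
  partner <- list(
    hla = select_atoms(model$structure,
                       selection(model$chains$hla, NULL, filter = "heavy")),
    peptide = model_part(model, "peptide", filter = "heavy"),
    b2m = model_part(model, "b2m", filter = "heavy"))
  out <- list()
  for (el in names(partner)) {
    ps <- partner[[el]]
    d2 <- outer(rowSums(kir$xyz^2), rowSums(ps$xyz^2), "+") -
      2 * kir$xyz %*% t(ps$xyz)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    kl <- kir$labels[hit[, 1], ]; pl <- ps$labels[hit[, 2], ]
    df <- data.frame(
      kir_resno = kl$resno, kir_resid = kl$resid,
      partner_chain = pl$chain, partner_resno = pl$resno,
      partner_resid = pl$resid, element = el,
      distance = sqrt(d2[hit]), kir_atom = kl$elety,
      partner_atom = pl$elety, stringsAsFactors = FALSE)
    key <- paste(df$kir_resno, df$element, df$partner_resno, sep = "\r")
    df <- df[order(key, df$distance), ]
    df <- df[!duplicated(paste(df$kir_resno, df$element, df$partner_resno,
                               sep = "\r")), ]
    out[[el]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kir_resno = integer(), kir_resid = character(),
               partner_chain = character(), partner_resno = integer(),
               partner_resid = character(), element = character(),
               distance = numeric(), kir_atom = character(),
               partner_atom = character(), stringsAsFactors = FALSE)
  res <- res[order(res$kir_resno, res$element, res$partner_resno), ]
  names(res)[names(res) == "distance"] <- "min_distance"
  rownames(res) <- NULL
  class(res) <- c("contact_table", "data.frame")
  res
}

region_of_kir_residue <- function(resno, model) {
  for (nm in names(model$loops)) {
    r <- model$loops[[nm]]
    if (resno >= r[1] && resno <= r[2]) return(nm)
  }
  if (resno >= model$d1_range[1] && resno <= model$d1_range[2]) return("D1:other")
  if (resno >= model$interdomain_range[1] && resno <= model$interdomain_range[2])
    return("interdomain")
  if (resno >= model$d2_range[1] && resno <= model$d2_range[2]) return("D2:other")
  NA_character_
}

element_of_partner <- function(element, resno, model, pep_resnos) {
  if (element == "peptide") {
    return(paste0("P", match(resno, pep_resnos)))
  }
  if (element == "hla") {
    for (nm in names(model$hla_elements)) {
      r <- model$hla_elements[[nm]]
      if (resno >= r[1] && resno <= r[2]) return(nm)
    }
  }
  "other"
}

#' Classify interface contacts into receptor-loop and HLA-element footprints
#'
#' Assigns every contact to exactly one receptor region (the named loops,
#' or `D1:other` / `interdomain` / `D2:other`) and one target element
#' (`alpha1`, `alpha2`, peptide position `P1..Pn`, or `other`). When a
#' [buried_surface_area()] result is supplied, each region additionally
#' receives its share of the receptor-side buried area.
#'
#' @param contacts A `contact_table` from [find_contacts()] on the same model.
#' @param model The `complex_model` the contacts were computed from.
#' @param bsa Optional `bsa_result` from [buried_surface_area()].
#' @return A `footprint_summary`: list with `regions` (data frame `region`,
#'   `n_contacts`, and `bsa` when available), `elements` (data frame
#'   `element`, `n_contacts`) and `n_total`.
#' @export
classify_footprint <- function(contacts, model, bsa = NULL) {
  stopifnot(inherits(contacts, "contact_table"),
            inherits(model, "complex_model"))
  region_levels <- c(names(model$loops), "D1:other", "D2:other")
  pep <- model_part(model, "peptide")
  pep_resnos <- sort(unique(pep$labels$resno))
  if (nrow(contacts)) {
    regions <- vapply(contacts$kir_resno, region_of_kir_residue, character(1),
                      model = model)
    if (anyNA(regions)) {
      kd_stop("contact references receptor residues outside the model's ranges",
              "kirdock_config_error")
    }
    elements <- mapply(element_of_partner, contacts$element,
                       contacts$partner_resno,
                       MoreArgs = list(model = model, pep_resnos = pep_resnos))
  } else {
    regions <- character(0); elements <- character(0)
  }
  reg_tab <- data.frame(region = region_levels,
                        n_contacts = as.integer(table(factor(regions,
                                                             region_levels))),
                        stringsAsFactors = FALSE)
  el_levels <- c("alpha1", "alpha2", paste0("P", seq_along(pep_resnos)), "other")
  el_tab <- data.frame(element = el_levels,
                       n_contacts = as.integer(table(factor(elements,
                                                            el_levels))),
                       stringsAsFactors = FALSE)
  if (!is.null(bsa)) {
    stopifnot(inherits(bsa, "bsa_result"))
    side_a <- bsa$per_atom[bsa$per_atom$side == "a", ]
    reg_a <- vapply(side_a$resno, region_of_kir_residue, character(1),
                    model = model)
    reg_tab$bsa <- vapply(reg_tab$region, function(r) {
      sum(side_a$buried[!is.na(reg_a) & reg_a == r])
    }, numeric(1))
  }
  structure(list(regions = reg_tab, elements = el_tab,
                 n_total = nrow(contacts)),
            class = "footprint_summary")
}

#' @export
print.footprint_summary <- function(x, ...) {
  cat(sprintf("<footprint_summary> %d contacts\n", x$n_total))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

# Deterministic quasi-uniform sphere points: golden-spiral (Fibonacci)
# lattice. No RNG, so SASA values are reproducible bit-for-bit.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA by uniform sphere sampling: each atom's sphere of radius
#' vdW + probe is covered with a deterministic golden-spiral point set and
#' the fraction of points outside all neighbouring spheres gives the
#' accessible area.
#'
#' @param atoms A data frame with columns `x`, `y`, `z` and `elesy`
#'   (element symbol), e.g. the `atoms` table of a `kir_structure` after
#'   water/heteroatom removal, or a `coordset`'s labels joined to its
#'   coordinates (see [structure_atoms()]).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param sample_points Points per atom sphere (default 960).
#' @param radii Named vdW radii vector (default [vdw_radii()]).
#' @return A `sasa_result`: list with `area` (per-atom, Angstrom^2),
#'   `total`, `probe`, `sample_points`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, sample_points = 960,
                               radii = vdw_radii()) {
  stopifnot(nrow(atoms) >= 1L)
  el <- toupper(atoms$elesy)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) {
    kd_stop(sprintf("no van der Waals radius for element(s): %s",
                    paste(unknown, collapse = ", ")),
            "kirdock_unknown_element")
  }
  r <- unname(radii[el]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(sample_points)
  area <- numeric(n)
  sq <- rowSums(xyz^2)
  for (i in seq_len(n)) {
    d2 <- sq + sq[i] - 2 * drop(xyz %*% xyz[i, ])
    nb <- which(d2 < (r[i] + r)^2)
    nb <- nb[nb != i]
    if (!length(nb)) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    # squared distances from each sphere point to each neighbour centre
    pd2 <- outer(rowSums(p^2), sq[nb], "+") - 2 * p %*% t(xyz[nb, , drop = FALSE])
    occluded <- pd2 < matrix(r[nb]^2, nrow(p), length(nb), byrow = TRUE)
    acc <- sum(rowSums(occluded) == 0L)
    area[i] <- 4 * pi * r[i]^2 * acc / sample_points
  }
  structure(list(area = area, total = sum(area), probe = probe,
                 sample_points = sample_points), class = "sasa_result")
}

#' Heavy-atom table of a structure part
#'
#' Convenience accessor returning the heavy (non-water, non-het) atoms of
#' one or more chains as a data frame suitable for [shrake_rupley_sasa()].
#'
#' @param structure A `kir_structure`.
#' @param chains Character vector of chain ids.
#' @return Data frame of atoms (same columns as `structure$atoms`).
#' @export
structure_atoms <- function(structure, chains) {
  at <- structure$atoms
  at <- at[at$chain %in% chains & !at$het, , drop = FALSE]
  rownames(at) <- NULL
  at
}

#' Buried surface area of the receptor-ligand interface
#'
#' BSA = SASA(receptor alone) + SASA(ligand alone) - SASA(complex), the
#' both-sides convention. Per-atom buried contributions are retained so the
#' footprint classifier can apportion receptor-side buried area to loops.
#'
#' @param model A `complex_model`.
#' @param include_b2m Include beta-2 microglobulin on the ligand side
#'   (default `TRUE`: it is part of the ternary-complex surface).
#' @param probe,sample_points Passed to [shrake_rupley_sasa()].
#' @return A `bsa_result`: list with `bsa` (total, both sides), `bsa_side_a`
#'   (receptor side), `bsa_side_b`, and `per_atom` (data frame with `side`,
#'   `chain`, `resno`, `elety`, `buried`).
#' @export
buried_surface_area <- function(model, include_b2m = TRUE, probe = 1.4,
                                sample_points = 960) {
  stopifnot(inherits(model, "complex_model"))
  side_a_chains <- model$chains$kir
  side_b_chains <- c(model$chains$hla, model$chains$peptide,
                     if (include_b2m) model$chains$b2m)
  if (length(intersect(side_a_chains, side_b_chains))) {
    kd_stop("interface side definitions overlap", "kirdock_config_error")
  }
  a <- structure_atoms(model$structure, side_a_chains)
  b <- structure_atoms(model$structure, side_b_chains)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    kd_stop("both interface sides must be non-empty", "kirdock_config_error")
  }
  sa <- shrake_rupley_sasa(a, probe, sample_points)
  sb <- shrake_rupley_sasa(b, probe, sample_points)
  ab <- shrake_rupley_sasa(rbind(a, b), probe, sample_points)
  buried <- c(sa$area, sb$area) - ab$area
  per_atom <- data.frame(
    side = rep(c("a", "b"), c(nrow(a), nrow(b))),
    chain = c(a$chain, b$chain), resno = c(a$resno, b$resno),
    elety = c(a$elety, b$elety), buried = buried,
    stringsAsFactors = FALSE)
  structure(list(bsa = sa$total + sb$total - ab$total,
                 bsa_side_a = sum(buried[per_atom$side == "a"]),
                 bsa_side_b = sum(buried[per_atom$side == "b"]),
                 per_atom = per_atom,
                 probe = probe, sample_points = sample_points),
            class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf("<bsa_result> BSA %.0f A^2 (receptor side %.0f, ligand side %.0f)\n",
              x$bsa, x$bsa_side_a, x$bsa_side_b))
  invisible(x)
}
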