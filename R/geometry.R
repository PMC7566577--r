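# 3D base-pair geometry: idealized pair construction from standard base
# geometries, Leontis-Westhof classification of pairs from coordinates, and
# C1'-C1' distances.

new_residue_coords <- function(residue_label, base_type, atoms) {
  r <- list(residue_label = residue_label, base_type = base_type,
            atoms = atoms)
  class(r) <- "residue_coords"
  r
}

#' @export
print.residue_coords <- function(x, ...) {
  cat(sprintf("residue %s (%s): %d atoms [%s]\n", x$residue_label,
              x$base_type, nrow(x$atoms),
              paste(rownames(x$atoms), collapse = " ")))
  invisible(x)
}

is_purine <- function(base) base %in% PURINES

glycosidic_atom <- function(base) if (is_purine(base)) "N9" else "N1"

required_atoms <- function(base) {
  ring <- if (is_purine(base))
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
  exo <- switch(base, A = "N6", G = c("O6", "N2"), C = c("N4", "O2"),
                U = c("O4", "O2"))
  c("C1'", ring, exo)
}

atom_xyz <- function(res, atom) {
  if (!atom %in% rownames(res$atoms))
    trna_error(sprintf("residue %s: required atom %s missing",
                       res$residue_label, atom), "trnaclover_geometry_error")
  res$atoms[atom, ]
}

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

bonded_neighbors <- function(base, atom) {
  b <- .base_bonds[[base]]
  c(b[b[, 1] == atom, 2], b[b[, 2] == atom, 1])
}

# sanity check on a residue: every covalent bond within 2.0 A
validate_residue <- function(res) {
  b <- .base_bonds[[res$base_type]]
  for (k in seq_len(nrow(b))) {
    if (!all(b[k, ] %in% rownames(res$atoms))) next
    d <- vnorm(res$atoms[b[k, 1], ] - res$atoms[b[k, 2], ])
    if (d > 2.0)
      trna_error(sprintf("residue %s: atoms %s-%s %.2f A apart (broken geometry)",
                         res$residue_label, b[k, 1], b[k, 2], d),
                 "trnaclover_geometry_error")
  }
  invisible(res)
}

#' C1'-C1' distance of two residues
#'
#' @param r5,r3 \code{residue_coords} objects with C1' atoms.
#' @return Distance in Angstrom (nonnegative, symmetric in its arguments).
#' @export
c1_distance <- function(r5, r3) {
  vnorm(atom_xyz(r5, "C1'") - atom_xyz(r3, "C1'"))
}

# in-plane outward direction of an atom: away from its bonded neighbors
out_direction <- function(base, atom, coords) {
  nb <- bonded_neighbors(base, atom)
  nb <- nb[nb %in% rownames(coords)]
  p <- coords[atom, ]
  v <- numeric(length(p))
  for (n in nb) v <- v + unitv(p - coords[n, ])
  unitv(v)
}

rot2 <- function(th) matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)

apply_tf2 <- function(xy, th, tr, refl) {
  if (refl) xy[, 2] <- -xy[, 2]
  xy %*% t(rot2(th)) + matrix(tr, nrow(xy), 2, byrow = TRUE)
}

pair_orientation <- function(r5, r3) {
  g5 <- glycosidic_atom(r5$base_type); g3 <- glycosidic_atom(r3$base_type)
  axis <- unitv(atom_xyz(r3, g3) - atom_xyz(r5, g5))
  v5 <- atom_xyz(r5, "C1'") - atom_xyz(r5, g5)
  v3 <- atom_xyz(r3, "C1'") - atom_xyz(r3, g3)
  p5 <- v5 - sum(v5 * axis) * axis
  p3 <- v3 - sum(v3 * axis) * axis
  if (sum(p5 * p3) > 0) "cis" else "trans"
}

#' Build an idealized base pair from standard base geometries
#'
#' Positions two standard planar bases so that the template hydrogen bonds of
#' the requested pair family close at 2.9 A with near-linear donor
#' geometries; both bases stay coplanar (z = 0) and the output is
#' deterministic for fixed inputs. Templates are provided for the canonical
#' cis WC/WC pairs and the GoU wobble, the trans WC/WC (reverse WC) pairs
#' G/C, A/U and A/A seen at 15/48, and the trans WC/Hoogsteen pairs U/A and
#' A/A seen at 54/58. Asking for the mirrored argument order of a supported
#' template is also accepted.
#'
#' The placement is found by a deterministic multi-start rigid-body
#' optimization: H-bond distances are pulled to 2.9 A, donor/acceptor
#' out-of-ring directions are aligned with the bond, and steric overlap below
#' 2.8 A between non-bonded atoms is penalized; among the converged placements
#' with every H-bond within 0.05 A of target, the one with the requested
#' cis/trans orientation and the lowest residual wins.
#'
#' @param base5,base3 Bases (A/C/G/U) of the 5' and 3' partner.
#' @param edge5,edge3 Interacting edge of each base ("WC", "Hoogsteen",
#'   "Sugar").
#' @param orientation "cis" or "trans".
#' @return List of two \code{residue_coords} (named \code{r5}, \code{r3}).
#' @export
build_ideal_pair <- function(base5, edge5, base3, edge3, orientation) {
  base5 <- match.arg(base5, RNA_BASES); base3 <- match.arg(base3, RNA_BASES)
  edge5 <- match.arg(edge5, c("WC", "Hoogsteen", "Sugar"))
  edge3 <- match.arg(edge3, c("WC", "Hoogsteen", "Sugar"))
  orientation <- match.arg(orientation, c("cis", "trans"))
  key <- paste(base5, edge5, base3, edge3, orientation, sep = "|")
  tmpl <- .pair_templates[[key]]
  if (is.null(tmpl)) {
    # mirrored argument order of a supported template
    key2 <- paste(base3, edge3, base5, edge5, orientation, sep = "|")
    tmpl <- lapply(.pair_templates[[key2]], rev)
    if (!length(tmpl)) tmpl <- NULL
  }
  if (is.null(tmpl))
    trna_error(sprintf("unsupported pair: no H-bond template for %s(%s)/%s(%s) %s",
                       base5, edge5, base3, edge3, orientation),
               "trnaclover_geometry_error")
  m5 <- .base_coords[[base5]][, 1:2]
  m3 <- .base_coords[[base3]][, 1:2]
  a <- vapply(tmpl, `[`, "", 1)
  b <- vapply(tmpl, `[`, "", 2)
  out5 <- t(vapply(a, function(at) out_direction(base5, at, m5), c(0, 0)))
  out3 <- t(vapply(b, function(at) out_direction(base3, at, m3), c(0, 0)))
  u <- unitv(colMeans(out5))
  cand <- list()
  for (refl in c(FALSE, TRUE)) {
    obj <- function(p) {
      m3t <- apply_tf2(m3, p[1], p[2:3], refl)
      s <- 0
      for (k in seq_along(a)) {
        pa <- m5[a[k], ]; pb <- m3t[b[k], ]
        dd <- vnorm(pa - pb)
        s <- s + 100 * (dd - 2.9)^2
        ob <- out3[k, ]; if (refl) ob[2] <- -ob[2]
        ob <- c(rot2(p[1]) %*% ob)
        s <- s + (1 - sum(out5[k, ] * (pb - pa)) / dd)^2 +
          (1 + sum(ob * (pb - pa)) / dd)^2
      }
      D <- sqrt(pmax(0, outer(rowSums(m5^2), rowSums(m3t^2), "+") -
                       2 * m5 %*% t(m3t)))
      s + 10 * sum(pmax(0, 2.8 - D)^2)
    }
    ctr <- colMeans(m5[a, , drop = FALSE]) + 2.9 * u
    cs <- colMeans(apply_tf2(m3[b, , drop = FALSE], 0, c(0, 0), refl))
    for (th in seq(0, 2 * pi, length.out = 13)[-13]) {
      t0 <- ctr - c(rot2(th) %*% cs)
      o <- stats::optim(c(th, t0), obj, method = "BFGS",
                        control = list(maxit = 1000))
      m3t <- apply_tf2(m3, o$par[1], o$par[2:3], refl)
      hb <- vapply(seq_along(a),
                   function(k) vnorm(m5[a[k], ] - m3t[b[k], ]), 0)
      if (max(abs(hb - 2.9)) > 0.05) next
      r5 <- new_residue_coords("5", base5, cbind(m5, z = 0))
      r3 <- new_residue_coords("3", base3, cbind(m3t, z = 0))
      rownames(r3$atoms) <- rownames(m3)
      if (pair_orientation(r5, r3) != orientation) next
      cand[[length(cand) + 1L]] <- list(val = o$value, r5 = r5, r3 = r3)
    }
  }
  if (!length(cand))
    trna_error(sprintf("no %s placement satisfies the %s(%s)/%s(%s) template",
                       orientation, base5, edge5, base3, edge3),
               "trnaclover_geometry_error")
  best <- cand[[which.min(vapply(cand, `[[`, 0, "val"))]]
  list(r5 = best$r5, r3 = best$r3)
}

detect_hbonds <- function(r5, r3, max_dist = 3.5, min_dist = 2.4,
                          min_donor_angle = 110) {
  res <- list()
  add <- function(donor_res, donor_atom, acc_res, acc_atom, from5) {
    pd <- atom_xyz(donor_res, donor_atom)
    pa <- atom_xyz(acc_res, acc_atom)
    d <- vnorm(pd - pa)
    if (d > max_dist || d < min_dist) return()
    # donor angle with the hydrogen inferred on the donor's outward bisector:
    # D-H...A >= min_donor_angle is deviation(bisector, D->A) <= 180 - it
    h <- out_direction(donor_res$base_type, donor_atom, donor_res$atoms)
    v2 <- unitv(pa - pd)
    dev <- acos(pmin(1, pmax(-1, sum(h * v2)))) * 180 / pi
    if (dev > 180 - min_donor_angle) return()
    res[[length(res) + 1L]] <<- data.frame(
      donor = if (from5) sprintf("5:%s", donor_atom) else sprintf("3:%s", donor_atom),
      acceptor = if (from5) sprintf("3:%s", acc_atom) else sprintf("5:%s", acc_atom),
      atom5 = if (from5) donor_atom else acc_atom,
      atom3 = if (from5) acc_atom else donor_atom,
      distance = d, stringsAsFactors = FALSE)
  }
  for (dn in .base_donors[[r5$base_type]])
    if (dn %in% rownames(r5$atoms))
      for (ac in .base_acceptors[[r3$base_type]])
        if (ac %in% rownames(r3$atoms)) add(r5, dn, r3, ac, TRUE)
  for (dn in .base_donors[[r3$base_type]])
    if (dn %in% rownames(r3$atoms))
      for (ac in .base_acceptors[[r5$base_type]])
        if (ac %in% rownames(r5$atoms)) add(r3, dn, r5, ac, FALSE)
  if (!length(res))
    return(data.frame(donor = character(0), acceptor = character(0),
                      atom5 = character(0), atom3 = character(0),
                      distance = numeric(0)))
  do.call(rbind, res)
}

edge_of_atoms <- function(base, atoms) {
  fam <- if (is_purine(base)) .edge_members$purine else .edge_members$pyrimidine
  score <- vapply(c("WC", "Hoogsteen", "Sugar"),
                  function(e) sum(atoms %in% fam[[e]]), 0L)
  # majority with deterministic tie-break WC > Hoogsteen > Sugar
  names(score)[which.max(score)]
}

#' Classify a base pair into its Leontis-Westhof family
#'
#' Detects hydrogen bonds between the two bases (heavy-atom donor-acceptor
#' distance 2.4-3.5 A, donor angle at least 110 degrees, donors inferred from
#' heavy-atom chemistry), assigns each H-bonded atom to its base edge
#' (Watson-Crick, Hoogsteen or Sugar; border atoms count for both adjoining
#' edges) and takes the majority edge per base with the deterministic
#' tie-break WC > Hoogsteen > Sugar. The cis/trans orientation is the sign of
#' the dot product of the two glycosidic-bond vectors projected perpendicular
#' to the pairing axis. With no H-bonds in range the pair is reported
#' unpaired, not an error.
#'
#' @param r5,r3 \code{residue_coords} objects.
#' @return An \code{lw_classification} list: \code{paired}, \code{edge5},
#'   \code{edge3}, \code{orientation}, \code{hbonds} (data.frame with donor,
#'   acceptor, distance) and \code{c1_c1}.
#' @export
classify_lw <- function(r5, r3) {
  hb <- detect_hbonds(r5, r3)
  out <- list(paired = nrow(hb) > 0L, edge5 = NA_character_,
              edge3 = NA_character_, orientation = NA_character_,
              hbonds = hb[, c("donor", "acceptor", "distance")],
              c1_c1 = c1_distance(r5, r3))
  if (out$paired) {
    out$edge5 <- edge_of_atoms(r5$base_type, unique(hb$atom5))
    out$edge3 <- edge_of_atoms(r3$base_type, unique(hb$atom3))
    out$orientation <- pair_orientation(r5, r3)
  }
  class(out) <- "lw_classification"
  out
}

#' @export
print.lw_classification <- function(x, ...) {
  if (!x$paired) {
    cat(sprintf("unpaired (C1'-C1' %.2f A, no H-bonds in range)\n", x$c1_c1))
    return(invisible(x))
  }
  cat(sprintf("%s %s/%s pair: %d H-bond(s), C1'-C1' %.2f A\n",
              x$orientation, x$edge5, x$edge3, nrow(x$hbonds), x$c1_c1))
  for (k in seq_len(nrow(x$hbonds)))
    cat(sprintf("  %s ... %s  %.2f A\n", x$hbonds$donor[k],
                x$hbonds$acceptor[k], x$hbonds$distance[k]))
  invisible(x)
}

#' Read residues from a PDB-format file
#'
#' Fixed-column ATOM/HETATM records, first MODEL only. Modified residues are
#' mapped to their parent base through [residue_parent_table()] (e.g. 5MU at
#' position 54 and 1MA at 58 both read as their parents). Each requested
#' residue must carry its C1', ring and exocyclic pairing atoms; a missing
#' atom is an error naming it.
#'
#' @param path PDB file path.
#' @param chain Chain identifier.
#' @param residues Integer vector of residue numbers.
#' @param name_table Residue-name to parent-base mapping.
#' @return List of \code{residue_coords}, one per requested residue.
#' @export
read_pdb_residues <- function(path, chain, residues,
                              name_table = residue_parent_table()) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM") & at$chain == chain, , drop = FALSE]
  out <- vector("list", length(residues))
  for (k in seq_along(residues)) {
    rn <- residues[k]
    sel <- at[at$resno == rn, , drop = FALSE]
    if (!nrow(sel))
      trna_error(sprintf("%s: residue %s not found in chain %s", path, rn, chain),
                 "trnaclover_geometry_error")
    resid <- trimws(sel$resid[1])
    if (!resid %in% names(name_table))
      trna_error(sprintf("%s: unknown residue name '%s' at %s/%s", path, resid,
                         chain, rn), "trnaclover_geometry_error")
    parent <- name_table[[resid]]
    elety <- chartr("*", "'", trimws(sel$elety))
    coords <- as.matrix(sel[, c("x", "y", "z")])
    rownames(coords) <- elety
    keep <- intersect(c(required_atoms(parent), "O2'"), elety)
    res <- new_residue_coords(as.character(rn), parent,
                              coords[keep, , drop = FALSE])
    for (atom in required_atoms(parent)) atom_xyz(res, atom)  # error if missing
    validate_residue(res)
    out[[k]] <- res
  }
  out
}

#' Write residues as a minimal PDB-format file
#'
#' Emits fixed-column ATOM records (chain A, one residue per
#' \code{residue_coords}); useful for exporting built pairs and for creating
#' synthetic fixtures.
#'
#' @param residues List of \code{residue_coords}.
#' @param path Output path.
#' @param resno Residue numbers (default 1..n).
#' @param resid Residue names written to the file (default: each residue's
#'   base type; override to emit modified-residue names such as 5MU).
#' @export
write_pdb_residues <- function(residues, path, resno = seq_along(residues),
                               resid = NULL) {
  if (is.null(resid))
    resid <- vapply(residues, `[[`, "", "base_type")
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(residues)) {
    r <- residues[[k]]
    for (atom in rownames(r$atoms)) {
      serial <- serial + 1L
      p <- r$atoms[atom, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, substr(atom, 1, 4), resid[k], resno[k],
        p[1], p[2], p[3], substr(atom, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
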