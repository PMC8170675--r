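#' Dye-linker attachment geometry
#'
#' Describes how a fluorophore linker chain is anchored: the first linker
#' atom position plus the two reference directions needed to define the
#' first bond's geometry and dihedral (the anchor bond direction and the
#' preceding in-plane direction). Use [dye_anchor_from_base()] to construct
#' the attachment from purine base atoms: a nitrogen anchor placed 132 pm
#' from the C8 atom, in the base plane, at an N-C8-N9 angle of 123 degrees.
#'
#' @param anchor 3-vector, anchor (nitrogen) position in nm.
#' @param axis 3-vector, direction of the bond leading into the anchor
#'   (defines the first linker bond's bond angle).
#' @param plane 3-vector, direction of the preceding bond (defines the first
#'   dihedral); must not be parallel to `axis`.
#' @param n_bonds number of rotatable chain bonds (default 7, a
#'   seven-carbon polyethylene linker).
#' @param bond_length C-C bond length in nm (default 0.153).
#' @param bond_angle tetrahedral bond angle in degrees (default 109.5).
#' @param gauche_penalty energetic penalty per gauche rotamer in kJ/mol
#'   (default 2.1).
#' @param fluorophore_radius radius of the bulky fluorophore sphere at the
#'   chain end, in nm.
#' @param atom_radius van der Waals radius of chain atoms for clash checks,
#'   in nm.
#' @param RT thermal energy in kJ/mol.
#' @return An object of class `dye_attachment`.
#' @export
dye_attachment <- function(anchor = c(0, 0, 0), axis = c(1, 0, 0),
                           plane = c(0, 1, 0), n_bonds = 7L,
                           bond_length = 0.153, bond_angle = 109.5,
                           gauche_penalty = 2.1, fluorophore_radius = 0.35,
                           atom_radius = 0.17, RT = 2.48) {
  stop_if_not(n_bonds >= 1L, "'n_bonds' must be at least 1")
  stop_if_not(gauche_penalty >= 0, "'gauche_penalty' must be non-negative")
  axis <- axis / sqrt(sum(axis^2))
  plane <- plane / sqrt(sum(plane^2))
  stop_if_not(abs(sum(axis * plane)) < 1 - 1e-8,
              "'axis' and 'plane' must not be parallel")
  structure(list(anchor = anchor, axis = axis, plane = plane,
                 n_bonds = as.integer(n_bonds), bond_length = bond_length,
                 bond_angle = bond_angle, gauche_penalty = gauche_penalty,
                 fluorophore_radius = fluorophore_radius,
                 atom_radius = atom_radius, RT = RT),
            class = "dye_attachment")
}

#' @rdname dye_attachment
#' @param c8,n9,ref 3-vectors (nm): positions of the purine C8 and N9 atoms
#'   and a third in-plane base atom fixing the base plane.
#' @param n_c8_distance anchor nitrogen to C8 distance in nm (default 0.132).
#' @param n_c8_n9_angle N-C8-N9 angle in degrees (default 123).
#' @param ... passed to [dye_attachment()].
#' @export
dye_anchor_from_base <- function(c8, n9, ref, n_c8_distance = 0.132,
                                 n_c8_n9_angle = 123, ...) {
  u <- n9 - c8; u <- u / sqrt(sum(u^2))
  normal <- cross3(u, ref - c8)
  stop_if_not(sqrt(sum(normal^2)) > 1e-8, "base atoms are collinear")
  normal <- normal / sqrt(sum(normal^2))
  w <- cross3(normal, u)
  ang <- deg2rad(n_c8_n9_angle)
  anchor <- c8 + n_c8_distance * (cos(ang) * u + sin(ang) * w)
  axis <- (anchor - c8) / n_c8_distance
  dye_attachment(anchor = anchor, axis = axis, plane = u, ...)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# vectorized row-wise cross product for n x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Dye position cloud
#'
#' Discrete cloud of possible fluorophore positions with probabilities, as
#' produced by [enumerate_conformers()] or constructed directly from points.
#'
#' @param positions `n x 3` matrix of positions in nm.
#' @param weights probabilities (normalized internally).
#' @return An object of class `dye_cloud`.
#' @export
dye_cloud <- function(positions, weights = NULL) {
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  stop_if_not(n >= 1L, "empty cloud")
  weights <- weights %||% rep(1 / n, n)
  stop_if_not(length(weights) == n && all(weights >= 0) && sum(weights) > 0,
              "invalid weights")
  structure(list(positions = positions, weights = weights / sum(weights)),
            class = "dye_cloud")
}

#' @export
print.dye_cloud <- function(x, ...) {
  com <- colSums(x$positions * x$weights)
  cat(sprintf("dye cloud: %d positions, centre (%.2f, %.2f, %.2f) nm\n",
              nrow(x$positions), com[1], com[2], com[3]))
  invisible(x)
}

#' Enumerate dye-linker conformers by the rotational isomeric state model
#'
#' Exhaustively enumerates all `3^n_bonds` linker chains (2187 for the
#' default seven-bond chain): each bond samples the anti, gauche+ and
#' gauche- rotamers (dihedrals 180, +60, -60 degrees) on a tetrahedral
#' backbone. Conformers are Boltzmann-weighted by the number of gauche
#' bonds. Chains whose atoms beyond the tolerated prefix, or whose terminal
#' fluorophore sphere, overlap any clash atom are discarded and the weights
#' renormalized; raising `allowed_clash_prefix` exempts the first linker
#' atoms from the clash test (the chain start is tightly packed against the
#' bases and backbone, which low-resolution models do not resolve reliably).
#'
#' @param att a [dye_attachment()].
#' @param clash_atoms optional data frame with columns `x`, `y`, `z` (nm)
#'   and `radius` (nm), e.g. from [read_clash_atoms()].
#' @param allowed_clash_prefix number of initial linker atoms whose clashes
#'   are tolerated (0, 1, 4 or 7 in typical use).
#' @return A [dye_cloud()] of fluorophore positions (chain-end atoms), with
#'   the number of enumerated and retained conformers as attributes.
#' @export
#' @examples
#' cloud <- enumerate_conformers(dye_attachment())
#' attr(cloud, "n_enumerated")   # 3^7 = 2187
enumerate_conformers <- function(att, clash_atoms = NULL,
                                 allowed_clash_prefix = 0L) {
  nb <- att$n_bonds
  dihedrals <- c(180, 60, -60)
  grid <- as.matrix(do.call(expand.grid, rep(list(dihedrals), nb)))
  n <- nrow(grid)                       # 3^nb
  phi <- deg2rad(180 - att$bond_angle)  # deviation from straight continuation

  P <- matrix(rep(att$anchor, each = n), ncol = 3)
  b <- matrix(rep(att$axis, each = n), ncol = 3)
  p <- matrix(rep(-att$plane, each = n), ncol = 3)  # direction of bond before
  atoms <- vector("list", nb)
  for (k in seq_len(nb)) {
    delta <- deg2rad(grid[, k])
    m <- p - rowSums(p * b) * b
    m <- m / sqrt(rowSums(m^2))
    nn <- cross_rows(b, m)
    d <- cos(phi) * b - sin(phi) * cos(delta) * m + sin(phi) * sin(delta) * nn
    P <- P + att$bond_length * d
    atoms[[k]] <- P
    p <- b
    b <- d
  }

  n_gauche <- rowSums(grid != 180)
  w <- exp(-n_gauche * att$gauche_penalty / att$RT)

  keep <- rep(TRUE, n)
  if (!is.null(clash_atoms) && nrow(clash_atoms) > 0) {
    cm <- as.matrix(clash_atoms[, c("x", "y", "z")])
    cr <- clash_atoms$radius
    for (k in seq_len(nb)) {
      r_k <- if (k == nb) att$fluorophore_radius else att$atom_radius
      if (k <= allowed_clash_prefix && k < nb) next
      # fluorophore sphere is always tested, chain atoms only beyond prefix
      if (k == nb && nb <= allowed_clash_prefix) r_k <- att$fluorophore_radius
      A <- atoms[[k]]
      d2 <- outer(rowSums(A^2), rowSums(cm^2), "+") - 2 * A %*% t(cm)
      lim <- (cr + r_k)^2
      keep <- keep & !apply(sweep(d2, 2, lim, "<"), 1, any)
    }
  }
  if (!any(keep))
    stop("all conformers clash with the excluded volume", call. = FALSE)

  cloud <- dye_cloud(atoms[[nb]][keep, , drop = FALSE], w[keep])
  attr(cloud, "n_enumerated") <- n
  attr(cloud, "n_retained") <- sum(keep)
  cloud
}

#' Cloud-averaged FRET efficiency between two dye clouds
#'
#' `E = sum_i sum_j p_i q_j R0^6 / (R0^6 + r_ij^6)` with
#' `r_ij = |s_i - t_j|`: the probability-weighted double sum of the Foerster
#' efficiency over all donor and acceptor positions. Invariant under joint
#' rigid transformation of both clouds.
#'
#' @param donor,acceptor [dye_cloud()] objects.
#' @param R0 Foerster distance in nm.
#' @param chunk donor positions processed per block (memory control).
#' @return the predicted mean transfer efficiency in `[0, 1]`.
#' @export
#' @examples
#' d <- dye_cloud(c(0, 0, 0))
#' a <- dye_cloud(c(5.4, 0, 0))
#' predicted_fret(d, a)   # 0.5 at r = R0
predicted_fret <- function(donor, acceptor, R0 = 5.4, chunk = 512L) {
  stop_if_not(inherits(donor, "dye_cloud") && inherits(acceptor, "dye_cloud"),
              "inputs must be dye_cloud objects")
  S <- donor$positions; Tm <- acceptor$positions
  p <- donor$weights; q <- acceptor$weights
  t2 <- rowSums(Tm^2)
  E <- 0
  for (i0 in seq(1, nrow(S), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(S))
    Sb <- S[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(Sb^2), t2, "+") - 2 * Sb %*% t(Tm)
    d2 <- pmax(d2, 0)
    eff <- R0^6 / (R0^6 + d2^3)
    E <- E + drop(p[i0:i1] %*% eff %*% q)
  }
  E
}

#' Read clash atoms for dye-cloud filtering
#'
#' Reads an atom list with radii for the steric filter in
#' [enumerate_conformers()]. PDB files are parsed with the bio3d package
#' (coordinates converted from Angstrom to nm, one van der Waals radius per
#' atom); any other file is read as columnar text with columns
#' `x`, `y`, `z` (nm) and optionally `radius`.
#'
#' @param path file path (`.pdb` or columnar text/CSV).
#' @param radius default atom radius in nm when the file carries none.
#' @return data frame with columns `x`, `y`, `z`, `radius`.
#' @export
read_clash_atoms <- function(path, radius = 0.17) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    stop_if_not(requireNamespace("bio3d", quietly = TRUE),
                "reading PDB files requires the bio3d package")
    pdb <- bio3d::read.pdb(path)
    xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10
    return(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = radius))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  x <- utils::read.table(path, header = TRUE, sep = sep)
  stop_if_not(all(c("x", "y", "z") %in% names(x)),
              "clash-atom file needs columns x, y, z")
  if (is.null(x$radius)) x$radius <- radius
  x[, c("x", "y", "z", "radius")]
}
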