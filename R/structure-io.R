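# Coordinate input, atom selection, idealized methyl-proton building, and the
# geometric primitives consumed by the NOE and jump models.

# methyl topology: for each (residue, methyl carbon), the bonded antecedent
# heavy atom and a reference substituent of the antecedent used to set the
# staggered rotor phase
.METHYL_TOPOLOGY <- list(
  ILE = list(CD1 = c("CG1", "CB"), CG2 = c("CB", "CA")),
  VAL = list(CG1 = c("CB", "CA"), CG2 = c("CB", "CA")),
  LEU = list(CD1 = c("CG", "CB"), CD2 = c("CG", "CB")),
  THR = list(CG2 = c("CB", "CA")),
  ALA = list(CB  = c("CA", "N")),
  MET = list(CE  = c("SD", "CG"))
)

#' Read a protein structure from a PDB or mmCIF file
#'
#' Wraps [bio3d::read.pdb()] / [bio3d::read.cif()] and flattens the chosen
#' model into a plain atom table.  Alternate locations are resolved uniformly
#' by the chosen policy; hydrogens present in the file are retained.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param model Model index (for multi-model files), default 1.
#' @param altloc Altloc policy: `"highest"` keeps the highest-occupancy
#'   conformer per atom (ties broken by altloc label), `"A"` keeps blank or
#'   `'A'`-labelled records, `"error"` fails on any alternate location.
#' @param label Structure label; defaults to the file base name.
#' @return An object of class `noemix_structure`: a list with `label` and
#'   `atoms`, a data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `alt`, `x`, `y`, `z`, `o`.
#' @export
read_structure <- function(path, model = 1,
                           altloc = c("highest", "A", "error"),
                           label = NULL) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stopf("coordinate file not found: %s", path)
  if (file.size(path) == 0) stopf("parse error: %s is empty", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stopf("parse error in %s: %s", path, conditionMessage(e))
  )
  nmod <- max(1, nrow(pdb$xyz))
  if (model < 1 || model > nmod)
    stopf("model %d out of range: file has %d model(s)", model, nmod)
  at <- pdb$atom
  if (nrow(at) == 0) stopf("parse error: %s contains no atoms", path)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    resid = at$resid,
    elety = at$elety,
    alt   = ifelse(is.na(at$alt), "", at$alt),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms <- .apply_altloc(atoms, altloc)
  new_structure(atoms, label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

.apply_altloc <- function(atoms, policy) {
  has_alt <- atoms$alt != ""
  if (!any(has_alt)) return(atoms)
  if (policy == "error")
    stopf("structure contains alternate locations (%s) under policy 'error'",
          paste(unique(atoms$alt[has_alt]), collapse = ","))
  if (policy == "A") {
    atoms <- atoms[!has_alt | atoms$alt == "A", , drop = FALSE]
  } else { # highest occupancy per (chain, resno, elety)
    key <- paste(atoms$chain, atoms$resno, atoms$elety)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      if (length(i) == 1) return(i)
      i[order(-atoms$o[i], atoms$alt[i])][1]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  atoms
}

#' Construct a structure object from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   and coordinates `x`, `y`, `z` (Angstrom); optional `alt`, `o`.
#' @param label Structure label.
#' @return A `noemix_structure`.
#' @export
new_structure <- function(atoms, label = "structure") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stopf("a structure must contain at least one atom")
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$elety, atoms$alt)
  if (anyDuplicated(key))
    stopf("duplicate atom record(s): %s", paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(list(label = label, atoms = atoms), class = "noemix_structure")
}

#' @export
print.noemix_structure <- function(x, ...) {
  cat(sprintf("<noemix_structure '%s': %d atoms, %d residues, chain(s) %s>\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Write a structure to PDB text
#'
#' @param struct A `noemix_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain, o = a$o, b = rep(0, nrow(a)))
  invisible(path)
}

# parse "chain:resno:atom" selections with '*' wildcards into a logical mask
.selection_mask <- function(atoms, sel) {
  if (is.null(sel)) return(rep(TRUE, nrow(atoms)))
  parts <- strsplit(sel, ":", fixed = TRUE)
  mask <- rep(FALSE, nrow(atoms))
  for (p in parts) {
    if (length(p) != 3)
      stopf("selection '%s' is not of the form chain:resno:atom",
            paste(p, collapse = ":"))
    m <- rep(TRUE, nrow(atoms))
    if (p[1] != "*") m <- m & atoms$chain == p[1]
    if (p[2] != "*") m <- m & atoms$resno == as.integer(p[2])
    if (p[3] != "*") m <- m & atoms$elety == p[3]
    mask <- mask | m
  }
  mask
}

#' Select atoms by "chain:resno:atom" patterns
#'
#' @param struct A `noemix_structure`.
#' @param sel Character vector of `"chain:resno:atom"` selections; `'*'`
#'   wildcards any field (e.g. `"A:59:HE1"`, `"*:*:CG1"`).
#' @return The matching rows of the atom table.
#' @export
select_atoms <- function(struct, sel) {
  struct$atoms[.selection_mask(struct$atoms, sel), , drop = FALSE]
}

.atom_xyz <- function(atoms, i) as.numeric(atoms[i, c("x", "y", "z")])

# find one atom or fail with context
.find_atom <- function(struct, chain, resno, elety, what = "atom") {
  a <- struct$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (length(i) != 1)
    stopf("%s %s:%s:%s matched %d atoms in '%s'", what, chain, resno, elety,
          length(i), struct$label)
  i
}

#' Build idealized methyl protons
#'
#' Crystal structures usually lack refined methyl hydrogens; this places three
#' protons per selected methyl carbon at |C-H| = 1.09 A, an H-C-antecedent
#' angle of 109.47 degrees, 120 degrees apart about the rotor axis, in the
#' staggered rotamer relative to the antecedent's reference substituent.
#'
#' @param struct A `noemix_structure`.
#' @param selection Optional `"chain:resno:atom"` selection restricting which
#'   methyl carbons are built; default all methyls known to the topology table
#'   (Ile CD1/CG2, Val CG1/CG2, Leu CD1/CD2, Thr CG2, Ala CB, Met CE).
#' @param use_explicit If `TRUE` and the file already contains the three
#'   methyl protons (H<carbon-suffix>1..3), use their coordinates verbatim
#'   instead of building ideal ones.
#' @param bond_length C-H bond length in Angstrom.
#' @param tetra_angle H-C-antecedent angle in degrees.
#' @return A list of `methyl_group` objects, each a list with `chain`,
#'   `resno`, `resid`, `carbon_name`, `carbon`, `antecedent`, `protons`
#'   (3 x 3 matrix), and `provenance`.
#' @export
build_methyl_protons <- function(struct, selection = NULL, use_explicit = FALSE,
                                 bond_length = 1.09, tetra_angle = 109.47) {
  a <- struct$atoms
  mask <- .selection_mask(a, selection)
  out <- list()
  for (i in seq_len(nrow(a))) {
    if (!mask[i]) next
    topo <- .METHYL_TOPOLOGY[[a$resid[i]]]
    if (is.null(topo)) next
    ante_ref <- topo[[a$elety[i]]]
    if (is.null(ante_ref)) next
    ch <- a$chain[i]; rn <- a$resno[i]
    ante_i <- which(a$chain == ch & a$resno == rn & a$elety == ante_ref[1])
    if (length(ante_i) != 1)
      stopf("topology error: residue %s %s%d lacks antecedent atom %s for %s",
            a$resid[i], ch, rn, ante_ref[1], a$elety[i])
    ref_i <- which(a$chain == ch & a$resno == rn & a$elety == ante_ref[2])
    C <- .atom_xyz(a, i); A <- .atom_xyz(a, ante_i)
    R <- if (length(ref_i) == 1) .atom_xyz(a, ref_i) else NULL
    H <- NULL
    prov <- "built-ideal"
    if (use_explicit) {
      hn <- paste0("H", sub("^C", "", a$elety[i]), 1:3)
      hi <- match(paste(ch, rn, hn), paste(a$chain, a$resno, a$elety))
      if (!anyNA(hi)) {
        H <- as.matrix(a[hi, c("x", "y", "z")])
        prov <- "read-from-file"
      }
    }
    if (is.null(H))
      H <- .ideal_methyl_protons(C, A, R, bond_length, tetra_angle)
    dimnames(H) <- NULL
    out[[length(out) + 1]] <- structure(
      list(chain = ch, resno = rn, resid = a$resid[i],
           carbon_name = a$elety[i], carbon = C, antecedent = A,
           protons = H, provenance = prov),
      class = "methyl_group")
  }
  out
}

# place three protons on carbon C with antecedent A; R (a substituent of A)
# sets the staggered phase: dihedrals H-C-A-R at 180 and +/-60 degrees
.ideal_methyl_protons <- function(C, A, R, bond_length, tetra_angle) {
  u <- unitv(A - C)
  e1 <- if (is.null(R)) perpv(u) else {
    rp <- (R - A) - sum((R - A) * u) * u
    if (vnorm(rp) < 1e-8) perpv(u) else unitv(rp)
  }
  e2 <- cross3(u, e1)
  th <- deg2rad(tetra_angle)
  t(vapply(deg2rad(c(180, 60, -60)), function(phi)
    C + bond_length * (cos(th) * u + sin(th) * (cos(phi) * e1 + sin(phi) * e2)),
    numeric(3)))
}

#' Resolve a probe site (a proton and its attached heavy atom)
#'
#' @param struct A `noemix_structure`.
#' @param sel A single `"chain:resno:atom"` selection naming the probe proton
#'   (e.g. the tryptophan indole `HE1`).
#' @param heavy Optional atom name of the attached heavy atom; by default the
#'   nearest non-hydrogen atom of the same residue within 1.2 A.
#' @return A `probe_site` list: `chain`, `resno`, `resid`, `atom`, `position`,
#'   `heavy_name`, `heavy`.
#' @export
probe_site <- function(struct, sel, heavy = NULL) {
  hit <- select_atoms(struct, sel)
  if (nrow(hit) != 1)
    stopf("probe selection '%s' matched %d atoms in '%s'", sel, nrow(hit),
          struct$label)
  a <- struct$atoms
  pos <- as.numeric(hit[, c("x", "y", "z")])
  res <- a[a$chain == hit$chain & a$resno == hit$resno, , drop = FALSE]
  if (!is.null(heavy)) {
    hv <- res[res$elety == heavy, , drop = FALSE]
    if (nrow(hv) != 1) stopf("attached heavy atom %s not found for probe %s", heavy, sel)
  } else {
    cand <- res[!grepl("^H|^[0-9]H", res$elety) & res$elety != hit$elety, , drop = FALSE]
    if (nrow(cand) == 0) stopf("no heavy atom candidate for probe %s", sel)
    d <- sqrt((cand$x - pos[1])^2 + (cand$y - pos[2])^2 + (cand$z - pos[3])^2)
    hv <- cand[which.min(d), , drop = FALSE]
  }
  hpos <- as.numeric(hv[, c("x", "y", "z")])
  blen <- vnorm(pos - hpos)
  if (blen < 0.8 || blen > 1.2)
    stopf("probe %s: |H-heavy| = %.2f A outside [0.8, 1.2] A (attached atom %s)",
          sel, blen, hv$elety)
  structure(list(chain = hit$chain, resno = hit$resno, resid = hit$resid,
                 atom = hit$elety, position = pos,
                 heavy_name = hv$elety, heavy = hpos),
            class = "probe_site")
}

#' Methyl-probe interaction geometry
#'
#' Distances from a distal probe proton to the three methyl protons and the
#' matrix of angles subtended at the probe between pairs of methyl protons.
#'
#' @param methyl A `methyl_group`.
#' @param probe A `probe_site`, or a length-3 numeric position.
#' @return List with `r` (three distances, Angstrom) and `theta` (3 x 3
#'   symmetric angle matrix, degrees, zero diagonal).
#' @export
methyl_probe_geometry <- function(methyl, probe) {
  p <- if (inherits(probe, "probe_site")) probe$position else as.numeric(probe)
  V <- sweep(methyl$protons, 2, p)  # vectors probe -> proton
  r <- sqrt(rowSums(V * V))
  if (any(r < 1e-6)) stopf("geometry error: probe coincides with a methyl proton")
  U <- V / r
  cth <- U %*% t(U)
  cth[] <- pmin(1, pmax(-1, cth))
  theta <- rad2deg(acos(cth))
  diag(theta) <- 0
  list(r = r, theta = theta)
}

#' Inter-structure bond-vector reorientation angle
#'
#' Superposes structure B onto structure A by least-squares rigid-body fit on
#' a reference atom set, then reports the angle between the two H-heavy bond
#' vectors of the probe site.
#'
#' @param struct_a,struct_b `noemix_structure` objects.
#' @param probe_sel `"chain:resno:atom"` selection of the probe proton,
#'   resolvable in both structures.
#' @param ref_sel Selection(s) defining the reference atom set for
#'   superposition; must match one-to-one between structures.  Default: all
#'   CA atoms common to both.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bond_vector_angle <- function(struct_a, struct_b, probe_sel, ref_sel = NULL) {
  sel_tab <- function(s) {
    t <- if (is.null(ref_sel)) s$atoms[s$atoms$elety == "CA", , drop = FALSE]
         else select_atoms(s, ref_sel)
    t$k <- paste(t$chain, t$resno, t$elety)
    t
  }
  ta <- sel_tab(struct_a); tb <- sel_tab(struct_b)
  common <- intersect(ta$k, tb$k)
  if (length(ta$k) != length(tb$k) || length(common) != length(ta$k))
    stopf("mapping error: reference sets differ (%d vs %d atoms, %d shared)",
          nrow(ta), nrow(tb), length(common))
  if (length(common) < 3) stopf("mapping error: need >= 3 reference atoms")
  ia <- ta[match(common, ta$k), c("x", "y", "z")]
  ib <- tb[match(common, tb$k), c("x", "y", "z")]
  pa <- probe_site(struct_a, probe_sel)
  pb <- probe_site(struct_b, probe_sel)
  # rigid-body Kabsch fit of B's reference set onto A's, applied to B's bond
  fixed  <- as.numeric(t(as.matrix(ia)))
  mobile <- as.numeric(t(as.matrix(rbind(ib, pb$position, pb$heavy))))
  n <- nrow(ib)
  moved <- bio3d::fit.xyz(fixed, mobile,
                          fixed.inds = seq_len(3 * n),
                          mobile.inds = seq_len(3 * n))
  hb  <- moved[(3 * n + 1):(3 * n + 3)]
  nb  <- moved[(3 * n + 4):(3 * n + 6)]
  vec_angle(pa$position - pa$heavy, hb - nb)
}
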