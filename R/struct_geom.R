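# Rigid-body structural geometry: Kabsch superposition, per-residue C-alpha
# RMSD, van der Waals clash detection, DNA-frame docking of a DNA-binding
# domain, minor-groove anchor contacts and DNA unwrap angles.

.atom_key <- function(df) paste(df$chain, df$resno, df$atom, sep = "|")

#' Pair matching atoms of two models
#'
#' Atoms are matched on (chain, residue number, atom name), optionally after
#' translating chain ids of the first model through `chain_map`.
#'
#' @param a,b `StructureModel`s.
#' @param chain_map Named character vector mapping chains of `a` to chains of
#'   `b` (default identity).
#' @param atoms Optional atom-name filter (e.g. `"CA"`).
#' @param chains Optional chain filter (on `a`, before mapping).
#' @return List of two equal-length index vectors `ia`, `ib`.
#' @export
pair_atoms <- function(a, b, chain_map = NULL, atoms = NULL, chains = NULL) {
  da <- as.data.frame(a); db <- as.data.frame(b)
  if (!is.null(chains)) da <- da[da$chain %in% chains, , drop = FALSE]
  if (!is.null(atoms)) {
    da <- da[da$atom %in% atoms, , drop = FALSE]
    db <- db[db$atom %in% atoms, , drop = FALSE]
  }
  mapped <- da$chain
  if (!is.null(chain_map)) {
    hit <- mapped %in% names(chain_map)
    mapped[hit] <- chain_map[mapped[hit]]
  }
  ka <- paste(mapped, da$resno, da$atom, sep = "|")
  kb <- .atom_key(db)
  m <- match(ka, kb)
  keep <- !is.na(m)
  list(ia = as.integer(rownames(da))[keep], ib = m[keep])
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `reference` over the paired atoms; reflections are corrected.
#'
#' @param mobile,reference `StructureModel`s or n x 3 coordinate matrices.
#' @param pairing For models, a list `(ia, ib)` of paired row indices (see
#'   [pair_atoms()]); `NULL` matches on (chain, residue, atom name).
#'   Matrices pair row by row.
#' @return A `Superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n` atoms paired. The
#'   map sends a coordinate row `x` to `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, pairing = NULL) {
  if (is.matrix(mobile)) {
    P <- mobile; Q <- reference
  } else {
    if (is.null(pairing)) pairing <- pair_atoms(mobile, reference)
    P <- coords(mobile)[pairing$ia, , drop = FALSE]
    Q <- coords(reference)[pairing$ib, , drop = FALSE]
  }
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L)
  n <- nrow(P)
  if (n < 3L) stop("need >= 3 paired atoms for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2L) stop("degenerate (collinear or coincident) pairing")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd, n = n),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d atoms, rmsd %.4f A, rotation %.2f deg\n",
              x$n, x$rmsd, rotation_angle(x$rotation)))
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R A 3 x 3 rotation matrix.
#' @return Angle in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Apply a superposition to a model or coordinate matrix
#' @param x `StructureModel` or n x 3 matrix.
#' @param sp A `Superposition`.
#' @return Transformed object of the same type.
#' @export
apply_superposition <- function(x, sp) {
  if (is.matrix(x)) {
    return(sweep(x %*% t(sp$rotation), 2, sp$translation, `+`))
  }
  xy <- coords(x) %*% t(sp$rotation)
  xy <- sweep(xy, 2, sp$translation, `+`)
  x$x <- xy[, 1]; x$y <- xy[, 2]; x$z <- xy[, 3]
  x
}

#' Per-residue C-alpha displacement between two models
#'
#' Models are superposed on the C-alpha atoms of `anchor_chains` (all shared
#' chains when `NULL`; set `superpose = FALSE` for pre-superposed inputs),
#' then the displacement of every shared C-alpha is reported per residue.
#'
#' @param model_a,model_b `StructureModel`s.
#' @param chain_map Named chain translation from `model_a` to `model_b`.
#' @param anchor_chains Chains (of `model_a`) whose C-alphas define the
#'   superposition anchor.
#' @param superpose Superpose before measuring (default TRUE).
#' @return data.frame with `chain`, `resno`, `rmsd_ca` (Angstrom), residues
#'   missing a C-alpha in either model omitted.
#' @export
residue_rmsd <- function(model_a, model_b, chain_map = NULL,
                         anchor_chains = NULL, superpose = TRUE) {
  all_pairs <- pair_atoms(model_a, model_b, chain_map = chain_map,
                          atoms = "CA")
  if (!length(all_pairs$ia)) stop("no shared C-alpha atoms (empty chain map?)")
  if (superpose) {
    anchor <- pair_atoms(model_a, model_b, chain_map = chain_map,
                         atoms = "CA", chains = anchor_chains)
    sp <- kabsch_superpose(model_a, model_b, pairing = anchor)
    model_a <- apply_superposition(model_a, sp)
  }
  pa <- coords(model_a)[all_pairs$ia, , drop = FALSE]
  pb <- coords(model_b)[all_pairs$ib, , drop = FALSE]
  da <- as.data.frame(model_a)[all_pairs$ia, ]
  data.frame(chain = da$chain, resno = da$resno,
             rmsd_ca = sqrt(rowSums((pa - pb)^2)))
}

#' Default van der Waals radii (Bondi), in Angstrom
#' @return Named numeric vector.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, ZN = 1.39)
}

#' Detect steric clashes between two atom sets
#'
#' A pair clashes when its distance is below the sum of van der Waals radii
#' minus `tolerance`. Hydrogens are ignored.
#'
#' @param factor_atoms,target_atoms `StructureModel`s (e.g. a docked
#'   DNA-binding domain vs histones).
#' @param radii Named per-element radius table (default [vdw_radii()]).
#' @param tolerance Softness allowance in Angstrom (default 0.4).
#' @param default_radius Radius for elements missing from `radii`; `NULL`
#'   makes an unknown element an error.
#' @return A `ClashReport` data.frame (one row per clashing pair: chains,
#'   residues, atoms, `distance`, `overlap`), sorted by decreasing overlap.
#' @export
detect_clashes <- function(factor_atoms, target_atoms, radii = vdw_radii(),
                           tolerance = 0.4, default_radius = NULL) {
  fa <- as.data.frame(factor_atoms); ta <- as.data.frame(target_atoms)
  fa <- fa[fa$element != "H", , drop = FALSE]
  ta <- ta[ta$element != "H", , drop = FALSE]
  rad <- function(el) {
    r <- radii[el]
    if (anyNA(r)) {
      if (is.null(default_radius))
        stop("no van der Waals radius for element(s): ",
             paste(unique(el[is.na(r)]), collapse = ", "))
      r[is.na(r)] <- default_radius
    }
    unname(r)
  }
  rf <- rad(fa$element); rt <- rad(ta$element)
  cf <- as.matrix(fa[, c("x", "y", "z")])
  ct <- as.matrix(ta[, c("x", "y", "z")])
  d2 <- outer(rowSums(cf^2), rowSums(ct^2), `+`) - 2 * cf %*% t(ct)
  d <- sqrt(pmax(d2, 0))
  lim <- outer(rf, rt, `+`) - tolerance
  hit <- which(d < lim, arr.ind = TRUE)
  out <- data.frame(
    chain_i = fa$chain[hit[, 1]], resno_i = fa$resno[hit[, 1]],
    resname_i = fa$resname[hit[, 1]], atom_i = fa$atom[hit[, 1]],
    chain_j = ta$chain[hit[, 2]], resno_j = ta$resno[hit[, 2]],
    resname_j = ta$resname[hit[, 2]], atom_j = ta$atom[hit[, 2]],
    distance = d[hit], overlap = (lim - d)[hit])
  out <- out[order(-out$overlap), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ClashReport", "data.frame"))
}

#' Dock a DNA-binding domain onto nucleosomal DNA
#'
#' Superposes the DNA backbone (P and C1' atoms) of the domain's bound
#' duplex onto the nucleosomal DNA residues covering the motif, then applies
#' the resulting rigid transform to the whole domain model. DNA-frame
#' alignment is the standard way to transplant a DNA-bound domain onto a
#' nucleosome for clash analysis.
#'
#' @param dbd_model Domain plus its DNA duplex (`StructureModel`).
#' @param nucleosome_model Nucleosome (`StructureModel`).
#' @param residue_map data.frame with columns `dbd_chain`, `dbd_resno`,
#'   `nuc_chain`, `nuc_resno`: the base-paired residues of the motif segment
#'   (recommended: motif +/- 2 bp).
#' @param backbone_atoms Atom names used for the alignment.
#' @return List with `docked` (transformed `dbd_model`), `superposition`,
#'   and `combined` (nucleosome plus docked domain, domain chains prefixed
#'   `"F."` to keep atom keys unique).
#' @export
dock_dbd <- function(dbd_model, nucleosome_model, residue_map,
                     backbone_atoms = c("P", "C1'")) {
  stopifnot(all(c("dbd_chain", "dbd_resno", "nuc_chain", "nuc_resno") %in%
                  names(residue_map)))
  dd <- as.data.frame(dbd_model); nd <- as.data.frame(nucleosome_model)
  ia <- integer(); ib <- integer()
  for (r in seq_len(nrow(residue_map))) {
    for (at in backbone_atoms) {
      i <- which(dd$chain == residue_map$dbd_chain[r] &
                   dd$resno == residue_map$dbd_resno[r] & dd$atom == at)
      j <- which(nd$chain == residue_map$nuc_chain[r] &
                   nd$resno == residue_map$nuc_resno[r] & nd$atom == at)
      if (length(i) == 1L && length(j) == 1L) {
        ia <- c(ia, i); ib <- c(ib, j)
      }
    }
  }
  if (length(ia) < 3L)
    stop("motif segment backbone atoms missing: only ", length(ia),
         " paired atoms found")
  sp <- kabsch_superpose(coords(dbd_model)[ia, , drop = FALSE],
                         coords(nucleosome_model)[ib, , drop = FALSE])
  docked <- apply_superposition(dbd_model, sp)
  dockdf <- as.data.frame(docked)
  dockdf$chain <- paste0("F.", dockdf$chain)
  combined <- structure_model(rbind(as.data.frame(nucleosome_model), dockdf))
  list(docked = docked, superposition = sp, combined = combined)
}

# canonical minor-groove floor atoms: purine N3, pyrimidine O2
.mg_floor <- function(df) {
  pur <- df$resname %in% c("DA", "DG", "A", "G")
  pyr <- df$resname %in% c("DC", "DT", "C", "T", "DU", "U")
  (pur & df$atom == "N3") | (pyr & df$atom == "O2")
}
.mg_flank <- function(df) {
  dna <- df$resname %in% c("DA", "DG", "DC", "DT", "DU", "A", "G", "C", "T", "U")
  dna & df$atom %in% c("C1'", "C4'")
}

#' Minor-groove anchor contacts
#'
#' For each anchor residue (a histone or factor arginine/lysine), reports the
#' minimum distance from its listed side-chain nitrogens to the DNA
#' minor-groove floor atoms (purine N3, pyrimidine O2). Sugar C1'/C4' flank
#' distances are reported but excluded from the occupancy call.
#'
#' @param model A `StructureModel` containing protein and DNA.
#' @param anchor_spec data.frame with columns `chain`, `resno`, `atoms`
#'   (comma-separated side-chain nitrogen names, e.g. `"NH1,NH2,NE"`).
#' @param contact_cutoff Occupancy distance cutoff in Angstrom (default 4.0).
#' @param dna_resnos Optional residue-number filter restricting the DNA
#'   region considered (e.g. the motif half-turn).
#' @return data.frame per anchor: `chain`, `resno`, `anchor_atom`,
#'   `groove_atom`, `groove_chain`, `groove_resno`, `distance`,
#'   `flank_distance`, `occupied`.
#' @export
anchor_contacts <- function(model, anchor_spec, contact_cutoff = 4.0,
                            dna_resnos = NULL) {
  df <- as.data.frame(model)
  floor_atoms <- df[.mg_floor(df), , drop = FALSE]
  flank_atoms <- df[.mg_flank(df), , drop = FALSE]
  if (!is.null(dna_resnos)) {
    floor_atoms <- floor_atoms[floor_atoms$resno %in% dna_resnos, , drop = FALSE]
    flank_atoms <- flank_atoms[flank_atoms$resno %in% dna_resnos, , drop = FALSE]
  }
  if (!nrow(floor_atoms)) stop("no DNA minor-groove atoms in model")
  rows <- lapply(seq_len(nrow(anchor_spec)), function(i) {
    at <- trimws(strsplit(anchor_spec$atoms[i], ",")[[1]])
    sel <- df[df$chain == anchor_spec$chain[i] &
                df$resno == anchor_spec$resno[i] & df$atom %in% at, ,
              drop = FALSE]
    if (!nrow(sel))
      stop("anchor residue ", anchor_spec$chain[i], ":",
           anchor_spec$resno[i], " (atoms ", anchor_spec$atoms[i],
           ") absent from model")
    sc <- as.matrix(sel[, c("x", "y", "z")])
    fc <- as.matrix(floor_atoms[, c("x", "y", "z")])
    d <- sqrt(outer(rowSums(sc^2), rowSums(fc^2), `+`) - 2 * sc %*% t(fc))
    best <- arrayInd(which.min(d), dim(d))
    fl <- if (nrow(flank_atoms)) {
      kc <- as.matrix(flank_atoms[, c("x", "y", "z")])
      min(sqrt(outer(rowSums(sc^2), rowSums(kc^2), `+`) - 2 * sc %*% t(kc)))
    } else NA_real_
    data.frame(chain = anchor_spec$chain[i], resno = anchor_spec$resno[i],
               anchor_atom = sel$atom[best[1]],
               groove_atom = floor_atoms$atom[best[2]],
               groove_chain = floor_atoms$chain[best[2]],
               groove_resno = floor_atoms$resno[best[2]],
               distance = min(d), flank_distance = fl,
               occupied = min(d) <= contact_cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Base-pair centers of a DNA segment
#'
#' The center of a base pair is the midpoint of the two paired C1' atoms.
#'
#' @param model A `StructureModel`.
#' @param bp_pairs data.frame with columns `chain_i`, `res_i`, `chain_j`,
#'   `res_j`, ordered along the segment.
#' @return n x 3 matrix of centers.
#' @export
base_pair_centers <- function(model, bp_pairs) {
  df <- as.data.frame(model)
  t(vapply(seq_len(nrow(bp_pairs)), function(r) {
    i <- which(df$chain == bp_pairs$chain_i[r] & df$resno == bp_pairs$res_i[r] &
                 df$atom == "C1'")
    j <- which(df$chain == bp_pairs$chain_j[r] & df$resno == bp_pairs$res_j[r] &
                 df$atom == "C1'")
    if (length(i) != 1L || length(j) != 1L)
      stop("missing C1' for base pair ", bp_pairs$res_i[r], "/",
           bp_pairs$res_j[r])
    as.numeric(df[i, c("x", "y", "z")] + df[j, c("x", "y", "z")]) / 2
  }, numeric(3)))
}

#' DNA unwrap (reorientation) angle between two models
#'
#' After superposing the second model onto the first on a stated anchor
#' pairing (histone-core C-alphas by default), a least-squares line is fitted
#' through the base-pair centers of the terminal DNA segment in each model;
#' the angle between the two direction vectors (oriented from the first to
#' the last listed base pair) is returned in degrees.
#'
#' @param model_bound,model_free `StructureModel`s.
#' @param bp_pairs Base-pair table for the terminal segment (see
#'   [base_pair_centers()]); at least 4 base pairs.
#' @param core_chains Chains whose C-alphas anchor the superposition;
#'   `NULL` with `superpose = TRUE` uses all shared C-alphas.
#' @param superpose Set `FALSE` for pre-superposed models.
#' @return Angle in degrees, in `[0, 180)`.
#' @export
unwrap_angle <- function(model_bound, model_free, bp_pairs,
                         core_chains = NULL, superpose = TRUE) {
  if (nrow(bp_pairs) < 4L) stop("segment too short: need >= 4 base pairs")
  if (superpose) {
    anchor <- pair_atoms(model_bound, model_free, atoms = "CA",
                         chains = core_chains)
    sp <- kabsch_superpose(model_bound, model_free, pairing = anchor)
    model_bound <- apply_superposition(model_bound, sp)
  }
  dir_of <- function(model) {
    ctr <- base_pair_centers(model, bp_pairs)
    cc <- sweep(ctr, 2, colMeans(ctr))
    v <- svd(cc)$v[, 1]
    # orient along the listed order of the segment
    if (sum((ctr[nrow(ctr), ] - ctr[1, ]) * v) < 0) v <- -v
    v
  }
  v1 <- dir_of(model_bound); v2 <- dir_of(model_free)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}
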