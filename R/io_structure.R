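# Atomic coordinate I/O. A StructureModel is a plain data.frame of atoms
# (chain, resno, resname, atom, element, x, y, z, occ) with class
# "StructureModel" and an optional per-chain entity annotation attribute.
# Only the subset of the PDB/mmCIF formats needed for rigid-body geometry is
# supported: ATOM/HETATM coordinates, altloc resolution by occupancy, model 1.

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z` and optionally `occ`.
#' @param entities Optional named character vector mapping chain id to an
#'   entity label (e.g. `c(A = "histone H3", I = "DNA strand I")`).
#' @return A `StructureModel`.
#' @export
structure_model <- function(atoms, entities = NULL) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$resno <- as.integer(atoms$resno)
  for (cc in c("x", "y", "z")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("StructureModel: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("StructureModel: duplicate (chain, residue, atom): ",
         key[anyDuplicated(key)])
  rownames(atoms) <- NULL
  structure(atoms, class = c("StructureModel", "data.frame"),
            entities = entities)
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x), "atoms,",
      length(unique(x$chain)), "chain(s):",
      paste(sort(unique(x$chain)), collapse = " "), "\n")
  invisible(x)
}

#' Coordinate matrix of a model
#' @param model A `StructureModel`.
#' @return An n x 3 numeric matrix.
#' @export
coords <- function(model) {
  as.matrix(as.data.frame(model)[, c("x", "y", "z")])
}

.parse_pdb <- function(lines, path) {
  keep <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  end1 <- which(startsWith(lines, "ENDMDL"))          # model 1 only
  if (length(end1)) keep[seq_along(lines) > end1[1]] <- FALSE
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records in '", path, "'")
  rec <- lines[idx]
  short <- nchar(rec) < 54L
  if (any(short))
    stop("malformed coordinate line ", idx[short][1], " in '", path,
         "': fewer than 54 columns")
  fx <- function(a, b) trimws(substr(rec, a, b))
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(fx(a, b)))
    if (anyNA(v))
      stop("malformed coordinate line ", idx[is.na(v)][1], " in '", path,
           "': unreadable ", what)
    v
  }
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1
  element <- fx(77, 78)
  # fall back on the atom-name convention when the element column is absent
  guess <- sub("^[0-9]*", "", fx(13, 16))
  element <- ifelse(element == "", substr(guess, 1, 1), element)
  df <- data.frame(
    chain   = fx(22, 22),
    resno   = as.integer(num(23, 26, "residue number")),
    resname = fx(18, 20),
    atom    = fx(13, 16),
    altloc  = fx(17, 17),
    element = toupper(element),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = occ,
    stringsAsFactors = FALSE
  )
  df
}

.parse_mmcif <- function(lines, path) {
  hdr_i <- grep("^_atom_site\\.", lines)
  if (!length(hdr_i)) stop("no _atom_site loop in '", path, "'")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_i]))
  body_start <- max(hdr_i) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_") || startsWith(ln, "data_")) break
    body <- c(body, ln)
  }
  if (!length(body)) stop("empty _atom_site loop in '", path, "'")
  toks <- strsplit(body, "[[:space:]]+")
  nf <- length(fields)
  bad <- vapply(toks, length, 1L) != nf
  if (any(bad))
    stop("malformed coordinate line ", body_start + which(bad)[1] - 1L,
         " in '", path, "': expected ", nf, " fields")
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  get <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  model_num <- get("pdbx_PDB_model_num")
  if (!all(is.na(model_num))) {
    first <- model_num[1]
    m <- m[model_num == first, , drop = FALSE]
  }
  get2 <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  strip <- function(v) gsub("^\"|\"$", "", v)
  df <- data.frame(
    chain   = strip(get2("auth_asym_id", "label_asym_id")),
    resno   = as.integer(get2("auth_seq_id", "label_seq_id")),
    resname = strip(get2("auth_comp_id", "label_comp_id")),
    atom    = strip(get2("auth_atom_id", "label_atom_id")),
    altloc  = strip(get2("label_alt_id")),
    element = toupper(strip(get2("type_symbol"))),
    x = as.numeric(get2("Cartn_x")),
    y = as.numeric(get2("Cartn_y")),
    z = as.numeric(get2("Cartn_z")),
    occ = suppressWarnings(as.numeric(get2("occupancy"))),
    stringsAsFactors = FALSE
  )
  df$altloc[df$altloc %in% c(".", "?")] <- ""
  df$occ[is.na(df$occ)] <- 1
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) || anyNA(df$resno))
    stop("malformed coordinate values in '", path, "'")
  df
}

.resolve_altloc <- function(df) {
  if (all(df$altloc %in% c("", " "))) {
    df$altloc <- NULL
    return(df)
  }
  key <- paste(df$chain, df$resno, df$atom)
  keep <- rep(TRUE, nrow(df))
  for (k in unique(key[duplicated(key)])) {
    i <- which(key == k)
    best <- i[which.max(df$occ[i])]   # ties: which.max takes the first listed
    keep[setdiff(i, best)] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df$altloc <- NULL
  df
}

#' Read an atomic coordinate file (PDB or mmCIF)
#'
#' Captures ATOM/HETATM records of model 1 only. Alternate locations are
#' resolved to the highest-occupancy conformer (ties: first listed).
#'
#' @param path Path to the coordinate file.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` are mmCIF, anything else PDB).
#' @param entities Optional named chain -> entity annotation, stored on the
#'   returned model.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           entities = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  df <- if (dialect == "pdb") .parse_pdb(lines, path) else .parse_mmcif(lines, path)
  df <- .resolve_altloc(df)
  structure_model(df, entities = entities)
}

#' Write a StructureModel as a PDB file
#'
#' Coordinates are written with the standard three-decimal PDB precision.
#'
#' @param model A `StructureModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  df <- as.data.frame(model)
  name <- ifelse(nchar(df$atom) < 4L, sprintf(" %-3s", df$atom),
                 sprintf("%-4s", df$atom))
  lines <- sprintf(
    "ATOM  %5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(df)) %% 100000L, name, df$resname,
    substr(df$chain, 1, 1), df$resno,
    df$x, df$y, df$z, df$occ, 0, df$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
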