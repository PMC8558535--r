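#' Construct an atomic structure
#'
#' A structure is a tibble of atoms (one row per atom) carrying an optional
#' orthorhombic periodic box and free-form metadata as attributes, so it
#' flows through dplyr verbs while keeping its cell information.
#'
#' @param atoms A data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`, `occupancy`, `altloc`.
#'   Missing `occupancy` defaults to 1, missing `altloc` to `""`, and a
#'   missing `element` column is inferred from the atom name.
#' @param box Numeric length-3 vector of orthorhombic cell edge lengths in
#'   Angstrom, or `NULL` for a non-periodic system.
#' @param metadata Named list (e.g. `entry_id`, `method`, `resolution`).
#'
#' @return A `wat_structure`, a tibble subclass.
#' @export
#' @examples
#' s <- new_structure(tibble::tibble(
#'   serial = 1:3, name = c("O", "H1", "H2"), resname = "HOH",
#'   resid = 1, chain = "W",
#'   x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0
#' ), box = c(20, 20, 20))
new_structure <- function(atoms, box = NULL, metadata = list()) {
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) == 0) stop("structure has no atoms", call. = FALSE)
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$name)
  needed <- c("serial", "name", "element", "resname", "resid", "chain",
              "x", "y", "z", "occupancy", "altloc")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  if (anyDuplicated(atoms$serial)) {
    stop("atom serial numbers must be unique", call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates", call. = FALSE)
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    stop("occupancy must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(box)) box <- validate_box(box)
  atoms <- atoms[, c(needed, setdiff(names(atoms), needed))]
  structure(atoms,
            box = box, metadata = metadata,
            class = c("wat_structure", class(tibble::tibble())))
}

validate_box <- function(box) {
  box <- as.numeric(box)
  if (length(box) != 3 || !all(is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive edge lengths (Angstrom)", call. = FALSE)
  }
  box
}

#' @export
print.wat_structure <- function(x, ...) {
  box <- structure_box(x)
  cat(sprintf("# A structure: %d atoms, %d residues%s\n",
              nrow(x), dplyr::n_distinct(paste(x$chain, x$resid)),
              if (is.null(box)) ", no periodic box"
              else sprintf(", box %.2f x %.2f x %.2f A",
                           box[1], box[2], box[3])))
  NextMethod()
}

# keep box/metadata/class through dplyr verbs and subsetting
#' @export
dplyr_reconstruct.wat_structure <- function(data, template) {
  out <- NextMethod()
  attr(out, "box") <- attr(template, "box")
  attr(out, "metadata") <- attr(template, "metadata")
  class(out) <- class(template)
  out
}

#' @export
`[.wat_structure` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "box") <- attr(x, "box")
    attr(out, "metadata") <- attr(x, "metadata")
    class(out) <- class(x)
  }
  out
}

#' Periodic box and metadata accessors
#'
#' @param s A `wat_structure`.
#' @param value Replacement box (length-3 numeric) or metadata list.
#' @return `structure_box()` returns the length-3 edge vector or `NULL`;
#'   `structure_metadata()` the metadata list.
#' @export
structure_box <- function(s) attr(s, "box")

#' @rdname structure_box
#' @export
`structure_box<-` <- function(s, value) {
  attr(s, "box") <- if (is.null(value)) NULL else validate_box(value)
  s
}

#' @rdname structure_box
#' @export
structure_metadata <- function(s) attr(s, "metadata") %||% list()

#' @rdname structure_box
#' @export
`structure_metadata<-` <- function(s, value) {
  attr(s, "metadata") <- value
  s
}

#' Coordinate matrix of a structure
#' @param s A `wat_structure`.
#' @return An n x 3 numeric matrix.
#' @export
coords <- function(s) {
  m <- as.matrix(s[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- substr(sub("^[0-9']+", "", nm), 1, 1)
  el[two %in% c("CL", "NA", "MG", "ZN", "BR", "FE", "MN")] <-
    two[two %in% c("CL", "NA", "MG", "ZN", "BR", "FE", "MN")]
  # names like 1H, 2HB, HD11 are hydrogens
  el[grepl("^[0-9]*H", nm)] <- "H"
  el
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations,
#' and picks up the periodic cell from CRYST1 plus resolution/method
#' metadata from REMARK 2 and EXPDTA when present. Only the first MODEL of
#' a multi-model file is read; use [read_trajectory()] for all models.
#'
#' @param path Path to a PDB file.
#' @param altloc_policy How to resolve alternate locations: `"occupancy"`
#'   (keep the highest-occupancy location, ties broken by altloc
#'   identifier order, the default) or `"first"` (keep the first record).
#' @return A [new_structure()] object.
#' @export
read_structure <- function(path, altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no atoms found in ", path, call. = FALSE)
  }
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                     guess_element(at$elety), trimws(at$elesy)),
    resname = trimws(at$resid),
    resid = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  atoms <- resolve_altlocs(atoms, altloc_policy)
  header <- read_pdb_header(path)
  new_structure(atoms, box = header$box, metadata = header$metadata)
}

resolve_altlocs <- function(atoms, policy) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resid, atoms$resname, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[atoms$altloc != ""])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    pick <- if (policy == "occupancy") {
      idx[order(-atoms$occupancy[idx], atoms$altloc[idx])][1]
    } else {
      idx[1]
    }
    keep[setdiff(idx, pick)] <- FALSE
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("dropped ", n_drop, " alternate-location record(s)")
  }
  atoms[keep, , drop = FALSE]
}

read_pdb_header <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  box <- NULL
  metadata <- list()
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) > 0) {
    edges <- suppressWarnings(as.numeric(c(
      substr(cry[1], 7, 15), substr(cry[1], 16, 24), substr(cry[1], 25, 33))))
    if (all(is.finite(edges)) && all(edges > 0) &&
        # a 1x1x1 cell is the PDB placeholder for "no crystal"
        !all(edges == 1)) {
      box <- edges
    }
    sg <- trimws(substr(cry[1], 56, 66))
    if (nzchar(sg)) metadata$space_group <- sg
  }
  exp <- grep("^EXPDTA", lines, value = TRUE)
  if (length(exp) > 0) {
    m <- toupper(exp[1])
    metadata$method <- if (grepl("NEUTRON", m)) "neutron"
      else if (grepl("X-RAY", m)) "xray"
      else if (grepl("NMR", m)) "nmr"
      else tolower(trimws(substr(exp[1], 11, 79)))
  }
  res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(res_line) > 0) {
    r <- suppressWarnings(as.numeric(
      sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", res_line[1])))
    if (is.finite(r)) metadata$resolution <- r
  }
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) > 0) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(id)) metadata$entry_id <- id
  }
  list(box = box, metadata = metadata)
}

#' Write a structure to a PDB file
#'
#' Atoms are written in input order; the periodic box, if present, becomes
#' a CRYST1 record with 90 degree angles. Serial numbers above 99999 and
#' residue numbers above 9999 wrap around modulo the field width (the
#' original identifiers are retained in the in-memory object).
#'
#' @param s A `wat_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "wat_structure"))
  xyz <- as.vector(t(coords(s)))
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = s$resid %% 10000L, resid = s$resname,
    eleno = s$serial %% 100000L, elety = s$name,
    chain = ifelse(s$chain == "", " ", substr(s$chain, 1, 1)),
    o = s$occupancy, b = rep(0, nrow(s)), elesy = s$element))
  box <- structure_box(s)
  if (!is.null(box)) {
    meta <- structure_metadata(s)
    sg <- meta$space_group %||% "P 1"
    cry <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   box[1], box[2], box[3], 90, 90, 90, sg, 1L)
    body <- readLines(path, warn = FALSE)
    writeLines(c(cry, body), path)
  }
  invisible(path)
}

#' Minimum-image distance under an orthorhombic periodic box
#'
#' @param p,q Numeric length-3 vectors, or n x 3 matrices of positions
#'   (compared row-wise).
#' @param box Length-3 edge vector, or `NULL` for plain Euclidean distance.
#' @return Distance(s) in Angstrom; each per-axis displacement magnitude is
#'   at most half the corresponding box edge.
#' @export
#' @examples
#' min_image_distance(c(1, 0, 0), c(9, 0, 0), c(10, 10, 10)) # 2
min_image_distance <- function(p, q, box = NULL) {
  p <- rbind(p); q <- rbind(q)
  d <- min_image_disp(p - q, box)
  unname(sqrt(rowSums(d * d)))
}

# wrap a displacement matrix into the minimum image; box NULL = no wrap
min_image_disp <- function(d, box) {
  if (is.null(box)) return(d)
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# all minimum-image distances between rows of a (n x 3) and b (m x 3);
# returns n x m matrix
cross_dist <- function(a, b, box = NULL) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

#' Standard residue-name sets
#'
#' `hydrophobic_residues()` is the default apolar set used to split side
#' chains into hydrophobic and hydrophilic classes; `water_residues()` and
#' `ion_residues()` name the solvent and monatomic-ion residue codes the
#' package recognises.
#' @return Character vector of 3-letter (or shorter) residue codes.
#' @export
hydrophobic_residues <- function() {
  c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP", "GLY")
}

#' @rdname hydrophobic_residues
#' @export
water_residues <- function() c("HOH", "WAT", "TIP", "TIP3", "SOL", "SPC")

#' @rdname hydrophobic_residues
#' @export
ion_residues <- function() {
  c("CL", "CLA", "CL-", "NA", "SOD", "NA+", "K", "MG", "ZN", "CA2", "BR", "IOD")
}

backbone_atom_names <- function() {
  c("N", "CA", "C", "O", "OXT",
    "H", "H1", "H2", "H3", "HN", "HA", "HA1", "HA2", "HA3", "HT1", "HT2", "HT3")
}

#' Classify atoms into water / ion / main-chain / side-chain classes
#'
#' Every atom receives exactly one label: `water`, `ion`, `main_chain`
#' (backbone N, CA, C, O, OXT and their hydrogens), or a side-chain label
#' determined by whether the residue belongs to the hydrophobic set.
#'
#' @param s A `wat_structure` (or atom tibble).
#' @param hydrophobic Residue codes treated as hydrophobic side chains.
#' @param unknown_class Label for residues that are neither water, ion,
#'   nor a standard amino acid (a warning lists them).
#' @return `s` with an added `atom_class` character column.
#' @export
classify_atoms <- function(s, hydrophobic = hydrophobic_residues(),
                           unknown_class = "side_chain_hydrophilic") {
  amino <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN")
  res <- toupper(s$resname)
  cls <- character(nrow(s))
  cls[res %in% water_residues()] <- "water"
  cls[res %in% ion_residues()] <- "ion"
  todo <- cls == ""
  is_amino <- res %in% amino
  unknown <- todo & !is_amino
  if (any(unknown)) {
    warning("unknown residue(s) ",
            paste(unique(res[unknown]), collapse = ", "),
            " labelled as ", unknown_class, call. = FALSE)
    cls[unknown] <- unknown_class
    todo <- todo & !unknown
  }
  bb <- todo & toupper(s$name) %in% backbone_atom_names()
  cls[bb] <- "main_chain"
  side <- todo & !bb
  cls[side] <- ifelse(res[side] %in% toupper(hydrophobic),
                      "side_chain_hydrophobic", "side_chain_hydrophilic")
  s$atom_class <- cls
  s
}

#' Total mass of the protein atoms of a structure
#'
#' @param s A `wat_structure`.
#' @return Mass in Dalton, summed over atoms classified as `main_chain` or
#'   side chain (waters and ions excluded).
#' @export
protein_mass <- function(s) {
  if (!"atom_class" %in% names(s)) s <- suppressWarnings(classify_atoms(s))
  prot <- s$atom_class %in%
    c("main_chain", "side_chain_hydrophilic", "side_chain_hydrophobic")
  sum(atomic_mass(s$element[prot]))
}

atomic_mass <- function(element) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              P = 30.974, CL = 35.45, NA. = 22.99, K = 39.098, MG = 24.305,
              ZN = 65.38, CA = 40.078, BR = 79.904, F = 18.998, FE = 55.845)
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- masses[key]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
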