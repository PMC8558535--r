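#' Read a crystal-structure entry set from a manifest
#'
#' The manifest is a CSV with columns `entry_id`, `method`, `resolution`,
#' `path` (relative to `dir` unless absolute). Each file is read with
#' [read_structure()]; manifest metadata overrides anything parsed from
#' the file header.
#'
#' @param manifest Path to the manifest CSV, or a data frame with those
#'   columns.
#' @param dir Directory holding the PDB files.
#' @return A tibble with `entry_id`, `method`, `resolution` and a
#'   `structure` list-column.
#' @export
read_entry_set <- function(manifest, dir = ".") {
  m <- if (is.character(manifest)) {
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    as.data.frame(manifest)
  }
  needed <- c("entry_id", "method", "resolution", "path")
  if (!all(needed %in% names(m))) {
    stop("manifest needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  structs <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$path[i]
    if (!file.exists(p)) p <- file.path(dir, m$path[i])
    s <- read_structure(p)
    md <- structure_metadata(s)
    md$entry_id <- m$entry_id[i]
    md$method <- m$method[i]
    md$resolution <- m$resolution[i]
    structure_metadata(s) <- md
    s
  })
  tibble::tibble(entry_id = m$entry_id, method = m$method,
                 resolution = as.numeric(m$resolution), structure = structs)
}

#' Filter crystal entries by experimental method and resolution
#'
#' Keeps entries whose method belongs to `methods` and whose resolution
#' is numerically at most `resolution_max` (i.e. at least that good).
#' Entries with missing method or resolution are dropped with a message.
#'
#' @param entries Entry tibble from [read_entry_set()] (columns
#'   `entry_id`, `method`, `resolution`, ...).
#' @param methods Set of accepted methods (default neutron only).
#' @param resolution_max Worst accepted resolution (A).
#' @return The kept subset, same columns.
#' @export
filter_entries <- function(entries, methods = "neutron",
                           resolution_max = 2.0) {
  stopifnot(resolution_max > 0)
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) return(entries)
  missing_md <- is.na(entries$method) | is.na(entries$resolution)
  if (any(missing_md)) {
    message("dropped ", sum(missing_md),
            " entr(ies) with missing method/resolution: ",
            paste(entries$entry_id[missing_md], collapse = ", "))
  }
  keep <- !missing_md & tolower(entries$method) %in% tolower(methods) &
    entries$resolution <= resolution_max
  entries[keep, , drop = FALSE]
}

#' O-H...O geometry map over a set of crystal structures
#'
#' Computes (r, theta) for all water-donor O-H groups against water and
#' protein oxygen acceptors within the scoring gate, per entry, and sums
#' the maps (additive over entries, deterministic). Waters modelled
#' without hydrogens cannot donate and are skipped; their count is
#' reported in the `skipped_waters` attribute rather than being given
#' fabricated hydrogen positions. With `expand_symmetry = TRUE` and a
#' known cell plus supported space group, acceptors additionally include
#' symmetry mates of the whole entry (a no-op for P1).
#'
#' @param entries Entry tibble (after [filter_entries()]) with a
#'   `structure` list-column, or a list of structures.
#' @param pair_class `"water_water"` or `"water_protein"`.
#' @inheritParams geometry_map
#' @param expand_symmetry Include symmetry-mate acceptor environments.
#' @return A `wat_geometry_map` (see [geometry_map()]) with additional
#'   attributes `n_entries` and `skipped_waters`.
#' @export
crystal_geometry_map <- function(entries,
                                 pair_class = c("water_water",
                                                "water_protein"),
                                 r_edges = default_r_edges(),
                                 theta_edges = default_theta_edges(),
                                 gate = c("distance", "hydrogen"),
                                 d_gate = 3.5, r_gate = 4.0,
                                 expand_symmetry = FALSE) {
  pair_class <- match.arg(pair_class)
  gate <- match.arg(gate)
  structs <- if (is.data.frame(entries)) entries$structure else entries
  if (length(structs) == 0) {
    stop("no entries to analyse", call. = FALSE)
  }
  total <- NULL
  skipped <- 0L
  n_scored <- 0
  spill <- 0
  for (s in structs) {
    s <- suppressWarnings(classify_atoms(s))
    skipped <- skipped + count_dry_waters(s)
    donor_chains <- NULL
    if (expand_symmetry) {
      asym_chains <- unique(s$chain)
      expanded <- expand_entry_symmetry(s)
      if (nrow(expanded) > nrow(s)) {
        # donors stay in the first (identity) copy; acceptors come from
        # the whole expanded cell
        n_chains <- length(asym_chains)
        donor_chains <- unique(expanded$chain)[seq_len(n_chains)]
      }
      s <- expanded
    }
    m <- tryCatch(
      geometry_map(s, pair_class = pair_class, r_edges = r_edges,
                   theta_edges = theta_edges, gate = gate,
                   d_gate = d_gate, r_gate = r_gate,
                   donor_chains = donor_chains),
      error = function(e) NULL)
    if (is.null(m)) next
    n_scored <- n_scored + attr(m, "n_scored")
    spill <- spill + attr(m, "spill")
    total <- if (is.null(total)) m else {
      t2 <- total; t2$count <- total$count + m$count; t2
    }
  }
  if (is.null(total) || all(total$count == 0)) {
    stop("no scorable O-H...O geometry in any entry", call. = FALSE)
  }
  attr(total, "n_scored") <- n_scored
  attr(total, "spill") <- spill
  attr(total, "n_entries") <- length(structs)
  attr(total, "skipped_waters") <- skipped
  total
}

# waters registered without any hydrogen atoms
count_dry_waters <- function(s) {
  w <- s[s$atom_class == "water", ]
  if (nrow(w) == 0) return(0L)
  mol <- paste(w$chain, w$resid)
  has_h <- tapply(toupper(w$element) == "H", mol, any)
  sum(!has_h)
}

expand_entry_symmetry <- function(s) {
  md <- structure_metadata(s)
  box <- structure_box(s)
  sg <- gsub("[ _]", "", toupper(md$space_group %||% "P1"))
  if (is.null(box) || sg == "P1") return(s)
  ops <- tryCatch(space_group_ops(sg), error = function(e) NULL)
  if (is.null(ops)) {
    warning("space group ", sg, " not supported for symmetry expansion; ",
            "using direct contacts only", call. = FALSE)
    return(s)
  }
  suppressWarnings(classify_atoms(apply_space_group(s, ops, box)))
}
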