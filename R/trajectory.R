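#' Construct a trajectory
#'
#' A trajectory is an ordered sequence of frames sharing one topology: the
#' atom table of a [new_structure()] plus, per frame, a coordinate matrix
#' and a periodic box.
#'
#' @param topology A `wat_structure` providing atom identities.
#' @param coords List of n_atoms x 3 coordinate matrices, one per frame.
#' @param boxes List of length-3 edge vectors (or `NULL`s), one per frame;
#'   a single vector is recycled. Defaults to the topology's box.
#' @return A `wat_trajectory`.
#' @export
new_trajectory <- function(topology, coords, boxes = NULL) {
  stopifnot(inherits(topology, "wat_structure"))
  if (is.matrix(coords)) coords <- list(coords)
  n <- nrow(topology)
  ok <- vapply(coords, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3,
               logical(1))
  if (!all(ok)) {
    stop("every frame needs one coordinate triple per topology atom",
         call. = FALSE)
  }
  if (is.null(boxes)) {
    boxes <- rep(list(structure_box(topology)), length(coords))
  } else if (is.numeric(boxes)) {
    boxes <- rep(list(validate_box(boxes)), length(coords))
  }
  if (length(boxes) != length(coords)) {
    stop("need one box (or NULL) per frame", call. = FALSE)
  }
  structure(list(topology = topology, coords = coords, boxes = boxes),
            class = "wat_trajectory")
}

#' @export
print.wat_trajectory <- function(x, ...) {
  cat(sprintf("# A trajectory: %d frames x %d atoms\n",
              n_frames(x), nrow(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `wat_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame as a structure
#' @param traj A `wat_trajectory`.
#' @param i Frame index (1-based).
#' @return A `wat_structure` with that frame's coordinates and box.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  s <- traj$topology
  s$x <- traj$coords[[i]][, 1]
  s$y <- traj$coords[[i]][, 2]
  s$z <- traj$coords[[i]][, 3]
  structure_box(s) <- traj$boxes[[i]]
  s
}

#' Treat a single structure as a one-frame trajectory
#' @param s A `wat_structure` or an existing trajectory (returned as is).
#' @return A `wat_trajectory`.
#' @export
as_trajectory <- function(s) {
  if (inherits(s, "wat_trajectory")) return(s)
  new_trajectory(s, coords(s))
}

#' Read a multi-model PDB file as a trajectory
#'
#' All MODEL blocks are read; the single CRYST1 record (if any) provides
#' the box for every frame.
#'
#' @inheritParams read_structure
#' @return A `wat_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  top <- read_structure(path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  new_trajectory(top, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `wat_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  s <- traj$topology
  xyz <- do.call(rbind, lapply(traj$coords, function(m) as.vector(t(m))))
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = s$resid %% 10000L, resid = s$resname,
    eleno = s$serial %% 100000L, elety = s$name,
    chain = ifelse(s$chain == "", " ", substr(s$chain, 1, 1)),
    o = s$occupancy, b = rep(0, nrow(s)), elesy = s$element))
  box <- traj$boxes[[1]]
  if (!is.null(box)) {
    cry <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   box[1], box[2], box[3], 90, 90, 90, "P 1", 1L)
    body <- readLines(path, warn = FALSE)
    writeLines(c(cry, body), path)
  }
  invisible(path)
}
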