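## Trajectory frames are kept in angstrom (the on-disk unit); conversion to
## bohr happens where displacements enter the LVC model.

#' A single trajectory frame
#'
#' @param time frame time (fs)
#' @param coordinates N x 3 matrix (angstrom)
#' @param symbols element symbols (or point-charge labels), length N
#' @param site_flags optional "atom"/"charge" per site; by default symbols
#'   in `charge_symbols` are flagged as point charges
#' @param charge_symbols symbols treated as point charges
#' @return object of class `traj_frame`
#' @export
traj_frame <- function(time, coordinates, symbols,
                       site_flags = NULL, charge_symbols = c("X", "XQ", "Q")) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) .stopf("coordinates must be N x 3")
  n <- nrow(coordinates)
  symbols <- rep_len(as.character(symbols), n)
  if (is.null(site_flags))
    site_flags <- ifelse(toupper(symbols) %in% charge_symbols, "charge", "atom")
  structure(list(time = as.numeric(time), coordinates = coordinates,
                 symbols = symbols, site_flags = rep_len(site_flags, n)),
            class = "traj_frame")
}

#' Orthorhombic periodic box
#'
#' @param lengths three positive edge lengths (angstrom); a scalar is
#'   recycled to a cubic box
#' @return object of class `periodic_box`
#' @export
periodic_box <- function(lengths) {
  lengths <- rep_len(as.numeric(lengths), 3L)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    .stopf("box edge lengths must be positive")
  structure(list(lengths = lengths), class = "periodic_box")
}

#' Read an (extended) XYZ trajectory
#'
#' Standard multi-frame XYZ; the comment line may carry `time=<fs>` and
#' `box=<a b c>` (angstrom) tokens.  Frames must all have the same site
#' count; a malformed count line raises an error naming the frame index.
#'
#' @param path XYZ file
#' @param box optional [periodic_box()] overriding any box on the comment
#'   lines
#' @return list with `frames` (list of [traj_frame()]) and `box`
#'   (a [periodic_box()] or NULL)
#' @export
read_trajectory <- function(path, box = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fidx <- 0L
  file_box <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      .stopf("frame %d: malformed atom-count line '%s'", fidx, lines[i])
    if (i + 1L + n > length(lines))
      .stopf("frame %d: truncated (expected %d sites)", fidx, n)
    comment <- lines[i + 1L]
    t <- .xyz_token(comment, "time")
    b <- .xyz_token(comment, "box", n = 3L)
    if (!is.null(b)) file_box <- periodic_box(b)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad))
      .stopf("frame %d: malformed coordinate line %d", fidx, bad[1])
    sym <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      .stopf("frame %d: non-numeric coordinate", fidx)
    frames[[fidx]] <- traj_frame(
      time = if (is.null(t)) fidx - 1 else t,
      coordinates = xyz, symbols = sym)
    i <- i + 2L + n
  }
  if (!length(frames)) .stopf("no frames found in %s", path)
  counts <- vapply(frames, function(f) nrow(f$coordinates), 1L)
  if (length(unique(counts)) != 1L)
    .stopf("inconsistent site counts across frames: %s",
           paste(unique(counts), collapse = ", "))
  tt <- vapply(frames, `[[`, 0, "time")
  if (any(diff(tt) <= 0)) .stopf("frame times must be strictly increasing")
  list(frames = frames, box = box %||% file_box)
}

.xyz_token <- function(comment, key, n = 1L) {
  m <- regmatches(comment,
                  regexpr(sprintf("%s=[^[:space:]]+", key), comment))
  if (!length(m)) return(NULL)
  vals <- as.numeric(strsplit(sub(sprintf("^%s=", key), "", m), ",")[[1]])
  if (length(vals) != n || any(!is.finite(vals))) return(NULL)
  vals
}

#' Write frames as extended XYZ
#'
#' @param frames list of [traj_frame()]
#' @param path output path
#' @param box optional [periodic_box()] recorded on each comment line
#' @param digits decimal places for coordinates
#' @return `path` invisibly
#' @export
write_trajectory <- function(frames, path, box = NULL, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$coordinates)
    comment <- sprintf("time=%.6f", f$time)
    if (!is.null(box))
      comment <- paste0(comment, sprintf(" box=%g,%g,%g",
                                         box$lengths[1], box$lengths[2],
                                         box$lengths[3]))
    writeLines(as.character(n), con)
    writeLines(comment, con)
    fmt <- sprintf("%%-4s %%.%df %%.%df %%.%df", digits, digits, digits)
    writeLines(sprintf(fmt, f$symbols,
                       f$coordinates[, 1], f$coordinates[, 2],
                       f$coordinates[, 3]), con)
  }
  invisible(path)
}

#' Unwrap a frame to the minimum image relative to a reference
#'
#' Shifts every site by integer multiples of the box edges so that each
#' displacement component from the reference has magnitude at most half the
#' corresponding edge.  This undoes periodic-boundary wrapping of solvent
#' point charges between the parametrization geometry and a later frame.
#' Idempotent; never changes a coordinate by a non-integer multiple of an
#' edge.
#'
#' @param frame,reference [traj_frame()] objects with identical site counts
#' @param box a [periodic_box()]
#' @return the unwrapped [traj_frame()]
#' @export
unwrap_to_reference <- function(frame, reference, box) {
  if (is.null(box)) .stopf("unwrap requires a periodic box")
  stopifnot(inherits(box, "periodic_box"))
  if (nrow(frame$coordinates) != nrow(reference$coordinates))
    .stopf("frame and reference differ in site count")
  d <- frame$coordinates - reference$coordinates
  shift <- sweep(d, 2, box$lengths, "/")
  shift <- round(shift)
  frame$coordinates <- frame$coordinates -
    sweep(shift, 2, box$lengths, "*")
  frame
}

#' Kabsch-aligned RMSD between two frames
#'
#' Root-mean-square deviation of site positions after removing the optimal
#' translation (centroid superposition) and the optimal proper rotation
#' (Kabsch algorithm, reflection excluded).  No mass weighting; point-charge
#' sites are included unless masked out.
#'
#' @param a,b [traj_frame()] objects (or plain N x 3 matrices, angstrom)
#' @param mask optional logical or integer site subset used for the
#'   superposition and the deviation
#' @return RMSD in angstrom
#' @export
kabsch_rmsd <- function(a, b, mask = NULL) {
  A <- if (inherits(a, "traj_frame")) a$coordinates else as.matrix(a)
  B <- if (inherits(b, "traj_frame")) b$coordinates else as.matrix(b)
  if (!identical(dim(A), dim(B))) .stopf("site counts differ")
  if (!is.null(mask)) {
    A <- A[mask, , drop = FALSE]
    B <- B[mask, , drop = FALSE]
  }
  n <- nrow(A)
  if (n < 1L) .stopf("at least one site required")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  ## optimal proper rotation via SVD of the covariance; det forced +1
  C <- crossprod(A, B)                      # 3 x 3
  sv <- svd(C)
  s <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, s))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- A %*% t(R) - B
  sqrt(sum(diffs^2) / n)
}

#' Per-frame Kabsch RMSD trace against a reference frame
#'
#' @param frames list of [traj_frame()]
#' @param reference reference [traj_frame()]
#' @param mask optional site subset
#' @return data.frame with columns `time` and `rmsd` (angstrom)
#' @export
rmsd_trace <- function(frames, reference, mask = NULL) {
  data.frame(
    time = vapply(frames, `[[`, 0, "time"),
    rmsd = vapply(frames, kabsch_rmsd, 0, b = reference, mask = mask))
}

#' Displacement of a frame from an anchor geometry, in bohr
#'
#' Flattens (frame - anchor geometry) row-wise into the 3N vector consumed
#' by the LVC model, converting angstrom to bohr.  If a box is given the
#' frame is unwrapped to the anchor first.
#'
#' @param frame a [traj_frame()] (coordinates in angstrom)
#' @param param an [lvc_param()] (geometry in bohr)
#' @param box optional [periodic_box()]
#' @return numeric displacement vector, length 3N (bohr)
#' @export
frame_displacement <- function(frame, param, box = NULL) {
  ref_ang <- param$geometry / .bohr()
  if (!is.null(box))
    frame <- unwrap_to_reference(frame,
                                 traj_frame(param$anchor_time, ref_ang,
                                            symbols = param$site_flags), box)
  d_ang <- frame$coordinates - ref_ang
  as.numeric(t(d_ang)) * .bohr()
}
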