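# Extended XYZ reading and writing.  Frames carry the cell in the Lattice
# field, per-atom positions and (optionally) momenta in the Properties
# column layout, and free key=value scalars (time, conserved quantity,
# c(q), instantaneous temperature).

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write frames to an extended XYZ file
#'
#' @param frames Either an `mtmd_trajectory` or a list of frames; each
#'   frame is a list with `elements`, `x` (3 x N Cartesian positions, A),
#'   `h` (3 x 3 cell), optional `momenta` (3 x N) and optional named
#'   `scalars`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_extxyz <- function(frames, path) {
  if (inherits(frames, "mtmd_trajectory")) frames <- trajectory_frames(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- ncol(fr$x)
    lat <- paste(.fmt_num(as.numeric(fr$h)), collapse = " ")
    props <- "species:S:1:pos:R:3"
    if (!is.null(fr$momenta)) props <- paste0(props, ":momenta:R:3")
    comment <- sprintf('Lattice="%s" Properties=%s', lat, props)
    if (!is.null(fr$scalars)) {
      for (k in names(fr$scalars)) {
        comment <- paste0(comment, sprintf(" %s=%s", k,
                                           .fmt_num(fr$scalars[[k]])))
      }
    }
    writeLines(c(as.character(n), comment), con)
    for (i in seq_len(n)) {
      line <- paste(c(fr$elements[i], .fmt_num(fr$x[, i]),
                      if (!is.null(fr$momenta)) .fmt_num(fr$momenta[, i])),
                    collapse = " ")
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read an extended XYZ file
#'
#' @param path File path.
#' @return List of frames (`elements`, `x`, `h`, `momenta` or `NULL`,
#'   `scalars`).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("parse error at line %d: expected an atom count", i))
    n <- as.integer(lines[i])
    if (i + 1 + n > length(lines))
      stop(sprintf(paste0("parse error at line %d: %d atoms declared but ",
                          "file ends early"), i, n))
    comment <- lines[i + 1]
    lat_m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat_m) < 2)
      stop(sprintf("parse error at line %d: missing Lattice field", i + 1))
    latv <- as.numeric(strsplit(trimws(lat_m[2]), "\\s+")[[1]])
    if (length(latv) != 9 || any(is.na(latv)))
      stop(sprintf("parse error at line %d: malformed Lattice field", i + 1))
    h <- matrix(latv, 3, 3)
    props_m <- regmatches(comment,
                          regexec("Properties=([^ ]+)", comment))[[1]]
    has_momenta <- length(props_m) >= 2 && grepl("momenta", props_m[2])
    scalars <- list()
    rest <- gsub('Lattice="[^"]+"', "", comment)
    rest <- gsub("Properties=[^ ]+", "", rest)
    for (kv in regmatches(rest,
                          gregexpr("[A-Za-z_][A-Za-z0-9_]*=[-+0-9.eE]+",
                                   rest))[[1]]) {
      parts <- strsplit(kv, "=")[[1]]
      scalars[[parts[1]]] <- as.numeric(parts[2])
    }
    elements <- character(n)
    x <- matrix(0, 3, n)
    momenta <- if (has_momenta) matrix(0, 3, n) else NULL
    for (a in seq_len(n)) {
      ln <- i + 1 + a
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      need <- if (has_momenta) 7L else 4L
      if (length(tok) < need)
        stop(sprintf("parse error at line %d: expected %d fields, found %d",
                     ln, need, length(tok)))
      elements[a] <- tok[1]
      x[, a] <- as.numeric(tok[2:4])
      if (has_momenta) momenta[, a] <- as.numeric(tok[5:7])
      if (any(is.na(x[, a])))
        stop(sprintf("parse error at line %d: non-numeric coordinate", ln))
    }
    frames[[length(frames) + 1]] <-
      list(elements = elements, x = x, h = h, momenta = momenta,
           scalars = scalars)
    i <- i + 2L + n
  }
  frames
}

#' Convert a trajectory to a list of extended-XYZ frames
#'
#' @param traj An `mtmd_trajectory`.
#' @return List of frames suitable for [write_extxyz()].
#' @export
trajectory_frames <- function(traj) {
  nf <- dim(traj$x)[3]
  lapply(seq_len(nf), function(k) {
    list(elements = traj$elements,
         x = traj$x[, , k],
         h = traj$h[, , k],
         momenta = if (!is.null(traj$ps)) traj$ps[, , k] else NULL,
         scalars = list(time = traj$times[k],
                        conserved = traj$conserved[k],
                        c_q = traj$c_q[k],
                        T_inst = traj$T_inst[k]))
  })
}

#' Build a state and topology from a single extended-XYZ frame
#'
#' @param frame One frame from [read_extxyz()].
#' @param scale Bond-detection scale factor.
#' @param include_angles,include_dihedrals Coordinate-set flags.
#' @return List with `state` (momenta from the file if present) and `top`.
#' @export
frame_to_system <- function(frame, scale = 1.2, include_angles = TRUE,
                            include_dihedrals = TRUE) {
  top <- build_topology(frame$x, frame$elements, frame$h, scale,
                        include_angles, include_dihedrals)
  s <- make_molecules_whole(solve(frame$h, frame$x), top)
  st <- system_state(s, frame$h, ps = frame$momenta,
                     t = if (!is.null(frame$scalars$time))
                       frame$scalars$time else 0)
  list(state = st, top = top)
}
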